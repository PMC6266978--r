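# CpG sensitivity signature: platform harmonization, PDX-augmented
# refinement to a top-k probe panel, and per-sample classification by
# hierarchical clustering against the labeled reference panel.

#' Restrict candidate probes to those shared by two platforms
#'
#' @param probes_a,probes_b Probe ids present on platform A / B.
#' @param candidate_probes Ordered candidate probe ids.
#' @return `candidate_probes` intersected with both platforms, original
#'   order preserved; errors if nothing survives.
#' @export
harmonize_probes <- function(probes_a, probes_b, candidate_probes) {
  out <- candidate_probes[candidate_probes %in% probes_a &
                            candidate_probes %in% probes_b]
  if (length(out) == 0) {
    stop("no candidate probe is present on both platforms; signature impossible")
  }
  out
}

#' Refine a candidate probe set to a top-k CpG signature
#'
#' Re-runs the supervised two-group methylation test on the reference
#' panel with the PDXs counted in the sensitive class, keeps probes
#' with `p < p_threshold`, ranks by ascending p (ties: descending
#' `|delta_beta|`, then probe id) and returns the top `k` as a
#' deployable signature model.
#'
#' @param beta_panel Beta matrix over candidate probes x panel samples
#'   (cell lines and PDXs).
#' @param labels Supervision labels (`sensitive`/`other`) per panel
#'   sample, with PDXs labeled sensitive.
#' @param p_threshold Refinement significance threshold.
#' @param k Signature size.
#' @param scale Test scale for the underlying test (`"M"` or
#'   `"beta"`).
#' @param distance,linkage Clustering parameters recorded in (and used
#'   by) the resulting model.
#' @param moderated Use empirical-Bayes variance shrinkage?
#' @param sample_type Optional per-sample sub-label (e.g.
#'   `cell_line`/`pdx`) stored for provenance.
#' @return Object of class `ra_signature`: probe list, reference beta
#'   matrix, labels, clustering parameters and refinement record. If
#'   fewer than `k` probes pass, all passing probes are returned and
#'   the `warning_flag` is set; zero passing probes is an error.
#' @export
refine_signature <- function(beta_panel, labels, p_threshold = 0.01, k = 6,
                             scale = "M", distance = "euclidean",
                             linkage = "complete", moderated = TRUE,
                             sample_type = NULL) {
  dmp <- differential_methylation(beta_panel, labels, scale = scale,
                                  p_cutoff = p_threshold,
                                  moderated = moderated)
  pass <- dmp[dmp$p_value < p_threshold, , drop = FALSE]
  if (nrow(pass) == 0) stop("no probe passes p < ", p_threshold,
                            "; signature impossible")
  warn <- nrow(pass) < k
  if (warn) {
    warning("only ", nrow(pass), " probe(s) pass p < ", p_threshold,
            " (requested k = ", k, ")")
  }
  top <- utils::head(pass, k)  # already ranked p, |delta_beta|, probe id
  model <- list(
    probes = top$probe_id,
    reference_beta = beta_panel[top$probe_id, , drop = FALSE],
    reference_labels = stats::setNames(as.character(labels),
                                       colnames(beta_panel)),
    sample_type = if (is.null(sample_type)) NULL else
      stats::setNames(as.character(sample_type), colnames(beta_panel)),
    distance = distance, linkage = linkage,
    refinement = list(p_threshold = p_threshold, k = k,
                      ranking = "p, then |delta_beta|, then probe_id",
                      test_scale = scale, moderated = moderated),
    warning_flag = warn
  )
  class(model) <- "ra_signature"
  model
}

#' Agglomerative clustering of sample rows
#'
#' Standard hierarchical clustering via [stats::hclust]. `"ward"`
#' linkage maps to `"ward.D2"` (on the chosen distance);
#' `"correlation"` distance is `1 - Pearson r` between rows.
#'
#' @param mat Numeric matrix, samples x features; no missing values.
#' @param distance `"euclidean"`, `"manhattan"` or `"correlation"`.
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return An `hclust` object.
#' @export
cluster_panel <- function(mat, distance = c("euclidean", "manhattan", "correlation"),
                          linkage = c("complete", "average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (anyNA(mat)) stop("matrix contains missing values")
  if (nrow(mat) < 2) stop("need at least two rows to cluster")
  d <- switch(distance,
              euclidean = stats::dist(mat, method = "euclidean"),
              manhattan = stats::dist(mat, method = "manhattan"),
              correlation = stats::as.dist(1 - stats::cor(t(mat))))
  stats::hclust(d, method = switch(linkage, complete = "complete",
                                   average = "average", ward = "ward.D2"))
}

# leaves under each node of an hclust merge tree
.node_leaves <- function(merge, node) {
  if (node < 0) return(-node)
  c(.node_leaves(merge, merge[node, 1]), .node_leaves(merge, merge[node, 2]))
}

#' Classify a single query sample against the reference panel
#'
#' The query's beta-values over the signature probes are appended to
#' the reference matrix and the joint set is clustered. The smallest
#' dendrogram cluster containing the query and at least one reference
#' determines the call by label purity: all sensitive-class references
#' gives `predicted-sensitive`, all other-class `resistant`, a mixture
#' `ambiguous`. A reference panel that is constant on every signature
#' probe offers no separation and always yields `ambiguous`.
#'
#' An alternative nearest-centroid rule (`rule = "centroid"`) calls
#' the class whose centroid is closer by more than
#' `margin_frac * ||centroid difference||`, and `ambiguous` inside the
#' margin.
#'
#' @param query Named numeric vector of beta-values covering every
#'   signature probe (extra probes ignored).
#' @param model An `ra_signature` from [refine_signature()].
#' @param rule `"clade"` (default) or `"centroid"`.
#' @param margin_frac Margin for the centroid rule, as a fraction of
#'   the between-centroid distance.
#' @return List (class `ra_classification`): `category`
#'   (`predicted-sensitive`/`ambiguous`/`resistant`), `cluster_members`
#'   (reference ids in the enclosing cluster), `cluster_labels`,
#'   `height` (cophenetic height of the enclosing cluster).
#' @export
classify_sample <- function(query, model, rule = c("clade", "centroid"),
                            margin_frac = 0.25) {
  rule <- match.arg(rule)
  missing <- setdiff(model$probes, names(query))
  if (length(missing)) {
    stop("query lacks signature probe(s): ", paste(missing, collapse = ", "))
  }
  q <- query[model$probes]
  ref <- t(model$reference_beta[model$probes, , drop = FALSE])  # samples x probes
  labs <- model$reference_labels[rownames(ref)]

  if (all(apply(ref, 2, function(v) max(v) - min(v) == 0))) {
    # constant panel: no separation is possible by construction
    return(structure(list(category = "ambiguous",
                          cluster_members = rownames(ref),
                          cluster_labels = labs, height = NA_real_,
                          note = "constant reference panel"),
                     class = "ra_classification"))
  }

  if (rule == "centroid") {
    cs <- colMeans(ref[labs == "sensitive", , drop = FALSE])
    co <- colMeans(ref[labs != "sensitive", , drop = FALSE])
    margin <- margin_frac * sqrt(sum((cs - co)^2))
    ds <- sqrt(sum((q - cs)^2)); do <- sqrt(sum((q - co)^2))
    cat <- if (ds < do - margin) "predicted-sensitive"
    else if (do < ds - margin) "resistant" else "ambiguous"
    return(structure(list(category = cat, cluster_members = character(0),
                          cluster_labels = character(0),
                          height = abs(ds - do)),
                     class = "ra_classification"))
  }

  mat <- rbind(ref, query = q)
  hc <- cluster_panel(mat, distance = model$distance, linkage = model$linkage)
  qleaf <- nrow(mat)
  # first merge node whose subtree contains the query leaf
  node <- which(hc$merge[, 1] == -qleaf | hc$merge[, 2] == -qleaf)
  leaves <- .node_leaves(hc$merge, node)
  members <- rownames(mat)[setdiff(leaves, qleaf)]
  mlabs <- labs[members]
  cat <- if (all(mlabs == "sensitive")) "predicted-sensitive"
  else if (all(mlabs != "sensitive")) "resistant"
  else "ambiguous"
  structure(list(category = cat, cluster_members = members,
                 cluster_labels = mlabs, height = hc$height[node]),
            class = "ra_classification")
}

#' Classify every column of a query beta matrix
#'
#' @param queries Beta matrix (probes x query samples) covering all
#'   signature probes.
#' @param model An `ra_signature`.
#' @param ... Passed to [classify_sample()].
#' @return data.frame: `query_id`, `category`, `cluster_members`
#'   (semicolon-joined), `height`.
#' @export
classify_cohort <- function(queries, model, ...) {
  rows <- lapply(colnames(queries), function(s) {
    r <- classify_sample(queries[, s], model, ...)
    data.frame(query_id = s, category = r$category,
               cluster_members = paste(r$cluster_members, collapse = ";"),
               height = if (is.null(r$height)) NA_real_ else r$height,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize classification calls over a cohort
#'
#' @param results data.frame from [classify_cohort()] (needs a
#'   `category` column).
#' @return data.frame with one row per category
#'   (`predicted-sensitive`, `ambiguous`, `resistant`): `count` and
#'   `fraction` (fractions sum to 1; `NA` for an empty cohort).
#' @export
cohort_summary <- function(results) {
  cats <- c("predicted-sensitive", "ambiguous", "resistant")
  n <- nrow(results)
  counts <- as.integer(table(factor(results$category, levels = cats)))
  data.frame(category = cats, count = counts,
             fraction = if (n == 0) rep(NA_real_, 3) else counts / n,
             stringsAsFactors = FALSE)
}

#' @export
print.ra_signature <- function(x, ...) {
  cat("CpG sensitivity signature (", length(x$probes), " probes)\n", sep = "")
  cat("  probes: ", paste(x$probes, collapse = ", "), "\n", sep = "")
  cat("  reference: ", ncol(x$reference_beta), " samples (",
      sum(x$reference_labels == "sensitive"), " sensitive-class)\n", sep = "")
  cat("  clustering: ", x$distance, " / ", x$linkage, "\n", sep = "")
  if (isTRUE(x$warning_flag)) cat("  WARNING: fewer probes than requested k\n")
  invisible(x)
}
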