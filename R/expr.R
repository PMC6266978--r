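# Differential expression between supervision classes (baseline and
# atRA-induced contrasts) and efficiency-corrected relative qPCR
# quantification.

#' Per-model atRA induction values
#'
#' `treated - control` per feature per model, on the log2 scale. The
#' two matrices must be paired: identical feature ids and identical
#' model (column) ids.
#'
#' @param expr_treated,expr_control Log2 expression matrices
#'   (features x models).
#' @return Matrix of log2 induction values with the same dimnames.
#' @export
induction_table <- function(expr_treated, expr_control) {
  if (!identical(dim(expr_treated), dim(expr_control)) ||
      !identical(rownames(expr_treated), rownames(expr_control)) ||
      !identical(sort(colnames(expr_treated)), sort(colnames(expr_control)))) {
    stop("treated and control matrices must be paired on features and models")
  }
  expr_treated - expr_control[, colnames(expr_treated), drop = FALSE]
}

#' Differential expression between supervision classes
#'
#' `contrast = "baseline"` tests untreated (control) expression
#' between the sensitive class and all others; `contrast = "induced"`
#' first reduces each model to its per-model induction value
#' (treated - control per feature) and tests those inductions between
#' the classes. Both use the shared moderated two-group engine
#' ([two_group_test()]). No multiple-testing adjustment is applied to
#' the cutoff by default (raw p), but BH q-values are always emitted.
#'
#' @param expr Log2 expression matrix (features x models) — control
#'   arm values for `"baseline"`.
#' @param classes Supervision labels (`sensitive`/`other`) per column.
#' @param contrast `"baseline"` or `"induced"`.
#' @param expr_treated Treated-arm matrix, required for `"induced"`.
#' @param fc_cutoff,p_cutoff Flagging thresholds (absolute log2 fold
#'   change and raw p).
#' @param moderated Use empirical-Bayes variance shrinkage?
#' @return data.frame sorted by p: `feature`, `log2_fc`, `t`,
#'   `p_value`, `q_value`, `passes_cutoff`, `contrast`.
#' @export
differential_expression <- function(expr, classes,
                                    contrast = c("baseline", "induced"),
                                    expr_treated = NULL,
                                    fc_cutoff = 0.7, p_cutoff = 0.01,
                                    moderated = TRUE) {
  contrast <- match.arg(contrast)
  cl <- factor(as.character(classes), levels = c("sensitive", "other"))
  if (anyNA(cl)) stop("classes must be 'sensitive' or 'other'")
  x <- if (contrast == "induced") {
    if (is.null(expr_treated)) stop("contrast 'induced' requires expr_treated")
    induction_table(expr_treated, expr)
  } else expr
  res <- two_group_test(x, cl, moderated = moderated)
  out <- data.frame(
    feature = res$feature,
    log2_fc = res$diff,
    t = res$t,
    p_value = res$p_value,
    q_value = stats::p.adjust(res$p_value, method = "BH"),
    stringsAsFactors = FALSE
  )
  out$passes_cutoff <- abs(out$log2_fc) > fc_cutoff & out$p_value < p_cutoff
  out$contrast <- contrast
  out[order(out$p_value, -abs(out$log2_fc), out$feature), , drop = FALSE]
}

#' Efficiency-corrected relative qPCR expression
#'
#' Relative expression of gene g in sample s is
#' `E_g^(-Cq_gs)` divided by the geometric mean over the reference
#' genes r of `E_r^(-Cq_rs)`, where `E` is the primer's amplification
#' efficiency (2 = perfect doubling per cycle). Two reference genes
#' are the default design. Ratios of two genes' outputs (e.g. a
#' FABP5/CRABP2 ratio) are plain quotients of the returned values.
#'
#' @param cq Numeric matrix of quantification cycles (genes x
#'   samples), reference genes included as rows.
#' @param efficiencies Named numeric vector of per-gene primer
#'   efficiencies in `(1, 2]`.
#' @param reference_genes Character vector of reference gene ids
#'   (default exactly two).
#' @return Matrix of relative expression for the non-reference genes
#'   (genes x samples).
#' @export
qpcr_relative_expression <- function(cq, efficiencies, reference_genes) {
  if (length(reference_genes) < 1) stop("at least one reference gene required")
  genes <- rownames(cq)
  if (is.null(genes)) stop("cq must have gene rownames")
  miss_ref <- setdiff(reference_genes, genes)
  if (length(miss_ref)) stop("reference gene(s) missing from cq: ",
                             paste(miss_ref, collapse = ", "))
  need <- union(genes, reference_genes)
  if (!all(need %in% names(efficiencies))) {
    stop("missing primer efficiency for: ",
         paste(setdiff(need, names(efficiencies)), collapse = ", "))
  }
  E <- efficiencies[genes]
  if (any(E <= 1 | E > 2)) stop("primer efficiencies must lie in (1, 2]")
  if (anyNA(cq) || any(!is.finite(cq))) {
    bad <- which(!is.finite(cq), arr.ind = TRUE)
    stop("missing Cq for gene ", genes[bad[1, 1]], ", sample ",
         colnames(cq)[bad[1, 2]])
  }
  if (any(cq <= 0)) stop("Cq values must be positive")
  # work in logs for numerical stability: log(E^-Cq) = -Cq * log(E)
  log_q <- -cq * log(E)
  log_ref <- colMeans(log_q[reference_genes, , drop = FALSE])
  rel <- exp(sweep(log_q, 2, log_ref, "-"))
  rel[setdiff(genes, reference_genes), , drop = FALSE]
}
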