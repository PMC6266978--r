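# Differential-methylation module: probe filtering, supervised DMP
# discovery, CpG island context, probe->gene mapping, gene-set
# intersection, and methylation-expression correlation.

#' Remove blacklisted (cross-reactive / SNP-associated) probes
#'
#' @param beta Beta-value matrix, probes x samples.
#' @param manifest Probe manifest data.frame with columns `probe_id`
#'   and `blacklist` (logical).
#' @return The beta matrix without blacklisted rows; number of dropped
#'   probes is reported via `message()`.
#' @export
filter_probes <- function(beta, manifest) {
  missing <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing)) {
    stop("probes absent from manifest: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  }
  black <- manifest$probe_id[manifest$blacklist]
  keep <- !(rownames(beta) %in% black)
  message(sum(!keep), " blacklisted probe(s) removed; ", sum(keep), " retained")
  beta[keep, , drop = FALSE]
}

#' Supervised differential methylation (DMP discovery)
#'
#' Tests each probe for a difference between the sensitive class and
#' all other samples with the shared moderated two-group engine
#' ([two_group_test()]). Testing is done on the variance-stabilized
#' M scale by default; the effect size `delta_beta` (mean sensitive
#' beta minus mean other beta) is always reported on the beta scale.
#'
#' @param beta Beta-value matrix, probes x samples.
#' @param classes Supervision labels (`"sensitive"` / `"other"`) per
#'   sample, aligned with columns.
#' @param scale Test scale, `"M"` (default) or `"beta"`.
#' @param p_cutoff Significance threshold on the unadjusted p-value.
#' @param moderated Use empirical-Bayes variance shrinkage?
#' @return data.frame sorted by p: `probe_id`, `delta_beta`, `t`,
#'   `p_value`, `q_value` (Benjamini-Hochberg), `significant`.
#' @export
differential_methylation <- function(beta, classes, scale = c("M", "beta"),
                                     p_cutoff = 0.01, moderated = TRUE) {
  scale <- match.arg(scale)
  cl <- factor(as.character(classes), levels = c("sensitive", "other"))
  if (anyNA(cl)) stop("classes must be 'sensitive' or 'other'")
  x <- if (scale == "M") beta_to_m(beta) else beta
  res <- two_group_test(x, cl, moderated = moderated)
  sens <- cl == "sensitive"
  delta <- rowMeans(beta[, sens, drop = FALSE]) -
    rowMeans(beta[, !sens, drop = FALSE])
  out <- data.frame(
    probe_id = res$feature,
    delta_beta = unname(delta),
    t = res$t,
    p_value = res$p_value,
    q_value = stats::p.adjust(res$p_value, method = "BH"),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_value < p_cutoff
  out[order(out$p_value, -abs(out$delta_beta), out$probe_id), , drop = FALSE]
}

#' Classify positions relative to CpG islands
#'
#' Interval arithmetic with fixed flanks: distance 0 from an island is
#' `island`; `[1, 2000)` bp from the nearest island edge is a shore;
#' `[2000, 4000)` a shelf; anything farther is open sea. A position
#' exactly 2,000 bp from an edge is therefore a shelf (half-open
#' convention). North/south is resolved by which side of the nearest
#' island the probe lies on.
#'
#' @param chrom,pos Probe coordinates (`pos` 1-based, as in Illumina
#'   MAPINFO).
#' @param islands data.frame of island intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open, BED convention).
#' @return Character vector over
#'   `{island, n_shore, s_shore, n_shelf, s_shelf, open_sea}`.
#' @export
island_relation <- function(chrom, pos, islands) {
  if (length(chrom) != length(pos)) stop("chrom and pos must be aligned")
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0) { out[idx] <- "open_sea"; next }
    lo <- isl$start + 1L  # 1-based inclusive island span [lo, hi]
    hi <- isl$end
    for (j in idx) {
      p <- pos[j]
      inside <- any(p >= lo & p <= hi)
      if (inside) { out[j] <- "island"; next }
      d_left <- lo - p   # >0 when probe is left (north) of the island
      d_right <- p - hi  # >0 when probe is right (south) of the island
      d <- pmax(d_left, d_right)
      k <- which.min(d)
      dist <- d[k]
      side <- if (d_left[k] > 0) "n" else "s"
      out[j] <- if (dist < 2000) paste0(side, "_shore")
      else if (dist < 4000) paste0(side, "_shelf")
      else "open_sea"
    }
  }
  out
}

#' Island-context annotation of a DMP set versus background
#'
#' Computes the island relation of every probe in `dmp_ids` and of the
#' full manifest background, and returns the two relation frequency
#' tables (each summing to 1) for comparison.
#'
#' @param dmp_ids Character vector of probe ids (the DMP set).
#' @param manifest Probe manifest (columns `probe_id`, `chrom`, `pos`).
#' @param islands Island intervals (BED-style, 0-based half-open).
#' @return List with `relation` (named per-probe relations for the DMP
#'   set) and `frequency` (data.frame: relation, dmp_freq,
#'   background_freq).
#' @export
annotate_island_context <- function(dmp_ids, manifest, islands) {
  idx <- match(dmp_ids, manifest$probe_id)
  if (anyNA(idx)) {
    stop("probes absent from manifest: ",
         paste(utils::head(dmp_ids[is.na(idx)], 5), collapse = ", "))
  }
  if (anyNA(manifest$chrom[idx]) || anyNA(manifest$pos[idx])) {
    stop("probe(s) without coordinates in manifest")
  }
  levels <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf", "open_sea")
  rel_dmp <- island_relation(manifest$chrom[idx], manifest$pos[idx], islands)
  rel_bg <- island_relation(manifest$chrom, manifest$pos, islands)
  f_dmp <- table(factor(rel_dmp, levels = levels)) / length(rel_dmp)
  f_bg <- table(factor(rel_bg, levels = levels)) / length(rel_bg)
  names(rel_dmp) <- dmp_ids
  list(relation = rel_dmp,
       frequency = data.frame(relation = levels,
                              dmp_freq = as.numeric(f_dmp),
                              background_freq = as.numeric(f_bg),
                              stringsAsFactors = FALSE))
}

#' Map probes to the unique set of associated genes
#'
#' Union semantics: every gene associated with any of the probes is
#' included once; probes without a gene annotation contribute nothing.
#'
#' @param probe_ids Character vector of probe ids.
#' @param manifest Probe manifest with a `gene` column
#'   (semicolon-separated gene ids, empty for none).
#' @return Sorted character vector of unique gene ids.
#' @export
probes_to_genes <- function(probe_ids, manifest) {
  idx <- match(probe_ids, manifest$probe_id)
  g <- manifest$gene[idx[!is.na(idx)]]
  g <- unlist(strsplit(g[!is.na(g) & nzchar(g)], ";", fixed = TRUE))
  as.character(sort(unique(g)))
}

#' Three-way gene-set intersection (Venn regions)
#'
#' Exact set algebra over the differentially methylated, baseline
#' differentially expressed and induction differentially expressed
#' gene sets. The triple intersection is the predicted
#' methylation-regulated gene list.
#'
#' @param dm_genes,de_baseline_genes,de_induced_genes Character vectors
#'   of gene ids.
#' @return List with `regions` (named list of the 7 disjoint Venn
#'   regions), `counts` (named integer vector) and `triple` (the
#'   triple intersection).
#' @export
intersect_gene_sets <- function(dm_genes, de_baseline_genes, de_induced_genes) {
  A <- unique(dm_genes); B <- unique(de_baseline_genes); C <- unique(de_induced_genes)
  regions <- list(
    dm_only = setdiff(A, union(B, C)),
    de_baseline_only = setdiff(B, union(A, C)),
    de_induced_only = setdiff(C, union(A, B)),
    dm_de_baseline = setdiff(intersect(A, B), C),
    dm_de_induced = setdiff(intersect(A, C), B),
    de_baseline_de_induced = setdiff(intersect(B, C), A),
    triple = Reduce(intersect, list(A, B, C))
  )
  list(regions = regions,
       counts = vapply(regions, length, integer(1)),
       triple = sort(regions$triple))
}

#' Methylation-expression Spearman correlation for probe-gene pairs
#'
#' Rank correlation (average ranks for ties) between a probe's
#' beta-values and a gene's expression across shared samples. P-values
#' use the exact permutation distribution for n <= 9 (no ties) and the
#' t-approximation otherwise. A constant methylation or expression
#' vector yields `rho = NA` with a degenerate-input note.
#'
#' @param beta Beta matrix (probes x samples).
#' @param expr Expression matrix (genes x samples).
#' @param pairs data.frame with columns `probe_id`, `gene_id`.
#' @return data.frame: `probe_id`, `gene_id`, `n`, `rho`, `p_value`,
#'   `note`.
#' @export
methylation_expression_correlation <- function(beta, expr, pairs) {
  shared <- intersect(colnames(beta), colnames(expr))
  if (length(shared) < 4) stop("fewer than 4 shared samples between matrices")
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$probe_id[i]; g <- pairs$gene_id[i]
    if (!p %in% rownames(beta)) stop("probe not in beta matrix: ", p)
    if (!g %in% rownames(expr)) stop("gene not in expression matrix: ", g)
    x <- beta[p, shared]; y <- expr[g, shared]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) stop("fewer than 4 shared samples for pair ", p, "/", g)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(probe_id = p, gene_id = g, n = length(x),
                        rho = NA_real_, p_value = NA_real_,
                        note = "degenerate: constant input",
                        stringsAsFactors = FALSE))
    }
    n <- length(x)
    ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = (n <= 9 && !ties))
    )
    data.frame(probe_id = p, gene_id = g, n = n,
               rho = unname(ct$estimate), p_value = ct$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
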