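#' Configuration for a synthetic atRA-sensitivity cohort
#'
#' Bundles every parameter of the synthetic-data generator with
#' defaults that mirror the design of the xenograft study the pipeline
#' targets: a labeled reference panel of 13 TNBC cell lines
#' (5 sensitive, 4 resistant, 4 promoted) plus 4 PDXs, a 70-sample
#' query cohort with ~17% truly sensitive tumors, 10,000 CpG probes
#' with 100 planted differentially methylated positions at a beta
#' difference of 0.3, and paired control/treated expression with
#' coupled methylation-expression pairs.
#'
#' @param n_probes Number of CpG probes on the synthetic array.
#' @param n_genes Number of genes/transcript features.
#' @param n_sensitive_lines,n_resistant_lines,n_promoted_lines Panel
#'   cell-line counts per response category.
#' @param n_pdx Number of patient-derived xenografts (all truly
#'   sensitive, as in the validation panel).
#' @param n_queries Size of the query cohort.
#' @param true_sensitive_fraction Fraction of queries that are truly
#'   sensitive.
#' @param n_planted_dmp Number of probes with a planted group effect.
#' @param delta_beta Planted between-class difference in beta units,
#'   in (0, 1).
#' @param n_planted_de Number of genes with a planted baseline effect
#'   (and, independently, the number with a planted induction effect).
#' @param de_log2fc Planted expression effect size (log2).
#' @param n_coupled Number of coupled DMP-gene pairs (negatively
#'   correlated methylation and expression; these genes carry both the
#'   baseline and the induction effect).
#' @param d0,s0_sq Scaled inverse-chi-square variance prior for
#'   per-probe residual variance on the M scale (degrees of freedom and
#'   scale).
#' @param platform_both_fraction Fraction of probes present on both the
#'   HM450 and EPIC platforms; the remainder is split evenly between
#'   the platform-exclusive classes.
#' @param sensitive_fc,resistant_fc,promoted_fc Multiplicative effect
#'   of treatment on final tumor weight per response category.
#' @param mice_per_arm Mice per treatment arm in growth simulations.
#' @param growth_sdlog Lognormal sd (log scale) of final tumor weights.
#' @param motif_gene_fraction Fraction of genes with a response element
#'   planted within 10 kb of the gene.
#' @param genome_length Total length (bp) of the toy genome (two
#'   chromosomes).
#' @param seed Integer seed; the same config and seed give bit-identical
#'   cohorts.
#' @return Object of class `ra_synth_config` (a validated list).
#' @export
synthetic_config <- function(n_probes = 10000,
                             n_genes = 300,
                             n_sensitive_lines = 5,
                             n_resistant_lines = 4,
                             n_promoted_lines = 4,
                             n_pdx = 4,
                             n_queries = 70,
                             true_sensitive_fraction = 0.17,
                             n_planted_dmp = 100,
                             delta_beta = 0.3,
                             n_planted_de = 50,
                             de_log2fc = 1.5,
                             n_coupled = 17,
                             d0 = 4,
                             s0_sq = 0.04,
                             platform_both_fraction = 0.85,
                             sensitive_fc = 0.4,
                             resistant_fc = 1.0,
                             promoted_fc = 1.8,
                             mice_per_arm = 8,
                             growth_sdlog = 0.25,
                             motif_gene_fraction = 0.3,
                             genome_length = 6e6,
                             seed = 1L) {
  cfg <- list(
    n_probes = n_probes, n_genes = n_genes,
    n_sensitive_lines = n_sensitive_lines,
    n_resistant_lines = n_resistant_lines,
    n_promoted_lines = n_promoted_lines,
    n_pdx = n_pdx, n_queries = n_queries,
    true_sensitive_fraction = true_sensitive_fraction,
    n_planted_dmp = n_planted_dmp, delta_beta = delta_beta,
    n_planted_de = n_planted_de, de_log2fc = de_log2fc,
    n_coupled = n_coupled, d0 = d0, s0_sq = s0_sq,
    platform_both_fraction = platform_both_fraction,
    sensitive_fc = sensitive_fc, resistant_fc = resistant_fc,
    promoted_fc = promoted_fc, mice_per_arm = mice_per_arm,
    growth_sdlog = growth_sdlog,
    motif_gene_fraction = motif_gene_fraction,
    genome_length = genome_length, seed = as.integer(seed)
  )
  class(cfg) <- "ra_synth_config"
  validate_synthetic_config(cfg)
  cfg
}

#' Validate a synthetic-cohort configuration
#'
#' Checks count, proportion and effect-size invariants; errors name the
#' offending field.
#'
#' @param cfg An `ra_synth_config` (or plain list with its fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_synthetic_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (is.null(v) || length(v) != 1 || !is.finite(v) || v < min || v != round(v)) {
      stop("invalid config field '", field, "': must be an integer >= ", min,
           call. = FALSE)
    }
  }
  chk_prop <- function(field) {
    v <- cfg[[field]]
    if (is.null(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop("invalid config field '", field, "': must be a proportion in [0, 1]",
           call. = FALSE)
    }
  }
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (is.null(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("invalid config field '", field, "': must be positive", call. = FALSE)
    }
  }
  for (f in c("n_probes", "n_genes", "n_sensitive_lines", "n_resistant_lines",
              "n_promoted_lines", "n_pdx", "n_queries", "n_planted_dmp",
              "n_planted_de", "n_coupled", "mice_per_arm")) chk_count(f)
  for (f in c("true_sensitive_fraction", "platform_both_fraction",
              "motif_gene_fraction")) chk_prop(f)
  for (f in c("d0", "s0_sq", "sensitive_fc", "resistant_fc", "promoted_fc",
              "growth_sdlog", "genome_length")) chk_pos(f)
  if (cfg$delta_beta <= 0 || cfg$delta_beta >= 1) {
    stop("invalid config field 'delta_beta': must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$n_planted_dmp > cfg$n_probes) {
    stop("invalid config field 'n_planted_dmp': exceeds n_probes", call. = FALSE)
  }
  if (cfg$n_planted_de > cfg$n_genes) {
    stop("invalid config field 'n_planted_de': exceeds n_genes", call. = FALSE)
  }
  if (cfg$n_coupled > min(cfg$n_planted_dmp, cfg$n_planted_de)) {
    stop("invalid config field 'n_coupled': exceeds min(n_planted_dmp, n_planted_de)",
         call. = FALSE)
  }
  if (cfg$n_sensitive_lines + cfg$n_pdx > 0 &&
      cfg$n_sensitive_lines + cfg$n_resistant_lines + cfg$n_promoted_lines > 0) {
    # panel exists; nothing further to check here
  }
  invisible(cfg)
}
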