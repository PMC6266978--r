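# Plain-text readers/writers for the pipeline's exchange formats:
# beta/expression TSV (first column = feature id), manifest and sample
# CSV, growth CSV, BED (0-based half-open), FASTA (via Biostrings),
# and JSON for truth files and signature models.

#' Read a feature-by-sample matrix from TSV
#'
#' First column = feature id, header = sample ids.
#' @param path File path.
#' @return Numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix to TSV
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the first (id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  d <- data.frame(id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read/write a BED file (0-based half-open)
#'
#' Minimal BED support: chrom, start, end and optional name/score/strand.
#' @param path File path.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(d))]
  d
}

#' @rdname read_bed
#' @param bed data.frame with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(bed))
  utils::write.table(bed[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Serialize a signature model to JSON
#'
#' @param model An `ra_signature`.
#' @param path Output path.
#' @export
write_signature <- function(model, path) {
  obj <- list(
    probes = model$probes,
    reference_beta = as.data.frame(model$reference_beta),
    reference_samples = colnames(model$reference_beta),
    reference_labels = as.list(model$reference_labels),
    sample_type = as.list(model$sample_type),
    distance = model$distance, linkage = model$linkage,
    refinement = model$refinement,
    warning_flag = model$warning_flag
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a signature model from JSON
#' @param path Path written by [write_signature()].
#' @return An `ra_signature`.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- as.matrix(obj$reference_beta)
  rownames(ref) <- obj$probes
  colnames(ref) <- obj$reference_samples
  model <- list(
    probes = obj$probes,
    reference_beta = ref,
    reference_labels = unlist(obj$reference_labels),
    sample_type = if (length(obj$sample_type)) unlist(obj$sample_type) else NULL,
    distance = obj$distance, linkage = obj$linkage,
    refinement = obj$refinement,
    warning_flag = isTRUE(obj$warning_flag)
  )
  class(model) <- "ra_signature"
  model
}

#' Write every component of a synthetic cohort to a directory
#'
#' Emits: `beta_panel.tsv`, `beta_queries.tsv`, `expr_control.tsv`,
#' `expr_treated.tsv`, `growth.csv`, `manifest.csv`, `samples.csv`,
#' `genes.bed`, `islands.bed`, `genome.fa`, `truth.json` (components
#' that were not generated are skipped).
#'
#' @param cohort An `ra_cohort` from [generate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  if (!is.null(cohort$beta_panel)) {
    write_matrix_tsv(cohort$beta_panel, p("beta_panel.tsv"))
    write_matrix_tsv(cohort$beta_queries, p("beta_queries.tsv"))
  }
  if (!is.null(cohort$expr_control)) {
    write_matrix_tsv(cohort$expr_control, p("expr_control.tsv"), id_col = "gene_id")
    write_matrix_tsv(cohort$expr_treated, p("expr_treated.tsv"), id_col = "gene_id")
  }
  if (!is.null(cohort$growth)) {
    utils::write.csv(cohort$growth, p("growth.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$manifest, p("manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$samples, p("samples.csv"), row.names = FALSE)
  genes_bed <- data.frame(chrom = cohort$genes$chrom,
                          start = cohort$genes$start, end = cohort$genes$end,
                          name = cohort$genes$gene_id, score = 0,
                          strand = cohort$genes$strand)
  write_bed(genes_bed, p("genes.bed"))
  write_bed(cohort$islands, p("islands.bed"))
  if (!is.null(cohort$genome)) {
    Biostrings::writeXStringSet(cohort$genome, p("genome.fa"))
  }
  truth <- cohort$truth
  truth$coupled_pairs <- as.data.frame(truth$coupled_pairs)
  truth$sample_truth <- as.data.frame(truth$sample_truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(outdir)
}
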