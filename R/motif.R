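# Direct-repeat response-element scanning (RARE/PPRE) and gene
# proximity annotation. Matching is exact IUPAC (no PWM scoring):
# ambiguity codes in the half-site are wildcards, but an N in the
# genome never matches a non-N pattern letter.

.IUPAC_LETTERS <- names(Biostrings::IUPAC_CODE_MAP)

#' Specify a direct-repeat response-element motif
#'
#' A motif is two copies of an IUPAC half-site separated by a fixed
#' number of spacer bases (direct repeat, both strands scanned). The
#' canonical nuclear-receptor half-site `RGKTCA` is the default;
#' RARE-type elements use DR1/DR2/DR5 spacers, PPRE-type DR1.
#'
#' @param name `"RARE"`, `"PPRE"` or `"custom"`.
#' @param half_site IUPAC half-site string.
#' @param spacers Integer vector of spacer lengths (>= 0); defaults by
#'   `name`: RARE `c(1, 2, 5)`, PPRE `1`.
#' @return Object of class `ra_motif_spec`.
#' @export
motif_spec <- function(name = c("RARE", "PPRE", "custom"),
                       half_site = "RGKTCA", spacers = NULL) {
  name <- match.arg(name)
  if (is.null(spacers)) {
    spacers <- switch(name, RARE = c(1L, 2L, 5L), PPRE = 1L,
                      stop("custom motif_spec requires explicit spacers"))
  }
  half_site <- toupper(half_site)
  if (nchar(half_site) == 0) stop("half_site must be non-empty")
  letters <- strsplit(half_site, "")[[1]]
  bad <- setdiff(letters, .IUPAC_LETTERS)
  if (length(bad)) stop("invalid IUPAC code(s) in half_site: ",
                        paste(unique(bad), collapse = ", "))
  if (any(spacers < 0) || any(spacers != round(spacers))) {
    stop("spacers must be non-negative integers")
  }
  structure(list(name = name, half_site = half_site,
                 spacers = sort(unique(as.integer(spacers)))),
            class = "ra_motif_spec")
}

# 0-based start positions where the half-site matches strand `seq`
.half_site_starts <- function(seq, half_site) {
  m <- Biostrings::matchPattern(half_site, seq, fixed = "subject")
  Biostrings::start(m) - 1L
}

#' Scan sequences for direct-repeat motif hits
#'
#' Reports every position, on both strands, where
#' half-site + spacer + half-site matches exactly under IUPAC
#' semantics, for each spacer length in the spec. Overlapping hits are
#' all reported; coordinates are 0-based half-open on the forward
#' strand.
#'
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA
#'   file).
#' @param spec A [motif_spec()].
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `spacer`,
#'   `match` (forward-strand sequence of the hit).
#' @export
scan_motifs <- function(genome, spec) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!inherits(spec, "ra_motif_spec")) stop("spec must be a motif_spec()")
  L <- nchar(spec$half_site)
  rows <- list()
  for (ch in names(genome)) {
    seq <- genome[[ch]]
    slen <- length(seq)
    fwd <- .half_site_starts(seq, spec$half_site)
    rev_seq <- Biostrings::reverseComplement(seq)
    rev <- .half_site_starts(rev_seq, spec$half_site)
    for (sp in spec$spacers) {
      w <- 2L * L + sp
      # forward: two half-site matches separated by spacer
      a <- intersect(fwd, fwd + L + sp) - (L + sp)
      if (length(a)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = a, end = a + w, strand = "+", spacer = sp,
          stringsAsFactors = FALSE)
      }
      # reverse strand: same on the reverse complement, mirrored back
      b <- intersect(rev, rev + L + sp) - (L + sp)
      if (length(b)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = slen - (b + w), end = slen - b, strand = "-",
          spacer = sp, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      spacer = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$chrom, hits$start, hits$strand, hits$spacer), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits$match <- vapply(seq_len(nrow(hits)), function(i) {
    as.character(Biostrings::subseq(genome[[hits$chrom[i]]],
                                    start = hits$start[i] + 1L,
                                    end = hits$end[i]))
  }, character(1))
  hits
}

# bp between the closest bases of two 0-based half-open intervals
# (0 when overlapping, 1 when adjacent)
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - (e1 - 1L), s1 - (e2 - 1L)))
}

#' Genes with a motif hit within a window
#'
#' A gene is included iff the distance between its full span and the
#' nearest hit on the same chromosome is at most `window_bp` (distance
#' 0 for an overlapping hit; a hit exactly `window_bp + 1` bp beyond
#' the gene span is excluded). Hits on other chromosomes never count.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param hits Motif hits from [scan_motifs()].
#' @param window_bp Window in bp (default 10,000).
#' @return data.frame: `gene_id`, `distance` (bp to nearest hit, `Inf`
#'   when no hit shares the chromosome), `near` (logical).
#' @export
genes_near_motifs <- function(genes, hits, window_bp = 10000) {
  dist <- rep(Inf, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    h <- hits[hits$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(h) == 0) next
    dist[i] <- min(.interval_gap(genes$start[i], genes$end[i], h$start, h$end))
  }
  data.frame(gene_id = genes$gene_id, distance = dist,
             near = dist <= window_bp, stringsAsFactors = FALSE)
}

#' Count DE features near RARE / PPRE elements
#'
#' Splits a differential-expression feature list into four disjoint
#' groups by response-element proximity of the mapped gene: near a
#' RARE only, near a PPRE only, near both, or neither. Features
#' without a gene mapping are counted as neither (and reported).
#'
#' @param de_features Character vector of feature ids.
#' @param feature_to_gene Named character vector mapping feature id to
#'   gene id (`NA`/missing = unmapped).
#' @param rare_genes,ppre_genes Character vectors of gene ids near the
#'   respective element.
#' @return Named integer vector
#'   `c(rare_only, ppre_only, both, neither)`; attribute `unmapped`
#'   holds the unmapped feature ids.
#' @export
annotate_de_lists <- function(de_features, feature_to_gene,
                              rare_genes, ppre_genes) {
  g <- feature_to_gene[de_features]
  unmapped <- de_features[is.na(g)]
  if (length(unmapped)) {
    message(length(unmapped), " feature(s) without gene mapping counted as neither")
  }
  in_r <- !is.na(g) & g %in% rare_genes
  in_p <- !is.na(g) & g %in% ppre_genes
  counts <- c(rare_only = sum(in_r & !in_p),
              ppre_only = sum(in_p & !in_r),
              both = sum(in_r & in_p),
              neither = sum(!in_r & !in_p))
  stopifnot(sum(counts) == length(de_features))
  attr(counts, "unmapped") <- unmapped
  counts
}
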