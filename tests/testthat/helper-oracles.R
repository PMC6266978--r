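# Independent brute-force oracles used to validate the package's
# statistics and scanners. These deliberately avoid the code paths
# they check.

# classical pooled-variance two-sample t-test, textbook formulas
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Welch t-test, textbook formulas
oracle_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# two-sided Fisher exact p by exhaustive enumeration over all tables
# with the observed margins; table probabilities from binomial
# coefficients directly
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  prob <- function(aa) {
    exp(lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(n, c1))
  }
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, prob, numeric(1))
  p_obs <- prob(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exact two-sided Spearman p by full permutation enumeration
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 8)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  all_p <- perms(seq_len(n))
  rhos <- vapply(all_p, function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# IUPAC code -> regex character class
.iupac_class <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(code, "")[[1]], function(ch) {
    s <- map[[ch]]
    if (nchar(s) == 1) s else paste0("[", s, "]")
  }, character(1)), collapse = "")
}

# regex-based direct-repeat scan over both strands (lookahead so
# overlapping hits are all found); returns forward-strand 0-based
# half-open coordinates
oracle_scan <- function(seq_str, half_site, spacers) {
  L <- nchar(half_site)
  slen <- nchar(seq_str)
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hs_re <- .iupac_class(half_site)
  out <- list()
  for (sp in spacers) {
    w <- 2 * L + sp
    pat <- paste0("(?=", hs_re, "[ACGTN]{", sp, "}", hs_re, ")")
    scan_one <- function(s) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1) integer(0) else as.integer(m) - 1L
    }
    # spacer must be real bases but N should be allowed there? No:
    # an N in the spacer is a real genome letter; spacer is
    # unconstrained, so any letter incl. N is fine.
    f <- scan_one(seq_str)
    r <- scan_one(revcomp(seq_str))
    if (length(f)) out[[length(out) + 1]] <-
        data.frame(start = f, end = f + w, strand = "+", spacer = sp)
    if (length(r)) out[[length(out) + 1]] <-
        data.frame(start = slen - (r + w), end = slen - r, strand = "-",
                   spacer = sp)
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0),
                                      spacer = integer(0)))
  d <- do.call(rbind, out)
  d[order(d$start, d$strand, d$spacer), , drop = FALSE]
}

# brute-force island relation: scan every island per probe
oracle_island_relation <- function(chrom, pos, islands) {
  vapply(seq_along(pos), function(i) {
    isl <- islands[islands$chrom == chrom[i], , drop = FALSE]
    if (nrow(isl) == 0) return("open_sea")
    best <- Inf; side <- ""
    for (j in seq_len(nrow(isl))) {
      lo <- isl$start[j] + 1; hi <- isl$end[j]
      if (pos[i] >= lo && pos[i] <= hi) return("island")
      if (pos[i] < lo) { d <- lo - pos[i]; s <- "n" } else { d <- pos[i] - hi; s <- "s" }
      if (d < best) { best <- d; side <- s }
    }
    if (best < 2000) paste0(side, "_shore")
    else if (best < 4000) paste0(side, "_shelf")
    else "open_sea"
  }, character(1))
}

# all-pairs base-level distance between gene spans and hits
oracle_gene_near <- function(genes, hits, window) {
  vapply(seq_len(nrow(genes)), function(i) {
    h <- hits[hits$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(h) == 0) return(FALSE)
    gb <- seq(genes$start[i], genes$end[i] - 1)
    dmin <- min(vapply(seq_len(nrow(h)), function(j) {
      hb <- seq(h$start[j], h$end[j] - 1)
      min(abs(outer(gb, hb, "-")))
    }, numeric(1)))
    dmin <= window
  }, logical(1))
}

# naive agglomerative clustering returning the cophenetic distance
# matrix (complete or average linkage)
oracle_cophenetic <- function(mat, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  cd <- function(c1, c2) {
    vals <- d[c1, c2, drop = FALSE]
    if (linkage == "complete") max(vals) else mean(vals)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- cd(clusters[[i]], clusters[[j]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    ci <- clusters[[best[1]]]; cj <- clusters[[best[2]]]
    coph[ci, cj] <- bh; coph[cj, ci] <- bh
    clusters[[best[1]]] <- c(ci, cj)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# reference Benjamini-Hochberg step-up
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# small labeled toy beta matrix for classifier tests
toy_signature <- function(k = 4, n_sens = 3, n_other = 3, delta = 0.4,
                          sd = 0.02, seed = 42) {
  set.seed(seed)
  probes <- sprintf("cg%03d", seq_len(k))
  base <- runif(k, 0.2, 0.5)
  ref <- cbind(
    matrix(rep(base + delta, n_sens), ncol = n_sens) +
      rnorm(k * n_sens, 0, sd),
    matrix(rep(base, n_other), ncol = n_other) + rnorm(k * n_other, 0, sd)
  )
  ref <- pmin(pmax(ref, 0.01), 0.99)
  rownames(ref) <- probes
  colnames(ref) <- c(sprintf("S%d", seq_len(n_sens)),
                     sprintf("O%d", seq_len(n_other)))
  labels <- setNames(rep(c("sensitive", "other"), c(n_sens, n_other)),
                     colnames(ref))
  model <- list(probes = probes, reference_beta = ref,
                reference_labels = labels, sample_type = NULL,
                distance = "euclidean", linkage = "complete",
                refinement = list(), warning_flag = FALSE)
  class(model) <- "ra_signature"
  list(model = model, base = base, delta = delta)
}
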