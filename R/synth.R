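# Synthetic-cohort generator. Emits a fully self-consistent study:
# methylation panel + queries, paired expression, xenograft growth,
# probe manifest, gene/island coordinates, a toy genome with planted
# response elements, and a ground-truth record for recovery testing.

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.iupac_realize <- function(code) {
  # one concrete base per IUPAC letter, sampled uniformly
  sets <- Biostrings::IUPAC_CODE_MAP
  vapply(strsplit(code, "")[[1]], function(ch) {
    opts <- strsplit(sets[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
}

#' Simulate xenograft tumor-growth records
#'
#' Final tumor weights are lognormal around a control geometric mean,
#' with the treated arm's location multiplied by the model's effect
#' (e.g. 0.4 for a sensitive model, 1.8 for a tumor-promoted one).
#' A short tumor-volume time series (mm^3; caliper convention
#' length x width x depth / 2, recorded as an attribute) accompanies
#' each mouse.
#'
#' @param models Character vector of model ids.
#' @param mice_per_arm Mice per arm per model (>= 2 for testing).
#' @param effects Positive multiplicative treatment effects, recycled
#'   or named by model.
#' @param seed Integer seed.
#' @param control_mean Geometric-mean final weight (grams) of control
#'   arms.
#' @param sdlog Lognormal sd on the log scale.
#' @param timepoints Number of volume measurements per mouse.
#' @return data.frame with columns `model_id`, `arm`, `mouse_id`,
#'   `final_weight`, and `vol_t1..vol_tK`; attribute
#'   `volume_convention`.
#' @export
generate_growth <- function(models, mice_per_arm, effects, seed,
                            control_mean = 1.0, sdlog = 0.25,
                            timepoints = 5) {
  if (any(!is.finite(effects)) || any(effects <= 0)) {
    stop("growth effects must be positive")
  }
  if (mice_per_arm < 1) stop("mice_per_arm must be >= 1")
  eff <- if (!is.null(names(effects))) effects[models] else
    rep_len(effects, length(models))
  .with_seed(seed, {
    rows <- lapply(seq_along(models), function(i) {
      w_ctl <- stats::rlnorm(mice_per_arm, log(control_mean), sdlog)
      w_trt <- stats::rlnorm(mice_per_arm, log(control_mean * eff[i]), sdlog)
      w <- c(w_ctl, w_trt)
      arm <- rep(c("control", "treated"), each = mice_per_arm)
      vols <- t(vapply(w, function(wt) {
        final_vol <- wt * 1000  # ~1 g == 1000 mm^3
        tt <- seq_len(timepoints)
        final_vol * exp(-0.4 * (timepoints - tt)) *
          exp(stats::rnorm(timepoints, 0, 0.08))
      }, numeric(timepoints)))
      colnames(vols) <- paste0("vol_t", seq_len(timepoints))
      data.frame(model_id = models[i], arm = arm,
                 mouse_id = sprintf("%s_%s_%02d", models[i],
                                    ifelse(arm == "control", "c", "t"),
                                    c(seq_len(mice_per_arm), seq_len(mice_per_arm))),
                 final_weight = w, vols,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "volume_convention") <- "length x width x depth / 2 (mm^3)"
    out
  })
}

# gene layout on a regular grid: guarantees >= ~12 kb between gene
# spans at default sizes so a motif planted inside one gene span is
# outside the 10 kb window of every other gene
.layout_genes <- function(n_genes, chrom_len) {
  total <- sum(chrom_len)
  sp <- floor(total / max(1, n_genes))
  offs_max <- max(2000, sp - 16000)
  starts0 <- ends0 <- integer(n_genes)
  chrom <- character(n_genes)
  bounds <- cumsum(c(0, chrom_len))
  for (i in seq_len(n_genes)) {
    g0 <- (i - 1) * sp
    u <- if (offs_max > 2000) sample(2000:offs_max, 1) else 2000
    len <- sample(2000:6000, 1)
    s <- g0 + u
    ci <- findInterval(s, bounds, rightmost.closed = TRUE)
    ci <- min(max(ci, 1), length(chrom_len))
    s_local <- s - bounds[ci]
    # keep the whole span on one chromosome
    if (s_local + len >= chrom_len[ci]) s_local <- max(0, chrom_len[ci] - len - 1)
    chrom[i] <- names(chrom_len)[ci]
    starts0[i] <- s_local
    ends0[i] <- s_local + len
  }
  data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
             chrom = chrom, start = starts0, end = ends0,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

.layout_islands <- function(n_probes, chrom_len) {
  n_isl <- max(1, round(n_probes / 25))
  ci <- sample(seq_along(chrom_len), n_isl, replace = TRUE)
  w <- sample(300:1500, n_isl, replace = TRUE)
  s <- vapply(seq_len(n_isl), function(i) {
    sample.int(max(1, chrom_len[ci[i]] - w[i] - 1), 1)
  }, integer(1))
  data.frame(chrom = names(chrom_len)[ci], start = s, end = s + w,
             stringsAsFactors = FALSE)
}

# probe positions: a realistic mix of island / shore / shelf / open sea
.place_probes <- function(n_probes, islands, chrom_len) {
  comp <- sample(1:4, n_probes, replace = TRUE, prob = c(0.30, 0.20, 0.10, 0.40))
  isl_idx <- sample.int(nrow(islands), n_probes, replace = TRUE)
  pos <- integer(n_probes)
  chrom <- character(n_probes)
  for (i in seq_len(n_probes)) {
    if (comp[i] == 4) {
      ci <- sample(seq_along(chrom_len), 1)
      chrom[i] <- names(chrom_len)[ci]
      pos[i] <- sample.int(chrom_len[ci], 1)
    } else {
      isl <- islands[isl_idx[i], ]
      chrom[i] <- isl$chrom
      p <- switch(comp[i],
        isl$start + 1 + sample.int(isl$end - isl$start, 1) - 1,   # in island
        {off <- sample.int(1999, 1); side <- sample(c(-1, 1), 1)  # shore
         if (side < 0) isl$start + 1 - off else isl$end + off},
        {off <- sample(2000:3999, 1); side <- sample(c(-1, 1), 1) # shelf
         if (side < 0) isl$start + 1 - off else isl$end + off})
      pos[i] <- min(max(p, 1), chrom_len[[chrom[i]]])
    }
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

# associate probes with genes whose span (plus 2 kb promoter flank)
# they fall near; up to two genes, tagged TSS200/TSS1500/Body
.assign_genes <- function(probes, genes, flank = 2000) {
  gene_col <- character(nrow(probes))
  region_col <- character(nrow(probes))
  for (ch in unique(probes$chrom)) {
    pi <- which(probes$chrom == ch)
    gs <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gs) == 0) next
    for (j in pi) {
      p <- probes$pos[j]
      d <- pmax(0L, pmax(gs$start + 1L - p, p - gs$end))
      hit <- which(d <= flank)
      if (!length(hit)) next
      hit <- hit[order(d[hit])][seq_len(min(2, length(hit)))]
      tags <- vapply(hit, function(k) {
        g <- gs[k, ]
        tss <- if (g$strand == "+") g$start + 1L else g$end
        dt <- abs(p - tss)
        if (p > g$start && p <= g$end && dt > 1500) "Body"
        else if (dt <= 200) "TSS200"
        else if (dt <= 1500) "TSS1500"
        else "Body"
      }, character(1))
      gene_col[j] <- paste(gs$gene_id[hit], collapse = ";")
      region_col[j] <- paste(tags, collapse = ";")
    }
  }
  list(gene = gene_col, region = region_col)
}

#' Generate a complete synthetic atRA-sensitivity cohort
#'
#' Produces every input the downstream pipeline consumes, with known
#' ground truth. Per-probe baseline M-values come from a
#' hypo/hyper-methylated mixture; per-probe residual variances from a
#' scaled inverse-chi-square prior; planted DMPs shift the sensitive
#' class (sensitive cell lines, PDXs and truly sensitive queries) by
#' `delta_beta` on the beta scale (planted on the M scale via the
#' baseline mode, sign random per probe). Planted expression effects
#' cover baseline and induced (treated - control) contrasts; coupled
#' probe-gene pairs tie expression negatively and monotonically to
#' methylation across the panel. A small blacklist deliberately
#' overlaps a few planted DMPs so the probe filter is consequential.
#'
#' @param config An [synthetic_config()] object.
#' @param components Character subset of
#'   `c("meth", "expr", "growth", "genome")`; coordinates, manifest and
#'   truth are always generated. Restricting components speeds up
#'   simulations that only need part of the study.
#' @return Object of class `ra_cohort`: a list with elements `config`,
#'   `samples`, `beta_panel`, `beta_queries`, `expr_control`,
#'   `expr_treated`, `growth`, `manifest`, `genes`, `islands`,
#'   `genome` (a [Biostrings::DNAStringSet] or `NULL`), and `truth`.
#' @export
generate_cohort <- function(config,
                            components = c("meth", "expr", "growth", "genome")) {
  validate_synthetic_config(config)
  cfg <- config
  components <- match.arg(components, several.ok = TRUE)
  seeds <- .with_seed(cfg$seed, sample.int(2^30, 8))

  half <- floor(cfg$genome_length / 2)
  chrom_len <- c(chr1 = half, chr2 = cfg$genome_length - half)

  ## ---- layout, planted sets, manifest (always) ----
  layout <- .with_seed(seeds[1], {
    genes <- .layout_genes(cfg$n_genes, chrom_len)
    islands <- .layout_islands(cfg$n_probes, chrom_len)

    coupled_genes <- if (cfg$n_coupled > 0) sample.int(cfg$n_genes, cfg$n_coupled) else integer(0)
    pool <- setdiff(seq_len(cfg$n_genes), coupled_genes)
    extra_base <- sample(pool, cfg$n_planted_de - cfg$n_coupled)
    pool2 <- setdiff(pool, extra_base)
    extra_ind <- sample(pool2, min(length(pool2), cfg$n_planted_de - cfg$n_coupled))
    de_base <- sort(c(coupled_genes, extra_base))
    de_ind <- sort(c(coupled_genes, extra_ind))

    probe_ids <- sprintf("cg%08d", seq_len(cfg$n_probes))
    planted <- if (cfg$n_planted_dmp > 0) sample.int(cfg$n_probes, cfg$n_planted_dmp) else integer(0)
    coupled_probes <- planted[seq_len(cfg$n_coupled)]

    probes <- .place_probes(cfg$n_probes, islands, chrom_len)
    # coupled probes sit at their gene's TSS so the proximity rule
    # associates them with the coupled gene
    if (cfg$n_coupled > 0) {
      for (k in seq_len(cfg$n_coupled)) {
        g <- genes[coupled_genes[k], ]
        off <- sample.int(400, 1)
        probes$chrom[coupled_probes[k]] <- g$chrom
        probes$pos[coupled_probes[k]] <-
          if (g$strand == "+") g$start + off else g$end - off
      }
    }
    assoc <- .assign_genes(probes, genes)
    relation <- island_relation(probes$chrom, probes$pos, islands)

    platform <- sample(c("both", "HM450", "EPIC"), cfg$n_probes, replace = TRUE,
                       prob = c(cfg$platform_both_fraction,
                                (1 - cfg$platform_both_fraction) / 2,
                                (1 - cfg$platform_both_fraction) / 2))
    # blacklist: mostly null probes, plus up to 3 planted (non-coupled)
    n_black <- max(5L, round(0.005 * cfg$n_probes))
    planted_noncoupled <- setdiff(planted, coupled_probes)
    black_planted <- if (length(planted_noncoupled))
      planted_noncoupled[seq_len(min(3, length(planted_noncoupled)))] else integer(0)
    null_pool <- setdiff(seq_len(cfg$n_probes), planted)
    black <- c(black_planted,
               sample(null_pool, max(0, n_black - length(black_planted))))

    manifest <- data.frame(
      probe_id = probe_ids, chrom = probes$chrom, pos = probes$pos,
      island_relation = relation, gene = assoc$gene, gene_region = assoc$region,
      platform = platform,
      blacklist = seq_len(cfg$n_probes) %in% black,
      stringsAsFactors = FALSE
    )
    list(genes = genes, islands = islands, manifest = manifest,
         probe_ids = probe_ids, planted = planted,
         coupled_probes = coupled_probes, coupled_genes = coupled_genes,
         de_base = de_base, de_ind = de_ind,
         black_planted = black_planted)
  })
  genes <- layout$genes; islands <- layout$islands; manifest <- layout$manifest
  gene_ids <- genes$gene_id

  ## ---- samples ----
  line_ids <- c(sprintf("CL_S%02d", seq_len(cfg$n_sensitive_lines)),
                sprintf("CL_R%02d", seq_len(cfg$n_resistant_lines)),
                sprintf("CL_P%02d", seq_len(cfg$n_promoted_lines)))
  line_cat <- c(rep("sensitive", cfg$n_sensitive_lines),
                rep("resistant", cfg$n_resistant_lines),
                rep("promoted", cfg$n_promoted_lines))
  pdx_ids <- if (cfg$n_pdx > 0) sprintf("PDX_%02d", seq_len(cfg$n_pdx)) else character(0)
  query_ids <- if (cfg$n_queries > 0) sprintf("Q%03d", seq_len(cfg$n_queries)) else character(0)

  n_true <- round(cfg$true_sensitive_fraction * cfg$n_queries)
  query_true <- .with_seed(seeds[2], {
    lab <- rep("resistant", cfg$n_queries)
    if (n_true > 0) lab[sample.int(cfg$n_queries, n_true)] <- "sensitive"
    lab
  })

  samples <- data.frame(
    sample_id = c(line_ids, pdx_ids, query_ids),
    type = c(rep("cell_line", length(line_ids)), rep("pdx", length(pdx_ids)),
             rep("query", length(query_ids))),
    true_category = c(line_cat, rep("sensitive", length(pdx_ids)), query_true),
    stringsAsFactors = FALSE
  )
  samples$supervision_class <- ifelse(samples$true_category == "sensitive",
                                      "sensitive", "other")

  sens_flag <- samples$true_category == "sensitive"
  n_samples <- nrow(samples)

  ## ---- methylation ----
  beta_panel <- beta_queries <- NULL
  planted_sign <- rep(NA_integer_, cfg$n_probes)
  mu_m <- dm <- NULL
  meth <- .with_seed(seeds[3], {
    comp <- sample(1:3, cfg$n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    mu <- c(-2.5, 2.5, 0)[comp] + stats::rnorm(cfg$n_probes, 0, c(0.8, 0.8, 1)[comp])
    dmv <- numeric(cfg$n_probes)
    if (length(layout$planted)) {
      s <- sample(c(-1L, 1L), length(layout$planted), replace = TRUE)
      planted_sign[layout$planted] <- s
      b0 <- ifelse(s > 0,
                   stats::runif(length(s), 0.08, 0.92 - cfg$delta_beta),
                   stats::runif(length(s), 0.08 + cfg$delta_beta, 0.92))
      b1 <- b0 + s * cfg$delta_beta
      mu[layout$planted] <- beta_to_m(b0)
      dmv[layout$planted] <- beta_to_m(b1) - beta_to_m(b0)
    }
    sigma2 <- cfg$d0 * cfg$s0_sq / stats::rchisq(cfg$n_probes, cfg$d0)
    noise <- matrix(stats::rnorm(cfg$n_probes * n_samples, 0, sqrt(sigma2)),
                    nrow = cfg$n_probes, ncol = n_samples)
    M <- mu + outer(dmv, as.numeric(sens_flag)) + noise
    B <- m_to_beta(M)
    dimnames(B) <- list(layout$probe_ids, samples$sample_id)
    list(B = B, mu = mu, dm = dmv, M = M)
  })
  mu_m <- meth$mu; dm <- meth$dm
  is_query <- samples$type == "query"
  if ("meth" %in% components) {
    beta_panel <- meth$B[, !is_query, drop = FALSE]
    beta_queries <- meth$B[, is_query, drop = FALSE]
  }

  ## ---- expression (panel cell lines, paired arms) ----
  expr_control <- expr_treated <- NULL
  if ("expr" %in% components && length(line_ids) > 0) {
    line_sens <- sens_flag[samples$type == "cell_line"]
    M_lines <- meth$M[, samples$type == "cell_line", drop = FALSE]
    expr <- .with_seed(seeds[4], {
      a <- stats::rnorm(cfg$n_genes, 7, 1.5)
      sign_b <- sample(c(-1, 1), cfg$n_genes, replace = TRUE)
      sign_i <- sample(c(-1, 1), cfg$n_genes, replace = TRUE)
      nl <- length(line_ids)
      base_eff <- matrix(0, cfg$n_genes, nl)
      base_extra <- setdiff(layout$de_base, layout$coupled_genes)
      base_eff[base_extra, line_sens] <- cfg$de_log2fc * sign_b[base_extra]
      ctl <- a + base_eff + matrix(stats::rnorm(cfg$n_genes * nl, 0, 0.25),
                                   cfg$n_genes, nl)
      trt <- a + base_eff + matrix(stats::rnorm(cfg$n_genes * nl, 0, 0.25),
                                   cfg$n_genes, nl)
      # coupled genes: expression is a decreasing function of the
      # probe's M-value across the panel (negative monotone coupling)
      if (cfg$n_coupled > 0) {
        for (k in seq_len(cfg$n_coupled)) {
          g <- layout$coupled_genes[k]; p <- layout$coupled_probes[k]
          slope <- -cfg$de_log2fc / abs(dm[p])
          centered <- M_lines[p, ] - mean(M_lines[p, ])
          ctl[g, ] <- a[g] + slope * centered + stats::rnorm(nl, 0, 0.15)
          trt[g, ] <- a[g] + slope * centered + stats::rnorm(nl, 0, 0.15)
        }
      }
      ind_eff <- matrix(0, cfg$n_genes, nl)
      ind_eff[layout$de_ind, line_sens] <- cfg$de_log2fc * sign_i[layout$de_ind]
      trt <- trt + ind_eff
      dimnames(ctl) <- dimnames(trt) <- list(gene_ids, line_ids)
      list(ctl = ctl, trt = trt)
    })
    expr_control <- expr$ctl
    expr_treated <- expr$trt
  }

  ## ---- growth ----
  growth <- NULL
  if ("growth" %in% components) {
    model_ids <- c(line_ids, pdx_ids)
    cat_eff <- c(sensitive = cfg$sensitive_fc, resistant = cfg$resistant_fc,
                 promoted = cfg$promoted_fc)
    effects <- cat_eff[samples$true_category[match(model_ids, samples$sample_id)]]
    names(effects) <- model_ids
    growth <- generate_growth(model_ids, cfg$mice_per_arm, effects,
                              seed = seeds[5], sdlog = cfg$growth_sdlog)
  }

  ## ---- toy genome with planted response elements ----
  genome <- NULL
  motif_genes <- character(0)
  if ("genome" %in% components) {
    gen <- .with_seed(seeds[6], {
      seqs <- lapply(chrom_len, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                     prob = c(0.295, 0.205, 0.205, 0.295)), collapse = "")
      })
      dna <- Biostrings::DNAStringSet(unlist(seqs))
      names(dna) <- names(chrom_len)
      dna <- .scrub_incidental_motifs(dna)
      n_motif <- round(cfg$motif_gene_fraction * cfg$n_genes)
      mg <- if (n_motif > 0) sort(sample.int(cfg$n_genes, n_motif)) else integer(0)
      for (gi in mg) {
        g <- genes[gi, ]
        spacer <- sample(c(1, 2, 5), 1)
        motif <- paste0(paste(.iupac_realize("RGKTCA"), collapse = ""),
                        paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
                              collapse = ""),
                        paste(.iupac_realize("RGKTCA"), collapse = ""))
        if (sample(c(TRUE, FALSE), 1)) {
          motif <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        }
        len <- nchar(motif)
        at0 <- g$start + sample.int(max(1, g$end - g$start - len), 1)
        Biostrings::subseq(dna[[g$chrom]], start = at0 + 1, width = len) <-
          Biostrings::DNAString(motif)
      }
      list(dna = dna, motif_genes = genes$gene_id[mg])
    })
    genome <- gen$dna
    motif_genes <- gen$motif_genes
  }

  truth <- list(
    planted_dmp_ids = layout$probe_ids[layout$planted],
    planted_dmp_sign = planted_sign[layout$planted],
    planted_de_baseline_ids = gene_ids[layout$de_base],
    planted_de_induced_ids = gene_ids[layout$de_ind],
    coupled_pairs = data.frame(
      probe_id = layout$probe_ids[layout$coupled_probes],
      gene_id = gene_ids[layout$coupled_genes],
      stringsAsFactors = FALSE),
    blacklisted_planted_ids = layout$probe_ids[layout$black_planted],
    sample_truth = samples,
    motif_genes = motif_genes
  )

  structure(list(
    config = cfg, samples = samples,
    beta_panel = beta_panel, beta_queries = beta_queries,
    expr_control = expr_control, expr_treated = expr_treated,
    growth = growth, manifest = manifest, genes = genes, islands = islands,
    genome = genome, truth = truth
  ), class = "ra_cohort")
}

# disrupt every incidental direct-repeat (DR1/DR2/DR5) half-site pair
# in the random background so planted motifs are the only ones present
.scrub_incidental_motifs <- function(dna) {
  spec <- motif_spec("RARE")
  for (iter in 1:12) {
    hits <- scan_motifs(dna, spec)
    if (nrow(hits) == 0) return(dna)
    for (ch in unique(hits$chrom)) {
      # 0-based offset 4 of the leftmost half-site is an invariant 'C'
      # on both strands (RGKTCA / its reverse complement TGAMCY);
      # replacing it with 'A' disrupts the match
      at <- unique(hits$start[hits$chrom == ch] + 5L)  # 1-based
      for (p in at) {
        Biostrings::subseq(dna[[ch]], start = p, width = 1) <- Biostrings::DNAString("A")
      }
    }
  }
  hits <- scan_motifs(dna, spec)
  if (nrow(hits) > 0) stop("failed to scrub incidental motifs from background")
  dna
}

#' @export
print.ra_cohort <- function(x, ...) {
  cat("Synthetic atRA-sensitivity cohort\n")
  cat(sprintf("  probes: %d  genes: %d\n", x$config$n_probes, x$config$n_genes))
  cat(sprintf("  panel: %d samples  queries: %d\n",
              sum(x$samples$type != "query"), sum(x$samples$type == "query")))
  cat(sprintf("  planted DMPs: %d (delta_beta = %.2f)\n",
              length(x$truth$planted_dmp_ids), x$config$delta_beta))
  invisible(x)
}
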