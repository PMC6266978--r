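# Probe filtering, DMP discovery, island annotation, gene mapping,
# Venn intersection, methylation-expression correlation

test_that("beta/M transforms round-trip within 1e-12", {
  b <- c(1e-6, 1e-4, 0.25, 0.5, 0.75, 1 - 1e-4, 1 - 1e-6)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  set.seed(41)
  b2 <- matrix(runif(200, 1e-6, 1 - 1e-6), 20, 10)
  expect_equal(m_to_beta(beta_to_m(b2)), b2, tolerance = 1e-12)
  expect_error(beta_to_m(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("probe filtering drops exactly the blacklist and validates ids", {
  set.seed(42)
  beta <- matrix(runif(50), 10, 5,
                 dimnames = list(sprintf("cg%02d", 1:10), sprintf("s%d", 1:5)))
  man <- data.frame(probe_id = sprintf("cg%02d", 1:10),
                    blacklist = c(rep(FALSE, 7), rep(TRUE, 3)))
  expect_message(out <- filter_probes(beta, man), "3 blacklisted")
  expect_equal(nrow(out), 7)
  expect_false(any(man$probe_id[man$blacklist] %in% rownames(out)))
  man0 <- man; man0$blacklist <- FALSE
  expect_message(same <- filter_probes(beta, man0))
  expect_identical(same, beta)
  expect_error(filter_probes(beta, man[-1, ]), "cg01")
})

test_that("unmoderated DMP p-values equal the brute-force t oracle", {
  set.seed(43)
  beta <- matrix(runif(20 * 8, 0.1, 0.9), 20, 8,
                 dimnames = list(sprintf("cg%02d", 1:20), sprintf("s%d", 1:8)))
  cl <- rep(c("sensitive", "other"), each = 4)
  res <- differential_methylation(beta, cl, moderated = FALSE)
  res <- res[match(rownames(beta), res$probe_id), ]
  m <- beta_to_m(beta)
  for (i in 1:20) {
    o <- oracle_pooled_t(m[i, 1:4], m[i, 5:8])
    expect_equal(res$p_value[i], o$p, tolerance = 1e-10)
    expect_equal(res$delta_beta[i],
                 mean(beta[i, 1:4]) - mean(beta[i, 5:8]), tolerance = 1e-12)
  }
})

test_that("DMP results are column-permutation invariant and sign-flip on label swap", {
  set.seed(44)
  beta <- matrix(runif(30 * 10, 0.05, 0.95), 30, 10,
                 dimnames = list(sprintf("cg%02d", 1:30), sprintf("s%d", 1:10)))
  cl <- rep(c("sensitive", "other"), each = 5)
  r1 <- differential_methylation(beta, cl)
  perm <- sample(10)
  r2 <- differential_methylation(beta[, perm], cl[perm])
  expect_equal(r1, r2)
  flipped <- ifelse(cl == "sensitive", "other", "sensitive")
  r3 <- differential_methylation(beta, flipped)
  r3 <- r3[match(r1$probe_id, r3$probe_id), ]
  expect_equal(r1$delta_beta, -r3$delta_beta, tolerance = 1e-12)
  expect_equal(r1$p_value, r3$p_value, tolerance = 1e-12)
})

test_that("BH q-values match the reference step-up and are monotone in p-rank", {
  set.seed(45)
  p <- runif(200)^2
  q <- p.adjust(p, method = "BH")
  expect_equal(q, ref_bh(p), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("island relations follow the boundary rules and match the brute-force scan", {
  islands <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  # inside (1-based span is [10001, 11000])
  expect_equal(island_relation("chr1", 10500, islands), "island")
  expect_equal(island_relation("chr1", 10001, islands), "island")
  expect_equal(island_relation("chr1", 11000, islands), "island")
  # 1 bp off either edge -> shore, with north/south sides
  expect_equal(island_relation("chr1", 10000, islands), "n_shore")
  expect_equal(island_relation("chr1", 11001, islands), "s_shore")
  # exactly 2000 bp from an edge -> shelf (half-open shore)
  expect_equal(island_relation("chr1", 11000 + 2000, islands), "s_shelf")
  expect_equal(island_relation("chr1", 10001 - 2000, islands), "n_shelf")
  expect_equal(island_relation("chr1", 11000 + 1999, islands), "s_shore")
  # exactly 4000 bp -> open sea
  expect_equal(island_relation("chr1", 11000 + 4000, islands), "open_sea")
  expect_equal(island_relation("chr2", 10500, islands), "open_sea")

  set.seed(46)
  isl <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                    start = sample.int(2e5, 30))
  isl$end <- isl$start + sample(200:1500, 30, TRUE)
  chrom <- sample(c("chr1", "chr2"), 1000, TRUE)
  pos <- sample.int(210000, 1000)
  expect_equal(island_relation(chrom, pos, isl),
               oracle_island_relation(chrom, pos, isl))
})

test_that("island-context frequencies sum to one for DMPs and background", {
  cfg <- synthetic_config(n_probes = 1000, n_planted_dmp = 20, n_coupled = 5,
                          n_planted_de = 10, seed = 47)
  coh <- generate_cohort(cfg, components = "meth")
  ann <- annotate_island_context(coh$truth$planted_dmp_ids, coh$manifest,
                                 coh$islands)
  expect_equal(sum(ann$frequency$dmp_freq), 1, tolerance = 1e-12)
  expect_equal(sum(ann$frequency$background_freq), 1, tolerance = 1e-12)
  # manifest island_relation agrees with the annotation machinery
  expect_equal(unname(ann$relation),
               coh$manifest$island_relation[match(coh$truth$planted_dmp_ids,
                                                  coh$manifest$probe_id)])
  expect_error(annotate_island_context("cgXXXX", coh$manifest, coh$islands),
               "absent")
})

test_that("probe-to-gene mapping uses union semantics", {
  man <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene = c("GA;GB", "GB", "", "GC"))
  expect_equal(probes_to_genes(c("p1", "p2"), man), c("GA", "GB"))
  expect_equal(probes_to_genes("p3", man), character(0))
  expect_equal(probes_to_genes(c("p1", "p2", "p3", "p4"), man),
               c("GA", "GB", "GC"))
  # random manifest vs flatten-and-unique oracle
  set.seed(48)
  genes <- sprintf("G%02d", 1:20)
  man2 <- data.frame(
    probe_id = sprintf("p%03d", 1:100),
    gene = vapply(1:100, function(i) {
      paste(sample(genes, sample(0:2, 1)), collapse = ";")
    }, character(1)))
  pick <- sample(man2$probe_id, 40)
  want <- sort(unique(unlist(strsplit(man2$gene[match(pick, man2$probe_id)], ";"))))
  want <- want[nzchar(want)]
  expect_equal(probes_to_genes(pick, man2), want)
})

test_that("three-way gene-set intersection enumerates all Venn regions", {
  r0 <- intersect_gene_sets(c("g1"), c("g2"), c("g3"))
  expect_equal(length(r0$triple), 0)
  r <- intersect_gene_sets(c("g1", "g2", "g3"), c("g2", "g3"), c("g3"))
  expect_equal(r$triple, "g3")
  expect_equal(unname(r$counts),
               c(1L, 0L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(sum(r$counts), 3)
})

test_that("coupled planted pairs surface in the triple intersection", {
  cfg <- synthetic_config(n_probes = 2000, n_genes = 300, n_planted_dmp = 60,
                          n_planted_de = 40, n_coupled = 17, seed = 49)
  coh <- generate_cohort(cfg, components = c("meth", "expr"))
  lines <- coh$samples$type == "cell_line"
  ids <- coh$samples$sample_id[lines]
  cl <- coh$samples$supervision_class[lines]
  beta <- filter_probes(coh$beta_panel, coh$manifest)
  dmp <- differential_methylation(beta[, ids], cl)
  dm_genes <- probes_to_genes(dmp$probe_id[dmp$significant], coh$manifest)
  de_b <- differential_expression(coh$expr_control, cl, "baseline")
  de_i <- differential_expression(coh$expr_control, cl, "induced",
                                  expr_treated = coh$expr_treated)
  venn <- intersect_gene_sets(dm_genes,
                              de_b$feature[de_b$passes_cutoff],
                              de_i$feature[de_i$passes_cutoff])
  coupled <- coh$truth$coupled_pairs$gene_id
  expect_gte(mean(coupled %in% venn$triple), 0.8)
})

test_that("Spearman correlation handles monotone, degenerate and random pairs", {
  set.seed(50)
  n <- 8
  beta <- matrix(runif(2 * n, 0.1, 0.9), 2, n,
                 dimnames = list(c("cg1", "cg2"), sprintf("s%d", 1:n)))
  expr <- rbind(gA = -beta["cg1", ], gB = rnorm(n))
  colnames(expr) <- colnames(beta)
  # expression = -beta exactly -> rho = -1
  r <- methylation_expression_correlation(beta, expr,
                                          data.frame(probe_id = "cg1",
                                                     gene_id = "gA"))
  expect_equal(r$rho, -1)
  # constant beta -> NA with a note
  beta2 <- beta; beta2["cg2", ] <- 0.5
  r2 <- methylation_expression_correlation(beta2, expr,
                                           data.frame(probe_id = "cg2",
                                                      gene_id = "gB"))
  expect_true(is.na(r2$rho))
  expect_match(r2$note, "degenerate")
  # n = 8 random pair: rho equals rank formula, p equals permutation oracle
  r3 <- methylation_expression_correlation(beta, expr,
                                           data.frame(probe_id = "cg2",
                                                      gene_id = "gB"))
  rx <- rank(beta["cg2", ]); ry <- rank(expr["gB", ])
  expect_equal(r3$rho, cor(rx, ry), tolerance = 1e-12)
  expect_equal(r3$p_value, oracle_spearman_p(beta["cg2", ], expr["gB", ]),
               tolerance = 1e-10)
  # too few shared samples errors
  expect_error(methylation_expression_correlation(
    beta[, 1:3], expr[, 1:3],
    data.frame(probe_id = "cg1", gene_id = "gA")), "4 shared")
})
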