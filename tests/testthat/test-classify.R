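# Signature building and per-sample reference-panel classification

test_that("harmonization is exactly set intersection with order preserved", {
  a <- sprintf("p%02d", 1:10)
  b <- sprintf("p%02d", 4:12)
  cand <- c("p09", "p02", "p05", "p11")
  expect_equal(harmonize_probes(a, b, cand), c("p09", "p05"))
  expect_equal(harmonize_probes(a, a, a), a)
  # random membership flags vs direct intersection
  set.seed(71)
  for (i in 1:20) {
    pa <- sample(a, 6); pb <- sample(a, 6); cc <- sample(a, 7)
    got <- tryCatch(harmonize_probes(pa, pb, cc), error = function(e) character(0))
    expect_equal(got, cc[cc %in% intersect(pa, pb)])
  }
  expect_error(harmonize_probes("x", "y", "z"), "both platforms")
})

test_that("refinement ranks a perfectly separating probe first and flags short panels", {
  set.seed(72)
  beta <- matrix(runif(10 * 10, 0.4, 0.6), 10, 10,
                 dimnames = list(sprintf("cg%02d", 1:10), sprintf("s%d", 1:10)))
  labels <- rep(c("sensitive", "other"), each = 5)
  beta["cg07", ] <- c(rep(0.9, 5), rep(0.1, 5)) + runif(10, 0, 0.01)
  sig <- suppressWarnings(refine_signature(beta, labels, p_threshold = 0.05,
                                           k = 3))
  expect_equal(sig$probes[1], "cg07")
  expect_warning(
    sig2 <- refine_signature(beta, labels, p_threshold = 1e-6, k = 6),
    "probe")
  expect_true(sig2$warning_flag)
  expect_lt(length(sig2$probes), 6)
  # nothing passing is an error
  beta0 <- matrix(runif(40, 0.45, 0.55), 4, 10,
                  dimnames = list(sprintf("cg9%d", 1:4), sprintf("s%d", 1:10)))
  expect_error(refine_signature(beta0, labels, p_threshold = 1e-12),
               "impossible|no probe")
})

test_that("dendrograms match hand agglomeration and the brute-force oracle", {
  # 1-D points 0,1,2,10,11 with euclidean/complete:
  # (0,1)@1, (10,11)@1, 2 joins (0,1)@2, root @ 11
  m <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
  rownames(m) <- letters[1:5]
  hc <- cluster_panel(m, "euclidean", "complete")
  expect_equal(sort(hc$height), c(1, 1, 2, 11))
  coph <- as.matrix(cophenetic(hc))
  expect_equal(coph["a", "b"], 1)
  expect_equal(coph["a", "c"], 2)
  expect_equal(coph["d", "e"], 1)
  expect_equal(coph["a", "d"], 11)
  # identical rows merge at height 0
  m2 <- rbind(x = c(1, 2), y = c(1, 2), z = c(5, 5))
  expect_equal(min(cluster_panel(m2, "euclidean", "complete")$height), 0)
  # random matrices vs the naive agglomerator
  set.seed(73)
  for (link in c("complete", "average")) {
    for (i in 1:8) {
      n <- sample(4:7, 1)
      mm <- matrix(rnorm(n * 3), n, 3)
      rownames(mm) <- paste0("r", seq_len(n))
      got <- as.matrix(cophenetic(cluster_panel(mm, "euclidean", link)))
      want <- oracle_cophenetic(mm, link)
      dimnames(want) <- dimnames(got)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  expect_error(cluster_panel(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("a query duplicating a sensitive reference is called predicted-sensitive", {
  ts <- toy_signature()
  q <- ts$model$reference_beta[, "S1"]
  r <- classify_sample(q, ts$model)
  expect_equal(r$category, "predicted-sensitive")
  expect_true("S1" %in% r$cluster_members)
  # and a resistant-side duplicate is resistant
  r2 <- classify_sample(ts$model$reference_beta[, "O2"], ts$model)
  expect_equal(r2$category, "resistant")
})

test_that("a query joining a mixed cluster first is ambiguous", {
  # 2-D geometry: two tight reference pairs 1.02 apart on the first
  # axis; the query sits between them but far off-axis, so the two
  # reference clusters merge (height 1.02) before the query joins the
  # root -> its smallest enclosing cluster is the full mixed panel
  ref <- rbind(cg1 = c(0.00, 0.02, 1.00, 1.02),
               cg2 = c(0, 0, 0, 0))
  colnames(ref) <- c("O1", "O2", "S1", "S2")
  model <- structure(list(
    probes = c("cg1", "cg2"), reference_beta = ref,
    reference_labels = setNames(c("other", "other", "sensitive", "sensitive"),
                                colnames(ref)),
    sample_type = NULL, distance = "euclidean", linkage = "complete",
    refinement = list(), warning_flag = FALSE), class = "ra_signature")
  r <- classify_sample(c(cg1 = 0.51, cg2 = 0.9), model)
  expect_equal(r$category, "ambiguous")
  expect_setequal(r$cluster_members, colnames(ref))
})

test_that("classification is probe-order invariant and deterministic", {
  ts <- toy_signature(k = 5)
  set.seed(74)
  q <- ts$model$reference_beta[, "S2"] + rnorm(5, 0, 0.01)
  r1 <- classify_sample(q, ts$model)
  r2 <- classify_sample(q[rev(names(q))], ts$model)
  expect_equal(r1$category, r2$category)
  expect_equal(r1$height, r2$height)
  expect_identical(classify_sample(q, ts$model), r1)
  expect_error(classify_sample(q[-1], ts$model), "lacks")
})

test_that("a constant reference panel always yields ambiguous", {
  ref <- matrix(0.5, 3, 6,
                dimnames = list(sprintf("cg%d", 1:3),
                                c("S1", "S2", "S3", "O1", "O2", "O3")))
  model <- structure(list(
    probes = rownames(ref), reference_beta = ref,
    reference_labels = setNames(rep(c("sensitive", "other"), each = 3),
                                colnames(ref)),
    sample_type = NULL, distance = "euclidean", linkage = "complete",
    refinement = list(), warning_flag = FALSE), class = "ra_signature")
  set.seed(75)
  for (i in 1:5) {
    q <- setNames(runif(3), rownames(ref))
    expect_equal(classify_sample(q, model)$category, "ambiguous")
  }
})

test_that("an all-sensitive panel never produces a resistant call", {
  set.seed(76)
  ref <- matrix(runif(4 * 5, 0.2, 0.8), 4, 5,
                dimnames = list(sprintf("cg%d", 1:4), sprintf("S%d", 1:5)))
  model <- structure(list(
    probes = rownames(ref), reference_beta = ref,
    reference_labels = setNames(rep("sensitive", 5), colnames(ref)),
    sample_type = NULL, distance = "euclidean", linkage = "complete",
    refinement = list(), warning_flag = FALSE), class = "ra_signature")
  for (i in 1:10) {
    q <- setNames(runif(4), rownames(ref))
    expect_true(classify_sample(q, model)$category %in%
                  c("predicted-sensitive", "ambiguous"))
  }
})

test_that("the centroid rule distinguishes clear and marginal queries", {
  ts <- toy_signature(k = 4, delta = 0.4, sd = 0.01)
  qs <- ts$base + ts$delta
  names(qs) <- ts$model$probes
  expect_equal(classify_sample(qs, ts$model, rule = "centroid")$category,
               "predicted-sensitive")
  qo <- ts$base; names(qo) <- ts$model$probes
  expect_equal(classify_sample(qo, ts$model, rule = "centroid")$category,
               "resistant")
  qm <- ts$base + ts$delta / 2; names(qm) <- ts$model$probes
  expect_equal(classify_sample(qm, ts$model, rule = "centroid")$category,
               "ambiguous")
})

test_that("cohort summaries count and normalize correctly", {
  s0 <- cohort_summary(data.frame(category = character(0)))
  expect_equal(s0$count, c(0L, 0L, 0L))
  expect_true(all(is.na(s0$fraction)))
  res <- data.frame(category = rep(c("predicted-sensitive", "resistant"),
                                   c(12, 58)))
  s <- cohort_summary(res)
  expect_equal(s$fraction[s$category == "predicted-sensitive"], 12 / 70,
               tolerance = 1e-12)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-12)
})

test_that("signature models survive a JSON round trip", {
  ts <- toy_signature()
  f <- tempfile(fileext = ".json")
  write_signature(ts$model, f)
  back <- read_signature(f)
  expect_equal(back$probes, ts$model$probes)
  expect_equal(back$reference_beta, ts$model$reference_beta,
               tolerance = 1e-12)
  expect_equal(back$reference_labels, ts$model$reference_labels)
  q <- ts$model$reference_beta[, "S1"]
  expect_equal(classify_sample(q, back)$category,
               classify_sample(q, ts$model)$category)
  unlink(f)
})

test_that("refinement machinery is consistent with DMP discovery under relabeling", {
  # with PDXs removed and the threshold fully loosened, refinement
  # ranks candidates exactly as the discovery-stage test does
  set.seed(77)
  beta <- matrix(runif(30 * 13, 0.1, 0.9), 30, 13,
                 dimnames = list(sprintf("cg%02d", 1:30), sprintf("s%d", 1:13)))
  labels <- rep(c("sensitive", "other"), c(5, 8))
  dmp <- differential_methylation(beta, labels, p_cutoff = 1)
  sig <- refine_signature(beta, labels, p_threshold = 1 + 1e-9, k = 30)
  expect_equal(sig$probes, dmp$probe_id)
})
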