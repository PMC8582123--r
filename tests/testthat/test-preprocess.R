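test_that("normexp correction matches the convolution-model conditional mean", {
  # fixed parameters, closed form vs numeric quadrature
  mu <- 100; sigma <- 10; alpha <- 1000
  for (x in c(90, 110, 150, 500)) {
    cf <- limma::normexp.signal(c(mu, log(sigma), log(alpha)), x)
    expect_equal(cf, oracle_normexp_signal(mu, sigma, alpha, x),
                 tolerance = 1e-6)
  }
  # asymptotically, corrected ~ observed - background mean
  big <- 1e5
  cf <- limma::normexp.signal(c(mu, log(sigma), log(alpha)), big)
  expect_equal(cf, big - mu, tolerance = 1e-2)
})

test_that("normexp corrections are positive, monotone, and robust to degenerate columns", {
  set.seed(42)
  vals <- matrix(rexp(200, 1 / 500) + rnorm(200, 100, 10), 100, 2,
                 dimnames = list(sprintf("p%03d", 1:100), c("s1", "s2")))
  vals <- pmax(vals, 0)
  em <- expression_matrix(vals, "AG", "raw")
  out <- normexp_background_correct(em)
  expect_true(all(out$values > 0))
  for (j in 1:2) {
    ord <- order(vals[, j])
    expect_true(all(diff(out$values[ord, j]) >= -1e-9))
  }
  # negative-control moment estimation path
  nc <- rownames(vals)[1:10]
  vals[nc, ] <- matrix(rnorm(20, 100, 10), 10, 2)
  em <- expression_matrix(pmax(vals, 0), "AG", "raw")
  out <- normexp_background_correct(em, negative_control_probes = nc)
  expect_true(all(out$values > 0))
  # all-equal column falls back with a warning and stays positive
  flat <- matrix(5, 10, 1, dimnames = list(sprintf("p%d", 1:10), "s1"))
  expect_warning(
    outf <- normexp_background_correct(expression_matrix(flat, "AG", "raw")),
    "degenerate")
  expect_true(all(outf$values > 0))
})

test_that("cyclic loess removes constant offsets and leaves identical columns alone", {
  set.seed(7)
  base <- rnorm(400, 10, 1.5)
  vals <- cbind(s1 = base, s2 = base)
  rownames(vals) <- sprintf("p%03d", seq_along(base))
  em <- expression_matrix(vals, "AG", "log2")
  out <- cyclic_loess_normalize(em, method = "pairs")
  expect_equal(out$values, vals, tolerance = 1e-8)

  vals2 <- cbind(s1 = base, s2 = base + 1)
  rownames(vals2) <- rownames(vals)
  out2 <- cyclic_loess_normalize(expression_matrix(vals2, "AG", "log2"),
                                 method = "pairs")
  offset_left <- median(out2$values[, 2] - out2$values[, 1])
  expect_lt(abs(offset_left), 0.05)

  expect_warning(
    cyclic_loess_normalize(
      expression_matrix(vals[, 1, drop = FALSE], "AG", "log2")),
    "single sample")
})

test_that("cyclic loess flattens a planted intensity-dependent distortion", {
  set.seed(8)
  base <- runif(600, 8, 14)
  amp <- 0.5
  distort <- amp * sin((base - 8) / 6 * pi)
  vals <- cbind(s1 = base + rnorm(600, 0, 0.05),
                s2 = base + distort + rnorm(600, 0, 0.05))
  rownames(vals) <- sprintf("p%03d", seq_len(600))
  out <- cyclic_loess_normalize(expression_matrix(vals, "AG", "log2"),
                                method = "pairs")
  M <- out$values[, 2] - out$values[, 1]
  A <- rowMeans(out$values)
  trend <- lowess(A, M, f = 0.4)
  expect_lt(max(abs(trend$y)), 0.1 * amp)
})

test_that("quantile normalization equalizes distributions and matches brute force", {
  # permuted columns end up identical after sorting
  set.seed(9)
  v <- sort(runif(50, 10, 1000))
  vals <- cbind(s1 = sample(v), s2 = sample(v), s3 = sample(v))
  rownames(vals) <- sprintf("p%02d", 1:50)
  out <- quantile_normalize_with_offset(
    expression_matrix(vals, "IL", "raw"), offset = 16)
  sorted <- apply(out$values, 2, sort)
  expect_equal(sorted[, 1], sorted[, 2], tolerance = 1e-12)
  expect_equal(sorted[, 1], sorted[, 3], tolerance = 1e-12)

  # 3x3 grid against the hand-computed average-quantile mapping
  g <- matrix(c(2, 6, 4,   9, 1, 5,   3, 8, 7), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("a", "b", "c")))
  out3 <- quantile_normalize_with_offset(
    expression_matrix(g, "IL", "raw"), offset = 0)
  ranks <- apply(g, 2, rank)
  avg_q <- rowMeans(apply(g, 2, sort))
  expected <- log2(matrix(avg_q[ranks], 3, 3, dimnames = dimnames(g)))
  expect_equal(out3$values, expected, tolerance = 1e-12)

  # single column: log2(x + offset) only
  one <- quantile_normalize_with_offset(
    expression_matrix(g[, 1, drop = FALSE], "IL", "raw"), offset = 16)
  expect_equal(one$values, log2(g[, 1, drop = FALSE] + 16))
  expect_error(
    quantile_normalize_with_offset(
      expression_matrix(g, "IL", "log2")), "raw")
})

test_that("batch adjustment without shrinkage removes planted shifts exactly", {
  set.seed(10)
  n_probe <- 50
  vals <- matrix(rnorm(n_probe * 12, 10, 1), n_probe, 12,
                 dimnames = list(sprintf("p%02d", 1:n_probe),
                                 sprintf("s%02d", 1:12)))
  batch <- rep(c("b1", "b2"), each = 6)
  shifted <- vals
  shifted[, batch == "b1"] <- shifted[, batch == "b1"] - 0.8
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 0.8
  em <- expression_matrix(shifted, "AG", "log2")
  adj <- combat_adjust(em, setNames(batch, colnames(vals)),
                       parametric_eb = FALSE)
  m1 <- rowMeans(adj$values[, batch == "b1"])
  m2 <- rowMeans(adj$values[, batch == "b2"])
  expect_lt(max(abs(m1 - m2)), 1e-6)
  # single batch is the identity
  one <- combat_adjust(em, setNames(rep("b1", 12), colnames(vals)))
  expect_equal(one$values, shifted)
  # batch of size one is an error naming the batch
  expect_error(
    combat_adjust(em, setNames(c("solo", batch[-1]), colnames(vals))),
    "solo")
})

test_that("EB batch adjustment removes planted shifts and matches sva closely", {
  set.seed(11)
  n_probe <- 500
  vals <- matrix(rnorm(n_probe * 18, 10, 1), n_probe, 18,
                 dimnames = list(sprintf("p%03d", 1:n_probe),
                                 sprintf("s%02d", 1:18)))
  batch <- rep(c("b1", "b2", "b3"), each = 6)
  vals[, batch == "b1"] <- vals[, batch == "b1"] - 0.8
  vals[, batch == "b3"] <- vals[, batch == "b3"] + 0.8
  em <- expression_matrix(vals, "AG", "log2")
  adj <- combat_adjust(em, setNames(batch, colnames(vals)),
                       parametric_eb = TRUE)
  # the systematic (across-probe average) batch shift is removed; per-probe
  # batch means retain only irreducible within-batch sampling noise
  for (b in unique(batch)) {
    resid <- rowMeans(adj$values[, batch == b]) - rowMeans(adj$values)
    expect_lt(abs(mean(resid)), 0.05)
  }
  ref <- suppressMessages(sva::ComBat(vals, batch = batch))
  expect_lt(max(abs(adj$values - ref)), 0.01)
})

test_that("hierarchical batch combination adjusts within parts first", {
  set.seed(12)
  vals <- matrix(rnorm(40 * 16, 10, 1), 40, 16,
                 dimnames = list(sprintf("p%02d", 1:40),
                                 sprintf("s%02d", 1:16)))
  batch <- rep(c("b1", "b2", "b3", "b4"), each = 4)
  part <- rep(c("I", "II"), each = 8)
  for (b in unique(batch))
    vals[, batch == b] <- vals[, batch == b] +
      c(b1 = -0.6, b2 = 0.2, b3 = 0.5, b4 = -0.3)[b]
  adj <- combat_adjust(expression_matrix(vals, "AG", "log2"),
                       setNames(batch, colnames(vals)),
                       part = setNames(part, colnames(vals)),
                       parametric_eb = FALSE)
  grand <- rowMeans(adj$values)
  for (b in unique(batch))
    expect_lt(max(abs(rowMeans(adj$values[, batch == b]) - grand)), 1e-6)
})

test_that("flooring truncates, translates, detects, and is idempotent", {
  vals <- matrix(c(10, 5, 8, 12, 3, 9), 3, 2,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  em <- expression_matrix(vals, "AG", "log2")
  fl <- truncate_translate(em, 8)
  expect_equal(fl$values[, 1], c(p1 = 2, p2 = 0, p3 = 0))
  expect_equal(fl$values[, 2], c(p1 = 4, p2 = 0, p3 = 1))
  expect_identical(fl$scale, "floored_log2")
  expect_true(all(fl$values >= 0))
  # idempotent: re-flooring a floored matrix is a no-op
  expect_identical(truncate_translate(fl, 8)$values, fl$values)
  # entire matrix under the floor: all zero, all undetected
  low <- expression_matrix(matrix(c(1, 2, 1.5, 2.5, 1, 2), 2, 3,
                                  dimnames = list(c("p1", "p2"),
                                                  c("s1", "s2", "s3"))),
                           "AG", "log2")
  fl2 <- truncate_translate(low, 8)
  expect_true(all(fl2$values == 0))
  st <- compute_probe_stats(fl2)
  expect_false(any(st$detected))
})

test_that("duplicate collapse averages probes, drops bad probes and repeats", {
  vals <- matrix(c(4, 6, 5, 7,
                   2, 2, 3, 3,
                   1, 1, 1, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(c("dup", "dup2", "bad"),
                                 sprintf("s%d", 1:4)))
  # duplicated probe id built in memory (allowed pre-collapse)
  rownames(vals) <- c("dup", "dup", "bad")
  em <- expression_matrix(vals, "P1", "log2", allow_duplicate_probes = TRUE)
  ann <- toy_annotation(c("dup", "bad"), c("G1", "G2"),
                        status = c("ok", "bad"))
  sheet <- toy_sheet(sprintf("s%d", 1:4), rep(c("A", "B"), each = 2))
  out <- collapse_duplicates(em, ann, sheet)
  expect_identical(rownames(out$matrix$values), "dup")
  expect_equal(out$matrix$values["dup", ], c(s1 = 3, s2 = 4, s3 = 4, s4 = 5))

  # no duplicates: identity on the ok probes
  em2 <- expression_matrix(vals[c(1, 3), ], "P1", "log2",
                           allow_duplicate_probes = TRUE)
  rownames(em2$values) <- c("dup", "bad")
  out2 <- collapse_duplicates(em2, ann, sheet)
  expect_equal(out2$matrix$values["dup", ], vals[1, ])

  # repeated QC sample dropped from matrix and sheet
  sheet$is_repeat <- c(FALSE, FALSE, FALSE, TRUE)
  out3 <- collapse_duplicates(em, ann, sheet)
  expect_false("s4" %in% colnames(out3$matrix$values))
  expect_false("s4" %in% out3$sheet$sample_id)
})

test_that("gene panel profiles geometric-mean probes then median-center samples", {
  vals <- matrix(c(2, 4, 6,
                   4, 6, 8,
                   1, 2, 3,
                   5, 5, 5), nrow = 4, byrow = TRUE,
                 dimnames = list(c("g1p1", "g1p2", "g2p1", "g3p1"),
                                 c("s1", "s2", "s3")))
  ann <- toy_annotation(c("g1p1", "g1p2", "g2p1", "g3p1"),
                        c("G1", "G1", "G2", "G3"))
  prof <- gene_panel_profile(expression_matrix(vals, "P1", "log2"), ann)
  # brute force: per-gene probe means, then subtract per-sample median
  raw <- rbind(G1 = colMeans(vals[1:2, ]), G2 = vals[3, ], G3 = vals[4, ])
  expected <- sweep(raw, 2, apply(raw, 2, median), `-`)
  expect_equal(prof, expected, tolerance = 1e-12)
  expect_equal(unname(apply(prof, 2, median)), c(0, 0, 0))
  # a gene with no measured probes is omitted with a warning
  ann2 <- toy_annotation(c("g1p1", "g1p2", "g2p1", "g3p1", "ghost"),
                         c("G1", "G1", "G2", "G3", "G4"))
  expect_warning(gene_panel_profile(
    expression_matrix(vals, "P1", "log2"), ann2), "G4")
})
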