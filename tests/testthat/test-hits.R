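test_that("baseline and MAD are the all-sample median and median absolute deviation", {
  vals <- matrix(c(1, 2, 3, 4, 100), 1, 5,
                 dimnames = list("p1", sprintf("s%d", 1:5)))
  st <- compute_probe_stats(toy_expr(vals))
  expect_equal(st$baseline, 3)
  expect_equal(st$mad, 1)
  expect_true(st$detected)
  # scaled variant
  st_s <- compute_probe_stats(toy_expr(vals), mad_scaled = TRUE)
  expect_equal(st_s$mad, 1.4826)
  # constant probe: degenerate
  cst <- matrix(2, 1, 5, dimnames = list("p1", sprintf("s%d", 1:5)))
  stc <- compute_probe_stats(toy_expr(cst))
  expect_equal(stc$mad, 0)
  expect_true(stc$degenerate)
  expect_error(compute_probe_stats(toy_expr(vals[, 1:2, drop = FALSE])),
               "3 samples")
})

test_that("vectorized statistics equal the scalar brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    nr <- sample(5:20, 1)
    nc <- sample(6:20, 1)
    vals <- matrix(round(abs(rnorm(nr * nc, 3, 2)), 3), nr, nc,
                   dimnames = list(sprintf("p%02d", seq_len(nr)),
                                   sprintf("s%02d", seq_len(nc))))
    em <- toy_expr(vals)
    st <- compute_probe_stats(em)
    orc <- oracle_probe_stats(vals)
    expect_equal(st$baseline, orc$baseline, tolerance = 1e-12)
    expect_equal(st$mad, orc$mad, tolerance = 1e-12)

    orfs <- rep(c("A", EMPTY_VECTOR), c(3, nc - 3))
    sheet <- toy_sheet(colnames(vals), orfs)
    rec <- score_orf(em, sheet, st, "A")
    orc_s <- oracle_score(vals, colnames(vals)[1:3], st$baseline, st$mad)
    expect_equal(rec$xbar, orc_s$xbar, tolerance = 1e-12)
    expect_equal(rec$deviation, orc_s$deviation, tolerance = 1e-12)
    expect_equal(rec$z, orc_s$z, tolerance = 1e-12)
    expect_identical(rec$probe_hit, orc_s$hit)
  }
})

test_that("the Z formula and double threshold behave as specified", {
  # reference distribution chosen so that with the ORF's own 3 samples at
  # 6.5 included (the baseline uses ALL samples) the median is exactly 5
  # and the MAD exactly 0.5
  ref <- c(4.4, 4.5, 4.6, 4.7, 4.75, 4.8, 5, 5, 5.5, 5.5, 5.6)
  vals <- matrix(c(ref, 6.5, 6.5, 6.5), 1,
                 dimnames = list("p1", sprintf("s%02d", 1:14)))
  em <- toy_expr(vals)
  sheet <- toy_sheet(colnames(vals), c(rep(EMPTY_VECTOR, 11), rep("A", 3)))
  st <- compute_probe_stats(em)
  rec <- score_orf(em, sheet, st, "A")
  expect_equal(st$baseline, 5)
  expect_equal(st$mad, 0.5)
  expect_equal(rec$deviation, 1.5)
  expect_equal(rec$z, 1.5 * sqrt(3) / 0.5, tolerance = 1e-12) # 5.196
  expect_true(rec$probe_hit)
  expect_error(score_orf(em, sheet, st, "NOPE"), "unknown ORF")

  # threshold logic on hand-made statistics: both criteria must hold
  mkstats <- function(b, mad) {
    st <- data.frame(probe_id = "p1", baseline = b, mad = mad,
                     detected = TRUE, degenerate = mad == 0,
                     stringsAsFactors = FALSE)
    class(st) <- c("probe_stats", "data.frame")
    st
  }
  score1 <- function(rep_val, b, mad) {
    vals <- matrix(rep(rep_val, 3), 1,
                   dimnames = list("p1", c("a1", "a2", "a3")))
    score_orf(toy_expr(vals), toy_sheet(c("a1", "a2", "a3"), rep("A", 3)),
              mkstats(b, mad), "A")
  }
  # deviation 0.9 with tiny MAD: Z huge but fold effect <= 2, NOT a hit
  r <- score1(5.9, b = 5, mad = 0.05)
  expect_equal(r$deviation, 0.9)
  expect_gt(abs(r$z), 10)
  expect_false(r$probe_hit)
  # deviation 1.2 with Z = 1.2*sqrt(3)/0.6 = 3.46 < 4, NOT a hit
  r2 <- score1(6.2, b = 5, mad = 0.6)
  expect_equal(r2$deviation, 1.2)
  expect_lt(abs(r2$z), 4)
  expect_false(r2$probe_hit)
})

test_that("raising one replicate never lowers that probe's Z (fixed baseline/MAD)", {
  set.seed(21)
  vals <- matrix(abs(rnorm(8 * 10, 4, 1)), 8, 10,
                 dimnames = list(sprintf("p%d", 1:8), sprintf("s%02d", 1:10)))
  em <- toy_expr(vals)
  sheet <- toy_sheet(colnames(vals), rep(c("A", EMPTY_VECTOR), c(3, 7)))
  st <- compute_probe_stats(em)
  z0 <- score_orf(em, sheet, st, "A")$z
  for (delta in c(0.1, 0.5, 2)) {
    vals2 <- vals
    vals2[3, 1] <- vals2[3, 1] + delta
    z1 <- score_orf(toy_expr(vals2), sheet, st, "A")$z
    expect_gte(z1[3], z0[3])
    expect_equal(z1[-3], z0[-3], tolerance = 1e-12)
  }
})

test_that("mirroring all values around the baseline swaps up and down counts", {
  set.seed(22)
  vals <- matrix(abs(rnorm(30 * 12, 6, 0.3)), 30, 12,
                 dimnames = list(sprintf("p%02d", 1:30),
                                 sprintf("s%02d", 1:12)))
  vals[1:6, 1:3] <- vals[1:6, 1:3] + 2    # up hits for A
  vals[7:10, 1:3] <- vals[7:10, 1:3] - 2.5 # down hits for A
  vals <- pmax(vals, 0)
  em <- toy_expr(vals)
  sheet <- toy_sheet(colnames(vals), rep(c("A", EMPTY_VECTOR), c(3, 9)))
  ann <- toy_annotation(rownames(vals), sprintf("G%02d", 1:30))
  st <- compute_probe_stats(em)
  rec <- score_orf(em, sheet, st, "A")
  hits <- call_gene_hits(rec, ann)
  # reflect around each probe's baseline: median and MAD invariant
  mirrored <- pmax(2 * st$baseline - vals, 0)
  stm <- compute_probe_stats(toy_expr(mirrored))
  expect_equal(stm$baseline, st$baseline, tolerance = 1e-12)
  expect_equal(stm$mad, st$mad, tolerance = 1e-12)
  recm <- score_orf(toy_expr(mirrored), sheet, stm, "A")
  hitsm <- call_gene_hits(recm, ann)
  a <- hits$orf_counts[hits$orf_counts$orf == "A", ]
  am <- hitsm$orf_counts[hitsm$orf_counts$orf == "A", ]
  expect_identical(a$n_genes_up, am$n_genes_down)
  expect_identical(a$n_genes_down, am$n_genes_up)
  expect_identical(a$n_genes_total, am$n_genes_total)
})

test_that("gene roll-up needs one hit probe and resolves directions by |deviation|", {
  rec <- data.frame(
    orf = "A", platform = "P1",
    probe_id = c("g1a", "g1b", "g2a", "g3a", "g3b"),
    n = 3,
    xbar = 0,
    deviation = c(2.0, 0.1, 0.3, -2.5, 1.8),
    z = c(10, 0.5, 1, -12, 9),
    detected = TRUE, degenerate = FALSE,
    probe_hit = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  class(rec) <- c("hit_records", "data.frame")
  ann <- toy_annotation(rec$probe_id, c("G1", "G1", "G2", "G3", "G3"))
  expect_message(hits <- call_gene_hits(rec, ann), "conflicting")
  gh <- hits$gene_hits
  expect_setequal(gh$gene, c("G1", "G3"))
  expect_identical(gh$direction[gh$gene == "G1"], "up")
  # G3: hit probes at -2.5 and +1.8; largest |deviation| wins
  expect_identical(gh$direction[gh$gene == "G3"], "down")
  expect_true(gh$direction_conflict[gh$gene == "G3"])
  cnt <- hits$orf_counts
  expect_identical(cnt$n_genes_total, 2L)
  expect_identical(cnt$n_genes_up + cnt$n_genes_down, cnt$n_genes_total)
  expect_identical(cnt$n_probe_hits, 3L)
})

test_that("MAD-degenerate detected probes fall back to the deviation rule", {
  vals <- matrix(c(rep(3, 9), 5.5, 5.5, 5.5), 1, 12,
                 dimnames = list("p1", sprintf("s%02d", 1:12)))
  em <- toy_expr(vals)
  sheet <- toy_sheet(colnames(vals), c(rep(EMPTY_VECTOR, 9), rep("A", 3)))
  st <- compute_probe_stats(em)
  expect_true(st$degenerate)
  rec <- score_orf(em, sheet, st, "A")
  expect_true(is.na(rec$z))
  expect_true(rec$probe_hit)      # |deviation| = 2.5 > 1
  expect_true(rec$degenerate)
})

test_that("empty-vector resampling is deterministic and validates inputs", {
  fx <- get_fixture()
  fit <- get_fit()
  floored <- lapply(fit$platforms, `[[`, "matrix")
  fp1 <- estimate_false_positive_hits(floored, fx$sheet, fx$annotations,
                                      fit$config, n_resamples = 20L,
                                      seed = 33L)
  fp2 <- estimate_false_positive_hits(floored, fx$sheet, fx$annotations,
                                      fit$config, n_resamples = 20L,
                                      seed = 33L)
  expect_identical(fp1$counts, fp2$counts)
  expect_identical(fp1$n_pseudo_orfs, 20L * 4L)
  expect_error(
    estimate_false_positive_hits(floored, fx$sheet, fx$annotations,
                                 fit$config, group_size = 7L),
    "at least 14")
})
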