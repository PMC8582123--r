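toy_effects <- function(m) {
  class(m) <- c("effect_matrix", class(m))
  m
}

test_that("similarity scores are the self-normalized projection", {
  m <- toy_effects(matrix(c(1, 2,   2, 1,   -1, -2), 2, 3,
                          dimnames = list(c("G1", "G2"),
                                          c("R", "S", "N"))))
  # worked example: e_ref = (1,2), e_src = (2,1) -> (2+2)/(1+4) = 0.8
  expect_equal(similarity_score(m, "S", "R", c("G1", "G2")), 0.8)
  # self score exactly 1
  expect_equal(similarity_score(m, "R", "R", c("G1", "G2")), 1)
  # antisymmetric source scores -1
  expect_equal(similarity_score(m, "N", "R", c("G1", "G2")), -1)
  # linearity in the source vector
  m2 <- m
  m2[, "S"] <- 3.7 * m2[, "S"]
  expect_equal(similarity_score(m2, "S", "R", c("G1", "G2")), 3.7 * 0.8)
  expect_error(similarity_score(m, "S", "R", character()), "empty")
})

test_that("the score matrix matches a scalar oracle on a 5-ORF toy", {
  set.seed(41)
  eff <- toy_effects(matrix(rnorm(40 * 5), 40, 5,
                            dimnames = list(sprintf("G%02d", 1:40),
                                            sprintf("O%d", 1:5))))
  # hand-build a hit table: O1 and O2 are references
  gh <- rbind(
    data.frame(orf = "O1", gene = sprintf("G%02d", 1:25)),
    data.frame(orf = "O2", gene = sprintf("G%02d", 10:32)),
    data.frame(orf = "O3", gene = sprintf("G%02d", 1:5)))
  gh$direction <- "up"
  counts <- data.frame(orf = sprintf("O%d", 1:5),
                       n_genes_total = c(25L, 23L, 5L, 0L, 0L))
  hits <- structure(list(gene_hits = gh, orf_counts = counts,
                         probe_records = NULL), class = "hit_table")
  cfg <- screen_config(min_hits_reference = 20L)
  res <- score_matrix(eff, hits, cfg)
  expect_identical(res$references, c("O1", "O2"))
  for (r in res$references) for (s in sprintf("O%d", 1:5)) {
    expect_equal(res$scores[s, r],
                 oracle_similarity(unclass(eff), s, r,
                                   res$reference_hits[[r]]),
                 tolerance = 1e-12)
  }
  # edges: strict threshold, positive only, targeting references only,
  # no self-edges
  expect_true(all(res$edges$score > cfg$edge_score_threshold))
  expect_true(all(res$edges$reference %in% res$references))
  expect_false(any(res$edges$source == res$edges$reference))
})

test_that("cluster-mates score high on each other, unrelated ORFs near zero", {
  fit <- get_fit()
  sc <- fit$similarity$scores
  for (cl in 1:2) {
    members <- cluster_members(cl)
    block <- sc[members, members]
    off <- block[row(block) != col(block)]
    expect_true(all(off > 0.6))
  }
  cross <- c(sc[cluster_members(1), cluster_members(2)],
             sc[cluster_members(2), cluster_members(1)])
  expect_lt(max(abs(cross)), 0.25)
  # self-scores exactly 1
  self <- diag(sc[fit$similarity$references, fit$similarity$references])
  expect_equal(unname(self), rep(1, length(self)), tolerance = 1e-12)
})

test_that("t-SNE embedding is deterministic and respects input geometry", {
  set.seed(42)
  eff <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("G%02d", 1:30),
                                sprintf("O%02d", 1:10)))
  eff[, "O02"] <- eff[, "O01"]   # two identical effect profiles
  eff <- toy_effects(eff)
  cfg <- screen_config(tsne_perplexity = 2, tsne_runs = 5L, rng_seed = 5L)
  refs <- colnames(eff)
  e1 <- tsne_embed(eff, refs, cfg, max_iter = 300L)
  e2 <- tsne_embed(eff, refs, cfg, max_iter = 300L)
  expect_identical(e1, e2)
  d <- as.matrix(dist(e1))
  pair <- d["O01", "O02"]
  others <- d[upper.tri(d)]
  expect_lte(pair, stats::quantile(others, 0.01))
  # guards
  expect_error(tsne_embed(eff, refs[1:2], cfg), "at least 3")
  expect_error(tsne_embed(eff, refs[1:5], cfg), "perplexity")
})

test_that("the fixture embedding separates the planted clusters", {
  fit <- get_fit()
  emb <- fit$similarity$embedding
  expect_setequal(rownames(emb), c(cluster_members(1), cluster_members(2)))
  d <- as.matrix(dist(emb))
  within <- c(d[cluster_members(1), cluster_members(1)][
    upper.tri(matrix(0, 6, 6))],
    d[cluster_members(2), cluster_members(2)][upper.tri(matrix(0, 6, 6))])
  between <- d[cluster_members(1), cluster_members(2)]
  expect_lt(mean(within), mean(between))
})

test_that("graph export round-trips nodes, edges and the reference rule", {
  fit <- get_fit()
  gml <- withr::local_tempfile(fileext = ".graphml")
  etsv <- withr::local_tempfile(fileext = ".tsv")
  g <- export_graph(fit$similarity, gml, etsv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), nrow(fit$similarity$edges))
  # node size ordering equals HIT-count ordering
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_identical(order(v$size), order(v$hits))
  # ORFs below the reference threshold are not flagged as references
  low <- v$name[v$hits < fit$config$min_hits_reference]
  expect_false(any(low %in% fit$similarity$references))
  expect_false(any(v$is_reference[v$hits < fit$config$min_hits_reference]))
  edges_back <- read.delim(etsv)
  expect_identical(nrow(edges_back), nrow(fit$similarity$edges))
})
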