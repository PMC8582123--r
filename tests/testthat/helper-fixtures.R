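# Shared, lazily built fixtures. The default synthetic screen and its full
# fit are expensive enough to build once per test session.

fixture_env <- new.env(parent = emptyenv())

fixture_config <- function(...) {
  screen_config(floor_by_platform = c(AG = 8, IL = 3.5),
                tsne_perplexity = 3, rng_seed = 1L, ...)
}

get_fixture <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- default_fixture()
  fixture_env$fx
}

get_fit <- function() {
  if (is.null(fixture_env$fit)) {
    fx <- get_fixture()
    fixture_env$fit <- suppressMessages(
      orf_screen(fx$matrices, fx$sheet, fx$annotations, fixture_config()))
  }
  fixture_env$fit
}

cluster_members <- function(i) {
  if (i == 1L) sprintf("ORF%02d", 1:6) else sprintf("ORF%02d", 7:12)
}

# a small floored-log2 matrix with matching sheet/stats for formula tests
toy_expr <- function(values, platform = "P1", scale = "floored_log2") {
  expression_matrix(values, platform = platform, scale = scale)
}

toy_sheet <- function(sample_ids, orfs, platform = "P1") {
  sample_sheet(data.frame(
    sample_id = sample_ids, orf = orfs,
    replicate = stats::ave(seq_along(orfs), orfs, FUN = seq_along),
    batch = "B1", platform = platform,
    is_empty_vector = orfs == EMPTY_VECTOR,
    stringsAsFactors = FALSE))
}

toy_annotation <- function(probe_ids, genes, platform = "P1",
                           status = "ok") {
  probe_annotation(data.frame(
    probe_id = probe_ids, gene = genes, platform = platform,
    status = status, stringsAsFactors = FALSE))
}
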