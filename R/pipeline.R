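#' Run the screen analysis end to end, writing all stage outputs
#'
#' Orchestrates simulate (or load) -> normalize/batch-adjust/floor ->
#' HIT calling -> effect merging -> similarity network and embedding ->
#' empty-vector null-rate estimation, writing every stage's output as TSV
#' (plus GraphML for the network) into a run directory together with a JSON
#' run manifest (configuration snapshot, input checksums, per-stage output
#' paths, seed, package version). Re-running with the same seed and inputs
#' reproduces identical outputs.
#'
#' @param out_dir run directory (created if needed).
#' @param config a \code{\link{screen_config}}.
#' @param screen optional \code{synthetic_screen} to analyse; if NULL one is
#'   simulated from \code{design} and \code{effects}, or the packaged
#'   default fixture when those are NULL too.
#' @param design,effects optional \code{\link{screen_design}} /
#'   \code{\link{effect_model}} for simulation.
#' @param seed integer run seed; overrides \code{config$rng_seed} and fans
#'   out deterministically to the per-stage seeds.
#' @param gmt optional path to a GMT file; when given, HIT lists are tested
#'   for over-representation against the detected-gene universe.
#' @param null_resamples empty-vector resampling draws (default 200).
#' @param ... passed to \code{\link{orf_screen}}.
#' @return The run manifest (a list), invisibly; the fitted
#'   \code{orf_screen} is attached as attribute \code{"fit"}.
#' @export
run_screen_pipeline <- function(out_dir, config = screen_config(),
                                screen = NULL, design = NULL, effects = NULL,
                                seed = config$rng_seed, gmt = NULL,
                                null_resamples = 200L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$rng_seed <- as.integer(seed)

  if (is.null(screen)) {
    screen <- if (is.null(design) || is.null(effects)) {
      default_fixture(seed = stage_seed(cfg$rng_seed, "simulate") + 1L)
    } else {
      design$rng_seed <- stage_seed(cfg$rng_seed, "simulate") + 1L
      simulate_screen(design, effects)
    }
  }
  input_dir <- file.path(out_dir, "inputs")
  input_paths <- write_screen(screen, input_dir)

  fit <- orf_screen(screen$matrices, screen$sheet, screen$annotations,
                    config = cfg, ...)

  outputs <- c()
  save_tsv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[name] <<- p
    p
  }
  for (pf in names(fit$platforms))
    save_tsv(fit$platforms[[pf]]$stats, sprintf("probe_stats_%s", pf))
  save_tsv(fit$records, "probe_hit_records")
  save_tsv(fit$hits$gene_hits, "gene_hits")
  save_tsv(fit$hits$orf_counts, "orf_hit_counts")
  p <- file.path(out_dir, "effect_matrix.tsv")
  write_effect_matrix(fit$effects, p)
  outputs["effect_matrix"] <- p
  save_tsv(data.frame(orf = rownames(fit$similarity$scores),
                      fit$similarity$scores, check.names = FALSE),
           "similarity_scores")
  save_tsv(fit$similarity$edges, "similarity_edges")
  if (!is.null(fit$similarity$embedding))
    save_tsv(data.frame(orf = rownames(fit$similarity$embedding),
                        fit$similarity$embedding), "embedding")
  gml <- file.path(out_dir, "similarity_network.graphml")
  export_graph(fit$similarity, gml)
  outputs["similarity_network"] <- gml

  floored <- lapply(fit$platforms, `[[`, "matrix")
  null_rate <- estimate_false_positive_hits(
    floored, screen$sheet, screen$annotations, cfg,
    n_resamples = null_resamples,
    seed = stage_seed(cfg$rng_seed, "null_rate"))
  save_tsv(data.frame(statistic = c("mean", "min", "max", "n_pseudo_orfs"),
                      value = c(null_rate$mean, null_rate$min,
                                null_rate$max, null_rate$n_pseudo_orfs)),
           "null_rate")

  if (!is.null(gmt)) {
    sets <- read_gmt(gmt)
    enr <- enrich_hit_lists(fit$hits, sets, fit$detected_genes)
    if (!is.null(enr)) save_tsv(enr, "enrichment")
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_screen_config(cfg, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("orfscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$rng_seed,
    config = cfg_path,
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(unname(input_paths))), names(input_paths))),
    outputs = as.list(outputs),
    null_rate = list(mean = null_rate$mean, min = null_rate$min,
                     max = null_rate$max))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(manifest, "fit") <- fit
  invisible(manifest)
}
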