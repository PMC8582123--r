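#' Screen analysis configuration
#'
#' Bundles the tunable constants of the screen analysis. The defaults are the
#' dataset-scale operating point of the method: a probe is a HIT when its
#' replicate mean deviates from the all-sample baseline by more than
#' \code{deviation_threshold} log2 units (a fold effect greater than 2) AND
#' its robust Z statistic exceeds \code{z_threshold} in absolute value; ORFs
#' with at least \code{min_hits_reference} gene HITs anchor similarity scores;
#' directed network edges keep positive scores above
#' \code{edge_score_threshold}.
#'
#' @param z_threshold positive; HIT requires |Z| > this (default 4).
#' @param deviation_threshold positive, log2 units; HIT requires
#'   |mean - baseline| > this (default 1, i.e. two-fold).
#' @param min_hits_reference integer; minimum gene-HIT count for an ORF to be
#'   a similarity reference (default 20).
#' @param edge_score_threshold positive; directed edges keep scores strictly
#'   greater than this (default 0.6).
#' @param tsne_perplexity t-SNE perplexity (default 10). Must be below
#'   (number of reference ORFs - 1)/3 when embedding.
#' @param tsne_runs number of independent t-SNE runs averaged before the
#'   final refinement run (default 30).
#' @param floor_by_platform named numeric vector of log2 detection floors,
#'   one entry per platform id.
#' @param mad_scaled logical; if TRUE the MAD carries the 1.4826 normal
#'   consistency factor. Default FALSE (plain MAD).
#' @param rng_seed integer seed from which all stage seeds are derived.
#' @param loess_span,loess_iterations cyclic loess parameters.
#' @param quantile_offset raw-scale offset added before log2 in
#'   \code{\link{quantile_normalize_with_offset}} (default 16).
#' @param parametric_eb logical; parametric empirical-Bayes shrinkage in
#'   \code{\link{combat_adjust}} (default TRUE).
#'
#' @return An object of class \code{screen_config} (a validated list).
#' @seealso \code{\link{orf_screen}}, \code{\link{read_screen_config}}
#' @export
screen_config <- function(z_threshold = 4,
                          deviation_threshold = 1,
                          min_hits_reference = 20L,
                          edge_score_threshold = 0.6,
                          tsne_perplexity = 10,
                          tsne_runs = 30L,
                          floor_by_platform = numeric(),
                          mad_scaled = FALSE,
                          rng_seed = 1L,
                          loess_span = 0.7,
                          loess_iterations = 3L,
                          quantile_offset = 16,
                          parametric_eb = TRUE) {
  cfg <- list(
    z_threshold = as.numeric(z_threshold),
    deviation_threshold = as.numeric(deviation_threshold),
    min_hits_reference = as.integer(min_hits_reference),
    edge_score_threshold = as.numeric(edge_score_threshold),
    tsne_perplexity = as.numeric(tsne_perplexity),
    tsne_runs = as.integer(tsne_runs),
    floor_by_platform = unlist(floor_by_platform),
    mad_scaled = isTRUE(mad_scaled),
    rng_seed = as.integer(rng_seed),
    loess_span = as.numeric(loess_span),
    loess_iterations = as.integer(loess_iterations),
    quantile_offset = as.numeric(quantile_offset),
    parametric_eb = isTRUE(parametric_eb)
  )
  thr <- c(cfg$z_threshold, cfg$deviation_threshold, cfg$edge_score_threshold,
           cfg$tsne_perplexity)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("thresholds and perplexity must be strictly positive", call. = FALSE)
  if (cfg$min_hits_reference < 1L || cfg$tsne_runs < 1L)
    stop("min_hits_reference and tsne_runs must be >= 1", call. = FALSE)
  if (length(cfg$floor_by_platform) &&
      (is.null(names(cfg$floor_by_platform)) ||
       any(cfg$floor_by_platform < 0)))
    stop("floor_by_platform must be a named vector of floors >= 0",
         call. = FALSE)
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Screen analysis configuration\n")
  cat(sprintf("  HIT thresholds : |Z| > %g and |log2 deviation| > %g\n",
              x$z_threshold, x$deviation_threshold))
  cat(sprintf("  references     : >= %d gene HITs\n", x$min_hits_reference))
  cat(sprintf("  network edges  : score > %g\n", x$edge_score_threshold))
  cat(sprintf("  t-SNE          : perplexity %g, %d averaged runs\n",
              x$tsne_perplexity, x$tsne_runs))
  if (length(x$floor_by_platform))
    cat("  floors (log2)  :",
        paste(sprintf("%s=%g", names(x$floor_by_platform),
                      x$floor_by_platform), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a screen configuration as YAML
#'
#' @param path file path.
#' @return \code{read_screen_config} returns a \code{screen_config};
#'   \code{write_screen_config} returns \code{path} invisibly.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(screen_config, raw)
}

#' @rdname read_screen_config
#' @param config a \code{screen_config}.
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  out <- unclass(config)
  out$floor_by_platform <- as.list(out$floor_by_platform)
  yaml::write_yaml(out, path)
  invisible(path)
}

# Deterministic per-stage child seeds derived from the run seed, so a stage
# re-run alone reproduces the full-run result. Offsets keep seeds < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, null_rate = 104729L, tsne = 224737L,
               resample = 350377L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000000L) + offsets[[stage]]
}
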