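#' Fit the full screen analysis to a set of expression matrices
#'
#' The central fitting function of the package. Takes one or two platforms'
#' probe intensity matrices with a sample sheet and probe annotations, and
#' runs the complete analysis: per-platform normalization, batch
#' adjustment, detection flooring, duplicate collapse, baseline/MAD probe
#' statistics, robust Z-score HIT calling per condition (the empty-vector
#' control is scored like any other condition), gene-level roll-up, the
#' merged gene-by-ORF effect matrix, asymmetric similarity scores with a
#' thresholded directed network, and (when enough reference ORFs exist) the
#' averaged t-SNE embedding.
#'
#' @param matrices named list of \code{expr_matrix} objects, one per
#'   platform, on the raw or log2 scale (raw values are log2-transformed,
#'   or quantile-normalized with offset when \code{normalize = "quantile"}).
#' @param sheet a \code{\link{sample_sheet}} covering all samples.
#' @param annotations named list of \code{probe_annotation}, one per
#'   platform.
#' @param config a \code{\link{screen_config}}; must provide a
#'   \code{floor_by_platform} entry for every platform.
#' @param normalize between-sample normalization: \code{"cyclic_loess"}
#'   (fast variant against the mean array), \code{"cyclic_loess_pairs"}
#'   (all-pairs), \code{"quantile"} (raw input only), or \code{"none"}.
#' @param batch_correct adjust known batches from the sample sheet
#'   (location/scale EB model) when more than one batch is present.
#' @param embed compute the t-SNE embedding of the reference ORFs (skipped
#'   with a message when fewer than 3 references or when the configured
#'   perplexity is too large for the reference count).
#' @return An object of class \code{orf_screen} with elements
#'   \code{config}, \code{platforms} (per-platform floored matrix, retained
#'   sheet, probe stats), \code{records} (all probe-level scores),
#'   \code{hits} (a \code{hit_table}), \code{effects} (gene x ORF
#'   \code{effect_matrix}), \code{similarity} (a \code{similarity_result},
#'   embedding included when computed), \code{detected_genes} and
#'   \code{call}. Methods: \code{print}, \code{summary}, \code{coef}
#'   (the effect matrix), \code{plot} (the embedded similarity network).
#' @seealso \code{\link{default_fixture}} for a synthetic screen to try it
#'   on, \code{\link{run_screen_pipeline}} for a file-based end-to-end run.
#' @export
orf_screen <- function(matrices, sheet, annotations,
                       config = screen_config(),
                       normalize = c("cyclic_loess", "cyclic_loess_pairs",
                                     "quantile", "none"),
                       batch_correct = TRUE,
                       embed = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            inherits(sheet, "sample_sheet"))
  platforms <- vapply(matrices, function(m) m$platform, character(1L))
  missing_floor <- setdiff(platforms, names(config$floor_by_platform))
  if (length(missing_floor))
    stop("config$floor_by_platform lacks entries for platform(s): ",
         paste(missing_floor, collapse = ", "), call. = FALSE)
  missing_ann <- setdiff(platforms, names(annotations))
  if (length(missing_ann))
    stop("no annotation for platform(s): ",
         paste(missing_ann, collapse = ", "), call. = FALSE)

  plat <- list()
  records <- list()
  for (pf in platforms) {
    x <- matrices[[which(platforms == pf)]]
    validate_samples(x, sheet)
    if (x$scale == "raw") {
      x <- if (normalize == "quantile")
        quantile_normalize_with_offset(x, offset = config$quantile_offset)
      else
        expression_matrix(log2(pmax(x$values, 2^-10)), platform = pf,
                          scale = "log2")
    }
    if (x$scale == "log2" && startsWith(normalize, "cyclic_loess") &&
        ncol(x$values) >= 2L) {
      x <- cyclic_loess_normalize(
        x, span = config$loess_span, iterations = config$loess_iterations,
        method = if (normalize == "cyclic_loess_pairs") "pairs" else "fast")
    }
    if (batch_correct) {
      batches <- stats::setNames(sheet$batch, sheet$sample_id)
      batches <- batches[colnames(x$values)]
      if (length(unique(batches)) > 1L)
        x <- combat_adjust(x, batches,
                           parametric_eb = config$parametric_eb)
    }
    x <- truncate_translate(x, config$floor_by_platform[[pf]])
    coll <- collapse_duplicates(x, annotations[[pf]], sheet)
    st <- compute_probe_stats(coll$matrix, mad_scaled = config$mad_scaled)
    conds <- unique(coll$sheet$orf)
    rec <- lapply(conds, function(o)
      score_orf(coll$matrix, coll$sheet, st, o, config))
    records[[pf]] <- do.call(rbind, rec)
    plat[[pf]] <- list(matrix = coll$matrix, sheet = coll$sheet, stats = st)
  }
  all_records <- do.call(rbind, records)
  class(all_records) <- c("hit_records", "data.frame")
  hits <- call_gene_hits(all_records, annotations)
  effects <- build_effect_matrix(hits)
  sim <- score_matrix(effects, hits, config)
  if (embed && length(sim$references) >= 3L) {
    if (config$tsne_perplexity < (length(sim$references) - 1) / 3) {
      sim$embedding <- tsne_embed(effects, sim$references, config,
                                  seed = stage_seed(config$rng_seed, "tsne"))
    } else {
      message("skipping embedding: perplexity ", config$tsne_perplexity,
              " too large for ", length(sim$references),
              " reference ORFs")
    }
  } else if (embed) {
    message("skipping embedding: fewer than 3 reference ORFs")
  }

  detected <- unique(unlist(lapply(platforms, function(pf) {
    st <- plat[[pf]]$stats
    ann <- annotations[[pf]]
    g <- ann$gene[match(st$probe_id[st$detected], ann$probe_id)]
    g[!is.na(g)]
  })))

  structure(list(config = config, platforms = plat,
                 records = all_records, hits = hits, effects = effects,
                 similarity = sim, detected_genes = detected,
                 call = match.call()),
            class = "orf_screen")
}

#' @export
print.orf_screen <- function(x, ...) {
  n_cond <- nrow(x$hits$orf_counts)
  cat("ORF overexpression screen fit\n")
  cat(sprintf("  platforms   : %s\n",
              paste(names(x$platforms), collapse = ", ")))
  cat(sprintf("  conditions  : %d (incl. %s)\n", n_cond,
              if (EMPTY_VECTOR %in% x$hits$orf_counts$orf)
                "empty vector" else "no empty vector"))
  cat(sprintf("  gene HITs   : %d (ORF, gene) pairs; %d genes in effect matrix\n",
              nrow(x$hits$gene_hits), nrow(x$effects)))
  cat(sprintf("  references  : %d ORFs with >= %d gene HITs; %d network edges\n",
              length(x$similarity$references),
              x$config$min_hits_reference, nrow(x$similarity$edges)))
  if (!is.null(x$similarity$embedding))
    cat("  embedding   : 2-D t-SNE of the references\n")
  invisible(x)
}

#' @export
summary.orf_screen <- function(object, ...) {
  counts <- object$hits$orf_counts
  counts <- counts[order(-counts$n_genes_total), ]
  rownames(counts) <- NULL
  out <- list(counts = counts,
              n_references = length(object$similarity$references),
              references = object$similarity$references,
              n_edges = nrow(object$similarity$edges),
              n_effect_genes = nrow(object$effects),
              config = object$config)
  class(out) <- "summary.orf_screen"
  out
}

#' @export
print.summary.orf_screen <- function(x, ...) {
  cat("Gene HITs per condition (up / down / total, plus probe-level hits):\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("\n%d reference ORFs (>= %d gene HITs): %s\n",
              x$n_references, x$config$min_hits_reference,
              paste(x$references, collapse = ", ")))
  cat(sprintf("%d directed edges with score > %g; %d genes in the effect matrix\n",
              x$n_edges, x$config$edge_score_threshold, x$n_effect_genes))
  invisible(x)
}

#' @export
coef.orf_screen <- function(object, ...) object$effects

#' Plot the embedded ORF similarity network
#'
#' Draws the t-SNE embedding of the reference ORFs, point area proportional
#' to the gene-HIT count, with arrows source -> reference for every retained
#' similarity edge (both endpoints must be embedded).
#'
#' @param x an \code{orf_screen} fit with an embedding.
#' @param labels draw ORF labels.
#' @param ... passed to \code{plot.default}.
#' @export
plot.orf_screen <- function(x, labels = TRUE, ...) {
  emb <- x$similarity$embedding
  if (is.null(emb))
    stop("no embedding in this fit (see ?tsne_embed)", call. = FALSE)
  hitn <- x$similarity$hit_counts[rownames(emb)]
  cex <- 1 + 2 * sqrt(hitn / max(hitn, 1))
  graphics::plot(emb[, "x"], emb[, "y"], pch = 21,
                 bg = grDevices::adjustcolor("steelblue", 0.6),
                 cex = cex, xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  e <- x$similarity$edges
  e <- e[e$source %in% rownames(emb) & e$reference %in% rownames(emb), ]
  if (nrow(e))
    graphics::arrows(emb[e$source, "x"], emb[e$source, "y"],
                     emb[e$reference, "x"], emb[e$reference, "y"],
                     length = 0.08,
                     lwd = 0.5 + 2 * (e$score - min(e$score)) /
                       max(1e-9, diff(range(e$score))),
                     col = grDevices::adjustcolor("grey30", 0.7))
  if (labels)
    graphics::text(emb[, "x"], emb[, "y"], rownames(emb), pos = 3,
                   cex = 0.7)
  invisible(x)
}
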