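#' Per-probe baseline and variability statistics
#'
#' The screen leverages the full sample collection to define, for every
#' probe, a baseline b (median log2 expression over ALL samples, including
#' the condition later tested) and an expected range of variation (the
#' median absolute deviation over all samples). The MAD is plain
#' (median |x - b|) by default; \code{mad_scaled} applies the 1.4826 normal
#' consistency factor.
#'
#' @param x an \code{expr_matrix} on the \code{floored_log2} scale (>= 3
#'   samples).
#' @param mad_scaled logical, see above.
#' @return data frame of class \code{probe_stats} with columns
#'   \code{probe_id}, \code{baseline}, \code{mad}, \code{detected}
#'   (floored baseline > 0) and \code{degenerate} (mad == 0).
#' @export
compute_probe_stats <- function(x, mad_scaled = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "floored_log2")
    stop("probe statistics are computed on floored log2 values",
         call. = FALSE)
  if (ncol(x$values) < 3L)
    stop("at least 3 samples are required", call. = FALSE)
  b <- apply(x$values, 1L, stats::median)
  mad <- apply(abs(x$values - b), 1L, stats::median)
  if (mad_scaled) mad <- mad * 1.4826
  out <- data.frame(probe_id = rownames(x$values),
                    baseline = b,
                    mad = mad,
                    detected = b > 0,
                    degenerate = mad == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Score one ORF condition against the probe baselines
#'
#' For every probe, computes the replicate mean \eqn{\bar{x}}, the deviation
#' from baseline \eqn{\bar{x} - b} (the log2 fold effect), and the robust
#' statistic
#' \deqn{Z = (\bar{x} - b)\,\sqrt{n}\,/\,\mathrm{MAD}.}
#' A probe is a HIT when the probe is detected, \eqn{|\bar{x} - b|} exceeds
#' the deviation threshold (default 1, i.e. a fold effect greater than 2)
#' AND \eqn{|Z|} exceeds the Z threshold (default 4). Probes with MAD = 0
#' have no defined Z; they are flagged degenerate and their HIT call falls
#' back to the deviation criterion alone.
#'
#' @param x an \code{expr_matrix} (floored log2) for one platform.
#' @param sheet a \code{sample_sheet}.
#' @param stats a \code{probe_stats} for this matrix.
#' @param orf ORF label present in the sheet (the empty-vector sentinel is a
#'   valid condition).
#' @param config a \code{\link{screen_config}}.
#' @return data frame of class \code{hit_records}: one row per probe with
#'   columns \code{orf}, \code{platform}, \code{probe_id}, \code{n},
#'   \code{xbar}, \code{deviation}, \code{z}, \code{detected},
#'   \code{degenerate}, \code{probe_hit}.
#' @export
score_orf <- function(x, sheet, stats, orf, config = screen_config()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(stats, "probe_stats"))
  ids <- sheet$sample_id[sheet$platform == x$platform & sheet$orf == orf]
  ids <- intersect(ids, colnames(x$values))
  if (!length(ids))
    stop("unknown ORF '", orf, "' on platform ", x$platform, call. = FALSE)
  if (length(ids) < 2L)
    stop("ORF '", orf, "' has fewer than 2 replicates on platform ",
         x$platform, call. = FALSE)
  st <- stats[match(rownames(x$values), stats$probe_id), ]
  n <- length(ids)
  xbar <- rowMeans(x$values[, ids, drop = FALSE])
  deviation <- xbar - st$baseline
  z <- ifelse(st$mad > 0, deviation * sqrt(n) / st$mad, NA_real_)
  hit <- st$detected &
    abs(deviation) > config$deviation_threshold &
    ifelse(st$degenerate, TRUE, abs(z) > config$z_threshold)
  out <- data.frame(orf = orf, platform = x$platform,
                    probe_id = rownames(x$values),
                    n = n, xbar = xbar, deviation = deviation, z = z,
                    detected = st$detected, degenerate = st$degenerate,
                    probe_hit = hit,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("hit_records", "data.frame")
  out
}

#' Roll probe-level HIT calls up to genes
#'
#' A gene is a HIT for an ORF if at least one of its probes — on either
#' platform — passed the probe-level HIT thresholds. The gene's direction is
#' the sign of the hit probe with the largest |deviation|; conflicting
#' directions among a gene's hit probes are resolved the same way and
#' counted. Probes annotated \code{bad} / \code{no_match} are excluded.
#'
#' @param records a \code{hit_records} data frame (rows from
#'   \code{\link{score_orf}}, typically rbind-ed over ORFs and platforms).
#' @param annotations a \code{probe_annotation} or list of them (one per
#'   platform).
#' @return An object of class \code{hit_table}: list with
#'   \code{probe_records} (records with a \code{gene} column),
#'   \code{gene_hits} (orf, gene, direction, max_abs_deviation, max_abs_z,
#'   n_probes_hit, direction_conflict), and \code{orf_counts} (orf,
#'   n_genes_up, n_genes_down, n_genes_total, n_probe_hits).
#' @export
call_gene_hits <- function(records, annotations) {
  if (inherits(annotations, "probe_annotation"))
    annotations <- list(annotations)
  ann <- do.call(rbind, lapply(annotations, as.data.frame))
  key <- paste(records$platform, records$probe_id)
  akey <- paste(ann$platform, ann$probe_id)
  m <- match(key, akey)
  records$gene <- ann$gene[m]
  records$status <- ann$status[m]
  uncovered <- is.na(m)
  if (any(uncovered))
    stop("probes missing from the annotation: ",
         paste(utils::head(unique(records$probe_id[uncovered]), 5L),
               collapse = ", "), call. = FALSE)
  usable <- records[records$status == "ok", , drop = FALSE]

  hits <- usable[usable$probe_hit, , drop = FALSE]
  if (nrow(hits)) {
    grp <- paste(hits$orf, hits$gene, sep = "\r")
    ord <- order(grp, -abs(hits$deviation))
    hits_o <- hits[ord, ]
    grp_o <- grp[ord]
    first <- !duplicated(grp_o)
    top <- hits_o[first, ]
    n_probes <- as.vector(table(grp_o)[unique(grp_o)])
    dir_tab <- tapply(sign(hits_o$deviation), grp_o, function(s)
      length(unique(s)) > 1L)
    maxz <- tapply(abs(hits_o$z), grp_o, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    gene_hits <- data.frame(
      orf = top$orf, gene = top$gene,
      direction = ifelse(top$deviation > 0, "up", "down"),
      max_abs_deviation = abs(top$deviation),
      max_abs_z = as.numeric(maxz[unique(grp_o)]),
      n_probes_hit = n_probes,
      direction_conflict = as.logical(dir_tab[unique(grp_o)]),
      row.names = NULL, stringsAsFactors = FALSE)
    gene_hits <- gene_hits[order(gene_hits$orf, gene_hits$gene), ]
    rownames(gene_hits) <- NULL
    if (any(gene_hits$direction_conflict))
      message(sum(gene_hits$direction_conflict),
              " gene(s) with conflicting probe directions; direction set ",
              "by the largest |deviation|")
  } else {
    gene_hits <- data.frame(orf = character(), gene = character(),
                            direction = character(),
                            max_abs_deviation = numeric(),
                            max_abs_z = numeric(),
                            n_probes_hit = integer(),
                            direction_conflict = logical(),
                            stringsAsFactors = FALSE)
  }

  orfs <- unique(records$orf)
  cnt <- function(o, d) sum(gene_hits$orf == o & gene_hits$direction == d)
  orf_counts <- data.frame(
    orf = orfs,
    n_genes_up = vapply(orfs, cnt, integer(1L), d = "up"),
    n_genes_down = vapply(orfs, cnt, integer(1L), d = "down"),
    n_genes_total = vapply(orfs, function(o)
      sum(gene_hits$orf == o), integer(1L)),
    n_probe_hits = vapply(orfs, function(o)
      sum(usable$probe_hit[usable$orf == o]), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(probe_records = usable, gene_hits = gene_hits,
                 orf_counts = orf_counts),
            class = "hit_table")
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("<hit_table> %d conditions, %d gene HITs total\n",
              nrow(x$orf_counts), nrow(x$gene_hits)))
  top <- x$orf_counts[order(-x$orf_counts$n_genes_total), ]
  print(utils::head(top, 10L), row.names = FALSE)
  invisible(x)
}

#' Gene HIT list of one ORF
#' @param hits a \code{hit_table}.
#' @param orf ORF label.
#' @return character vector of HIT gene symbols.
#' @export
hit_genes <- function(hits, orf) {
  stopifnot(inherits(hits, "hit_table"))
  if (!orf %in% hits$orf_counts$orf)
    stop("unknown ORF: ", orf, call. = FALSE)
  hits$gene_hits$gene[hits$gene_hits$orf == orf]
}

#' Empty-vector resampling estimate of the false-positive HIT rate
#'
#' Randomly partitions the empty-vector control samples into disjoint groups
#' of \code{group_size}, scores each group as a pseudo-ORF with the same
#' statistic used for real conditions, and counts its gene HITs. A fresh
#' random partition is drawn for each resample. The empirical distribution
#' of gene-HIT counts over all pseudo-ORFs estimates the false-positive rate
#' of the HIT criteria.
#'
#' @param matrices named list of floored \code{expr_matrix}, one per
#'   platform.
#' @param sheet a \code{sample_sheet}.
#' @param annotations list of \code{probe_annotation} per platform.
#' @param config a \code{\link{screen_config}}.
#' @param group_size pseudo-ORF replicate count (default 3).
#' @param n_resamples number of random partitions (each contributing
#'   \code{floor(n_empty / group_size)} pseudo-ORFs).
#' @param seed integer seed; the estimate is deterministic given it.
#' @return List of class \code{fp_estimate}: \code{mean}, \code{min},
#'   \code{max}, \code{counts} (per pseudo-ORF gene-HIT counts),
#'   \code{n_pseudo_orfs}.
#' @export
estimate_false_positive_hits <- function(matrices, sheet, annotations,
                                         config = screen_config(),
                                         group_size = 3L,
                                         n_resamples = 500L,
                                         seed = config$rng_seed) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  if (inherits(annotations, "probe_annotation"))
    annotations <- list(annotations)
  ev <- sheet[sheet$is_empty_vector, , drop = FALSE]
  ev_reps <- sort(unique(ev$replicate))
  if (length(ev_reps) < 2L * group_size)
    stop("need at least ", 2L * group_size, " empty-vector replicates, got ",
         length(ev_reps), call. = FALSE)
  n_groups <- length(ev_reps) %/% group_size

  prep <- lapply(matrices, function(m) {
    st <- compute_probe_stats(m, mad_scaled = config$mad_scaled)
    ev_p <- ev[ev$platform == m$platform, ]
    cols <- stats::setNames(match(ev_p$sample_id, colnames(m$values)),
                            ev_p$replicate)
    list(m = m, st = st, cols = cols)
  })
  ann <- do.call(rbind, lapply(annotations, as.data.frame))

  set.seed(seed)
  counts <- integer(0)
  for (r in seq_len(n_resamples)) {
    perm <- sample(ev_reps)
    for (g in seq_len(n_groups)) {
      reps <- perm[((g - 1L) * group_size + 1L):(g * group_size)]
      n_hit_genes <- 0L
      hit_gene_set <- character()
      for (p in prep) {
        cols <- p$cols[as.character(reps)]
        cols <- cols[!is.na(cols)]
        if (length(cols) < 2L) next
        xbar <- rowMeans(p$m$values[, cols, drop = FALSE])
        dev <- xbar - p$st$baseline
        z <- ifelse(p$st$mad > 0, dev * sqrt(length(cols)) / p$st$mad,
                    NA_real_)
        hit <- p$st$detected & abs(dev) > config$deviation_threshold &
          ifelse(p$st$degenerate, TRUE, abs(z) > config$z_threshold)
        if (any(hit)) {
          akey <- paste(p$m$platform, p$st$probe_id[hit])
          gk <- ann$gene[match(akey, paste(ann$platform, ann$probe_id))]
          ok <- ann$status[match(akey, paste(ann$platform, ann$probe_id))]
          hit_gene_set <- union(hit_gene_set, gk[!is.na(ok) & ok == "ok"])
        }
      }
      counts <- c(counts, length(hit_gene_set))
    }
  }
  structure(list(mean = mean(counts), min = min(counts), max = max(counts),
                 counts = counts, n_pseudo_orfs = length(counts),
                 group_size = group_size, n_resamples = n_resamples),
            class = "fp_estimate")
}

#' @export
print.fp_estimate <- function(x, ...) {
  cat(sprintf(
    "Empty-vector pseudo-ORFs (n = %d, groups of %d): %d-%d false-positive gene HITs (mean %.2f)\n",
    x$n_pseudo_orfs, x$group_size, x$min, x$max, x$mean))
  invisible(x)
}
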