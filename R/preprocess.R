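#' Normexp background correction
#'
#' Removes local background from raw fluorescence intensities under the
#' convolution model observed = signal + background, with exponential signal
#' and Gaussian background. The corrected value is the conditional
#' expectation E[signal | observed], which is strictly positive and monotone
#' non-decreasing in the observed value. Parameters are estimated per sample:
#' by method of moments from negative-control probes when supplied, otherwise
#' by maximum likelihood from the full per-sample intensity distribution
#' (via \code{limma::normexp.fit}).
#'
#' @param x an \code{expr_matrix} on the raw scale.
#' @param negative_control_probes optional character vector of probe ids used
#'   as negative controls for moment estimation of the background.
#' @return An \code{expr_matrix} of strictly positive corrected intensities
#'   (raw scale).
#' @export
normexp_background_correct <- function(x, negative_control_probes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw")
    stop("normexp background correction expects raw intensities",
         call. = FALSE)
  vals <- x$values
  out <- vals
  nc_idx <- if (!is.null(negative_control_probes))
    which(rownames(vals) %in% negative_control_probes) else integer()
  for (j in seq_len(ncol(vals))) {
    col <- vals[, j]
    if (stats::sd(col) == 0 || !is.finite(stats::sd(col))) {
      warning("degenerate intensity distribution in sample '",
              colnames(vals)[j], "'; subtracting the minimum instead")
      out[, j] <- col - min(col) + 0.5
      next
    }
    par <- tryCatch({
      if (length(nc_idx) >= 3L) {
        nc <- col[nc_idx]
        mu <- mean(nc)
        sigma <- stats::sd(nc)
        alpha <- max(mean(col) - mu, 10 * .Machine$double.eps)
        if (sigma <= 0) stop("zero-variance negative controls")
        c(mu, log(sigma), log(alpha))
      } else {
        limma::normexp.fit(col)$par
      }
    }, error = function(e) NULL)
    if (is.null(par)) {
      warning("normexp fit failed in sample '", colnames(vals)[j],
              "'; subtracting the minimum instead")
      out[, j] <- col - min(col) + 0.5
    } else {
      out[, j] <- limma::normexp.signal(par, col)
    }
  }
  expression_matrix(out, platform = x$platform, scale = "raw")
}

#' Cyclic loess normalization
#'
#' Removes intensity-dependent differences between samples by iteratively
#' fitting and subtracting loess trends of M (between-sample log-ratio)
#' against A (average log-intensity), via
#' \code{limma::normalizeCyclicLoess}. \code{method = "pairs"} cycles over
#' all sample pairs (the textbook algorithm); \code{"fast"} normalizes each
#' sample against the mean array and scales to large sample counts.
#'
#' @param x an \code{expr_matrix} on the log2 scale with >= 2 samples
#'   (a single sample is returned unchanged with a warning).
#' @param span loess span (default 0.7).
#' @param iterations number of cycles (default 3).
#' @param method \code{"pairs"} or \code{"fast"}.
#' @return The normalized \code{expr_matrix} (log2).
#' @export
cyclic_loess_normalize <- function(x, span = 0.7, iterations = 3L,
                                   method = c("pairs", "fast")) {
  stopifnot(inherits(x, "expr_matrix"))
  method <- match.arg(method)
  if (x$scale != "log2")
    stop("cyclic loess normalization expects log2 values", call. = FALSE)
  if (ncol(x$values) < 2L) {
    warning("single sample: cyclic loess is the identity")
    return(x)
  }
  norm <- limma::normalizeCyclicLoess(x$values, span = span,
                                      iterations = iterations,
                                      method = method)
  dimnames(norm) <- dimnames(x$values)
  expression_matrix(norm, platform = x$platform, scale = "log2")
}

#' Quantile normalization with a log2 offset
#'
#' Forces every sample to share the average empirical distribution (quantile
#' normalization via \code{limma::normalizeQuantiles}) and returns
#' \code{log2(value + offset)}. The offset damps the variance of
#' near-background intensities, in the spirit of bead-array "neqc"
#' processing.
#'
#' @param x an \code{expr_matrix} of nonnegative raw intensities.
#' @param offset raw-scale offset added before the log2 transform
#'   (default 16).
#' @return An \code{expr_matrix} on the log2 scale.
#' @export
quantile_normalize_with_offset <- function(x, offset = 16) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw")
    stop("quantile normalization expects raw intensities", call. = FALSE)
  if (any(x$values < 0))
    stop("negative intensities are not allowed", call. = FALSE)
  vals <- if (ncol(x$values) >= 2L)
    limma::normalizeQuantiles(x$values) else x$values
  out <- log2(vals + offset)
  dimnames(out) <- dimnames(x$values)
  expression_matrix(out, platform = x$platform, scale = "log2")
}

# Location/scale batch adjustment for one grouping level. Probe-wise
# standardization, per-batch location (gamma) and scale (delta^2) estimates,
# optional parametric empirical-Bayes shrinkage (normal prior on gamma,
# inverse-gamma on delta^2), then removal. Zero-variance probes pass through.
combat_core <- function(vals, batch, parametric_eb, eb_tol = 1e-4,
                        eb_maxit = 200L) {
  batch <- as.character(batch)
  levels_b <- unique(batch)
  if (length(levels_b) < 2L) return(vals)
  n_b <- table(batch)[levels_b]
  small <- names(n_b)[n_b < 2L]
  if (length(small))
    stop("batch with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  N <- ncol(vals)
  ghat <- vapply(levels_b, function(b)
    rowMeans(vals[, batch == b, drop = FALSE]), numeric(nrow(vals)))
  ghat <- matrix(ghat, nrow = nrow(vals))
  alpha <- as.vector(ghat %*% (as.numeric(n_b) / N))
  fitted <- ghat[, match(batch, levels_b), drop = FALSE]
  var_pooled <- rowSums((vals - fitted)^2) / N
  keep <- var_pooled > 0
  if (!any(keep)) return(vals)
  z <- (vals[keep, , drop = FALSE] - alpha[keep]) / sqrt(var_pooled[keep])

  gamma_hat <- vapply(levels_b, function(b)
    rowMeans(z[, batch == b, drop = FALSE]), numeric(nrow(z)))
  delta2_hat <- vapply(levels_b, function(b)
    apply(z[, batch == b, drop = FALSE], 1L, stats::var),
    numeric(nrow(z)))
  gamma_hat <- matrix(gamma_hat, nrow = nrow(z))
  delta2_hat <- matrix(delta2_hat, nrow = nrow(z))
  delta2_hat[delta2_hat <= 0] <- .Machine$double.eps

  if (parametric_eb && nrow(z) >= 2L) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (k in seq_along(levels_b)) {
      nb <- as.numeric(n_b[k])
      gbar <- mean(gamma_hat[, k])
      t2 <- stats::var(gamma_hat[, k])
      m <- mean(delta2_hat[, k])
      s2 <- stats::var(delta2_hat[, k])
      if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) next
      aprior <- (2 * s2 + m^2) / s2
      bprior <- (m * s2 + m^3) / s2
      zb <- z[, batch == levels_b[k], drop = FALSE]
      g_old <- gamma_hat[, k]
      d_old <- delta2_hat[, k]
      for (it in seq_len(eb_maxit)) {
        g_new <- (t2 * nb * gamma_hat[, k] + d_old * gbar) /
          (t2 * nb + d_old)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + bprior) / (nb / 2 + aprior - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                      abs(d_new - d_old) / d_old)
        g_old <- g_new
        d_old <- d_new
        if (change < eb_tol) break
      }
      gamma_star[, k] <- g_old
      delta2_star[, k] <- d_old
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  idx <- match(batch, levels_b)
  z_adj <- (z - gamma_star[, idx, drop = FALSE]) /
    sqrt(delta2_star[, idx, drop = FALSE])
  out <- vals
  out[keep, ] <- z_adj * sqrt(var_pooled[keep]) + alpha[keep]
  out
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Removes known-batch effects from a log2 expression matrix using the
#' standard location/scale model: probe-wise standardization, per-batch
#' mean and variance estimates optionally shrunk toward common priors
#' (normal prior on batch means, inverse-gamma on batch variances, with
#' method-of-moments hyperparameters and the usual iterative conditional
#' solution), then removal. When the experiment was processed hierarchically
#' (e.g. several parts each split into batches), supply \code{part}: batches
#' are combined within each part first, and the parts are then combined
#' together.
#'
#' @param x an \code{expr_matrix} on the log2 scale.
#' @param batch batch label per sample — either a vector named by sample id
#'   or a vector aligned with the matrix columns.
#' @param part optional higher-level grouping (same form as \code{batch})
#'   for hierarchical combination.
#' @param parametric_eb logical; if FALSE no shrinkage is applied and the
#'   adjustment removes the observed per-batch location/scale exactly.
#' @return The adjusted \code{expr_matrix} (log2). With a single batch the
#'   input is returned unchanged.
#' @export
combat_adjust <- function(x, batch, part = NULL, parametric_eb = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2")
    stop("batch adjustment expects log2 values", call. = FALSE)
  align <- function(v) {
    if (!is.null(names(v))) {
      missing <- setdiff(colnames(x$values), names(v))
      if (length(missing))
        stop("samples without a batch assignment: ",
             paste(missing, collapse = ", "), call. = FALSE)
      v <- v[colnames(x$values)]
    } else if (length(v) != ncol(x$values)) {
      stop("batch vector must be named by sample or match the sample count",
           call. = FALSE)
    }
    as.character(v)
  }
  batch <- align(batch)
  vals <- x$values
  if (is.null(part)) {
    vals <- combat_core(vals, batch, parametric_eb)
  } else {
    part <- align(part)
    for (p in unique(part)) {
      idx <- part == p
      if (length(unique(batch[idx])) > 1L)
        vals[, idx] <- combat_core(vals[, idx, drop = FALSE], batch[idx],
                                   parametric_eb)
    }
    vals <- combat_core(vals, part, parametric_eb)
  }
  expression_matrix(vals, platform = x$platform, scale = "log2")
}

#' Floor and translate log2 intensities
#'
#' Truncates log2 intensities at a platform detection floor and translates
#' down by the same amount: \code{y = max(x, floor) - floor}. All outputs are
#' >= 0, and a probe counts as detected iff its floored baseline (median over
#' samples) is > 0. Applying the operation to an already-floored matrix is a
#' no-op, so the operation is idempotent.
#'
#' @param x an \code{expr_matrix} on the log2 (or already floored) scale.
#' @param floor log2 detection floor (>= 0).
#' @return An \code{expr_matrix} on the \code{floored_log2} scale.
#' @export
truncate_translate <- function(x, floor) {
  stopifnot(inherits(x, "expr_matrix"), is.numeric(floor), floor >= 0)
  if (x$scale == "floored_log2") return(x)
  if (x$scale != "log2")
    stop("flooring expects log2 values", call. = FALSE)
  out <- pmax(x$values, floor) - floor
  expression_matrix(out, platform = x$platform, scale = "floored_log2")
}

#' Collapse duplicated probes, drop bad probes and repeated samples
#'
#' Combines rows sharing a probe id by the arithmetic mean on the log2 scale
#' (geometric mean on the raw scale), removes probes whose annotation status
#' is \code{bad} or \code{no_match} (and, with a warning, probes missing from
#' the annotation), and drops samples flagged \code{is_repeat} in the sample
#' sheet (re-run QC samples).
#'
#' @param x an \code{expr_matrix} (any scale).
#' @param annotation a \code{probe_annotation} for the platform.
#' @param sheet a \code{sample_sheet}; only its rows for this platform are
#'   used and returned.
#' @return A list with elements \code{matrix} (collapsed \code{expr_matrix})
#'   and \code{sheet} (the retained samples for this platform).
#' @export
collapse_duplicates <- function(x, annotation, sheet) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- x$values
  status <- annotation$status[match(rownames(vals), annotation$probe_id)]
  unknown <- is.na(status)
  if (any(unknown)) {
    warning(sum(unknown), " probes missing from the annotation were dropped")
    status[unknown] <- "no_match"
  }
  vals <- vals[status == "ok", , drop = FALSE]

  if (anyDuplicated(rownames(vals))) {
    f <- factor(rownames(vals), levels = unique(rownames(vals)))
    if (x$scale == "raw") {
      lv <- log2(pmax(vals, .Machine$double.xmin))
      m <- rowsum(lv, f) / as.vector(table(f))
      vals <- 2^m
    } else {
      vals <- rowsum(vals, f) / as.vector(table(f))
    }
  }

  sh <- sheet[sheet$platform == x$platform, , drop = FALSE]
  if ("is_repeat" %in% names(sh) && any(sh$is_repeat, na.rm = TRUE)) {
    drop_ids <- sh$sample_id[isTRUE_vec(sh$is_repeat)]
    sh <- sh[!sh$sample_id %in% drop_ids, , drop = FALSE]
    vals <- vals[, !colnames(vals) %in% drop_ids, drop = FALSE]
  }
  out <- expression_matrix(vals, platform = x$platform, scale = x$scale)
  list(matrix = out, sheet = sh)
}

isTRUE_vec <- function(v) !is.na(v) & v

#' Gene-level expression profile for a reporting panel
#'
#' Summarizes probe-level log2 expression to one value per gene and sample —
#' the mean of log2 probe values (the geometric mean on the original scale) —
#' then median-normalizes each sample by subtracting its median across
#' genes, so per-sample medians are exactly zero.
#'
#' @param x an \code{expr_matrix} on the log2 scale.
#' @param annotation a \code{probe_annotation}; only status-\code{ok} probes
#'   contribute. Genes with no usable probes are omitted with a warning.
#' @return A genes-by-samples numeric matrix of median-centered log2 values.
#' @export
gene_panel_profile <- function(x, annotation) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "raw")
    stop("gene panel profiling expects log2 values", call. = FALSE)
  ok <- annotation[annotation$status == "ok", , drop = FALSE]
  idx <- match(rownames(x$values), ok$probe_id)
  keep <- !is.na(idx)
  genes_all <- unique(ok$gene)
  vals <- x$values[keep, , drop = FALSE]
  gene_of <- ok$gene[idx[keep]]
  if (!nrow(vals)) stop("no annotated probes in the matrix", call. = FALSE)
  f <- factor(gene_of, levels = unique(gene_of))
  prof <- rowsum(vals, f) / as.vector(table(f))
  missing <- setdiff(genes_all, rownames(prof))
  if (length(missing))
    warning("genes with no measured probes omitted: ",
            paste(missing, collapse = ", "))
  med <- apply(prof, 2L, stats::median)
  sweep(prof, 2L, med, `-`)
}
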