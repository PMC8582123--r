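#' Exact p-value for complete separation of two small groups
#'
#' The strongest evidence a non-parametric rank test can give for two groups
#' of sizes n_a and n_b is complete separation (every value in one group
#' above every value in the other). Its exact two-sided p-value is the
#' probability of either fully separated labeling under the permutation
#' null:
#' \deqn{p = 2 / \binom{n_a + n_b}{n_a}.}
#' Two triplets give p = 0.1, the floor for reporting three datapoints per
#' condition.
#'
#' @param n_a,n_b group sizes (>= 1).
#' @return The exact two-sided p-value (capped at 1).
#' @export
exact_separation_pvalue <- function(n_a, n_b) {
  stopifnot(n_a >= 1L, n_b >= 1L)
  min(1, 2 / choose(n_a + n_b, n_a))
}

#' Coverage of the geometric-mean +/- SEM interval for the median
#'
#' Under a lognormal model, the geometric mean of n observations estimates
#' the population median, and the plotted interval geometric mean divided /
#' multiplied by the SEM factor corresponds on the log scale to mean +/- one
#' standard error. Its coverage of the true median is
#' \deqn{P(|T_{n-1}| \le 1)}
#' (Student t with n - 1 degrees of freedom): about 58\% for n = 3, rising
#' toward \eqn{P(|N(0,1)| \le 1) \approx 0.6827} for large n.
#'
#' @param n number of observations (>= 2).
#' @return Coverage probability in (0, 1).
#' @export
interval_coverage <- function(n) {
  stopifnot(n >= 2L)
  2 * stats::pt(1, df = n - 1) - 1
}

#' Geometric mean with SEM interval
#'
#' Summarizes positive measurements as the geometric mean (an estimator of
#' the population median under a lognormal model) with the interval obtained
#' by dividing/multiplying by the SEM factor: on the log2 scale,
#' mean +/- sd/sqrt(n), transformed back.
#'
#' @param x positive numeric values on the original scale.
#' @return List of class \code{summary_interval}: \code{geomean},
#'   \code{lower}, \code{upper}, \code{n}, \code{sem_log2}.
#' @export
geometric_mean_sem <- function(x) {
  x <- x[is.finite(x)]
  if (any(x <= 0)) stop("values must be positive", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  l <- log2(x)
  m <- mean(l)
  sem <- stats::sd(l) / sqrt(length(l))
  structure(list(geomean = 2^m, lower = 2^(m - sem), upper = 2^(m + sem),
                 n = length(l), sem_log2 = sem),
            class = "summary_interval")
}

#' @export
print.summary_interval <- function(x, ...) {
  cat(sprintf(
    "geometric mean %.4g [%.4g, %.4g] (n = %d, interval = %.0f%% CI for the median)\n",
    x$geomean, x$lower, x$upper, x$n, 100 * interval_coverage(x$n)))
  invisible(x)
}

#' Normalize qPCR measurements to a reference gene with plate centering
#'
#' Converts qPCR readouts to log2 expression relative to an endogenous
#' reference gene measured in the same sample, then removes systematic plate
#' effects (and optionally systematic cell-line differences) by centering:
#' for each target gene, each plate's (or line's) values are shifted so the
#' plate means (medians when \code{robust_plate}, for large between-condition
#' variation) coincide with the gene's overall mean.
#'
#' @param data data frame with columns \code{sample}, \code{gene},
#'   \code{value}, and optionally \code{plate} and \code{cell_line}.
#' @param reference_gene label of the endogenous reference (e.g. "HPRT");
#'   it must be measured in every sample (and hence on every plate).
#' @param value_type \code{"expression"} (positive linear values,
#'   log2-transformed) or \code{"ct"} (cycle thresholds; relative log2
#'   expression is reference Ct minus gene Ct).
#' @param robust_plate use medians instead of means for plate centering.
#' @param center_lines also remove per-cell-line means (per gene), for
#'   designs comparing treatments within lines.
#' @return The input data frame without the reference-gene rows, with a
#'   \code{norm_log2} column of normalized log2 relative expression.
#' @export
qpcr_normalize <- function(data, reference_gene,
                           value_type = c("expression", "ct"),
                           robust_plate = FALSE, center_lines = FALSE) {
  value_type <- match.arg(value_type)
  req <- c("sample", "gene", "value")
  missing <- setdiff(req, names(data))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  ref <- data[data$gene == reference_gene, , drop = FALSE]
  if (!nrow(ref))
    stop("reference gene '", reference_gene, "' not in the data",
         call. = FALSE)
  no_ref <- setdiff(unique(data$sample), unique(ref$sample))
  if (length(no_ref))
    stop("samples without the reference gene: ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  if ("plate" %in% names(data)) {
    ref_plates <- unique(ref$plate)
    missing_pl <- setdiff(unique(data$plate), ref_plates)
    if (length(missing_pl))
      stop("plates without the reference gene: ",
           paste(missing_pl, collapse = ", "), call. = FALSE)
  }

  out <- data[data$gene != reference_gene, , drop = FALSE]
  ref_val <- ref$value[match(out$sample, ref$sample)]
  out$norm_log2 <- if (value_type == "expression") {
    if (any(out$value <= 0) || any(ref_val <= 0))
      stop("expression values must be positive", call. = FALSE)
    log2(out$value) - log2(ref_val)
  } else {
    ref_val - out$value
  }

  center <- function(v, grp, robust) {
    fun <- if (robust) stats::median else mean
    overall <- fun(v)
    shift <- stats::ave(v, grp, FUN = fun)
    v - shift + overall
  }
  if ("plate" %in% names(out) && length(unique(out$plate)) > 1L) {
    for (g in unique(out$gene)) {
      i <- out$gene == g
      out$norm_log2[i] <- center(out$norm_log2[i], out$plate[i],
                                 robust_plate)
    }
  }
  if (center_lines && "cell_line" %in% names(out) &&
      length(unique(out$cell_line)) > 1L) {
    for (g in unique(out$gene)) {
      i <- out$gene == g
      out$norm_log2[i] <- center(out$norm_log2[i], out$cell_line[i], FALSE)
    }
  }
  rownames(out) <- NULL
  out
}
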