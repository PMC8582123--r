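#' Expression matrix container
#'
#' A probes-by-samples matrix of fluorescence intensities for one microarray
#' platform, together with the platform id and the scale of the values:
#' \code{"raw"} (linear intensities), \code{"log2"}, or \code{"floored_log2"}
#' (log2 values truncated at a detection floor and translated down, so all
#' entries are >= 0 and 0 means "at or below the floor").
#'
#' @param values numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @param platform platform identifier (single string).
#' @param scale one of \code{"raw"}, \code{"log2"}, \code{"floored_log2"}.
#' @param allow_duplicate_probes allow duplicated probe ids (pre-collapse
#'   matrices built in memory); file readers never allow them.
#' @return An object of class \code{expr_matrix}.
#' @export
expression_matrix <- function(values, platform,
                              scale = c("log2", "raw", "floored_log2"),
                              allow_duplicate_probes = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe rownames and sample colnames",
         call. = FALSE)
  if (!allow_duplicate_probes && anyDuplicated(rownames(values)))
    stop("duplicated probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (scale == "floored_log2" && any(values < 0, na.rm = TRUE))
    stop("floored_log2 values must be >= 0", call. = FALSE)
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw intensities must be >= 0", call. = FALSE)
  structure(list(values = values,
                 platform = as.character(platform)[1L],
                 scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> platform %s: %d probes x %d samples (%s scale)\n",
              x$platform, nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a probes-by-samples expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds probe ids and whose
#' header row holds sample ids. Every cell must parse as a number; duplicate
#' probe or sample ids are an error.
#'
#' @param path file path.
#' @param platform platform identifier attached to the matrix.
#' @param scale scale of the stored values (see
#'   \code{\link{expression_matrix}}).
#' @return An \code{expr_matrix} with ids in file order.
#' @export
read_expression_matrix <- function(path,
                                   platform,
                                   scale = c("log2", "raw", "floored_log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expected a probe-id column plus at least one sample column",
         call. = FALSE)
  probes <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(probes))
    stop("duplicated probe ids in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(probes, samples))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at probe '%s', sample '%s'",
                 probes[bad[1L]], samples[bad[2L]]), call. = FALSE)
  }
  expression_matrix(vals, platform = platform, scale = scale)
}

#' @rdname read_expression_matrix
#' @param x an \code{expr_matrix}.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(probe_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sentinel ORF label used for empty-vector control samples
#' @export
EMPTY_VECTOR <- "EMPTY_VECTOR"

#' Sample sheet constructor and reader
#'
#' A sample sheet carries one row per array sample: sample id, the ORF
#' transduced (empty-vector controls carry the sentinel label
#' \code{"EMPTY_VECTOR"}), replicate index, processing batch, platform, an
#' empty-vector flag, and optionally an \code{is_repeat} flag marking re-run
#' QC samples that \code{\link{collapse_duplicates}} drops.
#'
#' @param df data frame with columns \code{sample_id}, \code{orf},
#'   \code{replicate}, \code{batch}, \code{platform}, \code{is_empty_vector}
#'   (and optionally \code{is_repeat}).
#' @return A validated \code{sample_sheet} data frame.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "orf", "replicate", "batch", "platform",
           "is_empty_vector")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("sample sheet is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$orf <- as.character(df$orf)
  df$replicate <- as.integer(df$replicate)
  df$batch <- as.character(df$batch)
  df$platform <- as.character(df$platform)
  df$is_empty_vector <- as.logical(df$is_empty_vector)
  if ("is_repeat" %in% names(df)) df$is_repeat <- as.logical(df$is_repeat)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (any(df$replicate < 1L, na.rm = TRUE) || anyNA(df$replicate))
    stop("replicate indices must be positive integers", call. = FALSE)
  if (any(df$is_empty_vector != (df$orf == EMPTY_VECTOR)))
    stop("empty-vector flag and the '", EMPTY_VECTOR,
         "' sentinel ORF label must agree", call. = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname sample_sheet
#' @param path tab-delimited file with the required columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' @rdname sample_sheet
#' @param sheet a \code{sample_sheet}.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Replicate count per ORF on a platform
#' @param sheet a \code{sample_sheet}.
#' @param platform optional platform id to restrict to.
#' @return named integer vector, ORF label -> number of replicate samples.
#' @export
replicate_counts <- function(sheet, platform = NULL) {
  if (!is.null(platform)) sheet <- sheet[sheet$platform == platform, ]
  tab <- table(sheet$orf)
  stats::setNames(as.integer(tab), names(tab))
}

#' Probe annotation reader
#'
#' One row per probe: probe id, target gene symbol, platform, and a status
#' flag (\code{ok}, \code{bad}, \code{no_match}). Probes whose status is not
#' \code{ok} are removed before gene-level analysis.
#'
#' @param path tab-delimited file with columns \code{probe_id}, \code{gene},
#'   \code{platform} and optionally \code{status} (defaults to \code{ok}).
#' @return data frame of class \code{probe_annotation}.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param df data frame with the annotation columns.
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "gene", "platform")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("probe annotation is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"status" %in% names(df)) df$status <- "ok"
  bad <- setdiff(unique(df$status), c("ok", "bad", "no_match"))
  if (length(bad))
    stop("unknown probe status values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("a probe must map to exactly one gene; duplicated probe ids: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "),
         call. = FALSE)
  df$probe_id <- as.character(df$probe_id)
  df$gene <- as.character(df$gene)
  df$platform <- as.character(df$platform)
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' @rdname read_probe_annotation
#' @param annotation a \code{probe_annotation}.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name  description  member  member ...}. Duplicate members within a
#' set are deduplicated; a line with fewer than three fields is malformed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> unique members) with
#'   a \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- structure(list(), names = character())
    attr(out, "description") <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed GMT line ", which(nf < 3L)[1L],
         ": expected name, description and at least one member",
         call. = FALSE)
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicated gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Cross-validate a sample sheet against an expression matrix
#'
#' Checks that the matrix's samples and the sheet's samples for that platform
#' coincide exactly; any sample present on only one side is an error.
#'
#' @param x an \code{expr_matrix}.
#' @param sheet a \code{sample_sheet}.
#' @return invisibly TRUE on success.
#' @export
validate_samples <- function(x, sheet) {
  stopifnot(inherits(x, "expr_matrix"))
  in_sheet <- sheet$sample_id[sheet$platform == x$platform]
  in_mat <- colnames(x$values)
  only_mat <- setdiff(in_mat, in_sheet)
  only_sheet <- setdiff(in_sheet, in_mat)
  if (length(only_mat) || length(only_sheet))
    stop("sample sheet / matrix mismatch for platform ", x$platform,
         if (length(only_mat))
           paste0("; only in matrix: ", paste(only_mat, collapse = ", ")),
         if (length(only_sheet))
           paste0("; only in sheet: ", paste(only_sheet, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}
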