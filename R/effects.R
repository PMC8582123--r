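#' Gene-level effect matrix merged across platforms
#'
#' Builds the genes-by-ORFs matrix of log2 effect sizes that similarity
#' scoring and embedding consume. The probe set is the union of all probes
#' flagged HIT in ANY condition on either platform; for each gene and each
#' ORF — including ORFs for which the gene was not a HIT — the effect is the
#' arithmetic mean on the log2 scale (the geometric mean of fold effects) of
#' the selected probes' deviations, pooling probes across platforms with
#' equal weight per probe.
#'
#' @param hits a \code{hit_table} from \code{\link{call_gene_hits}} whose
#'   probe records cover every (ORF, probe) pair of the screen.
#' @param per_platform_average if TRUE, average probes within each platform
#'   first and then average the platform means (default FALSE: equal weight
#'   per probe).
#' @return An object of class \code{effect_matrix}: a genes-by-ORFs numeric
#'   matrix (rows = genes hit in >= 1 condition).
#' @export
build_effect_matrix <- function(hits, per_platform_average = FALSE) {
  stopifnot(inherits(hits, "hit_table"))
  rec <- hits$probe_records
  key <- paste(rec$platform, rec$probe_id)
  sel_keys <- unique(key[rec$probe_hit])
  if (!length(sel_keys))
    stop("no probe was flagged HIT in any condition", call. = FALSE)
  sel <- rec[key %in% sel_keys, , drop = FALSE]
  genes <- sort(unique(sel$gene))
  orfs <- unique(rec$orf)
  if (per_platform_average) {
    pg <- paste(sel$gene, sel$orf, sel$platform, sep = "\r")
    pm <- tapply(sel$deviation, pg, mean)
    parts <- do.call(rbind, strsplit(names(pm), "\r", fixed = TRUE))
    eff <- tapply(as.numeric(pm),
                  list(factor(parts[, 1L], levels = genes),
                       factor(parts[, 2L], levels = orfs)), mean)
  } else {
    eff <- tapply(sel$deviation,
                  list(factor(sel$gene, levels = genes),
                       factor(sel$orf, levels = orfs)), mean)
  }
  eff <- matrix(as.numeric(eff), nrow = length(genes),
                dimnames = list(genes, orfs))
  if (anyNA(eff))
    stop("internal error: effect matrix has missing entries", call. = FALSE)
  class(eff) <- c("effect_matrix", class(eff))
  eff
}

#' Write / read an effect matrix as TSV
#' @param effects an \code{effect_matrix} (genes x ORFs).
#' @param path file path.
#' @export
write_effect_matrix <- function(effects, path) {
  out <- data.frame(gene = rownames(effects), unclass(effects),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_matrix
#' @export
read_effect_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[-1L])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  class(m) <- c("effect_matrix", class(m))
  m
}
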