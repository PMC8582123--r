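#' Hypergeometric gene-set over-representation of a HIT list
#'
#' For each gene set, tests whether the HIT list overlaps the set more than
#' expected by chance against a fixed gene universe (upper-tail
#' hypergeometric probability of at least the observed overlap), with
#' Benjamini-Hochberg adjustment across the sets tested. The natural
#' universe for a screen is the set of genes detected on the arrays, not the
#' whole genome. Fold enrichment is
#' (overlap / HIT-list size) / (set size / universe size).
#'
#' @param hits character vector of HIT genes; must be a subset of
#'   \code{universe}.
#' @param sets named list of gene sets (e.g. from \code{\link{read_gmt}});
#'   each set is intersected with the universe before testing.
#' @param universe character vector of all eligible genes.
#' @return data frame of class \code{enrichment_result}: one row per set
#'   with \code{set}, \code{overlap}, \code{set_size}, \code{n_hits},
#'   \code{universe_size}, \code{fold}, \code{p}, \code{q} (BH), sorted by
#'   p.
#' @export
hypergeometric_enrichment <- function(hits, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  out_of <- setdiff(hits, universe)
  if (length(out_of))
    stop("HIT genes outside the universe: ",
         paste(utils::head(out_of, 5L), collapse = ", "), call. = FALSE)
  N <- length(universe)
  n <- length(hits)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    m <- length(s)
    k <- length(intersect(hits, s))
    p <- if (m == 0L) 1 else
      stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    fold <- if (m == 0L || n == 0L) NA_real_ else (k / n) / (m / N)
    data.frame(set = nm, overlap = k, set_size = m, n_hits = n,
               universe_size = N, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(set = character(), overlap = integer(),
                      set_size = integer(), n_hits = integer(),
                      universe_size = integer(), fold = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Over-representation across all ORF HIT lists
#'
#' Runs \code{\link{hypergeometric_enrichment}} for every ORF's gene-HIT
#' list and adjusts p-values by Benjamini-Hochberg across all (ORF, set)
#' tests jointly.
#'
#' @param hit_table a \code{hit_table}.
#' @param sets named list of gene sets.
#' @param universe character vector of eligible genes (typically the genes
#'   detected in the screen).
#' @param min_hits skip ORFs with fewer HIT genes than this (default 1).
#' @return data frame with an \code{orf} column plus the columns of
#'   \code{\link{hypergeometric_enrichment}}; \code{q} is joint-BH.
#' @export
enrich_hit_lists <- function(hit_table, sets, universe, min_hits = 1L) {
  stopifnot(inherits(hit_table, "hit_table"))
  orfs <- hit_table$orf_counts$orf[
    hit_table$orf_counts$n_genes_total >= min_hits]
  res <- lapply(orfs, function(o) {
    h <- intersect(hit_genes(hit_table, o), universe)
    if (!length(h)) return(NULL)
    r <- hypergeometric_enrichment(h, sets, universe)
    cbind(orf = o, as.data.frame(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Overlap between two ORFs' gene-HIT lists
#'
#' Direction-agnostic intersection of two HIT lists, with shared fractions
#' relative to each ORF (e.g. "ORF A had 119 of its 268 HITs in common with
#' ORF B" style statements).
#'
#' @param hit_table a \code{hit_table}.
#' @param orf_a,orf_b ORF labels.
#' @return List with \code{count_a}, \code{count_b}, \code{shared},
#'   \code{fraction_a} (shared / count_a), \code{fraction_b}, and the
#'   \code{shared_genes}.
#' @export
hit_overlap <- function(hit_table, orf_a, orf_b) {
  a <- hit_genes(hit_table, orf_a)
  b <- hit_genes(hit_table, orf_b)
  shared <- intersect(a, b)
  list(count_a = length(a), count_b = length(b), shared = length(shared),
       fraction_a = if (length(a)) length(shared) / length(a) else NA_real_,
       fraction_b = if (length(b)) length(shared) / length(b) else NA_real_,
       shared_genes = shared)
}
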