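#' Asymmetric ORF similarity score
#'
#' The score of a source ORF on a reference ORF is the inner product of
#' their gene-level log2 effects over the reference's HIT genes, scaled so
#' that the reference scores exactly 1 on itself:
#' \deqn{s(\mathrm{src}, \mathrm{ref}) =
#'   \frac{\sum_{g \in H(\mathrm{ref})} e_\mathrm{src}(g)\, e_\mathrm{ref}(g)}
#'        {\sum_{g \in H(\mathrm{ref})} e_\mathrm{ref}(g)^2}.}
#' Scores are not symmetric (only the reference's HIT list enters); a
#' negative score means an opposite effect on that transcriptomic program.
#'
#' @param effects an \code{effect_matrix} (genes x ORFs).
#' @param source,reference ORF labels (columns of \code{effects}).
#' @param reference_hits character vector of the reference's HIT genes.
#' @return A single numeric score.
#' @export
similarity_score <- function(effects, source, reference, reference_hits) {
  if (!length(reference_hits))
    stop("the reference has an empty HIT list", call. = FALSE)
  g <- intersect(reference_hits, rownames(effects))
  if (!length(g))
    stop("none of the reference's HIT genes are in the effect matrix",
         call. = FALSE)
  er <- effects[g, reference]
  es <- effects[g, source]
  sum(es * er) / sum(er * er)
}

#' Score all ORFs against all reference ORFs
#'
#' Every ORF with at least \code{config$min_hits_reference} gene HITs is a
#' reference; every ORF (reference or not) is scored as a source against
#' every reference. Directed edges source -> reference are retained for
#' scores strictly greater than \code{config$edge_score_threshold}
#' (positive scores only); self-edges are excluded.
#'
#' @param effects an \code{effect_matrix}.
#' @param hits a \code{hit_table}.
#' @param config a \code{\link{screen_config}}.
#' @return List of class \code{similarity_result}: \code{scores} (sources x
#'   references matrix), \code{references}, \code{reference_hits} (named
#'   list), \code{edges} (data frame source / reference / score),
#'   \code{hit_counts} (named, per scored ORF), and \code{embedding}
#'   (NULL until \code{\link{tsne_embed}} fills it).
#' @export
score_matrix <- function(effects, hits, config = screen_config()) {
  stopifnot(inherits(hits, "hit_table"))
  counts <- stats::setNames(hits$orf_counts$n_genes_total,
                            hits$orf_counts$orf)
  orfs <- colnames(effects)
  counts <- counts[orfs]
  refs <- orfs[!is.na(counts) & counts >= config$min_hits_reference]
  if (!length(refs)) {
    warning("no ORF reaches ", config$min_hits_reference,
            " gene HITs; empty similarity result")
    return(structure(list(scores = matrix(numeric(), nrow = length(orfs),
                                          ncol = 0L,
                                          dimnames = list(orfs, NULL)),
                          references = character(),
                          reference_hits = list(),
                          edges = data.frame(source = character(),
                                             reference = character(),
                                             score = numeric()),
                          hit_counts = counts, embedding = NULL,
                          config = config),
                     class = "similarity_result"))
  }
  ref_hits <- lapply(refs, function(r)
    intersect(hit_genes(hits, r), rownames(effects)))
  names(ref_hits) <- refs
  scores <- vapply(refs, function(r) {
    g <- ref_hits[[r]]
    er <- effects[g, r]
    as.vector(crossprod(effects[g, , drop = FALSE], er)) / sum(er * er)
  }, numeric(length(orfs)))
  scores <- matrix(scores, nrow = length(orfs),
                   dimnames = list(orfs, refs))
  idx <- which(scores > config$edge_score_threshold, arr.ind = TRUE)
  edges <- data.frame(source = orfs[idx[, 1L]],
                      reference = refs[idx[, 2L]],
                      score = scores[idx], stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$reference, , drop = FALSE]
  edges <- edges[order(-edges$score), ]
  rownames(edges) <- NULL
  structure(list(scores = scores, references = refs,
                 reference_hits = ref_hits, edges = edges,
                 hit_counts = counts, embedding = NULL, config = config),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> %d sources x %d references, %d edges (score > %g)\n",
    nrow(x$scores), length(x$references), nrow(x$edges),
    x$config$edge_score_threshold))
  if (!is.null(x$embedding)) cat("  with 2-D embedding\n")
  invisible(x)
}

## ---- exact t-SNE -----------------------------------------------------------

# Perplexity-calibrated joint probabilities: per-point binary search on the
# Gaussian precision so each conditional distribution has entropy
# log(perplexity); then symmetrize.
tsne_joint_p <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf
    hi <- Inf
    for (it in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) {
        H <- 0
      } else {
        H <- log(sp) + beta * sum(di * p) / sp
      }
      if (abs(H - logU) < 1e-7) break
      if (H > logU) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- if (sp > 0) p / sp else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Gradient descent on the KL divergence with Student-t low-dimensional
# kernel; standard early exaggeration, momentum switch and adaptive gains.
tsne_descent <- function(P, Y, max_iter = 500L, eta = 100,
                         exaggerate = TRUE) {
  n <- nrow(Y)
  inc <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  exag_until <- if (exaggerate) 100L else 0L
  for (iter in seq_len(max_iter)) {
    Pc <- if (iter <= exag_until) P * 4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pc - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter < 250L) 0.5 else 0.8
    same <- sign(grad) == sign(inc)
    gains <- pmax((gains + 0.2) * !same + gains * 0.8 * same, 0.01)
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y), `-`)
  }
  Y
}

#' Averaged t-SNE embedding of reference ORFs
#'
#' Embeds the reference ORFs' gene-level effect vectors (log2 scale) in 2-D
#' with exact t-SNE. Because t-SNE solutions vary with initialization, the
#' embedding is run \code{config$tsne_runs} times with independent seeds;
#' runs 2..k are aligned to the first by Procrustes rotation (rotation,
#' reflection and scaling, via \code{vegan::procrustes}) before averaging —
#' averaging unaligned runs would cancel structure — and the average is used
#' as the initialization of a final refinement run. Deterministic given
#' \code{seed}.
#'
#' @param effects an \code{effect_matrix}.
#' @param references ORF labels to embed (>= 3; typically the references of
#'   a \code{similarity_result}).
#' @param config a \code{\link{screen_config}}; \code{tsne_perplexity} must
#'   be below \code{(length(references) - 1) / 3}.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations per run.
#' @return Matrix (references x 2, columns \code{x}, \code{y}).
#' @export
tsne_embed <- function(effects, references, config = screen_config(),
                       seed = config$rng_seed, max_iter = 500L) {
  if (length(references) < 3L)
    stop("at least 3 reference ORFs are needed for an embedding; ",
         "consider lowering min_hits_reference", call. = FALSE)
  if (config$tsne_perplexity >= (length(references) - 1) / 3)
    stop("perplexity must be below (number of references - 1)/3 = ",
         format((length(references) - 1) / 3, digits = 3L),
         "; lower tsne_perplexity", call. = FALSE)
  X <- t(unclass(effects)[, references, drop = FALSE])
  P <- tsne_joint_p(X, config$tsne_perplexity)
  n <- nrow(X)
  runs <- vector("list", config$tsne_runs)
  for (k in seq_len(config$tsne_runs)) {
    set.seed(seed + k)
    Y0 <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
    runs[[k]] <- tsne_descent(P, Y0, max_iter = max_iter, exaggerate = TRUE)
  }
  aligned <- runs
  if (length(runs) > 1L) {
    for (k in 2:length(runs))
      aligned[[k]] <- vegan::procrustes(runs[[1L]], runs[[k]],
                                        symmetric = FALSE)$Yrot
  }
  Ybar <- Reduce(`+`, aligned) / length(aligned)
  Y <- tsne_descent(P, Ybar, max_iter = max_iter, exaggerate = FALSE)
  dimnames(Y) <- list(references, c("x", "y"))
  Y
}

#' Export the similarity network to GraphML and TSV
#'
#' Builds a directed igraph graph whose nodes are the scored ORFs (with HIT
#' count, reference flag, and embedding coordinates where available; node
#' size is proportional to the HIT count) and whose edges are the
#' thresholded similarity scores, then writes GraphML and an edge-list TSV.
#'
#' @param result a \code{similarity_result} (with or without embedding).
#' @param graphml_path output GraphML path.
#' @param edges_path optional output TSV path for the edge list.
#' @return The igraph graph, invisibly.
#' @export
export_graph <- function(result, graphml_path, edges_path = NULL) {
  stopifnot(inherits(result, "similarity_result"))
  orfs <- rownames(result$scores)
  hitn <- result$hit_counts[orfs]
  hitn[is.na(hitn)] <- 0L
  nodes <- data.frame(name = orfs,
                      hits = as.integer(hitn),
                      is_reference = orfs %in% result$references,
                      size = 1 + as.integer(hitn),
                      stringsAsFactors = FALSE)
  if (!is.null(result$embedding)) {
    nodes$x <- result$embedding[match(orfs, rownames(result$embedding)), "x"]
    nodes$y <- result$embedding[match(orfs, rownames(result$embedding)), "y"]
  }
  edges <- result$edges
  names(edges)[names(edges) == "reference"] <- "to"
  names(edges)[names(edges) == "source"] <- "from"
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  igraph::E(g)$weight <- edges$score
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(result$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(g)
}
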