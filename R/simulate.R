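#' Design of a synthetic two-platform overexpression screen
#'
#' Describes the layout of a simulated screen: how many ORF conditions and
#' replicates, how many empty-vector controls, the processing batches with
#' their additive log2 shifts and multiplicative noise scales, and the
#' probe/baseline model per platform. Values on disk and in memory are log2
#' fluorescence intensities.
#'
#' The generative model for a probe p (targeting gene g) in sample s of batch
#' b transduced with ORF o is
#' \deqn{x_{ps} = \beta_p + e(g, o) + \mu_b + \sigma_b \epsilon,\quad
#'   \epsilon \sim N(0, \mathrm{noise\_sd}^2)}
#' with per-probe baseline \eqn{\beta_p}, planted ORF effect \eqn{e(g,o)}
#' (log2), batch shift \eqn{\mu_b} and batch noise scale \eqn{\sigma_b} —
#' exactly the location/scale model the batch-adjustment stage assumes.
#' Baselines of genes that carry planted effects are drawn well above the
#' platform detection floor so that planted effects stay measurable after
#' flooring.
#'
#' @param n_orfs number of ORF conditions (excluding the empty vector).
#' @param replicates_per_orf default replicate count per ORF (3, as in a
#'   triplicate screen).
#' @param orfs_n2 character vector of ORF labels run with only 2 replicates.
#' @param n_empty_vector number of empty-vector control samples (default 12).
#' @param batches data frame with columns \code{batch}, \code{shift} (log2
#'   additive), \code{scale} (multiplier on the noise sd).
#' @param platforms named list; each element a list with
#'   \code{probes_per_gene = c(lo, hi)} and \code{floor} (log2 detection
#'   floor).
#' @param n_genes number of genes on each platform.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param baseline_mean,baseline_sd log2 baseline distribution for genes
#'   without planted effects.
#' @param probe_offset_sd sd of the per-probe offset around the gene
#'   baseline.
#' @param frac_bad_probes fraction of extra probes annotated \code{bad} /
#'   \code{no_match} (removed downstream).
#' @param rng_seed integer seed; all randomness flows from it.
#' @return An object of class \code{screen_design}.
#' @export
screen_design <- function(n_orfs = 30L,
                          replicates_per_orf = 3L,
                          orfs_n2 = character(),
                          n_empty_vector = 12L,
                          batches = data.frame(
                            batch = c("B1", "B2", "B3"),
                            shift = c(-0.5, 0, 0.5),
                            scale = c(0.95, 1, 1.05)),
                          platforms = list(
                            AG = list(probes_per_gene = c(1L, 8L), floor = 8),
                            IL = list(probes_per_gene = c(1L, 3L),
                                      floor = 3.5)),
                          n_genes = 300L,
                          noise_sd = 0.25,
                          baseline_mean = 10,
                          baseline_sd = 1.5,
                          probe_offset_sd = 0.5,
                          frac_bad_probes = 0.02,
                          rng_seed = 1L) {
  stopifnot(noise_sd > 0, replicates_per_orf >= 2L, n_empty_vector >= 3L,
            n_genes >= 1L, n_orfs >= 1L)
  stopifnot(all(c("batch", "shift", "scale") %in% names(batches)))
  for (p in platforms) {
    stopifnot(length(p$probes_per_gene) == 2L,
              p$probes_per_gene[1L] >= 1L,
              p$probes_per_gene[2L] >= p$probes_per_gene[1L],
              p$floor >= 0)
  }
  structure(list(n_orfs = as.integer(n_orfs),
                 replicates_per_orf = as.integer(replicates_per_orf),
                 orfs_n2 = as.character(orfs_n2),
                 n_empty_vector = as.integer(n_empty_vector),
                 batches = batches,
                 platforms = platforms,
                 n_genes = as.integer(n_genes),
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 probe_offset_sd = probe_offset_sd,
                 frac_bad_probes = frac_bad_probes,
                 rng_seed = as.integer(rng_seed)),
            class = "screen_design")
}

#' Planted effect structure for a synthetic screen
#'
#' Defines which ORFs share a transcriptomic signature (clusters), the shared
#' signature itself (gene -> log2 effect), per-ORF private effects, and the
#' null ORFs with no effect at all.
#'
#' @param genes character vector of all gene symbols in the screen.
#' @param clusters list of clusters; each a list with \code{members}
#'   (ORF labels), \code{signature} (named numeric, gene -> log2 effect
#'   shared by every member) and optionally \code{private} (named list,
#'   ORF -> named numeric of member-specific effects).
#' @param null_orfs ORF labels with zero planted effect.
#' @return An object of class \code{effect_model}.
#' @export
effect_model <- function(genes, clusters = list(), null_orfs = character()) {
  members <- unlist(lapply(clusters, `[[`, "members"))
  if (anyDuplicated(c(members, null_orfs)))
    stop("cluster memberships and null ORFs must be disjoint", call. = FALSE)
  for (cl in clusters) {
    if (!length(cl$signature) || is.null(names(cl$signature)))
      stop("each cluster needs a named signature", call. = FALSE)
    if (any(!is.finite(cl$signature)))
      stop("signature effects must be finite", call. = FALSE)
  }
  structure(list(genes = as.character(genes), clusters = clusters,
                 null_orfs = as.character(null_orfs)),
            class = "effect_model")
}

# gene x orf matrix of planted log2 effects (zero elsewhere)
planted_effect_matrix <- function(effects, orfs) {
  E <- matrix(0, nrow = length(effects$genes), ncol = length(orfs),
              dimnames = list(effects$genes, orfs))
  for (cl in effects$clusters) {
    for (o in cl$members) {
      E[names(cl$signature), o] <- cl$signature
      priv <- cl$private[[o]]
      if (length(priv)) E[names(priv), o] <- E[names(priv), o] + priv
    }
  }
  E
}

#' Simulate a two-platform ORF overexpression screen
#'
#' Generates per-platform probe intensity matrices (log2 scale), a sample
#' sheet, probe annotations, and a ground-truth table of planted (ORF, gene)
#' effects. Deterministic given \code{design$rng_seed}.
#'
#' @param design a \code{\link{screen_design}}.
#' @param effects an \code{\link{effect_model}}; its genes must be a subset
#'   of the design's genes, and its ORFs must number \code{design$n_orfs}.
#' @return A list of class \code{synthetic_screen} with elements
#'   \code{matrices} (named list of \code{expr_matrix}, log2 scale),
#'   \code{sheet}, \code{annotations} (named list of
#'   \code{probe_annotation}), \code{truth} (data frame orf / gene / effect /
#'   detectable), \code{design}, \code{effects} and \code{orfs}.
#' @export
simulate_screen <- function(design, effects) {
  stopifnot(inherits(design, "screen_design"), inherits(effects, "effect_model"))
  genes <- sprintf("G%03d", seq_len(design$n_genes))
  if (!all(effects$genes %in% genes))
    stop("effect model genes must be a subset of the design's genes",
         call. = FALSE)
  orfs <- c(unlist(lapply(effects$clusters, `[[`, "members")),
            effects$null_orfs)
  if (length(orfs) != design$n_orfs)
    stop("effect model defines ", length(orfs), " ORFs but the design asks ",
         "for ", design$n_orfs, call. = FALSE)

  set.seed(design$rng_seed)
  eff_full <- effect_model(genes, effects$clusters, effects$null_orfs)
  E <- planted_effect_matrix(eff_full, orfs)

  ## transductions: one row per (condition, replicate); shared by platforms
  nrep <- stats::setNames(rep(design$replicates_per_orf, length(orfs)), orfs)
  nrep[design$orfs_n2] <- 2L
  cond <- c(rep(orfs, nrep), rep(EMPTY_VECTOR, design$n_empty_vector))
  repl <- c(unlist(lapply(nrep, seq_len), use.names = FALSE),
            seq_len(design$n_empty_vector))
  base_id <- sprintf("%s_r%d", cond, repl)
  batch <- sample(rep(design$batches$batch,
                      length.out = length(base_id)))

  sheets <- list()
  mats <- list()
  annots <- list()
  effect_genes <- rownames(E)[rowSums(E != 0) > 0]
  for (pf in names(design$platforms)) {
    spec <- design$platforms[[pf]]
    ppg <- sample(seq(spec$probes_per_gene[1L], spec$probes_per_gene[2L]),
                  length(genes), replace = TRUE)
    probe_gene <- rep(genes, ppg)
    probe_id <- sprintf("%s_%s_p%d", pf, probe_gene,
                        unlist(lapply(ppg, seq_len), use.names = FALSE))
    ## gene baselines; planted-effect genes stay clear of the floor
    gbase <- stats::rnorm(length(genes), design$baseline_mean,
                          design$baseline_sd)
    names(gbase) <- genes
    idx <- genes %in% effect_genes
    gbase[idx] <- stats::runif(sum(idx), spec$floor + 3.5, spec$floor + 6)
    baseline <- gbase[probe_gene] +
      stats::rnorm(length(probe_id), 0, design$probe_offset_sd)

    ## extra probes with bad / no_match annotation status
    n_bad <- max(0L, round(design$frac_bad_probes * length(probe_id)))
    if (n_bad > 0L) {
      bad_id <- sprintf("%s_BADPROBE_p%d", pf, seq_len(n_bad))
      bad_status <- sample(c("bad", "no_match"), n_bad, replace = TRUE)
      probe_id <- c(probe_id, bad_id)
      probe_gene <- c(probe_gene, rep(NA_character_, n_bad))
      baseline <- c(baseline,
                    stats::rnorm(n_bad, design$baseline_mean,
                                 design$baseline_sd))
    } else {
      bad_status <- character()
    }

    sid <- paste0(base_id, "_", pf)
    shift <- design$batches$shift[match(batch, design$batches$batch)]
    scl <- design$batches$scale[match(batch, design$batches$batch)]
    eff <- matrix(0, nrow = length(probe_id), ncol = length(sid))
    known <- !is.na(probe_gene)
    eff[known, ] <- E[probe_gene[known], match(cond, colnames(E))]
    eff[, cond == EMPTY_VECTOR] <- 0
    noise <- matrix(stats::rnorm(length(probe_id) * length(sid),
                                 0, design$noise_sd),
                    nrow = length(probe_id))
    vals <- baseline + eff +
      matrix(shift, nrow = length(probe_id), ncol = length(sid),
             byrow = TRUE) +
      sweep(noise, 2L, scl, `*`)
    dimnames(vals) <- list(probe_id, sid)
    mats[[pf]] <- expression_matrix(vals, platform = pf, scale = "log2")
    annots[[pf]] <- probe_annotation(data.frame(
      probe_id = probe_id,
      gene = ifelse(is.na(probe_gene), "NONE", probe_gene),
      platform = pf,
      status = c(rep("ok", sum(known)), bad_status),
      stringsAsFactors = FALSE))
    sheets[[pf]] <- data.frame(sample_id = sid, orf = cond,
                               replicate = repl, batch = batch,
                               platform = pf,
                               is_empty_vector = cond == EMPTY_VECTOR,
                               stringsAsFactors = FALSE)
  }
  sheet <- sample_sheet(do.call(rbind, sheets))
  rownames(sheet) <- NULL

  nz <- which(E != 0, arr.ind = TRUE)
  truth <- data.frame(orf = colnames(E)[nz[, 2L]],
                      gene = rownames(E)[nz[, 1L]],
                      effect = E[nz], stringsAsFactors = FALSE)
  has_probe <- Reduce(union, lapply(annots, function(a)
    a$gene[a$status == "ok"]))
  truth$detectable <- truth$gene %in% has_probe
  if (any(!truth$detectable))
    warning("planted effects on genes with no probes: ",
            paste(unique(truth$gene[!truth$detectable]), collapse = ", "))
  truth <- truth[order(truth$orf, truth$gene), ]
  rownames(truth) <- NULL

  structure(list(matrices = mats, sheet = sheet, annotations = annots,
                 truth = truth, design = design, effects = eff_full,
                 orfs = orfs),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "<synthetic_screen> %d ORFs (+%d empty vectors), %d planted effects\n",
    length(x$orfs), x$design$n_empty_vector, nrow(x$truth)))
  for (pf in names(x$matrices))
    cat(sprintf("  %s: %d probes x %d samples\n", pf,
                nrow(x$matrices[[pf]]$values),
                ncol(x$matrices[[pf]]$values)))
  invisible(x)
}

#' Default synthetic screen fixture
#'
#' The reference test screen: 30 ORFs — two planted clusters of 6 ORFs
#' sharing 40 and 30 signature genes respectively (shared log2 effects of
#' magnitude 2–3, plus 5 private effect genes of magnitude 2 per member) and
#' 18 null ORFs (two of them with only 2 replicates) — profiled in triplicate
#' on two platforms (an exon-array-like platform with 1–8 probes per gene and
#' a bead-array-like platform with 1–3), in 3 batches, with 12 empty-vector
#' controls. Deterministic given \code{seed}.
#'
#' @param seed integer seed (a fixed package default so the fixture is
#'   reproducible everywhere).
#' @return A \code{synthetic_screen}; see \code{\link{simulate_screen}}.
#' @export
default_fixture <- function(seed = 1847L) {
  set.seed(seed)
  genes <- sprintf("G%03d", 1:300)
  sig_mag <- function(n) sample(c(2, 2.5, 3), n, replace = TRUE) *
    sample(c(-1, 1), n, replace = TRUE)
  sig1 <- stats::setNames(sig_mag(40L), genes[1:40])
  sig2 <- stats::setNames(sig_mag(30L), genes[41:70])
  cl1 <- sprintf("ORF%02d", 1:6)
  cl2 <- sprintf("ORF%02d", 7:12)
  nulls <- sprintf("ORF%02d", 13:30)
  pool <- genes[71:300]
  private_for <- function(members) {
    out <- list()
    for (o in members) {
      g <- sample(pool, 5L)
      out[[o]] <- stats::setNames(2 * sample(c(-1, 1), 5L, replace = TRUE), g)
    }
    out
  }
  eff <- effect_model(
    genes,
    clusters = list(
      list(members = cl1, signature = sig1, private = private_for(cl1)),
      list(members = cl2, signature = sig2, private = private_for(cl2))),
    null_orfs = nulls)
  design <- screen_design(n_orfs = 30L, orfs_n2 = c("ORF29", "ORF30"),
                          rng_seed = seed + 1L)
  simulate_screen(design, eff)
}

#' Write a synthetic screen to TSV files
#'
#' Writes the per-platform expression matrices, sample sheet, probe
#' annotations and the planted-truth table into a directory.
#'
#' @param screen a \code{synthetic_screen}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the paths written.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (pf in names(screen$matrices)) {
    p <- file.path(dir, sprintf("expression_%s.tsv", pf))
    write_expression_matrix(screen$matrices[[pf]], p)
    paths[sprintf("expression_%s", pf)] <- p
    p <- file.path(dir, sprintf("annotation_%s.tsv", pf))
    write_probe_annotation(screen$annotations[[pf]], p)
    paths[sprintf("annotation_%s", pf)] <- p
  }
  p <- file.path(dir, "sample_sheet.tsv")
  write_sample_sheet(screen$sheet, p)
  paths["sample_sheet"] <- p
  p <- file.path(dir, "truth.tsv")
  utils::write.table(screen$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- p
  invisible(paths)
}
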