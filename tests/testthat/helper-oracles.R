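# Independent brute-force oracles: scalar re-implementations kept separate
# from the vectorized package code paths they check.

oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

oracle_probe_stats <- function(mat, mad_scaled = FALSE) {
  out <- data.frame(probe_id = rownames(mat), baseline = NA_real_,
                    mad = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    b <- oracle_median(mat[i, ])
    dev <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat))) dev[j] <- abs(mat[i, j] - b)
    out$baseline[i] <- b
    out$mad[i] <- oracle_median(dev) * if (mad_scaled) 1.4826 else 1
  }
  out
}

oracle_score <- function(mat, cols, b, mad, z_thr = 4, dev_thr = 1) {
  n <- length(cols)
  out <- data.frame(probe_id = rownames(mat), xbar = NA_real_,
                    deviation = NA_real_, z = NA_real_, hit = NA)
  for (i in seq_len(nrow(mat))) {
    xb <- sum(mat[i, cols]) / n
    d <- xb - b[i]
    z <- if (mad[i] > 0) d * sqrt(n) / mad[i] else NA_real_
    out$xbar[i] <- xb
    out$deviation[i] <- d
    out$z[i] <- z
    out$hit[i] <- b[i] > 0 && abs(d) > dev_thr &&
      (if (mad[i] > 0) abs(z) > z_thr else TRUE)
  }
  out
}

# per-gene mean of selected probes' deviations, scalar loops
oracle_effect_matrix <- function(records, selected_keys) {
  sel <- records[paste(records$platform, records$probe_id) %in%
                   selected_keys, ]
  genes <- sort(unique(sel$gene))
  orfs <- unique(records$orf)
  E <- matrix(NA_real_, length(genes), length(orfs),
              dimnames = list(genes, orfs))
  for (g in genes) for (o in orfs) {
    v <- sel$deviation[sel$gene == g & sel$orf == o]
    E[g, o] <- sum(v) / length(v)
  }
  E
}

oracle_similarity <- function(effects, source, reference, ref_hits) {
  num <- 0
  den <- 0
  for (g in ref_hits) {
    num <- num + effects[g, source] * effects[g, reference]
    den <- den + effects[g, reference]^2
  }
  num / den
}

# upper-tail hypergeometric by direct enumeration of the pmf
oracle_hyper_p <- function(k, m, N, n) {
  tot <- 0
  for (i in k:min(m, n))
    tot <- tot + choose(m, i) * choose(N - m, n - i) / choose(N, n)
  tot
}

# numeric-quadrature conditional mean of the normexp convolution model; the
# posterior of the signal is supported near (x - mu) +/- a few sigma, so
# integrate over that finite window for numerical stability
oracle_normexp_signal <- function(mu, sigma, alpha, x) {
  f <- function(s) exp(-s / alpha) * stats::dnorm(x - s, mu, sigma)
  lo <- max(0, x - mu - 15 * sigma)
  hi <- max(x - mu, 0) + 15 * sigma
  num <- stats::integrate(function(s) s * f(s), lo, hi,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
  num / den
}

# exhaustive two-sided rank-sum p-value for completely separated groups
oracle_separation_p <- function(n_a, n_b) {
  n <- n_a + n_b
  combs <- utils::combn(n, n_a)
  w_obs_low <- sum(seq_len(n_a))            # group A takes the lowest ranks
  w_all <- apply(combs, 2L, sum)
  w_hi <- max(w_all)
  w_lo <- min(w_all)
  stopifnot(w_obs_low == w_lo)
  mean(w_all <= w_lo | w_all >= w_hi)
}
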