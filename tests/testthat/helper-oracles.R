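## Independent oracles used across the suite. These deliberately use direct,
## brute-force formulations so they share no code with the implementation.

## Exhaustive single-change-point conjugate Gaussian posterior (flat prior
## over boundaries, flat prior on segment means, Jeffreys prior on the common
## variance): log posterior of boundary j is
##   -m/2 log(n1 n2) - (N - 2m)/2 log(RSS_j)
## where RSS_j pools within-segment squares over all series.
oracle_changepoint <- function(X) {
  n <- nrow(X); m <- ncol(X); N <- n * m
  lp <- vapply(seq_len(n - 1L), function(j) {
    top <- X[seq_len(j), , drop = FALSE]
    bot <- X[(j + 1L):n, , drop = FALSE]
    rss <- sum(sweep(top, 2L, colMeans(top))^2) +
      sum(sweep(bot, 2L, colMeans(bot))^2)
    if (rss <= 0) return(Inf)
    -m / 2 * log(j * (n - j)) - (N - 2 * m) / 2 * log(rss)
  }, numeric(1))
  which.max(lp)
}

## Brute-force BH definition: q_i = min_{k: p_k >= p_i} m p_k / rank_k
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    ks <- which(r >= r[i])
    min(1, min(m * p[ks] / r[ks]))
  }, numeric(1))
}

## Brute-force O(P*T) probe-in-tandem containment scan (genomic footprint of
## a tandem is [utr_start, distal_end) in transcript orientation)
oracle_probe_tandems <- function(probe_map, candidates) {
  lapply(seq_len(nrow(probe_map)), function(p) {
    hits <- integer(0)
    for (t in seq_len(nrow(candidates))) {
      if (candidates$strand[t] == "+") {
        lo <- candidates$utr_start[t]; hi <- candidates$distal_end[t]
      } else {
        lo <- candidates$distal_end[t]; hi <- candidates$utr_start[t]
      }
      if (probe_map$start[p] >= lo && probe_map$end[p] <= hi) hits <- c(hits, t)
    }
    hits
  })
}

## small planted-break matrix: first nc rows at 0, rest at -effect, noise sd
make_step_matrix <- function(nc = 4L, ne = 4L, m = 3L, effect = 1,
                             sd = 0, seed = 1L) {
  set.seed(seed)
  mu <- rep(c(0, -effect), c(nc, ne))
  matrix(mu, nc + ne, m) + matrix(rnorm((nc + ne) * m, 0, sd), nc + ne, m)
}

## a fabricated changepoint_result for unit-testing QC and SUI in isolation
fake_cp_result <- function(rho, posterior_means, change_index = which.max(rho),
                           qc_status = "OK") {
  structure(list(rho = rho, posterior_means = posterior_means,
                 change_index = as.integer(change_index),
                 max_rho = max(rho), qc_status = qc_status,
                 n = nrow(posterior_means), m = ncol(posterior_means)),
            class = "changepoint_result")
}
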