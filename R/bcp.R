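#' Parameters for the Bayesian change-point sampler
#'
#' Priors follow the product-partition model of Barry and Hartigan: the
#' boundary change probability has a uniform prior on `(0, p0)` and the
#' signal-to-noise weight a uniform prior on `(0, w0)`.
#'
#' @param p0 prior upper bound on the change probability (default 0.2).
#' @param w0 prior upper bound on the signal-to-noise weight (default 0.2).
#' @param burnin discarded Gibbs sweeps (default 50).
#' @param mcmc retained Gibbs sweeps (default 500).
#' @param seed integer seed; the sampler is deterministic given the seed.
#' @return A `bcp_params` list.
#' @export
bcp_params <- function(p0 = 0.2, w0 = 0.2, burnin = 50L, mcmc = 500L, seed = 1L) {
  stopifnot(p0 > 0, p0 <= 1, w0 > 0, w0 <= 1, mcmc >= 1L, burnin >= 0L)
  structure(list(p0 = p0, w0 = w0, burnin = as.integer(burnin),
                 mcmc = as.integer(mcmc), seed = as.integer(seed)),
            class = "bcp_params")
}

#' Multivariate Bayesian change-point detection for one tandem 3'UTR
#'
#' Treats all samples of a tandem 3'UTR as a multivariate series with a
#' common change point: a Gibbs sampler over the binary change-indicator
#' vector of the product-partition model, with the partition shared across
#' all sample series. `rho[j]` is the fraction of retained sweeps carrying a
#' change at inter-probe boundary `j` (between probes `j` and `j+1`);
#' posterior means are the sweep-average of within-block means per sample.
#' The change point is the boundary with maximal posterior probability
#' (ties broken toward the smallest index).
#'
#' @param X probes x samples matrix, rows ordered 5'->3' in transcript
#'   orientation (typically normal-median normalized log2 intensities).
#' @param params a [bcp_params()].
#' @return A `changepoint_result`: `rho` (length `nrow(X) - 1`),
#'   `posterior_means` (same shape as `X`), `change_index`, `max_rho`,
#'   `qc_status` (`"OK"` here; see [qc_filter()]), `n`, `m`. Inputs with
#'   fewer than 8 probes return `qc_status = "TOO_FEW_PROBES"` without
#'   sampling: four probes are required on each side of a prospective site.
#' @export
bcp_multivariate <- function(X, params = bcp_params()) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in change-point input")
  n <- nrow(X); m <- ncol(X)
  if (n < 8L) {
    return(structure(list(rho = NULL, posterior_means = NULL,
                          change_index = NA_integer_, max_rho = NA_real_,
                          qc_status = "TOO_FEW_PROBES", n = n, m = m),
                     class = "changepoint_result"))
  }
  set.seed(params$seed)
  fit <- .bcp_gibbs_cpp(X, params$p0, params$w0, params$burnin, params$mcmc)
  dimnames(fit$posterior_means) <- dimnames(X)
  ci <- which.max(fit$rho)               # first max = smallest boundary on ties
  structure(list(rho = fit$rho, posterior_means = fit$posterior_means,
                 change_index = as.integer(ci), max_rho = fit$rho[ci],
                 qc_status = "OK", n = n, m = m),
            class = "changepoint_result")
}

#' QC a change-point fit for multiple APAs and unstable segments
#'
#' Reproduces the exclusion rules applied after change-point fitting:
#' `MULTI_PEAK` when the posterior change probability has more than one local
#' maximum reaching `peak_frac` of the global maximum with maxima at least 2
#' boundaries apart (multiple APA sites); `UNSTABLE` when, averaged over
#' samples, the within-segment standard deviation of the posterior means
#' exceeds `stability_ratio` times the absolute between-segment mean
#' difference in either segment.
#'
#' @param result a `changepoint_result` from [bcp_multivariate()].
#' @param peak_frac fraction of the global maximum a secondary peak must
#'   reach to count (default 0.5).
#' @param stability_ratio allowed ratio of within-segment SD to the
#'   between-segment mean difference (default 0.5).
#' @return `"OK"`, `"MULTI_PEAK"`, `"UNSTABLE"`, or `"TOO_FEW_PROBES"`.
#' @export
qc_filter <- function(result, peak_frac = 0.5, stability_ratio = 0.5) {
  if (result$qc_status == "TOO_FEW_PROBES") return("TOO_FEW_PROBES")
  rho <- result$rho
  nb <- length(rho)
  ## local maxima (plateaus collapse to their first boundary)
  is_peak <- vapply(seq_len(nb), function(j) {
    left <- if (j == 1L) -Inf else rho[j - 1L]
    right <- if (j == nb) -Inf else rho[j + 1L]
    rho[j] > left && rho[j] >= right
  }, logical(1))
  peaks <- which(is_peak & rho >= peak_frac * max(rho))
  if (length(peaks) > 1L && any(diff(peaks) >= 2L)) {
    ## at least two qualifying maxima separated by >= 2 boundaries
    sep <- outer(peaks, peaks, function(a, b) abs(a - b))
    if (any(sep[upper.tri(sep)] >= 2L)) return("MULTI_PEAK")
  }
  pm <- result$posterior_means
  c <- result$change_index
  m1 <- colMeans(pm[seq_len(c), , drop = FALSE])
  m2 <- colMeans(pm[(c + 1L):nrow(pm), , drop = FALSE])
  sd1 <- apply(pm[seq_len(c), , drop = FALSE], 2L, sd)
  sd2 <- apply(pm[(c + 1L):nrow(pm), , drop = FALSE], 2L, sd)
  gap <- mean(abs(m1 - m2))
  if (mean(sd1) > stability_ratio * gap || mean(sd2) > stability_ratio * gap) {
    return("UNSTABLE")
  }
  "OK"
}

#' Short 3'UTR index (SUI) per sample for one tandem
#'
#' The change point partitions probes into the common region (ordinals up to
#' the change index) and the extended region (beyond it). For sample i the
#' SUI contrasts the posterior segment levels, `SUI_i = wbar_ic - wbar_ie`
#' (means of the posterior means over common and extended probes). On
#' normal-median normalized input a normal-like sample has SUI near 0, and a
#' higher SUI means a higher proportion of the short 3'UTR isoform. The
#' contrast is isolated in this one function so an alternative combination
#' of the two segment summaries can be substituted in a single place.
#'
#' @param result a `changepoint_result` with `qc_status == "OK"`.
#' @return named numeric vector of per-sample SUI values.
#' @export
compute_sui <- function(result) {
  stopifnot(inherits(result, "changepoint_result"))
  if (result$qc_status != "OK") {
    stop("SUI requires a change-point fit with qc_status 'OK', got '",
         result$qc_status, "'")
  }
  pm <- result$posterior_means
  c <- result$change_index
  if (c < 1L || c >= nrow(pm)) stop("change index leaves an empty segment")
  w_common <- colMeans(pm[seq_len(c), , drop = FALSE])
  w_extended <- colMeans(pm[(c + 1L):nrow(pm), , drop = FALSE])
  w_common - w_extended
}

#' Per-tandem z-scores of an SUI matrix
#'
#' Standardizes each tandem's SUI across samples using the sample (n-1)
#' standard deviation. Tandems with zero spread cannot be standardized and
#' are flagged with missing z-scores.
#'
#' @param sui tandems x samples SUI matrix.
#' @return list: `z` (same shape; rows with zero SD set to `NA`), `flagged`
#'   (tandem IDs with zero SD).
#' @export
sui_zscores <- function(sui) {
  stopifnot(is.matrix(sui))
  mu <- rowMeans(sui)
  s <- apply(sui, 1L, sd)
  z <- (sui - mu) / s
  flagged <- rownames(sui)[s == 0 | !is.finite(s)]
  z[s == 0 | !is.finite(s), ] <- NA_real_
  list(z = z, flagged = flagged)
}
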