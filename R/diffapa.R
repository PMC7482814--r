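#' Select the most variant tandems by coefficient of variation
#'
#' Ranks tandems by the absolute coefficient of variation of SUI across all
#' samples, `CV = sd / |mean|` (sample SD), and keeps the top fraction.
#' SUI can be negative, hence the absolute mean; a mean of exactly zero is
#' treated as maximally variable (infinite CV).
#'
#' @param sui tandems x samples SUI matrix with rownames.
#' @param top_fraction fraction to keep (default 0.25, i.e. the top 25% most
#'   variant tandems); `floor(top_fraction * n)` are returned.
#' @return character vector of selected tandem IDs, ties broken by ID.
#' @export
cv_rank_select <- function(sui, top_fraction = 0.25) {
  stopifnot(is.matrix(sui), ncol(sui) >= 2L, !is.null(rownames(sui)))
  mu <- rowMeans(sui)
  s <- apply(sui, 1L, sd)
  cv <- ifelse(mu == 0, Inf, s / abs(mu))
  if (any(mu == 0)) {
    message(sum(mu == 0), " tandem(s) with zero mean SUI ranked as maximally variable")
  }
  n_keep <- floor(top_fraction * nrow(sui))
  ord <- order(-cv, rownames(sui))
  rownames(sui)[ord][seq_len(n_keep)]
}

## Newton inversion of the trigamma function (used for the prior df estimate)
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Moderated two-group test on SUI profiles
#'
#' Per-tandem two-group comparison with empirical-Bayes variance moderation
#' in the microarray linear-model style: the pooled residual variance
#' `s2[t]` (df `d`) is shrunk toward a prior `s0^2` with prior df `d0`,
#' `s2_tilde = (d0 s0^2 + d s2) / (d0 + d)`, and the t statistic uses
#' `d0 + d` degrees of freedom. `d0` and `s0` are estimated by moment
#' matching of the scaled-F distribution of the sample variances (matching
#' the mean and variance of `log s2` against digamma/trigamma moments).
#'
#' @param sui tandems x samples SUI matrix.
#' @param labels two-level factor/character vector aligned with columns; the
#'   first level is group A and `dsui = mean(A) - mean(B)`.
#' @return data.frame: `tandem_id`, `mean_a`, `mean_b`, `dsui`, `t`, `p`,
#'   `q` (BH-adjusted), plus attributes `d0` and `s0`.
#' @export
moderated_two_group_test <- function(sui, labels) {
  stopifnot(is.matrix(sui))
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, length(labels) == ncol(sui))
  ia <- which(labels == levels(labels)[1L])
  ib <- which(labels == levels(labels)[2L])
  n1 <- length(ia); n2 <- length(ib)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  d <- n1 + n2 - 2L
  ma <- rowMeans(sui[, ia, drop = FALSE])
  mb <- rowMeans(sui[, ib, drop = FALSE])
  ssa <- rowSums((sui[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((sui[, ib, drop = FALSE] - mb)^2)
  s2 <- (ssa + ssb) / d

  pos <- s2 > 0
  if (!any(pos)) stop("all tandems have zero residual variance")
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  mod <- .moderated_t(ma - mb, s2, n1, n2, d0, s0_2)
  res <- data.frame(tandem_id = rownames(sui), mean_a = ma, mean_b = mb,
                    dsui = ma - mb, t = mod$t, p = mod$p, q = bh_adjust(mod$p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0") <- sqrt(s0_2)
  res
}

## shrink s2 toward s0_2 with prior df d0 and form the moderated two-group t;
## d0 -> 0 recovers the ordinary pooled t, d0 -> Inf the s0-only denominator
.moderated_t <- function(diff, s2, n1, n2, d0, s0_2) {
  d <- n1 + n2 - 2
  s2_tilde <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  tt <- diff / sqrt(s2_tilde * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = d0 + d), df = d0 + d)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q[i] = min_{k: p[k] >= p[i]} m * p[k] / rank(k)`, capped at 1, with
#' monotonicity enforced by the cumulative minimum over the descending sort.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call shortened/lengthened APA events from moderated-test results
#'
#' An event is reported when the effect and significance thresholds are both
#' met: shortened if `dsui >= dsui_min` and `q <= q_max`, lengthened if
#' `dsui <= -dsui_min` and `q <= q_max`. The effect-size threshold applies
#' only at reporting, never during testing.
#'
#' @param results data.frame from [moderated_two_group_test()].
#' @param dsui_min minimum absolute SUI difference (default 0.2).
#' @param q_max FDR ceiling (default 0.05).
#' @return `results` with a `direction` column
#'   (`"shortened"`/`"lengthened"`/`"none"`).
#' @export
classify_direction <- function(results, dsui_min = 0.2, q_max = 0.05) {
  dir <- rep("none", nrow(results))
  dir[results$dsui >= dsui_min & results$q <= q_max] <- "shortened"
  dir[results$dsui <= -dsui_min & results$q <= q_max] <- "lengthened"
  results$direction <- dir
  results
}

#' Summarize shortening vs lengthening event proportions
#'
#' Reporting utility: percentages of shortening and lengthening events among
#' all called events, rounded to one decimal.
#'
#' @param results output of [classify_direction()], or omit and pass counts.
#' @param n_shortened,n_lengthened optional explicit event counts.
#' @return named vector: counts and percentages.
#' @export
apa_event_summary <- function(results = NULL, n_shortened = NULL, n_lengthened = NULL) {
  if (!is.null(results)) {
    n_shortened <- sum(results$direction == "shortened")
    n_lengthened <- sum(results$direction == "lengthened")
  }
  total <- n_shortened + n_lengthened
  c(n_shortened = n_shortened, n_lengthened = n_lengthened, n_total = total,
    pct_shortened = round(100 * n_shortened / total, 1),
    pct_lengthened = round(100 * n_lengthened / total, 1))
}

## 2-component 1-d Gaussian mixture by EM, best of n_restarts seeded starts
.gmm2 <- function(x, n_restarts = 10L, seed = 1L, max_iter = 200L, tol = 1e-8) {
  x <- x[is.finite(x)]
  n <- length(x)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- sort(sample(x, 2L))
    s2 <- rep(var(x) / 2, 2L)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- cbind(w[1] * stats::dnorm(x, mu[1], sqrt(s2[1])),
                    w[2] * stats::dnorm(x, mu[2], sqrt(s2[2])))
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      g <- dens / tot
      nk <- colSums(g)
      if (any(nk < 1e-8)) break
      w <- nk / n
      mu <- colSums(g * x) / nk
      s2 <- pmax(1e-8, colSums(g * (outer(x, mu, "-"))^2) / nk)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      ord <- order(mu)
      best <- list(means = mu[ord], sds = sqrt(s2[ord]), weights = w[ord],
                   loglik = ll)
    }
  }
  best
}

#' Correlate SUI with gene expression and summarize bimodality
#'
#' Computes the Pearson correlation between each gene's SUI and expression
#' across shared samples, then summarizes the shape of the correlation
#' distribution with a seeded 2-component Gaussian mixture fit (EM, best of
#' `n_restarts` random starts), reporting component means, SDs and weights.
#'
#' @param sui tandems x samples SUI matrix (rownames are tandem IDs).
#' @param expression genes x samples matrix.
#' @param gene_of named map tandem_id -> gene_id; defaults to the tandem IDs
#'   themselves matching expression rownames.
#' @param n_restarts,seed EM restarts and seed.
#' @return list: `r` (named per-gene correlations, `NA` for constant rows),
#'   `mixture` (component means/sds/weights/loglik).
#' @export
sui_expression_correlation <- function(sui, expression, gene_of = NULL,
                                       n_restarts = 10L, seed = 1L) {
  shared <- intersect(colnames(sui), colnames(expression))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  if (is.null(gene_of)) {
    gene_of <- structure(rownames(sui), names = rownames(sui))
  }
  genes <- gene_of[rownames(sui)]
  keep <- which(genes %in% rownames(expression))
  r <- vapply(keep, function(i) {
    a <- sui[i, shared]
    b <- expression[genes[i], shared]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  names(r) <- genes[keep]
  mix <- if (sum(is.finite(r)) >= 4L) .gmm2(r, n_restarts, seed) else NULL
  list(r = r, mixture = mix)
}

#' Fraction of tandems with large SUI variability per sample group
#'
#' For each sample group, computes the interquartile range (linear
#' interpolation, quantile type 7) of SUI across that group's samples for
#' each tandem in the subset, and reports the percentage of tandems with
#' `IQR >= iqr_min`.
#'
#' @param sui tandems x samples SUI matrix.
#' @param groups vector of group labels aligned with columns.
#' @param tandem_subset tandem IDs to summarize (default all).
#' @param iqr_min IQR threshold (default 0.8).
#' @return named numeric vector: percentage per group.
#' @export
iqr_variance_summary <- function(sui, groups, tandem_subset = rownames(sui),
                                 iqr_min = 0.8) {
  stopifnot(length(groups) == ncol(sui), length(tandem_subset) > 0)
  sub <- sui[tandem_subset, , drop = FALSE]
  out <- vapply(unique(groups), function(g) {
    cols <- which(groups == g)
    if (length(cols) < 4L) {
      warning("group '", g, "' has fewer than 4 samples; IQR is unstable")
    }
    iqr <- apply(sub[, cols, drop = FALSE], 1L, function(v) {
      qs <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      qs[2L] - qs[1L]
    })
    100 * mean(iqr >= iqr_min)
  }, numeric(1))
  names(out) <- unique(groups)
  out
}
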