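#' Min-max scale SUI features for factorization
#'
#' NMF requires a nonnegative input; each feature (row) is scaled linearly
#' to `[0, 1]`. Constant features carry no clustering information and cannot
#' be scaled, so they are dropped with a message.
#'
#' @param sui tandems x samples SUI matrix.
#' @return nonnegative matrix with attributes `min` and `range` per retained
#'   feature so the transform can be inverted.
#' @export
scale_features <- function(sui) {
  stopifnot(is.matrix(sui))
  lo <- apply(sui, 1L, min)
  hi <- apply(sui, 1L, max)
  keep <- hi > lo
  if (any(!keep)) {
    message(sum(!keep), " constant feature(s) dropped before scaling")
  }
  x <- (sui[keep, , drop = FALSE] - lo[keep]) / (hi - lo)[keep]
  attr(x, "min") <- lo[keep]
  attr(x, "range") <- (hi - lo)[keep]
  x
}

#' Invert [scale_features()]
#' @param x scaled matrix carrying `min`/`range` attributes.
#' @return matrix on the original SUI scale.
#' @export
unscale_features <- function(x) {
  x * attr(x, "range") + attr(x, "min")
}

## KL divergence D(X || Y) with the 0 log 0 = 0 convention
.kl_div <- function(X, Y) {
  Y <- pmax(Y, 1e-300)
  pos <- X > 0
  sum(X[pos] * log(X[pos] / Y[pos])) - sum(X) + sum(Y)
}

## one nsNMF run: multiplicative KL updates with the smoothing matrix
## S = (1 - theta) I + (theta/k) J absorbed alternately into W and H
.nsnmf_run <- function(X, k, theta, max_iter, tol) {
  eps <- 1e-16
  f <- nrow(X); n <- ncol(X)
  W <- matrix(runif(f * k), f, k)
  H <- matrix(runif(k * n), k, n)
  S <- (1 - theta) * diag(k) + (theta / k) * matrix(1, k, k)
  trace <- numeric(0)
  d_old <- Inf
  for (it in seq_len(max_iter)) {
    ## update H against smoothed basis
    Ws <- W %*% S
    V <- X / pmax(Ws %*% H, eps)
    H <- H * (crossprod(Ws, V) / pmax(colSums(Ws), eps))
    ## update W against smoothed coefficients
    Hs <- S %*% H
    V <- X / pmax(W %*% Hs, eps)
    W <- W * (tcrossprod(V, Hs) / rep(pmax(rowSums(Hs), eps), each = f))
    d <- .kl_div(X, W %*% S %*% H)
    trace <- c(trace, d)
    if (is.finite(d_old) && abs(d_old - d) <= tol * max(1, abs(d_old))) break
    d_old <- d
  }
  converged <- it < max_iter
  list(W = W, H = H, S = S, divergence = d, trace = trace,
       converged = converged)
}

#' Non-smooth NMF clustering of SUI profiles
#'
#' Factorizes a nonnegative matrix as `X ~ W S H` with the smoothing matrix
#' `S = (1 - theta) I + (theta/k) J`, which promotes sparse factors
#' (`theta = 0` recovers plain KL-NMF). Multiplicative KL-divergence updates
#' absorb `S` alternately into the basis and the coefficients. Of `n_runs`
#' random restarts (uniform init from a seeded stream) the run with the
#' lowest divergence is kept; the consensus matrix averages the sample
#' connectivity (co-assignment by argmax of `H`) over all runs.
#'
#' @param X nonnegative features x samples matrix (see [scale_features()]).
#' @param k factorization rank (number of subtypes), `2 <= k < min(dim(X))`.
#' @param theta smoothing in `[0, 1]` (default 0.5).
#' @param n_runs random restarts (default 30).
#' @param max_iter update cap per run (default 2000).
#' @param tol relative divergence change declaring convergence (default 1e-6).
#' @param seed integer seed.
#' @return A `subtype_solution`: `W`, `H`, `k`, `theta`, `labels` (argmax of
#'   `H`), `consensus`, `divergence`, `trace` (divergence per iteration of
#'   the best run), `converged`.
#' @export
nsnmf <- function(X, k, theta = 0.5, n_runs = 30L, max_iter = 2000L,
                  tol = 1e-6, seed = 1L) {
  stopifnot(is.matrix(X), all(X >= 0), k >= 2L, k < min(dim(X)))
  n <- ncol(X)
  consensus <- matrix(0, n, n)
  best <- NULL
  for (r in seq_len(n_runs)) {
    set.seed(child_seed(seed, "nsnmf", r))
    run <- .nsnmf_run(X, k, theta, max_iter, tol)
    lab <- apply(run$H, 2L, which.max)
    consensus <- consensus + outer(lab, lab, "==")
    if (is.null(best) || run$divergence < best$divergence) best <- run
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(X), colnames(X))
  if (!best$converged) {
    warning("best nsNMF run did not meet the divergence tolerance at max_iter")
  }
  labels <- apply(best$H, 2L, which.max)
  names(labels) <- colnames(X)
  structure(list(W = best$W, H = best$H, k = k, theta = theta,
                 labels = labels, consensus = consensus,
                 divergence = best$divergence, trace = best$trace,
                 converged = best$converged),
            class = "subtype_solution")
}

## mean silhouette width of labels under a distance matrix (n x n)
.mean_silhouette <- function(d, labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2L) return(NA_real_)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    if (sum(own) == 1L || max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

## rank-selection metrics from a consensus matrix
.consensus_metrics <- function(C, k) {
  n <- nrow(C)
  dispersion <- mean(4 * (C - 0.5)^2)
  d <- as.dist(1 - C)
  hc <- hclust(d, method = "average")
  coph <- cophenetic(hc)
  cophenetic_coef <- if (sd(d) == 0 || sd(coph) == 0) 1 else cor(d, coph)
  labels <- cutree(hc, k = k)
  sil <- .mean_silhouette(as.matrix(1 - C), labels)
  c(cophenetic = cophenetic_coef, dispersion = dispersion, silhouette = sil)
}

#' Survey factorization ranks for subtype discovery
#'
#' Runs [nsnmf()] at each rank and scores the consensus matrix with the
#' cophenetic coefficient (correlation between consensus distances `1 - C`
#' and the cophenetic distances of their average-linkage dendrogram), the
#' dispersion coefficient `mean(4 (C - 1/2)^2)` (1 for a perfectly binary
#' consensus), and the mean silhouette width of consensus-derived labels
#' under `1 - C`.
#'
#' @param X nonnegative features x samples matrix.
#' @param ranks candidate ranks (default 2:10).
#' @param n_runs restarts per rank (default 50, the rank-survey convention).
#' @param theta,max_iter,tol,seed passed to [nsnmf()].
#' @return data.frame: rank, cophenetic, dispersion, silhouette, divergence.
#' @export
rank_survey <- function(X, ranks = 2:10, n_runs = 50L, theta = 0.5,
                        max_iter = 2000L, tol = 1e-6, seed = 1L) {
  rows <- lapply(ranks, function(k) {
    sol <- nsnmf(X, k, theta = theta, n_runs = n_runs, max_iter = max_iter,
                 tol = tol, seed = child_seed(seed, "rank_survey", k))
    m <- .consensus_metrics(sol$consensus, k)
    data.frame(rank = k, cophenetic = m["cophenetic"],
               dispersion = m["dispersion"], silhouette = m["silhouette"],
               divergence = sol$divergence, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Select the factorization rank from survey metrics
#'
#' Picks the rank maximizing the mean of the cophenetic, dispersion and
#' silhouette metrics; when several ranks tie (the metrics plateau at 1 for
#' every rank that yields a perfectly stable consensus), the largest tied
#' rank is chosen, i.e. the finest stable partition.
#'
#' @param survey data.frame from [rank_survey()].
#' @param tie_tol ties closer than this in composite score collapse
#'   (default 1e-6, i.e. only exact plateaus tie).
#' @return the selected rank (integer).
#' @export
select_rank <- function(survey, tie_tol = 1e-6) {
  comp <- rowMeans(survey[, c("cophenetic", "dispersion", "silhouette")])
  best <- max(comp, na.rm = TRUE)
  max(survey$rank[!is.na(comp) & comp >= best - tie_tol])
}

## k-means++ seeding: first center uniform, then prob proportional to the
## squared distance to the nearest chosen center
.kmeanspp_centers <- function(data, k) {
  n <- nrow(data)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((data - matrix(data[centers[1L], ], n, ncol(data), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- pool[sample.int(length(pool), 1L)]
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    dj <- rowSums((data - matrix(data[centers[j], ], n, ncol(data), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  data[centers, , drop = FALSE]
}

#' Consensus k-means clustering by resampling
#'
#' Repeatedly subsamples samples without replacement, clusters each subsample
#' with k-means (k-means++ initialization, seeded), and records how often two
#' samples land in the same cluster. The consensus entry `C[i, j]` is the
#' co-clustering count divided by the co-sampling count; pairs never sampled
#' together are imputed at 0.5 with a warning. Final labels come from
#' average-linkage clustering of `1 - C` cut at `k`.
#'
#' @param X features x samples matrix (samples are clustered).
#' @param k number of clusters.
#' @param n_iter resampling iterations (default 1000).
#' @param subsample_frac fraction of samples per iteration (default 0.8).
#' @param seed integer seed.
#' @return list: `consensus` (samples x samples), `labels`.
#' @export
consensus_kmeans <- function(X, k, n_iter = 1000L, subsample_frac = 0.8,
                             seed = 1L) {
  stopifnot(k >= 2L)
  data <- t(X)
  n <- nrow(data)
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  n_sub <- max(k + 1L, floor(subsample_frac * n))
  set.seed(child_seed(seed, "consensus_kmeans"))
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, n_sub)
    centers <- .kmeanspp_centers(data[idx, , drop = FALSE], k)
    km <- suppressWarnings(kmeans(data[idx, , drop = FALSE], centers = centers,
                                  iter.max = 100L))
    lab <- km$cluster
    same <- outer(lab, lab, "==")
    co[idx, idx] <- co[idx, idx] + same
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  never <- tog == 0
  if (any(never[upper.tri(never)])) {
    warning(sum(never[upper.tri(never)]),
            " sample pair(s) never co-sampled; consensus imputed at 0.5")
  }
  C <- ifelse(tog > 0, co / pmax(tog, 1), 0.5)
  diag(C) <- 1
  dimnames(C) <- list(colnames(X), colnames(X))
  hc <- hclust(as.dist(1 - C), method = "average")
  labels <- cutree(hc, k = k)
  names(labels) <- colnames(X)
  list(consensus = C, labels = labels)
}

#' Principal-component coordinates of samples from SUI profiles
#'
#' Feature-centered SVD scores with a deterministic sign convention (the
#' largest-magnitude loading of each component is made positive).
#'
#' @param sui features x samples matrix.
#' @param n_components number of components (default 3).
#' @return samples x n_components score matrix with attribute
#'   `var_explained`.
#' @export
pca_coords <- function(sui, n_components = 3L) {
  stopifnot(ncol(sui) >= n_components)
  M <- t(sui)
  M <- sweep(M, 2L, colMeans(M))
  sv <- svd(M, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components) %*% diag(flip, n_components)
  rownames(scores) <- colnames(sui)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  attr(scores, "var_explained") <- sv$d^2 / sum(sv$d^2)
  scores
}
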