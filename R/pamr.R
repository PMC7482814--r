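#' Quantile-normalize columns to a reference distribution
#'
#' Maps each column onto the reference quantiles (the mean-of-sorted-values
#' reference of a training matrix): the k-th smallest value of a column
#' becomes the k-th reference quantile, with average ranks (hence linear
#' interpolation into the reference) for ties. A column that already matches
#' the reference quantiles is returned unchanged.
#'
#' @param x features x samples matrix to normalize.
#' @param reference either a training matrix (features x samples) from which
#'   the mean-of-sorted reference is computed, or a pre-sorted numeric vector
#'   of reference quantiles with `length == nrow(x)`.
#' @return normalized matrix, same shape as `x`.
#' @export
quantile_normalize_to <- function(x, reference) {
  stopifnot(is.matrix(x))
  ref <- if (is.matrix(reference)) {
    rowMeans(apply(reference, 2L, sort))
  } else sort(reference)
  if (length(ref) != nrow(x)) stop("reference length must equal nrow(x)")
  apply(x, 2L, function(col) {
    rk <- rank(col, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = rk, rule = 2)$y
  })
}

#' Train a nearest shrunken centroid classifier on SUI profiles
#'
#' Standard nearest-shrunken-centroid training: standardized centroid
#' deviations `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, pooled within-class SD `s_i`, fudge
#' `s0 = median(s_i)`, soft-thresholded by `Delta`
#' (`d'_ik = sign(d_ik) max(|d_ik| - Delta, 0)`). `Delta` is chosen to
#' minimize cross-validated misclassification (stratified folds, seeded);
#' ties go to the largest `Delta`, i.e. the sparsest classifier.
#'
#' @param x features x samples matrix.
#' @param labels class labels aligned with columns; every class needs at
#'   least 2 samples.
#' @param delta_grid thresholds to evaluate; default 30 values from 0 to the
#'   largest `|d_ik|`.
#' @param cv_folds folds for cross-validation (default 10, capped at the
#'   smallest class size).
#' @param seed integer seed for fold assignment.
#' @return A `shrunken_centroid_model`: class centroids (shrunken), overall
#'   centroid, `s`, `s0`, `delta`, class priors, CV error table.
#' @export
train_shrunken_centroids <- function(x, labels, delta_grid = NULL,
                                     cv_folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  n <- ncol(x)
  nk <- table(labels)
  if (any(nk < 2L)) {
    stop("class(es) with a single sample: ",
         paste(names(nk)[nk < 2L], collapse = ", "))
  }
  fit <- .nsc_fit(x, labels)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(fit$d)), length.out = 30L)
  }
  ## stratified CV over Delta
  set.seed(child_seed(seed, "nsc_cv"))
  cv_folds <- max(2L, min(cv_folds, min(nk)))
  fold <- integer(n)
  for (cl in classes) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  errs <- matrix(0L, cv_folds, length(delta_grid))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit_f <- .nsc_fit(x[, tr, drop = FALSE], droplevels(labels[tr]))
    for (g in seq_along(delta_grid)) {
      pred <- .nsc_predict(fit_f, x[, !tr, drop = FALSE], delta_grid[g])
      errs[f, g] <- sum(pred != as.character(labels[!tr]))
    }
  }
  total_err <- colSums(errs)
  best <- max(which(total_err == min(total_err)))  # ties -> largest Delta
  delta <- delta_grid[best]
  d_shr <- .soft_threshold(fit$d, delta)
  centroids <- fit$overall + t(t(d_shr) * fit$mk) * (fit$s + fit$s0)
  structure(list(centroids = centroids, overall = fit$overall,
                 d = fit$d, s = fit$s, s0 = fit$s0, mk = fit$mk,
                 priors = as.numeric(nk) / n, classes = classes,
                 features = rownames(x), delta = delta,
                 cv_errors = data.frame(delta = delta_grid, errors = total_err)),
            class = "shrunken_centroid_model")
}

.soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

.nsc_fit <- function(x, labels) {
  classes <- levels(labels)
  n <- ncol(x)
  k <- length(classes)
  overall <- rowMeans(x)
  cent <- sapply(classes, function(cl) rowMeans(x[, labels == cl, drop = FALSE]))
  ss <- 0
  for (cl in classes) {
    xi <- x[, labels == cl, drop = FALSE]
    ss <- ss + rowSums((xi - cent[, cl])^2)
  }
  s <- sqrt(ss / (n - k))
  s0 <- median(s)
  nk <- as.numeric(table(labels))
  mk <- sqrt(1 / nk - 1 / n)
  d <- (cent - overall) / outer(s + s0, mk)
  list(overall = overall, cent = cent, s = s, s0 = s0, mk = mk, d = d,
       priors = nk / n, classes = classes)
}

.nsc_predict <- function(fit, newx, delta) {
  d_shr <- .soft_threshold(fit$d, delta)
  cent <- fit$overall + t(t(d_shr) * fit$mk) * (fit$s + fit$s0)
  scale2 <- (fit$s + fit$s0)^2
  scores <- sapply(seq_along(fit$classes), function(j) {
    colSums((newx - cent[, j])^2 / scale2) - 2 * log(fit$priors[j])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  fit$classes[apply(scores, 1L, which.min)]
}

#' Classify new samples with a shrunken centroid model
#'
#' New sample columns are first quantile-normalized to the training pooled
#' quantiles, then assigned by the discriminant score
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`
#' (argmin over classes).
#'
#' @param model a `shrunken_centroid_model`.
#' @param new_sui features x new-samples matrix; rownames must cover the
#'   model's features.
#' @param reference_sui training features x samples matrix used for quantile
#'   normalization; omit to skip normalization (e.g. when the new data are
#'   already on the training scale).
#' @return list: `labels` (named character), `scores` (samples x classes
#'   discriminant matrix).
#' @export
classify_samples <- function(model, new_sui, reference_sui = NULL) {
  missing_feats <- setdiff(model$features, rownames(new_sui))
  if (length(missing_feats)) {
    stop("new samples missing model feature(s): ",
         paste(utils::head(missing_feats, 10L), collapse = ", "),
         if (length(missing_feats) > 10L) ", ..." else "")
  }
  x <- new_sui[model$features, , drop = FALSE]
  if (!is.null(reference_sui)) {
    x <- quantile_normalize_to(x, reference_sui[model$features, , drop = FALSE])
    rownames(x) <- model$features
  }
  scale2 <- (model$s + model$s0)^2
  scores <- sapply(seq_along(model$classes), function(j) {
    colSums((x - model$centroids[, j])^2 / scale2) - 2 * log(model$priors[j])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  dimnames(scores) <- list(colnames(new_sui), model$classes)
  labels <- model$classes[apply(scores, 1L, which.min)]
  names(labels) <- colnames(new_sui)
  list(labels = labels, scores = scores)
}
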