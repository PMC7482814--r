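test_that("CV selection keeps the top fraction with deterministic ties", {
  set.seed(10)
  sui <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(sprintf("t%03d", 1:100), paste0("s", 1:6)))
  sel <- cv_rank_select(sui, 0.25)
  expect_length(sel, 25L)
  ## low |mean| outranks high |mean| at equal sd
  two <- rbind(hi_mean = c(9, 10, 11), lo_mean = c(0, 1, 2))
  colnames(two) <- paste0("s", 1:3)
  expect_equal(cv_rank_select(two, 0.5), "lo_mean")
  ## zero-mean row is maximally variable
  zm <- rbind(a = c(-1, 0, 1), b = c(10, 11, 12))
  colnames(zm) <- paste0("s", 1:3)
  expect_message(sel0 <- cv_rank_select(zm, 0.5), "zero mean")
  expect_equal(sel0, "a")
  ## exact ties broken lexicographically, stable across calls
  tied <- matrix(rep(c(1, 2, 3), each = 4), 4, 3,
                 dimnames = list(c("d", "b", "a", "c"), paste0("s", 1:3)))
  expect_equal(cv_rank_select(tied, 0.5), c("a", "b"))
})

test_that("moderated t handles equal means and matches its analytic limits", {
  sui <- rbind(t1 = c(1, 2, 3, 1, 2, 3), t2 = c(0, 1, 0, 2, 3, 2))
  colnames(sui) <- paste0("s", 1:6)
  lab <- rep(c("a", "b"), each = 3)
  res <- moderated_two_group_test(sui, lab)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  ## d0 -> 0: moderated t equals the ordinary pooled two-sample t
  x <- c(0.3, 1.2, 0.8, -0.2); y <- c(1.1, 2.3, 1.9, 1.4)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 6
  pooled_t <- (mean(x) - mean(y)) / sqrt(s2 * (1 / 4 + 1 / 4))
  mod <- tandemAPA:::.moderated_t(mean(x) - mean(y), s2, 4, 4, d0 = 1e-12,
                                  s0_2 = 99)
  expect_equal(mod$t, pooled_t, tolerance = 1e-9)
  expect_equal(mod$p, t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-6)
  ## d0 -> Inf: denominator collapses to s0
  modi <- tandemAPA:::.moderated_t(mean(x) - mean(y), s2, 4, 4, d0 = Inf,
                                   s0_2 = 0.5)
  expect_equal(modi$t, (mean(x) - mean(y)) / sqrt(0.5 * 0.5), tolerance = 1e-9)
})

test_that("moderated t agrees with an independent microarray implementation", {
  skip_if_not_installed("limma")
  set.seed(20)
  sui <- matrix(rnorm(200 * 12), 200, 12,
                dimnames = list(sprintf("t%03d", 1:200), paste0("s", 1:12)))
  sui[1:20, 1:6] <- sui[1:20, 1:6] + 1
  lab <- rep(c("a", "b"), each = 6)
  res <- moderated_two_group_test(sui, lab)
  design <- cbind(1, lab == "a")
  fit <- limma::eBayes(limma::lmFit(sui, design))
  expect_gt(cor(res$t, fit$t[, 2]), 0.9999)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s0")^2, fit$s2.prior, tolerance = 0.05)
})

test_that("the moderated test controls type-I error under the null", {
  set.seed(30)
  sui <- matrix(rnorm(1000 * 20, 0, 0.3), 1000, 20,
                dimnames = list(sprintf("t%04d", 1:1000), paste0("s", 1:20)))
  res <- moderated_two_group_test(sui, rep(c("a", "b"), each = 10))
  frac <- mean(res$p < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lte(mean(res$q < 0.05), 0.05)
})

test_that("BH adjustment matches closed forms and the brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1.0), 1.0)
  set.seed(40)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
    ## monotone in sorted-p order and >= raw p
    o <- order(p)
    expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("direction calls need both effect size and FDR", {
  res <- data.frame(tandem_id = c("a", "b", "c", "d"),
                    dsui = c(0.25, 0.25, -0.3, 0.1),
                    q = c(0.01, 0.2, 0.01, 0.01))
  out <- classify_direction(res)
  expect_equal(out$direction, c("shortened", "none", "lengthened", "none"))
  s <- apa_event_summary(out)
  expect_equal(unname(s["pct_shortened"]), 50)
})

test_that("planted shifts are called exactly at the stated settings", {
  set.seed(50)
  n_t <- 200L
  shifted <- 1:40
  sui <- matrix(rnorm(n_t * 80, 0, 0.1), n_t, 80,
                dimnames = list(sprintf("t%03d", 1:n_t), paste0("s", 1:80)))
  sui[shifted, 1:40] <- sui[shifted, 1:40] + 1   # |log2 f shift| = 1 -> dSUI 1
  lab <- factor(rep(c("tumorA", "rest"), each = 40), levels = c("tumorA", "rest"))
  out <- classify_direction(moderated_two_group_test(sui, lab))
  expect_setequal(which(out$direction == "shortened"), shifted)
})

test_that("SUI-expression correlation recovers planted bimodality", {
  set.seed(60)
  n_g <- 60L; n_s <- 50L
  sui <- matrix(rnorm(n_g * n_s), n_g, n_s,
                dimnames = list(sprintf("g%03d", 1:n_g), paste0("s", 1:n_s)))
  expr <- sui * NA
  for (g in 1:n_g) {
    r <- if (g <= 30) 0.6 else -0.3
    noise_sd <- sqrt(1 / r^2 - 1)
    expr[g, ] <- sign(r) * (sui[g, ] + rnorm(n_s, 0, noise_sd))
  }
  rownames(expr) <- rownames(sui); colnames(expr) <- colnames(sui)
  out <- sui_expression_correlation(sui, expr, seed = 3L)
  expect_lt(out$mixture$means[1], 0)
  expect_gt(out$mixture$means[2], 0)
  ## perfect linear relation -> r = 1
  expr1 <- 2 * sui + 5
  out1 <- sui_expression_correlation(sui, expr1)
  expect_equal(unname(out1$r), rep(1, n_g), tolerance = 1e-12)
  ## independent rows -> mean r near 0
  expr0 <- matrix(rnorm(n_g * n_s), n_g, n_s, dimnames = dimnames(sui))
  out0 <- sui_expression_correlation(sui, expr0)
  expect_lt(abs(mean(out0$r)), 3 / sqrt(n_s * n_g) * 3)
})

test_that("IQR summaries count large-variance tandems per group", {
  sui <- rbind(const = rep(1, 12), wide = rep(seq(0, 2, length.out = 6), 2))
  colnames(sui) <- paste0("s", 1:12)
  groups <- rep(c("g1", "g2"), each = 6)
  out <- iqr_variance_summary(sui, groups)
  expect_equal(unname(out), c(50, 50))  # 'wide' has IQR exactly 1.0 in each group
  ## order invariance
  perm <- sample(12)
  expect_equal(unname(iqr_variance_summary(sui[, perm], groups[perm])),
               unname(out))
  expect_warning(iqr_variance_summary(sui[, 1:3, drop = FALSE],
                                      rep("g1", 3)), "fewer than 4")
})
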