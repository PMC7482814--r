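test_that("noiseless generator reproduces the probe-level identity", {
  cfg <- simulation_config(n_tandems = 3L, n_normals = 2L,
                           subtype_sizes = 2L, f0 = c(0.5, 0.8, 1),
                           abundance_sd = 0, probe_affinity_sd = 0,
                           noise_sd = 0, seed = 11L)
  sim <- simulate_probe_dataset(cfg)
  for (t in 1:3) {
    rows <- grep(sprintf("tnd%04d", t), rownames(sim$intensity))
    common <- sim$intensity[rows[1:6], ]
    extended <- sim$intensity[rows[7:12], ]
    expect_equal(unname(common), matrix(0, 6, 4))
    expect_equal(unname(extended), matrix(log2(cfg$f0[t]), 6, 4))
  }
})

test_that("a planted halving of f lowers extended probes by exactly 1 log2 unit", {
  eff <- matrix(-1, 1, 1)  # one tandem, one subtype, f -> f0/2
  cfg <- simulation_config(n_tandems = 1L, n_normals = 2L, subtype_sizes = 1L,
                           f0 = 0.8, subtype_effects = eff,
                           abundance_sd = 0, probe_affinity_sd = 0,
                           noise_sd = 0, seed = 1L)
  sim <- simulate_probe_dataset(cfg)
  tum <- sim$intensity[, "tumor001"]
  nor <- sim$intensity[, "normal001"]
  ext <- grepl("_p(07|08|09|10|11|12)$", rownames(sim$intensity))
  ## extended-vs-common contrast of the tumor, relative to a normal
  expect_equal(mean(tum[ext] - tum[!ext]) - mean(nor[ext] - nor[!ext]), -1)
  expect_equal(unname(sim$truth$true_sui["tnd0001", "tumor001"]), 1)
})

test_that("identical configs write byte-identical files", {
  cfg <- simulation_config(n_tandems = 50L, n_normals = 4L,
                           subtype_sizes = c(3L, 3L), seed = 7L)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- write_probe_dataset(simulate_probe_dataset(cfg), d1)
  p2 <- write_probe_dataset(simulate_probe_dataset(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("generator validates its preconditions", {
  expect_error(simulation_config(probes_per_segment = c(common = 3L, extended = 6L)),
               ">= 4")
  expect_error(simulation_config(f0 = 1.2), "f0")
  ## positive effect pushing f above 1 must be rejected
  expect_error(simulation_config(n_tandems = 1L, subtype_sizes = 1L, f0 = 0.9,
                                 subtype_effects = matrix(1, 1, 1)),
               "fraction > 1")
})

test_that("extended-minus-common contrast converges to log2(f) at low noise", {
  cfg <- simulation_config(n_tandems = 10L, n_normals = 2L, subtype_sizes = 2L,
                           probes_per_segment = c(common = 8L, extended = 8L),
                           f0 = 0.5, abundance_sd = 0, probe_affinity_sd = 0,
                           noise_sd = 0.05, seed = 3L)
  sim <- simulate_probe_dataset(cfg)
  ext <- grepl("_p(09|10|11|12|13|14|15|16)$", rownames(sim$intensity))
  n_sam <- ncol(sim$intensity)
  ## per-sample contrast has variance sigma^2 (1/8 + 1/8); 3 SE tolerance
  tol <- 3 * 0.05 * sqrt(2 / 8) / sqrt(n_sam)
  for (t in 1:10) {
    rows <- grepl(sprintf("tnd%04d_", t), rownames(sim$intensity))
    contrast <- colMeans(sim$intensity[rows & ext, , drop = FALSE]) -
      colMeans(sim$intensity[rows & !ext, , drop = FALSE])
    expect_lt(abs(mean(contrast) - log2(0.5)), tol)
  }
})

test_that("screen counts respect the multinomial depth and determinism", {
  scr <- simulate_screen_counts(n_genes = 5L, depleted_genes = "gene01",
                                library_size = 1e5, seed = 4L)
  cols <- grep("^d", names(scr$counts), value = TRUE)
  expect_true(all(colSums(scr$counts[cols]) == 1e5))
  scr2 <- simulate_screen_counts(n_genes = 5L, depleted_genes = "gene01",
                                 library_size = 1e5, seed = 4L)
  expect_identical(scr$counts, scr2$counts)
  expect_error(simulate_screen_counts(n_genes = 5L, library_size = 10),
               "library_size")
  expect_error(simulate_screen_counts(depleted_genes = "nope"), "subset")
})

test_that("null screens keep relative abundance flat; phi=-1 gives 8-fold by day 21", {
  ## null: no depletion; day-21 vs day-0 log ratio centred at 0
  scr <- simulate_screen_counts(n_genes = 10L, depletion_rate = 0,
                                library_size = 2e6, seed = 5L)
  lr <- log2((scr$counts$d21_r1 + 1) / (scr$counts$d0_r1 + 1))
  expect_lt(abs(mean(lr)), 0.05)
  ## one depleted gene at phi = -1 log2/week: 2^-3 at day 21 before renorm.
  ## with a large library the relative-abundance drop vs controls is ~ -3
  scr <- simulate_screen_counts(n_genes = 23L, depleted_genes = "gene07",
                                depletion_rate = 1, library_size = 5e6,
                                seed = 6L)
  lr <- log2((scr$counts$d21_r1 + 1) / (scr$counts$d0_r1 + 1))
  dep <- scr$counts$gene == "gene07"
  expect_lt(abs((mean(lr[dep]) - mean(lr[!dep])) - (-3)), 0.15)
})

test_that("simulated SUI matrices carry the planted block structure", {
  s <- simulate_sui_matrix(n_tandems = 40L, subtype_sizes = c(5L, 5L),
                           n_signature = 10L, effect_size = 1,
                           noise_sd = 0.01, seed = 2L)
  expect_equal(dim(s$sui), c(40L, 10L))
  in_sig <- mean(s$sui[1:10, s$true_subtype == "S1"])
  out_sig <- mean(s$sui[1:10, s$true_subtype == "S2"])
  expect_lt(abs(in_sig - 1), 0.05)
  expect_lt(abs(out_sig), 0.05)
})
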