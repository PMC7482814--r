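tx_row <- function(id, gene, strand, start, end) {
  data.frame(transcript_id = id, gene_id = gene, strand = strand,
             utr_start = start, utr_end = end, stringsAsFactors = FALSE)
}

test_that("shared-start transcripts with two ends yield one proximal/distal pair", {
  tx <- rbind(tx_row("t1", "g1", "+", 1000, 1100),
              tx_row("t2", "g1", "+", 1000, 1200))
  cand <- identify_tandems(tx)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$proximal_end, 1100)
  expect_equal(cand$distal_end, 1200)
  ## three ends still collapse to (shortest, longest)
  tx3 <- rbind(tx, tx_row("t3", "g1", "+", 1000, 1400))
  expect_equal(identify_tandems(tx3)$distal_end, 1400)
  ## minus strand: start is the high coordinate
  txm <- rbind(tx_row("m1", "g2", "-", 2000, 1900),
               tx_row("m2", "g2", "-", 2000, 1700))
  cm <- identify_tandems(txm)
  expect_equal(cm$proximal_end, 1900)
  expect_equal(cm$distal_end, 1700)
})

test_that("differing 3'UTR starts and malformed coordinates are handled", {
  tx <- rbind(tx_row("t1", "g1", "+", 1000, 1100),
              tx_row("t2", "g1", "+", 1001, 1200))
  expect_equal(nrow(identify_tandems(tx)), 0L)
  bad <- tx_row("t9", "g1", "+", 1000, 900)
  expect_error(identify_tandems(bad), "t9")
})

test_that("synthetic transcript tables yield one candidate per planted tandem", {
  sim <- simulate_probe_dataset(simulation_config(n_tandems = 20L,
                                                  n_normals = 2L,
                                                  subtype_sizes = 2L,
                                                  seed = 5L))
  cand <- identify_tandems(sim$transcripts)
  expect_equal(nrow(cand), 20L)
  tandems <- assign_probes(cand, sim$probe_map)
  expect_equal(length(tandems), 20L)
  for (td in tandems) {
    expect_equal(td$n_common, 6L)
    expect_equal(td$n_extended, 6L)
    ## ordinals 0..n-1, genomic positions monotone by strand
    expect_equal(td$ordinal, 0:11)
    pos <- sim$probe_map$start[match(td$probes, sim$probe_map$probe_id)]
    if (td$strand == "+") expect_true(all(diff(pos) > 0))
    else expect_true(all(diff(pos) < 0))
  }
})

test_that("the four-probes-per-segment filter is enforced", {
  cand <- data.frame(tandem_id = "td1", gene_id = "g1", strand = "+",
                     utr_start = 0, proximal_end = 400, distal_end = 1000,
                     stringsAsFactors = FALSE)
  mk_probes <- function(starts) {
    data.frame(chrom = "chr1", start = starts, end = starts + 25,
               probe_id = sprintf("p%02d", seq_along(starts)), score = 0,
               strand = "+", stringsAsFactors = FALSE)
  }
  ## 4 common + 4 extended -> retained
  pm <- mk_probes(c(0, 100, 200, 300, 500, 600, 700, 800))
  expect_equal(length(assign_probes(cand, pm)), 1L)
  ## 3 common + 10 extended -> discarded
  pm <- mk_probes(c(0, 100, 200, seq(410, 950, by = 60)))
  expect_equal(length(assign_probes(cand, pm)), 0L)
})

test_that("probes overlapping two tandems are dropped from both", {
  cand <- data.frame(tandem_id = c("a", "b"), gene_id = c("ga", "gb"),
                     strand = "+", utr_start = c(0, 600),
                     proximal_end = c(300, 900), distal_end = c(700, 1300),
                     stringsAsFactors = FALSE)
  starts <- c(10, 80, 150, 220, 350, 450, 640, 700, 800, 850, 950, 1050, 1150, 1250)
  pm <- data.frame(chrom = "chr1", start = starts, end = starts + 25,
                   probe_id = sprintf("p%02d", seq_along(starts)), score = 0,
                   strand = "+", stringsAsFactors = FALSE)
  hits <- oracle_probe_tandems(pm, cand)
  shared <- which(lengths(hits) > 1L)
  expect_true(length(shared) > 0L)  # the fixture does contain ambiguous probes
  tandems <- assign_probes(cand, pm)
  kept <- unlist(lapply(tandems, `[[`, "probes"))
  expect_false(any(pm$probe_id[shared] %in% kept))
  ## survivors agree with the brute-force containment scan
  for (td in tandems) {
    t_idx <- match(td$tandem_id, cand$tandem_id)
    expected <- pm$probe_id[vapply(hits, identical, logical(1), t_idx)]
    expect_setequal(td$probes, expected)
  }
})

test_that("assign_probes matches the brute-force scan on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    nt <- sample(2:4, 1)
    origins <- cumsum(sample(300:800, nt))
    cand <- data.frame(tandem_id = paste0("td", seq_len(nt)),
                       gene_id = paste0("g", seq_len(nt)), strand = "+",
                       utr_start = origins, proximal_end = origins + 150,
                       distal_end = origins + sample(300:500, nt),
                       stringsAsFactors = FALSE)
    np <- sample(10:30, 1)
    ps <- sample(min(origins):max(cand$distal_end), np)
    pm <- data.frame(chrom = "chr1", start = ps, end = ps + 25,
                     probe_id = sprintf("r%03d", seq_len(np)), score = 0,
                     strand = "+", stringsAsFactors = FALSE)
    hits <- oracle_probe_tandems(pm, cand)
    tandems <- assign_probes(cand, pm)
    for (td in tandems) {
      t_idx <- match(td$tandem_id, cand$tandem_id)
      expected <- pm$probe_id[vapply(hits, identical, logical(1), t_idx)]
      expect_setequal(td$probes, expected)
      expect_gte(td$n_common, 4L)
      expect_gte(td$n_extended, 4L)
    }
  }
})

test_that("a probe straddling the proximal site goes to the majority segment", {
  cand <- data.frame(tandem_id = "td1", gene_id = "g1", strand = "+",
                     utr_start = 0, proximal_end = 400, distal_end = 1000,
                     stringsAsFactors = FALSE)
  ## probe [390, 415): 10 bases common, 15 extended -> extended;
  ## probe [388, 413): 12 vs 13 -> extended; probe [385, 410): 15 vs 10 -> common
  starts <- c(0, 100, 200, 300, 385, 500, 600, 700, 800)
  pm <- data.frame(chrom = "chr1", start = starts, end = starts + 25,
                   probe_id = sprintf("p%d", seq_along(starts)), score = 0,
                   strand = "+", stringsAsFactors = FALSE)
  td <- assign_probes(cand, pm)[[1]]
  expect_equal(td$segment[td$probes == "p5"], "common")
  pm$start[5] <- 390; pm$end[5] <- 415
  td <- assign_probes(cand, pm)[[1]]
  expect_equal(td$segment[td$probes == "p5"], "extended")
  ## exact tie (probe [388, 412): 12 vs 12, even length 24) -> common
  pm$start[5] <- 388; pm$end[5] <- 412
  td <- assign_probes(cand, pm)[[1]]
  expect_equal(td$segment[td$probes == "p5"], "common")
})

test_that("strand-conflicting probes are dropped with a warning", {
  cand <- data.frame(tandem_id = "td1", gene_id = "g1", strand = "+",
                     utr_start = 0, proximal_end = 400, distal_end = 1000,
                     stringsAsFactors = FALSE)
  starts <- c(0, 100, 200, 300, 500, 600, 700, 800, 900)
  pm <- data.frame(chrom = "chr1", start = starts, end = starts + 25,
                   probe_id = sprintf("p%d", seq_along(starts)), score = 0,
                   strand = c(rep("+", 8), "-"), stringsAsFactors = FALSE)
  expect_warning(tandems <- assign_probes(cand, pm), "strand")
  expect_false("p9" %in% tandems[[1]]$probes)
})
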