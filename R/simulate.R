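#' Simulation configuration for synthetic probe-level APA data
#'
#' Defines the generative model used throughout the package's validation:
#' each tandem 3'UTR has a baseline long-isoform fraction `f0`; common-region
#' probes measure total transcript abundance while extended-region probes
#' measure distal (long) isoform abundance, so on the log2 scale an extended
#' probe sits `log2(f)` below the common level. Normals are generated exactly
#' at `f0`; tumors of subtype k have `f = f0 * 2^effect[t, k]` (clipped to 1).
#'
#' @param n_tandems number of tandem 3'UTRs.
#' @param probes_per_segment named list/vector with `common` and `extended`
#'   probe counts, each at least 4 (tandems with fewer probes per segment are
#'   not analyzable and the generator refuses to produce them).
#' @param n_normals number of normal (reference) samples.
#' @param subtype_sizes integer vector of tumor counts per planted subtype.
#' @param f0 baseline long-isoform fraction per tandem, recycled to
#'   `n_tandems`; each value in (0, 1].
#' @param subtype_effects `n_tandems x length(subtype_sizes)` matrix of log2
#'   shifts applied to `f0` (0 = not a signature tandem for that subtype).
#'   Negative values plant 3'UTR shortening.
#' @param abundance_sd per-(tandem, sample) log2 abundance SD.
#' @param probe_affinity_sd per-probe log2 affinity SD.
#' @param noise_sd residual Gaussian log2 noise SD.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_tandems = 50L,
                              probes_per_segment = c(common = 6L, extended = 6L),
                              n_normals = 33L,
                              subtype_sizes = c(36L, 36L, 67L, 26L),
                              f0 = 0.6,
                              subtype_effects = NULL,
                              abundance_sd = 0.5,
                              probe_affinity_sd = 0.3,
                              noise_sd = 0.25,
                              seed = 1L) {
  n_tandems <- as.integer(n_tandems)
  nc <- as.integer(probes_per_segment[["common"]])
  ne <- as.integer(probes_per_segment[["extended"]])
  stopifnot(n_tandems >= 1L, n_normals >= 1L, all(subtype_sizes >= 1L))
  if (nc < 4L || ne < 4L) {
    stop("probes_per_segment must be >= 4 on each side of the APA site; ",
         "tandems with fewer probes cannot enter change-point analysis")
  }
  f0 <- rep_len(as.double(f0), n_tandems)
  if (any(f0 <= 0) || any(f0 > 1)) stop("f0 must lie in (0, 1]")
  k <- length(subtype_sizes)
  if (is.null(subtype_effects)) {
    subtype_effects <- matrix(0, n_tandems, k)
  }
  subtype_effects <- as.matrix(subtype_effects)
  stopifnot(nrow(subtype_effects) == n_tandems, ncol(subtype_effects) == k)
  f_tum <- f0 * 2^subtype_effects
  if (any(f_tum > 1 + 1e-6)) {
    stop("subtype_effects imply a long-isoform fraction > 1 for some tandem; ",
         "reduce the effect or the baseline f0")
  }
  stopifnot(abundance_sd >= 0, probe_affinity_sd >= 0, noise_sd >= 0)
  structure(list(
    n_tandems = n_tandems, n_common = nc, n_extended = ne,
    n_normals = as.integer(n_normals),
    subtype_sizes = as.integer(subtype_sizes),
    f0 = f0, subtype_effects = subtype_effects,
    abundance_sd = abundance_sd, probe_affinity_sd = probe_affinity_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a probe-level tandem-3'UTR dataset with planted ground truth
#'
#' Generates log2 probe intensities
#' `y[p, s] = beta_p + a[t, s] + I(p in extended) * log2(f[t, s]) + eps`,
#' along with a BED-style probe map (0-based half-open, minus-strand tandems
#' reversed genomically relative to transcript order), a transcript-level
#' 3'UTR table (two isoforms per tandem sharing a 3'UTR start), a tandem-level
#' annotation table, a sample sheet, and the planted truth.
#'
#' @param config a [simulation_config()].
#' @return list with elements `intensity` (probes x samples matrix),
#'   `probe_map` (BED6 data.frame), `transcripts` (per-isoform 3'UTR table),
#'   `annotation` (tandem-level table), `samples` (sample sheet), and `truth`
#'   (list: `long_fraction`, `true_change_index`, `true_subtype`, `true_sui`,
#'   all on the tandem x sample / tumor grid).
#' @export
simulate_probe_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_tandems
  nc <- config$n_common
  ne <- config$n_extended
  np <- nc + ne
  n_tum <- sum(config$subtype_sizes)
  n_sam <- config$n_normals + n_tum

  tandem_id <- sprintf("tnd%04d", seq_len(nt))
  gene_id <- sprintf("gene%04d", seq_len(nt))
  sample_id <- c(sprintf("normal%03d", seq_len(config$n_normals)),
                 sprintf("tumor%03d", seq_len(n_tum)))
  group <- rep(c("normal", "tumor"), c(config$n_normals, n_tum))
  subtype <- c(rep(NA_character_, config$n_normals),
               rep(sprintf("S%d", seq_along(config$subtype_sizes)),
                   config$subtype_sizes))

  strand <- sample(c("+", "-"), nt, replace = TRUE)

  ## long-isoform fraction per tandem x sample
  f <- matrix(config$f0, nt, n_sam)
  tum_subtype_idx <- rep(seq_along(config$subtype_sizes), config$subtype_sizes)
  for (j in seq_len(n_tum)) {
    s <- config$n_normals + j
    f[, s] <- pmin(1, config$f0 * 2^config$subtype_effects[, tum_subtype_idx[j]])
  }

  beta <- rnorm(nt * np, 0, config$probe_affinity_sd)
  a <- matrix(rnorm(nt * n_sam, 0, config$abundance_sd), nt, n_sam)
  eps <- matrix(rnorm(nt * np * n_sam, 0, config$noise_sd), nt * np, n_sam)

  is_ext <- rep(rep(c(FALSE, TRUE), c(nc, ne)), nt)  # transcript 5'->3' order
  probe_tandem <- rep(seq_len(nt), each = np)
  y <- beta + a[probe_tandem, , drop = FALSE] +
    outer(as.double(is_ext), rep(1, n_sam)) * log2(f)[probe_tandem, , drop = FALSE] +
    eps
  probe_id <- sprintf("%s_p%02d", tandem_id[probe_tandem],
                      rep(seq_len(np), nt))
  dimnames(y) <- list(probe_id, sample_id)

  ## genomic layout: 25-bp probes every 35 bp; tandems spaced well apart
  probe_len <- 25L; pitch <- 35L
  seg_len <- function(k) k * pitch + 10L
  utr_span <- seg_len(nc) + seg_len(ne)
  tandem_base <- 10000L + (seq_len(nt) - 1L) * (utr_span + 5000L)

  probe_rows <- vector("list", nt)
  ann_rows <- vector("list", nt)
  tx_rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    off <- (seq_len(np) - 1L) * pitch + 5L          # transcript offsets of probe starts
    if (strand[t] == "+") {
      us <- tandem_base[t]
      pstart <- us + off
      pend <- pstart + probe_len
      prox <- us + seg_len(nc)
      dist <- us + utr_span
    } else {
      us <- tandem_base[t] + utr_span               # 3'UTR starts at the high coordinate
      pend <- us - off                              # half-open: probe covers [pend-len, pend)
      pstart <- pend - probe_len
      prox <- us - seg_len(nc)
      dist <- us - utr_span
    }
    probe_rows[[t]] <- data.frame(
      chrom = "chr1", start = pstart, end = pend,
      probe_id = sprintf("%s_p%02d", tandem_id[t], seq_len(np)),
      score = 0L, strand = strand[t], stringsAsFactors = FALSE)
    ann_rows[[t]] <- data.frame(
      tandem_id = tandem_id[t], gene_id = gene_id[t], strand = strand[t],
      utr_start = us, proximal_end = prox, distal_end = dist,
      stringsAsFactors = FALSE)
    tx_rows[[t]] <- data.frame(
      transcript_id = sprintf("%s_tx%d", gene_id[t], 1:2),
      gene_id = gene_id[t], strand = strand[t],
      utr_start = us, utr_end = c(prox, dist), stringsAsFactors = FALSE)
  }

  truth <- list(
    long_fraction = structure(f, dimnames = list(tandem_id, sample_id)),
    true_change_index = structure(rep(nc, nt), names = tandem_id),
    true_subtype = structure(subtype[group == "tumor"],
                             names = sample_id[group == "tumor"]),
    true_sui = structure(log2(config$f0 / f),
                         dimnames = list(tandem_id, sample_id))
  )

  list(intensity = y,
       probe_map = do.call(rbind, probe_rows),
       transcripts = do.call(rbind, tx_rows),
       annotation = do.call(rbind, ann_rows),
       samples = data.frame(sample_id = sample_id, group = group,
                            subtype = subtype, stringsAsFactors = FALSE),
       truth = truth,
       config = config)
}

#' Write a simulated probe dataset to TSV/BED files
#'
#' File schemas: intensity TSV (probe rows, sample columns), probe map BED6,
#' annotation TSV, transcript TSV, sample sheet TSV. Output is byte-identical
#' for identical configs.
#'
#' @param sim result of [simulate_probe_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_probe_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensity = file.path(dir, "intensity.tsv"),
             probe_map = file.path(dir, "probe_map.bed"),
             annotation = file.path(dir, "annotation.tsv"),
             transcripts = file.path(dir, "transcripts.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_matrix_tsv(sim$intensity, paths["intensity"], id_name = "probe_id")
  write.table(sim$probe_map, paths["probe_map"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$annotation, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$transcripts, paths["transcripts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Simulate an SUI matrix with planted subtypes
#'
#' Direct simulation on the SUI scale (short 3'UTR index,
#' `SUI = log2(f0 / f)`): each subtype carries a block of signature tandems
#' shifted by `effect_size` (planted 3'UTR shortening gives positive SUI),
#' remaining tandems are null, and Gaussian noise is added.
#'
#' @param n_tandems total number of tandem features.
#' @param subtype_sizes tumor counts per subtype.
#' @param n_signature signature tandems per subtype (blocks are disjoint;
#'   `n_signature * length(subtype_sizes) <= n_tandems`).
#' @param effect_size SUI shift of a signature tandem in its subtype.
#' @param noise_sd Gaussian noise SD on the SUI scale.
#' @param seed integer seed.
#' @return list: `sui` (tandems x samples), `true_subtype`, `signature`
#'   (tandem x subtype 0/1 matrix).
#' @export
simulate_sui_matrix <- function(n_tandems = 200L, subtype_sizes = c(15L, 15L, 15L, 15L),
                                n_signature = 40L, effect_size = 1,
                                noise_sd = 0.25, seed = 1L) {
  k <- length(subtype_sizes)
  stopifnot(n_signature * k <= n_tandems, all(subtype_sizes >= 1L))
  set.seed(seed)
  n_sam <- sum(subtype_sizes)
  lab <- rep(seq_len(k), subtype_sizes)
  sig <- matrix(0L, n_tandems, k)
  for (j in seq_len(k)) sig[(j - 1L) * n_signature + seq_len(n_signature), j] <- 1L
  mu <- sig[, lab, drop = FALSE] * effect_size
  sui <- mu + matrix(rnorm(n_tandems * n_sam, 0, noise_sd), n_tandems, n_sam)
  dimnames(sui) <- list(sprintf("tnd%04d", seq_len(n_tandems)),
                        sprintf("tumor%03d", seq_len(n_sam)))
  list(sui = sui,
       true_subtype = structure(sprintf("S%d", lab), names = colnames(sui)),
       signature = sig)
}

#' Simulate pooled shRNA screen barcode counts
#'
#' Counts at day `d` are drawn `multinomial(library_size, w_h * 2^(phi_h d/7))`
#' independently per replicate, where `phi_h = -depletion_rate` for hairpins of
#' depleted genes and 0 otherwise (controls included). Multinomial sampling
#' models a fixed sequencing depth per sample.
#'
#' @param n_genes number of targeted genes.
#' @param hairpins_per_gene hairpins per targeted gene.
#' @param n_controls number of non-targeting control hairpins.
#' @param depleted_genes character vector of depleted gene names (subset of
#'   the generated `gene01..` names).
#' @param depletion_rate depletion in log2 units per week for depleted genes.
#' @param timepoints days sampled; must include day 0.
#' @param n_replicates biological replicates.
#' @param library_size reads per sample (multinomial total).
#' @param baseline_sd SD of baseline log2 hairpin abundance.
#' @param seed integer seed.
#' @return list: `counts` (data.frame hairpin_id, gene, is_control, then one
#'   `d<day>_r<rep>` column per sample), `hairpin_map`, `truth` (depleted
#'   hairpins and per-hairpin `phi`).
#' @export
simulate_screen_counts <- function(n_genes = 23L, hairpins_per_gene = 4L,
                                   n_controls = 3L, depleted_genes = character(),
                                   depletion_rate = 1, timepoints = c(0, 7, 14, 21),
                                   n_replicates = 2L, library_size = 5e5,
                                   baseline_sd = 0.5, seed = 1L) {
  genes <- sprintf("gene%02d", seq_len(n_genes))
  if (!all(depleted_genes %in% genes)) {
    stop("depleted_genes must be a subset of the generated gene names")
  }
  if (!0 %in% timepoints) stop("timepoints must include day 0")
  hp_gene <- c(rep(genes, each = hairpins_per_gene),
               rep("control", n_controls))
  n_hp <- length(hp_gene)
  if (library_size < n_hp) stop("library_size smaller than the number of hairpins")
  hairpin_id <- c(sprintf("sh_%s_%d", rep(genes, each = hairpins_per_gene),
                          rep(seq_len(hairpins_per_gene), n_genes)),
                  sprintf("sh_ctrl_%d", seq_len(n_controls)))
  is_control <- hp_gene == "control"
  set.seed(seed)
  w <- 2^rnorm(n_hp, 0, baseline_sd)
  phi <- ifelse(hp_gene %in% depleted_genes, -depletion_rate, 0)

  cols <- list()
  for (r in seq_len(n_replicates)) {
    for (d in timepoints) {
      p <- w * 2^(phi * d / 7)
      cols[[sprintf("d%d_r%d", d, r)]] <-
        as.integer(rmultinom(1, size = library_size, prob = p / sum(p)))
    }
  }
  counts <- data.frame(hairpin_id = hairpin_id, gene = hp_gene,
                       is_control = is_control, cols,
                       stringsAsFactors = FALSE, check.names = FALSE)
  list(counts = counts,
       hairpin_map = data.frame(hairpin_id = hairpin_id, gene = hp_gene,
                                stringsAsFactors = FALSE),
       truth = list(depleted_genes = depleted_genes,
                    depleted_hairpins = hairpin_id[phi < 0],
                    phi = structure(phi, names = hairpin_id)))
}
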