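#' Assemble and validate a pipeline configuration
#'
#' Inputs are in-memory objects (matrices/data.frames as produced by the
#' simulator or read from TSV/BED with the package readers). Parameter
#' blocks only accept known keys; unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param intensity probes x samples log2 matrix.
#' @param transcripts transcript-level 3'UTR table (see [identify_tandems()]).
#' @param probe_map BED6 probe map (see [assign_probes()]).
#' @param samples sample sheet data.frame: `sample_id`, `group`, `subtype`.
#' @param bcp named list overriding [bcp_params()] defaults.
#' @param qc named list: `peak_frac`, `stability_ratio`.
#' @param subtype named list: `top_fraction`, `ranks`, `n_runs_survey`,
#'   `n_runs_final`, `theta`, `consensus_iter`.
#' @param screen named list: `pseudocount`, `endpoint_day`.
#' @param seed global seed fanned out to every stochastic stage.
#' @param output_dir optional directory for TSV outputs and the run log.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(intensity = NULL, transcripts = NULL,
                            probe_map = NULL, samples = NULL,
                            bcp = list(), qc = list(), subtype = list(),
                            screen = list(), seed = 1L, output_dir = NULL) {
  .check_keys(bcp, c("p0", "w0", "burnin", "mcmc"), "bcp")
  .check_keys(qc, c("peak_frac", "stability_ratio"), "qc")
  .check_keys(subtype, c("top_fraction", "ranks", "n_runs_survey",
                         "n_runs_final", "theta", "consensus_iter"), "subtype")
  .check_keys(screen, c("pseudocount", "endpoint_day"), "screen")
  structure(list(intensity = intensity, transcripts = transcripts,
                 probe_map = probe_map, samples = samples,
                 bcp = utils::modifyList(list(p0 = 0.2, w0 = 0.2, burnin = 50L,
                                              mcmc = 500L), bcp),
                 qc = utils::modifyList(list(peak_frac = 0.5,
                                             stability_ratio = 0.5), qc),
                 subtype = utils::modifyList(list(top_fraction = 0.25,
                                                  ranks = 2:10,
                                                  n_runs_survey = 50L,
                                                  n_runs_final = 200L,
                                                  theta = 0.5,
                                                  consensus_iter = 1000L),
                                             subtype),
                 screen = utils::modifyList(list(pseudocount = 1,
                                                 endpoint_day = NULL), screen),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

.check_keys <- function(x, allowed, block) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown ", block, " config key(s): ", paste(unknown, collapse = ", "))
  }
}

#' Run the APA profiling stage: tandems, change points, SUI
#'
#' Chains tandem identification, probe assignment, normal-median
#' normalization, per-tandem multivariate change-point detection, QC
#' filtering, SUI computation and per-tandem z-scoring. Stage counts
#' (candidates, probe-filtered tandems, QC outcomes) are recorded in
#' `counts`; when `output_dir` is set, the SUI matrix, QC table and a run
#' log are written there.
#'
#' @param config a [pipeline_config()] with `intensity`, `transcripts`,
#'   `probe_map` and `samples` set.
#' @return list: `sui` (tandems x samples, QC-passing tandems only), `z`,
#'   `qc` (per-tandem table), `tandems`, `counts`.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$samples) || nrow(config$samples) == 0L) {
    stop("validation: sample sheet is empty")
  }
  if (is.null(config$intensity) || is.null(config$transcripts) ||
      is.null(config$probe_map)) {
    stop("validation: intensity, transcripts and probe_map are all required")
  }
  samples <- config$samples
  x <- config$intensity[, samples$sample_id, drop = FALSE]

  candidates <- identify_tandems(config$transcripts)
  tandems <- assign_probes(candidates, config$probe_map)
  norm <- normalize_to_normal_median(x, samples$group)

  qc_rows <- vector("list", length(tandems))
  sui_rows <- list()
  for (i in seq_along(tandems)) {
    td <- tandems[[i]]
    X <- norm[td$probes, , drop = FALSE]
    params <- bcp_params(p0 = config$bcp$p0, w0 = config$bcp$w0,
                         burnin = config$bcp$burnin, mcmc = config$bcp$mcmc,
                         seed = child_seed(config$seed, "bcp", i))
    res <- bcp_multivariate(X, params)
    status <- qc_filter(res, config$qc$peak_frac, config$qc$stability_ratio)
    qc_rows[[i]] <- data.frame(tandem_id = td$tandem_id,
                               change_index = res$change_index,
                               max_rho = ifelse(is.na(res$max_rho), NA,
                                                res$max_rho),
                               qc_status = status, stringsAsFactors = FALSE)
    if (status == "OK") sui_rows[[td$tandem_id]] <- compute_sui(res)
  }
  qc <- do.call(rbind, qc_rows)
  sui <- do.call(rbind, sui_rows)
  counts <- c(candidates = nrow(candidates),
              probe_filtered = length(tandems),
              ok = sum(qc$qc_status == "OK"),
              multi_peak = sum(qc$qc_status == "MULTI_PEAK"),
              unstable = sum(qc$qc_status == "UNSTABLE"))
  z <- if (!is.null(sui)) sui_zscores(sui) else NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sui)) {
      write_matrix_tsv(sui, file.path(config$output_dir, "sui.tsv"), "tandem_id")
    }
    write.table(qc, file.path(config$output_dir, "tandem_qc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(counts), counts, sep = "\t"),
               file.path(config$output_dir, "run_log.txt"))
  }
  list(sui = sui, z = z, qc = qc, tandems = tandems, counts = counts)
}

#' Run subtype discovery on an SUI matrix
#'
#' CV-based feature selection, min-max scaling, rank survey, rank selection,
#' a final nsNMF fit and a consensus k-means robustness check.
#'
#' @param sui tandems x samples SUI matrix (tumor samples).
#' @param config a [pipeline_config()] (only the `subtype` block and `seed`
#'   are used).
#' @param rank override the surveyed rank (skips the survey when given).
#' @return list: `selected` (feature IDs), `survey`, `rank`, `nmf`
#'   (`subtype_solution`), `consensus` (consensus k-means output), `pca`.
#' @export
run_subtype <- function(sui, config = pipeline_config(), rank = NULL) {
  sc <- config$subtype
  selected <- cv_rank_select(sui, sc$top_fraction)
  X <- scale_features(sui[selected, , drop = FALSE])
  survey <- NULL
  if (is.null(rank)) {
    survey <- rank_survey(X, ranks = sc$ranks, n_runs = sc$n_runs_survey,
                          theta = sc$theta,
                          seed = child_seed(config$seed, "survey"))
    rank <- select_rank(survey)
  }
  nmf <- nsnmf(X, rank, theta = sc$theta, n_runs = sc$n_runs_final,
               seed = child_seed(config$seed, "nmf_final"))
  cons <- consensus_kmeans(X, rank, n_iter = sc$consensus_iter,
                           seed = child_seed(config$seed, "consensus"))
  pca <- pca_coords(sui[selected, , drop = FALSE])
  list(selected = selected, survey = survey, rank = rank, nmf = nmf,
       consensus = cons, pca = pca)
}

#' Train on reference subtypes and classify new samples
#'
#' @param reference_sui features x reference-samples matrix.
#' @param labels subtype labels of the reference samples.
#' @param new_sui features x new-samples matrix (e.g. cell lines); quantile
#'   normalized to the reference before prediction.
#' @param seed seed for the shrinkage cross-validation.
#' @return list: `model`, `labels`, `scores`.
#' @export
run_classify <- function(reference_sui, labels, new_sui, seed = 1L) {
  model <- train_shrunken_centroids(reference_sui, labels, seed = seed)
  pred <- classify_samples(model, new_sui, reference_sui = reference_sui)
  list(model = model, labels = pred$labels, scores = pred$scores)
}

#' Run the pooled shRNA screen analysis
#'
#' CPM normalization, enrichment scores, gene-level depletion tests,
#' replicate concordance and the day-0 vs endpoint diversity shift (per
#' replicate).
#'
#' @param counts screen counts data.frame (simulator schema).
#' @param config a [pipeline_config()] (only the `screen` block is used).
#' @return list: `cpm`, `scores`, `depletion`, `concordance`, `diversity`.
#' @export
run_screen <- function(counts, config = pipeline_config()) {
  cpm <- normalize_counts(counts)
  scores <- enrichment_scores(cpm, pseudocount = config$screen$pseudocount)
  endpoint <- config$screen$endpoint_day
  if (is.null(endpoint)) endpoint <- max(scores$hairpin$day)
  depletion <- depletion_test(scores, day = endpoint)
  concordance <- replicate_concordance(cpm)
  cols <- .screen_count_cols(cpm)
  reps <- unique(.col_rep(cols))
  diversity <- lapply(reps, function(r) {
    c0 <- cols[.col_day(cols) == 0 & .col_rep(cols) == r]
    ce <- cols[.col_day(cols) == endpoint & .col_rep(cols) == r]
    diversity_shift(cpm[[c0]], cpm[[ce]])
  })
  names(diversity) <- paste0("r", reps)
  list(cpm = cpm, scores = scores, depletion = depletion,
       concordance = concordance, diversity = diversity)
}
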