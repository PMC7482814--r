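#' Normalize probes to the per-sample median of their transcript
#'
#' For every sample, subtracts from each probe the median log2 intensity of
#' all probes mapped to the same transcript (log2-space subtraction, the
#' log-scale analogue of dividing intensities by the transcript median). Used
#' by the expression branch of the pipeline.
#'
#' @param x probes x samples log2 matrix with probe rownames.
#' @param probe_transcript data.frame with columns `probe_id`,
#'   `transcript_id`; every probe in `x` must map to exactly one transcript.
#' @return matrix of the same shape and ordering.
#' @export
normalize_to_transcript_median <- function(x, probe_transcript) {
  stopifnot(is.matrix(x), !is.null(rownames(x)),
            all(c("probe_id", "transcript_id") %in% names(probe_transcript)))
  if (anyNA(x) || any(!is.finite(x))) stop("intensity matrix has missing/non-finite values")
  map <- probe_transcript$transcript_id[match(rownames(x), probe_transcript$probe_id)]
  if (anyNA(map)) {
    stop("probes without a transcript mapping: ",
         paste(utils::head(rownames(x)[is.na(map)], 5L), collapse = ", "))
  }
  out <- x
  for (tx in unique(map)) {
    rows <- which(map == tx)
    med <- apply(x[rows, , drop = FALSE], 2L, median)
    out[rows, ] <- sweep(x[rows, , drop = FALSE], 2L, med)
  }
  out
}

#' Normalize probes to the median intensity across normal samples
#'
#' Subtracts from every sample's value at probe p the median of that probe
#' across the normal reference samples. After this step a normal-like sample
#' is centered at zero probe-by-probe, which anchors the SUI of normals at 0.
#' Applied before change-point analysis.
#'
#' @param x probes x samples log2 matrix.
#' @param groups character vector (`"tumor"`/`"normal"`) aligned with columns.
#' @return matrix of the same shape and ordering.
#' @export
normalize_to_normal_median <- function(x, groups) {
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  if (anyNA(x) || any(!is.finite(x))) stop("intensity matrix has missing/non-finite values")
  normals <- which(groups == "normal")
  if (!length(normals)) {
    stop("no normal samples present: supply a normal reference panel ",
         "(a 'normal' group in the sample sheet) before APA analysis")
  }
  ref <- apply(x[, normals, drop = FALSE], 1L, median)
  sweep(x, 1L, ref)
}
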