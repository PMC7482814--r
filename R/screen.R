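## Pooled shRNA proliferation-screen statistics. The counts table schema is
## the one the simulator writes: hairpin_id, gene, is_control, then one
## integer column per day/replicate named d<day>_r<rep>.

.screen_count_cols <- function(counts) {
  grep("^d[0-9]+_r[0-9]+$", names(counts), value = TRUE)
}

.col_day <- function(cols) as.integer(sub("^d([0-9]+)_r.*$", "\\1", cols))
.col_rep <- function(cols) as.integer(sub("^d[0-9]+_r([0-9]+)$", "\\1", cols))

#' Counts-per-million normalization of screen counts
#'
#' `cpm = 1e6 * count / column total`, per sample column.
#'
#' @param counts screen counts data.frame (see file header for schema).
#' @return data.frame of the same shape with count columns replaced by CPM.
#' @export
normalize_counts <- function(counts) {
  cols <- .screen_count_cols(counts)
  if (!length(cols)) stop("no d<day>_r<rep> count columns found")
  totals <- colSums(counts[cols])
  if (any(totals <= 0)) {
    stop("zero-total sample column(s): ",
         paste(cols[totals <= 0], collapse = ", "))
  }
  counts[cols] <- sweep(counts[cols], 2L, totals, "/") * 1e6
  counts
}

#' Hairpin- and gene-level enrichment scores
#'
#' Per hairpin, replicate and day `d > 0`:
#' `e = log2((cpm_d + pseudocount) / (cpm_0 + pseudocount))` against the same
#' replicate's day 0. The gene score per day is the mean over the gene's
#' hairpins and replicates; hairpins are ranked per day in descending score
#' order (the waterfall ranking).
#'
#' @param cpm CPM table from [normalize_counts()].
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return list: `hairpin` (long data.frame hairpin_id, gene, is_control,
#'   day, replicate, score, rank), `gene` (gene x day matrix of mean scores,
#'   controls under `"control"`).
#' @export
enrichment_scores <- function(cpm, pseudocount = 1) {
  cols <- .screen_count_cols(cpm)
  days <- .col_day(cols)
  reps <- .col_rep(cols)
  if (!any(days == 0)) stop("day 0 columns are required")
  rows <- list()
  for (j in which(days > 0)) {
    ref_col <- cols[days == 0 & reps == reps[j]]
    if (length(ref_col) != 1L) stop("missing day 0 for replicate ", reps[j])
    e <- log2((cpm[[cols[j]]] + pseudocount) / (cpm[[ref_col]] + pseudocount))
    rows[[cols[j]]] <- data.frame(
      hairpin_id = cpm$hairpin_id, gene = cpm$gene,
      is_control = cpm$is_control, day = days[j], replicate = reps[j],
      score = e, stringsAsFactors = FALSE)
  }
  hp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  hp$rank <- ave(-hp$score, hp$day, FUN = rank)
  gene_days <- sort(unique(hp$day))
  genes <- unique(hp$gene)
  gene_mat <- sapply(gene_days, function(d) {
    sub <- hp[hp$day == d, ]
    vapply(genes, function(g) mean(sub$score[sub$gene == g]), numeric(1))
  })
  gene_mat <- matrix(gene_mat, nrow = length(genes),
                     dimnames = list(genes, paste0("day", gene_days)))
  list(hairpin = hp, gene = gene_mat)
}

#' One-sided depletion test per gene against control hairpins
#'
#' Compares each gene's hairpin x replicate log2 ratios at the assay
#' endpoint against the control hairpins' ratios with a one-sided
#' Mann-Whitney U test (alternative: gene depleted below controls), exact
#' tail when group sizes permit, mid-ranks under ties; BH adjustment across
#' genes.
#'
#' @param scores output of [enrichment_scores()].
#' @param day endpoint day (default: the latest day present).
#' @return data.frame: gene, median score, p, q (sorted by p).
#' @export
depletion_test <- function(scores, day = max(scores$hairpin$day)) {
  hp <- scores$hairpin[scores$hairpin$day == day, ]
  ctrl <- hp$score[hp$is_control]
  if (!length(ctrl)) stop("no control hairpins present")
  genes <- setdiff(unique(hp$gene[!hp$is_control]), "control")
  res <- lapply(genes, function(g) {
    x <- hp$score[hp$gene == g]
    x <- x[is.finite(x)]
    if (length(x) < 2L) {
      warning("gene '", g, "' has fewer than 2 usable scores; skipped")
      return(NULL)
    }
    p <- suppressWarnings(
      wilcox.test(x, ctrl, alternative = "less", exact = NULL)$p.value)
    data.frame(gene = g, median_score = median(x), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res[order(res$p, res$gene), ]
}

#' Diversity-shift test between two screen timepoints
#'
#' Two-sample Kolmogorov-Smirnov test comparing the hairpin abundance
#' distributions of two samples on the `log10(cpm + 1)` scale; a shifted
#' cumulative curve (depletion of a hairpin subset) yields a large `D`.
#'
#' @param cpm_a,cpm_b numeric CPM vectors over the same hairpin set.
#' @param pseudocount added before the log (default 1).
#' @return list: `D`, `p`.
#' @export
diversity_shift <- function(cpm_a, cpm_b, pseudocount = 1) {
  stopifnot(length(cpm_a) == length(cpm_b))
  kt <- suppressWarnings(
    ks.test(log10(cpm_a + pseudocount), log10(cpm_b + pseudocount)))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Pairwise Spearman concordance of screen samples
#'
#' Rank correlation (mid-rank ties) of normalized read counts between all
#' pairs of sample columns.
#'
#' @param cpm CPM table from [normalize_counts()].
#' @return symmetric correlation matrix over sample columns.
#' @export
replicate_concordance <- function(cpm) {
  cols <- .screen_count_cols(cpm)
  if (length(cols) < 2L) stop("need at least 2 sample columns")
  cor(as.matrix(cpm[cols]), method = "spearman")
}
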