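## Tandem 3'UTR model building.
##
## Coordinates are 0-based half-open (BED convention) throughout. For a
## minus-strand 3'UTR the shared start is the HIGH genomic coordinate and end
## coordinates decrease along the transcript, so the genomic footprint of a
## tandem is [distal_end, utr_start) on "-" and [utr_start, distal_end) on "+".

## transcript-orientation length from the shared start to an end coordinate
.tx_len <- function(start, end, strand) (end - start) * ifelse(strand == "+", 1, -1)

#' Identify tandem 3'UTR candidates from a transcript annotation
#'
#' Transcripts of a gene sharing the same 3'UTR start but ending at different
#' poly(A) sites form a tandem 3'UTR. Genes whose transcripts all end at the
#' same site yield no candidate. When more than two distinct ends share a
#' start, the shortest end is taken as the proximal APA site and the longest
#' as the distal one (a single candidate per shared start), restricting the
#' analysis to the first functional APA site.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `strand`, `utr_start`, `utr_end` (genomic, 0-based half-open; see file
#'   header for the minus-strand convention).
#' @return data.frame of candidates: `tandem_id`, `gene_id`, `strand`,
#'   `utr_start`, `proximal_end`, `distal_end`.
#' @export
identify_tandems <- function(transcripts) {
  req <- c("transcript_id", "gene_id", "strand", "utr_start", "utr_end")
  stopifnot(all(req %in% names(transcripts)))
  len <- .tx_len(transcripts$utr_start, transcripts$utr_end, transcripts$strand)
  bad <- which(len <= 0)
  if (length(bad)) {
    stop("3'UTR end precedes start in transcript orientation for transcript(s): ",
         paste(transcripts$transcript_id[bad], collapse = ", "))
  }
  key <- paste(transcripts$gene_id, transcripts$utr_start, transcripts$strand,
               sep = "\r")
  out <- lapply(split(seq_len(nrow(transcripts)), key), function(idx) {
    tx <- transcripts[idx, , drop = FALSE]
    ends <- unique(tx$utr_end)
    if (length(ends) < 2L) return(NULL)
    l <- .tx_len(tx$utr_start[1L], ends, tx$strand[1L])
    data.frame(gene_id = tx$gene_id[1L], strand = tx$strand[1L],
               utr_start = tx$utr_start[1L],
               proximal_end = ends[which.min(l)],
               distal_end = ends[which.max(l)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(tandem_id = character(), gene_id = character(),
                      strand = character(), utr_start = integer(),
                      proximal_end = integer(), distal_end = integer()))
  }
  out <- out[order(out$gene_id, out$utr_start), , drop = FALSE]
  rownames(out) <- NULL
  cbind(data.frame(tandem_id = sprintf("%s:%d", out$gene_id, out$utr_start),
                   stringsAsFactors = FALSE),
        out)
}

#' Assign probes to tandem 3'UTRs and apply structural filters
#'
#' A probe belongs to a tandem when its genomic interval is contained in the
#' tandem's `[utr_start, distal_end)` footprint (transcript orientation).
#' Probes contained in more than one tandem are dropped entirely (only
#' uniquely mapped probes are kept); probes whose strand conflicts with their
#' tandem are dropped with a warning. Surviving probes are ordered 5'->3' in
#' transcript orientation and split at the proximal APA site into common and
#' extended segments; a probe straddling the boundary goes to the segment
#' holding the majority of its bases (tie -> common). Tandems with fewer than
#' four probes in either segment are discarded: the change-point model needs
#' at least four probes on each side of a prospective APA site.
#'
#' @param candidates data.frame from [identify_tandems()].
#' @param probe_map BED6-style data.frame: `chrom`, `start`, `end`,
#'   `probe_id`, `score`, `strand` (0-based half-open).
#' @return list of `tandem_utr` objects; each has `tandem_id`, `gene_id`,
#'   `strand`, coordinates, `probes` (IDs in transcript order), `ordinal`
#'   (0..n-1), `segment` (`"common"`/`"extended"`), `n_common`, `n_extended`.
#' @export
assign_probes <- function(candidates, probe_map) {
  stopifnot(all(c("chrom", "start", "end", "probe_id", "strand") %in% names(probe_map)))
  np <- nrow(probe_map)
  nt <- nrow(candidates)
  ## genomic footprint of each tandem
  lo <- ifelse(candidates$strand == "+", candidates$utr_start, candidates$distal_end)
  hi <- ifelse(candidates$strand == "+", candidates$distal_end, candidates$utr_start)
  ## containment: probe [s, e) inside [lo, hi)
  hit <- lapply(seq_len(np), function(p) {
    which(probe_map$start[p] >= lo & probe_map$end[p] <= hi)
  })
  n_hits <- lengths(hit)
  keep_probe <- n_hits == 1L                # "uniquely mapped probes were kept"
  tandem_of <- rep(NA_integer_, np)
  tandem_of[keep_probe] <- unlist(hit[keep_probe])

  conflict <- keep_probe & probe_map$strand != candidates$strand[tandem_of]
  if (any(conflict)) {
    warning(sum(conflict), " probe(s) dropped: strand conflicts with tandem (",
            paste(utils::head(probe_map$probe_id[conflict], 5L), collapse = ", "),
            if (sum(conflict) > 5L) ", ..." else "", ")")
    tandem_of[conflict] <- NA_integer_
  }

  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    idx <- which(tandem_of == t)
    if (!length(idx)) next
    pm <- probe_map[idx, , drop = FALSE]
    strand <- candidates$strand[t]
    ord <- if (strand == "+") order(pm$start) else order(-pm$end)
    pm <- pm[ord, , drop = FALSE]
    us <- candidates$utr_start[t]
    prox <- candidates$proximal_end[t]
    ## bases of each probe on the common side of the proximal APA site
    common_bases <- if (strand == "+") {
      pmax(0L, pmin(pm$end, prox) - pm$start)
    } else {
      pmax(0L, pm$end - pmax(pm$start, prox))
    }
    plen <- pm$end - pm$start
    segment <- ifelse(common_bases * 2L >= plen, "common", "extended")
    n_common <- sum(segment == "common")
    n_extended <- sum(segment == "extended")
    if (n_common < 4L || n_extended < 4L) next
    if (any(segment == "extended") && any(segment == "common")) {
      ## transcript order must place all common probes first
      stopifnot(max(which(segment == "common")) < min(which(segment == "extended")))
    }
    out[[t]] <- structure(list(
      tandem_id = candidates$tandem_id[t],
      gene_id = candidates$gene_id[t],
      strand = strand,
      utr_start = us, proximal_end = prox,
      distal_end = candidates$distal_end[t],
      probes = pm$probe_id,
      ordinal = seq_along(idx) - 1L,
      segment = segment,
      n_common = n_common, n_extended = n_extended
    ), class = "tandem_utr")
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Flatten tandem models to a summary table
#'
#' @param tandems list of `tandem_utr` objects from [assign_probes()].
#' @return data.frame: `tandem_id`, `gene_id`, `strand`, `n_common`,
#'   `n_extended`, `probes` (semicolon-joined, transcript order).
#' @export
tandem_table <- function(tandems) {
  do.call(rbind, lapply(tandems, function(td) {
    data.frame(tandem_id = td$tandem_id, gene_id = td$gene_id,
               strand = td$strand, n_common = td$n_common,
               n_extended = td$n_extended,
               probes = paste(td$probes, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
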