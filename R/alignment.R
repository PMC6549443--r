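#' Total length covered by a union of 1-based inclusive intervals
#'
#' @param starts,ends Integer vectors of equal length; `starts[i] <= ends[i]`.
#' @return Number of positions covered by at least one interval.
#' @keywords internal
interval_union_length <- function(starts, ends) {
  n <- length(starts)
  if (n == 0L) return(0L)
  stopifnot(length(ends) == n, all(starts <= ends))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L
  cur_s <- starts[1L]; cur_e <- ends[1L]
  if (n > 1L) for (i in 2L:n) {
    if (starts[i] <= cur_e + 1L) {
      if (ends[i] > cur_e) cur_e <- ends[i]
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Identity-weighted coverage of a union of intervals
#'
#' Each interval carries a percent identity; overlapping positions take the
#' highest identity among the intervals covering them. Returns the sum of
#' `identity/100` over all covered positions — an estimate of the number of
#' identical nucleotides implied by a set of HSPs on one sequence.
#'
#' @param starts,ends 1-based inclusive interval coordinates.
#' @param pident Percent identity per interval, in \[0, 100\].
#' @return Weighted coverage (real, in nucleotide units).
#' @keywords internal
weighted_identity_length <- function(starts, ends, pident) {
  n <- length(starts)
  if (n == 0L) return(0)
  stopifnot(length(ends) == n, length(pident) == n, all(starts <= ends))
  # sweep over elementary segments between breakpoints
  pts <- sort(unique(c(starts, ends + 1L)))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    a <- pts[i]; b <- pts[i + 1L] - 1L
    cover <- starts <= a & ends >= b
    if (any(cover)) total <- total + (b - a + 1L) * max(pident[cover]) / 100
  }
  total
}

#' Filter HSPs on identity and E-value
#'
#' Retains HSPs with percent identity strictly above `min_identity` and
#' E-value strictly below `max_evalue` (defaults: identity over 70%,
#' E-value smaller than 1e-5).
#'
#' @param hsp HSP data.frame from [read_blast_tabular()].
#' @param min_identity Identity threshold in percent.
#' @param max_evalue E-value threshold.
#' @return The filtered data.frame.
#' @export
filter_hsps <- function(hsp, min_identity = 70, max_evalue = 1e-5) {
  stopifnot(is.finite(min_identity), is.finite(max_evalue))
  hsp[hsp$pident > min_identity & hsp$evalue < max_evalue, , drop = FALSE]
}

#' Merge the HSPs of one contig-transcript pair into a global alignment
#'
#' Projects every retained HSP onto the coordinates of both sequences and
#' takes the union of the covered intervals on each side. The summary
#' statistics are:
#' \describe{
#'   \item{recovery}{fraction of transcript positions covered by the union
#'     of subject-side intervals}
#'   \item{accuracy}{fraction of contig positions covered by the union of
#'     query-side intervals}
#'   \item{alignment_score}{`sqrt(recovery * accuracy)`}
#'   \item{diff_length_pct}{`(l_c - l_t) / (l_c + l_t) * 100`, the
#'     percentage difference in length between contig and transcript}
#' }
#' Overlapping HSPs count each base once; no colinearity is required. With
#' `identity_weighted = TRUE` coverage on each side is weighted by HSP
#' percent identity (max at overlaps) before normalization.
#'
#' @param hsp HSPs of a single (contig = query, transcript = subject) pair.
#' @param contig_len,transcript_len Sequence lengths in nt.
#' @param identity_weighted Weight coverage by HSP identity? Default `FALSE`.
#' @return One-row data.frame: `contig_id, transcript_id, recovery,
#'   accuracy, alignment_score, diff_length_pct, n_hsps`.
#' @export
merge_global <- function(hsp, contig_len, transcript_len,
                         identity_weighted = FALSE) {
  if (nrow(hsp) == 0L) {
    stop("cannot merge an empty HSP set into a global alignment")
  }
  stopifnot(contig_len > 0, transcript_len > 0)
  if (length(unique(hsp$qseqid)) != 1L || length(unique(hsp$sseqid)) != 1L) {
    stop("merge_global expects HSPs of a single (contig, transcript) pair")
  }
  if (identity_weighted) {
    cov_t <- weighted_identity_length(hsp$sstart, hsp$send, hsp$pident)
    cov_c <- weighted_identity_length(hsp$qstart, hsp$qend, hsp$pident)
  } else {
    cov_t <- interval_union_length(hsp$sstart, hsp$send)
    cov_c <- interval_union_length(hsp$qstart, hsp$qend)
  }
  recovery <- min(cov_t / transcript_len, 1)
  accuracy <- min(cov_c / contig_len, 1)
  data.frame(
    contig_id = hsp$qseqid[1L],
    transcript_id = hsp$sseqid[1L],
    recovery = recovery,
    accuracy = accuracy,
    alignment_score = sqrt(recovery * accuracy),
    diff_length_pct = diff_length_pct(contig_len, transcript_len),
    n_hsps = nrow(hsp),
    stringsAsFactors = FALSE
  )
}

#' Percentage difference in length between two sequences
#'
#' `(l_c - l_t) / (l_c + l_t) * 100`; antisymmetric under swapping the two
#' lengths and bounded in (-100, 100).
#'
#' @param l_c,l_t Lengths in nt (contig, transcript).
#' @return Percent difference.
#' @export
diff_length_pct <- function(l_c, l_t) {
  (l_c - l_t) / (l_c + l_t) * 100
}

#' Build global alignments for every contig-transcript pair with HSPs
#'
#' Groups a filtered HSP table by (query, subject) pair and merges each
#' group with [merge_global()]. Mixed-strand pairs are merged into one
#' union and flagged with a warning.
#'
#' @param hsp Filtered HSP data.frame (query = contig, subject = transcript).
#' @param contigs,transcripts DNAStringSet (or named lengths from
#'   [seq_lengths()]) used to resolve sequence lengths.
#' @param identity_weighted Passed to [merge_global()].
#' @return Data.frame of global alignments, one row per pair, sorted by
#'   contig then transcript id.
#' @export
align_all <- function(hsp, contigs, transcripts, identity_weighted = FALSE) {
  clen <- if (is.numeric(contigs)) contigs else seq_lengths(contigs)
  tlen <- if (is.numeric(transcripts)) transcripts else seq_lengths(transcripts)
  if (nrow(hsp) == 0L) return(empty_alignment_table())
  unknown_c <- setdiff(unique(hsp$qseqid), names(clen))
  if (length(unknown_c) > 0L) {
    stop("HSP query id(s) not in the contig set: ",
         paste(unknown_c, collapse = ", "))
  }
  unknown_t <- setdiff(unique(hsp$sseqid), names(tlen))
  if (length(unknown_t) > 0L) {
    stop("HSP subject id(s) not in the transcript set: ",
         paste(unknown_t, collapse = ", "))
  }
  key <- paste(hsp$qseqid, hsp$sseqid, sep = "\r")
  groups <- split(seq_len(nrow(hsp)), key)
  res <- lapply(groups, function(idx) {
    g <- hsp[idx, , drop = FALSE]
    if (length(unique(g$minus_strand)) > 1L) {
      warning("mixed-strand HSPs merged for pair ", g$qseqid[1L], " / ",
              g$sseqid[1L])
    }
    merge_global(g, clen[[g$qseqid[1L]]], tlen[[g$sseqid[1L]]],
                 identity_weighted = identity_weighted)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$contig_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_alignment_table <- function() {
  data.frame(
    contig_id = character(0), transcript_id = character(0),
    recovery = numeric(0), accuracy = numeric(0),
    alignment_score = numeric(0), diff_length_pct = numeric(0),
    n_hsps = integer(0), stringsAsFactors = FALSE
  )
}
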