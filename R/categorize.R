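#' Assign transcripts to contigs
#'
#' A transcript is assigned to a contig when either recovery or accuracy of
#' their global alignment reaches the threshold (boundary inclusive,
#' default 0.90). Assignment is many-to-many: a contig may receive several
#' transcripts and a transcript may be assigned to several contigs.
#'
#' @param alignments Global alignment table from [align_all()].
#' @param threshold Assignment threshold in (0, 1], default 0.9.
#' @param inclusive Treat the boundary as assigned? Default `TRUE`.
#' @return The subset of `alignments` that passes, with an `assigned`
#'   column removed (all rows pass).
#' @export
assign_transcripts <- function(alignments, threshold = 0.9,
                               inclusive = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  pass <- if (inclusive) {
    alignments$recovery >= threshold | alignments$accuracy >= threshold
  } else {
    alignments$recovery > threshold | alignments$accuracy > threshold
  }
  out <- alignments[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize contigs into assembly-error classes
#'
#' Every contig receives exactly one category:
#' \describe{
#'   \item{unassigned}{no transcript passes the assignment rule}
#'   \item{family-collapse}{two or more transcripts assigned and every
#'     assigned alignment has accuracy at or above the gate — one contig
#'     standing in for a family of similar transcripts}
#'   \item{duplication}{the contig sits in an ambiguity component of size
#'     two or more, has a single assigned transcript recovered at or above
#'     the gate, and at least one other contig in the same component is
#'     assigned that same transcript — redundant near-copies}
#'   \item{full-length / incompleteness / over-extension}{unique contigs
#'     (singleton ambiguity component) with exactly one assigned
#'     transcript, split on whether recovery and accuracy reach the gate:
#'     both — full-length; accuracy only — incompleteness; recovery only —
#'     over-extension}
#'   \item{ambiguous-other}{anything else (e.g. non-unique contigs whose
#'     component shares no transcript assignment)}
#' }
#' The decision is taken in the order listed: collapse before duplication,
#' both before the completeness split.
#'
#' @param assignments Assigned alignment table from [assign_transcripts()].
#' @param contig_components Component table for contigs
#'   ([build_components()]).
#' @param gate Recovery/accuracy gate used inside the category definitions,
#'   default 0.9.
#' @return Data.frame with one row per contig in `contig_components`:
#'   `contig_id, category, is_unique, component_id, n_assigned,
#'   best_transcript, recovery, accuracy, alignment_score,
#'   diff_length_pct` (best = highest alignment score, ties by transcript
#'   id), sorted by contig id.
#' @export
categorize_contigs <- function(assignments, contig_components, gate = 0.9) {
  comp <- contig_components
  asg <- split(assignments, assignments$contig_id)

  # transcript -> contigs assigned to it (for the duplication test)
  contigs_of_transcript <- split(assignments$contig_id,
                                 assignments$transcript_id)
  comp_of_contig <- stats::setNames(comp$component_id, comp$seq_id)

  rows <- lapply(seq_len(nrow(comp)), function(i) {
    cid <- comp$seq_id[i]
    a <- asg[[cid]]
    n_assigned <- if (is.null(a)) 0L else nrow(a)
    best <- NULL
    if (n_assigned > 0L) {
      a <- a[order(-a$alignment_score, a$transcript_id), , drop = FALSE]
      best <- a[1L, ]
    }
    category <- if (n_assigned == 0L) {
      "unassigned"
    } else if (n_assigned >= 2L && all(a$accuracy >= gate)) {
      "family-collapse"
    } else if (comp$component_size[i] >= 2L && n_assigned == 1L &&
               best$recovery >= gate &&
               sum(comp_of_contig[contigs_of_transcript[[best$transcript_id]]] ==
                     comp$component_id[i]) >= 2L) {
      "duplication"
    } else if (comp$is_unique[i] && n_assigned == 1L) {
      if (best$recovery >= gate && best$accuracy >= gate) {
        "full-length"
      } else if (best$accuracy >= gate && best$recovery < gate) {
        "incompleteness"
      } else if (best$recovery >= gate && best$accuracy < gate) {
        "over-extension"
      } else {
        "ambiguous-other"
      }
    } else {
      "ambiguous-other"
    }
    data.frame(
      contig_id = cid,
      category = category,
      is_unique = comp$is_unique[i],
      component_id = comp$component_id[i],
      n_assigned = n_assigned,
      best_transcript = if (is.null(best)) NA_character_ else
        best$transcript_id,
      recovery = if (is.null(best)) NA_real_ else best$recovery,
      accuracy = if (is.null(best)) NA_real_ else best$accuracy,
      alignment_score = if (is.null(best)) NA_real_ else
        best$alignment_score,
      diff_length_pct = if (is.null(best)) NA_real_ else
        best$diff_length_pct,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin length differences for completeness profiles
#'
#' Assigns each percentage difference in length to a half-open,
#' lower-inclusive bin of the given width; the bin label is its lower
#' bound, so e.g. values in \[-10, 0) fall in bin -10 and 0 falls in bin 0.
#'
#' @param diff_length_pct Numeric vector of percent differences.
#' @param width Bin width in percentage points, default 10.
#' @return Integer-valued numeric vector of lower bounds.
#' @export
completeness_bins <- function(diff_length_pct, width = 10) {
  floor(diff_length_pct / width) * width
}
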