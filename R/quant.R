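#' Effective length of a sequence under a fragment model
#'
#' `max(length - mean_fragment + 1, 1)`: the number of positions a fragment
#' of the mean length can start at, floored at 1 for sequences shorter than
#' a fragment.
#'
#' @param length Sequence length(s) in nt.
#' @param mean_fragment Mean fragment (insert) length in nt.
#' @return Effective length(s), real.
#' @export
effective_length <- function(length, mean_fragment) {
  stopifnot(all(length >= 1))
  pmax(length - mean_fragment + 1, 1)
}

#' Ground-truth TPM from read counts
#'
#' Converts per-sequence read counts into transcripts-per-million:
#' `tpm_i = (f_i / l_i) / sum_k(f_k / l_k) * 1e6` with `l_i` the effective
#' length. The result sums to 1e6.
#'
#' @param read_count Non-negative read counts `f_i`.
#' @param eff_length Effective lengths `l_i` (all >= 1).
#' @return TPM vector of the same length.
#' @export
ground_truth_tpm <- function(read_count, eff_length) {
  stopifnot(length(read_count) == length(eff_length),
            all(eff_length >= 1), all(read_count >= 0))
  dens <- read_count / eff_length
  denom <- sum(dens)
  if (denom <= 0) stop("cannot normalize TPM: total read density is zero")
  dens / denom * 1e6
}

#' Relative quantification error in percent
#'
#' `(est - gt) / (est + gt) * 100`, a symmetric percent error bounded in
#' \[-100, 100\]; defined as 0 when both values are 0 (unexpressed and
#' unestimated agree).
#'
#' @param tpm_est Estimated abundance (TPM).
#' @param tpm_gt Ground-truth abundance (TPM).
#' @return Percent error, vectorized.
#' @export
relative_error <- function(tpm_est, tpm_gt) {
  denom <- tpm_est + tpm_gt
  out <- ifelse(denom > 0, (tpm_est - tpm_gt) / denom * 100, 0)
  out
}

#' Read proportion of estimated abundance (RPEA) within components
#'
#' Each contig's share of the reads the quantifier allocated within its
#' ambiguity component: `rpea_i = count_i / sum_j count_j` over the
#' component members. A max RPEA near 1 means the quantifier concentrated
#' the component's reads on one contig; near `1/n` means it spread them
#' evenly. Components whose members all have zero allocated reads get the
#' uniform value `1/n`, preserving the sum-to-one property.
#'
#' @param components Component table from [build_components()] (contigs).
#' @param expr Estimated expression data.frame (`seq_id, read_count`).
#' @return Data.frame: `seq_id, component_id, rpea`, sorted by `seq_id`.
#' @export
rpea <- function(components, expr) {
  m <- match(components$seq_id, expr$seq_id)
  if (anyNA(m)) {
    stop("no expression record for contig(s): ",
         paste(components$seq_id[is.na(m)], collapse = ", "))
  }
  counts <- expr$read_count[m]
  stopifnot(all(counts >= 0))
  totals <- tapply(counts, components$component_id, sum)
  sizes <- tapply(counts, components$component_id, length)
  tot_i <- totals[components$component_id]
  n_i <- sizes[components$component_id]
  val <- ifelse(tot_i > 0, counts / tot_i, 1 / n_i)
  out <- data.frame(seq_id = components$seq_id,
                    component_id = components$component_id,
                    rpea = as.numeric(val),
                    stringsAsFactors = FALSE)
  out[order(out$seq_id), , drop = FALSE]
}

#' Bin maximum RPEA values
#'
#' Lower-inclusive bins of width 0.05 labeled by their lower bound, so a
#' max RPEA of 0.47 falls in bin 0.45 (the range \[0.45, 0.50)). Values of
#' exactly 1 are kept in the top bin 0.95.
#'
#' @param max_rpea Numeric vector in \[0, 1\].
#' @param width Bin width, default 0.05.
#' @return Numeric vector of lower bounds.
#' @export
rpea_bins <- function(max_rpea, width = 0.05) {
  b <- floor(max_rpea / width) * width
  pmin(b, 1 - width)
}

#' Evaluate family-collapse contigs against three candidate references
#'
#' A family-collapse contig carries the reads of several similar
#' transcripts, so its ground truth is ambiguous. For each such contig the
#' estimated abundance is compared against three references: (1) the
#' ground-truth TPM of the assigned transcript with the highest alignment
#' score, (2) the ground-truth TPM of the most highly expressed assigned
#' transcript, and (3) the total ground-truth TPM of the transcript
#' ambiguity component containing the assigned transcripts.
#'
#' @param annotations Contig annotation table from [categorize_contigs()]
#'   (only rows with category `family-collapse` are used).
#' @param assignments Assigned alignment table.
#' @param est Estimated contig expression (`seq_id, tpm`).
#' @param gt Ground-truth transcript expression (`seq_id, tpm`).
#' @param transcript_components Component table for transcripts.
#' @return Data.frame: one row per family-collapse contig with
#'   `contig_id, tpm_est, n_family, gt_best_score, gt_max_expr,
#'   gt_component_total, err_best_score, err_max_expr, err_component`.
#' @export
family_collapse_eval <- function(annotations, assignments, est, gt,
                                 transcript_components) {
  fc <- annotations[annotations$category == "family-collapse", , drop = FALSE]
  if (nrow(fc) == 0L) return(empty_fc_table())
  est_tpm <- stats::setNames(est$tpm, est$seq_id)
  gt_tpm <- stats::setNames(gt$tpm, gt$seq_id)
  tcomp <- stats::setNames(transcript_components$component_id,
                           transcript_components$seq_id)
  rows <- lapply(fc$contig_id, function(cid) {
    a <- assignments[assignments$contig_id == cid, , drop = FALSE]
    a <- a[order(-a$alignment_score, a$transcript_id), , drop = FALSE]
    e <- est_tpm[[cid]]
    g <- gt_tpm[a$transcript_id]
    ref_best <- unname(g[1L])
    ref_maxe <- max(g)
    comps <- unique(tcomp[a$transcript_id])
    members <- transcript_components$seq_id[
      transcript_components$component_id %in% comps]
    ref_comp <- sum(gt_tpm[members])
    data.frame(
      contig_id = cid, tpm_est = e, n_family = nrow(a),
      gt_best_score = ref_best, gt_max_expr = ref_maxe,
      gt_component_total = ref_comp,
      err_best_score = relative_error(e, ref_best),
      err_max_expr = relative_error(e, ref_maxe),
      err_component = relative_error(e, ref_comp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_fc_table <- function() {
  data.frame(contig_id = character(0), tpm_est = numeric(0),
             n_family = integer(0), gt_best_score = numeric(0),
             gt_max_expr = numeric(0), gt_component_total = numeric(0),
             err_best_score = numeric(0), err_max_expr = numeric(0),
             err_component = numeric(0), stringsAsFactors = FALSE)
}

#' Evaluate duplicated contigs against three reference selections
#'
#' For each transcript assigned to a set of duplicated contigs (one
#' ambiguity component), the transcript's ground-truth TPM is compared
#' with: (1) the estimated TPM of the contig with the highest alignment
#' score, (2) the estimated TPM of the contig allocated the most reads
#' (highest RPEA), and (3) the total estimated TPM of the contig
#' component. The component's maximum RPEA is reported with its 0.05-wide
#' lower-inclusive bin.
#'
#' @param annotations Contig annotation table (category `duplication`).
#' @param assignments Assigned alignment table.
#' @param est Estimated contig expression (`seq_id, read_count, tpm`).
#' @param gt Ground-truth transcript expression (`seq_id, tpm`).
#' @param contig_components Component table for contigs.
#' @return Data.frame: one row per (transcript, component):
#'   `transcript_id, component_id, n_contigs, tpm_gt, est_best_score,
#'   est_max_rpea, est_component_total, err_best_score, err_max_rpea,
#'   err_component, max_rpea, max_rpea_bin`.
#' @export
duplication_eval <- function(annotations, assignments, est, gt,
                             contig_components) {
  dup <- annotations[annotations$category == "duplication", , drop = FALSE]
  if (nrow(dup) == 0L) return(empty_dup_table())
  est_tpm <- stats::setNames(est$tpm, est$seq_id)
  gt_tpm <- stats::setNames(gt$tpm, gt$seq_id)
  rp <- rpea(contig_components, est)
  rp_of <- stats::setNames(rp$rpea, rp$seq_id)
  key <- unique(dup[, c("best_transcript", "component_id")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    tid <- key$best_transcript[i]
    comp <- key$component_id[i]
    members <- dup$contig_id[dup$best_transcript == tid &
                               dup$component_id == comp]
    a <- assignments[assignments$contig_id %in% members &
                       assignments$transcript_id == tid, , drop = FALSE]
    a <- a[order(-a$alignment_score, a$contig_id), , drop = FALSE]
    g <- gt_tpm[[tid]]
    e_best <- est_tpm[[a$contig_id[1L]]]
    rp_m <- rp_of[members]
    c_maxrp <- members[order(-rp_m, members)][1L]
    e_rpea <- est_tpm[[c_maxrp]]
    # component total over the full ambiguity component, not just the
    # duplicated members, since the quantifier spread reads over all of it
    all_members <- contig_components$seq_id[
      contig_components$component_id == comp]
    e_comp <- sum(est_tpm[all_members])
    max_rp <- max(rp_of[all_members])
    data.frame(
      transcript_id = tid, component_id = comp,
      n_contigs = length(members), tpm_gt = g,
      est_best_score = e_best, est_max_rpea = e_rpea,
      est_component_total = e_comp,
      err_best_score = relative_error(e_best, g),
      err_max_rpea = relative_error(e_rpea, g),
      err_component = relative_error(e_comp, g),
      max_rpea = max_rp, max_rpea_bin = rpea_bins(max_rp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$component_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_dup_table <- function() {
  data.frame(transcript_id = character(0), component_id = character(0),
             n_contigs = integer(0), tpm_gt = numeric(0),
             est_best_score = numeric(0), est_max_rpea = numeric(0),
             est_component_total = numeric(0), err_best_score = numeric(0),
             err_max_rpea = numeric(0), err_component = numeric(0),
             max_rpea = numeric(0), max_rpea_bin = numeric(0),
             stringsAsFactors = FALSE)
}

#' Component-level quantification error
#'
#' Builds "super-components": connected components of the union graph whose
#' nodes are contigs and transcripts, with edges from the contig ambiguity
#' network, the transcript ambiguity network, and the contig-transcript
#' assignment map. For each super-component containing at least one
#' assignment the total estimated TPM of its contigs is compared with the
#' total ground-truth TPM of its transcripts. Aggregating to this level
#' removes the ambiguity of multiple assignment and typically yields a more
#' accurate estimate than per-sequence comparison.
#'
#' @param assignments Assigned alignment table.
#' @param contig_components,transcript_components Component tables.
#' @param est Estimated contig expression (`seq_id, tpm`).
#' @param gt Ground-truth transcript expression (`seq_id, tpm`).
#' @return Data.frame: `super_component, n_contigs, n_transcripts,
#'   tpm_est_total, tpm_gt_total, err_component`.
#' @export
component_level_eval <- function(assignments, contig_components,
                                 transcript_components, est, gt) {
  if (nrow(assignments) == 0L) {
    return(data.frame(super_component = character(0), n_contigs = integer(0),
                      n_transcripts = integer(0), tpm_est_total = numeric(0),
                      tpm_gt_total = numeric(0), err_component = numeric(0),
                      stringsAsFactors = FALSE))
  }
  cnode <- paste0("c:", contig_components$seq_id)
  tnode <- paste0("t:", transcript_components$seq_id)
  nodes <- sort(c(cnode, tnode))
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  link <- function(parent, a, b) {
    ra <- uf_find(parent, idx[[a]])
    rb <- uf_find(parent, idx[[b]])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    parent
  }
  # contig-contig and transcript-transcript edges within components
  for (tab in list(
    data.frame(node = cnode, comp = contig_components$component_id),
    data.frame(node = tnode, comp = transcript_components$component_id))) {
    for (grp in split(tab$node, tab$comp)) {
      if (length(grp) > 1L) for (k in 2L:length(grp)) {
        parent <- link(parent, grp[1L], grp[k])
      }
    }
  }
  for (k in seq_len(nrow(assignments))) {
    parent <- link(parent, paste0("c:", assignments$contig_id[k]),
                   paste0("t:", assignments$transcript_id[k]))
  }
  root <- vapply(seq_along(nodes), function(i) uf_find(parent, i), integer(1))
  est_tpm <- stats::setNames(est$tpm, paste0("c:", est$seq_id))
  gt_tpm <- stats::setNames(gt$tpm, paste0("t:", gt$seq_id))
  matched_roots <- unique(root[idx[paste0("c:", assignments$contig_id)]])
  rows <- lapply(sort(matched_roots), function(r) {
    members <- nodes[root == r]
    cm <- members[startsWith(members, "c:")]
    tm <- members[startsWith(members, "t:")]
    e <- sum(est_tpm[cm], na.rm = TRUE)
    g <- sum(gt_tpm[tm], na.rm = TRUE)
    data.frame(
      super_component = sprintf("S%04d", r),
      n_contigs = length(cm), n_transcripts = length(tm),
      tpm_est_total = e, tpm_gt_total = g,
      err_component = relative_error(e, g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-pair (sequence-level) quantification error
#'
#' Relative error of each assigned contig-transcript pair: estimated contig
#' TPM against ground-truth transcript TPM.
#'
#' @param assignments Assigned alignment table.
#' @param est Estimated contig expression (`seq_id, tpm`).
#' @param gt Ground-truth transcript expression (`seq_id, tpm`).
#' @return `assignments` with `tpm_est, tpm_gt, relative_error_pct` added.
#' @export
pair_level_eval <- function(assignments, est, gt) {
  est_tpm <- stats::setNames(est$tpm, est$seq_id)
  gt_tpm <- stats::setNames(gt$tpm, gt$seq_id)
  out <- assignments
  out$tpm_est <- unname(est_tpm[out$contig_id])
  out$tpm_gt <- unname(gt_tpm[out$transcript_id])
  if (anyNA(out$tpm_est) || anyNA(out$tpm_gt)) {
    stop("missing expression record for an assigned contig or transcript")
  }
  out$relative_error_pct <- relative_error(out$tpm_est, out$tpm_gt)
  out
}

#' Average-TPM ground truth from several quantifier tables
#'
#' When no simulation truth exists, the per-transcript mean TPM across the
#' supplied quantifier outputs serves as the ground-truth expression.
#'
#' @param tables List of expression data.frames (`seq_id, tpm`, same id
#'   universe).
#' @return Data.frame `seq_id, tpm` with the mean TPM, sorted by id.
#' @export
average_truth <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ids <- sort(unique(unlist(lapply(tables, function(x) x$seq_id))))
  tpm <- rowMeans(vapply(tables, function(x) {
    m <- match(ids, x$seq_id)
    if (anyNA(m)) stop("quantifier tables disagree on the sequence set")
    x$tpm[m]
  }, numeric(length(ids))))
  data.frame(seq_id = ids, tpm = tpm, stringsAsFactors = FALSE)
}
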