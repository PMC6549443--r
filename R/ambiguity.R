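# Union-find root lookup; ids are integer indices into a parent vector.
# No path compression: component sizes here are small and R copies on write.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Per-pair identity summaries from self-alignment HSPs
#'
#' Collapses a filtered self-alignment HSP table (both query and subject
#' drawn from the same sequence set) into one row per unordered sequence
#' pair, with the implied number of identical nucleotides on each side.
#' Self hits are dropped; symmetric rows are combined. On each sequence the
#' HSP intervals are merged with overlaps resolved by the higher identity
#' (see [weighted_identity_length()]); `aln_a`/`aln_b` carry the plain
#' union coverage instead, for the alignment-length join metric.
#'
#' @param hsp Filtered self-alignment HSPs.
#' @return Data.frame: `id_a, id_b, ident_a, ident_b, aln_a, aln_b` with
#'   `id_a < id_b`.
#' @export
pair_identities <- function(hsp) {
  hsp <- hsp[hsp$qseqid != hsp$sseqid, , drop = FALSE]
  if (nrow(hsp) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      ident_a = numeric(0), ident_b = numeric(0),
                      aln_a = numeric(0), aln_b = numeric(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(hsp$qseqid, hsp$sseqid)
  b <- pmax(hsp$qseqid, hsp$sseqid)
  key <- paste(a, b, sep = "\r")
  groups <- split(seq_len(nrow(hsp)), key)
  rows <- lapply(groups, function(idx) {
    g <- hsp[idx, , drop = FALSE]
    id_a <- min(g$qseqid[1L], g$sseqid[1L])
    id_b <- max(g$qseqid[1L], g$sseqid[1L])
    q_is_a <- g$qseqid == id_a
    sa <- c(g$qstart[q_is_a], g$sstart[!q_is_a])
    ea <- c(g$qend[q_is_a], g$send[!q_is_a])
    sb <- c(g$sstart[q_is_a], g$qstart[!q_is_a])
    eb <- c(g$send[q_is_a], g$qend[!q_is_a])
    pa <- c(g$pident[q_is_a], g$pident[!q_is_a])
    data.frame(
      id_a = id_a, id_b = id_b,
      ident_a = weighted_identity_length(sa, ea, pa),
      ident_b = weighted_identity_length(sb, eb, pa),
      aln_a = interval_union_length(sa, ea),
      aln_b = interval_union_length(sb, eb),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Should two sequences join one ambiguity component?
#'
#' Two sequences are considered ambiguous — placed in the same connected
#' component — when the proportion of identical nucleotides between them
#' exceeds the threshold fraction of either sequence's length (strictly
#' greater than; default 0.9).
#'
#' @param ident_a,ident_b Identical-nucleotide estimates on each sequence.
#' @param len_a,len_b Sequence lengths in nt.
#' @param threshold Joining fraction, default 0.9.
#' @return Logical.
#' @export
join_predicate <- function(ident_a, ident_b, len_a, len_b, threshold = 0.9) {
  ident_a / len_a > threshold | ident_b / len_b > threshold
}

#' Build ambiguity components over a sequence set
#'
#' Constructs the ambiguity network: every sequence starts as its own
#' cluster and clusters are joined whenever a filtered pairwise
#' self-alignment satisfies [join_predicate()]. The transitive closure is
#' computed with union-find, so the result is a partition of the sequence
#' set into connected components. Sequences in a singleton component are
#' "unique sequences".
#'
#' @param seqs DNAStringSet or named length vector for the full set.
#' @param self_hsp Filtered self-alignment HSP table (may be empty).
#' @param threshold Joining fraction, default 0.9.
#' @param join_metric `"identity"` (identical nucleotides; default) or
#'   `"alignment-length"` (plain aligned-length coverage).
#' @return Data.frame with one row per sequence: `seq_id, component_id,
#'   component_size, is_unique`, sorted by `seq_id`. Component ids are
#'   assigned deterministically from the sorted smallest member id.
#' @export
build_components <- function(seqs, self_hsp, threshold = 0.9,
                             join_metric = c("identity", "alignment-length")) {
  join_metric <- match.arg(join_metric)
  lens <- if (is.numeric(seqs)) seqs else seq_lengths(seqs)
  ids <- sort(names(lens))
  n <- length(ids)
  if (n == 0L) {
    return(data.frame(seq_id = character(0), component_id = character(0),
                      component_size = integer(0), is_unique = logical(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- pair_identities(self_hsp)
  unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), ids)
  if (length(unknown) > 0L) {
    stop("self-alignment references sequence(s) absent from the set: ",
         paste(unknown, collapse = ", "))
  }
  if (join_metric == "identity") {
    va <- pairs$ident_a; vb <- pairs$ident_b
  } else {
    va <- pairs$aln_a; vb <- pairs$aln_b
  }
  joins <- pairs[join_predicate(va, vb, lens[pairs$id_a], lens[pairs$id_b],
                                threshold), , drop = FALSE]
  parent <- seq_len(n)
  idx <- stats::setNames(seq_len(n), ids)
  for (k in seq_len(nrow(joins))) {
    ra <- uf_find(parent, idx[[joins$id_a[k]]])
    rb <- uf_find(parent, idx[[joins$id_b[k]]])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  # label components by rank of their smallest member id (ids are sorted)
  comp_label <- stats::setNames(
    sprintf("C%04d", seq_along(unique(root))), unique(root))
  component_id <- unname(comp_label[as.character(root)])
  size <- table(component_id)
  data.frame(
    seq_id = ids,
    component_id = component_id,
    component_size = as.integer(size[component_id]),
    is_unique = as.integer(size[component_id]) == 1L,
    stringsAsFactors = FALSE
  )
}

#' Aggregate expression over ambiguity components
#'
#' Sums TPM and read counts of the members of each component.
#'
#' @param components Component table from [build_components()].
#' @param expr Expression data.frame (`seq_id, read_count, tpm`).
#' @return Data.frame: `component_id, component_size, total_tpm,
#'   total_count`, sorted by `component_id`.
#' @export
component_expression <- function(components, expr) {
  missing_rec <- setdiff(components$seq_id, expr$seq_id)
  if (length(missing_rec) > 0L) {
    stop("no expression record for component member(s): ",
         paste(missing_rec, collapse = ", "))
  }
  m <- match(components$seq_id, expr$seq_id)
  agg <- stats::aggregate(
    cbind(total_tpm = expr$tpm[m], total_count = expr$read_count[m]),
    by = list(component_id = components$component_id), FUN = sum)
  size <- stats::aggregate(
    list(component_size = components$seq_id),
    by = list(component_id = components$component_id), FUN = length)
  out <- merge(size, agg, by = "component_id", sort = TRUE)
  out[order(out$component_id), , drop = FALSE]
}
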