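# Independent brute-force oracles used to check the fast implementations.

# Per-base boolean coverage: length of the union of 1-based intervals.
coverage_oracle <- function(starts, ends, len) {
  v <- logical(len)
  for (i in seq_along(starts)) v[starts[i]:ends[i]] <- TRUE
  sum(v)
}

# Per-base identity-weighted coverage: each base takes the highest percent
# identity among the intervals covering it.
weighted_coverage_oracle <- function(starts, ends, pident, len) {
  v <- numeric(len)
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    v[idx] <- pmax(v[idx], pident[i] / 100)
  }
  sum(v)
}

# Breadth-first transitive closure over an undirected edge list; returns a
# membership vector (component label per node, labels arbitrary but
# consistent).
bfs_closure <- function(nodes, edge_a, edge_b) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(edge_a)) {
    adj[[edge_a[k]]] <- c(adj[[edge_a[k]]], edge_b[k])
    adj[[edge_b[k]]] <- c(adj[[edge_b[k]]], edge_a[k])
  }
  label <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (n in nodes) {
    if (!is.na(label[[n]])) next
    cur <- cur + 1L
    queue <- n
    while (length(queue) > 0L) {
      x <- queue[1L]; queue <- queue[-1L]
      if (!is.na(label[[x]])) next
      label[[x]] <- cur
      queue <- c(queue, adj[[x]])
    }
  }
  label
}

# Same partition? Compare two membership vectors up to label renaming.
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  key_a <- split(names(a), a)
  key_b <- split(names(b), b)
  setequal(lapply(key_a, sort), lapply(key_b, sort))
}

# Minimal HSP table builder for hand-written alignment cases.
hsp_rows <- function(q, s, qstart, qend, sstart, send,
                     pident = 100, evalue = 1e-50) {
  n <- max(length(qstart), length(pident))
  normalize_hsp_coords(data.frame(
    qseqid = rep_len(q, n), sseqid = rep_len(s, n),
    pident = rep_len(pident, n),
    length = abs(rep_len(qend, n) - rep_len(qstart, n)) + 1L,
    mismatch = 0L, gapopen = 0L,
    qstart = rep_len(qstart, n), qend = rep_len(qend, n),
    sstart = rep_len(sstart, n), send = rep_len(send, n),
    evalue = rep_len(evalue, n), bitscore = 100,
    stringsAsFactors = FALSE
  ))
}
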