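#' Specification for a synthetic evaluation world
#'
#' Bundles the parameters of the synthetic transcriptome / assembly
#' generator. Families are built by point-mutating a founder sequence, so
#' family members share the founder's length; contigs are derived from
#' transcripts according to a per-category corruption plan. Defaults
#' describe a small but structured transcriptome: 115 genes of which 87
#' are singletons and 28 are families of two or three, transcript lengths
#' uniform in 1000-2500 nt (all above the conventional 500 nt cutoff, and
#' long enough that truncated contigs stay above it too), 2% within-family
#' divergence, and log-normal expression with a heavy tail.
#'
#' @param n_genes Number of genes (family founders).
#' @param family_sizes Named integer vector of counts per family size,
#'   summing to `n_genes`; names are the sizes.
#' @param transcript_length_range Length range in nt (uniform).
#' @param mutation_rate Within-family per-base substitution rate.
#' @param plan Named counts per planted category:
#'   `full_length, truncate, extend, collapse, duplicate`.
#' @param expr_meanlog,expr_sdlog Log-normal read-count model parameters.
#' @param allocation_policy How the emulated quantifier distributes a
#'   component's reads: `"winner_take_all"`, `"even_split"` or
#'   `"proportional"`.
#' @param mean_fragment Mean fragment length in nt for effective lengths.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 115L,
                         family_sizes = c("1" = 87L, "2" = 12L, "3" = 16L),
                         transcript_length_range = c(1000L, 2500L),
                         mutation_rate = 0.02,
                         plan = c(full_length = 20L, truncate = 20L,
                                  extend = 20L, collapse = 20L,
                                  duplicate = 20L),
                         expr_meanlog = log(300), expr_sdlog = 1,
                         allocation_policy = c("winner_take_all",
                                               "even_split", "proportional"),
                         mean_fragment = 200L,
                         seed = 20190605L) {
  allocation_policy <- match.arg(allocation_policy)
  stopifnot(sum(family_sizes) == n_genes,
            mutation_rate >= 0, mutation_rate <= 1,
            all(plan >= 0), diff(transcript_length_range) >= 0,
            transcript_length_range[1L] > 500L)
  structure(list(
    n_genes = as.integer(n_genes),
    family_sizes = family_sizes,
    transcript_length_range = as.integer(transcript_length_range),
    mutation_rate = mutation_rate,
    plan = plan,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    allocation_policy = allocation_policy,
    mean_fragment = as.integer(mean_fragment),
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute bases at `rate`; substitutions only, length preserved.
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Fraction of equal positions between equal-length strings.
seq_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

#' Generate a synthetic transcriptome with gene families
#'
#' Draws a founder sequence per gene and derives family members by point
#' mutation at the specified rate (the first member is the founder
#' itself), so members share the founder's length. With the default 2%
#' rate, members differ from the founder by about 2% and from each other
#' by about 4%, well inside the 90% ambiguity joining rule.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return List: `transcripts` (named character vector of sequences) and
#'   `family_map` (data.frame `transcript_id, gene_id, family_size,
#'   member`).
#' @export
make_transcriptome <- function(spec, seed = spec$seed) {
  set.seed(seed)
  sizes <- rep(as.integer(names(spec$family_sizes)), spec$family_sizes)
  if (any(sizes < 1L)) stop("family sizes must be >= 1")
  lo <- spec$transcript_length_range[1L]
  hi <- spec$transcript_length_range[2L]
  seqs <- character(0)
  map <- list()
  for (g in seq_along(sizes)) {
    gene <- sprintf("g%03d", g)
    len <- sample(lo:hi, 1L)
    founder <- random_seq(len)
    for (m in seq_len(sizes[g])) {
      tid <- if (sizes[g] == 1L) paste0("t_", gene) else
        sprintf("t_%s_m%d", gene, m)
      seqs[[tid]] <- if (m == 1L) founder else
        mutate_seq(founder, spec$mutation_rate)
      map[[length(map) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gene,
        family_size = sizes[g], member = m, stringsAsFactors = FALSE)
    }
  }
  list(transcripts = seqs, family_map = do.call(rbind, map))
}

#' Corrupt transcripts into contigs with planted error categories
#'
#' Derives a contig set from the transcriptome according to the corruption
#' plan, recording the true category and alignment provenance of every
#' contig:
#' \describe{
#'   \item{full_length}{exact copy of a singleton transcript}
#'   \item{truncate}{a substring covering 55-85% of a singleton transcript
#'     (planted incompleteness)}
#'   \item{extend}{the whole transcript plus a random 15-60% tail (planted
#'     over-extension; the tail is long enough that accuracy falls below
#'     the 0.9 gate)}
#'   \item{collapse}{one exact copy of a family founder standing in for
#'     the whole family (planted family-collapse)}
#'   \item{duplicate}{2-4 copies of a singleton transcript, each mutated
#'     at 1-3% (planted duplication)}
#' }
#' Singleton transcripts serve the first four single-transcript
#' categories; families of size >= 2 serve collapse. The plan must fit the
#' available transcripts.
#'
#' @param world Output of [make_transcriptome()].
#' @param plan Named category counts (see [fixture_spec()]).
#' @param seed Seed.
#' @return List: `contigs` (named character vector), `truth` (data.frame
#'   `contig_id, category, gene_id, source_transcript` with the category
#'   labels used by [categorize_contigs()]), and `provenance` (data.frame
#'   of exact contig-transcript alignment coordinates and the planted
#'   divergence of the copied segment).
#' @export
corrupt_contigs <- function(world, plan, seed) {
  set.seed(seed)
  fam <- world$family_map
  singles <- fam$transcript_id[fam$family_size == 1L]
  families <- unique(fam$gene_id[fam$family_size >= 2L])
  need_singles <- sum(plan[c("full_length", "truncate", "extend",
                             "duplicate")])
  if (length(singles) < need_singles) {
    stop("corruption plan needs ", need_singles,
         " singleton transcripts but only ", length(singles),
         " are available")
  }
  if (length(families) < plan[["collapse"]]) {
    stop("corruption plan needs ", plan[["collapse"]],
         " families but only ", length(families), " are available")
  }
  singles <- sample(singles)
  families <- sample(families)
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- singles[seq_len(n)]
    singles <<- singles[-seq_len(n)]
    out
  }
  contigs <- character(0)
  truth <- list()
  prov <- list()
  add <- function(cid, category, gene, tid, seq, qs, qe, ss, se, div) {
    contigs[[cid]] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      contig_id = cid, category = category, gene_id = gene,
      source_transcript = tid, stringsAsFactors = FALSE)
    prov[[length(prov) + 1L]] <<- data.frame(
      contig_id = cid, transcript_id = tid,
      qstart = qs, qend = qe, sstart = ss, send = se,
      divergence = div, stringsAsFactors = FALSE)
  }
  gene_of <- stats::setNames(fam$gene_id, fam$transcript_id)

  for (tid in take(plan[["full_length"]])) {
    s <- world$transcripts[[tid]]
    add(paste0("ctg_fl_", tid), "full-length", gene_of[[tid]], tid,
        s, 1L, nchar(s), 1L, nchar(s), 0)
  }
  for (tid in take(plan[["truncate"]])) {
    s <- world$transcripts[[tid]]
    L <- nchar(s)
    keep <- floor(stats::runif(1L, 0.55, 0.85) * L)
    start <- sample(seq_len(L - keep + 1L), 1L)
    add(paste0("ctg_tr_", tid), "incompleteness", gene_of[[tid]], tid,
        substr(s, start, start + keep - 1L), 1L, keep,
        start, start + keep - 1L, 0)
  }
  for (tid in take(plan[["extend"]])) {
    s <- world$transcripts[[tid]]
    L <- nchar(s)
    tail_len <- floor(stats::runif(1L, 0.15, 0.60) * L)
    add(paste0("ctg_ex_", tid), "over-extension", gene_of[[tid]], tid,
        paste0(s, random_seq(tail_len)), 1L, L, 1L, L, 0)
  }
  for (tid in take(plan[["duplicate"]])) {
    s <- world$transcripts[[tid]]
    k <- sample(2:4, 1L)
    for (j in seq_len(k)) {
      d <- stats::runif(1L, 0.01, 0.03)
      add(sprintf("ctg_du_%s_%d", tid, j), "duplication", gene_of[[tid]],
          tid, mutate_seq(s, d), 1L, nchar(s), 1L, nchar(s), d)
    }
  }
  for (gene in families[seq_len(plan[["collapse"]])]) {
    members <- fam$transcript_id[fam$gene_id == gene]
    founder <- members[fam$member[match(members, fam$transcript_id)] == 1L]
    s <- world$transcripts[[founder]]
    add(paste0("ctg_co_", gene), "family-collapse", gene, founder,
        s, 1L, nchar(s), 1L, nchar(s), 0)
  }
  list(contigs = contigs, truth = do.call(rbind, truth),
       provenance = do.call(rbind, prov))
}

blast_row <- function(q, s, qs, qe, ss, se, pident) {
  len <- qe - qs + 1L
  data.frame(
    qseqid = q, sseqid = s, pident = round(pident, 2L), length = len,
    mismatch = as.integer(round((1 - pident / 100) * len)), gapopen = 0L,
    qstart = qs, qend = qe, sstart = ss, send = se,
    evalue = 1e-180, bitscore = round(2 * len, 1),
    minus_strand = FALSE, stringsAsFactors = FALSE
  )
}

#' Emit analytic BLAST-tabular alignments for a corrupted world
#'
#' Computes the HSPs an aligner would report, directly from the known
#' corruption provenance: each contig aligns to its source transcript over
#' the copied segment, and additionally to every other member of the
#' source's family over the same coordinates (members share the founder
#' length). Contig-contig rows connect duplicated copies of the same
#' transcript; transcript-transcript rows connect family members.
#' Coordinates are exact; percent identity is measured from the actual
#' sequences; unrelated pairs emit no rows. Symmetric pairs are reported
#' in both directions, as an aligner would.
#'
#' @param world Output of [make_transcriptome()].
#' @param corrupted Output of [corrupt_contigs()].
#' @return List of three HSP data.frames: `c2t`, `c2c`, `t2t`.
#' @export
emit_hsps <- function(world, corrupted) {
  fam <- world$family_map
  prov <- corrupted$provenance
  contigs <- corrupted$contigs
  transcripts <- world$transcripts

  c2t <- list()
  for (i in seq_len(nrow(prov))) {
    cid <- prov$contig_id[i]
    src <- prov$transcript_id[i]
    gene <- fam$gene_id[match(src, fam$transcript_id)]
    members <- fam$transcript_id[fam$gene_id == gene]
    for (tid in members) {
      seg_c <- substr(contigs[[cid]], prov$qstart[i], prov$qend[i])
      seg_t <- substr(transcripts[[tid]], prov$sstart[i], prov$send[i])
      pid <- 100 * seq_identity(seg_c, seg_t)
      c2t[[length(c2t) + 1L]] <- blast_row(
        cid, tid, prov$qstart[i], prov$qend[i],
        prov$sstart[i], prov$send[i], pid)
    }
  }

  c2c <- list()
  dup_groups <- split(prov$contig_id[grepl("^ctg_du_", prov$contig_id)],
                      prov$transcript_id[grepl("^ctg_du_", prov$contig_id)])
  for (grp in dup_groups) {
    if (length(grp) < 2L) next
    for (a in grp) for (b in grp) {
      if (a == b) next
      L <- nchar(contigs[[a]])
      pid <- 100 * seq_identity(contigs[[a]], contigs[[b]])
      c2c[[length(c2c) + 1L]] <- blast_row(a, b, 1L, L, 1L, L, pid)
    }
  }

  t2t <- list()
  for (gene in unique(fam$gene_id[fam$family_size >= 2L])) {
    members <- fam$transcript_id[fam$gene_id == gene]
    for (a in members) for (b in members) {
      if (a == b) next
      L <- nchar(transcripts[[a]])
      pid <- 100 * seq_identity(transcripts[[a]], transcripts[[b]])
      t2t[[length(t2t) + 1L]] <- blast_row(a, b, 1L, L, 1L, L, pid)
    }
  }

  bind <- function(x) if (length(x) == 0L) empty_hsp_table() else {
    out <- do.call(rbind, x)
    out$n_identical <- as.integer(round(out$pident / 100 * out$length))
    out[order(out$qseqid, out$sseqid, out$qstart), , drop = FALSE]
  }
  list(c2t = bind(c2t), c2c = bind(c2c), t2t = bind(t2t))
}

#' Simulate ground-truth read counts
#'
#' Draws per-transcript read counts from a log-normal model (rounded to
#' integers), the conventional heavy-tailed shape of expression data.
#'
#' @param transcript_ids Character vector of ids.
#' @param lengths Named lengths in nt.
#' @param meanlog,sdlog Log-normal parameters.
#' @param seed Seed.
#' @return Data.frame `seq_id, read_count, length`.
#' @export
sim_expression <- function(transcript_ids, lengths, meanlog = log(300),
                           sdlog = 1, seed) {
  set.seed(seed)
  counts <- round(stats::rlnorm(length(transcript_ids), meanlog, sdlog))
  data.frame(seq_id = transcript_ids,
             read_count = pmax(counts, 0),
             length = as.integer(lengths[transcript_ids]),
             stringsAsFactors = FALSE)
}

#' Emulate a quantifier's read allocation over ambiguity components
#'
#' Models the one behavior of quantifiers under sequence ambiguity that
#' the evaluation metrics probe: reads generated by a transcript end up in
#' the ambiguity component of the contigs it is assigned to, and the
#' quantifier then splits the component's reads among member contigs
#' according to a policy — all to one contig (`winner_take_all`, the
#' common behavior), equal shares (`even_split`), or random Dirichlet
#' shares (`proportional`). Each transcript's reads are pooled into the
#' component of its best-aligned contig, so reads are conserved. Contig
#' TPM is then recomputed from the allocated counts over contig effective
#' lengths.
#'
#' @param gt Ground-truth expression (`seq_id, read_count`) for
#'   transcripts.
#' @param assignments Assigned alignment table (contig vs transcript).
#' @param contig_components Component table for contigs.
#' @param contig_lengths Named contig lengths in nt.
#' @param policy Allocation policy.
#' @param mean_fragment Mean fragment length for effective lengths.
#' @param seed Seed (used by `proportional` and harmless otherwise).
#' @return Estimated contig expression data.frame
#'   (`seq_id, read_count, length, effective_length, tpm`).
#' @export
emulate_quantifier <- function(gt, assignments, contig_components,
                               contig_lengths,
                               policy = c("winner_take_all", "even_split",
                                          "proportional"),
                               mean_fragment = 200L, seed = 1L) {
  policy <- match.arg(policy)
  set.seed(seed)
  comp_of <- stats::setNames(contig_components$component_id,
                             contig_components$seq_id)
  pool <- stats::setNames(numeric(length(unique(comp_of))),
                          sort(unique(comp_of)))
  counts_gt <- stats::setNames(gt$read_count, gt$seq_id)
  for (tid in gt$seq_id) {
    a <- assignments[assignments$transcript_id == tid, , drop = FALSE]
    if (nrow(a) == 0L) next
    a <- a[order(-a$alignment_score, a$contig_id), , drop = FALSE]
    target <- comp_of[[a$contig_id[1L]]]
    pool[[target]] <- pool[[target]] + counts_gt[[tid]]
  }
  members_of <- split(contig_components$seq_id,
                      contig_components$component_id)
  alloc <- stats::setNames(numeric(length(comp_of)), names(comp_of))
  for (comp in names(pool)) {
    members <- sort(members_of[[comp]])
    total <- pool[[comp]]
    if (total <= 0) next
    share <- switch(policy,
      winner_take_all = {
        s <- numeric(length(members)); s[1L] <- 1; s
      },
      even_split = rep(1 / length(members), length(members)),
      proportional = {
        w <- stats::rgamma(length(members), shape = 1)
        w / sum(w)
      })
    alloc[members] <- total * share
  }
  ids <- sort(names(alloc))
  len <- as.numeric(contig_lengths[ids])
  eff <- effective_length(len, mean_fragment)
  data.frame(
    seq_id = ids,
    read_count = unname(alloc[ids]),
    length = as.integer(len),
    effective_length = eff,
    tpm = ground_truth_tpm(unname(alloc[ids]), eff),
    stringsAsFactors = FALSE
  )
}

#' Generate and write a complete synthetic evaluation world
#'
#' Runs the whole generator — transcriptome, corrupted contigs, analytic
#' alignments, ground-truth counts, emulated quantifier output — and
#' writes every file the evaluation pipeline consumes:
#' `transcripts.fasta`, `contigs.fasta`, `c2t.blast.tsv`, `c2c.blast.tsv`,
#' `t2t.blast.tsv`, `ground_truth.tsv`, `abundance.tsv` (kallisto
#' dialect), `truth_categories.tsv`. The in-memory world is returned so
#' tests can compare pipeline output against the planted truth without
#' re-reading files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return List: `spec, transcripts, family_map, contigs, truth,
#'   provenance, hsps, gt, est, assignments, contig_components,
#'   transcript_components, paths`.
#' @export
make_fixture_world <- function(spec = fixture_spec(), out_dir = NULL) {
  world <- make_transcriptome(spec, seed = spec$seed)
  corrupted <- corrupt_contigs(world, spec$plan, seed = spec$seed + 1L)
  hsps <- emit_hsps(world, corrupted)
  tlen <- stats::setNames(nchar(world$transcripts),
                          names(world$transcripts))
  clen <- stats::setNames(nchar(corrupted$contigs),
                          names(corrupted$contigs))
  gt <- sim_expression(names(world$transcripts), tlen,
                       meanlog = spec$expr_meanlog,
                       sdlog = spec$expr_sdlog, seed = spec$seed + 2L)
  gt$effective_length <- effective_length(gt$length, spec$mean_fragment)
  gt$tpm <- ground_truth_tpm(gt$read_count, gt$effective_length)

  aln <- align_all(filter_hsps(hsps$c2t), clen, tlen)
  asg <- assign_transcripts(aln)
  ccomp <- build_components(clen, filter_hsps(hsps$c2c))
  tcomp <- build_components(tlen, filter_hsps(hsps$t2t))
  est <- emulate_quantifier(gt, asg, ccomp, clen,
                            policy = spec$allocation_policy,
                            mean_fragment = spec$mean_fragment,
                            seed = spec$seed + 3L)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      transcripts = file.path(out_dir, "transcripts.fasta"),
      contigs = file.path(out_dir, "contigs.fasta"),
      c2t = file.path(out_dir, "c2t.blast.tsv"),
      c2c = file.path(out_dir, "c2c.blast.tsv"),
      t2t = file.path(out_dir, "t2t.blast.tsv"),
      ground_truth = file.path(out_dir, "ground_truth.tsv"),
      abundance = file.path(out_dir, "abundance.tsv"),
      truth_categories = file.path(out_dir, "truth_categories.tsv")
    )
    write_fasta(world$transcripts, paths$transcripts)
    write_fasta(corrupted$contigs, paths$contigs)
    write_blast_tabular(hsps$c2t, paths$c2t)
    write_blast_tabular(hsps$c2c, paths$c2c)
    write_blast_tabular(hsps$t2t, paths$t2t)
    write_abundance(gt, paths$ground_truth, dialect = "groundtruth-tsv")
    write_abundance(est, paths$abundance, dialect = "kallisto")
    utils::write.table(corrupted$truth, paths$truth_categories,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(spec = spec, transcripts = world$transcripts,
       family_map = world$family_map, contigs = corrupted$contigs,
       truth = corrupted$truth, provenance = corrupted$provenance,
       hsps = hsps, gt = gt, est = est, assignments = asg,
       contig_components = ccomp, transcript_components = tcomp,
       paths = paths)
}
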