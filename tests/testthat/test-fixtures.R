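small_spec <- function(seed = 101L, ...) {
  fixture_spec(
    n_genes = 24L, family_sizes = c("1" = 16L, "2" = 4L, "3" = 4L),
    plan = c(full_length = 4L, truncate = 4L, extend = 4L,
             collapse = 4L, duplicate = 4L),
    seed = seed, ...)
}

test_that("the generated transcriptome respects lengths and family structure", {
  sp <- small_spec()
  w <- make_transcriptome(sp)
  expect_equal(length(w$transcripts), 16L + 4L * 2L + 4L * 3L)
  lens <- nchar(w$transcripts)
  expect_true(all(lens > 500))
  expect_true(all(lens >= sp$transcript_length_range[1]))
  expect_true(all(lens <= sp$transcript_length_range[2]))
  # family members share the founder length and ~rate divergence
  fam <- w$family_map
  for (g in unique(fam$gene_id[fam$family_size == 3L])) {
    members <- fam$transcript_id[fam$gene_id == g]
    L <- unique(nchar(w$transcripts[members]))
    expect_length(L, 1L)
    pairs <- t(combn(members, 2))
    for (k in seq_len(nrow(pairs))) {
      a <- strsplit(w$transcripts[[pairs[k, 1]]], "")[[1]]
      b <- strsplit(w$transcripts[[pairs[k, 2]]], "")[[1]]
      ident <- mean(a == b)
      expect_gt(ident, 0.92)
      expect_lt(ident, 1 + 1e-9)
    }
  }
})

test_that("fixture generation is deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_world(small_spec(seed = 77L), out_dir = d1)
  make_fixture_world(small_spec(seed = 77L), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  w_alt <- make_fixture_world(small_spec(seed = 78L))
  w_ref <- make_fixture_world(small_spec(seed = 77L))
  expect_false(identical(w_ref$contigs, w_alt$contigs))
})

test_that("corruption truth matches the plan and provenance is exact", {
  w <- make_fixture_world(small_spec())
  expect_equal(sum(w$truth$category == "full-length"), 4L)
  expect_equal(sum(w$truth$category == "incompleteness"), 4L)
  expect_equal(sum(w$truth$category == "over-extension"), 4L)
  expect_equal(sum(w$truth$category == "family-collapse"), 4L)
  expect_gte(sum(w$truth$category == "duplication"), 8L)
  # provenance coordinates cut the exact planted segment
  for (i in seq_len(nrow(w$provenance))) {
    p <- w$provenance[i, ]
    if (p$divergence == 0) {
      expect_identical(
        substr(w$contigs[[p$contig_id]], p$qstart, p$qend),
        substr(w$transcripts[[p$transcript_id]], p$sstart, p$send))
    }
  }
  # infeasible plans are rejected
  expect_error(
    corrupt_contigs(make_transcriptome(small_spec()),
                    c(full_length = 100L, truncate = 0L, extend = 0L,
                      collapse = 0L, duplicate = 0L), seed = 1L),
    "singleton")
})

test_that("emitted HSPs round-trip through the BLAST tabular parser", {
  w <- make_fixture_world(small_spec(), out_dir = withr::local_tempdir())
  for (tab in c("c2t", "c2c", "t2t")) {
    back <- read_blast_tabular(w$paths[[tab]])
    orig <- w$hsps[[tab]]
    expect_equal(nrow(back), nrow(orig))
    expect_equal(back$qseqid, orig$qseqid)
    expect_equal(back$qstart, orig$qstart)
    expect_equal(back$send, orig$send)
    expect_equal(back$pident, orig$pident, tolerance = 1e-9)
  }
  # duplicate pairs appear in both directions
  c2c <- w$hsps$c2c
  key <- paste(c2c$qseqid, c2c$sseqid)
  rev <- paste(c2c$sseqid, c2c$qseqid)
  expect_true(all(rev %in% key))
})

test_that("the emulated quantifier follows its allocation policy", {
  comp <- data.frame(seq_id = c("a", "b", "c", "d"),
                     component_id = c("K1", "K1", "K1", "K1"),
                     component_size = 4L, is_unique = FALSE,
                     stringsAsFactors = FALSE)
  asg <- data.frame(contig_id = "a", transcript_id = "t1",
                    alignment_score = 1, stringsAsFactors = FALSE)
  gt <- data.frame(seq_id = "t1", read_count = 400,
                   stringsAsFactors = FALSE)
  lens <- c(a = 1000, b = 1000, c = 1000, d = 1000)
  wta <- emulate_quantifier(gt, asg, comp, lens, "winner_take_all")
  expect_equal(sort(wta$read_count, decreasing = TRUE), c(400, 0, 0, 0))
  expect_equal(sort(rpea(comp, wta)$rpea, decreasing = TRUE), c(1, 0, 0, 0))
  even <- emulate_quantifier(gt, asg, comp, lens, "even_split")
  expect_equal(even$read_count, rep(100, 4))
  expect_equal(max(rpea(comp, even)$rpea), 0.25)
  prop <- emulate_quantifier(gt, asg, comp, lens, "proportional", seed = 3L)
  expect_equal(sum(prop$read_count), 400)
  expect_true(all(prop$read_count >= 0))
})

test_that("allocated reads are conserved for assigned components", {
  for (pol in c("winner_take_all", "even_split", "proportional")) {
    w <- make_fixture_world(small_spec(allocation_policy = pol))
    assigned <- unique(w$assignments$transcript_id)
    expect_equal(sum(w$est$read_count),
                 sum(w$gt$read_count[w$gt$seq_id %in% assigned]))
  }
})
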