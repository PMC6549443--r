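aln_row <- function(contig, transcript, recovery, accuracy,
                    l_c = 1000, l_t = 1000) {
  data.frame(contig_id = contig, transcript_id = transcript,
             recovery = recovery, accuracy = accuracy,
             alignment_score = sqrt(recovery * accuracy),
             diff_length_pct = diff_length_pct(l_c, l_t),
             n_hsps = 1L, stringsAsFactors = FALSE)
}

comp_rows <- function(ids, component) {
  sizes <- table(component)
  data.frame(seq_id = ids, component_id = component,
             component_size = as.integer(sizes[component]),
             is_unique = as.integer(sizes[component]) == 1L,
             stringsAsFactors = FALSE)
}

test_that("assignment passes when either recovery or accuracy reaches 0.9", {
  aln <- rbind(aln_row("c1", "t1", 0.92, 0.55),
               aln_row("c2", "t1", 0.50, 0.89),
               aln_row("c3", "t1", 0.90, 0.90))
  asg <- assign_transcripts(aln)
  expect_setequal(asg$contig_id, c("c1", "c3"))
  strict <- assign_transcripts(aln, inclusive = FALSE)
  expect_equal(strict$contig_id, "c1")
})

test_that("unique single-assignment contigs split on the completeness gate", {
  aln <- rbind(aln_row("c_fl", "t1", 0.96, 0.97),
               aln_row("c_in", "t2", 0.60, 0.98),
               aln_row("c_ov", "t3", 0.95, 0.70))
  comp <- comp_rows(c("c_fl", "c_in", "c_ov", "c_un"),
                    c("K1", "K2", "K3", "K4"))
  ann <- categorize_contigs(assign_transcripts(aln), comp)
  got <- stats::setNames(ann$category, ann$contig_id)
  expect_equal(got[["c_fl"]], "full-length")
  expect_equal(got[["c_in"]], "incompleteness")
  expect_equal(got[["c_ov"]], "over-extension")
  expect_equal(got[["c_un"]], "unassigned")
})

test_that("multi-transcript accurate contigs are family-collapse", {
  aln <- rbind(aln_row("c1", "t1", 0.99, 0.95),
               aln_row("c1", "t2", 0.98, 0.96),
               aln_row("c1", "t3", 0.97, 0.95))
  comp <- comp_rows("c1", "K1")
  ann <- categorize_contigs(assign_transcripts(aln), comp)
  expect_equal(ann$category, "family-collapse")
  expect_equal(ann$n_assigned, 3L)
})

test_that("co-assigned contigs sharing a component are duplication", {
  aln <- rbind(aln_row("d1", "t1", 0.99, 0.98),
               aln_row("d2", "t1", 0.97, 0.99),
               aln_row("e1", "t2", 0.99, 0.98),
               aln_row("e2", "t2", 0.97, 0.99))
  # d1/d2 share a component; e1/e2 are assigned the same transcript but
  # sit in different components, so they stay ambiguous-other
  comp <- comp_rows(c("d1", "d2", "e1", "e2"),
                    c("K1", "K1", "K2", "K3"))
  comp$is_unique[comp$seq_id %in% c("e1", "e2")] <- FALSE
  comp$component_size[comp$seq_id %in% c("e1", "e2")] <- 2L
  ann <- categorize_contigs(assign_transcripts(aln), comp)
  got <- stats::setNames(ann$category, ann$contig_id)
  expect_equal(unname(got[c("d1", "d2")]),
               c("duplication", "duplication"))
  expect_equal(unname(got[c("e1", "e2")]),
               c("ambiguous-other", "ambiguous-other"))
})

test_that("every contig receives exactly one category", {
  set.seed(7)
  w <- make_fixture_world(fixture_spec(seed = 301L))
  ann <- categorize_contigs(w$assignments, w$contig_components)
  expect_equal(sort(ann$contig_id), sort(names(w$contigs)))
  expect_equal(anyDuplicated(ann$contig_id), 0L)
  expect_true(all(ann$category %in% c(
    "full-length", "incompleteness", "over-extension", "family-collapse",
    "duplication", "unassigned", "ambiguous-other")))
  expect_true(all((ann$n_assigned > 0) == (ann$category != "unassigned")))
})

test_that("completeness bins are lower-inclusive with lower-bound labels", {
  expect_equal(completeness_bins(c(-10, 0, -0.01, 9.99, -10.01)),
               c(-10, 0, -10, 0, -20))
})
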