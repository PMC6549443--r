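test_that("ground-truth TPM normalizes read density to one million", {
  expect_equal(ground_truth_tpm(c(10, 10), c(100, 200)),
               c(2e6 / 3, 1e6 / 3))
  expect_equal(ground_truth_tpm(5, 300), 1e6)
  expect_equal(ground_truth_tpm(c(0, 5), c(100, 100)), c(0, 1e6))
  expect_error(ground_truth_tpm(c(0, 0), c(100, 100)), "zero")
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    tpm <- ground_truth_tpm(stats::runif(n, 0.1, 1e4),
                            sample(200:3000, n, replace = TRUE))
    expect_equal(sum(tpm), 1e6, tolerance = 1e-6)
    expect_true(all(tpm >= 0))
  }
})

test_that("effective length subtracts the fragment and clips at one", {
  expect_equal(effective_length(1000, 200), 801)
  expect_equal(effective_length(100, 200), 1)
  expect_equal(effective_length(750, 1), 750)
})

test_that("relative error is antisymmetric, bounded, and zero-safe", {
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(300, 100), 50)
  expect_equal(relative_error(0, 123), -100)
  expect_equal(relative_error(0, 0), 0)
  set.seed(2)
  a <- stats::runif(200, 0, 1e5)
  b <- stats::runif(200, 0, 1e5)
  expect_equal(relative_error(a, b), -relative_error(b, a))
  expect_true(all(abs(relative_error(a, b)) <= 100))
})

test_that("RPEA normalizes per component and handles degenerate cases", {
  comp <- data.frame(
    seq_id = c("a", "b", "c", "solo", "z1", "z2"),
    component_id = c("C1", "C1", "C1", "C2", "C3", "C3"),
    component_size = c(3L, 3L, 3L, 1L, 2L, 2L),
    is_unique = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  expr <- data.frame(seq_id = comp$seq_id,
                     read_count = c(30, 10, 10, 8, 0, 0),
                     stringsAsFactors = FALSE)
  rp <- rpea(comp, expr)
  v <- stats::setNames(rp$rpea, rp$seq_id)
  expect_equal(unname(v[c("a", "b", "c")]), c(0.6, 0.2, 0.2))
  expect_equal(v[["solo"]], 1)
  # all-zero component gets the uniform share
  expect_equal(unname(v[c("z1", "z2")]), c(0.5, 0.5))
  sums <- tapply(rp$rpea, rp$component_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("max-RPEA bins are 0.05-wide and lower-inclusive", {
  expect_equal(rpea_bins(c(0.47, 0.45, 0.4499, 1.0)),
               c(0.45, 0.45, 0.40, 0.95))
})

test_that("family-collapse evaluation degenerates gracefully and ties agree", {
  ann <- data.frame(contig_id = "c1", category = "family-collapse",
                    stringsAsFactors = FALSE)
  asg <- data.frame(contig_id = c("c1", "c1"),
                    transcript_id = c("t1", "t2"),
                    alignment_score = c(0.99, 0.95),
                    stringsAsFactors = FALSE)
  est <- data.frame(seq_id = "c1", tpm = 120, stringsAsFactors = FALSE)
  gt <- data.frame(seq_id = c("t1", "t2"), tpm = c(60, 60),
                   stringsAsFactors = FALSE)
  tcomp <- data.frame(seq_id = c("t1", "t2"),
                      component_id = c("T1", "T1"),
                      component_size = c(2L, 2L),
                      is_unique = c(FALSE, FALSE), stringsAsFactors = FALSE)
  fc <- family_collapse_eval(ann, asg, est, gt, tcomp)
  # equal family expression: best-score and max-expression references tie
  expect_equal(fc$err_best_score, fc$err_max_expr)
  # estimate equals the component total exactly
  expect_equal(fc$err_component, 0)

  # single-member family degenerates to the ordinary relative error
  asg1 <- asg[1, ]
  tcomp1 <- tcomp[1, ]; tcomp1$component_size <- 1L
  fc1 <- family_collapse_eval(ann, asg1, est, gt, tcomp1)
  expect_equal(fc1$err_best_score, relative_error(120, 60))
  expect_equal(fc1$err_component, relative_error(120, 60))
})

test_that("duplication evaluation reproduces the even-split arithmetic", {
  ann <- data.frame(
    contig_id = c("d1", "d2"), category = "duplication",
    best_transcript = "t1", component_id = "K1",
    stringsAsFactors = FALSE)
  asg <- data.frame(contig_id = c("d1", "d2"), transcript_id = "t1",
                    alignment_score = c(0.99, 0.98),
                    stringsAsFactors = FALSE)
  ccomp <- data.frame(seq_id = c("d1", "d2"), component_id = "K1",
                      component_size = 2L, is_unique = FALSE,
                      stringsAsFactors = FALSE)
  gt <- data.frame(seq_id = "t1", tpm = 100, stringsAsFactors = FALSE)
  # even split of reads and expression across the two duplicates
  est <- data.frame(seq_id = c("d1", "d2"), read_count = c(50, 50),
                    tpm = c(50, 50), stringsAsFactors = FALSE)
  de <- duplication_eval(ann, asg, est, gt, ccomp)
  expect_equal(de$err_component, 0)
  expect_equal(de$err_max_rpea, (0.5 - 1) / (0.5 + 1) * 100)
  expect_equal(de$max_rpea, 0.5)
  expect_equal(de$max_rpea_bin, 0.5)

  # winner take all: the max-RPEA reference coincides with the total
  est2 <- data.frame(seq_id = c("d1", "d2"), read_count = c(100, 0),
                     tpm = c(100, 0), stringsAsFactors = FALSE)
  de2 <- duplication_eval(ann, asg, est2, gt, ccomp)
  expect_equal(de2$err_max_rpea, de2$err_component)
  expect_equal(de2$max_rpea, 1)
})

test_that("component-level evaluation merges linked contigs and transcripts", {
  asg <- data.frame(contig_id = c("c1", "c2"), transcript_id = c("t1", "t1"),
                    stringsAsFactors = FALSE)
  ccomp <- data.frame(seq_id = c("c1", "c2", "lone"),
                      component_id = c("K1", "K1", "K2"),
                      component_size = c(2L, 2L, 1L),
                      is_unique = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  tcomp <- data.frame(seq_id = "t1", component_id = "T1",
                      component_size = 1L, is_unique = TRUE,
                      stringsAsFactors = FALSE)
  est <- data.frame(seq_id = c("c1", "c2", "lone"), tpm = c(60, 40, 5),
                    stringsAsFactors = FALSE)
  gt <- data.frame(seq_id = "t1", tpm = 100, stringsAsFactors = FALSE)
  ce <- component_level_eval(asg, ccomp, tcomp, est, gt)
  expect_equal(nrow(ce), 1L)
  expect_equal(ce$n_contigs, 2L)
  expect_equal(ce$err_component, 0)
  # the unassigned contig forms no matched super-component
  none <- component_level_eval(asg[0, ], ccomp, tcomp, est, gt)
  expect_equal(nrow(none), 0L)
})

test_that("average truth is the per-transcript mean TPM", {
  t1 <- data.frame(seq_id = c("a", "b"), tpm = c(10, 30),
                   stringsAsFactors = FALSE)
  t2 <- data.frame(seq_id = c("b", "a"), tpm = c(50, 20),
                   stringsAsFactors = FALSE)
  avg <- average_truth(list(t1, t2))
  expect_equal(avg$tpm[avg$seq_id == "a"], 15)
  expect_equal(avg$tpm[avg$seq_id == "b"], 40)
})
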