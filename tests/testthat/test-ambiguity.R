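test_that("join_predicate uses a strict reciprocal-OR 90% rule", {
  expect_true(join_predicate(950, 950, 1000, 2000))
  expect_false(join_predicate(900, 900, 1000, 1000))
  expect_false(join_predicate(0, 0, 1000, 1000))
  # over 90% of either sequence suffices
  expect_true(join_predicate(100, 1900, 1000, 2000))
})

test_that("pair_identities collapses symmetric HSP rows per pair", {
  hsp <- rbind(
    hsp_rows("a", "b", 1, 950, 1, 950, pident = 100),
    hsp_rows("b", "a", 1, 950, 1, 950, pident = 100),
    hsp_rows("a", "a", 1, 1000, 1, 1000, pident = 100))
  p <- pair_identities(hsp)
  expect_equal(nrow(p), 1L)
  expect_equal(p$id_a, "a")
  expect_equal(p$ident_a, 950)
  expect_equal(p$ident_b, 950)
  expect_equal(p$aln_a, 950)
})

test_that("components form the transitive closure with isolated singletons", {
  lens <- c(A = 1000, B = 1000, C = 1000, D = 1000)
  hsp <- rbind(
    hsp_rows("A", "B", 1, 950, 1, 950),
    hsp_rows("B", "C", 1, 920, 1, 920))
  comp <- build_components(lens, hsp)
  expect_equal(sort(comp$seq_id), c("A", "B", "C", "D"))
  abc <- comp$component_id[match(c("A", "B", "C"), comp$seq_id)]
  expect_equal(length(unique(abc)), 1L)
  expect_false(comp$component_id[comp$seq_id == "D"] %in% abc)
  expect_true(comp$is_unique[comp$seq_id == "D"])
  expect_equal(comp$component_size[comp$seq_id == "A"], 3L)

  none <- build_components(lens, hsp[0, ])
  expect_true(all(none$is_unique))
  expect_equal(length(unique(none$component_id)), 4L)

  expect_error(build_components(lens[1:2], hsp), "absent")
})

test_that("component construction is invariant to edge order and matches igraph", {
  skip_if_not_installed("igraph")
  set.seed(99)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  lens <- stats::setNames(rep(1000, n), ids)
  pairs <- t(combn(ids, 2))
  sel <- pairs[runif(nrow(pairs)) < 0.05, , drop = FALSE]
  hsp <- do.call(rbind, lapply(seq_len(nrow(sel)), function(k) {
    hsp_rows(sel[k, 1], sel[k, 2], 1, 950, 1, 950)
  }))
  comp <- build_components(lens, hsp)
  shuffled <- hsp[sample(nrow(hsp)), , drop = FALSE]
  expect_identical(build_components(lens, shuffled), comp)

  g <- igraph::graph_from_data_frame(
    data.frame(from = sel[, 1], to = sel[, 2]), directed = FALSE,
    vertices = ids)
  ig <- igraph::components(g)$membership
  mine <- stats::setNames(comp$component_id, comp$seq_id)[ids]
  expect_true(same_partition(mine, ig))
})

test_that("components always partition the sequence set", {
  set.seed(123)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    ids <- sprintf("x%02d", 1:n)
    lens <- stats::setNames(sample(600:2000, n, replace = TRUE), ids)
    k <- sample(0:15, 1)
    hsp <- empty_rows <- NULL
    if (k > 0) {
      a <- sample(ids, k, replace = TRUE)
      b <- sample(ids, k, replace = TRUE)
      span <- sample(100:1900, k, replace = TRUE)
      hsp <- do.call(rbind, lapply(seq_len(k), function(i) {
        e <- min(span[i], lens[[a[i]]], lens[[b[i]]])
        hsp_rows(a[i], b[i], 1, e, 1, e,
                 pident = runif(1, 70, 100))
      }))
    } else {
      hsp <- hsp_rows("x01", "x01", 1, 10, 1, 10)[0, ]
    }
    comp <- build_components(lens, hsp)
    expect_equal(sort(comp$seq_id), sort(ids))
    expect_equal(anyDuplicated(comp$seq_id), 0L)
    sizes <- table(comp$component_id)
    expect_equal(unname(comp$component_size),
                 as.integer(sizes[comp$component_id]))
  }
})

test_that("component expression sums members and preserves totals", {
  comp <- data.frame(
    seq_id = c("a", "b", "c", "d"),
    component_id = c("C1", "C1", "C1", "C2"),
    component_size = c(3L, 3L, 3L, 1L),
    is_unique = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  expr <- data.frame(seq_id = c("a", "b", "c", "d"),
                     read_count = c(5, 1, 4, 2), tpm = c(10, 20, 30, 7),
                     stringsAsFactors = FALSE)
  ce <- component_expression(comp, expr)
  expect_equal(ce$total_tpm[ce$component_id == "C1"], 60)
  expect_equal(ce$total_tpm[ce$component_id == "C2"], 7)
  expect_equal(sum(ce$total_tpm), sum(expr$tpm))
  expect_equal(sum(ce$total_count), sum(expr$read_count))
  expect_error(component_expression(comp, expr[-1, ]), "a")
})
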