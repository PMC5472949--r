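mk_part <- function(sets, gene_ids, aligned = FALSE) {
  K <- length(sets)
  m <- matrix(0L, K, length(gene_ids), dimnames = list(NULL, gene_ids))
  for (k in seq_len(K)) m[k, match(sets[[k]], gene_ids)] <- 1L
  p <- partition(m)
  p$aligned <- aligned
  p
}

test_that("min-min relabelling restores permuted rows exactly", {
  ids <- c("A", "B", "C", "D")
  ref <- mk_part(list(c("A", "B"), c("C"), c("D")), ids)
  tgt <- mk_part(list(c("D"), c("A", "B"), c("C")), ids)  # rows rotated
  out <- relabel_min_min(ref, tgt)
  expect_identical(out$membership, ref$membership)
  expect_true(out$aligned)
  # content preserved as a multiset of gene sets
  expect_setequal(vapply(uncles:::partition_contents(out), paste, "", collapse = ","),
                  vapply(uncles:::partition_contents(tgt), paste, "", collapse = ","))
  # K mismatch rejected
  ref2 <- mk_part(list(c("A", "B"), c("C", "D")), ids)
  expect_error(relabel_min_min(ref2, tgt), "K mismatch")
})

test_that("greedy matching follows the global min-first order", {
  cost <- rbind(c(1, 5, 9), c(4, 2, 8), c(7, 6, 0))
  # min 0 at (3,3), then 1 at (1,1), then 2 at (2,2)
  expect_identical(uncles:::greedy_min_match(cost), c(1L, 2L, 3L))
  # exhaustive check: force a conflict so greedy differs from optimal order
  cost2 <- rbind(c(0, 1, 9), c(1, 0, 9), c(9, 2, 3))
  # picks (1,1)=0, then (2,2)=0, then (3,3)=3
  expect_identical(uncles:::greedy_min_match(cost2), c(1L, 2L, 3L))
  # tie broken by lowest (i, j) row-major
  tied <- matrix(1, 2, 2)
  expect_identical(uncles:::greedy_min_match(tied), c(1L, 2L))
})

test_that("relabelling uses only genes shared by the two partitions", {
  ref <- mk_part(list(c("A", "B"), c("C", "D")), c("A", "B", "C", "D"))
  # target misses D; its clusters match ref's after swapping
  tgt <- mk_part(list(c("C"), c("A", "B")), c("A", "B", "C"))
  out <- relabel_min_min(ref, tgt)
  expect_identical(uncles:::partition_contents(out),
                   list(c("A", "B"), "C"))
})

test_that("CoPaM averaging weights by gene presence", {
  ids <- c("A", "B", "C")
  ds <- list(
    expression_dataset(named_matrix(rnorm(6), 3, ids), dataset_id = "d1"),
    expression_dataset(named_matrix(rnorm(6), 3, ids), dataset_id = "d2"),
    expression_dataset(named_matrix(rnorm(4), 2, ids[1:2]), dataset_id = "d3"),
    expression_dataset(named_matrix(rnorm(4), 2, ids[1:2]), dataset_id = "d4"))
  coll <- build_collection(ds, min_presence = 2)
  parts <- list(
    mk_part(list(c("A"), c("B", "C")), ids, aligned = TRUE),
    mk_part(list(c("A"), c("B", "C")), ids, aligned = TRUE),
    mk_part(list(c("A", "B"), character(0)), ids[1:2], aligned = TRUE),
    mk_part(list(c("A"), c("B")), ids[1:2], aligned = TRUE))
  cp <- build_copam(parts, coll)
  # A in all four partitions, always cluster 1
  expect_equal(unname(cp$fuzzy[, "A"]), c(1, 0))
  expect_identical(cp$support[match("A", cp$gene_ids)], 4L)
  # B: cluster 2, 2, 1, 2 -> [0.25, 0.75]
  expect_equal(unname(cp$fuzzy[, "B"]), c(0.25, 0.75))
  # C only in the first two partitions: averaged over those alone
  expect_equal(unname(cp$fuzzy[, "C"]), c(0, 1))
  expect_identical(cp$support[match("C", cp$gene_ids)], 2L)
  # column sums are 1 for all supported genes
  expect_equal(unname(colSums(cp$fuzzy)), rep(1, 3))
  # unaligned partitions are a usage error
  parts[[1]]$aligned <- FALSE
  expect_error(build_copam(parts, coll), "relabelled")
})

test_that("DTB assigns by margin and leaves ties unassigned", {
  cp <- structure(list(K = 3, gene_ids = c("g1", "g2"),
                       fuzzy = cbind(g1 = c(0.7, 0.2, 0.1),
                                     g2 = c(0.5, 0.5, 0.0)),
                       support = c(4L, 4L)), class = "copam")
  b04 <- dtb_binarise(cp, 0.4)
  expect_equal(unname(b04[, "g1"]), c(1L, 0L, 0L))   # margins 0.5, 0.6 >= 0.4
  b06 <- dtb_binarise(cp, 0.6)
  expect_equal(unname(b06[, "g1"]), c(0L, 0L, 0L))   # margin 0.5 < 0.6
  b0 <- dtb_binarise(cp, 0)
  expect_equal(unname(b0[, "g2"]), c(0L, 0L, 0L))    # exact tie at delta = 0
  expect_equal(unname(b0[, "g1"]), c(1L, 0L, 0L))
  expect_error(dtb_binarise(cp, 1.5), "delta")
})

test_that("consensus of identical partitions reproduces the partition", {
  coll <- normalise_collection(small_collection(noise_sd = 0, missing_fraction = 0))
  x <- coll$datasets[[1]]$values
  p <- kmeans_ka(x, 4)
  p$aligned <- TRUE
  cp <- build_copam(list(p, p, p), coll)
  for (delta in c(0, 0.5, 1)) {
    b <- dtb_binarise(cp, delta)
    expect_identical(unname(b), unname(p$membership))
  }
})

test_that("full fit: columns sum to one and the delta grid nests", {
  coll <- small_collection()
  fit <- uncles(coll, k_values = c(4, 6), delta_grid = seq(0, 1, 0.25),
                seed = 1, som_epochs = 20)
  for (cp in fit$copams) {
    sums <- colSums(cp$fuzzy)[cp$support > 0]
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-9)
    expect_true(all(cp$support >= 3 * coll$min_presence))  # C x L* floor
    # nesting: clusters at a higher delta are subsets of the same index
    for (d1 in c(0, 0.25, 0.5, 0.75)) {
      b1 <- dtb_binarise(cp, d1)
      b2 <- dtb_binarise(cp, d1 + 0.25)
      expect_true(all(b2 <= b1))
    }
  }
  # delta = 1 keeps only unanimously assigned genes
  cp <- fit$copams[["4"]]
  b1 <- dtb_binarise(cp, 1)
  assigned <- colSums(b1) == 1
  expect_true(all(apply(cp$fuzzy[, assigned, drop = FALSE], 2, max) == 1))
  # grid arithmetic: every (K, delta, index) is tagged
  tags <- vapply(fit$candidates, function(cc) sprintf("%d_%g_%d", cc$K, cc$delta, cc$index), "")
  expect_false(anyDuplicated(tags) > 0)
})
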