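test_that("expressed filter is a strict max-over-time threshold", {
  x <- toy_matrix()
  expect_setequal(filter_expressed(x, 1), c("spike42", "spike96", "flat", "rise"))
  expect_length(filter_expressed(expression_matrix(
    matrix(0, 2, 7, dimnames = list(c("a", "b"), NULL)), grid7), 1), 0L)
  # matches a brute-force scan for several floors
  x <- random_matrix(n = 20, seed = 5)
  for (fl in c(0, 1, 5, 50)) {
    manual <- rownames(x$fpkm)[vapply(seq_len(nrow(x$fpkm)),
      function(i) any(x$fpkm[i, ] > fl), TRUE)]
    expect_identical(filter_expressed(x, fl), manual)
  }
})

test_that("specificity fractions are elementwise shares of the gene total", {
  x <- toy_matrix()
  pr <- specificity_fractions(x, universe = rownames(x$fpkm), min_total = 0)
  expect_false("silent" %in% rownames(pr$fraction))  # zero-total excluded
  expect_equal(unname(pr$fraction["flat", ]), rep(1 / 7, 7))
  m <- matrix(c(0, 0, 10, 0, 0, 0, 0), 1, dimnames = list("one", NULL))
  p1 <- specificity_fractions(expression_matrix(m, grid7), universe = "one")
  expect_equal(unname(p1$fraction[1, 3]), 1)
  expect_equal(p1$peak_time, 62)
  # elementwise oracle on random rows
  x <- random_matrix(n = 15, seed = 11)
  pr <- specificity_fractions(x, universe = rownames(x$fpkm))
  expect_equal(pr$fraction, x$fpkm / rowSums(x$fpkm))
  expect_equal(unname(rowSums(pr$fraction)), rep(1, 15), tolerance = 1e-9)
})

test_that("fractions are invariant under per-gene and global rescaling", {
  x <- random_matrix(n = 8, seed = 2)
  pr <- specificity_fractions(x, universe = rownames(x$fpkm))
  scaled <- x$fpkm * stats::runif(8, 0.1, 10)   # row-wise recycling
  pr2 <- specificity_fractions(expression_matrix(scaled, grid7),
                               universe = rownames(scaled))
  expect_equal(pr2$fraction, pr$fraction)
  pr3 <- specificity_fractions(expression_matrix(x$fpkm * 1000, grid7),
                               universe = rownames(x$fpkm))
  expect_equal(pr3$fraction, pr$fraction)
})

test_that("stage-specific counts are strict, exclusive above 0.5, antitone in alpha", {
  x <- toy_matrix()
  pr <- specificity_fractions(x)
  cs <- count_stage_specific(pr, 0.9)
  expect_equal(unname(cs$counts[c("42", "96")]), c(1L, 1L))
  expect_equal(cs$genes[["42"]], "spike42")
  # single dominant column: every expressed gene specific to it
  m <- matrix(c(9, 0.01, 5, 0.02), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  pr1 <- specificity_fractions(expression_matrix(m, c(42, 52)),
                               universe = c("a", "b"))
  expect_equal(unname(count_stage_specific(pr1, 0.9)$counts), c(2L, 0L))
  # monotonicity and exclusivity on random profiles
  x <- random_matrix(n = 40, seed = 8)
  pr <- specificity_fractions(x, universe = rownames(x$fpkm))
  prev <- NULL
  for (a in c(0.9, 0.8, 0.5)) {
    cs <- count_stage_specific(pr, a)
    if (!is.null(prev)) expect_true(all(cs$counts >= prev))
    expect_lte(length(unlist(cs$genes)),
               length(unique(unlist(cs$genes))) + 0L)  # no gene twice
    prev <- cs$counts
  }
})

test_that("top-expressed union equals per-column sort-and-union brute force", {
  x <- random_matrix(n = 30, seed = 4)
  res <- top_expressed_union(x, n = 5)
  tot <- rowSums(x$fpkm)
  ids <- rownames(x$fpkm)
  manual <- unique(unlist(lapply(1:7, function(j)
    ids[order(-x$fpkm[, j], -tot, ids)][1:5])))
  expect_setequal(res$union, manual)
  expect_gte(length(res$union), 5)
  expect_lte(length(res$union), 35)
  small <- top_expressed_union(toy_matrix(), n = 10)
  expect_setequal(small$union, rownames(toy_matrix()$fpkm))
})

test_that("cumulative contributors return the shortest prefix past the share", {
  m <- matrix(rep(1, 70), 10, 7,
              dimnames = list(sprintf("eq%02d", 1:10), NULL))
  x <- expression_matrix(m, grid7)
  expect_length(cumulative_contributors(x, rownames(m), 0.25), 3L)
  # one dominant gene carrying more than the share -> prefix of 1
  m2 <- m; m2["eq01", ] <- 100
  x2 <- expression_matrix(m2, grid7)
  expect_equal(cumulative_contributors(x2, rownames(m2), 0.7), "eq01")
  expect_error(cumulative_contributors(
    expression_matrix(matrix(0, 2, 7, dimnames = list(c("a", "b"), NULL)),
                      grid7), c("a", "b"), 0.5), "zero total")
})

test_that("neighbor fold changes follow the max/min formula with zero conventions", {
  m <- rbind(updown = c(2, 50, 2, 2, 2, 2, 2),
             zeros = c(0, 0, 5, 0, 0, 0, 0))
  x <- expression_matrix(m, grid7)
  nf <- neighbor_fold_change(x)
  expect_equal(unname(nf$fold["updown", 1:2]), c(25, 25))
  expect_equal(unname(nf$direction["updown", 1:2]), c("rising", "falling"))
  expect_equal(unname(nf$fold["zeros", 1]), 1)      # 0/0 -> 1
  expect_equal(unname(nf$fold["zeros", 2]), Inf)    # 0 -> 5
  # random pairs against the direct formula
  set.seed(13)
  x <- random_matrix(n = 12, seed = 13)
  nf <- neighbor_fold_change(x, pseudo = 0.5)
  for (j in 1:6) {
    a <- x$fpkm[, j]; b <- x$fpkm[, j + 1]
    expect_equal(unname(nf$fold[, j]),
                 unname((pmax(a, b) + 0.5) / (pmin(a, b) + 0.5)))
  }
})
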