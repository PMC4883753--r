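test_that("probability normalization is proportional and sums to one", {
  expect_equal(to_probability_profile(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(to_probability_profile(c(0, 10)), c(0, 1))
  expect_error(to_probability_profile(c(0, 0)), "all-zero")
  set.seed(21)
  for (i in 1:20) {
    v <- stats::rexp(7)
    p <- to_probability_profile(v)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, v / sum(v))
  }
})

test_that("JS distance matches its definition and the base-2 extremes", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(js_distance(c(1, 0), c(0.5, 0.5)), 0.557922, tolerance = 1e-5)
  expect_error(js_distance(c(1, 0), c(1, 0, 0)), "length")
  set.seed(31)
  for (i in 1:25) {
    p <- random_simplex(7); q <- random_simplex(7)
    expect_equal(js_distance(p, q), jsd_oracle(p, q), tolerance = 1e-12)
  }
})

test_that("JS distance satisfies the metric axioms on random triples", {
  set.seed(17)
  for (i in 1:50) {
    p <- random_simplex(7); q <- random_simplex(7); r <- random_simplex(7)
    dpq <- js_distance(p, q)
    expect_gte(dpq, 0); expect_lte(dpq, 1)
    expect_equal(dpq, js_distance(q, p), tolerance = 1e-12)
    expect_equal(js_distance(p, p), 0)
    expect_lte(dpq, js_distance(p, r) + js_distance(r, q) + 1e-12)
  }
})

test_that("sample distance matrix composes column profiles with js_distance", {
  x <- random_matrix(n = 25, seed = 6)
  d <- sample_distance_matrix(x)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 7))
  p1 <- x$fpkm[, 1] / sum(x$fpkm[, 1])
  p4 <- x$fpkm[, 4] / sum(x$fpkm[, 4])
  expect_equal(d[1, 4], jsd_oracle(p1, p4), tolerance = 1e-12)
  # duplicate columns are at distance zero
  m <- cbind(x$fpkm[, 1], x$fpkm[, 1], x$fpkm[, 2])
  rownames(m) <- rownames(x$fpkm)
  d2 <- sample_distance_matrix(expression_matrix(m, c(42, 52, 62)))
  expect_equal(d2[1, 2], 0)
  bad <- matrix(c(1, 0, 1, 0), 2, dimnames = list(c("a", "b"), NULL))
  bad[, 2] <- 0
  expect_error(sample_distance_matrix(expression_matrix(bad, c(42, 52))),
               "zero column")
})

test_that("gene trajectory distances are scale invariant and compositional", {
  x <- random_matrix(n = 10, seed = 10)
  g <- rownames(x$fpkm)
  d <- gene_trajectory_distances(x, g)
  p <- x$fpkm / rowSums(x$fpkm)
  expect_equal(d[2, 7], jsd_oracle(p[2, ], p[7, ]), tolerance = 1e-12)
  # proportional genes at distance zero
  m <- rbind(a = c(1, 2, 3, 4, 5, 6, 7), b = 10 * c(1, 2, 3, 4, 5, 6, 7),
             s1 = c(50, 0, 0, 0, 0, 0, 0), s2 = c(0, 0, 0, 0, 0, 0, 50))
  d2 <- gene_trajectory_distances(expression_matrix(m, grid7), rownames(m))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["s1", "s2"], 1)   # disjoint support
})

test_that("dendrograms merge tight pairs first and export Newick", {
  d <- matrix(c(0, 0.1, 0.9, 0.95,
                0.1, 0, 0.92, 0.9,
                0.9, 0.92, 0, 0.08,
                0.95, 0.9, 0.08, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- build_dendrogram(d)
  expect_equal(sort(hc$height)[1:2], c(0.08, 0.1))
  expect_setequal(abs(hc$merge[1, ]), c(3, 4))   # tightest pair merges first
  nk <- withr::local_tempfile(fileext = ".nwk")
  build_dendrogram(d, newick = nk)
  tree <- ape::read.tree(nk)
  expect_setequal(tree$tip.label, letters[1:4])
  # two items: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(build_dendrogram(d2)$height, 0.4)
  expect_error(build_dendrogram(matrix(0, 1, 1)), "2 items")
})

test_that("PAM recovers the obvious 1-D partition and trivial cases", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(stats::dist(pts))
  fit <- pam_fit(d, 2)
  expect_equal(unname(fit$assignment), c(1, 1, 2, 2))
  expect_equal(fit$total_cost, 2)
  # k = n: every item its own medoid, cost 0
  fit4 <- pam_fit(d, 4)
  expect_equal(fit4$total_cost, 0)
  expect_length(unique(fit4$assignment), 4)
  expect_error(pam_fit(d, 5), "between 1")
})

test_that("PAM equals the exhaustive optimum on small random instances", {
  set.seed(99)
  for (i in 1:12) {
    n <- sample(5:9, 1)
    k <- sample(2:3, 1)
    pts <- matrix(stats::rnorm(n * 2), n)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(as.character(1:n), as.character(1:n))
    fit <- pam_fit(d, k)
    expect_equal(fit$total_cost, pam_brute_cost(d, k), tolerance = 1e-10)
  }
})

test_that("PAM cost matches the independent reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(123)
  pts <- matrix(stats::rnorm(60), 30)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(as.character(1:30), as.character(1:30))
  ours <- pam_fit(d, 4)
  ref <- cluster::pam(stats::as.dist(d), 4)
  # both are local optima of the same objective; BUILD+SWAP should match
  ref_cost <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
  expect_equal(ours$total_cost, ref_cost, tolerance = 1e-8)
})

test_that("cluster assignment is invariant under per-gene rescaling", {
  x <- random_matrix(n = 30, seed = 44)
  g <- rownames(x$fpkm)
  d1 <- gene_trajectory_distances(x, g)
  scaled <- x$fpkm * stats::runif(30, 0.05, 20)
  d2 <- gene_trajectory_distances(expression_matrix(scaled, grid7), g)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(pam_fit(d1, 4)$assignment, pam_fit(d2, 4)$assignment)
})

test_that("silhouettes follow (b-a)/max(a,b) with the degenerate conventions", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(as.character(1:4), as.character(1:4))
  fit <- silhouette_scores(pam_fit(d, 2), d)
  expect_equal(unname(fit$silhouette[1]), (10.5 - 1) / 10.5, tolerance = 1e-10)
  # identical items: a = b = 0 convention scores 0
  dz <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  fz <- pam_fit(dz, 2)
  expect_equal(unname(silhouette_scores(fz, dz)$silhouette), rep(0, 4))
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(unname(fit$assignment), stats::as.dist(d))
  expect_equal(unname(fit$silhouette), unname(ref[, "sil_width"]),
               tolerance = 1e-10)
})
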