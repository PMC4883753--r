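two_iso <- function(a, b, times = grid7) {
  fpkm <- rbind(`g-RA` = a, `g-RB` = b)
  isoform_matrix(fpkm, gene = c("g", "g"), times = times)
}

test_that("isoform fractions divide by the gene total per time point", {
  iso <- two_iso(c(3, 0, 1, 1, 1, 1, 1), c(1, 0, 3, 3, 3, 3, 3))
  fr <- isoform_fractions(iso)
  expect_equal(unname(fr["g-RA", 1]), 0.75)
  expect_equal(unname(fr["g-RB", 1]), 0.25)
  expect_true(all(is.na(fr[, 2])))   # zero gene total -> undefined
  # single-isoform gene: fraction 1 wherever expressed
  solo <- isoform_matrix(matrix(c(5, 0, 2, 1, 1, 1, 1), 1,
                                dimnames = list("s-RA", NULL)),
                         gene = "s", times = grid7)
  frs <- isoform_fractions(solo)
  expect_equal(unname(frs[1, c(1, 3)]), c(1, 1))
  expect_true(is.na(frs[1, 2]))
  # random tables: fractions sum to 1 per gene-time with positive total
  set.seed(3)
  fpkm <- matrix(stats::rexp(40), 8, 5)
  rownames(fpkm) <- sprintf("i%02d", 1:8)
  iso <- isoform_matrix(fpkm, gene = rep(c("gA", "gB", "gC", "gD"), each = 2),
                        times = c(1, 2, 3, 4, 5))
  fr <- isoform_fractions(iso)
  sums <- rowsum(fr, iso$gene)
  expect_equal(unname(as.vector(sums)), rep(1, 20), tolerance = 1e-12)
})

test_that("a clean dominant swap yields exactly one switch event", {
  iso <- two_iso(c(10, 1, 1, 1, 1, 1, 1), c(1, 10, 10, 10, 10, 10, 10))
  ev <- detect_switches(iso)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t1, 42); expect_equal(ev$t2, 52)
  expect_equal(ev$isoform_down, "g-RA")
  expect_equal(ev$isoform_up, "g-RB")
})

test_that("switch detection respects its floors and single-isoform genes never fire", {
  # dominant swap but below the absolute FPKM floor
  iso <- two_iso(c(0.5, 0.1, rep(0.1, 5)), c(0.1, 0.5, rep(0.5, 5)))
  expect_equal(nrow(detect_switches(iso, min_fpkm = 1)), 0L)
  expect_equal(nrow(detect_switches(iso, min_fpkm = 0.05)), 1L)
  # dominance change with too small a fraction shift
  iso2 <- two_iso(c(10, 9, rep(9, 5)), c(9, 10, rep(10, 5)))
  expect_equal(nrow(detect_switches(iso2)), 0L)
  solo <- isoform_matrix(matrix(c(10, 1, 10, 1, 10, 1, 10), 1,
                                dimnames = list("s-RA", NULL)),
                         gene = "s", times = grid7)
  expect_equal(nrow(detect_switches(solo)), 0L)
})

test_that("switch events are invariant to per-time rescaling except via the floor", {
  iso <- two_iso(c(10, 1, 1, 1, 1, 1, 1), c(1, 10, 10, 10, 10, 10, 10))
  scaled <- iso
  scaled$fpkm <- iso$fpkm * rep(c(7, 3, 1, 1, 1, 1, 2), each = 2)
  ev1 <- detect_switches(iso); ev2 <- detect_switches(scaled)
  expect_equal(ev1[c("gene", "t1", "t2", "isoform_down", "isoform_up")],
               ev2[c("gene", "t1", "t2", "isoform_down", "isoform_up")])
})

test_that("isoform change counting scans all time pairs with the fold conventions", {
  fpkm <- rbind(flat = rep(1, 7),
                mid = c(1, 2, 5, 2, 1, 1, 1),
                big = c(1, 1, 1, 1, 1, 1, 12),
                inf = c(1, 0, 1, 1, 1, 1, 1))
  iso <- isoform_matrix(fpkm, gene = c("a", "b", "c", "d"), times = grid7)
  res <- count_isoform_changes(iso, fold = 10)
  expect_equal(res$per_isoform$max_fold, c(1, 5, 12, Inf))
  expect_equal(res$n_changed, 2L)
  # brute force over all time pairs on random tables
  set.seed(5)
  m <- matrix(stats::rlnorm(35, 1, 1), 5, 7,
              dimnames = list(sprintf("i%d", 1:5), NULL))
  iso2 <- isoform_matrix(m, gene = sprintf("g%d", 1:5), times = grid7)
  res2 <- count_isoform_changes(iso2, fold = 3, pseudo = 0.1)
  brute <- apply(m, 1, function(v) {
    mx <- 1
    for (i in 1:6) for (j in (i + 1):7) {
      f <- (max(v[i], v[j]) + 0.1) / (min(v[i], v[j]) + 0.1)
      mx <- max(mx, f)
    }
    mx
  })
  expect_equal(res2$per_isoform$max_fold, unname(brute))
})

test_that("trajectory correlation is Pearson on the log10(FPKM+1) scale", {
  fpkm <- rbind(a = c(1, 2, 4, 8, 16, 32, 64),
                b = c(1, 2, 4, 8, 16, 32, 64),
                c = rev(c(1, 2, 4, 8, 16, 32, 64)),
                k = rep(3, 7))
  iso <- isoform_matrix(fpkm, gene = c("gA", "gA", "gB", "gC"), times = grid7)
  expect_equal(trajectory_correlation(iso, "a", "b"), 1)
  expect_lt(trajectory_correlation(iso, "a", "c"), -0.9)
  expect_true(is.na(trajectory_correlation(iso, "a", "k")))
  expect_error(trajectory_correlation(iso, "a", "zz"), "unknown isoform")
  expect_equal(trajectory_correlation(iso, "a", "c"),
               stats::cor(log10(fpkm["a", ] + 1), log10(fpkm["c", ] + 1)))
})

test_that("the hand-written example table contains one early switch", {
  iso <- read_isoform_table(extdata("example_isoforms.tsv"))
  ev <- detect_switches(iso)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene, "swA")
  expect_equal(c(ev$t1, ev$t2), c(42, 52))
})
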