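# shared fixtures and independent oracles

grid7 <- c(42, 52, 62, 72, 80, 88, 96)

toy_matrix <- function() {
  m <- rbind(
    spike42 = c(100, 1, 0.5, 0.2, 0.1, 0.1, 0.2),
    spike96 = c(0.1, 0.2, 0.1, 0.3, 0.5, 1, 120),
    flat    = rep(10, 7),
    rise    = 2^(0:6),
    silent  = rep(0, 7))
  expression_matrix(m, grid7)
}

random_matrix <- function(n = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n * 7, 2, 1), n, 7,
              dimnames = list(sprintf("r%03d", seq_len(n)), NULL))
  expression_matrix(m, grid7)
}

random_simplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# definitional JS distance, independent of the package's vectorized path
jsd_oracle <- function(p, q, base = 2) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i], base = base))
  }
  sqrt((kl(p, m) + kl(q, m)) / 2)
}

# exhaustive PAM optimum: minimal cost over all medoid subsets
pam_brute_cost <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  for (meds in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, meds, drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# hypergeometric upper tail by direct summation of the pmf (choose only)
hyper_tail_oracle <- function(x, K, N, n, upper = TRUE) {
  i <- if (upper) seq(x, min(K, n)) else seq(0, x)
  sum(choose(K, i) * choose(N - K, n - i) / choose(N, n))
}

# pooled-variance two-sample t statistic, closed form
student_t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

extdata <- function(f) system.file("extdata", f, package = "cuticleCourse")
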