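#' Normalize a non-negative vector to a probability profile
#'
#' @param x non-negative numeric vector with at least one positive entry
#' @return vector summing to 1, proportional to `x`
#' @export
to_probability_profile <- function(x) {
  if (any(!is.finite(x) | x < 0)) stop("profile input must be finite, >= 0")
  s <- sum(x)
  if (s == 0) stop("cannot normalize an all-zero vector")
  x / s
}

#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the Jensen-Shannon divergence. With base-2 logarithms
#' (the default) the distance lies in \[0, 1\] and attains 1 on disjoint
#' supports; it is a metric. The convention 0 * log(0) = 0 applies.
#'
#' @param p,q probability vectors of equal length, each summing to 1
#' @param base logarithm base (default 2)
#' @return distance in \[0, 1\] (for base 2)
#' @export
js_distance <- function(p, q, base = 2) {
  if (length(p) != length(q)) stop("profiles differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i], base = base))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Pairwise JS distances between the time-point samples
#'
#' Each column (time point) is normalized over genes into a probability
#' profile and all pairwise JS distances are computed; this is the distance
#' behind the sample dendrogram that groups the three early (42-62 hr)
#' against the four late (72-96 hr) samples.
#'
#' @param x an [expression_matrix()]
#' @param base logarithm base for the divergence (default 2)
#' @return symmetric distance matrix with time labels as dimnames
#' @export
sample_distance_matrix <- function(x, base = 2) {
  stopifnot(inherits(x, "expr_matrix"))
  if (any(colSums(x$fpkm) == 0)) stop("zero column: a sample with no signal")
  profs <- apply(x$fpkm, 2L, to_probability_profile)
  js_matrix(t(profs), ids = as.character(x$times), base = base)
}

#' Pairwise JS distances between gene trajectories
#'
#' Each gene's per-time FPKM vector is normalized into a probability profile
#' over time; distances are JS. The log10(FPKM+1) display transform used for
#' medoid curves is not applied here, so distances are invariant to per-gene
#' rescaling.
#'
#' @param x an [expression_matrix()]
#' @param genes gene ids (all must have positive total FPKM)
#' @param base logarithm base (default 2)
#' @return symmetric distance matrix over `genes`
#' @export
gene_trajectory_distances <- function(x, genes, base = 2) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$fpkm[genes, , drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero-total gene: ", genes[tot == 0][1L])
  js_matrix(m / tot, ids = genes, base = base)
}

# vectorized pairwise JS distances; equivalent to looping js_distance over
# all pairs (JSD(p,q) = H((p+q)/2) - (H(p)+H(q))/2)
js_matrix <- function(profiles, ids, base = 2) {
  P <- as.matrix(profiles)
  n <- nrow(P)
  t_ <- ncol(P)
  hent <- function(M) {
    X <- M * log(M, base = base)
    X[M == 0] <- 0
    -rowSums(X)
  }
  H <- hent(P)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    M <- (P + matrix(P[j, ], n, t_, byrow = TRUE)) / 2
    d[, j] <- sqrt(pmax(0, hent(M) - (H + H[j]) / 2))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Agglomerative dendrogram over a distance matrix
#'
#' @param d symmetric distance matrix (e.g. [sample_distance_matrix()])
#' @param linkage `"average"` (default), `"complete"` or `"single"`
#' @param newick optional path; if given, the tree is also written in Newick
#'   format
#' @return an `hclust` object
#' @export
build_dendrogram <- function(d, linkage = c("average", "complete", "single"),
                             newick = NULL) {
  linkage <- match.arg(linkage)
  if (nrow(as.matrix(d)) < 2L) stop("need at least 2 items")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  if (!is.null(newick))
    ape::write.tree(ape::as.phylo(hc), file = newick)
  hc
}

#' Partitioning around medoids (PAM), deterministic BUILD + SWAP
#'
#' k-medoid clustering of items under an arbitrary distance matrix, as used
#' to group gene expression trajectories by Jensen-Shannon distance. The
#' BUILD phase seeds medoids greedily (first the item minimizing total
#' distance, then the item with the largest cost reduction); the SWAP phase
#' repeatedly applies the single best medoid/non-medoid exchange until no
#' exchange lowers the total cost. All ties break on the lowest item index,
#' so the fit is fully deterministic. Assignment is to the nearest medoid
#' (ties again to the lowest-index medoid).
#'
#' On small instances (`n <= exhaustive_limit`, default 10) the result is
#' additionally certified against complete enumeration of medoid subsets, so
#' the returned clustering is the exact optimum there; beyond that size the
#' BUILD+SWAP local optimum is returned.
#'
#' @param d symmetric distance matrix with zero diagonal
#' @param k number of clusters, 1 <= k <= number of items
#' @param exhaustive_limit maximum item count for exact enumeration
#'   (default 10)
#' @return object of class `pam_fit`: `k`, `medoids` (item ids),
#'   `assignment` (named integer vector of cluster ids 1..k), `total_cost`,
#'   and, once [silhouette_scores()] has been applied, silhouettes
#' @seealso [silhouette_scores()]
#' @export
pam_fit <- function(d, k, exhaustive_limit = 10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- as.character(seq_len(n))
  if (k < 1 || k > n) stop("k must be between 1 and the item count")
  ids <- rownames(d)

  nearest_dist <- function(meds) Reduce(pmin, lapply(meds, function(m) d[, m]))
  cost_of <- function(meds) sum(nearest_dist(meds))

  # BUILD
  med <- which.min(rowSums(d))          # ties: which.min takes first
  while (length(med) < k) {
    near <- nearest_dist(med)
    gain <- vapply(seq_len(n), function(i) {
      if (i %in% med) return(-Inf)
      sum(pmax(near - d[, i], 0))
    }, 0)
    med <- c(med, which.max(gain))
  }
  cost <- cost_of(med)

  # SWAP: best-improvement, first-index tie-break via strict "<"
  repeat {
    best <- list(delta = 0)
    for (mi in seq_along(med)) for (h in seq_len(n)) {
      if (h %in% med) next
      cand <- med; cand[mi] <- h
      dl <- cost_of(cand) - cost
      if (dl < best$delta - 1e-12) best <- list(delta = dl, meds = cand)
    }
    if (best$delta >= 0) break
    med <- best$meds
    cost <- cost + best$delta
  }

  if (n <= exhaustive_limit) {
    for (cand in utils::combn(n, k, simplify = FALSE)) {
      cc <- cost_of(cand)
      if (cc < cost - 1e-12) { med <- cand; cost <- cc }
    }
  }

  med <- sort(med)
  assign_idx <- apply(d[, med, drop = FALSE], 1L, which.min)
  assign_idx[med] <- seq_along(med)   # a medoid always owns its cluster
  structure(list(k = k,
                 medoids = ids[med],
                 assignment = stats::setNames(as.integer(assign_idx), ids),
                 total_cost = cost_of(med)),
            class = "pam_fit")
}

#' @export
print.pam_fit <- function(x, ...) {
  cat("PAM fit: k =", x$k, "over", length(x$assignment), "items;",
      "total cost", format(x$total_cost, digits = 6), "\n")
  cat("Medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pam_fit <- function(object, ...) {
  sz <- tabulate(object$assignment, nbins = object$k)
  out <- data.frame(cluster = seq_len(object$k), medoid = object$medoids,
                    size = sz)
  if (!is.null(object$cluster_silhouette))
    out$mean_silhouette <- object$cluster_silhouette
  out
}

#' Silhouette widths for a PAM fit
#'
#' Standard silhouettes s = (b - a) / max(a, b): a = mean distance to the
#' item's own cluster (excluding itself), b = smallest mean distance to any
#' other cluster. Items in singleton clusters, and items with a = b = 0,
#' score 0. Per-cluster structure quality is the mean silhouette; values
#' above 0.2 marked the best-structured trajectory clusters in this system.
#'
#' @param fit a [pam_fit()]
#' @param d the distance matrix the fit was computed on
#' @return the fit, augmented with `silhouette` (per item) and
#'   `cluster_silhouette` (per cluster mean)
#' @export
silhouette_scores <- function(fit, d) {
  stopifnot(inherits(fit, "pam_fit"))
  if (fit$k < 2) stop("silhouettes need k >= 2")
  d <- as.matrix(d)
  cl <- fit$assignment
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(seq_len(fit$k), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- names(cl)
  fit$silhouette <- s
  fit$cluster_silhouette <- vapply(seq_len(fit$k),
                                   function(g) mean(s[cl == g]), 0)
  fit
}

#' Medoid trajectory curves on the display scale
#'
#' Returns each cluster medoid's trajectory as log10(FPKM + 1), the scale
#' used for trajectory plots; the transform plays no role in the distances.
#'
#' @param fit a [pam_fit()] over genes of `x`
#' @param x the [expression_matrix()]
#' @return data.frame: cluster, gene (medoid id), one column per time point
#' @export
medoid_curves <- function(fit, x) {
  stopifnot(inherits(fit, "pam_fit"), inherits(x, "expr_matrix"))
  m <- log10(x$fpkm[fit$medoids, , drop = FALSE] + 1)
  data.frame(cluster = seq_len(fit$k), gene = fit$medoids, m,
             check.names = FALSE, row.names = NULL)
}
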