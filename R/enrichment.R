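#' Per-cluster fraction of genes carrying a binary label
#'
#' @param fit a [pam_fit()] over genes
#' @param label character vector of labeled gene ids (e.g. genes with
#'   homologs restricted to arthropods)
#' @return data.frame: cluster, size, labeled, fraction
#' @export
cluster_label_fractions <- function(fit, label) {
  stopifnot(inherits(fit, "pam_fit"))
  cl <- fit$assignment
  out <- data.frame(cluster = seq_len(fit$k),
                    size = tabulate(cl, nbins = fit$k))
  out$labeled <- vapply(seq_len(fit$k), function(g)
    sum(names(cl)[cl == g] %in% label), 0L)
  out$fraction <- out$labeled / out$size
  out
}

#' Two-group t-test on per-cluster label fractions
#'
#' Compares label fractions between two disjoint groups of clusters — the
#' test behind contrasting the dynamically changing trajectory clusters
#' (strongly enriched in arthropod-restricted genes) against the rest.
#'
#' @param summary a [cluster_label_fractions()] data.frame
#' @param group_a,group_b disjoint cluster-id vectors, each of >= 2 clusters
#' @param flavor `"student"` (pooled variance, default) or `"welch"`
#' @return list: mean_a, mean_b, t, df, p (two-sided), flavor
#' @export
two_group_fraction_test <- function(summary, group_a, group_b,
                                    flavor = c("student", "welch")) {
  flavor <- match.arg(flavor)
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 clusters")
  fa <- summary$fraction[match(group_a, summary$cluster)]
  fb <- summary$fraction[match(group_b, summary$cluster)]
  if (anyNA(fa) || anyNA(fb)) stop("unknown cluster id in a group")
  tt <- stats::t.test(fa, fb, var.equal = (flavor == "student"))
  list(mean_a = mean(fa), mean_b = mean(fb),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, flavor = flavor)
}

#' Categorical over/under-representation per cluster
#'
#' Hypergeometric tail tests of each category in each cluster against the
#' clustered-gene universe, with Benjamini-Hochberg correction within each
#' cluster (over- and under-representation p-values adjusted separately).
#'
#' @param fit a [pam_fit()] over genes
#' @param categories named list mapping category -> gene id vector
#' @param universe gene universe (default: the clustered genes)
#' @return data.frame: cluster, category, cluster_size, category_size,
#'   overlap, p_over, p_under, q_over, q_under
#' @export
category_enrichment <- function(fit, categories, universe = NULL) {
  stopifnot(inherits(fit, "pam_fit"), length(categories) > 0)
  cl <- fit$assignment
  if (is.null(universe)) universe <- names(cl)
  N <- length(universe)
  rows <- list()
  for (g in seq_len(fit$k)) {
    members <- intersect(names(cl)[cl == g], universe)
    n <- length(members)
    for (cat_ in names(categories)) {
      K <- length(intersect(categories[[cat_]], universe))
      x <- length(intersect(members, categories[[cat_]]))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = g, category = cat_, cluster_size = n, category_size = K,
        overlap = x,
        p_over = stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
        p_under = stats::phyper(x, K, N - K, n))
    }
  }
  out <- do.call(rbind, rows)
  out$q_over <- NA_real_
  out$q_under <- NA_real_
  for (g in seq_len(fit$k)) {
    i <- out$cluster == g
    out$q_over[i] <- stats::p.adjust(out$p_over[i], method = "BH")
    out$q_under[i] <- stats::p.adjust(out$p_under[i], method = "BH")
  }
  rownames(out) <- NULL
  out
}
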