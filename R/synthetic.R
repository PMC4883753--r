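#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the simulators with defaults matching the study
#' conditions the package analyzes: a 7-point 42-96 hr awp grid, five
#' trajectory archetypes, multiplicative log-normal FPKM noise whose squared
#' coefficient of variation decreases with expression level
#' (CV2(mu) = a/mu + b), planted dominant-isoform switches, compositionally
#' biased protein sets, and dorsal/ventral thickness ratios with group
#' means/SDs of 1.2/0.11 (wild type) and 2.1/0.43 (knockdown). Identical
#' seed and config give bit-identical outputs.
#'
#' @param seed integer seed driving every generator
#' @param times time grid (hours awp)
#' @param n_genes genes in the simulated time course
#' @param archetype_mix named proportions over archetypes
#'   spike / rise / fall / flat / bimodal; must sum to 1
#' @param expr_meanlog,expr_sdlog log-normal parameters of the per-gene
#'   baseline FPKM
#' @param cv2_a,cv2_b parameters of CV2(mu) = a/mu + b
#' @param noise multiplier on the CV2 curve (0 = noiseless)
#' @param n_replicates replicates generated per condition (merged by mean)
#' @param iso list: n_genes, n_switch, dominant_frac, noise_sd (logit-scale
#'   jitter of isoform fractions), meanlog/sdlog of gene totals
#' @param protein list: n, len_meanlog, len_sdlog, n_no_trp, n_short and a
#'   `high` table of planted single-residue biases
#' @param thickness list: wt_mean, wt_sd, kd_mean, kd_sd (ratio
#'   distributions), n_wings, n_meas, base_nm, jitter_nm
#' @param qpcr list: n_replicates, noise_sd (cycles), control_ct, base_delta
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       times = c(42, 52, 62, 72, 80, 88, 96),
                       n_genes = 500,
                       archetype_mix = c(spike = 0.2, rise = 0.2, fall = 0.2,
                                         flat = 0.2, bimodal = 0.2),
                       expr_meanlog = log(50), expr_sdlog = 0.8,
                       cv2_a = 2, cv2_b = 0.02, noise = 1,
                       n_replicates = 2,
                       iso = list(),
                       protein = list(),
                       thickness = list(),
                       qpcr = list()) {
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype proportions must sum to 1")
  if (any(archetype_mix < 0)) stop("archetype proportions must be >= 0")
  stopifnot(expr_sdlog > 0 || expr_sdlog == 0, cv2_a >= 0, cv2_b >= 0,
            noise >= 0, n_genes >= 1)
  iso <- utils::modifyList(list(n_genes = 100, n_switch = 20,
                                dominant_frac = 0.85, noise_sd = 0.15,
                                meanlog = log(50), sdlog = 0.5), iso)
  protein <- utils::modifyList(list(
    n = 20, len_meanlog = log(180), len_sdlog = 0.45,
    n_no_trp = 9, n_short = 10,
    high = data.frame(residue = c("A", "A", "V", "H", "G"),
                      fraction = c(0.25, 0.25, 0.25, 0.22, 0.35))), protein)
  thickness <- utils::modifyList(list(
    wt_mean = 1.2, wt_sd = 0.11, kd_mean = 2.1, kd_sd = 0.43,
    n_wings = 8, n_meas = 10, base_nm = 300, jitter_nm = 5), thickness)
  if (thickness$wt_mean <= 0 || thickness$kd_mean <= 0)
    stop("thickness ratio means must be positive")
  qpcr <- utils::modifyList(list(n_replicates = 3, noise_sd = 0.05,
                                 control_ct = 20, base_delta = 5), qpcr)
  structure(list(seed = as.integer(seed),
                 times = validate_time_grid(times),
                 n_genes = n_genes, archetype_mix = archetype_mix,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 cv2_a = cv2_a, cv2_b = cv2_b, noise = noise,
                 n_replicates = n_replicates,
                 iso = iso, protein = protein, thickness = thickness,
                 qpcr = qpcr), class = "sim_config")
}

archetype_shape <- function(kind, nt, peak = NULL) {
  switch(kind,
    spike = { s <- rep(0.002, nt); s[peak] <- 1; s },
    rise = 2^(seq_len(nt) - 1),
    fall = rev(2^(seq_len(nt) - 1)),
    flat = rep(1, nt),
    bimodal = { s <- rep(0.03, nt); s[1L] <- 1; s[nt] <- 1; s },
    stop("unknown archetype: ", kind))
}

# mean-1 multiplicative log-normal factors with CV^2 = cv2
lnorm_noise_factor <- function(n, cv2) {
  sdlog <- sqrt(log1p(cv2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an FPKM time course with planted trajectory archetypes
#'
#' Gene mean trajectories follow their archetype shape scaled by a
#' log-normal baseline; replicate FPKM values add multiplicative log-normal
#' noise with CV2 decreasing in the expected value per the configured
#' CV2(mu) = a/mu + b curve (capped at 3); the reported matrix is the
#' replicate mean. Spike genes place > 90% of their expected total FPKM at
#' one time point by construction.
#'
#' @param config a [sim_config()]
#' @return list: `matrix` (an [expression_matrix()] with replicates
#'   attached), `archetype` (named archetype family per gene), `labels`
#'   (named trajectory-class label per gene: the archetype, with spikes
#'   split by peak time, since spikes peaking at different stages are
#'   distinct trajectories), `peak` (named spike peak times, NA
#'   elsewhere). `length(unique(labels))` is the true cluster count for
#'   recovery experiments.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- length(config$times)
  n <- config$n_genes
  kinds <- names(config$archetype_mix)
  counts <- round(config$archetype_mix * n)
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  labels <- rep(kinds, counts)
  base <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  peaks <- ifelse(labels == "spike", sample.int(nt, n, replace = TRUE),
                  NA_integer_)
  mu <- t(vapply(seq_len(n), function(i) {
    s <- archetype_shape(labels[i], nt, peaks[i])
    base[i] * s / max(s)
  }, numeric(nt)))
  reps <- array(0, dim = c(n, nt, config$n_replicates))
  for (r in seq_len(config$n_replicates)) {
    cv2 <- config$noise * pmin(config$cv2_a / pmax(mu, 1e-6) + config$cv2_b, 3)
    reps[, , r] <- mu * matrix(lnorm_noise_factor(n * nt, cv2), n, nt)
  }
  if (config$noise == 0) reps[] <- rep(mu, config$n_replicates)
  fpkm <- apply(reps, c(1, 2), mean)
  ids <- sprintf("g%04d", seq_len(n))
  rownames(fpkm) <- ids
  dimnames(reps)[[1]] <- ids
  classes <- ifelse(labels == "spike",
                    paste0("spike@", config$times[peaks]), labels)
  list(matrix = expression_matrix(fpkm, config$times, replicates = reps),
       archetype = stats::setNames(labels, ids),
       labels = stats::setNames(classes, ids),
       peak = stats::setNames(config$times[peaks], ids))
}

#' Simulate an isoform matrix with planted dominant-isoform switches
#'
#' Every gene carries two isoforms. Non-switching genes keep a stable
#' dominant isoform (fraction `dominant_frac`); switching genes swap the
#' dominant isoform at a planted adjacent time pair, moving its fraction
#' from `dominant_frac` to `1 - dominant_frac` (a fraction change of
#' 2*dominant_frac - 1, the generator's documented separation margin: 0.7
#' at the default 0.85). Fractions are jittered on the logit scale.
#'
#' @param config a [sim_config()]
#' @return list: `matrix` (an [isoform_matrix()]), `truth` (data.frame
#'   gene, t1, t2, isoform_down, isoform_up of planted switches)
#' @export
simulate_isoforms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p <- config$iso
  nt <- length(config$times)
  pairs <- neighbor_pairs(config$times)
  n <- p$n_genes
  if (p$n_switch > n) stop("more switches than genes")
  genes <- sprintf("sg%03d", seq_len(n))
  switch_at <- c(sample.int(nrow(pairs), p$n_switch, replace = TRUE),
                 rep(NA_integer_, n - p$n_switch))
  totals <- stats::rlnorm(n, p$meanlog, p$sdlog)
  fpkm <- matrix(0, 2L * n, nt)
  truth <- list()
  logit <- function(x) log(x / (1 - x))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  for (i in seq_len(n)) {
    f1 <- rep(p$dominant_frac, nt)
    if (!is.na(switch_at[i])) {
      f1[seq(switch_at[i] + 1L, nt)] <- 1 - p$dominant_frac
      truth[[length(truth) + 1L]] <- data.frame(
        gene = genes[i],
        t1 = pairs[switch_at[i], 1L], t2 = pairs[switch_at[i], 2L],
        isoform_down = paste0(genes[i], "-RA"),
        isoform_up = paste0(genes[i], "-RB"))
    }
    f1 <- inv_logit(logit(f1) + stats::rnorm(nt, 0, p$noise_sd))
    tot_t <- totals[i] * lnorm_noise_factor(nt, 0.05)
    fpkm[2L * i - 1L, ] <- tot_t * f1
    fpkm[2L * i, ] <- tot_t * (1 - f1)
  }
  ids <- as.vector(rbind(paste0(genes, "-RA"), paste0(genes, "-RB")))
  rownames(fpkm) <- ids
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(), t1 = numeric(), t2 = numeric(),
               isoform_down = character(), isoform_up = character())
  truth <- truth[order(truth$gene), , drop = FALSE]
  rownames(truth) <- NULL
  list(matrix = isoform_matrix(fpkm, gene = rep(genes, each = 2L),
                               times = config$times),
       truth = truth)
}

#' Simulate a protein set with planted compositional biases
#'
#' Residue counts are allocated deterministically from each protein's
#' target composition (largest-remainder rounding), so planted flags —
#' absent residues, a single residue at or above a planted fraction, short
#' length — hold exactly; only lengths and the residue order are random.
#'
#' @param config a [sim_config()]
#' @return list: `proteins` (a `protein_set`), `truth` (data.frame id,
#'   length, short, no_trp, high_residue, high_fraction)
#' @export
simulate_proteins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  p <- config$protein
  n <- p$n
  nh <- nrow(p$high)
  if (p$n_no_trp + nh > n)
    stop("more planted biases than proteins")
  lens <- pmax(30L, round(stats::rlnorm(n, p$len_meanlog, p$len_sdlog)))
  # force the planted count of short proteins
  ord <- order(lens)
  short_target <- rep(FALSE, n)
  short_target[ord[seq_len(min(p$n_short, n))]] <- TRUE
  lens[short_target & lens >= 200] <- 150L
  lens[!short_target & lens < 200] <- 250L
  no_trp <- seq_len(p$n_no_trp)
  high_idx <- seq(p$n_no_trp + 1L, length.out = nh)
  seqs <- character(n)
  truth <- data.frame(id = sprintf("prot%02d", seq_len(n)), length = lens,
                      short = lens < 200, no_trp = FALSE,
                      high_residue = NA_character_,
                      high_fraction = NA_real_)
  for (i in seq_len(n)) {
    probs <- stats::setNames(rep(1 / 20, 20), AA20)
    boost <- NULL
    if (i %in% no_trp) { probs["W"] <- 0; truth$no_trp[i] <- TRUE }
    if (i %in% high_idx) {
      h <- p$high[match(i, high_idx), ]
      if (probs[h$residue] == 0)
        stop("infeasible bias: residue ", h$residue,
             " both absent and enriched")
      boost <- h
      truth$high_residue[i] <- h$residue
      truth$high_fraction[i] <- h$fraction
    }
    counts <- stats::setNames(integer(20), AA20)
    if (!is.null(boost)) counts[boost$residue] <- ceiling(boost$fraction * lens[i])
    rest <- lens[i] - sum(counts)
    free <- if (is.null(boost)) AA20 else setdiff(AA20, boost$residue)
    pf <- probs[free] / sum(probs[free])
    alloc <- floor(pf * rest)
    rem <- rest - sum(alloc)
    if (rem > 0) {
      extra <- order(pf * rest - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1L
    }
    counts[free] <- alloc
    seqs[i] <- paste(sample(rep(AA20, counts)), collapse = "")
  }
  names(seqs) <- truth$id
  list(proteins = structure(seqs, class = "protein_set"), truth = truth)
}

#' Simulate dorsal/ventral cuticle thickness measurement sets
#'
#' Per wing a true thickness ratio is drawn from the group's normal
#' distribution (wild type 1.2 +/- 0.11, knockdown 2.1 +/- 0.43 by
#' default); the thinner surface's base thickness is drawn around
#' `base_nm`, and `n_meas` measurements per surface add normal jitter. In
#' the wild-type group the thicker surface is assigned to dorsal or ventral
#' at random (its identity being uncertain); in the knockdown group the
#' thicker surface is always dorsal (the driven side).
#'
#' @param config a [sim_config()]
#' @return list with [thickness_set()]s `wt` and `kd`, and `truth`
#'   (drawn per-wing ratios per group)
#' @export
simulate_thickness <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  p <- config$thickness
  draw_group <- function(mean_r, sd_r, fixed_dorsal) {
    wings <- list()
    ratios <- numeric(p$n_wings)
    for (i in seq_len(p$n_wings)) {
      r <- max(1.001, stats::rnorm(1, mean_r, sd_r))
      ratios[i] <- r
      b <- max(50, stats::rnorm(1, p$base_nm, p$base_nm / 10))
      thin <- pmax(1, b + stats::rnorm(p$n_meas, 0, p$jitter_nm))
      thick <- pmax(1, b * r + stats::rnorm(p$n_meas, 0, p$jitter_nm))
      dorsal_thicker <- if (fixed_dorsal) TRUE else stats::runif(1) < 0.5
      wings[[sprintf("wing%02d", i)]] <-
        if (dorsal_thicker) list(dorsal = thick, ventral = thin)
        else list(dorsal = thin, ventral = thick)
    }
    list(set = thickness_set(wings), ratios = ratios)
  }
  wt <- draw_group(p$wt_mean, p$wt_sd, fixed_dorsal = FALSE)
  kd <- draw_group(p$kd_mean, p$kd_sd, fixed_dorsal = TRUE)
  list(wt = wt$set, kd = kd$set,
       truth = list(wt = wt$ratios, kd = kd$ratios))
}

#' Simulate a qPCR plate realizing given true RQ values
#'
#' Inverse model of [relative_quantification()]: control Ct is constant
#' (plus replicate noise); the target Ct in sample s sits
#' `base_delta - log2(true_rq[s])` cycles above the control. At zero noise
#' the recovered RQ equals `true_rq` exactly.
#'
#' @param config a [sim_config()]
#' @param true_rq named positive vector of per-sample RQ values; the
#'   calibrator's entry must be 1
#' @param calibrator calibrator sample id (default: first name of
#'   `true_rq`)
#' @param target,control_gene gene names written on the plate
#' @return a [qpcr_plate()]
#' @export
simulate_qpcr <- function(config, true_rq, calibrator = names(true_rq)[1L],
                          target = "target", control_gene = "ctrl") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(true_rq))) stop("true_rq must be named by sample")
  if (any(true_rq <= 0)) stop("true RQ values must be positive")
  if (abs(true_rq[[calibrator]] - 1) > 1e-12)
    stop("calibrator true RQ must be 1")
  set.seed(config$seed + 4L)
  p <- config$qpcr
  rows <- list()
  for (s in names(true_rq)) for (r in seq_len(p$n_replicates)) {
    ct_ctl <- p$control_ct + stats::rnorm(1, 0, p$noise_sd)
    ct_tgt <- p$control_ct + p$base_delta - log2(true_rq[[s]]) +
      stats::rnorm(1, 0, p$noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, target = c(control_gene, target), replicate = r,
      ct = c(ct_ctl, ct_tgt))
  }
  qpcr_plate(do.call(rbind, rows), control_gene = control_gene,
             calibrator = calibrator)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between a clustering and reference
#' labels, corrected for chance; 1 = identical partitions, ~0 = random.
#' Used to score archetype recovery of the trajectory clustering on
#' synthetic data.
#'
#' @param a,b label vectors of equal length
#' @return the adjusted Rand index
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
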