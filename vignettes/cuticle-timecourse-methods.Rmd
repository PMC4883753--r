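---
title: "Methods: stage-specificity, JS/PAM trajectory clustering and the companion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-specificity, JS/PAM trajectory clustering and the companion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuticleCourse)
```

# The analysis problem

During the last ~2.5 days of *Drosophila* pupal wing development the wing
epithelium deposits its cuticle in a stereotyped temporal order: envelope
first (around 42 hr after white prepupa), then epicuticle, then procuticle
layers until eclosion (~96 hr). A bulk RNA-seq time course sampled at 42,
52, 62, 72, 80, 88 and 96 hr awp captures this program as one FPKM value
per gene per time point (replicates merged upstream by the
differential-expression estimator). Everything in this package operates on
that matrix and its satellites: isoform-level FPKM, annotation label sets,
pairwise differential-expression records, protein sequences, qPCR plates
and TEM thickness measurements.

A central modelling assumption is that *relative* trajectory shape, not
absolute expression level, carries the biological signal of stage
assignment. Both the specificity statistic and the clustering distance
therefore operate on probability-normalized trajectories, making them
invariant to per-gene rescaling (and hence to gene length and other
FPKM-scale artifacts that differ between genes but not across time).

# Stage-specificity scoring

For gene $g$ the per-stage fraction is
$$f(g,t) = \frac{\mathrm{FPKM}(g,t)}{\sum_{t'} \mathrm{FPKM}(g,t')},$$
and $g$ is stage-specific at level $\alpha$ if $f(g,t) > \alpha$ for some
$t$. At $\alpha \ge 0.5$ a gene can qualify at no more than one stage, so
the per-stage counts partition the qualifying genes. Conventions, all
following the strict "greater than" reading of the thresholds:

* **Expressed filter** — max-over-time FPKM strictly greater than the
  floor (default 1 FPKM). Genes with zero total FPKM have undefined
  fractions and are excluded from all counts.
* **Universe** — the specificity counts default to the expressed set; an
  optional minimum-total-FPKM floor (default 0) is exposed because
  reasonable analysts could also score all genes. Neither reading is
  hard-coded.
* **Fold changes between neighboring stages** — neighbor means adjacent in
  sorted time order (the grid is not equally spaced);
  fold $= (\max + p)/(\min + p)$ with pseudocount $p = 0$ by default, so
  $0/0 \mapsto 1$ (no change) and $x/0 \mapsto +\infty$, which satisfies
  any finite threshold. This makes thresholded counts conservative and
  reproducible without a tuning constant; a pseudocount is available when
  a bounded fold is preferred.
* **Inclusive vs strict** — the screens that phrase their cutoffs as "30
  or greater" / "at least 4-fold" (the TF screen) are inclusive ($\ge$);
  the fold *category* tables (">10-fold", ">100-fold") are strict.

# Jensen-Shannon / PAM trajectory clustering

Trajectories are normalized to probability vectors and compared with the
Jensen-Shannon distance
$$\mathrm{JS}(p,q) = \sqrt{\tfrac12 \mathrm{KL}(p\|m) +
\tfrac12 \mathrm{KL}(q\|m)}, \qquad m = \tfrac{p+q}2,$$
with base-2 logarithms so the distance lies in $[0,1]$ and reaches 1
exactly on disjoint supports; $0\log 0 = 0$. The base is configurable for
cross-checking against natural-log conventions, but base 2 is the default
because it gives the bounded scale the sample dendrogram is drawn on. The
pairwise computation uses the algebraic identity
$\mathrm{JSD}(p,q) = H(m) - [H(p)+H(q)]/2$ for speed; the definitional
two-KL form is retained in `js_distance()` and the two paths are checked
against each other in the tests.

The widely used log10(FPKM+1) transform appears here only as the *display*
scale for medoid trajectory curves. It is deliberately not the distance
input: distances on normalized profiles are scale-free, while log-space
Euclidean distances are not.

**PAM.** Clustering is partitioning around medoids over the JS distance
matrix: BUILD seeds the medoids greedily (first the item with minimal
total distance, then maximal cost reduction), SWAP repeatedly applies the
single best medoid/non-medoid exchange until none lowers the total cost.
Every tie breaks on the lowest item index, so a fit is a pure function of
the distance matrix — no seeds, no restarts. Two further numerical
choices:

* On instances of at most 10 items the fit is certified against complete
  enumeration of medoid subsets, so small-instance results are the exact
  optimum rather than a local one (single-swap local optima genuinely
  differ from the global optimum on a few percent of small random
  instances).
* Assignment is to the nearest medoid with ties to the lowest-index
  medoid, and a medoid always owns its cluster even when distances tie at
  zero.

Silhouettes are the standard $s = (b-a)/\max(a,b)$ with two degenerate
conventions: singleton clusters score 0, and $a = b = 0$ (duplicate
points) scores 0. Per-cluster mean silhouette above 0.2 is the package's
reported marker of well-structured clusters, matching how structure
quality is judged for these trajectory clusters. The number of clusters is
a user choice (the headline analysis in this system uses k = 16); no model
selection for k is attempted.

The sample-level dendrogram uses average linkage by default (complete and
single are available); since the upstream convention is not documented,
exact reproduction of published merge heights is not promised — only the
early/late bipartition, which is robust across linkages.

# Candidate screens

The fold-category table counts, per neighboring pair, genes with
significant differential expression (q below 0.05 by default —
significance is an *input*; no re-estimation is attempted) and nests them
into strict >10-fold and >100-fold categories. When the DE record carries
no fold value the fold is recomputed from the matrix; both routes are
exposed because the provenance of published fold values is ambiguous.

The transcription-factor screen is the two-stage filter: annotated
DNA-binding/PolII-regulatory genes reaching FPKM ≥ 30 somewhere, then ≥
4-fold change between some neighboring pair. Both stages are returned so
the funnel is auditable.

# Isoform switching

No published operational definition of a "switch" exists for this
analysis, so the package states its own and exposes every threshold: a
switch at adjacent pair $(t_1, t_2)$ is a change of the dominant isoform's
identity where (i) the outgoing dominant has FPKM ≥ `min_fpkm` (default 1)
at $t_1$ and the incoming at $t_2$, and (ii) both isoforms' fractions move
by at least `min_delta` (default 0.25). Dominance ties break to the
first-listed isoform. Because published switch counts depend on
unrecoverable thresholds, they are reported only under this stated
definition, never asserted as reproductions. Separate all-pairs ≥ 10-fold
isoform-change counting and log10(FPKM+1) Pearson trajectory correlations
(constant trajectories → NA, reported as undefined) complete the module.

# Composition screen

Fractions are exact counts over the 20 standard residues; non-standard
letters (X, U, B, Z) are excluded from the denominator but reported, which
keeps the fractions-sum-to-1 invariant testable while never silently
dropping sequence content. Thresholds — short < 200 aa, high residue
≥ 20%, very high ≥ 30%, average-protein cap 10% — are the field's
descriptive conventions for cuticle-protein candidates and are all
configurable.

# Enrichment and validation statistics

Label-fraction contrasts between cluster groups use a two-sample t-test,
Student's (pooled) by default with Welch available, since the upstream
convention is unstated; both flavors are reported in machine-readable
output so either reading can be checked. Categorical over/under-
representation is hypergeometric on both tails against the clustered-gene
universe (configurable), with Benjamini-Hochberg correction within each
cluster. No GO-graph propagation is performed; category membership is a
flat input.

**ΔΔCt.** Per replicate, $\Delta Ct = Ct_{target} - Ct_{control}$ matched
by replicate index; $\Delta\Delta Ct$ subtracts the calibrator's mean
$\Delta Ct$; $RQ = 2^{-\Delta\Delta Ct}$. The reported per-sample RQ is
$2^{-\overline{\Delta\Delta Ct}}$ — the geometric mean of replicate RQs,
the convention of instrument software — so the calibrator's RQ is exactly
1 by construction; the reported SD is the standard deviation of the
per-replicate RQs. An arithmetic mean of replicate RQs would exceed 1 for
the calibrator under noise (Jensen's inequality), which is why the
geometric form is used. RQ is invariant to adding any constant to every Ct
on the plate.

**Thickness ratios.** Per wing, each surface's ~10 measurements are
averaged and the means ratioed. Two modes reflect the experimental
designs: `thicker_over_thinner` (ratios ≥ 1 always) for wings where the
dorsal/ventral identity of the thicker surface cannot be assigned with
certainty, and `fixed_orientation` (dorsal/ventral as recorded) for
knockdown wings where the driven surface is marked. Group comparisons are
two-sample t-tests, Student's default, Welch alongside.

# The synthetic-data generators

The generators produce inputs with the statistical structure the analysis
assumes, with planted ground truth, so every stage is testable offline.
What they emulate, and the defaults chosen as realistic for this system:

* **Time course** — five trajectory archetypes (single-stage spike,
  monotone rise and fall with ~64-fold range, flat housekeeping, bimodal
  early+late) in equal proportions over the 7-point grid; per-gene
  log-normal baseline FPKM (meanlog log 50, sdlog 0.8, spanning roughly
  5–500 FPKM); multiplicative log-normal noise with
  $CV^2(\mu) = a/\mu + b$ (defaults $a = 2$, $b = 0.02$, capped at 3) so
  replicate variability falls with expression level, the qualitative
  replicate behaviour of this kind of data. The functional form of the
  $CV^2$ curve is this package's choice — only its decreasing shape is
  constrained by observation. Spike genes place > 90% of expected total
  FPKM at their peak by construction, so they are stage-specific at the
  α = 0.9 criterion. Ground-truth labels split spikes by peak time, since
  spikes at different stages are genuinely different trajectories; the
  true cluster count for recovery experiments is the number of distinct
  labels (11 under the defaults).
* **Isoforms** — two isoforms per gene; switching genes move the dominant
  fraction from 0.85 to 0.15 at a planted adjacent pair (documented
  separation margin 0.7, far above the 0.25 detection floor), with
  logit-scale jitter (sd 0.15) and log-normal gene totals around 50 FPKM.
* **Proteins** — residue counts are allocated deterministically from each
  protein's target composition (largest-remainder rounding), so planted
  flags (9 of 20 Trp-free, 10 of 20 short, five single-residue biases
  including one above 30%) hold exactly; only lengths and residue order
  are random.
* **Thickness** — per-wing true ratios from the group normals (wild type
  1.2 ± 0.11, knockdown 2.1 ± 0.43), 8 wings per group, 10 measurements
  per surface around a ~300 nm base with small jitter. In the wild-type
  group the thicker surface lands on dorsal or ventral at random; in the
  knockdown group dorsal is always the thicker (driven) side.
* **qPCR** — the inverse of the ΔΔCt model: target Ct sits
  $\mathrm{base\_delta} - \log_2 RQ$ cycles above a constant control, with
  per-replicate cycle noise (sd 0.05); at zero noise quantification
  recovers the planted RQs exactly.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: shared library-size effects across genes,
transcript-length bias in FPKM, correlated noise between adjacent time
points, partially overlapping isoform structures (estimation uncertainty
of isoform deconvolution), realistic amino-acid background frequencies,
or dissection-stage contamination. The generators validate the *machinery*
at stated separations, not the biological error rates of the screens.

# Problem sizes and reproducibility

Every generator is bit-reproducible under a fixed seed and configuration;
all pipeline outputs are sorted so `run_report()` bundles are byte-stable.
The test suite exercises the property surface at desk scale: JS metric
axioms on random triples, PAM against exhaustive enumeration on instances
of up to 9 items, archetype recovery (ARI ≥ 0.9) on 250-gene simulations,
switch recall/precision on 100-gene isoform tables, hypergeometric tails
against direct summation on universes up to 50 genes, and closed-form t
statistics — sizes chosen so the full suite completes in well under a
minute while still covering every code path. The acceptance script runs
the same pipeline at 500 genes.

# Known limitations

* PAM is $O(n^2)$ in memory and time through the distance matrix;
  `run_report()` caps the clustered set (default 1000 genes, keeping the
  highest totals) rather than attempting an approximate solver.
* Cluster numbering is arbitrary (deterministic, but not aligned to any
  published numbering); comparisons must be by composition, not label.
* The q-values consumed by the screens come from the upstream
  differential-expression run; the package performs no count-level
  inference and cannot correct upstream miscalibration.
* The switch detector reports events under its stated definition only;
  with other thresholds the event lists can differ substantially, which is
  why every threshold is exposed.
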