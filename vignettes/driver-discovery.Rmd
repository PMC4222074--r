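---
title: "Copy-number-driven driver discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-driven driver discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnadrivers)
```

# The scientific problem

Tumor genomes accumulate many copy-number alterations (CNAs), most of
them passengers. A *driver* gene is one whose recurrent copy-number gain
(or loss) propagates to its own expression and, through shared pathways,
to the expression of many other genes. `cnadrivers` implements an
integrated search for such drivers from three paired tumor/normal data
layers — probe-level aCGH log2(T/N) profiles, a gene expression matrix and
a miRNA expression matrix — together with histology labels
(adenocarcinoma AC, squamous-cell carcinoma SCC, large-cell carcinoma
LCC), the setting in which this class of analysis is typically run for
non-small-cell lung cancer.

The search proceeds in three steps:

1. **Recurrent CNA regions.** Each subject's profile is segmented and
   aberrations are called with fixed thresholds (amplitude at least 0.15
   in |log2 ratio|, per-segment FDR below 1e-5, at least 10 probes, at
   least 1 kb). Regions altered in at least 10% of subjects (among
   subjects with at least one call) are recurrent; regions mixing
   amplifications and deletions are excluded (strictly for genes; miRNAs
   tolerate a minority polarity below 10%). Genes in the surviving
   regions are candidate drivers.
2. **Initial modules.** Candidates are filtered on expression
   variability (SD at least 0.25), a one-sided Welch test of altered vs
   copy-neutral subjects (p below 0.05 with fold change above 2 for
   genes; p below 0.01 and no fold-change rule for miRNAs) and
   sign-consistency of the altered subjects' expression. Every remaining
   gene is a candidate target and joins the candidate driver it is most
   strongly correlated with, requiring raw p below 0.001.
3. **Final modules.** Each module is refined by rank-1 sparse canonical
   correlation analysis between the driver block and the target block;
   targets with zero canonical weight are dropped. Drivers passing the
   final thresholds (fold change above 4, p below 0.001 — gene regime
   only) are ranked by refined module size, the working proxy for a
   driver's importance.

Downstream, drivers are validated predictively (rank-based AUC against
histology with a Monte-Carlo null of random genes), a 15-gene
L1-penalized histology signature is built and tested against 1000 random
signatures, and each driver's target set is tested for
over-representation of functional-network links to pathway gene sets
(network enrichment analysis, NEA).

# Segmentation and calling

Profiles are segmented per chromosome by circular binary segmentation:
the candidate split is the circular arc maximizing a mean-shift t-like
statistic, accepted when its permutation p-value is below `alpha`
(default 0.01, 1000 permutations, early stopping disabled, minimum
segment width 2 probes). The permutation statistic scales the mean
difference by the arc-size factor only, since the overall variance is
permutation-invariant. The scan is O(n²) per permutation and is
implemented in C++; a 50-probe chromosome scans in a few milliseconds.

Two calling regimes share this segmentation:

* **Noise-adaptive calls** (`call_aberrations()`): a segment is called
  when it has at least 3 probes and its |mean| exceeds the profile's
  internal noise, defined as one fourth of the median absolute
  difference between consecutive probe log2 ratios (within chromosomes,
  pooled). Amplifications are gains with mean above 1.0 log2 units.
  These calls feed the histology-differential ANOVA.
* **Fixed-threshold calls** (`call_cna_dgs()`): the four conjunctive
  conditions listed above. The per-segment FDR is computed as a
  two-sided one-sample t-test of the member probes against zero,
  BH-adjusted within the profile — the filter is stated by the method but
  its computation is not, so this is the package's documented choice
  (per-profile adjustment; a cohort-wide variant would only make the
  filter stricter). Inequalities follow the printed wording: "less than
  10 probes ... filtered out" keeps exactly the segments with 10 or
  more.

Segment bounds are reported both closed on probe positions (SEG
convention) and half-open (`end_open`, the next segment's first probe
position), so that cohort-level interval arithmetic is exact: with zero
probe noise the recovered region bounds equal the planted ones base for
base.

# Recurrent regions and differential clusters

Region boundaries are not prescribed by the method's description, so the
package uses the most conservative reading: the genome is atomized at
the union of all call breakpoints and maximal runs of atoms with a
constant per-subject state assignment are merged. This definition has an
exact per-base brute-force oracle against which it is tested. The
recurrence denominator is the number of subjects with at least one call
anywhere; the count threshold is `round(0.10 × n)` with half-up
rounding, which reproduces the reference arithmetic in which 12 of 121
subjects qualifies at "10%".

The histology ANOVA runs on the segmented dataset: one value per
(region, subject) — the mean segment value over the subject's probes in
the region — with a one-way F test across AC/SCC/LCC and BH adjustment
across regions (significance at FDR below 1e-5). Adjacent significant
regions merge into clusters while every (state, histology) aberration
frequency stays within 1 percentage point of the cluster's *first*
region; anchoring to the first region rather than the previous one
prevents slow drift across a long cluster. Both the anchoring and the
tolerance are configurable.

# Driver filters and sparse CCA

Fold change is computed on the linear scale as `2^(Δ mean log2)`; the
altered-vs-"non-mutated" comparison treats every subject that is
copy-neutral *at that region* as non-mutated, even if altered elsewhere.
"Consistent over-expression" is operationalized as at least 90% of
altered subjects having expression of the polarity's sign — strict 100%
concordance would reject true drivers on the strength of a single noisy
subject; the threshold is configurable (including a strict mode).
Correlation is Pearson on log2 ratios (Spearman by flag), with t-based
two-sided p-values; ties in the initial module assignment go to the
lexicographically first driver id.

The sparse CCA refinement uses alternating soft-thresholded power
iterations on the cross-covariance. Two regimes are distinguished:

* **No penalties, more subjects than features**: the blocks are whitened
  by their inverse covariance square roots, so the leading singular pair
  is exactly classical CCA (verified against `stats::cancor` to 1e-6).
* **Penalized (or singular)**: within-block covariances are treated as
  identity — the penalized-matrix-decomposition formulation, the standard
  choice when features outnumber subjects. Penalties are expressed in
  [0, 1], 0 meaning no constraint and 1 maximal sparsity; internally the
  L1 bound on a weight vector of length p is `sqrt(p) − penalty (sqrt(p)
  − 1)`, enforced by binary search on the soft threshold.

When no penalty is supplied, the target-side penalty is selected by a
permutation gap criterion: over a small grid, the canonical correlation
on the real data is compared with its mean over subject-permuted target
blocks, and the penalty with the largest gap wins (fixed seed). The
iteration starts from the leading singular pair of the cross-covariance
and is deterministic; non-convergence raises a typed condition carrying
the last iterate.

# Predictive validation

AUC is the Mann-Whitney statistic with midrank ties. The 15-gene
classifier is an L1-penalized logistic regression (glmnet path): in each
stratified fold the regularization is chosen so the active set has the
requested size, out-of-fold linear predictors are standardized within
the fold (a monotone transform that stops fold-specific scale from
leaking rank structure) and pooled into one cross-validated AUC; the
reported signature is the full-data active set at the matched size.
Pooling was chosen over fold-averaging as the lower-variance estimate at
cohort sizes near 100; an important caveat, quantified in the test
suite, is that forcing the active set to a fixed size leaves substantial
selection variance in any single null CV-AUC (sd ≈ 0.1) because
overlapping training folds select nearly the same spurious features.
The Monte-Carlo significance test absorbs this by construction: random
signatures are scored with the *identical* protocol, so observed and
null AUCs are exchangeable under the null and the add-one p-value
`(1 + #{null ≥ observed})/(n_draws + 1)` is exact (and never zero,
matching the convention of reporting "p < 0.001" at 1000 draws).
Single-feature validation draws random *features* rather than permuting
labels, mirroring the "AUCs of 1000 random genes" design, and folds the
statistic around 0.5 by default. The regional-amplification check used
for external-cohort style validation is a one-sided one-sample t-test of
windowed probe intensities against the standardized global mean.

# Network enrichment

The functional network is an undirected simple graph. The enrichment
statistic for a (target set, pathway) pair is the number of edges with
one endpoint in each set, counting an edge inside the intersection once
(a double-count mode exists). The null preserves the degree multiset by
double-edge-swap rewiring (10 swap attempts per edge per permutation);
z-scores and one-sided add-one p-values come from the permutation
distribution, with BH adjustment across testable pathways. A closed-form
mode approximates the expectation under the configuration model with a
Poisson upper tail — faster but cruder; the test suite cross-checks that
both modes agree on which pathway is most enriched. Because link counts
are integers, permutation ties make the p-values conservative: they are
super-uniform (never anti-conservative), not exactly uniform, and the
calibration tests check precisely that one-sided property. Target sets
for NEA are trimmed to roughly 100 genes by choosing the smallest
correlation cutoff on a grid whose count fits; miRNA target sets bypass
the correlation filter, since miRNA-target expression need not be
correlated.

# The synthetic cohort

`generate_cohort()` draws the cohort all downstream stages are tested
on. It emulates: recurrent amplified/deleted regions carried by a
configurable fraction of subjects (probe log2 ratios offset by the
region amplitude inside the region, i.i.d. Gaussian probe noise —
matching the consecutive-probe-difference noise statistic); driver genes
whose expression is a copy-state effect plus noise; target modules whose
members load on a standardized copy of the driver signal so the
*population* driver-target correlation equals `module_corr` exactly;
histology labels with fixed composition; and optional histology-biased
carrier fractions. Defaults are the package's reference study
conditions: 120 subjects, 5 chromosomes × 50 probes at 10 kb spacing,
2000 genes, 80 miRNAs, histology 46% AC / 41% SCC / 13% LCC, probe noise
sd 0.1, expression noise sd 0.3, module correlation 0.6, three amplified
driver regions (carrier fractions 0.35/0.30/0.25, expression effect 2.5
log2 units ≈ fold change 5.7, modules of 150/150/120 targets, one region
histology-biased towards SCC), one amplified miRNA-driver region, and
one deletion region without an expression-coupled driver. Thirty
background genes carry a histology main effect of 0.6 log2 units —
single-gene AUC ≈ 0.9, strong but not perfect markers, so the 15-gene
signature task is non-degenerate in both directions: informative genes
exist, yet no single random gene separates the classes outright.
Bystander genes inside regions respond only weakly to copy state
(0.5 log2 units per copy state — a dosage response below the fold-change
filter), which is what the expression filters must reject.

What the generator does *not* emulate: GC/wave artifacts and spatially
correlated probe noise, dye effects, subclonality and tumor purity
dilution, copy-neutral LOH, and expression networks beyond the
single-latent-factor module structure. Passing the planted-recovery
tests therefore shows the algorithmic chain is correct and calibrated
under its own assumptions, not that real cohorts of this design will
yield equally clean driver lists.

One global seed drives everything; stage-level streams are derived from
it by a labelled hash (`derive_seed()`), so any stage can be rerun
independently and reproducibly.

# Numerical choices and degenerate inputs

* Threshold comparisons are strict exactly as printed (FDR < 1e-5,
  p < 0.001, fold change > 4); amplitude and size thresholds are
  inclusive (≥ 0.15, ≥ 10 probes, ≥ 1 kb, SD ≥ 0.25).
* Zero-variance segments get p = 0 (nonzero mean) or 1; constant
  features are excluded from correlation (NA) and rejected by the AUC
  test with an explicit error; an all-tied score vector has AUC 0.5.
* The CBS scan declines to split constant sequences or any piece
  shorter than twice the minimum width; equal maximal arcs resolve to
  the first in scan order, deterministically.
* Monte-Carlo p-values use the add-one rule throughout, so they are
  never exactly zero and remain valid at any number of draws.
* The recurrence threshold uses half-up rounding of
  `min_recurrence × n` (banker's rounding would silently drop boundary
  cohorts).

# Problem sizes in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
reference cohort above (120 subjects, 250 probes, 2000 genes); a full
pipeline pass takes a few seconds on one core. The test suite uses a
40-subject, 200-gene variant of the same design for unit-level checks
and reserves the full-size cohort for the end-to-end planted-recovery
property (20 replicate seeds). Null-calibration checks use 200 simulated
nulls with reduced draw counts (19-39), which is sufficient to detect
anti-conservatism at the tested levels.

# Known limitations

* A single CBS engine serves both calling regimes; no alternative
  robust smooth-segmentation engine is provided. The driver-search
  filters consume only segment attributes (mean, probe count, length,
  FDR), which the CBS segments supply.
* The per-segment FDR definition, the region-boundary rule, the
  consistency rule, the cluster-merge anchoring and the sparse-CCA
  penalty form are all under-specified by the method's published
  description; each implemented choice is documented above and
  configurable where alternatives are defensible.
* `nea_test`'s binomial mode ignores degree correlations and
  intersection structure beyond a first-order correction; use the
  permutation mode for inference.
* The pipeline assumes expression and copy-number matrices are already
  normalized log2(T/N); no normalization is performed in-package.
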