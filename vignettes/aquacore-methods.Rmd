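---
title: "Methods: core clades, niche-adaptive genes and productivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core clades, niche-adaptive genes and productivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquacore)
```

# Scope

aquacore asks two questions about aquaculture microbiomes. First, does the
farm environment *select* microbial lineages — are host-associated sequences
phylogenetically distinct from the surrounding seawater, and are there core
clades conserved across farms worldwide? Second, does community composition
*predict* productivity — can the survival rate of larvae, or the body weight
of adults, be predicted from a sample-by-ASV abundance table, and how does
that predictive power behave under permutation nulls and growing sample
sizes?

The package operates strictly downstream of sequence processing. Its inputs
are (i) a rooted phylogeny with per-tip metadata (source class and culture
occurrence), (ii) sample-by-feature abundance tables with sample metadata,
and (iii) genome-by-gene-family presence/absence matrices with genome
metadata. Amplicon denoising, tree building, and protein clustering are
upstream tools' jobs; their outputs are this package's starting point.

# Phylogenetic niche separation (MPD and NRI)

`mpd_between()` computes the observed mean pairwise patristic distance (oMPD)
over all *cross-class* tip pairs — every (host, environment) pair — and
deliberately excludes within-class pairs: the question is how far
host-associated sequences sit from environmental ones, not how clustered
either class is internally.

`nri_test()` builds the null by reshuffling source-class labels across tips
with class sizes held fixed, recomputing the MPD each time (default 1000
permutations). The net relatedness index is the standardised effect size

$$\mathrm{NRI} = \frac{\mathrm{oMPD} - \overline{\mathrm{rMPD}}}{\mathrm{sd}(\mathrm{rMPD})},$$

reported so that a *positive* NRI means the observed separation exceeds the
null mean. This is the negative of the sign convention common in community
phylogenetics, where NRI is defined for within-community clustering; the
sign is chosen here so that "larger = more niche separation" reads naturally
for the between-class question. The p-value is one-sided (upper tail,
separation greater than chance) with the add-one correction
$p = (1 + \#\{\mathrm{rMPD} \ge \mathrm{oMPD}\})/(n_{perm}+1)$, so it is
never exactly zero. A degenerate null (zero spread, e.g. an equal-length star
tree where every labelling gives the same MPD) is an error, not a silent
infinity.

Because the statistic is standardised, NRI is invariant to rescaling all
branch lengths, which the test suite checks. Under random labels the NRI is
approximately standard normal; the suite verifies |mean| < 0.2 and a standard
deviation within [0.7, 1.3] over 200 replicate label draws (the estimate of
the null sd from a finite number of permutations inflates the spread slightly
above 1).

# Core-clade detection

`find_core_clades()` scans every candidate clade — all non-root internal
nodes with at least `min_tips` tips (default 2); the candidate set is a
design choice, and the Bonferroni factor *m* is the number of candidates —
against three criteria:

1. **Enrichment.** Host-derived tips are modelled as binomially distributed
   across the tree with global fraction $p$ = overall host-tip share. A clade
   with $k$ host tips out of $n$ gets the one-sided upper tail
   $P(X \ge k \mid n, p)$, Bonferroni-adjusted; adjusted $p < \alpha$
   (default 0.05) passes.
2. **Ubiquity.** The union of cultures over the clade's host tips must cover
   at least `ubiquity_min` (default 80%) of all sampled cultures.
3. **Homology.** The clade's diameter — its maximum within-clade patristic
   distance — must be at most `tol`. The default `tol = 0` demands zero
   branch length (100% sequence identity); an epsilon such as 1e-9 is
   appropriate for trees whose zero lengths have passed through floating
   point.

Nested clades that all pass collapse to the maximal (most tip-rich) one, so
a core clade is reported once rather than once per internal node it
contains. When an abundance table is supplied, each clade's maximal
per-sample summed relative abundance is attached — the quantity used to size
clades when plotting their distribution across farms.

# Occupancy power law

`occurrence_spectrum()` tabulates $N(f)$, the number of phylogenetic
clusters occurring in exactly $f$ cultures; `fit_power_law()` fits
$N(f) \propto f^{-a}$ by ordinary least squares of $\log N$ on $\log f$ over
the non-zero points (at least 3 required), reporting the exponent as the
magnitude $a$ of the slope. The fit is on the binned spectrum, not
rank-frequency: $f$ is a small discrete quantity (a cluster can occupy at
most all sampled cultures, 12 in the motivating dataset). A large $a$ means
occupancy falls off steeply — the community is dominated by a few nearly
ubiquitous clusters. On noiseless log-linear input the slope is recovered to
1e-9; on multinomial samples of 5,000 clusters at $a = 3.6$ the mean
estimate over 20 seeds lands within ±0.3 (small-count noise at the sparse
tail biases individual fits).

# Source-tracking similarity trajectories

`source_trajectory()` follows larval communities across developmental stages
and scores, per stage and candidate source, the mean Bray-Curtis similarity
$1 - \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on relative abundances, and
the shared-feature fraction. Two conventions are deliberate:

* **Shared fraction = Jaccard of supports** (intersection over union of
  detected features, presence = abundance > threshold, default any non-zero
  read). Intersection over larval richness alone was the other candidate;
  union was chosen because it is symmetric in larvae and source.
* **Per-stage source means.** Larvae at a stage are compared against the
  source's mean composition (at that stage if the source table carries stage
  metadata, else its overall profile). A `mode = "pairwise"` flag averages
  over all larva-source sample pairs instead, for data where source
  replicates are meaningful.

Feature universes are unioned with zero fill, so a source missing some ASVs
is not an error — absence is data.

# Niche-adaptive gene sweeps

`find_sweep_genes()` screens a binary genome-by-family matrix for families
with the sweep signature, within each clade group (e.g. taxonomic order):
present in **all** focal genomes of the group, and present in strictly less
than `max_bg_prev` (default 10%) of the group's background — the non-focal
genomes whose genus matches a focal genus. The strict inequality matters: a
family at exactly 10% background prevalence is excluded. Pooled mode applies
the rarity bound to the pooled background; `per_genus` mode requires it
within every genus separately — the stricter reading of "rarely present in
other genomes of the same genera". Both are exposed because the filter's
published description admits either; neither is asserted as canonical.
The scan is a per-column filter, so it provably equals a brute-force loop
over families (tested), is monotone in `max_bg_prev`, and is invariant to
row and column order.

# Predictivity evaluation

`evaluate_predictivity()` quantifies how much of a phenotype (survival rate,
body weight) composition explains, by leave-one-out cross-validation: the
regressor is fitted $n$ times, each time predicting the single held-out
sample, and predictive power is the $R^2$ of the linear regression of
observed on predicted values — the squared Pearson correlation. Constant
predictions score 0 by convention; the anti-correlation quirk (a strongly
*negative* association also yields a high $R^2$) is inherited from this
definition and documented rather than patched.

The default model (`model_config()`) is a random-forest regressor with the
classic regression defaults — 500 trees, $\lfloor p/3 \rfloor$ features per
split. The default engine is ranger, a fast implementation of the same
algorithm; the randomForest package is available as an engine, and gradient
boosting (xgboost) and lasso (glmnet) sit behind the same contract so model
families can be compared like for like. On the package's planted nonlinear
signal the tree ensembles beat the lasso, which the suite checks — the
generator's signal (saturating terms plus an interaction) is chosen
precisely so that nonlinear learners have something to find.

Supporting analyses:

* `permutation_null()` reshuffles the outcome vector (default 100 times),
  recomputing the **full** LOO $R^2$ each time; the empirical p uses the
  add-one correction. No information leaks from a sample's outcome into its
  own prediction — a leakage test corrupts one outcome and asserts the
  held-out prediction is bit-identical.
* `learning_curve()` draws, per subset size (default 40 to 110 in steps of
  10), `reps` random subsets without replacement and runs full LOO within
  each. The trend is summarised by OLS of the per-size mean $R^2$ on size,
  scaled to `slope_per_10` — the gain in $R^2$ per 10 added samples. The
  mean-per-size regression (not all points pooled) defines the slope;
  subsets are uniform, not stratified by outcome.
* `rank_features()` fits once on all samples and reports normalised
  importances (impurity for forests, gain for boosting, |coefficients| for
  lasso), ties broken by feature id.

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of its parameters and a seed, and each
plants a known ground truth so the pipeline can be scored end to end:

* `simulate_tree()`: Yule topology, iid exponential branch lengths (mean 1).
* `plant_core_clades()`: defaults plant 3 clades of ~12 tips in a 500-tip
  tree, all-host, all-culture, zero diameter, over a background whose tips
  are host with probability 0.3. These defaults are a deliberate power
  calculation: a fully host-labelled 12-tip clade at a global host fraction
  near 0.36 has binomial tail ≈ 4e-6, surviving a Bonferroni correction over
  ~500 internal nodes with two orders of magnitude to spare, so recovery
  failures indicate implementation defects, not underpowered simulation.
* `simulate_occurrences()`: occupancy drawn from $P(f) \propto f^{-a}$,
  default $a = 3.6$, $f \in 1..12$.
* `simulate_survival_data()`: log-normal compositions closed to 1; survival
  = sum of saturating (Monod-type) terms over 5 signal features plus one
  pairwise interaction, rescaled to mean 0.55 / sd 0.12 (non-collapsed tanks
  span roughly 30–80% survival), Gaussian noise (default sd 0.05), clipped
  to [0, 1]. An optional collapse regime forces a designated pathogen-like
  feature above 50% relative abundance and survival to ~0 in a chosen
  fraction of tanks (default datasets use 130 tanks, emulating 13/130
  collapses when enabled).
* `simulate_gene_matrix()`: two clade groups with 5 + 4 focal isolates (one
  per genus, 12 congeneric background genomes each); 8 planted sweeps with
  realised background prevalence strictly below 10%; ~2,000 decoys at
  background rates 0.2–0.9. Decoys that would satisfy the sweep criterion by
  chance have one focal entry cleared, so the planted set is exactly the
  ground truth.
* `simulate_stage_series()`: larvae = $w(s)\cdot$feed $+ (1-w(s))\cdot$
  seawater with multiplicative log-normal noise and closure, $w$ linear 0 to
  1 over 9 stages by default; the two source profiles have partially
  overlapping supports.

What these simulations do **not** contain: read-level sequencing error,
compositional zero inflation beyond what log-normal sparsity induces, batch
and site effects, phylogenetic correlation between abundance and tree
position, or any real taxonomic structure. Passing tests therefore
demonstrate that the estimators recover what was planted under their own
model assumptions — not that real shrimp-farm data will be as kind. What the
shipped tests and the acceptance script do establish on these simulations:
exact recovery of planted core clades and gene sweeps, an occupancy exponent
recovered to within sampling error of its true value, a calibrated NRI null,
and a permuted-outcome LOO $R^2$ whose mean stays below 0.05 while the
planted signal remains strongly predictable.

# Numerical choices and problem sizes

* Newick output is written at 15 significant digits so tree round trips
  preserve distances to 1e-12; the stock writer truncates at 10.
* `tol = 0` for clade homology by default, with 1e-9 suggested for trees
  that have been through floating-point arithmetic.
* Permutation p-values always use the add-one correction.
* All seeded entry points save and restore the caller's RNG state, and heavy
  loops derive per-iteration child seeds, so results are bit-identical on
  repeat and independent of evaluation order.
* Problem sizes in the shipped tests and acceptance script are chosen to
  exercise the full evaluation designs at desk scale: permutation nulls use
  n = 100 samples x 100 reshuffles with 100-tree forests, learning curves
  n = 40..110 with 10 reps x 100 trees, single LOO evaluations the full
  500-tree default. Forest size mainly trades variance for time here; the
  null-mean bound and the curve's monotone trend are insensitive to it.

# Known limitations

* The enrichment model treats tips as exchangeable Bernoulli draws; it
  ignores phylogenetic autocorrelation of the labels, as does the motivating
  analysis.
* MPD uses a dense tip-distance matrix: memory is quadratic in tips, fine to
  ~20k tips, beyond which a streaming traversal would be needed.
* `evaluate_r2` rewards any strong linear association, including negative.
* The power-law fit is OLS on log counts; it is the field's convention for
  occupancy spectra but is a biased estimator at small counts compared with
  maximum likelihood on the discrete distribution.
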