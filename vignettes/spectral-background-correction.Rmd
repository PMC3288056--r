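---
title: "Background-calibrated spectral counting: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-calibrated spectral counting: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcproteome)
```

# The correction model

A plated subcellular fraction profiled by label-free spectral counting is
a mixture: genuine particle proteins plus two background components, the
plating matrix ("laminin") and co-purifying cytosol (high-speed
supernatant, HSS). Per protein $i$ the model is

$$\mathrm{gross}_i = \mathrm{true}_i + \mathrm{lam}_i + m \cdot \mathrm{hss}_i,$$

where $m$ is the unknown fraction of the HSS profile present in the gross
preparation. Matrix counts are subtracted one-to-one because the matrix
control is the same physical surface; the cytosolic component must be
*scaled*, and $m$ is estimated from calibration proteins known not to be
genuine components (serum proteins: abundant in fetal-brain cytosol,
absent from growth cones). For each calibration protein,
$m_i = \max(0, \mathrm{gcp}_i - \mathrm{lam}_i)/\mathrm{hss}_i$ is the
scaling that drives its net count exactly to zero; the pooled $m$ is the
unweighted arithmetic mean of the $m_i$. `compute_calibration_multipliers()`
also offers an HSS-spectra-weighted mean (off by default) and a switch
that ignores the matrix term during calibration, for data where the
matrix control was not subtracted upstream.

Proteins with $\mathrm{net}_i \le 0$ are excluded. Two numerical choices
matter here:

* the comparison is made on the raw, un-rounded values — flooring or
  rounding first would move proteins across the boundary;
* ties at exactly zero are excluded, so a calibration protein subtracted
  with its *own* multiplier is always removed. Under the pooled mean the
  calibration proteins retain small mean-zero residuals instead; that is
  inherent to averaging, not an implementation artifact.

The key model assumption is proportionality: every contaminant is assumed
present in the gross fraction and the HSS in the *same* proportion as the
calibration proteins. Under that assumption the residual net of any
contaminant has expectation zero. Two consequences are worth
understanding before interpreting recovery numbers:

* **spectra-weighted elimination is near-total** — the residual left on a
  contaminant is sampling noise of order $\sqrt{\text{counts}}$, so the
  *fraction of contaminant spectra removed* is close to 1 (the simulation
  stages of the test suite and `scripts/acceptance.R` measure it above
  0.95 at the default conditions);
* **protein-level exclusion of a non-calibration contaminant is close to
  a coin flip** — a mean-zero residual is $\le 0$ with probability only
  slightly above one half, so roughly half of the contaminant *species*
  survive with a handful of residual spectra. This is a property of any
  calibrated mean-zero subtraction, not of this implementation;
  `validate_elimination()` therefore reports both the per-protein status
  and the spectra-weighted summary.

# Abundance profiles

Net counts are a semi-quantitative abundance proxy; no length or
molecular-weight correction is applied (deliberately: counts are treated
as a rough abundance estimate, and corrections would not change
species-level conclusions). `top_proteins()` uses an inclusive threshold
(default 400 spectra) with lexicographic tie-breaks so output is stable
under row permutation. `group_spectral_fraction()` reports each
functional group's share of total net spectra; in partition mode the
groups must be disjoint and exhaustive and the shares sum to 100.
Percentages are rounded to one decimal in reports only; full precision is
kept internally.

# Over-representation statistics

For a term annotating $K$ of $N$ universe proteins, with $k$ hits in a
list of $n$:

* `fisher_exact()` is the upper-tail hypergeometric probability
  $P(X \ge k)$ (one-tailed Fisher exact);
* `ease_score()` is the jackknifed variant: one list hit is removed and
  $P(X \ge k-1)$ is computed against unchanged margins, so $k \le 1$
  scores exactly 1 and the EASE score is always at least the Fisher
  probability. This penalizes terms supported by one protein;
* `fold_enrichment()` is $(k/n)/(K/N)$ — over-representation of protein
  *species* relative to random expression, not abundance;
* the `% count` is $100\,k/n$;
* `benjamini_hochberg()` is the standard step-up FDR adjustment
  (delegated to `stats::p.adjust`), applied per annotation category over
  *all* tested terms (every term with at least one list hit) before any
  display filtering, so reported values do not depend on the `min_count`
  (default 5) and `ease_max` (default 0.1) report thresholds.

The universe is an explicit argument of `enrich()` because it materially
changes fold values and no offline default can reproduce a hosted
annotation service's species background. The pipeline exposes two
conventions: the union of all GMT members (default) or the detected net
proteome. Published analyses against genome-wide backgrounds are
therefore reproducible in *structure* here, but their exact p-values are
not — they depend on the annotation snapshot used at the time.

# Annotation clustering

Over-represented terms that annotate largely the same proteins are
grouped by `cluster_terms()`: membership agreement between two terms is
Cohen's kappa over the protein list (degenerate all-agree cases defined
as 1 for identical vectors, else 0), each term seeds a group of itself
plus its kappa-partners, seeds with fewer than `seed_min` partners are
dropped, and groups merge while they share at least `merge_overlap` of
the smaller group's terms. The stringency presets are
low (0.35, 2, 0.50), medium (0.50, 3, 0.50; the default) and
high (0.85, 4, 0.50); the medium triple follows the published defaults
of the clustering tool this emulates, the other two are package choices.
A cluster's enrichment score is $-\log_{10}$ of the geometric mean of
its members' EASE scores, computed by log-space summation so p-values
near $10^{-15}$ do not underflow; clusters are reported sorted by score
with unclustered terms returned as singletons.

# Transcriptome overlap

Published family tables list every member for which *either* protein or
transcript evidence exists, which creates two defensible denominators.
`overlap_stats()` defaults to: denominator = entries with positive net
spectra, numerator = all transcript-flagged entries. This is the single
convention that reproduces all three printed percentages of the bundled
panels (15%, 50%, 43%) including their zero-spectra, transcript-positive
rows; `include_zero` and `numerator = "detected_only"` expose the
alternatives. Percentages are rounded to the nearest integer, matching
how such overlaps are reported. `correlation_check()` tests abundance
against transcript detection with a rank-biserial statistic and a seeded
two-sided permutation test (default $10^4$ shuffles); constant spectra or
one-class labels are reported as undefined rather than forced to a
number.

# The synthetic generator

`synthetic_truth()` / `generate_dataset()` emulate the statistical
structure the correction assumes:

* within-pool relative abundances are Zipf with exponent $s = 1.1$,
  chosen so that a $10^5$-spectra run spans counts from single digits to
  thousands, the dynamic range typical of such experiments;
* gross counts are multinomial over
  $(1-\varphi)\cdot\text{true pool} + \varphi\cdot\text{HSS pool}$ with
  $\varphi = 0.3$ by default — a heavily contaminated preparation worth
  correcting; HSS and matrix fractions are independent multinomials, so
  column sums equal the configured depths exactly (default $10^5$ gross
  and HSS, $5 \times 10^3$ matrix);
* pool sizes default to 2000 true proteins, 300 contaminants, 50 matrix
  proteins;
* the two calibration contaminants occupy the top HSS abundance ranks —
  the analogue of choosing serum albumin: abundant calibrators give
  low-variance multipliers;
* the matrix fraction carries a 5% trace of the true pool (adsorbed
  genuine protein) but no contaminants, so the generator's exact zeroing
  ratio is $\varphi \cdot \mathrm{depth}/\mathrm{depth}_{hss}$ and
  multiplier recovery can be scored against a closed form;
* annotation terms are drawn over a 3000-symbol universe with planted
  terms realizing a target fold enrichment by construction
  (`round(f K n / N)` members from the list), and transcriptome panels
  get labels independent of abundance;
* one seed governs everything through deterministically derived per-stage
  substreams, and the generator is bit-reproducible.

What the generator does **not** emulate: peptide-level identification and
protein inference, shared peptides, protein-length bias in spectral
counts, correlated contamination (contaminants whose gross proportions
differ from the calibrators'), and annotation-term hierarchy. Passing
recovery tests therefore demonstrate correctness of the computation under
the model's assumptions, not robustness to their violation in real data.

# Validation design and problem sizes

The test suite checks every statistic against an independent route:
hypergeometric tails against direct summation of point masses (log-scale
binomials) over all margins up to $N = 60$ and against
`stats::fisher.test`; BH against a quadratic brute force; subtraction
against per-row recomputation, with monotonicity-in-$m$ and
net-below-gross properties; clustering against a planted family
partition scored by adjusted Rand index; permutation p-values against a
uniformity KS test under independence. Simulation-based checks use 10–20
seeds at gross depth $10^5$ and 100 null replicates for FDR control —
sizes chosen to make sampling error negligible relative to the margins
being asserted while keeping the default suite fast.

# Known limitations

* No uncertainty is attached to $m$ (the study design provides only two
  calibrators); a Poisson or negative-binomial count model would allow
  one but is out of scope.
* Protein-level contaminant exclusion is intrinsically ~50% for
  non-calibration contaminants (see above); interpretation of the net
  proteome should rely on the near-total spectra-weighted elimination
  and on the fact that surviving contaminant residuals are small.
* The enrichment stage takes term sets as given; no ontology-aware
  propagation or term filtering is performed.
* Run manifests record stage wall times, so manifests differ between
  reruns; all TSV products are byte-identical for identical input and
  config.
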