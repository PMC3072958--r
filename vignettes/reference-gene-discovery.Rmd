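---
title: "Condition-specific reference gene discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific reference gene discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstable)
```

## The problem

RT-qPCR quantification is normalized against internal-control ("reference"
or "housekeeping") genes that are assumed to be stably expressed. In
practice no gene is stable in every biological context: the commonly used
reference genes (GAPDH, ACTB, B2M, ...) are extremely highly expressed and
can vary strongly under particular tissues, developmental stages or
perturbations. `refstable` implements the alternative: mine a large,
uniformly normalized expression compendium for the genes with the *lowest
variance within the specific context of the planned experiment*, optionally
constrained to an expression range similar to that of the target genes, and
then validate the candidates in the RT-qPCR experiment itself.

## The stability model

All statistics operate on log2 signal. For a selection $S$ of arrays
(samples) chosen by annotation — a tissue, a stage, a perturbation — each
probe $g$ gets

$$\mathrm{sd}_S(g) = \sqrt{\tfrac{1}{|S|-1}\sum_{s\in S}
  \left(y_{gs}-\bar y_{gS}\right)^2},$$

the sample standard deviation of its log2 signal over exactly those arrays.
Probes are ranked ascending by $\mathrm{sd}_S$; ties break by probe id
(byte order) so rankings are reproducible across platforms and locales. The
search (`find_reference_genes()`) filters probes to an expression band
before ranking and returns the `k = 25` lowest-SD survivors, mirroring the
interactive tool behaviour this package reimplements.

Two auxiliary decisions deserve stating:

* **SD of log2 signal, not CV of linear signal.** Compendium-wide SD
  distributions (roughly 0.5–5 per probe) are consistent with log-scale
  variability, and log-SD makes stability independent of absolute
  abundance. The scale is tagged explicitly on every matrix
  (`expression_matrix(..., scale =)`) and enforced, because flat-file
  exports do not say which scale they store.
* **Band membership tests the probe's *median within the selection*,
  inclusive at both bounds.** The median is robust against the handful of
  outlying arrays that motivate reference-gene validation in the first
  place. The "medium" band offered by
  `expression_band_from_platform()` is the interquartile range of all probe
  medians, computed with linear-interpolation (type-7) quantiles — recorded
  because IQR banding depends on the quantile convention.

### Normalization convention

Compendia mixing many experiments are assumed to be cross-normalized by
global scaling: each array is multiplied so its trimmed-mean signal equals a
common target (default 1000). `global_scale()` reproduces this convention;
the trim fraction defaults to 0.02 per side (the Affymetrix scaling
convention, with the cut count floor-rounded), and is exposed because the
convention, not the data, fixes it. The operation is exact (the post-scaling
trimmed mean equals the target to machine precision), idempotent, and
independent across columns. Probe-level summarization, background
correction and batch correction are out of scope: the model here is a
curated compendium where scaling plus annotation-driven selection is the
whole normalization story.

Detection-call filtering (`detection_filter()`) keeps probes Present in at
least 10% of arrays (inclusive), with Marginal counting as not-Present.
It is optional because non-Affymetrix matrices carry no calls.

### Advisory selection size

`selection_advice()` flags selections smaller than 60 arrays or drawn from
fewer than 3 independent experiments (by `experiment_id`). These are
recommendations about estimator stability, not hard preconditions, so the
advice never blocks a search.

## Cross-context analyses

* `cross_condition_profile()` re-computes a candidate's SD within every
  category of an annotation axis, to catch genes that are quiet in the
  search context but responsive elsewhere. Categories with fewer than two
  samples are skipped and recorded. The "high variability" flag threshold
  defaults to 1.0 log2 units; this is a package convention (no principled
  universal value exists) and is a parameter.
* `top_n_overlap()` counts shared members of two contexts' top-N stable
  lists (N = 20 and 50 by default, via `overlap_matrix()`).
* `overlap_permutation_test()` asks whether one pair's overlap is high
  relative to other pairs. The null population is the multiset of
  off-diagonal overlaps excluding every pair containing either tested
  context (to avoid leakage of the tested value into its own null); each of
  the `n_permutations` draws resamples one value from it with replacement
  and $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$. This is the only
  null constructible from pairwise overlap counts alone; it needs at least
  four contexts, since with three the exclusion empties the population.
  Because overlap counts are small integers, the test is conservative
  (super-uniform p-values) under an exchangeable null — the calibration
  test asserts exactly that.
* `rank_sd_progression()` reports the percent increase of SD at ranks
  20/50/100/200 over rank 1 — the cost of using "suboptimal" candidates.
* `related_contexts()` supports widening a data-poor context: it correlates
  per-context mean-expression profiles (Pearson, across 10 random sets of
  400 genes by default) against the target context and ranks contexts by
  mean correlation. Raw profiles are correlated, as the clustering this
  emulates operates on profiles; note that shared per-gene baselines make
  absolute correlations high on realistic data — the *ranking*, not the
  absolute value, is the output of interest.

## RT-qPCR validation layer

Candidates are validated in the target assay itself:

* **Delta-Ct** (`cq_to_relative_quantity()`): $rq = E^{(\min_s Cq - Cq)}$
  per gene with per-gene amplification efficiency $E \in (1, 2]$, default
  2 (perfect doubling). GeNorm is computed on these relative quantities
  (the delta-Ct-then-GeNorm workflow); with $E = 2$ this is equivalent to
  working on Cq differences, but declaring $E$ makes non-ideal efficiencies
  first-class.
* **GeNorm** (`genorm_m()`, `genorm_rank()`): $M_j$ is the mean over
  partners $k$ of the SD across samples of $\log_2(rq_j/rq_k)$, computed
  via the covariance identity
  $V_{jk}^2 = \mathrm{var}(L_j)+\mathrm{var}(L_k)-2\,\mathrm{cov}(L_j,L_k)$
  (clamped at zero against rounding). Ranking iteratively removes the
  max-$M$ gene — ties break by gene id and are flagged, as real data
  essentially never ties — down to the final pair, recording the mean $M$
  of the survivors after each removal (the "Avg M" trajectory). The full
  per-iteration record is kept so either reading of "average M" (before or
  after a removal) is recoverable.
* **NormFinder, ungrouped** (`normfinder_stability()`): log2 relative
  quantities are double-centred (gene effects and sample effects removed)
  and each gene is scored by the SD of its residuals. This is the
  no-treatment-group form of the model-based estimator; the grouped
  variance decomposition with its bias correction is deliberately not
  implemented — it needs a group design that a plain Cq table does not
  carry. Note one consequence: with few genes, one gene's noise leaks into
  the others' residuals through the per-sample means, so stabilities are
  comparative, not absolute.
* `compare_panels()` summarises either result by panel (novel candidates
  vs the laboratory's common reference genes): mean stability and mean Cq
  per panel and the top-3 genes. For a GeNorm result a gene's stability is
  its $M$ at the iteration where it was excluded.

## The synthetic-data generator

Because the analyses are defined relative to a large curated compendium
that cannot ship with a package, every claim here is exercised on generated
data with planted truth. `simulate_compendium()` draws

$$y_{gs} = \mu_g + \tau_{g,c(s)} + \beta_{e(s)} + \varepsilon_{gs}$$

with baseline abundances $\mu_g \sim N(9, 1.2^2)$ (log2 units), per-gene
noise SDs uniform over 0.5–5 for background genes (reproducing the roughly
15-fold SD range seen compendium-wide, without claiming its exact shape),
context effects $\tau \sim N(0, 1)$, and additive per-experiment batch
effects $\beta \sim N(0, 0.3^2)$ shared by all genes of a sample — small by
default, since curation and scaling are assumed to have removed most
cross-experiment signal. Planted structure:

* **Context-stable genes** (20 per context): noise SD 0.25 and $\tau = 0$
  inside their context, background behaviour elsewhere.
* **Housekeeping-like genes** (20): $\mu_g \sim N(13, 0.3^2)$ — very
  highly expressed, as real reference-gene panels are — $\tau = 0$
  everywhere, and per-gene noise SDs spread uniformly over a 5-fold range
  geometrically centred on 0.6 (0.27–1.34). The spread is essential: a
  nominally stable panel whose members differ several-fold in actual SD is
  precisely the situation that motivates context-specific search, and a
  constant-SD panel could not reproduce it.

Detection calls are `"P"` when linear signal exceeds the 10th percentile of
all simulated signals. A single seeded RNG stream with a fixed draw order
makes every output byte-reproducible; the RNG state of the caller is left
untouched.

What the generator does *not* emulate: probe-level hybridization,
cross-hybridizing probe families (the high-abundance "cloud" of ribosomal
probe sets), MAS5's call algorithm, heavy-tailed or correlated noise, and
real ontology structure. Tests passing on this generator therefore
demonstrate correctness of the algorithms and their qualitative behaviour
under the stated variance structure — not performance guarantees on any
real compendium.

`simulate_cq_experiment()` plants $Cq_{gs} = b_g + \delta_s + \eta_{gs}$
with a shared sample loading effect $\delta_s \sim N(0, 1)$ (the component
normalization must remove) and per-gene noise $\eta$; the default 8-gene,
16-sample shape mirrors a typical validation run (four novel candidates
against four common reference genes, measured over 16 samples).

## Numerical choices and degenerate inputs

* Sample SD uses the $n-1$ denominator throughout; selections of fewer
  than 2 samples are errors, not NaNs.
* SD ties rank by probe/gene id byte order; GeNorm exclusion ties are
  additionally flagged in the result.
* Linear-scale matrices must be strictly positive at construction, so the
  log2 transform is total; missing cells are rejected at parse time with
  the offending probe and sample named.
* Failed Cq wells are dropped before replicate averaging; a well with no
  surviving replicate is an error — no imputation rule is invented.
* Degenerate bands ($q_1 = q_3$) and empty query results are legal; an
  empty post-filter survivor set is an error naming the cause.
* `rank_sd_progression()` with a zero rank-1 SD returns NA with a warning
  rather than dividing by zero.

## Problem sizes used in the test suite

The packaged tests exercise: 5000-probe, 3-context (60 samples each)
compendia for recovery and context-specificity claims, 100 seeds for the
stochastic ones; 100 simulated 8x16 Cq experiments for GeNorm truth
recovery; 200 replicates of 10-context top-50 overlap matrices (1200-probe
universe, so the expected pair overlap is about 2, matching the scale seen
on real tissue panels) at 2000 permutations each for p-value calibration;
and brute-force oracle comparisons up to 200x50 matrices and 12x30 Cq
tables. These sizes were chosen so the full statistical content runs in a
few minutes on a laptop while keeping Monte-Carlo bands comfortably away
from the asserted thresholds.

## Known limitations

* The package consumes an already-summarized signal matrix; CEL-file
  processing, array QC and probe-to-gene mapping live upstream.
* Ortholog-based transfer of candidates between species is supported only
  in the trivial sense: join your own mapping table to the candidate
  report.
* GeNorm's pairwise-variation $V_{n/n+1}$ criterion for choosing *how many*
  reference genes to use, and BestKeeper, are not implemented.
* The permutation test conditions on the realized overlap population, not
  on tissue sample sizes; with very few contexts its resolution is
  correspondingly coarse.
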