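# refstable

Condition-specific reference-gene discovery and validation for RT-qPCR
normalization.

## Why

RT-qPCR measurements are normalized against internal-control ("reference"
or "housekeeping") genes, assumed to be stably expressed across the
samples of an experiment. That assumption routinely fails: the classic
panel genes (GAPDH, ACTB, B2M, UBC, ...) are extremely highly expressed
relative to typical targets, and each of them varies strongly in *some*
biological context. `refstable` is for experimentalists and core
facilities who instead want to mine a large, uniformly normalized
expression compendium for genes that are demonstrably stable **in the
specific context of their planned experiment** — and then validate those
candidates in the RT-qPCR assay itself.

## What it computes

* **Minimal-variance search.** For a selection $S$ of arrays chosen by
  sample annotation (e.g. `anatomy = liver`), every probe is scored by the
  sample standard deviation of its log2 signal over $S$,
  $\mathrm{sd}_S(g)$, ranked ascending, optionally restricted to an
  expression band (by default the interquartile range of all probe
  medians, so candidates match medium-abundance targets), and the top
  $k = 25$ survivors are reported (`find_reference_genes`).
* **Compendium normalization convention.** Global scaling of each array to
  a trimmed-mean target of 1000 (`global_scale`), log2 transform, and
  Present-call filtering at ≥ 10% of arrays (`detection_filter`).
* **Context analyses.** Per-category SD profiles of candidates
  (`cross_condition_profile`), overlap of top-20/top-50 stable lists
  between contexts with a resampling significance test
  (`top_n_overlap`, `overlap_permutation_test`), the percent increase of
  SD along the ranking (`rank_sd_progression`), and related-context
  suggestion by expression-profile correlation (`related_contexts`).
* **RT-qPCR validation.** Delta-Ct relative quantities
  $rq = E^{\min_s Cq - Cq}$ (`cq_to_relative_quantity`), GeNorm's
  $M$-value — the mean SD of pairwise log ratios — with iterative
  exclusion and the Avg-M trajectory (`genorm_m`, `genorm_rank`), an
  ungrouped NormFinder stability (`normfinder_stability`), and
  novel-vs-common panel summaries (`compare_panels`).
* **Synthetic data with planted truth.** `simulate_compendium` and
  `simulate_cq_experiment` generate multi-context compendia (context
  effects, experiment batch effects, planted context-stable and
  housekeeping-like genes) and Cq experiments with a known noise ranking,
  so every analysis is testable end to end.

See `vignettes/reference-gene-discovery.Rmd` for the model, parameter and
design details.

## Worked example

```r
library(refstable)

# A 5000-probe compendium, three contexts x 60 samples, with 20 planted
# context-stable genes per context and a 20-gene housekeeping-like panel.
sim <- simulate_compendium(compendium_config(
  5000, c(liver = 60, brain = 60, lung = 60),
  noise_sd_range_log2 = c(0.75, 3.75), seed = 11))

liver <- select_samples(sim$annotations, c(anatomy = "liver"))
selection_advice(sim$annotations, liver)   # 60 samples, 3 experiments: ok

head(find_reference_genes(sim$matrix, liver, k = 25), 5)
#>      probe_id median   mean     sd rank present_fraction
#> 1 probe_00088  7.072  7.059 0.2516    1               NA
#> 2 probe_00909  8.203  8.168 0.2541    2               NA
#> 3 probe_01771  9.497  9.486 0.2645    3               NA
#> 4 probe_04504 10.588 10.567 0.2759    4               NA
#> 5 probe_04325  6.994  6.956 0.2836    5               NA
```

All 25 candidates include the 20 planted liver-stable genes (their
within-liver SD, ~0.25–0.33 log2 units, undercuts every background and
housekeeping gene). Validating a candidate panel in a simulated 8-gene,
16-sample Cq experiment where `gene_08` carries 4x the noise of the rest:

```r
cqx <- simulate_cq_experiment(8, 16, noise_sd = c(rep(0.2, 7), 0.8),
                              seed = 11)
genorm_rank(cq_to_relative_quantity(cqx$cq))
#> <genorm_result>
#>   exclusion order (least stable first): gene_08, gene_06, gene_05,
#>   gene_02, gene_03, gene_07
#>   final pair: gene_01, gene_04
#>   Avg M after each removal: 0.271, 0.257, 0.242, 0.227, 0.201, 0.190
```

GeNorm excludes the planted noisy gene first and the Avg-M trajectory
falls as less stable genes are removed; NormFinder agrees
(`normfinder_stability` scores `gene_08` at 0.63 against 0.14–0.24 for the
rest).

## Command line

A thin CLI over the same functions is installed at
`exec/refstable`:

```sh
refstable normalize --target 1000 --trim 0.02 in.tsv out.tsv
refstable search --matrix m.tsv --annotations a.tsv \
    --where anatomy=liver --band-iqr --k 25 --report candidates.tsv
refstable overlap --matrix m.tsv --annotations a.tsv --axis anatomy \
    --top 20,50 --report overlap.tsv --test liver,brain --seed 17
refstable validate --cq cq.tsv --efficiency 2.0 --panel panel.tsv \
    --report validation.tsv
```

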