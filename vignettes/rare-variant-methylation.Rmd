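---
title: "Detecting methylation and expression outliers driven by rare TFBS variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting methylation and expression outliers driven by rare TFBS variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvmeth)
```

## The model

Transcription factors (TFs) recognize short DNA motifs, and their binding
shapes the DNA methylation of nearby CpGs — some factors protect their
surroundings from methylation, others recruit the methylation machinery.
A rare single-nucleotide variant (SNV) that lands inside a transcription
factor binding site (TFBS) can weaken binding and thereby push the local
methylation of its carrier away from the population distribution.
`rvmeth` operationalizes this idea for a cohort with matched whole-genome
genotypes and array methylation (β-values in $[0,1]$):

1. **Rare-variant spectrum.** Only autosomal SNVs with minor allele
   frequency ≤ 1% in the cohort and in the external reference databases,
   carried by at most 2 individuals, are considered
   (`filter_rare_variants()`).
2. **SNV:TFBS pairs.** Each rare SNV is intersected with the motif
   catalogue; overlapping motif instances of the *same* TF that share the
   SNV are merged into one interval so a binding site is never counted
   twice (`intersect_and_merge()`). A pair built from a single instance
   is *isolated* and retains its strand — only isolated pairs are eligible
   for PWM scoring.
3. **Rank-based outlier calling.** At every CpG within ±1 kb of a pair's
   motif, β-values are converted to ascending ranks $1..n$ across the
   cohort (`rank_betas()`). A carrier is an outlier at a CpG when its rank
   falls in the 5% tails ($k = \lfloor 0.05\,n\rfloor$ per tail) **and**
   its β differs from the mean of the non-carriers by at least 0.05
   (`call_outliers()`). For small cohorts where $k = 0$ (e.g. $n = 20$),
   only the exact extremes (rank 1 or $n$) qualify.
4. **Per-TF permutation enrichment.** For each TF, the *enrichment ratio*
   pools all (probe, sample) cells of its pair windows:
   $(c_o/c_t)/(n_o/n_t)$, the fraction of extreme cells among carriers
   over the fraction among non-carriers. Carrier labels are then
   re-drawn uniformly per pair (carrier count preserved) and the ratio is
   recomputed; $p = (1 + \#\{\text{ratio}_{perm} \ge
   \text{ratio}_{obs}\})/(1 + B)$, Bonferroni-corrected for the number of
   TFs tested (`tf_permutation_test()`, `tf_enrichment_test()`).
5. **Pair-level association.** A pair is *associated* with extreme local
   methylation when at least 1/3 of the CpGs in its window are outliers
   for the carrier (`pair_association()`).
6. **PWM disruption (ΔPWM).** The constraint of the mutated motif
   position is `|p(ref) − p(alt)|` at the variant's motif column, with
   offsets counted from the interval end and alleles complemented for −
   strand motifs (`delta_pwm()`). Two companion analyses ask whether
   disrupting constrained positions produces larger methylation changes:
   a per-TF matched Wilcoxon signed-rank test of median ΔPWM in
   associated vs non-associated pairs, and the Pearson correlation of
   per-bin median ΔPWM against binned effect size
   (`pwm_association_wilcoxon()`, `pwm_effectsize_correlation()`).
7. **DMRs.** Independently of the variants, each sample is screened for
   differentially methylated regions: ≥ 3 probes within a 1 kb window
   whose β lies beyond the per-probe 95th (or 5th) cohort percentile and
   ≥ 0.1 from the cohort mean, same direction (`detect_dmrs()`), then
   intersected with the pairs (`dmr_tfbs_intersection()`).
8. **Distance and flank controls.** The same outlier/permutation
   machinery is applied to CpGs binned 1–100 kb from the motif
   (`distance_bin_analysis()`), and to rare SNVs that flank but do not
   touch any motif — the per-chromosome enrichment of the two classes is
   compared with a paired t-test (`flank_comparison()`).
9. **Expression integration.** For a small cohort with matched
   expression, pairs inside a promoter (TSS ± 2 kb of the closest gene)
   are crossed with the carrier's expression Z-score ($|z| > 2$ defines
   an expression outlier) in a 2×2 Fisher test
   (`promoter_pairs()`, `expression_outlier_enrichment()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tail_frac` | 0.05 | rank-tail size; $k=\lfloor 0.05 n\rfloor$ per tail |
| `delta_min` | 0.05 | minimum \|Δβ\| (β units) for an outlier call |
| `flank_bp` | 1000 | window half-width around a merged motif (bp) |
| `n_perm` | 10000 | permutations per TF |
| `min_frac` | 1/3 | pair-association threshold |
| `promoter_bp` | 2000 | promoter half-width around the TSS (bp) |
| `bin_edges` | 1, 10, …, 100 kb | distance bins (10 kb width; the bin width is not dictated by the method and is configurable) |
| `max_excluded_frac` | 0.05 | quota of probes removed as cell-fraction-correlated |

All of these are the method's defining constants except the bin width,
which we fixed at 10 kb as a round value giving ten far bins.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` builds a cohort in which every assumption of the
analysis is true by construction, with a `truth` table recording the
planted effects:

* **β structure.** Per-probe baselines from a 50/50 mixture of Beta
  distributions with means ≈ 0.1 and 0.9 (the bimodality of array data),
  per-sample Beta noise with concentration 60, i.e. an inter-individual
  SD of roughly 0.02–0.06 across the β range — typical of post-QC blood
  EPIC data. The ±0.05 Δβ threshold is therefore meaningful at both
  methylation poles.
* **Variants.** Heterozygous, 1–2 carriers each, with external allele
  frequencies drawn below 1% — all pass the rare filter unless a test
  deliberately violates it. Motif-overlapping variants take the
  consensus base as reference so ΔPWM spans its full range; PWM columns
  have conservation uniform in [0.28, 0.97], covering degenerate to
  near-fixed positions as real motifs do.
* **Planted effects.** Carriers of variants in "effect" TFs get a β
  shift (default 0.3, sign 59% gains, emulating the observed excess of
  methylation gains) at the probes of the motif window, clipped to
  [0,1] with clip events counted. Probes in a planted window take the
  baseline pole that leaves room for the shift, so the planted magnitude
  is realized rather than truncated. With `effect_pwm_coupling` the
  magnitude is `0.3 × ΔPWM`. With `long_range`, far probes decay as
  `exp(−d/15 kb)`.
* **Confounders.** A configurable fraction of probes tracks one blood
  cell fraction (Dirichlet-distributed around realistic blood
  composition); manifest QC flags are sprinkled at 1%.
* **Expression.** Genes assigned to motif variants get a TSS within
  ±1.5 kb; carriers of planted promoter variants receive an expression
  shift of 3 Z units opposite in sign to the methylation shift.

Not emulated: linkage disequilibrium, array normalization artefacts,
probe cross-hybridization structure, shared genetic background, and the
genomic clustering of real motifs. Passing tests therefore demonstrate
that the statistics recover what they claim under the model's own
assumptions — not that those assumptions hold in any particular real
cohort.

The canonical study conditions are frozen as `sim_scenario_*()` presets
(null calibration, planted recovery, ΔPWM coupling, DMR clusters,
distance decay, expression coupling); tests, the reproduction script and
this vignette all draw from the same presets. Problem sizes were chosen
so each scenario runs in seconds to a few minutes on one CPU: the full
null and planted cohorts use 247 samples, 133 TFs and ~10 informative
pairs per TF with 6 probes per ±1 kb window; the coupling scenario uses
45 TFs × 16 pairs; the cardiac-style expression scenario uses 20 samples
and 550 single-carrier promoter pairs (50 planted).

## Numerical choices and degenerate inputs

* **Ranks and ties.** Ranks are ordinal with ties broken by sample id,
  so every probe's ranks are a permutation of $1..n$ and results are
  order-free and reproducible.
* **Two Δβ references.** Reported outlier calls compare the carrier
  against the *mean of controls* (all carriers excluded from the control
  mean).
  The permutation statistic instead marks each (probe, sample) cell
  extreme by its leave-one-out Δβ, identically for observed and permuted
  carrier assignments — exchangeability is what makes the permutation p
  valid. With 1–2 carriers in a cohort of 247 the two references differ
  by $O(1/n)$.
* **p-value estimator.** $(1+x)/(1+B)$, never exactly 0. Because the
  pooled extreme-cell count is integer-valued, permutation ties make the
  null p-values slightly conservative (stochastically ≥ uniform); they
  are valid but not exactly uniform. An `exact = TRUE` mode enumerates
  all carrier assignments when the joint space is small and is used to
  verify the estimator.
* **Infinite ratios.** Carriers extreme / controls never → ratio $+\infty$,
  which compares above all finite values; permuted infinities count
  against significance ($\infty \ge \infty$).
* **Zero denominators.** A TF with no carrier or no control observation
  is skipped with a log entry; `enrichment_ratio()` returns `NA` there.
* **ΔPWM scale.** The "score" of an allele is its raw PWM probability at
  the variant column (the natural reading of a per-site score in
  $[0,1]$); a log2 variant with pseudocount $10^{-3}$ is available via
  `scale = "log2"`.
* **DMR windows.** The per-probe percentile is nearest-rank over all n
  samples (own value included). Qualifying probes are clustered greedily
  left-to-right: a cluster is the maximal run of qualifying probes
  within `window_bp` of its first probe. This is deterministic,
  order-free, and guarantees no call spans more than `window_bp` —
  wholesale merging of overlapping windows could not.
* **Probe filters.** Each filter is evaluated against the full input
  probe set and the survivors are the complement of the union of
  removals, so the surviving set does not depend on filter order; report
  reasons are attributed first-match. The cell-fraction filter ranks
  probes by their maximum absolute Pearson correlation over the six
  fractions and removes a single top-5% quota (the per-fraction
  allocation is not dictated by the method; a single max-|r| cut
  reproduces the intended union bound deterministically). Zero-variance
  probes score 0 and are retained.
* **Degenerate paired t.** Identical per-chromosome enrichments give
  $t = 0$, $p = 1$; constant non-zero differences degenerate to $p \to 0$
  with a zero-variance warning rather than an error.
* **Fisher's exact test.** Implemented by hypergeometric enumeration
  (two-tailed, by table probability); the odds ratio reported is the
  sample odds ratio $ad/bc$. Null Fisher p-values on small tables are
  discrete and conservative; their null behaviour is assessed as
  calibration ($P(p \le \alpha) \le \alpha$) rather than literal
  uniformity, which a discrete test cannot attain.
* **Small-cohort rare filter.** Rare-ness is defined at the
  WGS-cohort/database level; in the 20-sample expression cohort the
  variants are consumed as pre-filtered, since 1 carrier in 20 samples
  already exceeds a 1% within-cohort frequency.

## Open design points resolved here

* **Permutation unit.** The method's description of randomization is not
  fully explicit; we resample carrier labels independently per pair with
  carrier counts preserved, which keeps the pooled ratio's carrier/control
  totals fixed.
* **Observation unit.** The enrichment ratio needs commensurable
  carrier and control fractions; we define one observation as one
  (probe, sample) cell within a pair window.
* **Closest gene.** Measured TSS-to-midpoint (strand-aware TSS), with
  the variant required to lie within TSS ± 2 kb inclusive.
* **Per-pair Fisher table.** When several pairs hit one promoter each
  contributes a row (pair-level counting).
* **Direction fold.** Reported as gains/losses; the gains-over-50%
  version is also returned (`fold_vs_expected`).

## Worked example

```{r example, eval = FALSE}
library(rvmeth)

co <- generate_cohort(sim_scenario_planted(11))
rare  <- filter_rare_variants(co$variants)
pairs <- intersect_and_merge(rare, co$motifs)
ranked <- rank_betas(co$beta)

obs <- build_tf_observations(ranked, pairs, co$manifest)
res <- tf_enrichment_test(obs, n_perm = 10000, seed = 2)
head(res[order(res$p_raw), ])

calls <- call_outliers(ranked, pairs, co$manifest)
assoc <- pair_association(calls, assign_probes_to_pairs(pairs, co$manifest))
direction_enrichment(calls)$fold
```

The planted TFs surface with Bonferroni-significant enrichment while the
remaining TFs stay at null p-values; the same objects feed the DMR,
distance, flank, ΔPWM and expression stages (see the README for a
transcript with the printed numbers). `run_pipeline(run_config(...))`
chains all stages over a cohort directory and writes the result tables
plus a JSON run manifest.

## Known limitations

* Permutation p-values are conservative at coarse pooled counts (few
  pairs or probes per TF); interpret borderline Bonferroni calls
  accordingly.
* The DMR caller's greedy clustering reports maximal sub-window runs; a
  regional effect spanning much more than `window_bp` is reported as
  several adjacent DMRs.
* `exclude_cellfrac_correlated()` removes a fixed quota, not a
  significance-based set; with fewer than eight samples it refuses to
  run.
* Expression integration assumes one carrier (the first by sample id is
  used if there are two) and consumes Z-scores as given; covariate
  correction beyond plain least squares (`residualize_expression()`) is
  out of scope.
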