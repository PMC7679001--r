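# Canonical simulation scenarios: the study conditions under which the
# pipeline's statistical properties are demonstrated.  Each returns a
# sim_config; only the seed varies between replicates.

#' Canonical simulation scenarios
#'
#' Preset [sim_config()]s describing the conditions under which the
#' pipeline's operating characteristics are demonstrated:
#'
#' * `sim_scenario_null()`: the full-scale null -- 247 samples, 133 TFs,
#'   ~9 informative pairs per TF, no planted effects.  Per-TF permutation
#'   p-values must be uniform here.
#' * `sim_scenario_planted()`: 20 of 133 TFs planted with a carrier beta
#'   shift of 0.3 at the CpGs of each variant's motif window (>= 3 CpGs
#'   per pair after probe assignment), 1-2 carriers per variant.
#' * `sim_scenario_coupling()`: 45 TFs, all planted, with the shift
#'   magnitude proportional to the variant's deltaPWM (`coupled = TRUE`);
#'   the decoupled control (`coupled = FALSE`) uses a constant shift at
#'   the detection margin (0.08) so that association status varies but is
#'   independent of deltaPWM.
#' * `sim_scenario_dmr()`: probes concentrated within ±450 bp of each
#'   motif so planted carrier shifts (+0.25, gains only) form >= 3-probe
#'   clusters spanning < 1 kb; `planted = FALSE` gives the matching null.
#' * `sim_scenario_distance()`: long-range probes 2-100 kb from each
#'   motif with the planted shift decaying as `exp(-d / 15 kb)`.
#' * `sim_scenario_expression()`: the small cardiac-style cohort -- 20
#'   samples, 550 single-carrier promoter variants (50 planted under
#'   `planted = TRUE`), methylation shift 0.3 at 3 promoter CpGs and an
#'   expression shift of 3 Z units for the carrier, opposite in sign to
#'   the methylation change.
#'
#' @param seed integer RNG seed.
#' @param coupled,planted scenario switches (see above).
#' @return a [sim_config()].
#' @name sim_scenarios
NULL

#' @rdname sim_scenarios
#' @export
sim_scenario_null <- function(seed) {
  sim_config(frac_effect_tfs = 0, seed = seed)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_planted <- function(seed) {
  sim_config(frac_effect_tfs = 20 / 133, effect_beta_shift = 0.3, seed = seed)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_coupling <- function(seed, coupled = TRUE) {
  if (coupled) {
    sim_config(n_samples = 247, n_tfs = 45, n_motif_instances = 1080,
               n_variants = 720, frac_effect_tfs = 1,
               effect_pwm_coupling = TRUE, frac_flank_variants = 0,
               seed = seed)
  } else {
    sim_config(n_samples = 100, n_tfs = 20, n_motif_instances = 240,
               n_variants = 160, frac_effect_tfs = 1,
               effect_pwm_coupling = FALSE, effect_beta_shift = 0.08,
               frac_flank_variants = 0, seed = seed)
  }
}

#' @rdname sim_scenarios
#' @export
sim_scenario_dmr <- function(seed, planted = TRUE) {
  sim_config(n_samples = 150, n_tfs = 30, n_motif_instances = 300,
             n_variants = 150, frac_effect_tfs = if (planted) 0.5 else 0,
             effect_beta_shift = 0.25, frac_gain = 1, probe_window_bp = 450,
             frac_flank_variants = 0, seed = seed)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_distance <- function(seed) {
  sim_config(n_samples = 247, n_tfs = 20, n_motif_instances = 200,
             n_variants = 200, frac_effect_tfs = 0.5, effect_beta_shift = 0.3,
             long_range = TRUE, far_probes_per_pair = 12,
             probes_per_window = 3, frac_flank_variants = 0, seed = seed)
}

#' @rdname sim_scenarios
#' @export
sim_scenario_expression <- function(seed, planted = TRUE) {
  sim_config(n_samples = 20, n_tfs = 11, n_motif_instances = 1100,
             n_variants = 550, frac_effect_tfs = if (planted) 1 / 11 else 0,
             effect_beta_shift = 0.3, probes_per_window = 3,
             frac_two_carrier = 0, frac_flank_variants = 0, n_genes = 688,
             frac_low_expr_genes = 0, frac_nuisance_probes = 0,
             expression_effect_z = 3, seed = seed)
}

#' Run the small-cohort expression integration on a cohort
#'
#' Convenience wrapper: builds SNV:TFBS pairs (the variants are already
#' rare by construction at the WGS-cohort level), calls small-cohort
#' methylation outliers, applies the 1/3 pair-association rule, maps
#' pairs to promoters, and tests expression-outlier enrichment.
#'
#' @param cohort a [generate_cohort()] result (small cohort).
#' @return [expression_outlier_enrichment()] result.
#' @export
run_expression_integration <- function(cohort) {
  pairs <- intersect_and_merge(cohort$variants, cohort$motifs)
  ranked <- rank_betas(cohort$beta)
  calls <- small_cohort_outliers(ranked, pairs, cohort$manifest)
  map <- assign_probes_to_pairs(pairs, cohort$manifest, 1000)
  assoc <- pair_association(calls, map)
  pg <- promoter_pairs(pairs, cohort$gene_models)
  expression_outlier_enrichment(assoc, pg, cohort$expression$z, pairs)
}
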