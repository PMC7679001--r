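# End-to-end orchestration of the stages over a cohort directory.

#' Build and validate a pipeline run configuration
#'
#' Defaults are the analysis constants of the method: 5% rank tails,
#' minimum beta difference 0.05, ±1 kb motif windows, 10,000
#' permutations, TSS ± 2 kb promoters, and the 1/3 pair-association rule.
#'
#' @param input_dir directory of cohort files (layout of
#'   [write_cohort()]).
#' @param out_dir output directory for result tables and the run
#'   manifest.
#' @param tail_frac,delta_min,flank_bp,n_perm,promoter_bp,min_frac
#'   analysis thresholds.
#' @param bin_edges distance-bin edges for the long-range stage.
#' @param max_excluded_frac cell-fraction probe exclusion quota.
#' @param seed integer seed for all randomized stages.
#' @param stages character vector of stages to run, a subset of
#'   `preprocess, pairs, outliers, dmr, distance, flank, expression`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, tail_frac = 0.05,
                       delta_min = 0.05, flank_bp = 1000, n_perm = 10000,
                       promoter_bp = 2000, min_frac = 1 / 3,
                       bin_edges = c(1e3, seq(1e4, 1e5, by = 1e4)),
                       max_excluded_frac = 0.05, seed = 1L,
                       stages = c("preprocess", "pairs", "outliers", "dmr",
                                  "distance", "flank", "expression")) {
  all_stages <- c("preprocess", "pairs", "outliers", "dmr", "distance",
                  "flank", "expression")
  stopifnot(all(stages %in% all_stages),
            tail_frac > 0, tail_frac < 0.5, delta_min >= 0, flank_bp >= 0,
            n_perm >= 1, promoter_bp >= 0, min_frac > 0, min_frac <= 1)
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              tail_frac = tail_frac, delta_min = delta_min,
              flank_bp = flank_bp, n_perm = n_perm,
              promoter_bp = promoter_bp, min_frac = min_frac,
              bin_edges = bin_edges, max_excluded_frac = max_excluded_frac,
              seed = as.integer(seed), stages = stages)
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  nrow(x)
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Executes probe preprocessing, rare-variant filtering and SNV:TFBS pair
#' construction, local outlier calling with per-TF permutation
#' enrichment, DMR detection and intersection, distance-binned analysis,
#' the flanking-variant contrast, and (when expression data are present)
#' the promoter methylation to expression-outlier integration.  All
#' result tables are written as TSV under `config$out_dir`, together with
#' a JSON run manifest recording versions, seed, configuration, and stage
#' row counts.  Cohorts too small for 5% tails automatically use the
#' small-cohort extreme-rank rule.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of in-memory results per stage plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ip <- function(f) file.path(config$input_dir, f)
  op <- function(f) file.path(config$out_dir, f)
  counts <- list()
  results <- list()

  bm <- load_beta(ip("beta.tsv"), ip("manifest.tsv"))
  beta <- bm$beta
  manifest <- bm$manifest
  variants <- load_variants(ip("cohort.vcf"))
  motifs <- load_motifs(ip("motifs.bed"))
  pwms <- if (file.exists(ip("pwms.tsv"))) load_pwms(ip("pwms.tsv")) else list()
  fractions <- if (file.exists(ip("cell_fractions.tsv"))) {
    load_cell_fractions(ip("cell_fractions.tsv"))
  } else {
    NULL
  }

  rare <- filter_rare_variants(variants)
  counts$rare_variants <- nrow(rare)

  pairs <- intersect_and_merge(rare, motifs)
  if (length(pwms) > 0) pairs <- delta_pwm_table(pairs, pwms)
  counts$pairs <- write_tsv(pairs, op("pairs.tsv"))

  if ("preprocess" %in% config$stages) {
    rep_ <- preprocess_probes(manifest, beta, fractions,
                              variants = pairs[!duplicated(pairs$variant_id), ],
                              max_excluded_frac = config$max_excluded_frac)
    audit <- data.frame(reason = names(rep_$removed),
                        n_removed = as.integer(rep_$removed))
    write_tsv(audit, op("probe_filter_report.tsv"))
    beta <- beta[rep_$surviving, , drop = FALSE]
    manifest <- manifest[manifest$probe_id %in% rep_$surviving, , drop = FALSE]
    counts$probes_surviving <- nrow(beta)
    results$filter_report <- rep_
  }

  n <- ncol(beta)
  mode <- if (floor(config$tail_frac * n) >= 1) "tail" else "extreme"
  ranked <- rank_betas(beta)
  map <- assign_probes_to_pairs(pairs, manifest, config$flank_bp)

  if ("outliers" %in% config$stages) {
    calls <- call_outliers(ranked, pairs, manifest,
                           tail_frac = config$tail_frac,
                           delta_min = config$delta_min,
                           flank_bp = config$flank_bp, mode = mode)
    counts$outlier_calls <- write_tsv(calls, op("outlier_calls.tsv"))
    assoc <- pair_association(calls, map, config$min_frac)
    counts$associated_pairs <- sum(assoc$associated)
    write_tsv(assoc, op("pair_association.tsv"))
    obs <- build_tf_observations(ranked, pairs, manifest,
                                 flank_bp = config$flank_bp,
                                 tail_frac = config$tail_frac,
                                 delta_min = config$delta_min, mode = mode)
    tf_res <- tf_enrichment_test(obs, n_perm = config$n_perm,
                                 seed = config$seed)
    counts$tf_tests <- write_tsv(tf_res, op("tf_enrichment.tsv"))
    dir_res <- direction_enrichment(calls)
    results <- c(results, list(calls = calls, assoc = assoc, tf_res = tf_res,
                               direction = dir_res))
    if ("delta_pwm" %in% names(pairs) && any(!is.na(pairs$delta_pwm))) {
      wil <- pwm_association_wilcoxon(pairs, assoc)
      if (!is.null(wil$per_tf)) write_tsv(wil$per_tf, op("pwm_constraint.tsv"))
      results$pwm_wilcoxon <- wil
    }
  }

  if ("dmr" %in% config$stages) {
    dmrs <- detect_dmrs(beta, manifest, window_bp = config$flank_bp)
    counts$dmrs <- write_tsv(dmrs, op("dmrs.tsv"))
    if ("outliers" %in% config$stages) {
      link <- dmr_tfbs_intersection(dmrs, pairs, results$calls, manifest,
                                    flank_bp = config$flank_bp)
      counts$dmr_linked_pairs <- link$n_linked
      write_tsv(link$links, op("dmr_pair_links.tsv"))
      results$dmr_links <- link
    }
    results$dmrs <- dmrs
  }

  if ("distance" %in% config$stages && mode == "tail") {
    dist_res <- distance_bin_analysis(ranked, pairs, manifest,
                                      bin_edges = config$bin_edges,
                                      n_perm = config$n_perm,
                                      seed = config$seed,
                                      tail_frac = config$tail_frac,
                                      delta_min = config$delta_min)
    counts$distance_tests <- write_tsv(dist_res, op("distance_bins.tsv"))
    results$distance <- dist_res
  }

  if ("flank" %in% config$stages) {
    fl <- find_flank_snvs(rare, motifs, config$flank_bp)
    if (nrow(fl) > 0 && nrow(pairs) > 0) {
      tf_chrom <- per_chrom_enrichment(ranked, pairs, manifest,
                                       config$flank_bp, config$tail_frac,
                                       config$delta_min, mode)
      fl_chrom <- per_chrom_enrichment(ranked, flank_windows(fl), manifest,
                                       config$flank_bp, config$tail_frac,
                                       config$delta_min, mode)
      cmp <- tryCatch(flank_comparison(tf_chrom, fl_chrom),
                      error = function(e) NULL)
      per_chrom <- data.frame(chrom = union(names(tf_chrom), names(fl_chrom)))
      per_chrom$tfbs_enrichment <- tf_chrom[per_chrom$chrom]
      per_chrom$flank_enrichment <- fl_chrom[per_chrom$chrom]
      write_tsv(per_chrom, op("flank_contrast.tsv"))
      results$flank <- list(per_chrom = per_chrom, comparison = cmp)
      counts$flank_snvs <- nrow(fl)
    }
  }

  if ("expression" %in% config$stages && file.exists(ip("expression.tsv")) &&
      "outliers" %in% config$stages) {
    z <- load_expression(ip("expression.tsv"))
    genes <- load_gene_models(ip("genes.bed"))
    pg <- promoter_pairs(pairs, genes, config$promoter_bp)
    counts$promoter_pairs <- write_tsv(pg, op("promoter_pairs.tsv"))
    if (nrow(pg) > 0) {
      enr <- expression_outlier_enrichment(results$assoc, pg, z, pairs)
      enr_tab <- data.frame(
        fold = enr$fold, p = enr$p, n_pairs = enr$n_pairs,
        a = enr$table[1, 1], b = enr$table[1, 2],
        c = enr$table[2, 1], d = enr$table[2, 2]
      )
      write_tsv(enr_tab, op("expression_enrichment.tsv"))
      results$expression <- enr
    }
  }

  manifest_json <- list(
    package = "rvmeth",
    version = as.character(utils::packageVersion("rvmeth")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), c("input_dir", "out_dir"))],
    stage_counts = counts
  )
  jsonlite::write_json(manifest_json, op("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest_json
  invisible(results)
}
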