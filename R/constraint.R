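# Functional-constraint analyses: does disrupting more constrained motif
# positions (larger deltaPWM) produce larger methylation changes?

#' Per-CpG carrier effect table
#'
#' For every (pair, carrier, probe-in-window) cell, regardless of outlier
#' status, records the carrier's rank and beta difference versus the
#' control mean (controls = non-carriers of the variant) and whether the
#' cell meets the outlier criteria.
#'
#' @param ranked a [rank_betas()] result.
#' @param pairs pair table.
#' @param manifest probe manifest.
#' @param tail_frac,delta_min,mode outlier thresholds (see
#'   [extreme_matrix()]).
#' @param flank_bp window flank (default 1000).
#' @return data.frame `pair_id, tf_name, probe_id, sample_id, rank,
#'   delta_beta, outlier`.
#' @export
carrier_effect_table <- function(ranked, pairs, manifest, tail_frac = 0.05,
                                 delta_min = 0.05, flank_bp = 1000,
                                 mode = c("tail", "extreme")) {
  mode <- match.arg(mode)
  n <- ranked$n
  k <- floor(tail_frac * n)
  map <- assign_probes_to_pairs(pairs, manifest, flank_bp)
  carr <- carrier_list(pairs)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    probes <- map$probe_id[map$pair_id == pairs$pair_id[i]]
    probes <- probes[probes %in% rownames(ranked$beta)]
    if (length(probes) == 0) next
    carriers <- intersect(carr[[i]], ranked$samples)
    controls <- setdiff(ranked$samples, carr[[i]])
    if (length(carriers) == 0 || length(controls) == 0) next
    ctrl_mean <- rowMeans(ranked$beta[probes, controls, drop = FALSE])
    for (s in carriers) {
      rk <- ranked$rank[probes, s]
      db <- ranked$beta[probes, s] - ctrl_mean
      extreme <- if (mode == "tail") rk <= k | rk >= n - k + 1L else rk == 1L | rk == n
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], tf_name = pairs$tf_name[i],
        probe_id = probes, sample_id = s, rank = unname(rk),
        delta_beta = unname(db),
        outlier = unname(extreme & abs(db) >= delta_min),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(pair_id = character(0), tf_name = character(0),
                      probe_id = character(0), sample_id = character(0),
                      rank = integer(0), delta_beta = numeric(0),
                      outlier = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Matched-pairs Wilcoxon test of deltaPWM by association status
#'
#' For each TF with both associated and non-associated isolated pairs,
#' computes the median absolute deltaPWM of the two groups, then compares
#' the per-TF medians with a two-sided Wilcoxon matched-pairs signed rank
#' test.  Larger deltaPWM among associated pairs indicates that variants
#' at constrained motif positions drive the methylation changes.
#'
#' @param pairs_delta pair table with a `delta_pwm` column
#'   ([delta_pwm_table()]); non-isolated pairs (NA delta) are ignored.
#' @param assoc pair-association table ([pair_association()]).
#' @return list `per_tf` (data.frame `tf_name, median_assoc, median_non,
#'   n_assoc, n_non`), `p`, `n_tf`.
#' @export
pwm_association_wilcoxon <- function(pairs_delta, assoc) {
  tab <- merge(pairs_delta[!is.na(pairs_delta$delta_pwm),
                           c("pair_id", "tf_name", "delta_pwm")],
               assoc[, c("pair_id", "associated")], by = "pair_id")
  per_tf <- list()
  for (tf in unique(tab$tf_name)) {
    sub <- tab[tab$tf_name == tf, , drop = FALSE]
    da <- sub$delta_pwm[sub$associated]
    dn <- sub$delta_pwm[!sub$associated]
    if (length(da) == 0 || length(dn) == 0) next
    per_tf[[length(per_tf) + 1L]] <- data.frame(
      tf_name = tf, median_assoc = stats::median(da),
      median_non = stats::median(dn), n_assoc = length(da),
      n_non = length(dn), stringsAsFactors = FALSE
    )
  }
  if (length(per_tf) == 0) {
    return(list(per_tf = NULL, p = NA_real_, n_tf = 0L))
  }
  per_tf <- do.call(rbind, per_tf)
  p <- if (nrow(per_tf) >= 3) {
    suppressWarnings(
      wilcox.test(per_tf$median_assoc, per_tf$median_non, paired = TRUE)$p.value
    )
  } else {
    NA_real_
  }
  list(per_tf = per_tf, p = p, n_tf = nrow(per_tf))
}

#' Correlation of deltaPWM with methylation effect size across bins
#'
#' Annotates every window CpG with its pair's absolute deltaPWM and the
#' magnitude of the carrier's methylation change, stratifies the CpGs
#' into `n_bins` equal-count bins of increasing `|delta beta|`, and
#' returns the Pearson correlation between the per-bin median deltaPWM
#' and the per-bin median methylation change.
#'
#' @param effect_table per-CpG effect table ([carrier_effect_table()]).
#' @param pairs_delta pair table with `delta_pwm`.
#' @param n_bins number of effect-size bins (default 8).
#' @return list `bins` (data.frame `bin, median_delta_beta,
#'   median_delta_pwm, n`), `pearson_r`.
#' @export
pwm_effectsize_correlation <- function(effect_table, pairs_delta, n_bins = 8) {
  tab <- merge(effect_table,
               pairs_delta[!is.na(pairs_delta$delta_pwm),
                           c("pair_id", "delta_pwm")], by = "pair_id")
  if (nrow(tab) < n_bins) stop("too few annotated CpGs to bin")
  mag <- abs(tab$delta_beta)
  qs <- unique(stats::quantile(mag, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mag, breaks = qs, include.lowest = TRUE, labels = FALSE)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(bin = b,
               median_delta_beta = stats::median(mag[bin == b]),
               median_delta_pwm = stats::median(tab$delta_pwm[bin == b]),
               n = sum(bin == b))
  }))
  r <- if (nrow(bins) >= 3) {
    cor(bins$median_delta_beta, bins$median_delta_pwm, method = "pearson")
  } else {
    NA_real_
  }
  list(bins = bins, pearson_r = r)
}
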