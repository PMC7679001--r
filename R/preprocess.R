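# Probe-level quality filtering and cell-composition confounder removal,
# applied before any outlier statistics.

new_filter_report <- function(input_probes, removed_reason) {
  # removed_reason: named character vector probe_id -> reason (first match)
  reasons <- c("snp_in_last5", "multimapping", "cellfrac_correlated",
               "snv_at_probe", "user_blacklist")
  counts <- vapply(reasons, function(r) sum(removed_reason == r), integer(1))
  surviving <- setdiff(input_probes, names(removed_reason))
  out <- list(removed = counts, surviving = surviving,
              removed_probes = removed_reason,
              n_input = length(input_probes))
  class(out) <- "probe_filter_report"
  out
}

#' @export
print.probe_filter_report <- function(x, ...) {
  cat("Probe filter report:", x$n_input, "probes in,",
      length(x$surviving), "surviving\n")
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  %-20s %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' Remove probes with manifest QC flags or on a user blacklist
#'
#' Drops probes flagged for a common SNP within the last 5 bases of the
#' probe 3' end or for non-unique mapping to the bisulfite-converted
#' genome, plus any probe named in `blacklist` (probe ids) or whose CpG
#' falls in a blacklisted region (`GRanges`).
#'
#' @param manifest probe manifest data.frame.
#' @param blacklist optional character vector of probe ids or `GRanges` of
#'   regions.
#' @return a `probe_filter_report` with removal counts per reason and the
#'   surviving probe ids.
#' @export
filter_flagged_probes <- function(manifest, blacklist = NULL) {
  reason <- character(0)
  add <- function(reason, ids, why) {
    new <- setdiff(ids, names(reason))
    c(reason, stats::setNames(rep(why, length(new)), new))
  }
  reason <- add(reason, manifest$probe_id[manifest$snp_in_last5], "snp_in_last5")
  reason <- add(reason, manifest$probe_id[manifest$multimapping], "multimapping")
  if (!is.null(blacklist)) {
    if (inherits(blacklist, "GRanges")) {
      hits <- GenomicRanges::findOverlaps(cpg_granges(manifest), blacklist)
      ids <- manifest$probe_id[unique(S4Vectors::queryHits(hits))]
    } else {
      unknown <- setdiff(blacklist, manifest$probe_id)
      if (length(unknown) > 0) {
        warning(sprintf("blacklist references %d unknown probe id(s)", length(unknown)))
      }
      ids <- intersect(blacklist, manifest$probe_id)
    }
    reason <- add(reason, ids, "user_blacklist")
  }
  new_filter_report(manifest$probe_id, reason)
}

#' Exclude probes most correlated with blood cell-type fractions
#'
#' For each probe the Pearson correlation of its beta values against each
#' of the six cell fractions is computed; the probe's score is the maximum
#' absolute correlation, and the top `floor(max_excluded_frac * n_probes)`
#' probes by score are removed (ties broken by probe id order).  Probes
#' with zero variance have undefined correlation and are retained with
#' score 0.
#'
#' @param beta probes x samples beta matrix.
#' @param fractions cell-fraction data.frame ([load_cell_fractions()]),
#'   one row per sample of `beta`.
#' @param max_excluded_frac maximum fraction of probes to drop (default
#'   0.05).
#' @return a `probe_filter_report`; the per-probe score is attached as
#'   attribute `score`.
#' @export
exclude_cellfrac_correlated <- function(beta, fractions, max_excluded_frac = 0.05) {
  stopifnot(max_excluded_frac >= 0, max_excluded_frac <= 1)
  if (ncol(beta) < 8) stop("need >= 8 samples for meaningful correlations")
  fr <- as.matrix(fractions[match(colnames(beta), fractions$sample_id), CELL_TYPES])
  if (anyNA(fr)) stop("cell fractions missing for some samples")
  score <- rep(0, nrow(beta))
  sds_b <- apply(beta, 1L, sd)
  sds_f <- apply(fr, 2L, sd)
  ok_f <- sds_f > 0
  if (any(ok_f)) {
    r <- suppressWarnings(cor(t(beta), fr[, ok_f, drop = FALSE]))
    r[!is.finite(r)] <- 0
    score <- apply(abs(r), 1L, max)
  }
  score[sds_b == 0] <- 0
  n_remove <- floor(max_excluded_frac * nrow(beta))
  n_defined <- sum(score > 0)
  n_remove <- min(n_remove, n_defined)
  removed <- character(0)
  if (n_remove > 0) {
    ord <- order(-score, rownames(beta))
    removed <- rownames(beta)[ord[seq_len(n_remove)]]
  }
  rep_ <- new_filter_report(
    rownames(beta),
    stats::setNames(rep("cellfrac_correlated", length(removed)), removed)
  )
  attr(rep_, "score") <- stats::setNames(score, rownames(beta))
  rep_
}

#' Exclude probes overlapped by a TFBS rare variant
#'
#' A probe is removed when any SNV-TFBS variant position lies inside the
#' probe body (1-based `[body_start + 1, body_end]`), at the interrogated
#' CpG, or at its adjacent base (`cpg_pos + 1`).
#'
#' @param manifest probe manifest data.frame.
#' @param variants variant data.frame already restricted to SNV-TFBS.
#' @return a `probe_filter_report`.
#' @export
exclude_snv_overlapping_probes <- function(manifest, variants) {
  removed <- logical(nrow(manifest))
  if (nrow(variants) > 0) {
    vg <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1L))
    body <- GenomicRanges::GRanges(
      manifest$chrom,
      IRanges::IRanges(start = manifest$body_start + 1L, end = manifest$body_end)
    )
    cpg <- GenomicRanges::GRanges(
      manifest$chrom,
      IRanges::IRanges(start = manifest$cpg_pos, end = manifest$cpg_pos + 1L)
    )
    removed <- GenomicRanges::countOverlaps(body, vg) > 0 |
      GenomicRanges::countOverlaps(cpg, vg) > 0
  }
  new_filter_report(
    manifest$probe_id,
    stats::setNames(rep("snv_at_probe", sum(removed)),
                    manifest$probe_id[removed])
  )
}

#' Run all probe filters and combine them order-free
#'
#' Each filter is evaluated on the full input probe set; the surviving set
#' is the complement of the union of removals, so it does not depend on
#' any filter ordering.  For the report, reasons are attributed in
#' first-match order: `snp_in_last5`, `multimapping`,
#' `cellfrac_correlated`, `snv_at_probe`, `user_blacklist`.
#'
#' @param manifest probe manifest.
#' @param beta probes x samples beta matrix.
#' @param fractions cell-fraction table (or `NULL` to skip that filter).
#' @param variants SNV-TFBS variant data.frame (or `NULL` to skip).
#' @param blacklist optional probe-id vector or `GRanges`.
#' @param max_excluded_frac quota for the cell-fraction filter.
#' @return a `probe_filter_report`.
#' @export
preprocess_probes <- function(manifest, beta, fractions = NULL,
                              variants = NULL, blacklist = NULL,
                              max_excluded_frac = 0.05) {
  flag_rep <- filter_flagged_probes(manifest, blacklist)
  reports <- list(flag_rep)
  if (!is.null(fractions)) {
    reports <- c(reports, list(
      exclude_cellfrac_correlated(beta, fractions, max_excluded_frac)
    ))
  }
  if (!is.null(variants)) {
    reports <- c(reports, list(exclude_snv_overlapping_probes(manifest, variants)))
  }
  first_order <- c("snp_in_last5", "multimapping", "cellfrac_correlated",
                   "snv_at_probe", "user_blacklist")
  all_removed <- unlist(lapply(reports, function(r) r$removed_probes))
  reason <- character(0)
  for (why in first_order) {
    ids <- setdiff(unique(names(all_removed)[all_removed == why]), names(reason))
    reason <- c(reason, stats::setNames(rep(why, length(ids)), ids))
  }
  new_filter_report(manifest$probe_id, reason)
}
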