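# Central statistics: per-CpG ranking, outlier calling, per-TF permutation
# enrichment, direction-of-effect summary, sliding-window DMR detection,
# distance-binned analysis, flank comparison, region-overlap enrichment.

#' Rank beta values across the cohort at each CpG
#'
#' Transforms each probe's beta values into ascending ordinal ranks 1..n
#' across all individuals (ties broken by sample id lexicographic order so
#' ranks are always a permutation of 1..n), and computes each sample's
#' leave-one-out beta difference `beta(s) - mean(beta of all other
#' samples)`.
#'
#' @param beta probes x samples beta matrix.
#' @param probes optional probe id subset.
#' @return object of class `ranked_cpgs`: list with `rank` (integer
#'   matrix), `delta_loo`, `beta`, `n`, `samples`.
#' @export
rank_betas <- function(beta, probes = NULL) {
  stopifnot(is.matrix(beta), !is.null(colnames(beta)), !is.null(rownames(beta)))
  if (!is.null(probes)) beta <- beta[probes, , drop = FALSE]
  n <- ncol(beta)
  samp_ord <- order(colnames(beta))
  rk <- t(apply(beta, 1L, function(x) {
    r <- integer(n)
    r[order(x, samp_ord)] <- seq_len(n)
    r
  }))
  dimnames(rk) <- dimnames(beta)
  rs <- rowSums(beta)
  delta_loo <- beta - (rs - beta) / (n - 1)
  structure(list(rank = rk, delta_loo = delta_loo, beta = beta, n = n,
                 samples = colnames(beta)),
            class = "ranked_cpgs")
}

#' Extreme-cell indicator matrix
#'
#' Marks each (probe, sample) cell as extreme.  Under `mode = "tail"` a
#' cell is extreme when its rank falls in the `tail_frac` tails
#' (`rank <= k` or `rank >= n - k + 1`, `k = floor(tail_frac * n)`) and
#' its absolute leave-one-out beta difference is at least `delta_min`.
#' Under `mode = "extreme"` (small cohorts) only ranks 1 and n qualify.
#'
#' @param ranked a [rank_betas()] result.
#' @param tail_frac tail size as a fraction (default 0.05).
#' @param delta_min minimum absolute beta difference (default 0.05).
#' @param mode `"tail"` or `"extreme"`.
#' @return logical probes x samples matrix.
#' @export
extreme_matrix <- function(ranked, tail_frac = 0.05, delta_min = 0.05,
                           mode = c("tail", "extreme")) {
  mode <- match.arg(mode)
  n <- ranked$n
  if (mode == "tail") {
    k <- floor(tail_frac * n)
    if (k < 1) stop("cohort too small for tail ranking; use mode = \"extreme\"")
    in_tail <- ranked$rank <= k | ranked$rank >= n - k + 1L
  } else {
    if (n < 4) stop("n_samples < 4")
    in_tail <- ranked$rank == 1L | ranked$rank == n
  }
  in_tail & abs(ranked$delta_loo) >= delta_min
}

#' Assign probes to SNV:TFBS pair windows
#'
#' A probe belongs to a pair when its CpG position is within `max_dist` bp
#' of the pair's merged motif interval; the distance is 0 inside the
#' interval and the bp gap to the nearest edge outside.
#'
#' @param pairs pair table ([intersect_and_merge()] or [flank_windows()]).
#' @param manifest probe manifest.
#' @param max_dist maximum CpG-to-motif distance in bp (default 1000).
#' @return data.frame `pair_id, probe_id, distance`.
#' @export
assign_probes_to_pairs <- function(pairs, manifest, max_dist = 1000) {
  empty <- data.frame(pair_id = character(0), probe_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || nrow(manifest) == 0) return(empty)
  win <- GenomicRanges::GRanges(pairs$chrom,
                                IRanges::IRanges(pairs$start, pairs$end))
  hits <- GenomicRanges::findOverlaps(win, cpg_granges(manifest),
                                      maxgap = max_dist)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  cpg <- manifest$cpg_pos[si]
  dist <- pmax(0L, pairs$start[qi] - cpg, cpg - pairs$end[qi])
  out <- data.frame(pair_id = pairs$pair_id[qi],
                    probe_id = manifest$probe_id[si],
                    distance = as.integer(dist), stringsAsFactors = FALSE)
  out[out$distance <= max_dist, , drop = FALSE]
}

#' Call per-CpG methylation outliers for variant carriers
#'
#' For every (pair, carrier, probe-in-window) triple, the carrier is an
#' outlier at the probe when its rank is extreme (see [extreme_matrix()]
#' for the two modes) and its beta value differs from the mean of the
#' controls -- all samples not carrying the variant; with two carriers
#' both are excluded from the control mean -- by at least `delta_min` in
#' absolute value.
#'
#' @param ranked a [rank_betas()] result over the full cohort.
#' @param pairs pair table.
#' @param manifest probe manifest.
#' @param tail_frac,delta_min,mode outlier thresholds (see
#'   [extreme_matrix()]).
#' @param flank_bp window flank around the merged motif (default 1000).
#' @return data.frame of calls: `pair_id, tf_name, probe_id, sample_id,
#'   rank, delta_beta, direction` (`gain`/`loss`).
#' @export
call_outliers <- function(ranked, pairs, manifest, tail_frac = 0.05,
                          delta_min = 0.05, flank_bp = 1000,
                          mode = c("tail", "extreme")) {
  mode <- match.arg(mode)
  n <- ranked$n
  if (mode == "tail") {
    k <- floor(tail_frac * n)
    if (k < 1) stop("floor(tail_frac * n) = 0: cohort too small, use mode = \"extreme\"")
  }
  map <- assign_probes_to_pairs(pairs, manifest, flank_bp)
  out <- list()
  carr <- carrier_list(pairs)
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
      extreme <- if (mode == "tail") rk <= k | rk >= n - k + 1L else rk == 1L | rk == n
      db <- ranked$beta[probes, s] - ctrl_mean
      hit <- extreme & abs(db) >= delta_min
      if (!any(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], tf_name = pairs$tf_name[i],
        probe_id = probes[hit], sample_id = s, rank = unname(rk[hit]),
        delta_beta = unname(db[hit]),
        direction = ifelse(db[hit] > 0, "gain", "loss"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(pair_id = character(0), tf_name = character(0),
                      probe_id = character(0), sample_id = character(0),
                      rank = integer(0), delta_beta = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Carrier/control enrichment ratio
#'
#' Ratio of the fraction of extreme (probe, sample) observations among
#' carriers over the fraction among non-carriers:
#' `(co/ct) / (no/nt)`.  Returns 0 when no carrier observation is
#' extreme, `Inf` when carriers have extreme observations but controls
#' have none, and `NA` (with a message) when either total is 0.
#'
#' @param carrier_outlier,carrier_total extreme and total carrier cells.
#' @param control_outlier,control_total extreme and total control cells.
#' @return numeric ratio.
#' @examples
#' enrichment_ratio(2, 4, 10, 1000)  # 50
#' @export
enrichment_ratio <- function(carrier_outlier, carrier_total,
                             control_outlier, control_total) {
  if (carrier_total == 0 || control_total == 0) {
    message("enrichment_ratio: undefined (zero carrier or control total)")
    return(NA_real_)
  }
  if (carrier_outlier == 0) return(0)
  if (control_outlier == 0) return(Inf)
  (carrier_outlier / carrier_total) / (control_outlier / control_total)
}

# vectorized ratio over candidate carrier-extreme counts `co`;
# no = tot_extreme - co varies with co, ct/nt are fixed totals.
ratio_vec <- function(co, ct, tot_extreme, nt) {
  no <- tot_extreme - co
  r <- (co / ct) * (nt / pmax(no, 1))
  r[no == 0] <- Inf
  r[co == 0] <- 0
  r
}

#' Build per-TF observation sets for enrichment testing
#'
#' Pools, for each TF, the (probe, sample) cells of all its pair windows.
#' For each pair the per-sample count of extreme cells over the window
#' probes is precomputed, which is sufficient to recompute the pooled
#' carrier/control enrichment ratio under any carrier relabeling.
#'
#' @param ranked a [rank_betas()] result.
#' @param pairs pair table.
#' @param manifest probe manifest.
#' @param flank_bp window flank (ignored when `map` is supplied).
#' @param tail_frac,delta_min,mode passed to [extreme_matrix()].
#' @param map optional precomputed probe assignment
#'   ([assign_probes_to_pairs()]), e.g. restricted to a distance bin.
#' @return named list (one element per TF with >= 1 informative pair):
#'   `tf_name, cmat` (pairs x samples extreme-cell counts), `n_probes`,
#'   `carriers` (sample index sets), `n_samples, n_cpg, pair_ids`.
#' @export
build_tf_observations <- function(ranked, pairs, manifest, flank_bp = 1000,
                                  tail_frac = 0.05, delta_min = 0.05,
                                  mode = "tail", map = NULL) {
  E <- extreme_matrix(ranked, tail_frac, delta_min, mode)
  if (is.null(map)) map <- assign_probes_to_pairs(pairs, manifest, flank_bp)
  map <- map[map$probe_id %in% rownames(E), , drop = FALSE]
  if (nrow(map) == 0) return(list())
  probes_by_pair <- split(map$probe_id, map$pair_id)
  pairs <- pairs[pairs$pair_id %in% names(probes_by_pair), , drop = FALSE]
  carr <- carrier_list(pairs)
  obs <- list()
  for (tf in unique(pairs$tf_name)) {
    rows <- which(pairs$tf_name == tf)
    cmat <- matrix(0L, nrow = length(rows), ncol = ranked$n,
                   dimnames = list(pairs$pair_id[rows], ranked$samples))
    n_probes <- integer(length(rows))
    carriers <- vector("list", length(rows))
    all_probes <- character(0)
    for (j in seq_along(rows)) {
      pid <- pairs$pair_id[rows[j]]
      pr <- probes_by_pair[[pid]]
      cmat[j, ] <- colSums(E[pr, , drop = FALSE])
      n_probes[j] <- length(pr)
      carriers[[j]] <- match(intersect(carr[[rows[j]]], ranked$samples),
                             ranked$samples)
      all_probes <- c(all_probes, pr)
    }
    keep <- lengths(carriers) > 0 & lengths(carriers) < ranked$n
    if (!any(keep)) next
    obs[[tf]] <- list(tf_name = tf, cmat = cmat[keep, , drop = FALSE],
                      n_probes = n_probes[keep], carriers = carriers[keep],
                      n_samples = ranked$n,
                      n_cpg = length(unique(all_probes)),
                      pair_ids = pairs$pair_id[rows][keep])
  }
  obs
}

observed_counts <- function(ob) {
  m <- lengths(ob$carriers)
  co <- sum(vapply(seq_along(ob$carriers), function(i) {
    sum(ob$cmat[i, ob$carriers[[i]]])
  }, numeric(1)))
  ct <- sum(m * ob$n_probes)
  tot <- sum(ob$cmat)
  nt <- sum((ob$n_samples - m) * ob$n_probes)
  list(co = co, ct = ct, tot = tot, nt = nt)
}

#' Permutation enrichment test for one TF
#'
#' Recomputes the pooled carrier/control enrichment ratio under random
#' reassignment of carrier labels: in each permutation, independently for
#' each pair, the carrier set is replaced by a uniformly random sample
#' subset of the same size.  The p-value is the add-one estimator
#' `(1 + #\{permutation ratio >= observed\}) / (1 + n_perm)` (never
#' exactly 0); an infinite observed ratio is only reached by permutations
#' that are themselves infinite.  With `exact = TRUE` all joint carrier
#' assignments are enumerated instead and the p-value is the exact
#' fraction of assignments with ratio >= observed.
#'
#' @param ob one element of [build_tf_observations()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; required unless `NA` (caller manages RNG).
#' @param exact enumerate all carrier assignments (refused when the joint
#'   assignment space exceeds `max_enumeration`).
#' @param max_enumeration enumeration size cap.
#' @return list `tf_name, observed_ratio, p_raw, n_pairs, n_cpg, n_perm`.
#' @export
tf_permutation_test <- function(ob, n_perm = 10000, seed = NULL,
                                exact = FALSE, max_enumeration = 2e5) {
  if (!exact) {
    if (is.null(seed)) stop("a seed is required for reproducible permutation testing")
    if (!is.na(seed)) set.seed(seed)
  }
  oc <- observed_counts(ob)
  if (oc$ct == 0 || oc$nt == 0) {
    message(sprintf("TF %s skipped: zero carrier or control observations", ob$tf_name))
    return(list(tf_name = ob$tf_name, observed_ratio = NA_real_,
                p_raw = NA_real_, n_pairs = nrow(ob$cmat), n_cpg = ob$n_cpg,
                n_perm = if (exact) NA_integer_ else n_perm))
  }
  r_obs <- ratio_vec(oc$co, oc$ct, oc$tot, oc$nt)
  n <- ob$n_samples
  m <- lengths(ob$carriers)

  if (exact) {
    per_pair <- lapply(seq_along(m), function(i) {
      if (m[i] == 1L) {
        as.numeric(ob$cmat[i, ])
      } else {
        cmb <- utils::combn(n, m[i])
        apply(cmb, 2L, function(ix) sum(ob$cmat[i, ix]))
      }
    })
    total <- prod(vapply(per_pair, length, numeric(1)))
    if (total > max_enumeration) {
      stop(sprintf("exact enumeration infeasible: %g joint assignments", total))
    }
    co_all <- Reduce(function(a, b) as.vector(outer(a, b, "+")), per_pair)
    r_all <- ratio_vec(co_all, oc$ct, oc$tot, oc$nt)
    p <- mean(r_all >= r_obs)
    return(list(tf_name = ob$tf_name, observed_ratio = r_obs, p_raw = p,
                n_pairs = nrow(ob$cmat), n_cpg = ob$n_cpg,
                n_perm = as.integer(total)))
  }

  co_perm <- numeric(n_perm)
  for (i in seq_along(m)) {
    if (m[i] == 1L) {
      idx <- sample.int(n, n_perm, replace = TRUE)
      co_perm <- co_perm + ob$cmat[i, idx]
    } else if (m[i] == 2L) {
      a <- sample.int(n, n_perm, replace = TRUE)
      b <- sample.int(n - 1L, n_perm, replace = TRUE)
      b <- b + (b >= a)
      co_perm <- co_perm + ob$cmat[i, a] + ob$cmat[i, b]
    } else {
      draws <- vapply(seq_len(n_perm), function(p) {
        sum(ob$cmat[i, sample.int(n, m[i])])
      }, numeric(1))
      co_perm <- co_perm + draws
    }
  }
  r_perm <- ratio_vec(co_perm, oc$ct, oc$tot, oc$nt)
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  list(tf_name = ob$tf_name, observed_ratio = r_obs, p_raw = p,
       n_pairs = nrow(ob$cmat), n_cpg = ob$n_cpg, n_perm = n_perm)
}

#' Permutation enrichment test across all TFs
#'
#' Runs [tf_permutation_test()] for every TF observation set and applies a
#' Bonferroni correction for the number of TFs tested in the run.
#'
#' @param observations list from [build_tf_observations()].
#' @param n_perm permutations per TF.
#' @param seed integer seed (one seed governs the whole run).
#' @param exact use exact enumeration per TF.
#' @param n_tests Bonferroni multiplier; defaults to the number of TFs
#'   with a defined observed ratio.
#' @return data.frame `tf_name, n_pairs, n_cpg, observed_ratio, p_raw,
#'   p_bonferroni`.
#' @export
tf_enrichment_test <- function(observations, n_perm = 10000, seed = 1L,
                               exact = FALSE, n_tests = NULL) {
  if (!exact) set.seed(seed)
  res <- lapply(observations, function(ob) {
    tf_permutation_test(ob, n_perm = n_perm, seed = NA, exact = exact)
  })
  out <- data.frame(
    tf_name = vapply(res, `[[`, character(1), "tf_name"),
    n_pairs = vapply(res, `[[`, numeric(1), "n_pairs"),
    n_cpg = vapply(res, `[[`, numeric(1), "n_cpg"),
    observed_ratio = vapply(res, `[[`, numeric(1), "observed_ratio"),
    p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
    stringsAsFactors = FALSE
  )
  n_tests <- n_tests %||% sum(!is.na(out$p_raw))
  out$p_bonferroni <- pmin(1, n_tests * out$p_raw)
  rownames(out) <- NULL
  out
}

#' Direction-of-effect summary over outlier calls
#'
#' @param calls outlier-call table ([call_outliers()]).
#' @return list `fold` (gains/losses), `gains`, `losses`, and
#'   `fold_vs_expected` (gains over the 50% expectation).
#' @export
direction_enrichment <- function(calls) {
  gains <- sum(calls$direction == "gain")
  losses <- sum(calls$direction == "loss")
  fold <- if (losses == 0) {
    if (gains > 0) warning("no methylation losses: gain/loss fold is infinite")
    if (gains > 0) Inf else NA_real_
  } else {
    gains / losses
  }
  total <- gains + losses
  list(fold = fold, gains = gains, losses = losses,
       fold_vs_expected = if (total > 0) gains / (0.5 * total) else NA_real_)
}

#' Pair-level association with extreme methylation (1/3 rule)
#'
#' A pair is associated with local extreme methylation when at least
#' `min_frac` of the CpGs in its window are outliers for the carrier.
#'
#' @param calls outlier-call table.
#' @param map probe assignment ([assign_probes_to_pairs()]), defines each
#'   pair's CpG denominator; pairs with zero CpGs are dropped.
#' @param min_frac association threshold (default 1/3).
#' @return data.frame `pair_id, n_cpg, n_outlier, frac, associated`.
#' @export
pair_association <- function(calls, map, min_frac = 1 / 3) {
  n_cpg <- table(map$pair_id)
  if (length(n_cpg) == 0) {
    return(data.frame(pair_id = character(0), n_cpg = integer(0),
                      n_outlier = integer(0), frac = numeric(0),
                      associated = logical(0), stringsAsFactors = FALSE))
  }
  out_probes <- unique(calls[, c("pair_id", "probe_id")])
  n_out <- table(factor(out_probes$pair_id, levels = names(n_cpg)))
  frac <- as.numeric(n_out) / as.numeric(n_cpg)
  data.frame(pair_id = names(n_cpg), n_cpg = as.integer(n_cpg),
             n_outlier = as.integer(n_out), frac = frac,
             associated = frac >= min_frac - 1e-12,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect differentially methylated regions (DMRs) per sample
#'
#' For each sample and direction, a probe qualifies as hypermethylated
#' when its beta value is above the cohort 95th percentile for that probe
#' (nearest-rank, the sample's own value included) and at least `delta`
#' above the cohort mean; hypomethylated is the mirror rule.  Qualifying
#' probes are clustered left-to-right: a cluster is the maximal run of
#' qualifying probes within `window_bp` of its first probe, and clusters
#' with at least `min_probes` probes are emitted as DMRs spanning the
#' first to last contributing probe.
#'
#' @param beta probes x samples beta matrix.
#' @param manifest probe manifest (positions).
#' @param window_bp sliding-window width (default 1000).
#' @param min_probes minimum qualifying probes per DMR (default 3).
#' @param pct upper percentile (default 0.95; the lower tail uses
#'   `1 - pct`).
#' @param delta minimum distance from the cohort mean (default 0.1).
#' @return data.frame `sample_id, chrom, start, end, n_probes, direction`
#'   (`hyper`/`hypo`).
#' @export
detect_dmrs <- function(beta, manifest, window_bp = 1000, min_probes = 3,
                        pct = 0.95, delta = 0.1) {
  manifest <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  ord <- order(manifest$chrom, manifest$cpg_pos, manifest$probe_id)
  beta <- beta[ord, , drop = FALSE]
  manifest <- manifest[ord, , drop = FALSE]
  q_hi <- apply(beta, 1L, nearest_rank_quantile, p = pct)
  q_lo <- apply(beta, 1L, nearest_rank_quantile, p = 1 - pct)
  mu <- rowMeans(beta)
  H <- beta > q_hi & beta >= mu + delta
  L <- beta < q_lo & beta <= mu - delta
  cluster_emit <- function(pos_idx, sample_id, direction) {
    pos <- manifest$cpg_pos[pos_idx]
    chrom <- manifest$chrom[pos_idx]
    res <- list()
    for (ch in unique(chrom)) {
      p <- pos[chrom == ch]
      i <- 1L
      while (i <= length(p)) {
        j <- max(which(p <= p[i] + window_bp & seq_along(p) >= i))
        if (j - i + 1L >= min_probes) {
          res[[length(res) + 1L]] <- data.frame(
            sample_id = sample_id, chrom = ch, start = p[i], end = p[j],
            n_probes = j - i + 1L, direction = direction,
            stringsAsFactors = FALSE
          )
          i <- j + 1L
        } else {
          i <- i + 1L
        }
      }
    }
    res
  }
  out <- list()
  for (s in colnames(beta)) {
    hi <- which(H[, s])
    lo <- which(L[, s])
    if (length(hi) >= min_probes) out <- c(out, cluster_emit(hi, s, "hyper"))
    if (length(lo) >= min_probes) out <- c(out, cluster_emit(lo, s, "hypo"))
  }
  if (length(out) == 0) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$start, res$direction), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Link SNV:TFBS pairs to carrier-matched DMRs
#'
#' Restricts to pairs with at least `min_cpg` CpGs within the flank and at
#' least one outlier CpG, then links a pair to a DMR when a DMR called in
#' the carrier's sample overlaps the pair's motif interval +/- `flank_bp`.
#'
#' @param dmrs DMR table ([detect_dmrs()]).
#' @param pairs pair table.
#' @param calls outlier-call table.
#' @param manifest probe manifest.
#' @param flank_bp flank width (default 1000).
#' @param min_cpg minimum CpGs in window for eligibility (default 3).
#' @return list `links` (data.frame `pair_id, sample_id, dmr_chrom,
#'   dmr_start, dmr_end, direction`), `n_eligible`, `n_linked`,
#'   `frac_linked`.
#' @export
dmr_tfbs_intersection <- function(dmrs, pairs, calls, manifest,
                                  flank_bp = 1000, min_cpg = 3) {
  map <- assign_probes_to_pairs(pairs, manifest, flank_bp)
  n_cpg <- table(map$pair_id)
  with_out <- unique(calls$pair_id)
  eligible <- names(n_cpg)[n_cpg >= min_cpg]
  eligible <- intersect(eligible, with_out)
  links <- list()
  if (length(eligible) > 0 && nrow(dmrs) > 0) {
    ep <- pairs[match(eligible, pairs$pair_id), , drop = FALSE]
    carr <- carrier_list(ep)
    dg <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start, dmrs$end))
    wg <- GenomicRanges::GRanges(
      ep$chrom,
      IRanges::IRanges(pmax(1L, ep$start - flank_bp), ep$end + flank_bp)
    )
    hits <- GenomicRanges::findOverlaps(wg, dg)
    for (h in seq_along(hits)) {
      i <- S4Vectors::queryHits(hits)[h]
      j <- S4Vectors::subjectHits(hits)[h]
      if (!(dmrs$sample_id[j] %in% carr[[i]])) next
      links[[length(links) + 1L]] <- data.frame(
        pair_id = ep$pair_id[i], sample_id = dmrs$sample_id[j],
        dmr_chrom = dmrs$chrom[j], dmr_start = dmrs$start[j],
        dmr_end = dmrs$end[j], direction = dmrs$direction[j],
        stringsAsFactors = FALSE
      )
    }
  }
  links <- if (length(links) > 0) {
    unique(do.call(rbind, links))
  } else {
    data.frame(pair_id = character(0), sample_id = character(0),
               dmr_chrom = character(0), dmr_start = integer(0),
               dmr_end = integer(0), direction = character(0),
               stringsAsFactors = FALSE)
  }
  n_linked <- length(unique(links$pair_id))
  list(links = links, n_eligible = length(eligible), n_linked = n_linked,
       frac_linked = if (length(eligible) > 0) n_linked / length(eligible) else NA_real_)
}

#' Distance-binned enrichment analysis (1-100 kb)
#'
#' Bins CpGs by their distance from each pair's merged motif interval
#' (local CpGs at <= the first bin edge are excluded) and runs the
#' per-TF permutation machinery separately in each bin, with a Bonferroni
#' correction within each bin over the TFs tested there.
#'
#' @param ranked a [rank_betas()] result.
#' @param pairs pair table.
#' @param manifest probe manifest.
#' @param bin_edges increasing distance edges in bp; bin b is
#'   `(edges[b], edges[b+1]]`.  Default: 1 kb then 10-kb bins to 100 kb.
#' @param n_perm permutations per TF per bin.
#' @param seed integer seed for the whole analysis.
#' @param tail_frac,delta_min,mode outlier thresholds.
#' @return data.frame with one row per (TF, bin):
#'   `tf_name, bin_lo, bin_hi, n_pairs, n_cpg, observed_ratio, p_raw,
#'   p_bonferroni`.
#' @export
distance_bin_analysis <- function(ranked, pairs, manifest,
                                  bin_edges = c(1e3, seq(1e4, 1e5, by = 1e4)),
                                  n_perm = 1000, seed = 1L,
                                  tail_frac = 0.05, delta_min = 0.05,
                                  mode = "tail") {
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  set.seed(seed)
  map <- assign_probes_to_pairs(pairs, manifest, max_dist = max(bin_edges))
  out <- list()
  for (b in seq_len(length(bin_edges) - 1L)) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1L]
    sub <- map[map$distance > lo & map$distance <= hi, , drop = FALSE]
    if (nrow(sub) == 0) next
    obs <- build_tf_observations(ranked, pairs, manifest,
                                 tail_frac = tail_frac, delta_min = delta_min,
                                 mode = mode, map = sub)
    if (length(obs) == 0) next
    res <- lapply(obs, tf_permutation_test, n_perm = n_perm, seed = NA)
    df <- data.frame(
      tf_name = vapply(res, `[[`, character(1), "tf_name"),
      bin_lo = lo, bin_hi = hi,
      n_pairs = vapply(res, `[[`, numeric(1), "n_pairs"),
      n_cpg = vapply(res, `[[`, numeric(1), "n_cpg"),
      observed_ratio = vapply(res, `[[`, numeric(1), "observed_ratio"),
      p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
      stringsAsFactors = FALSE
    )
    df$p_bonferroni <- pmin(1, sum(!is.na(df$p_raw)) * df$p_raw)
    out[[length(out) + 1L]] <- df
  }
  if (length(out) == 0) {
    return(data.frame(tf_name = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), n_pairs = numeric(0),
                      n_cpg = numeric(0), observed_ratio = numeric(0),
                      p_raw = numeric(0), p_bonferroni = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build pseudo-pair windows around flanking (non-TFBS) variants
#'
#' Wraps flank variants ([find_flank_snvs()]) as single-base "pairs" so
#' the same window/enrichment machinery applies to the SNV-noTFBS class.
#'
#' @param variants flank variant data.frame.
#' @param tf_label label used as the `tf_name` of the class.
#' @return pair-table data.frame.
#' @export
flank_windows <- function(variants, tf_label = "SNV_noTFBS") {
  data.frame(
    pair_id = paste(variants$variant_id, tf_label, sep = "|"),
    variant_id = variants$variant_id, chrom = variants$chrom,
    pos = variants$pos, ref = variants$ref, alt = variants$alt,
    carriers = variants$carriers, tf_name = tf_label,
    start = variants$pos, end = variants$pos,
    n_instances = 0L, isolated = NA, strand = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Pooled enrichment ratio per chromosome
#'
#' Computes the observed carrier/control enrichment ratio pooled over all
#' pairs of each chromosome (used to contrast the SNV-TFBS and
#' SNV-noTFBS classes chromosome by chromosome).
#'
#' @param ranked a [rank_betas()] result.
#' @param pairs pair table (real pairs or [flank_windows()]).
#' @param manifest probe manifest.
#' @param flank_bp window flank.
#' @param tail_frac,delta_min,mode outlier thresholds.
#' @return named numeric vector, chromosome -> ratio (`NA` when
#'   undefined).
#' @export
per_chrom_enrichment <- function(ranked, pairs, manifest, flank_bp = 1000,
                                 tail_frac = 0.05, delta_min = 0.05,
                                 mode = "tail") {
  E <- extreme_matrix(ranked, tail_frac, delta_min, mode)
  map <- assign_probes_to_pairs(pairs, manifest, flank_bp)
  map <- map[map$probe_id %in% rownames(E), , drop = FALSE]
  carr <- carrier_list(pairs)
  chroms <- sort(unique(pairs$chrom))
  out <- stats::setNames(rep(NA_real_, length(chroms)), chroms)
  for (ch in chroms) {
    rows <- which(pairs$chrom == ch)
    co <- ct <- no <- nt <- 0
    for (i in rows) {
      pr <- map$probe_id[map$pair_id == pairs$pair_id[i]]
      if (length(pr) == 0) next
      carriers <- intersect(carr[[i]], ranked$samples)
      if (length(carriers) == 0 || length(carriers) == ranked$n) next
      sub <- E[pr, , drop = FALSE]
      ci <- match(carriers, ranked$samples)
      co <- co + sum(sub[, ci])
      no <- no + sum(sub[, -ci])
      ct <- ct + length(pr) * length(ci)
      nt <- nt + length(pr) * (ranked$n - length(ci))
    }
    if (ct > 0 && nt > 0) {
      out[ch] <- if (co == 0) 0 else if (no == 0) Inf else (co / ct) / (no / nt)
    }
  }
  out
}

#' Contrast TFBS and flank enrichment across chromosomes
#'
#' Pairs the per-chromosome enrichment of the SNV-TFBS class with that of
#' the SNV-noTFBS class and reports the fold difference of means and a
#' two-sided paired t-test.  With zero variance of the differences the t
#' statistic degenerates: all-zero differences give p = 1, constant
#' nonzero differences give p = 0 with a warning.
#'
#' @param tfbs_enrich,flank_enrich named per-chromosome ratio vectors
#'   ([per_chrom_enrichment()]).
#' @return list `fold, t, p, n_chroms`.
#' @export
flank_comparison <- function(tfbs_enrich, flank_enrich) {
  chroms <- intersect(names(tfbs_enrich), names(flank_enrich))
  x <- tfbs_enrich[chroms]
  y <- flank_enrich[chroms]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 chromosomes with defined enrichment in both classes")
  fold <- mean(x) / mean(y)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(fold = fold, t = 0, p = 1, n_chroms = length(x)))
    warning("zero variance of paired differences: p-value degenerates to 0")
    return(list(fold = fold, t = sign(mean(d)) * Inf, p = 0, n_chroms = length(x)))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(fold = fold, t = unname(tt$statistic), p = tt$p.value,
       n_chroms = length(x))
}

#' Region-overlap enrichment of outlier CpGs (meQTL / HSM)
#'
#' Tests whether outlier probes fall inside a region list (e.g. known
#' meQTL or haplotype-specific methylation intervals) more often than
#' non-outlier probes, via the sample odds ratio and a two-tailed exact
#' test ([fisher_exact_2x2()]).
#'
#' @param outlier_probes,nonoutlier_probes character vectors of probe ids.
#' @param regions `GRanges` region list.
#' @param manifest probe manifest (CpG coordinates).
#' @return list `odds_ratio, p, table` (2x2: outlier status x in-region).
#' @export
region_overlap_enrichment <- function(outlier_probes, nonoutlier_probes,
                                      regions, manifest) {
  in_region <- function(ids) {
    sub <- manifest[manifest$probe_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) return(0L)
    sum(GenomicRanges::countOverlaps(cpg_granges(sub), regions) > 0)
  }
  a <- in_region(outlier_probes)
  b <- length(outlier_probes) - a
  cc <- in_region(nonoutlier_probes)
  d <- length(nonoutlier_probes) - cc
  fisher_exact_2x2(a, b, cc, d)
}
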