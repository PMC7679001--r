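# Rare-variant filtering, SNV x TFBS intersection with same-TF merging,
# flanking (non-TFBS) SNV identification, and PWM disruption scoring.

carrier_list <- function(variants) {
  strsplit(variants$carriers, ",", fixed = TRUE)
}

#' Filter variants to the rare, autosomal spectrum
#'
#' Retains a variant iff its cohort allele frequency and every external
#' allele frequency are at most the thresholds, it is carried by at most
#' `max_carriers` individuals, and it is autosomal.  Missing external
#' frequencies are treated as 0 (absent from the database) and logged.
#'
#' @param variants variant data.frame ([load_variants()]).
#' @param cohort_maf_max,external_maf_max MAF thresholds (default 1%).
#' @param max_carriers maximum number of carrier individuals (default 2).
#' @return the filtered variant data.frame.
#' @export
filter_rare_variants <- function(variants, cohort_maf_max = 0.01,
                                 external_maf_max = 0.01, max_carriers = 2) {
  if (nrow(variants) == 0) return(variants)
  ext <- as.matrix(variants[, intersect(c("gnomad_af", "kg_af"), names(variants)),
                            drop = FALSE])
  n_missing <- sum(is.na(ext))
  if (n_missing > 0) {
    message(sprintf("filter_rare_variants: %d missing external AF value(s) treated as 0",
                    n_missing))
    ext[is.na(ext)] <- 0
  }
  n_carriers <- lengths(carrier_list(variants))
  keep <- variants$cohort_af <= cohort_maf_max &
    apply(ext <= external_maf_max, 1L, all) &
    n_carriers <= max_carriers &
    n_carriers >= 1L &
    is_autosome(variants$chrom)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Intersect rare SNVs with motif instances, merging same-TF overlaps
#'
#' Builds one SNV:TFBS pair per (variant, TF) where the variant overlaps
#' at least one motif instance of that TF (1-based position `p` overlaps a
#' 1-based inclusive interval `[s, e]` iff `s <= p <= e`).  Overlapping
#' instances of the same TF that share the variant are merged to their
#' union interval and the pair is marked non-isolated; a pair built from a
#' single instance is isolated and keeps the instance strand.
#'
#' @param variants rare variant data.frame.
#' @param motifs motif `GRanges` with `tf_name` ([load_motifs()]).
#' @return data.frame of pairs: `pair_id, variant_id, chrom, pos, ref,
#'   alt, carriers, tf_name, start, end` (1-based inclusive merged
#'   interval), `n_instances, isolated, strand`.
#' @export
intersect_and_merge <- function(variants, motifs) {
  empty <- data.frame(
    pair_id = character(0), variant_id = character(0), chrom = character(0),
    pos = integer(0), ref = character(0), alt = character(0),
    carriers = character(0), tf_name = character(0), start = integer(0),
    end = integer(0), n_instances = integer(0), isolated = logical(0),
    strand = character(0), stringsAsFactors = FALSE
  )
  if (nrow(variants) == 0 || length(motifs) == 0) return(empty)
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(vg, motifs, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  vi <- S4Vectors::queryHits(hits)
  mi <- S4Vectors::subjectHits(hits)
  key <- paste(vi, motifs$tf_name[mi], sep = "\r")
  starts <- GenomicRanges::start(motifs)[mi]
  ends <- GenomicRanges::end(motifs)[mi]
  strands <- as.character(GenomicRanges::strand(motifs))[mi]
  f <- factor(key, levels = unique(key))
  first <- match(levels(f), key)
  n_inst <- tabulate(f)
  res <- data.frame(
    variant_row = vi[first],
    tf_name = motifs$tf_name[mi[first]],
    start = as.integer(tapply(starts, f, min)),
    end = as.integer(tapply(ends, f, max)),
    n_instances = n_inst,
    isolated = n_inst == 1L,
    strand = ifelse(n_inst == 1L, strands[first], NA_character_),
    stringsAsFactors = FALSE
  )
  out <- data.frame(
    pair_id = paste(variants$variant_id[res$variant_row], res$tf_name, sep = "|"),
    variant_id = variants$variant_id[res$variant_row],
    chrom = variants$chrom[res$variant_row],
    pos = variants$pos[res$variant_row],
    ref = variants$ref[res$variant_row],
    alt = variants$alt[res$variant_row],
    carriers = variants$carriers[res$variant_row],
    tf_name = res$tf_name,
    start = res$start,
    end = res$end,
    n_instances = res$n_instances,
    isolated = res$isolated,
    strand = res$strand,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pair_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify rare SNVs flanking, but outside, all motifs
#'
#' Returns the variants lying within `flank_bp` of at least one motif edge
#' while overlapping no motif instance of any TF (the SNV-noTFBS class).
#'
#' @param variants rare variant data.frame.
#' @param motifs motif `GRanges`.
#' @param flank_bp flank width in bp (default 1000).
#' @return subset of `variants`.
#' @export
find_flank_snvs <- function(variants, motifs, flank_bp = 1000) {
  if (nrow(variants) == 0) return(variants)
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1L))
  inside <- GenomicRanges::countOverlaps(vg, motifs, ignore.strand = TRUE) > 0
  # a position is flanking iff it lies in [start - flank_bp, end + flank_bp]
  near <- GenomicRanges::countOverlaps(
    vg, suppressWarnings(motifs + flank_bp), ignore.strand = TRUE
  ) > 0
  out <- variants[near & !inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- attr(variants, "samples")
  out
}

#' Score the PWM disruption of a variant (deltaPWM)
#'
#' For an isolated SNV:TFBS pair, looks up the PWM probability of the
#' reference and alternate alleles at the variant's motif column and
#' returns their absolute difference.  On the `-` strand the motif offset
#' is counted from the interval end and both alleles are complemented
#' before lookup, so the score is invariant to the strand the motif was
#' annotated on.  By default the "score" of an allele is its raw
#' probability; `scale = "log2"` instead uses log2 probabilities with a
#' pseudocount.
#'
#' @param pair a single row of the pair table ([intersect_and_merge()]).
#' @param pwms named PWM list ([load_pwms()]).
#' @param scale `"prob"` (default) or `"log2"`.
#' @param pseudocount added to probabilities under `scale = "log2"`.
#' @return list `pair_id, motif_offset` (0-based), `ref_weight,
#'   alt_weight, delta`.
#' @export
delta_pwm <- function(pair, pwms, scale = c("prob", "log2"), pseudocount = 1e-3) {
  scale <- match.arg(scale)
  stopifnot(nrow(pair) == 1)
  if (!isTRUE(pair$isolated)) {
    stop("deltaPWM is only defined for isolated (unmerged) SNV:TFBS pairs")
  }
  pwm <- pwms[[pair$tf_name]]
  if (is.null(pwm)) stop(sprintf("no PWM available for TF %s", pair$tf_name))
  width <- pair$end - pair$start + 1L
  if (ncol(pwm) != width) {
    stop(sprintf("motif width %d != PWM width %d for TF %s",
                 width, ncol(pwm), pair$tf_name))
  }
  if (pair$pos < pair$start || pair$pos > pair$end) {
    stop("variant position outside the motif interval")
  }
  minus <- identical(pair$strand, "-")
  offset <- if (minus) pair$end - pair$pos else pair$pos - pair$start
  ref_m <- if (minus) complement_base(pair$ref) else pair$ref
  alt_m <- if (minus) complement_base(pair$alt) else pair$alt
  w_ref <- pwm[ref_m, offset + 1L]
  w_alt <- pwm[alt_m, offset + 1L]
  if (scale == "log2") {
    w_ref <- log2(w_ref + pseudocount)
    w_alt <- log2(w_alt + pseudocount)
  }
  list(pair_id = pair$pair_id, motif_offset = as.integer(offset),
       ref_weight = unname(w_ref), alt_weight = unname(w_alt),
       delta = unname(abs(w_ref - w_alt)))
}

#' deltaPWM for every eligible pair of a pair table
#'
#' Applies [delta_pwm()] to every isolated pair whose TF has a PWM of
#' matching width; other pairs get `NA` with the skip reason recorded.
#'
#' @param pairs pair table.
#' @param pwms named PWM list.
#' @param scale,pseudocount passed to [delta_pwm()].
#' @return `pairs` with added columns `motif_offset, ref_weight,
#'   alt_weight, delta_pwm`.
#' @export
delta_pwm_table <- function(pairs, pwms, scale = "prob", pseudocount = 1e-3) {
  out <- pairs
  out$motif_offset <- NA_integer_
  out$ref_weight <- NA_real_
  out$alt_weight <- NA_real_
  out$delta_pwm <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    row <- pairs[i, , drop = FALSE]
    if (!isTRUE(row$isolated) || is.null(pwms[[row$tf_name]])) next
    if (ncol(pwms[[row$tf_name]]) != row$end - row$start + 1L) next
    d <- delta_pwm(row, pwms, scale = scale, pseudocount = pseudocount)
    out$motif_offset[i] <- d$motif_offset
    out$ref_weight[i] <- d$ref_weight
    out$alt_weight[i] <- d$alt_weight
    out$delta_pwm[i] <- d$delta
  }
  out
}
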