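test_that("rare-variant filtering applies every exclusion rule", {
  v <- rbind(
    make_variants(pos = 100L, carriers = "S1"),
    make_variants(pos = 200L, carriers = "S1,S2,S3"),            # >2 carriers
    make_variants(pos = 300L, gnomad_af = 0.02, cohort_af = 0.002), # gnomAD common
    make_variants(chrom = "chrX", pos = 400L),                   # not autosomal
    make_variants(pos = 500L, kg_af = 0.05),                     # 1000G common
    make_variants(pos = 600L, cohort_af = 0.02)                  # cohort common
  )
  out <- filter_rare_variants(v)
  expect_equal(out$pos, c(100L))

  # missing external AF treated as 0, with a log message
  v2 <- make_variants(pos = 700L); v2$gnomad_af <- NA_real_
  expect_message(out2 <- filter_rare_variants(v2), "treated as 0")
  expect_equal(nrow(out2), 1L)
})

test_that("intersection merges overlapping same-TF motifs sharing the SNV", {
  # BED [90,110) and [95,115) as 1-based [91,110], [96,115]; SNV at 100
  motifs <- c(motif_gr("chr1", 91L, 110L, "CTCF"),
              motif_gr("chr1", 96L, 115L, "CTCF", strand = "-"))
  v <- make_variants(pos = 100L)
  pairs <- intersect_and_merge(v, motifs)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$start, 91L)            # union = BED [90, 115)
  expect_equal(pairs$end, 115L)
  expect_false(pairs$isolated)
  expect_true(is.na(pairs$strand))

  # distinct TFs give distinct pairs
  motifs2 <- c(motif_gr("chr1", 91L, 110L, "CTCF"),
               motif_gr("chr1", 96L, 115L, "SP1"))
  pairs2 <- intersect_and_merge(v, motifs2)
  expect_equal(sort(pairs2$tf_name), c("CTCF", "SP1"))
  expect_true(all(pairs2$isolated))

  # no overlap: no pairs
  expect_equal(nrow(intersect_and_merge(make_variants(pos = 5000L), motifs)), 0L)

  # invariant: start <= pos <= end for every pair
  expect_true(all(pairs2$start <= pairs2$pos & pairs2$pos <= pairs2$end))
})

test_that("merging agrees with a brute-force variant x motif scan", {
  co <- small_cohort()
  pairs <- intersect_and_merge(co$variants, co$motifs)
  mo <- as.data.frame(co$motifs)
  n_bf <- 0L
  for (i in seq_len(nrow(co$variants))) {
    for (tf in unique(mo$tf_name)) {
      sub <- mo[mo$tf_name == tf & mo$seqnames == co$variants$chrom[i] &
                  mo$start <= co$variants$pos[i] & mo$end >= co$variants$pos[i], ]
      if (nrow(sub) == 0) next
      n_bf <- n_bf + 1L
      pr <- pairs[pairs$variant_id == co$variants$variant_id[i] &
                    pairs$tf_name == tf, ]
      expect_equal(nrow(pr), 1L)
      expect_equal(pr$start, min(sub$start))
      expect_equal(pr$end, max(sub$end))
      expect_equal(pr$isolated, nrow(sub) == 1L)
    }
  }
  expect_equal(nrow(pairs), n_bf)
})

test_that("flank SNVs are near motifs but inside none", {
  motifs <- motif_gr("chr1", 1000L, 1019L, "TF1")
  near <- make_variants(pos = 950L)          # 50 bp upstream
  inside <- make_variants(pos = 1010L)
  far <- make_variants(pos = 2600L)          # > 1.5 kb away
  v <- rbind(near, inside, far)
  out <- find_flank_snvs(v, motifs, flank_bp = 1000)
  expect_equal(out$pos, 950L)
  # distance-scan oracle
  for (p in c(1L, 999L, 1000L, 1019L, 1020L, 2019L, 2020L, 2021L)) {
    r <- find_flank_snvs(make_variants(pos = p), motifs, flank_bp = 1000)
    in_motif <- p >= 1000 && p <= 1019
    near_m <- p >= 1000 - 1000 && p <= 1019 + 1000
    expect_identical(nrow(r) == 1L, near_m && !in_motif, info = paste("pos", p))
  }
})

test_that("deltaPWM uses the variant column, with strand complementation", {
  pwm <- matrix(1 / 4, nrow = 4, ncol = 10,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwms <- list(TF1 = pwm)
  pair <- make_pair(pos = 95L, start = 91L, end = 100L)
  d <- delta_pwm(pair, pwms)
  expect_equal(d$delta, 0)                    # uniform PWM: any substitution is 0
  expect_equal(d$motif_offset, 4L)

  # hand arithmetic: p(A)=0.97, p(T)=0.01 at offset 2, ref A alt T on +
  pwm2 <- matrix(1 / 4, nrow = 4, ncol = 5,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm2[, 3] <- c(0.97, 0.01, 0.01, 0.01)
  pair2 <- make_pair(pos = 93L, start = 91L, end = 95L, ref = "A", alt = "T")
  d2 <- delta_pwm(pair2, list(TF1 = pwm2))
  expect_equal(d2$delta, 0.96)
  expect_equal(d2$motif_offset, 2L)

  # minus strand: genomic ref A / alt G looked up as T and C at offset end - pos
  pwm3 <- matrix(c(0.1, 0.2, 0.3, 0.4,
                   0.7, 0.1, 0.1, 0.1,
                   0.25, 0.25, 0.25, 0.25), nrow = 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  pair3 <- make_pair(pos = 92L, start = 91L, end = 93L, ref = "A", alt = "G",
                     strand = "-")
  d3 <- delta_pwm(pair3, list(TF1 = pwm3))
  # offset = 93 - 92 = 1; lookup T vs C in column 2: |0.1 - 0.1| = 0
  expect_equal(d3$motif_offset, 1L)
  expect_equal(d3$delta, unname(abs(pwm3["T", 2] - pwm3["C", 2])))

  expect_error(delta_pwm(make_pair(isolated = FALSE), pwms), "isolated")
  expect_error(delta_pwm(make_pair(tf = "NOPE"), pwms), "no PWM")
  expect_error(delta_pwm(make_pair(start = 91L, end = 95L), pwms), "width")
})

test_that("deltaPWM is strand-involutive", {
  # brute-force oracle: a motif annotated on + and the same motif
  # annotated on - (with reverse-complemented PWM) give identical deltas
  set.seed(4)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    w <- sample(4:12, 1)
    pwm <- matrix(rgamma(4 * w, 1), nrow = 4, dimnames = list(bases, NULL))
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
    # reverse complement of the PWM: reverse columns, swap A<->T, C<->G
    pwm_rc <- pwm[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
    rownames(pwm_rc) <- bases
    start <- 1000L; end <- start + w - 1L
    pos <- sample(start:end, 1)
    ref <- sample(bases, 1); alt <- sample(setdiff(bases, ref), 1)
    d_plus <- delta_pwm(make_pair(pos = pos, start = start, end = end,
                                  ref = ref, alt = alt, strand = "+"),
                        list(TF1 = pwm))
    d_minus <- delta_pwm(make_pair(pos = pos, start = start, end = end,
                                   ref = ref, alt = alt, strand = "-"),
                         list(TF1 = pwm_rc))
    expect_equal(d_minus$delta, d_plus$delta, tolerance = 1e-12)
  }
})

test_that("delta_pwm_table annotates isolated pairs and skips the rest", {
  co <- small_cohort()
  pairs <- intersect_and_merge(co$variants, co$motifs)
  tab <- delta_pwm_table(pairs, co$pwms)
  iso <- tab$isolated & (tab$end - tab$start + 1L) ==
    vapply(tab$tf_name, function(tf) ncol(co$pwms[[tf]]), integer(1))
  expect_true(all(!is.na(tab$delta_pwm[iso])))
  expect_true(all(is.na(tab$delta_pwm[!tab$isolated])))
  expect_true(all(tab$delta_pwm >= 0 & tab$delta_pwm <= 1, na.rm = TRUE))
  # generator truth records the same deltas (for the variant's host TF)
  tr <- co$truth[match(tab$variant_id[iso], co$truth$variant_id), ]
  same_tf <- !is.na(tr$tf_name) & tr$tf_name == tab$tf_name[iso]
  expect_gt(sum(same_tf), 0)
  expect_equal(tab$delta_pwm[iso][same_tf], tr$delta_pwm[same_tf],
               tolerance = 1e-12)
})
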