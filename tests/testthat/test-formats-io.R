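test_that("minimal VCF round-trips and skips non-SNV records", {
  samples <- c("S1", "S2", "S3")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\tGAF=0.002;KAF=0.001\tGT\t0/1\t0/0\t0/0",
    "chr1\t200\t.\tA\tAT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "chr2\t300\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t0/1"
  ), path)
  v <- suppressMessages(load_variants(path))
  expect_equal(nrow(v), 2L)              # indel skipped
  expect_equal(attr(v, "n_skipped"), 1L)
  expect_equal(v$chrom, c("chr1", "chr2"))
  expect_equal(v$carriers, c("S1", "S2,S3"))
  expect_equal(v$gnomad_af[1], 0.002)
  expect_equal(v$kg_af[1], 0.001)
  expect_equal(v$cohort_af, c(1, 2) / 6)

  # write -> read identity on parsed fields
  out <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, samples, out)
  v2 <- load_variants(out)
  expect_equal(v2$variant_id, v$variant_id)
  expect_equal(v2$carriers, v$carriers)
  expect_equal(v2$gnomad_af, v$gnomad_af)
})

test_that("empty variant sets produce header-only VCFs that load back", {
  path <- withr::local_tempfile(fileext = ".vcf")
  empty <- make_variants()[0, ]
  write_variants_vcf(empty, c("S1", "S2"), path)
  v <- load_variants(path)
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "samples"), c("S1", "S2"))
})

test_that("BED motifs follow the 0-based half-open convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t89\t104\tCTCF\t0\t+", path)
  m <- load_motifs(path)
  expect_equal(GenomicRanges::start(m), 90L)   # 1-based inclusive
  expect_equal(GenomicRanges::end(m), 104L)
  expect_equal(GenomicRanges::width(m), 15L)
  expect_equal(m$tf_name, "CTCF")
  out <- withr::local_tempfile(fileext = ".bed")
  write_motifs_bed(m, out)
  expect_equal(readLines(out), "chr1\t89\t104\tCTCF\t0\t+")
})

test_that("variant-motif overlap matches the exhaustive half-open oracle", {
  # motif BED [s0, e0) = [5, 9): 1-based bases 6..9
  motifs <- motif_gr("chr1", 6L, 9L, "TF1")
  s0 <- 5L; e0 <- 9L
  for (p in 1:15) {
    v <- make_variants(pos = p)
    pairs <- intersect_and_merge(v, motifs)
    expect_identical(nrow(pairs) == 1L, s0 < p && p <= e0, info = paste("pos", p))
  }
})

test_that("PWM loader renormalizes small deviations and rejects large ones", {
  pwms <- list(TFA = matrix(c(0.97, 0.01, 0.01, 0.01,
                              0.25, 0.25, 0.25, 0.25), nrow = 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwms(pwms, path)
  back <- load_pwms(path)
  expect_equal(back$TFA, pwms$TFA, tolerance = 1e-12)

  # column sum 1.0005: within tolerance, renormalized
  writeLines(c("tf_name\twidth\tA\tC\tG\tT",
               "TFB\t1\t0.9705\t0.01\t0.01\t0.01"), path)
  expect_message(b2 <- load_pwms(path), "renormalized")
  expect_equal(sum(b2$TFB), 1, tolerance = 1e-12)

  # off by more than 1e-3: rejected
  writeLines(c("tf_name\twidth\tA\tC\tG\tT",
               "TFC\t1\t0.9\t0.01\t0.01\t0.01"), path)
  expect_error(load_pwms(path), "column sum")
})

test_that("beta loader enforces bounds, completeness, and manifest match", {
  beta <- make_beta(matrix(c(0.1, 0.9, 0.5, 0.4), 2))
  man <- make_manifest(c(100, 200))
  bp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_beta(beta, bp, man, mp)
  back <- load_beta(bp, mp)
  expect_equal(back$beta, beta, tolerance = 1e-12)
  expect_equal(back$manifest$cpg_pos, man$cpg_pos)

  bad <- beta; bad[1, 1] <- 1.2
  write_beta(bad, bp)
  expect_error(load_beta(bp, mp), "outside \\[0,1\\].*cg001.*S001")
})

test_that("cell fractions, expression, and gene models round-trip", {
  fr <- data.frame(sample_id = c("S1", "S2"),
                   CD4T = 0.15, CD8T = 0.1, Bcell = 0.05, NK = 0.05,
                   Gran = 0.6, Mono = 0.05, stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_cell_fractions(fr, p1)
  expect_equal(load_cell_fractions(p1), fr, tolerance = 1e-12)

  bad <- fr; bad$Gran <- 0.1
  write_cell_fractions(bad, p1)
  expect_error(load_cell_fractions(p1), "sum")

  z <- make_beta(matrix(rnorm(6), 2), probe_ids = c("G1", "G2"),
                 sample_ids = c("S1", "S2", "S3"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(z, p2)
  expect_equal(load_expression(p2), z, tolerance = 1e-10)

  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(1000L, 5000L),
                      stringsAsFactors = FALSE)
  p3 <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(genes, p3)
  expect_equal(load_gene_models(p3), genes)
})

test_that("region lists load as GRanges (BED) or probe-id vectors", {
  p <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\tR1\t0\t+", "chr2\t5\t50\tR2\t0\t-"), p)
  gr <- load_region_list(p)
  expect_s4_class(gr, "GRanges")
  expect_length(gr, 2L)
  writeLines(c("cg001", "cg007"), p)
  expect_equal(load_region_list(p), c("cg001", "cg007"))
})
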