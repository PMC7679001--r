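# Shared fixtures, built in code.  Heavier cohorts are cached per session
# so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small, fully analyzable cohort with a handful of planted TFs
small_cohort <- function() {
  cached("small", {
    cfg <- sim_config(n_samples = 60, n_tfs = 10, n_motif_instances = 120,
                      n_variants = 60, frac_effect_tfs = 0.3,
                      frac_two_carrier = 0, seed = 42)
    suppressMessages(generate_cohort(cfg))
  })
}

# manifest builder: probes at given positions on one chromosome
make_manifest <- function(pos, chrom = "chr1", snp_in_last5 = FALSE,
                          multimapping = FALSE) {
  n <- length(pos)
  data.frame(
    probe_id = sprintf("cg%03d", seq_len(n)),
    chrom = rep(chrom, length.out = n),
    cpg_pos = as.integer(pos),
    body_start = as.integer(pos) - 50L,
    body_end = as.integer(pos),
    snp_in_last5 = rep(snp_in_last5, length.out = n),
    multimapping = rep(multimapping, length.out = n),
    stringsAsFactors = FALSE
  )
}

# beta matrix builder from a probes x samples numeric matrix
make_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probe_ids %||% sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("S%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-row pair table
make_pair <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                      carriers = "S001", tf = "TF1", start = 91L, end = 110L,
                      isolated = TRUE, strand = "+") {
  vid <- paste(chrom, pos, ref, alt, sep = ":")
  data.frame(
    pair_id = paste(vid, tf, sep = "|"), variant_id = vid, chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt, carriers = carriers,
    tf_name = tf, start = as.integer(start), end = as.integer(end),
    n_instances = 1L, isolated = isolated, strand = strand,
    stringsAsFactors = FALSE
  )
}

# variant table row(s)
make_variants <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                          carriers = "S001", cohort_af = 0.002,
                          gnomad_af = 0.001, kg_af = 0.001) {
  data.frame(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    carriers = carriers, cohort_af = cohort_af, gnomad_af = gnomad_af,
    kg_af = kg_af, stringsAsFactors = FALSE
  )
}

motif_gr <- function(chrom, start, end, tf, strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand,
                         tf_name = tf)
}
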