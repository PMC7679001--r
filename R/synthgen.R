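# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: a rare-variant
# spectrum with 1-2 heterozygous carriers per SNV, Factorbook-style motif
# instances and PWMs, an EPIC-like bimodal beta-value matrix with
# Beta-distributed per-probe noise, carrier-specific beta shifts planted at
# CpGs near mutated motifs (optionally proportional to the PWM disruption
# of the variant), cell-fraction-correlated nuisance probes, and
# promoter-methylation-linked expression outliers.  A ground-truth table
# records every planted effect.

#' Build and validate a simulation configuration
#'
#' Defaults describe the cohort the pipeline targets: 247 samples, 133 TFs
#' with ~10 variant-bearing motifs each, six EPIC-like probes per ±1 kb
#' motif window, Beta noise with concentration 60 (inter-individual SD
#' ~0.02-0.06 across the beta range), heterozygous variants carried by 1-2
#' samples, and a planted carrier shift of 0.3 beta units at CpGs around
#' motifs of the effect TFs.
#'
#' @param n_samples cohort size (>= 4).
#' @param n_tfs number of transcription factors.
#' @param n_motif_instances motif instances placed genome-wide (before
#'   adding deliberately overlapping duplicates).
#' @param n_variants rare SNVs (split between motif-overlapping and
#'   flanking variants by `frac_flank_variants`).
#' @param n_probes total probes; `NULL` sizes the array as all window/far
#'   probes plus 15% genomic background.
#' @param frac_effect_tfs fraction of TFs whose variants carry planted
#'   effects.
#' @param effect_beta_shift planted carrier beta shift (beta units).
#' @param effect_pwm_coupling if `TRUE`, the planted shift magnitude is
#'   `effect_beta_shift * deltaPWM` of the variant; otherwise constant.
#' @param noise_concentration Beta-distribution concentration of per-probe
#'   noise (larger = tighter).
#' @param frac_nuisance_probes fraction of probes made to track one blood
#'   cell fraction.
#' @param expression_effect_z expression shift (Z units) planted for genes
#'   whose promoter probes were beta-shifted.
#' @param seed integer RNG seed; a fixed seed makes the cohort
#'   byte-reproducible.
#' @param genome_length_per_chrom,n_chroms synthetic genome geometry.
#' @param probes_per_window probes placed in each variant's motif ±1 kb
#'   window.
#' @param frac_flank_variants fraction of variants placed 100-900 bp
#'   outside a motif (the SNV-noTFBS class).
#' @param frac_overlap_motifs fraction of motif instances duplicated with a
#'   half-width offset to create overlapping same-TF clusters (exercises
#'   merging).
#' @param frac_two_carrier probability a variant has 2 carriers (else 1).
#' @param frac_gain probability a planted shift is a methylation gain;
#'   the default emulates the observed excess of gains.
#' @param long_range if `TRUE`, additionally place probes 2-100 kb from
#'   each variant-bearing motif and decay planted shifts as
#'   `exp(-d / decay_tau_bp)`.
#' @param decay_tau_bp distance-decay scale in bp.
#' @param far_max_bp maximum probe distance for the long-range scenario.
#' @param far_probes_per_pair far probes per variant-bearing motif.
#' @param n_genes genes in the expression set.
#' @param frac_low_expr_genes fraction of background genes given mean
#'   RPKM < 1 (removed by the expression filter).
#' @param frac_flagged_probes per-flag probability of the manifest QC flags.
#' @param probe_window_bp half-width of the probe placement window around
#'   each variant-bearing motif (default 1000, matching the analysis
#'   flank).
#' @return validated config (list) of class `sim_config`.
#' @export
sim_config <- function(n_samples = 247, n_tfs = 133,
                       n_motif_instances = 20 * n_tfs,
                       n_variants = 10 * n_tfs, n_probes = NULL,
                       frac_effect_tfs = 0.15, effect_beta_shift = 0.3,
                       effect_pwm_coupling = FALSE, noise_concentration = 60,
                       frac_nuisance_probes = 0.02, expression_effect_z = 3,
                       seed = 1L, genome_length_per_chrom = 2e7, n_chroms = 4,
                       probes_per_window = 6, frac_flank_variants = 0.1,
                       frac_overlap_motifs = 0.05, frac_two_carrier = 0.5,
                       frac_gain = 0.59, long_range = FALSE,
                       decay_tau_bp = 15000, far_max_bp = 1e5,
                       far_probes_per_pair = 10, n_genes = 300,
                       frac_low_expr_genes = 0.1, frac_flagged_probes = 0.01,
                       probe_window_bp = 1000) {
  cfg <- as.list(environment())
  props <- c("frac_effect_tfs", "frac_nuisance_probes", "frac_flank_variants",
             "frac_overlap_motifs", "frac_two_carrier", "frac_gain",
             "frac_low_expr_genes", "frac_flagged_probes")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must be in [0, 1]", p))
  }
  counts <- c("n_samples", "n_tfs", "n_motif_instances", "n_variants",
              "n_chroms", "probes_per_window", "n_genes")
  for (p in counts) {
    if (cfg[[p]] < 1) stop(sprintf("%s must be a positive count", p))
  }
  if (n_samples < 4) stop("n_samples must be >= 4 (permutation enumeration impossible below)")
  if (effect_beta_shift < 0 || effect_beta_shift > 1) {
    stop("effect_beta_shift must be in [0, 1] beta units")
  }
  n_motif_variants <- n_variants - round(frac_flank_variants * n_variants)
  if (n_motif_variants > n_motif_instances) {
    stop("more motif-overlapping variants requested than motif instances")
  }
  min_probes <- n_motif_variants * probes_per_window +
    if (long_range) n_motif_variants * far_probes_per_pair else 0L
  if (is.null(cfg$n_probes)) {
    cfg$n_probes <- ceiling(1.15 * max(min_probes, 10))
  } else if (cfg$n_probes < min_probes) {
    stop("n_probes too small for the requested per-window probe placement")
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# random PWM for one TF: one dominant base per column, conservation
# (dominant-base probability) uniform in [0.28, 0.97] so deltaPWM spans
# near-degenerate to near-fixed positions, as real motifs do.
random_pwm <- function(width) {
  cons <- sample.int(4L, width, replace = TRUE)
  consv <- runif(width, 0.28, 0.97)
  mat <- matrix(rep((1 - consv) / 3, each = 4L), nrow = 4L)
  mat[cbind(cons, seq_len(width))] <- consv
  rownames(mat) <- DNA_BASES
  mat
}

#' Generate a fully self-consistent synthetic cohort
#'
#' Produces genotypes, motif instances, PWMs, a methylation beta matrix
#' with probe manifest, blood cell-type fractions, an expression set with
#' gene models, and a ground-truth table.  All randomness flows from
#' `config$seed`: the same config yields byte-identical cohorts.
#'
#' Planted variants sit inside motif instances of the effect TFs; their
#' carriers' beta values at the probes of the motif ±1 kb window are
#' shifted by the planted amount (clipped to \[0,1\], clip count logged in
#' the `clip_count` element).  Probe baselines are drawn from a 50/50
#' mixture of Beta distributions with means ~0.1 and ~0.9 (EPIC-like
#' bimodality); probes in a planted window take the baseline pole that
#' leaves room for the planted shift direction.  Genes assigned to motif
#' variants get a TSS within ±1.5 kb of the variant, and carriers of
#' planted promoter variants receive an expression shift of
#' `expression_effect_z` standard units opposite in sign to the
#' methylation shift.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `config, samples,
#'   variants, motifs, pwms, beta, manifest, cell_fractions, expression`
#'   (list `raw`, `rpkm_mean`, `z`), `gene_models, truth, clip_count`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  chroms <- paste0("chr", seq_len(config$n_chroms))
  samples <- sprintf("S%03d", seq_len(n))
  tf_names <- sprintf("TF%03d", seq_len(config$n_tfs))

  ## PWMs -------------------------------------------------------------
  widths <- sample(8:24, config$n_tfs, replace = TRUE)
  pwms <- lapply(widths, random_pwm)
  names(pwms) <- tf_names

  ## motif instances ---------------------------------------------------
  margin <- max(150000, config$far_max_bp + 2000)
  if (config$genome_length_per_chrom <= 2 * margin) {
    stop("genome_length_per_chrom too small for probe placement margins")
  }
  span <- as.integer(config$genome_length_per_chrom - 2 * margin)
  n_base <- config$n_motif_instances
  m_tf <- rep(seq_len(config$n_tfs), length.out = n_base)
  m_chrom <- sample(chroms, n_base, replace = TRUE)
  m_w <- widths[m_tf]
  m_start <- sample.int(span, n_base, replace = TRUE) + as.integer(margin)
  m_strand <- sample(c("+", "-"), n_base, replace = TRUE)
  n_ov <- round(config$frac_overlap_motifs * n_base)
  if (n_ov > 0) {
    ov <- sample.int(n_base, n_ov)
    m_tf <- c(m_tf, m_tf[ov])
    m_chrom <- c(m_chrom, m_chrom[ov])
    m_w <- c(m_w, m_w[ov])
    m_start <- c(m_start, m_start[ov] + pmax(1L, m_w[ov] %/% 2L))
    m_strand <- c(m_strand, m_strand[ov])
  }
  motifs <- GenomicRanges::GRanges(
    seqnames = m_chrom,
    ranges = IRanges::IRanges(start = m_start, width = m_w),
    strand = m_strand,
    tf_name = tf_names[m_tf]
  )

  ## variants ----------------------------------------------------------
  n_flank <- round(config$frac_flank_variants * config$n_variants)
  n_mv <- config$n_variants - n_flank
  n_eff <- round(config$frac_effect_tfs * config$n_tfs)
  effect_tfs <- if (n_eff > 0) sample(tf_names, n_eff) else character(0)

  # balanced host selection: round-robin variants over TFs, hosts drawn
  # from that TF's base instances without replacement where possible
  per_tf <- tabulate(rep(seq_len(config$n_tfs), length.out = n_mv),
                     nbins = config$n_tfs)
  host <- integer(0)
  for (t in seq_len(config$n_tfs)) {
    if (per_tf[t] == 0) next
    inst <- which(m_tf == t)
    host <- c(host, sample(inst, per_tf[t], replace = per_tf[t] > length(inst)))
  }
  h_tf <- tf_names[m_tf[host]]
  h_start <- m_start[host]
  h_end <- m_start[host] + m_w[host] - 1L
  h_strand <- m_strand[host]
  h_chrom <- m_chrom[host]
  h_w <- m_w[host]

  offset <- vapply(h_w, function(w) sample.int(w, 1L) - 1L, integer(1))
  pwm_col <- offset + 1L
  cons_base <- vapply(seq_len(n_mv), function(i) {
    DNA_BASES[which.max(pwms[[h_tf[i]]][, pwm_col[i]])]
  }, character(1))
  alt_motif <- vapply(cons_base, function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
  delta <- vapply(seq_len(n_mv), function(i) {
    col <- pwms[[h_tf[i]]][, pwm_col[i]]
    abs(col[cons_base[i]] - col[alt_motif[i]])
  }, numeric(1))
  pos <- ifelse(h_strand == "+", h_start + offset, h_end - offset)
  ref <- ifelse(h_strand == "+", cons_base, complement_base(cons_base))
  alt <- ifelse(h_strand == "+", alt_motif, complement_base(alt_motif))

  planted <- h_tf %in% effect_tfs
  sgn <- ifelse(runif(n_mv) < config$frac_gain, 1, -1)
  magnitude <- if (config$effect_pwm_coupling) {
    config$effect_beta_shift * delta
  } else {
    rep(config$effect_beta_shift, n_mv)
  }
  shift <- ifelse(planted, sgn * magnitude, 0)

  n_carrier <- 1L + rbinom(config$n_variants, 1L, config$frac_two_carrier)
  carriers <- lapply(n_carrier, function(k) sort(sample(samples, k)))

  # flanking (SNV-noTFBS) variants
  f_host <- if (n_flank > 0) sample.int(n_base, n_flank, replace = TRUE) else integer(0)
  f_gap <- sample(100:900, n_flank, replace = TRUE)
  f_side <- sample(c(-1L, 1L), n_flank, replace = TRUE)
  f_pos <- ifelse(f_side < 0, m_start[f_host] - f_gap,
                  m_start[f_host] + m_w[f_host] - 1L + f_gap)
  f_ref <- sample(DNA_BASES, n_flank, replace = TRUE)
  f_alt <- vapply(f_ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))

  v_chrom <- c(h_chrom, m_chrom[f_host])
  v_pos <- as.integer(c(pos, f_pos))
  v_ref <- c(ref, f_ref)
  v_alt <- c(alt, f_alt)
  v_class <- c(rep("motif", n_mv), rep("flank", n_flank))
  v_tf <- c(h_tf, rep(NA_character_, n_flank))
  v_shift <- c(shift, rep(0, n_flank))
  v_delta <- c(delta, rep(NA_real_, n_flank))
  v_planted <- c(planted, rep(FALSE, n_flank))
  variant_id <- variant_key(v_chrom, v_pos, v_ref, v_alt)
  keep <- !duplicated(variant_id)
  if (!all(keep)) {
    idx <- which(keep)
  } else {
    idx <- seq_along(variant_id)
  }

  variants <- data.frame(
    variant_id = variant_id[idx],
    chrom = v_chrom[idx],
    pos = v_pos[idx],
    ref = v_ref[idx],
    alt = v_alt[idx],
    carriers = vapply(carriers[idx], paste, character(1), collapse = ","),
    cohort_af = n_carrier[idx] / (2 * n),
    gnomad_af = round(runif(length(idx), 0, 0.009), 6),
    kg_af = round(runif(length(idx), 0, 0.009), 6),
    stringsAsFactors = FALSE
  )
  attr(variants, "samples") <- samples

  ## probes -------------------------------------------------------------
  # window probes around each motif variant (>= 60 bp from the variant so
  # the probe-body SNV exclusion never removes them)
  ppw <- config$probes_per_window
  wbp <- as.integer(config$probe_window_bp)
  win_variant <- rep(seq_len(n_mv), each = ppw)
  lo <- h_start[win_variant] - wbp
  hi <- h_end[win_variant] + wbp
  w_pos <- integer(length(win_variant))
  for (i in seq_along(w_pos)) {
    repeat {
      p <- lo[i] + sample.int(hi[i] - lo[i] + 1L, 1L) - 1L
      if (abs(p - pos[win_variant[i]]) >= 60L) break
    }
    w_pos[i] <- p
  }
  probe_chrom <- h_chrom[win_variant]
  probe_pos <- w_pos
  probe_origin <- win_variant            # originating motif-variant index
  probe_kind <- rep("window", length(w_pos))

  if (config$long_range) {
    fpp <- config$far_probes_per_pair
    far_variant <- rep(seq_len(n_mv), each = fpp)
    d <- round(runif(length(far_variant), 2000, config$far_max_bp))
    side <- sample(c(-1L, 1L), length(far_variant), replace = TRUE)
    fpos <- ifelse(side < 0, h_start[far_variant] - d, h_end[far_variant] + d)
    probe_chrom <- c(probe_chrom, h_chrom[far_variant])
    probe_pos <- c(probe_pos, as.integer(fpos))
    probe_origin <- c(probe_origin, far_variant)
    probe_kind <- c(probe_kind, rep("far", length(fpos)))
  }

  n_bg <- config$n_probes - length(probe_pos)
  if (n_bg > 0) {
    bg_chrom <- sample(chroms, n_bg, replace = TRUE)
    bg_pos <- sample.int(span, n_bg, replace = TRUE) + as.integer(margin)
    probe_chrom <- c(probe_chrom, bg_chrom)
    probe_pos <- c(probe_pos, bg_pos)
    probe_origin <- c(probe_origin, rep(NA_integer_, n_bg))
    probe_kind <- c(probe_kind, rep("background", n_bg))
  }

  ord <- order(probe_chrom, probe_pos)
  probe_chrom <- probe_chrom[ord]
  probe_pos <- probe_pos[ord]
  probe_origin <- probe_origin[ord]
  probe_kind <- probe_kind[ord]
  P <- length(probe_pos)
  probe_id <- sprintf("cg%06d", seq_len(P))

  manifest <- data.frame(
    probe_id = probe_id,
    chrom = probe_chrom,
    cpg_pos = probe_pos,
    body_start = probe_pos - 50L,       # 0-based half-open, CpG = last base
    body_end = probe_pos,
    snp_in_last5 = runif(P) < config$frac_flagged_probes,
    multimapping = runif(P) < config$frac_flagged_probes,
    stringsAsFactors = FALSE
  )

  ## beta matrix --------------------------------------------------------
  low_pole <- runif(P) < 0.5
  is_planted_window <- !is.na(probe_origin) & planted[ifelse(is.na(probe_origin), 1L, probe_origin)]
  low_pole[is_planted_window] <- shift[probe_origin[is_planted_window]] > 0
  mu <- ifelse(low_pole, rbeta(P, 2, 18), rbeta(P, 18, 2))
  mu <- pmin(pmax(mu, 0.02), 0.98)
  conc <- config$noise_concentration
  beta <- matrix(
    rbeta(P * n, rep(mu * conc, each = n), rep((1 - mu) * conc, each = n)),
    nrow = P, byrow = TRUE, dimnames = list(probe_id, samples)
  )

  ## cell fractions and nuisance probes ---------------------------------
  fr <- rdirichlet(n, c(CD4T = 9, CD8T = 5, Bcell = 3, NK = 2, Gran = 35, Mono = 4))
  colnames(fr) <- CELL_TYPES
  cell_fractions <- data.frame(sample_id = samples, fr, stringsAsFactors = FALSE)
  n_nu <- round(config$frac_nuisance_probes * P)
  bg_idx <- which(probe_kind == "background")
  nuis <- if (n_nu > 0 && length(bg_idx) > 0) {
    sample(bg_idx, min(n_nu, length(bg_idx)))
  } else integer(0)
  nuis_type <- sample(CELL_TYPES, length(nuis), replace = TRUE)
  for (j in seq_along(nuis)) {
    f <- fr[, nuis_type[j]]
    mu_ps <- pmin(pmax(mu[nuis[j]] + 1.2 * (f - mean(f)), 0.02), 0.98)
    beta[nuis[j], ] <- rbeta(n, mu_ps * conc, (1 - mu_ps) * conc)
  }

  ## planted carrier shifts ---------------------------------------------
  clip_count <- 0L
  affected <- vector("list", n_mv)
  kept_mv <- idx[idx <= n_mv]
  for (i in intersect(which(planted), kept_mv)) {
    pr <- which(!is.na(probe_origin) & probe_origin == i)
    if (length(pr) == 0) next
    d_edge <- pmax(0L, h_start[i] - probe_pos[pr], probe_pos[pr] - h_end[i])
    eff <- ifelse(probe_kind[pr] == "far" & config$long_range,
                  shift[i] * exp(-d_edge / config$decay_tau_bp), shift[i])
    car <- carriers[[i]]
    newv <- beta[pr, car, drop = FALSE] + eff
    clip_count <- clip_count + sum(newv < 0 | newv > 1)
    beta[pr, car] <- pmin(pmax(newv, 0), 1)
    affected[[i]] <- probe_id[pr[abs(eff) > 1e-12]]
  }
  if (clip_count > 0) {
    message(sprintf("generate_cohort: clipped %d planted beta value(s) to [0,1]", clip_count))
  }

  ## genes and expression ------------------------------------------------
  n_genes <- config$n_genes
  n_prom <- min(n_mv, round(0.8 * n_genes))
  prom_variant <- if (n_prom > 0) {
    ord_v <- order(!planted)            # planted variants get genes first
    ord_v[seq_len(n_prom)]
  } else integer(0)
  g_chrom <- character(n_genes); g_tss <- integer(n_genes)
  g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  if (n_prom > 0) {
    g_chrom[seq_len(n_prom)] <- h_chrom[prom_variant]
    g_tss[seq_len(n_prom)] <- pos[prom_variant] +
      sample(-1500:1500, n_prom, replace = TRUE)
  }
  if (n_genes > n_prom) {
    rest <- (n_prom + 1):n_genes
    g_chrom[rest] <- sample(chroms, length(rest), replace = TRUE)
    g_tss[rest] <- sample.int(span, length(rest), replace = TRUE) + as.integer(margin)
  }
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  gene_models <- data.frame(
    gene_id = gene_id, chrom = g_chrom, strand = g_strand,
    tss = pmax(1L, g_tss), stringsAsFactors = FALSE
  )
  rpkm_mean <- runif(n_genes, 1.5, 50)
  if (n_genes > n_prom && config$frac_low_expr_genes > 0) {
    rest <- (n_prom + 1):n_genes
    low <- rest[runif(length(rest)) < config$frac_low_expr_genes]
    rpkm_mean[low] <- runif(length(low), 0.05, 0.9)
  }
  raw <- matrix(rnorm(n_genes * n), nrow = n_genes,
                dimnames = list(gene_id, samples))
  expr_gene <- rep(NA_character_, n_mv)
  for (j in seq_along(prom_variant)) {
    i <- prom_variant[j]
    if (!planted[i]) next
    raw[j, carriers[[i]]] <- raw[j, carriers[[i]]] -
      sign(shift[i]) * config$expression_effect_z
    expr_gene[i] <- gene_id[j]
  }
  keep_g <- rpkm_mean >= 1
  z <- raw[keep_g, , drop = FALSE]
  z <- t(scale(t(z)))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL

  ## truth table ----------------------------------------------------------
  truth <- data.frame(
    variant_id = variant_id,
    tf_name = v_tf,
    class = v_class,
    planted = v_planted,
    planted_shift = v_shift,
    delta_pwm = v_delta,
    affected_probes = c(
      vapply(seq_len(n_mv), function(i) {
        paste(affected[[i]] %||% character(0), collapse = ",")
      }, character(1)),
      rep("", n_flank)
    ),
    planted_expression_gene = c(expr_gene, rep(NA_character_, n_flank)),
    stringsAsFactors = FALSE
  )[idx, , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(
    config = config, samples = samples, variants = variants, motifs = motifs,
    pwms = pwms, beta = beta, manifest = manifest,
    cell_fractions = cell_fractions,
    expression = list(raw = raw, rpkm_mean = stats::setNames(rpkm_mean, gene_id), z = z),
    gene_models = gene_models, truth = truth, clip_count = clip_count
  ), class = "sim_cohort")
}

#' Write a synthetic cohort to its on-disk formats
#'
#' Emits `cohort.vcf` (minimal VCF 4.2), `motifs.bed`, `pwms.tsv`,
#' `beta.tsv` + `manifest.tsv`, `cell_fractions.tsv`, `expression.tsv`
#' (Z-scores), `expression_raw.tsv`, `rpkm_means.tsv`, `genes.bed`, and
#' `truth.tsv` under `out_dir`.  Everything round-trips through the
#' package loaders.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_variants_vcf(cohort$variants, cohort$samples, p("cohort.vcf"))
  write_motifs_bed(cohort$motifs, p("motifs.bed"))
  write_pwms(cohort$pwms, p("pwms.tsv"))
  write_beta(cohort$beta, p("beta.tsv"), cohort$manifest, p("manifest.tsv"))
  write_cell_fractions(cohort$cell_fractions, p("cell_fractions.tsv"))
  write_expression(cohort$expression$z, p("expression.tsv"))
  write_expression(cohort$expression$raw, p("expression_raw.tsv"))
  write.table(
    data.frame(gene_id = names(cohort$expression$rpkm_mean),
               rpkm_mean = cohort$expression$rpkm_mean),
    p("rpkm_means.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_gene_models(cohort$gene_models, p("genes.bed"))
  write.table(cohort$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return list with the loaded components (`variants, motifs, pwms, beta,
#'   manifest, cell_fractions, expression_z, expression_raw, rpkm_mean,
#'   gene_models, truth`).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  bm <- load_beta(p("beta.tsv"), p("manifest.tsv"))
  rp <- read.delim(p("rpkm_means.tsv"), stringsAsFactors = FALSE)
  list(
    variants = load_variants(p("cohort.vcf")),
    motifs = load_motifs(p("motifs.bed")),
    pwms = load_pwms(p("pwms.tsv")),
    beta = bm$beta,
    manifest = bm$manifest,
    cell_fractions = load_cell_fractions(p("cell_fractions.tsv")),
    expression_z = load_expression(p("expression.tsv")),
    expression_raw = load_expression(p("expression_raw.tsv")),
    rpkm_mean = stats::setNames(rp$rpkm_mean, rp$gene_id),
    gene_models = load_gene_models(p("genes.bed")),
    truth = read.delim(p("truth.tsv"), stringsAsFactors = FALSE)
  )
}
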