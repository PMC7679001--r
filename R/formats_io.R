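# Readers and writers for every external format the pipeline touches.
#
# Coordinate conventions (applied once, at load):
#   * VCF positions are 1-based.
#   * BED intervals on disk are 0-based half-open; they are converted to
#     1-based inclusive GRanges by rtracklayer at load and stay that way
#     internally.  A variant at 1-based position p overlaps a BED interval
#     [s, e) iff s < p <= e, i.e. 1-based start <= p <= 1-based end.

#' Load rare-variant genotypes from a minimal VCF
#'
#' Parses biallelic SNV records from a minimal VCF 4.2 file (`CHROM POS ID
#' REF ALT QUAL FILTER INFO FORMAT` plus per-sample `GT` columns).
#' Multiallelic and non-SNV records are skipped and counted.  Carriers are
#' the samples whose genotype contains the alternate allele.  The cohort
#' allele frequency is recomputed from the genotypes (heterozygous = 1
#' allele); external allele frequencies are read from the `GAF` (gnomAD)
#' and `KAF` (1000 Genomes) INFO keys when present.
#'
#' @param vcf_path path to the VCF file.
#' @return data.frame of variants with columns `variant_id, chrom, pos,
#'   ref, alt, carriers` (comma-separated sample ids), `cohort_af,
#'   gnomad_af, kg_af`, and attributes `samples` (all sample ids) and
#'   `n_skipped` (records dropped as multiallelic/non-SNV).
#' @export
load_variants <- function(vcf_path) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "##")]
  header <- body[1]
  stopifnot(startsWith(header, "#CHROM"))
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  samples <- if (length(cols) > 9) cols[-(1:9)] else character(0)
  if (anyDuplicated(samples)) stop("duplicate sample ids in VCF header")
  n_records <- length(body) - 1L

  empty <- data.frame(
    variant_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), carriers = character(0),
    cohort_af = numeric(0), gnomad_af = numeric(0), kg_af = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n_records == 0L) {
    attr(empty, "samples") <- samples
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  info <- vcfR::getINFO(v)

  is_snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    message(sprintf("load_variants: skipped %d multiallelic/non-SNV record(s)", n_skipped))
  }
  if (!any(is_snv)) {
    attr(empty, "samples") <- samples
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  fix <- fix[is_snv, , drop = FALSE]
  gt <- gt[is_snv, , drop = FALSE]
  info <- info[is_snv]

  if (any(!grepl("^[01.]([/|][01.])?$", gt))) stop("malformed GT field")
  alt_count <- matrix(
    vapply(gt, function(g) sum(strsplit(g, "[/|]")[[1]] == "1"), integer(1)),
    nrow = nrow(fix)
  )
  carriers <- apply(alt_count > 0, 1L, function(row) {
    paste(samples[row], collapse = ",")
  })
  grab_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    out <- rep(NA_real_, length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), info) > 0
    out[hit] <- as.numeric(sub(paste0(".*", key, "="), "", m))
    out
  }
  out <- data.frame(
    variant_id = variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    carriers = carriers,
    cohort_af = rowSums(alt_count) / (2 * max(1L, length(samples))),
    gnomad_af = grab_info("GAF"),
    kg_af = grab_info("KAF"),
    stringsAsFactors = FALSE
  )
  bad_af <- c(out$cohort_af, out$gnomad_af, out$kg_af)
  stopifnot(all(is.na(bad_af) | (bad_af >= 0 & bad_af <= 1)))
  attr(out, "samples") <- samples
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write variants as a minimal VCF 4.2
#'
#' @param variants variant data.frame as returned by [load_variants()].
#' @param samples character vector of all sample ids (column order).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, samples, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GAF,Number=1,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=KAF,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- character(0)
  if (nrow(variants) > 0) {
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    info <- vapply(seq_len(nrow(variants)), function(i) {
      parts <- character(0)
      if (!is.na(variants$gnomad_af[i])) {
        parts <- c(parts, sprintf("GAF=%.6g", variants$gnomad_af[i]))
      }
      if (!is.na(variants$kg_af[i])) {
        parts <- c(parts, sprintf("KAF=%.6g", variants$kg_af[i]))
      }
      if (length(parts) == 0) "." else paste(parts, collapse = ";")
    }, character(1))
    carrier_sets <- strsplit(variants$carriers, ",", fixed = TRUE)
    gt <- vapply(seq_len(nrow(variants)), function(i) {
      g <- ifelse(samples %in% carrier_sets[[i]], "0/1", "0/0")
      paste(g, collapse = "\t")
    }, character(1))
    recs <- paste(variants$chrom, variants$pos, variants$variant_id,
                  variants$ref, variants$alt, ".", "PASS", info, "GT", gt,
                  sep = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Load TFBS motif instances from BED6
#'
#' The BED name column holds the TF name and the strand column is used; the
#' score column is ignored.  Intervals are returned as a 1-based inclusive
#' `GRanges` with a `tf_name` metadata column.
#'
#' @param bed_path path to a BED6 file.
#' @return `GRanges` of motif instances.
#' @export
load_motifs <- function(bed_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (length(gr) > 0 && (is.null(gr$name) || anyNA(gr$name))) {
    stop("motif BED must carry the TF name in column 4")
  }
  names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "name"] <- "tf_name"
  gr
}

#' Write motifs as BED6
#' @param motifs `GRanges` with `tf_name` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motifs_bed <- function(motifs, path) {
  gr <- motifs
  gr$name <- gr$tf_name
  gr$tf_name <- NULL
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load per-TF position weight matrices
#'
#' Tab-separated file with one row per TF: `tf_name`, `width`, then four
#' comma-separated probability lists ordered A, C, G, T.  Columns whose
#' probabilities sum to within 1e-3 of 1 are renormalized (and logged);
#' larger deviations are rejected.
#'
#' @param pwm_path path to the PWM table.
#' @return named list of 4 x width probability matrices with rownames
#'   `A, C, G, T`.
#' @export
load_pwms <- function(pwm_path) {
  lines <- readLines(pwm_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) return(structure(list(), names = character(0)))
  lines <- lines[-1]  # header
  pwms <- list()
  n_renorm <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    stopifnot(length(f) == 6L)
    tf <- f[1]
    width <- as.integer(f[2])
    rows <- lapply(f[3:6], function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
    mat <- do.call(rbind, rows)
    rownames(mat) <- DNA_BASES
    if (ncol(mat) != width) stop(sprintf("PWM %s: row length != declared width", tf))
    if (any(mat < 0)) stop(sprintf("PWM %s: negative probability", tf))
    cs <- colSums(mat)
    off <- abs(cs - 1)
    if (any(off > 1e-3)) {
      stop(sprintf("PWM %s: column sum off by > 1e-3 (max deviation %.4g)", tf, max(off)))
    }
    if (any(off > 1e-6)) {
      mat <- sweep(mat, 2L, cs, "/")
      n_renorm <- n_renorm + 1L
    }
    pwms[[tf]] <- mat
  }
  if (n_renorm > 0) message(sprintf("load_pwms: renormalized columns of %d PWM(s)", n_renorm))
  pwms
}

#' Write a PWM set to the tab-separated table format
#' @param pwms named list of 4 x width probability matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  lines <- c("tf_name\twidth\tA\tC\tG\tT")
  for (tf in names(pwms)) {
    mat <- pwms[[tf]]
    rows <- vapply(DNA_BASES, function(b) {
      paste(format(mat[b, ], digits = 15, scientific = FALSE, trim = TRUE),
            collapse = ",")
    }, character(1))
    lines <- c(lines, paste(c(tf, ncol(mat), rows), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a methylation beta matrix and its probe manifest
#'
#' The matrix is probes x samples with a `probe_id` first column; the
#' manifest carries 1-based CpG positions and a 0-based half-open
#' probe-body interval plus QC flags.  Values outside \[0,1\] and missing
#' entries are load errors (the rank-based outlier statistic cannot
#' tolerate imputation).
#'
#' @param matrix_path path to the beta-value TSV.
#' @param manifest_path path to the probe manifest TSV.
#' @return list with `beta` (numeric matrix, rownames = probe ids) and
#'   `manifest` (data.frame).
#' @export
load_beta <- function(matrix_path, manifest_path) {
  tab <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "probe_id")
  beta <- as.matrix(tab[, -1, drop = FALSE])
  rownames(beta) <- tab$probe_id
  if (anyNA(beta)) {
    bad <- which(is.na(beta), arr.ind = TRUE)[1, ]
    stop(sprintf("missing beta value at probe %s, sample %s",
                 rownames(beta)[bad[1]], colnames(beta)[bad[2]]))
  }
  if (any(beta < 0 | beta > 1)) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value outside [0,1] at probe %s, sample %s",
                 rownames(beta)[bad[1]], colnames(beta)[bad[2]]))
  }
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "cpg_pos", "body_start", "body_end",
            "snp_in_last5", "multimapping")
  stopifnot(all(need %in% names(manifest)))
  manifest$snp_in_last5 <- as.logical(manifest$snp_in_last5)
  manifest$multimapping <- as.logical(manifest$multimapping)
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe ids in manifest")
  if (!setequal(manifest$probe_id, rownames(beta)) ||
      nrow(manifest) != nrow(beta)) {
    stop("manifest and beta matrix disagree on probe set")
  }
  manifest <- manifest[match(rownames(beta), manifest$probe_id), , drop = FALSE]
  rownames(manifest) <- NULL
  list(beta = beta, manifest = manifest)
}

#' Write a beta matrix (and optionally its manifest) to TSV
#' @param beta probes x samples numeric matrix.
#' @param path output path for the matrix.
#' @param manifest optional manifest data.frame.
#' @param manifest_path output path for the manifest (required with
#'   `manifest`).
#' @return `path`, invisibly.
#' @export
write_beta <- function(beta, path, manifest = NULL, manifest_path = NULL) {
  tab <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(manifest)) {
    stopifnot(!is.null(manifest_path))
    write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Load per-sample blood cell-type fractions
#'
#' TSV with a `sample_id` column plus the six estimated blood cell-type
#' fractions (CD4T, CD8T, Bcell, NK, Gran, Mono).  Per-sample sums must be
#' within \[0.9, 1.1\] (estimation slack).
#'
#' @param path path to the TSV.
#' @return data.frame with `sample_id` and the six fraction columns.
#' @export
load_cell_fractions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", CELL_TYPES)
  stopifnot(all(need %in% names(tab)))
  fr <- as.matrix(tab[, CELL_TYPES])
  stopifnot(all(fr >= 0 & fr <= 1))
  s <- rowSums(fr)
  if (any(s < 0.9 | s > 1.1)) stop("cell fractions per sample must sum to within [0.9, 1.1]")
  tab[, need]
}

CELL_TYPES <- c("CD4T", "CD8T", "Bcell", "NK", "Gran", "Mono")

#' Write cell fractions to TSV
#' @param fractions data.frame as from [load_cell_fractions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_fractions <- function(fractions, path) {
  write.table(fractions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a gene x sample expression table
#' @param path TSV with `gene_id` first column, one column per sample.
#' @return numeric matrix, rownames = gene ids.
#' @export
load_expression <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "gene_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  m
}

#' Write a gene x sample expression table
#' @param mat numeric matrix, rownames = gene ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  tab <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load gene models from BED6
#'
#' Each record is a single-base interval marking the transcription start
#' site; the TSS is the interval start for `+` genes and the end for `-`
#' genes (identical for single-base records).  The name column is the gene
#' id.
#'
#' @param path BED6 path.
#' @return data.frame `gene_id, chrom, strand, tss` (1-based).
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  tss <- ifelse(strand == "-", GenomicRanges::end(gr), GenomicRanges::start(gr))
  out <- data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = as.integer(tss),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids")
  stopifnot(all(out$tss >= 1))
  out
}

#' Write gene models as BED6 (single-base TSS intervals)
#' @param genes data.frame as from [load_gene_models()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss, width = 1L),
    strand = genes$strand,
    name = genes$gene_id,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load a region list (BED or one probe id per line)
#'
#' Used for meQTL/HSM interval lists and user probe blacklists.  A file
#' whose first data line has 3+ tab-separated fields is treated as BED and
#' returned as a `GRanges`; otherwise it is read as a plain list of probe
#' ids (character vector).
#'
#' @param path input path.
#' @return `GRanges` or character vector.
#' @export
load_region_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(character(0))
  if (length(strsplit(lines[1], "\t", fixed = TRUE)[[1]]) >= 3L) {
    rtracklayer::import(path, format = "BED")
  } else {
    lines
  }
}
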