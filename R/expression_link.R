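# Integration of promoter methylation outliers with expression outliers
# in a small (cardiac-style) cohort.

#' Z-score an expression matrix after the expression filter
#'
#' Genes with mean RPKM below 1 are dropped (not expressed); remaining
#' genes are converted per gene to Z-scores across samples.  Genes with
#' zero variance are dropped with a log entry.
#'
#' @param expr_matrix genes x samples expression values.
#' @param rpkm_means named per-gene mean RPKM vector.
#' @return Z-score matrix (retained genes x samples) with attribute
#'   `dropped` listing genes removed and why.
#' @export
zscore_expression <- function(expr_matrix, rpkm_means) {
  if (ncol(expr_matrix) < 4) stop("need >= 4 samples to Z-score expression")
  rp <- rpkm_means[rownames(expr_matrix)]
  if (anyNA(rp)) stop("rpkm_means missing for some genes")
  low <- rownames(expr_matrix)[rp < 1]
  keep <- expr_matrix[rp >= 1, , drop = FALSE]
  sds <- apply(keep, 1L, sd)
  flat <- rownames(keep)[sds == 0]
  if (length(flat) > 0) {
    message(sprintf("zscore_expression: dropped %d zero-variance gene(s)", length(flat)))
  }
  keep <- keep[sds > 0, , drop = FALSE]
  z <- t(scale(t(keep)))
  attr(z, "dropped") <- list(low_expression = low, zero_variance = flat)
  z
}

#' Expression records with outlier flags
#'
#' @param z Z-score matrix ([zscore_expression()]).
#' @param z_thresh outlier threshold on `|z|` (strict, default 2).
#' @return data.frame `gene_id, sample_id, z, outlier`.
#' @export
expression_records <- function(z, z_thresh = 2) {
  data.frame(
    gene_id = rep(rownames(z), times = ncol(z)),
    sample_id = rep(colnames(z), each = nrow(z)),
    z = as.vector(z),
    outlier = abs(as.vector(z)) > z_thresh,
    stringsAsFactors = FALSE
  )
}

#' Least-squares residualization of expression against covariates
#'
#' Optional helper for removing known covariates (tissue, platform, age,
#' ...) before Z-scoring, by per-gene ordinary least squares.
#'
#' @param expr_matrix genes x samples values.
#' @param covariates data.frame of per-sample covariates (rows aligned to
#'   the columns of `expr_matrix`).
#' @return residual matrix of the same shape.
#' @export
residualize_expression <- function(expr_matrix, covariates) {
  stopifnot(nrow(covariates) == ncol(expr_matrix))
  mm <- stats::model.matrix(~ ., data = covariates)
  res <- t(apply(expr_matrix, 1L, function(y) stats::lm.fit(mm, y)$residuals))
  dimnames(res) <- dimnames(expr_matrix)
  res
}

#' Small-cohort extreme methylation calls
#'
#' For cohorts too small for 5% tails (e.g. n = 20), a carrier is an
#' outlier at a CpG when its rank is exactly 1 (bottom) or n (top) of the
#' rank distribution and its beta value differs from the control mean by
#' at least `delta_min`.
#'
#' @param ranked a [rank_betas()] result (n >= 4).
#' @param pairs pair table.
#' @param manifest probe manifest.
#' @param delta_min minimum absolute beta difference (default 0.05).
#' @param flank_bp window flank (default 1000).
#' @return outlier-call data.frame (see [call_outliers()]).
#' @export
small_cohort_outliers <- function(ranked, pairs, manifest, delta_min = 0.05,
                                  flank_bp = 1000) {
  if (ranked$n < 4) stop("n_samples < 4")
  call_outliers(ranked, pairs, manifest, delta_min = delta_min,
                flank_bp = flank_bp, mode = "extreme")
}

#' Assign each SNV:TFBS pair to the promoter of its closest gene
#'
#' The closest gene is chosen by distance from the merged-interval
#' midpoint to the (strand-aware) TSS; the pair is retained iff the
#' variant position lies within `[tss - promoter_bp, tss + promoter_bp]`
#' inclusive.  Pairs on chromosomes without genes are dropped.
#'
#' @param pairs pair table.
#' @param genes gene models ([load_gene_models()]).
#' @param promoter_bp promoter half-width (default 2000).
#' @return data.frame `pair_id, gene_id, tss, distance` (midpoint-to-TSS).
#' @export
promoter_pairs <- function(pairs, genes, promoter_bp = 2000) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- genes[genes$chrom == pairs$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    mid <- (pairs$start[i] + pairs$end[i]) %/% 2L
    d <- abs(g$tss - mid)
    j <- order(d, g$gene_id)[1]
    if (pairs$pos[i] < g$tss[j] - promoter_bp ||
        pairs$pos[i] > g$tss[j] + promoter_bp) next
    out[[length(out) + 1L]] <- data.frame(
      pair_id = pairs$pair_id[i], gene_id = g$gene_id[j], tss = g$tss[j],
      distance = d[j], stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(pair_id = character(0), gene_id = character(0),
                      tss = integer(0), distance = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of expression outliers at methylation-outlier promoters
#'
#' Crosses each promoter pair's methylation-outlier association with its
#' carrier's expression-outlier status (`|z| > z_thresh` for the pair's
#' gene in the carrier sample) in a 2x2 table; reports the fold
#' difference of the outlier-expression fractions and a two-tailed exact
#' p-value.  With two carriers the first (sorted sample id) defines the
#' expression cell.
#'
#' @param assoc pair-association table ([pair_association()]).
#' @param pair_gene promoter map ([promoter_pairs()]).
#' @param z Z-score matrix.
#' @param pairs pair table (provides carriers).
#' @param z_thresh expression-outlier threshold (default 2).
#' @return list `fold, p, table, n_pairs` (`fold` is `NA` when a margin
#'   is empty, with p = 1).
#' @export
expression_outlier_enrichment <- function(assoc, pair_gene, z, pairs,
                                          z_thresh = 2) {
  tab <- merge(pair_gene, assoc, by = "pair_id")
  tab <- tab[tab$gene_id %in% rownames(z), , drop = FALSE]
  carr <- carrier_list(pairs)
  names(carr) <- pairs$pair_id
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(tab))) {
    carriers <- sort(carr[[tab$pair_id[i]]])
    carrier <- carriers[carriers %in% colnames(z)][1]
    if (is.na(carrier)) next
    expr_out <- abs(z[tab$gene_id[i], carrier]) > z_thresh
    if (tab$associated[i]) {
      if (expr_out) a <- a + 1L else b <- b + 1L
    } else {
      if (expr_out) cc <- cc + 1L else d <- d + 1L
    }
  }
  fe <- fisher_exact_2x2(a, b, cc, d)
  fold <- if ((a + b) > 0 && (cc + d) > 0 && (cc / (cc + d)) > 0) {
    (a / (a + b)) / (cc / (cc + d))
  } else if ((a + b) > 0 && (cc + d) > 0 && a > 0) {
    Inf
  } else {
    NA_real_
  }
  list(fold = fold, p = fe$p, table = fe$table, n_pairs = a + b + cc + d)
}
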