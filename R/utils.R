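#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta rbinom rnorm runif rgamma sd cor t.test wilcox.test
#'   ks.test dhyper setNames model.matrix lm.fit
#' @importFrom utils read.delim write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

#' Is a chromosome name autosomal?
#'
#' Sex chromosomes and the mitochondrial contig are excluded from all
#' rare-variant analyses; everything else is treated as autosomal.
#'
#' @param chrom character vector of chromosome names (with or without a
#'   `chr` prefix).
#' @return logical vector.
#' @export
is_autosome <- function(chrom) {
  !grepl("^(chr)?(X|Y|M|MT)$", chrom, ignore.case = TRUE)
}

#' Nearest-rank quantile
#'
#' The percentile definition used by the DMR caller: the value at index
#' `ceiling(p * n)` of the sorted vector (the tested sample's own value is
#' included in the cohort distribution).
#'
#' @param x numeric vector, no NAs.
#' @param p probability in (0, 1).
#' @return a single value of `x`.
#' @export
nearest_rank_quantile <- function(x, p) {
  stopifnot(length(x) >= 1L, p > 0, p < 1)
  sort(x)[max(1L, ceiling(p * length(x)))]
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration (sum of all table
#' probabilities not exceeding that of the observed table, conditional on
#' the margins) and the sample odds ratio `(a*d)/(b*c)`.
#'
#' @param a,b,c,d non-negative integer cell counts of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio`, `p`, and `table`.
#' @examples
#' fisher_exact_2x2(10, 90, 10, 890) # OR ~ 9.89
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  odds_ratio <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else {
    (a * d) / (b * c)
  }
  # degenerate margin: no information
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = odds_ratio, p = 1, table = tab))
  }
  m <- a + b        # row-1 total
  n2 <- c + d       # row-2 total
  k <- a + c        # column-1 total
  support <- max(0L, k - n2):min(k, m)
  dens <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(odds_ratio = odds_ratio, p = min(1, p), table = tab)
}

# Dirichlet draws via gamma normalization (rows sum to 1).
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# stable variant key
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# GRanges helper for CpG positions of a manifest
cpg_granges <- function(manifest) {
  GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$cpg_pos, width = 1L),
    probe_id = manifest$probe_id
  )
}
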