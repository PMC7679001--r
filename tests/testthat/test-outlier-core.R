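test_that("ranks are ascending with lexicographic tie-breaking", {
  b <- make_beta(matrix(c(0.3, 0.1, 0.2), 1), sample_ids = c("S1", "S2", "S3"))
  r <- rank_betas(b)
  expect_equal(unname(r$rank[1, ]), c(3L, 1L, 2L))

  b2 <- make_beta(matrix(c(0.2, 0.2, 0.1), 1), sample_ids = c("S1", "S2", "S3"))
  r2 <- rank_betas(b2)
  expect_equal(unname(r2$rank[1, ]), c(2L, 3L, 1L))    # tie S1 before S2

  # property: ranks are a permutation of 1..n on random matrices with ties
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    b3 <- make_beta(matrix(sample(seq(0, 1, 0.05), 5 * n, replace = TRUE), 5))
    r3 <- rank_betas(b3)
    for (i in 1:5) expect_setequal(r3$rank[i, ], seq_len(n))
  }

  # n = 247: ranks span exactly 1..247
  b4 <- make_beta(matrix(runif(247), 1), sample_ids = sprintf("S%03d", 1:247))
  r4 <- rank_betas(b4)
  expect_equal(range(r4$rank), c(1L, 247L))
})

test_that("outlier calls require both an extreme rank and the beta difference", {
  n <- 247
  samples <- sprintf("S%03d", seq_len(n))
  # carrier S001 sits at rank 13 (k = floor(0.05 * 247) = 12): not extreme
  vals <- 0.5 + seq_len(n) * 1e-4
  b <- make_beta(matrix(vals[c(13, setdiff(seq_len(n), 13))], 1),
                 sample_ids = samples)
  man <- make_manifest(100L)
  pair <- make_pair(carriers = "S001")
  ranked <- rank_betas(b)
  expect_equal(unname(ranked$rank[1, "S001"]), 13L)
  calls <- call_outliers(ranked, pair, man)
  expect_equal(nrow(calls), 0L)

  # carrier at rank 247 with delta beta = +0.06: a methylation gain
  b2 <- make_beta(matrix(c(0.56, rep(0.5, n - 1)) , 1), sample_ids = samples)
  calls2 <- call_outliers(rank_betas(b2), pair, man)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$rank, 247L)
  expect_equal(calls2$direction, "gain")
  expect_equal(calls2$delta_beta, 0.06, tolerance = 1e-12)

  # identical beta everywhere: no outlier regardless of rank
  b3 <- make_beta(matrix(rep(0.5, n), 1), sample_ids = samples)
  expect_equal(nrow(call_outliers(rank_betas(b3), pair, man)), 0L)

  # k = 0 refused
  b4 <- make_beta(matrix(runif(10), 1))
  expect_error(call_outliers(rank_betas(b4), pair, man), "extreme")
})

test_that("enrichment ratio handles zeros and infinities", {
  expect_equal(enrichment_ratio(2, 4, 10, 1000), 50)
  expect_equal(enrichment_ratio(0, 4, 10, 1000), 0)
  expect_equal(enrichment_ratio(1, 4, 0, 1000), Inf)
  expect_message(r <- enrichment_ratio(1, 0, 10, 1000), "undefined")
  expect_true(is.na(r))
})

test_that("permutation test matches exhaustive enumeration", {
  # 4 samples, 1 pair, 1 probe, only the carrier cell extreme: p = 1/4
  ob <- list(tf_name = "T", cmat = matrix(c(1, 0, 0, 0), 1), n_probes = 1L,
             carriers = list(1L), n_samples = 4L, n_cpg = 1L, pair_ids = "p")
  expect_equal(tf_permutation_test(ob, exact = TRUE)$p_raw, 0.25)
  mc <- tf_permutation_test(ob, n_perm = 10000, seed = 1)
  expect_equal(mc$p_raw, 0.25, tolerance = 0.02)

  # the same case through the full stack (carrier 0.56, controls 0.50)
  b <- make_beta(matrix(c(0.56, 0.5, 0.5, 0.5), 1), sample_ids = paste0("S", 1:4))
  man <- make_manifest(100L)
  pair <- make_pair(carriers = "S1")
  obs <- build_tf_observations(rank_betas(b), pair, man, mode = "extreme")
  expect_equal(tf_permutation_test(obs[[1]], exact = TRUE)$p_raw, 0.25)

  # random small cohorts (n <= 8, 1-2 carriers): MC within the add-one
  # estimator's binomial error of the enumerated value
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    n_pairs <- sample(1:3, 1)
    cmat <- matrix(rpois(n_pairs * n, 0.8), n_pairs, n)
    carriers <- lapply(seq_len(n_pairs), function(i) {
      sort(sample.int(n, sample(1:2, 1)))
    })
    ob2 <- list(tf_name = "T", cmat = cmat,
                n_probes = pmax(1L, apply(cmat, 1, max)),
                carriers = carriers, n_samples = n, n_cpg = sum(cmat > 0),
                pair_ids = paste0("p", seq_len(n_pairs)))
    p_ex <- tf_permutation_test(ob2, exact = TRUE)$p_raw
    B <- 20000
    p_mc <- tf_permutation_test(ob2, n_perm = B, seed = rep)$p_raw
    se <- sqrt(p_ex * (1 - p_ex) / B)
    expect_lt(abs(p_mc - p_ex), 4 * se + 2 / B)
  }

  # no extreme cells anywhere: observed ratio 0, every permutation >= 0
  ob0 <- list(tf_name = "T", cmat = matrix(0, 1, 4), n_probes = 1L,
              carriers = list(1L), n_samples = 4L, n_cpg = 1L, pair_ids = "p")
  expect_equal(tf_permutation_test(ob0, n_perm = 100, seed = 1)$p_raw, 1)

  # infinite observed ratio reached only by the matching assignment
  ob_inf <- list(tf_name = "T", cmat = matrix(c(1, rep(0, 9)), 1),
                 n_probes = 1L, carriers = list(1L), n_samples = 10L,
                 n_cpg = 1L, pair_ids = "p")
  expect_equal(tf_permutation_test(ob_inf, exact = TRUE)$p_raw, 0.1)
  expect_error(tf_permutation_test(ob0, n_perm = 10), "seed")
})

test_that("direction enrichment reports the gain/loss fold", {
  calls <- data.frame(direction = c(rep("gain", 29), rep("loss", 20)))
  expect_equal(direction_enrichment(calls)$fold, 1.45)
  calls2 <- data.frame(direction = c(rep("gain", 5), rep("loss", 5)))
  expect_equal(direction_enrichment(calls2)$fold, 1)
  calls3 <- data.frame(direction = rep("loss", 5))
  expect_equal(direction_enrichment(calls3)$fold, 0)
  calls4 <- data.frame(direction = rep("gain", 3))
  expect_warning(d4 <- direction_enrichment(calls4), "infinite")
  expect_equal(d4$fold, Inf)
})

test_that("the 1/3 rule decides pair association", {
  map <- data.frame(pair_id = c(rep("p1", 3), rep("p2", 4), "p3"),
                    probe_id = sprintf("cg%03d", 1:8), distance = 0L)
  calls <- data.frame(pair_id = c("p1", "p2", "p3"),
                      probe_id = c("cg001", "cg004", "cg008"))
  a <- pair_association(calls, map)
  expect_equal(a$associated[a$pair_id == "p1"], TRUE)     # 1/3 >= 1/3
  expect_equal(a$associated[a$pair_id == "p2"], FALSE)    # 1/4
  expect_equal(a$associated[a$pair_id == "p3"], TRUE)     # 1/1
  # zero-CpG pairs never appear (dropped, not FALSE)
  expect_false("p4" %in% a$pair_id)
})

test_that("per-cell outlier probability under the null respects the tail bound", {
  co <- cached("medium_null", {
    cfg <- sim_config(n_samples = 150, n_tfs = 20, n_motif_instances = 200,
                      n_variants = 120, frac_effect_tfs = 0, seed = 55)
    suppressMessages(generate_cohort(cfg))
  })
  ranked <- rank_betas(co$beta)
  E <- extreme_matrix(ranked, tail_frac = 0.05, delta_min = 0.05)
  k <- floor(0.05 * ranked$n)
  expect_gt(length(E), 1e5)
  expect_lte(mean(E), 2 * k / ranked$n)
  # and the rank component alone hits the bound exactly
  in_tail <- ranked$rank <= k | ranked$rank >= ranked$n - k + 1L
  expect_equal(mean(in_tail), 2 * k / ranked$n)
})

test_that("distance binning assigns CpGs to the declared 10-kb bins", {
  pair <- make_pair(carriers = "S001", start = 10000L, end = 10019L)
  man <- make_manifest(c(10005L, 10500L, 15519L, 95000L, 160019L))
  map <- assign_probes_to_pairs(pair, man, max_dist = 1e5)
  expect_equal(map$distance, c(0L, 481L, 5500L, 84981L))   # 160 kb probe absent
  bins <- c(1e3, seq(1e4, 1e5, by = 1e4))
  bin_of <- function(d) which(d > bins[-length(bins)] & d <= bins[-1])
  expect_equal(bin_of(5500), 1L)                            # (1 kb, 10 kb]
  expect_length(bin_of(500), 0L)                            # local: excluded
  expect_length(bin_of(150000), 0L)                         # out of range
})

test_that("flank comparison handles degenerate and textbook cases", {
  x <- setNames(rep(1.5, 5), paste0("chr", 1:5))
  expect_equal(flank_comparison(x, x), list(fold = 1, t = 0, p = 1, n_chroms = 5))

  y <- x - 0.5
  expect_warning(r <- flank_comparison(x, y), "zero variance")
  expect_equal(r$p, 0)

  expect_error(flank_comparison(x[1:2], y[1:2]), ">= 3")

  # closed-form paired-t oracle on 22 constructed chromosome pairs
  set.seed(7)
  d <- rnorm(22, 0.2, 0.1)
  base <- runif(22, 0.8, 1.6)
  tf <- setNames(base + d, paste0("chr", 1:22))
  fl <- setNames(base, paste0("chr", 1:22))
  r2 <- flank_comparison(tf, fl)
  t_hand <- mean(d) / (sd(d) / sqrt(22))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 21)
  expect_equal(r2$t, t_hand, tolerance = 1e-12)
  expect_equal(r2$p, p_hand, tolerance = 1e-12)
  expect_equal(r2$fold, mean(tf) / mean(fl), tolerance = 1e-12)
})

test_that("Fisher's exact 2x2 matches stats::fisher.test exhaustively", {
  expect_equal(fisher_exact_2x2(10, 90, 10, 890)$odds_ratio, 9.888889,
               tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(10, 90, 10, 890)$p,
               stats::fisher.test(matrix(c(10, 10, 90, 890), 2))$p.value,
               tolerance = 1e-9)
  # proportional table: OR 1
  expect_equal(fisher_exact_2x2(10, 90, 20, 180)$odds_ratio, 1)
  # empty margin: p 1, OR undefined
  z <- fisher_exact_2x2(0, 0, 5, 10)
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
  # exhaustive small tables
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) for (d in 0:5) {
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    expect_equal(
      fisher_exact_2x2(a, b, cc, d)$p,
      stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
      tolerance = 1e-9, info = paste(a, b, cc, d)
    )
  }
})

test_that("region-overlap enrichment builds the right 2x2 table", {
  man <- make_manifest(seq(100, 2000, by = 100))           # 20 probes
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 550))
  r <- region_overlap_enrichment(man$probe_id[1:4], man$probe_id[5:20],
                                 regions, man)
  # probes 1..5 are in-region (positions 100..500)
  expect_equal(unname(r$table[1, ]), c(4L, 0L))
  expect_equal(unname(r$table[2, ]), c(1L, 15L))
  expect_equal(r$p, stats::fisher.test(matrix(c(4, 1, 0, 15), 2))$p.value,
               tolerance = 1e-9)
  # zero outliers
  r0 <- region_overlap_enrichment(character(0), man$probe_id, regions, man)
  expect_equal(r0$p, 1)
})
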