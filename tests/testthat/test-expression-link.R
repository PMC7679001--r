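test_that("expression Z-scoring filters and standardizes genes", {
  set.seed(10)
  x <- make_beta(matrix(rnorm(5 * 12, mean = 8), 5),
                 probe_ids = paste0("G", 1:5))
  x[4, ] <- 3                                # constant gene
  rpkm <- setNames(c(10, 0.5, 2, 5, 1), paste0("G", 1:5))
  expect_message(z <- zscore_expression(x, rpkm), "zero-variance")
  expect_false("G2" %in% rownames(z))        # mean RPKM 0.5 < 1
  expect_false("G4" %in% rownames(z))        # zero variance
  expect_true("G5" %in% rownames(z))         # boundary: RPKM 1 is expressed
  # per-gene mean 0 and sd 1 to 1e-9
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))

  # value at mean + 2 sd is z = 2: NOT an outlier under the strict rule
  zz <- make_beta(matrix(c(2, -1, 1, 0, -2, 0), 1), probe_ids = "G1",
                  sample_ids = paste0("S", 1:6))
  rec <- expression_records(zz)
  expect_false(any(rec$outlier[abs(rec$z) == 2]))
  expect_equal(sum(expression_records(zz, z_thresh = 1.9)$z > 1.9), 1L)
})

test_that("small-cohort outliers require the exact extreme rank", {
  n <- 20
  samples <- sprintf("S%03d", seq_len(n))
  man <- make_manifest(100L)
  pair <- make_pair(carriers = "S001")

  # carrier at rank 20 with delta +0.07
  b <- make_beta(matrix(c(0.57, seq(0.49, 0.51, length.out = n - 1)), 1),
                 sample_ids = samples)
  calls <- small_cohort_outliers(rank_betas(b), pair, man)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$rank, 20L)
  expect_equal(calls$direction, "gain")

  # carrier at rank 19: not an outlier even with a large delta
  vals <- c(0.6, seq(0.1, 0.2, length.out = n - 2), 0.7)
  b2 <- make_beta(matrix(vals, 1), sample_ids = samples)
  expect_equal(unname(rank_betas(b2)$rank[1, "S001"]), 19L)
  expect_equal(nrow(small_cohort_outliers(rank_betas(b2), pair, man)), 0L)

  # rank 1 with |delta| below 0.05: threshold oracle
  b3 <- make_beta(matrix(c(0.46, seq(0.49, 0.52, length.out = n - 1)), 1),
                  sample_ids = samples)
  expect_equal(unname(rank_betas(b3)$rank[1, "S001"]), 1L)
  expect_equal(nrow(small_cohort_outliers(rank_betas(b3), pair, man)), 0L)

  expect_error(small_cohort_outliers(rank_betas(b[, 1:3, drop = FALSE]), pair, man),
               "n_samples")
})

test_that("promoter assignment is closest-gene with a hard +/-2 kb cutoff", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(10000L, 50000L),
                      stringsAsFactors = FALSE)
  # variant at 11,500: within TSS + 2 kb
  p1 <- make_pair(pos = 11500L, start = 11491L, end = 11510L)
  expect_equal(promoter_pairs(p1, genes)$gene_id, "G1")
  # variant at 12,001: just beyond the inclusive boundary
  p2 <- make_pair(pos = 12001L, start = 11992L, end = 12011L)
  expect_equal(nrow(promoter_pairs(p2, genes)), 0L)
  # boundary 12,000 retained
  p3 <- make_pair(pos = 12000L, start = 11991L, end = 12010L)
  expect_equal(nrow(promoter_pairs(p3, genes)), 1L)
  # two genes: assigned to the closer TSS
  p4 <- make_pair(pos = 11000L, start = 10991L, end = 11010L)
  expect_equal(promoter_pairs(p4, genes)$gene_id, "G1")
  # no genes on the chromosome: dropped
  p5 <- make_pair(chrom = "chr9", pos = 11000L, start = 10991L, end = 11010L)
  expect_equal(nrow(promoter_pairs(p5, genes)), 0L)
})

test_that("expression-outlier enrichment computes fold and exact p", {
  # construct pairs/genes so the 2x2 table is [[4,16],[10,190]]
  n_pairs <- 220
  pairs <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    make_pair(pos = 1000L + i * 10L, start = 991L + i * 10L,
              end = 1010L + i * 10L, carriers = "S01", tf = "TF1")
  }))
  pairs$pair_id <- paste0("p", seq_len(n_pairs))
  assoc <- data.frame(pair_id = pairs$pair_id, n_cpg = 3L, n_outlier = 0L,
                      frac = 0, associated = rep(c(TRUE, FALSE), c(20, 200)))
  pair_gene <- data.frame(pair_id = pairs$pair_id,
                          gene_id = paste0("G", seq_len(n_pairs)),
                          tss = 1000L, distance = 10L)
  z_carrier <- rep(0, n_pairs)
  z_carrier[c(1:4, 21:30)] <- 3             # 4 assoc + 10 non-assoc outliers
  z <- cbind(S01 = z_carrier,
             matrix(0, n_pairs, 9, dimnames = list(NULL, paste0("S", 2:10))))
  rownames(z) <- pair_gene$gene_id
  enr <- expression_outlier_enrichment(assoc, pair_gene, z, pairs)
  expect_equal(unname(enr$table[1, ]), c(4L, 16L))
  expect_equal(unname(enr$table[2, ]), c(10L, 190L))
  expect_equal(enr$fold, 4)                 # (4/20) / (10/200)
  expect_equal(enr$p,
               stats::fisher.test(matrix(c(4, 10, 16, 190), 2))$p.value,
               tolerance = 1e-9)

  # proportional table: fold 1, p 1
  assoc2 <- assoc
  z2 <- z; z2[, "S01"] <- 0
  z2[c(1:2, 21:40), "S01"] <- 3             # 2/20 vs 20/200
  enr2 <- expression_outlier_enrichment(assoc2, pair_gene, z2, pairs)
  expect_equal(enr2$fold, 1)
  expect_equal(enr2$p, 1)
})

test_that("planted promoter coupling is recovered by the integration", {
  co <- cached("expr_planted", {
    suppressMessages(generate_cohort(sim_scenario_expression(1)))
  })
  enr <- run_expression_integration(co)
  expect_gt(enr$fold, 1)
  expect_lt(enr$p, 0.05)
})

test_that("covariate residualization removes linear structure", {
  set.seed(11)
  cov <- data.frame(age = rnorm(30), batch = gl(3, 10))
  x <- matrix(rnorm(5 * 30), 5)
  x[1, ] <- x[1, ] + 2 * cov$age
  colnames(x) <- paste0("S", 1:30); rownames(x) <- paste0("G", 1:5)
  r <- residualize_expression(x, cov)
  expect_lt(abs(cor(r[1, ], cov$age)), 1e-10)
  expect_equal(dim(r), dim(x))
})
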