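test_that("test statistics agree with their definitions", {
  Z <- array(0, c(5, 5, 3))
  expect_equal(stat_tensor(Z, seed = 1), 0)
  expect_equal(stat_max(Z), 0)
  expect_equal(stat_sum(Z), 0)
  expect_equal(stat_tensor_sq(Z, seed = 1), 0)

  pt <- planted_tensor(p = 20, support = 20, Lambda = 2.5, seed = 2)
  expect_equal(stat_tensor(pt$D, R = 20, seed = 3, restarts = 5), 2.5,
               tolerance = 1e-6)
  expect_equal(stat_tensor_sq(pt$D, R = 20, seed = 3, restarts = 5), 6.25,
               tolerance = 1e-5)
  # definitional identity with the decomposition
  expect_equal(stat_tensor(pt$D, R = 20, seed = 3, restarts = 5),
               sstd(pt$D, R = 20, seed = 3, restarts = 5)$Lambda)

  # slides (M, 0, -M) with M = diag(2, 0): max sLME = 2
  D <- array(0, c(2, 2, 3))
  D[, , 1] <- diag(c(2, 0)); D[, , 3] <- -diag(c(2, 0))
  expect_equal(stat_max(D, R = 2), 2, tolerance = 1e-8)

  # max dominates each slide; sum dominates max
  set.seed(8)
  Dr <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  for (l in 1:3) Dr[, , l] <- (Dr[, , l] + t(Dr[, , l])) / 2
  expect_gte(stat_max(Dr, R = 6),
             pmd_sparse_eigen(Dr[, , 1], R = 6)$lambda - 1e-10)
  expect_gte(stat_sum(Dr, R = 6), stat_max(Dr, R = 6) - 1e-10)
})

test_that("empirical p-values follow the printed counting formula", {
  set.seed(31)
  vals <- matrix(rnorm(10 * 30), nrow = 10)
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:5, each = 2))
  codes <- matrix(rep(c("A", "H", "B"), each = 10), nrow = 1,
                  dimnames = list("m1", ex$sample_ids))
  geno <- genotype_matrix(codes)
  cfg <- scan_config(statistic = "max", B0 = 25, seed = 42, min_group = 5)
  grp <- group_by_genotype(geno, "m1", min_group = 5)
  r <- permutation_pvalue(ex, grp, gm, cfg, B_use = 25)
  expect_equal(r$p_value, r$exceed / 25)
  expect_equal(r$exceed, sum(r$perm_stats >= r$S - 1e-12))
  expect_gte(r$p_value, 0); expect_lte(r$p_value, 1)

  # corrected variant
  cfg2 <- scan_config(statistic = "max", B0 = 25, seed = 42, min_group = 5,
                      correct = TRUE)
  r2 <- permutation_pvalue(ex, grp, gm, cfg2, B_use = 25)
  expect_equal(r2$p_value, (1 + r2$exceed) / 26)
  expect_error(permutation_pvalue(ex, grp, gm, cfg, B_use = 0), "B_use")
})

test_that("identical expression across samples gives p = 1", {
  vals <- matrix(rep(rnorm(8), 24), nrow = 8)  # every sample identical
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:4, each = 2))
  codes <- matrix(rep(c("A", "H", "B"), each = 8), nrow = 1,
                  dimnames = list("m1", ex$sample_ids))
  geno <- genotype_matrix(codes)
  cfg <- scan_config(statistic = "max", B0 = 10, seed = 3, min_group = 2)
  grp <- group_by_genotype(geno, "m1", min_group = 2)
  r <- suppressWarnings(permutation_pvalue(ex, grp, gm, cfg, B_use = 10))
  expect_equal(r$p_value, 1)
})

test_that("a strong planted effect yields p = 0 under few permutations", {
  cfg <- sim_config(n = 120, n_genes = 30, n_chrom = 6, effect_size = 1,
                    seed = 6)
  ds <- simulate_dataset(cfg)
  expr <- preprocess(ds$expr)
  sc <- scan_config(statistic = "max", B0 = 10, seed = 9)
  grp <- group_by_genotype(ds$geno, ds$truth$snqtl_marker)
  r <- permutation_pvalue(expr, grp, ds$gmap, sc, B_use = 10)
  expect_equal(r$p_value, 0)
})

test_that("relabeling the homozygous genotypes leaves statistics unchanged", {
  set.seed(17)
  vals <- matrix(rnorm(8 * 45), nrow = 8)
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:4, each = 2))
  sid <- ex$sample_ids
  D1 <- snqtl:::build_marker_tensor(ex, sid[1:15], sid[16:30], sid[31:45],
                                    gmap = gm, mask = TRUE)
  D2 <- snqtl:::build_marker_tensor(ex, sid[31:45], sid[16:30], sid[1:15],
                                    gmap = gm, mask = TRUE)
  expect_equal(stat_max(D1, R = 8), stat_max(D2, R = 8), tolerance = 1e-8)
  expect_equal(stat_tensor(D1, R = 8, seed = 5, restarts = 5),
               stat_tensor(D2, R = 8, seed = 5, restarts = 5),
               tolerance = 1e-6)
})

test_that("the two-stage scan is deterministic and labels stages", {
  cfg <- sim_config(n = 150, n_genes = 30, n_chrom = 6, effect_size = 0.8,
                    seed = 12)
  ds <- simulate_dataset(cfg)
  expr <- preprocess(ds$expr)
  markers <- unique(c(ds$truth$snqtl_marker, paste0("M", c(1, 7, 13, 19, 25))))
  sc <- scan_config(statistic = "max", B0 = 20, B = 40, seed = 77)
  res1 <- snqtl_scan(expr, ds$geno, ds$gmap, sc, markers = markers)
  res2 <- snqtl_scan(expr, ds$geno, ds$gmap, sc, markers = markers)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), length(markers))
  expect_true(all(res1$stage %in% c("screened_out", "confirmed", "untestable")))
  # the planted marker is screened in and re-tested with B permutations
  planted <- res1[res1$marker_id == ds$truth$snqtl_marker, ]
  expect_identical(planted$stage, "confirmed")
  expect_equal(planted$B_used, 40L)

  # marker iteration order does not change per-marker results
  res3 <- snqtl_scan(expr, ds$geno, ds$gmap, sc, markers = rev(markers))
  res3 <- res3[match(res1$marker_id, res3$marker_id), ]
  expect_equal(res1$p_value, res3$p_value)
  expect_equal(res1$statistic, res3$statistic)
})

test_that("untestable markers are recorded with a reason", {
  set.seed(3)
  vals <- matrix(rnorm(6 * 20), nrow = 6)
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:3, each = 2))
  codes <- rbind(mall = rep("A", 20),
                 mok = rep(c("A", "H", "B", "H"), 5))
  colnames(codes) <- ex$sample_ids
  geno <- genotype_matrix(codes)
  sc <- scan_config(statistic = "max", B0 = 5, seed = 2, min_group = 2)
  res <- snqtl_scan(ex, geno, gm, sc)
  expect_identical(res$stage[res$marker_id == "mall"], "untestable")
  expect_match(res$reason[res$marker_id == "mall"], "fewer than 2")
  expect_false(is.na(res$p_value[res$marker_id == "mok"]))
})

test_that("two-genotype markers are routed to the matrix statistic", {
  set.seed(4)
  vals <- matrix(rnorm(6 * 24), nrow = 6)
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:3, each = 2))
  codes <- matrix(rep(c("A", "B"), each = 12), nrow = 1,
                  dimnames = list("m1", ex$sample_ids))
  geno <- genotype_matrix(codes)
  sc <- scan_config(statistic = "tensor", B0 = 10, seed = 5, min_group = 2)
  grp <- group_by_genotype(geno, "m1", min_group = 2)
  r <- permutation_pvalue(ex, grp, gm, sc, B_use = 10)
  # observed statistic equals the sLME of the single pairwise difference
  nA <- mask_within_chromosome(correlation_network(ex, ex$sample_ids[1:12]), gm)
  nB <- mask_within_chromosome(correlation_network(ex, ex$sample_ids[13:24]), gm)
  expect_equal(r$S, pmd_sparse_eigen(nB$matrix - nA$matrix, R = 6)$lambda,
               tolerance = 1e-8)
})

test_that("baseline local F-test matches an lm() oracle and handles edge cases", {
  set.seed(19)
  p <- 10; n <- 40
  vals <- matrix(rnorm(p * n), nrow = p)
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:5, each = 2))
  codes <- matrix(sample(c("A", "H", "B"), n, replace = TRUE), nrow = 1,
                  dimnames = list("m1", ex$sample_ids))
  geno <- genotype_matrix(codes)
  res <- baseline_local_test(ex, geno, gm, "m1")
  dose <- c(A = 0, H = 0.5, B = 1)[codes[1, ]]
  orc <- oracle_baseline(ex$values, rep(1:5, each = 2), as.numeric(dose))
  expect_equal(res$n_pairs, orc$n_pairs)
  expect_equal(res$min_pair_p, orc$min_pair_p, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-10)

  # degenerate dosage -> untestable
  codes2 <- matrix(rep("A", n), nrow = 1,
                   dimnames = list("m2", ex$sample_ids))
  res2 <- baseline_local_test(ex, genotype_matrix(codes2), gm, "m2")
  expect_true(res2$untestable)

  # a pair whose co-expression is exactly linear in dosage -> tiny p
  dose3 <- rep(c(0, 0.5, 1), length.out = n)
  z <- rnorm(n)
  g1 <- z
  g2 <- (2 * dose3 - 1) * z  # product g1*g2 = (2d-1) z^2, linear in d
  vals3 <- rbind(g1, g2, matrix(rnorm(2 * n, sd = 0.1), 2))
  ex3 <- resid_expr(vals3)
  gm3 <- gmap_for(ex3$gene_ids, chrom = c(1, 2, 3, 4))
  codes3 <- matrix(c("A", "H", "B")[round(2 * dose3) + 1], nrow = 1,
                   dimnames = list("m3", ex3$sample_ids))
  res3 <- baseline_local_test(ex3, genotype_matrix(codes3), gm3, "m3")
  expect_lt(res3$min_pair_p, 1e-4)
})

test_that("consistent sample permutation leaves scan statistics unchanged", {
  cfg <- sim_config(n = 90, n_genes = 20, n_chrom = 4, effect_size = 0.5,
                    seed = 23)
  ds <- simulate_dataset(cfg)
  expr <- preprocess(ds$expr)
  sc <- scan_config(statistic = "max", B0 = 10, seed = 31)
  grp <- group_by_genotype(ds$geno, "M3")
  r1 <- permutation_pvalue(expr, grp, ds$gmap, sc, B_use = 1)

  perm <- sample(seq_len(cfg$n))
  expr2 <- expr
  expr2$values <- expr$values[, perm]
  expr2$sample_ids <- expr$sample_ids[perm]
  colnames(expr2$values) <- expr2$sample_ids
  geno2 <- ds$geno
  geno2$codes <- geno2$codes[, perm]
  geno2$sample_ids <- geno2$sample_ids[perm]
  grp2 <- group_by_genotype(geno2, "M3")
  r2 <- permutation_pvalue(expr2, grp2, ds$gmap, sc, B_use = 1)
  expect_equal(r1$S, r2$S, tolerance = 1e-10)
})
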