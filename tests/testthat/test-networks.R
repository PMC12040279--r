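test_that("group_by_genotype partitions samples and flags degenerate markers", {
  codes <- rbind(m1 = c("A", "A", "H", "H", "B", "B"),
                 m2 = rep("A", 6))
  colnames(codes) <- paste0("s", 1:6)
  g <- genotype_matrix(codes)
  grp <- group_by_genotype(g, "m1", min_group = 2)
  expect_equal(unname(grp$counts), c(2L, 2L, 2L))
  expect_true(grp$testable)
  expect_identical(grp$samples_B, c("s5", "s6"))

  grp2 <- group_by_genotype(g, "m2", min_group = 2)
  expect_false(grp2$testable)
  expect_match(grp2$reason, "fewer than 2")

  grp3 <- group_by_genotype(g, "m1", min_group = 3)
  expect_false(grp3$testable)
  expect_match(grp3$reason, "min_group")

  expect_error(group_by_genotype(g, "nope"), "unknown marker")
})

test_that("correlation networks match the textbook Pearson formula", {
  set.seed(5)
  vals <- matrix(rnorm(5 * 20), nrow = 5)
  ex <- resid_expr(vals)
  net <- correlation_network(ex, ex$sample_ids)
  for (j in 1:4) for (k in (j + 1):5) {
    expect_equal(net$matrix[j, k], oracle_pearson(vals[j, ], vals[k, ]),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(net$matrix) <= 1 + 1e-12))
  expect_equal(net$matrix, t(net$matrix))
})

test_that("identical gene rows give correlation 1; flat genes are zeroed", {
  vals <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4) * 1, c(2, 2, 2, 2))
  ex <- resid_expr(vals)
  expect_warning(net <- correlation_network(ex, ex$sample_ids),
                 "zero variance")
  expect_equal(net$matrix[1, 2], 1)
  expect_equal(unname(net$matrix[3, 1:2]), c(0, 0))
  expect_error(correlation_network(ex, ex$sample_ids[1]), "at least 2")
})

test_that("within-chromosome masking zeroes the right entries", {
  vals <- matrix(rnorm(3 * 10), nrow = 3)
  ex <- resid_expr(vals)
  net <- correlation_network(ex, ex$sample_ids)

  # genes 1,2 on chr1; gene 3 on chr2
  gm <- gmap_for(ex$gene_ids, chrom = c(1, 1, 2))
  masked <- mask_within_chromosome(net, gm)
  expect_true(masked$masked)
  expect_equal(masked$matrix[1, 2], 0)
  expect_equal(masked$matrix[2, 1], 0)
  expect_equal(unname(diag(masked$matrix)), rep(0, 3))
  expect_equal(masked$matrix[1, 3], net$matrix[1, 3])
  expect_equal(masked$matrix[2, 3], net$matrix[2, 3])

  # all genes on one chromosome -> zero matrix
  all1 <- mask_within_chromosome(net, gmap_for(ex$gene_ids, chrom = c(1, 1, 1)))
  expect_true(all(all1$matrix == 0))

  # all distinct chromosomes -> only the diagonal is zeroed
  dis <- mask_within_chromosome(net, gmap_for(ex$gene_ids))
  off <- net$matrix; diag(off) <- 0
  expect_equal(dis$matrix, off)

  expect_error(mask_within_chromosome(masked, gm), "already masked")
  expect_error(mask_within_chromosome(net, gm[-1, ]), "missing from gene map")
})

test_that("differential tensor slides follow the printed definitions", {
  mk_net <- function(M, g) {
    structure(list(matrix = M, masked = TRUE, genotype = g,
                   gene_ids = rownames(M), n_samples = 10L),
              class = "correlation_network")
  }
  gid <- c("G1", "G2")
  Z <- matrix(0, 2, 2, dimnames = list(gid, gid))
  M <- matrix(c(0, .5, .5, 0), 2, dimnames = list(gid, gid))

  # nA = nH = nB -> zero tensor
  nets <- mk_net(M, "A")
  D0 <- differential_tensor(nets, mk_net(M, "H"), mk_net(M, "B"))
  expect_true(all(D0$slides == 0))

  # nA = 0, nH = 0, nB = M -> slides (M, 0, -M)
  D1 <- differential_tensor(mk_net(Z, "A"), mk_net(Z, "H"), mk_net(M, "B"))
  expect_equal(unname(D1$slides[, , "AB"]), unname(M))
  expect_true(all(D1$slides[, , "AH"] == 0))
  expect_equal(unname(D1$slides[, , "BH"]), unname(-M))

  # dimension mismatch
  M3 <- matrix(0, 3, 3, dimnames = list(paste0("G", 1:3), paste0("G", 1:3)))
  expect_error(differential_tensor(mk_net(Z, "A"), mk_net(Z, "H"),
                                   mk_net(M3, "B")), "dimensions")
})

test_that("slide BH equals slide AH minus slide AB on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(rnorm(8 * 30), nrow = 8)
    ex <- resid_expr(vals)
    gm <- gmap_for(ex$gene_ids, chrom = rep(1:4, each = 2))
    sid <- ex$sample_ids
    nets <- lapply(list(sid[1:10], sid[11:20], sid[21:30]), function(s)
      mask_within_chromosome(correlation_network(ex, s), gm))
    D <- differential_tensor(nets[[1]], nets[[2]], nets[[3]])
    expect_lt(max(abs(D$slides[, , "BH"] -
                        (D$slides[, , "AH"] - D$slides[, , "AB"]))), 1e-12)
    for (l in 1:3)
      expect_equal(D$slides[, , l], t(D$slides[, , l]))
  }
})

test_that("gene order permutation permutes slides and leaves stat_max unchanged", {
  set.seed(9)
  vals <- matrix(rnorm(6 * 36), nrow = 6)
  ex <- resid_expr(vals)
  gm <- gmap_for(ex$gene_ids, chrom = rep(1:3, each = 2))
  sid <- ex$sample_ids
  groups <- list(sid[1:12], sid[13:24], sid[25:36])
  build <- function(e, g) {
    nets <- lapply(groups, function(s)
      mask_within_chromosome(correlation_network(e, s), g))
    differential_tensor(nets[[1]], nets[[2]], nets[[3]])
  }
  D <- build(ex, gm)
  perm <- c(4, 1, 6, 2, 5, 3)
  ex2 <- resid_expr(vals[perm, ], gene_ids = ex$gene_ids[perm])
  gm2 <- gm[match(ex2$gene_ids, gm$gene_id), ]
  D2 <- build(ex2, gm2)
  for (l in 1:3)
    expect_equal(unname(D2$slides[, , l]), unname(D$slides[perm, perm, l]),
                 tolerance = 1e-12)
  expect_equal(stat_max(D2, R = 6), stat_max(D, R = 6), tolerance = 1e-8)
})
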