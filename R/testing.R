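# Test statistics, permutation p-values, the two-stage genome scan, and the
# local F-test baseline.
#
# All statistics are nonnegative functions of the differential tensor; under
# the null N_A = N_H = N_B every slide is (in population) the zero matrix.
# Empirical p-values come from shuffling genotype labels over the pooled
# samples at a marker, preserving the group sizes, and recomputing the full
# correlation -> masking -> tensor -> statistic pipeline:
#   p = (1/B) * sum_b I{ S_b >= S }.

#' Scan configuration
#'
#' @param statistic One of `"tensor"` (sparse leading tensor eigenvalue),
#'   `"max"` (maximal slide-wise sLME), `"sum"` (sum of slide sLMEs),
#'   `"tensor_sq"` (squared sLTE).
#' @param R Sparsity parameter; `NULL` means `R = p` (non-sparse).
#' @param B0 Screening permutations (default 100).
#' @param B Confirmation permutations for markers passing the screen
#'   (default 500).
#' @param alpha_screen Screening threshold on the stage-1 empirical p-value
#'   (default 0.05).
#' @param seed Master seed; all permutation randomness derives from it.
#' @param min_group Minimum per-genotype-group size (default 10).
#' @param mask Apply within-chromosome masking (default TRUE).
#' @param correct If TRUE report the (1 + count) / (1 + B) corrected p-value
#'   instead of the plain count / B (default FALSE, the plain formula).
#' @param sstd_restarts,sstd_T Solver settings for the tensor statistics.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(statistic = c("tensor", "max", "sum", "tensor_sq"),
                        R = NULL, B0 = 100, B = 500, alpha_screen = 0.05,
                        seed = 1, min_group = 10, mask = TRUE,
                        correct = FALSE, sstd_restarts = 3, sstd_T = 30) {
  statistic <- match.arg(statistic)
  if (B0 < 1 || B < 1) stop("B0 and B must be >= 1")
  if (alpha_screen <= 0 || alpha_screen >= 1)
    stop("alpha_screen must be in (0, 1)")
  structure(list(statistic = statistic, R = R, B0 = as.integer(B0),
                 B = as.integer(B), alpha_screen = alpha_screen,
                 seed = as.integer(seed), min_group = as.integer(min_group),
                 mask = isTRUE(mask), correct = isTRUE(correct),
                 sstd_restarts = sstd_restarts, sstd_T = sstd_T),
            class = "scan_config")
}

#' Tensor statistic: sparse leading tensor eigenvalue
#'
#' `Stat_tensor = Lambda(D)`, the sLTE of the differential tensor from
#' [sstd()]; always nonnegative.
#'
#' @param D A [differential_tensor()] or p x p x 3 array.
#' @param R Sparsity (default p, non-sparse).
#' @param seed,restarts,T Passed to [sstd()].
#' @return A single nonnegative number.
#' @export
stat_tensor <- function(D, R = NULL, seed = 1, restarts = 3, T = 30) {
  Dt <- as_diff_tensor(D)
  if (is.null(R)) R <- dim(Dt$slides)[1]
  sstd(Dt, R = R, T = T, restarts = restarts, seed = seed)$Lambda
}

#' Max statistic: maximal slide-wise sLME
#'
#' `Stat_max = max{ lambda(D_AB), lambda(D_AH), lambda(D_BH) }` with each
#' sLME from [pmd_sparse_eigen()]. Zero slides give a zero max statistic.
#'
#' @inheritParams stat_tensor
#' @return A single nonnegative number.
#' @export
stat_max <- function(D, R = NULL, seed = 1) {
  max(slide_slmes(D, R))
}

#' Sum statistic: sum of the three slide sLMEs
#' @inheritParams stat_tensor
#' @return A single nonnegative number.
#' @export
stat_sum <- function(D, R = NULL, seed = 1) {
  sum(slide_slmes(D, R))
}

#' Squared-tensor statistic: squared sLTE
#' @inheritParams stat_tensor
#' @return A single nonnegative number.
#' @export
stat_tensor_sq <- function(D, R = NULL, seed = 1, restarts = 3, T = 30) {
  stat_tensor(D, R = R, seed = seed, restarts = restarts, T = T)^2
}

slide_slmes <- function(D, R = NULL) {
  Dt <- as_diff_tensor(D)
  p <- dim(Dt$slides)[1]
  if (is.null(R)) R <- p
  vapply(seq_len(dim(Dt$slides)[3]),
         function(l) pmd_sparse_eigen(Dt$slides[, , l], R = R)$lambda,
         numeric(1))
}

compute_stat <- function(D, cfg, seed = 1) {
  Dt <- as_diff_tensor(D)
  q <- dim(Dt$slides)[3]
  if (q == 1) {
    # two-genotype marker: tensor statistic undefined, use the single sLME
    p <- dim(Dt$slides)[1]
    R <- if (is.null(cfg$R)) p else cfg$R
    return(pmd_sparse_eigen(Dt$slides[, , 1], R = R)$lambda)
  }
  switch(cfg$statistic,
         tensor = stat_tensor(Dt, R = cfg$R, seed = seed,
                              restarts = cfg$sstd_restarts, T = cfg$sstd_T),
         max = stat_max(Dt, R = cfg$R),
         sum = stat_sum(Dt, R = cfg$R),
         tensor_sq = stat_tensor_sq(Dt, R = cfg$R, seed = seed,
                                    restarts = cfg$sstd_restarts,
                                    T = cfg$sstd_T))
}

# Build the per-marker differential structure for a given assignment of
# samples to groups. Two-group markers yield a p x p x 1 "tensor" routed to
# matrix statistics.
build_marker_tensor <- function(expr, sA, sH, sB, gmap = NULL, mask = TRUE,
                                marker_id = NA_character_) {
  sets <- list(A = sA, H = sH, B = sB)
  sets <- sets[vapply(sets, length, integer(1)) >= 2]
  nets <- lapply(names(sets), function(g) {
    net <- suppressWarnings(correlation_network(expr, sets[[g]], genotype = g))
    if (mask) net <- mask_within_chromosome(net, gmap) else net
  })
  names(nets) <- names(sets)
  if (length(nets) == 3) {
    return(differential_tensor(nets$A, nets$H, nets$B, marker_id = marker_id))
  }
  if (length(nets) == 2) {
    d <- nets[[2]]$matrix - nets[[1]]$matrix
    slides <- array(d, dim = c(nrow(d), ncol(d), 1),
                    dimnames = list(rownames(d), colnames(d),
                                    paste0(names(nets)[1], names(nets)[2])))
    return(structure(list(slides = slides, gene_ids = nets[[1]]$gene_ids,
                          marker_id = marker_id, masked = mask),
                     class = "differential_tensor"))
  }
  stop("fewer than 2 groups with >= 2 samples")
}

#' Permutation p-value at one marker
#'
#' Computes the observed statistic S on the given grouping, then for
#' `B_use` permutations reassigns genotype labels uniformly at random over
#' the pooled samples (preserving the group sizes), recomputes the full
#' Step-0 pipeline (within-group correlations, masking, differential tensor)
#' and the statistic, and returns the empirical p-value
#' `p = (1/B) sum_b I{S_b >= S}` (or the (1+count)/(1+B) variant when
#' `cfg$correct` is TRUE).
#'
#' @param expr Residualized [expression_matrix()].
#' @param groups A [group_by_genotype()] result.
#' @param gmap Gene map (needed when `cfg$mask` is TRUE).
#' @param cfg A [scan_config()].
#' @param B_use Number of permutations (>= 1).
#' @param seed Seed for this marker's permutation stream (defaults to
#'   `cfg$seed`).
#' @return A list: `S`, `p_value`, `exceed` (count of S_b >= S), `B_used`,
#'   `perm_stats`.
#' @export
permutation_pvalue <- function(expr, groups, gmap = NULL, cfg = scan_config(),
                               B_use = cfg$B0, seed = cfg$seed) {
  if (B_use < 1) stop("B_use must be >= 1")
  stopifnot(inherits(groups, "genotype_groups"))
  D <- build_marker_tensor(expr, groups$samples_A, groups$samples_H,
                           groups$samples_B, gmap = gmap, mask = cfg$mask,
                           marker_id = groups$marker_id)
  S <- compute_stat(D, cfg, seed = seed)
  pooled <- c(groups$samples_A, groups$samples_H, groups$samples_B)
  nA <- length(groups$samples_A); nH <- length(groups$samples_H)
  nB <- length(groups$samples_B)
  set.seed(seed %% 2147483647L)
  perm_stats <- numeric(B_use)
  for (b in seq_len(B_use)) {
    idx <- sample.int(length(pooled))
    sA <- pooled[idx[seq_len(nA)]]
    sH <- pooled[idx[nA + seq_len(nH)]]
    sB <- pooled[idx[nA + nH + seq_len(nB)]]
    Db <- build_marker_tensor(expr, sA, sH, sB, gmap = gmap, mask = cfg$mask)
    perm_stats[b] <- compute_stat(Db, cfg, seed = seed + b)
  }
  exceed <- sum(perm_stats >= S - 1e-12)
  p <- if (cfg$correct) (1 + exceed) / (1 + B_use) else exceed / B_use
  list(S = S, p_value = p, exceed = exceed, B_used = as.integer(B_use),
       perm_stats = perm_stats)
}

marker_seed <- function(master, i) {
  (as.integer(master) + 7919L * as.integer(i)) %% 2147483647L
}

#' Two-stage genome scan for network QTLs
#'
#' For every marker: group samples by genotype, screen with `B0`
#' permutations, and re-test markers with screening p-value below
#' `alpha_screen` using `B` permutations. Untestable markers (fewer than two
#' groups, or a group below `min_group`) are recorded with their reason.
#' Each marker draws from its own RNG stream keyed by `(seed, marker index)`,
#' so results do not depend on iteration order.
#'
#' @param expr Residualized [expression_matrix()].
#' @param geno A [genotype_matrix()] aligned with `expr` by sample id.
#' @param gmap Gene map data.frame.
#' @param cfg A [scan_config()].
#' @param markers Optional subset of marker ids to scan (default: all).
#' @return A data.frame of class `scan_result`, one row per marker:
#'   marker_id, chrom, pos, nA, nH, nB, statistic, p_value, exceed, B_used,
#'   stage (`"screened_out"`, `"confirmed"`, `"untestable"`), reason.
#' @export
snqtl_scan <- function(expr, geno, gmap, cfg = scan_config(), markers = NULL) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(geno, "genotype_matrix"))
  if (expr$state != "residualized")
    stop("expression must be preprocessed (residualized) before scanning")
  check_alignment(expr, geno)
  if (is.null(markers)) markers <- geno$marker_ids
  midx <- match(markers, geno$marker_ids)
  if (anyNA(midx)) stop("unknown marker(s): ",
                        paste(markers[is.na(midx)], collapse = ", "))
  rows <- vector("list", length(markers))
  for (k in seq_along(markers)) {
    i <- midx[k]
    mid <- geno$marker_ids[i]
    grp <- group_by_genotype(geno, mid, min_group = cfg$min_group)
    base <- list(marker_id = mid, chrom = geno$chrom[i], pos = geno$pos[i],
                 nA = unname(grp$counts[1]), nH = unname(grp$counts[2]),
                 nB = unname(grp$counts[3]))
    if (!grp$testable) {
      rows[[k]] <- c(base, list(statistic = NA_real_, p_value = NA_real_,
                                exceed = NA_integer_, B_used = NA_integer_,
                                stage = "untestable", reason = grp$reason))
      next
    }
    ms <- marker_seed(cfg$seed, i)
    r1 <- permutation_pvalue(expr, grp, gmap, cfg, B_use = cfg$B0, seed = ms)
    if (r1$p_value < cfg$alpha_screen) {
      r2 <- permutation_pvalue(expr, grp, gmap, cfg, B_use = cfg$B,
                               seed = ms + 1L)
      rows[[k]] <- c(base, list(statistic = r2$S, p_value = r2$p_value,
                                exceed = r2$exceed, B_used = r2$B_used,
                                stage = "confirmed", reason = NA_character_))
    } else {
      rows[[k]] <- c(base, list(statistic = r1$S, p_value = r1$p_value,
                                exceed = r1$exceed, B_used = r1$B_used,
                                stage = "screened_out",
                                reason = NA_character_))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("scan_result", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Local F-test baseline (pairwise co-expression regression)
#'
#' Reconstruction of the classical local (co-QTL style) comparator: for every
#' cross-chromosome gene pair, the per-sample co-expression proxy (product of
#' the two genes' standardized residual expressions) is regressed on genotype
#' dosage (A = 0, H = 1/2, B = 1) and tested with the regression F-test; the
#' pair p-values are combined into one marker-level p-value by the
#' Bonferroni-adjusted minimum. The pair proxy and combination rule are this
#' package's documented reconstruction of the standard approach.
#'
#' @param expr Residualized [expression_matrix()].
#' @param geno A [genotype_matrix()].
#' @param gmap Gene map data.frame.
#' @param marker_id Marker to test.
#' @return A list: `p_value` (marker-level), `n_pairs`, `min_pair_p`,
#'   `untestable` (TRUE when the dosage is degenerate).
#' @export
baseline_local_test <- function(expr, geno, gmap, marker_id) {
  stopifnot(inherits(expr, "expression_matrix"))
  i <- match(marker_id, geno$marker_ids)
  if (is.na(i)) stop("unknown marker: ", marker_id)
  z <- geno$codes[i, ]
  keep <- !is.na(z)
  dose <- c(A = 0, H = 0.5, B = 1)[z[keep]]
  ids <- geno$sample_ids[keep]
  if (length(unique(dose)) < 2)
    return(list(p_value = NA_real_, n_pairs = 0L, min_pair_p = NA_real_,
                untestable = TRUE))
  sidx <- match(ids, expr$sample_ids)
  X <- expr$values[, sidx, drop = FALSE]            # genes x n
  n <- ncol(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  s[s == 0] <- 1
  Z <- (X - mu) / s                                  # standardized rows

  gidx <- match(expr$gene_ids, gmap$gene_id)
  if (anyNA(gidx)) stop("gene(s) missing from gene map")
  chrom <- gmap$chrom[gidx]
  pairs <- which(outer(chrom, chrom, "!=") & upper.tri(diag(length(chrom))),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0)
    return(list(p_value = NA_real_, n_pairs = 0L, min_pair_p = NA_real_,
                untestable = TRUE))

  # y = z_j * z_k regressed on dosage; F = (n-2) r^2 / (1 - r^2), r = cor(y, d)
  d <- as.numeric(dose)
  dc <- d - mean(d)
  dss <- sum(dc^2)
  Y <- Z[pairs[, 1], , drop = FALSE] * Z[pairs[, 2], , drop = FALSE]
  Yc <- Y - rowMeans(Y)
  num <- as.numeric(Yc %*% dc)
  den <- sqrt(rowSums(Yc^2) * dss)
  r <- ifelse(den > 0, num / den, 0)
  r2 <- pmin(r^2, 1 - 1e-15)
  Fst <- (n - 2) * r2 / (1 - r2)
  pp <- pf(Fst, 1, n - 2, lower.tail = FALSE)
  list(p_value = min(1, min(pp) * nrow(pairs)), n_pairs = nrow(pairs),
       min_pair_p = min(pp), untestable = FALSE)
}

#' Write a scan result as a Manhattan-style TSV
#'
#' @param scan A [snqtl_scan()] result.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
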