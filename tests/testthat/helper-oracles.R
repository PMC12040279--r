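# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use brute-force / textbook formulas, never the
# package's own solver path.

rsym <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  (A + t(A)) / 2
}

# Textbook Pearson correlation, one pair at a time.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Dense eigensolver oracle for the non-sparse sLME.
oracle_abs_eig <- function(D) max(abs(eigen(D, symmetric = TRUE)$values))

# Exact sparse rank-1 tensor with ||v0||_0 = support.
planted_tensor <- function(p, support, Lambda = 2.5, seed = 1, q = 3) {
  set.seed(seed)
  v0 <- rep(0, p)
  idx <- sample.int(p, support)
  v0[idx] <- rnorm(support)
  v0 <- v0 / sqrt(sum(v0^2))
  u0 <- abs(rnorm(q))
  u0 <- u0 / sqrt(sum(u0^2))
  D <- array(0, c(p, p, q))
  M <- tcrossprod(v0)
  for (l in seq_len(q)) D[, , l] <- Lambda * M * u0[l]
  list(D = D, v0 = v0, u0 = u0, Lambda = Lambda, support = sort(idx))
}

# Coarse grid oracle for the best symmetric rank-1 tensor fit (R = p):
# Lambda* = max over unit u of max|eigenvalue|(D x_3 u); sweep u over a grid
# on the sphere and solve each inner problem densely.
oracle_rank1_grid <- function(D, n_grid = 24) {
  q <- dim(D)[3]
  stopifnot(q == 3)
  best <- 0
  for (theta in seq(0, pi, length.out = n_grid)) {
    for (phi in seq(0, 2 * pi, length.out = 2 * n_grid)) {
      u <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      Du <- D[, , 1] * u[1] + D[, , 2] * u[2] + D[, , 3] * u[3]
      best <- max(best, oracle_abs_eig(Du))
    }
  }
  best
}

# Direct evaluation of the BIC formula on a given fit.
oracle_bic <- function(slides, Lambda, v, u) {
  p <- dim(slides)[1]; q <- dim(slides)[3]
  M <- Lambda * tcrossprod(v)
  loss <- 0
  for (l in seq_len(q)) loss <- loss + sum((slides[, , l] - M * u[l])^2)
  npar <- q * p^2
  npar * log(max(loss, 1e-12) / npar) + (2 + 2 * sum(abs(v) > 1e-12)) * log(npar)
}

# lm()-based re-implementation of the local pairwise F-test baseline.
oracle_baseline <- function(values, gene_chrom, dose) {
  p <- nrow(values)
  Z <- t(scale(t(values)))
  pvals <- c()
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      if (gene_chrom[j] == gene_chrom[k]) next
      y <- Z[j, ] * Z[k, ]
      fit <- summary(lm(y ~ dose))
      fs <- fit$fstatistic
      pvals <- c(pvals, pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    }
  }
  list(p_value = min(1, min(pvals) * length(pvals)), n_pairs = length(pvals),
       min_pair_p = min(pvals))
}

write_expr_tsv <- function(mat, path, gene_ids = rownames(mat)) {
  df <- data.frame(gene_id = gene_ids, mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_geno_tsv <- function(codes, path, marker_ids = rownames(codes)) {
  df <- data.frame(marker_id = marker_ids, codes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A tiny residualized expression_matrix with given genes x samples values.
resid_expr <- function(values, gene_ids = NULL, sample_ids = NULL) {
  p <- nrow(values); n <- ncol(values)
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  vc <- values - rowMeans(values)
  expression_matrix(vc, gene_ids, sample_ids, state = "residualized")
}

# Gene map placing each gene on its own chromosome (masking only kills the
# diagonal) unless chrom is supplied.
gmap_for <- function(gene_ids, chrom = seq_along(gene_ids)) {
  data.frame(gene_id = gene_ids, chrom = as.integer(chrom),
             pos = seq_along(gene_ids) * 100L, stringsAsFactors = FALSE)
}
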