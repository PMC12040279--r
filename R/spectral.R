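# Sparse spectral solvers.
#
# Two primitives drive all test statistics:
#   * sLME of a symmetric matrix D: max |v' D v| over unit vectors v with a
#     sparsity budget, solved approximately by penalized matrix decomposition
#     (soft-thresholded power iteration) run on both D and -D;
#   * SSTD of a p x p x q tensor D: the best sparse symmetric rank-1 fit
#     D ~ Lambda v o v o u, solved by alternating PMD v-updates on the
#     u-contracted matrix and closed-form u-updates.
#
# Sparsity convention: the integer R in [1, p] is a target support size; the
# PMD L1 budget is sqrt(R), under which ||v||_1^2 <= ||v||_0 <= R holds and
# R = p is exactly the non-sparse problem.

l1_budget <- function(R, p) {
  if (!is.numeric(R) || length(R) != 1 || R < 1 || R > p)
    stop("sparsity R must be a single value in [1, p]")
  sqrt(R)
}

check_symmetric <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (max(abs(D - t(D))) > tol * max(1, max(abs(D))))
    stop("D is not symmetric within tolerance")
  (D + t(D)) / 2
}

# Deterministic starting vectors: the extreme eigenvectors of M from one
# decomposition (shifted power iteration fallback for large p keeps the cost
# at O(p^2) per step).
extreme_eigvecs <- function(M) {
  p <- nrow(M)
  if (p <= 500) {
    e <- eigen(M, symmetric = TRUE)
    return(list(max = e$vectors[, 1], min = e$vectors[, p]))
  }
  one <- function(A) {
    shift <- sum(abs(A)) / p  # crude bound making A + shift*I dominant-PSD
    v <- rep(1 / sqrt(p), p)
    for (t in 1:200) {
      w <- A %*% v + shift * v
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- w / nw
      if (sqrt(sum((w - v)^2)) < 1e-10) { v <- w; break }
      v <- w
    }
    as.numeric(v)
  }
  list(max = one(M), min = one(-M))
}

# Fix the +/- ambiguity of an eigenvector: largest-magnitude entry positive.
canonical_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Sparse leading matrix eigenvalue (sLME) via penalized matrix decomposition
#'
#' Approximately solves `max |v' D v|` over unit vectors `v` with an L1
#' budget `sqrt(R)` (so `R` acts as a target support size and `R = p` is the
#' dense problem). The soft-thresholded power ascent targets the maximal
#' signed quadratic form, so the solver is run on both `D` and `-D` and the
#' larger objective is returned. Returned vectors always have unit L2 norm.
#'
#' @param D Symmetric p x p matrix.
#' @param R Sparsity parameter in \[1, p\].
#' @param iters Maximum power iterations per run (default 100).
#' @param tol Convergence tolerance on successive v change (default 1e-6).
#' @param v_init Optional warm-start vector (used as an extra candidate).
#' @return An object of class `matrix_spectral_result`: `lambda` (= |v'Dv|),
#'   `v` (unit vector, largest-magnitude entry positive), `sign` (+1 if the
#'   optimum was attained on D, -1 on -D), `nnz`, `iterations`, `converged`.
#' @export
pmd_sparse_eigen <- function(D, R, iters = 100, tol = 1e-6, v_init = NULL) {
  D <- check_symmetric(D)
  p <- nrow(D)
  cbud <- l1_budget(R, p)
  ev <- extreme_eigvecs(D)
  cands <- list(list(M = D, s = 1, v0 = ev$max),
                list(M = -D, s = -1, v0 = ev$min))
  if (!is.null(v_init)) {
    v0 <- v_init / sqrt(sum(v_init^2))
    q0 <- sum(v0 * (D %*% v0))
    s <- if (q0 >= 0) 1 else -1
    cands <- c(cands, list(list(M = s * D, s = s, v0 = v0)))
  }
  best <- NULL
  for (cd in cands) {
    fit <- pmd_core(cd$M, cbud, cd$v0, as.integer(iters), tol)
    obj <- abs(fit$objective)
    if (is.null(best) || obj > best$lambda + 1e-15) {
      vq <- sum(fit$v * (D %*% fit$v))
      best <- list(lambda = obj, v = canonical_sign(as.numeric(fit$v)),
                   sign = if (vq >= 0) 1L else -1L,
                   iterations = fit$iterations, converged = fit$converged)
    }
  }
  best$nnz <- sum(abs(best$v) > 1e-12)
  structure(best, class = "matrix_spectral_result")
}

#' @export
print.matrix_spectral_result <- function(x, ...) {
  cat(sprintf("sLME: lambda=%.6g (sign %+d), ||v||_0=%d\n",
              x$lambda, x$sign, x$nnz))
  invisible(x)
}

# Mode-3 contraction: (D x_3 u) is the p x p matrix sum_l u_l D[,,l].
tensor_times_u <- function(slides, u) {
  Dt <- slides[, , 1] * u[1]
  for (l in 2:dim(slides)[3]) Dt <- Dt + slides[, , l] * u[l]
  Dt
}

# Modes-1,2 contraction: g_l = v' D[,,l] v, the length-q comparison vector.
tensor_times_vv <- function(slides, v) {
  q <- dim(slides)[3]
  vapply(seq_len(q), function(l) sum(v * (slides[, , l] %*% v)), numeric(1))
}

#' Sparse symmetric tensor decomposition (SSTD)
#'
#' Fits the best sparse symmetric rank-1 model `D ~ Lambda v o v o u`
#' (`||v||_2 = ||u||_2 = 1`, `||v||_0 <= R`, `Lambda >= 0`) to a p x p x q
#' tensor of symmetric slides by alternating updates: the v-update solves the
#' PMD subproblem on the contracted matrix `D x_3 u`, and the u-update is the
#' normalized contraction `D x_1 v x_2 v`. Because the final u-update
#' normalizes that contraction, `Lambda = ||D x_1 v x_2 v||_2 >= 0` by
#' construction. The best of `restarts` random initializations (seeded from
#' `seed`) is returned; within each restart the objective trace of Lambda is
#' non-decreasing (a failed PMD step keeps the previous iterate and stops).
#'
#' @param D A [differential_tensor()] or a p x p x q array of symmetric
#'   slides.
#' @param R Sparsity parameter in \[1, p\].
#' @param T Maximum alternating iterations per restart (default 50).
#' @param restarts Number of random initializations (default 5).
#' @param seed Integer master seed for the initializations.
#' @param tol Early-stop tolerance on the change of Lambda (default 1e-6).
#' @return An object of class `spectral_result`: `Lambda` (sLTE, >= 0), `v`
#'   (sparse unit eigenvector, largest-magnitude entry positive), `u`
#'   (length-q unit loading over comparisons, sign folded here),
#'   `objective_trace`, `restarts_used`, `R`, `degenerate`, `gene_ids`.
#' @export
sstd <- function(D, R, T = 50, restarts = 5, seed = 1, tol = 1e-6) {
  Dt <- as_diff_tensor(D)
  slides <- Dt$slides
  if (!all(is.finite(slides))) stop("tensor contains non-finite values")
  p <- dim(slides)[1]
  q <- dim(slides)[3]
  if (T < 1) stop("T must be >= 1")
  cbud <- l1_budget(R, p)  # validates R

  if (max(abs(slides)) == 0) {
    v <- c(1, rep(0, p - 1)); u <- c(1, rep(0, q - 1))
    return(structure(list(Lambda = 0, v = v, u = u,
                          objective_trace = list(0), restarts_used = 0L,
                          R = R, degenerate = TRUE, gene_ids = Dt$gene_ids),
                     class = "spectral_result"))
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed((as.integer(seed) + r) %% 2147483647L)
    u <- rnorm(q); u <- u / sqrt(sum(u^2))
    v <- NULL; Lam <- 0
    trace <- numeric(0)
    for (t in seq_len(T)) {
      Dm <- tensor_times_u(slides, u)
      fit <- pmd_sparse_eigen(Dm, R, v_init = v)
      v_new <- fit$v
      g <- tensor_times_vv(slides, v_new)
      Lam_new <- sqrt(sum(g^2))
      if (Lam_new <= Lam + 1e-15) break  # PMD step failed to improve: stop
      v <- v_new
      u <- g / Lam_new
      Lam <- Lam_new
      trace <- c(trace, Lam)
      if (t > 1 && abs(trace[t] - trace[t - 1]) < tol) break
    }
    if (is.null(v)) { v <- c(1, rep(0, p - 1)); trace <- 0 }
    if (is.null(best) || Lam > best$Lambda) {
      best <- list(Lambda = Lam, v = canonical_sign(v), u = u,
                   objective_trace = as.list(trace), restarts_used = r)
    }
  }
  best$restarts_used <- as.integer(restarts)
  best$R <- R
  best$degenerate <- best$Lambda == 0
  best$gene_ids <- Dt$gene_ids
  structure(best, class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("SSTD: Lambda=%.6g, ||v||_0=%d, u=(%s), R=%s%s\n",
              x$Lambda, sum(abs(x$v) > 1e-12),
              paste(sprintf("%.3f", x$u), collapse = ", "),
              format(x$R), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Squared Frobenius loss of the rank-1 fit Lambda v o v o u.
sstd_loss <- function(slides, Lambda, v, u) {
  M <- Lambda * tcrossprod(v)
  tot <- 0
  for (l in seq_len(dim(slides)[3]))
    tot <- tot + sum((slides[, , l] - M * u[l])^2)
  tot
}

#' BIC-based selection of the sparsity parameter R
#'
#' For each R on the grid, fits the SSTD and evaluates
#' `BIC(R) = 3 p^2 log(||D - Lambda v o v o u||_F^2 / (3 p^2))
#'           + (2 + 2 ||v||_0) log(3 p^2)`,
#' with an epsilon floor (1e-12) on the loss so that noiseless fixtures do
#' not take log(0). Returns the R minimizing BIC; ties go to the smallest R.
#'
#' @param D A [differential_tensor()] or p x p x 3 array.
#' @param grid Integer vector of candidate R values in \[1, p\].
#' @param ... Passed on to [sstd()] (T, restarts, seed, tol).
#' @return A list: `R` (selected), `table` (data.frame R, Lambda, nnz, loss,
#'   bic), `fits` (the spectral_result per R).
#' @export
bic_select_R <- function(D, grid, ...) {
  Dt <- as_diff_tensor(D)
  if (length(grid) < 1) stop("grid must be non-empty")
  slides <- Dt$slides
  p <- dim(slides)[1]; q <- dim(slides)[3]
  npar <- q * p^2   # 3 p^2 cells in the tensor
  fits <- lapply(grid, function(R) sstd(Dt, R = R, ...))
  loss <- vapply(seq_along(grid), function(i)
    sstd_loss(slides, fits[[i]]$Lambda, fits[[i]]$v, fits[[i]]$u), numeric(1))
  nnz <- vapply(fits, function(f) sum(abs(f$v) > 1e-12), numeric(1))
  bic <- npar * log(pmax(loss, 1e-12) / npar) + (2 + 2 * nnz) * log(npar)
  ord <- order(bic, grid)
  sel <- grid[ord[1]]
  list(R = sel,
       table = data.frame(R = grid, Lambda = vapply(fits, `[[`, numeric(1), "Lambda"),
                          nnz = nnz, loss = loss, bic = bic),
       fits = setNames(fits, paste0("R", grid)))
}
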