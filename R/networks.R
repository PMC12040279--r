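# Per-genotype correlation networks and the 3-slide differential tensor.
#
# At a marker, samples are grouped by genotype (A/H/B), a Pearson correlation
# matrix is computed within each group, within-chromosome entries are
# optionally zeroed (the "set-to-zero" masking step focusing on trans
# effects), and the three pairwise differences are stacked into a
# p x p x 3 tensor with slides (AB, AH, BH):
#   D_AB = N_B - N_A,  D_AH = N_H - N_A,  D_BH = N_H - N_B,
# so slide BH = slide AH - slide AB identically.

#' Group samples by genotype at a marker
#'
#' Samples with missing genotype at the marker belong to no group (they are
#' excluded from this marker's test only). A marker is testable when at least
#' two groups are non-empty; groups smaller than `min_group` flag the marker.
#'
#' @param geno A [genotype_matrix()].
#' @param marker_id Marker to group on.
#' @param min_group Minimum per-group sample count (default 10) below which
#'   the marker is flagged as too small.
#' @return An object of class `genotype_groups` with fields `samples_A`,
#'   `samples_H`, `samples_B`, counts, `testable`, and `reason`.
#' @export
group_by_genotype <- function(geno, marker_id, min_group = 10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  i <- match(marker_id, geno$marker_ids)
  if (is.na(i)) stop("unknown marker: ", marker_id)
  z <- geno$codes[i, ]
  grp <- list(samples_A = geno$sample_ids[which(z == "A")],
              samples_H = geno$sample_ids[which(z == "H")],
              samples_B = geno$sample_ids[which(z == "B")])
  counts <- vapply(grp, length, integer(1))
  names(counts) <- c("nA", "nH", "nB")
  nonempty <- sum(counts > 0)
  testable <- TRUE; reason <- NA_character_
  if (nonempty < 2) {
    testable <- FALSE
    reason <- "fewer than 2 non-empty genotype groups"
  } else if (any(counts > 0 & counts < min_group)) {
    testable <- FALSE
    reason <- sprintf("group below min_group=%d (nA=%d nH=%d nB=%d)",
                      min_group, counts[1], counts[2], counts[3])
  }
  structure(c(list(marker_id = marker_id), grp,
              list(counts = counts, testable = testable, reason = reason)),
            class = "genotype_groups")
}

#' @export
print.genotype_groups <- function(x, ...) {
  cat(sprintf("genotype_groups at %s: nA=%d nH=%d nB=%d (%s)\n",
              x$marker_id, x$counts[1], x$counts[2], x$counts[3],
              if (x$testable) "testable" else x$reason))
  invisible(x)
}

#' Within-group Pearson correlation network
#'
#' Computes the gene-gene Pearson correlation matrix over the given samples.
#' Genes with zero variance within the group get correlation 0 to all others
#' (with a warning), keeping downstream tensors well-defined.
#'
#' @param expr A residualized [expression_matrix()].
#' @param samples Sample ids of one genotype group (at least 2).
#' @param genotype Optional label ("A", "H", or "B") carried for display.
#' @return An object of class `correlation_network`: fields `matrix`
#'   (p x p symmetric, entries in \[-1, 1\]), `masked` (FALSE), `genotype`,
#'   `gene_ids`, `n_samples`.
#' @export
correlation_network <- function(expr, samples, genotype = NA_character_) {
  if (!inherits(expr, "expression_matrix"))
    stop("expr must be an expression_matrix")
  idx <- match(samples, expr$sample_ids)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  if (length(idx) < 2) stop("at least 2 samples are required for correlation")
  x <- t(expr$values[, idx, drop = FALSE])   # samples x genes
  n <- nrow(x)
  mu <- colMeans(x)
  ss <- .colSums((x - rep(mu, each = n))^2, n, ncol(x))
  flat <- ss <= 0 | !is.finite(ss)
  cm <- suppressWarnings(cor(x))
  if (any(flat)) {
    warning(sprintf("%d gene(s) with zero variance in group; correlations set to 0",
                    sum(flat)))
    cm[flat, ] <- 0
    cm[, flat] <- 0
    diag(cm)[flat] <- 1
  }
  cm[!is.finite(cm)] <- 0
  cm <- (cm + t(cm)) / 2
  structure(list(matrix = cm, masked = FALSE, genotype = genotype,
                 gene_ids = expr$gene_ids, n_samples = length(idx)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network (%s): %d genes, n=%d, %s\n",
              x$genotype, nrow(x$matrix), x$n_samples,
              if (x$masked) "masked" else "unmasked"))
  invisible(x)
}

#' Zero out within-chromosome correlations
#'
#' Sets entry (j, k) to zero whenever genes j and k lie on the same
#' chromosome (the diagonal included), focusing the analysis on
#' cross-chromosome (trans) co-expression. Skipping this step is allowed by
#' passing `mask = FALSE` to the scan functions.
#'
#' @param net A [correlation_network()] (unmasked).
#' @param gmap Gene map data.frame (gene_id, chrom, pos) covering all genes.
#' @return The network with same-chromosome entries zeroed and `masked = TRUE`.
#' @export
mask_within_chromosome <- function(net, gmap) {
  stopifnot(inherits(net, "correlation_network"))
  if (net$masked) stop("network is already masked")
  idx <- match(net$gene_ids, gmap$gene_id)
  if (anyNA(idx))
    stop("gene(s) missing from gene map: ",
         paste(net$gene_ids[is.na(idx)], collapse = ", "))
  chrom <- gmap$chrom[idx]
  same <- outer(chrom, chrom, "==")
  m <- net$matrix
  m[same] <- 0
  net$matrix <- m
  net$masked <- TRUE
  net
}

#' Stack pairwise differential networks into a tensor
#'
#' Builds the order-3 differential tensor with slides
#' `D_AB = N_B - N_A`, `D_AH = N_H - N_A`, `D_BH = N_H - N_B`
#' (so slide BH equals slide AH minus slide AB).
#'
#' @param nA,nH,nB [correlation_network()] objects for genotype groups A, H,
#'   B, masked consistently and over the same genes in the same order.
#' @param marker_id Optional marker label.
#' @return An object of class `differential_tensor`: `slides` is a
#'   p x p x 3 array with dimnames `c("AB","AH","BH")` on the third mode.
#' @export
differential_tensor <- function(nA, nH, nB, marker_id = NA_character_) {
  nets <- list(nA, nH, nB)
  if (!all(vapply(nets, inherits, logical(1), "correlation_network")))
    stop("inputs must be correlation_network objects")
  p <- nrow(nA$matrix)
  if (nrow(nH$matrix) != p || nrow(nB$matrix) != p)
    stop("network dimensions do not match")
  if (!identical(nA$gene_ids, nH$gene_ids) ||
      !identical(nA$gene_ids, nB$gene_ids))
    stop("networks are over different gene sets/orders")
  if (length(unique(vapply(nets, `[[`, logical(1), "masked"))) != 1)
    stop("networks are not masked consistently")
  slides <- array(0, dim = c(p, p, 3),
                  dimnames = list(nA$gene_ids, nA$gene_ids,
                                  c("AB", "AH", "BH")))
  slides[, , 1] <- nB$matrix - nA$matrix
  slides[, , 2] <- nH$matrix - nA$matrix
  slides[, , 3] <- nH$matrix - nB$matrix
  structure(list(slides = slides, gene_ids = nA$gene_ids,
                 marker_id = marker_id, masked = nA$masked),
            class = "differential_tensor")
}

#' @export
print.differential_tensor <- function(x, ...) {
  cat(sprintf("differential_tensor at %s: %d x %d x 3 (%s)\n",
              x$marker_id, dim(x$slides)[1], dim(x$slides)[2],
              if (x$masked) "masked" else "unmasked"))
  invisible(x)
}

# Coerce: accept a raw p x p x 3 array anywhere a differential_tensor is
# expected (handy in tests and for planted tensors).
as_diff_tensor <- function(D) {
  if (inherits(D, "differential_tensor")) return(D)
  if (is.array(D) && length(dim(D)) == 3) {
    gid <- dimnames(D)[[1]]
    if (is.null(gid)) gid <- paste0("g", seq_len(dim(D)[1]))
    return(structure(list(slides = D, gene_ids = gid,
                          marker_id = NA_character_, masked = NA),
                     class = "differential_tensor"))
  }
  stop("expected a differential_tensor or a p x p x q array")
}
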