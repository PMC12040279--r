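# Interpretation of the SSTD output at a marker: gene leverages (v^2), the
# joint differential network (v v'), per-comparison loadings (u), and raw
# per-genotype correlation views for retained edges.

#' Gene leverage scores
#'
#' The element-wise square of the sparse tensor eigenvector. Since
#' `||v||_2 = 1`, the leverages are nonnegative and sum to one; higher values
#' indicate greater connectivity of the gene within the joint differential
#' network.
#'
#' @param res A [sstd()] result.
#' @return Named numeric vector of leverages (sums to 1).
#' @export
leverage_scores <- function(res) {
  stopifnot(inherits(res, "spectral_result"))
  lv <- res$v^2
  names(lv) <- res$gene_ids
  lv
}

#' Rank genes by leverage
#'
#' @param leverage A leverage vector (from [leverage_scores()]).
#' @param k How many genes to return (default all).
#' @return A data.frame: gene_id, leverage, rank, cumulative (cumulative
#'   leverage). Descending by leverage, ties broken by gene_id.
#' @export
top_genes <- function(leverage, k = length(leverage)) {
  if (k < 1 || k > length(leverage)) stop("k must be in [1, p]")
  ids <- names(leverage)
  if (is.null(ids)) ids <- paste0("g", seq_along(leverage))
  ord <- order(-leverage, ids)
  out <- data.frame(gene_id = ids[ord], leverage = as.numeric(leverage[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out$cumulative <- cumsum(out$leverage)
  out[seq_len(k), , drop = FALSE]
}

#' Build the joint differential network from an SSTD fit
#'
#' Edges connect genes with nonzero eigenvector entries; the edge weight is
#' `w_jk = v_j v_k` (the entry of the rank-1 joint differential network
#' `v v'`), and each edge carries the reconstructed per-comparison change
#' `Lambda v_j v_k u_l` for l in (AB, AH, BH), whose sign encodes
#' enhancement (+) or reduction (-) of the co-expression. Edges are ranked by
#' `|w_jk|` and truncated to the strongest `top_fraction`.
#'
#' @param res A [sstd()] result.
#' @param top_fraction Fraction of strongest edges to keep, in (0, 1\]
#'   (default 0.10).
#' @return An object of class `joint_differential_network`: `gene_ids`,
#'   `leverage`, `edges` (data.frame gene_j, gene_k, weight, change_AB,
#'   change_AH, change_BH), `Lambda`, `u`, `degenerate`.
#' @export
build_network <- function(res, top_fraction = 0.10) {
  stopifnot(inherits(res, "spectral_result"))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  lv <- leverage_scores(res)
  q <- length(res$u)
  cmp <- if (q == 3) c("AB", "AH", "BH") else paste0("cmp", seq_len(q))
  empty <- data.frame(gene_j = character(0), gene_k = character(0),
                      weight = numeric(0))
  for (nm in cmp) empty[[paste0("change_", nm)]] <- numeric(0)
  if (res$degenerate || res$Lambda == 0) {
    warning("degenerate fit (Lambda = 0): empty differential network")
    return(structure(list(gene_ids = res$gene_ids, leverage = lv,
                          edges = empty, Lambda = res$Lambda, u = res$u,
                          degenerate = TRUE),
                     class = "joint_differential_network"))
  }
  nz <- which(abs(res$v) > 1e-12)
  if (length(nz) < 2) {
    return(structure(list(gene_ids = res$gene_ids, leverage = lv,
                          edges = empty, Lambda = res$Lambda, u = res$u,
                          degenerate = FALSE),
                     class = "joint_differential_network"))
  }
  pr <- t(utils::combn(nz, 2))
  w <- res$v[pr[, 1]] * res$v[pr[, 2]]
  ord <- order(-abs(w))
  keep <- ord[seq_len(max(1, ceiling(top_fraction * length(w))))]
  ed <- data.frame(gene_j = res$gene_ids[pr[keep, 1]],
                   gene_k = res$gene_ids[pr[keep, 2]],
                   weight = w[keep], stringsAsFactors = FALSE)
  for (l in seq_len(q))
    ed[[paste0("change_", cmp[l])]] <- res$Lambda * w[keep] * res$u[l]
  structure(list(gene_ids = res$gene_ids, leverage = lv, edges = ed,
                 Lambda = res$Lambda, u = res$u, degenerate = FALSE),
            class = "joint_differential_network")
}

#' @export
print.joint_differential_network <- function(x, ...) {
  cat(sprintf("joint_differential_network: %d genes, %d edges, Lambda=%.4g\n",
              length(x$gene_ids), nrow(x$edges), x$Lambda))
  invisible(x)
}

#' Per-genotype correlation views of retained edges
#'
#' For every edge of the joint differential network, reports the raw
#' within-genotype correlations side by side (corr_A, corr_H, corr_B). A
#' monotone triple across A -> H -> B indicates a nearly additive genetic
#' effect on that gene pair's co-expression.
#'
#' @param nA,nH,nB [correlation_network()] objects over the same genes.
#' @param network A [build_network()] result.
#' @return A data.frame: gene_j, gene_k, weight, corr_A, corr_H, corr_B.
#' @export
genotype_network_views <- function(nA, nH, nB, network) {
  stopifnot(inherits(network, "joint_differential_network"))
  for (net in list(nA, nH, nB))
    if (!identical(net$gene_ids, network$gene_ids))
      stop("networks are over a different gene universe")
  ed <- network$edges
  j <- match(ed$gene_j, network$gene_ids)
  k <- match(ed$gene_k, network$gene_ids)
  data.frame(gene_j = ed$gene_j, gene_k = ed$gene_k, weight = ed$weight,
             corr_A = nA$matrix[cbind(j, k)],
             corr_H = nH$matrix[cbind(j, k)],
             corr_B = nB$matrix[cbind(j, k)],
             stringsAsFactors = FALSE)
}

#' Write leverage and edge tables as TSV
#'
#' @param network A [build_network()] result.
#' @param gmap Optional gene map to annotate chromosomes in the leverage
#'   table.
#' @param leverage_path,edges_path Output paths (NULL to skip either).
#' @return Invisibly, a list with the two data.frames.
#' @export
write_network_tsv <- function(network, gmap = NULL, leverage_path = NULL,
                              edges_path = NULL) {
  tg <- top_genes(network$leverage)
  if (!is.null(gmap))
    tg$chrom <- gmap$chrom[match(tg$gene_id, gmap$gene_id)]
  if (!is.null(leverage_path))
    write.table(tg, leverage_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(edges_path))
    write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(leverage = tg, edges = network$edges))
}
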