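# Synthetic F2-intercross data with a planted network QTL.
#
# The generator emulates the simulation design used to validate the method:
#   * two genetically divergent fully homozygous parents (A x B);
#   * F1 all heterozygous; F2 individuals formed from two F1 gametes, each
#     gamete carrying exactly one crossover per chromosome at a
#     uniform-random position (no interference, no genetic-map distances);
#   * Poisson read counts whose log-rate is
#       mu_j + d_i * effect_size * f_i * s_j,
#     with d_i in {0, 1/2, 1} the individual's scaled dosage at one planted
#     marker, f_i ~ N(0,1) a per-individual latent factor, and s_j ~ N(0,1)
#     fixed gene loadings — so the planted marker modulates cross-gene
#     correlation additively across genotype classes and all genes are
#     affected.
# Genes are co-located with markers (every gene is a candidate locus),
# evenly spaced along each chromosome.

#' Simulation configuration
#'
#' Defaults state the reference simulation world: 200 genes across 20
#' chromosomes, Poisson counts around `baseline_mean = 10` with per-gene
#' log-mean jitter (sd 0.5), and a planted network QTL of moderate strength.
#' The default `effect_size = 0.07` is calibrated so the planted signal
#' eigenvalue crosses the random-matrix noise level of the group correlation
#' differences between n = 50 and n = 300 — detection power grows over that
#' population-size range instead of saturating at the smallest n.
#'
#' @param n Number of F2 individuals.
#' @param n_genes Number of genes (= markers), default 200.
#' @param n_chrom Number of chromosomes, default 20; must divide `n_genes`.
#' @param snqtl_index Index of the planted marker (default: middle marker of
#'   chromosome 1).
#' @param effect_size Network effect strength (>= 0; 0 = null model).
#' @param baseline_mean Baseline Poisson mean of the counts (default 10).
#' @param mu_sd Per-gene log-mean jitter (default 0.5).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 300, n_genes = 200, n_chrom = 20,
                       snqtl_index = NULL, effect_size = 0.07,
                       baseline_mean = 10, mu_sd = 0.5, seed = 1) {
  if (n_genes %% n_chrom != 0)
    stop("n_genes must be divisible by n_chrom")
  per <- n_genes / n_chrom
  if (is.null(snqtl_index)) snqtl_index <- ceiling(per / 2)
  if (snqtl_index < 1 || snqtl_index > n_genes)
    stop("snqtl_index out of range")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  structure(list(n = as.integer(n), n_genes = as.integer(n_genes),
                 n_chrom = as.integer(n_chrom),
                 snqtl_index = as.integer(snqtl_index),
                 effect_size = effect_size, baseline_mean = baseline_mean,
                 mu_sd = mu_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# One F1 gamete for one chromosome: a recombinant of the two parental
# haplotypes (all-A and all-B) with exactly one crossover at a
# uniform-random point along (0, 1); marker positions are evenly spaced.
f1_gamete_chrom <- function(pos01) {
  start_a <- runif(1) < 0.5
  x <- runif(1)
  left <- pos01 <= x
  alleles <- ifelse(left == start_a, "A", "B")
  alleles
}

#' Simulate F2 intercross genotypes
#'
#' Parents are fully homozygous (A x B), F1 all heterozygous. Each F2
#' individual inherits two independent F1 gametes; each gamete carries
#' exactly one crossover per chromosome, uniformly placed. Markers are
#' evenly spaced along each chromosome, producing the expected
#' within-chromosome LD blocks and ~1:2:1 genotype segregation.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] of `n_genes` markers x `n` samples with
#'   chromosome/position map attached.
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  per <- cfg$n_genes / cfg$n_chrom
  pos01 <- (seq_len(per) - 0.5) / per
  codes <- matrix(NA_character_, nrow = cfg$n_genes, ncol = cfg$n)
  for (i in seq_len(cfg$n)) {
    for (ch in seq_len(cfg$n_chrom)) {
      g1 <- f1_gamete_chrom(pos01)
      g2 <- f1_gamete_chrom(pos01)
      geno <- ifelse(g1 == g2, g1, "H")
      codes[(ch - 1) * per + seq_len(per), i] <- geno
    }
  }
  marker_ids <- paste0("M", seq_len(cfg$n_genes))
  sample_ids <- paste0("S", seq_len(cfg$n))
  chrom <- rep(seq_len(cfg$n_chrom), each = per)
  pos <- rep(seq_len(per) * 1000L, times = cfg$n_chrom)
  dimnames(codes) <- list(marker_ids, sample_ids)
  genotype_matrix(codes, marker_ids, sample_ids, chrom = chrom, pos = pos)
}

#' Simulate Poisson expression with a planted network QTL
#'
#' Counts for gene j in individual i are Poisson with log-rate
#' `mu_j + d_i * effect_size * f_i * s_j`, where `d_i` in \{0, 1/2, 1\} is
#' the scaled dosage at the planted marker, `f_i ~ N(0,1)` a per-individual
#' latent factor and `s_j ~ N(0,1)` fixed gene loadings. With
#' `effect_size = 0` the counts are independent Poisson (null model); with a
#' positive effect the cross-gene correlation increases with dosage, all
#' genes being affected.
#'
#' @param geno A [simulate_cross()] result.
#' @param cfg The same [sim_config()].
#' @return An [expression_matrix()] in `raw_counts` state; the truth
#'   (`snqtl_marker`, `s`, `f`, `mu`) is attached as attribute `"truth"`.
#' @export
simulate_expression <- function(geno, cfg) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 104729L)  # independent stream from the cross
  p <- cfg$n_genes; n <- cfg$n
  mu <- log(cfg$baseline_mean) + rnorm(p, 0, cfg$mu_sd)
  s <- rnorm(p)
  f <- rnorm(n)
  z <- geno$codes[cfg$snqtl_index, ]
  d <- c(A = 0, H = 0.5, B = 1)[z]
  d[is.na(d)] <- 0.5
  lograte <- outer(mu, rep(1, n)) +
    cfg$effect_size * (s %o% (d * f))
  counts <- matrix(rpois(p * n, exp(lograte)), nrow = p)
  gene_ids <- paste0("G", seq_len(p))
  dimnames(counts) <- list(gene_ids, geno$sample_ids)
  expr <- expression_matrix(counts, gene_ids, geno$sample_ids,
                            state = "raw_counts")
  attr(expr, "truth") <- list(snqtl_marker = geno$marker_ids[cfg$snqtl_index],
                              snqtl_index = cfg$snqtl_index,
                              effect_size = cfg$effect_size,
                              s = s, f = f, mu = mu)
  expr
}

#' Simulate a complete dataset (expression, genotypes, gene map)
#'
#' Genes are co-located with markers (gene `Gk` at marker `Mk`), so every
#' gene is a candidate locus. Optionally writes the standard TSVs plus a
#' `truth.json` with the planted marker and generator parameters.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory for expression.tsv, genotypes.tsv,
#'   genemap.tsv, markermap.tsv and truth.json.
#' @return A list: `expr` ([expression_matrix()], raw counts), `geno`
#'   ([genotype_matrix()]), `gmap` (gene map data.frame), `truth`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  geno <- simulate_cross(cfg)
  expr <- simulate_expression(geno, cfg)
  per <- cfg$n_genes / cfg$n_chrom
  gmap <- data.frame(gene_id = expr$gene_ids,
                     chrom = rep(seq_len(cfg$n_chrom), each = per),
                     pos = rep(seq_len(per) * 1000L, times = cfg$n_chrom),
                     stringsAsFactors = FALSE)
  truth <- attr(expr, "truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    em <- data.frame(gene_id = expr$gene_ids, expr$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(em, file.path(dir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gm <- data.frame(marker_id = geno$marker_ids, geno$codes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(gm, file.path(dir, "genotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gmap, file.path(dir, "genemap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mm <- data.frame(marker_id = geno$marker_ids, chrom = geno$chrom,
                     pos = geno$pos, stringsAsFactors = FALSE)
    write.table(mm, file.path(dir, "markermap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(snqtl_marker = truth$snqtl_marker,
                              snqtl_index = truth$snqtl_index,
                              effect_size = truth$effect_size,
                              n = cfg$n, n_genes = cfg$n_genes,
                              n_chrom = cfg$n_chrom, seed = cfg$seed),
                         file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  list(expr = expr, geno = geno, gmap = gmap, truth = truth)
}
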