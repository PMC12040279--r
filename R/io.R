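# Input tables, validation, and expression preprocessing.
#
# Coordinate conventions shared by the whole package:
#   * expression is genes x samples; genotypes are markers x samples;
#   * samples are aligned across tables by exact id match;
#   * chromosome codes: positive integers = autosome/sex chromosome,
#     0 = mitochondrial genome, -1 = unplaced scaffold.

#' Construct an expression matrix object
#'
#' Container for a genes x samples expression matrix, either raw read counts
#' or covariate-adjusted residuals.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene ids (rownames).
#' @param sample_ids Character vector of unique sample ids (colnames).
#' @param state Either `"raw_counts"` (nonnegative integers) or
#'   `"residualized"` (each gene row has zero mean across samples).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              state = c("raw_counts", "residualized")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sample_ids)
  if (state == "raw_counts") {
    bad <- which(values < 0 | abs(values - round(values)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                   gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  } else {
    rm_ <- rowMeans(values)
    if (nrow(values) > 0 && max(abs(rm_)) > 1e-6)
      stop("residualized state requires zero-mean gene rows")
  }
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, state = state,
                 adj_mean = NULL),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (nrow(dt) == 0) stop("no data rows in ", path)
  dt
}

#' Read a gene expression count table
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. Entries must be nonnegative integers (read counts).
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()] in `raw_counts` state.
#' @export
load_expression <- function(path) {
  dt <- read_tsv_table(path)
  gene_ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    nonnum <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) &
                      !is.na(vals), arr.ind = TRUE)
    if (nrow(nonnum) > 0)
      stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                   gene_ids[nonnum[1, 1]], colnames(vals)[nonnum[1, 2]]))
    storage.mode(vals) <- "double"
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("missing count at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  expression_matrix(vals, gene_ids, colnames(vals), state = "raw_counts")
}

#' Read a gene map table
#'
#' TSV with columns `gene_id`, `chrom`, `pos`. Chromosomes are integers
#' (0 = mitochondrial, -1 = unplaced scaffold); positions are nonnegative
#' integers used for ordering only.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns gene_id, chrom, pos.
#' @export
load_gene_map <- function(path) {
  dt <- read_tsv_table(path)
  need <- c("gene_id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stop("gene map must have columns: ", paste(need, collapse = ", "))
  gm <- data.frame(gene_id = as.character(dt$gene_id),
                   chrom = as.integer(dt$chrom),
                   pos = as.integer(dt$pos),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(gm$gene_id))
    stop("duplicate gene id(s) in gene map: ",
         paste(unique(gm$gene_id[duplicated(gm$gene_id)]), collapse = ", "))
  if (any(gm$pos < 0, na.rm = TRUE)) stop("gene positions must be >= 0")
  gm
}

#' Read a sample covariate table
#'
#' TSV with a `sample_id` column plus covariate columns. Factors and character
#' columns are one-hot encoded with the first level dropped; the result is a
#' full-rank numeric design (intercept added downstream).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with rownames = sample ids and numeric columns.
#' @export
load_covariates <- function(path) {
  dt <- read_tsv_table(path)
  if (!"sample_id" %in% names(dt))
    stop("covariate table must have a sample_id column")
  ids <- as.character(dt$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample id(s) in covariates")
  cov <- dt[, setdiff(names(dt), "sample_id"), drop = FALSE]
  rownames(cov) <- ids
  if (anyNA(cov)) stop("missing values in covariates are not allowed")
  encode_covariates(cov)
}

# One-hot encode factors/characters (drop first level); keep numerics.
encode_covariates <- function(cov) {
  if (is.null(cov) || ncol(cov) == 0)
    return(matrix(numeric(0), nrow = NROW(cov), ncol = 0,
                  dimnames = list(rownames(cov), NULL)))
  df <- as.data.frame(cov, stringsAsFactors = TRUE)
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  mm <- model.matrix(~ ., data = df)
  mm <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  rownames(mm) <- rownames(cov)
  mm
}

#' Genotype matrix constructor
#'
#' Markers x samples genotype codes over \{A, H, B, NA\}: A and B are the two
#' homozygous classes, H heterozygous. An optional marker map attaches
#' chromosome and position per marker.
#'
#' @param codes Character matrix over \{"A","H","B",NA\}.
#' @param marker_ids,sample_ids Row/column ids.
#' @param chrom,pos Optional integer vectors per marker.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, marker_ids = rownames(codes),
                            sample_ids = colnames(codes),
                            chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  marker_ids <- as.character(marker_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(marker_ids)) stop("duplicate marker id(s)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample id(s)")
  ok <- codes %in% c("A", "H", "B") | is.na(codes)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' at marker '%s', sample '%s'",
                 codes[bad[1], bad[2]], marker_ids[bad[1]], sample_ids[bad[2]]))
  }
  nclass <- apply(codes, 1, function(z) length(unique(z[!is.na(z)])))
  if (any(nclass < 1))
    stop("marker(s) with no non-missing genotype: ",
         paste(marker_ids[nclass < 1], collapse = ", "))
  dimnames(codes) <- list(marker_ids, sample_ids)
  if (is.null(chrom)) chrom <- rep(NA_integer_, length(marker_ids))
  if (is.null(pos)) pos <- rep(NA_integer_, length(marker_ids))
  structure(list(codes = codes, marker_ids = marker_ids,
                 sample_ids = sample_ids,
                 chrom = as.integer(chrom), pos = as.integer(pos)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples\n",
              nrow(x$codes), ncol(x$codes)))
  invisible(x)
}

#' Read a marker genotype table
#'
#' TSV with marker ids in the first column and sample ids in the header.
#' Tokens "NA", "." and "" are treated as missing. Dosage coding maps
#' 0 -> A, 1 -> H, 2 -> B; AHB coding accepts A/H/B or AA/AB/BB.
#'
#' @param path Path to the TSV file.
#' @param coding `"AHB"` or `"dosage012"`.
#' @param marker_map Optional data.frame with columns marker_id, chrom, pos.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, coding = c("AHB", "dosage012"),
                           marker_map = NULL) {
  coding <- match.arg(coding)
  dt <- read_tsv_table(path)
  marker_ids <- as.character(dt[[1]])
  raw <- as.matrix(dt[, -1, drop = FALSE])
  raw <- matrix(trimws(as.character(raw)), nrow = nrow(raw),
                dimnames = list(marker_ids, colnames(raw)))
  raw[raw %in% c("NA", ".", "")] <- NA_character_
  map <- if (coding == "dosage012") {
    c("0" = "A", "1" = "H", "2" = "B")
  } else {
    c(A = "A", H = "H", B = "B", AA = "A", AB = "H", BB = "B")
  }
  codes <- raw
  tofill <- !is.na(raw)
  known <- raw[tofill] %in% names(map)
  if (!all(known)) {
    bad <- which(tofill & !matrix(raw %in% c(names(map), NA), nrow(raw)),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype token '%s' at marker '%s', sample '%s'",
                 raw[bad[1], bad[2]], marker_ids[bad[1]],
                 colnames(raw)[bad[2]]))
  }
  codes[tofill] <- unname(map[raw[tofill]])
  chrom <- pos <- NULL
  if (!is.null(marker_map)) {
    idx <- match(marker_ids, marker_map$marker_id)
    if (anyNA(idx))
      stop("marker(s) missing from marker map: ",
           paste(marker_ids[is.na(idx)], collapse = ", "))
    chrom <- marker_map$chrom[idx]
    pos <- marker_map$pos[idx]
  }
  genotype_matrix(codes, marker_ids, colnames(raw), chrom, pos)
}

#' Read a marker map table
#'
#' TSV with columns `marker_id`, `chrom`, `pos`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns marker_id, chrom, pos.
#' @export
load_marker_map <- function(path) {
  dt <- read_tsv_table(path)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(dt)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  data.frame(marker_id = as.character(dt$marker_id),
             chrom = as.integer(dt$chrom), pos = as.integer(dt$pos),
             stringsAsFactors = FALSE)
}

#' Normalize, residualize, and filter an expression matrix
#'
#' Pipeline: library-size normalization (counts per million) -> log2(x + 1)
#' -> per-gene least-squares residualization on the covariates (with
#' intercept) -> ranking by post-normalization mean -> restriction to the
#' `top_k` highest-mean genes. Every retained gene row has zero mean.
#'
#' The normalization recipe is a documented default (CPM then log2); it is
#' configurable via `normalize`. Applying `preprocess()` to its own output
#' (same covariates, same `top_k`) is a no-op up to numerical tolerance.
#'
#' @param expr An [expression_matrix()].
#' @param covariates Optional data.frame/matrix of per-sample covariates
#'   (rownames = sample ids, or rows aligned with `expr$sample_ids`).
#' @param top_k Number of genes to retain (default: all).
#' @param normalize `"cpm_log2"` (default) or `"log2"` (no library scaling).
#' @return An [expression_matrix()] in `residualized` state with `top_k` rows;
#'   the ranking means are kept in `$adj_mean`.
#' @export
preprocess <- function(expr, covariates = NULL, top_k = NULL,
                       normalize = c("cpm_log2", "log2")) {
  stopifnot(inherits(expr, "expression_matrix"))
  normalize <- match.arg(normalize)
  p <- nrow(expr$values); n <- ncol(expr$values)
  if (is.null(top_k)) top_k <- p
  if (top_k < 1 || top_k > p) stop("top_k must be in [1, number of genes]")

  if (expr$state == "raw_counts") {
    libsize <- colSums(expr$values)
    if (any(libsize == 0)) stop("sample(s) with zero library size")
    y <- switch(normalize,
                cpm_log2 = log2(sweep(expr$values, 2, libsize, "/") * 1e6 + 1),
                log2 = log2(expr$values + 1))
    adj_mean <- rowMeans(y)
  } else {
    # already residualized: re-running must be idempotent, so reuse the
    # stored ranking means (gene rows are zero-mean by construction)
    y <- expr$values
    adj_mean <- if (!is.null(expr$adj_mean)) expr$adj_mean[expr$gene_ids]
                else rowMeans(y)
  }

  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cm <- if (is.matrix(covariates) && is.numeric(covariates)) covariates
          else encode_covariates(covariates)
    if (!is.null(rownames(cm))) {
      idx <- match(expr$sample_ids, rownames(cm))
      if (anyNA(idx)) stop("covariates missing for sample(s): ",
                           paste(expr$sample_ids[is.na(idx)], collapse = ", "))
      cm <- cm[idx, , drop = FALSE]
    } else if (nrow(cm) != n) {
      stop("covariate rows do not match samples")
    }
    X <- cbind(X, cm)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate design matrix is rank-deficient")
  Q <- qr.Q(qx)
  resid <- y - (y %*% Q) %*% t(Q)

  keep <- order(-adj_mean, expr$gene_ids)[seq_len(top_k)]
  keep <- sort(keep)  # preserve input gene order among the retained genes
  out <- expression_matrix(resid[keep, , drop = FALSE],
                           expr$gene_ids[keep], expr$sample_ids,
                           state = "residualized")
  out$adj_mean <- setNames(adj_mean[keep], expr$gene_ids[keep])
  out
}

#' Check sample alignment across input tables
#'
#' @param expr An [expression_matrix()].
#' @param geno A [genotype_matrix()].
#' @param covariates Optional covariate table with sample rownames.
#' @return Invisibly TRUE; errors if the sample id sets differ.
#' @export
check_alignment <- function(expr, geno, covariates = NULL) {
  if (!identical(sort(expr$sample_ids), sort(geno$sample_ids)))
    stop("expression and genotype sample ids do not match")
  if (!is.null(covariates) && !is.null(rownames(covariates))) {
    if (!all(expr$sample_ids %in% rownames(covariates)))
      stop("covariates missing for some samples")
  }
  invisible(TRUE)
}
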