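#' Gene expression matrix container
#'
#' Genes x cells raw counts with optional normalized layer and cell metadata.
#' Counts must be non-negative integers with unique gene and cell ids; the
#' normalized layer exists only after \code{\link{normalize_counts}}.
#'
#' @param counts genes x cells matrix (base matrix or \code{Matrix}) with
#'   dimnames
#' @param meta data.frame of cell metadata, rownames = cell ids; a
#'   \code{qc_pass} logical column is added (TRUE) if absent
#' @return object of class \code{gene_expr}
#' @export
gene_expr <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("cell ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("raw counts must be non-negative integers")
  if (is.null(meta))
    meta <- data.frame(row.names = colnames(counts))
  else {
    if (!all(colnames(counts) %in% rownames(meta)))
      stop("metadata missing cells: ",
           paste(utils::head(setdiff(colnames(counts), rownames(meta))), collapse = ", "))
    meta <- meta[colnames(counts), , drop = FALSE]
  }
  if (is.null(meta$qc_pass)) meta$qc_pass <- TRUE
  structure(list(counts = counts, norm = NULL, meta = meta),
            class = "gene_expr")
}

#' @export
print.gene_expr <- function(x, ...) {
  cat("gene_expr:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      sum(x$meta$qc_pass), "passing QC;",
      if (is.null(x$norm)) "raw only" else "normalized layer present", "\n")
  invisible(x)
}

#' @rdname gene_expr
#' @param x object
#' @export
is_gene_expr <- function(x) inherits(x, "gene_expr")

#' Read a count matrix
#'
#' Reads MatrixMarket (\code{matrix.mtx} + \code{genes.tsv} +
#' \code{barcodes.tsv} in a directory) or dense TSV (genes as rows, first
#' column gene id). A \code{metadata.csv} sidecar (first column cell id) in
#' the same directory is joined when present.
#'
#' @param path directory (mtx) or file (tsv)
#' @param format "mtx" or "tsv"
#' @return a \code{gene_expr}
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) if (!file.exists(f)) stop("missing file: ", f)
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop(sprintf("dimension mismatch: matrix %d x %d vs %d genes, %d cells",
                   nrow(m), ncol(m), length(genes), length(cells)))
    dimnames(m) <- list(genes, cells)
    meta_path <- file.path(path, "metadata.csv")
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) == 0 || ncol(tab) < 2) stop("empty or malformed count TSV: ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    meta_path <- file.path(dirname(path), "metadata.csv")
  }
  if (any(m != round(m))) stop("non-integer counts in ", path)
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    rownames(meta) <- meta[[1]]
    meta <- meta[, -1, drop = FALSE]
  }
  gene_expr(m, meta)
}

#' Write a count matrix
#'
#' Inverse of \code{\link{read_counts}}: MTX triplet directory or dense TSV,
#' plus a \code{metadata.csv} sidecar when metadata is present.
#'
#' @param m a \code{gene_expr}
#' @param path directory (mtx) or file path (tsv)
#' @param format "mtx" or "tsv"
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m$counts), file.path(path, "genes.tsv"))
    writeLines(colnames(m$counts), file.path(path, "barcodes.tsv"))
    meta_path <- file.path(path, "metadata.csv")
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    tab <- data.frame(gene = rownames(m$counts), m$counts,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta_path <- file.path(dirname(path), "metadata.csv")
  }
  if (ncol(m$meta) > 0) {
    out <- data.frame(cell = rownames(m$meta), m$meta, check.names = FALSE)
    utils::write.csv(out, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Flag cells failing quality control
#'
#' Cells need at least \code{min_genes_detected} genes with a positive count
#' and a total count of at least \code{min_total_counts}; failing cells are
#' flagged \code{qc_pass = FALSE} (and excluded from downstream aggregation)
#' but kept in the matrix.
#'
#' @param m a \code{gene_expr}
#' @param min_genes_detected,min_total_counts thresholds (>= 0)
#' @return the matrix with updated \code{qc_pass}
#' @export
qc_filter <- function(m, min_genes_detected = 2000, min_total_counts = 50000) {
  stopifnot(is_gene_expr(m))
  if (min_genes_detected < 0 || min_total_counts < 0)
    stop("QC thresholds must be >= 0")
  detected <- colSums(m$counts > 0)
  totals <- colSums(m$counts)
  pass <- detected >= min_genes_detected & totals >= min_total_counts
  if (!any(pass))
    stop(sprintf("all %d cells fail QC (min_genes_detected = %g, min_total_counts = %g)",
                 ncol(m$counts), min_genes_detected, min_total_counts))
  m$meta$qc_pass <- unname(pass)
  m
}

cp10k_log1p <- function(counts) {
  totals <- colSums(counts)
  log1p(sweep(counts, 2, pmax(totals, 1), "/") * 1e4)
}

#' Normalize counts (counts-per-10K, log1p)
#'
#' \code{norm[g, c] = ln(1 + raw[g, c] * 1e4 / total[c])}, the documented
#' default of the common single-cell toolchains, applied to every cell with a
#' positive total. A QC-passing cell with zero total is an error.
#'
#' @param m a \code{gene_expr}
#' @return the matrix with a \code{norm} layer
#' @export
normalize_counts <- function(m) {
  stopifnot(is_gene_expr(m))
  totals <- colSums(m$counts)
  zero_pass <- totals == 0 & m$meta$qc_pass
  if (any(zero_pass))
    stop("QC-passing cell(s) with zero total counts: ",
         paste(utils::head(colnames(m$counts)[zero_pass]), collapse = ", "))
  m$norm <- cp10k_log1p(m$counts)
  m
}

#' Select highly variable genes
#'
#' The \code{k} genes with the largest normalized-layer variance across
#' QC-passing cells; ties broken deterministically by gene order.
#'
#' @param m a normalized \code{gene_expr}
#' @param k number of genes (1..n_genes)
#' @return character vector of gene ids
#' @export
select_hvg <- function(m, k) {
  stopifnot(is_gene_expr(m))
  if (is.null(m$norm)) stop("normalize_counts() must be run before select_hvg()")
  if (k <= 0) stop("k must be positive")
  if (k > nrow(m$norm)) stop("k exceeds the number of genes")
  v <- apply(m$norm[, m$meta$qc_pass, drop = FALSE], 1, stats::var)
  ord <- order(-v, seq_along(v))   # stable: gene order breaks ties
  rownames(m$norm)[ord[seq_len(k)]]
}

#' Pseudo-bulk aggregation
#'
#' Per-group arithmetic mean of the normalized layer over QC-passing cells.
#'
#' @param m a normalized \code{gene_expr}
#' @param group_key name of a metadata column defining groups
#' @return object of class \code{pb_set}: \code{profiles} (genes x groups),
#'   \code{n_cells} (named), \code{group_key}
#' @export
pseudo_bulk <- function(m, group_key = "condition") {
  stopifnot(is_gene_expr(m))
  if (is.null(m$norm)) stop("normalize_counts() must be run before pseudo_bulk()")
  if (!group_key %in% colnames(m$meta)) stop("no metadata column: ", group_key)
  groups <- as.character(m$meta[[group_key]])
  lev <- unique(groups)
  keep <- m$meta$qc_pass
  n_cells <- vapply(lev, function(g) sum(keep & groups == g), integer(1))
  if (any(n_cells == 0))
    stop("group(s) without QC-passing cells: ",
         paste(lev[n_cells == 0], collapse = ", "))
  profiles <- vapply(lev, function(g)
    rowMeans(m$norm[, keep & groups == g, drop = FALSE]),
    numeric(nrow(m$norm)))
  structure(list(profiles = profiles, n_cells = n_cells,
                 group_key = group_key),
            class = "pb_set")
}

#' @export
print.pb_set <- function(x, ...) {
  cat("pb_set:", ncol(x$profiles), "profiles x", nrow(x$profiles),
      "genes (grouped by", x$group_key, ")\n")
  print(x$n_cells)
  invisible(x)
}

#' Extract one pseudo-bulk profile as a named vector
#' @param pb a \code{pb_set}
#' @param group group name
#' @return named numeric vector over genes
#' @export
pb_profile <- function(pb, group) {
  if (!group %in% colnames(pb$profiles)) stop("no such group: ", group)
  pb$profiles[, group]
}

#' Per-gene z-scores across pseudo-bulk profiles
#'
#' For every gene: \code{(x - mean) / sd} across profiles (sample sd);
#' zero-variance genes are set to 0.
#'
#' @param pb a \code{pb_set} with >= 2 profiles (or a genes x profiles matrix)
#' @return genes x profiles matrix of z-scores
#' @export
zscore_by_gene <- function(pb) {
  x <- if (inherits(pb, "pb_set")) pb$profiles else as.matrix(pb)
  if (ncol(x) < 2) stop("z-scoring requires at least 2 profiles")
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Differential expression (rank-sum test)
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalized values between two
#' cell groups, Benjamini-Hochberg adjustment across tested genes, and
#' \code{log2FC = log2((meanA + eps) / (meanB + eps))} with \code{eps = 0.01}
#' on the normalized scale. Rows sorted by q, then decreasing |log2FC|.
#'
#' @param m a normalized \code{gene_expr}
#' @param groupA,groupB group labels in \code{group_key}
#' @param group_key metadata column defining groups
#' @param eps pseudocount on the normalized scale
#' @return data.frame: gene, log2fc, p, q, meanA, meanB, nA, nB
#' @export
differential_expression <- function(m, groupA, groupB,
                                    group_key = "condition", eps = 0.01) {
  stopifnot(is_gene_expr(m))
  if (is.null(m$norm)) stop("normalize_counts() must be run first")
  grp <- as.character(m$meta[[group_key]])
  selA <- m$meta$qc_pass & grp == groupA
  selB <- m$meta$qc_pass & grp == groupB
  if (sum(selA) < 3 || sum(selB) < 3)
    stop(sprintf("both groups need >= 3 QC-passing cells (A: %d, B: %d)",
                 sum(selA), sum(selB)))
  A <- m$norm[, selA, drop = FALSE]
  B <- m$norm[, selB, drop = FALSE]
  p <- vapply(seq_len(nrow(A)), function(g) {
    a <- A[g, ]; b <- B[g, ]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  meanA <- rowMeans(A); meanB <- rowMeans(B)
  tab <- data.frame(gene = rownames(A),
                    log2fc = log2((meanA + eps) / (meanB + eps)),
                    p = p, q = stats::p.adjust(p, "BH"),
                    meanA = meanA, meanB = meanB,
                    nA = sum(selA), nB = sum(selB),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab[order(tab$q, -abs(tab$log2fc), tab$gene), , drop = FALSE]
}

#' Write a differential expression table as TSV
#' @param tab output of \code{\link{differential_expression}}
#' @param path file path
#' @export
write_de_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
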