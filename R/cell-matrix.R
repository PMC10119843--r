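#' Cell-by-gene count container
#'
#' A light container for UMI counts plus per-cell metadata, the input type
#' shared by every downstream stage. Counts are stored genes x cells (the
#' 10x MTX orientation) as a sparse `dgCMatrix`.
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   unique rownames (gene symbols) and colnames (cell barcodes).
#' @param meta data.frame with one row per cell; must contain a `barcode`
#'   column matching `colnames(counts)` and normally `time_point` and
#'   `cell_type` columns.
#' @return An object of class `cell_matrix`: list with elements `counts`
#'   (dgCMatrix) and `meta` (data.frame, rownames = barcodes).
#' @export
cell_matrix <- function(counts, meta) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (ncol(counts) == 0L) stop("empty matrix: 0 cells")
  if (nrow(counts) == 0L) stop("empty matrix: 0 genes")
  if (any(counts@x < 0)) stop("counts contain negative entries")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    rn <- make.unique(rownames(counts), sep = ".")
    pd_log("cell_matrix", deduplicated_genes = sum(rn != rownames(counts)))
    rownames(counts) <- rn
  }
  if (!"barcode" %in% names(meta)) stop("meta must have a 'barcode' column")
  missing <- setdiff(colnames(counts), meta$barcode)
  if (length(missing)) {
    stop("barcodes missing from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  extra <- setdiff(meta$barcode, colnames(counts))
  if (length(extra)) {
    stop("metadata barcodes absent from matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  rownames(meta) <- meta$barcode
  structure(list(counts = counts, meta = meta), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if ("time_point" %in% names(x$meta)) {
    cat("time points:", paste(levels(factor(x$meta$time_point)), collapse = " "), "\n")
  }
  if ("cell_type" %in% names(x$meta)) {
    tt <- table(x$meta$cell_type)
    cat("cell types:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset cells of a cell_matrix
#'
#' @param cells a `cell_matrix`.
#' @param idx logical/integer index over cells, or character barcodes.
#' @return A `cell_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(cells, idx) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (is.character(idx)) idx <- match(idx, colnames(cells$counts))
  if (anyNA(idx)) stop("unknown barcodes in subset")
  cell_matrix(cells$counts[, idx, drop = FALSE],
              cells$meta[idx, , drop = FALSE])
}

#' Library-size log-normalized expression
#'
#' log1p of counts scaled to `scale` total counts per cell, the
#' normalization used for embeddings, differential tests and Moran's I.
#'
#' @param counts genes x cells (sparse) count matrix.
#' @param scale target total per cell (default 1e4).
#' @return dense genes x cells matrix of log-normalized values.
#' @export
lognorm <- function(counts, scale = 1e4) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  log1p(sweep(as.matrix(counts), 2L, scale / libs, "*"))
}
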