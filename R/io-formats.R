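#' Read a cell matrix from disk
#'
#' Accepts either a directory holding a 10x-style MTX triplet
#' (`matrix.mtx`, `barcodes.tsv`, `features.tsv`) or a dense CSV (genes as
#' rows, first column = gene symbol), plus a cell-metadata CSV with columns
#' `barcode`, `time_point`, `cell_type` (and optionally `fate`).
#'
#' @param path MTX directory or dense CSV file.
#' @param meta_path metadata CSV; defaults to `metadata.csv` inside an MTX
#'   directory.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(path, meta_path = NULL) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path)
    counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
    feats <- readLines(file.path(path, "features.tsv"))
    bcs <- readLines(file.path(path, "barcodes.tsv"))
    feats <- vapply(strsplit(feats, "\t"), `[[`, character(1), 1L)
    if (length(feats) != nrow(counts) || length(bcs) != ncol(counts)) {
      stop("features/barcodes length does not match matrix dimensions")
    }
    dimnames(counts) <- list(feats, bcs)
    if (is.null(meta_path)) meta_path <- file.path(path, "metadata.csv")
  } else {
    df <- read.csv(path, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
    counts <- Matrix::Matrix(counts, sparse = TRUE)
    if (is.null(meta_path)) stop("meta_path required for dense CSV input")
  }
  if (any(counts@x != round(counts@x)) || any(counts@x < 0)) {
    stop("counts must be non-negative integers")
  }
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  cm <- cell_matrix(counts, meta)
  pd_log("read_cell_matrix", genes = nrow(cm$counts), cells = ncol(cm$counts))
  cm
}

#' Write a cell matrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `metadata.csv`
#' into `dir`.
#'
#' @param cells a [cell_matrix()].
#' @param dir output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_cell_matrix <- function(cells, dir) {
  stopifnot(inherits(cells, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cells$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  write.csv(cells$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Spot quality filter
#'
#' Removes spots with fewer detected genes (count > 0) than `min_genes` and
#' rebuilds the neighbor graph on the survivors. The default reproduces the
#' standard Visium QC rule: spots with detected genes < 2000 are dropped
#' (strict inequality: a spot at exactly `min_genes` is kept).
#'
#' @param section a [spatial_section()].
#' @param min_genes minimum detected-gene count (default 2000).
#' @return Filtered [spatial_section()].
#' @export
filter_spots <- function(section, min_genes = 2000L) {
  stopifnot(inherits(section, "spatial_section"))
  detected <- Matrix::colSums(section$counts > 0)
  keep <- detected >= min_genes
  if (!any(keep)) stop("all spots removed by filter_spots (min_genes = ",
                       min_genes, ")")
  pd_log("filter_spots", min_genes = min_genes,
         kept = sum(keep), removed = sum(!keep))
  spatial_section(section$counts[, keep, drop = FALSE],
                  section$positions[keep, , drop = FALSE],
                  neighbor_rule = section$neighbor_rule)
}

#' Read and merge ligand-receptor databases
#'
#' Takes one or more CSVs with `ligand` and `receptor` columns (and an
#' optional `source_db` column) and returns their union with exact
#' duplicate (ligand, receptor) rows collapsed; provenance is kept as a
#' comma-joined set.
#'
#' @param paths character vector of CSV paths.
#' @return An `lr_database`: data.frame with columns ligand, receptor,
#'   source_db.
#' @export
read_lr_database <- function(paths) {
  tabs <- lapply(paths, function(p) {
    df <- read.csv(p, stringsAsFactors = FALSE)
    if (!all(c("ligand", "receptor") %in% names(df))) {
      stop("missing ligand/receptor columns in ", p)
    }
    if (!"source_db" %in% names(df)) df$source_db <- basename(p)
    df[, c("ligand", "receptor", "source_db")]
  })
  merge_lr_tables(tabs)
}

# collapse a list of lr data.frames into the deduplicated union
merge_lr_tables <- function(tabs) {
  df <- do.call(rbind, tabs)
  key <- paste(df$ligand, df$receptor, sep = "|")
  prov <- vapply(split(df$source_db, key), function(s) {
    paste(sort(unique(s)), collapse = ",")
  }, character(1))
  out <- df[!duplicated(key), c("ligand", "receptor")]
  out$source_db <- unname(prov[paste(out$ligand, out$receptor, sep = "|")])
  out <- out[order(out$ligand, out$receptor), ]
  rownames(out) <- NULL
  class(out) <- c("lr_database", "data.frame")
  out
}

#' Generate the synthetic ligand-receptor database
#'
#' Planted channel(s) from the configuration plus decoy pairs between genes
#' with no type-specific expression, with two pseudo-source provenance
#' labels so database merging is exercised.
#'
#' @param config a [sim_config()].
#' @return An `lr_database` data.frame.
#' @export
generate_lr_database <- function(config) {
  lay <- config$layout
  planted <- do.call(rbind, lapply(config$planted_lr_pairs, function(p) {
    data.frame(ligand = config$gene_names[p$ligand],
               receptor = config$gene_names[p$receptor],
               source_db = "synthdb_a", stringsAsFactors = FALSE)
  }))
  decoys <- data.frame(ligand = config$gene_names[lay$lig_decoy],
                       receptor = config$gene_names[lay$rec_decoy],
                       source_db = rep(c("synthdb_a", "synthdb_b"),
                                       length.out = config$n_decoy_lr),
                       stringsAsFactors = FALSE)
  merge_lr_tables(list(planted, decoys))
}

#' Read / write Visium-dialect tissue positions
#'
#' Columns: barcode, in_tissue, array_row, array_col, pxl_row, pxl_col
#' (extra columns such as `region` are preserved).
#'
#' @param path CSV path.
#' @return `read_tissue_positions`: data.frame.
#' @export
read_tissue_positions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "in_tissue", "array_row", "array_col")
  if (!all(need %in% names(df))) {
    stop("tissue positions missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' @rdname read_tissue_positions
#' @param positions data.frame of positions.
#' @return `write_tissue_positions`: invisibly, `path`.
#' @export
write_tissue_positions <- function(positions, path) {
  write.csv(positions, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a cells x spots mapping-probability matrix
#'
#' CSV with cell barcodes in the first column and spot barcodes as headers.
#'
#' @param path CSV path.
#' @return `read_mapping_matrix`: numeric matrix, rows = cells.
#' @export
read_mapping_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("mapping probabilities must be non-negative")
  dev <- max(abs(rowSums(m) - 1))
  if (dev > 1e-6) stop("mapping matrix rows must sum to 1 (max dev ",
                       format(dev), ")")
  m
}

#' @rdname read_mapping_matrix
#' @param mapping cells x spots matrix.
#' @return `write_mapping_matrix`: invisibly, `path`.
#' @export
write_mapping_matrix <- function(mapping, path) {
  df <- data.frame(barcode = rownames(mapping), mapping, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
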