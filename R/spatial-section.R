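#' Spatial section container
#'
#' Spots x genes counts on a lattice with a neighbor graph, the container
#' for the Visium-style stages (spot QC, Moran's I, adjacency scores,
#' neighbor-spot interaction scoring).
#'
#' @param counts genes x spots sparse count matrix (gene rownames, spot
#'   barcode colnames).
#' @param positions data.frame in the tissue-positions dialect: columns
#'   `barcode`, `in_tissue`, `array_row`, `array_col`, `pxl_row`, `pxl_col`;
#'   optionally a `region` column. Row order must match `colnames(counts)`.
#' @param neighbor_rule "hex" (offset-coordinate 6-neighborhood, the Visium
#'   geometry) or "rook" (4-neighborhood on a square lattice).
#' @param neighbors optional explicit neighbor list (list of integer vectors,
#'   one per spot), overriding `neighbor_rule`.
#' @return An object of class `spatial_section`.
#' @export
spatial_section <- function(counts, positions, neighbor_rule = c("hex", "rook"),
                            neighbors = NULL) {
  neighbor_rule <- match.arg(neighbor_rule)
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  stopifnot(is.data.frame(positions),
            all(c("barcode", "array_row", "array_col") %in% names(positions)))
  if (ncol(counts) != nrow(positions) ||
      !all(colnames(counts) == positions$barcode)) {
    stop("positions must match counts columns (same barcodes, same order)")
  }
  if (is.null(neighbors)) {
    neighbors <- build_neighbor_graph(positions, rule = neighbor_rule)
  }
  structure(list(counts = counts, positions = positions,
                 neighbors = neighbors, neighbor_rule = neighbor_rule),
            class = "spatial_section")
}

#' @export
print.spatial_section <- function(x, ...) {
  cat(sprintf("spatial_section: %d genes x %d spots (%s neighbors)\n",
              nrow(x$counts), ncol(x$counts), x$neighbor_rule))
  if ("region" %in% names(x$positions)) {
    tt <- table(x$positions$region)
    cat("regions:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Lattice neighbor graph
#'
#' Builds the spot neighbor list from array coordinates. The hex rule is the
#' odd-row offset 6-neighborhood matching Visium's hexagonally packed spots;
#' boundary spots keep only in-grid neighbors. The rook rule (4-neighborhood)
#' is provided for square lattices.
#'
#' @param positions data.frame with `array_row`, `array_col`.
#' @param rule "hex" or "rook".
#' @return List of integer neighbor indices, one element per spot.
#' @export
build_neighbor_graph <- function(positions, rule = c("hex", "rook")) {
  rule <- match.arg(rule)
  key <- paste(positions$array_row, positions$array_col, sep = "_")
  lookup <- setNames(seq_along(key), key)
  offs_even <- switch(rule,
    hex = cbind(c(0, 0, -1, -1, 1, 1), c(-1, 1, -1, 0, -1, 0)),
    rook = cbind(c(0, 0, -1, 1), c(-1, 1, 0, 0)))
  offs_odd <- switch(rule,
    hex = cbind(c(0, 0, -1, -1, 1, 1), c(-1, 1, 0, 1, 0, 1)),
    rook = offs_even)
  lapply(seq_along(key), function(i) {
    r <- positions$array_row[i]; cc <- positions$array_col[i]
    offs <- if (r %% 2 == 0) offs_even else offs_odd
    cand <- paste(r + offs[, 1], cc + offs[, 2], sep = "_")
    unname(lookup[cand[cand %in% names(lookup)]])
  })
}

# deterministic region labels for the generated lattice: a contiguous
# proximal tube (two center columns, middle rows) and a distal border
# (bottom two rows)
section_regions <- function(nr, nc) {
  if (nr < 8L || nc < 6L) {
    stop("configuration error in grid_shape: grid too small to contain both ",
         "a proximal tube and a distal border (need >= 8 x 6)")
  }
  grid <- expand.grid(array_col = seq_len(nc) - 1L,
                      array_row = seq_len(nr) - 1L)[, c(2, 1)]
  region <- rep("other", nrow(grid))
  tube_cols <- c(floor(nc / 2) - 1L, floor(nc / 2), floor(nc / 2) + 1L)
  tube_rows <- seq(ceiling(nr / 6), floor(0.75 * nr)) - 1L
  region[grid$array_col %in% tube_cols & grid$array_row %in% tube_rows] <- "proximal_tube"
  region[grid$array_row >= nr - 2L] <- "distal_border"
  cbind(grid, region = region, stringsAsFactors = FALSE)
}
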