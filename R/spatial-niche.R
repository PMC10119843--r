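#' Spot-level cell-type composition
#'
#' Sums the cells x spots mapping probabilities within each cell type:
#' entry (spot, type) = total mapped probability mass of that type on that
#' spot. The normalized form divides each spot row by its total mass, so
#' rows of spots with mass > 0 sum to 1.
#'
#' @param mapping cells x spots row-stochastic matrix.
#' @param cell_types per-cell type labels (same order as mapping rows).
#' @param normalize return proportions (default) instead of raw mass.
#' @return Spots x cell-types matrix (class `spot_composition` attribute
#'   `normalized`).
#' @export
spot_proportions <- function(mapping, cell_types, normalize = TRUE) {
  if (length(cell_types) != nrow(mapping)) {
    stop("cell_types must have one label per mapping row")
  }
  if (anyNA(cell_types)) stop("unlabeled cell(s) in cell_types")
  dev <- max(abs(rowSums(mapping) - 1))
  if (dev > 1e-6) stop("mapping is not row-stochastic (max dev ", format(dev), ")")
  comp <- t(rowsum(mapping, factor(cell_types)))
  if (normalize) {
    mass <- rowSums(comp)
    comp <- sweep(comp, 1L, ifelse(mass > 0, mass, 1), "/")
  }
  attr(comp, "normalized") <- normalize
  comp
}

#' Moran's I spatial autocorrelation
#'
#' Classical Moran's I with row-normalized binary adjacency weights on
#' centered values: `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`.
#' By default computed on log-normalized counts of `gene`; pass `values`
#' to score an arbitrary spot vector. Spots without neighbors are excluded
#' with a warning; a constant vector returns 0 with an `undefined` flag.
#'
#' @param section a [spatial_section()].
#' @param gene gene symbol (ignored when `values` given).
#' @param values optional numeric vector over spots.
#' @return List: `I`, `undefined` flag, `n_spots` used.
#' @export
morans_i <- function(section, gene = NULL, values = NULL) {
  stopifnot(inherits(section, "spatial_section"))
  if (is.null(values)) {
    if (is.null(gene) || !gene %in% rownames(section$counts)) {
      stop("gene not found in section")
    }
    values <- lognorm(section$counts)[gene, ]
  }
  stats <- morans_i_all(section, matrix(values, nrow = 1,
                                        dimnames = list("v", NULL)))
  list(I = unname(stats$I[1]), undefined = unname(stats$undefined[1]),
       n_spots = stats$n_spots)
}

#' Moran's I for many genes at once
#'
#' Vectorized Moran's I over the rows of a values matrix (default:
#' log-normalized counts of all genes).
#'
#' @param section a [spatial_section()].
#' @param values optional genes x spots matrix.
#' @return Data.frame-like list: `I` (named vector), `undefined` (logical),
#'   `n_spots`.
#' @export
morans_i_all <- function(section, values = NULL) {
  stopifnot(inherits(section, "spatial_section"))
  if (is.null(values)) values <- lognorm(section$counts)
  deg <- lengths(section$neighbors)
  keep <- deg > 0
  if (any(!keep)) {
    warning(sum(!keep), " isolated spot(s) excluded from Moran's I")
  }
  idx <- which(keep)
  remap <- match(seq_along(deg), idx)
  # sparse row-normalized weight matrix over the kept spots
  ii <- rep(remap[idx], deg[idx])
  jj <- remap[unlist(section$neighbors[idx])]
  ok <- !is.na(jj)
  w <- Matrix::sparseMatrix(i = ii[ok], j = jj[ok],
                            x = 1 / rep(deg[idx], deg[idx])[ok],
                            dims = c(length(idx), length(idx)))
  s0 <- sum(w)
  v <- values[, idx, drop = FALSE]
  z <- sweep(v, 1L, rowMeans(v))
  denom <- rowSums(z^2)
  wz <- as.matrix(Matrix::tcrossprod(w, z))   # spots x genes: (W z)^T
  cross <- rowSums(z * t(wz))
  undefined <- denom <= 0
  i_stat <- ifelse(undefined, 0,
                   (length(idx) / s0) * cross / ifelse(undefined, 1, denom))
  list(I = setNames(i_stat, rownames(values)),
       undefined = setNames(undefined, rownames(values)),
       n_spots = length(idx))
}

#' Select spatially variable genes
#'
#' Genes whose |Moran's I| is strictly greater than `threshold` (default
#' 0.05). Genes flagged undefined (constant) are never selected.
#'
#' @param section a [spatial_section()].
#' @param threshold |I| cutoff (default 0.05, strict).
#' @param stats optional precomputed [morans_i_all()] result.
#' @return Character vector of gene symbols.
#' @export
select_svgs <- function(section, threshold = 0.05, stats = NULL) {
  if (is.null(stats)) stats <- morans_i_all(section)
  names(stats$I)[abs(stats$I) > threshold & !stats$undefined]
}

#' Epithelium adjacency scores
#'
#' Identifies proximal- and distal-associated spots (the epithelial region
#' plus its lattice neighbors), prunes cell types with proportion strictly
#' below `min_prop` within each associated spot, and sums the surviving
#' proportions per cell type: the adjacency score. Shares normalize the
#' scores within each region.
#'
#' The epithelial region defaults to spots whose proximal (resp. distal)
#' epithelial proportion is >= `min_prop`, i.e. the same 0.4 rule used for
#' pruning; pass `region_spots` (named list of spot barcodes) to use an
#' explicit region annotation instead.
#'
#' @param composition normalized spots x types matrix from
#'   [spot_proportions()] (rownames = spot barcodes).
#' @param section a [spatial_section()] sharing the spot universe.
#' @param epithelial_types named character vector
#'   `c(proximal = ..., distal = ...)` of epithelial composition types.
#' @param min_prop exclusion threshold (default 0.4; proportions < 0.4 are
#'   zeroed, exactly 0.4 is kept).
#' @param region_spots optional named list (proximal, distal) of epithelial
#'   spot barcodes overriding the threshold rule.
#' @return An `adjacency_scores` data.frame: region, cell_type, score,
#'   share.
#' @export
adjacency_scores <- function(composition, section,
                             epithelial_types = c(proximal = "EPI_proximal",
                                                  distal = "EPI_distal"),
                             min_prop = 0.4, region_spots = NULL) {
  stopifnot(inherits(section, "spatial_section"),
            all(c("proximal", "distal") %in% names(epithelial_types)))
  spots <- section$positions$barcode
  composition <- composition[spots, , drop = FALSE]
  out <- list()
  for (rg in c("proximal", "distal")) {
    ety <- epithelial_types[[rg]]
    if (!ety %in% colnames(composition)) {
      stop("epithelial type '", ety, "' not found in composition")
    }
    epi <- if (is.null(region_spots)) {
      which(composition[, ety] >= min_prop)
    } else {
      match(region_spots[[rg]], spots)
    }
    if (!length(epi) || anyNA(epi)) {
      stop("no epithelial spots found for region '", rg, "' (type ", ety, ")")
    }
    assoc <- sort(unique(c(epi, unlist(section$neighbors[epi]))))
    sub <- composition[assoc, , drop = FALSE]
    sub[sub < min_prop] <- 0
    score <- colSums(sub)
    share <- if (sum(score) > 0) score / sum(score) else score
    out[[rg]] <- data.frame(region = rg, cell_type = colnames(composition),
                            score = unname(score), share = unname(share),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("adjacency_scores", "data.frame")
  res
}
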