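#' Generate the synthetic spatial section and cell-to-spot mapping
#'
#' Builds a hex-lattice section whose true cell-type composition follows the
#' planted histology: a contiguous proximal tube dominated by
#' proximal-epithelium with a peri-tube stromal sheath in the surrounding
#' spots, and a distal border dominated by distal epithelium with the niche
#' stromal type concentrated in the spots just inside it. Spot counts are
#' negative-binomial draws from composition-weighted mixtures of the type
#' expression profiles (at full fate drift). The mapping matrix places each
#' time-course cell mostly (weight 0.85) on a home spot sampled according to
#' the true composition of its type, with the remaining 0.15 spread over the
#' home spot's neighbors, so rows sum to 1 and concentrate on spots
#' containing the cell's type.
#'
#' @param config a [sim_config()].
#' @param truth the `ground_truth` from [generate_timecourse()] (its
#'   `cell_fate` table decides which spots each cell can map to); updated
#'   copy is returned.
#' @param cells the [cell_matrix()] from [generate_timecourse()].
#' @param region_templates optional named list overriding the per-region
#'   composition templates (names: proximal_tube, tube_adjacent,
#'   distal_border, border_adjacent, other; each a named proportion vector
#'   over composition types summing to 1).
#' @return List with `section` (a [spatial_section()] whose positions carry
#'   the true `region` labels), `mapping` (cells x spots row-stochastic
#'   matrix), and `truth` (input truth with `spot_composition` filled:
#'   spots x composition-types proportion matrix).
#' @export
generate_spatial <- function(config, truth, cells, region_templates = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(cells, "cell_matrix"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  grid <- section_regions(nr, nc)
  n_spots <- nrow(grid)
  barcodes <- sprintf("spot%04d", seq_len(n_spots))
  positions <- data.frame(
    barcode = barcodes, in_tissue = 1L,
    array_row = grid$array_row, array_col = grid$array_col,
    pxl_row = grid$array_row * 100L + 1000L,
    pxl_col = grid$array_col * 100L + 1000L,
    region = grid$region, stringsAsFactors = FALSE)
  nbrs <- build_neighbor_graph(positions, "hex")

  # refine regions: spots adjacent to (but not in) the tube / border
  reg <- positions$region
  adj_of <- function(members) {
    unique(unlist(nbrs[members]))
  }
  tube <- which(reg == "proximal_tube")
  border <- which(reg == "distal_border")
  tube_adj <- setdiff(adj_of(tube), c(tube, border))
  border_adj <- setdiff(adj_of(border), c(border, tube, tube_adj))
  reg[tube_adj] <- "tube_adjacent"
  reg[border_adj] <- "border_adjacent"
  positions$region <- reg

  templates <- if (is.null(region_templates)) {
    list(
      proximal_tube   = c(EPI_proximal = 0.60, SC_peritube = 0.25,
                          SC_general = 0.10, Endothelium = 0.05),
      tube_adjacent   = c(SC_peritube = 0.45, SC_general = 0.30,
                          Endothelium = 0.15, EPI_proximal = 0.10),
      distal_border   = c(EPI_distal = 0.55, SC_niche = 0.30,
                          SC_general = 0.10, Immune = 0.05),
      border_adjacent = c(SC_niche = 0.45, SC_general = 0.30,
                          Endothelium = 0.15, EPI_distal = 0.10),
      other           = c(SC_general = 0.50, Endothelium = 0.30, Immune = 0.20)
    )
  } else region_templates
  comp_types <- unique(unlist(lapply(templates, names)))
  comp <- matrix(0, n_spots, length(comp_types),
                 dimnames = list(barcodes, comp_types))
  for (rg in names(templates)) {
    idx <- which(reg == rg)
    if (length(idx)) comp[idx, names(templates[[rg]])] <-
        matrix(templates[[rg]], length(idx), length(templates[[rg]]),
               byrow = TRUE)
  }

  # per-composition-type mean expression profiles at full fate drift
  profiles <- type_expression_profiles(config)
  profiles <- profiles[, comp_types, drop = FALSE]
  spot_mu <- profiles %*% t(comp)                       # genes x spots
  spot_mu <- sweep(spot_mu, 2L, colSums(spot_mu), "/")  # per-spot composition
  with_seed(config$seed + 200L, {
    depth <- rlnorm(n_spots, meanlog = log(config$spot_depth) - 0.02, sdlog = 0.2)
    spot_mu <- sweep(spot_mu, 2L, depth, "*")
    spot_counts <- matrix(rnbinom(length(spot_mu), mu = as.vector(spot_mu),
                                  size = 1 / (config$spot_dispersion %||% config$dispersion)),
                          nrow = nrow(spot_mu))
  })
  dimnames(spot_counts) <- list(config$gene_names, barcodes)
  section <- spatial_section(Matrix::Matrix(spot_counts, sparse = TRUE),
                             positions, "hex", neighbors = nbrs)

  # mapping matrix for all time-course cells
  ctype <- composition_labels(cells$meta)
  missing_type <- setdiff(unique(ctype), comp_types)
  if (length(missing_type)) {
    stop("configuration error: no spatial composition for type(s) ",
         paste(missing_type, collapse = ", "))
  }
  n_cells <- ncol(cells$counts)
  mapping <- matrix(0, n_cells, n_spots,
                    dimnames = list(colnames(cells$counts), barcodes))
  with_seed(config$seed + 300L, {
    for (i in seq_len(n_cells)) {
      w <- comp[, ctype[i]]
      home <- sample.int(n_spots, 1L, prob = w)
      nb <- nbrs[[home]]
      wn <- comp[nb, ctype[i]]
      if (length(nb) == 0L) {
        mapping[i, home] <- 1
      } else {
        if (sum(wn) <= 0) wn <- rep(1, length(nb))
        mapping[i, home] <- 0.85
        mapping[i, nb] <- 0.15 * wn / sum(wn)
      }
    }
  })

  truth$spot_composition <- comp
  truth$spot_region <- setNames(positions$region, barcodes)
  pd_log("generate_spatial", spots = n_spots, grid = paste(nr, nc, sep = "x"),
         seed = config$seed)
  list(section = section, mapping = mapping, truth = truth)
}

# genes x composition-types matrix of mean expression, fate drift = 1
type_expression_profiles <- function(config) {
  lay <- config$layout
  base <- base_gene_means(config)
  type_names <- vapply(config$cell_type_spec, `[[`, character(1), "name")
  comp_types <- c("EPI_proximal", "EPI_distal", setdiff(type_names, "EPI"))
  prof <- matrix(base, config$n_genes, length(comp_types),
                 dimnames = list(config$gene_names, comp_types))
  for (ty in config$cell_type_spec) {
    target <- if (ty$name == "EPI") c("EPI_proximal", "EPI_distal") else ty$name
    prof[ty$sig_genes, target] <- prof[ty$sig_genes, target] * ty$sig_fc
  }
  for (p in config$planted_lr_pairs) {
    prov <- if (p$provider == "EPI") c("EPI_proximal", "EPI_distal") else p$provider
    rec <- if (p$recipient == "EPI") c("EPI_proximal", "EPI_distal") else p$recipient
    prof[p$ligand, prov] <- prof[p$ligand, prov] * p$effect
    prof[p$receptor, rec] <- prof[p$receptor, rec] * (p$receptor_effect %||% p$effect)
  }
  fc <- config$fate_fc
  prof[config$fate_targets$proximal, "EPI_proximal"] <-
    prof[config$fate_targets$proximal, "EPI_proximal"] * fc
  prof[config$fate_targets$distal, "EPI_distal"] <-
    prof[config$fate_targets$distal, "EPI_distal"] * fc
  prof[lay$tf_prox, "EPI_proximal"] <- prof[lay$tf_prox, "EPI_proximal"] * 4
  prof[lay$tf_dist, "EPI_distal"] <- prof[lay$tf_dist, "EPI_distal"] * 4
  prof
}

#' Composition labels (epithelium split by fate)
#'
#' Spatial stages resolve epithelial cells into their proximal / distal
#' fate, matching the composition types of the generated section.
#'
#' @param meta cell metadata with `cell_type` and `fate` columns.
#' @return Character vector of composition-type labels per cell.
#' @export
composition_labels <- function(meta) {
  ifelse(meta$cell_type == "EPI" & meta$fate %in% c("proximal", "distal"),
         paste0("EPI_", meta$fate), meta$cell_type)
}

#' Expected spot occupancy implied by the generator
#'
#' For each spot, the expected number of cells whose mapping-matrix home is
#' that spot: `sum_t n_t * comp[s, t] / sum_s' comp[s', t]`.
#'
#' @param truth `ground_truth` with `spot_composition` filled.
#' @param meta cell metadata of the mapped cells.
#' @return Numeric vector over spots.
#' @export
expected_spot_occupancy <- function(truth, meta) {
  comp <- truth$spot_composition
  ctype <- composition_labels(meta)
  n_t <- table(factor(ctype, levels = colnames(comp)))
  colmass <- colSums(comp)
  occ <- rep(0, nrow(comp))
  for (t in colnames(comp)) {
    if (colmass[t] > 0) occ <- occ + as.numeric(n_t[t]) * comp[, t] / colmass[t]
  }
  setNames(occ, rownames(comp))
}
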