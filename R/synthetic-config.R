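#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic embryonic-lung
#' dataset: a multi-time-point scRNA-seq count matrix with two epithelial
#' fates drifting apart over developmental time, stromal subtypes including a
#' border niche population, planted fate-specific regulons with decoys,
#' planted ligand-receptor channels, and a hexagonal-lattice spatial section
#' with a proximal tube and a distal border region.
#'
#' Defaults describe the emulated study design: 5 time points labelled
#' "wk4".."wk8", 300 cells per time point, 500 genes, negative-binomial
#' counts (dispersion 0.5, i.e. NB size 2) with log-normal library-size
#' variation (sigma 0.3), 40-gene epithelial fate programs at 6-fold change
#' whose expression drifts from 0.3 to 1 of full effect across the time
#' course, and a 24 x 24 spot lattice. `expr_scale` (default 3) sets the
#' sequencing depth: mean ~600 UMI per cell over the 500-gene panel,
#' matching the per-gene UMI density of a deeply sequenced 10x run
#' restricted to its top-expressed genes.
#'
#' @param n_time_points number of time points (labels wk4, wk5, ...).
#' @param cells_per_time cells simulated per time point.
#' @param n_genes total genes.
#' @param cell_type_spec list of per-type specs: `name`, `prop` (base
#'   proportion), `sig_genes` (signature gene indices), `sig_fc` (signature
#'   fold change). Proportions must sum to 1. `NULL` for the default 6-type
#'   design.
#' @param planted_regulons list of `(tf, targets, fate)` records: `tf` a gene
#'   index, `targets` gene indices, `fate` one of "proximal", "distal",
#'   "none". `NULL` for the default 4 fate TFs + 6 decoys.
#' @param planted_lr_pairs list of `(ligand, receptor, provider, recipient,
#'   effect, receptor_effect)` records: gene indices, type names, and the
#'   ligand- / receptor-side mean multipliers. `NULL` for the default single
#'   niche -> epithelium channel (ligand near-exclusive to the niche type at
#'   24x over a low baseline, receptor 4x enriched in epithelium), mirroring
#'   a growth factor secreted almost solely by one stromal subtype.
#' @param n_decoy_lr number of decoy (unplanted) ligand-receptor pairs in the
#'   generated database.
#' @param grid_shape integer (rows, cols) of the hex lattice.
#' @param dispersion negative-binomial dispersion of single-cell counts
#'   (variance = mu + dispersion * mu^2).
#' @param spot_dispersion negative-binomial dispersion of spot counts
#'   (default 0.1, lower than the cell-level value because each Visium spot
#'   pools several cells).
#' @param lib_sigma sd of log library-size factor.
#' @param fate_fc fold change of fate signature genes at full drift.
#' @param fate_drift per-time-point fraction of full fate effect; `NULL` for
#'   `seq(0.3, 1, length.out = n_time_points)`.
#' @param n_fate_genes genes per epithelial fate program (default 40).
#' @param expr_scale global mean-expression (sequencing depth) multiplier.
#' @param spot_depth mean total UMI per spot of the spatial section.
#' @param seed integer random seed; all generator randomness flows from it
#'   through per-artifact sub-streams.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_time_points = 5L,
                       cells_per_time = 300L,
                       n_genes = 500L,
                       cell_type_spec = NULL,
                       planted_regulons = NULL,
                       planted_lr_pairs = NULL,
                       n_decoy_lr = 10L,
                       grid_shape = c(24L, 24L),
                       dispersion = 0.5,
                       spot_dispersion = 0.1,
                       lib_sigma = 0.3,
                       fate_fc = 6,
                       fate_drift = NULL,
                       n_fate_genes = 40L,
                       expr_scale = 3,
                       spot_depth = 4000,
                       seed = 7L) {
  cfg <- list(
    n_time_points = as.integer(n_time_points),
    cells_per_time = as.integer(cells_per_time),
    n_genes = as.integer(n_genes),
    time_labels = paste0("wk", seq(4L, length.out = as.integer(n_time_points))),
    grid_shape = as.integer(grid_shape),
    dispersion = dispersion,
    spot_dispersion = spot_dispersion,
    lib_sigma = lib_sigma,
    fate_fc = fate_fc,
    spot_depth = spot_depth,
    n_decoy_lr = as.integer(n_decoy_lr),
    n_fate_genes = as.integer(n_fate_genes),
    expr_scale = expr_scale,
    seed = as.integer(seed)
  )
  cfg$fate_drift <- if (is.null(fate_drift)) {
    seq(0.3, 1, length.out = cfg$n_time_points)
  } else fate_drift

  # default gene-role layout (indices into 1..n_genes); roles only make
  # sense for the default specs, custom specs bring their own indices
  lay <- default_gene_layout(cfg$n_genes, cfg$n_decoy_lr, cfg$n_fate_genes)
  cfg$gene_names <- lay$names
  cfg$layout <- lay

  cfg$cell_type_spec <- if (is.null(cell_type_spec)) {
    default_cell_types(lay)
  } else cell_type_spec
  cfg$planted_regulons <- if (is.null(planted_regulons)) {
    default_regulons(lay)
  } else planted_regulons
  cfg$planted_lr_pairs <- if (is.null(planted_lr_pairs)) {
    list(list(ligand = lay$lig_planted[1], receptor = lay$rec_planted[1],
              provider = "SC_niche", recipient = "EPI",
              effect = 24, receptor_effect = 4))
  } else planted_lr_pairs

  # proximal / distal fate signature targets
  cfg$fate_targets <- list(proximal = lay$prox_targets, distal = lay$dist_targets)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# carve the gene universe into named roles
default_gene_layout <- function(n_genes, n_decoy_lr, n_fate_genes = 15L) {
  need <- 6 * 8 + 2 * n_fate_genes + 4 + 6 + 2 + 2 * n_decoy_lr
  if (n_genes < need + 20) {
    stop("configuration error: n_genes too small for the default layout (need >= ",
         need + 20, ")")
  }
  i <- 0L
  take <- function(k) { out <- (i + 1L):(i + k); i <<- i + k; out }
  lay <- list()
  lay$type_sig <- list(
    EPI = take(8), SC_niche = take(8), SC_peritube = take(8),
    SC_general = take(8), Endothelium = take(8), Immune = take(8))
  lay$prox_targets <- take(n_fate_genes)
  lay$dist_targets <- take(n_fate_genes)
  lay$tf_prox <- take(2)
  lay$tf_dist <- take(2)
  lay$tf_decoy <- take(6)
  lay$lig_planted <- take(1)
  lay$rec_planted <- take(1)
  lay$lig_decoy <- take(n_decoy_lr)
  lay$rec_decoy <- take(n_decoy_lr)
  lay$background <- (i + 1L):n_genes

  nm <- paste0("g", sprintf("%03d", seq_len(n_genes)))
  for (ty in names(lay$type_sig)) {
    nm[lay$type_sig[[ty]]] <- paste0(toupper(substr(ty, 1, 3)), "SIG",
                                     seq_along(lay$type_sig[[ty]]))
  }
  nm[lay$prox_targets] <- paste0("PTG", sprintf("%02d", seq_along(lay$prox_targets)))
  nm[lay$dist_targets] <- paste0("DTG", sprintf("%02d", seq_along(lay$dist_targets)))
  nm[lay$tf_prox] <- paste0("TFP", seq_along(lay$tf_prox))
  nm[lay$tf_dist] <- paste0("TFD", seq_along(lay$tf_dist))
  nm[lay$tf_decoy] <- paste0("TFX", seq_along(lay$tf_decoy))
  nm[lay$lig_planted] <- "LIGA"
  nm[lay$rec_planted] <- "RECA"
  nm[lay$lig_decoy] <- paste0("LX", sprintf("%02d", seq_along(lay$lig_decoy)))
  nm[lay$rec_decoy] <- paste0("RX", sprintf("%02d", seq_along(lay$rec_decoy)))
  lay$names <- nm
  lay
}

default_cell_types <- function(lay) {
  list(
    list(name = "EPI",         prop = 0.30, sig_genes = lay$type_sig$EPI,         sig_fc = 8),
    list(name = "SC_niche",    prop = 0.10, sig_genes = lay$type_sig$SC_niche,    sig_fc = 8),
    list(name = "SC_peritube", prop = 0.12, sig_genes = lay$type_sig$SC_peritube, sig_fc = 8),
    list(name = "SC_general",  prop = 0.18, sig_genes = lay$type_sig$SC_general,  sig_fc = 8),
    list(name = "Endothelium", prop = 0.15, sig_genes = lay$type_sig$Endothelium, sig_fc = 8),
    list(name = "Immune",      prop = 0.15, sig_genes = lay$type_sig$Immune,      sig_fc = 8)
  )
}

# overlapping two-thirds splits of a fate program, one per planted TF
head2of3 <- function(x) x[seq_len(ceiling(2 * length(x) / 3))]
tail2of3 <- function(x) x[(length(x) - ceiling(2 * length(x) / 3) + 1L):length(x)]

default_regulons <- function(lay) {
  c(
    list(
      list(tf = lay$tf_prox[1], targets = head2of3(lay$prox_targets), fate = "proximal"),
      list(tf = lay$tf_prox[2], targets = tail2of3(lay$prox_targets), fate = "proximal"),
      list(tf = lay$tf_dist[1], targets = head2of3(lay$dist_targets), fate = "distal"),
      list(tf = lay$tf_dist[2], targets = tail2of3(lay$dist_targets), fate = "distal")
    ),
    lapply(seq_along(lay$tf_decoy), function(k) {
      list(tf = lay$tf_decoy[k], targets = NULL, fate = "none")
    })
  )
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` (or compatible list).
#' @return Invisibly `TRUE`; stops with a configuration error naming the
#'   offending field otherwise.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_time_points < 2L) {
    stop("configuration error in n_time_points: need >= 2 time points")
  }
  props <- vapply(cfg$cell_type_spec, `[[`, numeric(1), "prop")
  if (abs(sum(props) - 1) > 1e-8) {
    stop("configuration error in cell_type_spec: proportions sum to ",
         format(sum(props)), ", not 1")
  }
  if (any(props < 0)) stop("configuration error in cell_type_spec: negative proportion")
  all_idx <- c(unlist(lapply(cfg$cell_type_spec, `[[`, "sig_genes")),
               unlist(lapply(cfg$planted_regulons, `[[`, "targets")),
               vapply(cfg$planted_regulons, `[[`, numeric(1), "tf"),
               unlist(cfg$fate_targets))
  if (any(all_idx < 1 | all_idx > cfg$n_genes)) {
    stop("configuration error: gene index outside 1..n_genes in ",
         "cell_type_spec/planted_regulons/fate_targets")
  }
  for (p in cfg$planted_lr_pairs) {
    if (p$ligand > cfg$n_genes || p$receptor > cfg$n_genes) {
      stop("configuration error in planted_lr_pairs: gene index outside 1..n_genes")
    }
    types <- vapply(cfg$cell_type_spec, `[[`, character(1), "name")
    if (!p$provider %in% types || !p$recipient %in% types) {
      stop("configuration error in planted_lr_pairs: unknown cell type '",
           setdiff(c(p$provider, p$recipient), types)[1], "'")
    }
  }
  tfs <- vapply(cfg$planted_regulons, `[[`, numeric(1), "tf")
  if (anyDuplicated(tfs)) {
    stop("configuration error in planted_regulons: duplicate TF gene")
  }
  if (length(cfg$grid_shape) != 2L || any(cfg$grid_shape < 1L)) {
    stop("configuration error in grid_shape: need two positive integers")
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d time points (%s), %d cells/time, ",
                     "%d genes, grid %dx%d, seed %d\n"),
              x$n_time_points, paste(x$time_labels, collapse = " "),
              x$cells_per_time, x$n_genes, x$grid_shape[1], x$grid_shape[2],
              x$seed))
  invisible(x)
}

#' Read / write a simulation config as YAML
#'
#' The YAML mirror stores the scalar fields; list-valued design fields
#' (cell types, planted regulons and pairs) are re-derived from the default
#' layout unless present in the file as index lists.
#'
#' @param path YAML file path.
#' @return `read_sim_config`: a `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("n_time_points", "cells_per_time", "n_genes", "grid_shape",
               "dispersion", "lib_sigma", "fate_fc", "fate_drift",
               "spot_depth", "n_decoy_lr", "seed")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @param cfg a `sim_config`.
#' @return `write_sim_config`: invisibly, `path`.
#' @export
write_sim_config <- function(cfg, path) {
  keep <- c("n_time_points", "cells_per_time", "n_genes", "grid_shape",
            "dispersion", "lib_sigma", "fate_fc", "fate_drift",
            "spot_depth", "n_decoy_lr", "seed")
  yaml::write_yaml(cfg[keep], path)
  invisible(path)
}
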