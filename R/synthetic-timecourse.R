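# base mean expression per gene; role genes pinned to fixed levels so the
# planted effects sit at a known scale
base_gene_means <- function(config) {
  lay <- config$layout
  base <- with_seed(config$seed + 1L,
                    pmax(rgamma(config$n_genes, shape = 0.8, rate = 2), 0.05))
  for (ty in config$cell_type_spec) base[ty$sig_genes] <- 0.5
  base[config$fate_targets$proximal] <- 0.4
  base[config$fate_targets$distal] <- 0.4
  base[c(lay$tf_prox, lay$tf_dist, lay$tf_decoy)] <- 0.4
  planted_lig <- vapply(config$planted_lr_pairs, `[[`, numeric(1), "ligand")
  planted_rec <- vapply(config$planted_lr_pairs, `[[`, numeric(1), "receptor")
  base[c(planted_rec, lay$lig_decoy, lay$rec_decoy)] <- 0.3
  base[planted_lig] <- 0.03
  base * (config$expr_scale %||% 1)
}

#' Generate the synthetic time-course scRNA-seq dataset
#'
#' Draws negative-binomial UMI counts for `n_time_points x cells_per_time`
#' cells. Each cell type has signature genes at `sig_fc`-fold elevated mean;
#' epithelial cells carry a fate label (proximal or distal) and their fate
#' signature genes drift from a fraction `fate_drift[1]` of the full
#' `fate_fc` effect at the first time point to the full effect at the last,
#' giving adjacent time points the transport structure the temporal OT stage
#' assumes. Planted ligand/receptor genes are elevated in their provider /
#' recipient types. Per-cell library sizes are log-normal.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cells` (a [cell_matrix()] whose `meta` has
#'   columns barcode, time_point, cell_type, fate) and `truth` (a
#'   `ground_truth` list: per-cell fate table, active regulon-fate pairs,
#'   true interaction tuples, spatially patterned / decoy gene sets; the
#'   spot composition slot is filled by [generate_spatial()]).
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  lay <- config$layout
  base <- base_gene_means(config)

  type_names <- vapply(config$cell_type_spec, `[[`, character(1), "name")
  props <- vapply(config$cell_type_spec, `[[`, numeric(1), "prop")
  n_per_type <- round(props * config$cells_per_time)
  n_per_type[1] <- config$cells_per_time - sum(n_per_type[-1])
  if (any(n_per_type < 0)) stop("configuration error: cells_per_time too small")

  # per-type mean multipliers that do not depend on time
  static_mult <- matrix(1, config$n_genes, length(type_names),
                        dimnames = list(NULL, type_names))
  for (ty in config$cell_type_spec) {
    static_mult[ty$sig_genes, ty$name] <- ty$sig_fc
  }
  for (p in config$planted_lr_pairs) {
    static_mult[p$ligand, p$provider] <- static_mult[p$ligand, p$provider] * p$effect
    static_mult[p$receptor, p$recipient] <-
      static_mult[p$receptor, p$recipient] * (p$receptor_effect %||% p$effect)
  }

  mats <- vector("list", config$n_time_points)
  meta <- vector("list", config$n_time_points)
  size <- 1 / config$dispersion
  for (t in seq_len(config$n_time_points)) {
    tt <- config$time_labels[t]
    type_vec <- rep(type_names, n_per_type)
    fate_vec <- rep("none", length(type_vec))
    epi <- which(type_vec == "EPI")
    if (length(epi)) {
      half <- length(epi) %/% 2
      fate_vec[epi[seq_len(half)]] <- "proximal"
      fate_vec[epi[-seq_len(half)]] <- "distal"
    }
    mu <- base * static_mult[, type_vec, drop = FALSE]
    drift <- config$fate_drift[t]
    for (f in c("proximal", "distal")) {
      idx <- which(fate_vec == f)
      if (length(idx)) {
        mu[config$fate_targets[[f]], idx] <-
          mu[config$fate_targets[[f]], idx] * (1 + (config$fate_fc - 1) * drift)
        tf_idx <- if (f == "proximal") lay$tf_prox else lay$tf_dist
        mu[tf_idx, idx] <- mu[tf_idx, idx] * (1 + 3 * drift)
      }
    }
    with_seed(config$seed + 100L + t, {
      sf <- rlnorm(length(type_vec), meanlog = -config$lib_sigma^2 / 2,
                   sdlog = config$lib_sigma)
      mu <- sweep(mu, 2L, sf, "*")
      cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                    nrow = config$n_genes)
    })
    rownames(cnt) <- config$gene_names
    colnames(cnt) <- sprintf("%s_c%04d", tt, seq_along(type_vec))
    mats[[t]] <- cnt
    meta[[t]] <- data.frame(barcode = colnames(cnt), time_point = tt,
                            cell_type = type_vec, fate = fate_vec,
                            stringsAsFactors = FALSE)
  }
  counts <- Matrix::Matrix(do.call(cbind, mats), sparse = TRUE)
  meta <- do.call(rbind, meta)
  cells <- cell_matrix(counts, meta)

  truth <- list(
    cell_fate = meta[, c("barcode", "time_point", "cell_type", "fate")],
    regulon_fates = data.frame(
      tf = config$gene_names[vapply(config$planted_regulons, `[[`, numeric(1), "tf")],
      fate = vapply(config$planted_regulons, `[[`, character(1), "fate"),
      stringsAsFactors = FALSE),
    interactions = do.call(rbind, lapply(config$planted_lr_pairs, function(p) {
      data.frame(ligand = config$gene_names[p$ligand],
                 receptor = config$gene_names[p$receptor],
                 provider = p$provider, recipient = p$recipient,
                 effect = p$effect, stringsAsFactors = FALSE)
    })),
    patterned_genes = config$gene_names[c(lay$type_sig$EPI,
                                          config$fate_targets$proximal,
                                          config$fate_targets$distal,
                                          lay$type_sig$SC_niche,
                                          lay$type_sig$SC_peritube)],
    decoy_genes = config$gene_names[lay$background],
    spot_composition = NULL
  )
  class(truth) <- "ground_truth"
  pd_log("generate_timecourse", cells = ncol(counts), genes = nrow(counts),
         seed = config$seed)
  list(cells = cells, truth = truth)
}
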