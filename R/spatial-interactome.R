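#' Assign cells to spots by maximum mapping probability
#'
#' Argmax over each mapping row; ties broken deterministically by the
#' lowest spot index.
#'
#' @param mapping cells x spots probability matrix.
#' @return A `cell_placement`: data.frame (barcode, spot) plus attribute
#'   `spot_cells` (list of resident cell indices per spot).
#' @export
assign_cells <- function(mapping) {
  if (any(rowSums(mapping) <= 0)) {
    stop("all-zero mapping row(s): ",
         paste(head(rownames(mapping)[rowSums(mapping) <= 0], 5), collapse = ", "))
  }
  spot <- max.col(mapping, ties.method = "first")
  placement <- data.frame(barcode = rownames(mapping),
                          spot = colnames(mapping)[spot],
                          spot_index = spot, stringsAsFactors = FALSE)
  attr(placement, "spot_cells") <- split(seq_len(nrow(mapping)),
                                         factor(spot, levels = seq_len(ncol(mapping))))
  class(placement) <- c("cell_placement", "data.frame")
  placement
}

#' Neighbor-spot constrained ligand-receptor scoring
#'
#' The spatial version of [lr_permutation_test()]: for every spot holding
#' at least one recipient-type cell, the recipient population is the
#' recipient cells resident in that spot and the provider population is
#' the provider-type cells resident in the spot's lattice neighbors
#' (optionally including the spot itself). Expression percentages, the
#' score product and the permutation null are computed on these spatially
#' restricted populations; one shared label permutation per iteration is
#' applied to all cells and the per-spot scores are aggregated by their
#' mean over recipient spots with at least one provider cell.
#'
#' @param placement a [assign_cells()] result for the same cells.
#' @param section a [spatial_section()] sharing the spot universe.
#' @param cells a [cell_matrix()].
#' @param db an `lr_database` data.frame.
#' @param provider_type,recipient_type cell-type labels.
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.001).
#' @param seed RNG seed.
#' @param include_self count the recipient spot itself as part of the
#'   provider neighborhood (default FALSE: neighbors only).
#' @return List: `aggregated` (interaction_table with one row per pair:
#'   mean score over contributing spots, z, p_perm, significant,
#'   n_spots_used), `per_spot` (data.frame of per-spot observed scores).
#'   Errors when no recipients or no providers exist anywhere.
#' @export
neighborhood_lr <- function(placement, section, cells, db,
                            provider_type, recipient_type,
                            n_perm = 1000L, alpha = 0.001, seed = 1L,
                            include_self = FALSE) {
  stopifnot(inherits(section, "spatial_section"), inherits(cells, "cell_matrix"))
  if (!all(placement$spot %in% section$positions$barcode)) {
    stop("placement and section must share the spot universe")
  }
  labels <- cells$meta$cell_type
  if (!any(labels == recipient_type)) stop("no cells of recipient type anywhere")
  if (!any(labels == provider_type)) stop("no cells of provider type anywhere")

  present <- db$ligand %in% rownames(cells$counts) &
    db$receptor %in% rownames(cells$counts)
  db <- db[present, , drop = FALSE]
  if (!nrow(db)) stop("no ligand-receptor pairs with both genes present")
  genes <- unique(c(db$ligand, db$receptor))
  incidence <- t(as.matrix(cells$counts[genes, , drop = FALSE] > 0)) * 1
  colnames(incidence) <- genes

  spot_idx <- match(placement$spot, section$positions$barcode)
  cells_in_spot <- split(seq_len(nrow(placement)),
                         factor(spot_idx, levels = seq_len(ncol(section$counts))))
  nbrs <- section$neighbors

  # per recipient spot: resident cell indices + neighborhood cell indices
  rec_spots <- which(vapply(cells_in_spot, function(ix) {
    any(labels[ix] == recipient_type)
  }, logical(1)))
  if (!length(rec_spots)) stop("no cells of recipient type anywhere")
  hood <- lapply(rec_spots, function(s) {
    ns <- if (include_self) c(s, nbrs[[s]]) else nbrs[[s]]
    list(rec = cells_in_spot[[s]], prov = unlist(cells_in_spot[ns]))
  })

  score_once <- function(lab, log_skips = FALSE) {
    # pairs x spots matrix of restricted scores; NA where spot unusable
    sc <- matrix(NA_real_, nrow(db), length(hood))
    for (h in seq_along(hood)) {
      rec_cells <- hood[[h]]$rec[lab[hood[[h]]$rec] == recipient_type]
      prov_cells <- hood[[h]]$prov[lab[hood[[h]]$prov] == provider_type]
      if (!length(rec_cells)) next
      if (!length(prov_cells)) {
        if (log_skips) {
          pd_log("neighborhood_lr", spot = rec_spots[h], skipped = "no providers")
        }
        next
      }
      pl <- colMeans(incidence[prov_cells, db$ligand, drop = FALSE])
      pr <- colMeans(incidence[rec_cells, db$receptor, drop = FALSE])
      sc[, h] <- pl * pr
    }
    sc
  }
  obs_spot <- score_once(labels, log_skips = TRUE)
  obs <- rowMeans(obs_spot, na.rm = TRUE)
  obs[is.nan(obs)] <- NA_real_
  if (all(is.na(obs))) stop("no recipient spot has providers in its neighborhood")

  perm <- matrix(0, n_perm, nrow(db))
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      lab <- labels[sample.int(length(labels))]
      perm[it, ] <- rowMeans(score_once(lab), na.rm = TRUE)
    }
  })
  perm[is.nan(perm)] <- 0
  mu <- colMeans(perm)
  sdv <- apply(perm, 2L, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  p_perm <- (1 + colSums(sweep(perm, 2L, obs, ">="))) / (n_perm + 1)

  n_spots_used <- sum(apply(!is.na(obs_spot), 2L, any))
  aggregated <- data.frame(provider = provider_type, recipient = recipient_type,
                           ligand = db$ligand, receptor = db$receptor,
                           score = obs, z = z, p_perm = p_perm,
                           significant = !is.na(obs) & p_perm < alpha,
                           n_spots_used = n_spots_used,
                           stringsAsFactors = FALSE)
  class(aggregated) <- c("interaction_table", "data.frame")
  per_spot <- data.frame(
    spot = rep(section$positions$barcode[rec_spots], each = nrow(db)),
    ligand = rep(db$ligand, length(hood)),
    receptor = rep(db$receptor, length(hood)),
    score = as.vector(obs_spot), stringsAsFactors = FALSE)
  pd_log("neighborhood_lr", provider = provider_type,
         recipient = recipient_type, spots_used = aggregated$n_spots_used[1],
         n_perm = n_perm, seed = seed)
  list(aggregated = aggregated, per_spot = per_spot)
}
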