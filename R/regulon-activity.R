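#' Filter regulons by enrichment score
#'
#' Keeps regulons whose NES is strictly greater than `nes_min` (the
#' "significant regulon" rule, NES > 1). Records without an NES are dropped
#' unless the filter is disabled.
#'
#' @param regulons a [regulon_set()].
#' @param nes_min NES cutoff (default 1; strict inequality).
#' @param disable if `TRUE`, return all regulons unfiltered (records lacking
#'   an NES included).
#' @return A filtered [regulon_set()]; warns (does not error) when the
#'   result is empty.
#' @export
filter_regulons <- function(regulons, nes_min = 1.0, disable = FALSE) {
  stopifnot(inherits(regulons, "regulon_set"), is.finite(nes_min) || disable)
  if (disable) return(regulons)
  keep <- vapply(regulons$records, function(r) {
    !is.na(r$nes) && r$nes > nes_min
  }, logical(1))
  if (!any(keep)) {
    warning("no regulons pass NES > ", nes_min)
    return(structure(list(records = list()), class = "regulon_set"))
  }
  regulon_set(regulons$records[keep])
}

#' AUC-style regulon activity
#'
#' Per-cell transcription-factor activity as the area under the
#' target-recovery curve: genes are ranked by descending expression within
#' each cell and, as the rank cutoff k runs from 1 to
#' `ceiling(top_fraction * n_genes)`, the number of regulon targets found in
#' the top k is accumulated. The integral is normalized by its maximum
#' (all targets packed at the top of the ranking), so a regulon entirely
#' inside the top block scores 1 and one entirely below it scores 0.
#'
#' Activity depends only on within-cell ranks, so raw counts are ranked
#' directly; set `log_normalize = TRUE` only for parity with upstream
#' pipelines (it does not change ranks). Expression ties are broken by a
#' seeded global gene permutation fixed per run (deterministic, unbiased in
#' expectation). Cells with all-zero counts score 0 for every regulon, with
#' a warning.
#'
#' @param cells a [cell_matrix()].
#' @param regulons a [regulon_set()]; targets absent from the gene universe
#'   are dropped (logged); regulons with zero overlap yield a zero column
#'   with a warning.
#' @param top_fraction fraction of the ranking treated as the "top block"
#'   (default 0.05).
#' @param tie_seed seed for the tie-breaking gene permutation.
#' @param log_normalize rank log-normalized instead of raw counts.
#' @return Cells x TFs matrix of activities in \[0, 1\].
#' @export
auc_activity <- function(cells, regulons, top_fraction = 0.05,
                         tie_seed = 1L, log_normalize = FALSE) {
  stopifnot(inherits(cells, "cell_matrix"), inherits(regulons, "regulon_set"),
            top_fraction > 0, top_fraction < 1)
  expr <- if (log_normalize) lognorm(cells$counts) else as.matrix(cells$counts)
  n_genes <- nrow(expr)
  n_cells <- ncol(expr)
  k_max <- as.integer(ceiling(top_fraction * n_genes))
  genes <- rownames(expr)
  tie_key <- with_seed(tie_seed, sample.int(n_genes))

  target_idx <- lapply(regulons$records, function(r) {
    idx <- match(r$targets, genes)
    dropped <- sum(is.na(idx))
    if (dropped) pd_log("auc_activity", tf = r$tf, dropped_targets = dropped)
    idx[!is.na(idx)]
  })
  tfs <- vapply(regulons$records, `[[`, character(1), "tf")
  empty <- lengths(target_idx) == 0L
  if (any(empty)) {
    warning("regulon(s) with no targets in the matrix: ",
            paste(tfs[empty], collapse = ", "), " (activity set to 0)")
  }
  zero_cells <- Matrix::colSums(cells$counts) == 0
  if (any(zero_cells)) {
    warning(sum(zero_cells), " all-zero cell(s): activity set to 0")
  }

  act <- matrix(0, n_cells, length(tfs),
                dimnames = list(colnames(expr), tfs))
  # per-regulon normalization: targets packed into ranks 1..m
  max_int <- vapply(target_idx, function(idx) {
    m <- min(length(idx), k_max)
    if (m == 0L) return(1)
    sum(k_max - seq_len(m) + 1)
  }, numeric(1))
  for (ci in seq_len(n_cells)) {
    if (zero_cells[ci]) next
    ord <- order(-expr[, ci], tie_key)
    rnk <- integer(n_genes)
    rnk[ord] <- seq_len(n_genes)
    for (ri in seq_along(target_idx)) {
      if (empty[ri]) next
      rho <- rnk[target_idx[[ri]]]
      rho <- rho[rho <= k_max]
      act[ci, ri] <- sum(k_max - rho + 1) / max_int[ri]
    }
  }
  act
}
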