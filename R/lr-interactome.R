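#' Expression percentage of a gene in a cell type
#'
#' Fraction of cells of `cell_type` with UMI count > 0 for `gene`.
#'
#' @param cells a [cell_matrix()].
#' @param cell_type type label.
#' @param gene gene symbol.
#' @return Fraction in \[0, 1\].
#' @export
expression_percentage <- function(cells, cell_type, gene) {
  stopifnot(inherits(cells, "cell_matrix"))
  idx <- which(cells$meta$cell_type == cell_type)
  if (!length(idx)) stop("no cells of type '", cell_type, "'")
  if (!gene %in% rownames(cells$counts)) stop("gene '", gene, "' not in matrix")
  mean(cells$counts[gene, idx] > 0)
}

#' Ligand-receptor score
#'
#' The product of the ligand's expression percentage in the provider type
#' and the receptor's expression percentage in the recipient type.
#'
#' @param cells a [cell_matrix()].
#' @param pair length-2 character vector `(ligand, receptor)`.
#' @param provider,recipient cell-type labels.
#' @return The score, or `NA` (with a logged reason) when either gene is
#'   absent from the matrix.
#' @export
lr_score <- function(cells, pair, provider, recipient) {
  absent <- setdiff(pair, rownames(cells$counts))
  if (length(absent)) {
    pd_log("lr_score", skipped_pair = paste(pair, collapse = "-"),
           reason = paste("absent:", paste(absent, collapse = ",")))
    return(NA_real_)
  }
  expression_percentage(cells, provider, pair[1]) *
    expression_percentage(cells, recipient, pair[2])
}

# expression-percentage matrix (types x genes) for a label vector
pct_by_type <- function(incidence, labels) {
  f <- factor(labels)
  s <- rowsum(incidence, f)
  sweep(s, 1L, as.vector(table(f)), "/")
}

#' Permutation test for ligand-receptor interactions
#'
#' Scores every (provider, recipient, ligand-receptor pair) combination and
#' builds its null by shuffling the whole cell-type label vector `n_perm`
#' times (one shared permutation per iteration, preserving gene-gene
#' structure under the null). Reports the permutation z-score
#' ((observed - mean) / sd of the background, 0 when the background is
#' degenerate), the add-one empirical p-value
#' `(1 + #(perm >= observed)) / (n_perm + 1)`, and a secondary rank-based
#' (Mann-Whitney) p comparing the observed score against the background.
#' Significance = empirical p < `alpha`. Autocrine (provider == recipient)
#' rows are computed but flagged.
#'
#' @param cells a [cell_matrix()] with `cell_type` metadata (>= 2 types).
#' @param db an `lr_database` data.frame (ligand, receptor columns); pairs
#'   with genes absent from the matrix are skipped with a logged reason.
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance level on the empirical p (default 0.001).
#' @param seed RNG seed for the permutations.
#' @param providers,recipients optional type subsets (default: all types).
#' @param adjust apply Benjamini-Hochberg to the empirical p into a
#'   `p_adj` column (significance still uses raw p, as in the source
#'   scoring scheme).
#' @return An `interaction_table` data.frame: provider, recipient, ligand,
#'   receptor, pct_ligand, pct_receptor, score, z, p_perm, p_mw,
#'   significant, autocrine (and p_adj when `adjust`).
#' @export
lr_permutation_test <- function(cells, db, n_perm = 1000L, alpha = 0.001,
                                seed = 1L, providers = NULL, recipients = NULL,
                                adjust = FALSE) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- cells$meta$cell_type
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need >= 2 cell types")
  if (is.null(providers)) providers <- types
  if (is.null(recipients)) recipients <- types

  present <- db$ligand %in% rownames(cells$counts) &
    db$receptor %in% rownames(cells$counts)
  if (any(!present)) {
    pd_log("lr_permutation_test", skipped_pairs = sum(!present),
           reason = "gene absent from matrix")
  }
  db <- db[present, , drop = FALSE]
  if (!nrow(db)) stop("no ligand-receptor pairs with both genes present")
  genes <- unique(c(db$ligand, db$receptor))
  incidence <- t(as.matrix(cells$counts[genes, , drop = FALSE] > 0)) * 1
  colnames(incidence) <- genes

  obs_pct <- pct_by_type(incidence, labels)
  combos <- expand.grid(provider = providers, recipient = recipients,
                        pair = seq_len(nrow(db)), stringsAsFactors = FALSE)
  lig <- db$ligand[combos$pair]; rec <- db$receptor[combos$pair]
  pct_l <- obs_pct[cbind(combos$provider, lig)]
  pct_r <- obs_pct[cbind(combos$recipient, rec)]
  obs <- pct_l * pct_r

  perm_scores <- matrix(0, n_perm, nrow(combos))
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      pl <- labels[sample.int(length(labels))]
      pp <- pct_by_type(incidence, pl)
      perm_scores[it, ] <- pp[cbind(combos$provider, lig)] *
        pp[cbind(combos$recipient, rec)]
    }
  })
  mu <- colMeans(perm_scores)
  sdv <- apply(perm_scores, 2L, sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  p_perm <- (1 + colSums(sweep(perm_scores, 2L, obs, ">="))) / (n_perm + 1)
  p_mw <- vapply(seq_along(obs), function(i) {
    suppressWarnings(wilcox.test(obs[i], perm_scores[, i],
                                 alternative = "greater")$p.value)
  }, numeric(1))

  out <- data.frame(provider = combos$provider, recipient = combos$recipient,
                    ligand = lig, receptor = rec,
                    pct_ligand = pct_l, pct_receptor = pct_r,
                    score = obs, z = z, p_perm = p_perm, p_mw = p_mw,
                    significant = p_perm < alpha,
                    autocrine = combos$provider == combos$recipient,
                    stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_perm, "BH")
  class(out) <- c("interaction_table", "data.frame")
  pd_log("lr_permutation_test", pairs = nrow(db), combos = nrow(out),
         n_perm = n_perm, alpha = alpha, seed = seed,
         significant = sum(out$significant))
  out
}

#' Provider connectivity summary
#'
#' Per provider type: the number of significant pairs toward the recipient
#' set, the share of all significant provider->recipient pairs it
#' contributes, and (for juxtaposition) the provider's share of cells among
#' the listed providers.
#'
#' @param table an `interaction_table` from [lr_permutation_test()] or
#'   [neighborhood_lr()].
#' @param providers provider types to summarize.
#' @param recipients recipient types defining the target set.
#' @param cells optional [cell_matrix()] for the cell-proportion column.
#' @return Data.frame (provider, n_significant, fraction, cell_proportion).
#' @export
connectivity_summary <- function(table, providers, recipients, cells = NULL) {
  sub <- table[table$provider %in% providers &
                 table$recipient %in% recipients, , drop = FALSE]
  n_sig <- vapply(providers, function(p) {
    sum(sub$significant[sub$provider == p])
  }, numeric(1))
  total <- sum(n_sig)
  cellp <- if (!is.null(cells)) {
    n <- vapply(providers, function(p) sum(cells$meta$cell_type == p), numeric(1))
    n / sum(n)
  } else NA_real_
  data.frame(provider = providers, n_significant = n_sig,
             fraction = if (total > 0) n_sig / total else 0,
             cell_proportion = cellp, row.names = NULL,
             stringsAsFactors = FALSE)
}
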