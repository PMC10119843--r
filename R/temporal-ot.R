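#' Entropic optimal-transport coupling of two point clouds
#'
#' Log-domain Sinkhorn iteration for the entropy-regularized transport plan
#' between `source_embedding` and `target_embedding` under squared-Euclidean
#' cost. Converged when the largest marginal deviation drops below `tol`.
#'
#' @param source_embedding n x d matrix of source points.
#' @param target_embedding m x d matrix of target points.
#' @param epsilon entropic regularization; default 0.05 x mean cost.
#' @param max_iter maximum Sinkhorn iterations (default 5000).
#' @param tol maximum allowed marginal deviation (default 1e-8).
#' @param a,b source / target marginals (default uniform).
#' @return List: `plan` (n x m, non-negative, row sums ~ a, col sums ~ b),
#'   `epsilon`, `iterations`, `converged`, `marginal_dev`. Warns on
#'   non-convergence.
#' @export
sinkhorn_couple <- function(source_embedding, target_embedding,
                            epsilon = NULL, max_iter = 5000L, tol = 1e-8,
                            a = NULL, b = NULL) {
  x <- as.matrix(source_embedding)
  y <- as.matrix(target_embedding)
  if (!nrow(x) || !nrow(y)) stop("empty embedding")
  if (ncol(x) != ncol(y)) stop("embeddings must share dimensionality")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite coordinates in embedding")
  }
  n <- nrow(x); m <- nrow(y)
  if (is.null(a)) a <- rep(1 / n, n)
  if (is.null(b)) b <- rep(1 / m, m)
  stopifnot(length(a) == n, length(b) == m,
            abs(sum(a) - 1) < 1e-8, abs(sum(b) - 1) < 1e-8)
  cost <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  cost <- pmax(cost, 0)
  if (is.null(epsilon)) epsilon <- 0.05 * mean(cost)
  if (epsilon <= 0) stop("epsilon must be > 0")

  la <- log(a); lb <- log(b)
  f <- rep(0, n); g <- rep(0, m)
  mdev <- Inf; it <- 0L
  plan_from <- function(f, g) {
    exp((outer(f, g, "+") - cost) / epsilon)
  }
  while (it < max_iter) {
    it <- it + 1L
    f <- f + epsilon * (la - row_logsumexp((outer(f, g, "+") - cost) / epsilon))
    g <- g + epsilon * (lb - col_logsumexp((outer(f, g, "+") - cost) / epsilon))
    p <- plan_from(f, g)
    mdev <- max(max(abs(rowSums(p) - a)), max(abs(colSums(p) - b)))
    if (mdev < tol) break
  }
  if (mdev >= tol) {
    warning(sprintf("Sinkhorn did not converge in %d iterations (deviation %.3g)",
                    max_iter, mdev))
  }
  dimnames(p) <- list(rownames(x), rownames(y))
  list(plan = p, epsilon = epsilon, iterations = it,
       converged = mdev < tol, marginal_dev = mdev)
}

#' PCA embedding for transport cost
#'
#' Top principal components of log-normalized counts over the most
#' variable genes, the default cost space for temporal coupling. Gene
#' selection before PCA mirrors the standard trajectory workflow (the
#' emulated analysis embeds on a selected TF/HVG panel): without it the
#' squared-Euclidean cost is dominated by genes carrying no structure and
#' the entropic plan blurs across populations.
#'
#' @param cells a [cell_matrix()].
#' @param n_pcs number of components (default 30, capped by data rank).
#' @param n_hvg number of top-variance genes retained before PCA (default
#'   100; `Inf` for all genes).
#' @return cells x n_pcs matrix, rownames = barcodes.
#' @export
pca_embedding <- function(cells, n_pcs = 30L, n_hvg = 100L) {
  x <- t(lognorm(cells$counts))
  if (is.finite(n_hvg) && n_hvg < ncol(x)) {
    v <- apply(x, 2L, var)
    x <- x[, order(-v)[seq_len(n_hvg)], drop = FALSE]
  }
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  rownames(emb) <- colnames(cells$counts)
  emb
}

#' Couple all adjacent time points
#'
#' Runs [sinkhorn_couple()] between every adjacent pair of time points with
#' uniform marginals, in a shared embedding (caller-supplied, or top 30 PCs
#' of log-normalized counts).
#'
#' @param cells a [cell_matrix()] whose meta has `time_point`.
#' @param embedding optional cells x d matrix (rownames = barcodes).
#' @param time_order optional explicit ordering of time labels.
#' @param epsilon,max_iter,tol forwarded to [sinkhorn_couple()].
#' @return An object of class `temporal_coupling`: `times`, per-pair
#'   `plans`, `cells_by_time` (barcode lists), and the solver diagnostics.
#' @export
temporal_coupling <- function(cells, embedding = NULL, time_order = NULL,
                              epsilon = NULL, max_iter = 5000L, tol = 1e-8) {
  stopifnot(inherits(cells, "cell_matrix"))
  tp <- cells$meta$time_point
  times <- if (is.null(time_order)) sort(unique(tp)) else time_order
  if (length(times) < 2L) stop("need >= 2 time points")
  if (is.null(embedding)) embedding <- pca_embedding(cells)
  embedding <- embedding[colnames(cells$counts), , drop = FALSE]
  idx_by_time <- lapply(times, function(t) which(tp == t))
  plans <- vector("list", length(times) - 1L)
  diags <- vector("list", length(times) - 1L)
  for (k in seq_len(length(times) - 1L)) {
    i <- idx_by_time[[k]]; j <- idx_by_time[[k + 1L]]
    res <- sinkhorn_couple(embedding[i, , drop = FALSE],
                           embedding[j, , drop = FALSE],
                           epsilon = epsilon, max_iter = max_iter, tol = tol)
    plans[[k]] <- res$plan
    diags[[k]] <- res[c("epsilon", "iterations", "converged", "marginal_dev")]
    pd_log("temporal_coupling", pair = paste(times[k], times[k + 1], sep = "->"),
           epsilon = signif(res$epsilon, 4), iterations = res$iterations,
           dev = signif(res$marginal_dev, 3))
  }
  structure(list(times = times, plans = plans, diagnostics = diags,
                 cells_by_time = lapply(idx_by_time, function(i) {
                   colnames(cells$counts)[i]
                 })),
            class = "temporal_coupling")
}

#' @export
print.temporal_coupling <- function(x, ...) {
  cat(sprintf("temporal_coupling: %s\n", paste(x$times, collapse = " -> ")))
  for (k in seq_along(x$plans)) {
    d <- x$diagnostics[[k]]
    cat(sprintf("  %s->%s: %dx%d plan, eps %.4g, %d iter, dev %.2g\n",
                x$times[k], x$times[k + 1], nrow(x$plans[[k]]),
                ncol(x$plans[[k]]), d$epsilon, d$iterations, d$marginal_dev))
  }
  invisible(x)
}

#' Ancestor trajectory scores for a fate
#'
#' Pulls uniform mass on `fate_cells` (a set of cells at one time point)
#' backward through the adjacent couplings: at each step the plan's columns
#' are normalized to 1 so each descendant distributes its mass over its
#' ancestors, and the resulting per-time-point score vectors are normalized
#' to sum to 1.
#'
#' @param coupling a [temporal_coupling()].
#' @param fate_cells barcodes of the fate population (all at one time point).
#' @param fate name attached to the result.
#' @return A `trajectory_scores` data.frame (barcode, time_point, score)
#'   covering the fate time point and all earlier ones, with attribute
#'   `fate`.
#' @export
trajectory_scores <- function(coupling, fate_cells, fate = "fate") {
  stopifnot(inherits(coupling, "temporal_coupling"), length(fate_cells) > 0)
  wt <- vapply(coupling$cells_by_time, function(b) any(fate_cells %in% b),
               logical(1))
  if (sum(wt) != 1L) stop("fate_cells must all lie at a single time point")
  t_idx <- which(wt)
  if (!all(fate_cells %in% coupling$cells_by_time[[t_idx]])) {
    stop("unknown fate cell barcodes")
  }
  res <- vector("list", t_idx)
  m <- setNames(rep(0, length(coupling$cells_by_time[[t_idx]])),
                coupling$cells_by_time[[t_idx]])
  m[fate_cells] <- 1 / length(fate_cells)
  res[[t_idx]] <- m
  for (k in rev(seq_len(t_idx - 1L))) {
    p <- coupling$plans[[k]]
    cs <- colSums(p)
    live <- cs > 0
    if (!any(live & res[[k + 1L]] > 0)) {
      stop("degenerate coupling: fate cells receive zero transported mass at ",
           coupling$times[k + 1L])
    }
    pc <- sweep(p[, live, drop = FALSE], 2L, cs[live], "/")
    m <- as.vector(pc %*% res[[k + 1L]][live])
    if (sum(m) <= 0) {
      stop("degenerate coupling: zero ancestor mass at ", coupling$times[k])
    }
    res[[k]] <- setNames(m / sum(m), rownames(p))
  }
  out <- do.call(rbind, lapply(seq_len(t_idx), function(k) {
    data.frame(barcode = names(res[[k]]), time_point = coupling$times[k],
               score = unname(res[[k]]), stringsAsFactors = FALSE)
  }))
  attr(out, "fate") <- fate
  class(out) <- c("trajectory_scores", "data.frame")
  out
}

#' Select a lineage by trajectory score
#'
#' Cells whose trajectory score is strictly greater than `threshold`
#' (default 1e-4, the lineage-selection rule).
#'
#' @param scores a [trajectory_scores()] data.frame.
#' @param threshold score cutoff (default 1e-4).
#' @return Character vector of barcodes; warns when empty.
#' @export
select_lineage <- function(scores, threshold = 1e-4) {
  stopifnot(threshold >= 0)
  sel <- scores$barcode[scores$score > threshold]
  if (!length(sel)) warning("no cells exceed trajectory score ", threshold)
  sel
}

#' Fate probabilities from descendant mass
#'
#' For each cell at a pre-final time point, the fraction of its descendant
#' mass (row-normalized plans composed forward) landing in each declared
#' fate set, normalized across fates.
#'
#' @param coupling a [temporal_coupling()].
#' @param fate_sets named list of disjoint barcode sets at the final time
#'   point.
#' @return Data.frame (barcode, time_point, one probability column per
#'   fate, `flagged` = TRUE where total fate mass was 0 and probabilities
#'   are NA).
#' @export
fate_probabilities <- function(coupling, fate_sets) {
  stopifnot(inherits(coupling, "temporal_coupling"), length(fate_sets) >= 2L)
  final <- coupling$cells_by_time[[length(coupling$cells_by_time)]]
  all_fate <- unlist(fate_sets)
  if (anyDuplicated(all_fate)) stop("fate sets overlap")
  if (!all(all_fate %in% final)) {
    stop("fate sets must be subsets of the final time point")
  }
  n_t <- length(coupling$cells_by_time)
  fate_idx <- lapply(fate_sets, function(b) match(b, final))
  out <- list()
  fwd <- NULL
  for (k in rev(seq_len(n_t - 1L))) {
    p <- coupling$plans[[k]]
    rn <- sweep(p, 1L, pmax(rowSums(p), .Machine$double.xmin), "/")
    fwd <- if (is.null(fwd)) rn else rn %*% fwd
    mass <- vapply(fate_idx, function(ix) rowSums(fwd[, ix, drop = FALSE]),
                   numeric(nrow(fwd)))
    tot <- rowSums(mass)
    flagged <- tot <= 0
    probs <- mass / ifelse(tot > 0, tot, NA_real_)
    df <- data.frame(barcode = rownames(p),
                     time_point = coupling$times[k],
                     probs, flagged = flagged,
                     stringsAsFactors = FALSE, check.names = FALSE)
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
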