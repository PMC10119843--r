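#' Differential expression direction per TF
#'
#' Welch two-sample t-test on log-normalized expression for each listed
#' gene between two cell groups; a gene is called for the side with the
#' higher mean when p < `p_max` (default 0.01), otherwise "ns". Genes with
#' zero variance in both groups are "ns" and flagged.
#'
#' @param cells a [cell_matrix()].
#' @param group_a,group_b cell-type labels of the contrasted groups (>= 2
#'   cells each). `group_a` is the first level of the returned direction
#'   (e.g. "proximal").
#' @param genes gene symbols to test (the TF subset).
#' @param p_max significance threshold (default 0.01).
#' @param lfc_min optional absolute log fold-change floor (default 0 = off).
#' @return Data.frame (gene, direction in \{group_a, group_b, "ns"\},
#'   p_value, lfc, flagged).
#' @export
differential_direction <- function(cells, group_a, group_b, genes,
                                   p_max = 0.01, lfc_min = 0) {
  stopifnot(inherits(cells, "cell_matrix"))
  ia <- which(cells$meta$cell_type == group_a)
  ib <- which(cells$meta$cell_type == group_b)
  if (length(ia) < 2L || length(ib) < 2L) stop("both groups need >= 2 cells")
  genes <- intersect(genes, rownames(cells$counts))
  x <- lognorm(cells$counts[, c(ia, ib), drop = FALSE])
  na <- length(ia)
  raw <- cells$counts[genes, c(ia, ib), drop = FALSE]
  rows <- lapply(genes, function(g) {
    va <- x[g, seq_len(na)]; vb <- x[g, -seq_len(na)]
    lfc <- mean(va) - mean(vb)
    # degenerate: no within-group variation on either scale -> untestable
    ra <- raw[g, seq_len(na)]; rb <- raw[g, -seq_len(na)]
    if ((var(va) == 0 && var(vb) == 0) ||
        (var(ra) == 0 && var(rb) == 0 && ra[1] == rb[1])) {
      return(data.frame(gene = g, direction = "ns", p_value = NA_real_,
                        lfc = lfc, flagged = TRUE, stringsAsFactors = FALSE))
    }
    p <- tryCatch(t.test(va, vb)$p.value, error = function(e) NA_real_)
    if (is.na(p)) {
      return(data.frame(gene = g, direction = "ns", p_value = NA_real_,
                        lfc = lfc, flagged = TRUE, stringsAsFactors = FALSE))
    }
    dir <- if (p < p_max && abs(lfc) >= lfc_min) {
      if (lfc > 0) group_a else group_b
    } else "ns"
    data.frame(gene = g, direction = dir, p_value = p, lfc = lfc,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify cross-species TF conservation
#'
#' Joins per-TF differential directions from two species through a
#' one-to-one orthology table and applies the category truth table:
#' (proximal, proximal) -> proximal shared; (distal, distal) -> distal
#' shared; (significant, ns) -> human-specific; (ns, significant) ->
#' mouse-specific; opposite significant directions -> human-mouse inverse;
#' (ns, ns) -> unclassified.
#'
#' @param human_dirs,mouse_dirs data.frames from
#'   [differential_direction()] with directions coded "proximal", "distal"
#'   or "ns" (use those group labels when testing).
#' @param orthology data.frame (human_symbol, mouse_symbol); many-to-many
#'   rows are dropped so the mapping is one-to-one (logged).
#' @return A `tf_category_table` data.frame: tf (human symbol),
#'   mouse_symbol, human_direction, mouse_direction, category. TFs absent
#'   from the orthology are excluded with a log line.
#' @export
classify_conservation <- function(human_dirs, mouse_dirs, orthology) {
  stopifnot(all(c("human_symbol", "mouse_symbol") %in% names(orthology)))
  dup <- orthology$human_symbol %in%
    orthology$human_symbol[duplicated(orthology$human_symbol)] |
    orthology$mouse_symbol %in%
    orthology$mouse_symbol[duplicated(orthology$mouse_symbol)]
  if (any(dup)) {
    pd_log("classify_conservation", dropped_many_to_many = sum(dup))
    orthology <- orthology[!dup, , drop = FALSE]
  }
  hd <- setNames(human_dirs$direction, human_dirs$gene)
  md <- setNames(mouse_dirs$direction, mouse_dirs$gene)
  unmapped <- setdiff(names(hd), orthology$human_symbol)
  if (length(unmapped)) {
    pd_log("classify_conservation", excluded_no_ortholog = length(unmapped))
  }
  orthology <- orthology[orthology$human_symbol %in% names(hd) &
                           orthology$mouse_symbol %in% names(md), , drop = FALSE]
  h <- hd[orthology$human_symbol]
  m <- md[orthology$mouse_symbol]
  category <- mapply(conservation_category, h, m, USE.NAMES = FALSE)
  out <- data.frame(tf = orthology$human_symbol,
                    mouse_symbol = orthology$mouse_symbol,
                    human_direction = unname(h), mouse_direction = unname(m),
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("tf_category_table", "data.frame")
  out
}

# the category truth table; directions in {"proximal", "distal", "ns"}
conservation_category <- function(h, m) {
  sig <- c("proximal", "distal")
  if (h %in% sig && m %in% sig) {
    if (h == m) paste(h, "shared") else "human-mouse inverse"
  } else if (h %in% sig) {
    "human-specific"
  } else if (m %in% sig) {
    "mouse-specific"
  } else {
    "unclassified"
  }
}

#' Synthetic paired human / mouse epithelial matrices
#'
#' Generates matched human and mouse cell matrices with proximal and distal
#' epithelial groups, a one-to-one orthology table (mouse symbols are the
#' human symbols in sentence case), and TFs planted in each conservation
#' category at >= 2-fold shifts, for exercising
#' [differential_direction()] + [classify_conservation()].
#'
#' @param n_per_group cells per group and species (default 60).
#' @param n_background extra untested background genes (default 40).
#' @param base_mean baseline NB mean (default 1).
#' @param fc planted fold change (default 3).
#' @param seed RNG seed.
#' @return List: `human`, `mouse` ([cell_matrix()]s with cell_type in
#'   \{proximal, distal\}), `orthology`, `tf_genes` (human symbols),
#'   `truth` (data.frame tf, category).
#' @export
simulate_species_tf_data <- function(n_per_group = 80L, n_background = 40L,
                                     base_mean = 1, fc = 4, seed = 11L) {
  plan <- data.frame(
    tf = c("TFSHP1", "TFSHP2", "TFSHD1", "TFSHD2", "TFHUM1", "TFHUM2",
           "TFMOU1", "TFMOU2", "TFINV1", "TFINV2", "TFNSX1", "TFNSX2"),
    human = c("proximal", "proximal", "distal", "distal", "proximal", "distal",
              "ns", "ns", "proximal", "distal", "ns", "ns"),
    mouse = c("proximal", "proximal", "distal", "distal", "ns", "ns",
              "proximal", "distal", "distal", "proximal", "ns", "ns"),
    stringsAsFactors = FALSE)
  truth_cat <- mapply(conservation_category, plan$human, plan$mouse,
                      USE.NAMES = FALSE)
  genes <- c(plan$tf, paste0("bg", sprintf("%02d", seq_len(n_background))))

  one_species <- function(dirs, tag, sub_seed) {
    mu <- matrix(base_mean, length(genes), 2L,
                 dimnames = list(genes, c("proximal", "distal")))
    for (i in seq_len(nrow(plan))) {
      if (dirs[i] != "ns") mu[plan$tf[i], dirs[i]] <- base_mean * fc
    }
    grp <- rep(c("proximal", "distal"), each = n_per_group)
    mm <- mu[, grp]
    cnt <- with_seed(sub_seed, matrix(rnbinom(length(mm), mu = as.vector(mm),
                                              size = 2),
                                      nrow = length(genes)))
    rownames(cnt) <- genes
    colnames(cnt) <- sprintf("%s_c%03d", tag, seq_along(grp))
    cell_matrix(Matrix::Matrix(cnt, sparse = TRUE),
                data.frame(barcode = colnames(cnt), cell_type = grp,
                           stringsAsFactors = FALSE))
  }
  sentence_case <- function(s) {
    paste0(substr(s, 1, 1), tolower(substr(s, 2, nchar(s))))
  }
  human <- one_species(plan$human, "hs", seed)
  mouse_genes <- sentence_case(genes)
  mouse <- one_species(plan$mouse, "mm", seed + 1L)
  rownames(mouse$counts) <- mouse_genes
  list(human = human, mouse = mouse,
       orthology = data.frame(human_symbol = genes,
                              mouse_symbol = mouse_genes,
                              stringsAsFactors = FALSE),
       tf_genes = plan$tf,
       tf_genes_mouse = sentence_case(plan$tf),
       truth = data.frame(tf = plan$tf, category = truth_cat,
                          stringsAsFactors = FALSE))
}
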