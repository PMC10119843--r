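toy_cells <- function(mat) {
  cell_matrix(Matrix::Matrix(mat, sparse = TRUE),
              data.frame(barcode = colnames(mat)))
}

test_that("NES filter is strict and can be disabled", {
  regs <- regulon_set(list(
    list(tf = "A", nes = 0.5, targets = c("g1", "g2")),
    list(tf = "B", nes = 1.0, targets = c("g3", "g4")),
    list(tf = "C", nes = 1.7, targets = c("g5", "g6")),
    list(tf = "D", nes = NA_real_, targets = c("g7", "g8"))))
  kept <- filter_regulons(regs, nes_min = 1)
  expect_equal(vapply(kept$records, `[[`, character(1), "tf"), "C")
  expect_length(filter_regulons(regs, disable = TRUE), 4L)
  expect_warning(empty <- filter_regulons(regs, nes_min = 10), "no regulons")
  expect_length(empty, 0L)
})

test_that("activity is 1 for a regulon filling the top block and 0 below it", {
  set.seed(1)
  expr <- matrix(100:1 + 0, 100, 1, dimnames = list(sprintf("g%03d", 1:100), "c1"))
  cells <- toy_cells(expr)
  regs <- regulon_set(list(
    list(tf = "TOP", nes = 2, targets = sprintf("g%03d", 1:5)),
    list(tf = "BOTTOM", nes = 2, targets = sprintf("g%03d", 96:100))))
  act <- auc_activity(cells, regs, top_fraction = 0.05)
  expect_equal(act["c1", "TOP"], 1)
  expect_equal(act["c1", "BOTTOM"], 0)
})

test_that("the worked 10-gene example matches the hand-enumerated curve", {
  # target ranks {1, 3} with cutoff k = 5: curve 1,1,2,2,2 -> 8, max 9
  expr <- matrix(10:1 + 0, 10, 1, dimnames = list(paste0("g", 1:10), "c1"))
  cells <- toy_cells(expr)
  regs <- regulon_set(list(list(tf = "R", nes = 2, targets = c("g1", "g3"))))
  act <- auc_activity(cells, regs, top_fraction = 0.5)
  expect_equal(act["c1", "R"], 8 / 9)
})

test_that("activity equals the brute-force recovery-curve oracle", {
  set.seed(42)
  n_genes <- 30
  n_cells <- 20
  genes <- sprintf("g%02d", seq_len(n_genes))
  expr <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells,
                 dimnames = list(genes, sprintf("c%02d", seq_len(n_cells))))
  expr[, 1] <- 0  # include an all-zero cell
  cells <- suppressWarnings(toy_cells(expr))
  regs <- regulon_set(lapply(1:5, function(r) {
    list(tf = paste0("R", r), nes = 2, targets = sample(genes, sample(3:8, 1)))
  }))
  tie_key <- with(list(), { set.seed(1); sample.int(n_genes) })
  act <- suppressWarnings(auc_activity(cells, regs, top_fraction = 0.2,
                                       tie_seed = 1L))
  for (ci in 2:n_cells) {
    v <- setNames(expr[, ci], genes)
    for (ri in seq_along(regs$records)) {
      expect_equal(act[ci, ri],
                   auc_oracle(v, regs$records[[ri]]$targets, 0.2, tie_key),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(act[1, ] == 0))  # all-zero cell
  expect_true(all(act >= 0 & act <= 1))
})

test_that("activity is invariant to positive rescaling of a cell's counts", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:30)
  expr <- matrix(rpois(30 * 5, 4), 30, 5,
                 dimnames = list(genes, paste0("c", 1:5)))
  regs <- regulon_set(list(list(tf = "R", nes = 2,
                                targets = sample(genes, 6))))
  a1 <- auc_activity(toy_cells(expr), regs, top_fraction = 0.2)
  a2 <- auc_activity(toy_cells(expr * 7), regs, top_fraction = 0.2)
  expect_equal(a1, a2)
})

test_that("adding an in-top-block target never lowers the raw recovery integral", {
  # asserted through the oracle's unnormalized integral on random cases
  raw_integral <- function(v, targets, top_fraction, tie_key) {
    k_max <- ceiling(top_fraction * length(v))
    ord <- order(-v, tie_key)
    rnk <- integer(length(v))
    rnk[ord] <- seq_along(v)
    rho <- rnk[match(targets, names(v))]
    sum(pmax(k_max - rho[rho <= k_max] + 1, 0))
  }
  set.seed(9)
  genes <- sprintf("g%02d", 1:40)
  tie_key <- sample.int(40)
  for (rep in 1:20) {
    v <- setNames(rpois(40, 5) + 0, genes)
    k_max <- ceiling(0.25 * 40)
    ord <- order(-v, tie_key)
    targets <- sample(genes, 5)
    extra <- setdiff(genes[ord[seq_len(k_max)]], targets)[1]
    if (is.na(extra)) next
    expect_gte(raw_integral(v, c(targets, extra), 0.25, tie_key),
               raw_integral(v, targets, 0.25, tie_key))
  }
})

test_that("zero-overlap regulons warn and score zero", {
  expr <- matrix(5:1 + 0, 5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  regs <- regulon_set(list(list(tf = "R", nes = 2, targets = c("zz1", "zz2"))))
  expect_warning(act <- auc_activity(toy_cells(expr), regs, top_fraction = 0.4),
                 "no targets in the matrix")
  expect_true(all(act == 0))
})

test_that("planted regulons are more active in their fate's cells than decoys", {
  ds <- default_dataset()
  cfg <- ds$config
  regs <- generate_regulons(cfg)
  act <- auc_activity(ds$cells, regs)
  meta <- ds$cells$meta
  decoy_tfs <- cfg$gene_names[cfg$layout$tf_decoy]
  for (f in c("proximal", "distal")) {
    fate_cells <- meta$barcode[meta$fate == f]
    planted_tfs <- cfg$gene_names[if (f == "proximal") cfg$layout$tf_prox
                                  else cfg$layout$tf_dist]
    for (tf in planted_tfs) {
      p <- wilcox.test(act[fate_cells, tf],
                       as.vector(act[fate_cells, decoy_tfs]),
                       alternative = "greater")$p.value
      expect_lt(p, 0.01)
    }
  }
})
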