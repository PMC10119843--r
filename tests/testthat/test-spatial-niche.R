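# square-lattice section with controllable counts for Moran's I tests
grid_section <- function(values_by_gene, nr, nc, rule = "rook") {
  grid <- expand.grid(array_col = seq_len(nc) - 1L,
                      array_row = seq_len(nr) - 1L)
  pos <- data.frame(barcode = sprintf("s%03d", seq_len(nr * nc)),
                    in_tissue = 1L,
                    array_row = grid$array_row, array_col = grid$array_col,
                    pxl_row = 0L, pxl_col = 0L)
  counts <- do.call(rbind, values_by_gene)
  dimnames(counts) <- list(names(values_by_gene), pos$barcode)
  spatial_section(Matrix::Matrix(counts, sparse = TRUE), pos,
                  neighbor_rule = rule)
}

test_that("spot proportions sum mapped mass by type", {
  # 4 cells x 2 spots hand example
  mapping <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1), c(0.25, 0.75))
  dimnames(mapping) <- list(paste0("c", 1:4), c("s1", "s2"))
  types <- c("A", "A", "B", "B")
  mass <- spot_proportions(mapping, types, normalize = FALSE)
  expect_equal(mass["s1", "A"], 1.5)
  expect_equal(mass["s1", "B"], 0.25)
  expect_equal(mass["s2", "A"], 0.5)
  expect_equal(mass["s2", "B"], 1.75)
  expect_equal(sum(mass), 4)                    # mass conservation
  prop <- spot_proportions(mapping, types)
  expect_equal(rowSums(prop), c(s1 = 1, s2 = 1))
  # one cell per spot with probability 1 -> one-hot rows
  eye <- diag(2)
  dimnames(eye) <- list(c("x", "y"), c("s1", "s2"))
  expect_equal(spot_proportions(eye, c("A", "B"))["s1", ], c(A = 1, B = 0))
  expect_error(spot_proportions(mapping, c("A", NA, "B", "B")), "unlabeled")
  expect_error(spot_proportions(mapping * 2, types), "row-stochastic")
})

test_that("Moran's I handles constant genes and the checkerboard limit", {
  nr <- 6; nc <- 6
  grid <- expand.grid(col = seq_len(nc) - 1, row = seq_len(nr) - 1)
  checker <- (grid$row + grid$col) %% 2
  sec <- grid_section(list(const = rep(3, 36),
                           checker = checker * 2 + 1),
                      nr, nc, rule = "rook")
  mo_const <- morans_i(sec, values = rep(3, 36))
  expect_true(mo_const$undefined)
  expect_equal(mo_const$I, 0)
  # perfect checkerboard under rook adjacency is forced to I = -1
  mo_check <- morans_i(sec, values = checker)
  expect_equal(mo_check$I, -1, tolerance = 1e-12)
})

test_that("Moran's I equals the brute-force double sum on a hex lattice", {
  set.seed(31)
  vals <- lapply(1:5, function(i) rpois(36, 5) + 0)
  names(vals) <- paste0("g", 1:5)
  sec <- grid_section(vals, 6, 6, rule = "hex")
  for (g in names(vals)) {
    direct <- morans_i(sec, values = vals[[g]])$I
    expect_equal(direct, moran_oracle(vals[[g]], sec$neighbors),
                 tolerance = 1e-12)
  }
  # bounds for row-normalized weights on connected lattices
  stats <- morans_i_all(sec, do.call(rbind, vals))
  expect_true(all(stats$I >= -1 - 1e-12 & stats$I <= 1 + 1e-12))
})

test_that("SVG selection is strict at the threshold", {
  sec <- grid_section(list(g1 = rpois(36, 5) + 0), 6, 6)
  stats <- list(I = c(a = 0.05, b = 0.0501, c = -0.2, d = 0.01),
                undefined = c(a = FALSE, b = FALSE, c = FALSE, d = FALSE),
                n_spots = 36)
  expect_setequal(select_svgs(sec, threshold = 0.05, stats = stats),
                  c("b", "c"))
  stats$undefined["c"] <- TRUE
  expect_setequal(select_svgs(sec, threshold = 0.05, stats = stats), "b")
  expect_setequal(select_svgs(sec, threshold = 0, stats = stats),
                  c("a", "b", "d"))
})

test_that("planted patterned genes are selected and decoys rejected", {
  ds <- default_dataset()
  section <- filter_spots(ds$section, min_genes = 300)
  stats <- morans_i_all(section)
  svgs <- select_svgs(section, stats = stats)
  expect_true(all(ds$truth$patterned_genes %in% svgs))
  expect_gte(mean(!(ds$truth$decoy_genes %in% svgs)), 0.9)
})

test_that("the 3x3 hand-enumerated adjacency example reproduces exactly", {
  # center spot is distal-epithelial (0.6 distal epi, 0.4 stromal-X);
  # every other spot sits below the 0.4 filter for every type
  comp <- matrix(c(rep(c(0.2, 0.1, 0.3), 8), 0, 0, 0), 9, 3, byrow = TRUE,
                 dimnames = list(sprintf("s%03d", 1:9),
                                 c("EPI_distal", "EPI_proximal", "stromal_X")))
  center <- 5
  comp[center, ] <- c(0.6, 0, 0.4)
  # give the proximal region its own spot so both regions resolve
  comp[1, ] <- c(0, 0.45, 0.35)
  sec <- grid_section(list(g1 = rep(1, 9)), 3, 3, rule = "hex")
  adj <- adjacency_scores(comp, sec, min_prop = 0.4)
  distal <- adj[adj$region == "distal", ]
  expect_equal(distal$score[distal$cell_type == "EPI_distal"], 0.6)
  expect_equal(distal$score[distal$cell_type == "stromal_X"], 0.4)
  expect_equal(distal$share[distal$cell_type == "EPI_distal"], 0.6)
  expect_equal(distal$share[distal$cell_type == "stromal_X"], 0.4)
  # shares always normalize within region
  for (rg in c("proximal", "distal")) {
    expect_equal(sum(adj$share[adj$region == rg]), 1, tolerance = 1e-12)
  }
  # the 0.4 exclusion is strict: 0.39 dropped, 0.40 kept
  comp2 <- comp
  comp2[2, ] <- c(0.39, 0, 0.40)
  adj2 <- adjacency_scores(comp2, sec, min_prop = 0.4)
  d2 <- adj2[adj2$region == "distal", ]
  expect_equal(d2$score[d2$cell_type == "stromal_X"], 0.8)   # 0.4 + 0.4 kept
  expect_equal(d2$score[d2$cell_type == "EPI_distal"], 0.6)  # 0.39 dropped
})

test_that("isolated epithelial regions fall back to the region itself", {
  comp <- matrix(0, 1, 2, dimnames = list("s001", c("EPI_proximal", "EPI_distal")))
  comp[1, ] <- c(0.5, 0.5)
  pos <- data.frame(barcode = "s001", in_tissue = 1L, array_row = 0L,
                    array_col = 0L, pxl_row = 0L, pxl_col = 0L)
  sec <- spatial_section(Matrix::Matrix(matrix(1, 1, 1,
                                               dimnames = list("g1", "s001")),
                                        sparse = TRUE), pos)
  adj <- suppressWarnings(adjacency_scores(comp, sec, min_prop = 0.4))
  expect_equal(adj$score[adj$region == "proximal" &
                           adj$cell_type == "EPI_proximal"], 0.5)
  # missing epithelial spots are an error naming the label
  comp0 <- comp
  comp0[1, "EPI_distal"] <- 0
  expect_error(adjacency_scores(comp0, sec, min_prop = 0.4), "distal")
})

test_that("planted niche types take the top non-epithelial adjacency shares", {
  ds <- default_dataset()
  section <- filter_spots(ds$section, min_genes = 300)
  mapping <- ds$mapping[, section$positions$barcode, drop = FALSE]
  mapping <- sweep(mapping, 1L, rowSums(mapping), "/")
  comp <- spot_proportions(mapping, composition_labels(ds$cells$meta))
  adj <- adjacency_scores(comp, section)
  non_epi <- !(adj$cell_type %in% c("EPI_proximal", "EPI_distal"))
  distal <- adj[adj$region == "distal" & non_epi, ]
  expect_equal(distal$cell_type[which.max(distal$share)], "SC_niche")
  proximal <- adj[adj$region == "proximal" & non_epi, ]
  expect_equal(proximal$cell_type[which.max(proximal$share)], "SC_peritube")
})
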