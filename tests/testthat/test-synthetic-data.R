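test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config()
  a <- generate_timecourse(cfg)
  b <- generate_timecourse(cfg)
  expect_identical(a$cells$counts, b$cells$counts)
  expect_identical(a$cells$meta, b$cells$meta)
  spa <- generate_spatial(cfg, a$truth, a$cells)
  spb <- generate_spatial(cfg, b$truth, b$cells)
  expect_identical(spa$section$counts, spb$section$counts)
  expect_identical(spa$mapping, spb$mapping)
  expect_identical(generate_regulons(cfg)$records,
                   generate_regulons(cfg)$records)
})

test_that("cell bookkeeping matches the configuration", {
  cfg <- sim_config(cells_per_time = 100L, n_time_points = 5L)
  tc <- generate_timecourse(cfg)
  expect_equal(ncol(tc$cells$counts), 500L)
  expect_equal(unname(table(tc$cells$meta$time_point)[cfg$time_labels]),
               rep(100L, 5L), ignore_attr = TRUE)
  expect_setequal(unique(tc$cells$meta$cell_type),
                  vapply(cfg$cell_type_spec, `[[`, character(1), "name"))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(cell_type_spec = list(
    list(name = "A", prop = 0.5, sig_genes = 1:3, sig_fc = 2))),
    "cell_type_spec")
  cfg <- small_config()
  bad <- cfg
  bad$planted_regulons[[1]]$targets <- c(1L, cfg$n_genes + 5L)
  expect_error(validate_sim_config(bad), "gene index")
  bad2 <- cfg
  bad2$planted_lr_pairs[[1]]$provider <- "NOPE"
  expect_error(validate_sim_config(bad2), "NOPE")
  bad3 <- cfg
  bad3$planted_regulons[[2]]$tf <- bad3$planted_regulons[[1]]$tf
  expect_error(validate_sim_config(bad3), "duplicate TF")
  expect_error(generate_spatial(sim_config(grid_shape = c(4L, 4L)),
                                small_timecourse()$truth,
                                small_timecourse()$cells),
               "grid too small")
})

test_that("planted fate targets carry the configured fold change at full drift", {
  cfg <- sim_config(cells_per_time = 600L)
  tc <- generate_timecourse(cfg)
  cells <- tc$cells
  wk8 <- cells$meta$time_point == "wk8" & cells$meta$cell_type == "EPI"
  for (f in c("proximal", "distal")) {
    targets <- cfg$gene_names[cfg$fate_targets[[f]]]
    own <- mean(as.matrix(cells$counts[targets, wk8 & cells$meta$fate == f]))
    other <- mean(as.matrix(cells$counts[targets, wk8 & cells$meta$fate != f]))
    expect_lt(abs(own / other - cfg$fate_fc) / cfg$fate_fc, 0.2)
  }
})

test_that("hex lattice has 6-neighbor adjacency with boundary truncation", {
  sp <- small_spatial()
  nbrs <- sp$section$neighbors
  expect_equal(ncol(sp$section$counts), 100L)
  degrees <- lengths(nbrs)
  pos <- sp$section$positions
  interior <- pos$array_row > 0 & pos$array_row < 9 &
    pos$array_col > 0 & pos$array_col < 9
  expect_true(all(degrees[interior] == 6L))
  expect_true(all(degrees >= 2L & degrees <= 6L))
  # symmetry
  for (i in seq_along(nbrs)) {
    for (j in nbrs[[i]]) expect_true(i %in% nbrs[[j]])
  }
})

test_that("region templates drive the true composition (one-hot case included)", {
  cfg <- small_config()
  tc <- small_timecourse()
  templates <- list(
    proximal_tube = c(EPI_proximal = 1),
    tube_adjacent = c(SC_peritube = 0.6, SC_general = 0.4),
    distal_border = c(EPI_distal = 0.7, SC_niche = 0.3),
    border_adjacent = c(SC_niche = 0.5, SC_general = 0.5),
    other = c(SC_general = 0.4, Endothelium = 0.3, Immune = 0.3))
  sp <- generate_spatial(cfg, tc$truth, tc$cells, region_templates = templates)
  comp <- sp$truth$spot_composition
  expect_true(all(abs(rowSums(comp) - 1) < 1e-12))
  tube <- sp$truth$spot_region == "proximal_tube"
  expect_true(all(comp[tube, "EPI_proximal"] == 1))
  expect_true(all(comp[tube, colnames(comp) != "EPI_proximal"] == 0))
})

test_that("mapping rows are stochastic and column mass tracks expected occupancy", {
  sp <- default_dataset()
  expect_lt(max(abs(rowSums(sp$mapping) - 1)), 1e-12)
  occ <- expected_spot_occupancy(sp$truth, sp$cells$meta)
  colmass <- colSums(sp$mapping)
  expect_equal(sum(colmass), sum(occ), tolerance = 1e-8)
  # per-spot agreement within multinomial sampling error
  expect_true(all(abs(colmass - occ) < 6 * sqrt(occ + 1)))
  expect_gt(cor(occ, colmass), 0.7)
})

test_that("generated regulons separate planted from decoys by NES construction", {
  cfg <- small_config()
  regs <- generate_regulons(cfg)
  expect_length(regs, length(cfg$planted_regulons))
  planted <- vapply(cfg$planted_regulons, function(r) r$fate != "none", logical(1))
  nes <- vapply(regs$records, `[[`, numeric(1), "nes")
  expect_true(all(nes[planted] >= 1))
  expect_true(all(nes[!planted] < 1))
  expect_error(regulon_set(c(regs$records, regs$records[1])), "duplicate TF")
})

test_that("config and regulons round-trip through their file formats", {
  cfg <- small_config()
  tmp <- withr::local_tempdir()
  ypath <- file.path(tmp, "cfg.yaml")
  write_sim_config(cfg, ypath)
  cfg2 <- read_sim_config(ypath)
  expect_equal(cfg2$cells_per_time, cfg$cells_per_time)
  expect_identical(cfg2$gene_names, cfg$gene_names)
  expect_identical(generate_timecourse(cfg2)$cells$counts,
                   generate_timecourse(cfg)$cells$counts)

  regs <- generate_regulons(cfg)
  gpath <- file.path(tmp, "regs.gmt")
  write_regulons_gmt(regs, gpath)
  expect_equal(read_regulons_gmt(gpath)$records, regs$records,
               tolerance = 1e-10)
})
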