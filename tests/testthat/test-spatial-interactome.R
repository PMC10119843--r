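two_spot_section <- function(n_spots = 2, fully_connected = TRUE) {
  pos <- data.frame(barcode = paste0("s", seq_len(n_spots)), in_tissue = 1L,
                    array_row = 0L, array_col = seq_len(n_spots) - 1L,
                    pxl_row = 0L, pxl_col = 0L)
  nbrs <- if (fully_connected) {
    lapply(seq_len(n_spots), function(i) setdiff(seq_len(n_spots), i))
  } else {
    rep(list(integer(0)), n_spots)
  }
  counts <- matrix(1, 1, n_spots, dimnames = list("g1", pos$barcode))
  spatial_section(Matrix::Matrix(counts, sparse = TRUE), pos,
                  neighbors = nbrs)
}

test_that("cells map to their argmax spot with lowest-index tie breaking", {
  mapping <- rbind(c(1, 0, 0), c(0, 0.2, 0.8), c(0.4, 0.4, 0.2))
  dimnames(mapping) <- list(paste0("c", 1:3), paste0("s", 1:3))
  pl <- assign_cells(mapping)
  expect_equal(pl$spot, c("s1", "s3", "s1"))   # tie in row 3 -> lower index
  eye <- diag(4)
  dimnames(eye) <- list(paste0("c", 1:4), paste0("s", 1:4))
  expect_equal(assign_cells(eye)$spot, paste0("s", 1:4))
  bad <- mapping
  bad[2, ] <- 0
  expect_error(assign_cells(bad), "all-zero")
})

test_that("placement concentrates cells on spots of their planted region", {
  ds <- default_dataset()
  pl <- assign_cells(ds$mapping)
  comp <- ds$truth$spot_composition
  ct <- composition_labels(ds$cells$meta)
  compatible <- comp[cbind(match(pl$spot, rownames(comp)),
                           match(ct, colnames(comp)))] > 0
  expect_gte(mean(compatible), 0.9)
})

test_that("a fully connected neighborhood reproduces the global test exactly", {
  # one spot whose neighborhood covers every cell (include_self on a
  # single-node graph): the spatial restriction becomes vacuous
  tc <- small_timecourse()
  cells <- subset_cells(tc$cells,
                        tc$cells$meta$cell_type %in% c("SC_niche", "EPI"))
  db <- generate_lr_database(small_config())
  sec <- two_spot_section(n_spots = 1, fully_connected = FALSE)
  mapping <- matrix(1, ncol(cells$counts), 1,
                    dimnames = list(colnames(cells$counts), "s1"))
  pl <- assign_cells(mapping)
  res <- neighborhood_lr(pl, sec, cells, db, provider_type = "SC_niche",
                         recipient_type = "EPI", n_perm = 100, seed = 5,
                         include_self = TRUE)
  glob <- lr_permutation_test(cells, db, n_perm = 100, seed = 5,
                              providers = "SC_niche", recipients = "EPI")
  glob <- glob[match(paste(res$aggregated$ligand, res$aggregated$receptor),
                     paste(glob$ligand, glob$receptor)), ]
  expect_equal(res$aggregated$score, glob$score, tolerance = 1e-12)
  expect_equal(res$aggregated$z, glob$z, tolerance = 1e-10)
  expect_equal(res$aggregated$p_perm, glob$p_perm, tolerance = 1e-12)
})

test_that("providers outside the neighborhood contribute nothing", {
  counts <- rbind(L = c(5, 5, 0, 0), R = c(0, 0, 4, 4))
  colnames(counts) <- paste0("c", 1:4)
  cells <- cell_matrix(Matrix::Matrix(counts, sparse = TRUE),
                       data.frame(barcode = colnames(counts),
                                  cell_type = c("prov", "prov", "rec", "rec")))
  db <- data.frame(ligand = "L", receptor = "R", source_db = "x")
  # disconnected spots: recipient spot has no provider neighborhood
  sec <- two_spot_section(fully_connected = FALSE)
  mapping <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  dimnames(mapping) <- list(colnames(counts), c("s1", "s2"))
  pl <- assign_cells(mapping)
  expect_error(neighborhood_lr(pl, sec, cells, db, "prov", "rec",
                               n_perm = 10, seed = 1),
               "no recipient spot has providers")
  expect_error(neighborhood_lr(pl, sec, cells, db, "prov", "missing",
                               n_perm = 10, seed = 1), "recipient type")
})

test_that("fixed seed makes the spatial test deterministic", {
  ds <- default_dataset()
  section <- filter_spots(ds$section, min_genes = 300)
  mapping <- ds$mapping[, section$positions$barcode, drop = FALSE]
  mapping <- sweep(mapping, 1L, rowSums(mapping), "/")
  pl <- assign_cells(mapping)
  db <- generate_lr_database(ds$config)
  r1 <- neighborhood_lr(pl, section, ds$cells, db, "SC_niche", "EPI",
                        n_perm = 50, seed = 2)
  r2 <- neighborhood_lr(pl, section, ds$cells, db, "SC_niche", "EPI",
                        n_perm = 50, seed = 2)
  expect_identical(r1$aggregated$z, r2$aggregated$z)
  expect_identical(r1$aggregated$p_perm, r2$aggregated$p_perm)
})

test_that("the planted border interaction is the only significant spatial pair", {
  ds <- default_dataset()
  section <- filter_spots(ds$section, min_genes = 300)
  mapping <- ds$mapping[, section$positions$barcode, drop = FALSE]
  mapping <- sweep(mapping, 1L, rowSums(mapping), "/")
  pl <- assign_cells(mapping)
  db <- generate_lr_database(ds$config)
  res <- neighborhood_lr(pl, section, ds$cells, db, "SC_niche", "EPI",
                         n_perm = 1000, seed = ds$config$seed + 600L)
  agg <- res$aggregated
  planted <- agg$ligand == "LIGA" & agg$receptor == "RECA"
  expect_true(agg$significant[planted])
  expect_lt(agg$p_perm[planted], 0.001)
  expect_false(any(agg$significant[!planted]))
})
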