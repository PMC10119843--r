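test_that("constant cost gives the independence coupling (outer product)", {
  x <- matrix(0, 4, 2)           # all points identical -> constant cost
  y <- matrix(0, 3, 2)
  a <- c(0.1, 0.2, 0.3, 0.4)
  b <- c(0.5, 0.3, 0.2)
  res <- sinkhorn_couple(x, y, epsilon = 0.7, a = a, b = b)
  expect_equal(res$plan, outer(a, b), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("converged plans satisfy the marginal constraints to 1e-6", {
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(12 * 3), 12, 3)
    y <- matrix(rnorm(9 * 3), 9, 3)
    res <- sinkhorn_couple(x, y)
    expect_true(res$converged)
    expect_lt(max(abs(rowSums(res$plan) - 1 / 12)), 1e-6)
    expect_lt(max(abs(colSums(res$plan) - 1 / 9)), 1e-6)
    expect_true(all(res$plan >= 0))
  }
})

test_that("the epsilon -> 0 limit matches the exact LP (assignment) oracle", {
  set.seed(8)
  for (n in c(3, 4)) {
    x <- matrix(rnorm(n * 2, sd = 2), n, 2)
    y <- matrix(rnorm(n * 2, sd = 2), n, 2)
    cost <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    oracle <- lp_transport_oracle(cost)
    gaps <- vapply(c(0.1, 0.02, 0.004), function(eps) {
      res <<- suppressWarnings(
        sinkhorn_couple(x, y, epsilon = eps, max_iter = 20000L, tol = 1e-10))
      max(abs(res$plan - oracle$plan))
    }, numeric(1))
    expect_lte(gaps[3], gaps[1] + 1e-6)   # shrinking blur approaches the vertex
    expect_lt(gaps[3], 0.01)
    # transported cost converges to the LP optimum
    expect_equal(sum(res$plan * cost), oracle$cost, tolerance = 1e-3)
  }
})

test_that("non-finite embeddings and bad epsilon are rejected", {
  x <- matrix(c(1, NA), 1, 2)
  expect_error(sinkhorn_couple(x, matrix(0, 1, 2)), "non-finite")
  expect_error(sinkhorn_couple(matrix(0, 2, 2), matrix(0, 2, 2), epsilon = 0),
               "epsilon")
  expect_error(sinkhorn_couple(matrix(0, 2, 2), matrix(0, 2, 3)),
               "dimensionality")
})

test_that("coupling cell order permutation permutes plans accordingly", {
  tc <- small_timecourse()
  epi <- subset_cells(tc$cells, tc$cells$meta$cell_type == "EPI")
  emb <- pca_embedding(epi)
  cp1 <- temporal_coupling(epi, embedding = emb)
  perm <- sample(ncol(epi$counts))
  epi2 <- subset_cells(epi, perm)
  cp2 <- temporal_coupling(epi2, embedding = emb[perm, , drop = FALSE])
  for (k in seq_along(cp1$plans)) {
    p1 <- cp1$plans[[k]]
    p2 <- cp2$plans[[k]]
    expect_equal(p2[rownames(p1), colnames(p1)], p1, tolerance = 1e-8)
  }
})

test_that("uniform fate pull-back through symmetric couplings is uniform", {
  # two time points of identical point clouds, fate = every final cell
  pts <- matrix(rnorm(10 * 2), 10, 2,
                dimnames = list(paste0("c", 1:10), NULL))
  cells <- cell_matrix(
    Matrix::Matrix(matrix(1, 3, 20, dimnames = list(
      paste0("g", 1:3), c(paste0("t1_", rownames(pts)), paste0("t2_", rownames(pts))))),
      sparse = TRUE),
    data.frame(barcode = c(paste0("t1_", rownames(pts)),
                           paste0("t2_", rownames(pts))),
               time_point = rep(c("t1", "t2"), each = 10)))
  emb <- rbind(pts, pts)
  rownames(emb) <- cells$meta$barcode
  cp <- temporal_coupling(cells, embedding = emb, epsilon = 1)
  sc <- trajectory_scores(cp, paste0("t2_", rownames(pts)), fate = "all")
  t1 <- sc[sc$time_point == "t1", ]
  expect_equal(t1$score, rep(1 / 10, 10), tolerance = 1e-6)
  # per-time-point normalization contract
  expect_equal(sum(t1$score), 1, tolerance = 1e-9)
  expect_equal(sum(sc$score[sc$time_point == "t2"]), 1, tolerance = 1e-12)
})

test_that("lineage selection is strict at the threshold and can come up empty", {
  sc <- data.frame(barcode = c("a", "b", "c"),
                   time_point = "t1",
                   score = c(1e-4, 2e-4, 0))
  attr(sc, "fate") <- "f"
  expect_equal(select_lineage(sc, threshold = 1e-4), "b")  # strictly greater
  expect_warning(sel <- select_lineage(sc, threshold = 1), "no cells")
  expect_length(sel, 0L)
})

test_that("fate probabilities are normalized, disjointness enforced", {
  traj <- default_trajectories()
  expect_error(fate_probabilities(traj$coupling,
                                  list(a = traj$fate_sets$proximal,
                                       b = traj$fate_sets$proximal)),
               "overlap")
  probs <- fate_probabilities(traj$coupling, traj$fate_sets)
  ok <- !probs$flagged
  expect_true(all(abs(probs$proximal[ok] + probs$distal[ok] - 1) < 1e-9))
})

test_that("well-separated fates put >= 10x score on aligned ancestors", {
  traj <- default_trajectories()
  epi <- traj$epi
  for (f in c("proximal", "distal")) {
    sc <- traj$scores[[f]]
    early <- sc[sc$time_point != traj$final_t, ]
    fate_of <- setNames(epi$meta$fate, epi$meta$barcode)
    aligned <- mean(early$score[fate_of[early$barcode] == f])
    other <- mean(early$score[fate_of[early$barcode] != f])
    expect_gt(aligned, 10 * other)
  }
})

test_that("degenerate couplings are reported as errors", {
  plans <- list(matrix(c(1, 0, 0, 0), 2, 2,
                       dimnames = list(c("a1", "a2"), c("b1", "b2"))))
  cp <- structure(list(times = c("t1", "t2"), plans = plans,
                       diagnostics = list(list()),
                       cells_by_time = list(c("a1", "a2"), c("b1", "b2"))),
                  class = "temporal_coupling")
  expect_error(trajectory_scores(cp, "b2", fate = "f"), "degenerate coupling")
})
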