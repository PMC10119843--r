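options(pdniche.verbose = FALSE)

# small configuration for unit tests: same structure, desk-scale sizes
small_config <- function(...) {
  sim_config(cells_per_time = 60L, grid_shape = c(10L, 10L), seed = 7L, ...)
}

# memoised fixtures so expensive objects are built once per test run
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_timecourse <- function() {
  memo("small_tc", function() generate_timecourse(small_config()))
}

small_spatial <- function() {
  memo("small_sp", function() {
    tc <- small_timecourse()
    generate_spatial(small_config(), tc$truth, tc$cells)
  })
}

# the default-scale dataset of the parameter-recovery checks (seed 7)
default_dataset <- function() {
  memo("default_ds", function() {
    cfg <- sim_config()
    tc <- generate_timecourse(cfg)
    sp <- generate_spatial(cfg, tc$truth, tc$cells)
    list(config = cfg, cells = tc$cells, truth = sp$truth,
         section = sp$section, mapping = sp$mapping)
  })
}

# epithelial coupling + per-fate trajectory scores on the default dataset
default_trajectories <- function() {
  memo("default_traj", function() {
    ds <- default_dataset()
    epi <- subset_cells(ds$cells, ds$cells$meta$cell_type == "EPI")
    coupling <- suppressWarnings(temporal_coupling(epi))
    final_t <- ds$config$time_labels[ds$config$n_time_points]
    fate_sets <- lapply(c(proximal = "proximal", distal = "distal"),
                        function(f) {
                          epi$meta$barcode[epi$meta$time_point == final_t &
                                             epi$meta$fate == f]
                        })
    scores <- lapply(names(fate_sets), function(f) {
      trajectory_scores(coupling, fate_sets[[f]], fate = f)
    })
    names(scores) <- names(fate_sets)
    list(epi = epi, coupling = coupling, fate_sets = fate_sets,
         scores = scores, final_t = final_t)
  })
}

# independent brute-force oracle: step recovery curve integrated by
# explicit enumeration (kept deliberately naive)
auc_oracle <- function(expr_vec, targets, top_fraction, tie_key) {
  n <- length(expr_vec)
  k_max <- ceiling(top_fraction * n)
  ord <- order(-expr_vec, tie_key)
  hits <- 0
  acc <- 0
  in_top <- character(0)
  for (k in seq_len(k_max)) {
    in_top <- c(in_top, names(expr_vec)[ord[k]])
    hits <- sum(targets %in% in_top)
    acc <- acc + hits
  }
  best <- 0
  m <- min(length(targets), k_max)
  for (k in seq_len(k_max)) best <- best + min(k, m)
  if (best == 0) 0 else acc / best
}

# brute-force Moran's I by the literal double sum with row-normalized
# binary weights
moran_oracle <- function(values, neighbors) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    ki <- length(neighbors[[i]])
    if (ki == 0) next
    for (j in neighbors[[i]]) {
      num <- num + (1 / ki) * z[i] * z[j]
      s0 <- s0 + 1 / ki
    }
  }
  (n / s0) * num / sum(z^2)
}

# exact optimal transport for uniform marginals on an n x n cost matrix:
# assignment problem solved by enumerating all permutations
lp_transport_oracle <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 5)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  plan <- matrix(0, n, n)
  plan[cbind(seq_len(n), best)] <- 1 / n
  list(plan = plan, cost = best_cost / n)
}
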