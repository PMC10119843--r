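#' Run the full synthetic analysis pipeline
#'
#' Chains every stage on one generated dataset: simulation, regulon
#' filtering and AUC activity, temporal OT on the epithelial subset with
#' trajectory scores / lineage selection / fate probabilities,
#' trajectory-weighted fate activity profiles and TF ranking, the global
#' permutation ligand-receptor test with provider connectivity, spot QC,
#' composition, Moran's I SVG selection and adjacency scores, neighbor-spot
#' constrained ligand-receptor scoring, and the cross-species TF
#' conservation classifier. All randomness flows from `config$seed`;
#' outputs are deterministic CSV tables plus a JSON summary.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory for result tables (`NULL` = don't write).
#' @param n_perm permutations for both ligand-receptor tests (default 1000).
#' @param min_spot_genes spot QC threshold used on the synthetic section
#'   (default 300; the conventional 2000 presumes a transcriptome-wide
#'   panel, not the simulated 500-gene universe).
#' @param lineage_threshold trajectory-score cutoff (default 1e-4).
#' @return Invisibly, a list with every stage result and a `summary` list
#'   of headline metrics.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         n_perm = 1000L, min_spot_genes = 300L,
                         lineage_threshold = 1e-4) {
  tc <- generate_timecourse(config)
  cells <- tc$cells
  sp <- generate_spatial(config, tc$truth, cells)
  truth <- sp$truth

  # regulon activity
  regulons <- generate_regulons(config)
  kept <- filter_regulons(regulons, nes_min = 1)
  activity_kept <- auc_activity(cells, kept)
  activity_all <- auc_activity(cells, regulons)

  # temporal OT on the epithelial subset
  epi <- subset_cells(cells, cells$meta$cell_type == "EPI")
  coupling <- temporal_coupling(epi)
  final_t <- config$time_labels[config$n_time_points]
  fate_sets <- lapply(c(proximal = "proximal", distal = "distal"), function(f) {
    epi$meta$barcode[epi$meta$time_point == final_t & epi$meta$fate == f]
  })
  scores <- lapply(names(fate_sets), function(f) {
    trajectory_scores(coupling, fate_sets[[f]], fate = f)
  })
  names(scores) <- names(fate_sets)
  lineages <- lapply(scores, select_lineage, threshold = lineage_threshold)
  probs <- fate_probabilities(coupling, fate_sets)

  lineage_metrics <- do.call(rbind, lapply(names(scores), function(f) {
    sc <- scores[[f]]
    early <- sc[sc$time_point != final_t, ]
    truth_set <- epi$meta$barcode[epi$meta$fate == f &
                                    epi$meta$time_point != final_t]
    sel <- intersect(lineages[[f]], early$barcode)
    data.frame(fate = f,
               precision = if (length(sel)) mean(sel %in% truth_set) else NA,
               recall = mean(truth_set %in% sel),
               jaccard = length(intersect(sel, truth_set)) /
                 length(union(sel, truth_set)),
               stringsAsFactors = FALSE)
  }))
  fate_lab <- setNames(epi$meta$fate, epi$meta$barcode)
  fate_auroc <- auroc(probs$proximal[!probs$flagged],
                      fate_lab[probs$barcode[!probs$flagged]] == "proximal")

  # fate-specific TF ranking
  profiles <- lapply(scores, function(sc) weighted_activity(activity_all, sc))
  ranked <- rank_fate_tfs(unname(profiles))

  # global ligand-receptor interactome
  db <- generate_lr_database(config)
  interactions <- lr_permutation_test(cells, db, n_perm = n_perm,
                                      seed = config$seed + 500L)
  stromal <- grep("^SC_", unique(cells$meta$cell_type), value = TRUE)
  connectivity <- connectivity_summary(interactions, providers = stromal,
                                       recipients = "EPI", cells = cells)

  # spatial niche
  section <- filter_spots(sp$section, min_genes = min_spot_genes)
  kept_spots <- section$positions$barcode
  mapping <- sp$mapping[, kept_spots, drop = FALSE]
  live <- rowSums(mapping) > 0
  mapping <- sweep(mapping[live, , drop = FALSE], 1L,
                   rowSums(mapping[live, , drop = FALSE]), "/")
  comp_labels <- composition_labels(cells$meta[live, ])
  composition <- spot_proportions(mapping, comp_labels)
  moran <- morans_i_all(section)
  svgs <- select_svgs(section, stats = moran)
  adjacency <- adjacency_scores(composition, section)

  # neighbor-spot constrained ligand-receptor scoring
  placement <- assign_cells(mapping)
  spatial_cells <- subset_cells(cells, which(live))
  spatial_lr <- neighborhood_lr(placement, section, spatial_cells, db,
                                provider_type = "SC_niche",
                                recipient_type = "EPI",
                                n_perm = n_perm, seed = config$seed + 600L)

  # cross-species TF conservation
  species <- simulate_species_tf_data(seed = config$seed + 700L)
  hd <- differential_direction(species$human, "proximal", "distal",
                               species$tf_genes)
  md <- differential_direction(species$mouse, "proximal", "distal",
                               species$tf_genes_mouse)
  conservation <- classify_conservation(hd, md, species$orthology)

  summary <- list(
    n_cells = ncol(cells$counts), n_genes = nrow(cells$counts),
    n_spots = ncol(section$counts),
    n_regulons_kept = length(kept),
    lineage_metrics = lineage_metrics,
    fate_auroc = fate_auroc,
    n_significant_interactions = sum(interactions$significant),
    n_svgs = length(svgs),
    seed = config$seed
  )
  res <- list(config = config, cells = cells, truth = truth,
              regulons = regulons, activity = activity_all,
              coupling = coupling, trajectory_scores = scores,
              lineages = lineages, fate_probabilities = probs,
              lineage_metrics = lineage_metrics, fate_auroc = fate_auroc,
              profiles = profiles, ranked_tfs = ranked,
              lr_database = db, interactions = interactions,
              connectivity = connectivity,
              section = section, mapping = mapping,
              composition = composition, moran = moran, svgs = svgs,
              adjacency = adjacency, placement = placement,
              spatial_lr = spatial_lr, conservation = conservation,
              summary = summary)
  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir)
  invisible(res)
}

# deterministic CSV/JSON writers for the pipeline result
write_pipeline_tables <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  traj <- do.call(rbind, lapply(names(res$trajectory_scores), function(f) {
    cbind(fate = f, res$trajectory_scores[[f]])
  }))
  w(traj, "trajectory_scores.csv")
  w(res$fate_probabilities, "fate_probabilities.csv")
  w(res$lineage_metrics, "lineage_metrics.csv")
  w(res$ranked_tfs, "ranked_tfs.csv")
  w(as.data.frame(res$interactions), "interactions.csv")
  w(res$connectivity, "connectivity.csv")
  comp <- data.frame(barcode = rownames(res$composition), res$composition,
                     check.names = FALSE)
  w(comp, "spot_composition.csv")
  writeLines(res$svgs, file.path(out_dir, "svgs.txt"))
  w(as.data.frame(res$adjacency), "adjacency.csv")
  w(res$placement[, c("barcode", "spot")], "placement.csv")
  w(res$spatial_lr$aggregated, "spatial_interactions.csv")
  w(res$spatial_lr$per_spot, "spatial_interactions_per_spot.csv")
  w(as.data.frame(res$conservation), "conservation.csv")
  prof <- do.call(rbind, lapply(res$profiles, function(p) {
    data.frame(fate = p$fate, tf = rownames(p$profile), p$profile,
               check.names = FALSE)
  }))
  w(prof, "fate_activity_profiles.csv")
  s <- res$summary
  s$lineage_metrics <- NULL
  jsonlite::write_json(c(s, as.list(res$lineage_metrics)),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(out_dir)
}
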