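# Spatially constrained ligand-receptor scoring: recipients in each spot,
# providers drawn from the neighboring spots.
source("analysis/00_config.R")

ds <- load_dataset()
section <- filter_spots(ds$section, min_genes = 300)
mapping <- ds$mapping[, section$positions$barcode, drop = FALSE]
mapping <- sweep(mapping, 1L, rowSums(mapping), "/")
placement <- assign_cells(mapping)
write.csv(placement[, c("barcode", "spot")],
          file.path(scratch_dir, "placement.csv"), row.names = FALSE)

db <- generate_lr_database(cfg)
res <- neighborhood_lr(placement, section, ds$cells, db,
                       provider_type = "SC_niche", recipient_type = "EPI",
                       n_perm = 1000, seed = cfg$seed + 600L)
write.csv(res$aggregated, file.path(results_dir, "07_spatial_interactions.csv"),
          row.names = FALSE)
write.csv(res$per_spot, file.path(scratch_dir, "spatial_lr_per_spot.csv"),
          row.names = FALSE)

agg <- res$aggregated
cat(sprintf("Scored %d pairs over %d recipient spots with providers nearby.\n",
            nrow(agg), agg$n_spots_used[1]))
print(agg[order(agg$p_perm), c("ligand", "receptor", "score", "z", "p_perm",
                               "significant")][1:5, ], row.names = FALSE)
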