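# Global ligand-receptor interactome with the 1000-permutation null and
# the stromal-provider connectivity summary toward the epithelium.
source("analysis/00_config.R")

ds <- load_dataset()
db <- generate_lr_database(cfg)
cat(sprintf("Ligand-receptor database: %d pairs (%d planted).\n",
            nrow(db), length(cfg$planted_lr_pairs)))

inter <- lr_permutation_test(ds$cells, db, n_perm = 1000,
                             seed = cfg$seed + 500L)
write.csv(inter, file.path(results_dir, "05_interactions.csv"),
          row.names = FALSE)

stromal <- grep("^SC_", unique(ds$cells$meta$cell_type), value = TRUE)
conn <- connectivity_summary(inter, providers = stromal, recipients = "EPI",
                             cells = ds$cells)
write.csv(conn, file.path(results_dir, "05_connectivity.csv"),
          row.names = FALSE)

sig <- inter[inter$significant & !inter$autocrine, ]
cat(sprintf("%d significant heterotypic interactions at p < 0.001.\n",
            nrow(sig)))
cat("Stromal connectivity toward the epithelium:\n")
print(conn, row.names = FALSE)
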