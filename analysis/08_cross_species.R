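# Cross-species TF conservation: per-species differential direction
# (t-test, p < 0.01) joined through one-to-one orthology into the five
# conservation categories (plus "unclassified").
source("analysis/00_config.R")

species <- simulate_species_tf_data(seed = cfg$seed + 700L)
hd <- differential_direction(species$human, "proximal", "distal",
                             species$tf_genes)
md <- differential_direction(species$mouse, "proximal", "distal",
                             species$tf_genes_mouse)
cons <- classify_conservation(hd, md, species$orthology)
cons$planted_category <- species$truth$category[match(cons$tf,
                                                      species$truth$tf)]
write.csv(cons, file.path(results_dir, "08_conservation.csv"),
          row.names = FALSE)

cat("Category counts:\n")
print(table(cons$category))
cat(sprintf("Planted categories recovered: %.0f%%.\n",
            100 * mean(cons$category == cons$planted_category,
                       na.rm = TRUE)))
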