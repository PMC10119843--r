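# Spot QC, composition from the mapping matrix, Moran's I spatially
# variable genes, and the epithelium adjacency score.
source("analysis/00_config.R")

ds <- load_dataset()
section <- filter_spots(ds$section, min_genes = 300)
mapping <- ds$mapping[, section$positions$barcode, drop = FALSE]
mapping <- sweep(mapping, 1L, rowSums(mapping), "/")
composition <- spot_proportions(mapping, composition_labels(ds$cells$meta))
write.csv(data.frame(barcode = rownames(composition), round(composition, 5)),
          file.path(scratch_dir, "spot_composition.csv"), row.names = FALSE)

stats <- morans_i_all(section)
svgs <- select_svgs(section, stats = stats)
writeLines(svgs, file.path(results_dir, "06_svgs.txt"))
cat(sprintf("%d spatially variable genes (|I| > 0.05) of %d.\n",
            length(svgs), nrow(section$counts)))
cat(sprintf("Planted patterned genes selected: %.0f%%; decoys rejected: %.0f%%.\n",
            100 * mean(ds$truth$patterned_genes %in% svgs),
            100 * mean(!(ds$truth$decoy_genes %in% svgs))))

adjacency <- adjacency_scores(composition, section)
write.csv(adjacency, file.path(results_dir, "06_adjacency.csv"),
          row.names = FALSE)
for (rg in c("proximal", "distal")) {
  sub <- adjacency[adjacency$region == rg & adjacency$share > 0, ]
  sub <- sub[order(-sub$share), ]
  cat(sprintf("%s-associated spots, top types: %s\n", rg,
              paste(sprintf("%s %.2f", sub$cell_type, sub$share)[1:3],
                    collapse = ", ")))
}
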