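# Shared settings for the numbered analysis scripts. Run each script from
# the repository root, e.g.  Rscript analysis/01_simulate.R
library(pdniche)
options(pdniche.verbose = TRUE)

cfg <- sim_config(seed = 7L)          # the study-default synthetic design
results_dir <- "results"
scratch_dir <- "scratch/analysis"     # large per-cell tables live here
dir.create(results_dir, showWarnings = FALSE)
dir.create(scratch_dir, showWarnings = FALSE, recursive = TRUE)

# every script regenerates its inputs deterministically from `cfg`; no
# intermediate files are required between scripts
load_dataset <- function() {
  tc <- generate_timecourse(cfg)
  sp <- generate_spatial(cfg, tc$truth, tc$cells)
  list(cells = tc$cells, truth = sp$truth, section = sp$section,
       mapping = sp$mapping)
}

epithelial_trajectories <- function(cells) {
  epi <- subset_cells(cells, cells$meta$cell_type == "EPI")
  coupling <- suppressWarnings(temporal_coupling(epi))
  final_t <- cfg$time_labels[cfg$n_time_points]
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
}
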