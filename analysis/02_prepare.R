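#!/usr/bin/env Rscript
## Step 2 — pairwise Sorensen similarity within basins, network covariates,
## the network/Euclidean ratio filter, the covariate correlation screen and
## the model design table.
library(riverddcs)

cfg <- read_config("analysis/config.yml")
data_dir <- file.path(cfg$out_dir, "data")
out <- file.path(cfg$out_dir, "prepared")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sites <- read_sites(file.path(data_dir, "sites.csv"))
comm <- read_community(file.path(data_dir, "community_wide.csv"), "wide")
networks <- lapply(setNames(nm = as.character(unique(sites$basin_id))),
  function(b) read_network(
    file.path(data_dir, sprintf("network_basin%s_edges.csv", b)),
    file.path(data_dir, sprintf("network_basin%s_nodes.csv", b))))

sim <- pairwise_sorensen(comm, setNames(sites$basin_id,
                                        as.character(sites$site_id)))
pairs <- build_pairs(sites, networks, sim)
filtered <- ratio_filter(pairs, threshold = cfg$prepare$ratio_threshold)
frep <- filter_report(filtered)
cat(sprintf("ratio filter: %d dyads -> %d retained (%d excluded, %d with zero Euclidean distance)\n",
            frep$n_before, frep$n_after, frep$n_excluded,
            frep$n_zero_euclidean))

scr <- covariate_screen(filtered, threshold = cfg$prepare$correlation_threshold)
print(scr)

design <- build_design(filtered)
write_pairs(filtered, file.path(out, "pairs.csv"))
write_design(design, file.path(out, "design.csv"),
             file.path(out, "design_index_maps.json"))
jsonlite::write_json(c(frep, list(
  covariate_max_abs_correlation = scr$max_abs,
  covariates_all_below_threshold = scr$all_below)),
  file.path(out, "filter_report.json"), auto_unbox = TRUE, digits = NA)
cat("design:", design$n_dyads, "dyads,", design$n_sites, "sites,",
    design$n_basins, "basins\n")
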