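## shared fixtures, built in code

## hand-built 7-node drainage tree:
## leaves 1,2 merge at 5; 5 and leaf 3 merge at 6; 6 and leaf 4 merge at
## outlet 7
tiny_network <- function() {
  nodes <- data.frame(id = 1:7,
                      x_km = c(0, 2, 3, 5, 1, 2, 3),
                      y_km = c(4, 4, 3, 2, 3, 2, 1))
  edges <- data.frame(child = c(1, 2, 5, 3, 6, 4),
                      parent = c(5, 5, 6, 6, 7, 7),
                      length_km = c(2, 2, 1.5, 2.5, 2, 3))
  river_network(nodes, edges, outlet = 7)
}

## random binary community matrix with no empty site
random_community <- function(n_sites, n_species, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species,
              dimnames = list(as.character(seq_len(n_sites)),
                              sprintf("sp%03d", seq_len(n_species))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  m
}

## design table over freshly generated basins, with placeholder similarities
## (replace via set_design_response for model-based simulation)
sim_design <- function(n_basins = 2, sites_per_basin = 8, seed = 1,
                       n_leaves = 16, filter = FALSE) {
  gb <- generate_basins(n_basins, sites_per_basin, n_leaves = n_leaves,
                        seed = seed)
  sim <- do.call(rbind, lapply(split(gb$sites, gb$sites$basin_id),
    function(s) {
      cmb <- combn(nrow(s), 2)
      data.frame(site_a = s$site_id[cmb[1, ]], site_b = s$site_id[cmb[2, ]],
                 basin_id = s$basin_id[1], sorensen = 0.5)
    }))
  pairs <- build_pairs(gb$sites, gb$networks, sim)
  if (filter) pairs <- ratio_filter(pairs)
  build_design(pairs)
}

## one small posterior fit shared across test files (computed once)
.fit_cache <- new.env(parent = emptyenv())
cached_small_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache$fit)
  design <- sim_design(n_basins = 2, sites_per_basin = 8, seed = 42)
  truth <- true_parameters(design$n_sites, design$n_basins, seed = 43)
  design <- set_design_response(
    design, simulate_sorensen_from_model(design, truth, seed = 44))
  fit <- fit_ddcs(design, chains = 2, warmup = 400, sampling = 600, seed = 45)
  .fit_cache$fit <- fit
  .fit_cache$design <- design
  .fit_cache$truth <- truth
  fit
}
cached_small_design <- function() {
  cached_small_fit()
  .fit_cache$design
}
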