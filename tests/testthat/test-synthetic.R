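test_that("basin generation book-keeps sites and basins", {
  gb <- generate_basins(n_basins = 11, sites_per_basin = 30, seed = 1)
  expect_length(gb$networks, 11)
  expect_equal(nrow(gb$sites), 330)
  expect_setequal(unique(gb$sites$basin_id), 1:11)
  expect_equal(gb$sites$site_id, 1:330)
  ## sites on distinct nodes within each basin
  for (b in 1:11) {
    s <- gb$sites[gb$sites$basin_id == b, ]
    expect_false(anyDuplicated(s$node_id) > 0)
    expect_true(all(s$node_id %in% gb$networks[[as.character(b)]]$nodes$id))
  }
  expect_true(all(gb$sites$precip_mm >= 0))
  expect_true(all(gb$sites$strahler >= 1))
})

test_that("basin generation is deterministic and validates its arguments", {
  a <- generate_basins(n_basins = 2, sites_per_basin = 5, n_leaves = 8,
                       seed = 2)
  b <- generate_basins(n_basins = 2, sites_per_basin = 5, n_leaves = 8,
                       seed = 2)
  expect_identical(a$sites, b$sites)
  expect_identical(a$networks[[1]]$edges, b$networks[[1]]$edges)
  expect_error(generate_basins(sites_per_basin = 1), ">= 2")
  ## more sites than nodes: 4 leaves -> 7 nodes
  expect_error(generate_basins(n_basins = 1, sites_per_basin = 8,
                               n_leaves = 4, seed = 3), "exceeds")
})

test_that("zero noise makes precipitation exactly linear in coordinates", {
  gb <- generate_basins(n_basins = 3, sites_per_basin = 12, n_leaves = 16,
                        precip_noise_sd = 0,
                        basin_precip_range = c(5000, 6000), seed = 4)
  for (b in 1:3) {
    s <- gb$sites[gb$sites$basin_id == b, ]
    fitlm <- lm(precip_mm ~ x_km + y_km, data = s)
    expect_lt(max(abs(resid(fitlm))), 1e-8)
    ## gradient magnitude equals the configured slope
    expect_equal(sqrt(sum(coef(fitlm)[2:3]^2)), 8, tolerance = 1e-6)
  }
})

test_that("within-basin pairs realise Strahler-difference levels 0..4", {
  gb <- generate_basins(seed = 5)   # default 11 basins x 30 sites
  diffs <- unlist(lapply(split(gb$sites, gb$sites$basin_id), function(s) {
    cmb <- combn(nrow(s), 2)
    abs(s$strahler[cmb[1, ]] - s$strahler[cmb[2, ]])
  }))
  expect_true(all(0:4 %in% diffs))
})

test_that("site spacing can be enforced through min_separation_km", {
  gb <- generate_basins(n_basins = 1, sites_per_basin = 6, n_leaves = 32,
                        min_separation_km = 10, seed = 6)
  s <- gb$sites
  cmb <- combn(6, 2)
  d <- network_distance(gb$networks[["1"]], s$node_id[cmb[1, ]],
                        s$node_id[cmb[2, ]])
  expect_true(all(d >= 10))
})

test_that("saturated occupancy makes every community identical", {
  ## one basin: with a0 large and no decay every species occupies every site
  gb <- generate_basins(n_basins = 1, sites_per_basin = 5, n_leaves = 8,
                        seed = 7)
  comm <- simulate_communities(gb$sites, gb$networks, n_species = 30,
                               a0 = 50, a1 = 0, a2 = 0, seed = 8)
  expect_true(all(comm == 1L))
  ## two basins: species are basin-endemic, but all within-basin pairs are
  ## still identical communities
  gb2 <- generate_basins(n_basins = 2, sites_per_basin = 5, n_leaves = 8,
                         seed = 9)
  comm2 <- simulate_communities(gb2$sites, gb2$networks, n_species = 30,
                                a0 = 50, a1 = 0, a2 = 0, seed = 10)
  sim <- pairwise_sorensen(comm2, setNames(gb2$sites$basin_id,
                                           as.character(gb2$sites$site_id)))
  expect_true(all(sim$sorensen == 1))
})

test_that("extreme dispersal limitation confines species to their cores", {
  gb <- generate_basins(n_basins = 1, sites_per_basin = 10, n_leaves = 32,
                        seed = 9)
  comm <- simulate_communities(gb$sites, gb$networks, n_species = 50,
                               a0 = 2.5, a1 = 100, a2 = 0, seed = 10)
  ## every site still has something, but occupancy is (near) point-wise
  expect_true(all(rowSums(comm) >= 1))
  expect_lt(mean(colSums(comm)), 1.5)
  sim <- pairwise_sorensen(comm, setNames(gb$sites$basin_id,
                                          as.character(gb$sites$site_id)))
  expect_gt(mean(sim$sorensen == 0), 0.8)
})

test_that("moderate occupancy yields distance decay of similarity", {
  gb <- generate_basins(n_basins = 4, sites_per_basin = 15, seed = 11)
  comm <- simulate_communities(gb$sites, gb$networks, seed = 12)
  sim <- pairwise_sorensen(comm, setNames(gb$sites$basin_id,
                                          as.character(gb$sites$site_id)))
  pairs <- build_pairs(gb$sites, gb$networks, sim)
  rho <- cor(pairs$sorensen, pairs$network_distance_km, method = "spearman")
  expect_lt(rho, -0.1)
  ## determinism
  comm2 <- simulate_communities(gb$sites, gb$networks, seed = 12)
  expect_identical(comm, comm2)
})

test_that("plain-text interchange round-trips networks, sites, communities", {
  gb <- generate_basins(n_basins = 1, sites_per_basin = 5, n_leaves = 8,
                        seed = 13)
  net <- gb$networks[["1"]]
  td <- tempdir()
  ef <- file.path(td, "edges.csv"); nf <- file.path(td, "nodes.csv")
  write_network(net, ef, nf)
  back <- read_network(ef, nf)
  expect_equal(back$outlet, net$outlet)
  expect_equal(back$edges$length_km, net$edges$length_km)
  sf <- file.path(td, "sites.csv")
  write_sites(gb$sites, sf)
  expect_equal(read_sites(sf)$precip_mm, gb$sites$precip_mm)
  comm <- simulate_communities(gb$sites, gb$networks, n_species = 12,
                               seed = 14)
  wf <- file.path(td, "comm_wide.csv"); lf <- file.path(td, "comm_long.csv")
  write_community(comm, wf, "wide")
  write_community(comm, lf, "long")
  wide <- read_community(wf, "wide")
  expect_equal(unname(wide), unname(comm))
  long <- read_community(lf, "long")
  ## long format drops all-absent species; compare on the occupied set
  occ <- colnames(comm)[colSums(comm) > 0]
  expect_equal(unname(long[rownames(comm), occ]),
               unname(comm[, occ, drop = FALSE]))
  ## design round-trip
  des <- sim_design(seed = 15)
  cf <- file.path(td, "design.csv"); jf <- file.path(td, "design.json")
  write_design(des, cf, jf)
  back2 <- read_design(cf, jf)
  expect_equal(back2$x_distance, des$x_distance)
  expect_equal(back2$site1, des$site1)
  expect_equal(back2$n_sites, des$n_sites)
  expect_equal(back2$maps$site_ids, des$maps$site_ids)
  unlink(c(ef, nf, sf, wf, lf, cf, jf))
})
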