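## independent oracles -------------------------------------------------------

## recursive post-order Strahler computation
strahler_oracle <- function(net) {
  kids <- split(net$edges$child, net$edges$parent)
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(1L)
    ords <- vapply(ch, rec, integer(1))
    mx <- max(ords)
    if (sum(ords == mx) >= 2L) mx + 1L else mx
  }
  vapply(setNames(net$nodes$id, as.character(net$nodes$id)), rec, integer(1))
}

## set of nodes on the downstream path of v (inclusive)
ancestors_oracle <- function(net, v) {
  p <- setNames(rep(NA_integer_, nrow(net$nodes)), as.character(net$nodes$id))
  p[as.character(net$edges$child)] <- net$edges$parent
  out <- v
  while (!is.na(p[[as.character(v)]])) {
    v <- p[[as.character(v)]]
    out <- c(out, v)
  }
  out
}

igraph_from_net <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$child),
               to = as.character(net$edges$parent),
               weight = net$edges$length_km),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id)))
}

## ---------------------------------------------------------------------------

test_that("Strahler order follows the merge rules on a hand-built tree", {
  net <- tiny_network()
  ord <- strahler_orders(net)
  ## two order-1 headwaters merging -> order 2
  expect_equal(unname(ord["5"]), 2L)
  ## order-2 stream joined by an order-1 tributary -> stays order 2
  expect_equal(unname(ord["6"]), 2L)
  expect_equal(unname(ord["7"]), 2L)
  expect_true(all(ord[c("1", "2", "3", "4")] == 1L))
})

test_that("Strahler orders match a recursive oracle on random trees", {
  for (seed in 1:6) {
    net <- generate_network(50, seed = seed)
    expect_identical(strahler_orders(net), strahler_oracle(net))
  }
})

test_that("the outlet carries the network's maximum order", {
  for (seed in 1:5) {
    net <- generate_network(30, seed = 10 + seed)
    ord <- strahler_orders(net)
    expect_equal(unname(ord[as.character(net$outlet)]), max(ord))
  }
})

test_that("network distance handles the trivial path cases", {
  net <- tiny_network()
  expect_equal(network_distance(net, 1, 5), 2)     # single edge
  expect_equal(network_distance(net, 4, 4), 0)     # identical nodes
  expect_equal(network_distance(net, 1, 2), 4)     # via the junction
  expect_equal(network_distance(net, 1, 2), network_distance(net, 2, 1))
  expect_error(network_distance(net, 1, 99), "same network")
})

test_that("network distance equals Dijkstra on the weighted graph", {
  library(igraph)
  for (seed in 1:4) {
    net <- generate_network(40, seed = 20 + seed)
    g <- igraph_from_net(net)
    ids <- net$nodes$id
    set.seed(seed)
    a <- sample(ids, 100, replace = TRUE)
    b <- sample(ids, 100, replace = TRUE)
    want <- mapply(function(x, y)
      igraph::distances(g, as.character(x), as.character(y))[1, 1], a, b)
    expect_equal(network_distance(net, a, b), unname(want), tolerance = 1e-10)
  }
})

test_that("euclidean distance matches the coordinate formula", {
  expect_equal(euclidean_distance(0, 0, 3, 4), 5)
  expect_equal(euclidean_distance(1.3, -2, 1.3, -2), 0)
  set.seed(30)
  xa <- rnorm(100); ya <- rnorm(100); xb <- rnorm(100); yb <- rnorm(100)
  expect_equal(euclidean_distance(xa, ya, xb, yb),
               sqrt((xa - xb)^2 + (ya - yb)^2))
})

test_that("flow connection is ancestor/descendant membership", {
  net <- tiny_network()
  expect_equal(flow_connected(net, 1, 7), 1L)   # outlet downstream of all
  expect_equal(flow_connected(net, 1, 2), 0L)   # sibling headwaters
  expect_equal(flow_connected(net, 5, 1), 1L)   # symmetric
  ## exhaustive check against the ancestor-set oracle on random trees
  for (seed in 1:3) {
    rnet <- generate_network(25, seed = 40 + seed)
    ids <- rnet$nodes$id
    pairs <- t(combn(ids, 2))
    want <- apply(pairs, 1, function(p) {
      as.integer(p[2] %in% ancestors_oracle(rnet, p[1]) ||
                 p[1] %in% ancestors_oracle(rnet, p[2]))
    })
    expect_equal(flow_connected(rnet, pairs[, 1], pairs[, 2]), want)
  }
})

test_that("the ratio filter excludes ratios at or below the threshold", {
  ratios <- c(1.0, 1.5, 2.0, 2.1, 3, 4, 5, 6, 7, 8)
  pairs <- data.frame(
    site_a = 1:10, site_b = 11:20, basin_id = 1, sorensen = 0.5,
    network_distance_km = 10 * ratios, euclidean_distance_km = 10,
    flow_connection = 0L, strahler_difference = 0L,
    precipitation_difference_mm = 0)
  out <- ratio_filter(pairs)
  ## retain strictly above 2: {2.1, 3, 4, 5, 6, 7, 8}
  expect_equal(nrow(out), 7)
  kept <- out$network_distance_km / out$euclidean_distance_km
  expect_false(any(abs(kept - 2) < 1e-12))   # ratio exactly 2 excluded
  expect_true(any(abs(kept - 2.1) < 1e-12))  # ratio 2.1 retained
  rep <- filter_report(out)
  expect_equal(rep$n_before, 10)
  expect_equal(rep$n_after, 7)
  ## idempotence
  out2 <- ratio_filter(out)
  expect_equal(out2[names(pairs)], out[names(pairs)], ignore_attr = TRUE)
  expect_equal(filter_report(out2)$n_after, 7)
})

test_that("coincident coordinates are excluded with a warning", {
  pairs <- data.frame(
    site_a = 1:2, site_b = 3:4, basin_id = 1, sorensen = 0.5,
    network_distance_km = c(30, 5), euclidean_distance_km = c(0, 1),
    flow_connection = 0L, strahler_difference = 0L,
    precipitation_difference_mm = 0)
  expect_warning(out <- ratio_filter(pairs), "zero Euclidean")
  expect_equal(nrow(out), 1)
  expect_equal(filter_report(out)$n_zero_euclidean, 1)
})

test_that("build_pairs populates every covariate of the dyad table", {
  gb <- generate_basins(n_basins = 2, sites_per_basin = 6, n_leaves = 16,
                        seed = 50)
  gb$sites$precip_mm <- seq(500, by = 50, length.out = nrow(gb$sites))
  comm <- random_community(12, 25, seed = 51)
  rownames(comm) <- as.character(gb$sites$site_id)
  sim <- pairwise_sorensen(comm, setNames(gb$sites$basin_id,
                                          as.character(gb$sites$site_id)))
  pairs <- build_pairs(gb$sites, gb$networks, sim)
  ## per-basin combinatorial counts, no cross-basin dyads
  expect_equal(nrow(pairs), 2 * choose(6, 2))
  expect_true(all(table(pairs$basin_id) == choose(6, 2)))
  ## absolute differences
  p1 <- gb$sites$precip_mm[match(pairs$site_a, gb$sites$site_id)]
  p2 <- gb$sites$precip_mm[match(pairs$site_b, gb$sites$site_id)]
  expect_equal(pairs$precipitation_difference_mm, abs(p1 - p2))
  o1 <- gb$sites$strahler[match(pairs$site_a, gb$sites$site_id)]
  o2 <- gb$sites$strahler[match(pairs$site_b, gb$sites$site_id)]
  expect_equal(pairs$strahler_difference, abs(o1 - o2))
  ## meander construction: network dominates Euclidean distance
  expect_true(all(pairs$network_distance_km >=
                  pairs$euclidean_distance_km - 1e-9))
  ## a two-site basin yields exactly one pre-filter pair
  gb2 <- generate_basins(n_basins = 1, sites_per_basin = 2, n_leaves = 4,
                         seed = 52)
  sim2 <- data.frame(site_a = 1, site_b = 2, basin_id = 1, sorensen = 0.4)
  expect_equal(nrow(build_pairs(gb2$sites, gb2$networks, sim2)), 1)
})

test_that("externally supplied Strahler orders override computed ones", {
  gb <- generate_basins(n_basins = 1, sites_per_basin = 4, n_leaves = 8,
                        seed = 53)
  sim <- do.call(rbind, lapply(list(gb$sites), function(s) {
    cmb <- combn(4, 2)
    data.frame(site_a = s$site_id[cmb[1, ]], site_b = s$site_id[cmb[2, ]],
               basin_id = 1, sorensen = 0.5)
  }))
  gb$sites$strahler <- c(1L, 3L, 5L, 7L)      # external values
  pairs <- build_pairs(gb$sites, gb$networks, sim)
  expect_setequal(unique(pairs$strahler_difference), c(2L, 4L, 6L))
})

test_that("flow connection implies a monotone downstream path for one site", {
  net <- generate_network(30, seed = 60)
  ids <- net$nodes$id
  pairs <- t(combn(ids, 2))
  fc <- flow_connected(net, pairs[, 1], pairs[, 2])
  for (k in which(fc == 1L)) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    pa <- ancestors_oracle(net, a); pb <- ancestors_oracle(net, b)
    expect_true(b %in% pa || a %in% pb)   # path direction audit
  }
})

test_that("covariate screen reports correlations and undefined entries", {
  pairs <- data.frame(
    site_a = 1:100, site_b = 101:200, basin_id = 1, sorensen = 0.5,
    network_distance_km = 1:100, euclidean_distance_km = 1,
    flow_connection = rep(0L, 100),          # constant column
    strahler_difference = rep(c(0L, 1L), 50),
    precipitation_difference_mm = (1:100)^1.3)
  scr <- covariate_screen(pairs)
  expect_true(any(scr$undefined))
  expect_true(is.na(scr$all_below))
  ## perfectly correlated pair flagged
  pairs$flow_connection <- pairs$network_distance_km
  scr2 <- covariate_screen(pairs)
  expect_equal(scr2$correlations["network_distance_km", "flow_connection"], 1)
  expect_false(isTRUE(scr2$all_below))
  ## independent columns at n = 5000 pass the 0.27 rule
  set.seed(61)
  ind <- data.frame(
    site_a = 1:5000, site_b = 5001:10000, basin_id = 1, sorensen = 0.5,
    network_distance_km = rnorm(5000), euclidean_distance_km = 1,
    flow_connection = rbinom(5000, 1, 0.3),
    strahler_difference = sample(0:6, 5000, TRUE),
    precipitation_difference_mm = rexp(5000))
  scr3 <- covariate_screen(ind)
  expect_true(scr3$all_below)
  expect_lt(scr3$max_abs, 0.27)
})
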