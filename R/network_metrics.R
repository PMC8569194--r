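## Network covariates: Strahler orders, network / Euclidean distance,
## flow connection, pair assembly, the distance-ratio filter and the
## covariate correlation screen.

#' Strahler stream orders for every node
#'
#' Headwater (leaf) nodes have order 1. A junction's order is the maximum of
#' its tributaries' orders, incremented by one when that maximum is attained
#' by at least two tributaries. Orders are therefore non-decreasing
#' downstream and the outlet carries the network's maximum order.
#'
#' @param net a [river_network()].
#' @return Named integer vector of orders, indexed by node id.
#' @export
strahler_orders <- function(net) {
  stopifnot(inherits(net, "river_network"))
  n <- nrow(net$nodes)
  ids <- net$nodes$id
  kids <- split(net$edges$child, net$edges$parent)
  n_kids <- vapply(as.character(ids), function(k) {
    v <- kids[[k]]; if (is.null(v)) 0L else length(v)
  }, integer(1))
  order_of <- setNames(rep(NA_integer_, n), as.character(ids))
  pending <- n_kids                      # unresolved tributaries per node
  queue <- ids[n_kids == 0L]             # leaves
  order_of[as.character(queue)] <- 1L
  parent <- parent_map(net)
  done <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    done <- done + 1L
    p <- parent[[as.character(v)]]
    if (is.na(p)) next
    pending[as.character(p)] <- pending[as.character(p)] - 1L
    if (pending[as.character(p)] == 0L) {
      ords <- order_of[as.character(kids[[as.character(p)]])]
      mx <- max(ords)
      order_of[as.character(p)] <- mx + as.integer(sum(ords == mx) >= 2L)
      queue <- c(queue, p)
    }
  }
  if (done != n || anyNA(order_of))
    stop("invalid network: could not resolve Strahler orders (cycle?)",
         call. = FALSE)
  setNames(as.integer(order_of), as.character(ids))
}

## distance from every node to the outlet along the drainage path (km)
distance_to_outlet <- function(net) {
  parent <- parent_map(net)
  elen <- edge_length_map(net)
  ids <- as.character(net$nodes$id)
  d <- setNames(rep(NA_real_, length(ids)), ids)
  d[as.character(net$outlet)] <- 0
  for (v in ids) {
    if (!is.na(d[[v]])) next
    path <- character(0)
    u <- v
    while (is.na(d[[u]])) {
      path <- c(path, u)
      u <- as.character(parent[[u]])
    }
    acc <- d[[u]]
    for (w in rev(path)) {
      acc <- acc + elen[[w]]
      d[[w]] <- acc
    }
  }
  d
}

## ordered downstream path (node ids, character) from a node to the outlet,
## inclusive of both endpoints
downstream_path <- function(net, node) {
  parent <- parent_map(net)
  u <- as.character(node)
  path <- u
  while (!is.na(parent[[u]])) {
    u <- as.character(parent[[u]])
    path <- c(path, u)
  }
  path
}

#' Network distance between two sites (km)
#'
#' Sum of edge lengths along the unique tree path between two nodes of the
#' same river network, computed from the downstream distances of both nodes
#' and of their lowest common ancestor on the drainage tree.
#'
#' @param net a [river_network()].
#' @param node_a,node_b node ids on `net`. Vectorised over pairs.
#' @return Numeric vector of path lengths in km (0 for identical nodes).
#' @export
network_distance <- function(net, node_a, node_b) {
  stopifnot(inherits(net, "river_network"))
  ids <- net$nodes$id
  if (!all(node_a %in% ids) || !all(node_b %in% ids))
    stop("both sites must lie on the same network", call. = FALSE)
  d2o <- distance_to_outlet(net)
  anc <- lapply(setNames(as.character(ids), as.character(ids)),
                function(v) downstream_path(net, v))
  mapply(function(a, b) {
    pa <- anc[[as.character(a)]]
    pb <- anc[[as.character(b)]]
    lca <- pa[match(TRUE, pa %in% pb)]
    d2o[[as.character(a)]] + d2o[[as.character(b)]] - 2 * d2o[[lca]]
  }, node_a, node_b, USE.NAMES = FALSE)
}

#' Euclidean (straight-line) distance between two sites (km)
#'
#' @param x_a,y_a,x_b,y_b planar coordinates in km; vectorised.
#' @return Numeric vector of straight-line distances.
#' @export
euclidean_distance <- function(x_a, y_a, x_b, y_b) {
  sqrt((x_a - x_b)^2 + (y_a - y_b)^2)
}

#' Flow connection between two sites
#'
#' Two sites are flow connected (1) when one lies on the other's downstream
#' path to the outlet, i.e. when one node is an ancestor of the other in the
#' drainage tree; otherwise 0.
#'
#' @param net a [river_network()].
#' @param node_a,node_b node ids on `net`; vectorised over pairs.
#' @return Integer vector of 0/1 flags.
#' @export
flow_connected <- function(net, node_a, node_b) {
  stopifnot(inherits(net, "river_network"))
  ids <- net$nodes$id
  if (!all(node_a %in% ids) || !all(node_b %in% ids))
    stop("both sites must lie on the same network", call. = FALSE)
  anc <- lapply(setNames(as.character(ids), as.character(ids)),
                function(v) downstream_path(net, v))
  mapply(function(a, b) {
    as.integer(as.character(b) %in% anc[[as.character(a)]] ||
               as.character(a) %in% anc[[as.character(b)]])
  }, node_a, node_b, USE.NAMES = FALSE)
}

#' Assemble dyadic pair observations with all raw covariates
#'
#' Joins a within-basin Sorensen pair table with the site table and the
#' basin networks, and populates for every dyad the four raw covariates:
#' network distance (km), Euclidean distance (km), flow connection (0/1),
#' absolute Strahler order difference and absolute precipitation difference
#' (mm). When the site table carries a `strahler` column (e.g. orders
#' supplied with the hydrographic database in a real-data workflow) those
#' values are used; otherwise orders are computed from the networks with
#' [strahler_orders()].
#'
#' @param sites data.frame with columns `site_id`, `basin_id`, `node_id`,
#'   `x_km`, `y_km`, `precip_mm` and optionally `strahler`.
#' @param networks named list of [river_network()] objects, one per basin id.
#' @param sim_table pair table from [pairwise_sorensen()] (columns `site_a`,
#'   `site_b`, `basin_id`, `sorensen`).
#' @return data.frame with one row per dyad: `site_a`, `site_b`, `basin_id`,
#'   `sorensen`, `network_distance_km`, `euclidean_distance_km`,
#'   `flow_connection`, `strahler_difference`, `precipitation_difference_mm`.
#' @export
build_pairs <- function(sites, networks, sim_table) {
  need <- c("site_id", "basin_id", "node_id", "x_km", "y_km", "precip_mm")
  if (!all(need %in% names(sites)))
    stop("`sites` is missing columns: ",
         paste(setdiff(need, names(sites)), collapse = ", "), call. = FALSE)
  if (!all(c("site_a", "site_b", "basin_id", "sorensen") %in% names(sim_table)))
    stop("`sim_table` must come from pairwise_sorensen()", call. = FALSE)
  if (!all(sim_table$site_a %in% sites$site_id) ||
      !all(sim_table$site_b %in% sites$site_id))
    stop("similarity table references sites absent from the site table",
         call. = FALSE)
  rownames(sites) <- as.character(sites$site_id)

  has_ext_strahler <- "strahler" %in% names(sites) && !anyNA(sites$strahler)
  out <- vector("list", length(unique(sim_table$basin_id)))
  i <- 0L
  for (b in unique(sim_table$basin_id)) {
    net <- networks[[as.character(b)]]
    if (is.null(net))
      stop("no network supplied for basin ", b, call. = FALSE)
    st <- sim_table[sim_table$basin_id == b, , drop = FALSE]
    sa <- sites[as.character(st$site_a), ]
    sb <- sites[as.character(st$site_b), ]
    ord <- if (has_ext_strahler) NULL else strahler_orders(net)
    o_a <- if (has_ext_strahler) sa$strahler else ord[as.character(sa$node_id)]
    o_b <- if (has_ext_strahler) sb$strahler else ord[as.character(sb$node_id)]
    i <- i + 1L
    out[[i]] <- data.frame(
      site_a = st$site_a, site_b = st$site_b, basin_id = b,
      sorensen = st$sorensen,
      network_distance_km = network_distance(net, sa$node_id, sb$node_id),
      euclidean_distance_km = euclidean_distance(sa$x_km, sa$y_km,
                                                 sb$x_km, sb$y_km),
      flow_connection = flow_connected(net, sa$node_id, sb$node_id),
      strahler_difference = abs(as.integer(o_a) - as.integer(o_b)),
      precipitation_difference_mm = abs(sa$precip_mm - sb$precip_mm),
      row.names = NULL)
  }
  do.call(rbind, out[seq_len(i)])
}

#' Filter dyads by the network/Euclidean distance ratio
#'
#' Network distance only isolates along-network separation when it clearly
#' exceeds the straight-line separation; dyads whose network-to-Euclidean
#' distance ratio is equal to or lower than the threshold (default 2) are
#' excluded, strictly larger ratios are retained. Dyads with zero Euclidean
#' distance (coincident coordinates) have an undefined ratio and are excluded
#' with a warning.
#'
#' @param pairs pair table from [build_pairs()].
#' @param threshold exclusion threshold for the ratio (default 2).
#' @return The retained rows, with a `filter_report` attribute (a list with
#'   `n_before`, `n_after`, `n_excluded`, `n_zero_euclidean`, `threshold`);
#'   see [filter_report()]. Filtering is idempotent.
#' @export
ratio_filter <- function(pairs, threshold = 2) {
  stopifnot(is.data.frame(pairs), threshold > 0)
  n_before <- nrow(pairs)
  zero <- pairs$euclidean_distance_km == 0
  if (any(zero))
    warning(sum(zero), " dyad(s) with zero Euclidean distance excluded: ",
            "distance ratio undefined", call. = FALSE)
  ratio <- pairs$network_distance_km / pairs$euclidean_distance_km
  keep <- !zero & ratio > threshold
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    n_before = n_before, n_after = nrow(out),
    n_excluded = n_before - nrow(out),
    n_zero_euclidean = sum(zero), threshold = threshold)
  out
}

#' Retrieve the book-keeping report of a ratio filter
#'
#' @param pairs output of [ratio_filter()].
#' @return list with counts before/after filtering.
#' @export
filter_report <- function(pairs) {
  rep <- attr(pairs, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run ratio_filter() first",
                         call. = FALSE)
  rep
}

#' Pairwise correlation screen of the dyadic covariates
#'
#' Computes the pairwise Pearson correlation matrix of the four raw
#' covariates (network distance, flow connection, Strahler difference,
#' precipitation difference) and reports whether every off-diagonal absolute
#' correlation lies below the threshold. Constant covariates yield `NA`
#' correlations, reported as undefined rather than as an error.
#'
#' @param pairs pair table from [build_pairs()].
#' @param threshold maximum tolerated absolute pairwise correlation
#'   (default 0.27).
#' @return list with `correlations` (4x4 matrix), `max_abs`, `all_below`
#'   (`NA` when any entry is undefined), `undefined` (logical matrix) and
#'   `threshold`.
#' @export
covariate_screen <- function(pairs, threshold = 0.27) {
  cols <- c("network_distance_km", "flow_connection",
            "strahler_difference", "precipitation_difference_mm")
  if (!all(cols %in% names(pairs)))
    stop("`pairs` must carry the four raw covariates", call. = FALSE)
  x <- as.matrix(pairs[, cols])
  if (nrow(x) < 2) stop("need at least 2 dyads", call. = FALSE)
  cc <- suppressWarnings(stats::cor(x))
  off <- abs(cc[upper.tri(cc)])
  structure(list(
    correlations = cc,
    max_abs = if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE),
    all_below = if (anyNA(off)) NA else all(off < threshold),
    undefined = is.na(cc) & upper.tri(cc),
    threshold = threshold), class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat("covariate correlation screen (threshold", x$threshold, ")\n")
  print(round(x$correlations, 3))
  cat("max |r| =", round(x$max_abs, 3), "; all below threshold:",
      x$all_below, "\n")
  invisible(x)
}
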