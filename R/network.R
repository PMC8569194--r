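## River-network container and synthetic drainage-tree generator.

#' Construct a river network
#'
#' A river network is a rooted drainage tree: every node except the outlet
#' drains into exactly one parent node, and edge lengths are the along-channel
#' distances in kilometres. Nodes carry planar coordinates so that Euclidean
#' (straight-line) distances can be compared with network distances.
#'
#' @param nodes data.frame with columns `id` (integer), `x_km`, `y_km`.
#' @param edges data.frame with columns `child`, `parent` (node ids; the edge
#'   is directed downstream, child -> parent) and `length_km` (> 0).
#' @param outlet id of the outlet node (the only node with no parent).
#' @param validate check the tree invariants (default `TRUE`).
#' @return An object of class `river_network`.
#' @seealso [generate_network()], [validate_river_network()]
#' @export
river_network <- function(nodes, edges, outlet, validate = TRUE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "x_km", "y_km") %in% names(nodes)))
    stop("`nodes` needs columns id, x_km, y_km", call. = FALSE)
  if (!all(c("child", "parent", "length_km") %in% names(edges)))
    stop("`edges` needs columns child, parent, length_km", call. = FALSE)
  net <- structure(
    list(nodes = nodes[, c("id", "x_km", "y_km")],
         edges = edges[, c("child", "parent", "length_km")],
         outlet = outlet),
    class = "river_network")
  if (validate) validate_river_network(net)
  net
}

#' Validate river-network invariants
#'
#' Checks that the graph is a tree (connected, acyclic, edge count = node
#' count - 1), that exactly one node (the outlet) has no outgoing edge, that
#' every other node has exactly one, and that all edge lengths are positive.
#'
#' @param net a [river_network()].
#' @return `net`, invisibly; stops with an informative error on violation.
#' @export
validate_river_network <- function(net) {
  stopifnot(inherits(net, "river_network"))
  ids <- net$nodes$id
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  e <- net$edges
  if (nrow(e) != n - 1L) stop("edge count must equal node count - 1", call. = FALSE)
  if (any(e$length_km <= 0)) stop("all edge lengths must be > 0", call. = FALSE)
  if (!all(c(e$child, e$parent) %in% ids)) stop("edge endpoints must be node ids", call. = FALSE)
  if (anyDuplicated(e$child)) stop("a node drains into more than one parent", call. = FALSE)
  if (!(net$outlet %in% ids)) stop("outlet must be a node id", call. = FALSE)
  if (net$outlet %in% e$child) stop("outlet must have no outgoing edge", call. = FALSE)
  if (!setequal(e$child, setdiff(ids, net$outlet)))
    stop("every non-outlet node needs exactly one outgoing edge", call. = FALSE)
  ## acyclic + connected: walk parents from every node; must reach the outlet
  parent <- parent_map(net)
  for (v in ids) {
    seen <- integer(0)
    u <- v
    while (!is.na(parent[[as.character(u)]])) {
      if (u %in% seen) stop("cycle detected in network", call. = FALSE)
      seen <- c(seen, u)
      u <- parent[[as.character(u)]]
      if (length(seen) > n) stop("cycle detected in network", call. = FALSE)
    }
    if (u != net$outlet) stop("network is not connected to the outlet", call. = FALSE)
  }
  invisible(net)
}

## named lookup: parent id per node (NA for the outlet)
parent_map <- function(net) {
  p <- rep(NA_integer_, nrow(net$nodes))
  names(p) <- as.character(net$nodes$id)
  p[as.character(net$edges$child)] <- net$edges$parent
  p
}

## named lookup: downstream edge length per node (NA for the outlet)
edge_length_map <- function(net) {
  l <- rep(NA_real_, nrow(net$nodes))
  names(l) <- as.character(net$nodes$id)
  l[as.character(net$edges$child)] <- net$edges$length_km
  l
}

#' @export
print.river_network <- function(x, ...) {
  cat("river_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges, outlet node", x$outlet, "\n")
  invisible(x)
}

#' Generate a random dendritic river network
#'
#' Builds a drainage tree by recursive binary merging of headwater branches:
#' starting from `n_leaves` headwater tips, two active tips are repeatedly
#' merged into a new downstream junction until a single tip - the outlet -
#' remains. With probability `balance` the merge picks two tips of equal
#' current Strahler order (when such a pair exists), which controls how fast
#' Strahler orders grow; the remaining merges pick uniformly at random.
#'
#' Edge lengths are Gamma-distributed with the requested mean (shape 3, so
#' strictly positive with moderate variability). Coordinates are laid out from
#' the outlet upstream; each edge's straight-line chord is its channel length
#' divided by a meander factor drawn from `meander_range`, so the chord never
#' exceeds the channel length and network distance dominates Euclidean
#' distance by construction.
#'
#' @param n_leaves number of headwater tips (>= 2).
#' @param mean_edge_length_km mean channel length of one edge (km, > 0).
#' @param balance probability that a merge joins two equal-order tips.
#' @param meander_range range of the per-edge meander factor (>= 1).
#' @param seed optional integer; when supplied the RNG is seeded so the
#'   network is reproducible, otherwise the current RNG stream is used.
#' @return A [river_network()] with `2 * n_leaves - 1` nodes.
#' @examples
#' net <- generate_network(8, seed = 1)
#' net
#' @export
generate_network <- function(n_leaves, mean_edge_length_km = 2,
                             balance = 0.7, meander_range = c(1.2, 1.6),
                             seed = NULL) {
  if (!is.numeric(n_leaves) || n_leaves < 2)
    stop("`n_leaves` must be at least 2", call. = FALSE)
  if (mean_edge_length_km <= 0)
    stop("`mean_edge_length_km` must be > 0", call. = FALSE)
  if (any(meander_range < 1))
    stop("meander factors must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_leaves <- as.integer(n_leaves)

  n_nodes <- 2L * n_leaves - 1L
  active <- seq_len(n_leaves)        # node ids of current tips
  order_of <- rep(1L, n_leaves)      # Strahler order carried by each tip
  child <- integer(n_nodes - 1L)
  parent <- integer(n_nodes - 1L)
  next_id <- n_leaves + 1L
  k <- 0L
  while (length(active) > 1L) {
    pick <- NULL
    if (stats::runif(1) < balance) {
      tab <- table(order_of)
      cand <- as.integer(names(tab)[tab >= 2L])
      if (length(cand)) {
        o <- if (length(cand) == 1L) cand else sample(cand, 1L)
        pool <- which(order_of == o)
        pick <- sample(pool, 2L)
      }
    }
    if (is.null(pick)) pick <- sample(seq_along(active), 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    oa <- order_of[pick[1L]]; ob <- order_of[pick[2L]]
    new <- next_id; next_id <- next_id + 1L
    child[k + 1L] <- a; parent[k + 1L] <- new
    child[k + 2L] <- b; parent[k + 2L] <- new
    k <- k + 2L
    keep <- setdiff(seq_along(active), pick)
    active <- c(active[keep], new)
    order_of <- c(order_of[keep], if (oa == ob) oa + 1L else max(oa, ob))
  }
  outlet <- active

  length_km <- stats::rgamma(n_nodes - 1L, shape = 3,
                             scale = mean_edge_length_km / 3)
  meander <- stats::runif(n_nodes - 1L, meander_range[1], meander_range[2])

  ## coordinates: outlet at origin, children placed upstream within a cone
  x <- numeric(n_nodes); y <- numeric(n_nodes)
  heading <- numeric(n_nodes)
  chord <- length_km / meander
  kids <- split(child, parent)
  heading[outlet] <- pi / 2
  queue <- outlet
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) next
    spread <- seq(-0.6, 0.6, length.out = length(ch)) +
      stats::runif(length(ch), -0.35, 0.35)
    for (j in seq_along(ch)) {
      u <- ch[j]
      heading[u] <- heading[v] + spread[j]
      eidx <- which(child == u)
      x[u] <- x[v] + chord[eidx] * cos(heading[u])
      y[u] <- y[v] + chord[eidx] * sin(heading[u])
      queue <- c(queue, u)
    }
  }

  river_network(
    nodes = data.frame(id = seq_len(n_nodes), x_km = x, y_km = y),
    edges = data.frame(child = child, parent = parent, length_km = length_km),
    outlet = outlet)
}
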