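## Plain-text interchange: CSV tables, JSON sidecars, provenance and YAML
## configuration.

#' Write / read a river network as CSV
#'
#' The network is stored as two tables: an edge list
#' (`child_id, parent_id, length_km`) and a node table (`id, x_km, y_km`).
#' The outlet is recoverable as the node absent from the child column.
#'
#' @param net a [river_network()].
#' @param edges_file,nodes_file CSV paths.
#' @return `write_network`: the paths, invisibly. `read_network`: a
#'   [river_network()].
#' @export
write_network <- function(net, edges_file, nodes_file) {
  stopifnot(inherits(net, "river_network"))
  e <- net$edges
  names(e) <- c("child_id", "parent_id", "length_km")
  write.csv(e, edges_file, row.names = FALSE)
  write.csv(net$nodes, nodes_file, row.names = FALSE)
  invisible(c(edges_file, nodes_file))
}

#' @rdname write_network
#' @export
read_network <- function(edges_file, nodes_file) {
  e <- read.csv(edges_file)
  nodes <- read.csv(nodes_file)
  outlet <- setdiff(nodes$id, e$child_id)
  if (length(outlet) != 1)
    stop("network file does not define a unique outlet", call. = FALSE)
  river_network(nodes,
                data.frame(child = e$child_id, parent = e$parent_id,
                           length_km = e$length_km),
                outlet)
}

#' Write / read the site table as CSV
#'
#' @param sites site table ([generate_basins()] layout).
#' @param file CSV path.
#' @export
write_sites <- function(sites, file) {
  write.csv(sites, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sites
#' @export
read_sites <- function(file) read.csv(file)

#' Write / read a presence/absence community table
#'
#' Two interchange formats are supported: `wide` (one row per site, one 0/1
#' column per species, site ids in the first column) and `long` (one row per
#' occurrence: `site_id, species_id`).
#'
#' @param comm binary site x species matrix (site ids as rownames).
#' @param file CSV path.
#' @param format `"wide"` or `"long"`.
#' @export
write_community <- function(comm, file, format = c("wide", "long")) {
  format <- match.arg(format)
  comm <- as.matrix(comm)
  if (format == "wide") {
    df <- data.frame(site_id = rownames(comm), comm, check.names = FALSE)
    write.csv(df, file, row.names = FALSE)
  } else {
    idx <- which(comm > 0, arr.ind = TRUE)
    df <- data.frame(site_id = rownames(comm)[idx[, 1]],
                     species_id = colnames(comm)[idx[, 2]])
    df <- df[order(df$site_id, df$species_id), ]
    write.csv(df, file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_community
#' @export
read_community <- function(file, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- read.csv(file, check.names = FALSE)
  if (format == "wide") {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "integer"
    m
  } else {
    sites <- sort(unique(as.character(df$site_id)))
    species <- sort(unique(as.character(df$species_id)))
    m <- matrix(0L, length(sites), length(species),
                dimnames = list(sites, species))
    m[cbind(match(as.character(df$site_id), sites),
            match(as.character(df$species_id), species))] <- 1L
    m
  }
}

#' Write / read the dyadic pair table as CSV
#'
#' Column order is documented and stable: `site_a, site_b, basin_id,
#' sorensen, network_distance_km, euclidean_distance_km, flow_connection,
#' strahler_difference, precipitation_difference_mm`.
#'
#' @param pairs pair table ([build_pairs()] layout).
#' @param file CSV path.
#' @export
write_pairs <- function(pairs, file) {
  cols <- c("site_a", "site_b", "basin_id", "sorensen",
            "network_distance_km", "euclidean_distance_km",
            "flow_connection", "strahler_difference",
            "precipitation_difference_mm")
  write.csv(pairs[, cols], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(file) read.csv(file)

#' Write a design table as CSV plus a JSON sidecar with the index maps
#'
#' @param design a [build_design()] object.
#' @param csv_file CSV path for the per-dyad columns.
#' @param json_file JSON path for the index maps and dimensions.
#' @export
write_design <- function(design, csv_file, json_file) {
  stopifnot(inherits(design, "ddcs_design"))
  df <- data.frame(x_distance = design$x_distance, x_precip = design$x_precip,
                   flow = design$flow, strahler_level = design$strahler_level,
                   site1 = design$site1, site2 = design$site2,
                   basin = design$basin, y = design$y)
  write.csv(df, csv_file, row.names = FALSE)
  jsonlite::write_json(
    list(n_dyads = design$n_dyads, n_sites = design$n_sites,
         n_basins = design$n_basins, n_strahler = design$n_strahler,
         site_ids = design$maps$site_ids,
         basin_ids = design$maps$basin_ids,
         baseline_km = design$maps$baseline_km,
         baseline_mm = design$maps$baseline_mm),
    json_file, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_file, json_file))
}

#' @rdname write_design
#' @export
read_design <- function(csv_file, json_file) {
  df <- read.csv(csv_file)
  meta <- jsonlite::read_json(json_file, simplifyVector = TRUE)
  structure(list(
    x_distance = df$x_distance, x_precip = df$x_precip, flow = df$flow,
    strahler_level = as.integer(df$strahler_level),
    site1 = as.integer(df$site1), site2 = as.integer(df$site2),
    basin = as.integer(df$basin), y = df$y,
    n_dyads = nrow(df), n_sites = as.integer(meta$n_sites),
    n_basins = as.integer(meta$n_basins),
    n_strahler = as.integer(meta$n_strahler),
    maps = list(site_ids = as.character(meta$site_ids),
                basin_ids = meta$basin_ids,
                baseline_km = meta$baseline_km,
                baseline_mm = meta$baseline_mm)),
    class = "ddcs_design")
}

#' Write posterior draws as a tidy CSV
#'
#' One row per (chain, iteration, parameter) triple.
#'
#' @param fit a [fit_ddcs()] object.
#' @param file CSV path.
#' @export
write_draws <- function(fit, file) {
  stopifnot(inherits(fit, "ddcs_fit"))
  S <- fit$config$sampling; C <- fit$config$chains
  pn <- fit$parameters
  df <- data.frame(
    chain = rep(seq_len(C), each = S * length(pn)),
    iteration = rep(rep(seq_len(S), each = length(pn)), C),
    parameter = rep(pn, S * C),
    value = as.numeric(aperm(fit$draws, c(3, 1, 2))))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_draws
#' @export
read_draws <- function(file) read.csv(file)

#' Write a provenance record (seed, configuration) as JSON
#'
#' @param file JSON path.
#' @param seed the master seed of the run.
#' @param config any JSON-serialisable configuration list.
#' @export
write_provenance <- function(file, seed, config = list()) {
  jsonlite::write_json(
    list(package = "riverddcs",
         version = as.character(utils::packageVersion("riverddcs")),
         seed = seed, config = config,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a YAML run configuration
#'
#' Thin wrapper used by the analysis drivers; requires the `yaml` package.
#'
#' @param file YAML path.
#' @return Named list of settings.
#' @export
read_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read configuration files",
         call. = FALSE)
  yaml::read_yaml(file)
}
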