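## Covariate transforms and index structures feeding the hierarchical model.

#' Transform a network distance to model scale
#'
#' Centres the distance at a 100 km baseline and scales by 100 km:
#' `(d - 100) / 100`. One transformed unit therefore corresponds to 100 km of
#' network distance, and 0 to the baseline itself.
#'
#' @param d_km network distance in km (>= 0), vectorised.
#' @param baseline_km baseline distance (default 100 km).
#' @return Unitless transformed distances.
#' @export
transform_distance <- function(d_km, baseline_km = 100) {
  if (any(d_km < 0)) stop("distances must be >= 0", call. = FALSE)
  (d_km - baseline_km) / baseline_km
}

#' Transform a precipitation difference to model scale
#'
#' Log-transforms with `log(x + 1)` (precipitation differences are skewed),
#' then centres at a 300 mm baseline and scales by the same constant:
#' `(log(dp + 1) - log(301)) / log(301)`. The exact constant `log(301)`
#' (~5.707, commonly printed as 5.71) is used. 300 mm is a typical minimum
#' annual precipitation for Mediterranean climates. The transform is strictly
#' increasing and maps 0 mm to -1 and 300 mm to 0.
#'
#' @param dp_mm precipitation difference in mm (>= 0), vectorised.
#' @param baseline_mm baseline difference (default 300 mm).
#' @return Unitless transformed differences.
#' @export
transform_precip <- function(dp_mm, baseline_mm = 300) {
  if (any(dp_mm < 0)) stop("precipitation differences must be >= 0", call. = FALSE)
  k <- log(baseline_mm + 1)
  (log1p(dp_mm) - k) / k
}

#' Build the model design table from dyadic pair observations
#'
#' Applies the covariate transforms and converts identifiers to the
#' contiguous integer indices the likelihood uses: site ids to `1..S` (in
#' increasing id order, shared across basins), basin ids to `1..B`, and
#' Strahler order differences to the levels `1..n_strahler_levels` (a
#' difference of `d` maps to level `d + 1`). Differences beyond the top level
#' are clamped there with a warning. Sorensen values are carried through
#' unchanged; boundary handling (values at exactly 0 or 1) is the fitting
#' function's responsibility.
#'
#' @param pairs pair table from [build_pairs()] (typically after
#'   [ratio_filter()]).
#' @param n_strahler_levels number of Strahler-difference levels (default 7,
#'   i.e. differences 0..6).
#' @param baseline_km,baseline_mm transform baselines, see
#'   [transform_distance()] and [transform_precip()].
#' @return An object of class `ddcs_design`: a list with numeric vectors
#'   `x_distance`, `x_precip`, `flow`, `y`, integer vectors `strahler_level`,
#'   `site1`, `site2`, `basin`, the dimensions `n_dyads`, `n_sites`,
#'   `n_basins`, `n_strahler`, and `maps` (site and basin id lookups for
#'   decoding indices back to ids).
#' @export
build_design <- function(pairs, n_strahler_levels = 7,
                         baseline_km = 100, baseline_mm = 300) {
  need <- c("site_a", "site_b", "basin_id", "sorensen", "network_distance_km",
            "flow_connection", "strahler_difference",
            "precipitation_difference_mm")
  if (!all(need %in% names(pairs)))
    stop("`pairs` is missing columns: ",
         paste(setdiff(need, names(pairs)), collapse = ", "), call. = FALSE)
  if (nrow(pairs) == 0) stop("no dyads to build a design from", call. = FALSE)

  site_ids <- sort(unique(c(as.character(pairs$site_a),
                            as.character(pairs$site_b))))
  num <- suppressWarnings(as.numeric(site_ids))
  if (!anyNA(num)) site_ids <- site_ids[order(num)]
  basin_ids <- sort(unique(pairs$basin_id))
  site_index <- setNames(seq_along(site_ids), site_ids)
  basin_index <- setNames(seq_along(basin_ids), as.character(basin_ids))

  sdiff <- as.integer(pairs$strahler_difference)
  if (any(sdiff < 0)) stop("Strahler differences must be >= 0", call. = FALSE)
  top <- n_strahler_levels - 1L
  if (any(sdiff > top)) {
    warning(sum(sdiff > top), " dyad(s) with Strahler difference > ", top,
            " clamped to the top level", call. = FALSE)
    sdiff <- pmin(sdiff, top)
  }

  s1 <- unname(site_index[as.character(pairs$site_a)])
  s2 <- unname(site_index[as.character(pairs$site_b)])
  if (any(s1 == s2)) stop("a dyad must involve two distinct sites", call. = FALSE)

  structure(list(
    x_distance = transform_distance(pairs$network_distance_km, baseline_km),
    x_precip = transform_precip(pairs$precipitation_difference_mm, baseline_mm),
    flow = as.numeric(pairs$flow_connection),
    strahler_level = sdiff + 1L,
    site1 = s1, site2 = s2,
    basin = unname(basin_index[as.character(pairs$basin_id)]),
    y = pairs$sorensen,
    n_dyads = nrow(pairs),
    n_sites = length(site_ids),
    n_basins = length(basin_ids),
    n_strahler = as.integer(n_strahler_levels),
    maps = list(site_ids = site_ids, basin_ids = basin_ids,
                baseline_km = baseline_km, baseline_mm = baseline_mm)),
    class = "ddcs_design")
}

#' @export
print.ddcs_design <- function(x, ...) {
  cat("ddcs_design:", x$n_dyads, "dyads,", x$n_sites, "sites,",
      x$n_basins, "basins,", x$n_strahler, "Strahler levels\n")
  invisible(x)
}

#' Replace the response vector of a design
#'
#' Convenience for simulation studies: keep the covariates and index
#' structure but swap in a new vector of similarities.
#'
#' @param design a [build_design()] object.
#' @param y replacement similarities, same length as `design$y`.
#' @return The design with `y` replaced.
#' @export
set_design_response <- function(design, y) {
  stopifnot(inherits(design, "ddcs_design"), length(y) == design$n_dyads)
  design$y <- as.numeric(y)
  design
}
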