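## Sorensen similarity between within-basin site pairs.

#' Sorensen similarity index from pairwise species counts
#'
#' Incidence-based similarity between two communities,
#' `2a / (2a + b + c)`, where `a` is the number of species shared by both
#' sites and `b`, `c` are the numbers of species unique to each site. It is
#' the number of shared species divided by the average species richness:
#' 1 means identical composition, 0 means no shared species.
#'
#' @param a,b,c non-negative species counts (vectorised).
#' @return Similarities in `[0, 1]`.
#' @export
sorensen_index <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0))
    stop("species counts must be non-negative", call. = FALSE)
  if (any(a + b == 0 | a + c == 0))
    stop("similarity undefined: at least one empty community", call. = FALSE)
  2 * a / (2 * a + b + c)
}

#' Sorensen similarity for all within-basin site pairs
#'
#' Emits every unordered pair of sites belonging to the same basin exactly
#' once (n(n-1)/2 pairs for a basin with n sites), with the dyad's first and
#' second roles assigned canonically by increasing site id; the index is
#' symmetric so the roles only fix a reproducible output order. Cross-basin
#' pairs are never formed. Abundance data are binarised (> 0 means present).
#'
#' @param comm community matrix: sites in rows (rownames = site ids), species
#'   in columns, non-negative entries.
#' @param basin_of named vector mapping site id to basin id, or a data.frame
#'   with columns `site_id` and `basin_id`.
#' @return data.frame with columns `site_a`, `site_b`, `basin_id`, `sorensen`.
#' @export
pairwise_sorensen <- function(comm, basin_of) {
  comm <- as.matrix(comm)
  if (is.null(rownames(comm)))
    stop("community matrix needs site ids as rownames", call. = FALSE)
  if (any(comm < 0)) stop("negative abundances are not allowed", call. = FALSE)
  x <- (comm > 0) * 1L
  if (any(rowSums(x) == 0))
    stop("every site must have at least one present species", call. = FALSE)
  if (is.data.frame(basin_of)) {
    if (!all(c("site_id", "basin_id") %in% names(basin_of)))
      stop("`basin_of` data.frame needs site_id and basin_id", call. = FALSE)
    basin_of <- setNames(basin_of$basin_id, as.character(basin_of$site_id))
  }
  sites <- rownames(x)
  if (!all(sites %in% names(basin_of)))
    stop("sites without a basin assignment: ",
         paste(head(setdiff(sites, names(basin_of))), collapse = ", "),
         call. = FALSE)
  basins <- basin_of[sites]
  out <- list(); k <- 0L
  for (b in unique(basins)) {
    members <- sites[basins == b]
    members <- members[order(suppressWarnings(as.numeric(members)), members)]
    if (length(members) < 2) next
    m <- x[members, , drop = FALSE]
    shared <- tcrossprod(m)              # a for every pair
    rich <- rowSums(m)
    idx <- which(upper.tri(shared), arr.ind = TRUE)
    a <- shared[idx]
    bb <- rich[idx[, 1]] - a
    cc <- rich[idx[, 2]] - a
    k <- k + 1L
    out[[k]] <- data.frame(
      site_a = members[idx[, 1]], site_b = members[idx[, 2]],
      basin_id = b, sorensen = sorensen_index(a, bb, cc),
      row.names = NULL)
  }
  if (k == 0L)
    return(data.frame(site_a = character(0), site_b = character(0),
                      basin_id = character(0), sorensen = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
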