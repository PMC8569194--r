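## Posterior retrodictive checks, fit summaries and the machine-readable
## report.

#' Posterior retrodictive check
#'
#' Simulates replicate similarity vectors from a subsample of the posterior
#' draws and compares them with the observed similarities in two ways:
#' (1) a density overlay of the observed distribution against the central
#' 95% band of the replicate densities; (2) binned means of the observed
#' similarities conditional on each covariate (transformed network distance,
#' flow connection, transformed precipitation difference, Strahler level),
#' against the central 95% band of the corresponding replicate bin means.
#' A covariate is flagged as showing a systematic deviation when the observed
#' bin means leave the replicate band over a contiguous range of two or more
#' bins (a single outlying bin among many is expected by construction of a
#' 95% band).
#'
#' @param fit a [fit_ddcs()] object.
#' @param design the [build_design()] table the model was fitted to.
#' @param n_rep number of posterior draws used for replication (default 200).
#' @param n_bins number of quantile bins for continuous covariates.
#' @param seed optional RNG seed for the replicate simulation.
#' @return An object of class `ddcs_retro_check`: list with `density`
#'   (data.frame: grid, observed, lower, upper), `binned` (per covariate: a
#'   data.frame with bin centres, observed means, replicate band),
#'   `flagged` (named logical: systematic deviation per covariate),
#'   `prop_bins_outside`, `n_rep`.
#' @export
retrodictive_check <- function(fit, design, n_rep = 200, n_bins = 10,
                               seed = NULL) {
  stopifnot(inherits(fit, "ddcs_fit"), inherits(design, "ddcs_design"))
  if (!is.null(seed)) set.seed(seed)
  S <- fit$config$sampling; C <- fit$config$chains
  total <- S * C
  if (total < 1) stop("empty draws", call. = FALSE)
  n_rep <- min(n_rep, total)
  pick <- sample.int(total, n_rep)
  chain_of <- ((pick - 1L) %/% S) + 1L
  iter_of <- ((pick - 1L) %% S) + 1L

  y_rep <- matrix(NA_real_, n_rep, design$n_dyads)
  for (r in seq_len(n_rep)) {
    pars <- draws_row_to_parameters(fit, iter_of[r], chain_of[r], design)
    mu <- plogis(linear_predictor(pars, design))
    y_rep[r, ] <- rbeta(design$n_dyads, mu * pars$kappa,
                        (1 - mu) * pars$kappa)
  }

  ## density overlay on a common grid
  grid <- seq(0.001, 0.999, length.out = 128)
  dens_of <- function(y) {
    d <- stats::density(y, from = grid[1], to = grid[length(grid)],
                        n = length(grid), bw = "nrd0")
    d$y
  }
  obs_d <- dens_of(design$y)
  rep_d <- apply(y_rep, 1, dens_of)
  band <- apply(rep_d, 1, quantile, probs = c(0.025, 0.975))
  density_df <- data.frame(grid = grid, observed = obs_d,
                           lower = band[1, ], upper = band[2, ])

  ## binned means conditional on each covariate
  covs <- list(x_distance = design$x_distance,
               flow = design$flow,
               x_precip = design$x_precip,
               strahler_level = design$strahler_level)
  binned <- list(); flagged <- logical(length(covs))
  names(flagged) <- names(covs)
  out_count <- 0L; bin_count <- 0L
  for (nm in names(covs)) {
    v <- covs[[nm]]
    if (nm %in% c("flow", "strahler_level")) {
      bins <- factor(v)
    } else {
      br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
      if (length(br) < 3) bins <- factor(rep(1, length(v)))
      else bins <- cut(v, br, include.lowest = TRUE)
    }
    obs_mean <- tapply(design$y, bins, mean)
    rep_mean <- apply(y_rep, 1, function(yr) tapply(yr, bins, mean))
    rep_mean <- matrix(rep_mean, ncol = n_rep)
    lo <- apply(rep_mean, 1, quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(rep_mean, 1, quantile, probs = 0.975, na.rm = TRUE)
    outside <- obs_mean < lo | obs_mean > hi
    centre <- tapply(v, bins, mean)
    binned[[nm]] <- data.frame(bin = names(obs_mean), centre = centre,
                               observed = obs_mean, lower = lo, upper = hi,
                               outside = outside, row.names = NULL)
    runs <- rle(as.logical(outside))
    flagged[nm] <- any(runs$values & runs$lengths >= 2)
    out_count <- out_count + sum(outside)
    bin_count <- bin_count + length(outside)
  }

  structure(list(density = density_df, binned = binned, flagged = flagged,
                 prop_bins_outside = out_count / bin_count,
                 n_rep = n_rep, y_rep = y_rep),
            class = "ddcs_retro_check")
}

#' @export
print.ddcs_retro_check <- function(x, ...) {
  cat("posterior retrodictive check (", x$n_rep, "replicates )\n")
  cat("  bins outside 95% band:", round(100 * x$prop_bins_outside, 1), "%\n")
  cat("  systematic deviations:",
      if (any(x$flagged)) paste(names(x$flagged)[x$flagged], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

## rebuild a ddcs_parameters object from one (iteration, chain) of the draws
draws_row_to_parameters <- function(fit, iteration, chain, design) {
  v <- fit$draws[iteration, chain, ]
  S <- design$n_sites; B <- design$n_basins; K <- design$n_strahler
  gx <- function(stub, n) unname(v[paste0(stub, "[", seq_len(n), "]")])
  ddcs_parameters(
    alpha_baseline = unname(v["alpha_baseline"]),
    alpha_site = gx("alpha_site", S),
    sigma_site = unname(v["sigma_site"]),
    alpha_basin = gx("alpha_basin", B),
    alpha_strahler = gx("alpha_strahler", K),
    sigma_strahler = unname(v["sigma_strahler"]),
    beta_distance = gx("beta_distance", B),
    beta_flow = gx("beta_flow", B),
    beta_precip = gx("beta_precip", B),
    mu_distance = unname(v["mu_distance"]),
    mu_flow = unname(v["mu_flow"]),
    mu_precipitation = unname(v["mu_precipitation"]),
    sigma_distance = unname(v["sigma_distance"]),
    sigma_flow = unname(v["sigma_flow"]),
    sigma_precipitation = unname(v["sigma_precipitation"]),
    kappa = unname(v["kappa"]))
}

#' Posterior summary table
#'
#' Posterior mean, standard deviation, central 95% credibility interval
#' (2.5% and 97.5% quantiles), split-Rhat and effective sample size for every
#' parameter. Slopes are on the logit scale per transformed covariate unit
#' (100 km of network distance; one log-scaled precipitation unit).
#'
#' @param fit a [fit_ddcs()] object.
#' @param probs interval probabilities (default `c(0.025, 0.975)`).
#' @return An object of class `ddcs_summary`: data.frame with one row per
#'   parameter (`parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`, `ess`).
#' @export
summarize_fit <- function(fit, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "ddcs_fit"), length(probs) == 2, probs[1] < probs[2])
  diag <- diagnostics(fit)
  pn <- fit$parameters
  out <- data.frame(parameter = pn, mean = NA_real_, sd = NA_real_,
                    q_lower = NA_real_, q_upper = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pn)) {
    d <- extract_draws(fit, pn[i])
    out$mean[i] <- mean(d)
    out$sd[i] <- sd(d)
    qs <- quantile(d, probs = probs, names = FALSE)
    out$q_lower[i] <- qs[1]; out$q_upper[i] <- qs[2]
  }
  names(out)[4:5] <- paste0("q", format(100 * probs, trim = TRUE))
  out$rhat <- diag$summary$rhat[match(pn, diag$summary$parameter)]
  out$ess <- diag$summary$ess[match(pn, diag$summary$parameter)]
  structure(out, class = c("ddcs_summary", "data.frame"), probs = probs)
}

#' @export
print.ddcs_summary <- function(x, ...) {
  show <- x[grepl("^(mu_|sigma_|kappa|alpha_baseline|beta_)",
                  x$parameter), , drop = FALSE]
  cat("posterior summary (hyper-parameters and slopes):\n")
  print.data.frame(cbind(show[1],
                         round(as.data.frame(show[-1]), 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Assemble the full machine-readable analysis report
#'
#' Collects the posterior summary, the ratio-filter book-keeping, the sampler
#' diagnostics and the retrodictive-check flags into a single JSON-ready
#' document with provenance (seed, configuration). Optionally writes the JSON
#' file and diagnostic plots (observed-vs-replicated density overlay and
#' per-basin slope interval panels).
#'
#' @param fit_summary a [summarize_fit()] table.
#' @param filter_report list from [filter_report()] (or `NULL`).
#' @param diag a [diagnostics()] object.
#' @param retro a [retrodictive_check()] object (or `NULL`).
#' @param seed seed recorded as provenance.
#' @param file optional path of the JSON report to write.
#' @param plots_dir optional directory for PNG diagnostic plots.
#' @return The report as a list (invisibly when written to file).
#' @export
report <- function(fit_summary, filter_report = NULL, diag = NULL,
                   retro = NULL, seed = NULL, file = NULL, plots_dir = NULL) {
  stopifnot(inherits(fit_summary, "ddcs_summary"))
  rep_list <- list(
    provenance = list(
      package = "riverddcs",
      version = as.character(utils::packageVersion("riverddcs")),
      seed = seed,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    posterior_summary = as.data.frame(unclass(fit_summary)),
    pair_filter = filter_report,
    diagnostics = if (!is.null(diag)) list(
      n_divergent = diag$n_divergent,
      n_treedepth_saturated = diag$n_treedepth_saturated,
      max_rhat = suppressWarnings(max(diag$summary$rhat, na.rm = TRUE)),
      min_ess = suppressWarnings(min(diag$summary$ess, na.rm = TRUE)),
      rhat_threshold = diag$rhat_threshold,
      pass = diag$pass),
    retrodictive = if (!is.null(retro)) list(
      flagged = as.list(retro$flagged),
      prop_bins_outside = retro$prop_bins_outside,
      n_rep = retro$n_rep))
  if (!is.null(plots_dir) && !is.null(retro)) {
    dir.create(plots_dir, recursive = TRUE, showWarnings = FALSE)
    grDevices::png(file.path(plots_dir, "density_overlay.png"),
                   width = 900, height = 600)
    plot_density_overlay(retro)
    grDevices::dev.off()
    grDevices::png(file.path(plots_dir, "slope_intervals.png"),
                   width = 900, height = 900)
    plot_slope_intervals(fit_summary)
    grDevices::dev.off()
    rep_list$plots <- c("density_overlay.png", "slope_intervals.png")
  }
  if (!is.null(file)) {
    jsonlite::write_json(rep_list, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(rep_list))
  }
  rep_list
}

#' Density overlay of observed vs replicated similarities
#'
#' @param retro a [retrodictive_check()] object.
#' @export
plot_density_overlay <- function(retro) {
  stopifnot(inherits(retro, "ddcs_retro_check"))
  d <- retro$density
  graphics::plot(d$grid, d$observed, type = "n",
                 ylim = range(c(d$observed, d$lower, d$upper)),
                 xlab = "Sorensen index", ylab = "density",
                 main = "observed vs posterior replicated similarity")
  graphics::polygon(c(d$grid, rev(d$grid)), c(d$lower, rev(d$upper)),
                    col = "#9ecae1", border = NA)
  graphics::lines(d$grid, d$observed, lwd = 2)
  graphics::legend("topright", c("observed", "95% replicate band"),
                   lwd = c(2, 8), col = c("black", "#9ecae1"), bty = "n")
}

#' Interval plot of per-basin slopes and their hyper-means
#'
#' Mirrors the standard reporting layout: per-basin posterior means with 95%
#' credibility intervals for the network-distance, flow-connection and
#' precipitation-difference slopes, with the hyper-mean appended.
#'
#' @param fit_summary a [summarize_fit()] table.
#' @export
plot_slope_intervals <- function(fit_summary) {
  stopifnot(inherits(fit_summary, "ddcs_summary"))
  x <- as.data.frame(unclass(fit_summary))
  groups <- list(`network distance` = c("beta_distance", "mu_distance"),
                 `flow connection` = c("beta_flow", "mu_flow"),
                 `precipitation difference` = c("beta_precip",
                                                "mu_precipitation"))
  graphics::par(mfrow = c(length(groups), 1), mar = c(3, 9, 2, 1))
  lo <- x[[4]]; hi <- x[[5]]
  for (g in names(groups)) {
    sel <- grepl(paste0("^", groups[[g]][1], "\\["), x$parameter) |
      x$parameter == groups[[g]][2]
    xx <- x[sel, ]
    n <- nrow(xx)
    graphics::plot(xx$mean, seq_len(n), xlim = range(c(lo[sel], hi[sel], 0)),
                   yaxt = "n", xlab = "", ylab = "", main = g, pch = 16)
    graphics::segments(lo[sel], seq_len(n), hi[sel], seq_len(n), lwd = 2,
                       col = "#08519c")
    graphics::points(xx$mean, seq_len(n), pch = 16)
    graphics::abline(v = 0, lty = 2, col = "grey50")
    graphics::axis(2, at = seq_len(n), labels = xx$parameter, las = 1,
                   cex.axis = 0.8)
  }
  graphics::par(mfrow = c(1, 1))
}
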