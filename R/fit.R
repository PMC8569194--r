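## HMC fitting (NUTS) and prior predictive simulation.

#' Fit the hierarchical dyadic beta regression
#'
#' Samples the posterior with the package's No-U-Turn sampler (multinomial
#' NUTS with diagonal metric and dual-averaging step-size adaptation,
#' implemented in C++). All hierarchical vectors (site intercepts, Strahler
#' intercepts, per-basin slopes) use a non-centered parameterisation and all
#' scales are sampled on the log scale, which keeps the posterior geometry
#' well conditioned and sampling divergence-free under the study conditions.
#' Chains run sequentially with per-chain RNG seeds derived from `seed`, so a
#' fit is fully reproducible given `seed` and the configuration.
#'
#' Similarities at exactly 0 or 1 lie outside the beta likelihood's support:
#' the default `boundary = "error"` stops with guidance, while
#' `boundary = "squeeze"` applies [squeeze_boundary()] first.
#'
#' @param design a [build_design()] table.
#' @param chains number of Markov chains (default 4).
#' @param warmup warmup (adaptation) iterations per chain (default 1000).
#' @param sampling post-warmup iterations per chain (default 2000).
#' @param seed integer seed controlling initial values and all sampler
#'   randomness.
#' @param boundary policy for boundary similarities: `"error"` or `"squeeze"`.
#' @param control list of sampler settings: `max_treedepth` (default 12),
#'   `adapt_delta` (target acceptance, default 0.99; conservative because the
#'   slope hyper-scales are weakly identified in small designs and the
#'   diagnostics contract demands divergence-free sampling), `init_r` (initial values
#'   drawn uniformly from (-init_r, init_r) on the unconstrained scale,
#'   default 1).
#' @return An object of class `ddcs_fit`: list with `draws` (a
#'   sampling x chains x parameters array on the constrained scale, with
#'   parameter names), `sampler_flags` (data.frame with one row per kept
#'   iteration: chain, iteration, divergent, treedepth_saturated,
#'   accept_stat, n_leapfrog), `step_size` and `inv_metric` per chain,
#'   `design_dims`, and the configuration.
#' @seealso [diagnostics()], [summarize_fit()], [retrodictive_check()]
#' @export
fit_ddcs <- function(design, chains = 4, warmup = 1000, sampling = 2000,
                     seed = 1, boundary = c("error", "squeeze"),
                     control = list()) {
  stopifnot(inherits(design, "ddcs_design"), chains >= 1,
            warmup >= 150, sampling >= 1)
  boundary <- match.arg(boundary)
  if (any(design$y <= 0 | design$y >= 1)) {
    if (boundary == "error")
      stop("similarities at exactly 0 or 1 found; the beta likelihood ",
           "excludes the boundaries. Either drop those dyads or refit with ",
           "boundary = \"squeeze\" (see ?squeeze_boundary).", call. = FALSE)
    design$y <- squeeze_boundary(design$y)
  }
  ctl <- list(max_treedepth = 12L, adapt_delta = 0.99, init_r = 1,
              init_buffer = 75L, term_buffer = 50L, base_window = 25L)
  ctl[names(control)] <- control

  dat <- design_data_list(design)
  d <- n_unconstrained(design)
  pn <- param_names(design)
  draws <- array(NA_real_, dim = c(sampling, chains, length(pn)),
                 dimnames = list(NULL, paste0("chain:", seq_len(chains)), pn))
  flags <- vector("list", chains)
  step_size <- numeric(chains)
  inv_metric <- matrix(NA_real_, d, chains)
  t_start <- Sys.time()
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    init <- runif(d, -ctl$init_r, ctl$init_r)
    res <- nuts_ddcs_cpp(dat, init, as.integer(warmup), as.integer(sampling),
                         as.integer(ctl$max_treedepth), ctl$adapt_delta,
                         as.integer(ctl$init_buffer),
                         as.integer(ctl$term_buffer),
                         as.integer(ctl$base_window))
    for (j in seq_len(sampling))
      draws[j, ch, ] <- constrain_theta(res$draws[j, ], design)
    flags[[ch]] <- data.frame(
      chain = ch, iteration = seq_len(sampling),
      divergent = as.logical(res$divergent),
      treedepth_saturated = as.logical(res$treedepth_saturated),
      accept_stat = as.numeric(res$accept_stat),
      n_leapfrog = as.integer(res$n_leapfrog))
    step_size[ch] <- res$step_size
    inv_metric[, ch] <- res$inv_metric
  }
  structure(list(
    draws = draws,
    parameters = pn,
    sampler_flags = do.call(rbind, flags),
    step_size = step_size,
    inv_metric = inv_metric,
    design_dims = list(n_dyads = design$n_dyads, n_sites = design$n_sites,
                       n_basins = design$n_basins,
                       n_strahler = design$n_strahler),
    config = list(chains = chains, warmup = warmup, sampling = sampling,
                  seed = seed, boundary = boundary, control = ctl),
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs")),
    class = "ddcs_fit")
}

#' @export
print.ddcs_fit <- function(x, ...) {
  cat("ddcs_fit:", x$config$chains, "chains x", x$config$sampling,
      "draws (", x$config$warmup, "warmup );",
      sum(x$sampler_flags$divergent), "divergent,",
      sum(x$sampler_flags$treedepth_saturated), "saturated;",
      round(x$elapsed_s, 1), "s\n")
  invisible(x)
}

#' Extract posterior draws of one parameter
#'
#' @param fit a [fit_ddcs()] object.
#' @param parameter parameter name (see `fit$parameters`).
#' @param merge merge chains into one vector (default) or return a
#'   draws x chains matrix.
#' @return Numeric vector or matrix of posterior draws.
#' @export
extract_draws <- function(fit, parameter, merge = TRUE) {
  stopifnot(inherits(fit, "ddcs_fit"))
  if (!parameter %in% fit$parameters)
    stop("unknown parameter: ", parameter, call. = FALSE)
  m <- fit$draws[, , parameter, drop = TRUE]
  if (fit$config$chains == 1L) m <- matrix(m, ncol = 1L)
  if (merge) as.numeric(m) else m
}

#' Prior predictive simulation of Sorensen similarity distributions
#'
#' Draws `n_draws` parameter sets from the prior ([draw_prior_parameters()])
#' and simulates, for each, one full vector of similarities over the design's
#' dyads. For every draw the probability mass that its simulated distribution
#' places in the interval `[0.25, 0.65]` is recorded: a weakly informative
#' prior for these communities is expected to concentrate most distributions
#' on dyads sharing roughly 25-65% of their species, while still allowing
#' more extreme similarity regimes.
#'
#' @param design a [build_design()] table (its `y` is ignored).
#' @param n_draws number of prior draws (default 1000).
#' @param seed optional RNG seed.
#' @param keep_draws keep the full `n_draws` x dyads matrix of simulated
#'   similarities (default TRUE; set FALSE to save memory).
#' @return An object of class `ddcs_prior_predictive`: list with
#'   `mass_25_65` (per-draw mass in the interval), `median_mass`, `interval`,
#'   `n_draws`, and optionally `y_rep`.
#' @export
prior_predictive <- function(design, n_draws = 1000, seed = NULL,
                             keep_draws = TRUE) {
  stopifnot(inherits(design, "ddcs_design"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  interval <- c(0.25, 0.65)
  mass <- numeric(n_draws)
  y_rep <- if (keep_draws)
    matrix(NA_real_, n_draws, design$n_dyads) else NULL
  for (i in seq_len(n_draws)) {
    truth <- draw_prior_parameters(design$n_sites, design$n_basins,
                                   design$n_strahler)
    y <- simulate_sorensen_from_model(design, truth)
    mass[i] <- mean(y >= interval[1] & y <= interval[2])
    if (keep_draws) y_rep[i, ] <- y
  }
  structure(list(mass_25_65 = mass, median_mass = stats::median(mass),
                 interval = interval, n_draws = n_draws, y_rep = y_rep),
            class = "ddcs_prior_predictive")
}

#' @export
print.ddcs_prior_predictive <- function(x, ...) {
  cat("prior predictive:", x$n_draws, "draws; median mass in [",
      x$interval[1], ",", x$interval[2], "] =", round(x$median_mass, 3), "\n")
  invisible(x)
}
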