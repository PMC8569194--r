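## Simulation-based calibration of the sampler + model pipeline.

#' Simulation-based calibration ranks
#'
#' Repeats, `n_iterations` times: draw a full parameter set from the prior,
#' simulate similarities over the design, fit the model, and record the rank
#' of each true parameter among `n_ranks` (approximately independent, evenly
#' thinned) posterior draws. When the sampler targets the correct posterior,
#' every rank is uniform on `0..n_ranks`; departures expose bias in the
#' sampler or an inconsistency between the generator and the likelihood.
#'
#' @param design a [build_design()] template (its responses are replaced at
#'   every iteration).
#' @param n_iterations number of calibration iterations.
#' @param parameters parameters whose ranks are tracked.
#' @param n_ranks posterior draws kept per iteration (ranks run `0..n_ranks`).
#' @param chains,warmup,sampling fit configuration per iteration (kept small:
#'   each iteration is one full MCMC run).
#' @param seed master seed.
#' @return An object of class `ddcs_sbc`: list with `ranks` (an
#'   `n_iterations` x `length(parameters)` matrix), `n_ranks`, and
#'   `uniformity` (per-parameter chi-squared p-values over `n_bins` rank
#'   bins).
#' @param n_bins bins for the uniformity chi-squared test (must divide
#'   `n_ranks + 1`).
#' @export
sbc_run <- function(design, n_iterations = 200,
                    parameters = c("mu_distance", "sigma_site", "kappa"),
                    n_ranks = 19, chains = 1, warmup = 500, sampling = 500,
                    n_bins = 5, seed = 1) {
  stopifnot(inherits(design, "ddcs_design"), n_iterations >= 10,
            (n_ranks + 1) %% n_bins == 0)
  ranks <- matrix(NA_integer_, n_iterations, length(parameters),
                  dimnames = list(NULL, parameters))
  set.seed(seed)
  iter_seeds <- sample.int(2^30, 2 * n_iterations)
  for (it in seq_len(n_iterations)) {
    truth <- draw_prior_parameters(design$n_sites, design$n_basins,
                                   design$n_strahler,
                                   seed = iter_seeds[2 * it - 1])
    des <- set_design_response(design,
                               simulate_sorensen_from_model(design, truth))
    fit <- fit_ddcs(des, chains = chains, warmup = warmup,
                    sampling = sampling, seed = iter_seeds[2 * it])
    keep <- round(seq(1, sampling * chains, length.out = n_ranks))
    for (j in seq_along(parameters)) {
      d <- extract_draws(fit, parameters[j])[keep]
      ranks[it, j] <- sum(d < truth[[parameters[j]]])
    }
  }
  uniformity <- apply(ranks, 2, function(r) {
    bins <- table(factor(r %/% ((n_ranks + 1) / n_bins),
                         levels = 0:(n_bins - 1)))
    suppressWarnings(stats::chisq.test(bins)$p.value)
  })
  structure(list(ranks = ranks, n_ranks = n_ranks, n_bins = n_bins,
                 uniformity = uniformity, n_iterations = n_iterations),
            class = "ddcs_sbc")
}

#' @export
print.ddcs_sbc <- function(x, ...) {
  cat("simulation-based calibration:", x$n_iterations, "iterations,",
      "ranks 0..", x$n_ranks, "\n")
  cat("  uniformity p-values:",
      paste(names(x$uniformity), round(x$uniformity, 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
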