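## Model parameters, likelihood pieces, and simulation from the model.

#' Construct a full parameter set for the dyadic beta regression
#'
#' Holds one draw of every model parameter: the global intercept, site and
#' basin and Strahler-level varying intercepts with their scales, per-basin
#' slopes for network distance, flow connection and precipitation difference
#' with their hyper-means and hyper-scales, and the beta concentration
#' ("sample size") kappa.
#'
#' @param alpha_baseline global intercept (logit scale).
#' @param alpha_site site intercepts (length = number of sites).
#' @param sigma_site scale of the site intercepts (> 0).
#' @param alpha_basin basin intercepts (length = number of basins).
#' @param alpha_strahler Strahler-difference level intercepts.
#' @param sigma_strahler scale of the Strahler intercepts (> 0).
#' @param beta_distance,beta_flow,beta_precip per-basin slopes.
#' @param mu_distance,mu_flow,mu_precipitation slope hyper-means.
#' @param sigma_distance,sigma_flow,sigma_precipitation slope hyper-scales (> 0).
#' @param kappa beta concentration (> 0).
#' @return An object of class `ddcs_parameters`.
#' @export
ddcs_parameters <- function(alpha_baseline, alpha_site, sigma_site,
                            alpha_basin, alpha_strahler, sigma_strahler,
                            beta_distance, beta_flow, beta_precip,
                            mu_distance, mu_flow, mu_precipitation,
                            sigma_distance, sigma_flow, sigma_precipitation,
                            kappa) {
  p <- list(alpha_baseline = alpha_baseline, alpha_site = alpha_site,
            sigma_site = sigma_site, alpha_basin = alpha_basin,
            alpha_strahler = alpha_strahler, sigma_strahler = sigma_strahler,
            beta_distance = beta_distance, beta_flow = beta_flow,
            beta_precip = beta_precip, mu_distance = mu_distance,
            mu_flow = mu_flow, mu_precipitation = mu_precipitation,
            sigma_distance = sigma_distance, sigma_flow = sigma_flow,
            sigma_precipitation = sigma_precipitation, kappa = kappa)
  validate_parameters(p)
  structure(p, class = "ddcs_parameters")
}

#' Validate model-parameter invariants
#'
#' All scale parameters and kappa must be strictly positive, and the
#' per-basin slope vectors must have equal lengths.
#'
#' @param p a parameter list.
#' @return `p`, invisibly.
#' @export
validate_parameters <- function(p) {
  scales <- c(p$sigma_site, p$sigma_strahler, p$sigma_distance,
              p$sigma_flow, p$sigma_precipitation, p$kappa)
  if (any(scales <= 0))
    stop("all scale parameters and kappa must be strictly positive",
         call. = FALSE)
  nb <- lengths(p[c("alpha_basin", "beta_distance", "beta_flow", "beta_precip")])
  if (length(unique(nb)) != 1)
    stop("basin-indexed vectors must have equal lengths", call. = FALSE)
  invisible(p)
}

#' Linear predictor of the dyadic beta regression (logit scale)
#'
#' For each dyad: baseline + site intercepts of both communities + basin
#' intercept + Strahler-difference level intercept + per-basin slopes times
#' the transformed network distance, the flow-connection indicator and the
#' transformed precipitation difference. The site intercepts enter
#' additively, so the predictor is invariant to swapping the two community
#' roles. The beta mean mu is the inverse logit of the returned value.
#'
#' @param params a [ddcs_parameters()] set.
#' @param design a [build_design()] table.
#' @return Numeric vector (one value per dyad) on the logit scale.
#' @export
linear_predictor <- function(params, design) {
  stopifnot(inherits(design, "ddcs_design"))
  validate_parameters(params)
  if (length(params$alpha_site) < design$n_sites ||
      length(params$alpha_basin) < design$n_basins ||
      length(params$alpha_strahler) < max(design$strahler_level))
    stop("parameter vectors shorter than the design index ranges", call. = FALSE)
  params$alpha_baseline +
    params$alpha_site[design$site1] + params$alpha_site[design$site2] +
    params$alpha_basin[design$basin] +
    params$alpha_strahler[design$strahler_level] +
    params$beta_distance[design$basin] * design$x_distance +
    params$beta_flow[design$basin] * design$flow +
    params$beta_precip[design$basin] * design$x_precip
}

#' Beta log density in the mean/sample-size parameterisation
#'
#' Similarities are modelled as Beta with shape parameters `mu * kappa` and
#' `(1 - mu) * kappa`, so `mu` is the mean and `kappa` acts as a
#' concentration ("sample size"). The density excludes the boundaries; values
#' at exactly 0 or 1 raise an error (see [squeeze_boundary()] for the
#' documented squeeze option).
#'
#' @param y observed similarity in (0, 1), vectorised.
#' @param mu mean in (0, 1).
#' @param kappa concentration (> 0).
#' @return Log density values.
#' @export
beta_log_density <- function(y, mu, kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in (0, 1)", call. = FALSE)
  if (any(y <= 0 | y >= 1))
    stop("similarities on the boundary (0 or 1) are outside the beta ",
         "likelihood's support; use squeeze_boundary() if appropriate",
         call. = FALSE)
  stats::dbeta(y, shape1 = mu * kappa, shape2 = (1 - mu) * kappa, log = TRUE)
}

#' Squeeze boundary similarities into the open unit interval
#'
#' The standard compression `y' = (y * (n - 1) + 0.5) / n`, mapping exact 0
#' and 1 to interior values while barely perturbing interior observations.
#' Off by default in [fit_ddcs()]; apply deliberately.
#'
#' @param y similarities in `[0, 1]`.
#' @param n sample size used for the compression (default `length(y)`).
#' @return Values strictly inside (0, 1).
#' @export
squeeze_boundary <- function(y, n = length(y)) {
  stopifnot(n > 1)
  (y * (n - 1) + 0.5) / n
}

#' Draw one parameter set from the prior distribution
#'
#' Samples every model parameter from its prior: Normal(0, 0.3) for the
#' baseline, basin intercepts and slope hyper-means; Exponential(1) for the
#' site-intercept scale and Exponential(2) for the Strahler and slope scales;
#' Normal(0, scale) for the group effects given their scales; half-Normal(0,
#' 50) for kappa (truncated at zero, since the mean/sample-size beta
#' parameterisation requires kappa > 0).
#'
#' @param n_sites,n_basins,n_strahler dimensions of the varying intercepts.
#' @param seed optional RNG seed.
#' @return A [ddcs_parameters()] draw.
#' @export
draw_prior_parameters <- function(n_sites, n_basins, n_strahler = 7,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma_site <- stats::rexp(1, 1)
  sigma_strahler <- stats::rexp(1, 2)
  sigma_d <- stats::rexp(1, 2); sigma_f <- stats::rexp(1, 2)
  sigma_p <- stats::rexp(1, 2)
  mu_d <- rnorm(1, 0, 0.3); mu_f <- rnorm(1, 0, 0.3); mu_p <- rnorm(1, 0, 0.3)
  ddcs_parameters(
    alpha_baseline = rnorm(1, 0, 0.3),
    alpha_site = rnorm(n_sites, 0, sigma_site),
    sigma_site = sigma_site,
    alpha_basin = rnorm(n_basins, 0, 0.3),
    alpha_strahler = rnorm(n_strahler, 0, sigma_strahler),
    sigma_strahler = sigma_strahler,
    beta_distance = rnorm(n_basins, mu_d, sigma_d),
    beta_flow = rnorm(n_basins, mu_f, sigma_f),
    beta_precip = rnorm(n_basins, mu_p, sigma_p),
    mu_distance = mu_d, mu_flow = mu_f, mu_precipitation = mu_p,
    sigma_distance = sigma_d, sigma_flow = sigma_f,
    sigma_precipitation = sigma_p,
    kappa = abs(rnorm(1, 0, 50)))
}

#' Construct a ground-truth parameter set for recovery experiments
#'
#' Fixes the hyper-parameters at chosen values and draws the group effects
#' (site, basin and Strahler intercepts; per-basin slopes) from the implied
#' hierarchy, so the fitted model is exactly the generating model.
#'
#' @param n_sites,n_basins,n_strahler dimensions.
#' @param mu_distance,mu_flow,mu_precipitation slope hyper-means.
#' @param sigma_distance,sigma_flow,sigma_precipitation slope hyper-scales.
#' @param alpha_baseline global intercept.
#' @param sigma_site,sigma_strahler intercept scales.
#' @param kappa beta concentration.
#' @param seed optional RNG seed.
#' @return A [ddcs_parameters()] set.
#' @export
true_parameters <- function(n_sites, n_basins, n_strahler = 7,
                            mu_distance = -0.4, mu_flow = 0.05,
                            mu_precipitation = -0.3,
                            sigma_distance = 0.2, sigma_flow = 0.1,
                            sigma_precipitation = 0.2,
                            alpha_baseline = 0.3, sigma_site = 0.3,
                            sigma_strahler = 0.2, kappa = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ddcs_parameters(
    alpha_baseline = alpha_baseline,
    alpha_site = rnorm(n_sites, 0, sigma_site),
    sigma_site = sigma_site,
    alpha_basin = rnorm(n_basins, 0, 0.3),
    alpha_strahler = rnorm(n_strahler, 0, sigma_strahler),
    sigma_strahler = sigma_strahler,
    beta_distance = rnorm(n_basins, mu_distance, sigma_distance),
    beta_flow = rnorm(n_basins, mu_flow, sigma_flow),
    beta_precip = rnorm(n_basins, mu_precipitation, sigma_precipitation),
    mu_distance = mu_distance, mu_flow = mu_flow,
    mu_precipitation = mu_precipitation,
    sigma_distance = sigma_distance, sigma_flow = sigma_flow,
    sigma_precipitation = sigma_precipitation,
    kappa = kappa)
}

#' Simulate Sorensen similarities from the model
#'
#' For each dyad of the design, computes the beta mean from the linear
#' predictor and draws one similarity from Beta(mu * kappa, (1 - mu) *
#' kappa). This is the model-faithful generator used for prior predictive
#' checks, parameter recovery and simulation-based calibration.
#'
#' @param design a [build_design()] table.
#' @param truth a [ddcs_parameters()] set.
#' @param seed optional RNG seed.
#' @return Numeric vector of similarities, strictly inside (0, 1).
#' @export
simulate_sorensen_from_model <- function(design, truth, seed = NULL) {
  stopifnot(inherits(design, "ddcs_design"))
  validate_parameters(truth)
  if (!is.null(seed)) set.seed(seed)
  mu <- plogis(linear_predictor(truth, design))
  y <- rbeta(design$n_dyads, mu * truth$kappa, (1 - mu) * truth$kappa)
  ## guard against floating-point rounding onto the boundary at extreme
  ## shapes; the beta likelihood excludes the endpoints
  eps <- .Machine$double.eps
  pmin(pmax(y, eps), 1 - eps)
}

## ---- packing between ddcs_parameters and the sampler's unconstrained vector

param_names <- function(design) {
  c("alpha_baseline",
    paste0("alpha_site[", seq_len(design$n_sites), "]"),
    "sigma_site",
    paste0("alpha_basin[", seq_len(design$n_basins), "]"),
    paste0("alpha_strahler[", seq_len(design$n_strahler), "]"),
    "sigma_strahler",
    paste0("beta_distance[", seq_len(design$n_basins), "]"),
    paste0("beta_flow[", seq_len(design$n_basins), "]"),
    paste0("beta_precip[", seq_len(design$n_basins), "]"),
    "mu_distance", "mu_flow", "mu_precipitation",
    "sigma_distance", "sigma_flow", "sigma_precipitation", "kappa")
}

## map one row of unconstrained draws to the constrained, centered parameters
constrain_theta <- function(theta, design) {
  S <- design$n_sites; B <- design$n_basins; K <- design$n_strahler
  i <- 1L
  a0 <- theta[i]; i <- i + 1L
  z_s <- theta[i:(i + S - 1L)]; i <- i + S
  sig_s <- exp(theta[i]); i <- i + 1L
  a_c <- theta[i:(i + B - 1L)]; i <- i + B
  z_o <- theta[i:(i + K - 1L)]; i <- i + K
  sig_o <- exp(theta[i]); i <- i + 1L
  z1 <- theta[i:(i + B - 1L)]; i <- i + B
  z2 <- theta[i:(i + B - 1L)]; i <- i + B
  z3 <- theta[i:(i + B - 1L)]; i <- i + B
  mu <- theta[i:(i + 2L)]; i <- i + 3L
  sig_b <- exp(theta[i:(i + 2L)]); i <- i + 3L
  kappa <- exp(theta[i])
  c(a0, sig_s * z_s, sig_s, a_c, sig_o * z_o, sig_o,
    mu[1] + sig_b[1] * z1, mu[2] + sig_b[2] * z2, mu[3] + sig_b[3] * z3,
    mu, sig_b, kappa)
}

## data list handed to the C++ target
design_data_list <- function(design) {
  list(site1 = as.integer(design$site1), site2 = as.integer(design$site2),
       basin = as.integer(design$basin),
       strahler_level = as.integer(design$strahler_level),
       x_distance = design$x_distance, flow = design$flow,
       x_precip = design$x_precip, y = design$y,
       n_sites = as.integer(design$n_sites),
       n_basins = as.integer(design$n_basins),
       n_strahler = as.integer(design$n_strahler))
}

#' Log posterior (and gradient) of the model on the unconstrained scale
#'
#' Returns a closure evaluating the joint log posterior of the
#' non-centered, log-transformed parameterisation used by the sampler,
#' together with its analytic gradient. Mainly exposed for testing and for
#' building alternative inference schemes on top of the same model.
#'
#' @param design a [build_design()] table with responses strictly in (0, 1).
#' @return Function of the unconstrained parameter vector returning
#'   `list(lp, grad)`.
#' @export
make_log_posterior <- function(design) {
  stopifnot(inherits(design, "ddcs_design"))
  dat <- design_data_list(design)
  function(theta) ddcs_lp_grad_cpp(theta, dat)
}

#' Number of unconstrained parameters for a design
#'
#' @param design a [build_design()] table.
#' @return Integer dimension of the sampler's parameter vector.
#' @export
n_unconstrained <- function(design) {
  design$n_sites + 4L * design$n_basins + design$n_strahler + 10L
}
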