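## Sampler diagnostics: split-Rhat, effective sample size, divergence and
## treedepth book-keeping.

#' Split potential scale reduction factor (split-Rhat)
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed over the resulting half-chains, so that trends within a
#' chain inflate the statistic as well as disagreement between chains. Values
#' near 1 indicate mixing; `NA` is returned for a single chain that cannot be
#' split, or when the draws are constant (zero variance).
#'
#' @param x matrix of draws, iterations x chains.
#' @return The split-Rhat statistic (scalar).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])))
  m <- ncol(splits); nn <- nrow(splits)
  mu <- colMeans(splits)
  s2 <- apply(splits, 2, stats::var)
  W <- mean(s2)
  Bv <- nn * stats::var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt((W * (nn - 1) / nn + Bv / nn) / W)
}

#' Effective sample size of merged chains
#'
#' Classic autocorrelation-based effective sample size using per-chain
#' autocovariances combined across chains and Geyer's initial monotone
#' positive sequence to truncate the autocorrelation sum.
#'
#' @param x matrix of draws, iterations x chains.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  max_lag <- min(n - 1L, 1000L)
  ## per-chain autocovariances; R's acf normalises by n (biased estimate)
  acov <- vapply(seq_len(m), function(j)
    stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
               type = "covariance", demean = TRUE)$acf[, 1, 1],
    numeric(max_lag + 1L))
  acov <- matrix(acov, ncol = m)
  chain_var <- acov[1, ] * n / (n - 1)
  mean_var <- mean(chain_var)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + stats::var(colMeans(x))
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus   # rho[1] is lag 0
  ## Geyer initial monotone positive sequence over consecutive lag pairs
  pair_sums <- numeric(0)
  k <- 1L
  while (k + 1L <= length(rho)) {
    ps <- rho[k] + rho[k + 1L]
    if (!is.finite(ps) || ps < 0) break
    pair_sums <- c(pair_sums, ps)
    k <- k + 2L
  }
  if (!length(pair_sums)) return(NA_real_)
  pair_sums <- cummin(pair_sums)
  tau <- max(-1 + 2 * sum(pair_sums), 1 / log10(n * m))
  n * m / tau
}

#' Convergence and sampler-health report for a fit
#'
#' Computes split-Rhat and effective sample size for every parameter, counts
#' divergent transitions and iterations that saturated the maximum tree
#' depth, and evaluates pass/fail against thresholds. Rhat requires at least
#' two chains; with one chain it is reported as `NA` and the Rhat check as
#' unavailable.
#'
#' @param fit a [fit_ddcs()] object (or any list with a draws array and a
#'   `sampler_flags` data.frame, so injected flags are counted as-is).
#' @param rhat_threshold pass threshold for split-Rhat (default 1.01,
#'   operationalising "consistent with 1").
#' @param parameters optional subset of parameter names.
#' @return An object of class `ddcs_diagnostics`: list with `summary`
#'   (data.frame: parameter, rhat, ess), `n_divergent`,
#'   `n_treedepth_saturated`, `rhat_ok`, `no_divergences`,
#'   `no_treedepth_saturation`, `pass`, `rhat_threshold`.
#' @export
diagnostics <- function(fit, rhat_threshold = 1.01, parameters = NULL) {
  stopifnot(!is.null(fit$draws), !is.null(fit$sampler_flags))
  pn <- if (is.null(parameters)) dimnames(fit$draws)[[3]] else parameters
  chains <- dim(fit$draws)[2]
  res <- data.frame(parameter = pn,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pn)) {
    m <- fit$draws[, , pn[i], drop = TRUE]
    if (chains == 1L) m <- matrix(m, ncol = 1L)
    res$rhat[i] <- if (chains >= 2) split_rhat(m) else NA_real_
    res$ess[i] <- ess_basic(m)
  }
  n_div <- sum(fit$sampler_flags$divergent)
  n_sat <- sum(fit$sampler_flags$treedepth_saturated)
  rhat_ok <- if (chains >= 2) all(res$rhat < rhat_threshold, na.rm = FALSE)
             else NA
  structure(list(
    summary = res,
    n_divergent = n_div,
    n_treedepth_saturated = n_sat,
    rhat_ok = rhat_ok,
    no_divergences = n_div == 0L,
    no_treedepth_saturation = n_sat == 0L,
    pass = isTRUE(rhat_ok) && n_div == 0L && n_sat == 0L,
    rhat_threshold = rhat_threshold,
    chains = chains), class = "ddcs_diagnostics")
}

#' @export
print.ddcs_diagnostics <- function(x, ...) {
  cat("sampler diagnostics (", nrow(x$summary), "parameters )\n")
  cat("  max split-Rhat:", round(max(x$summary$rhat, na.rm = TRUE), 4),
      "( threshold", x$rhat_threshold, ")\n")
  cat("  min ESS:", round(min(x$summary$ess, na.rm = TRUE)), "\n")
  cat("  divergent transitions:", x$n_divergent, "\n")
  cat("  treedepth saturations:", x$n_treedepth_saturated, "\n")
  cat("  overall:", if (isTRUE(x$pass)) "PASS" else "CHECK", "\n")
  invisible(x)
}
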