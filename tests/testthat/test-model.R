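zero_parameters <- function(des, kappa = 2) {
  ddcs_parameters(
    alpha_baseline = 0, alpha_site = rep(0, des$n_sites), sigma_site = 1,
    alpha_basin = rep(0, des$n_basins),
    alpha_strahler = rep(0, des$n_strahler), sigma_strahler = 1,
    beta_distance = rep(0, des$n_basins), beta_flow = rep(0, des$n_basins),
    beta_precip = rep(0, des$n_basins),
    mu_distance = 0, mu_flow = 0, mu_precipitation = 0,
    sigma_distance = 1, sigma_flow = 1, sigma_precipitation = 1,
    kappa = kappa)
}

test_that("linear predictor reproduces the stated additive structure", {
  des <- sim_design(seed = 4)
  p0 <- zero_parameters(des)
  expect_equal(linear_predictor(p0, des), rep(0, des$n_dyads))
  expect_equal(plogis(linear_predictor(p0, des)), rep(0.5, des$n_dyads))
  p1 <- p0; p1$alpha_baseline <- 0.3
  expect_equal(unique(linear_predictor(p1, des)), 0.3)
  expect_equal(unique(plogis(linear_predictor(p1, des))), 0.57444252,
               tolerance = 1e-7)
  ## full random parameter set against a direct recomputation
  set.seed(5)
  pr <- draw_prior_parameters(des$n_sites, des$n_basins, des$n_strahler)
  eta <- linear_predictor(pr, des)
  want <- pr$alpha_baseline + pr$alpha_site[des$site1] +
    pr$alpha_site[des$site2] + pr$alpha_basin[des$basin] +
    pr$alpha_strahler[des$strahler_level] +
    pr$beta_distance[des$basin] * des$x_distance +
    pr$beta_flow[des$basin] * des$flow +
    pr$beta_precip[des$basin] * des$x_precip
  expect_equal(eta, want)
})

test_that("the predictor is invariant to swapping the two community roles", {
  des <- sim_design(seed = 6)
  set.seed(7)
  pr <- draw_prior_parameters(des$n_sites, des$n_basins, des$n_strahler)
  swapped <- des
  swapped$site1 <- des$site2
  swapped$site2 <- des$site1
  expect_equal(linear_predictor(pr, des), linear_predictor(pr, swapped))
})

test_that("beta log density matches closed forms and stays normalised", {
  ## Beta(1, 1): uniform, log density 0 everywhere
  expect_equal(beta_log_density(c(0.1, 0.5, 0.93), 0.5, 2), rep(0, 3))
  ## Beta(2, 2) at its mode: density 1.5
  expect_equal(beta_log_density(0.5, 0.5, 4), log(1.5))
  ## integrates to one for random (mu, kappa)
  set.seed(8)
  for (k in 1:20) {
    mu <- runif(1, 0.05, 0.95); kap <- runif(1, 0.5, 80)
    int <- integrate(function(y) exp(beta_log_density(y, mu, kap)), 0, 1,
                     rel.tol = 1e-9)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
  ## agreement with an explicit log-gamma formulation on a grid
  g <- expand.grid(y = seq(0.02, 0.98, by = 0.06),
                   mu = seq(0.1, 0.9, by = 0.2), kappa = c(0.5, 2, 11, 60))
  want <- with(g, lgamma(kappa) - lgamma(mu * kappa) -
                  lgamma((1 - mu) * kappa) + (mu * kappa - 1) * log(y) +
                  ((1 - mu) * kappa - 1) * log(1 - y))
  expect_equal(beta_log_density(g$y, g$mu, g$kappa), want, tolerance = 1e-8)
})

test_that("boundary similarities and invalid parameters are rejected", {
  expect_error(beta_log_density(0, 0.5, 2), "boundary")
  expect_error(beta_log_density(1, 0.5, 2), "boundary")
  expect_error(beta_log_density(0.5, 0.5, -1), "kappa")
  expect_error(beta_log_density(0.5, 1.2, 2), "mu")
  bad <- zero_parameters(sim_design(seed = 9))
  bad$kappa <- 0
  expect_error(validate_parameters(bad), "positive")
})

test_that("squeeze_boundary compresses into the open interval", {
  y <- c(0, 0.3, 1)
  z <- squeeze_boundary(y, n = 100)
  expect_true(all(z > 0 & z < 1))
  expect_equal(z[2], (0.3 * 99 + 0.5) / 100)
})

test_that("all-zero parameters with kappa = 2 simulate uniform similarities", {
  des <- sim_design(n_basins = 4, sites_per_basin = 16, seed = 10)
  stopifnot(des$n_dyads >= 400)
  p0 <- zero_parameters(des, kappa = 2)
  reps <- ceiling(2000 / des$n_dyads)
  y <- as.numeric(replicate(reps, simulate_sorensen_from_model(des, p0)))
  ks <- suppressWarnings(ks.test(y[seq_len(2000)], "punif"))
  ## KS statistic below the 1% critical value at n = 2000
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))
})

test_that("huge kappa concentrates the similarities at the mean", {
  des <- sim_design(seed = 11)
  p <- zero_parameters(des, kappa = 1e6)
  y <- simulate_sorensen_from_model(des, p, seed = 12)
  expect_lt(abs(mean(y) - 0.5), 0.01)
})

test_that("beta draws reproduce the mean/concentration moments", {
  set.seed(13)
  for (cfg in list(c(0.3, 8), c(0.6, 35))) {
    mu <- cfg[1]; kap <- cfg[2]
    y <- rbeta(10000, mu * kap, (1 - mu) * kap)
    se_mean <- sqrt(mu * (1 - mu) / (1 + kap) / 10000)
    expect_lt(abs(mean(y) - mu), 3 * se_mean)
    v <- mu * (1 - mu) / (1 + kap)
    ## variance of the sample variance ~ (E[(y-mu)^4] - v^2)/n
    m4 <- mean((y - mean(y))^4)
    expect_lt(abs(var(y) - v), 3 * sqrt((m4 - v^2) / 10000))
  }
})

test_that("a negative distance hyper-slope leaves its sign in the data", {
  des <- sim_design(n_basins = 6, sites_per_basin = 16, seed = 14)
  stopifnot(des$n_dyads >= 600)
  truth <- true_parameters(des$n_sites, des$n_basins,
                           mu_distance = -0.4, sigma_distance = 0.05,
                           sigma_site = 0.1, seed = 15)
  ## stack replicated simulations to reach ~4000 dyads
  reps <- ceiling(4000 / des$n_dyads)
  y <- as.numeric(replicate(reps, simulate_sorensen_from_model(des, truth)))
  x <- rep(des$x_distance, reps)
  ols <- coef(lm(qlogis(y) ~ x))
  expect_lt(ols["x"], 0)
})

test_that("with no covariate effects the dyads are exchangeable", {
  des <- sim_design(n_basins = 3, sites_per_basin = 12, seed = 16)
  p0 <- zero_parameters(des, kappa = 20)
  y <- simulate_sorensen_from_model(des, p0, seed = 17)
  obs <- abs(cor(y, des$x_distance))
  set.seed(18)
  perm <- replicate(999, abs(cor(sample(y), des$x_distance)))
  p_value <- (1 + sum(perm >= obs)) / 1000
  expect_gt(p_value, 0.01)   # association indistinguishable from permutations
})

test_that("simulation is deterministic given the seed", {
  des <- sim_design(seed = 19)
  truth <- true_parameters(des$n_sites, des$n_basins, seed = 20)
  expect_identical(simulate_sorensen_from_model(des, truth, seed = 21),
                   simulate_sorensen_from_model(des, truth, seed = 21))
  bad <- truth
  bad$kappa <- -2
  expect_error(simulate_sorensen_from_model(des, bad, seed = 21), "positive")
})

test_that("log posterior matches an R-side reference implementation", {
  des <- sim_design(seed = 22)
  des <- set_design_response(
    des, simulate_sorensen_from_model(
      des, true_parameters(des$n_sites, des$n_basins, seed = 23), seed = 24))
  lp <- make_log_posterior(des)
  ref_lp <- function(th) {
    S <- des$n_sites; B <- des$n_basins; K <- des$n_strahler
    i <- 1; a0 <- th[i]; i <- i + 1
    zs <- th[i:(i + S - 1)]; i <- i + S; ts <- th[i]; i <- i + 1
    ac <- th[i:(i + B - 1)]; i <- i + B
    zo <- th[i:(i + K - 1)]; i <- i + K; to <- th[i]; i <- i + 1
    z1 <- th[i:(i + B - 1)]; i <- i + B
    z2 <- th[i:(i + B - 1)]; i <- i + B
    z3 <- th[i:(i + B - 1)]; i <- i + B
    mu <- th[i:(i + 2)]; i <- i + 3; tb <- th[i:(i + 2)]; i <- i + 3
    lam <- th[i]
    ss <- exp(ts); so <- exp(to); sb <- exp(tb); k <- exp(lam)
    as_ <- ss * zs; ao <- so * zo
    b1 <- mu[1] + sb[1] * z1; b2 <- mu[2] + sb[2] * z2
    b3 <- mu[3] + sb[3] * z3
    eta <- a0 + as_[des$site1] + as_[des$site2] + ac[des$basin] +
      ao[des$strahler_level] + b1[des$basin] * des$x_distance +
      b2[des$basin] * des$flow + b3[des$basin] * des$x_precip
    m <- plogis(eta)
    sum(dbeta(des$y, m * k, (1 - m) * k, log = TRUE)) +
      dnorm(a0, 0, 0.3, TRUE) + sum(dnorm(zs, log = TRUE)) +
      sum(dnorm(zo, log = TRUE)) + sum(dnorm(ac, 0, 0.3, TRUE)) +
      sum(dnorm(c(z1, z2, z3), log = TRUE)) +
      sum(dnorm(mu, 0, 0.3, TRUE)) +
      (-ss + ts) + (log(2) - 2 * so + to) + sum(log(2) - 2 * sb + tb) +
      (log(2) + dnorm(k, 0, 50, TRUE) + lam)
  }
  set.seed(25)
  for (r in 1:10) {
    th <- runif(n_unconstrained(des), -1.5, 1.5)
    expect_equal(lp(th)$lp, ref_lp(th), tolerance = 1e-9)
  }
})

test_that("analytic gradient agrees with finite differences", {
  des <- sim_design(n_basins = 2, sites_per_basin = 5, n_leaves = 8,
                    seed = 26)
  des <- set_design_response(
    des, simulate_sorensen_from_model(
      des, true_parameters(des$n_sites, des$n_basins, seed = 27), seed = 28))
  lp <- make_log_posterior(des)
  set.seed(29)
  for (r in 1:3) {
    th <- runif(n_unconstrained(des), -1, 1)
    v <- lp(th)
    h <- 1e-6
    ng <- vapply(seq_along(th), function(j) {
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (lp(tp)$lp - lp(tm)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(v$grad, ng, tolerance = 1e-4)
  }
})

test_that("swapping site roles leaves the log posterior unchanged", {
  des <- sim_design(seed = 30)
  des <- set_design_response(
    des, simulate_sorensen_from_model(
      des, true_parameters(des$n_sites, des$n_basins, seed = 31), seed = 32))
  swapped <- des
  swapped$site1 <- des$site2
  swapped$site2 <- des$site1
  lp1 <- make_log_posterior(des)
  lp2 <- make_log_posterior(swapped)
  set.seed(33)
  th <- runif(n_unconstrained(des), -1, 1)
  expect_equal(lp1(th)$lp, lp2(th)$lp)
})
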