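test_that("frequency paths stay in [0, 1] and respect the dt guard", {
  mod <- linear_model(mu = 0.01)
  run <- simulate_frequency_sde(mod, p0 = 0.5, t_max = 100, dt = 0.05,
                                seed = 1, thin = 1)
  expect_true(all(run$path$p >= 0 & run$path$p <= 1))
  expect_error(simulate_frequency_sde(mod, 0.5, t_max = 10, dt = 10),
               "demographic timescale")
})

test_that("without mutation or cost the frequency is a martingale", {
  mod <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
                    omega = 400, mu = 0)
  ends <- vapply(1:150, function(i) {
    run <- simulate_frequency_sde(mod, p0 = 0.3, t_max = 20, dt = 0.02,
                                  seed = 600 + i, thin = 1e6)
    run$path$p[nrow(run$path)]
  }, numeric(1))
  se <- stats::sd(ends) / sqrt(length(ends))
  expect_lt(abs(mean(ends) - 0.3), 3 * se)
})

test_that("halving dt leaves ensemble means unchanged within Monte-Carlo
           error (weak consistency)", {
  mod <- deathrate_model(nu = -0.95, mu = 0.05)
  mean_end <- function(dt, seed0) {
    ends <- vapply(1:120, function(i) {
      run <- simulate_frequency_sde(mod, p0 = 0.2, t_max = 15, dt = dt,
                                    seed = seed0 + i, thin = 1e6)
      run$path$p[nrow(run$path)]
    }, numeric(1))
    c(mean(ends), stats::sd(ends) / sqrt(length(ends)))
  }
  a <- mean_end(0.04, 3000)
  b <- mean_end(0.02, 7000)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("mutation lifts the path off the boundaries despite clipping", {
  mod <- deathrate_model(nu = 0, mu = 0.05, omega = 250)
  run <- simulate_frequency_sde(mod, p0 = 0, t_max = 500, dt = 0.01,
                                seed = 4, burn_in = 50, thin = 100)
  total <- 450
  expect_lt(run$boundary_time / total, 0.05)
  expect_gt(max(run$path$p), 0.5) # mixes across the interior
})

test_that("frequency-SDE occupancy matches the analytic stationary
           density", {
  mod <- deathrate_model() # altruism nu = -0.95
  bins <- 25
  htot <- numeric(bins)
  for (s in 1:3) {
    run <- simulate_frequency_sde(mod, p0 = 0.9, t_max = 15000, dt = 0.05,
                                  seed = 70 + s, bins = bins,
                                  burn_in = 1000, thin = 1e6)
    htot <- htot + run$occupancy$weight
  }
  d <- stationary_density(mod)
  expect_lt(tv_to_stationary(htot / sum(htot), d, bins), 0.05)
})

test_that("density-SDE trait ladder concentrates occupancy on the most
           altruistic death-rate trait", {
  x0 <- rep(2 / 3 / 3, 3)
  run <- simulate_density_sde("death_rate", list(beta = 3, d = 1),
                              nu_values = c(-0.9, 0, 0.9), x0 = x0,
                              t_max = 2500, dt = 0.02, omega = 250,
                              mu = 0.002, seed = 42, burn_in = 400,
                              thin = 100)
  occ <- run$occupancy
  expect_equal(which.max(occ$dominant_fraction), 1L)
  expect_gt(occ$dominant_fraction[1], occ$dominant_fraction[3])
  expect_true(all(run$path[, -1] >= 0))
})

test_that("density paths hug the deterministic equilibrium at large
           omega", {
  # mu = eps = 0, both types fully social (nu = 1 each): deterministic
  # equilibrium solves r + n = kappa n, i.e. n = r/(kappa - 1) = 3;
  # fluctuations around it are O(omega^-1/2)
  n_eq <- 0.6 / (1.2 - 1)
  for (om in c(1e3, 1e5)) {
    run <- simulate_density_sde("linear_altruism",
                                list(r = 0.6, kappa = 1.2),
                                nu_values = c(1, 1),
                                x0 = c(n_eq / 2, n_eq / 2),
                                t_max = 50, dt = 0.01, omega = om,
                                mu = 0, seed = 9, burn_in = 10, thin = 10)
    n_tot <- rowSums(run$path[, c("x1", "x2")])
    sel <- run$path$time > 10
    expect_lt(abs(mean(n_tot[sel]) - n_eq), 4 / sqrt(om))
    expect_lt(max(abs(n_tot[sel] - n_eq)), 30 / sqrt(om))
  }
})

test_that("noise-induced drift sits in the actor density, not the actor
           frequency", {
  mod <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
                    omega = 50, mu = 0)
  cmp <- frequency_vs_density_consistency(mod, p0 = 0.5, tau = 25,
                                          replicates = 400, dt = 0.02,
                                          seed = 9)
  expect_equal(cmp$alpha_analytic, 0)
  expect_lt(abs(cmp$dp_rate), 3 * cmp$dp_se)   # frequency: no drift
  expect_gt(cmp$dx1_rate, 3 * cmp$dx1_se)      # density: positive drift
})

test_that("empirical frequency drift follows mu(1 - 2p) with mutation", {
  # over a finite window the mutation drift relaxes p toward 1/2 as
  # E[p(t)] = 1/2 + (p0 - 1/2) exp(-2 mu t); compare mean rates over tau
  mu <- 0.05
  tau <- 5
  mod <- linear_model(omega = 200, mu = mu)
  for (p0 in c(0.2, 0.8)) {
    cmp <- frequency_vs_density_consistency(mod, p0 = p0, tau = tau,
                                            replicates = 400, dt = 0.02,
                                            seed = 17)
    expected_rate <- (p0 - 0.5) * (exp(-2 * mu * tau) - 1) / tau
    expect_lt(abs(cmp$dp_rate - expected_rate), 3 * cmp$dp_se)
    # and the instantaneous analytic drift has the right sign and size
    expect_equal(cmp$alpha_analytic, mu * (1 - 2 * p0))
  }
})

test_that("doubling omega halves the empirical frequency-increment
           variance", {
  var_rate <- function(om, seed) {
    mod <- make_model("linear_altruism",
                      list(r = 0.6, kappa = 1.2, nu = 1),
                      omega = om, mu = 0)
    dt <- 0.02
    set.seed(seed)
    n0 <- quasi_equilibrium_density(mod, 0.5)
    dp <- vapply(1:800, function(i) {
      run <- simulate_density_sde("linear_altruism",
                                  list(r = 0.6, kappa = 1.2),
                                  nu_values = c(1, 0),
                                  x0 = c(n0 / 2, n0 / 2), t_max = 0.5,
                                  dt = dt, omega = om, mu = 0,
                                  seed = seed + i, thin = 1e6)
      xe <- unlist(run$path[nrow(run$path), c("x1", "x2")])
      xe[1] / sum(xe) - 0.5
    }, numeric(1))
    stats::var(dp) / 0.5
  }
  v1 <- var_rate(100, 100)
  v2 <- var_rate(200, 900)
  expect_lt(abs(v1 / v2 - 2), 0.5)
})
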