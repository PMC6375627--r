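test_that("neutral models give a symmetric stationary density", {
  d <- stationary_density(model_preset("deathrate_neutral"),
                          grid_size = 2001)
  expect_equal(d$mass_above_half, 0.5, tolerance = 1e-9)
  # density symmetric under p -> 1 - p
  expect_equal(d$grid$density, rev(d$grid$density), tolerance = 1e-9)
  expect_true(d$integrable)
})

test_that("linear-altruism stationary density is the symmetric Beta", {
  # mu omega / kappa = 4.5 with epsilon = 0
  mod <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
                    omega = 900, mu = 4.5 * 1.2 / 900)
  d <- stationary_density(mod)
  sel <- d$grid$p >= 0.01 & d$grid$p <= 0.99
  ref <- stats::dbeta(d$grid$p[sel], 4.5, 4.5)
  expect_lt(max(abs(d$grid$density[sel] - ref) / ref), 1e-6)
})

test_that("mass conservation and closed-form tilt of the linear model", {
  m <- linear_model(epsilon = 0.003)
  d <- stationary_density(m)
  g <- d$grid
  w <- c(diff(g$p) / 2, 0) + c(0, diff(g$p) / 2)
  # interior quadrature mass + analytic boundary tails must give 1
  a <- unname(d$exponents)
  tails <- g$density[1] * g$p[1] / a[1] +
    g$density[nrow(g)] * (1 - g$p[nrow(g)]) / a[2]
  expect_equal(sum(g$density * w) + tails, 1, tolerance = 1e-8)

  # pi(p)/pi(1-p) = exp(-eps r omega (2p - 1) / kappa) < 1 for p > 1/2
  p <- seq(0.55, 0.95, 0.1)
  lr <- closed_form_linear_altruism(p, model = m, log = TRUE) -
    closed_form_linear_altruism(1 - p, model = m, log = TRUE)
  expect_equal(lr, -0.003 * 0.6 * 100 * (2 * p - 1) / 1.2)
  expect_true(all(lr < 0))
})

test_that("general integrator matches the linear-model closed form across
           a parameter sweep", {
  cases <- tidyr::expand_grid(momk = c(0.5, 1, 4.5), eps = c(0, 0.003))
  for (i in seq_len(nrow(cases))) {
    momk <- cases$momk[i]; eps <- cases$eps[i]
    m <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
                    omega = 300, mu = momk * 1.2 / 300, epsilon = eps)
    d <- stationary_density(m, grid_size = 2001)
    cf <- closed_form_linear_altruism(d$grid$p, model = m, log = TRUE)
    expect_lt(sup_rel_err_unnormalized(d$grid$p, log(d$grid$density), cf),
              1e-6)
  }
})

test_that("flat-density boundary case: mu omega / kappa = 1, no cost", {
  m <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
                  omega = 300, mu = 1.2 / 300)
  d <- stationary_density(m, grid_size = 2001)
  expect_lt(max(d$grid$density) / min(d$grid$density) - 1, 1e-6)
  expect_equal(max(abs(d$grid$density - 1)), 0, tolerance = 1e-6)
})

test_that("elevated-turnover closed form is certified against the
           integrator", {
  m2 <- turnover_model(epsilon = 0.003) # beta 3, d 2.4, kappa 1.2, nu 1
  d <- stationary_density(m2)
  cf <- closed_form_turnover_altruism(d$grid$p, model = m2, log = TRUE)
  expect_lt(sup_rel_err_unnormalized(d$grid$p, d$grid$log_unnormalized, cf),
            1e-4)

  # boundary exponents: A = mu omega r/(beta kappa) < B = mu omega r/(beta
  # kappa - d nu), so the cost-free density is skewed toward p = 1
  A <- 0.01 * 100 * 0.6 / (3 * 1.2)
  B <- 0.01 * 100 * 0.6 / (3 * 1.2 - 2.4)
  expect_equal(unname(d$exponents), c(A, B))
  expect_lt(A, B)

  # nu -> 0 limit collapses to the symmetric Beta form
  p <- seq(0.05, 0.95, 0.05)
  lim <- closed_form_turnover_altruism(p, beta = 3, d = 2.4, kappa = 1.2,
                                       nu = 0, mu = 0.01, omega = 100,
                                       log = TRUE)
  a <- 0.01 * 100 * 0.6 / 3.6
  ref <- (a - 1) * (log(p) + log(1 - p))
  expect_equal(lim - lim[1], ref - ref[1], tolerance = 1e-10)
  expect_error(closed_form_turnover_altruism(p, beta = 1, d = 0.9,
                                             kappa = 1, nu = 1.2,
                                             mu = 0.01, omega = 100),
               "beta \\* kappa")
})

test_that("mutation supply controls U versus bell shape", {
  kappa <- 1.2
  omega <- 300
  for (momk in c(0.3, 0.6)) { # mu omega / kappa < 1: U-shaped
    m <- make_model("linear_altruism", list(r = 0.6, kappa = kappa, nu = 1),
                    omega = omega, mu = momk * kappa / omega)
    f <- favourability(stationary_density(m, grid_size = 2001))
    expect_identical(f$shape, "U")
  }
  for (momk in c(1.5, 4)) { # > 1: interior mode at 1/2
    m <- make_model("linear_altruism", list(r = 0.6, kappa = kappa, nu = 1),
                    omega = omega, mu = momk * kappa / omega)
    d <- stationary_density(m, grid_size = 2001)
    f <- favourability(d)
    expect_identical(f$shape, "bell")
    expect_equal(d$grid$p[which.max(d$grid$density)], 0.5, tolerance = 1e-3)
  }
})

test_that("mu = 0 is flagged non-integrable, favourability refuses", {
  d <- stationary_density(linear_model(mu = 0))
  expect_false(d$integrable)
  expect_true(all(is.na(d$grid$density)))
  expect_error(favourability(d), "not integrable")
})

test_that("mass above one half responds monotonically to the social
           parameter in the death-rate family", {
  nus <- seq(-0.95, 0.95, length.out = 7)
  mass <- vapply(nus, function(nu) {
    stationary_density(deathrate_model(nu = nu),
                       grid_size = 1001)$mass_above_half
  }, numeric(1))
  expect_true(all(diff(mass) < 0))
  # altruism favoured, spite disfavoured
  expect_gt(mass[1], 0.5)
  expect_lt(mass[length(mass)], 0.5)
})

test_that("tidy, glance and autoplot work on stationary objects", {
  d <- stationary_density(model_preset("deathrate_altruism"),
                          grid_size = 1001)
  td <- tidy(d)
  expect_named(td, c("p", "density", "log_unnormalized"))
  gl <- glance(d)
  expect_identical(gl$family, "death_rate")
  expect_equal(gl$mass_above_half, d$mass_above_half)
  expect_s3_class(autoplot(d), "ggplot")
})
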