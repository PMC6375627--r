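test_that("optimal altruism strength: closed form and numeric optimum", {
  res <- optimal_social_action("birth_altruism",
                               list(beta = 1, d = 0.5, kappa1 = 0.75,
                                    kappa2 = 0.01))
  # beta = 2d makes |beta - 2d| = 0, so nu* = kappa1 exactly
  expect_identical(res$nu_star_closed, 0.75)
  expect_lt(abs(res$nu_star_numeric - 0.75), 1e-6)
  expect_true(res$agree)
  expect_false(res$boundary)

  # objective at nu* is a minimum over sampled nu
  obj_at <- function(nu) {
    mod <- make_model("birth_altruism",
                      list(beta = 1, d = 0.5, nu = nu, kappa1 = 0.75,
                           kappa2 = 0.01), omega = 1)
    sm <- diffusion_coefficients(mod, 1)
    sm$turnover / sm$n
  }
  for (nu in c(0.2, 0.5, 1, 1.5)) {
    expect_lte(res$objective, obj_at(nu) + 1e-12)
  }
})

test_that("optimal spite strength matches the closed form to two
           decimals", {
  res <- optimal_social_action("birth_spite",
                               list(beta = 8, d = 1, a = 0.05,
                                    kappa1 = 0.05, kappa2 = 0.2))
  theta <- sqrt(1 / 0.2)
  closed <- (0.05 + theta) * (8 - 2 - 0.05 * theta) / (8 * theta)
  expect_equal(res$nu_star_closed, closed)
  expect_equal(round(res$nu_star_numeric, 2), 0.75)
  expect_lt(abs(res$nu_star_numeric - res$nu_star_closed), 1e-6)
})

test_that("numeric minimiser recovers the closed forms across random
           admissible parameters (interior optima)", {
  set.seed(5)
  tries <- 0
  while (tries < 8) {
    d <- runif(1, 0.3, 1.5)
    beta <- 2 * d + runif(1, -0.2, 0.2) # near beta = 2d: interior optimum
    kappa2 <- runif(1, 0.05, 0.5)
    theta <- sqrt(d / kappa2)
    kappa1 <- runif(1, 0.5, 1.5)
    closed <- kappa1 - abs(beta - 2 * d) / theta
    if (beta <= d || closed <= 0.05 || beta <= 2 * d) next
    tries <- tries + 1
    res <- optimal_social_action("birth_altruism",
                                 list(beta = beta, d = d, kappa1 = kappa1,
                                      kappa2 = kappa2))
    expect_lt(abs(res$nu_star_numeric - closed), 1e-6)
    expect_true(res$agree)
  }
  # beta < 2d: the printed |beta - 2d| form bends the wrong way; the
  # numeric optimum sits at kappa1 + (2d - beta)/theta instead
  res <- optimal_social_action("birth_altruism",
                               list(beta = 0.8, d = 0.5, kappa1 = 0.75,
                                    kappa2 = 0.01))
  theta <- sqrt(0.5 / 0.01)
  expect_lt(abs(res$nu_star_numeric - (0.75 + 0.2 / theta)), 1e-6)
  expect_false(res$agree)
})

test_that("selective reversal: never for constant T/n, at small omega for
           decreasing T/n", {
  omegas <- c(25, 50, 100, 400)
  rs1 <- reversal_scan(linear_model(), omegas, 0.003)
  expect_true(all(!rs1$favoured))
  expect_true(all(!rs1$reversal))

  rs2 <- reversal_scan(turnover_model(), omegas, 0.003)
  expect_true(any(rs2$reversal))
  expect_true(rs2$favoured[rs2$omega == 25])

  # identical deterministic drift in the two models, opposite verdicts
  p <- seq(0, 1, 0.05)
  a1 <- diffusion_coefficients(linear_model(epsilon = 0.003), p)$alpha
  a2 <- diffusion_coefficients(turnover_model(epsilon = 0.003), p)$alpha
  expect_lt(max(abs(a1 - a2)), 1e-10)

  # without cost the linear model is exactly neutral at every omega
  rs0 <- reversal_scan(linear_model(), c(50, 400), 0)
  expect_equal(rs0$mass_above_half, rep(0.5, 2), tolerance = 1e-9)

  # the favourability boundary lies between the favoured and unfavoured
  # scan cells
  bd <- reversal_boundary(turnover_model(epsilon = 0.003), c(25, 2000),
                          tol = 5)
  expect_true(is.finite(bd))
  expect_gt(bd, 25)
  expect_lt(bd, 2000)
})

test_that("mutation sweep walks through U, boundary-unimodal and bell
           shapes for death-rate altruism", {
  sw <- mutation_sweep(deathrate_model(), c(2e-5, 1e-3, 2e-2))
  expect_identical(sw$shape, c("U", "boundary-unimodal", "bell"))
  expect_true(all(sw$favoured)) # altruism favoured throughout
  expect_true(all(sw$integrable))
})

test_that("monomorphic transition rates are independent of population
           size and symmetric mutation gives a uniform trait chain", {
  expect_identical(monomorphic_transition_rate(1e-6, 600), 1e-6)
  expect_identical(monomorphic_transition_rate(1e-6, 1e6), 1e-6)
  expect_error(monomorphic_transition_rate(1e-6, 0), "N_i")

  st <- trait_chain_stationary(matrix(1e-6, 4, 4))
  expect_equal(st$probability, rep(0.25, 4))
  # asymmetric rates: the state that is left faster holds less mass;
  # detailed balance gives pi1/pi2 = mu21/mu12 = 1/2 here
  mu <- matrix(c(0, 1e-6, 2e-6, 0), 2, 2) # mu12 = 2e-6, mu21 = 1e-6
  st2 <- trait_chain_stationary(mu)
  expect_equal(st2$probability, c(1, 2) / 3, tolerance = 1e-9)
})

test_that("neutral invasion favours the type with the larger equilibrium
           population", {
  mod <- deathrate_model(nu = -0.95, mu = 0) # altruism: n(1) > n(0)
  into_nonactors <- invasion_probability_neutral(mod, "non-actor")
  into_actors <- invasion_probability_neutral(mod, "actor")
  expect_gt(into_nonactors, into_actors)
})
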