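test_that("built-in families evaluate their printed rate formulas", {
  # death-rate model at neutral nu: b = 3(1 - 2/3) = 1, m = 1
  mod <- make_model("death_rate", list(beta = 3, d = 1, nu = 0), omega = 900)
  r <- evaluate_rates(mod, c(1 / 3, 1 / 3))
  expect_equal(r$b, 1)
  expect_equal(r$m, 1)

  # b = r + nu x1, m = kappa n at x = (0.25, 0.25)
  m1 <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
                   omega = 100)
  r1 <- evaluate_rates(m1, c(0.25, 0.25))
  expect_equal(r1$b, 0.85)
  expect_equal(r1$m, 0.6)
  expect_equal(r1$cost, 0.6)

  # no actors present: the social term vanishes regardless of n
  ba <- make_model("birth_altruism",
                   list(beta = 1, d = 0.5, nu = 0.75, kappa1 = 0.75,
                        kappa2 = 0.01), omega = 250)
  for (n in c(0.1, 0.5, 2)) {
    expect_equal(evaluate_rates(ba, c(0, n))$b, 1)
  }

  # spite blocks reproduction with probability nu x1 / (n + a)
  bs <- make_model("birth_spite",
                   list(beta = 8, d = 1, a = 0.05, nu = 0.5,
                        kappa1 = 0.05, kappa2 = 0.2), omega = 900)
  x <- c(0.3, 0.2)
  expect_equal(evaluate_rates(bs, x)$b, 8 * (1 - 0.5 * 0.3 / 0.55))
})

test_that("parameter constraints are enforced with informative errors", {
  expect_error(
    make_model("death_rate", list(beta = 3, d = 1, nu = 1.5), omega = 900),
    "nu in \\(-1, 1\\)"
  )
  expect_error(
    make_model("death_rate", list(beta = 1.5, d = 1, nu = 0.9), omega = 900),
    "beta > d"
  )
  # linear altruism rejects nu >= kappa
  expect_error(
    make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1.3),
               omega = 100),
    "kappa > nu"
  )
  expect_silent(
    make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
               omega = 100)
  )
  expect_error(
    make_model("birth_spite",
               list(beta = 8, d = 1, a = -0.1, nu = 0.5, kappa1 = 0.05,
                    kappa2 = 0.2), omega = 900),
    "a > 0"
  )
  expect_error(make_model("death_rate", list(beta = 3, d = 1, nu = 0)),
               "omega")
  expect_error(
    make_model("death_rate", list(beta = 3, d = 1), omega = 900),
    "nu"
  )
  expect_error(evaluate_rates(deathrate_model(), c(-0.1, 0.5)), ">= 0")
})

test_that("nu = 0 makes every two-type family symmetric under relabeling", {
  models <- list(
    make_model("death_rate", list(beta = 3, d = 1, nu = 0), omega = 1),
    make_model("birth_altruism",
               list(beta = 1, d = 0.5, nu = 0, kappa1 = 0.75,
                    kappa2 = 0.01), omega = 1),
    make_model("birth_spite",
               list(beta = 8, d = 1, a = 0.05, nu = 0, kappa1 = 0.05,
                    kappa2 = 0.2), omega = 1)
  )
  set.seed(42)
  for (mod in models) {
    for (i in 1:20) {
      x <- runif(2, 0, 0.4)
      expect_equal(evaluate_rates(mod, x), evaluate_rates(mod, rev(x)))
    }
  }
})

test_that("altruism/spite sign conventions hold by finite differences", {
  h <- 1e-6
  # death-rate family: sign of dm/dx1 equals sign of nu
  for (nu in c(-0.5, 0.5)) {
    mod <- make_model("death_rate", list(beta = 3, d = 1, nu = nu),
                      omega = 1)
    for (x1 in c(0.1, 0.3)) {
      dm <- (evaluate_rates(mod, c(x1 + h, 0.3))$m -
               evaluate_rates(mod, c(x1 - h, 0.3))$m) / (2 * h)
      expect_equal(sign(dm), sign(nu))
    }
  }
  # birth-rate altruism: db/dx1 > 0; spite: db/dx1 < 0
  ba <- make_model("birth_altruism",
                   list(beta = 1, d = 0.5, nu = 0.75, kappa1 = 0.75,
                        kappa2 = 0.01), omega = 1)
  db <- (evaluate_rates(ba, c(0.2 + h, 0.3))$b -
           evaluate_rates(ba, c(0.2 - h, 0.3))$b) / (2 * h)
  expect_gt(db, 0)
  bs <- make_model("birth_spite",
                   list(beta = 8, d = 1, a = 0.05, nu = 0.5,
                        kappa1 = 0.05, kappa2 = 0.2), omega = 1)
  db <- (evaluate_rates(bs, c(0.2 + h, 0.3))$b -
           evaluate_rates(bs, c(0.2 - h, 0.3))$b) / (2 * h)
  expect_lt(db, 0)
})

test_that("a custom model reproduces a built-in family exactly", {
  builtin <- make_model("death_rate", list(beta = 3, d = 1, nu = -0.95),
                        omega = 900, mu = 0.006)
  custom <- make_model("custom", list(
    beta = 3, d = 1, nu = -0.95,
    birth = function(x, pr) pr$beta * (1 - sum(x)),
    death = function(x, pr) pr$d * (1 + pr$nu * x[1] / sum(x))
  ), omega = 900, mu = 0.006)
  set.seed(7)
  for (i in 1:25) {
    x <- runif(2, 0.01, 0.45)
    expect_identical(evaluate_rates(builtin, x)[, c("b", "m")],
                     evaluate_rates(custom, x)[, c("b", "m")])
  }
})

test_that("negative rate formulas are clamped to zero", {
  mod <- make_model("death_rate", list(beta = 3, d = 1, nu = 0), omega = 10)
  r <- suppressWarnings(evaluate_rates(mod, c(0.8, 0.8))) # n > 1
  expect_identical(r$b, 0)
  expect_gte(r$m, 0)
})

test_that("presets build valid models with their documented parameters", {
  pres <- c("deathrate_altruism", "deathrate_neutral", "deathrate_spite",
            "birth_altruism", "birth_spite", "linear_altruism",
            "turnover_altruism")
  for (nm in pres) {
    mod <- model_preset(nm)
    expect_s3_class(mod, "demsoc_model")
  }
  expect_equal(model_preset("deathrate_altruism")$params$nu, -0.95)
  expect_equal(model_preset("turnover_altruism")$params$r, 0.6)
  expect_equal(nrow(list_models()), 6)
})
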