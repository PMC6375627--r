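#' Demographic models of indiscriminate social action
#'
#' A `demsoc_model` bundles per-capita birth, death and cost rate functions
#' for a well-mixed population of social actors (type 1) and non-actors
#' (type 2), together with the habitat size `omega`, per-capita mutation
#' rate `mu` and cost magnitude `epsilon`. Rate functions take the per-type
#' density vector `x = N / omega` and return a per-capita rate; the social
#' action is indiscriminate, so birth and death rates are shared by both
#' types and only the actor pays the cost `epsilon * c(x)`.
#'
#' Built-in families (densities `x1` = actors, `x2` = non-actors,
#' `n = x1 + x2`):
#'
#' * `death_rate`: `b = beta * (1 - n)`, `m = d * (1 + nu * x1 / n)`.
#'   `nu < 0` is altruism (actors lower everyone's death rate), `nu > 0`
#'   spite. Requires `nu` in (-1, 1) and `beta > d * (1 + |nu|)`.
#' * `birth_altruism`: `b = beta + nu * x1`,
#'   `m = d + kappa1 * n + kappa2 * n^2`. Actors release a public good that
#'   raises everyone's birth rate (`nu >= 0`).
#' * `birth_spite`: `b = beta * (1 - nu * x1 / (n + a))`, same `m` as
#'   `birth_altruism`. Actors block reproduction with probability
#'   `nu * x1 / (n + a)`; requires `nu` in \[0, 1\], `a > 0`.
#' * `linear_altruism`: `b = r + nu * x1`, `m = kappa * n`, cost `c = r`.
#'   Requires `0 < r` and `kappa > nu > 0`. The turnover-to-size ratio `T/n`
#'   is constant in the actor frequency, so stochasticity is unbiased.
#' * `turnover_altruism`: `b = beta + nu * x1`, `m = d + kappa * n`, cost
#'   `c = r = beta - d`. Same per-capita growth rate as `linear_altruism`
#'   but with elevated baseline turnover; `T/n` decreases with actor
#'   frequency, so stochasticity favours the altruist.
#' * `custom`: user-supplied `birth`, `death` (and optionally `cost`)
#'   functions of `(x, params)`.
#'
#' @param family One of `"death_rate"`, `"birth_altruism"`, `"birth_spite"`,
#'   `"linear_altruism"`, `"turnover_altruism"`, `"custom"`.
#' @param params Named list of model constants (`beta`, `d`, `nu`, `kappa`,
#'   `kappa1`, `kappa2`, `a`, `r` as required by the family). For
#'   `"custom"`, also `birth`, `death` and optionally `cost` functions.
#' @param omega Habitat size (individuals per unit density), > 0.
#' @param mu Per-capita mutation rate between the two types, >= 0.
#' @param epsilon Cost magnitude, >= 0. The actor's extra per-capita cost
#'   rate is `epsilon * cost(x)`.
#' @param cost_on_death If `TRUE` (default) the cost is added to the
#'   actor's death rate; if `FALSE` it is subtracted from the actor's birth
#'   rate. At the order kept by the frequency diffusion both placements
#'   are equivalent.
#'
#' @return An object of class `demsoc_model`: a list with elements
#'   `family`, `params`, `omega`, `mu`, `epsilon`, `cost_on_death`,
#'   `n_types`, `actor_index`, and rate functions `birth`, `death`, `cost`.
#' @examples
#' mod <- make_model("death_rate", list(beta = 3, d = 1, nu = -0.95),
#'                   omega = 900, mu = 0.006)
#' evaluate_rates(mod, c(1 / 3, 1 / 3))
#' @export
make_model <- function(family, params = list(), omega, mu = 0, epsilon = 0,
                       cost_on_death = TRUE) {
  family <- match.arg(family, c("death_rate", "birth_altruism", "birth_spite",
                                "linear_altruism", "turnover_altruism",
                                "custom"))
  if (missing(omega)) {
    stop("`omega` (habitat size) must be supplied", call. = FALSE)
  }
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega))
  if (omega <= 0) stop("`omega` must be > 0", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0) {
    stop("`mu` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("`epsilon` must be a single number >= 0", call. = FALSE)
  }

  spec <- switch(family,
    death_rate = validate_death_rate(params),
    birth_altruism = validate_birth_altruism(params),
    birth_spite = validate_birth_spite(params),
    linear_altruism = validate_linear_altruism(params),
    turnover_altruism = validate_turnover_altruism(params),
    custom = validate_custom(params)
  )

  model <- structure(
    list(
      family = family,
      params = spec$params,
      omega = omega,
      mu = mu,
      epsilon = epsilon,
      cost_on_death = isTRUE(cost_on_death),
      n_types = 2L,
      actor_index = 1L,
      birth = spec$birth,
      death = spec$death,
      cost = spec$cost
    ),
    class = "demsoc_model"
  )
  check_rates_finite(model)
  model
}

# --- family validators -------------------------------------------------------

need_params <- function(params, required, family) {
  missing <- setdiff(required, names(params))
  if (length(missing)) {
    stop(sprintf("model family '%s' requires parameter(s): %s",
                 family, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (nm in required) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
  }
  params[required]
}

constraint <- function(ok, msg) {
  if (!ok) stop(paste0("parameter constraint violated: ", msg), call. = FALSE)
}

validate_death_rate <- function(params) {
  p <- need_params(params, c("beta", "d", "nu"), "death_rate")
  constraint(p$nu > -1 && p$nu < 1, "death_rate requires nu in (-1, 1)")
  constraint(p$d > 0, "death_rate requires d > 0")
  constraint(p$beta > p$d * (1 + abs(p$nu)),
             "death_rate requires beta > d * (1 + |nu|)")
  list(
    params = p,
    birth = function(x, pr) pr$beta * (1 - sum(x)),
    death = function(x, pr) {
      n <- sum(x)
      if (n <= 0) return(pr$d)
      pr$d * (1 + pr$nu * x[1] / n)
    },
    cost = function(x, pr) 1
  )
}

validate_birth_altruism <- function(params) {
  p <- need_params(params, c("beta", "d", "nu", "kappa1", "kappa2"),
                   "birth_altruism")
  constraint(p$nu >= 0, "birth_altruism requires nu >= 0")
  constraint(p$beta > p$d, "birth_altruism requires beta > d")
  constraint(p$kappa2 >= 0 && p$kappa1 >= 0 && (p$kappa1 + p$kappa2) > 0,
             "birth_altruism requires kappa1, kappa2 >= 0, not both zero")
  list(
    params = p,
    birth = function(x, pr) pr$beta + pr$nu * x[1],
    death = function(x, pr) {
      n <- sum(x)
      pr$d + pr$kappa1 * n + pr$kappa2 * n^2
    },
    cost = function(x, pr) 1
  )
}

validate_birth_spite <- function(params) {
  p <- need_params(params, c("beta", "d", "a", "nu", "kappa1", "kappa2"),
                   "birth_spite")
  constraint(p$nu >= 0 && p$nu <= 1, "birth_spite requires nu in [0, 1]")
  constraint(p$a > 0, "birth_spite requires a > 0")
  constraint(p$beta > p$d, "birth_spite requires beta > d")
  constraint(p$kappa2 >= 0 && p$kappa1 >= 0 && (p$kappa1 + p$kappa2) > 0,
             "birth_spite requires kappa1, kappa2 >= 0, not both zero")
  list(
    params = p,
    birth = function(x, pr) {
      n <- sum(x)
      pr$beta * (1 - pr$nu * x[1] / (n + pr$a))
    },
    death = function(x, pr) {
      n <- sum(x)
      pr$d + pr$kappa1 * n + pr$kappa2 * n^2
    },
    cost = function(x, pr) 1
  )
}

validate_linear_altruism <- function(params) {
  p <- need_params(params, c("r", "kappa", "nu"), "linear_altruism")
  constraint(p$r > 0, "linear_altruism requires r > 0")
  constraint(p$kappa > p$nu && p$nu > 0,
             "linear_altruism requires kappa > nu > 0")
  list(
    params = p,
    birth = function(x, pr) pr$r + pr$nu * x[1],
    death = function(x, pr) pr$kappa * sum(x),
    cost = function(x, pr) pr$r
  )
}

validate_turnover_altruism <- function(params) {
  p <- need_params(params, c("beta", "d", "kappa", "nu"), "turnover_altruism")
  constraint(p$beta > p$d, "turnover_altruism requires beta > d (r = beta - d > 0)")
  constraint(p$d > 0, "turnover_altruism requires d > 0")
  constraint(p$kappa > p$nu && p$nu > 0,
             "turnover_altruism requires kappa > nu > 0")
  p$r <- p$beta - p$d
  list(
    params = p,
    birth = function(x, pr) pr$beta + pr$nu * x[1],
    death = function(x, pr) pr$d + pr$kappa * sum(x),
    cost = function(x, pr) pr$r
  )
}

validate_custom <- function(params) {
  if (!is.function(params$birth) || !is.function(params$death)) {
    stop("custom models require `birth` and `death` functions of (x, params)",
         call. = FALSE)
  }
  cost <- params$cost
  if (is.null(cost)) cost <- function(x, pr) 1
  if (!is.function(cost)) stop("`cost` must be a function of (x, params)",
                               call. = FALSE)
  consts <- params[setdiff(names(params), c("birth", "death", "cost"))]
  list(params = consts, birth = params$birth, death = params$death,
       cost = cost)
}

# Birth and death must be finite and non-negative on a sampling grid of the
# admissible density domain (rate formulas that go negative, e.g. logistic
# birth beyond n = 1, are clamped at evaluation time, so only finiteness is
# fatal here).
check_rates_finite <- function(model) {
  ns <- c(0.01, 0.1, 0.5, 1, 2)
  ps <- c(0, 0.25, 0.5, 0.75, 1)
  for (n in ns) {
    for (p in ps) {
      x <- c(p * n, (1 - p) * n)
      b <- model$birth(x, model$params)
      m <- model$death(x, model$params)
      if (!is.finite(b) || !is.finite(m)) {
        stop(sprintf("rates non-finite at density (%.3g, %.3g)", x[1], x[2]),
             call. = FALSE)
      }
    }
  }
  invisible(model)
}

#' @export
print.demsoc_model <- function(x, ...) {
  cat("<demsoc_model> family:", x$family, "\n")
  consts <- x$params[vapply(x$params, is.numeric, logical(1))]
  if (length(consts)) {
    cat("  params:",
        paste(sprintf("%s = %g", names(consts), unlist(consts)),
              collapse = ", "), "\n")
  }
  cat(sprintf("  omega = %g, mu = %g, epsilon = %g (cost on %s)\n",
              x$omega, x$mu, x$epsilon,
              if (x$cost_on_death) "death" else "birth"))
  invisible(x)
}

#' Evaluate per-capita rates at a density state
#'
#' Evaluates the per-capita birth, death and cost rates of a model at the
#' per-type density vector `x`. Birth and death formulas that evaluate
#' negative (reachable by stochastic excursions, e.g. logistic birth at
#' total density above 1) are clamped to zero; a warning is emitted once
#' per session.
#'
#' @param model A [make_model()] object.
#' @param x Numeric density vector `c(x1, x2)` with `x1` the social-actor
#'   density; all entries must be >= 0.
#' @return A one-row tibble with columns `b`, `m`, `cost` (per-capita
#'   rates per unit time).
#' @examples
#' mod <- make_model("death_rate", list(beta = 3, d = 1, nu = 0), omega = 900)
#' evaluate_rates(mod, c(1 / 3, 1 / 3)) # b = 1, m = 1
#' @export
evaluate_rates <- function(model, x) {
  stopifnot(inherits(model, "demsoc_model"))
  if (!is.numeric(x) || length(x) != model$n_types) {
    stop(sprintf("`x` must be a numeric density vector of length %d",
                 model$n_types), call. = FALSE)
  }
  if (any(x < 0)) stop("densities must be >= 0", call. = FALSE)
  r <- rates_raw(model, x)
  tibble::tibble(b = r[1], m = r[2], cost = r[3])
}

# internal fast path: returns c(b, m, cost), clamped at 0
rates_raw <- function(model, x) {
  pr <- model$params
  b <- model$birth(x, pr)
  m <- model$death(x, pr)
  cc <- model$cost(x, pr)
  if (b < 0 || m < 0) {
    rlang::warn("rate formula evaluated negative; clamped to 0",
                .frequency = "once", .frequency_id = "demsoc_rate_clamp")
    b <- max(b, 0)
    m <- max(m, 0)
  }
  c(b, m, max(cc, 0))
}

#' List built-in model families
#'
#' @return A tibble with one row per family: its name, rate formulas and
#'   parameter constraints.
#' @export
list_models <- function() {
  tibble::tibble(
    family = c("death_rate", "birth_altruism", "birth_spite",
               "linear_altruism", "turnover_altruism", "custom"),
    birth = c("beta * (1 - n)", "beta + nu * x1",
              "beta * (1 - nu * x1 / (n + a))",
              "r + nu * x1", "beta + nu * x1", "user-supplied"),
    death = c("d * (1 + nu * x1 / n)", "d + kappa1 * n + kappa2 * n^2",
              "d + kappa1 * n + kappa2 * n^2", "kappa * n",
              "d + kappa * n", "user-supplied"),
    cost = c("1", "1", "1", "r", "r = beta - d", "user-supplied"),
    constraints = c("nu in (-1,1); beta > d (1 + |nu|); d > 0",
                    "nu >= 0; beta > d; kappa1, kappa2 >= 0 (not both 0)",
                    "nu in [0,1]; a > 0; beta > d; kappa1, kappa2 >= 0",
                    "r > 0; kappa > nu > 0",
                    "beta > d; kappa > nu > 0",
                    "birth, death finite and >= 0 on the density domain")
  )
}

#' Named model presets
#'
#' Ready-made `demsoc_model` objects with the parameter sets used in the
#' worked analyses of the package (see the vignette). Available presets:
#'
#' * `deathrate_altruism`, `deathrate_neutral`, `deathrate_spite`:
#'   death-rate model, `beta = 3`, `d = 1`, `nu = -0.95 / 0 / 0.95`,
#'   `omega = 900`, `mu = 0.006`.
#' * `birth_altruism`: `beta = 1`, `d = 0.5`, `kappa1 = 0.75`,
#'   `kappa2 = 0.01`, `nu = 0.75`, `omega = 250`, `mu = 0.01`.
#' * `birth_spite`: `beta = 8`, `d = 1`, `a = 0.05`, `kappa1 = 0.05`,
#'   `kappa2 = 0.2`, `nu = 0.75`, `omega = 900`, `mu = 0.005`.
#' * `linear_altruism`: `r` = 0.6, `kappa = 1.2`, `nu = 1`,
#'   `epsilon = 0.003`, `omega = 100`, `mu = 0.01`.
#' * `turnover_altruism`: `beta = 3`, `d = 2.4`, `kappa = 1.2`, `nu = 1`
#'   (so `r` = 0.6), `epsilon = 0.003`, `omega = 100`, `mu = 0.01`.
#'
#' @param name Preset name.
#' @return A `demsoc_model`.
#' @examples
#' model_preset("deathrate_altruism")
#' @export
model_preset <- function(name) {
  name <- match.arg(name, c("deathrate_altruism", "deathrate_neutral",
                            "deathrate_spite", "birth_altruism",
                            "birth_spite", "linear_altruism",
                            "turnover_altruism"))
  switch(name,
    deathrate_altruism = make_model("death_rate",
      list(beta = 3, d = 1, nu = -0.95), omega = 900, mu = 0.006),
    deathrate_neutral = make_model("death_rate",
      list(beta = 3, d = 1, nu = 0), omega = 900, mu = 0.006),
    deathrate_spite = make_model("death_rate",
      list(beta = 3, d = 1, nu = 0.95), omega = 900, mu = 0.006),
    birth_altruism = make_model("birth_altruism",
      list(beta = 1, d = 0.5, nu = 0.75, kappa1 = 0.75, kappa2 = 0.01),
      omega = 250, mu = 0.01),
    birth_spite = make_model("birth_spite",
      list(beta = 8, d = 1, a = 0.05, nu = 0.75, kappa1 = 0.05, kappa2 = 0.2),
      omega = 900, mu = 0.005),
    linear_altruism = make_model("linear_altruism",
      list(r = 0.6, kappa = 1.2, nu = 1), omega = 100, mu = 0.01,
      epsilon = 0.003),
    turnover_altruism = make_model("turnover_altruism",
      list(beta = 3, d = 2.4, kappa = 1.2, nu = 1), omega = 100, mu = 0.01,
      epsilon = 0.003)
  )
}

# rebuild a model with some top-level fields replaced (omega, mu, epsilon,
# or a parameter value); used by scans and sweeps
update_model <- function(model, ..., params = NULL) {
  dots <- list(...)
  new_params <- model$params
  if (!is.null(params)) new_params[names(params)] <- params
  if (model$family == "custom") {
    new_params$birth <- model$birth
    new_params$death <- model$death
    new_params$cost <- model$cost
  }
  args <- list(
    family = model$family,
    params = new_params,
    omega = model$omega,
    mu = model$mu,
    epsilon = model$epsilon,
    cost_on_death = model$cost_on_death
  )
  args[names(dots)] <- dots
  do.call(make_model, args)
}
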