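#' Quasi-equilibrium population density n(p)
#'
#' On the slow evolutionary timescale the fast demographic dynamics sit on
#' the curve of ecological equilibria `b = m`. For a given actor frequency
#' `p` this function returns the dynamically stable positive density `n`
#' solving `b(x) = m(x)` with `x = (p n, (1 - p) n)`. The manifold is
#' computed at `epsilon = 0` (the cost only enters the frequency drift at
#' the order kept by the diffusion).
#'
#' Built-in families use their closed-form roots; custom models use a
#' bracketed numeric search with stability selected by the sign of
#' `d(b - m)/dn` (see `Details`).
#'
#' @details For custom models the root is located by scanning
#' `n` over `(0, n_max]` for sign changes of `b - m` and polishing each
#' with [stats::uniroot()]; a root is kept if the finite-difference slope
#' of `b - m` in `n` is negative (asymptotic stability of the fast
#' dynamics). `n_max` defaults to an expanding bracket. An error is raised
#' if no stable positive root exists, or if several do (supply `n_max`
#' to pick a bracket).
#'
#' @param model A [make_model()] object.
#' @param p Actor frequency (vectorised), in \[0, 1\].
#' @param n_max Upper end of the root bracket for numeric search
#'   (custom models only); `NULL` for automatic expansion.
#' @return Numeric vector of stable equilibrium densities, same length
#'   as `p`.
#' @examples
#' mod <- make_model("death_rate", list(beta = 3, d = 1, nu = 0), omega = 900)
#' quasi_equilibrium_density(mod, 0.5) # 2/3
#' @export
quasi_equilibrium_density <- function(model, p, n_max = NULL) {
  stopifnot(inherits(model, "demsoc_model"))
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  vapply(p, function(pi) n_of_p(model, pi, n_max), numeric(1))
}

n_of_p <- function(model, p, n_max = NULL) {
  pr <- model$params
  switch(model$family,
    death_rate = {
      # beta (1 - n) = d (1 + nu p)
      n <- 1 - pr$d * (1 + pr$nu * p) / pr$beta
      if (n <= 0) stop("no ecological equilibrium: density root <= 0",
                       call. = FALSE)
      n
    },
    birth_altruism = {
      # kappa2 n^2 + (kappa1 - nu p) n + (d - beta) = 0, positive root
      if (pr$kappa2 == 0) {
        denom <- pr$kappa1 - pr$nu * p
        if (denom <= 0) stop("no ecological equilibrium: unregulated growth",
                             call. = FALSE)
        (pr$beta - pr$d) / denom
      } else {
        bq <- pr$kappa1 - pr$nu * p
        disc <- bq^2 + 4 * pr$kappa2 * (pr$beta - pr$d)
        (-bq + sqrt(disc)) / (2 * pr$kappa2)
      }
    },
    birth_spite = {
      # beta (n + a - nu p n) = (d + kappa1 n + kappa2 n^2)(n + a)
      co <- c(pr$a * (pr$d - pr$beta),
              pr$d + pr$a * pr$kappa1 - pr$beta * (1 - pr$nu * p),
              pr$kappa1 + pr$a * pr$kappa2,
              pr$kappa2)
      while (length(co) > 1 && co[length(co)] == 0) co <- co[-length(co)]
      roots <- polyroot(co)
      re <- Re(roots)[abs(Im(roots)) < 1e-9 & Re(roots) > 0]
      stable <- re[vapply(re, function(n) stable_root(model, p, n), logical(1))]
      if (length(stable) == 0L) {
        stop("no ecological equilibrium for birth_spite at this p",
             call. = FALSE)
      }
      min(stable)
    },
    linear_altruism = pr$r / (pr$kappa - pr$nu * p),
    turnover_altruism = (pr$beta - pr$d) / (pr$kappa - pr$nu * p),
    custom = n_of_p_numeric(model, p, n_max)
  )
}

bm_gap <- function(model, p, n) {
  x <- c(p * n, (1 - p) * n)
  model$birth(x, model$params) - model$death(x, model$params)
}

stable_root <- function(model, p, n, h = NULL) {
  if (is.null(h)) h <- max(1e-6, 1e-6 * n)
  (bm_gap(model, p, n + h) - bm_gap(model, p, max(n - h, 1e-12))) < 0
}

n_of_p_numeric <- function(model, p, n_max = NULL) {
  f <- function(n) bm_gap(model, p, n)
  if (is.null(n_max)) {
    n_max <- 1
    while (f(n_max) > 0 && n_max < 2^20) n_max <- n_max * 2
  }
  grid <- seq(1e-8, n_max, length.out = 512L)
  vals <- vapply(grid, f, numeric(1))
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  roots <- c(roots, grid[vals == 0])
  stable <- roots[vapply(roots, function(n) stable_root(model, p, n),
                         logical(1))]
  if (length(stable) == 0L) {
    stop("no ecological equilibrium found in (0, n_max]", call. = FALSE)
  }
  if (length(stable) > 1L &&
      diff(range(stable)) > 1e-6 * max(stable)) {
    stop("multiple stable equilibria; supply an explicit `n_max` bracket",
         call. = FALSE)
  }
  stable[1]
}

# per-capita rates evaluated on the manifold at frequency p
manifold_rates <- function(model, p, n = NULL) {
  if (is.null(n)) n <- n_of_p(model, p)
  x <- c(p * n, (1 - p) * n)
  r <- rates_raw(model, x)
  list(n = n, b = r[1], m = r[2], cost = r[3], turnover = r[1] + r[2])
}

#' Drift and noise coefficients of the frequency diffusion
#'
#' On the slow manifold the actor frequency follows the one-dimensional
#' diffusion `dp = alpha(p) dt + sqrt(sigma2(p)) dW`, with
#' `alpha(p) = mu (1 - 2 p) - epsilon c(p) p (1 - p)` and
#' `sigma2(p) = p (1 - p) T(p) / (omega n(p))`, where
#' `T(p) = b(p) + m(p) = 2 m(p)` is the population turnover at
#' quasi-equilibrium.
#'
#' @inheritParams quasi_equilibrium_density
#' @return A tibble with columns `p`, `n`, `turnover`, `alpha`, `sigma2`.
#' @examples
#' mod <- make_model("death_rate", list(beta = 3, d = 1, nu = 0),
#'                   omega = 900, mu = 0.006)
#' diffusion_coefficients(mod, 0.5) # sigma2 = 1/1200
#' @export
diffusion_coefficients <- function(model, p) {
  stopifnot(inherits(model, "demsoc_model"))
  mr <- lapply(p, function(pi) manifold_rates(model, pi))
  n <- vapply(mr, `[[`, numeric(1), "n")
  turnover <- vapply(mr, `[[`, numeric(1), "turnover")
  cost <- vapply(mr, `[[`, numeric(1), "cost")
  tibble::tibble(
    p = p, n = n, turnover = turnover,
    alpha = model$mu * (1 - 2 * p) - model$epsilon * cost * p * (1 - p),
    sigma2 = p * (1 - p) * turnover / (model$omega * n)
  )
}

#' Slow-manifold summary on a frequency grid
#'
#' Tabulates the quasi-equilibrium density `n(p)`, turnover
#' `T(p) = b + m`, the diffusion coefficients `alpha(p)` and `sigma2(p)`,
#' the turnover-to-size ratio `T/n`, and the decomposition of its
#' derivative
#' `d/dp (T/n) = (T/n) * (term_size + term_turnover)` with
#' `term_size = -(dn/dp)/n` (effect of the social trait on population
#' size) and `term_turnover = (dT/dp)/T` (effect on turnover).
#' Derivatives use centred finite differences on the grid; the two
#' boundary rows use one-sided differences and are flagged in the
#' `fd_scheme` column.
#'
#' @inheritParams quasi_equilibrium_density
#' @param grid_size Number of equally spaced frequencies on \[0, 1\]
#'   (default 401).
#' @return A tibble with columns `p`, `n`, `turnover`, `alpha`, `sigma2`,
#'   `ratio`, `d_ratio`, `term_size`, `term_turnover`, `fd_scheme`.
#' @examples
#' mod <- model_preset("linear_altruism")
#' sm <- slow_manifold(mod, grid_size = 101)
#' all(abs(sm$d_ratio) < 1e-8) # T/n constant for this family
#' @export
slow_manifold <- function(model, grid_size = 401L) {
  stopifnot(grid_size >= 5L)
  p <- seq(0, 1, length.out = grid_size)
  tab <- diffusion_coefficients(model, p)
  dn <- fd_derivative(p, tab$n)
  dT <- fd_derivative(p, tab$turnover)
  term_size <- -dn / tab$n
  term_turnover <- ifelse(tab$turnover > 0, dT / tab$turnover, NA_real_)
  ratio <- tab$turnover / tab$n
  tab$ratio <- ratio
  tab$term_size <- term_size
  tab$term_turnover <- term_turnover
  tab$d_ratio <- ratio * (term_size + term_turnover)
  tab$fd_scheme <- c("one-sided", rep("centered", grid_size - 2L),
                     "one-sided")
  tab[, c("p", "n", "turnover", "alpha", "sigma2", "ratio", "d_ratio",
          "term_size", "term_turnover", "fd_scheme")]
}

fd_derivative <- function(x, y) {
  k <- length(x)
  d <- numeric(k)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[k] <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
  d[2:(k - 1)] <- (y[3:k] - y[1:(k - 2)]) / (x[3:k] - x[1:(k - 2)])
  d
}

#' Decomposition of the turnover-to-size ratio derivative at one frequency
#'
#' Convenience wrapper around [slow_manifold()] returning the
#' `d/dp (T/n)` decomposition at a single interior frequency.
#'
#' @inheritParams quasi_equilibrium_density
#' @param h Finite-difference half-step (default 1e-4).
#' @return A one-row tibble with columns `p`, `total` (the derivative),
#'   `term_size`, `term_turnover`.
#' @export
turnover_ratio_decomposition <- function(model, p, h = 1e-4) {
  stopifnot(length(p) == 1L)
  if (p < h || p > 1 - h) {
    stop("`p` must be an interior frequency (at least `h` from 0 and 1)",
         call. = FALSE)
  }
  lo <- manifold_rates(model, p - h)
  mid <- manifold_rates(model, p)
  hi <- manifold_rates(model, p + h)
  term_size <- -((hi$n - lo$n) / (2 * h)) / mid$n
  term_turnover <- ((hi$turnover - lo$turnover) / (2 * h)) / mid$turnover
  tibble::tibble(
    p = p,
    total = (mid$turnover / mid$n) * (term_size + term_turnover),
    term_size = term_size,
    term_turnover = term_turnover
  )
}
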