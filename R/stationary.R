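#' Stationary distribution of the frequency diffusion
#'
#' Computes the stationary density `pi(p)` of the one-dimensional
#' frequency diffusion `dp = alpha(p) dt + sqrt(sigma2(p)) dW` using the
#' standard speed-measure formula
#' `pi(p) ~ (1 / sigma2(p)) * exp(int 2 alpha / sigma2 dp)`.
#'
#' The mutational part of the exponent integral has integrable
#' singularities at the boundaries; they are split off analytically:
#' writing `g(p) = 2 omega n(p) / T(p)`, the density is
#' `p^(a0 - 1) (1 - p)^(a1 - 1) * exp(R(p))` with exact boundary exponents
#' `a0 = mu g(0)`, `a1 = mu g(1)` and a regular remainder `R` accumulated
#' by trapezoidal quadrature from `p = 1/2` outward. Normalisation adds
#' analytic power-law tail corrections below the first and above the last
#' grid point. The density is normalisable iff both boundary exponents are
#' positive (i.e. `mu > 0`); otherwise `integrable` is `FALSE` and the
#' unnormalised log-density is still returned.
#'
#' @param model A [make_model()] object with `mu >= 0`.
#' @param grid_size Number of interior grid points (default 4001).
#' @param delta Distance of the first/last grid point from the boundaries
#'   (default 1e-4).
#' @return An object of class `demsoc_stationary`: a list with
#'   * `grid`: tibble with columns `p`, `density` (normalised; `NA` when
#'     not integrable), `log_unnormalized`;
#'   * `exponents`: `c(a0, a1)`, the boundary exponents of the density;
#'   * `integrable`: logical;
#'   * `log_normalization`: log of the normalisation constant `Z` such
#'     that `density = exp(log_unnormalized - log_normalization)`;
#'   * `mass_above_half`: stationary mass on `(1/2, 1)`;
#'   * `model`: the input model.
#' @examples
#' mod <- model_preset("deathrate_neutral")
#' pi0 <- stationary_density(mod)
#' pi0$mass_above_half # 0.5 by symmetry
#' @export
stationary_density <- function(model, grid_size = 4001L, delta = 1e-4) {
  stopifnot(inherits(model, "demsoc_model"), grid_size >= 101L,
            delta > 0, delta < 0.05)
  p <- seq(delta, 1 - delta, length.out = grid_size)
  mid <- (grid_size + 1L) %/% 2L
  if (abs(p[mid] - 0.5) > 1e-12) {
    # force an anchor at exactly 1/2 (symmetric grids have one already)
    p <- sort(unique(c(p, 0.5)))
    mid <- which(p == 0.5)
    grid_size <- length(p)
  }

  mf <- lapply(p, function(pi) manifold_rates(model, pi))
  n <- vapply(mf, `[[`, numeric(1), "n")
  turnover <- vapply(mf, `[[`, numeric(1), "turnover")
  cost <- vapply(mf, `[[`, numeric(1), "cost")
  g <- 2 * model$omega * n / turnover

  mr0 <- manifold_rates(model, 0)
  mr1 <- manifold_rates(model, 1)
  g0 <- 2 * model$omega * mr0$n / mr0$turnover
  g1 <- 2 * model$omega * mr1$n / mr1$turnover
  a0 <- model$mu * g0
  a1 <- model$mu * g1

  # regular remainder of 2 alpha / sigma2 after removing the boundary poles
  r <- model$mu * (g - g0) / p - model$mu * (g - g1) / (1 - p) -
    model$epsilon * cost * g
  R <- cum_trapz_from(p, r, mid)

  log_u <- (a0 - 1) * log(p) + (a1 - 1) * log1p(-p) -
    log(turnover / (model$omega * n)) + R

  integrable <- is.finite(a0) && is.finite(a1) && a0 > 0 && a1 > 0

  if (integrable) {
    s <- max(log_u)
    w <- exp(log_u - s)
    # tails: pi ~ C p^(a0-1) near 0 => integral below p[1] is w[1] * p[1] / a0
    tail0 <- w[1] * p[1] / a0
    tail1 <- w[grid_size] * (1 - p[grid_size]) / a1
    upper <- trapz(p[mid:grid_size], w[mid:grid_size]) + tail1
    lower <- trapz(p[1:mid], w[1:mid]) + tail0
    z <- upper + lower
    density <- w / z
    log_z <- log(z) + s
    mass_above_half <- upper / z
  } else {
    density <- rep(NA_real_, grid_size)
    log_z <- NA_real_
    mass_above_half <- NA_real_
  }

  structure(
    list(
      grid = tibble::tibble(p = p, density = density,
                            log_unnormalized = log_u),
      exponents = c(a0 = unname(a0), a1 = unname(a1)),
      integrable = integrable,
      log_normalization = log_z,
      mass_above_half = mass_above_half,
      model = model
    ),
    class = "demsoc_stationary"
  )
}

trapz <- function(x, y) {
  k <- length(x)
  sum((x[-1] - x[-k]) * (y[-1] + y[-k])) / 2
}

# cumulative trapezoid of y over x, anchored to 0 at index `mid`
cum_trapz_from <- function(x, y, mid) {
  k <- length(x)
  inc <- c(0, cumsum((x[-1] - x[-k]) * (y[-1] + y[-k]) / 2))
  inc - inc[mid]
}

#' @export
print.demsoc_stationary <- function(x, ...) {
  cat("<demsoc_stationary>", x$model$family, "model\n")
  cat(sprintf("  boundary exponents a0 = %.4g, a1 = %.4g; integrable: %s\n",
              x$exponents[1], x$exponents[2], x$integrable))
  if (x$integrable) {
    cat(sprintf("  mass above p = 1/2: %.4f\n", x$mass_above_half))
  }
  invisible(x)
}

#' Closed-form stationary density, linear-altruism model
#'
#' Unnormalised stationary density of the frequency diffusion for the
#' `linear_altruism` family (`b = r + nu x1`, `m = kappa n`, cost
#' `c = r`):
#' `pi(p) ~ p^(mu omega / kappa - 1) (1 - p)^(mu omega / kappa - 1)
#'  exp(-epsilon r omega p / kappa)`.
#' At `epsilon = 0` this is a symmetric Beta density, so a cost-free
#' social trait of this family is exactly neutral; with `epsilon > 0` the
#' density is tilted toward the non-actor for every `omega` and `mu`.
#'
#' @param p Frequencies in (0, 1) (vectorised).
#' @param model A `linear_altruism` [make_model()] object, or `NULL` if
#'   the individual parameters are given.
#' @param r,kappa,mu,omega,epsilon Model constants (ignored when `model`
#'   is supplied).
#' @param log Return the log-density?
#' @return Unnormalised density (or log-density) values.
#' @export
closed_form_linear_altruism <- function(p, model = NULL, r, kappa, mu,
                                        omega, epsilon = 0, log = FALSE) {
  if (!is.null(model)) {
    stopifnot(model$family == "linear_altruism")
    r <- model$params$r; kappa <- model$params$kappa
    mu <- model$mu; omega <- model$omega; epsilon <- model$epsilon
  }
  a <- mu * omega / kappa
  lg <- (a - 1) * (log(p) + log1p(-p)) - epsilon * r * omega * p / kappa
  if (log) lg else exp(lg)
}

#' Closed-form stationary density, turnover-altruism model
#'
#' Unnormalised stationary density for the `turnover_altruism` family
#' (`b = beta + nu x1`, `m = d + kappa n`, cost `c = r = beta - d`):
#' `pi(p) ~ p^(A - 1) (1 - p)^(B - 1)
#'   (beta kappa - d nu p)^(E - A - B - 1)`
#' with `A = mu omega r / (beta kappa)`,
#' `B = mu omega r / (beta kappa - d nu)` and
#' `E = epsilon omega r^2 / (d nu)`. Requires
#' `beta kappa - d nu > 0`. At `nu = 0` the limiting form
#' `p^(A-1) (1-p)^(A-1) exp(-epsilon omega r^2 p / (beta kappa))` is used.
#'
#' Because `B > A`, the cost-free density is skewed toward the actor:
#' demographic noise shrinks as altruists become common (the
#' turnover-to-size ratio decreases in `p`), so the process lingers there.
#'
#' @inheritParams closed_form_linear_altruism
#' @param beta,d,kappa,nu,mu,omega,epsilon Model constants (ignored when
#'   `model` is supplied).
#' @return Unnormalised density (or log-density) values.
#' @export
closed_form_turnover_altruism <- function(p, model = NULL, beta, d, kappa,
                                          nu, mu, omega, epsilon = 0,
                                          log = FALSE) {
  if (!is.null(model)) {
    stopifnot(model$family == "turnover_altruism")
    beta <- model$params$beta; d <- model$params$d
    kappa <- model$params$kappa; nu <- model$params$nu
    mu <- model$mu; omega <- model$omega; epsilon <- model$epsilon
  }
  r <- beta - d
  if (beta * kappa - d * nu <= 0) {
    stop("requires beta * kappa - d * nu > 0", call. = FALSE)
  }
  if (nu == 0) {
    a <- mu * omega * r / (beta * kappa)
    lg <- (a - 1) * (log(p) + log1p(-p)) -
      epsilon * omega * r^2 * p / (beta * kappa)
  } else {
    A <- mu * omega * r / (beta * kappa)
    B <- mu * omega * r / (beta * kappa - d * nu)
    E <- epsilon * omega * r^2 / (d * nu)
    lg <- (A - 1) * log(p) + (B - 1) * log1p(-p) +
      (E - A - B - 1) * log(beta * kappa - d * nu * p)
  }
  if (log) lg else exp(lg)
}

#' Favourability of the social actor under the stationary distribution
#'
#' The social actor is stochastically favoured if the stationary
#' occupancy mass above `p = 1/2` exceeds 1/2: the process is then more
#' often observed in states where actors outnumber non-actors. A
#' favourable verdict with `epsilon > 0` is a selective reversal:
#' demographic stochasticity overcomes the deterministic selection
#' against the costly trait.
#'
#' Shape classes are assigned from the boundary exponents and the strict
#' interior modes of the log-density (tie threshold 1e-10): `"U"` (both
#' boundaries accumulate, no interior mode), `"bell"` (no boundary
#' accumulation, a single interior mode), `"boundary-unimodal"` (exactly
#' one boundary accumulates, at most one interior mode), `"other"`.
#'
#' @param dist A [stationary_density()] object.
#' @param model Optional model override (defaults to `dist$model`).
#' @return A one-row tibble: `mass_above_half`, `favoured`, `shape`,
#'   `reversal`, `epsilon`, `integrable`.
#' @export
favourability <- function(dist, model = dist$model) {
  stopifnot(inherits(dist, "demsoc_stationary"))
  if (!dist$integrable) {
    stop("stationary density is not integrable (boundary exponent <= 0); ",
         "increase mu", call. = FALSE)
  }
  shape <- classify_shape(dist)
  mass <- dist$mass_above_half
  favoured <- mass > 0.5
  tibble::tibble(
    mass_above_half = mass,
    favoured = favoured,
    shape = shape,
    reversal = favoured && model$epsilon > 0,
    epsilon = model$epsilon,
    integrable = dist$integrable
  )
}

classify_shape <- function(dist, tie_tol = 1e-10) {
  lg <- dist$grid$log_unnormalized
  k <- length(lg)
  interior <- which(lg[2:(k - 1)] > lg[1:(k - 2)] + tie_tol &
                      lg[2:(k - 1)] > lg[3:k] + tie_tol)
  n_modes <- count_mode_runs(lg, tie_tol)
  div0 <- dist$exponents[1] < 1
  div1 <- dist$exponents[2] < 1
  if (div0 && div1) {
    if (n_modes == 0) "U" else "other"
  } else if (!div0 && !div1) {
    if (n_modes == 1) "bell" else "other"
  } else {
    if (n_modes <= 1) "boundary-unimodal" else "other"
  }
}

# count strict local maxima of the log-density on the interior grid,
# merging plateau runs within the tie threshold
count_mode_runs <- function(lg, tie_tol) {
  k <- length(lg)
  is_max <- c(FALSE,
              lg[2:(k - 1)] > lg[1:(k - 2)] + tie_tol &
                lg[2:(k - 1)] > lg[3:k] + tie_tol,
              FALSE)
  idx <- which(is_max)
  if (length(idx) == 0L) return(0L)
  sum(c(TRUE, diff(idx) > 1))
}
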