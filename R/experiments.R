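#' Optimal social-action strength minimizing T/n
#'
#' In a monomorphic actor population (`p = 1`) the stochastically
#' favoured level of social action minimizes the turnover-to-size ratio
#' `T(1)/n(1)`. For the birth-rate families with mortality
#' `m = d + kappa1 n + kappa2 n^2` the minimum of
#' `T/n = 2 (d/n + kappa1 + kappa2 n)` over density sits at
#' `theta = sqrt(d / kappa2)`, giving the closed forms
#' `nu* = kappa1 - |beta - 2 d| / theta` (altruism) and
#' `nu* = (a + theta) (beta - 2 d - kappa1 theta) / (beta theta)` (spite).
#'
#' Both the closed form and a direct numeric minimization of `T(1)/n(1)`
#' over `nu` (golden-section search, tolerance 1e-9) are returned. The
#' numeric optimum is authoritative: for `beta < 2 d` the printed
#' altruism closed form can disagree with the interior optimum
#' (`agree = FALSE`), and a closed-form value outside the family's
#' admissible range is flagged as a boundary optimum.
#'
#' @param family `"birth_altruism"` or `"birth_spite"`.
#' @param params Named list with `beta`, `d`, `kappa1`, `kappa2` (and `a`
#'   for spite).
#' @param nu_upper Upper end of the numeric search interval for altruism
#'   (default wide enough to contain the interior optimum); spite
#'   searches \[0, 1\].
#' @return A one-row tibble: `family`, `nu_star_closed`,
#'   `nu_star_numeric`, `theta`, `objective` (T/n at the numeric
#'   optimum), `boundary`, `agree`.
#' @examples
#' optimal_social_action("birth_altruism",
#'   list(beta = 1, d = 0.5, kappa1 = 0.75, kappa2 = 0.01)) # nu* = 0.75
#' @export
optimal_social_action <- function(family = c("birth_altruism",
                                             "birth_spite"),
                                  params, nu_upper = NULL) {
  family <- match.arg(family)
  pr <- params
  stopifnot(pr$kappa2 > 0, pr$d > 0)
  theta <- sqrt(pr$d / pr$kappa2)
  closed <- if (family == "birth_altruism") {
    pr$kappa1 - abs(pr$beta - 2 * pr$d) / theta
  } else {
    (pr$a + theta) * (pr$beta - 2 * pr$d - pr$kappa1 * theta) /
      (pr$beta * theta)
  }

  objective <- function(nu) {
    p2 <- pr
    p2$nu <- nu
    mod <- make_model(family, p2, omega = 1, mu = 0)
    mr <- manifold_rates(mod, 1)
    mr$turnover / mr$n
  }

  if (family == "birth_altruism") {
    if (is.null(nu_upper)) {
      nu_upper <- pr$kappa1 + (2 * pr$d + pr$beta) / theta + 1
    }
    interval <- c(1e-9, nu_upper)
  } else {
    interval <- c(1e-9, 1)
  }
  opt <- stats::optimize(objective, interval, tol = 1e-9)
  numeric_star <- opt$minimum
  boundary <- min(abs(numeric_star - interval)) < 1e-6 ||
    closed < interval[1] || closed > interval[2]
  agree <- is.finite(closed) && abs(closed - numeric_star) < 1e-6

  tibble::tibble(
    family = family,
    nu_star_closed = closed,
    nu_star_numeric = numeric_star,
    theta = theta,
    objective = opt$objective,
    boundary = boundary,
    agree = agree
  )
}

#' Selective-reversal scan over habitat size and cost
#'
#' Tabulates the stationary occupancy mass above `p = 1/2` over a grid of
#' habitat sizes and cost magnitudes. A cell with `favoured = TRUE` and
#' `epsilon > 0` is a selective reversal: demographic stochasticity
#' overcomes the deterministic bias against the costly social trait.
#' Cells whose stationary density is not integrable are reported with
#' `integrable = FALSE` and the scan continues.
#'
#' @param model Base [make_model()] object (its `mu` is used throughout;
#'   it must be positive for a stationary distribution to exist).
#' @param omega_values Habitat sizes to scan.
#' @param epsilon_values Cost magnitudes to scan.
#' @param grid_size Stationary-density grid size.
#' @return A tibble with one row per `(omega, epsilon)` cell:
#'   `omega`, `epsilon`, `mass_above_half`, `favoured`, `shape`,
#'   `reversal`, `integrable`.
#' @export
reversal_scan <- function(model, omega_values, epsilon_values,
                          grid_size = 2001L) {
  stopifnot(inherits(model, "demsoc_model"))
  if (model$mu <= 0) {
    stop("reversal scans need mu > 0 (stationary distribution)",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(omega = omega_values, epsilon = epsilon_values)
  purrr::pmap_dfr(grid, function(omega, epsilon) {
    m <- update_model(model, omega = omega, epsilon = epsilon)
    d <- stationary_density(m, grid_size = grid_size)
    if (!d$integrable) {
      return(tibble::tibble(omega = omega, epsilon = epsilon,
                            mass_above_half = NA_real_, favoured = NA,
                            shape = NA_character_, reversal = NA,
                            integrable = FALSE))
    }
    f <- favourability(d)
    tibble::tibble(omega = omega, epsilon = epsilon,
                   mass_above_half = f$mass_above_half,
                   favoured = f$favoured, shape = f$shape,
                   reversal = f$reversal, integrable = TRUE)
  })
}

#' Habitat size at which favourability flips
#'
#' Locates, by bisection on `omega` (treated as continuous), the habitat
#' size at which the stationary mass above `p = 1/2` crosses 1/2 for a
#' costly social trait. Below the boundary (stronger demographic
#' stochasticity) the trait is favoured.
#'
#' @param model A [make_model()] object with `mu > 0` and `epsilon > 0`.
#' @param omega_range Bracketing interval `c(lo, hi)`; the mass must be
#'   above 1/2 at `lo` and below at `hi` (or vice versa).
#' @param tol Bisection tolerance on `omega`.
#' @param grid_size Stationary-density grid size.
#' @return The boundary habitat size, or `NA` with a warning when the
#'   bracket does not straddle the crossing.
#' @export
reversal_boundary <- function(model, omega_range, tol = 0.5,
                              grid_size = 2001L) {
  mass_at <- function(om) {
    stationary_density(update_model(model, omega = om),
                       grid_size = grid_size)$mass_above_half - 0.5
  }
  lo <- omega_range[1]; hi <- omega_range[2]
  f_lo <- mass_at(lo); f_hi <- mass_at(hi)
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0) {
    warning("no favourability crossing inside `omega_range`")
    return(NA_real_)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- mass_at(mid)
    if (f_lo * f_mid <= 0) {
      hi <- mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  (lo + hi) / 2
}

#' Mutation-rate sweep of the stationary distribution
#'
#' Recomputes the stationary distribution and favourability report for a
#' sequence of mutation rates, recording how the distribution's shape
#' moves through the U-shaped (low mutation supply), boundary-unimodal
#' and bell-shaped (high mutation supply) regimes.
#'
#' @param model Base [make_model()] object.
#' @param mu_values Mutation rates to sweep.
#' @param grid_size Stationary-density grid size.
#' @return A tibble: `mu`, `mass_above_half`, `favoured`, `shape`,
#'   `reversal`, `integrable`.
#' @export
mutation_sweep <- function(model, mu_values, grid_size = 2001L) {
  stopifnot(inherits(model, "demsoc_model"))
  purrr::map_dfr(mu_values, function(mu) {
    m <- update_model(model, mu = mu)
    d <- stationary_density(m, grid_size = grid_size)
    if (!d$integrable) {
      return(tibble::tibble(mu = mu, mass_above_half = NA_real_,
                            favoured = NA, shape = NA_character_,
                            reversal = NA, integrable = FALSE))
    }
    f <- favourability(d)
    tibble::tibble(mu = mu, mass_above_half = f$mass_above_half,
                   favoured = f$favoured, shape = f$shape,
                   reversal = f$reversal, integrable = TRUE)
  })
}

#' Transition rate between monomorphic states
#'
#' In the mutation-fixation regime (mutations rare enough that each is
#' lost or fixed before the next arises) the population jumps between
#' monomorphic trait states. The jump rate from trait i to trait j is the
#' mutant supply times the neutral fixation probability,
#' `mu_ij * N_i * (1 / N_i) = mu_ij`: the population size cancels
#' exactly, so a trait's effect on population size confers no long-run
#' advantage by itself.
#'
#' @param mu_ij Per-capita mutation rate from trait i to trait j (>= 0).
#' @param N_i Population size of the trait-i monomorphic state (>= 1).
#' @return The transition rate, `mu_ij`.
#' @examples
#' monomorphic_transition_rate(1e-6, 600) # 1e-6, independent of N
#' @export
monomorphic_transition_rate <- function(mu_ij, N_i) {
  stopifnot(mu_ij >= 0)
  if (any(N_i < 1)) stop("`N_i` must be >= 1", call. = FALSE)
  mu_ij * N_i * (1 / N_i)
}

#' Stationary distribution of the monomorphic-state Markov chain
#'
#' Builds the continuous-time Markov chain over monomorphic trait states
#' with jump rates `mu[i, j]` (population sizes cancel, see
#' [monomorphic_transition_rate()]) and returns its stationary
#' distribution. With symmetric mutation every trait is equally likely,
#' uniform `1/k`, irrespective of the population sizes the traits
#' sustain.
#'
#' @param mu_matrix k x k matrix of per-capita mutation rates
#'   (diagonal ignored).
#' @return A tibble: `trait`, `probability`.
#' @export
trait_chain_stationary <- function(mu_matrix) {
  k <- nrow(mu_matrix)
  stopifnot(k == ncol(mu_matrix), k >= 2L, all(mu_matrix >= 0))
  Q <- mu_matrix
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0, sum(pi) = 1
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- unname(stats::lm.fit(A, b)$coefficients)
  pi_hat <- pmax(pi_hat, 0)
  tibble::tibble(trait = seq_len(k), probability = pi_hat / sum(pi_hat))
}

#' Neutral invasion probability of a rare mutant
#'
#' For a weakly selected social trait (`epsilon` near 0, `mu = 0`), a
#' single mutant in a resident population at its quasi-equilibrium size
#' fixes with the neutral probability `1 / (omega n(p_resident))` --
#' one over the resident population size. An actor invading non-actors
#' uses `n(0)`; a non-actor invading actors uses `n(1)`.
#'
#' @param model A [make_model()] object.
#' @param resident `"non-actor"` (invading actor, default) or
#'   `"actor"`.
#' @return The invasion probability.
#' @examples
#' mod <- make_model("death_rate", list(beta = 3, d = 1, nu = 0),
#'                   omega = 900)
#' invasion_probability_neutral(mod) # 1 / 600
#' @export
invasion_probability_neutral <- function(model,
                                         resident = c("non-actor",
                                                      "actor")) {
  resident <- match.arg(resident)
  p_res <- if (resident == "non-actor") 0 else 1
  n <- quasi_equilibrium_density(model, p_res)
  if (n <= 0) stop("resident equilibrium density is 0", call. = FALSE)
  1 / (model$omega * n)
}
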