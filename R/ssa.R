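family_code <- function(model) {
  switch(model$family,
         death_rate = 1L, birth_altruism = 2L, birth_spite = 3L,
         linear_altruism = 4L, turnover_altruism = 5L, custom = 0L)
}

family_par_vector <- function(model) {
  pr <- model$params
  switch(model$family,
    death_rate = c(pr$beta, pr$d, pr$nu),
    birth_altruism = c(pr$beta, pr$d, pr$nu, pr$kappa1, pr$kappa2),
    birth_spite = c(pr$beta, pr$d, pr$a, pr$nu, pr$kappa1, pr$kappa2),
    linear_altruism = c(pr$r, pr$kappa, pr$nu),
    turnover_altruism = c(pr$beta, pr$d, pr$kappa, pr$nu),
    custom = numeric(0)
  )
}

ssa_stop_reasons <- c("t_max reached", "absorption", "event cap",
                      "deadlock")

#' Exact stochastic simulation of the individual-based process
#'
#' Simulates one realisation of the continuous-time two-type
#' birth-death-mutation process with the direct Gillespie method. Event
#' channels are: birth of type i at rate `Ni * b(x)`, death of type i at
#' rate `Ni * m(x)` (plus the actor's cost channel `N1 * epsilon * c(x)`
#' when the cost sits on the death rate), and mutation i -> j at rate
#' `Ni * mu` (type conversion of a living individual). Densities
#' `x = N / omega` and all rates are recomputed after every event, so the
#' realisation is statistically exact.
#'
#' Built-in model families run in compiled code; `custom` models use an R
#' event loop (slower, same event rules).
#'
#' @param model A [make_model()] object.
#' @param initial_counts Integer vector `c(N1, N2)` of starting counts
#'   (actors first), not all zero.
#' @param t_max Stop time (ignored when `stop = "until_absorption"`).
#' @param stop `"t_max"` or `"until_absorption"` (the latter requires
#'   `mu = 0` so that fixation/extinction states are absorbing).
#' @param seed Integer seed; the same seed reproduces the event sequence
#'   bit for bit.
#' @param max_events Event cap; hitting it truncates the run (flagged in
#'   `stop_reason`).
#' @param record `"events"` (every event), `"thin"` (piecewise-constant
#'   state sampled every `thin_dt`), or `"none"`.
#' @param thin_dt Sampling interval for `record = "thin"`.
#' @param bins Number of occupancy-histogram bins accumulated during the
#'   run (time-weighted, after `burn_in`).
#' @param burn_in Time discarded before occupancy accumulation.
#' @return An object of class `demsoc_ssa`: list with `trajectory`
#'   (tibble `time`, `N1`, `N2`, or `NULL`), `final` (tibble), `events`,
#'   `stop_reason`, `occupancy` (tibble of time-weighted frequency bins),
#'   `mean_density`, `clamped`, `seed`, `model`.
#' @examples
#' mod <- model_preset("linear_altruism")
#' mod <- update_model_mu(mod, 0) # no mutation: absorbing boundaries
#' sim <- simulate_ssa(mod, c(43, 43), stop = "until_absorption", seed = 1)
#' sim$stop_reason
#' @export
simulate_ssa <- function(model, initial_counts, t_max = Inf,
                         stop = c("t_max", "until_absorption"),
                         seed = NULL, max_events = 1e8,
                         record = c("events", "thin", "none"),
                         thin_dt = 1, bins = 50L, burn_in = 0) {
  stopifnot(inherits(model, "demsoc_model"))
  stop <- match.arg(stop)
  record <- match.arg(record)
  ic <- as.integer(round(initial_counts))
  if (length(ic) != 2L || any(ic < 0) || sum(ic) == 0L) {
    stop("`initial_counts` must be two non-negative integers, not all zero",
         call. = FALSE)
  }
  if (stop == "t_max" && !is.finite(t_max)) {
    stop("finite `t_max` required for stop = 't_max'", call. = FALSE)
  }
  if (stop == "until_absorption" && model$mu > 0) {
    stop("absorption requires mu = 0 (mutation makes the process recurrent)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  code <- family_code(model)
  if (code > 0L) {
    res <- ssa_core(code, family_par_vector(model), model$omega, model$mu,
                    model$epsilon, model$cost_on_death, ic,
                    if (is.finite(t_max)) t_max else 1e300, max_events,
                    if (stop == "t_max") 0L else 1L,
                    record != "none",
                    if (record == "thin") thin_dt else -1,
                    as.integer(bins), burn_in)
  } else {
    res <- ssa_r_loop(model, ic, t_max, stop, max_events, record, thin_dt,
                      as.integer(bins), burn_in)
  }
  reason <- ssa_stop_reasons[res$stop_reason + 1L]
  if (reason == "deadlock") {
    stop("total event rate hit 0 in a non-absorbing state (deadlock)",
         call. = FALSE)
  }
  occupancy <- tibble::tibble(
    p_mid = (seq_len(length(res$hist)) - 0.5) / length(res$hist),
    weight = res$hist,
    mass = if (sum(res$hist) > 0) res$hist / sum(res$hist) else res$hist
  )
  structure(
    list(
      trajectory = if (!is.null(res$trajectory))
        tibble::as_tibble(res$trajectory) else NULL,
      final = tibble::tibble(t_end = res$t_end, N1 = res$N1, N2 = res$N2),
      events = res$events,
      stop_reason = reason,
      occupancy = occupancy,
      mean_density = res$mean_density,
      clamped = res$clamped,
      seed = seed,
      model = model
    ),
    class = "demsoc_ssa"
  )
}

#' @export
print.demsoc_ssa <- function(x, ...) {
  cat("<demsoc_ssa>", x$model$family, "model;",
      format(x$events, big.mark = ","), "events;",
      "stop:", x$stop_reason, "\n")
  cat(sprintf("  final state t = %.4g, N = (%d, %d)\n",
              x$final$t_end, as.integer(x$final$N1),
              as.integer(x$final$N2)))
  invisible(x)
}

# R event loop for custom models (same channels as the compiled core)
ssa_r_loop <- function(model, ic, t_max, stop_mode, max_events, record,
                       thin_dt, bins, burn_in) {
  N <- as.numeric(ic)
  t <- 0
  events <- 0
  clamped <- 0L
  hist <- numeric(bins)
  time_weight <- 0
  n_int <- 0
  rec <- if (record == "events") list(t = 0, N1 = N[1], N2 = N[2]) else NULL
  rec_t <- c(0); rec_1 <- c(N[1]); rec_2 <- c(N[2])
  stop_reason <- 0L
  repeat {
    if (stop_mode == "until_absorption" && model$mu == 0 &&
        (N[1] == 0 || N[2] == 0)) {
      stop_reason <- 1L
      break
    }
    x <- N / model$omega
    r <- rates_raw(model, x)
    b <- r[1]; m <- r[2]; cc <- r[3]
    b1 <- b; d1 <- m
    if (model$cost_on_death) d1 <- d1 + model$epsilon * cc
    else b1 <- max(b1 - model$epsilon * cc, 0)
    ch <- c(N[1] * b1, N[2] * b, N[1] * d1, N[2] * m,
            N[1] * model$mu, N[2] * model$mu)
    total <- sum(ch)
    if (total <= 0) {
      stop_reason <- if (N[1] == 0 || N[2] == 0) {
        if (stop_mode == "until_absorption") 1L else 0L
      } else 3L
      if (stop_mode == "t_max" && stop_reason == 0L) t <- t_max
      break
    }
    dt <- stats::rexp(1, total)
    t_next <- t + dt
    past_end <- stop_mode == "t_max" && t_next > t_max
    t_hold <- if (past_end) t_max else t_next
    if (t_hold > burn_in && sum(N) > 0) {
      w <- t_hold - max(t, burn_in)
      p <- N[1] / sum(N)
      bin <- min(floor(p * bins) + 1, bins)
      hist[bin] <- hist[bin] + w
      n_int <- n_int + w * sum(N) / model$omega
      time_weight <- time_weight + w
    }
    if (past_end) { t <- t_max; break }
    t <- t_next
    ev <- sample.int(6L, 1L, prob = ch)
    N <- N + switch(ev, c(1, 0), c(0, 1), c(-1, 0), c(0, -1),
                    c(-1, 1), c(1, -1))
    events <- events + 1
    if (record == "events") {
      rec_t <- c(rec_t, t); rec_1 <- c(rec_1, N[1]); rec_2 <- c(rec_2, N[2])
    }
    if (events >= max_events) { stop_reason <- 2L; break }
  }
  list(t_end = t, N1 = N[1], N2 = N[2], events = events,
       stop_reason = stop_reason, clamped = clamped, hist = hist,
       time_weight = time_weight,
       mean_density = if (time_weight > 0) n_int / time_weight else NA_real_,
       trajectory = if (record == "events")
         data.frame(time = rec_t, N1 = rec_1, N2 = rec_2) else NULL)
}

# child seeds derived from a master seed: a fixed draw of integer seeds
# under the master seed (recorded by callers)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Monte-Carlo fixation probability of the social actor
#'
#' Runs independent Gillespie replicates to absorption (`mu` must be 0)
#' and reports the fraction that end in actor fixation with its binomial
#' standard error. Replicate seeds are derived from the master seed by a
#' fixed splitting rule and recorded in the result.
#'
#' @inheritParams simulate_ssa
#' @param replicates Number of replicates.
#' @param seed Master seed.
#' @return A one-row tibble: `estimate`, `stderr`, `fixed`, `replicates`,
#'   `excluded` (replicates truncated by the event cap), plus the
#'   replicate seeds in the `seeds` list-column.
#' @examples
#' \donttest{
#' mod <- make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
#'                   omega = 50, mu = 0)
#' estimate_fixation_probability(mod, c(21, 21), replicates = 100, seed = 1)
#' }
#' @export
estimate_fixation_probability <- function(model, initial_counts,
                                          replicates = 1000L, seed = 1L,
                                          max_events = 1e8) {
  stopifnot(inherits(model, "demsoc_model"), replicates >= 1L)
  if (model$mu > 0) {
    stop("fixation requires mu = 0 (no absorption otherwise)", call. = FALSE)
  }
  ic <- as.integer(round(initial_counts))
  if (ic[1] == 0L) {
    return(tibble::tibble(estimate = 0, stderr = 0, fixed = 0L,
                          replicates = replicates, excluded = 0L,
                          seeds = list(integer(0))))
  }
  if (ic[2] == 0L) {
    return(tibble::tibble(estimate = 1, stderr = 0, fixed = replicates,
                          replicates = replicates, excluded = 0L,
                          seeds = list(integer(0))))
  }
  seeds <- derive_seeds(seed, replicates)
  fixed <- 0L
  excluded <- 0L
  for (i in seq_len(replicates)) {
    sim <- simulate_ssa(model, ic, stop = "until_absorption",
                        seed = seeds[i], max_events = max_events,
                        record = "none")
    if (sim$stop_reason == "event cap") {
      excluded <- excluded + 1L
    } else if (sim$final$N2 == 0 && sim$final$N1 > 0) {
      fixed <- fixed + 1L
    }
  }
  if (excluded > 0.01 * replicates) {
    warning(sprintf("%d of %d replicates hit the event cap and were excluded",
                    excluded, replicates))
  }
  used <- replicates - excluded
  est <- fixed / used
  tibble::tibble(
    estimate = est,
    stderr = sqrt(est * (1 - est) / used),
    fixed = fixed,
    replicates = replicates,
    excluded = excluded,
    seeds = list(seeds)
  )
}

#' Time-weighted occupancy histogram of the actor frequency
#'
#' Builds the empirical occupancy distribution of `p = N1 / (N1 + N2)`
#' from one or more realisations, weighting each state by its holding
#' time (the stationary density is an occupancy measure, so event
#' sampling would bias toward high-turnover states). States after
#' `burn_in` are pooled over realisations.
#'
#' @param ensemble A `demsoc_ssa` object with a recorded trajectory, or a
#'   list of them.
#' @param burn_in Time discarded at the start of each realisation.
#' @param bins Number of equal-width frequency bins on \[0, 1\].
#' @return A tibble with columns `p_mid`, `weight` (total holding time)
#'   and `mass` (normalised).
#' @export
occupancy_histogram <- function(ensemble, burn_in = 0, bins = 50L) {
  if (inherits(ensemble, "demsoc_ssa")) ensemble <- list(ensemble)
  weight <- numeric(bins)
  for (sim in ensemble) {
    stopifnot(inherits(sim, "demsoc_ssa"))
    tr <- sim$trajectory
    if (is.null(tr)) {
      stop("realisation has no recorded trajectory; rerun with record != 'none'",
           call. = FALSE)
    }
    tt <- c(tr$time, sim$final$t_end)
    ntot <- tr$N1 + tr$N2
    if (any(ntot == 0)) {
      warning("realisation hit total extinction; dropped from histogram")
      next
    }
    if (burn_in >= max(tt)) {
      stop("`burn_in` exceeds the realisation length", call. = FALSE)
    }
    p <- tr$N1 / ntot
    w <- pmax(pmin(tt[-1], max(tt)) - pmax(tt[-length(tt)], burn_in), 0)
    bin <- pmin(floor(p * bins) + 1, bins)
    for (k in which(w > 0)) weight[bin[k]] <- weight[bin[k]] + w[k]
  }
  tibble::tibble(
    p_mid = (seq_len(bins) - 0.5) / bins,
    weight = weight,
    mass = if (sum(weight) > 0) weight / sum(weight) else weight
  )
}

#' Replace a model's mutation rate
#'
#' Convenience helper returning the same model with a new per-capita
#' mutation rate (validation re-run).
#'
#' @param model A [make_model()] object.
#' @param mu New mutation rate.
#' @return A `demsoc_model`.
#' @export
update_model_mu <- function(model, mu) update_model(model, mu = mu)
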