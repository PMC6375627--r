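# shared fixtures: the worked parameter sets used across the suite

deathrate_model <- function(nu = -0.95, omega = 900, mu = 0.006,
                            epsilon = 0) {
  make_model("death_rate", list(beta = 3, d = 1, nu = nu),
             omega = omega, mu = mu, epsilon = epsilon)
}

linear_model <- function(omega = 100, mu = 0.01, epsilon = 0) {
  make_model("linear_altruism", list(r = 0.6, kappa = 1.2, nu = 1),
             omega = omega, mu = mu, epsilon = epsilon)
}

turnover_model <- function(omega = 100, mu = 0.01, epsilon = 0) {
  make_model("turnover_altruism",
             list(beta = 3, d = 2.4, kappa = 1.2, nu = 1),
             omega = omega, mu = mu, epsilon = epsilon)
}

# total-variation distance between an empirical bin-mass vector and the
# analytic stationary density integrated over the same bins
tv_to_stationary <- function(emp_mass, dist, bins = length(emp_mass)) {
  edges <- seq(0, 1, length.out = bins + 1)
  g <- dist$grid
  bin_of <- pmin(findInterval(g$p, edges, rightmost.closed = TRUE), bins)
  w <- c(diff(g$p) / 2, 0) + c(0, diff(g$p) / 2)
  ana <- tapply(g$density * w, bin_of, sum)
  ana_mass <- numeric(bins)
  ana_mass[as.integer(names(ana))] <- ana
  ana_mass <- ana_mass / sum(ana_mass)
  0.5 * sum(abs(emp_mass - ana_mass))
}

# sup of |x/y - 1| over a restricted frequency window, after removing a
# common normalisation constant (geometric-mean alignment in log space)
sup_rel_err_unnormalized <- function(p, log_a, log_b, lo = 0.01, hi = 0.99) {
  sel <- p >= lo & p <= hi
  diffs <- (log_a - log_b)[sel]
  diffs <- diffs - mean(diffs)
  max(abs(expm1(diffs)))
}
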