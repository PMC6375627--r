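#include <Rcpp.h>
using namespace Rcpp;

// Per-capita birth/death/cost rates of the built-in two-type families,
// evaluated at densities (x1, x2). Family codes:
// 1 death_rate      b = beta (1 - n),              m = d (1 + nu x1 / n), c = 1
// 2 birth_altruism  b = beta + nu x1,              m = d + k1 n + k2 n^2, c = 1
// 3 birth_spite     b = beta (1 - nu x1 / (n+a)),  m = d + k1 n + k2 n^2, c = 1
// 4 linear_altruism b = r + nu x1,                 m = kappa n,           c = r
// 5 turnover_altr.  b = beta + nu x1,              m = d + kappa n,       c = r
static inline void family_rates(int family, const double *par,
                                double x1, double x2,
                                double &b, double &m, double &c) {
  double n = x1 + x2;
  switch (family) {
  case 1: // par: beta, d, nu
    b = par[0] * (1.0 - n);
    m = (n > 0.0) ? par[1] * (1.0 + par[2] * x1 / n) : par[1];
    c = 1.0;
    break;
  case 2: // par: beta, d, nu, kappa1, kappa2
    b = par[0] + par[2] * x1;
    m = par[1] + par[3] * n + par[4] * n * n;
    c = 1.0;
    break;
  case 3: // par: beta, d, a, nu, kappa1, kappa2
    b = par[0] * (1.0 - par[3] * x1 / (n + par[2]));
    m = par[1] + par[4] * n + par[5] * n * n;
    c = 1.0;
    break;
  case 4: // par: r, kappa, nu
    b = par[0] + par[2] * x1;
    m = par[1] * n;
    c = par[0];
    break;
  case 5: // par: beta, d, kappa, nu
    b = par[0] + par[3] * x1;
    m = par[1] + par[2] * n;
    c = par[0] - par[1];
    break;
  default:
    stop("unknown family code");
  }
}

// Direct-method Gillespie simulation of the two-type birth-death-mutation
// process. Channels: birth i (rate Ni * b), death i (rate Ni * m, plus
// Ni * eps * c for the actor when cost_on_death; otherwise the cost is
// subtracted from the actor birth channel), mutation i -> j (rate Ni * mu).
// Rates are recomputed after every event; negative per-capita channel
// rates are clamped at zero (counted in `clamped`).
//
// stop_mode: 0 = run to t_max, 1 = run until fixation/extinction (mu must
// be 0 for absorption to exist). Event cap always applies.
// Uses R's RNG (set.seed upstream gives bit-identical event sequences).
// [[Rcpp::export]]
List ssa_core(int family, NumericVector par, double omega, double mu,
              double eps, bool cost_on_death, IntegerVector N0,
              double t_max, double max_events, int stop_mode,
              bool record, double thin_dt,
              int nbins, double burn_in) {
  double N1 = N0[0], N2 = N0[1];
  double t = 0.0;
  double events = 0.0;
  long clamped = 0;
  NumericVector hist(nbins);
  double n_time_integral = 0.0, time_weight = 0.0;

  // record = every event when thin_dt <= 0, else the piecewise-constant
  // state sampled every thin_dt time units
  std::vector<double> rec_t, rec_n1, rec_n2;
  double next_rec = 0.0;
  bool thinned = thin_dt > 0.0;
  if (record) {
    rec_t.push_back(0.0); rec_n1.push_back(N1); rec_n2.push_back(N2);
    next_rec = thin_dt;
  }

  int stop_reason = 0; // 0 t_max, 1 absorption, 2 event cap, 3 deadlock
  const double pr[8] = {
    par.size() > 0 ? par[0] : 0, par.size() > 1 ? par[1] : 0,
    par.size() > 2 ? par[2] : 0, par.size() > 3 ? par[3] : 0,
    par.size() > 4 ? par[4] : 0, par.size() > 5 ? par[5] : 0, 0, 0};

  while (true) {
    if (stop_mode == 1 && mu == 0.0 && (N1 == 0.0 || N2 == 0.0)) {
      stop_reason = 1;
      break;
    }
    double b, m, c;
    family_rates(family, pr, N1 / omega, N2 / omega, b, m, c);
    if (b < 0 || m < 0) { ++clamped; if (b < 0) b = 0; if (m < 0) m = 0; }
    double b1 = b, d1 = m;
    if (cost_on_death) d1 += eps * c; else b1 -= eps * c;
    if (b1 < 0) { ++clamped; b1 = 0; }

    double rb1 = N1 * b1, rb2 = N2 * b;
    double rd1 = N1 * d1, rd2 = N2 * m;
    double rm1 = N1 * mu, rm2 = N2 * mu;
    double total = rb1 + rb2 + rd1 + rd2 + rm1 + rm2;

    if (total <= 0.0) {
      if (stop_mode == 0) {
        // frozen state: account remaining occupancy time and finish
        double t_next = t_max;
        double n = N1 + N2;
        if (t_next > burn_in && n > 0) {
          double w = t_next - std::max(t, burn_in);
          double p = N1 / n;
          int bin = (int)(p * nbins); if (bin >= nbins) bin = nbins - 1;
          hist[bin] += w;
          n_time_integral += w * n / omega;
          time_weight += w;
        }
        t = t_max;
        stop_reason = (N1 == 0.0 || N2 == 0.0) ? 0 : 3;
      } else {
        stop_reason = (N1 + N2 == 0.0) ? 1 : 3;
      }
      break;
    }

    double dt = R::exp_rand() / total;
    double t_next = t + dt;
    bool past_end = (stop_mode == 0 && t_next > t_max);
    double t_hold_end = past_end ? t_max : t_next;

    // time-weighted occupancy of p = N1 / (N1 + N2) over the holding time
    double n = N1 + N2;
    if (t_hold_end > burn_in && n > 0) {
      double w = t_hold_end - std::max(t, burn_in);
      double p = N1 / n;
      int bin = (int)(p * nbins); if (bin >= nbins) bin = nbins - 1;
      hist[bin] += w;
      n_time_integral += w * n / omega;
      time_weight += w;
    }

    if (record && thinned) {
      while (next_rec <= t_hold_end) {
        rec_t.push_back(next_rec); rec_n1.push_back(N1); rec_n2.push_back(N2);
        next_rec += thin_dt;
        if (rec_t.size() > 5000000) stop("trajectory record too large");
      }
    }
    if (past_end) { t = t_max; stop_reason = 0; break; }
    t = t_next;

    double u = unif_rand() * total;
    if ((u -= rb1) < 0) ++N1;
    else if ((u -= rb2) < 0) ++N2;
    else if ((u -= rd1) < 0) --N1;
    else if ((u -= rd2) < 0) --N2;
    else if ((u -= rm1) < 0) { --N1; ++N2; }
    else { --N2; ++N1; }

    events += 1.0;
    if (record && !thinned) {
      rec_t.push_back(t); rec_n1.push_back(N1); rec_n2.push_back(N2);
      if (rec_t.size() > 5000000) stop("trajectory record too large");
    }
    if (events >= max_events) { stop_reason = 2; break; }
    if (((long)events) % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["t_end"] = t, _["N1"] = N1, _["N2"] = N2,
    _["events"] = events, _["stop_reason"] = stop_reason,
    _["clamped"] = clamped, _["hist"] = hist,
    _["time_weight"] = time_weight,
    _["mean_density"] = time_weight > 0 ? n_time_integral / time_weight
                                        : NA_REAL);
  if (record) {
    out["trajectory"] = DataFrame::create(
      _["time"] = rec_t, _["N1"] = rec_n1, _["N2"] = rec_n2);
  }
  return out;
}

// Euler-Maruyama integration of the frequency diffusion, with drift and
// noise linearly interpolated from tables on a uniform p-grid. The state
// is clipped to [0, 1] after every step. Accumulates an occupancy
// histogram (each step weighted dt) after burn-in and a thinned path.
// [[Rcpp::export]]
List em_freq_core(double p0, double dt, double nsteps,
                  NumericVector p_grid, NumericVector alpha_grid,
                  NumericVector sigma2_grid, double burn_in,
                  int nbins, int thin) {
  int K = p_grid.size();
  double lo = p_grid[0], hi = p_grid[K - 1];
  double inv_h = (K - 1) / (hi - lo);
  NumericVector hist(nbins);
  double boundary_time = 0.0;
  std::vector<double> path_t, path_p;
  double p = p0;
  double t = 0.0;

  for (double step = 0; step < nsteps; step += 1.0) {
    if (((long)step) % thin == 0) { path_t.push_back(t); path_p.push_back(p); }
    // interpolate coefficients
    double u = (p - lo) * inv_h;
    int i = (int)u; if (i < 0) i = 0; if (i > K - 2) i = K - 2;
    double w = u - i; if (w < 0) w = 0; if (w > 1) w = 1;
    double a = alpha_grid[i] * (1 - w) + alpha_grid[i + 1] * w;
    double s2 = sigma2_grid[i] * (1 - w) + sigma2_grid[i + 1] * w;
    if (s2 < 0) s2 = 0;
    p += a * dt + sqrt(s2 * dt) * norm_rand();
    if (p < 0) p = 0;
    if (p > 1) p = 1;
    t += dt;
    if (t > burn_in) {
      int bin = (int)(p * nbins); if (bin >= nbins) bin = nbins - 1;
      hist[bin] += dt;
      if (p == 0.0 || p == 1.0) boundary_time += dt;
    }
    if (((long)step) % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  path_t.push_back(t); path_p.push_back(p);

  return List::create(
    _["p_end"] = p, _["hist"] = hist,
    _["boundary_time"] = boundary_time,
    _["path"] = DataFrame::create(_["time"] = path_t, _["p"] = path_p));
}
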