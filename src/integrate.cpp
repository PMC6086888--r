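#include <Rcpp.h>
using namespace Rcpp;

// Cascaded divisive-normalization network, classical RK4 over a
// piecewise-constant value timeline.
//
// State layout (length 4N): r_fast, g_fast, r_slow, g_slow.
// dG^F = (-G^F + omega R^F + alpha R^S) / tau_fast
// dR^F = (-R^F + V / (1 + G^F))        / tau_fast
// dG^S = (-G^S + beta R^S)             / tau_slow
// dR^S = (-R^S + V / (1 + G^S))        / tau_slow
//
// Segment boundaries must align with the dt grid (validated on the R
// side) so every RK4 substep evaluates V inside a single segment.

static inline void nn_deriv(int n,
                            const double *rf, const double *gf,
                            const double *rs, const double *gs,
                            const double *v,
                            const double *omega, const double *alpha,
                            const double *beta,
                            double tau_f, double tau_s,
                            double *drf, double *dgf,
                            double *drs, double *dgs) {
  for (int i = 0; i < n; ++i) {
    double wsum = 0.0, asum = 0.0, bsum = 0.0;
    for (int j = 0; j < n; ++j) {
      // column-major: element (i, j) at j * n + i
      wsum += omega[j * n + i] * rf[j];
      asum += alpha[j * n + i] * rs[j];
      bsum += beta[j * n + i] * rs[j];
    }
    dgf[i] = (-gf[i] + wsum + asum) / tau_f;
    drf[i] = (-rf[i] + v[i] / (1.0 + gf[i])) / tau_f;
    dgs[i] = (-gs[i] + bsum) / tau_s;
    drs[i] = (-rs[i] + v[i] / (1.0 + gs[i])) / tau_s;
  }
}

// [[Rcpp::export]]
List nn_integrate_cpp(NumericVector breaks,
                      NumericMatrix seg_values,
                      double dt,
                      double tau_fast,
                      double tau_slow,
                      NumericMatrix omega,
                      NumericMatrix alpha,
                      NumericMatrix beta,
                      NumericVector init,
                      NumericVector win_start,
                      NumericVector win_end,
                      int record_every) {
  const int n = seg_values.ncol();
  const int n_seg = seg_values.nrow();
  if (breaks.size() != n_seg + 1)
    stop("breaks must have one more element than timeline segments");
  if (init.size() != 4 * n)
    stop("init must have length 4 * n_options");

  const double t0 = breaks[0];
  const double t_end = breaks[n_seg];
  const long n_steps = (long)std::floor((t_end - t0) / dt + 0.5);
  if (std::fabs(t0 + n_steps * dt - t_end) > 1e-6 * dt)
    stop("dt does not divide the timeline duration");

  std::vector<double> rf(init.begin(), init.begin() + n);
  std::vector<double> gf(init.begin() + n, init.begin() + 2 * n);
  std::vector<double> rs(init.begin() + 2 * n, init.begin() + 3 * n);
  std::vector<double> gs(init.begin() + 3 * n, init.begin() + 4 * n);

  // scratch for RK4 stages
  std::vector<double> k1(4 * n), k2(4 * n), k3(4 * n), k4(4 * n),
      tmp(4 * n);
  std::vector<double> vbuf(n);

  // monotone segment pointer; eval times never decrease
  int seg = 0;
  const double *brk = breaks.begin();
  const double *segv = seg_values.begin();
  auto value_at = [&](double t) {
    while (seg < n_seg - 1 && t >= brk[seg + 1]) ++seg;
    for (int i = 0; i < n; ++i) vbuf[i] = segv[i * n_seg + seg];
    return vbuf.data();
  };

  // trajectory recording
  long n_rec = 0;
  NumericMatrix traj;
  if (record_every > 0) {
    n_rec = n_steps / record_every + 1;
    traj = NumericMatrix(n_rec, 1 + 4 * n);
  }
  long rec_row = 0;
  auto record = [&](double t) {
    traj(rec_row, 0) = t;
    for (int i = 0; i < n; ++i) {
      traj(rec_row, 1 + i) = rf[i];
      traj(rec_row, 1 + n + i) = gf[i];
      traj(rec_row, 1 + 2 * n + i) = rs[i];
      traj(rec_row, 1 + 3 * n + i) = gs[i];
    }
    ++rec_row;
  };

  // readout windows: sorted, non-overlapping, grid-aligned (R side)
  const int n_win = win_start.size();
  NumericMatrix win_sum(std::max(n_win, 0), n);
  IntegerVector win_n(std::max(n_win, 0));
  int w = 0;
  auto window_accum = [&](double t) {
    while (w < n_win && t >= win_end[w] - 1e-9 * dt) ++w;
    if (w < n_win && t >= win_start[w] - 1e-9 * dt) {
      for (int i = 0; i < n; ++i) win_sum(w, i) += rf[i];
      win_n[w] += 1;
    }
  };

  double t = t0;
  if (record_every > 0) record(t);
  window_accum(t);

  // Segment boundaries align with the step grid, so V is constant over
  // each step's open interval; all four RK4 stages use the value at the
  // step start (evaluating k4 in the next segment would degrade the
  // scheme to first order at every discontinuity).
  const double h = dt, h2 = dt / 2.0;
  for (long step = 0; step < n_steps; ++step) {
    const double *v1 = value_at(t);
    nn_deriv(n, rf.data(), gf.data(), rs.data(), gs.data(), v1,
             omega.begin(), alpha.begin(), beta.begin(), tau_fast,
             tau_slow, &k1[0], &k1[n], &k1[2 * n], &k1[3 * n]);

    for (int i = 0; i < n; ++i) {
      tmp[i] = rf[i] + h2 * k1[i];
      tmp[n + i] = gf[i] + h2 * k1[n + i];
      tmp[2 * n + i] = rs[i] + h2 * k1[2 * n + i];
      tmp[3 * n + i] = gs[i] + h2 * k1[3 * n + i];
    }
    nn_deriv(n, &tmp[0], &tmp[n], &tmp[2 * n], &tmp[3 * n], v1,
             omega.begin(), alpha.begin(), beta.begin(), tau_fast,
             tau_slow, &k2[0], &k2[n], &k2[2 * n], &k2[3 * n]);

    for (int i = 0; i < 4 * n; ++i) tmp[i] = (i < n ? rf[i] :
        i < 2 * n ? gf[i - n] : i < 3 * n ? rs[i - 2 * n] :
        gs[i - 3 * n]) + h2 * k2[i];
    nn_deriv(n, &tmp[0], &tmp[n], &tmp[2 * n], &tmp[3 * n], v1,
             omega.begin(), alpha.begin(), beta.begin(), tau_fast,
             tau_slow, &k3[0], &k3[n], &k3[2 * n], &k3[3 * n]);

    for (int i = 0; i < 4 * n; ++i) tmp[i] = (i < n ? rf[i] :
        i < 2 * n ? gf[i - n] : i < 3 * n ? rs[i - 2 * n] :
        gs[i - 3 * n]) + h * k3[i];
    nn_deriv(n, &tmp[0], &tmp[n], &tmp[2 * n], &tmp[3 * n], v1,
             omega.begin(), alpha.begin(), beta.begin(), tau_fast,
             tau_slow, &k4[0], &k4[n], &k4[2 * n], &k4[3 * n]);

    double chk = 0.0;
    for (int i = 0; i < n; ++i) {
      rf[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      gf[i] += h / 6.0 *
               (k1[n + i] + 2 * k2[n + i] + 2 * k3[n + i] + k4[n + i]);
      rs[i] += h / 6.0 * (k1[2 * n + i] + 2 * k2[2 * n + i] +
                          2 * k3[2 * n + i] + k4[2 * n + i]);
      gs[i] += h / 6.0 * (k1[3 * n + i] + 2 * k2[3 * n + i] +
                          2 * k3[3 * n + i] + k4[3 * n + i]);
      chk += rf[i] + gf[i] + rs[i] + gs[i];
    }
    if (!R_finite(chk))
      stop("integration produced non-finite state at t = %f", t + h);

    t = t0 + (step + 1) * dt;
    if (record_every > 0 && (step + 1) % record_every == 0) record(t);
    window_accum(t);
  }

  NumericMatrix win_mean(std::max(n_win, 0), n);
  for (int k = 0; k < n_win; ++k) {
    if (win_n[k] == 0)
      stop("readout window %d contains no integration samples", k + 1);
    for (int i = 0; i < n; ++i) win_mean(k, i) = win_sum(k, i) / win_n[k];
  }

  NumericVector final_state(4 * n);
  for (int i = 0; i < n; ++i) {
    final_state[i] = rf[i];
    final_state[n + i] = gf[i];
    final_state[2 * n + i] = rs[i];
    final_state[3 * n + i] = gs[i];
  }

  return List::create(
      _["trajectory"] = record_every > 0 ? (SEXP)traj : R_NilValue,
      _["win_mean"] = win_mean, _["win_n"] = win_n,
      _["final_state"] = final_state);
}
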