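// Exact simulation of the inhomogeneous master-equation jump process by
// Ogata thinning. The majorant (sum_k theta_k + ||f||_0 sum_k l(k)) / tau
// dominates the total rate between jumps (theta is constant there and the
// gain is bounded by ||f||_0), so candidate times proposed at the majorant
// rate and accepted with probability lambda(theta, t) / majorant give an
// exact sample of the process.
//
// The per-cell occupation integrals A_k(t) = int_0^t theta_k ds and gain
// integrals B_k(t) = int_0^t fbar_k(theta_s, s) ds are accumulated exactly
// between jumps (theta is piecewise constant; for time-dependent input the
// gain integral over a constant-state interval is done by 6-point
// Gauss-Legendre). They are what the martingale decomposition and the
// quadratic-variation oracle of the fluctuation analysis need.
//
// Draw order per candidate: one exponential (waiting time), one uniform
// (thinning test), and on acceptance one uniform (event selection by
// inverse CDF over deaths then births, cells in order). The pure-R
// reference implementation consumes the identical sequence, so both give
// bitwise-identical trajectories from the same seed.

#include <Rcpp.h>
using namespace Rcpp;

// gain kinds: 0 constant, 1 affine-clipped, 2 sigmoid, 3 tanh
static inline double gain_eval(const int kind, const double* gp,
                               const double z) {
  switch (kind) {
  case 0:
    return gp[0];
  case 1: {
    double v = gp[0] * z + gp[1];
    if (v < 0.0) v = 0.0;
    if (v > gp[2]) v = gp[2];
    return v;
  }
  case 2:
    return 1.0 / (1.0 + std::exp(-(gp[0] * z + gp[1])));
  default:
    return 0.5 * (std::tanh(gp[0] * z + gp[1]) + 1.0);
  }
}

// 6-point Gauss-Legendre on [0, 1]
static const double GLX[6] = {0.03376524289842399, 0.16939530676686776,
                              0.38069040695840155, 0.6193095930415985,
                              0.8306046932331322,  0.966234757101576};
static const double GLW[6] = {0.08566224618958517, 0.18038078652406930,
                              0.23395696728634552, 0.23395696728634552,
                              0.18038078652406930, 0.08566224618958517};

struct Sim {
  int P;
  std::vector<double> theta, l, u, fvals, A, B;
  const double* W;  // column-major P x P
  double tau, f0, su;
  int gkind;
  const double* gpar;
  const double* ibase;
  const double* iamp;
  double omega, phase;
  bool time_dep, bounded;

  double ibar(const int k, const double t) const {
    return time_dep ? ibase[k] + iamp[k] * std::sin(omega * t + phase)
                    : ibase[k];
  }
  void refresh_gains(const double t) {
    for (int k = 0; k < P; ++k)
      fvals[k] = gain_eval(gkind, gpar, u[k] + ibar(k, t));
  }
  // total event weight times tau: sum theta + sum l_k f_k [ind_k]
  double weight(const double t) {
    if (time_dep) refresh_gains(t);
    double s = su;
    for (int k = 0; k < P; ++k) {
      if (bounded && theta[k] >= l[k]) continue;
      s += l[k] * fvals[k];
    }
    return s;
  }
  // B accumulates the effective gain rate, including the bounded-scheme
  // indicator, so that l_k * B_k is exactly the integrated birth rate
  void accumulate(const double from, const double to) {
    const double dt = to - from;
    if (dt <= 0) return;
    for (int k = 0; k < P; ++k) A[k] += theta[k] * dt;
    if (!time_dep) {
      for (int k = 0; k < P; ++k)
        if (!(bounded && theta[k] >= l[k])) B[k] += fvals[k] * dt;
    } else {
      for (int q = 0; q < 6; ++q) {
        const double s = from + GLX[q] * dt, wq = GLW[q] * dt;
        for (int k = 0; k < P; ++k)
          if (!(bounded && theta[k] >= l[k]))
            B[k] += wq * gain_eval(gkind, gpar, u[k] + ibar(k, s));
      }
    }
  }
  void apply_jump(const int k, const int delta) {
    theta[k] += delta;
    su += delta;
    const double du = delta / l[k];
    for (int j = 0; j < P; ++j) u[j] += W[j + (size_t)P * k] * du;
    if (!time_dep) {
      if (gkind == 0) return;  // constant gain: fvals unchanged
      for (int j = 0; j < P; ++j)
        fvals[j] = gain_eval(gkind, gpar, u[j] + ibase[j]);
    }
  }
};

// [[Rcpp::export]]
List pdmp_simulate_cpp(NumericVector theta0, NumericVector l,
                       NumericMatrix Wbar, double tau, int gain_kind,
                       NumericVector gain_par, double f0,
                       NumericVector ibase, NumericVector iamp, double omega,
                       double phase, bool time_dep, double T,
                       NumericVector mesh, bool bounded, bool record_jumps) {
  const int P = theta0.size();
  const int M = mesh.size();
  Sim s;
  s.P = P;
  s.theta.assign(theta0.begin(), theta0.end());
  s.l.assign(l.begin(), l.end());
  s.W = Wbar.begin();
  s.tau = tau;
  s.f0 = f0;
  s.gkind = gain_kind;
  s.gpar = gain_par.begin();
  s.ibase = ibase.begin();
  s.iamp = iamp.begin();
  s.omega = omega;
  s.phase = phase;
  s.time_dep = time_dep;
  s.bounded = bounded;
  s.A.assign(P, 0.0);
  s.B.assign(P, 0.0);
  s.u.assign(P, 0.0);
  s.fvals.assign(P, 0.0);
  s.su = 0.0;
  double sl = 0.0;
  for (int k = 0; k < P; ++k) {
    s.su += s.theta[k];
    sl += s.l[k];
    for (int j = 0; j < P; ++j)
      s.u[j] += Wbar(j, k) * s.theta[k] / s.l[k];
  }
  s.refresh_gains(0.0);

  NumericMatrix countsM(P, M), AM(P, M), BM(P, M);
  std::vector<double> jt;
  std::vector<int> jc, jd;

  double t = 0.0, tlast = 0.0;
  int mi = 0;
  long n_jumps = 0, n_rejected = 0;

  // advance accumulators and mesh records up to tnew
  auto advance_to = [&](double tnew) {
    while (mi < M && mesh[mi] <= tnew + 1e-14) {
      s.accumulate(tlast, mesh[mi]);
      tlast = mesh[mi];
      for (int k = 0; k < P; ++k) {
        countsM(k, mi) = s.theta[k];
        AM(k, mi) = s.A[k];
        BM(k, mi) = s.B[k];
      }
      ++mi;
    }
    if (tnew > tlast) {
      s.accumulate(tlast, tnew);
      tlast = tnew;
    }
  };

  for (;;) {
    const double lambda_bar = (s.su + f0 * sl) / tau;
    if (lambda_bar <= 0.0) {  // absorbing: no event can ever occur
      advance_to(T);
      break;
    }
    const double dt = exp_rand() / lambda_bar;
    const double tc = t + dt;
    if (tc >= T) {
      advance_to(T);
      break;
    }
    advance_to(tc);
    t = tc;
    const double wsum = s.weight(t);  // refreshes gains if time-dependent
    const double u1 = unif_rand();
    if (u1 * (s.su + f0 * sl) > wsum) {
      ++n_rejected;
      continue;
    }
    // accepted: select event by inverse CDF (deaths by cell, then births)
    const double r = unif_rand() * wsum;
    double acc = 0.0;
    int cell = -1, delta = 0;
    for (int k = 0; k < P; ++k) {
      acc += s.theta[k];
      if (r <= acc) { cell = k; delta = -1; break; }
    }
    if (cell < 0) {
      for (int k = 0; k < P; ++k) {
        if (bounded && s.theta[k] >= s.l[k]) continue;
        acc += s.l[k] * s.fvals[k];
        if (r <= acc) { cell = k; delta = 1; break; }
      }
      if (cell < 0) { cell = P - 1; delta = 1; }  // guard rounding
    }
    s.apply_jump(cell, delta);
    ++n_jumps;
    if (record_jumps) {
      jt.push_back(t);
      jc.push_back(cell + 1);
      jd.push_back(delta);
    }
  }

  List out = List::create(
      _["counts"] = countsM, _["A"] = AM, _["B"] = BM,
      _["final"] = NumericVector(s.theta.begin(), s.theta.end()),
      _["n_jumps"] = (double)n_jumps, _["n_rejected"] = (double)n_rejected);
  if (record_jumps) {
    out["jump_times"] = NumericVector(jt.begin(), jt.end());
    out["jump_cells"] = IntegerVector(jc.begin(), jc.end());
    out["jump_deltas"] = IntegerVector(jd.begin(), jd.end());
  }
  return out;
}
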