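// Fast integration core for the coupled place-cell / grid-cell rate model.
//
// All linear operators in the model are circulant up to relabeling:
//   * the place recurrent matrix is a sum over maps of P_l C P_l^T with C
//     circulant in preferred-location coordinates,
//   * each grid module is a double ring whose even/odd kernels are circulant,
//   * the place<->grid coupling for map l and module mu is H_mu evaluated at
//     (q*j - c_mu*p_i - delta_{l,mu}) mod N, a decimated circulant.
// Each Euler step therefore reduces to a small number of length-N FFTs plus
// O(N) gathers/scatters, instead of dense matrix-vector products.
//
// Conventions: positions live on the N-point lattice of one environment
// (spacing D/N).  q = N/n maps ring indices onto that lattice (theta_j at
// fine index q*j).  c_mu = D/lambda_mu is the integer number of grid periods.
// All indices are 0-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Core {
  int N, n, nmod, L, q;
  ivec c;
  umat P;         // N x L cell -> position index
  umat Aidx;      // N x (L*nmod): (c_mu * P(i,l) + delta(l,mu)) mod N
  vec kp;         // place kernel, length N (index = position lag)
  vec ke, ko;     // ring kernels (even / odd presynaptic), length n
  double c0g;     // ring self-term correction (kernel at zero lag)
  mat H;          // N x nmod normalized coupling generator
  vec F;          // idealized place bump profile (peak at position 0)
  vec G;          // idealized ring bump profile (peak at theta 0), length n
  vec Gfine;      // G interpolated to the N-point phase lattice
  double tau, gamma_g, gamma_p, alpha, betaL, Ipc;
  vec Igc, eps;
  int phi_form;   // 0 = sqrt, 1 = linear
  bool has_H;

  // derived
  cx_vec Kpf, KEf, KOf;
  cx_mat Hf, HfC;
  uvec qidx;      // fine indices of ring cells: 0, q, 2q, ...
  uvec revidx;    // index-reversal permutation for Hermitian splits
  vec esign_n;    // +1 even ring index, -1 odd
};

umat as_umat(const Rcpp::IntegerMatrix& m) {
  umat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = (uword)m(i, j);
  return out;
}

Core build_core(const Rcpp::List& cl) {
  Core c;
  c.N = Rcpp::as<int>(cl["N"]);
  c.n = Rcpp::as<int>(cl["n"]);
  c.nmod = Rcpp::as<int>(cl["nmod"]);
  c.L = Rcpp::as<int>(cl["L"]);
  c.q = c.N / c.n;
  c.c = Rcpp::as<ivec>(cl["cycles"]);
  c.P = as_umat(Rcpp::as<Rcpp::IntegerMatrix>(cl["P"]));
  c.kp = Rcpp::as<vec>(cl["kp"]);
  c.ke = Rcpp::as<vec>(cl["ke"]);
  c.ko = Rcpp::as<vec>(cl["ko"]);
  c.c0g = Rcpp::as<double>(cl["c0g"]);
  c.tau = Rcpp::as<double>(cl["tau"]);
  c.gamma_g = Rcpp::as<double>(cl["gamma_g"]);
  c.gamma_p = Rcpp::as<double>(cl["gamma_p"]);
  c.alpha = Rcpp::as<double>(cl["alpha"]);
  c.betaL = Rcpp::as<double>(cl["betaL"]);
  c.Ipc = Rcpp::as<double>(cl["Ipc"]);
  c.Igc = Rcpp::as<vec>(cl["Igc"]);
  c.eps = Rcpp::as<vec>(cl["eps"]);
  c.phi_form = Rcpp::as<int>(cl["phi_form"]);
  c.has_H = !Rf_isNull(cl["H"]);
  if (c.has_H) {
    c.H = Rcpp::as<mat>(cl["H"]);
    c.Aidx = as_umat(Rcpp::as<Rcpp::IntegerMatrix>(cl["Aidx"]));
    c.Hf.set_size(c.N, c.nmod);
    for (int m = 0; m < c.nmod; ++m)
      c.Hf.col(m) = fft(cx_vec(c.H.col(m), zeros<vec>(c.N)));
    c.HfC = conj(c.Hf);
  }
  if (cl.containsElementNamed("F") && !Rf_isNull(cl["F"])) {
    c.F = Rcpp::as<vec>(cl["F"]);
    c.G = Rcpp::as<vec>(cl["G"]);
    c.Gfine = Rcpp::as<vec>(cl["Gfine"]);
  }
  c.Kpf = fft(cx_vec(c.kp, zeros<vec>(c.N)));
  c.KEf = fft(cx_vec(c.ke, zeros<vec>(c.n)));
  c.KOf = fft(cx_vec(c.ko, zeros<vec>(c.n)));
  c.qidx.set_size(c.n);
  for (int j = 0; j < c.n; ++j) c.qidx(j) = (uword)(j * c.q);
  c.revidx.set_size(c.N);
  c.revidx(0) = 0;
  for (int k = 1; k < c.N; ++k) c.revidx(k) = (uword)(c.N - k);
  c.esign_n.set_size(c.n);
  for (int j = 0; j < c.n; ++j) c.esign_n(j) = (j % 2 == 0) ? 1.0 : -1.0;
  return c;
}

inline void phi_vec(const vec& x, vec& out, int form) {
  const uword m = x.n_elem;
  if (form == 0) {
    for (uword i = 0; i < m; ++i) out(i) = x(i) > 0 ? std::sqrt(x(i)) : 0.0;
  } else {
    for (uword i = 0; i < m; ++i) out(i) = x(i) > 0 ? x(i) : 0.0;
  }
}

// Total synaptic drive for place cells (ip) and grid cells (ig, n x nmod),
// excluding constant currents, velocity and perturbation terms.
void recurrent_inputs(const Core& cc, const vec& S, const mat& s,
                      vec& ip, mat& ig) {
  const int N = cc.N, L = cc.L, nmod = cc.nmod;
  ip.zeros(N);
  ig.zeros(cc.n, nmod);

  // --- place recurrent: sum over maps of permuted circular convolutions,
  // two maps packed per complex FFT (shared real kernel).
  vec a(N), b(N);
  for (int l = 0; l < L; l += 2) {
    const bool pair = (l + 1 < L);
    a.zeros(); a.elem(cc.P.col(l)) = S;
    if (pair) { b.zeros(); b.elem(cc.P.col(l + 1)) = S; } else b.zeros();
    cx_vec z = fft(cx_vec(a, b));
    z %= cc.Kpf;
    cx_vec w = ifft(z);
    vec wr = real(w);
    ip += wr.elem(cc.P.col(l));
    if (pair) { vec wi = imag(w); ip += wi.elem(cc.P.col(l + 1)); }
  }

  if (cc.has_H) {
    // --- bidirectional coupling, one packed FFT pair per module.
    double sumS = accu(S), sum_s_all = 0.0;
    vec su(N), B(N);
    const double gg_a = cc.gamma_g * cc.alpha;
    const double gp_a = cc.gamma_p * cc.alpha;
    for (int m = 0; m < nmod; ++m) {
      su.zeros(); su.elem(cc.qidx) = s.col(m);
      B.zeros();
      for (int l = 0; l < L; ++l) {
        const uword* idx = cc.Aidx.colptr((uword)(m * L + l));
        for (int i = 0; i < N; ++i) B(idx[i]) += S(i);
      }
      cx_vec Z = fft(cx_vec(su, B));
      cx_vec Zr = Z.elem(cc.revidx);
      cx_vec Suf = 0.5 * (Z + conj(Zr));
      cx_vec Bf = cx_double(0, -0.5) * (Z - conj(Zr));
      // grid -> place is a cross-correlation with H, place -> grid a convolution
      cx_vec w = ifft(Suf % cc.HfC.col(m) + cx_double(0, 1) * (Bf % cc.Hf.col(m)));
      vec gp = real(w), pg = imag(w);
      for (int l = 0; l < L; ++l)
        ip += gg_a * gp.elem(cc.Aidx.col((uword)(m * L + l)));
      ig.col(m) += gp_a * pg.elem(cc.qidx);
      sum_s_all += accu(s.col(m));
    }
    ip += cc.gamma_g * cc.betaL * sum_s_all;
    ig += cc.gamma_p * cc.betaL * sumS;
  }

  // --- grid recurrent (double ring), per module.
  for (int m = 0; m < nmod; ++m) {
    vec se = s.col(m), so = s.col(m);
    for (int j = 0; j < cc.n; ++j) {
      if (j % 2 == 0) so(j) = 0.0; else se(j) = 0.0;
    }
    cx_vec Z = fft(cx_vec(se, so));
    cx_vec Zr(cc.n);
    Zr(0) = Z(0);
    for (int k2 = 1; k2 < cc.n; ++k2) Zr(k2) = Z(cc.n - k2);
    cx_vec SEf = 0.5 * (Z + conj(Zr));
    cx_vec SOf = cx_double(0, -0.5) * (Z - conj(Zr));
    ig.col(m) += real(ifft(cx_vec(SEf % cc.KEf + SOf % cc.KOf)))
                 - cc.c0g * s.col(m);
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_sim(Rcpp::List core, arma::vec S0, arma::mat s0,
                   int nsteps, double dt,
                   arma::mat vdrive,        // nmod x nsteps (or x 1)
                   arma::vec iper,          // nsteps (or 1)
                   bool noise,
                   int record_every,
                   arma::ivec bins,         // length nsteps or 0; -1 skips
                   int nbins) {
  Core cc = build_core(core);
  const int N = cc.N, n = cc.n, nmod = cc.nmod;
  vec S = S0;
  mat s = s0;
  vec ip(N), rp(N);
  mat ig(n, nmod), rg(n, nmod);

  const bool const_v = (vdrive.n_cols == 1);
  const bool const_iper = (iper.n_elem == 1);
  const bool do_bins = (bins.n_elem > 0 && nbins > 0);

  int K = (record_every > 0) ? nsteps / record_every : 0;
  mat recS, recG;
  vec rect;
  if (K > 0) {
    recS.set_size(N, K);
    recG.set_size(n * nmod, K);
    rect.set_size(K);
  }
  mat rmS, rmG;
  vec rmcount;
  if (do_bins) {
    rmS.zeros(N, nbins);
    rmG.zeros(n * nmod, nbins);
    rmcount.zeros(nbins);
  }

  const double dtau = dt / cc.tau;
  double last_delta = 0.0;
  int krec = 0;
  Rcpp::RNGScope rngscope;

  for (int t = 0; t < nsteps; ++t) {
    recurrent_inputs(cc, S, s, ip, ig);
    ip += cc.Ipc;
    const double ipt = const_iper ? iper(0) : iper(t);
    for (int m = 0; m < nmod; ++m) {
      const double v = const_v ? vdrive(m, 0) : vdrive(m, t);
      ig.col(m) += cc.Igc(m) + ipt + (cc.eps(m) * v) * cc.esign_n;
    }
    phi_vec(ip, rp, cc.phi_form);
    for (int m = 0; m < nmod; ++m) {
      vec tmp = ig.col(m), out(n);
      phi_vec(tmp, out, cc.phi_form);
      rg.col(m) = out;
    }

    vec dS = dtau * (rp - S);
    mat ds = dtau * (rg - s);
    S += dS;
    s += ds;
    // silent cells decay exponentially forever; flush vanishing
    // activations to exact zero before they reach the denormal range,
    // where hardware arithmetic slows by orders of magnitude
    S.for_each([](double& v) { if (v > -1e-12 && v < 1e-12) v = 0.0; });
    s.for_each([](double& v) { if (v > -1e-12 && v < 1e-12) v = 0.0; });
    if (noise) {
      for (int i = 0; i < N; ++i)
        if (rp(i) > 0) S(i) += std::sqrt(rp(i) * dt) * norm_rand();
      for (int m = 0; m < nmod; ++m)
        for (int j = 0; j < n; ++j)
          if (rg(j, m) > 0) s(j, m) += std::sqrt(rg(j, m) * dt) * norm_rand();
    }
    last_delta = std::max(abs(dS).max(), abs(ds).max());
    if (!S.is_finite() || !s.is_finite())
      Rcpp::stop("non-finite state at step %d (dt too large?)", t + 1);

    if (K > 0 && ((t + 1) % record_every == 0) && krec < K) {
      recS.col(krec) = rp;
      recG.col(krec) = vectorise(rg);
      rect(krec) = (t + 1) * dt;
      ++krec;
    }
    if (do_bins && bins(t) >= 0) {
      const int bidx = bins(t);
      rmS.col(bidx) += rp;
      rmG.col(bidx) += vectorise(rg);
      rmcount(bidx) += 1.0;
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // rates at the final state
  recurrent_inputs(cc, S, s, ip, ig);
  ip += cc.Ipc;
  const double ipt = const_iper ? iper(0) : (nsteps > 0 ? iper(nsteps - 1) : iper(0));
  for (int m = 0; m < nmod; ++m) {
    const double v = const_v ? vdrive(m, 0)
                             : (nsteps > 0 ? vdrive(m, nsteps - 1) : vdrive(m, 0));
    ig.col(m) += cc.Igc(m) + ipt + (cc.eps(m) * v) * cc.esign_n;
  }
  phi_vec(ip, rp, cc.phi_form);
  for (int m = 0; m < nmod; ++m) {
    vec tmp = ig.col(m), out(n);
    phi_vec(tmp, out, cc.phi_form);
    rg.col(m) = out;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("S") = S,
    Rcpp::Named("s") = s,
    Rcpp::Named("rates_place") = rp,
    Rcpp::Named("rates_grid") = rg,
    Rcpp::Named("last_delta") = last_delta);
  if (K > 0) {
    out["rec_place"] = recS;
    out["rec_grid"] = recG;
    out["rec_t"] = rect;
  }
  if (do_bins) {
    out["rm_place"] = rmS;
    out["rm_grid"] = rmG;
    out["rm_count"] = rmcount;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_inputs(Rcpp::List core, arma::vec S, arma::mat s) {
  Core cc = build_core(core);
  vec ip;
  mat ig;
  recurrent_inputs(cc, S, s, ip, ig);
  ip += cc.Ipc;
  for (int m = 0; m < cc.nmod; ++m) ig.col(m) += cc.Igc(m);
  return Rcpp::List::create(Rcpp::Named("input_place") = ip,
                            Rcpp::Named("input_grid") = ig);
}

// Template-matching decoder.  Rp: N x K place rates; Rg: (n*nmod) x K grid
// rates; P/delta describe the map set to score (possibly unembedded control
// maps).  Returns bump scores per map, winning map (1-based), place position
// and per-module grid positions on the fine lattice (0-based indices).
// [[Rcpp::export]]
Rcpp::List cpp_decode(Rcpp::List core, Rcpp::IntegerMatrix P,
                      Rcpp::IntegerMatrix delta,
                      arma::mat Rp, arma::mat Rg, bool want_grid) {
  Core cc = build_core(core);
  const int N = cc.N, n = cc.n, nmod = cc.nmod;
  const int Lm = P.ncol();
  const int K = Rp.n_cols;
  umat Pu = as_umat(P);
  cx_vec FfC = conj(fft(cx_vec(cc.F, zeros<vec>(N))));
  cx_vec GfC = conj(fft(cx_vec(cc.Gfine, zeros<vec>(N))));

  mat Q(Lm, K);
  imat xl(Lm, K);            // argmax position per map
  ivec win(K);
  ivec xp(K);
  imat xg(nmod, K, fill::zeros);

  vec a(N);
  for (int k = 0; k < K; ++k) {
    for (int l = 0; l < Lm; ++l) {
      a.zeros(); a.elem(Pu.col(l)) = Rp.col(k);
      vec ql = real(ifft(cx_vec(fft(cx_vec(a, zeros<vec>(N))) % FfC)));
      uword am = ql.index_max();
      Q(l, k) = ql(am);
      xl(l, k) = (int)am;
    }
    int w = 0;
    for (int l = 1; l < Lm; ++l) if (Q(l, k) > Q(w, k)) w = l;
    win(k) = w + 1;
    xp(k) = xl(w, k);
    if (want_grid) {
      for (int m = 0; m < nmod; ++m) {
        vec su(N, fill::zeros);
        for (int j = 0; j < n; ++j) su(j * cc.q) = Rg(m * n + j, k);
        vec u = real(ifft(cx_vec(fft(cx_vec(su, zeros<vec>(N))) % GfC)));
        const int cmu = (int)cc.c(m);
        const int period = N / cmu;
        const int dlt = delta(w, m);
        // best phase over one grid period
        int best = 0; double bv = -datum::inf;
        for (int x = 0; x < period; ++x) {
          double val = u((uword)((cmu * x + dlt) % N));
          if (val > bv) { bv = val; best = x; }
        }
        // among periodic candidates pick the one nearest the place bump
        int bestx = best; int bestd = N;
        for (int r = 0; r < cmu; ++r) {
          int xc = best + r * period;
          int d = std::abs(xc - xp(k)); d = std::min(d, N - d);
          if (d < bestd || (d == bestd && xc < bestx)) { bestd = d; bestx = xc; }
        }
        xg(m, k) = bestx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Q") = Q,
                            Rcpp::Named("win") = win,
                            Rcpp::Named("x_place") = xp,
                            Rcpp::Named("x_map") = xl,
                            Rcpp::Named("x_grid") = xg);
}

// Uncoupled single ring integrator (used for idealized tuning curves and
// velocity-gain calibration).  drive is the signed velocity current eps*v,
// applied +drive to even and -drive to odd cells.
// [[Rcpp::export]]
Rcpp::List cpp_ring_sim(arma::vec ke, arma::vec ko, double c0g,
                        double tau, double dt, double I0,
                        arma::vec drive, arma::vec s0, int nsteps,
                        int phi_form, int record_every) {
  const int n = s0.n_elem;
  cx_vec KEf = fft(cx_vec(ke, zeros<vec>(n)));
  cx_vec KOf = fft(cx_vec(ko, zeros<vec>(n)));
  vec esign(n);
  for (int j = 0; j < n; ++j) esign(j) = (j % 2 == 0) ? 1.0 : -1.0;
  vec costh(n), sinth(n);
  for (int j = 0; j < n; ++j) {
    costh(j) = std::cos(2.0 * datum::pi * j / n);
    sinth(j) = std::sin(2.0 * datum::pi * j / n);
  }
  const bool const_d = (drive.n_elem == 1);
  vec s = s0, r(n), inp(n);
  const double dtau = dt / tau;
  int K = (record_every > 0) ? nsteps / record_every : 0;
  vec phases(std::max(K, 0)), ptimes(std::max(K, 0));
  int krec = 0;
  double last_delta = 0.0;
  for (int t = 0; t < nsteps; ++t) {
    vec se = s, so = s;
    for (int j = 0; j < n; ++j) { if (j % 2 == 0) so(j) = 0; else se(j) = 0; }
    cx_vec Z = fft(cx_vec(se, so));
    cx_vec Zr(n);
    Zr(0) = Z(0);
    for (int k2 = 1; k2 < n; ++k2) Zr(k2) = Z(n - k2);
    cx_vec SEf = 0.5 * (Z + conj(Zr));
    cx_vec SOf = cx_double(0, -0.5) * (Z - conj(Zr));
    inp = real(ifft(cx_vec(SEf % KEf + SOf % KOf))) - c0g * s;
    const double d = const_d ? drive(0) : drive(t);
    inp += I0 + d * esign;
    phi_vec(inp, r, phi_form);
    vec ds = dtau * (r - s);
    s += ds;
    s.for_each([](double& v) { if (v > -1e-12 && v < 1e-12) v = 0.0; });
    last_delta = abs(ds).max();
    if (!s.is_finite()) Rcpp::stop("non-finite ring state at step %d", t + 1);
    if (K > 0 && ((t + 1) % record_every == 0) && krec < K) {
      phases(krec) = std::atan2(dot(s, sinth), dot(s, costh));
      ptimes(krec) = (t + 1) * dt;
      ++krec;
    }
  }
  vec se = s, so = s;
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("s") = s,
    Rcpp::Named("rates") = r,
    Rcpp::Named("last_delta") = last_delta);
  if (K > 0) { out["phases"] = phases; out["t"] = ptimes; }
  return out;
}
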