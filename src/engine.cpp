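// Hybrid ensemble stepper: explicit-Euler binding/phosphorylation ODEs,
// algebraic mean-field structure, per-subunit Bernoulli Pi-release events.
// Mirrors the pure-R reference (step_ensemble) operation for operation and
// consumes the same R random stream in the same order (hexamer-major,
// subunit-minor, draws only for non-ADP-bound subunits).
#include <Rcpp.h>
#include <cmath>
#include "flux_update.h"
using namespace Rcpp;

// canonical 29-state layout: index 0 = C6A2, then (i, j) lexicographic,
// 0 <= j <= i <= 6, at offset 1 + i*(i+1)/2 + j
static inline int sidx(int i, int j) { return 1 + (i * (i + 1)) / 2 + j; }

// [[Rcpp::export]]
List engine_run(NumericMatrix P0, NumericVector D0, NumericMatrix adp0,
                double t0, IntegerVector rel0, List params,
                int n_steps, double dt, int stride,
                IntegerVector record_idx) {
  const int N = P0.ncol();
  if (P0.nrow() != 29 || adp0.nrow() != 6 || adp0.ncol() != N)
    stop("bad state dimensions");

  const double V = as<double>(params["V"]);
  const double A_T = as<double>(params["A_T"]);
  const double B_T = as<double>(params["B_T"]);
  const double h_A0 = as<double>(params["h_A0"]);
  const double h_B0 = as<double>(params["h_B0"]);
  const double h_BA = as<double>(params["h_BA"]);
  const double f_A0 = as<double>(params["f_A0"]);
  const double f_B0 = as<double>(params["f_B0"]);
  const double f_BA = as<double>(params["f_BA"]);
  const double k_p = as<double>(params["k_p"]);
  const double k_dp = as<double>(params["k_dp"]);
  const double a = as<double>(params["a"]);
  const double c0 = as<double>(params["c0"]);
  const double c1 = as<double>(params["c1"]);
  const double c2 = as<double>(params["c2"]);
  const double c3 = as<double>(params["c3"]);
  const double beta = as<double>(params["beta"]);
  const double n_B = as<double>(params["n_B"]);
  const double f0 = as<double>(params["f0"]);
  const double q0 = as<double>(params["q0"]);
  const double delta0 = as<double>(params["delta0"]);
  const double gamma_ = as<double>(params["gamma"]);

  // per-state weights: sequestered KaiA monomers, bound KaiB monomers,
  // saturating KaiB-extent weight, membership in the CBA block
  double wA[29], wB[29], wpB[29];
  bool isCBA[29];
  wA[0] = 2.0; wB[0] = 0.0; wpB[0] = 0.0; isCBA[0] = false;
  for (int i = 0; i <= 6; ++i) {
    for (int j = 0; j <= i; ++j) {
      const int s = sidx(i, j);
      wA[s] = 2.0 * j;
      wB[s] = i;
      wpB[s] = (i >= 1) ? std::tanh((double)i / n_B) : 0.0;
      isCBA[s] = (i >= 1 && j >= 1);
    }
  }

  std::vector<double> P(P0.begin(), P0.end());       // 29 x N, col-major
  std::vector<double> D(D0.begin(), D0.end());
  std::vector<double> adp(adp0.begin(), adp0.end()); // 6 x N
  std::vector<double> X(N), pBv(N);
  std::vector<int> relcnt(rel0.begin(), rel0.end());

  // structure and running conservation sums from the incoming state
  double t = t0;
  double boundA = 0.0, boundB = 0.0;
  for (int k = 0; k < N; ++k) {
    const double *pk = &P[29 * k];
    double pb = 0.0, bA = 0.0, bB = 0.0, qq = 0.0;
    for (int s = 0; s < 29; ++s) {
      pb += wpB[s] * pk[s];
      bA += wA[s] * pk[s];
      bB += wB[s] * pk[s];
    }
    for (int s = 0; s < 6; ++s) if (adp[6 * k + s] > R_NegInf) qq += q0;
    X[k] = 0.5 * std::tanh(beta * (c0 - c1 * D[k] + c2 * pk[0]
                                   - c3 * pb - qq)) + 0.5;
    pBv[k] = pb;
    boundA += bA; boundB += bB;
  }

  const int n_samp = n_steps / stride + 1;
  const int n_rec = record_idx.size();
  NumericVector times(n_samp), Dbar(n_samp), Xbar(n_samp),
      PCA(n_samp), PCBA(n_samp), releases(n_samp),
      Afree(n_samp), Bfree(n_samp);
  NumericMatrix Dk(n_samp, n_rec);

  double max_corr = 0.0;
  int n_renorm_warn = 0, n_clamp = 0;
  const double p_rel = 1.0 - std::exp(-f0 * dt);
  long long rel_tot = 0;
  for (int k = 0; k < N; ++k) rel_tot += relcnt[k];
  long long rel_prev = rel_tot;

  // sample row 0 at t0
  {
    double sD = 0, sX = 0, sCA = 0, sCBA = 0;
    for (int k = 0; k < N; ++k) {
      sD += D[k]; sX += X[k];
      const double *pk = &P[29 * k];
      sCA += pk[0];
      for (int s = 1; s < 29; ++s) if (isCBA[s]) sCBA += pk[s];
    }
    times[0] = t0; Dbar[0] = sD / N; Xbar[0] = sX / N;
    PCA[0] = sCA / N; PCBA[0] = sCBA / N; releases[0] = 0;
    Afree[0] = std::max(A_T - boundA / V, 0.0);
    Bfree[0] = std::max(B_T - boundB / V, 0.0);
    for (int r = 0; r < n_rec; ++r) Dk(0, r) = D[record_idx[r] - 1];
  }

  double dPv[29];

  for (int step = 1; step <= n_steps; ++step) {
    // (1) free concentrations from the conservation laws
    double A = A_T - boundA / V;
    double B = B_T - boundB / V;
    if (A < -1e-3 * std::max(A_T, 1.0) || B < -1e-3 * std::max(B_T, 1.0))
      stop("free concentration deficit exceeds 1e-3 of the total at t=%g", t);
    if (A < -1e-6 || B < -1e-6) ++n_clamp;
    if (A < 0) A = 0;
    if (B < 0) B = 0;
    const double A2 = A * A;
    const double hA_A2 = h_A0 * A2, hB_B = h_B0 * B, hBA_A2 = h_BA * A2;
    const double t_new = t0 + step * dt;

    boundA = 0.0; boundB = 0.0;
    for (int k = 0; k < N; ++k) {
      double *pk = &P[29 * k];
      const double Xk = X[k];

      // (2) binding Euler step with structure-modulated rates
      binding_flux(pk, hA_A2 * Xk, f_A0 * (1.0 - Xk), hB_B * (1.0 - Xk),
                   f_B0 * Xk, hBA_A2, f_BA, dPv);
      double ssum = 0.0, clipped = 0.0;
      for (int s = 0; s < 29; ++s) {
        double v = pk[s] + dt * dPv[s];
        if (v < 0) { clipped -= v; v = 0; }
        pk[s] = v; ssum += v;
      }
      const double corr = clipped + std::fabs(1.0 - ssum);
      if (corr > max_corr) max_corr = corr;
      if (corr > 1e-3)
        stop("binding renormalization correction > 1e-3 at t=%g; reduce dt", t);
      if (corr > 1e-6) ++n_renorm_warn;
      const double inv = 1.0 / ssum;
      double pb = 0.0, bA = 0.0, bB = 0.0;
      for (int s = 0; s < 29; ++s) {
        const double v = pk[s] * inv;
        pk[s] = v;
        pb += wpB[s] * v;
        bA += wA[s] * v;
        bB += wB[s] * v;
      }
      boundA += bA; boundB += bB; pBv[k] = pb;

      // (3) phosphorylation Euler step (soft-spin force, analytic)
      const double pCA = pk[0];
      const double u = D[k] - 0.5;
      const double g1 = a * (4.0 * u * u * u - 0.5 * u);
      const double Dk_new = D[k] + dt * (k_p * pCA - k_dp * (1.0 - pCA) - g1);
      D[k] = Dk_new;

      // (4) ADP release and Pi-release events. A bound subunit frees
      // its ADP once its age exceeds the structure-dependent lifetime
      // delta0*(gamma - X_k(t)), tracked with the current X; an unbound
      // subunit fires with probability 1 - exp(-f0*dt) and becomes
      // ADP-bound from the release time (refractory while bound).
      double qq = 0.0;
      {
        double *au = &adp[6 * k];
        const double life = delta0 * (gamma_ - Xk);
        const double mInf = R_NegInf;
        for (int s = 0; s < 6; ++s) {
          if (au[s] > mInf && t - au[s] >= life) au[s] = mInf;
          if (!(au[s] > mInf) && f0 > 0) {
            if (unif_rand() < p_rel) { au[s] = t; ++relcnt[k]; ++rel_tot; }
          }
        }
        for (int s = 0; s < 6; ++s) if (au[s] > mInf) qq += q0;
      }

      // (5) quasi-equilibrium structure under the updated fields
      X[k] = 0.5 * std::tanh(beta * (c0 - c1 * Dk_new + c2 * pCA
                                     - c3 * pb - qq)) + 0.5;
    }
    t = t_new;

    if (step % stride == 0) {
      const int row = step / stride;
      double sD = 0, sX = 0, sCA = 0, sCBA = 0;
      for (int k = 0; k < N; ++k) {
        sD += D[k]; sX += X[k];
        const double *pk = &P[29 * k];
        sCA += pk[0];
        for (int s = 1; s < 29; ++s) if (isCBA[s]) sCBA += pk[s];
      }
      times[row] = t; Dbar[row] = sD / N; Xbar[row] = sX / N;
      PCA[row] = sCA / N; PCBA[row] = sCBA / N;
      Afree[row] = std::max(A_T - boundA / V, 0.0);
      Bfree[row] = std::max(B_T - boundB / V, 0.0);
      releases[row] = (double)(rel_tot - rel_prev);
      rel_prev = rel_tot;
      for (int r = 0; r < n_rec; ++r) Dk(row, r) = D[record_idx[r] - 1];
    }
    if (step % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  double A = std::max(A_T - boundA / V, 0.0);
  double B = std::max(B_T - boundB / V, 0.0);

  NumericMatrix Pout(29, N), adpOut(6, N);
  std::copy(P.begin(), P.end(), Pout.begin());
  std::copy(adp.begin(), adp.end(), adpOut.begin());

  List state = List::create(
      _["t"] = t, _["P"] = Pout, _["D"] = NumericVector(D.begin(), D.end()),
      _["X"] = NumericVector(X.begin(), X.end()), _["adp_since"] = adpOut,
      _["release_count"] = IntegerVector(relcnt.begin(), relcnt.end()),
      _["A_free"] = A, _["B_free"] = B);
  state.attr("class") = "kai_ensemble";

  return List::create(
      _["times"] = times, _["Dbar"] = Dbar, _["Xbar"] = Xbar,
      _["P_CA"] = PCA, _["P_CBA"] = PCBA, _["releases"] = releases,
      _["A_free"] = Afree, _["B_free"] = Bfree,
      _["Dk"] = Dk, _["state"] = state,
      _["diagnostics"] = List::create(
          _["max_renorm_correction"] = max_corr,
          _["n_renorm_warn"] = n_renorm_warn,
          _["n_clamped_conc"] = n_clamp));
}
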