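#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Double-cable myelinated axon integrator.
//
// Unknowns per compartment: intracellular potential u and periaxonal
// potential w (both absolute, mV).  Node-of-Ranvier compartments have the
// periaxonal layer shorted to the extracellular potential (w == e).  The
// linear system at each backward-Euler step is block-tridiagonal over the
// fiber tree (main trunk + at most one collateral branch) with symmetric
// 2x2 blocks, solved by Hines elimination from the leaves to the root.
// Gating variables advance by exponential Euler using the membrane
// potential of the previous step (staggered scheme).
//
// Units: mV, ms, nA, uS, nF.  (uS*mV = nA, nF*mV/ms = nA.)

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Rates {
  double am, bm, ah, bh, ap, bp, as_, bs;
};

static inline Rates axnode_rates(double v, double q10m, double q10h, double q10ps) {
  Rates r;
  r.am = q10m * 6.57 * vtrap(v + 20.4, 10.3);
  r.bm = q10m * 0.304 * vtrap(-(v + 25.7), 9.16);
  r.ah = q10h * 0.34 * vtrap(-(v + 114.0), 11.0);
  r.bh = q10h * 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  r.ap = q10ps * 0.0353 * vtrap(v + 27.0, 10.2);
  r.bp = q10ps * 0.000883 * vtrap(-(v + 34.0), 10.0);
  r.as_ = q10ps * 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
  r.bs = q10ps * 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  return r;
}

// [[Rcpp::export(name = ".cable_integrate")]]
List cable_integrate(List model,
                     NumericVector phi_in,     // unit-field potential per compartment (V)
                     NumericVector wave_in,    // normalized tissue waveform, length n_steps + 1
                     double amplitude,         // stimulus amplitude (V); e = 1000*amp*phi*wave (mV)
                     double dt_ms,
                     int n_steps,
                     IntegerVector record_idx, // 1-based compartment indices to record
                     int record_stride,
                     NumericVector init_state, // empty or packed [Vm, Vw, m, h, p, s]
                     int iinj_comp,            // 1-based, 0 = none
                     double iinj_nA,
                     double iinj_start_ms,
                     double iinj_dur_ms,
                     bool return_state) {
  const int n = as<int>(model["n"]);
  std::vector<int> parent = as<std::vector<int> >(model["parent"]); // 0-based, -1 root
  std::vector<int> is_node = as<std::vector<int> >(model["is_node"]);
  std::vector<int> active = as<std::vector<int> >(model["active"]);
  std::vector<double> C_axo = as<std::vector<double> >(model["c_axo_nF"]);
  std::vector<double> C_my = as<std::vector<double> >(model["c_my_nF"]);
  std::vector<double> g_my = as<std::vector<double> >(model["g_my_uS"]);
  std::vector<double> g_pas = as<std::vector<double> >(model["g_pas_uS"]);
  std::vector<double> e_pas = as<std::vector<double> >(model["e_pas_mV"]);
  std::vector<double> ga = as<std::vector<double> >(model["ga_uS"]); // edge to parent
  std::vector<double> gp = as<std::vector<double> >(model["gp_uS"]);
  std::vector<double> gnaf = as<std::vector<double> >(model["gnaf_uS"]);
  std::vector<double> gnap = as<std::vector<double> >(model["gnap_uS"]);
  std::vector<double> gks = as<std::vector<double> >(model["gks_uS"]);
  const double ena = as<double>(model["ena_mV"]);
  const double ek = as<double>(model["ek_mV"]);
  const double vrest = as<double>(model["v_rest_mV"]);
  const double celsius = as<double>(model["celsius"]);

  // rate constants are 36 C values; Q10 factors rescale away from 36 C
  const double q10m = std::pow(2.2, (celsius - 36.0) / 10.0);
  const double q10h = std::pow(2.9, (celsius - 36.0) / 10.0);
  const double q10ps = std::pow(3.0, (celsius - 36.0) / 10.0);

  if ((int)phi_in.size() != n) stop("phi length does not match compartment count");
  if ((int)wave_in.size() < n_steps + 1) stop("waveform shorter than requested duration");
  const double *phi = REAL(phi_in);
  const double *wave = REAL(wave_in);

  for (int i = 1; i < n; ++i)
    if (parent[i] < 0 || parent[i] >= i) stop("compartment ordering invalid");

  // state
  std::vector<double> Vm(n), Vw(n), m(n), h(n), p(n), s(n);
  if ((int)init_state.size() == 6 * n) {
    for (int i = 0; i < n; ++i) {
      Vm[i] = init_state[i];
      Vw[i] = init_state[n + i];
      m[i] = init_state[2 * n + i];
      h[i] = init_state[3 * n + i];
      p[i] = init_state[4 * n + i];
      s[i] = init_state[5 * n + i];
    }
  } else if (init_state.size() == 0) {
    Rates r0 = axnode_rates(vrest, q10m, q10h, q10ps);
    for (int i = 0; i < n; ++i) {
      Vm[i] = vrest; Vw[i] = 0.0;
      m[i] = r0.am / (r0.am + r0.bm);
      h[i] = r0.ah / (r0.ah + r0.bh);
      p[i] = r0.ap / (r0.ap + r0.bp);
      s[i] = r0.as_ / (r0.as_ + r0.bs);
    }
  } else {
    stop("init_state must be empty or of length 6 * n_compartments");
  }

  // loop-invariant coefficients
  std::vector<double> ca_dt(n), cm_dt(n), sum_ga(n, 0.0), sum_gp(n, 0.0);
  for (int i = 0; i < n; ++i) {
    ca_dt[i] = C_axo[i] / dt_ms;
    cm_dt[i] = C_my[i] / dt_ms;
  }
  for (int i = 1; i < n; ++i) {
    sum_ga[i] += ga[i]; sum_ga[parent[i]] += ga[i];
    sum_gp[i] += gp[i]; sum_gp[parent[i]] += gp[i];
  }
  // static diagonal blocks and sources for passive compartments; active
  // nodes overwrite theirs each step
  std::vector<double> D11s(n), D12s(n), D21s(n), D22s(n), Spas(n), bmy(n);
  std::vector<int> act_idx;
  for (int i = 0; i < n; ++i) {
    if (active[i]) act_idx.push_back(i);
    const double a = ca_dt[i] + g_pas[i];
    Spas[i] = g_pas[i] * e_pas[i];
    bmy[i] = cm_dt[i] + g_my[i];
    D11s[i] = a + sum_ga[i];
    D12s[i] = -a;
    if (is_node[i]) { D21s[i] = 0.0; D22s[i] = 1.0; }
    else { D21s[i] = -a; D22s[i] = a + bmy[i] + sum_gp[i]; }
  }

  std::vector<double> d11(n), d12(n), d21(n), d22(n), b1(n), b2(n);
  std::vector<double> u(n), w(n), e(n), Gact(n, 0.0), Sact(n, 0.0);

  const int nrec = record_idx.size();
  const int nout = n_steps / record_stride + 1;
  NumericMatrix rec(nrec, nout);
  NumericVector rec_t(nout);
  for (int r = 0; r < nrec; ++r) {
    int ci = record_idx[r] - 1;
    if (ci < 0 || ci >= n) stop("record index out of range");
    rec(r, 0) = Vm[ci];
  }
  rec_t[0] = 0.0;
  int out_col = 1;

  for (int k = 0; k < n_steps; ++k) {
    const double tnew = (k + 1) * dt_ms;
    const double scale = 1000.0 * amplitude * wave[k + 1];
    const bool inj_on = iinj_comp > 0 && tnew > iinj_start_ms &&
                        tnew <= iinj_start_ms + iinj_dur_ms;

    // gating + ionic conductances at active nodes (staggered)
    for (size_t ai = 0; ai < act_idx.size(); ++ai) {
      const int i = act_idx[ai];
      Rates r = axnode_rates(Vm[i], q10m, q10h, q10ps);
      const double tm = 1.0 / (r.am + r.bm), th = 1.0 / (r.ah + r.bh);
      const double tp = 1.0 / (r.ap + r.bp), ts = 1.0 / (r.as_ + r.bs);
      m[i] = r.am * tm + (m[i] - r.am * tm) * std::exp(-dt_ms / tm);
      h[i] = r.ah * th + (h[i] - r.ah * th) * std::exp(-dt_ms / th);
      p[i] = r.ap * tp + (p[i] - r.ap * tp) * std::exp(-dt_ms / tp);
      s[i] = r.as_ * ts + (s[i] - r.as_ * ts) * std::exp(-dt_ms / ts);
      const double gna = gnaf[i] * m[i] * m[i] * m[i] * h[i];
      const double gnp = gnap[i] * p[i] * p[i] * p[i];
      const double gk = gks[i] * s[i];
      Gact[i] = gna + gnp + gk;
      Sact[i] = (gna + gnp) * ena + gk * ek;
    }

    // assemble
    for (int i = 0; i < n; ++i) {
      e[i] = scale * phi[i];
      if (active[i]) {
        const double a = ca_dt[i] + g_pas[i] + Gact[i];
        const double S = Spas[i] + Sact[i];
        d11[i] = a + sum_ga[i];
        d12[i] = -a;
        d21[i] = 0.0; d22[i] = 1.0; // nodes are the only active compartments
        b1[i] = ca_dt[i] * Vm[i] + S;
        b2[i] = e[i];
      } else {
        d11[i] = D11s[i]; d12[i] = D12s[i];
        d21[i] = D21s[i]; d22[i] = D22s[i];
        b1[i] = ca_dt[i] * Vm[i] + Spas[i];
        b2[i] = is_node[i] ? e[i]
          : cm_dt[i] * Vw[i] - ca_dt[i] * Vm[i] - Spas[i] + bmy[i] * e[i];
      }
    }
    if (inj_on) b1[iinj_comp - 1] += iinj_nA;

    // Hines elimination, leaves to root
    for (int i = n - 1; i >= 1; --i) {
      const int pi = parent[i];
      const double l11 = -ga[i];
      const double l22 = is_node[i] ? 0.0 : -gp[i];
      const double u11 = -ga[i];
      const double u22 = is_node[pi] ? 0.0 : -gp[i];
      const double idet = 1.0 / (d11[i] * d22[i] - d12[i] * d21[i]);
      const double i11 = d22[i] * idet, i12 = -d12[i] * idet;
      const double i21 = -d21[i] * idet, i22 = d11[i] * idet;
      const double f11 = u11 * i11, f12 = u11 * i12;
      const double f21 = u22 * i21, f22 = u22 * i22;
      d11[pi] -= f11 * l11;
      d12[pi] -= f12 * l22;
      d21[pi] -= f21 * l11;
      d22[pi] -= f22 * l22;
      b1[pi] -= f11 * b1[i] + f12 * b2[i];
      b2[pi] -= f21 * b1[i] + f22 * b2[i];
    }
    {
      const double idet = 1.0 / (d11[0] * d22[0] - d12[0] * d21[0]);
      u[0] = (b1[0] * d22[0] - d12[0] * b2[0]) * idet;
      w[0] = (d11[0] * b2[0] - b1[0] * d21[0]) * idet;
    }
    for (int i = 1; i < n; ++i) {
      const int pi = parent[i];
      const double r1 = b1[i] + ga[i] * u[pi];
      const double r2 = b2[i] + (is_node[i] ? 0.0 : gp[i] * w[pi]);
      const double idet = 1.0 / (d11[i] * d22[i] - d12[i] * d21[i]);
      u[i] = (r1 * d22[i] - d12[i] * r2) * idet;
      w[i] = (d11[i] * r2 - r1 * d21[i]) * idet;
    }

    double vmax = 0.0;
    for (int i = 0; i < n; ++i) {
      Vm[i] = u[i] - w[i];
      Vw[i] = w[i] - e[i];
      const double av = std::fabs(Vm[i]);
      if (av > vmax) vmax = av;
    }
    if (!std::isfinite(vmax) || vmax > 1e5)
      stop("cable integration became unstable at t = %.4f ms; reduce dt", tnew);

    if ((k + 1) % record_stride == 0) {
      for (int r = 0; r < nrec; ++r) rec(r, out_col) = Vm[record_idx[r] - 1];
      rec_t[out_col] = tnew;
      ++out_col;
    }
  }

  List out = List::create(_["potentials"] = rec, _["times_ms"] = rec_t,
                          _["record_idx"] = record_idx);
  if (return_state) {
    NumericVector st(6 * n);
    for (int i = 0; i < n; ++i) {
      st[i] = Vm[i]; st[n + i] = Vw[i];
      st[2 * n + i] = m[i]; st[3 * n + i] = h[i];
      st[4 * n + i] = p[i]; st[5 * n + i] = s[i];
    }
    out["state"] = st;
  }
  return out;
}
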