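// Euler stepping engines for the four afferent spiking models.
//
// Two arithmetic back-ends share one control flow:
//  * double precision (the mathematical reference), and
//  * signed fixed point with a single register format (default Q13.18),
//    saturating adds, and products truncated toward -Inf after every
//    multiply, mirroring one shared register width per signal.
// Operation order is identical in both back-ends and in the R-level
// single-step functions, so cross-checks can demand exact agreement.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

typedef int64_t i64;
typedef __int128 i128;

enum Model { IZH = 0, LIZH = 1, QIF = 2, LQIF = 3 };

// parameter vector layout (quantized or not):
// 0 a, 1 b, 2 c, 3 d, 4 k1, 5 k2, 6 M1, 7 M2,
// 8 v_peak, 9 v_reset, 10 C_in (SA weight), 11 C_fa (FA weight)
enum Par { P_A = 0, P_B, P_C, P_D, P_K1, P_K2, P_M1, P_M2,
           P_VPEAK, P_VRESET, P_CIN, P_CFA };

// ---------------------------------------------------------------------------
// fixed-point helpers

struct FixedCtx {
  int F;            // fractional bits
  i64 maxr, minr;   // register bounds (two's complement value bits)
  i64 ovf;          // saturation event counter
  double qscale, dscale; // 2^F and 2^-F (exact doubles)

  FixedCtx(int int_bits, int frac_bits) : F(frac_bits), ovf(0) {
    int value_bits = int_bits + frac_bits; // excludes sign bit
    maxr = (value_bits >= 63) ? INT64_MAX : ((i64)1 << value_bits) - 1;
    minr = (value_bits >= 63) ? INT64_MIN : -((i64)1 << value_bits);
    qscale = std::ldexp(1.0, F);
    dscale = std::ldexp(1.0, -F);
  }
  i64 sat(i128 x) {
    if (x > (i128)maxr) { ovf++; return maxr; }
    if (x < (i128)minr) { ovf++; return minr; }
    return (i64)x;
  }
  // round-to-nearest, half away from zero (matches the R-level quantize())
  i64 quant(double x) {
    double s = x * qscale;
    double r = (s >= 0) ? std::floor(s + 0.5) : -std::floor(-s + 0.5);
    if (r > (double)maxr) { ovf++; return maxr; }
    if (r < (double)minr) { ovf++; return minr; }
    return (i64)r;
  }
  double deq(i64 r) const { return (double)r * dscale; }
  i64 add(i64 a, i64 b) { return sat((i128)a + (i128)b); }
  i64 sub(i64 a, i64 b) { return sat((i128)a - (i128)b); }
  // full-width product, then one truncation toward -Inf back to the format
  i64 mul(i64 a, i64 b) {
    i128 p = (i128)a * (i128)b;
    p >>= F; // arithmetic shift: floor division by 2^F
    return sat(p);
  }
  // multiply by +/-2^k realized as a logical/arithmetic shifter
  i64 shift(i64 a, int k, bool neg) {
    i128 x = neg ? -(i128)a : (i128)a;
    if (k >= 0) return sat(x << k);
    return sat(x >> (-k)); // arithmetic right shift truncates toward -Inf
  }
  i64 absv(i64 a) { return a < 0 ? sat(-(i128)a) : a; }
};

// is x = +/- 2^k for integer k? store k and sign
static bool pow2_coeff(double x, int &k, bool &neg) {
  if (x == 0 || !std::isfinite(x)) return false;
  neg = x < 0;
  double ax = std::fabs(x);
  double l = std::log2(ax);
  double rl = std::round(l);
  if (std::fabs(l - rl) > 1e-12) return false;
  k = (int)rl;
  return true;
}

// ---------------------------------------------------------------------------
// floating-point engine

// [[Rcpp::export]]
List cpp_sim_float(int model, bool fa, NumericVector I, double h,
                   NumericVector par, double v0, double u0,
                   bool return_trace, int n_steps = -1) {
  const R_xlen_t L = (n_steps < 0) ? I.size() : n_steps;
  const double a = par[P_A], b = par[P_B], c = par[P_C], d = par[P_D];
  const double k1 = par[P_K1], k2 = par[P_K2];
  const double M1 = par[P_M1], M2 = par[P_M2];
  const double vpeak = par[P_VPEAK], vreset = par[P_VRESET];
  const double Cin = par[P_CIN], Cfa = par[P_CFA];
  const bool two_var = (model == IZH || model == LIZH);

  NumericVector vt(return_trace ? L : 0);
  std::vector<int> spikes;
  double v = v0, u = u0;

  for (R_xlen_t i = 0; i < L; ++i) {
    const double I0 = I[i];
    const double I1 = (i + 1 < I.size()) ? I[i + 1] : I[I.size() - 1];
    double vn, un = u;
    switch (model) {
    case IZH: {
      double acc = 0.04 * (v * v) + 5 * v + 140 - u;
      if (!fa) acc = acc + Cin * I0;
      vn = v + h * acc;
      if (fa) vn = vn + Cfa * (I1 - I0);
      un = u + h * (a * ((b * v) - u));
      break;
    }
    case LIZH: {
      double acc = k1 * std::fabs(v + 62.5) - k2 - u;
      if (!fa) acc = acc + Cin * I0;
      vn = v + h * acc;
      if (fa) vn = vn + Cfa * (I1 - I0);
      un = u + h * (a * ((b * v) - u));
      break;
    }
    case QIF: {
      double acc = M1 * (v * v);
      if (!fa) acc = acc + Cin * I0;
      vn = v + h * acc;
      if (fa) vn = vn + Cfa * (I1 - I0);
      break;
    }
    default: { // LQIF
      double acc = M2 * std::fabs(v);
      if (!fa) acc = acc + Cin * I0;
      vn = v + h * acc;
      if (fa) vn = vn + Cfa * (I1 - I0);
      break;
    }
    }
    bool spiked = vn >= vpeak;
    if (spiked) {
      spikes.push_back((int)i + 1); // 1-based step index
      if (return_trace) vt[i] = vpeak; // plotting convention: peak at spike
      if (two_var) { vn = c; un = u + d; } else { vn = vreset; }
    } else if (return_trace) {
      vt[i] = vn;
    }
    v = vn;
    u = un;
  }
  return List::create(_["v"] = vt, _["spike_steps"] = wrap(spikes),
                      _["v_end"] = v, _["u_end"] = u);
}

// ---------------------------------------------------------------------------
// fixed-point engine

// [[Rcpp::export]]
List cpp_sim_fixed(int model, bool fa, NumericVector I, double h,
                   NumericVector par, double v0, double u0,
                   int int_bits, int frac_bits, bool use_shift,
                   bool return_trace, int n_steps = -1) {
  const R_xlen_t L = (n_steps < 0) ? I.size() : n_steps;
  FixedCtx fx(int_bits, frac_bits);
  const bool two_var = (model == IZH || model == LIZH);

  const i64 qa = fx.quant(par[P_A]), qb = fx.quant(par[P_B]);
  const i64 qc = fx.quant(par[P_C]), qd = fx.quant(par[P_D]);
  const i64 qk1 = fx.quant(par[P_K1]), qk2 = fx.quant(par[P_K2]);
  const i64 qM1 = fx.quant(par[P_M1]), qM2 = fx.quant(par[P_M2]);
  const i64 qvpeak = fx.quant(par[P_VPEAK]), qvreset = fx.quant(par[P_VRESET]);
  const i64 qCin = fx.quant(par[P_CIN]), qCfa = fx.quant(par[P_CFA]);
  const i64 q004 = fx.quant(0.04), q5 = fx.quant(5.0), q140 = fx.quant(140.0);
  const i64 q625 = fx.quant(62.5);
  const i64 qh = fx.quant(h);

  // shifter realization demands power-of-two coefficients
  int kM2 = 0, kCin = 0, kCfa = 0, kh = 0;
  bool nM2 = false, nCin = false, nCfa = false, nh = false;
  if (use_shift) {
    if (model != LQIF)
      stop("shift arithmetic is defined for the (improved) L-QIF model only");
    if (!pow2_coeff(par[P_M2], kM2, nM2) ||
        !pow2_coeff(par[P_CIN], kCin, nCin) ||
        !pow2_coeff(par[P_CFA], kCfa, nCfa) ||
        !pow2_coeff(h, kh, nh))
      stop("shift arithmetic requires all coefficients to be powers of two");
  }

  NumericVector vt(return_trace ? L : 0);
  std::vector<int> spikes;
  i64 v = fx.quant(v0), u = fx.quant(u0);
  const double *Ip = REAL(I);
  const R_xlen_t Ln = I.size();
  i64 qI_next = (L > 0) ? fx.quant(Ip[0]) : 0;

  for (R_xlen_t i = 0; i < L; ++i) {
    const i64 qI0 = qI_next;
    qI_next = (i + 1 < Ln) ? fx.quant(Ip[i + 1]) : qI0;
    const i64 qI1 = fa ? qI_next : qI0;
    i64 vn, un = u;
    switch (model) {
    case IZH: {
      i64 acc = fx.mul(q004, fx.mul(v, v));
      acc = fx.add(acc, fx.mul(q5, v));
      acc = fx.add(acc, q140);
      acc = fx.sub(acc, u);
      if (!fa) acc = fx.add(acc, fx.mul(qCin, qI0));
      vn = fx.add(v, fx.mul(qh, acc));
      if (fa) vn = fx.add(vn, fx.mul(qCfa, fx.sub(qI1, qI0)));
      un = fx.add(u, fx.mul(qh, fx.mul(qa, fx.sub(fx.mul(qb, v), u))));
      break;
    }
    case LIZH: {
      i64 acc = fx.mul(qk1, fx.absv(fx.add(v, q625)));
      acc = fx.sub(acc, qk2);
      acc = fx.sub(acc, u);
      if (!fa) acc = fx.add(acc, fx.mul(qCin, qI0));
      vn = fx.add(v, fx.mul(qh, acc));
      if (fa) vn = fx.add(vn, fx.mul(qCfa, fx.sub(qI1, qI0)));
      un = fx.add(u, fx.mul(qh, fx.mul(qa, fx.sub(fx.mul(qb, v), u))));
      break;
    }
    case QIF: {
      i64 acc = fx.mul(qM1, fx.mul(v, v));
      if (!fa) acc = fx.add(acc, fx.mul(qCin, qI0));
      vn = fx.add(v, fx.mul(qh, acc));
      if (fa) vn = fx.add(vn, fx.mul(qCfa, fx.sub(qI1, qI0)));
      break;
    }
    default: { // LQIF
      i64 acc;
      if (use_shift) {
        acc = fx.shift(fx.absv(v), kM2, nM2);
        if (!fa) acc = fx.add(acc, fx.shift(qI0, kCin, nCin));
        vn = fx.add(v, fx.shift(acc, kh, nh));
        if (fa) vn = fx.add(vn, fx.shift(fx.sub(qI1, qI0), kCfa, nCfa));
      } else {
        acc = fx.mul(qM2, fx.absv(v));
        if (!fa) acc = fx.add(acc, fx.mul(qCin, qI0));
        vn = fx.add(v, fx.mul(qh, acc));
        if (fa) vn = fx.add(vn, fx.mul(qCfa, fx.sub(qI1, qI0)));
      }
      break;
    }
    }
    bool spiked = vn >= qvpeak;
    if (spiked) {
      spikes.push_back((int)i + 1);
      if (return_trace) vt[i] = fx.deq(qvpeak);
      if (two_var) { vn = qc; un = fx.add(u, qd); } else { vn = qvreset; }
    } else if (return_trace) {
      vt[i] = fx.deq(vn);
    }
    v = vn;
    u = un;
  }
  return List::create(_["v"] = vt, _["spike_steps"] = wrap(spikes),
                      _["v_end"] = fx.deq(v), _["u_end"] = fx.deq(u),
                      _["overflow_events"] = (double)fx.ovf);
}

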