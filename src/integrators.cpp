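// Fixed-step RK4 integrators for the thalamo-cortical phase-oscillator model
// and its Ott-Antonsen reduction.
//
// Unit convention: natural frequencies, half-widths, coupling strengths and
// the stimulus intensity are all expressed on a common Hz-like scale; the
// whole right-hand side is converted to rad/ms by the factor 2*pi/1000.
// Time is in milliseconds throughout.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double UNIT = 2.0 * M_PI / 1000.0; // rad/ms per Hz

// Half-open stimulus window [onset, onset + duration)
static inline double stim(double t, double I, double onset, double dur) {
  return (t >= onset && t < onset + dur) ? I : 0.0;
}

// ---------------------------------------------------------------------------
// Full N-oscillator model.
//
// Population 0 is the thalamus; populations 1..B are cortical bands.
// Cortical oscillator k in band b:
//   dphi/dt = UNIT * ( f_b[k] + ktc[b] * R_T * sin(Theta_T - phi) )
// Thalamic oscillator k:
//   dphi/dt = UNIT * ( f_T[k] + sum_b kct[b] * R_b * sin(Theta_b - phi)
//                      + I(t) * cos(phi) )
// ---------------------------------------------------------------------------

struct FullModel {
  std::vector< std::vector<double> > freq; // natural frequencies, per pop
  std::vector<double> ktc, kct;            // per band
  double I, onset, dur;
  int B;                                   // number of cortical bands

  // mean field of one phase vector
  static void mf(const std::vector<double>& phi, double& re, double& im) {
    double sr = 0.0, si = 0.0;
    for (size_t k = 0; k < phi.size(); ++k) { sr += std::cos(phi[k]); si += std::sin(phi[k]); }
    re = sr / phi.size(); im = si / phi.size();
  }

  void rhs(double t, const std::vector< std::vector<double> >& phi,
           std::vector< std::vector<double> >& dphi) const {
    // mean fields of every population at the current stage state
    std::vector<double> re(B + 1), im(B + 1);
    for (int a = 0; a <= B; ++a) mf(phi[a], re[a], im[a]);
    double It = stim(t, I, onset, dur);
    // thalamus
    {
      const std::vector<double>& p = phi[0];
      std::vector<double>& d = dphi[0];
      for (size_t k = 0; k < p.size(); ++k) {
        double s = 0.0;
        for (int b = 1; b <= B; ++b)
          // R_b * sin(Theta_b - phi) = im_b*cos(phi) - re_b*sin(phi)
          s += kct[b - 1] * (im[b] * std::cos(p[k]) - re[b] * std::sin(p[k]));
        d[k] = UNIT * (freq[0][k] + s + It * std::cos(p[k]));
      }
    }
    // cortical bands
    for (int b = 1; b <= B; ++b) {
      const std::vector<double>& p = phi[b];
      std::vector<double>& d = dphi[b];
      double kT = ktc[b - 1];
      for (size_t k = 0; k < p.size(); ++k)
        d[k] = UNIT * (freq[b][k] + kT * (im[0] * std::cos(p[k]) - re[0] * std::sin(p[k])));
    }
  }
};

// [[Rcpp::export(name = ".full_rk4_cpp")]]
List full_rk4_cpp(List freqs, List phi0, NumericVector k_tc, NumericVector k_ct,
                  double I, double onset, double duration,
                  double t0, double t1, double dt, int thin,
                  bool store_phases) {
  FullModel m;
  int P = freqs.size();
  m.B = P - 1;
  for (int a = 0; a < P; ++a) {
    NumericVector f = freqs[a];
    m.freq.push_back(std::vector<double>(f.begin(), f.end()));
  }
  m.ktc.assign(k_tc.begin(), k_tc.end());
  m.kct.assign(k_ct.begin(), k_ct.end());
  m.I = I; m.onset = onset; m.dur = duration;

  std::vector< std::vector<double> > phi(P), k1(P), k2(P), k3(P), k4(P), tmp(P);
  for (int a = 0; a < P; ++a) {
    NumericVector p0 = phi0[a];
    phi[a].assign(p0.begin(), p0.end());
    size_t n = phi[a].size();
    k1[a].resize(n); k2[a].resize(n); k3[a].resize(n); k4[a].resize(n); tmp[a].resize(n);
  }

  long nsteps = (long) std::lround((t1 - t0) / dt);
  long nout = nsteps / thin + 1;
  NumericVector times(nout);
  NumericMatrix Yre(nout, P), Yim(nout, P);
  List phase_store;
  std::vector<NumericMatrix> pm;
  if (store_phases)
    for (int a = 0; a < P; ++a) pm.push_back(NumericMatrix(nout, (int) phi[a].size()));

  long iout = 0;
  for (long i = 0; i <= nsteps; ++i) {
    double t = t0 + i * dt;
    if (i % thin == 0) {
      times[iout] = t;
      for (int a = 0; a < P; ++a) {
        double re, im; FullModel::mf(phi[a], re, im);
        Yre(iout, a) = re; Yim(iout, a) = im;
        if (store_phases) {
          double twopi = 2.0 * M_PI;
          for (size_t k = 0; k < phi[a].size(); ++k) {
            double w = phi[a][k] - twopi * std::floor(phi[a][k] / twopi);
            pm[a](iout, (int) k) = w;
          }
        }
      }
      ++iout;
    }
    if (i == nsteps) break;
    m.rhs(t, phi, k1);
    for (int a = 0; a < P; ++a)
      for (size_t k = 0; k < phi[a].size(); ++k) tmp[a][k] = phi[a][k] + 0.5 * dt * k1[a][k];
    m.rhs(t + 0.5 * dt, tmp, k2);
    for (int a = 0; a < P; ++a)
      for (size_t k = 0; k < phi[a].size(); ++k) tmp[a][k] = phi[a][k] + 0.5 * dt * k2[a][k];
    m.rhs(t + 0.5 * dt, tmp, k3);
    for (int a = 0; a < P; ++a)
      for (size_t k = 0; k < phi[a].size(); ++k) tmp[a][k] = phi[a][k] + dt * k3[a][k];
    m.rhs(t + dt, tmp, k4);
    bool bad = false;
    for (int a = 0; a < P; ++a)
      for (size_t k = 0; k < phi[a].size(); ++k) {
        phi[a][k] += dt / 6.0 * (k1[a][k] + 2.0 * k2[a][k] + 2.0 * k3[a][k] + k4[a][k]);
        if (!std::isfinite(phi[a][k])) bad = true;
      }
    if (bad)
      stop("non-finite state encountered at t = %f ms", t + dt);
  }

  if (store_phases) {
    phase_store = List(P);
    for (int a = 0; a < P; ++a) phase_store[a] = pm[a];
  }
  return List::create(_["times_ms"] = times, _["Yre"] = Yre, _["Yim"] = Yim,
                      _["phases"] = store_phases ? SEXP(phase_store) : R_NilValue);
}

// ---------------------------------------------------------------------------
// Ott-Antonsen reduced model.
//
//   dY_a/dt = UNIT * ( (i fhat_a - Delta_a) Y_a + (H_a - conj(H_a) Y_a^2)/2 )
// with driving fields
//   H_T        = sum_b kct[b] Y_b + i I(t)
//   H_b (band) = ktc[b] Y_T
// ---------------------------------------------------------------------------

typedef std::complex<double> cplx;

static void reduced_rhs_c(double t, const std::vector<cplx>& Y,
                          const std::vector<double>& fhat,
                          const std::vector<double>& delta,
                          const std::vector<double>& ktc,
                          const std::vector<double>& kct,
                          double I, double onset, double dur,
                          std::vector<cplx>& dY) {
  int P = (int) Y.size();
  cplx HT(0.0, stim(t, I, onset, dur));
  for (int b = 1; b < P; ++b) HT += kct[b - 1] * Y[b];
  dY[0] = UNIT * ((cplx(0.0, fhat[0]) - delta[0]) * Y[0] +
                  0.5 * (HT - std::conj(HT) * Y[0] * Y[0]));
  for (int b = 1; b < P; ++b) {
    cplx H = ktc[b - 1] * Y[0];
    dY[b] = UNIT * ((cplx(0.0, fhat[b]) - delta[b]) * Y[b] +
                    0.5 * (H - std::conj(H) * Y[b] * Y[b]));
  }
}

// [[Rcpp::export(name = ".reduced_rk4_cpp")]]
List reduced_rk4_cpp(NumericVector fhat, NumericVector delta,
                     NumericVector k_tc, NumericVector k_ct,
                     double I, double onset, double duration,
                     ComplexVector y0, double t0, double t1, double dt,
                     int thin) {
  int P = fhat.size();
  std::vector<double> f(fhat.begin(), fhat.end()), d(delta.begin(), delta.end());
  std::vector<double> ktc(k_tc.begin(), k_tc.end()), kct(k_ct.begin(), k_ct.end());
  std::vector<cplx> Y(P), k1(P), k2(P), k3(P), k4(P), tmp(P);
  for (int a = 0; a < P; ++a) Y[a] = cplx(y0[a].r, y0[a].i);

  long nsteps = (long) std::lround((t1 - t0) / dt);
  long nout = nsteps / thin + 1;
  NumericVector times(nout);
  ComplexMatrix out(nout, P);

  long iout = 0;
  for (long i = 0; i <= nsteps; ++i) {
    double t = t0 + i * dt;
    if (i % thin == 0) {
      times[iout] = t;
      for (int a = 0; a < P; ++a) {
        Rcomplex z; z.r = Y[a].real(); z.i = Y[a].imag();
        out(iout, a) = z;
      }
      ++iout;
    }
    if (i == nsteps) break;
    reduced_rhs_c(t, Y, f, d, ktc, kct, I, onset, duration, k1);
    for (int a = 0; a < P; ++a) tmp[a] = Y[a] + 0.5 * dt * k1[a];
    reduced_rhs_c(t + 0.5 * dt, tmp, f, d, ktc, kct, I, onset, duration, k2);
    for (int a = 0; a < P; ++a) tmp[a] = Y[a] + 0.5 * dt * k2[a];
    reduced_rhs_c(t + 0.5 * dt, tmp, f, d, ktc, kct, I, onset, duration, k3);
    for (int a = 0; a < P; ++a) tmp[a] = Y[a] + dt * k3[a];
    reduced_rhs_c(t + dt, tmp, f, d, ktc, kct, I, onset, duration, k4);
    double amax = 0.0;
    for (int a = 0; a < P; ++a) {
      Y[a] += dt / 6.0 * (k1[a] + 2.0 * k2[a] + 2.0 * k3[a] + k4[a]);
      double m = std::abs(Y[a]);
      if (m > amax) amax = m;
      if (!std::isfinite(m))
        stop("non-finite order parameter at t = %f ms", t + dt);
    }
    if (amax > 1.0 + 1e-6)
      stop("order parameter left the unit disc (|Y| = %f) at t = %f ms", amax, t + dt);
  }
  return List::create(_["times_ms"] = times, _["Y"] = out);
}
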