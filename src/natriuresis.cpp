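#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-analytic integrator for the natriuresis turnover model with a
// threshold-activated reversible resistance modulator.
//
// States: E  natriuresis rate (mEq/h), R resistance fraction in [0,1],
//         Q  cumulative sodium excreted (mEq).
// Drive:  the daily urinary torasemide amount enters through the sigmoid
//         stimulus S = Emax*(1-R)*q^h/(EC50^h+q^h); q is piecewise constant
//         per 24 h dosing day, so within a day S varies only through R.
//   dE/dt = kfor*(1+S) - kabs*E
//   dR/dt = [kon if S > thr else 0] - koff*R
//   dQ/dt = E
// With q constant, R is a single exponential within each activation regime, so
// E and its integral have closed forms; the only events are day boundaries,
// requested output times, and threshold crossings of S (located analytically).
// When the on/off rule would chatter at the threshold (activation pulls S
// below thr, deactivation pushes it back above), the exact sliding solution
// pins S at thr with R constant.

struct NatPars {
  double kfor, kabs, emax, ec50, hill, kon, koff, thr;
};

// advance E and accumulate integral of E over dt, with R following
// R(t) = Rinf + (R0-Rinf)*exp(-koff*t) and S = c*(1-R)
static void advance(const NatPars &p, double c, double Rinf, double dt,
                    double &E, double &R, double &Q, bool slide) {
  double a, b;
  if (slide) {          // R pinned, S == thr exactly
    a = p.kfor * (1.0 + p.thr);
    b = 0.0;
  } else {
    a = p.kfor * (1.0 + c * (1.0 - Rinf));
    b = -p.kfor * c * (R - Rinf);
  }
  double E0 = E;
  double ek = std::exp(-p.kabs * dt);
  if (std::fabs(p.kabs - p.koff) > 1e-9 * p.kabs && b != 0.0) {
    double eo = std::exp(-p.koff * dt);
    double bb = b / (p.kabs - p.koff);
    double K = E0 - a / p.kabs - bb;
    E = a / p.kabs + bb * eo + K * ek;
    Q += a * dt / p.kabs + bb * (1.0 - eo) / p.koff + K * (1.0 - ek) / p.kabs;
  } else if (b != 0.0) { // kabs == koff resonance limit: b*t*exp(-kabs t)
    double K = E0 - a / p.kabs;
    E = a / p.kabs + K * ek + b * dt * ek;
    Q += a * dt / p.kabs + K * (1.0 - ek) / p.kabs +
         b * (1.0 - (1.0 + p.kabs * dt) * ek) / (p.kabs * p.kabs);
  } else {              // constant forcing
    double K = E0 - a / p.kabs;
    E = a / p.kabs + K * ek;
    Q += a * dt / p.kabs + K * (1.0 - ek) / p.kabs;
  }
  if (!slide) R = Rinf + (R - Rinf) * std::exp(-p.koff * dt);
}

// [[Rcpp::export(name = ".nat_sim_cpp")]]
NumericMatrix nat_sim_cpp(NumericVector pars, NumericVector q_daily,
                          NumericVector times, double E0, double R0) {
  NatPars p;
  p.kfor = pars[0]; p.kabs = pars[1]; p.emax = pars[2]; p.ec50 = pars[3];
  p.hill = pars[4]; p.kon = pars[5]; p.koff = pars[6]; p.thr = pars[7];
  const double Rcap = p.kon / p.koff;

  const int nt = times.size();
  NumericMatrix out(nt, 3); // Qcum, E, R
  double E = E0, R = R0, Q = 0.0, t = 0.0;
  int it = 0;
  // emit any outputs at t == 0
  while (it < nt && times[it] <= 1e-12) {
    out(it, 0) = Q; out(it, 1) = E; out(it, 2) = R; ++it;
  }

  while (it < nt) {
    int day = (int)std::floor(t / 24.0 + 1e-12);
    double day_end = 24.0 * (day + 1);
    double q = (day < q_daily.size()) ? q_daily[day] : 0.0;
    double c = 0.0;
    if (q > 0.0) {
      double qh = std::pow(q / p.ec50, p.hill);
      c = p.emax * qh / (1.0 + qh);
    }
    double seg_end = std::min(day_end, times[it]);

    // walk (possibly several) regimes inside [t, seg_end)
    while (t < seg_end - 1e-12) {
      bool on, slide = false;
      double Rstar = -1.0;
      if (c <= p.thr) {
        on = false;                       // S = c(1-R) <= c <= thr
      } else {
        Rstar = 1.0 - p.thr / c;
        double eps = 1e-10 * std::max(1.0, Rstar);
        if (std::fabs(R - Rstar) <= eps) {
          if (Rcap > Rstar) { slide = true; on = true; R = Rstar; }
          else on = true;                  // genuine activation, R -> Rcap <= Rstar
        } else {
          on = (R < Rstar);                // S0 > thr iff R0 < Rstar
        }
      }
      double Rinf = on ? Rcap : 0.0;
      // next threshold crossing inside this regime (exact, R exponential)
      double tc = R_PosInf;
      if (!slide && c > p.thr) {
        double num = Rstar - Rinf, den = R - Rinf;
        if (den != 0.0) {
          double ratio = num / den;
          if (ratio > 0.0 && ratio < 1.0)
            tc = -std::log(ratio) / p.koff;
        }
      }
      double dt = seg_end - t;
      if (tc < dt - 1e-12) {
        advance(p, c, Rinf, tc, E, R, Q, slide);
        R = Rstar; // land exactly on the switching surface
        t += tc;
      } else {
        advance(p, c, Rinf, dt, E, R, Q, slide);
        t = seg_end;
      }
    }
    t = seg_end;
    while (it < nt && times[it] <= t + 1e-12) {
      out(it, 0) = Q; out(it, 1) = E; out(it, 2) = R; ++it;
    }
  }
  return out;
}
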