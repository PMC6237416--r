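// Reduced-coordinate potential and overdamped integrator for the
// translocase-nucleosome ratchet.  Coordinate layout (length 16):
//   v[0..13]  contact indexes x at half-integer SHLs -6.5 .. +6.5 (bp)
//   v[14]     lobe-1 registration y1 (bp)
//   v[15]     lobe-2 registration y2 (bp)
// Energies in kBT (kBT = 1), lengths in bp.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NX = 14;   // contact sites
static const int ND = 13;   // defect sites (integer SHLs -6..6)
static const int NC = 16;   // total coordinates
static const double TWOPI = 6.283185307179586476925286766559;

struct PhaseParams {
  std::vector<double> depth, tilt;      // per contact, length 14
  std::vector<double> kk, mup, mum;     // per defect site, length 13
  double stab;                          // closed-state defect stabilization
  double smooth;                        // softmin temperature (kBT)
  double grip1, grip2;                  // lobe grip well depths (kBT)
  double strain;                        // ATP lobe-1 interface destabilization
  double release;                       // ADP lobe-2 interface destabilization
  double coup_off;                      // linear closed-state offset: dE/du
  double coup_h;                        // lobe-lobe double-well barrier height
  double eps_elec, elec_w2;             // spring depth, width^2
  double wall_hw, wall_h;
  bool octamer, remodeler, wall_on, elec_on;
  bool freeze_dna, freeze_lobes;
};

static PhaseParams parse_phase(const List& ph) {
  PhaseParams p;
  NumericVector depth = ph["depth"], tilt = ph["tilt"];
  NumericVector kk = ph["k"], mup = ph["mu_plus"], mum = ph["mu_minus"];
  if (depth.size() != NX || tilt.size() != NX)
    stop("contact parameter vectors must have length 14");
  if (kk.size() != ND || mup.size() != ND || mum.size() != ND)
    stop("defect parameter vectors must have length 13");
  p.depth.assign(depth.begin(), depth.end());
  p.tilt.assign(tilt.begin(), tilt.end());
  p.kk.assign(kk.begin(), kk.end());
  p.mup.assign(mup.begin(), mup.end());
  p.mum.assign(mum.begin(), mum.end());
  p.smooth     = as<double>(ph["smooth"]);
  p.stab       = as<double>(ph["stab"]);
  p.grip1      = as<double>(ph["grip1"]);
  p.grip2      = as<double>(ph["grip2"]);
  p.strain     = as<double>(ph["strain"]);
  p.release    = as<double>(ph["release"]);
  p.coup_off   = as<double>(ph["coup_off"]);
  p.coup_h     = as<double>(ph["coup_h"]);
  p.eps_elec   = as<double>(ph["eps_elec"]);
  double w     = as<double>(ph["elec_width"]);
  p.elec_w2    = w * w;
  p.wall_hw    = as<double>(ph["wall_halfwidth"]);
  p.wall_h     = as<double>(ph["wall_height"]);
  p.octamer    = as<bool>(ph["octamer"]);
  p.remodeler  = as<bool>(ph["remodeler"]);
  p.wall_on    = as<bool>(ph["wall"]);
  p.elec_on    = as<bool>(ph["elec"]);
  p.freeze_dna   = as<bool>(ph["freeze_dna"]);
  p.freeze_lobes = as<bool>(ph["freeze_lobes"]);
  return p;
}

// Smoothed three-well twist-defect energy: softmin (log-sum-exp at
// temperature `smooth`) of harmonic branches centred at d = -1, 0, +1 with
// offsets mu_minus, 0, mu_plus.  Branches further than 25*smooth above the
// lowest are dropped (weights < 1e-10), so far outside [-1, 1] the value is
// exactly the outermost branch.
static inline double twist_e(double d, double k, double mup, double mum,
                             double ts, double* dEdd,
                             double* dEdmup = 0, double* dEdmum = 0) {
  double f[3], df[3];
  const double mu[3] = {mum, 0.0, mup};
  const double m[3] = {-1.0, 0.0, 1.0};
  double fmin = R_PosInf;
  for (int i = 0; i < 3; ++i) {
    double dd = d - m[i];
    f[i] = mu[i] + 0.5 * k * dd * dd;
    df[i] = k * dd;
    if (f[i] < fmin) fmin = f[i];
  }
  double cut = 25.0 * ts;
  double z = 0.0, zf = 0.0, w[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < 3; ++i) {
    if (f[i] - fmin < cut) {
      w[i] = std::exp(-(f[i] - fmin) / ts);
      z += w[i];
      zf += w[i] * df[i];
    }
  }
  if (dEdd) *dEdd = zf / z;
  if (dEdmup) *dEdmup = w[2] / z;   // occupancy of the +1 branch
  if (dEdmum) *dEdmum = w[0] / z;   // occupancy of the -1 branch
  return fmin - ts * std::log(z);
}

// Lobe-lobe coupling along u = y1 - y2: quartic double well with minima at
// u = 0 (open) and u = 1 (closed), barrier coup_h at u = 1/2, plus the
// chemical-state dependent linear offset coup_off * u (negative favours the
// closed form).  The quartic grows outside [0, 1], confining u.
static inline double coup_e(double u, double h, double off, double* dEdu) {
  double um = 1.0 - u;
  if (dEdu) *dEdu = 32.0 * h * u * um * (1.0 - 2.0 * u) + off;
  return 16.0 * h * u * u * um * um + off * u;
}

// Full potential; fills grad (length 16) if non-null.  Optional harmonic
// bias 0.5*bias_k*(xbar - bias_c)^2 on xbar = (x_1.5 + x_2.5)/2 (umbrella
// sampling); bias_k = 0 disables it.
static double energy_grad(const double* v, const PhaseParams& p,
                          double bias_k, double bias_c, double* grad) {
  double E = 0.0;
  if (grad) for (int i = 0; i < NC; ++i) grad[i] = 0.0;
  if (p.octamer) {
    for (int j = 0; j < NX; ++j) {
      E += p.depth[j] * 0.5 * (1.0 - std::cos(TWOPI * v[j])) + p.tilt[j] * v[j];
      if (grad)
        grad[j] += p.depth[j] * 0.5 * TWOPI * std::sin(TWOPI * v[j]) + p.tilt[j];
    }
    // the closed translocase stabilizes the productive defect pair at its
    // binding site: mu_plus at SHL +1 (site 7) and mu_minus at SHL +2
    // (site 8) are reduced by stab * s(u), s a logistic in u = y1 - y2
    double sg = 0.0, dsg = 0.0;
    if (p.remodeler && p.stab > 0.0) {
      const double usw = 0.1;
      sg = 1.0 / (1.0 + std::exp(-(v[14] - v[15] - 0.5) / usw));
      dsg = sg * (1.0 - sg) / usw;
    }
    for (int i = 0; i < ND; ++i) {
      double d = v[i + 1] - v[i];
      double dd, wp, wm;
      double mup = p.mup[i], mum = p.mum[i];
      bool st = (sg > 0.0) && (i == 7 || i == 8);
      if (st) {
        if (i == 7) { mup -= p.stab * sg; if (mup < 0) mup = 0; }
        else        { mum -= p.stab * sg; if (mum < 0) mum = 0; }
      }
      E += twist_e(d, p.kk[i], mup, mum, p.smooth, grad ? &dd : 0,
                   (grad && st) ? &wp : 0, (grad && st) ? &wm : 0);
      if (grad) {
        grad[i + 1] += dd; grad[i] -= dd;
        if (st) {
          // d(mu_eff)/du = -stab * dsg while the clamp is inactive
          double act = (i == 7) ? ((p.mup[i] - p.stab * sg) > 0.0 ? wp : 0.0)
                                : ((p.mum[i] - p.stab * sg) > 0.0 ? wm : 0.0);
          double dEdu = -p.stab * dsg * act;
          grad[14] += dEdu; grad[15] -= dEdu;
        }
      }
    }
  }
  const double y1 = v[14], y2 = v[15];
  if (p.remodeler) {
    const double u = y1 - y2;
    // ATP strain destabilizes the lobe-1/DNA interface while lobe 1 is
    // still at its pre-closure register: the grip well depth is reduced by
    // strain * r(y1), r a logistic switching off around y1 = 0.5, so the
    // first forward step is facilitated and lobe 1 re-grips once closed.
    const double sw = 0.1;   // switch width (bp)
    double r1s = 1.0 / (1.0 + std::exp((y1 - 0.5) / sw));
    double d1 = p.grip1 - p.strain * r1s;
    double dD1dy1 = (d1 > 0.0) ? p.strain * r1s * (1.0 - r1s) / sw : 0.0;
    if (d1 < 0.0) d1 = 0.0;
    // ADP release: hydrolysis destabilizes the lobe-2/DNA interface while
    // lobe 2 is at its pre-opening register (y2 < ~0.5), facilitating its
    // forward step during translocase opening.
    double r2s = 1.0 / (1.0 + std::exp((y2 - 0.5) / sw));
    double d2 = p.grip2 - p.release * r2s;
    double dD2dy2 = (d2 > 0.0) ? p.release * r2s * (1.0 - r2s) / sw : 0.0;
    if (d2 < 0.0) d2 = 0.0;
    const double w1 = 0.5 * (1.0 - std::cos(TWOPI * y1));
    const double w2 = 0.5 * (1.0 - std::cos(TWOPI * y2));
    E += d1 * w1 + d2 * w2;
    double du;
    E += coup_e(u, p.coup_h, p.coup_off, grad ? &du : 0);
    if (grad) {
      grad[14] += d1 * 0.5 * TWOPI * std::sin(TWOPI * y1) + dD1dy1 * w1 + du;
      grad[15] += d2 * 0.5 * TWOPI * std::sin(TWOPI * y2) + dD2dy2 * w2 - du;
    }
  }
  const double xbar = 0.5 * (v[8] + v[9]);  // SHLs +1.5, +2.5
  if (p.wall_on) {
    double rho = xbar - 0.5 * (y1 + y2);
    double ex = std::fabs(rho) - p.wall_hw;
    if (ex > 0.0) {
      E += p.wall_h * ex * ex;
      if (grad) {
        double f = 2.0 * p.wall_h * ex * (rho > 0 ? 1.0 : -1.0);
        grad[8] += 0.5 * f; grad[9] += 0.5 * f;
        grad[14] -= 0.5 * f; grad[15] -= 0.5 * f;
      }
    }
  }
  if (p.elec_on && p.eps_elec != 0.0) {
    double r1 = xbar - y1;
    double g = std::exp(-0.5 * r1 * r1 / p.elec_w2);
    E += -p.eps_elec * g;
    if (grad) {
      double f = p.eps_elec * g * r1 / p.elec_w2;  // dE/dr1
      grad[8] += 0.5 * f; grad[9] += 0.5 * f;
      grad[14] -= f;
    }
  }
  if (bias_k > 0.0) {
    double dx = xbar - bias_c;
    E += 0.5 * bias_k * dx * dx;
    if (grad) { grad[8] += 0.5 * bias_k * dx; grad[9] += 0.5 * bias_k * dx; }
  }
  return E;
}

// [[Rcpp::export]]
double cpp_energy(NumericVector state, List phase,
                  double bias_k = 0.0, double bias_c = 0.0) {
  if (state.size() != NC) stop("state must have length 16");
  PhaseParams p = parse_phase(phase);
  return energy_grad(REAL(state), p, bias_k, bias_c, 0);
}

// [[Rcpp::export]]
NumericVector cpp_gradient(NumericVector state, List phase,
                           double bias_k = 0.0, double bias_c = 0.0) {
  if (state.size() != NC) stop("state must have length 16");
  PhaseParams p = parse_phase(phase);
  NumericVector g(NC);
  energy_grad(REAL(state), p, bias_k, bias_c, REAL(g));
  return g;
}

// [[Rcpp::export]]
double cpp_twist_energy(double d, double k, double mup, double mum,
                        double smooth) {
  return twist_e(d, k, mup, mum, smooth, 0);
}

// Propagate one trajectory through an ordered list of phases.
// phases: list of phase parameter lists; phase_steps: integer steps each.
// Snapshots every `stride` steps (the initial state is snapshot 1).
// Uses R's RNG (seed with set.seed() before calling).
// [[Rcpp::export]]
List cpp_simulate(NumericVector state0, List phases, IntegerVector phase_steps,
                  double dt, double D_dna, double D_lobe, int stride,
                  bool noise = true, double bias_k = 0.0, double bias_c = 0.0) {
  if (state0.size() != NC) stop("state0 must have length 16");
  int nph = phases.size();
  if (phase_steps.size() != nph) stop("phases and phase_steps lengths differ");
  if (stride < 1) stop("stride must be >= 1");
  std::vector<PhaseParams> pp(nph);
  long total = 0;
  for (int i = 0; i < nph; ++i) {
    pp[i] = parse_phase(phases[i]);
    if (phase_steps[i] < 0) stop("negative phase length");
    total += phase_steps[i];
  }
  int nsnap = 1 + (int)(total / stride);
  NumericMatrix snaps(nsnap, NC);
  IntegerVector snap_phase(nsnap);
  NumericVector snap_time(nsnap);

  double v[NC], grad[NC];
  for (int i = 0; i < NC; ++i) v[i] = state0[i];
  snaps(0, _) = state0;
  snap_phase[0] = 1;
  snap_time[0] = 0.0;

  RNGScope rng;
  long step = 0;
  int isnap = 1;
  for (int ph = 0; ph < nph; ++ph) {
    const PhaseParams& p = pp[ph];
    const double sd_d = noise ? std::sqrt(2.0 * D_dna * dt) : 0.0;
    const double sd_l = noise ? std::sqrt(2.0 * D_lobe * dt) : 0.0;
    const bool upd_x = !p.freeze_dna, upd_y = !p.freeze_lobes;
    for (int s = 0; s < phase_steps[ph]; ++s) {
      energy_grad(v, p, bias_k, bias_c, grad);
      if (upd_x) {
        for (int i = 0; i < NX; ++i) {
          v[i] += -grad[i] * D_dna * dt;
          if (noise) v[i] += sd_d * norm_rand();
        }
      }
      if (upd_y) {
        for (int i = NX; i < NC; ++i) {
          v[i] += -grad[i] * D_lobe * dt;
          if (noise) v[i] += sd_l * norm_rand();
        }
      }
      ++step;
      if (step % stride == 0) {
        bool ok = true;
        for (int i = 0; i < NC; ++i) if (!std::isfinite(v[i])) ok = false;
        if (!ok) {
          std::string msg = "non-finite coordinate during integration; state:";
          for (int i = 0; i < NC; ++i)
            msg += " " + std::to_string(v[i]);
          stop(msg.c_str());
        }
        for (int i = 0; i < NC; ++i) snaps(isnap, i) = v[i];
        snap_phase[isnap] = ph + 1;
        snap_time[isnap] = step * dt;
        ++isnap;
      }
    }
  }
  NumericVector fin(NC);
  for (int i = 0; i < NC; ++i) fin[i] = v[i];
  return List::create(_["coords"] = snaps, _["phase"] = snap_phase,
                      _["time"] = snap_time, _["final"] = fin);
}
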