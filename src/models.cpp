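#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shared fixed-step RK4 drivers for the two sequence circuit models.
// Time and position are interchangeable at constant velocity; the step is
// grid_step / velocity (0.002 s at defaults), below the 0.01 s max-step bound
// required so that no 1-cm cue window is stepped over.

namespace {

// 1 iff any cue lies strictly within 0.5 cm of p
inline double cue_ind(const std::vector<double>& cues, double p) {
  for (size_t k = 0; k < cues.size(); ++k) {
    if (std::fabs(p - cues[k]) < 0.5) return 1.0;
  }
  return 0.0;
}

struct Gate {
  int type;                      // 0 = piecewise boundaries, 1 = gaussian
  std::vector<double> bounds;    // piecewise: length n+1, unit i on [b_i, b_{i+1})
  double drive;                  // piecewise: value when on (T + X)
  std::vector<double> centers;   // gaussian centers mu_i
  double alpha, beta;            // gaussian amplitude / squared-width

  inline void eval(double p, std::vector<double>& P) const {
    size_t n = P.size();
    if (type == 0) {
      for (size_t i = 0; i < n; ++i)
        P[i] = (bounds[i] <= p && p < bounds[i + 1]) ? drive : 0.0;
    } else {
      for (size_t i = 0; i < n; ++i) {
        double d = p - centers[i];
        P[i] = alpha * std::exp(-d * d / beta);
      }
    }
  }
};

Gate gate_from_list(List g) {
  Gate gt;
  std::string ty = as<std::string>(g["type"]);
  if (ty == "piecewise") {
    gt.type = 0;
    gt.bounds = as<std::vector<double> >(g["boundaries"]);
    gt.drive = as<double>(g["drive"]);
  } else {
    gt.type = 1;
    gt.centers = as<std::vector<double> >(g["centers"]);
    gt.alpha = as<double>(g["alpha"]);
    gt.beta = as<double>(g["beta"]);
  }
  return gt;
}

} // namespace

// Mutually inhibiting / uncoupled competing chains (and, with n = 1 and a gate
// that is always on, the traditional competing accumulator).  State layout:
// rL[0..n-1], rR[0..n-1].
// [[Rcpp::export]]
NumericMatrix sim_chain_cpp(NumericVector left_cues, NumericVector right_cues,
                            double a, NumericVector bvec, double cc, double ee,
                            double f, double T, List gate, int variant,
                            NumericVector o_left, NumericVector o_right,
                            double precue_start, double maze_end,
                            double velocity, double grid_step,
                            double max_step) {
  const int n = bvec.size();
  Gate gt = gate_from_list(gate);
  std::vector<double> L = as<std::vector<double> >(left_cues);
  std::vector<double> R = as<std::vector<double> >(right_cues);

  const int ngrid = (int) std::floor((maze_end - precue_start) / grid_step + 0.5) + 1;
  const double h_grid = grid_step / velocity;
  const int nsub = std::max(1, (int) std::ceil(h_grid / max_step - 1e-12));
  const double h = h_grid / nsub;

  std::vector<double> s(2 * n, 0.0), k1(2 * n), k2(2 * n), k3(2 * n), k4(2 * n),
      tmp(2 * n), P(n);
  NumericMatrix out(2 * n, ngrid);
  for (int i = 0; i < 2 * n; ++i) out(i, 0) = 0.0;

  // rhs at position p into dr
  auto rhs = [&](const std::vector<double>& r, double p, std::vector<double>& dr) {
    gt.eval(p, P);
    double iL = cue_ind(L, p), iR = cue_ind(R, p);
    for (int i = 0; i < n; ++i) {
      double prevL = (i > 0) ? r[i - 1] : 0.0;
      double prevR = (i > 0) ? r[n + i - 1] : 0.0;
      double inL, inR;
      if (variant == 1) { // uncoupled push-pull: cues enter with opposite signs
        inL = f * (iL - iR);
        inR = f * (iR - iL);
      } else {
        inL = f * iL;
        inR = f * iR;
      }
      double brL = bvec[i] * r[i] + cc * prevL + P[i] - T + o_left[i] + inL;
      double brR = bvec[i] * r[n + i] + cc * prevR + P[i] - T + o_right[i] + inR;
      if (variant == 0) { // mutual inhibition between chains
        brL -= ee * r[n + i];
        brR -= ee * r[i];
      }
      dr[i] = -a * r[i] + (brL > 0.0 ? brL : 0.0);
      dr[n + i] = -a * r[n + i] + (brR > 0.0 ? brR : 0.0);
    }
  };

  double t = 0.0;
  for (int g = 1; g < ngrid; ++g) {
    for (int sub = 0; sub < nsub; ++sub) {
      double p0 = precue_start + velocity * t;
      double pm = precue_start + velocity * (t + h / 2.0);
      double p1 = precue_start + velocity * (t + h);
      rhs(s, p0, k1);
      for (int i = 0; i < 2 * n; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
      rhs(tmp, pm, k2);
      for (int i = 0; i < 2 * n; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
      rhs(tmp, pm, k3);
      for (int i = 0; i < 2 * n; ++i) tmp[i] = s[i] + h * k3[i];
      rhs(tmp, p1, k4);
      for (int i = 0; i < 2 * n; ++i) {
        s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (s[i] < 0.0) s[i] = 0.0; // rectified dynamics cannot cross zero
      }
      t += h;
    }
    for (int i = 0; i < 2 * n; ++i) {
      if (!R_finite(s[i])) stop("non-finite state in chain simulation at grid index %d", g);
      out(i, g) = s[i];
    }
  }
  return out;
}

// Position-gated bump attractor (and, with npos = 1, b = 0 and an always-on
// gate, the traditional bump attractor).  State layout: r[i * nev + j] for
// position layer i, evidence index j (level j - (nev-1)/2).
// [[Rcpp::export]]
NumericMatrix sim_bump_cpp(NumericVector left_cues, NumericVector right_cues,
                           double a, double b, double cc, double T,
                           double q, double gamma, NumericMatrix W,
                           int npos, int nev, List gate,
                           NumericVector o_term, NumericVector init,
                           double precue_start, double maze_end,
                           double velocity, double grid_step, double max_step,
                           bool cosine_fast = false, double omega0 = 0.0,
                           double omega1 = 0.0) {
  Gate gt = gate_from_list(gate);
  std::vector<double> L = as<std::vector<double> >(left_cues);
  std::vector<double> R = as<std::vector<double> >(right_cues);
  const int N = npos * nev;
  if (init.size() != N || o_term.size() != N)
    stop("init and o_term must have length npos * nev");

  const int ngrid = (int) std::floor((maze_end - precue_start) / grid_step + 0.5) + 1;
  const double h_grid = grid_step / velocity;
  const int nsub = std::max(1, (int) std::ceil(h_grid / max_step - 1e-12));
  const double h = h_grid / nsub;

  std::vector<double> s(init.begin(), init.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N), P(npos), wr(nev);
  std::vector<double> Wm(nev * nev);
  for (int j = 0; j < nev; ++j)
    for (int k = 0; k < nev; ++k) Wm[j * nev + k] = W(j, k);
  // the cosine profile W_jk = w0 (cos(th_j - th_k) + w1) factorizes, so the
  // recurrent term reduces to three population sums (exact, not approximate)
  std::vector<double> cth(nev), sth(nev);
  for (int j = 0; j < nev; ++j) {
    double th = 2.0 * M_PI * j / nev;
    cth[j] = std::cos(th);
    sth[j] = std::sin(th);
  }

  NumericMatrix out(N, ngrid);
  for (int i = 0; i < N; ++i) out(i, 0) = s[i];

  auto rhs = [&](const std::vector<double>& r, double p, std::vector<double>& dr) {
    gt.eval(p, P);
    double iL = cue_ind(L, p), iR = cue_ind(R, p);
    // layer activity bounds let silent, ungated layers be skipped:
    // there F(-T) == 0 to machine precision and the derivative vanishes.
    for (int i = 0; i < npos; ++i) {
      const double* ri = &r[i * nev];
      double mx = 0.0, mxprev = 0.0;
      for (int j = 0; j < nev; ++j) mx = std::max(mx, ri[j]);
      if (i > 0) {
        const double* rp = &r[(i - 1) * nev];
        for (int j = 0; j < nev; ++j) mxprev = std::max(mxprev, rp[j]);
      }
      double* di = &dr[i * nev];
      if (P[i] <= 0.0 && mx < 1e-12 && mxprev < 1e-12 && T >= 30.0) {
        for (int j = 0; j < nev; ++j) di[j] = 0.0;
        continue;
      }
      double sc = 0.0, ss = 0.0, sm = 0.0;
      if (cosine_fast) {
        for (int k = 0; k < nev; ++k) {
          sc += cth[k] * ri[k];
          ss += sth[k] * ri[k];
          sm += ri[k];
        }
      }
      for (int j = 0; j < nev; ++j) {
        double acc;
        if (cosine_fast) {
          acc = omega0 * (cth[j] * sc + sth[j] * ss + omega1 * sm);
        } else {
          acc = 0.0;
          const double* wrow = &Wm[j * nev];
          for (int k = 0; k < nev; ++k) acc += wrow[k] * ri[k];
        }
        if (i > 0) acc += b * r[(i - 1) * nev + j];
        double shift = 0.0;
        if (j + 1 < nev) shift += ri[j + 1] * iL; // left shifter from level j+1
        if (j - 1 >= 0) shift += ri[j - 1] * iR;  // right shifter from level j-1
        acc += cc * shift + P[i] - T + o_term[i * nev + j];
        double Fx = 0.5 * q * (1.0 + std::tanh(gamma * acc));
        di[j] = -a * ri[j] + Fx;
      }
    }
  };

  double t = 0.0;
  for (int g = 1; g < ngrid; ++g) {
    for (int sub = 0; sub < nsub; ++sub) {
      double p0 = precue_start + velocity * t;
      double pm = precue_start + velocity * (t + h / 2.0);
      double p1 = precue_start + velocity * (t + h);
      rhs(s, p0, k1);
      for (int i = 0; i < N; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
      rhs(tmp, pm, k2);
      for (int i = 0; i < N; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
      rhs(tmp, pm, k3);
      for (int i = 0; i < N; ++i) tmp[i] = s[i] + h * k3[i];
      rhs(tmp, p1, k4);
      for (int i = 0; i < N; ++i) {
        s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (s[i] < 0.0) s[i] = 0.0;
      }
      t += h;
    }
    for (int i = 0; i < N; ++i) {
      if (!R_finite(s[i])) stop("non-finite state in bump simulation at grid index %d", g);
      out(i, g) = s[i];
    }
  }
  return out;
}
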