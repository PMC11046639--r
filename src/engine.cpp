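// Vectorized simulation engine. Mirrors the reference R stepper
// (.engine_step in R/world.R) operation for operation, including the order
// in which random numbers are drawn from R's RNG, so that the two paths
// produce the same trajectories up to floating-point associativity.

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

namespace {

struct Stim {
  bool active = false;
  double amplitude = 0, phase_duration = 0, t_on = 0;
  int repetitions = 0;
  std::vector<int> neg, pos, agents; // 0-based sector / agent indices
};

// offsets added to y' at absolute time t; returns false outside the window
bool stim_offsets(const Stim& s, double t, int L, std::vector<double>& off) {
  if (!s.active || s.amplitude == 0) return false;
  double rel = t - s.t_on;
  double total = 2.0 * s.repetitions * s.phase_duration;
  if (rel < 0 || rel >= total) return false;
  std::fill(off.begin(), off.end(), 0.0);
  int phase = (int)std::floor(rel / s.phase_duration);
  if (phase % 2 == 0)
    for (int l : s.neg) off[l] = -s.amplitude;
  else
    for (int l : s.pos) off[l] = s.amplitude;
  return true;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericMatrix head0,
                  NumericMatrix mu0_, NumericMatrix mu1_, NumericMatrix mu2_,
                  NumericMatrix mut_, NumericVector lambda0,
                  LogicalVector informed, bool has_target,
                  NumericVector target, List par, double dt, int n_steps,
                  double t0, Nullable<List> stimulus, bool record) {
  const int n = pos0.nrow();
  const int L = as<int>(par["L"]);
  const NumericVector breaks = par["breaks"];
  const double radius = as<double>(par["radius"]);
  const double alpha = as<double>(par["alpha"]);
  const double eta = as<double>(par["eta"]);
  const double alpha_t = as<double>(par["alpha_t"]);
  const NumericVector Gz = par["Gamma_z"];
  const double Gzt = as<double>(par["Gamma_z_target"]);
  const double s11 = as<double>(par["s11"]), s13 = as<double>(par["s13"]);
  const double s22 = as<double>(par["s22"]), s33 = as<double>(par["s33"]);
  const double km = as<double>(par["kappa_mu"]);
  const double ka = as<double>(par["kappa_a"]);
  const double kt = as<double>(par["kappa_theta"]);
  const double sdz = as<double>(par["sd_z"]);
  const double sdzp = as<double>(par["sd_zp"]);
  const double lmin = as<double>(par["lambda_min"]);
  const double lmax = as<double>(par["lambda_max"]);
  const bool plast = as<bool>(par["plasticity"]);

  Stim st;
  if (stimulus.isNotNull()) {
    List sl(stimulus);
    st.active = true;
    st.amplitude = as<double>(sl["amplitude"]);
    st.phase_duration = as<double>(sl["phase_duration"]);
    st.repetitions = as<int>(sl["repetitions"]);
    st.t_on = as<double>(sl["t_on"]);
    IntegerVector ns = sl["neg_sectors"], ps = sl["pos_sectors"],
      ta = sl["target_agents"];
    for (int v : ns) st.neg.push_back(v - 1);
    for (int v : ps) st.pos.push_back(v - 1);
    for (int v : ta) st.agents.push_back(v - 1);
  }

  // working state (copies)
  std::vector<double> px(pos0.begin(), pos0.begin() + n),
    py(pos0.begin() + n, pos0.begin() + 2 * n);
  std::vector<double> vx(head0.begin(), head0.begin() + n),
    vy(head0.begin() + n, head0.begin() + 2 * n);
  std::vector<double> mu0(mu0_.begin(), mu0_.end()),
    mu1(mu1_.begin(), mu1_.end()), mu2(mu2_.begin(), mu2_.end());
  std::vector<double> mt0(n, 0), mt1(n, 0), mt2(n, 0);
  if (has_target && mut_.nrow() == n)
    for (int i = 0; i < n; ++i) {
      mt0[i] = mut_(i, 0); mt1[i] = mut_(i, 1); mt2[i] = mut_(i, 2);
    }
  std::vector<double> lam(lambda0.begin(), lambda0.end());

  // per-step scratch
  std::vector<double> x0(n * L), x1(n * L), Rx(n * L), Ry(n * L);
  std::vector<int> K(n * L);
  std::vector<double> y0(n * L), y1(n * L), off(L);
  std::vector<double> nvx(n), nvy(n);

  NumericVector pos_arr, head_arr, lam_mat;
  if (record) {
    pos_arr = NumericVector(Dimension(n_steps + 1, n, 2));
    head_arr = NumericVector(Dimension(n_steps + 1, n, 2));
    lam_mat = NumericVector(Dimension(n_steps + 1, n));
    for (int i = 0; i < n; ++i) {
      pos_arr[0 + (n_steps + 1) * i] = px[i];
      pos_arr[0 + (n_steps + 1) * (n + i)] = py[i];
      head_arr[0 + (n_steps + 1) * i] = vx[i];
      head_arr[0 + (n_steps + 1) * (n + i)] = vy[i];
      lam_mat[0 + (n_steps + 1) * i] = lam[i];
    }
  }

  RNGScope scope;
  double time = t0;
  const double lo = breaks[0], hi = breaks[L];

  for (int s = 0; s < n_steps; ++s) {
    // ---- sense: sector means of distance, radial rate, unit directions
    std::fill(x0.begin(), x0.end(), 0.0);
    std::fill(x1.begin(), x1.end(), 0.0);
    std::fill(Rx.begin(), Rx.end(), 0.0);
    std::fill(Ry.begin(), Ry.end(), 0.0);
    std::fill(K.begin(), K.end(), 0);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = px[j] - px[i], dy = py[j] - py[i];
        double d2 = dx * dx + dy * dy;
        if (d2 > radius * radius || d2 == 0) continue;
        double d = std::sqrt(d2);
        double dot = vx[i] * dx + vy[i] * dy;
        double crs = vx[i] * dy - vy[i] * dx;
        double bear = std::atan2(crs, dot) * (180.0 / M_PI);
        if (bear < lo || bear >= hi) continue;
        // same boundary comparisons as findInterval in the R reference
        int l = -1;
        for (int k = 0; k < L; ++k)
          if (bear >= breaks[k] && bear < breaks[k + 1]) { l = k; break; }
        if (l < 0) continue;
        double rr = (dx * (vx[j] - vx[i]) + dy * (vy[j] - vy[i])) / d;
        int idx = i + n * l;
        x0[idx] += d;
        x1[idx] += rr;
        Rx[idx] += dx / d;
        Ry[idx] += dy / d;
        K[idx] += 1;
      }
    }
    for (int idx = 0; idx < n * L; ++idx) {
      if (K[idx] > 0) {
        x0[idx] /= K[idx]; x1[idx] /= K[idx];
        Rx[idx] /= K[idx]; Ry[idx] /= K[idx];
      }
    }

    // ---- observe (same draw order as the R reference: y0 then y1,
    // column-major over agents within sector)
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < n; ++i)
        y0[i + n * l] = x0[i + n * l] + norm_rand() * sdz;
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < n; ++i)
        y1[i + n * l] = x1[i + n * l] + norm_rand() * sdzp;
    bool on = stim_offsets(st, time, L, off);
    if (on)
      for (int a : st.agents)
        for (int l = 0; l < L; ++l) y1[a + n * l] += off[l];

    // ---- belief + action + plasticity updates (parallel, pre-step state)
    for (int i = 0; i < n; ++i) { nvx[i] = 0; nvy[i] = 0; }
    std::vector<double> dFdl(plast ? n : 0, 0.0);
    for (int i = 0; i < n; ++i) {
      double lam2 = lam[i] * lam[i];
      double dvxi = 0, dvyi = 0, dli = 0;
      for (int l = 0; l < L; ++l) {
        int idx = i + n * l;
        bool obs = K[idx] > 0;
        double e0 = obs ? (y0[idx] - mu0[idx]) : 0.0;
        double e1 = obs ? (y1[idx] - mu1[idx]) : 0.0;
        double xi1 = 2.0 * Gz[l] * lam2 * e1;
        double ew0 = mu1[idx] + alpha * (mu0[idx] - eta);
        double ew1 = mu2[idx] + alpha * mu1[idx];
        double ew2 = alpha * mu2[idx];
        double w0 = s11 * ew0 + s13 * ew2;
        double w1 = s22 * ew1;
        double w2 = s13 * ew0 + s33 * ew2;
        double g0 = -Gz[l] * e0 + alpha * w0;
        double g1 = -xi1 + w0 + alpha * w1;
        double g2 = w1 + alpha * w2;
        double m0 = mu0[idx] + dt * (mu1[idx] - km * g0);
        double m1 = mu1[idx] + dt * (mu2[idx] - km * g1);
        double m2 = mu2[idx] + dt * (-km * g2);
        mu0[idx] = m0; mu1[idx] = m1; mu2[idx] = m2;
        dvxi += xi1 * Rx[idx];
        dvyi += xi1 * Ry[idx];
        if (plast && obs)
          dli += 2.0 * Gz[l] * lam[i] * e1 * e1 - 1.0 / lam[i];
      }
      nvx[i] = dvxi; nvy[i] = dvyi;
      if (plast) dFdl[i] = dli;
    }

    // ---- target modality for informed agents (noise draw order matches
    // the R reference: all order-0 draws first, then all order-1 draws)
    if (has_target) {
      std::vector<double> yt0v(n), yt1v(n), txv(n), tyv(n), dv(n);
      for (int i = 0; i < n; ++i) {
        txv[i] = target[0] - px[i]; tyv[i] = target[1] - py[i];
        dv[i] = std::sqrt(txv[i] * txv[i] + tyv[i] * tyv[i]);
        if (dv[i] == 0) dv[i] = DBL_EPSILON;
      }
      for (int i = 0; i < n; ++i) yt0v[i] = dv[i] + norm_rand() * sdz;
      for (int i = 0; i < n; ++i)
        yt1v[i] = -(txv[i] * vx[i] + tyv[i] * vy[i]) / dv[i] +
          norm_rand() * sdzp;
      for (int i = 0; i < n; ++i) {
        double tx = txv[i], ty = tyv[i], d = dv[i];
        double yt0 = yt0v[i], yt1 = yt1v[i];
        if (!informed[i]) { mt0[i] = mt1[i] = mt2[i] = 0; continue; }
        double lam2 = lam[i] * lam[i];
        double e0 = yt0 - mt0[i], e1 = yt1 - mt1[i];
        double xit = 2.0 * Gzt * lam2 * e1;
        double ew0 = mt1[i] + alpha_t * mt0[i];
        double ew1 = mt2[i] + alpha_t * mt1[i];
        double ew2 = alpha_t * mt2[i];
        double w0 = s11 * ew0 + s13 * ew2;
        double w1 = s22 * ew1;
        double w2 = s13 * ew0 + s33 * ew2;
        double g0 = -Gzt * e0 + alpha_t * w0;
        double g1 = -xit + w0 + alpha_t * w1;
        double g2 = w1 + alpha_t * w2;
        double m0 = mt0[i] + dt * (mt1[i] - km * g0);
        double m1 = mt1[i] + dt * (mt2[i] - km * g1);
        double m2 = mt2[i] + dt * (-km * g2);
        mt0[i] = m0; mt1[i] = m1; mt2[i] = m2;
        nvx[i] += xit * (tx / d);
        nvy[i] += xit * (ty / d);
        if (plast)
          dFdl[i] += 2.0 * Gzt * lam[i] * e1 * e1 - 1.0 / lam[i];
      }
    }

    // ---- heading update (normalized), plasticity clamp, advance positions
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double hx = vx[i] + ka * dt * nvx[i];
      double hy = vy[i] + ka * dt * nvy[i];
      double nrm = std::sqrt(hx * hx + hy * hy);
      if (nrm == 0) { hx = vx[i]; hy = vy[i]; nrm = 1.0; }
      vx[i] = hx / nrm; vy[i] = hy / nrm;
      if (plast && kt > 0) {
        double nl = lam[i] - kt * dt * dFdl[i];
        lam[i] = std::min(std::max(nl, lmin), lmax);
      }
      px[i] += vx[i] * dt;
      py[i] += vy[i] * dt;
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) ||
          !std::isfinite(mu0[i]))
        bad = true;
    }
    time = t0 + dt * (s + 1);
    if (bad)
      stop("integration failure at t = %f: non-finite state", time);

    if (record) {
      for (int i = 0; i < n; ++i) {
        pos_arr[(s + 1) + (n_steps + 1) * i] = px[i];
        pos_arr[(s + 1) + (n_steps + 1) * (n + i)] = py[i];
        head_arr[(s + 1) + (n_steps + 1) * i] = vx[i];
        head_arr[(s + 1) + (n_steps + 1) * (n + i)] = vy[i];
        lam_mat[(s + 1) + (n_steps + 1) * i] = lam[i];
      }
    }
  }

  NumericMatrix posf(n, 2), headf(n, 2), mu0f(n, L), mu1f(n, L), mu2f(n, L);
  NumericMatrix mutf(has_target ? n : 0, 3);
  for (int i = 0; i < n; ++i) {
    posf(i, 0) = px[i]; posf(i, 1) = py[i];
    headf(i, 0) = vx[i]; headf(i, 1) = vy[i];
    for (int l = 0; l < L; ++l) {
      mu0f(i, l) = mu0[i + n * l];
      mu1f(i, l) = mu1[i + n * l];
      mu2f(i, l) = mu2[i + n * l];
    }
    if (has_target) {
      mutf(i, 0) = mt0[i]; mutf(i, 1) = mt1[i]; mutf(i, 2) = mt2[i];
    }
  }
  List out = List::create(
    _["pos"] = posf, _["head"] = headf, _["mu0"] = mu0f, _["mu1"] = mu1f,
    _["mu2"] = mu2f, _["mut"] = mutf, _["lambda"] = NumericVector(lam.begin(), lam.end()),
    _["time"] = time);
  if (record) {
    out["pos_arr"] = pos_arr;
    out["head_arr"] = head_arr;
    out["lam_mat"] = lam_mat;
  }
  return out;
}
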