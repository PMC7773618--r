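// Planar rigid-link head-neck chain on a prescribed moving base, with
// Hill-type line muscles and a delayed PD reflex controller.
//
// Conventions (shared with the R layer):
//   x forward, z up; in-plane link angle phi measured from +z, positive
//   rearward (extension).  Link direction u(phi) = (-sin phi, cos phi).
//   Local frames: e_x = (cos phi, sin phi), e_z = u(phi).
//   Joint i (1..n) connects link i-1 to link i; link 0 is T1 (prescribed).
//   Relative joint angle q_i = phi_i - phi_{i-1}, phi_0 = T1 y-rotation.
// All dynamics in SI (m, kg, s); controller time constants in ms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Plant {
  int n;
  arma::vec L, m, Icom, k, c, q0;
  arma::mat rloc;  // 2 x n local COM offsets
  double g;
};

struct Mech {
  double fl_width, vmax_lopt, af, fv_ecc_max, fv_ecc_b, fpe_scale, fpe_shape;
};

struct Muscle {
  arma::ivec seg;   // segment index per path point (0 = T1)
  arma::mat pts;    // 2 x npts local coordinates
  double fmax;      // PCSA * sigma_max
  double lopt, lslack, pref;
};

struct Base {
  double px, pz, ry, vx, vz, w, ax, az;
};

inline arma::vec2 udir(double phi) { return {-std::sin(phi), std::cos(phi)}; }
inline arma::vec2 uder(double phi) { return {-std::cos(phi), -std::sin(phi)}; }
inline arma::vec2 rot(double phi, const arma::vec2& w) {
  return {w[0] * std::cos(phi) - w[1] * std::sin(phi),
          w[0] * std::sin(phi) + w[1] * std::cos(phi)};
}
inline arma::vec2 rotd(double phi, const arma::vec2& w) {
  return {-w[0] * std::sin(phi) - w[1] * std::cos(phi),
          w[0] * std::cos(phi) - w[1] * std::sin(phi)};
}

Plant plant_from_list(const List& pl) {
  Plant p;
  p.L = as<arma::vec>(pl["link_lengths"]);
  p.m = as<arma::vec>(pl["segment_masses"]);
  p.Icom = as<arma::vec>(pl["segment_inertias_com"]);
  p.k = as<arma::vec>(pl["joint_stiffness"]);
  p.c = as<arma::vec>(pl["joint_damping"]);
  p.q0 = as<arma::vec>(pl["rest_angles"]);
  p.rloc = as<arma::mat>(pl["com_local"]);
  p.g = as<double>(pl["gravity"]);
  p.n = p.L.n_elem;
  return p;
}

Mech mech_from_list(const List& ml) {
  Mech m;
  m.fl_width = as<double>(ml["fl_width"]);
  m.vmax_lopt = as<double>(ml["vmax_lopt_per_s"]);
  m.af = as<double>(ml["fv_af"]);
  m.fv_ecc_max = as<double>(ml["fv_ecc_max"]);
  m.fv_ecc_b = as<double>(ml["fv_ecc_b"]);
  m.fpe_scale = as<double>(ml["fpe_scale"]);
  m.fpe_shape = as<double>(ml["fpe_shape"]);
  return m;
}

std::vector<Muscle> muscles_from_list(const List& ms) {
  std::vector<Muscle> out;
  for (int i = 0; i < ms.size(); ++i) {
    List mi = ms[i];
    Muscle m;
    m.seg = as<arma::ivec>(mi["seg"]);
    m.pts = as<arma::mat>(mi["pts"]);
    m.fmax = as<double>(mi["fmax"]);
    m.lopt = as<double>(mi["lopt"]);
    m.lslack = as<double>(mi["lslack"]);
    m.pref = as<double>(mi["pref"]);
    out.push_back(m);
  }
  return out;
}

double fl_fun(double l, double lopt, const Mech& me) {
  double x = (l / lopt - 1.0) / me.fl_width;
  return std::exp(-x * x);
}

double fv_fun(double v, double lopt, const Mech& me) {
  double vmax = me.vmax_lopt * lopt;
  if (v <= -vmax) return 0.0;
  if (v <= 0.0) return (vmax + v) / (vmax - v / me.af);
  double b = me.fv_ecc_b * vmax;
  return me.fv_ecc_max - (me.fv_ecc_max - 1.0) * b / (v + b);
}

double fpe_fun(double l, double lslack, double lopt, const Mech& me) {
  double eps = (l - lslack) / lopt;
  if (eps <= 0.0) return 0.0;
  return me.fpe_scale * (std::exp(me.fpe_shape * eps) - 1.0);
}

// forward kinematics: joint positions (2 x n), Ppos.col(j) = distal end of
// link j+1's proximal joint... Ppos.col(0) = base; Ppos.col(j) = joint after
// link j (j = 1..n-1).  Only n columns needed (head tip unused).
arma::mat joint_positions(const Plant& p, const arma::vec& phi, const arma::vec2& base) {
  arma::mat P(2, p.n);
  P.col(0) = base;
  for (int j = 1; j < p.n; ++j) P.col(j) = P.col(j - 1) + p.L[j - 1] * udir(phi[j - 1]);
  return P;
}

// gradient of one muscle's path length wrt (phi_0, phi_1..phi_n), plus length
void muscle_geometry(const Plant& p, const Muscle& mu, const arma::vec& phi,
                     double bry, const arma::mat& P, const arma::vec2& base,
                     double& len, arma::vec& grad) {
  int n = p.n;
  int npts = mu.pts.n_cols;
  grad.zeros(n + 1);
  len = 0.0;
  // world coordinates and per-point segment index
  arma::mat W(2, npts);
  for (int a = 0; a < npts; ++a) {
    int s = mu.seg[a];
    arma::vec2 w = mu.pts.col(a);
    if (s == 0) {
      W.col(a) = base + rot(bry, w);
    } else {
      W.col(a) = P.col(s - 1) + rot(phi[s - 1], w);
    }
  }
  for (int a = 0; a + 1 < npts; ++a) {
    arma::vec2 d = W.col(a + 1) - W.col(a);
    double dl = arma::norm(d);
    if (dl < 1e-12) continue;
    arma::vec2 e = d / dl;
    len += dl;
    int sA = mu.seg[a], sB = mu.seg[a + 1];
    // d(point)/d(phi_k), k in 1..s-1 gives L_k u'(phi_k); k = s gives Rot' w.
    // Difference of the two points: contributions cancel below min(sA, sB).
    int lo = std::min(sA, sB), hi = std::max(sA, sB);
    for (int kk = lo; kk <= hi; ++kk) {
      arma::vec2 dB(arma::fill::zeros), dA(arma::fill::zeros);
      if (kk >= 1 && kk < sB) dB = p.L[kk - 1] * uder(phi[kk - 1]);
      else if (kk == sB && kk >= 1) dB = rotd(phi[kk - 1], mu.pts.col(a + 1));
      else if (kk == 0 && sB == 0) dB = rotd(bry, mu.pts.col(a + 1));
      if (kk >= 1 && kk < sA) dA = p.L[kk - 1] * uder(phi[kk - 1]);
      else if (kk == sA && kk >= 1) dA = rotd(phi[kk - 1], mu.pts.col(a));
      else if (kk == 0 && sA == 0) dA = rotd(bry, mu.pts.col(a));
      grad[kk] += arma::dot(e, dB - dA);
    }
  }
}

// accelerations of the chain; also optionally reports muscle length/vel/force
arma::vec chain_qdd(const Plant& p, const std::vector<Muscle>& mus, const Mech& me,
                    const arma::vec& phi, const arma::vec& phid, const Base& b,
                    const arma::vec& act,
                    arma::vec* mlen = nullptr, arma::vec* mvel = nullptr,
                    arma::vec* mfor = nullptr) {
  int n = p.n;
  arma::vec2 base = {b.px, b.pz};
  arma::mat P = joint_positions(p, phi, base);
  // Jacobian building blocks
  arma::mat A(2, n), B(2, n);          // A.col(k-1) = L_k u'(phi_k); B.col(i-1) = Rot'(phi_i) r_i
  for (int i = 0; i < n; ++i) {
    A.col(i) = p.L[i] * uder(phi[i]);
    B.col(i) = rotd(phi[i], p.rloc.col(i));
  }
  // mass matrix
  arma::mat M(n, n, arma::fill::zeros);
  arma::vec msuf(n + 1, arma::fill::zeros);  // msuf[i] = sum_{j >= i} m_j  (0-based)
  for (int i = n - 1; i >= 0; --i) msuf[i] = msuf[i + 1] + p.m[i];
  for (int pp = 0; pp < n; ++pp) {
    M(pp, pp) = p.m[pp] * arma::dot(B.col(pp), B.col(pp)) +
                msuf[pp + 1] * arma::dot(A.col(pp), A.col(pp)) + p.Icom[pp];
    for (int qq = pp + 1; qq < n; ++qq) {
      double v = arma::dot(A.col(pp), p.m[qq] * B.col(qq) + msuf[qq + 1] * A.col(qq));
      M(pp, qq) = v;
      M(qq, pp) = v;
    }
  }
  // rhs: sum_i m_i J_i^T G_i with G_i = (0,-g) - a_b - Jdot*phid (per link)
  arma::vec2 ab = {b.ax, b.az};
  arma::vec2 s(arma::fill::zeros);  // prefix sum_{k<i} -L_k u(phi_k) phid_k^2
  arma::mat G(2, n);
  for (int i = 0; i < n; ++i) {
    arma::vec2 jdot = s - rot(phi[i], p.rloc.col(i)) * (phid[i] * phid[i]);
    G.col(i) = arma::vec2({0.0, -p.g}) - ab - jdot;
    s += -p.L[i] * udir(phi[i]) * (phid[i] * phid[i]);
  }
  arma::mat mG(2, n + 1);  // suffix sums of m_i G_i
  mG.col(n).zeros();
  for (int i = n - 1; i >= 0; --i) mG.col(i) = mG.col(i + 1) + p.m[i] * G.col(i);
  arma::vec rhs(n, arma::fill::zeros);
  for (int kk = 0; kk < n; ++kk)
    rhs[kk] = arma::dot(B.col(kk), p.m[kk] * G.col(kk)) + arma::dot(A.col(kk), mG.col(kk + 1));
  // joint springs / dampers (rest at configured alignment)
  for (int i = 0; i < n; ++i) {
    double qi = phi[i] - (i == 0 ? b.ry : phi[i - 1]);
    double qdi = phid[i] - (i == 0 ? b.w : phid[i - 1]);
    double tau = -p.k[i] * (qi - p.q0[i]) - p.c[i] * qdi;
    rhs[i] += tau;
    if (i >= 1) rhs[i - 1] -= tau;
  }
  // muscles
  int nm = mus.size();
  if (mlen) mlen->set_size(nm);
  if (mvel) mvel->set_size(nm);
  if (mfor) mfor->set_size(nm);
  for (int mi = 0; mi < nm; ++mi) {
    double len;
    arma::vec grad;
    muscle_geometry(p, mus[mi], phi, b.ry, P, base, len, grad);
    double vel = grad[0] * b.w;
    for (int kk = 0; kk < n; ++kk) vel += grad[kk + 1] * phid[kk];
    double na = nm == 0 ? 0.0 : act[mi];
    double F = mus[mi].fmax * (na * fv_fun(vel, mus[mi].lopt, me) * fl_fun(len, mus[mi].lopt, me) +
                               fpe_fun(len, mus[mi].lslack, mus[mi].lopt, me));
    if (F < 0.0) F = 0.0;
    for (int kk = 0; kk < n; ++kk) rhs[kk] -= F * grad[kk + 1];
    if (mlen) (*mlen)[mi] = len;
    if (mvel) (*mvel)[mi] = vel;
    if (mfor) (*mfor)[mi] = F;
  }
  return arma::solve(M, rhs, arma::solve_opts::likely_sympd);
}

inline double wrap_pi(double a) {
  double x = (a + M_PI) / (2.0 * M_PI);
  double r = (x - std::floor(x)) * 2.0 * M_PI;  // in [0, 2*pi)
  if (r <= 0) r += 2.0 * M_PI;
  return r - M_PI;
}

Base base_at(const arma::mat& BH, int col) {
  Base b;
  b.px = BH(0, col); b.pz = BH(1, col); b.ry = BH(2, col);
  b.vx = BH(3, col); b.vz = BH(4, col); b.w = BH(5, col);
  b.ax = BH(6, col); b.az = BH(7, col);
  return b;
}

}  // namespace

// Single dynamics evaluation, exposed for the R-level plant_dynamics(),
// static settling, and oracle tests.
// [[Rcpp::export(name = ".chain_accel_cpp")]]
List chain_accel_cpp(List plant, List muscles, List mech,
                     arma::vec phi, arma::vec phid, arma::vec base_state,
                     arma::vec activations) {
  Plant p = plant_from_list(plant);
  Mech me = mech_from_list(mech);
  std::vector<Muscle> mus = muscles_from_list(muscles);
  Base b;
  b.px = base_state[0]; b.pz = base_state[1]; b.ry = base_state[2];
  b.vx = base_state[3]; b.vz = base_state[4]; b.w = base_state[5];
  b.ax = base_state[6]; b.az = base_state[7];
  arma::vec mlen, mvel, mfor;
  arma::vec qdd = chain_qdd(p, mus, me, phi, phid, b, activations, &mlen, &mvel, &mfor);
  return List::create(_["qdd"] = qdd, _["muscle_length"] = mlen,
                      _["muscle_velocity"] = mvel, _["muscle_force"] = mfor);
}

// Closed-loop fixed-step RK4 simulation over the event window.
//
// base_half: 8 x (2*n_steps + 1) matrix of base px,pz,ry,vx,vz,w,ax,az sampled
// on the half-step grid.  Controller (if enabled) runs once per full step with
// zero-order-hold muscle drives during the RK4 substeps.
// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List plant, List muscles, List mech, List controller,
                  arma::mat base_half, double dt_ms, int n_steps, int out_stride,
                  arma::vec phi0, arma::vec phid0) {
  Plant p = plant_from_list(plant);
  Mech me = mech_from_list(mech);
  std::vector<Muscle> mus = muscles_from_list(muscles);
  int n = p.n, nm = mus.size();
  double dt = dt_ms / 1000.0;

  bool enabled = as<bool>(controller["enabled"]);
  double kp = 0, kd = 0, tnd = 0, tna_a = 1, tna_d = 1, tne = 1;
  double cocon = as<double>(controller["cocontraction"]);
  double ref = 0;
  bool rate_before_delay = false;
  double rate_lp_ms = 0.0;
  double dir_pos = 0.0, dir_neg = M_PI;
  if (enabled) {
    kp = as<double>(controller["kp"]);
    kd = as<double>(controller["kd"]);
    tnd = as<double>(controller["tnd"]);
    tna_a = as<double>(controller["tna_a"]);
    tna_d = as<double>(controller["tna_d"]);
    tne = as<double>(controller["tne"]);
    ref = as<double>(controller["reference_angle"]);
    rate_before_delay = as<bool>(controller["rate_before_delay"]);
    rate_lp_ms = as<double>(controller["rate_lp_ms"]);
  }

  int n_out = n_steps / out_stride + 1;
  arma::mat out_head(n_out, 3);       // head cg x, z (lab), head abs angle
  arma::mat out_cerv(n_out, n - 1);   // absolute link angles C7..C1 (links 1..n-1)
  arma::mat out_act(n_out, std::max(nm, 1));
  arma::vec out_t(n_out);

  arma::vec phi = phi0, phid = phid0;
  arma::vec ne(nm), na(nm), drive(nm);
  ne.fill(cocon); na.fill(cocon); drive.fill(cocon);

  arma::vec ebuf(n_steps + 1, arma::fill::zeros);   // error (or error-rate) history
  arma::vec e2buf(n_steps + 1, arma::fill::zeros);  // raw error history for rate_before_delay
  double e_del_prev = 0.0, edot_f = 0.0;
  bool have_prev = false;
  int fail_step = -1;

  auto record = [&](int step) {
    int row = step / out_stride;
    Base b = base_at(base_half, 2 * step);
    arma::vec2 base = {b.px, b.pz};
    arma::mat P = joint_positions(p, phi, base);
    arma::vec2 cg = P.col(n - 1) + rot(phi[n - 1], p.rloc.col(n - 1));
    out_t[row] = step * dt_ms;
    out_head(row, 0) = cg[0];
    out_head(row, 1) = cg[1];
    out_head(row, 2) = phi[n - 1];
    for (int j = 0; j < n - 1; ++j) out_cerv(row, j) = phi[j];
    for (int mi = 0; mi < nm; ++mi) out_act(row, mi) = drive[mi];
  };

  for (int step = 0; step <= n_steps; ++step) {
    // sanity
    bool bad = !phi.is_finite() || !phid.is_finite();
    if (!bad) {
      Base b0 = base_at(base_half, 2 * step);
      for (int i = 0; i < n && !bad; ++i) {
        double qi = phi[i] - (i == 0 ? b0.ry : phi[i - 1]);
        if (std::abs(qi) > M_PI) bad = true;
      }
    }
    if (bad) { fail_step = step; break; }

    // controller update at time t = step*dt (uses current state)
    if (enabled) {
      Base b0 = base_at(base_half, 2 * step);
      arma::vec2 base = {b0.px, b0.pz};
      arma::mat P = joint_positions(p, phi, base);
      arma::vec2 cg = P.col(n - 1) + rot(phi[n - 1], p.rloc.col(n - 1));
      arma::vec2 d = cg - base;
      double ang = std::atan2(-d[0], d[1]);
      double err = wrap_pi(ang - ref);
      double t_now = step * dt_ms;
      double e_del, edot;
      ebuf[step] = err;
      if (step >= 1) e2buf[step] = (ebuf[step] - ebuf[step - 1]) / dt_ms;
      // linear interpolation at t - tnd; zero before warm-up
      auto delayed = [&](const arma::vec& buf) {
        double tq = t_now - tnd;
        if (tq < 0) return 0.0;
        double idx = tq / dt_ms;
        int j = (int)std::floor(idx);
        double fr = idx - j;
        if (j >= step) return buf[step];
        return buf[j] + fr * (buf[j + 1] - buf[j]);
      };
      if (!rate_before_delay) {
        e_del = delayed(ebuf);
        edot = have_prev ? (e_del - e_del_prev) / dt_ms : 0.0;
        e_del_prev = e_del; have_prev = true;
      } else {
        e_del = delayed(ebuf);
        edot = delayed(e2buf);
      }
      if (rate_lp_ms > 0) {
        double alpha = dt_ms / (rate_lp_ms + dt_ms);
        edot_f += alpha * (edot - edot_f);
        edot = edot_f;
      }
      double u = (kp * e_del + kd * edot) / 100.0;
      double dir = (u >= 0) ? dir_pos : dir_neg;
      double mag = std::min(std::abs(u), 1.0);
      for (int mi = 0; mi < nm; ++mi) {
        double tunecos = std::cos(mus[mi].pref - dir);
        double exc = mag * std::max(0.0, tunecos);
        // exact cascade update over one controller step
        double Ene = std::exp(-dt_ms / tne);
        double Ta = (ne[mi] >= na[mi]) ? tna_a : tna_d;
        double Ea = std::exp(-dt_ms / Ta);
        double ne0 = ne[mi], na0 = na[mi];
        ne[mi] = exc + (ne0 - exc) * Ene;
        if (std::abs(tne - Ta) > 1e-9) {
          na[mi] = exc + (na0 - exc) * Ea +
                   (ne0 - exc) * (tne / (tne - Ta)) * (Ene - Ea);
        } else {
          na[mi] = exc + (na0 - exc) * Ea + (ne0 - exc) * (dt_ms / Ta) * Ea;
        }
        drive[mi] = std::min(std::max(na[mi], cocon), 1.0);
      }
    }

    if (step % out_stride == 0) record(step);
    if (step == n_steps) break;

    // RK4 with activations held
    int c0 = 2 * step, c1 = 2 * step + 1, c2 = 2 * step + 2;
    Base b0 = base_at(base_half, c0), bh = base_at(base_half, c1), b1 = base_at(base_half, c2);
    arma::vec k1 = chain_qdd(p, mus, me, phi, phid, b0, drive);
    arma::vec p2 = phi + 0.5 * dt * phid, v2 = phid + 0.5 * dt * k1;
    arma::vec k2 = chain_qdd(p, mus, me, p2, v2, bh, drive);
    arma::vec p3 = phi + 0.5 * dt * v2, v3 = phid + 0.5 * dt * k2;
    arma::vec k3 = chain_qdd(p, mus, me, p3, v3, bh, drive);
    arma::vec p4 = phi + dt * v3, v4 = phid + dt * k3;
    arma::vec k4 = chain_qdd(p, mus, me, p4, v4, b1, drive);
    arma::vec phi_new = phi + dt / 6.0 * (phid + 2.0 * v2 + 2.0 * v3 + v4);
    arma::vec phid_new = phid + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    phi = phi_new;
    phid = phid_new;
  }

  return List::create(_["time_ms"] = out_t, _["head"] = out_head,
                      _["cervical"] = out_cerv, _["activation"] = out_act,
                      _["fail_step"] = fail_step,
                      _["phi_final"] = phi, _["phid_final"] = phid);
}
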