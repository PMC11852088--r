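// Compiled rollout engine for the human-aware NMPC.
//
// The receding-horizon controller evaluates its effort objective by
// simulating the full closed-loop hierarchy (optimal feedback gains ->
// synergy NNLS expansion -> Hill muscles -> coupled arm+robot RK4) for Np
// steps per candidate torque profile, thousands of times per simulated
// second. This file mirrors the R reference tick (sim_tick with
// light = TRUE, noise-free) step for step; the test suite asserts the two
// paths agree to near machine precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct TwoLink {
  double l1, l2, m1, m2, d1, d2, I1, I2;
  vec2 base;
};

TwoLink as_twolink(const Rcpp::List& p) {
  TwoLink t;
  t.l1 = p["l1"]; t.l2 = p["l2"];
  t.m1 = p["m1"]; t.m2 = p["m2"];
  t.d1 = p["d1"]; t.d2 = p["d2"];
  t.I1 = p["I1"]; t.I2 = p["I2"];
  Rcpp::NumericVector b = p["base"];
  t.base = {b[0], b[1]};
  return t;
}

mat22 mass_matrix(const TwoLink& p, const vec2& q) {
  double c2 = std::cos(q[1]);
  double m11 = p.I1 + p.I2 + p.m1 * p.d1 * p.d1 +
               p.m2 * (p.l1 * p.l1 + p.d2 * p.d2 + 2.0 * p.l1 * p.d2 * c2);
  double m12 = p.I2 + p.m2 * (p.d2 * p.d2 + p.l1 * p.d2 * c2);
  double m22 = p.I2 + p.m2 * p.d2 * p.d2;
  mat22 M = {{m11, m12}, {m12, m22}};
  return M;
}

vec2 velocity_torques(const TwoLink& p, const vec2& q, const vec2& qd) {
  double h = p.m2 * p.l1 * p.d2 * std::sin(q[1]);
  return {-h * qd[1] * (2.0 * qd[0] + qd[1]), h * qd[0] * qd[0]};
}

mat22 jacobian(const TwoLink& p, const vec2& q) {
  double s1 = std::sin(q[0]), c1 = std::cos(q[0]);
  double s12 = std::sin(q[0] + q[1]), c12 = std::cos(q[0] + q[1]);
  mat22 J = {{-p.l1 * s1 - p.l2 * s12, -p.l2 * s12},
             { p.l1 * c1 + p.l2 * c12,  p.l2 * c12}};
  return J;
}

vec2 jdot_qd(const TwoLink& p, const vec2& q, const vec2& qd) {
  double s1 = std::sin(q[0]), c1 = std::cos(q[0]);
  double s12 = std::sin(q[0] + q[1]), c12 = std::cos(q[0] + q[1]);
  double w12 = qd[0] + qd[1];
  return {-p.l1 * c1 * qd[0] * qd[0] - p.l2 * c12 * w12 * w12,
          -p.l1 * s1 * qd[0] * qd[0] - p.l2 * s12 * w12 * w12};
}

vec2 endpoint(const TwoLink& p, const vec2& q) {
  double c1 = std::cos(q[0]), s1 = std::sin(q[0]);
  double c12 = std::cos(q[0] + q[1]), s12 = std::sin(q[0] + q[1]);
  return {p.base[0] + p.l1 * c1 + p.l2 * c12,
          p.base[1] + p.l1 * s1 + p.l2 * s12};
}

struct ArmModel {
  TwoLink skel;
  mat org, ins;          // 2 x 6 attachment coordinates
  ivec forg, fins;       // frame codes 0/1/2
  vec fmax, l0;          // per muscle
  double fl_width, v_max, fv_max, tau_act, tau_deact, hand_mass;
};

struct Geometry {
  vec lengths;       // 6
  vec velocities;    // 6 (lengthening positive)
  mat Rm;            // 6 x 2 moment arms
};

Geometry muscle_geometry(const ArmModel& a, const vec2& q, const vec2& qd) {
  const int n = a.org.n_cols;
  Geometry g;
  g.lengths.set_size(n);
  g.velocities.set_size(n);
  g.Rm.set_size(n, 2);
  double c1 = std::cos(q[0]), s1 = std::sin(q[0]);
  double c12 = std::cos(q[0] + q[1]), s12 = std::sin(q[0] + q[1]);
  double bx = a.skel.base[0], by = a.skel.base[1];
  double ex = bx + a.skel.l1 * c1, ey = by + a.skel.l1 * s1;
  auto world = [&](const mat& P, const ivec& fr, int i, double& px, double& py) {
    if (fr[i] == 0) { px = bx + P(0, i); py = by + P(1, i); }
    else if (fr[i] == 1) { px = bx + c1 * P(0, i) - s1 * P(1, i);
                           py = by + s1 * P(0, i) + c1 * P(1, i); }
    else { px = ex + c12 * P(0, i) - s12 * P(1, i);
           py = ey + s12 * P(0, i) + c12 * P(1, i); }
  };
  for (int i = 0; i < n; ++i) {
    double ox, oy, ix, iy;
    world(a.org, a.forg, i, ox, oy);
    world(a.ins, a.fins, i, ix, iy);
    double dx = ix - ox, dy = iy - oy;
    double len = std::sqrt(dx * dx + dy * dy);
    double ux = dx / len, uy = dy / len;
    // dP/dq1 = rot90(P - base) on moving segments, dP/dq2 = rot90(P - elbow)
    auto d1 = [&](double px, double py, int fr, double& vx, double& vy) {
      if (fr >= 1) { vx = -(py - by); vy = px - bx; } else { vx = vy = 0.0; }
    };
    auto d2 = [&](double px, double py, int fr, double& vx, double& vy) {
      if (fr == 2) { vx = -(py - ey); vy = px - ex; } else { vx = vy = 0.0; }
    };
    double i1x, i1y, o1x, o1y, i2x, i2y, o2x, o2y;
    d1(ix, iy, a.fins[i], i1x, i1y); d1(ox, oy, a.forg[i], o1x, o1y);
    d2(ix, iy, a.fins[i], i2x, i2y); d2(ox, oy, a.forg[i], o2x, o2y);
    g.lengths[i] = len;
    g.Rm(i, 0) = -(ux * (i1x - o1x) + uy * (i1y - o1y));
    g.Rm(i, 1) = -(ux * (i2x - o2x) + uy * (i2y - o2y));
  }
  g.velocities = -(g.Rm * vec(qd));
  return g;
}

vec force_length(const ArmModel& a, const vec& lnorm) {
  vec d = (lnorm - 1.0) / a.fl_width;
  return exp(-square(d));
}

double force_velocity1(double vn, double fv_max, double k = 0.25) {
  double slope0 = 1.0 + 1.0 / k;
  if (vn <= 0.0) {
    double v = (1.0 + vn) / (1.0 - vn / k);
    return v > 0.0 ? v : 0.0;
  }
  return fv_max - (fv_max - 1.0) * std::exp(-slope0 * vn / (fv_max - 1.0));
}

vec muscle_forces(const ArmModel& a, const vec& act, const Geometry& g) {
  vec fl = force_length(a, g.lengths / a.l0);
  vec f(act.n_elem);
  for (uword i = 0; i < act.n_elem; ++i) {
    double vn = g.velocities[i] / (a.v_max * a.l0[i]);
    double fi = act[i] * fl[i] * force_velocity1(vn, a.fv_max) * a.fmax[i];
    f[i] = fi > 0.0 ? fi : 0.0;
  }
  return f;
}

vec activation_rate(const ArmModel& a, const vec& act, const vec& e) {
  vec out(act.n_elem);
  for (uword i = 0; i < act.n_elem; ++i) {
    double ai = act[i], ei = e[i];
    out[i] = (ei > ai) ? (ei - ai) / (a.tau_act * (0.5 + 1.5 * ai))
                       : (ei - ai) * (0.5 + 1.5 * ai) / a.tau_deact;
  }
  return out;
}

mat22 arm_mass(const ArmModel& a, const vec2& q) {
  mat22 M = mass_matrix(a.skel, q);
  if (a.hand_mass > 0.0) {
    mat22 J = jacobian(a.skel, q);
    M += a.hand_mass * (J.t() * J);
  }
  return M;
}

vec2 arm_velocity_torques(const ArmModel& a, const vec2& q, const vec2& qd) {
  vec2 cv = velocity_torques(a.skel, q, qd);
  if (a.hand_mass > 0.0) {
    mat22 J = jacobian(a.skel, q);
    cv += a.hand_mass * (J.t() * jdot_qd(a.skel, q, qd));
  }
  return cv;
}

// Lawson-Hanson NNLS, same tolerance semantics as the R implementation.
vec nnls(const mat& C, const vec& d) {
  const uword n = C.n_cols;
  double nC = norm(C, 2);
  double tol = 10.0 * datum::eps * nC * (std::max(C.n_rows, C.n_cols) + 1);
  double tol_w = tol * std::max(1.0, norm(d)) * std::max(1.0, nC);
  vec x = zeros<vec>(n);
  std::vector<bool> P(n, false), blocked(n, false);
  vec w = C.t() * (d - C * x);
  int it = 0, itmax = std::max(100, (int)(30 * n));
  while (true) {
    int best = -1; double wbest = tol_w;
    for (uword i = 0; i < n; ++i)
      if (!P[i] && !blocked[i] && w[i] > wbest) { wbest = w[i]; best = i; }
    if (best < 0) break;
    P[best] = true;
    bool progressed = true;
    vec z;
    while (true) {
      uvec idx(n); uword m = 0;
      for (uword i = 0; i < n; ++i) if (P[i]) idx[m++] = i;
      idx.resize(m);
      vec zp = solve(C.cols(idx), d);
      z = zeros<vec>(n);
      for (uword j = 0; j < m; ++j) z[idx[j]] = zp[j];
      bool ok = true;
      for (uword j = 0; j < m; ++j) if (zp[j] <= tol) { ok = false; break; }
      if (ok) break;
      if (++it > itmax) Rcpp::stop("NNLS iteration count exceeded");
      double alpha = datum::inf;
      for (uword i = 0; i < n; ++i)
        if (P[i] && z[i] <= tol) alpha = std::min(alpha, x[i] / (x[i] - z[i]));
      if (!std::isfinite(alpha)) alpha = 0.0;
      if (alpha <= 0.0 && z[best] <= tol) progressed = false;
      x += alpha * (z - x);
      for (uword i = 0; i < n; ++i) P[i] = P[i] && (x[i] > tol);
      if (!progressed) break;
    }
    if (!progressed) { blocked[best] = true; continue; }
    x = z;
    std::fill(blocked.begin(), blocked.end(), false);
    w = C.t() * (d - C * x);
    if (++it > itmax) Rcpp::stop("NNLS iteration count exceeded");
  }
  return x;
}

struct SimState {
  vec2 q, qd, theta, thetad;
  vec a;                 // 6
  vec xhat, xhat_del;    // 6
  mat buf_y;             // nd x 6
  mat buf_u;             // nd x 2
  int k;                 // 1-based global step
};

struct World {
  ArmModel arm;
  TwoLink robot;
  bool coupled;
  double field_b;
  mat S;                 // 6 x nsyn
  mat A, B;              // internal plant
  vec2 target;
  int n_delay, nL;
  cube L;                // 2 x 6 x nL
  cube K;                // 6 x 6 x nL
  double fmax_abstract, dt, baumgarte;
};

// plant accelerations (and activation rates) for the packed state
void deriv(const World& w, const vec& z, const vec& e, const vec2& torques,
           vec& dz) {
  vec2 q = {z[0], z[1]}, qd = {z[2], z[3]};
  vec act(6);
  for (int i = 0; i < 6; ++i) {
    double ai = z[4 + i];
    act[i] = ai < 0.0 ? 0.0 : (ai > 1.0 ? 1.0 : ai);
  }
  Geometry g = muscle_geometry(w.arm, q, qd);
  vec mf = muscle_forces(w.arm, act, g);
  vec adot = activation_rate(w.arm, act, e);
  vec2 tau_h = g.Rm.t() * mf;
  mat22 Jh = jacobian(w.arm.skel, q);
  if (!w.coupled) {
    vec2 f_ext = {0.0, 0.0};
    if (w.field_b != 0.0) {
      vec2 v = Jh * qd;
      f_ext = {w.field_b * v[1], -w.field_b * v[0]};
    }
    vec2 rhs = tau_h + Jh.t() * f_ext - arm_velocity_torques(w.arm, q, qd);
    vec2 qdd = solve(arm_mass(w.arm, q), rhs);
    dz = {qd[0], qd[1], qdd[0], qdd[1],
          adot[0], adot[1], adot[2], adot[3], adot[4], adot[5]};
  } else {
    vec2 th = {z[10], z[11]}, thd = {z[12], z[13]};
    mat22 Jr = jacobian(w.robot, th);
    vec2 ph = endpoint(w.arm.skel, q), pr = endpoint(w.robot, th);
    vec2 vh = Jh * qd, vr = Jr * thd;
    vec2 f_ext = {0.0, 0.0};
    if (w.field_b != 0.0) f_ext = {w.field_b * vh[1], -w.field_b * vh[0]};
    vec2 bias = jdot_qd(w.arm.skel, q, qd) - jdot_qd(w.robot, th, thd) +
                2.0 * w.baumgarte * (vh - vr) +
                w.baumgarte * w.baumgarte * (ph - pr);
    mat66 KKT(fill::zeros);
    KKT.submat(0, 0, 1, 1) = arm_mass(w.arm, q);
    KKT.submat(0, 4, 1, 5) = -Jh.t();
    KKT.submat(2, 2, 3, 3) = mass_matrix(w.robot, th);
    KKT.submat(2, 4, 3, 5) = Jr.t();
    KKT.submat(4, 0, 5, 1) = Jh;
    KKT.submat(4, 2, 5, 3) = -Jr;
    vec6 rhs;
    vec2 r1 = tau_h + Jh.t() * f_ext - arm_velocity_torques(w.arm, q, qd);
    vec2 r2 = vec2(torques) - velocity_torques(w.robot, th, thd);
    rhs = {r1[0], r1[1], r2[0], r2[1], -bias[0], -bias[1]};
    vec6 sol = solve(KKT, rhs);
    dz = {qd[0], qd[1], sol[0], sol[1],
          adot[0], adot[1], adot[2], adot[3], adot[4], adot[5],
          thd[0], thd[1], sol[2], sol[3]};
  }
}

// one control tick (noise-free, light), mirroring the R sim_tick
double tick(const World& w, SimState& s, const vec2& torques) {
  int kL = std::min(s.k, w.nL) - 1;            // 0-based slice
  vec2 hand = endpoint(w.arm.skel, s.q);
  mat22 J0 = jacobian(w.arm.skel, s.q);
  vec2 hvel = J0 * s.qd;
  vec y = {hand[0] - w.target[0], hand[1] - w.target[1],
           hvel[0], hvel[1], s.xhat[4], s.xhat[5]};
  vec2 u = w.L.slice(kL) * s.xhat;
  // velocity-compensated desired hand force
  vec2 cv = arm_velocity_torques(w.arm, s.q, s.qd);
  vec2 f_task = u * w.fmax_abstract + solve(J0.t(), cv);
  // synergy basis through the isometric statics map
  Geometry g0 = muscle_geometry(w.arm, s.q, s.qd);
  vec fl = force_length(w.arm, g0.lengths / w.arm.l0);
  mat Phi = solve(J0.t(), (g0.Rm.each_col() % (fl % w.arm.fmax)).t());
  mat basis = Phi * w.S;
  vec co = nnls(basis, vec(f_task));
  vec e_raw = w.S * co;
  vec e = clamp(e_raw, 0.0, 1.0);
  // integrate plant one RK4 step
  int nz = w.coupled ? 14 : 10;
  vec z(nz);
  z[0] = s.q[0]; z[1] = s.q[1]; z[2] = s.qd[0]; z[3] = s.qd[1];
  for (int i = 0; i < 6; ++i) z[4 + i] = s.a[i];
  if (w.coupled) {
    z[10] = s.theta[0]; z[11] = s.theta[1];
    z[12] = s.thetad[0]; z[13] = s.thetad[1];
  }
  vec k1(nz), k2(nz), k3(nz), k4(nz);
  deriv(w, z, e, torques, k1);
  deriv(w, z + 0.5 * w.dt * k1, e, torques, k2);
  deriv(w, z + 0.5 * w.dt * k2, e, torques, k3);
  deriv(w, z + w.dt * k3, e, torques, k4);
  z += (w.dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  s.q = {z[0], z[1]}; s.qd = {z[2], z[3]};
  for (int i = 0; i < 6; ++i) {
    double ai = z[4 + i];
    s.a[i] = ai < 0.0 ? 0.0 : (ai > 1.0 ? 1.0 : ai);
  }
  if (w.coupled) {
    s.theta = {z[10], z[11]}; s.thetad = {z[12], z[13]};
  }
  // belief update: delayed-time-base Kalman filter + forward prediction
  int kkK = std::min(std::max(s.k - w.n_delay, 1), w.nL) - 1;
  vec y_old, u_old;
  if (w.n_delay > 0) {
    y_old = s.buf_y.row(0).t();
    u_old = s.buf_u.row(0).t();
    for (int r = 0; r < w.n_delay - 1; ++r) {
      s.buf_y.row(r) = s.buf_y.row(r + 1);
      s.buf_u.row(r) = s.buf_u.row(r + 1);
    }
    s.buf_y.row(w.n_delay - 1) = y.t();
    s.buf_u.row(w.n_delay - 1) = vec(u).t();
  } else {
    y_old = y; u_old = vec(u);
  }
  vec innov = y_old - s.xhat_del;
  s.xhat_del = w.A * s.xhat_del + w.B * u_old + w.K.slice(kkK) * innov;
  vec x = s.xhat_del;
  for (int j = 0; j < w.n_delay; ++j)
    x = w.A * x + w.B * s.buf_u.row(j).t();
  s.xhat = x;
  s.k += 1;
  return dot(e, e);
}

World build_world(const Rcpp::List& snap) {
  World w;
  Rcpp::List armL = snap["arm"];
  w.arm.skel = as_twolink(armL["skeleton"]);
  Rcpp::List gc = armL["geom_cache"];
  w.arm.org = Rcpp::as<mat>(gc["org"]);
  w.arm.ins = Rcpp::as<mat>(gc["ins"]);
  w.arm.forg = Rcpp::as<ivec>(gc["forg"]);
  w.arm.fins = Rcpp::as<ivec>(gc["fins"]);
  w.arm.fmax = Rcpp::as<vec>(gc["fmax"]);
  w.arm.l0 = Rcpp::as<vec>(armL["l0"]);
  w.arm.fl_width = armL["fl_width"];
  w.arm.v_max = armL["v_max"];
  w.arm.fv_max = armL["fv_max"];
  w.arm.tau_act = armL["tau_act"];
  w.arm.tau_deact = armL["tau_deact"];
  w.arm.hand_mass = armL["hand_mass"];
  w.coupled = !Rf_isNull(snap["robot"]);
  if (w.coupled) w.robot = as_twolink(snap["robot"]);
  w.field_b = snap["field_b"];
  w.S = Rcpp::as<mat>(snap["S"]);
  w.A = Rcpp::as<mat>(snap["A"]);
  w.B = Rcpp::as<mat>(snap["B"]);
  Rcpp::NumericVector tg = snap["target"];
  w.target = {tg[0], tg[1]};
  w.n_delay = snap["n_delay"];
  w.nL = snap["nL"];
  w.L = Rcpp::as<cube>(snap["L"]);
  w.K = Rcpp::as<cube>(snap["K"]);
  w.fmax_abstract = snap["fmax_abstract"];
  w.dt = snap["dt"];
  w.baumgarte = snap["baumgarte"];
  return w;
}

SimState build_state(const Rcpp::List& snap) {
  SimState s;
  Rcpp::NumericVector q = snap["q"], qd = snap["qd"];
  s.q = {q[0], q[1]}; s.qd = {qd[0], qd[1]};
  s.a = Rcpp::as<vec>(snap["a"]);
  bool coupled = !Rf_isNull(snap["robot"]);
  if (coupled) {
    Rcpp::NumericVector th = snap["theta"], thd = snap["thetad"];
    s.theta = {th[0], th[1]}; s.thetad = {thd[0], thd[1]};
  } else {
    s.theta = s.thetad = {0.0, 0.0};
  }
  s.xhat = Rcpp::as<vec>(snap["xhat"]);
  s.xhat_del = Rcpp::as<vec>(snap["xhat_del"]);
  s.buf_y = Rcpp::as<mat>(snap["buf_y"]);
  s.buf_u = Rcpp::as<mat>(snap["buf_u"]);
  s.k = snap["k"];
  return s;
}

}  // namespace

//' @title Compiled NMPC effort rollout (internal)
//' @description Simulates the coupled closed-loop model forward `Np` steps
//'   under a polynomial torque profile and returns the mean squared
//'   excitation. Interface used by [rollout_objective()]; the snapshot list
//'   is assembled in R.
//' @param snap snapshot list (see `nmpc_snapshot()`)
//' @param beta 2x3 torque polynomial coefficients
//' @param Np horizon length (steps)
//' @return mean squared excitation over the horizon
//' @keywords internal
// [[Rcpp::export(name = ".cpp_rollout_effort")]]
double cpp_rollout_effort(Rcpp::List snap, arma::mat beta, int Np) {
  World w = build_world(snap);
  SimState s = build_state(snap);
  double J = 0.0;
  for (int k = 0; k < Np; ++k) {
    vec3 kk = {1.0, (double)k, (double)k * k};
    vec2 torques = beta * kk;
    J += tick(w, s, torques);
  }
  return J / Np;
}
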