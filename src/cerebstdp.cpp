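// Compiled core: LIF population stepping, the per-trial closed-loop engines
// (set-point tracking and 3-link arm torque correction), and planar-arm
// recursive Newton-Euler dynamics.  All randomness is injected from R as
// pre-drawn uniform variates so that runs are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Plasticity kernels (dimensionless argument)
// ---------------------------------------------------------------------------

static inline double kern_pfpc(double x) {
  // e^(-x) * sin(x)^20, x >= 0
  double s = std::sin(x);
  return std::exp(-x) * std::pow(s, 20.0);
}

static inline double kern_mfdcn(double x, double beta) {
  // e^(-|x*beta|) * cos(x)^2, even in x
  double c = std::cos(x);
  return std::exp(-std::fabs(x * beta)) * c * c;
}

static inline double kern_sym(double u) {
  // e^(-|u|) * cos(u)^2 (symmetric iSTDP envelope)
  double c = std::cos(u);
  return std::exp(-std::fabs(u)) * c * c;
}

// [[Rcpp::export]]
double cpp_kern_pfpc(double x) { return kern_pfpc(x); }

// [[Rcpp::export]]
double cpp_kern_mfdcn(double x, double beta) { return kern_mfdcn(x, beta); }

// [[Rcpp::export]]
double cpp_kern_sym(double u) { return kern_sym(u); }

// ---------------------------------------------------------------------------
// LIF population stepping
//
// Parameter vector layout (all per population):
//   0 C_pF, 1 gL_nS, 2 EL_mV, 3 Vth_mV, 4 Vreset_mV, 5 tref_ms,
//   6 Ee_mV, 7 Ei_mV, 8 taue_ms, 9 taui_ms
// Units: mV, nS, pF, ms; nS*mV/pF = mV/ms so no conversion constants appear.
// Conductance increments are applied at the start of the step; within the
// step the membrane is advanced with forward-Euler substeps while the
// conductances decay exactly exponentially per substep.
// ---------------------------------------------------------------------------

struct LifP {
  double C, gL, EL, Vth, Vreset, tref, Ee, Ei, taue, taui;
  explicit LifP(const NumericVector& p) {
    C = p[0]; gL = p[1]; EL = p[2]; Vth = p[3]; Vreset = p[4];
    tref = p[5]; Ee = p[6]; Ei = p[7]; taue = p[8]; taui = p[9];
  }
};

// Advance one population by one control step of dt_ms using nsub substeps.
// exc/inh are conductance increments (nS) delivered at step onset.
// Returns spike counts per neuron for this step in `spk`.
static void lif_step(std::vector<double>& V, std::vector<double>& gE,
                     std::vector<double>& gI, std::vector<double>& refr,
                     const LifP& P, double t_ms, double dt_ms, int nsub,
                     const double* exc, const double* inh, int n, int* spk,
                     int step_index, const double* vth_off = NULL) {
  const double h = dt_ms / nsub;
  const double dE = std::exp(-h / P.taue);
  const double dI = std::exp(-h / P.taui);
  for (int i = 0; i < n; ++i) {
    gE[i] += exc[i];
    gI[i] += inh[i];
    spk[i] = 0;
  }
  for (int s = 0; s < nsub; ++s) {
    double tt = t_ms + s * h;
    for (int i = 0; i < n; ++i) {
      if (tt < refr[i]) {
        V[i] = P.Vreset;
      } else {
        double I = -P.gL * (V[i] - P.EL) - gE[i] * (V[i] - P.Ee)
                   - gI[i] * (V[i] - P.Ei);
        V[i] += h * I / P.C;
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential (neuron %d, step %d)",
               i + 1, step_index + 1);
        double vth = vth_off ? P.Vth + vth_off[i] : P.Vth;
        if (V[i] >= vth) {
          V[i] = P.Vreset;
          refr[i] = tt + h + P.tref;
          spk[i] += 1;
        }
      }
      gE[i] *= dE;
      gI[i] *= dI;
    }
  }
}

// [[Rcpp::export]]
List cpp_lif_run(NumericVector V0, NumericVector gE0, NumericVector gI0,
                 NumericVector refr0, NumericVector par, double t0_ms,
                 double dt_ms, int nsub, NumericMatrix exc,
                 NumericMatrix inh) {
  int n = V0.size();
  int nsteps = exc.nrow();
  if (inh.nrow() != nsteps || exc.ncol() != n || inh.ncol() != n)
    stop("input increment matrices must be n_steps x n_neurons");
  LifP P(par);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> gE(gE0.begin(), gE0.end());
  std::vector<double> gI(gI0.begin(), gI0.end());
  std::vector<double> refr(refr0.begin(), refr0.end());
  IntegerMatrix spikes(nsteps, n);
  std::vector<double> e(n), iin(n);
  std::vector<int> spk(n);
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < n; ++i) { e[i] = exc(s, i); iin[i] = inh(s, i); }
    lif_step(V, gE, gI, refr, P, t0_ms + s * dt_ms, dt_ms, nsub,
             e.data(), iin.data(), n, spk.data(), s);
    for (int i = 0; i < n; ++i) spikes(s, i) = spk[i];
  }
  return List::create(_["V"] = NumericVector(V.begin(), V.end()),
                      _["g_exc"] = NumericVector(gE.begin(), gE.end()),
                      _["g_inh"] = NumericVector(gI.begin(), gI.end()),
                      _["refractory_until"] =
                          NumericVector(refr.begin(), refr.end()),
                      _["spikes"] = spikes);
}

// ---------------------------------------------------------------------------
// Planar 3-link arm: recursive Newton-Euler inverse dynamics.
// Joints are revolute, links move in a vertical plane, gravity acts along -y.
// A point-mass payload rides on the end effector.  Friction is handled by
// the caller (it is a plant property, not part of the rigid-body dynamics).
// ---------------------------------------------------------------------------

struct ArmP {
  std::vector<double> m, L, lc, I;
  double payload, g, base;
  int n;
  explicit ArmP(const List& par) {
    m = as<std::vector<double> >(par["masses"]);
    L = as<std::vector<double> >(par["lengths"]);
    lc = as<std::vector<double> >(par["coms"]);
    I = as<std::vector<double> >(par["inertias"]);
    payload = as<double>(par["payload"]);
    g = as<double>(par["gravity"]);
    base = as<double>(par["base_angle"]);
    n = (int)m.size();
  }
};

// Inverse dynamics: tau for given q, qd, qdd (gravity via base acceleration).
static void arm_rnea(const ArmP& A, const double* q, const double* qd,
                     const double* qdd, double grav, double* tau) {
  int n = A.n;
  // forward pass: absolute angle, angular velocity/acceleration,
  // linear acceleration of joint origins and of link COMs
  std::vector<double> th(n), w(n), al(n);
  std::vector<double> ax(n + 1), ay(n + 1);   // joint-origin accelerations
  std::vector<double> acx(n), acy(n);         // COM accelerations
  ax[0] = 0.0; ay[0] = grav;                  // gravity trick: base accelerates +g
  double thp = A.base, wp = 0.0, alp = 0.0;
  for (int i = 0; i < n; ++i) {
    thp += q[i]; wp += qd[i]; alp += qdd[i];
    th[i] = thp; w[i] = wp; al[i] = alp;
    double cx = std::cos(thp), sx = std::sin(thp);
    double rx = A.L[i] * cx, ry = A.L[i] * sx;
    double rcx = A.lc[i] * cx, rcy = A.lc[i] * sx;
    // a = a_prev + alpha x r + w x (w x r); in 2D: alpha x r = al*(-ry, rx)
    acx[i] = ax[i] + al[i] * (-rcy) - w[i] * w[i] * rcx;
    acy[i] = ay[i] + al[i] * (rcx) - w[i] * w[i] * rcy;
    ax[i + 1] = ax[i] + al[i] * (-ry) - w[i] * w[i] * rx;
    ay[i + 1] = ay[i] + al[i] * (rx) - w[i] * w[i] * ry;
  }
  // payload wrench at the end effector
  double fx_next = A.payload * ax[n];
  double fy_next = A.payload * ay[n];
  double n_next = 0.0;
  // backward pass
  for (int i = n - 1; i >= 0; --i) {
    double cx = std::cos(th[i]), sx = std::sin(th[i]);
    double rx = A.L[i] * cx, ry = A.L[i] * sx;
    double rcx = A.lc[i] * cx, rcy = A.lc[i] * sx;
    double Fx = A.m[i] * acx[i], Fy = A.m[i] * acy[i];
    double Ni = A.I[i] * al[i];
    double fx = Fx + fx_next, fy = Fy + fy_next;
    double ni = Ni + n_next + (rcx * Fy - rcy * Fx)
                + (rx * fy_next - ry * fx_next);
    tau[i] = ni;
    fx_next = fx; fy_next = fy; n_next = ni;
  }
}

// [[Rcpp::export]]
NumericVector cpp_arm_rnea(NumericVector q, NumericVector qd,
                           NumericVector qdd, List par) {
  ArmP A(par);
  if ((int)q.size() != A.n) stop("state dimension mismatch");
  NumericVector tau(A.n);
  arm_rnea(A, q.begin(), qd.begin(), qdd.begin(), A.g, tau.begin());
  return tau;
}

// Mass matrix by columns: M[,i] = rnea(q, 0, e_i) with gravity off.
static void arm_mass(const ArmP& A, const double* q, double* M) {
  int n = A.n;
  std::vector<double> z(n, 0.0), e(n, 0.0), col(n);
  for (int i = 0; i < n; ++i) {
    e[i] = 1.0;
    arm_rnea(A, q, z.data(), e.data(), 0.0, col.data());
    for (int r = 0; r < n; ++r) M[r + n * i] = col[r];
    e[i] = 0.0;
  }
}

// Solve M x = b for small n by Gaussian elimination with partial pivoting.
static void solve_small(int n, double* M, double* b) {
  for (int k = 0; k < n; ++k) {
    int p = k;
    for (int r = k + 1; r < n; ++r)
      if (std::fabs(M[r + n * k]) > std::fabs(M[p + n * k])) p = r;
    if (p != k) {
      for (int c = 0; c < n; ++c) std::swap(M[k + n * c], M[p + n * c]);
      std::swap(b[k], b[p]);
    }
    double piv = M[k + n * k];
    for (int r = k + 1; r < n; ++r) {
      double f = M[r + n * k] / piv;
      for (int c = k; c < n; ++c) M[r + n * c] -= f * M[k + n * c];
      b[r] -= f * b[k];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double s = b[k];
    for (int c = k + 1; c < n; ++c) s -= M[k + n * c] * b[c];
    b[k] = s / M[k + n * k];
  }
}

// Forward-dynamics step: semi-implicit Euler with substeps.
static void arm_fd_step(const ArmP& A, double friction, double* q, double* qd,
                        const double* tau_ext, double dt, int nsub) {
  int n = A.n;
  double h = dt / nsub;
  std::vector<double> M(n * n), rhs(n), hvec(n), z(n, 0.0);
  for (int s = 0; s < nsub; ++s) {
    arm_rnea(A, q, qd, z.data(), A.g, hvec.data());   // gravity + Coriolis
    arm_mass(A, q, M.data());
    for (int i = 0; i < n; ++i)
      rhs[i] = tau_ext[i] - hvec[i] - friction * qd[i];
    solve_small(n, M.data(), rhs.data());             // rhs <- qdd
    for (int i = 0; i < n; ++i) {
      qd[i] += h * rhs[i];
      q[i] += h * qd[i];
      if (!std::isfinite(q[i])) stop("arm state diverged");
    }
  }
}

// [[Rcpp::export]]
List cpp_arm_fd_step(NumericVector q0, NumericVector qd0, NumericVector tau,
                     List par, double friction, double dt, int nsub) {
  ArmP A(par);
  std::vector<double> q(q0.begin(), q0.end()), qd(qd0.begin(), qd0.end());
  arm_fd_step(A, friction, q.data(), qd.data(), tau.begin(), dt, nsub);
  return List::create(_["q"] = NumericVector(q.begin(), q.end()),
                      _["qd"] = NumericVector(qd.begin(), qd.end()));
}

// ---------------------------------------------------------------------------
// Closed-loop trial engine.
//
// One call = one learning trial (neuron state, traces, decoder and delay
// line start fresh; weights are modified in place and persist across calls).
// Spikes produced at step s are delivered to their targets at step s+1
// (one-step synaptic delay).  Plasticity is evaluated at spike emission.
//
// Case A (`qdes` empty): the controlled variable is the decoded DCN output
// itself; error = reference - y.
// Case B: the decoded output is a per-joint corrective torque added to the
// crude inverse-dynamics torque; error = desired - actual joint angle.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_trial(NumericMatrix w_pfpc,    // n_gc x n_pc, modified in place
                   NumericMatrix w_mfdcn,   // n_mf x n_dcn, in place
                   NumericVector w_pcdcn,   // n_pc (PC -> its DCN), in place
                   IntegerMatrix gc_ids,    // 4 x n_steps, 0-based
                   IntegerMatrix mf_ids,    // 4 x n_steps, 0-based
                   LogicalVector mf_fire,   // n_steps comb flags
                   NumericVector ref,       // n_steps (Case A) or empty
                   NumericMatrix qdes,      // n_steps x J (Case B) or 0 x 0
                   NumericMatrix qddes,     // n_steps x J desired velocities
                   NumericMatrix tau_crude, // n_steps x J (Case B)
                   NumericMatrix u_cf,      // n_steps x n_dcn uniforms
                   List cfg) {
  const double dt = as<double>(cfg["dt"]);           // seconds
  const double dt_ms = dt * 1000.0;
  const int n_steps = gc_ids.ncol();
  const int n_gc = w_pfpc.nrow();
  const int n_pc = w_pfpc.ncol();
  const int n_dcn = w_mfdcn.ncol();
  const int n_mf = w_mfdcn.nrow();
  const int pc_per = n_pc / n_dcn;                   // PCs per microcomplex
  const bool case_b = qdes.nrow() > 0;
  const int J = case_b ? qdes.ncol() : 1;

  const NumericVector pc_par = cfg["pc_params"], dcn_par = cfg["dcn_params"];
  const LifP PPC(pc_par), PDCN(dcn_par);
  const int nsub = as<int>(cfg["n_substeps"]);
  const double cf_w = as<double>(cfg["cf_weight"]);
  const double lambda = as<double>(cfg["decoder_lambda"]);
  const double gain = as<double>(cfg["decoder_gain"]);
  const int delay = as<int>(cfg["delay_steps"]);
  const NumericVector eps_norm = cfg["eps_norm"];    // length J
  const double r_max = as<double>(cfg["r_max"]);

  const bool froz_pf = as<bool>(cfg["freeze_pfpc"]);
  const bool froz_mf = as<bool>(cfg["freeze_mfdcn"]);
  const bool froz_pc = as<bool>(cfg["freeze_pcdcn"]);
  const double a_pf = as<double>(cfg["pfpc_alpha"]);
  const double ltd_pf = as<double>(cfg["pfpc_ltd_scale"]);
  const NumericVector tau_ltd_v = cfg["pfpc_tau_ltd"];   // per complex
  const int W1 = as<int>(cfg["pfpc_window_steps"]);
  const double a_mf = as<double>(cfg["mfdcn_alpha"]);
  const double ltd_mf = as<double>(cfg["mfdcn_ltd_scale"]);
  const double sig_mf = as<double>(cfg["mfdcn_sigma"]);
  const double beta = as<double>(cfg["mfdcn_beta"]);
  const int W2 = as<int>(cfg["mfdcn_window_steps"]);
  const double wmax_mf = as<double>(cfg["mfdcn_w_max"]);
  const int kern_choice = as<int>(cfg["pcdcn_kernel"]); // 0 hebbian, 1 symmetric
  const double sc_pc = as<double>(cfg["pcdcn_scale"]);
  const double pre_dec = as<double>(cfg["pcdcn_pre_decay"]);
  const double tau1 = as<double>(cfg["pcdcn_tau1"]);
  const double tau2 = as<double>(cfg["pcdcn_tau2"]);
  const double sig_pc = as<double>(cfg["pcdcn_sigma"]);
  const double ltp_max = as<double>(cfg["pcdcn_ltp_max"]);
  const double ltd_max = as<double>(cfg["pcdcn_ltd_max"]);
  const int W3 = as<int>(cfg["pcdcn_window_steps"]);
  const double wmax_pc = as<double>(cfg["pcdcn_w_max"]);
  const bool record = as<bool>(cfg["record_spikes"]);
  NumericVector pc_vth_off = cfg["pc_vth_offset"];
  if (pc_vth_off.size() != n_pc) stop("pc_vth_offset length mismatch");
  const double tq_gain = case_b ? as<double>(cfg["torque_gain"]) : 0.0;
  const double kv = case_b ? as<double>(cfg["velocity_error_weight"]) : 0.0;

  // plant (Case B)
  ArmP* arm = NULL;
  double friction = 0.0;
  int plant_sub = 1;
  std::vector<double> q(J, 0.0), qdv(J, 0.0);
  if (case_b) {
    List ap = cfg["arm"];
    arm = new ArmP(ap);
    friction = as<double>(cfg["friction"]);
    plant_sub = as<int>(cfg["plant_substeps"]);
    NumericVector q0 = cfg["q0"];
    for (int j = 0; j < J; ++j) q[j] = q0[j];
  }

  // neuron state
  std::vector<double> Vpc(n_pc, PPC.EL), gEpc(n_pc, 0), gIpc(n_pc, 0),
      rpc(n_pc, -1e9);
  std::vector<double> Vdc(n_dcn, PDCN.EL), gEdc(n_dcn, 0), gIdc(n_dcn, 0),
      rdc(n_dcn, -1e9);
  std::vector<int> pc_spk(n_pc, 0), dcn_spk(n_dcn, 0);
  std::vector<int> pc_prev(n_pc, 0), dcn_prev(n_dcn, 0);
  std::vector<int> cf_prev(n_dcn, 0);

  // spike histories within the trial (counts per step)
  std::vector<std::vector<int> > pc_hist(n_steps, std::vector<int>(n_pc, 0));
  std::vector<std::vector<int> > dcn_hist(n_steps, std::vector<int>(n_dcn, 0));
  std::vector<std::vector<int> > grp_hist(n_steps, std::vector<int>(n_dcn, 0));
  std::vector<double> last_pc(n_pc, -1e18), last_dcn(n_dcn, -1e18);

  // decoder + delay line
  std::vector<double> y(n_dcn, 0.0);
  std::vector<std::vector<double> > e_hist(J);
  for (int j = 0; j < J; ++j) e_hist[j].assign(n_steps, 0.0);

  std::vector<double> excPC(n_pc), inhPC(n_pc, 0.0);
  std::vector<double> excDC(n_dcn), inhDC(n_dcn);

  NumericMatrix y_out(n_steps, n_dcn);
  NumericMatrix err_out(n_steps, J);
  NumericMatrix q_out(case_b ? n_steps : 0, case_b ? J : 0);
  IntegerMatrix rec_pc(record ? n_steps : 0, record ? n_pc : 0);
  IntegerMatrix rec_dcn(record ? n_steps : 0, record ? n_dcn : 0);
  IntegerMatrix rec_cf(record ? n_steps : 0, record ? n_dcn : 0);
  IntegerVector cf_count(n_dcn);
  long pc_total = 0, dcn_total = 0;
  double abs_err = 0.0;

  for (int s = 0; s < n_steps; ++s) {
    // 1. deliver last step's spikes ----------------------------------------
    std::fill(excPC.begin(), excPC.end(), 0.0);
    std::fill(excDC.begin(), excDC.end(), 0.0);
    std::fill(inhDC.begin(), inhDC.end(), 0.0);
    if (s > 0) {
      for (int k = 0; k < gc_ids.nrow(); ++k) {
        int g = gc_ids(k, s - 1);
        for (int p = 0; p < n_pc; ++p) excPC[p] += w_pfpc(g, p);
      }
      for (int c = 0; c < n_dcn; ++c)
        if (cf_prev[c])
          for (int p = c * pc_per; p < (c + 1) * pc_per; ++p)
            excPC[p] += cf_w;
      if (mf_fire[s - 1]) {
        for (int k = 0; k < mf_ids.nrow(); ++k) {
          int m = mf_ids(k, s - 1);
          for (int d = 0; d < n_dcn; ++d) excDC[d] += w_mfdcn(m, d);
        }
      }
      for (int p = 0; p < n_pc; ++p)
        if (pc_prev[p]) inhDC[p / pc_per] += pc_prev[p] * w_pcdcn[p];
    }

    // 2. advance LIF populations ------------------------------------------
    double t_ms = s * dt_ms;
    lif_step(Vpc, gEpc, gIpc, rpc, PPC, t_ms, dt_ms, nsub, excPC.data(),
             inhPC.data(), n_pc, pc_spk.data(), s, pc_vth_off.begin());
    lif_step(Vdc, gEdc, gIdc, rdc, PDCN, t_ms, dt_ms, nsub, excDC.data(),
             inhDC.data(), n_dcn, dcn_spk.data(), s);
    for (int p = 0; p < n_pc; ++p) {
      pc_hist[s][p] = pc_spk[p];
      if (pc_spk[p]) { grp_hist[s][p / pc_per] += pc_spk[p]; pc_total += pc_spk[p]; }
    }
    for (int d = 0; d < n_dcn; ++d) { dcn_hist[s][d] = dcn_spk[d]; dcn_total += dcn_spk[d]; }

    // 3. decode DCN output --------------------------------------------------
    for (int d = 0; d < n_dcn; ++d) {
      y[d] = lambda * y[d] + gain * dcn_spk[d];
      y_out(s, d) = y[d];
    }

    // 4. plant / error ------------------------------------------------------
    // `err` is the logged tracking error (position for Case B); `teach`
    // is the error fed to the teaching pathway (adds the velocity lead
    // term in Case B).
    std::vector<double> err(J), teach(J);
    if (!case_b) {
      err[0] = ref[s] - (y[0] - y[1]);
      teach[0] = err[0];
    } else {
      std::vector<double> tau(J);
      for (int j = 0; j < J; ++j)
        tau[j] = tau_crude(s, j) + tq_gain * (y[2 * j] - y[2 * j + 1]);
      arm_fd_step(*arm, friction, q.data(), qdv.data(), tau.data(), dt,
                  plant_sub);
      for (int j = 0; j < J; ++j) {
        err[j] = qdes(s, j) - q[j];
        teach[j] = err[j] + kv * (qddes(s, j) - qdv[j]);
        q_out(s, j) = q[j];
      }
    }
    for (int j = 0; j < J; ++j) {
      e_hist[j][s] = teach[j];
      err_out(s, j) = err[j];
      abs_err += std::fabs(err[j]);
    }

    // 5. climbing-fiber encoding of the delayed error ----------------------
    std::vector<int> cf_now(n_dcn, 0);
    for (int j = 0; j < J; ++j) {
      double ed = (s >= delay) ? e_hist[j][s - delay] : 0.0;
      double ep = ed / eps_norm[j], en = -ed / eps_norm[j];
      ep = ep < 0 ? 0 : (ep > 1 ? 1 : ep);
      en = en < 0 ? 0 : (en > 1 ? 1 : en);
      if (u_cf(s, 2 * j) < ep * r_max * dt) cf_now[2 * j] = 1;
      if (n_dcn > 2 * j + 1 && u_cf(s, 2 * j + 1) < en * r_max * dt)
        cf_now[2 * j + 1] = 1;
    }
    if (!case_b) { /* J==1, channels 0 (pos) and 1 (neg) already set */ }
    for (int c = 0; c < n_dcn; ++c) if (cf_now[c]) cf_count[c] += 1;

    // 6. plasticity ---------------------------------------------------------
    // 6a. PF-PC LTP on each granule-cell spike
    if (!froz_pf && a_pf != 0.0) {
      for (int k = 0; k < gc_ids.nrow(); ++k) {
        int g = gc_ids(k, s);
        for (int p = 0; p < n_pc; ++p) w_pfpc(g, p) += a_pf;
      }
    }
    // 6b. PF-PC LTD on each climbing-fiber spike (eligibility over past PFs)
    if (!froz_pf) {
      for (int c = 0; c < n_dcn; ++c) {
        if (!cf_now[c]) continue;
        double tau_ltd = tau_ltd_v[c % tau_ltd_v.size()];
        int s0 = s - W1 < 0 ? 0 : s - W1;
        for (int sp = s0; sp <= s; ++sp) {
          double kv = kern_pfpc((s - sp) * dt / tau_ltd);
          if (kv <= 0.0) continue;
          double d = ltd_pf * kv;
          for (int k = 0; k < gc_ids.nrow(); ++k) {
            int g = gc_ids(k, sp);
            for (int p = c * pc_per; p < (c + 1) * pc_per; ++p) {
              double w = w_pfpc(g, p) - d;
              w_pfpc(g, p) = w < 0 ? 0 : w;
            }
          }
        }
      }
    }
    // 6c. MF-DCN LTP on each mossy-fiber spike
    if (!froz_mf && mf_fire[s] && a_mf != 0.0) {
      for (int k = 0; k < mf_ids.nrow(); ++k) {
        int m = mf_ids(k, s);
        for (int d = 0; d < n_dcn; ++d) {
          double w = w_mfdcn(m, d) + a_mf;
          w_mfdcn(m, d) = w > wmax_mf ? wmax_mf : w;
        }
      }
    }
    // 6d. MF-DCN LTD: PC spikes against past MF spikes; MF spikes against
    //     strictly earlier PC spikes (two-sided symmetric kernel)
    if (!froz_mf) {
      for (int d = 0; d < n_dcn; ++d) {
        int npc_s = grp_hist[s][d];
        if (npc_s == 0) continue;
        int s0 = s - W2 < 0 ? 0 : s - W2;
        for (int sp = s0; sp <= s; ++sp) {
          if (!mf_fire[sp]) continue;
          double kv = kern_mfdcn((s - sp) * dt / sig_mf, beta);
          double dec = ltd_mf * kv * npc_s;
          for (int k = 0; k < mf_ids.nrow(); ++k) {
            int m = mf_ids(k, sp);
            double w = w_mfdcn(m, d) - dec;
            w_mfdcn(m, d) = w < 0 ? 0 : w;
          }
        }
      }
      if (mf_fire[s]) {
        int s0 = s - W2 < 0 ? 0 : s - W2;
        for (int d = 0; d < n_dcn; ++d) {
          double acc = 0.0;
          for (int sp = s0; sp < s; ++sp)
            if (grp_hist[sp][d])
              acc += grp_hist[sp][d] *
                     kern_mfdcn((s - sp) * dt / sig_mf, beta);
          if (acc == 0.0) continue;
          double dec = ltd_mf * acc;
          for (int k = 0; k < mf_ids.nrow(); ++k) {
            int m = mf_ids(k, s);
            double w = w_mfdcn(m, d) - dec;
            w_mfdcn(m, d) = w < 0 ? 0 : w;
          }
        }
      }
    }
    // 6e. PC-DCN inhibitory STDP
    if (!froz_pc) {
      double t_now = s * dt;
      if (kern_choice == 0) {
        // Hebbian, nearest-neighbour pairing; coincident pair -> potentiation
        for (int p = 0; p < n_pc; ++p) {
          if (!pc_hist[s][p]) continue;
          int d = p / pc_per;
          double w = w_pcdcn[p] - pc_hist[s][p] * pre_dec;
          if (!dcn_spk[d] && last_dcn[d] > -1e17) {
            double del = t_now - last_dcn[d];
            if (del <= W3 * dt)
              w -= pc_hist[s][p] * sc_pc * std::exp(-del / tau2);
          }
          w_pcdcn[p] = w < 0 ? 0 : w;
          last_pc[p] = t_now;
        }
        for (int d = 0; d < n_dcn; ++d) {
          if (!dcn_spk[d]) continue;
          for (int p = d * pc_per; p < (d + 1) * pc_per; ++p) {
            if (last_pc[p] < -1e17) continue;
            double del = t_now - last_pc[p];
            if (del <= W3 * dt) {
              double w = w_pcdcn[p] + dcn_spk[d] * sc_pc * std::exp(-del / tau1);
              w_pcdcn[p] = w > wmax_pc ? wmax_pc : w;
            }
          }
          last_dcn[d] = t_now;
        }
      } else {
        // symmetric: every presynaptic spike depresses; near-coincident
        // pre/post pairs potentiate
        int s0 = s - W3 < 0 ? 0 : s - W3;
        for (int p = 0; p < n_pc; ++p) {
          if (!pc_hist[s][p]) continue;
          int d = p / pc_per;
          double dw = -ltd_max * pc_hist[s][p];
          for (int sp = s0; sp <= s; ++sp)
            if (dcn_hist[sp][d])
              dw += pc_hist[s][p] * dcn_hist[sp][d] * ltp_max *
                    kern_sym((s - sp) * dt / sig_pc);
          double w = w_pcdcn[p] + dw;
          w_pcdcn[p] = w < 0 ? 0 : (w > wmax_pc ? wmax_pc : w);
        }
        for (int d = 0; d < n_dcn; ++d) {
          if (!dcn_spk[d]) continue;
          for (int p = d * pc_per; p < (d + 1) * pc_per; ++p) {
            double dw = 0.0;
            for (int sp = s0; sp < s; ++sp)
              if (pc_hist[sp][p])
                dw += dcn_spk[d] * pc_hist[sp][p] * ltp_max *
                      kern_sym((s - sp) * dt / sig_pc);
            if (dw != 0.0) {
              double w = w_pcdcn[p] + dw;
              w_pcdcn[p] = w > wmax_pc ? wmax_pc : w;
            }
          }
        }
      }
    }

    // 7. bookkeeping --------------------------------------------------------
    if (record) {
      for (int p = 0; p < n_pc; ++p) rec_pc(s, p) = pc_hist[s][p];
      for (int d = 0; d < n_dcn; ++d) {
        rec_dcn(s, d) = dcn_hist[s][d];
        rec_cf(s, d) = cf_now[d];
      }
    }
    pc_prev = pc_spk;
    dcn_prev = dcn_spk;
    for (int c = 0; c < n_dcn; ++c) cf_prev[c] = cf_now[c];
  }

  if (arm) delete arm;
  double mae = abs_err / (n_steps * J);
  List out = List::create(
      _["mae"] = mae, _["y"] = y_out, _["error"] = err_out,
      _["cf_count"] = cf_count, _["pc_spikes_total"] = (double)pc_total,
      _["dcn_spikes_total"] = (double)dcn_total);
  if (case_b) out["q"] = q_out;
  if (record) {
    out["pc_raster"] = rec_pc;
    out["dcn_raster"] = rec_dcn;
    out["cf_raster"] = rec_cf;
  }
  return out;
}
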