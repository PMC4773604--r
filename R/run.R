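#' Assemble the per-trial engine configuration
#'
#' Internal helper collecting all constants the compiled trial engine
#' needs.  Exposed for reproducibility (it is stored in run results).
#'
#' @keywords internal
#' @noRd
build_engine_config <- function(net, pfpc, mfdcn, pcdcn, decoder, freeze,
                                dt, n_substeps, r_max, delay, error_norm,
                                cf_weight, record_spikes = FALSE,
                                extra = list()) {
  n_joints <- net$config$n_dcn / 2L
  cfg <- list(
    dt = dt, n_substeps = as.integer(n_substeps),
    pc_params = as_param_vector(net$populations$PC$params),
    dcn_params = as_param_vector(net$populations$DCN$params),
    cf_weight = cf_weight,
    decoder_lambda = decoder$decay, decoder_gain = decoder$gain,
    delay_steps = as.integer(round(delay / dt)),
    eps_norm = rep_len(error_norm, n_joints), r_max = r_max,
    freeze_pfpc = "pfpc" %in% freeze,
    freeze_mfdcn = "mfdcn" %in% freeze,
    freeze_pcdcn = "pcdcn" %in% freeze,
    pfpc_alpha = pfpc$alpha_ltp, pfpc_ltd_scale = pfpc$ltd_scale,
    # per-microcomplex eligibility constants (a scalar recycles; a
    # per-joint vector is expanded to the agonist/antagonist pair)
    pfpc_tau_ltd = if (length(pfpc$tau_ltd) == 1) pfpc$tau_ltd
                   else rep(pfpc$tau_ltd, each = 2),
    pfpc_window_steps = as.integer(round(pfpc$truncation_window / dt)),
    mfdcn_alpha = mfdcn$alpha_ltp, mfdcn_ltd_scale = mfdcn$ltd_scale,
    mfdcn_sigma = mfdcn$sigma, mfdcn_beta = mfdcn$beta,
    mfdcn_w_max = mfdcn$w_max,
    mfdcn_window_steps = as.integer(round(mfdcn$truncation_window / dt)),
    pcdcn_kernel = if (pcdcn$kernel_choice == "hebbian") 0L else 1L,
    pcdcn_scale = pcdcn$scale, pcdcn_pre_decay = pcdcn$pre_decay,
    pcdcn_tau1 = pcdcn$tau1,
    pcdcn_tau2 = pcdcn$tau2, pcdcn_sigma = pcdcn$sigma,
    pcdcn_ltp_max = pcdcn$ltp_max, pcdcn_ltd_max = pcdcn$ltd_max,
    pcdcn_w_max = pcdcn$w_max,
    pcdcn_window_steps = as.integer(round(pcdcn$truncation_window / dt)),
    pc_vth_offset = net$pc_vth_offset,
    record_spikes = record_spikes)
  c(cfg, extra)
}

# 0-based per-step cell-id matrices for the compiled engine
schedule_step_ids <- function(schedule) {
  idx <- rep(seq_len(schedule$n_states), each = schedule$steps_per_state)
  schedule$assignment[, idx, drop = FALSE] - 1L
}

complex_labels <- function(net) {
  cx <- net$complexes
  if (net$config$case == "A") ifelse(cx$sign == "+", "pos", "neg")
  else paste0("j", cx$joint, "_", ifelse(cx$sign == "+", "pos", "neg"))
}

new_trial_log <- function(n_trials, net) {
  lbl <- complex_labels(net)
  cols <- c("trial", "mae", "mean_w_pfpc",
            paste0("mean_w_mfdcn_", lbl), paste0("mean_w_pcdcn_", lbl),
            "cf_spikes")
  m <- matrix(NA_real_, n_trials, length(cols),
              dimnames = list(NULL, cols))
  as.data.frame(m)
}

log_trial <- function(log, i, mae, net_w, cf_total) {
  nd <- ncol(net_w$w_mfdcn)
  log[i, ] <- c(i, mae, mean(net_w$w_pfpc),
                colMeans(net_w$w_mfdcn),
                vapply(seq_len(nd), function(d)
                  mean(net_w$w_pcdcn[((d - 1) * 10 + 1):(d * 10)]),
                  numeric(1)),
                cf_total)
  log
}

#' Run the Case A set-point tracking experiment
#'
#' Repeatedly presents the twin-Gaussian reference to the spiking
#' cerebellar module in closed loop.  Per 2 ms step: the granule/mossy
#' state generators tick, the Purkinje and nuclei populations are
#' integrated, the two nuclei spike trains are decoded and combined into
#' the controlled variable, the (100 ms delayed) tracking error is split
#' into agonist/antagonist channels and sampled probabilistically by the
#' climbing fibers, and all enabled plasticity rules are applied.  Neuron
#' and trace state resets between trials; weights persist.
#'
#' @param n_trials Number of learning trials.
#' @param seed Seed for the climbing-fiber sampling stream.
#' @param net A Case A [build_network()]; its weight matrices are the
#'   initial condition.
#' @param pfpc,mfdcn,pcdcn Rule configurations (see
#'   [pfpc_rule_config()] etc.).
#' @param freeze Character subset of `c("pfpc", "mfdcn", "pcdcn")`: rules
#'   to disable.
#' @param reference [reference_config()] describing the set-point curve.
#' @param decoder [decoder_config()] for the nuclei output channels.
#' @param r_max Climbing-fiber rate cap, Hz.
#' @param delay Sensorimotor delay applied to the error pathway, s.
#' @param error_norm Raw-error magnitude mapping to `epsilon = 1`.
#' @param dt Simulation step, s.
#' @param mf_rate Mossy-fiber within-window rate, Hz.
#' @param cf_weight Climbing fiber-Purkinje conductance, nS.
#' @param snapshot_trials Trials after which to copy all weights.
#' @param record_last Record spike rasters of the final trial.
#' @return Object of class `cereb_run`: `log` (per-trial data frame),
#'   `net` (final weights), `snapshots`, `final` (last-trial traces and,
#'   if requested, rasters), plus the schedules and configuration used.
#' @export
run_case_a <- function(n_trials = 2500, seed = 1,
                       net = build_network(case_config("A")),
                       pfpc = pfpc_rule_config(),
                       mfdcn = mfdcn_rule_config(),
                       pcdcn = pcdcn_rule_config(),
                       freeze = character(0),
                       reference = reference_config(),
                       decoder = decoder_config(),
                       r_max = 10, delay = 0.1, error_norm = 1,
                       dt = 0.002, mf_rate = 100, cf_weight = 100,
                       snapshot_trials = integer(0),
                       record_last = TRUE) {
  stopifnot(net$config$case == "A")
  duration <- reference$period
  gc_sched <- build_state_schedule(net$config$n_gc, 4, duration, dt)
  mf_sched <- build_state_schedule(net$config$n_mf, 4, duration, dt)
  n_steps <- gc_sched$n_steps
  gc_ids <- schedule_step_ids(gc_sched)
  mf_ids <- schedule_step_ids(mf_sched)
  comb <- round(1 / (mf_rate * dt))
  mf_fire <- (seq_len(n_steps) - 1) %% comb == 0
  ref <- reference_variable((seq_len(n_steps) - 1) * dt, reference)
  run_loop(net, n_trials, seed, gc_ids, mf_ids, mf_fire, ref = ref,
           qdes = matrix(0, 0, 0), qddes = matrix(0, 0, 0),
           tau_crude = matrix(0, 0, 0),
           pfpc = pfpc, mfdcn = mfdcn, pcdcn = pcdcn, freeze = freeze,
           decoder = decoder, dt = dt, r_max = r_max, delay = delay,
           error_norm = error_norm, cf_weight = cf_weight,
           snapshot_trials = snapshot_trials, record_last = record_last,
           extra = list(),
           meta = list(reference = reference, gc_schedule = gc_sched,
                       mf_schedule = mf_sched))
}

#' Run the Case B robotic manipulation experiment
#'
#' Feed-forward torque control of the simulated three-link arm along the
#' eight-shaped joint trajectory: crude (payload-blind) inverse-dynamics
#' torques are corrected per joint by the decoded output of an
#' agonist/antagonist microcomplex pair; the per-joint tracking error,
#' delayed by the sensorimotor latency, drives the corresponding climbing
#' fiber pair.
#'
#' @inheritParams run_case_a
#' @param net A Case B [build_network()].
#' @param trajectory [trajectory_config()] for the desired motion.
#' @param arm A [planar_arm()]; its `payload` is carried by the true plant
#'   but hidden from the crude controller.
#' @param torque_gain N m of corrective torque per unit decoded output.
#' @param velocity_error_weight Weight (s) of the velocity-error term in
#'   the teaching signal: `e = (Qd - Q) + kv * (dQd - dQ)`.  A modest lead
#'   term compensates the plant's integration lag in the error pathway.
#' @param friction Viscous joint friction of the plant, N m s.
#' @param plant_substeps Plant integration substeps per control step.
#' @return A `cereb_run` (per-joint error traces in `final`).
#' @export
run_case_b <- function(n_trials = 2000, seed = 1,
                       net = build_network(case_config("B",
                                                       pcdcn_init_mode = "fixed")),
                       trajectory = trajectory_config(
                         amplitudes = c(0.2, 0.15, 0.1), duration = 2),
                       arm = planar_arm(payload = 6),
                       pfpc = pfpc_rule_config(
                         tau_ltd = calibrate_tau_ltd(0.3),
                         alpha_ltp = 4e-3, ltd_scale = 0.4),
                       mfdcn = mfdcn_rule_config(alpha_ltp = 0.02,
                                                 ltd_scale = 5e-3),
                       pcdcn = pcdcn_rule_config("hebbian", pre_decay = 0),
                       freeze = character(0),
                       decoder = decoder_config(tau_taps = 100, gain = 0.043),
                       r_max = 10, delay = 0.1, error_norm = 0.05,
                       dt = 0.002, mf_rate = 100, cf_weight = 10,
                       torque_gain = 15, friction = 10,
                       velocity_error_weight = 0.5,
                       plant_substeps = 10,
                       snapshot_trials = integer(0),
                       record_last = TRUE) {
  stopifnot(net$config$case == "B")
  duration <- trajectory$duration
  gc_sched <- build_state_schedule(net$config$n_gc, 4, duration, dt)
  mf_sched <- build_state_schedule(net$config$n_mf, 4, duration, dt)
  n_steps <- gc_sched$n_steps
  gc_ids <- schedule_step_ids(gc_sched)
  mf_ids <- schedule_step_ids(mf_sched)
  comb <- round(1 / (mf_rate * dt))
  mf_fire <- (seq_len(n_steps) - 1) %% comb == 0
  des <- desired_joint_state((seq_len(n_steps) - 1) * dt, trajectory)
  # payload-blind feed-forward torques; viscous friction is part of the
  # controller model (only the payload is unknown to it)
  tau_crude <- crude_inverse_dynamics(arm, des$q, des$qd, des$qdd) +
    friction * des$qd
  run_loop(net, n_trials, seed, gc_ids, mf_ids, mf_fire,
           ref = numeric(0), qdes = des$q, qddes = des$qd,
           tau_crude = tau_crude,
           pfpc = pfpc, mfdcn = mfdcn, pcdcn = pcdcn, freeze = freeze,
           decoder = decoder, dt = dt, r_max = r_max, delay = delay,
           error_norm = error_norm, cf_weight = cf_weight,
           snapshot_trials = snapshot_trials, record_last = record_last,
           extra = list(torque_gain = torque_gain,
                        velocity_error_weight = velocity_error_weight,
                        arm = unclass(arm),
                        friction = friction,
                        plant_substeps = as.integer(plant_substeps),
                        q0 = des$q[1, ]),
           meta = list(trajectory = trajectory, arm = arm,
                       desired = des, gc_schedule = gc_sched,
                       mf_schedule = mf_sched))
}

# shared trial loop
run_loop <- function(net, n_trials, seed, gc_ids, mf_ids, mf_fire, ref,
                     qdes, qddes, tau_crude, pfpc, mfdcn, pcdcn, freeze, decoder,
                     dt, r_max, delay, error_norm, cf_weight,
                     snapshot_trials, record_last, extra, meta) {
  n_steps <- ncol(gc_ids)
  n_dcn <- net$config$n_dcn
  cfg <- build_engine_config(net, pfpc, mfdcn, pcdcn, decoder, freeze,
                             dt, 10, r_max, delay, error_norm, cf_weight,
                             record_spikes = FALSE, extra = extra)
  # local copies: the engine updates these in place across trials
  w_pfpc <- net$w_pfpc + 0
  w_mfdcn <- net$w_mfdcn + 0
  w_pcdcn <- net$w_pcdcn + 0
  log <- new_trial_log(n_trials, net)
  snapshots <- list()
  final <- NULL
  set.seed(seed)
  for (i in seq_len(n_trials)) {
    u <- matrix(runif(n_steps * n_dcn), n_steps, n_dcn)
    cfg$record_spikes <- record_last && i == n_trials
    out <- cpp_run_trial(w_pfpc, w_mfdcn, w_pcdcn, gc_ids, mf_ids,
                         mf_fire, ref, qdes, qddes, tau_crude, u, cfg)
    log <- log_trial(log, i, out$mae,
                     list(w_pfpc = w_pfpc, w_mfdcn = w_mfdcn,
                          w_pcdcn = w_pcdcn), sum(out$cf_count))
    if (i %in% snapshot_trials)
      snapshots[[as.character(i)]] <- list(w_pfpc = w_pfpc + 0,
                                           w_mfdcn = w_mfdcn + 0,
                                           w_pcdcn = w_pcdcn + 0)
    if (i == n_trials) final <- out
  }
  net$w_pfpc <- w_pfpc
  net$w_mfdcn <- w_mfdcn
  net$w_pcdcn <- w_pcdcn
  structure(list(log = log, net = net, snapshots = snapshots,
                 final = final, seed = seed, engine_config = cfg,
                 rules = list(pfpc = pfpc, mfdcn = mfdcn, pcdcn = pcdcn,
                              freeze = freeze),
                 meta = meta),
            class = "cereb_run")
}

#' @export
print.cereb_run <- function(x, ...) {
  n <- nrow(x$log)
  cat("<cereb_run> case", x$net$config$case, "-", n, "trials\n")
  cat("  MAE: trial 1 =", signif(x$log$mae[1], 4),
      "; final =", signif(x$log$mae[n], 4), "\n")
  invisible(x)
}

#' Calibrate the fixed (pre-calculated) PC-DCN weight
#'
#' For runs with frozen inhibitory weights, finds by bisection the minimal
#' uniform Purkinje-to-nuclei conductance that silences a nuclei cell
#' driven by a reference level of mossy excitation while its 10-Purkinje
#' group fires at a reference rate, then applies a safety margin.  This
#' guarantees the inhibitory pathway can span the full output range (the
#' nuclei cell can be shut off, so the decoded output can reach zero, and
#' released, so it can reach the reference amplitude).
#'
#' @param mf_weight Reference mossy-fiber conductance (nS) per synapse at
#'   the excitation level the run is expected to reach.
#' @param pc_rate Reference per-Purkinje firing rate (Hz).
#' @param margin Multiplicative safety margin.
#' @param dt Simulation step, s.
#' @param params Nuclei-cell parameters.
#' @return Calibrated weight (nS).
#' @export
calibrate_pcdcn_fixed <- function(mf_weight = 20, pc_rate = 100,
                                  margin = 1.25, dt = 0.002,
                                  params = dcn_lif_params()) {
  n_steps <- 500
  # deterministic drive: 4 mossy fibers, 100 Hz comb; 10 Purkinje cells at
  # pc_rate, spread uniformly over steps
  exc <- matrix(0, n_steps, 1)
  exc[seq(1, n_steps, by = 5), 1] <- 4 * mf_weight
  pc_period <- max(1, round(1 / (pc_rate * dt)))
  pc_spikes_per_step <- vapply(seq_len(n_steps) - 1, function(s)
    sum((s - seq(0, 9) * pc_period %/% 10) %% pc_period == 0),
    numeric(1))
  silenced <- function(w) {
    inh <- matrix(pc_spikes_per_step * w, n_steps, 1)
    st <- population_state(1, params)
    res <- step_population(st, params, dt, exc, inh)
    sum(res$spikes) == 0
  }
  lo <- 0; hi <- 1
  while (!silenced(hi) && hi < 1e4) hi <- hi * 2
  for (k in 1:30) {
    mid <- (lo + hi) / 2
    if (silenced(mid)) hi <- mid else lo <- mid
  }
  margin * hi
}
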