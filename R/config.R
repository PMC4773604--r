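#' Leaky integrate-and-fire neuron parameters
#'
#' Conductance-based exponential-synapse LIF parameters.  Defaults describe
#' a generic small cell with a 10 ms membrane time constant; the closed-loop
#' experiments use per-population variants (see [pc_lif_params()] and
#' [dcn_lif_params()]) whose capacitance/leak are scaled so that the 5 nS
#' parallel-fiber conductances drive graded, not saturated, firing.
#'
#' @param membrane_capacitance pF.
#' @param leak_conductance nS.
#' @param resting_potential,threshold,reset_potential mV; `threshold` must
#'   exceed `reset_potential`.
#' @param refractory_period ms.
#' @param excitatory_reversal,inhibitory_reversal mV.
#' @param tau_exc,tau_inh Synaptic conductance decay constants, ms.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(membrane_capacitance = 2,
                       leak_conductance = 0.2,
                       resting_potential = -70,
                       threshold = -50,
                       reset_potential = -70,
                       refractory_period = 1,
                       excitatory_reversal = 0,
                       inhibitory_reversal = -80,
                       tau_exc = 0.5,
                       tau_inh = 10) {
  stopifnot(threshold > reset_potential,
            tau_exc > 0, tau_inh > 0,
            membrane_capacitance > 0, leak_conductance > 0,
            refractory_period >= 0)
  structure(list(membrane_capacitance = membrane_capacitance,
                 leak_conductance = leak_conductance,
                 resting_potential = resting_potential,
                 threshold = threshold,
                 reset_potential = reset_potential,
                 refractory_period = refractory_period,
                 excitatory_reversal = excitatory_reversal,
                 inhibitory_reversal = inhibitory_reversal,
                 tau_exc = tau_exc, tau_inh = tau_inh),
            class = "lif_params")
}

#' @rdname lif_params
#' @export
pc_lif_params <- function() {
  lif_params(membrane_capacitance = 120, leak_conductance = 12,
             refractory_period = 2)
}

#' @rdname lif_params
#' @export
dcn_lif_params <- function() {
  lif_params(membrane_capacitance = 60, leak_conductance = 6,
             refractory_period = 2)
}

# pack into the numeric layout the compiled core expects
as_param_vector <- function(p) {
  stopifnot(inherits(p, "lif_params"))
  c(p$membrane_capacitance, p$leak_conductance, p$resting_potential,
    p$threshold, p$reset_potential, p$refractory_period,
    p$excitatory_reversal, p$inhibitory_reversal, p$tau_exc, p$tau_inh)
}

#' PF-PC plasticity rule configuration
#'
#' @param tau_ltd Eligibility-kernel time constant (s); the default places
#'   peak depression on parallel-fiber spikes 100 ms before the teaching
#'   spike, compensating the sensorimotor delay.  May be a vector with one
#'   entry per controlled joint when plants with joint-dependent lag are
#'   driven (each joint's agonist/antagonist pair shares the value).
#' @param alpha_ltp Fixed potentiation per parallel-fiber spike (nS).
#' @param ltd_scale Depression per unit kernel value (nS).
#' @param truncation_window Eligibility-buffer extent (s).
#' @return List of class `pfpc_rule_config`.
#' @export
pfpc_rule_config <- function(tau_ltd = calibrate_tau_ltd(0.1),
                             alpha_ltp = 1.5e-4,
                             ltd_scale = 0.045,
                             truncation_window = 0.3) {
  stopifnot(all(tau_ltd > 0), alpha_ltp >= 0, ltd_scale >= 0,
            truncation_window > 0)
  structure(list(tau_ltd = tau_ltd, alpha_ltp = alpha_ltp,
                 ltd_scale = ltd_scale,
                 truncation_window = truncation_window),
            class = "pfpc_rule_config")
}

#' MF-DCN plasticity rule configuration
#'
#' @param sigma Window-time width of the symmetric kernel (s).
#' @param beta Damping of the kernel side lobes (dimensionless).
#' @param alpha_ltp Fixed potentiation per mossy-fiber spike (nS).
#' @param ltd_scale Depression per unit kernel value per Purkinje spike (nS).
#' @param w_max Saturation bound on the conductance (nS): fixed LTP cannot
#'   push a synapse above it.  Purkinje-driven LTD cannot act on synapses
#'   whose generator states fall in fully-silenced Purkinje epochs, so an
#'   explicit ceiling is what bounds those weights.
#' @param truncation_window Two-sided window extent (s).
#' @return List of class `mfdcn_rule_config`.
#' @export
mfdcn_rule_config <- function(sigma = 0.02, beta = 2,
                              alpha_ltp = 0.01,
                              ltd_scale = 2.5e-3,
                              w_max = 30,
                              truncation_window = 0.1) {
  stopifnot(sigma > 0, beta > 0, alpha_ltp >= 0, ltd_scale >= 0, w_max > 0)
  structure(list(sigma = sigma, beta = beta, alpha_ltp = alpha_ltp,
                 ltd_scale = ltd_scale, w_max = w_max,
                 truncation_window = truncation_window),
            class = "mfdcn_rule_config")
}

#' PC-DCN inhibitory STDP configuration
#'
#' Two alternative kernels act at the Purkinje-to-nuclei synapse: the
#' classical Hebbian exponential pair (`tau1` potentiation for pre-before-
#' post, `tau2` depression for post-before-pre) and the symmetric
#' coincidence rule (every presynaptic spike depresses by `ltd_max`;
#' near-coincident pairs potentiate up to `ltp_max`).  `ltp_max > ltd_max`
#' so exact coincidence potentiates.
#'
#' @param kernel_choice `"hebbian"` or `"symmetric"`.
#' @param tau1,tau2 Hebbian time constants (s).
#' @param sigma Symmetric-kernel width (s).
#' @param ltp_max,ltd_max Symmetric-rule bounds (weight units per event).
#' @param scale Hebbian weight change per unit kernel (weight units).
#' @param w_max Saturation bound on the inhibitory conductance (nS),
#'   shared by both kernels so that shape comparisons are at matched
#'   weight range.
#' @param pre_decay Constant depression per presynaptic spike for the
#'   Hebbian kernel (weight units); implements the requirement that
#'   inhibitory synapses decay in the absence of postsynaptic firing (the
#'   symmetric kernel has this built in through `ltd_max`).
#' @param truncation_window Pairing window (s).
#' @return List of class `pcdcn_rule_config`.
#' @export
pcdcn_rule_config <- function(kernel_choice = c("hebbian", "symmetric"),
                              tau1 = 0.05, tau2 = 0.02, sigma = 0.02,
                              ltp_max = 0.01, ltd_max = 3.5e-4,
                              scale = 0.02,
                              pre_decay = 8e-4,
                              w_max = 12,
                              truncation_window = 0.1) {
  kernel_choice <- match.arg(kernel_choice)
  stopifnot(tau1 > 0, tau2 > 0, sigma > 0, ltp_max > ltd_max, ltd_max > 0,
            scale >= 0, pre_decay >= 0)
  structure(list(kernel_choice = kernel_choice, tau1 = tau1, tau2 = tau2,
                 sigma = sigma, ltp_max = ltp_max, ltd_max = ltd_max,
                 scale = scale, pre_decay = pre_decay, w_max = w_max,
                 truncation_window = truncation_window),
            class = "pcdcn_rule_config")
}

#' Spike-train decoder configuration
#'
#' Exponentially-decaying one-tap recursive filter turning deep-nuclei spike
#' counts into an analog signal: `y[n] = exp(-1/tau) * y[n-1] + gain * c[n]`.
#'
#' @param tau_taps Decay constant in units of taps (one tap per simulation
#'   step); the default 15 taps is 30 ms at the 2 ms step.
#' @param gain Output units contributed per spike.
#' @param n_channels Number of decoded channels.
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(tau_taps = 15, gain = 0.28, n_channels = 1) {
  stopifnot(tau_taps > 0, n_channels >= 1)
  structure(list(tau_taps = tau_taps, gain = gain, n_channels = n_channels,
                 decay = exp(-1 / tau_taps)),
            class = "decoder_config")
}

#' Match the effective learning rates of the two inhibitory kernels
#'
#' Kernel-shape comparisons are only meaningful at matched learning rates:
#' this scales the symmetric rule's `ltp_max`/`ltd_max` so that both rules
#' produce the same mean absolute weight change per presynaptic spike on a
#' seeded Poisson calibration train.
#'
#' @param hebbian,symmetric [pcdcn_rule_config()] objects.
#' @param pre_rate,post_rate Calibration train rates, Hz.
#' @param duration Calibration duration, s.
#' @param seed Seed for the calibration trains.
#' @return The symmetric configuration with rescaled bounds; the scaling
#'   factor is attached as attribute `rate_factor`.
#' @export
match_istdp_rates <- function(hebbian = pcdcn_rule_config("hebbian"),
                              symmetric = pcdcn_rule_config("symmetric"),
                              pre_rate = 70, post_rate = 60,
                              duration = 20, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pre <- cumsum(stats::rexp(pre_rate * duration * 2, pre_rate))
  post <- cumsum(stats::rexp(post_rate * duration * 2, post_rate))
  pre <- pre[pre <= duration]; post <- post[post <= duration]
  # mean |dW| per presynaptic spike, rule by rule
  rate_of <- function(cfg) {
    tot <- abs_pcdcn_change(pre, post, cfg)
    tot / length(pre)
  }
  f <- rate_of(hebbian) / rate_of(symmetric)
  symmetric$ltp_max <- symmetric$ltp_max * f
  symmetric$ltd_max <- symmetric$ltd_max * f
  attr(symmetric, "rate_factor") <- f
  symmetric
}

# total |dW| accumulated event by event (magnitudes, not the signed sum)
abs_pcdcn_change <- function(pre_times, post_times, config) {
  W <- config$truncation_window
  tot <- 0
  if (config$kernel_choice == "symmetric") {
    for (tp in pre_times) {
      d <- post_times - tp
      u <- d[abs(d) <= W] / config$sigma
      tot <- tot + abs(-config$ltd_max +
                         sum(config$ltp_max * exp(-abs(u)) * cos(u)^2))
    }
    return(tot)
  }
  for (tpost in post_times) {
    prev <- pre_times[pre_times <= tpost]
    if (length(prev) && tpost - max(prev) <= W)
      tot <- tot + config$scale * exp(-(tpost - max(prev)) / config$tau1)
  }
  for (tpre in pre_times) {
    tot <- tot + config$pre_decay
    prev <- post_times[post_times < tpre]
    if (length(prev) && tpre - max(prev) <= W)
      tot <- tot + config$scale * exp(-(tpre - max(prev)) / config$tau2)
  }
  tot
}
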