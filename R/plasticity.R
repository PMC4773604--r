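#' Eligibility-trace LTD at PF-PC synapses on a climbing-fiber spike
#'
#' When a teaching spike arrives at time `t_cf`, each parallel-fiber synapse
#' of the target Purkinje cell is depressed by the kernel-weighted sum of
#' its buffered presynaptic spikes:
#' `dW_j = -ltd_scale * sum_k k((t_cf - t_k) / tau_ltd)` over buffered
#' spikes inside the truncation window.  Simultaneous parallel-fiber
#' activity contributes nothing (`k(0) = 0`); spikes one calibrated delay
#' earlier are depressed maximally.
#'
#' @param pf_spike_times List of numeric vectors: past spike times (s) per
#'   parallel fiber (the eligibility buffers).
#' @param t_cf Teaching-spike time (s); buffer entries after `t_cf` are an
#'   error.
#' @param config A [pfpc_rule_config()].
#' @return Numeric vector of non-positive weight changes, one per fiber.
#' @export
pfpc_on_cf_spike <- function(pf_spike_times, t_cf,
                             config = pfpc_rule_config()) {
  vapply(pf_spike_times, function(ts) {
    if (length(ts) == 0) return(0)
    if (any(ts > t_cf)) stop("eligibility buffer contains future spikes")
    lag <- t_cf - ts
    lag <- lag[lag <= config$truncation_window]
    -config$ltd_scale * sum(pfpc_ltd_kernel(lag / config$tau_ltd))
  }, numeric(1))
}

#' Fixed LTP at PF-PC synapses on each parallel-fiber spike
#'
#' @param config A [pfpc_rule_config()].
#' @param n_spikes Number of presynaptic spikes.
#' @return `+alpha_ltp * n_spikes`.
#' @export
pfpc_on_pf_spike <- function(config = pfpc_rule_config(), n_spikes = 1) {
  config$alpha_ltp * n_spikes
}

#' LTD at MF-DCN synapses when a Purkinje spike reaches the nuclei
#'
#' Depression of each mossy-fiber synapse by the symmetric kernel over the
#' mossy spikes already in the buffer (at or before `t_pc`); mossy spikes
#' arriving after the Purkinje spike are handled by
#' [mfdcn_on_mf_spike_ltd()], and kernel symmetry makes the two views add
#' up to the full two-sided window.
#'
#' @param mf_spike_times List of numeric vectors: buffered spike times per
#'   mossy fiber.
#' @param t_pc Purkinje-spike arrival time (s).
#' @param config An [mfdcn_rule_config()].
#' @return Non-positive weight change per mossy fiber.
#' @export
mfdcn_on_pc_spike <- function(mf_spike_times, t_pc,
                              config = mfdcn_rule_config()) {
  vapply(mf_spike_times, function(ts) {
    d <- t_pc - ts[ts <= t_pc & t_pc - ts <= config$truncation_window]
    if (length(d) == 0) return(0)
    -config$ltd_scale * sum(mfdcn_kernel(d / config$sigma, config$beta))
  }, numeric(1))
}

#' Deferred LTD at one MF-DCN synapse on a later mossy-fiber spike
#'
#' @param pc_spike_times Recent Purkinje spike times (s) strictly before
#'   `t_mf`.
#' @param t_mf Mossy-spike time (s).
#' @param config An [mfdcn_rule_config()].
#' @return Non-positive scalar weight change.
#' @export
mfdcn_on_mf_spike_ltd <- function(pc_spike_times, t_mf,
                                  config = mfdcn_rule_config()) {
  d <- t_mf - pc_spike_times
  d <- d[d > 0 & d <= config$truncation_window]
  if (length(d) == 0) return(0)
  -config$ltd_scale * sum(mfdcn_kernel(d / config$sigma, config$beta))
}

#' Fixed LTP at MF-DCN synapses on each mossy-fiber spike
#'
#' The constant potentiation that counteracts Purkinje-driven depression
#' and prevents weight saturation at zero.
#'
#' @param config An [mfdcn_rule_config()].
#' @param n_spikes Number of presynaptic spikes.
#' @return `+alpha_ltp * n_spikes`.
#' @export
mfdcn_on_mf_spike <- function(config = mfdcn_rule_config(), n_spikes = 1) {
  config$alpha_ltp * n_spikes
}

#' Apply inhibitory STDP to one PC-DCN spike-train pair
#'
#' Sequence-level semantics of the two inhibitory rules, matching the
#' per-event processing of the simulation engine:
#'
#' * `hebbian`: nearest-neighbour pairing.  Each postsynaptic spike
#'   potentiates against the most recent presynaptic spike
#'   (`+scale * exp(-dt/tau1)`); each presynaptic spike depresses against
#'   the most recent postsynaptic spike (`-scale * exp(-dt/tau2)`) unless a
#'   postsynaptic spike is exactly coincident (tie-break: potentiation
#'   only), and additionally pays the constant `pre_decay` so inhibition
#'   decays when the postsynaptic cell is silent.  Pairs farther apart
#'   than the truncation window are ignored.
#' * `symmetric`: every presynaptic spike contributes `-ltd_max` plus
#'   `ltp_max * exp(-|u|) cos(u)^2` for every postsynaptic spike within the
#'   window (`u = dt/sigma`), both past and future.
#'
#' @param pre_times,post_times Spike times (s) of the Purkinje (pre) and
#'   nuclei (post) cell.
#' @param config A [pcdcn_rule_config()].
#' @return Total weight change (positive = stronger inhibition).
#' @export
apply_pcdcn_stdp <- function(pre_times, post_times,
                             config = pcdcn_rule_config()) {
  W <- config$truncation_window
  if (config$kernel_choice == "symmetric") {
    dw <- -config$ltd_max * length(pre_times)
    for (tp in pre_times) {
      d <- post_times - tp
      dw <- dw + sum(config$ltp_max *
                       mfdcn_kernel((d[abs(d) <= W]) / config$sigma, 1))
    }
    return(dw)
  }
  # hebbian, processed in event order
  dw <- -config$pre_decay * length(pre_times)
  for (tpost in post_times) {
    prev <- pre_times[pre_times <= tpost]
    if (length(prev)) {
      d <- tpost - max(prev)
      if (d <= W) dw <- dw + config$scale * exp(-d / config$tau1)
    }
  }
  for (tpre in pre_times) {
    if (any(post_times == tpre)) next  # coincident pair: potentiation only
    prev <- post_times[post_times < tpre]
    if (length(prev)) {
      d <- tpre - max(prev)
      if (d <= W) dw <- dw - config$scale * exp(-d / config$tau2)
    }
  }
  dw
}
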