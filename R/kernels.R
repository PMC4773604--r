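#' Parallel fiber-Purkinje cell LTD eligibility kernel
#'
#' The kernel `k(x) = exp(-x) * sin(x)^20` weighting past parallel-fiber
#' activity when a climbing-fiber (teaching) spike arrives.  Its sharp main
#' lobe, peaking at `x* = arctan(20)`, implements an eligibility trace that
#' singles out parallel-fiber spikes arriving roughly one sensorimotor delay
#' before the teaching spike; the second local maximum is below 5% of the
#' main peak and is truncated away in practice.
#'
#' @param x Dimensionless non-negative argument (elapsed time over
#'   `tau_LTD`).
#' @return Kernel values, same length as `x`.  `k(0) = 0`.
#' @seealso [calibrate_tau_ltd()] to map a target delay to `tau_LTD`.
#' @export
#' @examples
#' pfpc_ltd_kernel(atan(20))  # main peak
pfpc_ltd_kernel <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  exp(-x) * sin(x)^20
}

#' Mossy fiber-deep nuclei LTD kernel
#'
#' Symmetric kernel `k(x) = exp(-|x * beta|) * cos(x)^2` weighting mossy
#' fiber spikes that arrive before or after a Purkinje spike reaches the
#' target deep-nuclei cell.  `beta` damps the secondary lobes at
#' `|x| >= pi`.
#'
#' @param x Dimensionless argument (time offset over `sigma`), any sign.
#' @param beta Positive damping constant.
#' @return Kernel values; `k(0) = 1`, even in `x`.
#' @export
mfdcn_kernel <- function(x, beta = 2) {
  stopifnot(is.numeric(x), beta > 0)
  exp(-abs(x * beta)) * cos(x)^2
}

#' Calibrate the LTD time constant from a target sensorimotor delay
#'
#' The eligibility kernel [pfpc_ltd_kernel()] peaks at `x* = arctan(20)`
#' (where `d/dx [exp(-x) sin(x)^20] = 0`, i.e. `tan(x) = 20`).  Choosing
#' `tau_LTD = delay / x*` places maximal depression on parallel-fiber spikes
#' that preceded the teaching spike by exactly `delay` seconds.
#'
#' @param target_delay Sensorimotor delay to compensate, in seconds.
#' @return `tau_LTD` in seconds.
#' @export
#' @examples
#' calibrate_tau_ltd(0.1)  # ~0.0658 s
calibrate_tau_ltd <- function(target_delay) {
  stopifnot(target_delay > 0)
  target_delay / atan(20)
}

#' Side-lobe ratio of the PF-PC eligibility kernel
#'
#' Dense-grid maximization of [pfpc_ltd_kernel()]: locates the global
#' maximum and the next local maximum and returns their positions, values,
#' and the secondary-to-main ratio (in percent).
#'
#' @param upper Upper end of the search interval (the kernel is negligible
#'   beyond `x = 10`).
#' @param step Grid resolution.
#' @return List with `x_main`, `peak_main`, `x_secondary`, `peak_secondary`,
#'   `ratio_pct`.
#' @export
pfpc_kernel_sidelobe <- function(upper = 10, step = 1e-4) {
  x <- seq(0, upper, by = step)
  k <- pfpc_ltd_kernel(x)
  n <- length(k)
  loc <- which(k > c(-Inf, k[-n]) & k > c(k[-1], -Inf))
  loc <- loc[order(k[loc], decreasing = TRUE)]
  if (length(loc) < 2) stop("fewer than two local maxima found")
  list(x_main = x[loc[1]], peak_main = k[loc[1]],
       x_secondary = x[loc[2]], peak_secondary = k[loc[2]],
       ratio_pct = 100 * k[loc[2]] / k[loc[1]])
}

#' Hebbian inhibitory STDP weight change
#'
#' Classical asymmetric-exponential rule for the Purkinje-to-deep-nuclei
#' inhibitory synapse: a presynaptic (Purkinje) spike followed by a
#' postsynaptic (nuclei) spike potentiates the inhibitory weight with time
#' constant `tau1`; the reverse order depresses it with `tau2`.  Exact
#' coincidence is treated as potentiation, consistent with the
#' coincidence-potentiating symmetric rule.
#'
#' @param delta_t `t_post - t_pre` in seconds (vectorized, any sign).
#' @param config A [pcdcn_rule_config()].
#' @return Weight changes (same units as `scale`), positive = potentiation
#'   of the inhibitory weight.
#' @export
pcdcn_hebbian <- function(delta_t, config = pcdcn_rule_config()) {
  ifelse(delta_t >= 0,
         config$scale * exp(-delta_t / config$tau1),
         -config$scale * exp(delta_t / config$tau2))
}

#' Symmetric inhibitory STDP weight change for one presynaptic spike
#'
#' Every presynaptic (Purkinje) spike depresses the inhibitory weight by
#' `LTD_max`; near-coincident postsynaptic (deep-nuclei) spikes add
#' potentiation `LTP_max * exp(-|u|) * cos(u)^2` with `u = delta_t / sigma`.
#'
#' @param delta_t Offsets `t_post - t_pre` (seconds) of the postsynaptic
#'   spikes falling inside the rule's window around this presynaptic spike;
#'   may be empty (isolated presynaptic spike).
#' @param config A [pcdcn_rule_config()].
#' @return Scalar weight change: `-LTD_max + sum(LTP terms)`.
#' @export
pcdcn_symmetric <- function(delta_t, config = pcdcn_rule_config()) {
  u <- delta_t / config$sigma
  -config$ltd_max + sum(config$ltp_max * exp(-abs(u)) * cos(u)^2)
}
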