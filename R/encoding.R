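#' Build a state schedule for a spike-coding population
#'
#' Partitions `n_cells` into disjoint groups of `cells_per_state` that are
#' activated in fixed order, tiling the trial: with 2000 granule cells and a
#' 2 ms step, 500 states of one step each cover a 1 s trial; with 100 mossy
#' fibers, 25 states of 20 consecutive steps each.  The sequence restarts at
#' each trial onset.
#'
#' @param n_cells Population size; must be divisible by `cells_per_state`.
#' @param cells_per_state Cells active per state (4 in the reference setup).
#' @param trial_duration Trial length, seconds.
#' @param dt Simulation step, seconds; `trial_duration/dt` must be divisible
#'   by the number of states.
#' @return List of class `state_schedule`: `n_states`, `steps_per_state`,
#'   `step_duration` (s), and `assignment` (a `cells_per_state x n_states`
#'   matrix of 1-based cell ids).
#' @export
#' @examples
#' build_state_schedule(2000, 4, 1, 0.002)$n_states  # 500
#' build_state_schedule(100, 4, 1, 0.002)$n_states   # 25
build_state_schedule <- function(n_cells, cells_per_state = 4,
                                 trial_duration = 1, dt = 0.002) {
  if (n_cells %% cells_per_state != 0)
    stop("n_cells must be divisible by cells_per_state")
  n_states <- n_cells %/% cells_per_state
  n_steps <- round(trial_duration / dt)
  if (n_steps %% n_states != 0)
    stop("trial steps (", n_steps, ") not divisible by n_states (",
         n_states, ")")
  structure(list(n_cells = n_cells, cells_per_state = cells_per_state,
                 n_states = n_states, steps_per_state = n_steps / n_states,
                 n_steps = n_steps, dt = dt,
                 trial_duration = trial_duration,
                 step_duration = trial_duration / n_states,
                 assignment = matrix(seq_len(n_cells), nrow = cells_per_state)),
            class = "state_schedule")
}

#' Active state index at a trial time
#' @param schedule A [build_state_schedule()] object.
#' @param trial_time Time since trial onset, seconds.
#' @return 1-based state index.
#' @export
state_at <- function(schedule, trial_time) {
  step <- floor(trial_time / schedule$dt)
  as.integer(step %/% schedule$steps_per_state) + 1L
}

#' Emit state-generator spikes for one step
#'
#' In `"gc"` mode each of the `cells_per_state` cells of the current state
#' emits exactly one spike per step.  In `"mf"` mode the currently active
#' group fires a deterministic comb at `rate` Hz during its window (one
#' spike every `1/(rate*dt)` steps) and all cells are silent between trials.
#'
#' @param schedule A [build_state_schedule()].
#' @param trial_time Seconds since trial onset; times at or beyond the trial
#'   end yield no spikes (the generator is silent between trials).  Negative
#'   times are an error.
#' @param mode `"gc"` or `"mf"`.
#' @param rate Within-window firing rate for `"mf"` mode, Hz.
#' @return Integer vector of spiking cell ids (possibly empty).
#' @export
emit_state_spikes <- function(schedule, trial_time, mode = c("gc", "mf"),
                              rate = 100) {
  mode <- match.arg(mode)
  if (any(trial_time < 0)) stop("trial_time must be >= 0")
  if (trial_time >= schedule$trial_duration) return(integer(0))
  st <- state_at(schedule, trial_time)
  cells <- schedule$assignment[, st]
  if (mode == "gc") return(cells)
  comb <- round(1 / (rate * schedule$dt))
  step <- floor(trial_time / schedule$dt)
  if (step %% comb == 0) cells else integer(0)
}

#' Probabilistic climbing-fiber encoding of a normalized error
#'
#' A climbing fiber fires when the normalized error exceeds a fresh uniform
#' variate; the per-step firing probability is scaled to
#' `epsilon * r_max * dt` so that sustained full error saturates at `r_max`
#' spikes per second per fiber (10 Hz in the reference setup).
#'
#' @param epsilon Normalized error in \[0, 1\] (vectorized over steps).
#' @param dt Step length, seconds.
#' @param r_max Rate cap, Hz.
#' @param u Optional uniform variates (same length as `epsilon`); drawn from
#'   the session RNG when omitted.
#' @return Logical vector: spike emitted per step.
#' @export
encode_error <- function(epsilon, dt = 0.002, r_max = 10, u = NULL) {
  if (any(epsilon < 0 | epsilon > 1)) stop("epsilon must lie in [0, 1]")
  stopifnot(r_max > 0, dt > 0)
  if (is.null(u)) u <- runif(length(epsilon))
  u < epsilon * r_max * dt
}

#' Decode spike counts into an analog signal
#'
#' One-tap recursive exponential filter:
#' `y[n] = exp(-1/tau_taps) * y[n-1] + gain * count[n]`, equivalent to
#' convolution with `h(k) = gain * exp(-k/tau_taps)`.
#'
#' @param counts Non-negative spike counts per step (vector or
#'   steps-by-channels matrix).
#' @param config A [decoder_config()].
#' @return Decoded signal, same shape as `counts`.
#' @export
decode_spikes <- function(counts, config = decoder_config()) {
  if (any(counts < 0)) stop("spike counts must be >= 0")
  dec <- function(x) as.numeric(stats::filter(config$gain * x,
                                              config$decay,
                                              method = "recursive"))
  if (is.matrix(counts)) apply(counts, 2, dec) else dec(counts)
}

#' Split a signed error into positive/negative normalized channels
#'
#' Positive and negative raw error route to disjoint climbing-fiber
#' channels: `eps_pos = clip(raw/normalization, 0, 1)` and
#' `eps_neg = clip(-raw/normalization, 0, 1)`; at most one is nonzero.
#'
#' @param raw_error Signed error (vectorized).
#' @param normalization Positive scale (raw-error units mapping to
#'   `epsilon = 1`).
#' @return List with `eps_pos` and `eps_neg`.
#' @export
split_error <- function(raw_error, normalization = 1) {
  stopifnot(normalization > 0)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  list(eps_pos = clip01(raw_error / normalization),
       eps_neg = clip01(-raw_error / normalization))
}

#' Combine agonist/antagonist decoded channels
#'
#' The deep nuclei pair acts as an adder/subtractor: the corrective output
#' is the positive channel minus the negative channel.
#'
#' @param y_pos,y_neg Decoded channel signals of equal length.
#' @return `y_pos - y_neg`.
#' @export
combine_channels <- function(y_pos, y_neg) {
  if (length(y_pos) != length(y_neg)) stop("channel length mismatch")
  y_pos - y_neg
}
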