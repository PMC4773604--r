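#' Create a fresh population state
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] object (membrane starts at rest).
#' @return List of class `population_state` with `membrane_potential` (mV),
#'   `g_exc`, `g_inh` (nS), `refractory_until` (ms, absolute) and `t_ms`
#'   (current absolute time, ms).
#' @export
population_state <- function(n, params) {
  structure(list(membrane_potential = rep(params$resting_potential, n),
                 g_exc = rep(0, n), g_inh = rep(0, n),
                 refractory_until = rep(-Inf, n), t_ms = 0),
            class = "population_state")
}

#' Advance a LIF population by simulation steps
#'
#' Conductance increments from incoming spikes are applied at step onset,
#' conductances then decay exponentially while the membrane is integrated
#' with forward-Euler substeps.  Neurons crossing threshold emit a spike,
#' are reset, and are clamped for the refractory period.
#'
#' @param state A [population_state()].
#' @param params A [lif_params()].
#' @param dt Step length in seconds.
#' @param exc_weights,inh_weights Summed synaptic weights (nS) of the
#'   excitatory / inhibitory spikes delivered to each neuron this step;
#'   either a vector (one step) or an `n_steps x n` matrix.
#' @param n_substeps Integration substeps per step.
#' @return List with the updated `state` and an integer `spikes` matrix
#'   (`n_steps x n`) of per-step spike counts.
#' @export
step_population <- function(state, params, dt, exc_weights = NULL,
                            inh_weights = NULL, n_substeps = 10) {
  stopifnot(inherits(state, "population_state"), dt > 0)
  n <- length(state$membrane_potential)
  to_mat <- function(w, n_steps = 1) {
    if (is.null(w)) return(matrix(0, n_steps, n))
    if (is.matrix(w)) w else matrix(w, 1, n, byrow = TRUE)
  }
  exc <- to_mat(exc_weights)
  inh <- to_mat(inh_weights, nrow(exc))
  if (nrow(inh) != nrow(exc)) stop("exc/inh step counts differ")
  if (any(exc < 0) || any(inh < 0)) stop("synaptic weights must be >= 0")
  out <- cpp_lif_run(state$membrane_potential, state$g_exc, state$g_inh,
                     state$refractory_until, as_param_vector(params),
                     state$t_ms, dt * 1000, as.integer(n_substeps), exc, inh)
  new_state <- structure(list(membrane_potential = out$V,
                              g_exc = out$g_exc, g_inh = out$g_inh,
                              refractory_until = out$refractory_until,
                              t_ms = state$t_ms + nrow(exc) * dt * 1000),
                         class = "population_state")
  list(state = new_state, spikes = out$spikes)
}

#' Advance a generic network by one step
#'
#' Synchronous update of all populations of a [build_network()] topology:
#' spikes emitted at the previous step are routed through the projection
#' tables (with a one-step synaptic delay) and delivered as conductance
#' increments, then every population is stepped.
#'
#' This generic router exists for small-scale verification; the closed-loop
#' experiments use the fused compiled engine.
#'
#' @param net A network with `populations` (name -> list(size, params)) and
#'   `projections` (list with `pre`, `post`, `type` ("exc"/"inh") and a
#'   synapse data frame `pre_id`, `post_id`, `weight`).
#' @param state List: per-population [population_state()] in `pops` and
#'   `pending` spike-count vectors (spikes emitted last step).
#' @param external Named list of extra spike-count vectors delivered to
#'   populations this step (sources outside the network).
#' @param dt Step length, seconds.
#' @return Updated `state`; `state$pending` holds this step's emissions.
#' @export
run_network_step <- function(net, state, external = list(), dt = 0.002) {
  pops <- names(net$populations)
  exc <- inh <- lapply(net$populations, function(p) rep(0, p$size))
  deliver <- function(tbl, counts, acc) {
    src <- counts[tbl$pre_id]
    act <- src > 0
    if (any(act)) {
      add <- tapply(tbl$weight[act] * src[act], tbl$post_id[act], sum)
      acc[as.integer(names(add))] <- acc[as.integer(names(add))] + add
    }
    acc
  }
  for (pr in net$projections) {
    if (!pr$pre %in% pops || !pr$post %in% pops)
      stop("projection references unknown population: ", pr$pre, "->", pr$post)
    if (max(pr$synapses$post_id) > net$populations[[pr$post]]$size)
      stop("dangling projection index in ", pr$pre, "->", pr$post)
    counts <- state$pending[[pr$pre]]
    if (is.null(counts) || !any(counts > 0)) next
    if (pr$type == "exc") {
      exc[[pr$post]] <- deliver(pr$synapses, counts, exc[[pr$post]])
    } else {
      inh[[pr$post]] <- deliver(pr$synapses, counts, inh[[pr$post]])
    }
  }
  for (nm in names(external)) {
    exc[[nm]] <- exc[[nm]] + external[[nm]]
  }
  pending <- list()
  for (nm in pops) {
    res <- step_population(state$pops[[nm]], net$populations[[nm]]$params,
                           dt, exc[[nm]], inh[[nm]])
    state$pops[[nm]] <- res$state
    pending[[nm]] <- as.vector(res$spikes)
  }
  state$pending <- pending
  state
}

#' Initialize state for [run_network_step()]
#' @param net A network topology.
#' @return A state list with fresh population states and empty pending spikes.
#' @export
network_state <- function(net) {
  pops <- lapply(net$populations, function(p) population_state(p$size, p$params))
  pending <- lapply(net$populations, function(p) rep(0L, p$size))
  list(pops = pops, pending = pending)
}
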