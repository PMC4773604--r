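# Brute-force oracles kept deliberately naive: straight double loops over
# spike pairs, independent of the package's buffered/event-driven paths.

oracle_pfpc_ltd <- function(pf_times, cf_times, tau_ltd, ltd_scale) {
  total <- 0
  for (tc in cf_times) {
    for (tp in pf_times) {
      if (tp <= tc) total <- total - ltd_scale * exp(-(tc - tp) / tau_ltd) *
          sin((tc - tp) / tau_ltd)^20
    }
  }
  total
}

oracle_mfdcn_ltd <- function(mf_times, pc_times, sigma, beta, ltd_scale,
                             window) {
  total <- 0
  for (tp in pc_times) {
    for (tm in mf_times) {
      d <- tm - tp
      if (abs(d) <= window)
        total <- total - ltd_scale * exp(-abs(d * beta / sigma)) *
          cos(d / sigma)^2
    }
  }
  total
}

oracle_pcdcn_symmetric <- function(pre_times, post_times, cfg) {
  total <- -cfg$ltd_max * length(pre_times)
  for (tp in pre_times) {
    for (tq in post_times) {
      d <- (tq - tp) / cfg$sigma
      if (abs(tq - tp) <= cfg$truncation_window)
        total <- total + cfg$ltp_max * exp(-abs(d)) * cos(d)^2
    }
  }
  total
}

# Poisson spike train on [0, duration)
poisson_train <- function(rate, duration) {
  t <- cumsum(rexp(ceiling(rate * duration * 3) + 10, rate))
  t[t < duration]
}

# runs shared between acceptance blocks (computed once, lazily)
.shared <- new.env()

shared_gain_runs <- function() {
  if (is.null(.shared$gain_runs)) {
    .shared$gain_runs <- lapply(c("zero", "random", "high"), function(m) {
      net <- build_network(case_config("A", pcdcn_init_mode = m), seed = 1)
      run_case_a(n_trials = 2500, seed = 1, net = net)
    })
    names(.shared$gain_runs) <- c("zero", "random", "high")
  }
  .shared$gain_runs
}
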