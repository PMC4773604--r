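#' Per-state weight profile of a plastic projection
#'
#' For state-coded projections the profile is the mean synaptic weight per
#' generator state: for GC-PC, the mean over the 4 granule cells of each of
#' the 500 states and over the 10 Purkinje cells of one microcomplex; for
#' MF-DCN, the mean over the 4 mossy fibers of each of the 25 states onto
#' one nuclei cell.  For PC-DCN the profile is indexed by presynaptic cell.
#'
#' @param net A network (typically `run$net` after learning).
#' @param projection `"pfpc"`, `"mfdcn"` or `"pcdcn"`.
#' @param complex 0-based microcomplex index.
#' @param schedule The matching [build_state_schedule()]; defaults to the
#'   canonical 1 s / 2 ms schedules.
#' @return Numeric profile vector (length = number of states, or number of
#'   Purkinje cells for `"pcdcn"`).
#' @export
weight_profile <- function(net, projection = c("pfpc", "mfdcn", "pcdcn"),
                           complex = 0, schedule = NULL) {
  projection <- match.arg(projection)
  if (projection == "pcdcn") {
    idx <- (complex * 10 + 1):(complex * 10 + 10)
    return(net$w_pcdcn[idx])
  }
  if (projection == "pfpc") {
    if (is.null(schedule))
      schedule <- build_state_schedule(net$config$n_gc, 4, 1, 0.002)
    w <- net$w_pfpc[, (complex * 10 + 1):(complex * 10 + 10), drop = FALSE]
    per_gc <- rowMeans(w)
  } else {
    if (is.null(schedule))
      schedule <- build_state_schedule(net$config$n_mf, 4, 1, 0.002)
    per_gc <- net$w_mfdcn[, complex + 1]
  }
  apply(schedule$assignment, 2, function(cells) mean(per_gc[cells]))
}

#' Counter-phase transfer score between PF-PC and MF-DCN profiles
#'
#' Learning consolidation transfers the weight pattern stored at PF-PC
#' synapses to the MF-DCN synapses in counter phase.  The score bins the
#' 500-state PF-PC profile down to the 25 mossy states (block means of 20)
#' and returns the Pearson correlation with the MF-DCN profile: successful
#' consolidation gives a clearly negative score.
#'
#' @param pfpc_profile Length-500 PF-PC profile (see [weight_profile()]).
#' @param mfdcn_profile Length-25 MF-DCN profile.
#' @return Correlation in \[-1, 1\], or `NA` (with a warning) if either
#'   profile has zero variance.
#' @export
counter_phase_score <- function(pfpc_profile, mfdcn_profile) {
  k <- length(pfpc_profile) / length(mfdcn_profile)
  if (k != round(k)) stop("profile lengths are not nested")
  binned <- vapply(seq_along(mfdcn_profile), function(i)
    mean(pfpc_profile[((i - 1) * k + 1):(i * k)]), numeric(1))
  if (stats::sd(binned) == 0 || stats::sd(mfdcn_profile) == 0) {
    warning("zero-variance profile: counter-phase score undefined")
    return(NA_real_)
  }
  cor(binned, mfdcn_profile)
}

#' Reverse cross-correlation between Purkinje and nuclei spike trains
#'
#' Bins both trains, computes the Pearson correlation at each lag in
#' `[-max_lag, +max_lag]`, and summarizes anti-correlation as the maximum
#' over lags of minus the correlation (Purkinje cells inhibit the nuclei,
#' so effective coupling appears as anti-correlation).
#'
#' @param pc_train,dcn_train Spike time vectors (s) within a common window,
#'   or pre-binned count vectors when `binned = TRUE`.
#' @param bin Bin width, s.
#' @param max_lag Maximum lag, s.
#' @param window Common observation window `c(t0, t1)`; defaults to the
#'   span of the data.
#' @param binned Interpret the inputs as already-binned counts.
#' @return List of class `correlogram`: `lag` (s), `correlation`, and
#'   `summary` (max over lags of minus the correlation); `NA` summary (with
#'   a warning) for empty or constant trains.
#' @export
reverse_cross_correlation <- function(pc_train, dcn_train, bin = 0.01,
                                      max_lag = 0.1, window = NULL,
                                      binned = FALSE) {
  stopifnot(bin > 0)
  if (binned) {
    x <- pc_train; y <- dcn_train
  } else {
    if (length(pc_train) == 0 || length(dcn_train) == 0) {
      warning("empty spike train: correlogram undefined")
      return(structure(list(lag = numeric(0), correlation = numeric(0),
                            summary = NA_real_), class = "correlogram"))
    }
    if (is.null(window)) window <- range(c(pc_train, dcn_train))
    br <- seq(window[1], window[2] + bin, by = bin)
    x <- as.vector(table(cut(pc_train, br)))
    y <- as.vector(table(cut(dcn_train, br)))
  }
  L <- round(max_lag / bin)
  n <- length(x)
  lags <- (-L):L
  cors <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- x[seq_len(n - l)]; b <- y[seq_len(n - l) + l]
    } else {
      a <- x[seq_len(n + l) - l]; b <- y[seq_len(n + l)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  s <- if (all(is.na(cors))) NA_real_ else max(-cors, na.rm = TRUE)
  if (is.na(s)) warning("constant binned trains: correlogram undefined")
  structure(list(lag = lags * bin, correlation = cors, summary = s),
            class = "correlogram")
}

#' Averaged synaptic gain of a microcomplex
#'
#' Arithmetic mean of a microcomplex's weights at one trial: the "averaged
#' gain" tracked over learning for the nuclei afferents.
#'
#' @param net Network holding the weights.
#' @param projection `"mfdcn"` or `"pcdcn"` (or `"pfpc"`).
#' @param complex 0-based microcomplex index.
#' @return Mean weight (nS).
#' @export
averaged_gain <- function(net, projection = c("mfdcn", "pcdcn", "pfpc"),
                          complex = 0) {
  projection <- match.arg(projection)
  switch(projection,
         mfdcn = mean(net$w_mfdcn[, complex + 1]),
         pcdcn = mean(net$w_pcdcn[(complex * 10 + 1):(complex * 10 + 10)]),
         pfpc = mean(net$w_pfpc[, (complex * 10 + 1):(complex * 10 + 10)]))
}

#' Convergence trial of a metric series
#'
#' First trial at which the smoothed series (centered moving mean) enters
#' and never again leaves a band around its final plateau value.  The band
#' is `fraction` of the plateau magnitude, or -- for plateaus near zero --
#' `fraction` of the series' overall magnitude.
#'
#' @param series Per-trial metric (e.g. an averaged gain).
#' @param fraction Plateau band half-width (relative).
#' @param smooth_window Moving-mean window, trials.
#' @return 1-based trial index, or `NA` (not converged / tie-free plateau
#'   undefined for constant-zero series).
#' @export
convergence_trial <- function(series, fraction = 0.05, smooth_window = 50) {
  stopifnot(length(series) > 0, fraction > 0, fraction < 1)
  n <- length(series)
  w <- min(smooth_window, n)
  cs <- cumsum(c(0, series))
  lo <- pmax(0, seq_len(n) - w)
  hi <- pmin(n, seq_len(n) + w - 1)
  sm <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
  plateau <- mean(sm[max(1, n - w + 1):n])
  band <- fraction * max(abs(plateau), 0.05 * max(abs(sm), 1e-12))
  ok <- abs(sm - plateau) <= band
  # first index from which all later values stay inside the band
  stay <- rev(cumprod(rev(ok))) > 0
  if (!any(stay)) return(NA_integer_)
  which(stay)[1]
}

#' Error-reduction percentage
#'
#' `100 * (mean(baseline) - mean(final)) / mean(baseline)` over two windows
#' of a per-trial MAE series.
#'
#' @param mae_series Per-trial mean absolute error.
#' @param baseline_window,final_window Index vectors into the series.
#' @return Percentage in `(-Inf, 100]`; errors on a zero baseline.
#' @export
error_reduction_pct <- function(mae_series,
                                baseline_window = 1,
                                final_window = length(mae_series)) {
  b <- mean(mae_series[baseline_window])
  f <- mean(mae_series[final_window])
  if (b == 0) stop("zero baseline: error reduction undefined")
  100 * (b - f) / b
}

#' Two-timescale ordering of convergence
#'
#' Cortical learning (PF-PC) stabilizes before nuclear gain adaptation:
#' computes the [convergence_trial()] of the PF-PC mean-weight series and
#' of the MF-DCN and PC-DCN averaged-gain series, and checks the ordering
#' `t(PF-PC) < t(MF-DCN) <= t(PC-DCN)`.
#'
#' @param pfpc_series,mfdcn_series,pcdcn_series Per-trial series on a
#'   common trial axis.
#' @param ... Passed to [convergence_trial()].
#' @return List with the three convergence trials, `pass`, and `tie`.
#' @export
two_timescale_check <- function(pfpc_series, mfdcn_series, pcdcn_series,
                                ...) {
  t1 <- convergence_trial(pfpc_series, ...)
  t2 <- convergence_trial(mfdcn_series, ...)
  t3 <- convergence_trial(pcdcn_series, ...)
  tie <- isTRUE(t1 == t2) || isTRUE(t2 > t3)
  pass <- !any(is.na(c(t1, t2, t3))) && t1 < t2 && t2 <= t3
  list(pfpc = t1, mfdcn = t2, pcdcn = t3, pass = pass, tie = tie)
}
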