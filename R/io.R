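#' Write / read a spike raster
#'
#' Two-column tab-separated text (`time_s`, `neuron_id`) sorted by time,
#' with a comment header carrying a network hash and the seed.
#'
#' @param events Data frame with `time_s` and `neuron_id`.
#' @param path Output file.
#' @param network_hash,seed Recorded in the header.
#' @return `path` invisibly (`write`); the events with attributes
#'   `network_hash` / `seed` (`read`).
#' @export
write_raster <- function(events, path, network_hash = "", seed = NA) {
  stopifnot(all(c("time_s", "neuron_id") %in% names(events)),
            all(events$time_s >= 0))
  events <- events[order(events$time_s, events$neuron_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network=%s seed=%s", network_hash, seed), con)
  writeLines("time_s\tneuron_id", con)
  write.table(events, con, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 1)
  ev <- read.table(path, skip = 2, sep = "\t",
                   col.names = c("time_s", "neuron_id"))
  attr(ev, "network_hash") <- sub(".*network=(\\S+).*", "\\1", hdr)
  attr(ev, "seed") <- sub(".*seed=(\\S+).*", "\\1", hdr)
  ev
}

#' Convert a recorded raster matrix to a spike-event data frame
#'
#' @param raster Integer steps-by-neurons spike-count matrix (as returned
#'   in `run$final`).
#' @param dt Step length, s.
#' @return Data frame `time_s`, `neuron_id` (1-based).
#' @export
raster_to_events <- function(raster, dt = 0.002) {
  idx <- which(raster > 0, arr.ind = TRUE)
  n <- raster[idx]
  out <- data.frame(time_s = rep((idx[, 1] - 1) * dt, n),
                    neuron_id = rep(idx[, 2], n))
  out[order(out$time_s, out$neuron_id), ]
}

#' Write / read a per-trial log
#'
#' Plain CSV serialization of a run's `log` data frame.
#'
#' @param log The `log` element of a `cereb_run`.
#' @param path File path.
#' @export
write_trial_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) read.csv(path)

#' Dump STDP curves for visual inspection
#'
#' Tabulates each learning rule's weight change against the spike-time
#' offset, for plotting against the textbook kernel shapes.
#'
#' @param delta_t_ms Offsets (`t_post - t_pre`), ms.
#' @param pcdcn A [pcdcn_rule_config()].
#' @param pfpc A [pfpc_rule_config()].
#' @param mfdcn An [mfdcn_rule_config()].
#' @return Data frame `delta_t_ms`, `rule`, `delta_w` (long format).
#' @export
stdp_curves <- function(delta_t_ms = seq(-200, 200, by = 2),
                        pcdcn = pcdcn_rule_config(),
                        pfpc = pfpc_rule_config(),
                        mfdcn = mfdcn_rule_config()) {
  dts <- delta_t_ms / 1000
  pf <- numeric(length(dts))
  pos <- dts >= 0
  pf[pos] <- -pfpc$ltd_scale * pfpc_ltd_kernel(dts[pos] / pfpc$tau_ltd)
  mf <- -mfdcn$ltd_scale * mfdcn_kernel(dts / mfdcn$sigma, mfdcn$beta)
  hb <- pcdcn_hebbian(dts, pcdcn)
  sy <- vapply(dts, function(d) pcdcn_symmetric(d, pcdcn), numeric(1))
  rbind(data.frame(delta_t_ms = delta_t_ms, rule = "pfpc_ltd", delta_w = pf),
        data.frame(delta_t_ms = delta_t_ms, rule = "mfdcn_ltd", delta_w = mf),
        data.frame(delta_t_ms = delta_t_ms, rule = "pcdcn_hebbian",
                   delta_w = hb),
        data.frame(delta_t_ms = delta_t_ms, rule = "pcdcn_symmetric",
                   delta_w = sy))
}
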