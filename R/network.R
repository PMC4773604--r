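#' Case configuration for the two benchmark networks
#'
#' Case A: one microcomplex pair (20 Purkinje cells, 2 climbing fibers,
#' 2 deep-nuclei cells) correcting a scalar set-point error.  Case B: three
#' pairs (60/6/6) correcting the three operated joints of the simulated arm.
#' Both share 100 mossy fibers and 2000 granule cells.
#'
#' @param case `"A"` or `"B"`.
#' @param pfpc_init_weight Initial parallel fiber-Purkinje conductance (nS).
#' @param mfdcn_init_weight Initial mossy fiber-nuclei conductance (nS).
#' @param pcdcn_init_mode `"zero"`, `"random"`, `"fixed"` (pre-calculated
#'   uniform value for runs with frozen inhibitory weights) or `"high"`.
#' @param pcdcn_fixed_value Weight used by `"fixed"` mode (nS); the
#'   pre-calculated value for runs with frozen inhibitory weights (see
#'   [calibrate_pcdcn_fixed()]).
#' @param pcdcn_init_scale Reference scale `s` (nS) for the plastic-rule
#'   initial conditions: `"random"` draws uniform on \[0, 2s\] and
#'   `"high"` starts at `3s`; the default is the typical converged
#'   averaged gain under the Hebbian rule.
#' @return List of class `case_config`.
#' @export
case_config <- function(case = c("A", "B"),
                        pfpc_init_weight = 5,
                        mfdcn_init_weight = 0,
                        pcdcn_init_mode = c("zero", "random", "fixed", "high"),
                        pcdcn_fixed_value = 16.5,
                        pcdcn_init_scale = 11) {
  case <- match.arg(case)
  pcdcn_init_mode <- match.arg(pcdcn_init_mode)
  n_cf <- if (case == "A") 2L else 6L
  structure(list(case = case, n_mf = 100L, n_gc = 2000L,
                 n_pc = 10L * n_cf, n_cf = n_cf, n_dcn = n_cf,
                 mf_fan_in = 4L,
                 pfpc_init_weight = pfpc_init_weight,
                 mfdcn_init_weight = mfdcn_init_weight,
                 pcdcn_init_mode = pcdcn_init_mode,
                 pcdcn_fixed_value = pcdcn_fixed_value,
                 pcdcn_init_scale = pcdcn_init_scale),
            class = "case_config")
}

#' Build a cerebellar network topology
#'
#' Constructs populations, projections and microcomplex bookkeeping.
#' Granule cells each receive 4 distinct, randomly chosen mossy fibers
#' (seeded); every granule cell contacts every Purkinje cell; every mossy
#' fiber contacts every deep-nuclei cell; each climbing fiber innervates its
#' 10-Purkinje group; each Purkinje cell inhibits exactly its
#' microcomplex's nuclei cell.  Weights are non-negative conductances; the
#' inhibitory sign is a property of the projection.
#'
#' @param config A [case_config()].
#' @param seed Integer seed for the randomized mossy fiber-granule wiring
#'   and the `"random"` inhibitory initialization.
#' @param pc_threshold_spread Total spread (mV) of the evenly-staggered
#'   per-cell threshold offsets that desynchronize the 10 Purkinje cells of
#'   a microcomplex (they would otherwise be identical); 0 disables.
#' @return Object of class `cereb_network` holding weight matrices
#'   (`w_pfpc`: granule x Purkinje; `w_mfdcn`: mossy x nuclei; `w_pcdcn`:
#'   per-Purkinje weight onto its nuclei cell), the mossy-granule wiring,
#'   population/projection metadata and the microcomplex map.
#' @export
build_network <- function(config = case_config("A"), seed = 1L,
                          pc_threshold_spread = 1) {
  stopifnot(inherits(config, "case_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # each granule cell draws 4 distinct mossy afferents
  mf_wiring <- t(vapply(seq_len(config$n_gc),
                        function(i) sort(sample.int(config$n_mf,
                                                    config$mf_fan_in)),
                        integer(config$mf_fan_in)))
  w_pfpc <- matrix(config$pfpc_init_weight, config$n_gc, config$n_pc)
  w_mfdcn <- matrix(config$mfdcn_init_weight, config$n_mf, config$n_dcn)
  w_pcdcn <- switch(config$pcdcn_init_mode,
                    zero = rep(0, config$n_pc),
                    fixed = rep(config$pcdcn_fixed_value, config$n_pc),
                    high = rep(3 * config$pcdcn_init_scale, config$n_pc),
                    random = runif(config$n_pc, 0,
                                   2 * config$pcdcn_init_scale))
  complexes <- data.frame(
    index = seq_len(config$n_dcn) - 1L,
    sign = ifelse(seq_len(config$n_dcn) %% 2 == 1, "+", "-"),
    joint = (seq_len(config$n_dcn) - 1L) %/% 2L + 1L,
    cf = seq_len(config$n_cf),
    dcn = seq_len(config$n_dcn),
    pc_first = 10L * (seq_len(config$n_dcn) - 1L) + 1L,
    pc_last = 10L * seq_len(config$n_dcn))
  populations <- list(
    MF = list(size = config$n_mf, params = lif_params()),
    GC = list(size = config$n_gc, params = lif_params()),
    PC = list(size = config$n_pc, params = pc_lif_params()),
    CF = list(size = config$n_cf, params = lif_params()),
    DCN = list(size = config$n_dcn, params = dcn_lif_params()))
  # small per-cell threshold spread desynchronizes otherwise-identical
  # Purkinje cells within a group (they share afferents and updates)
  pc_vth_offset <- pc_threshold_spread *
    ((seq_len(config$n_pc) - 1) %% 10 - 4.5) / 10
  structure(list(config = config, seed = seed,
                 pc_vth_offset = pc_vth_offset,
                 populations = populations,
                 mf_wiring = mf_wiring,
                 w_pfpc = w_pfpc, w_mfdcn = w_mfdcn, w_pcdcn = w_pcdcn,
                 complexes = complexes),
            class = "cereb_network")
}

# save/restore the session RNG so builders do not perturb user streams
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Audit the synapse counts of a network
#'
#' @param net A [build_network()] result.
#' @return Named integer vector with entries `MF_GC`, `MF_DCN`, `CF_PC`,
#'   `GC_PC`, `PC_DCN`.
#' @export
synapse_counts <- function(net) {
  cfg <- net$config
  c(MF_GC = nrow(net$mf_wiring) * ncol(net$mf_wiring),
    MF_DCN = cfg$n_mf * cfg$n_dcn,
    CF_PC = cfg$n_pc,
    GC_PC = cfg$n_gc * cfg$n_pc,
    PC_DCN = cfg$n_pc)
}

#' Microcomplex membership of a neuron
#'
#' Maps a Purkinje, climbing-fiber, or deep-nuclei cell to its
#' microcomplex: index (0-based), corrective sign (`"+"` = agonist /
#' positive error, `"-"` = antagonist / negative error; signs alternate per
#' pair) and, in Case B, the operated joint.
#'
#' @param neuron_id 1-based id within its population.
#' @param type `"PC"`, `"CF"` or `"DCN"`.
#' @param net A [build_network()] result.
#' @return List with `index`, `sign`, `joint`.
#' @export
microcomplex_of <- function(neuron_id, type = c("PC", "CF", "DCN"), net) {
  type <- match.arg(type)
  cfg <- net$config
  n <- switch(type, PC = cfg$n_pc, CF = cfg$n_cf, DCN = cfg$n_dcn)
  if (neuron_id < 1 || neuron_id > n)
    stop(type, " id out of range (mossy and granule cells are not ",
         "microzone members)")
  idx <- if (type == "PC") (neuron_id - 1L) %/% 10L else neuron_id - 1L
  list(index = as.integer(idx),
       sign = if (idx %% 2 == 0) "+" else "-",
       joint = as.integer(idx %/% 2L) + 1L)
}

#' Snapshot all plastic weights as per-projection tables
#'
#' @param net A [build_network()] result (or a run's network).
#' @return Named list of data frames `pre_id`, `post_id`, `weight_nS` for
#'   the GC-PC, MF-DCN and PC-DCN projections.
#' @export
snapshot_weights <- function(net) {
  gcpc <- data.frame(pre_id = rep(seq_len(nrow(net$w_pfpc)),
                                  times = ncol(net$w_pfpc)),
                     post_id = rep(seq_len(ncol(net$w_pfpc)),
                                   each = nrow(net$w_pfpc)),
                     weight_nS = as.vector(net$w_pfpc))
  mfdcn <- data.frame(pre_id = rep(seq_len(nrow(net$w_mfdcn)),
                                   times = ncol(net$w_mfdcn)),
                      post_id = rep(seq_len(ncol(net$w_mfdcn)),
                                    each = nrow(net$w_mfdcn)),
                      weight_nS = as.vector(net$w_mfdcn))
  pcdcn <- data.frame(pre_id = seq_along(net$w_pcdcn),
                      post_id = (seq_along(net$w_pcdcn) - 1L) %/% 10L + 1L,
                      weight_nS = net$w_pcdcn)
  list(GC_PC = gcpc, MF_DCN = mfdcn, PC_DCN = pcdcn)
}

#' Write / read a weight snapshot
#'
#' Per-projection CSV files (`pre_id,post_id,weight_nS`) plus a small
#' manifest recording case, trial index and seed.
#'
#' @param net Network whose weights to write.
#' @param dir Output directory (created if needed).
#' @param trial Trial index recorded in the manifest.
#' @return `dir`, invisibly (`write`); a list of data frames plus the
#'   manifest (`read`).
#' @export
write_weight_snapshot <- function(net, dir, trial = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- snapshot_weights(net)
  for (nm in names(tabs))
    write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  manifest <- c(case = net$config$case, trial = trial, seed = net$seed)
  writeLines(paste(names(manifest), manifest, sep = "="),
             file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' @rdname write_weight_snapshot
#' @export
read_weight_snapshot <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  tabs <- lapply(files, read.csv)
  names(tabs) <- sub("\\.csv$", "", basename(files))
  mf <- readLines(file.path(dir, "MANIFEST"))
  tabs$manifest <- stats::setNames(sub("^[^=]*=", "", mf),
                                   sub("=.*$", "", mf))
  tabs
}
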