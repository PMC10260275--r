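#' Default analysis configuration
#'
#' Bundles every tunable constant of the pipeline: frequency bands, detector
#' threshold multipliers, duration limits, the amplitude cap, and the epoch
#' artifact cutoff. Values default to the standard overnight-EEG settings
#' used throughout the package.
#'
#' @param ... named overrides replacing entries of the default list, using
#'   dotted paths for nested fields (e.g. `spindle.upper_mult = 4`).
#' @return A nested list of class `spindlelat_config`.
#' @examples
#' cfg <- default_config()
#' cfg$bands$spindle
#' cfg <- default_config(spindle.upper_mult = 4)
#' @export
default_config <- function(...) {
  cfg <- list(
    bands = list(
      broadband = c(0.2, 35),
      spindle   = c(13, 16),
      so        = c(0.2, 1.25),
      psd = list(delta = c(0.5, 4), theta = c(4, 7), alpha = c(8, 12),
                 sigma = c(12, 16), beta1 = c(16, 22), beta2 = c(22, 30))
    ),
    filter = list(
      broadband_transition = 0.2,   # Hz; -6 dB cutoffs land at edge -/+ half this
      spindle_order_256    = 2816,  # FIR order at 256 Hz, scaled for other rates
      so_lowpass_hz        = 3.5,   # cycle-geometry low-pass for SO detection
      so_lowpass_transition = 1.0,
      so_phase_transition   = 0.2   # for the 0.2-1.25 Hz phase band
    ),
    spindle = list(
      upper_mult = 5, lower_mult = 2,
      flank_s = 0.25, min_dur_s = 0.5, max_dur_s = 3.0,
      max_amp_uv = 200, gap_s = 0.0781,
      amplitude = "rectified"       # or "envelope" (Hilbert magnitude)
    ),
    so = list(dur_s = c(0.8, 5)),
    epoch = list(length_s = 30, artifact_cutoff_s = 8, artifact_rule = "sum"),
    psd = list(nfft = 1024, overlap = 0.5, scale = "db"),
    dprime = list(correction = "rate_2n"),  # or "loglinear"
    density = list(artifact_corrected = FALSE),
    seed = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg <- assign_path(cfg, path, dots[[nm]])
  }
  class(cfg) <- c("spindlelat_config", "list")
  validate_config(cfg)
  cfg
}

assign_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[1L]]] <- assign_path(x[[path[1L]]], path[-1L], value)
  }
  x
}

#' Validate an analysis configuration
#'
#' Checks the structural invariants: all limits strictly positive and every
#' band/duration range ordered min < max.
#'
#' @param cfg a configuration list as from [default_config()].
#' @return `cfg`, invisibly, or an error describing the violated invariant.
#' @export
validate_config <- function(cfg) {
  chk_range <- function(r, what) {
    if (!(length(r) == 2L && all(is.finite(r)) && r[1] > 0 && r[1] < r[2]))
      stop("config: ", what, " must be an increasing positive range", call. = FALSE)
  }
  chk_range(cfg$bands$broadband, "bands$broadband")
  chk_range(cfg$bands$spindle, "bands$spindle")
  chk_range(cfg$bands$so, "bands$so")
  for (b in names(cfg$bands$psd)) chk_range(cfg$bands$psd[[b]], paste0("bands$psd$", b))
  chk_range(cfg$so$dur_s, "so$dur_s")
  pos <- c(upper_mult = cfg$spindle$upper_mult, lower_mult = cfg$spindle$lower_mult,
           flank_s = cfg$spindle$flank_s, min_dur_s = cfg$spindle$min_dur_s,
           max_dur_s = cfg$spindle$max_dur_s, max_amp_uv = cfg$spindle$max_amp_uv,
           gap_s = cfg$spindle$gap_s, epoch_length_s = cfg$epoch$length_s,
           artifact_cutoff_s = cfg$epoch$artifact_cutoff_s, nfft = cfg$psd$nfft)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) stop("config: strictly positive value required for ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (cfg$spindle$min_dur_s >= cfg$spindle$max_dur_s)
    stop("config: spindle min_dur_s must be < max_dur_s", call. = FALSE)
  if (cfg$spindle$lower_mult >= cfg$spindle$upper_mult)
    stop("config: spindle lower_mult must be < upper_mult", call. = FALSE)
  invisible(cfg)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML (JSON is valid YAML and also accepted).
#'
#' @param path file path.
#' @rdname config_io
#' @return `read_config()` returns a validated `spindlelat_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg <- utils::modifyList(cfg, raw)
  class(cfg) <- c("spindlelat_config", "list")
  validate_config(cfg)
  cfg
}

#' @param cfg configuration list.
#' @rdname config_io
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Analytic design constants of the pipeline
#'
#' Derives the fixed quantities implied by the configuration and the task
#' design: the minimum inter-spindle gap expressed in samples at a given
#' sampling rate, the upper SO band frequency implied by the minimum cycle
#' duration, the minimum spindle duration implied by the bilateral flank
#' rule, and the total number of distinct picture stimuli implied by the
#' three-retrieval recognition design.
#'
#' @param cfg configuration, see [default_config()].
#' @param rate sampling rate in Hz.
#' @return Named list: `gap_ms`, `gap_samples`, `so_upper_hz`,
#'   `min_spindle_dur_s`, `n_stimuli_total`.
#' @export
design_constants <- function(cfg = default_config(), rate = 256) {
  td <- task_design()
  list(
    gap_ms = cfg$spindle$gap_s * 1000,
    gap_samples = round(cfg$spindle$gap_s * rate),
    so_upper_hz = 1 / cfg$so$dur_s[1],
    min_spindle_dur_s = 2 * cfg$spindle$flank_s,
    n_stimuli_total = td$n_stimuli_total
  )
}
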