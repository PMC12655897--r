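## Performance metrics around the cut: peak speed, peak acceleration and
## minimum deceleration in a 2 s entry window before the foot stance, peak
## speed and acceleration in the exit window after it. Values are compared
## to healthy-control norms as z-scores and discretized onto a seven-level
## "speedometer" dial (-3..+3, 0 = within one sigma of the control mean).

PERF_METRICS <- c("peak_vel_in", "peak_acc_in", "min_dec_in",
                  "peak_vel_out", "peak_acc_out")

#' Extract entry/exit performance metrics around the FC window
#'
#' Speed is the horizontal pelvis-velocity magnitude (center-of-mass proxy);
#' acceleration its central-difference derivative. The entry window is
#' `config$entry_window_s` seconds before the window start; the exit window
#' `config$exit_window_s` seconds after the window end, clipped to the trial
#' (clipping is flagged in the result).
#'
#' @param trial a [trial_kinematics()] object
#' @param window an `fc_window` from [locate_fc_window()]
#' @param config pipeline configuration
#' @return object of class `performance_metrics`: the five metrics plus
#'   `exit_clipped_s` (seconds of exit window lost to the trial end, 0 when
#'   none)
#' @export
extract_performance <- function(trial, window, config = default_config()) {
  fs <- trial$sample_rate
  n <- n_samples(trial)
  speed <- sqrt(trial$data$pelvis_vel_x^2 + trial$data$pelvis_vel_y^2)
  acc <- central_diff(speed, fs)
  in_len <- round(config$entry_window_s * fs)
  in_start <- window$start - in_len
  if (in_start < 1) {
    stop("validation error: trial too short for the ",
         config$entry_window_s, " s entry window before the foot stance")
  }
  entry <- seq(in_start, window$start - 1L)
  out_len <- round(config$exit_window_s * fs)
  out_end <- min(n, window$end + out_len - 1L)
  if (window$end > n) stop("FC window ends beyond the trial")
  exit <- seq(window$end, out_end)
  clipped <- config$exit_window_s - length(exit) / fs
  structure(list(
    peak_vel_in = max(speed[entry]),
    peak_acc_in = max(acc[entry]),
    min_dec_in = min(acc[entry]),
    peak_vel_out = max(speed[exit]),
    peak_acc_out = max(acc[exit]),
    exit_clipped_s = max(0, clipped)),
    class = "performance_metrics")
}

#' Standardize a value against normative statistics
#'
#' @param value measured value (metric units)
#' @param norms a [norm_stats()] object (sigma > 0)
#' @return z = (value - mu) / sigma
#' @export
#' @examples
#' zscore(4.2, norm_stats("peak_vel_in", mu = 5, sigma = 0.5, n = 40))
zscore <- function(value, norms) {
  if (!is.finite(norms$sigma) || norms$sigma <= 0)
    stop("zscore: sigma must be > 0")
  (value - norms$mu) / norms$sigma
}

#' Speedometer dial index for a z-score
#'
#' Seven dials: 0 for |z| < 1 (green, within one sigma of the control mean),
#' then one step per sigma band (yellow, orange) saturating at +/-3 (red,
#' beyond three sigma).
#'
#' @param z finite z-score
#' @return integer in -3..3: `sign(z) * min(3, floor(|z|))`
#' @export
#' @examples
#' dial_index(-1.6)  # -1
#' dial_index(4.2)   # 3
dial_index <- function(z) {
  if (!is.finite(z)) stop("dial_index: z must be finite")
  as.integer(sign(z) * min(3, floor(abs(z))))
}

# attach z-scores and dials to extracted metrics; norms is a named list of
# norm_stats keyed by metric id
score_performance <- function(perf, norms) {
  z <- list(); dial <- list()
  for (m in PERF_METRICS) {
    if (!is.null(norms[[m]])) {
      z[[m]] <- zscore(perf[[m]], norms[[m]])
      dial[[m]] <- dial_index(z[[m]])
    } else {
      z[[m]] <- NA_real_
      dial[[m]] <- NA_integer_
    }
  }
  perf$z <- z
  perf$dial <- dial
  perf
}
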