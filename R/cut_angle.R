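## Multistep cut-angle identification.
##
## Candidate angles are computed at every interior contact as the angle
## between the normalized horizontal pelvis displacement vectors to the k-th
## preceding and k-th following contact (k = 5 by default). Three filters
## then prune the candidates:
##   1. plausibility — only 10..110 degrees (inclusive) can be cut angles;
##   2. velocity interval — the cut lies between a local maximum of the
##      resultant horizontal pelvis speed and the subsequent local minimum;
##   3. derivative window — within 500 ms (total, centered) of the first
##      local maximum of the mediolateral-velocity derivative after the
##      global speed peak.
## The highest surviving angle is the trial's cut angle; ties break to the
## earliest sample.

#' Candidate cut angles at every interior step
#'
#' @param steps step table from [segment_steps()]
#' @param trial the [trial_kinematics()] object
#' @param k step offset (default `config$candidate_k` = 5)
#' @param config pipeline configuration
#' @return data.frame with `step_index`, `sample` (contact sample of the
#'   step), `angle_deg`
#' @export
candidate_angles <- function(steps, trial, k = NULL,
                             config = default_config()) {
  k <- as.integer(k %||% config$candidate_k)
  n_steps <- nrow(steps)
  if (n_steps < 2 * k + 1) {
    stop(sprintf("insufficient steps: need at least %d, got %d",
                 2 * k + 1, n_steps))
  }
  # contact positions: starts of each step plus the final end contact
  cs <- c(steps$start, steps$end[n_steps])
  px <- trial$data$pelvis_pos_x[cs]
  py <- trial$data$pelvis_pos_y[cs]
  rows <- lapply(seq(k + 1L, length(cs) - k), function(j) {
    vin <- c(px[j] - px[j - k], py[j] - py[j - k])
    vout <- c(px[j + k] - px[j], py[j + k] - py[j])
    nin <- sqrt(sum(vin^2)); nout <- sqrt(sum(vout^2))
    ang <- if (nin == 0 || nout == 0) NA_real_ else {
      acos(clamp(sum(vin * vout) / (nin * nout), -1, 1)) * 180 / pi
    }
    data.frame(step_index = j, sample = cs[j], angle_deg = ang)
  })
  out <- do.call(rbind, rows)
  out[is.finite(out$angle_deg), , drop = FALSE]
}

#' Plausibility filter on candidate angles
#'
#' Retains candidates whose angle lies within the plausible cut-angle range
#' (default 10 to 110 degrees, boundaries inclusive). Order is preserved;
#' the output may be empty.
#'
#' @param candidates data.frame from [candidate_angles()]
#' @param config pipeline configuration
#' @return filtered data.frame
#' @export
plausibility_filter <- function(candidates, config = default_config()) {
  keep <- candidates$angle_deg >= config$plaus_min_deg &
    candidates$angle_deg <= config$plaus_max_deg
  candidates[keep, , drop = FALSE]
}

# low-pass-filtered resultant horizontal pelvis speed
filtered_speed <- function(trial, config) {
  fs <- trial$sample_rate
  bf <- butter_lowpass(4, config$lowpass_hz, fs)
  vx <- filtfilt_zero_phase(bf$b, bf$a, trial$data$pelvis_vel_x)
  vy <- filtfilt_zero_phase(bf$b, bf$a, trial$data$pelvis_vel_y)
  sqrt(vx^2 + vy^2)
}

#' Velocity-interval eligibility filter
#'
#' Extracts local maxima of the resultant (anteroposterior + mediolateral)
#' pelvis speed and, for each, the subsequent local minimum; candidates whose
#' contact sample falls inside any such maximum-to-minimum interval remain
#' eligible (set `config$velocity_filter_first_only = TRUE` to use only the
#' first interval).
#'
#' @param plausible data.frame from [plausibility_filter()]
#' @param trial the [trial_kinematics()] object
#' @param config pipeline configuration
#' @return filtered data.frame
#' @export
velocity_interval_filter <- function(plausible, trial,
                                     config = default_config()) {
  fs <- trial$sample_rate
  sp <- filtered_speed(trial, config)
  sep <- config$min_separation_s * fs
  # ignore extrema inside the zero-phase filter's edge-transient region
  guard <- round(0.15 * fs)
  in_body <- function(i) i[i > guard & i <= length(sp) - guard]
  maxima <- in_body(find_peaks(sp, config$speed_prominence, sep))
  if (length(maxima) == 0)
    stop("eligibility error: no local maximum in resultant pelvis speed")
  minima <- in_body(find_troughs(sp, config$speed_prominence, sep))
  # the cut contact sits at the speed dip; detected contact and filtered
  # speed minimum can disagree by a few samples, so pad the interval end
  pad <- round(config$velocity_interval_margin_s * fs)
  intervals <- list()
  for (m in maxima) {
    nxt <- minima[minima > m]
    if (length(nxt)) intervals[[length(intervals) + 1L]] <- c(m, nxt[1] + pad)
  }
  if (isTRUE(config$velocity_filter_first_only) && length(intervals) > 1)
    intervals <- intervals[1]
  if (length(intervals) == 0 || nrow(plausible) == 0)
    return(plausible[0, , drop = FALSE])
  keep <- vapply(plausible$sample, function(s) {
    any(vapply(intervals, function(iv) s >= iv[1] && s <= iv[2], logical(1)))
  }, logical(1))
  plausible[keep, , drop = FALSE]
}

#' Derivative-window eligibility filter
#'
#' Differentiates the low-pass-filtered mediolateral pelvis velocity in a
#' search window (default 1 s) after the global resultant-speed peak, finds
#' the first local maximum of that derivative, and retains candidates within
#' half the eligibility window (default 250 ms) of it.
#'
#' @param velocity_eligible data.frame from [velocity_interval_filter()]
#' @param trial the [trial_kinematics()] object
#' @param config pipeline configuration
#' @return filtered data.frame
#' @export
derivative_window_filter <- function(velocity_eligible, trial,
                                     config = default_config()) {
  fs <- trial$sample_rate
  sp <- filtered_speed(trial, config)
  peak <- which.max(sp)
  bf <- butter_lowpass(4, config$lowpass_hz, fs)
  vyf <- filtfilt_zero_phase(bf$b, bf$a, trial$data$pelvis_vel_y)
  # magnitude of the derivative: the transient's sign depends on the cut
  # direction (left vs right), the event timing does not
  dml <- abs(central_diff(vyf, fs))
  lo <- peak
  hi <- min(length(dml), peak + round(config$derivative_search_s * fs))
  seg <- dml[lo:hi]
  # ignore ripple: a real direction-change transient towers over filter
  # ringing and noise, so require a fraction of the window's peak magnitude
  local_max <- find_peaks(seg, min_prominence =
                            config$deriv_prominence_frac * max(seg))
  if (length(local_max) == 0)
    stop("eligibility error: no local maximum of the mediolateral-velocity ",
         "derivative in the search window")
  m <- lo + local_max[1] - 1L
  half <- round(config$derivative_window_s / 2 * fs)
  keep <- abs(velocity_eligible$sample - m) <= half
  out <- velocity_eligible[keep, , drop = FALSE]
  attr(out, "derivative_peak_sample") <- m
  out
}

#' Compute the cut angle of a trial
#'
#' Chains [candidate_angles()], [plausibility_filter()],
#' [velocity_interval_filter()] and [derivative_window_filter()]; the final
#' cut angle is the highest eligible angle (ties break to the earliest
#' sample). An empty eligible set at any stage raises a no-cut-detected
#' error naming the stage.
#'
#' @param trial a [trial_kinematics()] object
#' @param contacts a `foot_contacts` object from [detect_foot_contacts()]
#' @param config pipeline configuration
#' @return object of class `cut_angle_result`: list with the candidate table
#'   of each stage (`candidates`, `plausible`, `velocity_eligible`,
#'   `derivative_eligible`), `final_angle_deg`, `final_sample`
#' @export
#' @examples
#' syn <- generate_cut_trial(synth_params(cut_angle_deg = 75, noise_sd = 0))
#' fc <- detect_foot_contacts(syn$trial)
#' compute_cut_angle(syn$trial, fc)$final_angle_deg
compute_cut_angle <- function(trial, contacts, config = default_config()) {
  steps <- segment_steps(contacts, trial)
  cand <- candidate_angles(steps, trial, config = config)
  stage <- function(df, name) {
    if (nrow(df) == 0) {
      stop("no-cut-detected: empty eligible set at stage '", name, "'")
    }
    df
  }
  cand <- stage(cand, "candidates")
  plaus <- stage(plausibility_filter(cand, config), "plausibility")
  vel <- stage(velocity_interval_filter(plaus, trial, config),
               "velocity_interval")
  der <- stage(derivative_window_filter(vel, trial, config),
               "derivative_window")
  best <- which(der$angle_deg == max(der$angle_deg))
  best <- best[which.min(der$sample[best])]
  structure(list(candidates = cand, plausible = plaus,
                 velocity_eligible = vel, derivative_eligible = der,
                 final_angle_deg = der$angle_deg[best],
                 final_sample = der$sample[best]),
            class = "cut_angle_result")
}

#' @export
print.cut_angle_result <- function(x, ...) {
  cat(sprintf(
    "<cut_angle_result> %.1f deg at sample %d (%d candidates -> %d plausible -> %d velocity -> %d derivative)\n",
    x$final_angle_deg, x$final_sample, nrow(x$candidates), nrow(x$plausible),
    nrow(x$velocity_eligible), nrow(x$derivative_eligible)))
  invisible(x)
}
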