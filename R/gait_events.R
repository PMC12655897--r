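## Gait events from the pelvis trajectory: local minima of low-pass-filtered
## pelvis vertical velocity mark foot contacts; the final contact at or
## before the cut locates the foot-contact (FC) stance window whose two
## evaluation frames are initial contact (IC, the foot strike itself) and
## peak knee flexion (pKF, the within-window knee-flexion maximum of the
## stance limb).

#' Detect foot contacts from pelvis vertical velocity
#'
#' Low-pass filters the pelvis vertical velocity (zero-lag 4th-order
#' Butterworth, `config$lowpass_hz`) and returns its local minima subject to
#' prominence (`config$min_prominence`, m/s) and minimum-separation
#' (`config$min_separation_s`) constraints.
#'
#' @param trial a [trial_kinematics()] object
#' @param config pipeline configuration, see [default_config()]
#' @return object of class `foot_contacts`: list with `contact_samples`
#'   (strictly increasing sample indices) and `source_signal`
#' @export
#' @examples
#' syn <- generate_cut_trial(synth_params(noise_sd = 0, seed = 1))
#' detect_foot_contacts(syn$trial)$contact_samples
detect_foot_contacts <- function(trial, config = default_config()) {
  fs <- trial$sample_rate
  vz <- trial$data$pelvis_vel_z
  bf <- butter_lowpass(4, config$lowpass_hz, fs)
  vzf <- filtfilt_zero_phase(bf$b, bf$a, vz)
  idx <- find_troughs(vzf, min_prominence = config$min_prominence,
                      min_separation = config$min_separation_s * fs)
  if (length(idx) < 2) {
    stop("event-detection error: fewer than 2 foot contacts found ",
         "in pelvis vertical velocity")
  }
  structure(list(contact_samples = as.integer(idx),
                 source_signal = "pelvis_vel_z"),
            class = "foot_contacts")
}

#' Segment a trial into single steps
#'
#' Consecutive contacts delimit steps; each step carries its horizontal
#' pelvis displacement vector.
#'
#' @param contacts a `foot_contacts` object from [detect_foot_contacts()]
#' @param trial the corresponding [trial_kinematics()] object
#' @return data.frame with one row per step: `start`, `end` (sample indices,
#'   half-open), `dx`, `dy` (m)
#' @export
segment_steps <- function(contacts, trial) {
  cs <- contacts$contact_samples
  if (length(cs) < 2) stop("need at least 2 contacts to segment steps")
  px <- trial$data$pelvis_pos_x
  py <- trial$data$pelvis_pos_y
  i <- cs[-length(cs)]
  j <- cs[-1]
  data.frame(start = i, end = j, dx = px[j] - px[i], dy = py[j] - py[i])
}

#' Locate the final pre-cut foot-contact window
#'
#' The FC window opens at the last detected contact at or before
#' `cut_sample` (this foot strike is the IC frame), and closes at the next
#' contact, capped at `config$max_stance_s` after the strike. The pKF frame
#' is the within-window maximum of the stance limb's knee flexion.
#'
#' @param trial a [trial_kinematics()] object
#' @param contacts a `foot_contacts` object
#' @param cut_sample sample index of the selected cut (from
#'   [compute_cut_angle()])
#' @param stance_limb "left" or "right" (the cutting limb from the metadata)
#' @param config pipeline configuration
#' @return object of class `fc_window`: list with `start`, `end` (half-open),
#'   `ic`, `pkf`, `stance_limb`, `duration_s`
#' @export
locate_fc_window <- function(trial, contacts, cut_sample, stance_limb,
                             config = default_config()) {
  stance_limb <- match.arg(stance_limb, c("left", "right"))
  cs <- contacts$contact_samples
  if (cut_sample < 1 || cut_sample > n_samples(trial))
    stop("cut_sample outside trial bounds")
  before <- cs[cs <= cut_sample]
  if (length(before) == 0)
    stop("event error: no foot contact at or before the cut sample")
  start <- max(before)
  fs <- trial$sample_rate
  nxt <- cs[cs > start]
  cap <- start + round(config$max_stance_s * fs)
  end <- if (length(nxt)) min(nxt[1], cap) else cap
  end <- min(end, n_samples(trial) + 1L)
  if (end <= start) stop("degenerate FC window")
  kf <- limb_signal(trial, "knee_flex", stance_limb)
  win <- seq(start, end - 1L)
  pkf <- win[which.max(kf[win])]
  structure(list(start = as.integer(start), end = as.integer(end),
                 ic = as.integer(start), pkf = as.integer(pkf),
                 stance_limb = stance_limb,
                 duration_s = (end - start) / fs),
            class = "fc_window")
}

#' @export
print.fc_window <- function(x, ...) {
  cat(sprintf("<fc_window> [%d, %d) ic=%d pkf=%d limb=%s (%.0f ms)\n",
              x$start, x$end, x$ic, x$pkf, x$stance_limb,
              1000 * x$duration_s))
  invisible(x)
}
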