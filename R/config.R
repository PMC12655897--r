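#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one flat list. Every stage takes a
#' `config` argument defaulting to `default_config()`; a JSON file with a
#' subset of these keys can be loaded with [load_config()] and is merged over
#' the defaults.
#'
#' @details Keys (units in brackets):
#' \describe{
#'   \item{lowpass_hz}{cutoff of the zero-lag 4th-order Butterworth low-pass
#'     applied to pelvis velocities before event detection [Hz], default 10.}
#'   \item{min_prominence}{minimum prominence of pelvis vertical-velocity
#'     minima accepted as foot contacts [m/s], default 0.1.}
#'   \item{min_separation_s}{minimum separation between contacts [s],
#'     default 0.2.}
#'   \item{max_stance_s}{cap on the stance (foot-contact window) duration when
#'     the next contact is missing or late [s], default 0.5.}
#'   \item{candidate_k}{step offset for the candidate cut-angle operator
#'     (angle between displacement to the k-th preceding and following
#'     contact), default 5.}
#'   \item{plaus_min_deg, plaus_max_deg}{plausibility bounds on candidate cut
#'     angles [degrees], defaults 10 and 110, both inclusive.}
#'   \item{speed_prominence}{prominence for local extrema of resultant
#'     horizontal speed in the velocity-interval filter [m/s], default 0.3;
#'     the entry-peak-to-cut-dip excursion is of order m/s, noise ripple an
#'     order of magnitude smaller.}
#'   \item{velocity_interval_margin_s}{tolerance added to the minimum end of
#'     each speed maximum-to-minimum interval [s], default 0.05; absorbs the
#'     few-sample disagreement between the detected contact and the filtered
#'     speed minimum.}
#'   \item{velocity_filter_first_only}{if TRUE only the first speed
#'     maximum-to-minimum interval confers eligibility, default FALSE (every
#'     interval does).}
#'   \item{derivative_search_s}{length of the search window after the global
#'     resultant-speed peak in which the first local maximum of the
#'     mediolateral-velocity derivative is sought [s], default 1.0.}
#'   \item{deriv_prominence_frac}{minimum prominence of the derivative's
#'     local maximum, as a fraction of the search window's peak magnitude
#'     (rejects filter ringing and noise ripple), default 0.5.}
#'   \item{derivative_window_s}{total width of the eligibility window centered
#'     on that maximum [s], default 0.5.}
#'   \item{entry_window_s, exit_window_s}{performance entry/exit window
#'     lengths around the foot-contact window [s], defaults 2 and 2.}
#'   \item{hk_window_s}{sub-window for the hip/knee ratio statistic, centered
#'     on the evaluation frame [s], default 0.1.}
#'   \item{tolerance_pct}{conservative tolerance applied when deriving
#'     normative thresholds (percent inflation of sigma), default 5.}
#'   \item{asym_denominator}{normalization of the asymmetry percentage:
#'     "mean" (default) or "max" of the two limb magnitudes.}
#' }
#'
#' @return named list of configuration values
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$entry_window_s
default_config <- function() {
  list(
    lowpass_hz = 10,
    min_prominence = 0.1,
    min_separation_s = 0.2,
    max_stance_s = 0.5,
    candidate_k = 5L,
    plaus_min_deg = 10,
    plaus_max_deg = 110,
    speed_prominence = 0.3,
    velocity_filter_first_only = FALSE,
    velocity_interval_margin_s = 0.05,
    derivative_search_s = 1.0,
    deriv_prominence_frac = 0.5,
    derivative_window_s = 0.5,
    entry_window_s = 2,
    exit_window_s = 2,
    hk_window_s = 0.1,
    tolerance_pct = 5,
    asym_denominator = "mean"
  )
}

#' Load a configuration file
#'
#' Reads a JSON file of configuration overrides and merges it over
#' [default_config()]. Unknown keys are rejected so typos fail loudly.
#'
#' @param path path to a JSON file, or NULL for pure defaults
#' @return merged configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}
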