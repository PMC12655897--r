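## Inter-limb sagittal-plane asymmetry for hip, knee and ankle: per joint,
## the peak sagittal angle within the FC stance window (sign-preserving:
## ankle plantarflexion summaries are negative), averaged over each limb's
## trials; the symmetric mean-normalized percent difference between limbs is
## binned onto the 0-3 Asymmetry Score and checked against normative
## asymmetry for extreme (z > 3) deviation.

ASYM_JOINTS <- c(hip = "hip_flex", knee = "knee_flex", ankle = "ankle_flex")

#' Per-joint sagittal summary of one limb across trials
#'
#' For every trial in which `limb` was the stance (cutting) limb, takes the
#' peak sagittal angle of that limb within the FC window — the sample of
#' largest magnitude, so plantarflexion-dominant ankle series keep their
#' negative sign — and averages across trials.
#'
#' @param trials_windows list of lists with elements `trial` and `window`
#' @param limb "left" or "right"
#' @return named numeric vector with elements `hip`, `knee`, `ankle`
#'   (degrees)
#' @export
limb_summary <- function(trials_windows, limb) {
  limb <- match.arg(limb, c("left", "right"))
  use <- Filter(function(tw) tw$window$stance_limb == limb, trials_windows)
  if (length(use) == 0)
    stop("insufficient-data error: no trials with stance limb ", limb)
  peaks <- vapply(use, function(tw) {
    win <- seq(tw$window$start, tw$window$end - 1L)
    vapply(ASYM_JOINTS, function(stem) {
      x <- limb_signal(tw$trial, stem, limb)[win]
      x[which.max(abs(x))]
    }, numeric(1))
  }, numeric(length(ASYM_JOINTS)))
  rowMeans(matrix(peaks, nrow = length(ASYM_JOINTS),
                  dimnames = list(names(ASYM_JOINTS), NULL)))
}

#' Inter-limb asymmetry percentage
#'
#' Symmetric mean-normalized percent difference:
#' `100 * |a_inj - a_non| / mean(|a_inj|, |a_non|)` (or max-normalized when
#' `config$asym_denominator == "max"`). Scale-invariant and symmetric under
#' limb swap; can exceed 100%.
#'
#' @param a_injured,a_noninjured per-joint limb summaries (degrees; not both
#'   zero)
#' @param config pipeline configuration
#' @return list with `pct` (>= 0) and `direction` ("injured_higher",
#'   "noninjured_higher" or "equal", by the signed difference)
#' @export
#' @examples
#' asymmetry_percent(40, 60)   # 40%, noninjured_higher
#' asymmetry_percent(-5, -20)  # 120%, injured_higher (less plantarflexed)
asymmetry_percent <- function(a_injured, a_noninjured,
                              config = default_config()) {
  if (a_injured == 0 && a_noninjured == 0)
    stop("undefined-asymmetry error: both limb summaries are zero")
  denom <- switch(config$asym_denominator,
                  mean = mean(c(abs(a_injured), abs(a_noninjured))),
                  max = max(abs(a_injured), abs(a_noninjured)),
                  stop("unknown asym_denominator: ", config$asym_denominator))
  pct <- 100 * abs(a_injured - a_noninjured) / denom
  direction <- if (a_injured > a_noninjured) "injured_higher"
  else if (a_injured < a_noninjured) "noninjured_higher"
  else "equal"
  list(pct = pct, direction = direction)
}

#' Asymmetry Score (0-3) for an asymmetry percentage
#'
#' Bins: below 20% scores 0 (green); 20 to below 50% scores 1 (yellow); 50 to
#' below 70% scores 2 (orange); 70% and above scores 3 (red). Shared edges go
#' to the higher score.
#'
#' @param pct asymmetry percentage (>= 0)
#' @return integer score in 0..3
#' @export
#' @examples
#' asymmetry_score(55)  # 2
#' asymmetry_score(70)  # 3
asymmetry_score <- function(pct) {
  if (!is.finite(pct) || pct < 0)
    stop("asymmetry_score: pct must be a non-negative number")
  if (pct < 20) 0L else if (pct < 50) 1L else if (pct < 70) 2L else 3L
}

#' Flag extreme deviation from normative asymmetry
#'
#' @param pct asymmetry percentage
#' @param norms a [norm_stats()] object for the normative asymmetry of the
#'   joint (control cohort)
#' @return TRUE iff the z-score of `pct` exceeds 3
#' @export
extreme_flag <- function(pct, norms) {
  zscore(pct, norms) > 3
}

#' Full per-joint asymmetry analysis for one player
#'
#' @param trials_windows list of lists with `trial` and `window` elements
#' @param injured_limb "left", "right", or "none" (controls compare left vs
#'   right)
#' @param asym_norms optional named list of [norm_stats()] per joint for the
#'   extreme-deviation flag
#' @param config pipeline configuration
#' @return named list (hip, knee, ankle) of per-joint results: limb
#'   summaries, `pct`, `direction`, `score`, `extreme`
#' @export
analyze_asymmetry <- function(trials_windows, injured_limb,
                              asym_norms = NULL, config = default_config()) {
  if (injured_limb == "none") injured_limb <- "left"  # controls: left vs right
  other <- if (injured_limb == "left") "right" else "left"
  a_inj <- limb_summary(trials_windows, injured_limb)
  a_non <- limb_summary(trials_windows, other)
  out <- lapply(names(ASYM_JOINTS), function(joint) {
    ap <- asymmetry_percent(a_inj[[joint]], a_non[[joint]], config)
    res <- list(joint = joint, injured = a_inj[[joint]],
                noninjured = a_non[[joint]], pct = ap$pct,
                direction = ap$direction, score = asymmetry_score(ap$pct),
                extreme = NA)
    if (!is.null(asym_norms[[joint]]))
      res$extreme <- extreme_flag(ap$pct, asym_norms[[joint]])
    res
  })
  stats::setNames(out, names(ASYM_JOINTS))
}
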