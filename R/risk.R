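## Nine-factor risk classification at the two evaluation frames (IC, pKF)
## of the FC window, with deviation percentages against the violated
## threshold, trial-level aggregation (overall risk at >= 4 simultaneous
## factors; category risk when every factor of a category is at risk),
## player-level percent-of-trials summaries with traffic-light color bins,
## and cohort-level contingency counts.

#' Extract the nine risk-factor values at one evaluation frame
#'
#' Instantaneous stance-limb values at the frame sample for HF, KF, AF, KV,
#' HA, HI, TIB, TCR; the HK ratio is median(knee flexion) / Q1(hip flexion)
#' over a `config$hk_window_s` sub-window centered on the frame sample and
#' clipped to the FC window.
#'
#' @param trial a [trial_kinematics()] object
#' @param window an `fc_window` from [locate_fc_window()]
#' @param frame "IC" or "pKF"
#' @param config pipeline configuration
#' @return object of class `factor_values`: named list of the nine factor
#'   values plus `frame`
#' @export
extract_factor_values <- function(trial, window, frame,
                                  config = default_config()) {
  frame <- match.arg(frame, c("IC", "pKF"))
  s <- if (frame == "IC") window$ic else window$pkf
  if (s < window$start || s >= window$end)
    stop("consistency error: frame sample outside the FC window")
  fs <- trial$sample_rate
  limb <- window$stance_limb
  at <- function(stem) limb_signal(trial, stem, limb)[s]
  half <- round(config$hk_window_s / 2 * fs)
  sub <- seq(max(window$start, s - half), min(window$end - 1L, s + half))
  kf <- limb_signal(trial, "knee_flex", limb)[sub]
  hf <- limb_signal(trial, "hip_flex", limb)[sub]
  q1 <- stats::quantile(hf, 0.25, names = FALSE)
  vals <- list(
    HK = stats::median(kf) / q1,
    HF = at("hip_flex"), KF = at("knee_flex"), AF = at("ankle_flex"),
    KV = at("knee_valgus"), HA = at("hip_abd"), HI = at("hip_rot"),
    TIB = trial$data$trunk_lat_bend[s], TCR = trial$data$trunk_rot[s],
    frame = frame)
  structure(vals, class = "factor_values")
}

#' Construct a factor-value vector directly
#'
#' For classification without a trial (testing, what-if analysis).
#'
#' @param frame "IC" or "pKF"
#' @param HK,HF,KF,AF,KV,HA,HI,TIB,TCR the nine factor values (HK a ratio,
#'   the rest degrees), all for the stance limb
#' @return a `factor_values` object
#' @export
factor_values <- function(frame, HK, HF, KF, AF, KV, HA, HI, TIB, TCR) {
  frame <- match.arg(frame, c("IC", "pKF"))
  vals <- list(HK = HK, HF = HF, KF = KF, AF = AF, KV = KV, HA = HA,
               HI = HI, TIB = TIB, TCR = TCR, frame = frame)
  if (!all(vapply(vals[FACTOR_IDS], is.finite, logical(1))))
    stop("factor_values: all nine values must be finite")
  structure(vals, class = "factor_values")
}

#' Classify factor values against a threshold set
#'
#' Per factor: "above" factors are at risk when the value exceeds the
#' threshold, "below" factors when it falls under it, and HA when the value
#' lies outside the [HAdd, HAbd] band. The deviation percentage is
#' `100 * |value - violated threshold| / |violated threshold|` (0 when not
#' at risk); when the violated threshold is exactly 0 the deviation is
#' reported in absolute factor units instead and excluded from the >100%
#' "extreme" rule.
#'
#' @param values a `factor_values` object
#' @param tset a `threshold_set` whose frame matches `values$frame`
#' @return object of class `factor_risk`: data.frame with one row per factor
#'   (`factor_id`, `value`, `threshold`, `direction`, `at_risk`,
#'   `deviation_pct`, `deviation_abs`, `extreme`) plus attribute `frame`
#' @export
classify_factors <- function(values, tset) {
  if (!identical(values$frame, tset$frame))
    stop(sprintf("stratum mismatch: values at frame %s, thresholds for %s",
                 values$frame, tset$frame))
  fd <- factor_defs()
  rows <- lapply(seq_len(nrow(fd)), function(j) {
    fid <- fd$factor_id[j]
    v <- values[[fid]]
    dir <- fd$direction[j]
    if (dir == "outside") {
      hi <- threshold_value(tset, "HAbd")
      lo <- threshold_value(tset, "HAdd")
      if (v > hi) { at_risk <- TRUE; thr <- hi }
      else if (v < lo) { at_risk <- TRUE; thr <- lo }
      else { at_risk <- FALSE; thr <- if (v >= 0) hi else lo }
    } else {
      thr <- threshold_value(tset, fid)
      at_risk <- if (dir == "above") v > thr else v < thr
    }
    dev_abs <- if (at_risk) abs(v - thr) else 0
    dev_pct <- if (!at_risk) 0
    else if (thr == 0) NA_real_  # percent-of-zero undefined
    else 100 * abs(v - thr) / abs(thr)
    data.frame(factor_id = fid, category = fd$category[j], value = v,
               threshold = thr, direction = dir, at_risk = at_risk,
               deviation_pct = dev_pct, deviation_abs = dev_abs,
               extreme = isTRUE(dev_pct > 100), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "frame") <- values$frame
  class(out) <- c("factor_risk", "data.frame")
  out
}

#' Aggregate factor risks to trial level
#'
#' @param factor_risk a `factor_risk` from [classify_factors()]
#' @return object of class `trial_risk`: list with `frame`,
#'   `n_factors_at_risk` (0-9), `overall_at_risk` (TRUE iff >= 4),
#'   `category_at_risk` (named logical: SKL requires 4/4 factors at risk,
#'   KVC 3/3, TPI 2/2)
#' @export
#' @examples
#' fv <- factor_values("IC", HK = 0.9, HF = 45, KF = 30, AF = -12,
#'                     KV = 1, HA = 0, HI = 5, TIB = 5, TCR = 3)
#' tr <- trial_risk(classify_factors(fv, threshold_set(bundled_table1(),
#'                                   "male", "AGTT", "IC")))
#' tr$overall_at_risk
trial_risk <- function(factor_risk) {
  stopifnot(nrow(factor_risk) == 9)
  n_risk <- sum(factor_risk$at_risk)
  cats <- tapply(factor_risk$at_risk, factor_risk$category, all)
  structure(list(frame = attr(factor_risk, "frame"),
                 n_factors_at_risk = as.integer(n_risk),
                 overall_at_risk = n_risk >= 4,
                 category_at_risk = cats[c("SKL", "KVC", "TPI")]),
            class = "trial_risk")
}

#' Traffic-light color bin for a percentage of trials at risk
#'
#' Below 20% green; 20-50% yellow; above 50 to 70% orange; above 70% red
#' (shared edges go to the lower bin).
#'
#' @param pct percentage in [0, 100]
#' @return one of "green", "yellow", "orange", "red"
#' @export
color_bin <- function(pct) {
  stopifnot(is.finite(pct), pct >= 0, pct <= 100)
  if (pct < 20) "green" else if (pct <= 50) "yellow"
  else if (pct <= 70) "orange" else "red"
}

#' Summarize one player's factor risks across trials
#'
#' @param factor_risks list of `factor_risk` objects (one per analyzed trial
#'   at a common frame)
#' @param trial_ids optional character vector of trial identifiers
#' @param injured_flags optional logical vector: was each trial cut with the
#'   injured limb
#' @return object of class `player_factor_summary`: per-factor data.frame
#'   (`factor_id`, `n_trials`, `n_at_risk`, `pct_trials_at_risk`,
#'   `color_bin`, `majority_flag` at >= 50%, `max_deviation_pct`,
#'   `max_deviation_trial`) plus overall-risk trial counts split by limb and
#'   per-category risk percentages
#' @export
player_summary <- function(factor_risks, trial_ids = NULL,
                           injured_flags = NULL) {
  n <- length(factor_risks)
  if (n == 0) stop("insufficient-data error: zero analyzed trials")
  if (is.null(trial_ids)) trial_ids <- as.character(seq_len(n))
  frame <- attr(factor_risks[[1]], "frame")
  fd <- factor_defs()
  rows <- lapply(fd$factor_id, function(fid) {
    at_risk <- vapply(factor_risks,
                      function(fr) fr$at_risk[fr$factor_id == fid],
                      logical(1))
    devs <- vapply(factor_risks,
                   function(fr) fr$deviation_pct[fr$factor_id == fid],
                   numeric(1))
    pct <- 100 * sum(at_risk) / n
    has_dev <- any(is.finite(devs) & devs > 0)
    data.frame(
      factor_id = fid, n_trials = n, n_at_risk = sum(at_risk),
      pct_trials_at_risk = pct, color_bin = color_bin(pct),
      majority_flag = pct >= 50,
      max_deviation_pct = if (has_dev) max(devs, na.rm = TRUE) else 0,
      max_deviation_trial = if (has_dev)
        trial_ids[which.max(ifelse(is.finite(devs), devs, -Inf))]
      else NA_character_,
      stringsAsFactors = FALSE)
  })
  trisks <- lapply(factor_risks, trial_risk)
  overall <- vapply(trisks, function(tr) tr$overall_at_risk, logical(1))
  cat_mat <- vapply(trisks, function(tr) tr$category_at_risk, logical(3))
  if (is.null(injured_flags)) injured_flags <- rep(NA, n)
  structure(list(
    frame = frame,
    factors = do.call(rbind, rows),
    n_trials = n,
    n_overall_at_risk = sum(overall),
    n_overall_injured = sum(overall & injured_flags %in% TRUE),
    n_overall_noninjured = sum(overall & injured_flags %in% FALSE),
    category_pct_trials = 100 * rowSums(cat_mat) / n,
    category_red = rowSums(cat_mat) > 0),
    class = "player_factor_summary")
}

#' Cohort-level counts of players per color bin
#'
#' @param player_summaries list of `player_factor_summary` objects at a
#'   common frame
#' @return data.frame of counts: one row per factor, columns green, yellow,
#'   orange, red; rows sum to the number of players
#' @export
cohort_summary <- function(player_summaries) {
  if (length(player_summaries) == 0) stop("no player summaries")
  fd <- factor_defs()
  bins <- c("green", "yellow", "orange", "red")
  counts <- matrix(0L, nrow = nrow(fd), ncol = 4,
                   dimnames = list(fd$factor_id, bins))
  for (ps in player_summaries) {
    for (j in seq_len(nrow(ps$factors))) {
      counts[ps$factors$factor_id[j], ps$factors$color_bin[j]] <-
        counts[ps$factors$factor_id[j], ps$factors$color_bin[j]] + 1L
    }
  }
  out <- data.frame(factor_id = fd$factor_id, counts,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
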