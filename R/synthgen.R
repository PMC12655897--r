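## Synthetic cut-maneuver generator.
##
## The stated world: a straight constant-heading approach, a single-sample
## direction change at the cut foot contact, a straight exit; pelvis vertical
## velocity is a cosine at step frequency whose minima (amplitude 0.4 m/s)
## mark foot contacts; joint angles are per-stance raised-cosine bumps whose
## initial-contact (IC) and mid-stance peak values are independently
## controllable, so factor values at IC and at peak knee flexion (pKF) can be
## planted exactly. Horizontal speed rises to a peak ~0.4 s before the cut,
## dips at the cut, and recovers to the exit speed — the minimal profile
## containing every feature the cut-angle filter chain keys on.

# factor id -> generated signal; HK is a derived ratio, not directly settable
FACTOR_SIGNAL <- c(HF = "hip_flex", KF = "knee_flex", AF = "ankle_flex",
                   KV = "knee_valgus", HA = "hip_abd", HI = "hip_rot",
                   TIB = "trunk_lat_bend", TCR = "trunk_rot")
FACTOR_IDS <- c("HK", "HF", "KF", "AF", "KV", "HA", "HI", "TIB", "TCR")

# default (IC value, mid-stance peak) of each generated signal, degrees
DEFAULT_BUMPS <- list(
  hip_flex = c(40, 45), knee_flex = c(35, 70), ankle_flex = c(-8, -18),
  hip_abd = c(5, 7), hip_rot = c(8, 9), knee_valgus = c(1.5, 1.8),
  trunk_lat_bend = c(5, 6), trunk_rot = c(3, 4))

#' Parameters of one synthetic cut trial
#'
#' @param cut_angle_deg true cut angle in degrees, within [10, 110]
#' @param approach_speed,exit_speed straight-line speeds in m/s (> 0)
#' @param step_frequency steps per second (> 0)
#' @param n_steps_before,n_steps_after steps on each side of the cut contact
#'   (>= 6 each; the candidate-angle operator needs 5 on each side)
#' @param noise_sd additive white Gaussian noise, degrees on angle series and
#'   m/s on pelvis velocity (>= 0)
#' @param seed integer RNG seed; output is bitwise-reproducible for a fixed
#'   seed
#' @param factor_targets optional named numeric vector planting factor values
#'   at the two evaluation frames of the cut stance, e.g.
#'   `c("KF@IC" = 30, "KV@pKF" = 4)`. Settable factors: HF, KF, AF, KV, HA,
#'   HI, TIB, TCR (HK is a derived ratio).
#' @param player_id,sex,task,cut_limb,injured_limb,trial_index trial metadata
#'   (see [trial_meta()])
#' @param sample_rate sampling frequency in Hz, default 100
#' @return object of class `synth_params`
#' @export
synth_params <- function(cut_angle_deg = 75, approach_speed = 5,
                         exit_speed = 3.5, step_frequency = 3,
                         n_steps_before = 8, n_steps_after = 8,
                         noise_sd = 0.05, seed = 1, factor_targets = NULL,
                         player_id = "SYN01", sex = "male", task = "AGTT",
                         cut_limb = "right", injured_limb = "none",
                         trial_index = 1L, sample_rate = 100) {
  if (cut_angle_deg < 10 || cut_angle_deg > 110)
    stop("cut_angle_deg must lie in [10, 110]")
  if (approach_speed <= 0 || exit_speed <= 0) stop("speeds must be positive")
  if (step_frequency <= 0) stop("step_frequency must be positive")
  if (n_steps_before < 6 || n_steps_after < 6)
    stop("need at least 6 steps on each side of the cut")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(factor_targets)) check_factor_targets(factor_targets)
  structure(list(cut_angle_deg = cut_angle_deg,
                 approach_speed = approach_speed, exit_speed = exit_speed,
                 step_frequency = step_frequency,
                 n_steps_before = as.integer(n_steps_before),
                 n_steps_after = as.integer(n_steps_after),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 factor_targets = factor_targets, player_id = player_id,
                 sex = sex, task = task, cut_limb = cut_limb,
                 injured_limb = injured_limb,
                 trial_index = as.integer(trial_index),
                 sample_rate = sample_rate),
            class = "synth_params")
}

check_factor_targets <- function(targets) {
  keys <- names(targets)
  if (is.null(keys) || any(!nzchar(keys)))
    stop("factor_targets must be a named vector of '<factor>@<frame>' keys")
  parts <- strsplit(keys, "@", fixed = TRUE)
  for (p in parts) {
    if (length(p) != 2 || !(p[2] %in% c("IC", "pKF")))
      stop("factor_targets keys must look like 'KF@IC' or 'KV@pKF'")
    if (identical(p[1], "HK"))
      stop("HK is a derived ratio and cannot be targeted directly; ",
           "set KF and HF instead")
    if (!p[1] %in% names(FACTOR_SIGNAL))
      stop("unknown factor_id in factor_targets: ", p[1])
  }
  invisible(TRUE)
}

target_for <- function(targets, factor_id, frame) {
  key <- paste0(factor_id, "@", frame)
  if (!is.null(targets) && key %in% names(targets)) unname(targets[[key]])
  else NA_real_
}

#' Generate one synthetic cut trial with embedded ground truth
#'
#' @param params a [synth_params()] object
#' @return list with `trial` ([trial_kinematics()]), `meta` ([trial_meta()]),
#'   and `truth`, a list holding `contact_samples`, `cut_contact_index`
#'   (index into `contact_samples`), `cut_sample`, `true_cut_angle`,
#'   `true_ic`, `true_pkf`, and `true_factor_values` (per-frame factor map,
#'   including the derived HK ratio).
#' @export
#' @examples
#' syn <- generate_cut_trial(synth_params(cut_angle_deg = 90, noise_sd = 0))
#' syn$truth$true_cut_angle
generate_cut_trial <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, generate_cut_trial_impl(params))
}

generate_cut_trial_impl <- function(p) {
  fs <- p$sample_rate
  f <- p$step_frequency
  lead <- 0.7
  tail <- 0.7
  n_contacts <- p$n_steps_before + p$n_steps_after + 1L
  t_contacts <- lead + (seq_len(n_contacts) - 1) / f
  t_cut <- t_contacts[p$n_steps_before + 1L]
  duration <- lead + (n_contacts - 1) / f + tail
  # entry window must fit before the cut stance
  if (t_cut < 2) duration <- duration + (2 - t_cut)  # never triggers at defaults
  n <- ceiling(duration * fs) + 1L
  tt <- (seq_len(n) - 1) / fs

  contact_samples <- round(t_contacts * fs) + 1L
  cut_idx <- p$n_steps_before + 1L
  s_cut <- contact_samples[cut_idx]

  ## --- horizontal kinematics -------------------------------------------
  theta <- p$cut_angle_deg * pi / 180
  side <- if (p$cut_limb == "right") +1 else -1  # plant right -> cut left (+Y)
  h_in <- c(1, 0)
  h_out <- c(cos(theta), side * sin(theta))
  t_peak <- t_cut - 0.4
  v_dip <- 0.55 * min(p$approach_speed, p$exit_speed)
  knots_t <- c(0, t_peak, t_cut, t_cut + 0.6, duration + 1)
  knots_v <- c(0.85 * p$approach_speed, p$approach_speed, v_dip,
               p$exit_speed, p$exit_speed)
  speed <- stats::approx(knots_t, knots_v, xout = tt, rule = 2)$y
  after <- tt >= tt[s_cut]
  vx <- speed * ifelse(after, h_out[1], h_in[1])
  vy <- speed * ifelse(after, h_out[2], h_in[2])

  ## --- vertical velocity: cosine with minima at contacts ----------------
  # support ends at zero crossings (quarter period past the end contacts) so
  # the signal tapers continuously into the flat regions
  quarter <- 1 / (4 * f)
  vz <- numeric(n)
  zone <- tt >= (t_contacts[1] - quarter) &
    tt <= (t_contacts[n_contacts] + quarter)
  vz[zone] <- -0.4 * cos(2 * pi * f * (tt[zone] - t_contacts[1]))

  ## --- joint-angle series -----------------------------------------------
  stance_s <- min(0.3, 0.9 / f)
  angles <- make_angle_series(p, tt, t_contacts, cut_idx, stance_s)

  ## --- noise and integration --------------------------------------------
  if (p$noise_sd > 0) {
    vx <- vx + stats::rnorm(n, 0, p$noise_sd)
    vy <- vy + stats::rnorm(n, 0, p$noise_sd)
    vz <- vz + stats::rnorm(n, 0, p$noise_sd)
    for (nm in names(angles))
      angles[[nm]] <- angles[[nm]] + stats::rnorm(n, 0, p$noise_sd)
  }
  px <- cumtrapz(vx, fs)
  py <- cumtrapz(vy, fs)
  pz <- 1.0 + cumtrapz(vz, fs)

  df <- data.frame(time = tt, pelvis_pos_x = px, pelvis_pos_y = py,
                   pelvis_pos_z = pz, pelvis_vel_x = vx, pelvis_vel_y = vy,
                   pelvis_vel_z = vz)
  df <- cbind(df, as.data.frame(angles))
  trial <- trial_kinematics(df, sample_rate = fs)
  meta <- trial_meta(p$player_id, p$sex, p$task, p$cut_limb, p$injured_limb,
                     p$trial_index)

  true_pkf <- s_cut + round(stance_s / 2 * fs)
  truth <- list(
    contact_samples = contact_samples,
    cut_contact_index = cut_idx,
    cut_sample = s_cut,
    true_cut_angle = p$cut_angle_deg,
    true_ic = s_cut,
    true_pkf = true_pkf,
    true_factor_values = true_factors(p, trial, s_cut, contact_samples,
                                      cut_idx, stance_s))
  list(trial = trial, meta = meta, truth = truth)
}

# trapezoidal cumulative integral starting at 0
cumtrapz <- function(x, fs) {
  n <- length(x)
  c(0, cumsum((x[-n] + x[-1]) / 2)) / fs
}

# build all per-limb and trunk angle series as stance-phase bumps
make_angle_series <- function(p, tt, t_contacts, cut_idx, stance_s) {
  n <- length(tt)
  out <- list()
  for (stem in LIMB_SIGNALS) {
    for (limb in c("left", "right")) {
      col <- paste0(stem, if (limb == "left") "_l" else "_r")
      out[[col]] <- rep(DEFAULT_BUMPS[[stem]][1], n)
    }
  }
  for (stem in TRUNK_SIGNALS) out[[stem]] <- rep(DEFAULT_BUMPS[[stem]][1], n)

  other <- if (p$cut_limb == "left") "right" else "left"
  for (j in seq_along(t_contacts)) {
    limb <- if ((j - cut_idx) %% 2 == 0) p$cut_limb else other
    is_cut <- j == cut_idx
    for (stem in LIMB_SIGNALS) {
      bp <- bump_params(p, stem, is_cut)
      col <- paste0(stem, if (limb == "left") "_l" else "_r")
      out[[col]] <- add_bump(out[[col]], tt, t_contacts[j], stance_s,
                             bp[1], bp[2])
    }
    for (stem in TRUNK_SIGNALS) {
      bp <- bump_params(p, stem, is_cut)
      out[[stem]] <- add_bump(out[[stem]], tt, t_contacts[j], stance_s,
                              bp[1], bp[2])
    }
  }
  out
}

# (ic, peak) of a signal's stance bump; factor targets only bind on the cut
# stance of the cutting limb
bump_params <- function(p, stem, is_cut) {
  bp <- DEFAULT_BUMPS[[stem]]
  if (!is_cut) return(bp)
  fid <- names(FACTOR_SIGNAL)[match(stem, FACTOR_SIGNAL)]
  ic <- target_for(p$factor_targets, fid, "IC")
  pk <- target_for(p$factor_targets, fid, "pKF")
  if (!is.na(ic)) bp[1] <- ic
  if (!is.na(pk)) bp[2] <- pk
  if (stem == "knee_flex" && bp[2] <= bp[1])
    stop("knee-flexion pKF target must exceed the IC value (pKF is located ",
         "as the within-stance knee-flexion maximum)")
  bp
}

# raised-cosine bump: value `ic` at the contact, `peak` at mid-stance
add_bump <- function(base, tt, tc, stance_s, ic, peak) {
  u <- (tt - tc) / stance_s
  inside <- u >= 0 & u < 1
  base[inside] <- ic + (peak - ic) * 0.5 * (1 - cos(2 * pi * u[inside]))
  # the IC value of the bump also resets the local baseline at the contact
  base
}

# ground-truth factor values at IC and pKF (HK derived from the clean series)
true_factors <- function(p, trial, s_cut, contact_samples, cut_idx, stance_s) {
  fs <- trial$sample_rate
  vals <- list(IC = list(), pKF = list())
  for (fid in names(FACTOR_SIGNAL)) {
    bp <- bump_params(p, FACTOR_SIGNAL[[fid]], is_cut = TRUE)
    vals$IC[[fid]] <- bp[1]
    vals$pKF[[fid]] <- bp[2]
  }
  # HK over the same sub-window the extractor uses, on the clean bumps
  end <- if (cut_idx < length(contact_samples)) {
    contact_samples[cut_idx + 1L]
  } else {
    min(s_cut + round(0.5 * fs), n_samples(trial))
  }
  pkf <- s_cut + round(stance_s / 2 * fs)
  kf_bp <- bump_params(p, "knee_flex", TRUE)
  hf_bp <- bump_params(p, "hip_flex", TRUE)
  for (frame in c("IC", "pKF")) {
    centre <- if (frame == "IC") s_cut else pkf
    w <- seq(max(s_cut, centre - round(0.05 * fs)),
             min(end - 1, centre + round(0.05 * fs)))
    u <- ((w - s_cut) / fs) / stance_s
    kf <- kf_bp[1] + (kf_bp[2] - kf_bp[1]) * 0.5 * (1 - cos(2 * pi * u))
    hf <- hf_bp[1] + (hf_bp[2] - hf_bp[1]) * 0.5 * (1 - cos(2 * pi * u))
    vals[[frame]][["HK"]] <- stats::median(kf) /
      stats::quantile(hf, 0.25, names = FALSE)
  }
  vals
}

#' Generate a synthetic healthy-control cohort
#'
#' Draws per-player factor values from stated normal distributions and embeds
#' them in generated cut trials, standing in for a recorded control group
#' when deriving normative thresholds and statistics.
#'
#' @param n_players number of players (>= 2)
#' @param population named list mapping `'<factor>@<frame>'` keys to
#'   `c(mu, sigma)` (sigma > 0); factors not listed keep generator defaults
#' @param seed integer seed (one cohort is bitwise-reproducible per seed)
#' @param sex,task stratum of the cohort
#' @param trials_per_player repetitions per player (cut limb alternates)
#' @param cut_angle_deg,noise_sd passed to [synth_params()]
#' @return list of per-trial lists `(trial, meta, truth)`
#' @export
generate_control_cohort <- function(n_players, population = NULL, seed = 1,
                                    sex = "male", task = "AGTT",
                                    trials_per_player = 1,
                                    cut_angle_deg = if (task == "AGTT") 75 else 33,
                                    noise_sd = 0.05) {
  if (n_players < 2) stop("n_players must be >= 2")
  if (!is.null(population)) {
    for (key in names(population)) {
      ms <- population[[key]]
      if (length(ms) != 2 || ms[2] <= 0)
        stop("population entries must be c(mu, sigma) with sigma > 0 (", key, ")")
    }
    check_factor_targets(stats::setNames(
      vapply(population, `[`, numeric(1), 1), names(population)))
  }
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_players)) {
      targets <- NULL
      if (!is.null(population)) {
        targets <- vapply(population, function(ms) stats::rnorm(1, ms[1], ms[2]),
                          numeric(1))
      }
      for (k in seq_len(trials_per_player)) {
        p <- synth_params(
          cut_angle_deg = cut_angle_deg, noise_sd = noise_sd,
          seed = sample.int(.Machine$integer.max, 1),
          factor_targets = targets,
          player_id = sprintf("CTRL%02d", i), sex = sex, task = task,
          cut_limb = if (k %% 2 == 1) "right" else "left",
          injured_limb = "none", trial_index = k)
        out[[length(out) + 1L]] <- generate_cut_trial(p)
      }
    }
    out
  })
}
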