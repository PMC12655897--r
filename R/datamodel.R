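## Shared data model: one recorded cut trial = a trial_kinematics object
## (synchronized 100 Hz joint-angle and pelvis series) plus a trial_meta
## object (who/what/which limb). Sign conventions are fixed package-wide and
## enforced at ingest:
##   flexion positive; knee valgus positive; hip abduction positive /
##   adduction negative; hip internal rotation positive; ankle dorsiflexion
##   positive / plantarflexion negative; trunk lateral bending positive
##   toward the cutting limb; trunk rotation positive away from it.
## Pelvis position is in a ground-fixed frame, X anteroposterior,
## Y mediolateral, Z up. Indices are 1-based (R); windows are half-open
## [start, end) in sample indices.

# canonical per-limb signal stems and scalar trunk signals
LIMB_SIGNALS <- c("hip_flex", "hip_abd", "hip_rot",
                  "knee_flex", "knee_valgus", "ankle_flex")
TRUNK_SIGNALS <- c("trunk_lat_bend", "trunk_rot")

trial_columns <- function(with_velocity = TRUE) {
  cols <- c("time",
            paste0("pelvis_pos_", c("x", "y", "z")),
            if (with_velocity) paste0("pelvis_vel_", c("x", "y", "z")),
            paste0(rep(LIMB_SIGNALS, each = 2), c("_l", "_r")),
            TRUNK_SIGNALS)
  cols
}

#' Construct a trial_kinematics object
#'
#' @param data data.frame with the full trial column schema (see
#'   [read_trial()]): `time`, pelvis position (m) and velocity (m/s), and the
#'   twelve per-limb joint-angle columns plus two trunk columns (degrees).
#' @param sample_rate sampling frequency in Hz
#' @return object of class `trial_kinematics`
#' @export
trial_kinematics <- function(data, sample_rate) {
  stopifnot(is.data.frame(data), is.numeric(sample_rate), sample_rate > 0)
  missing_cols <- setdiff(trial_columns(with_velocity = FALSE), names(data))
  if (length(missing_cols)) {
    stop("trial data missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vel_cols <- paste0("pelvis_vel_", c("x", "y", "z"))
  if (!all(vel_cols %in% names(data))) {
    data <- derive_pelvis_velocity(data, sample_rate)
  }
  structure(list(data = data[, trial_columns(TRUE)], sample_rate = sample_rate),
            class = "trial_kinematics")
}

# pelvis velocity from central differences of position for any missing axis
derive_pelvis_velocity <- function(data, fs) {
  for (ax in c("x", "y", "z")) {
    vcol <- paste0("pelvis_vel_", ax)
    if (!vcol %in% names(data)) {
      data[[vcol]] <- central_diff(data[[paste0("pelvis_pos_", ax)]], fs)
    }
  }
  data
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf("<trial_kinematics> %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), x$sample_rate, nrow(x$data) / x$sample_rate))
  invisible(x)
}

n_samples <- function(trial) nrow(trial$data)

# per-limb signal accessor; limb is "left" or "right"
limb_signal <- function(trial, stem, limb) {
  stopifnot(stem %in% LIMB_SIGNALS, limb %in% c("left", "right"))
  trial$data[[paste0(stem, if (limb == "left") "_l" else "_r")]]
}

#' Construct trial metadata
#'
#' @param player_id player identifier string
#' @param sex "male" or "female"
#' @param task "AGTT" (pre-planned agility T-test cut) or "FS"
#'   (unplanned football-specific deceiving action)
#' @param cut_limb stance limb of the cut, "left" or "right"
#' @param injured_limb "left", "right", or "none" (healthy controls)
#' @param trial_index positive integer repetition index
#' @param age player age in years (optional)
#' @param months_post_surgery months since reconstruction (optional)
#' @return object of class `trial_meta`
#' @export
trial_meta <- function(player_id, sex, task, cut_limb,
                       injured_limb = "none", trial_index = 1L,
                       age = NA_real_, months_post_surgery = NA_real_) {
  sex <- enum_arg(sex, c("male", "female"))
  task <- enum_arg(task, c("AGTT", "FS"))
  cut_limb <- enum_arg(cut_limb, c("left", "right"))
  injured_limb <- enum_arg(injured_limb, c("left", "right", "none"))
  stopifnot(trial_index >= 1)
  structure(list(player_id = as.character(player_id), sex = sex, task = task,
                 cut_limb = cut_limb, injured_limb = injured_limb,
                 trial_index = as.integer(trial_index),
                 age = as.numeric(age),
                 months_post_surgery = as.numeric(months_post_surgery)),
            class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("<trial_meta> %s #%d %s %s cut=%s injured=%s\n", x$player_id,
              x$trial_index, x$sex, x$task, x$cut_limb, x$injured_limb))
  invisible(x)
}

#' Normative statistics for one metric in one stratum
#'
#' Healthy-control mean and standard deviation used for z-scores (performance
#' dials, asymmetry deviation flags).
#'
#' @param metric_id metric identifier string
#' @param mu,sigma control mean and standard deviation (sigma > 0)
#' @param n number of contributing control observations (>= 2)
#' @param sex,task,frame stratum labels (frame optional, NA when not
#'   frame-specific)
#' @return object of class `norm_stats`
#' @export
norm_stats <- function(metric_id, mu, sigma, n, sex = NA, task = NA,
                       frame = NA) {
  if (!is.finite(sigma) || sigma <= 0) stop("norm_stats: sigma must be > 0")
  if (n < 2) stop("norm_stats: n must be >= 2")
  structure(list(metric_id = metric_id, mu = mu, sigma = sigma, n = n,
                 sex = sex, task = task, frame = frame),
            class = "norm_stats")
}

validation_report <- function(issues) {
  structure(list(ok = nrow(issues) == 0, issues = issues),
            class = "validation_report")
}

issue_df <- function(code = character(), message = character()) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("<validation_report> OK\n")
  else {
    cat(sprintf("<validation_report> %d issue(s):\n", nrow(x$issues)))
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$code[i], x$issues$message[i]))
  }
  invisible(x)
}

#' Validate a trial against the data-model invariants
#'
#' Checks every structural invariant of the kinematics and metadata: positive
#' sample rate, duration sufficient for the 2 s performance entry window,
#' strictly increasing uniformly spaced time, finite values in every series,
#' and metadata enumerations. Issues are reported, never raised.
#'
#' @param trial a [trial_kinematics()] object
#' @param meta a [trial_meta()] object (optional)
#' @param config pipeline configuration, see [default_config()]
#' @return a `validation_report` with fields `ok` and `issues`
#' @export
#' @examples
#' syn <- generate_cut_trial(synth_params(seed = 1))
#' validate_trial(syn$trial, syn$meta)$ok
validate_trial <- function(trial, meta = NULL, config = default_config()) {
  iss <- issue_df()
  add <- function(code, msg) {
    iss <<- rbind(iss, issue_df(code, msg))
  }
  if (!inherits(trial, "trial_kinematics")) {
    add("bad_type", "not a trial_kinematics object")
    return(validation_report(iss))
  }
  fs <- trial$sample_rate
  n <- n_samples(trial)
  if (!is.finite(fs) || fs <= 0) add("bad_sample_rate", "sample_rate must be > 0")
  need <- config$entry_window_s
  if (n < need * fs) {
    add("too_short", sprintf(
      "trial of %.2f s is too short for the %g s entry window before the foot stance",
      n / fs, need))
  }
  tt <- trial$data$time
  if (n >= 2) {
    dt <- diff(tt)
    if (any(dt <= 0)) add("time_not_increasing", "time must be strictly increasing")
    else if (max(abs(dt - 1 / fs)) > 1e-6)
      add("time_not_uniform",
          sprintf("non-uniform time step (max deviation %.3g s)", max(abs(dt - 1 / fs))))
  }
  for (col in setdiff(names(trial$data), "time")) {
    bad <- which(!is.finite(trial$data[[col]]))
    if (length(bad)) {
      add("nonfinite_value",
          sprintf("non-finite value in %s at sample %d", col, bad[1]))
    }
  }
  if (!is.null(meta)) {
    if (!inherits(meta, "trial_meta")) add("bad_meta", "not a trial_meta object")
  }
  validation_report(iss)
}

#' Read a trial file (CSV with embedded metadata header)
#'
#' One trial per comma-separated text file, wide layout. Metadata lives in a
#' leading comment block of `# key=value` lines (player_id, sex, task,
#' cut_limb, injured_limb, trial_index, optionally age,
#' months_post_surgery, sample_rate), followed by one CSV header row and the
#' numeric data. Columns: `time, pelvis_pos_{x,y,z}, pelvis_vel_{x,y,z}`
#' (velocity optional; derived by central differences of position when
#' absent), `hip_flex_{l,r}, hip_abd_{l,r}, hip_rot_{l,r}, knee_flex_{l,r},
#' knee_valgus_{l,r}, ankle_flex_{l,r}, trunk_lat_bend, trunk_rot`. Units:
#' s, m, m/s, degrees.
#'
#' @param path path to the trial file
#' @return list with elements `trial` ([trial_kinematics()]) and `meta`
#'   ([trial_meta()])
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta_kv <- sub("^#\\s*", "", lines[hdr])
  kv <- strsplit(meta_kv[nzchar(meta_kv)], "=", fixed = TRUE)
  meta_list <- stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
    vapply(kv, function(p) trimws(p[1]), character(1)))
  for (key in c("player_id", "sex", "task", "cut_limb")) {
    if (is.null(meta_list[[key]]))
      stop("metadata header missing mandatory key: ", key)
  }
  body <- lines[!hdr]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns(with_velocity = FALSE), names(df))
  if (length(missing_cols)) {
    stop("trial file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  fs <- as.numeric(meta_list$sample_rate %||% NA)
  if (!is.finite(fs)) {
    dt <- diff(df$time)
    fs <- 1 / stats::median(dt)
  }
  dt <- diff(df$time)
  if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6) {
    stop("non-uniform or non-increasing time step in ", path)
  }
  trial <- trial_kinematics(df, sample_rate = fs)
  meta <- trial_meta(
    player_id = meta_list$player_id,
    sex = meta_list$sex,
    task = meta_list$task,
    cut_limb = meta_list$cut_limb,
    injured_limb = meta_list$injured_limb %||% "none",
    trial_index = as.integer(meta_list$trial_index %||% 1L),
    age = as.numeric(meta_list$age %||% NA),
    months_post_surgery = as.numeric(meta_list$months_post_surgery %||% NA))
  list(trial = trial, meta = meta)
}

#' Write a trial file
#'
#' Inverse of [read_trial()]: metadata as a `# key=value` comment block, then
#' the CSV body. Numeric values are serialized with 15 significant digits so
#' a write/read round trip preserves every field to better than 1e-9 relative
#' tolerance.
#'
#' @param trial a [trial_kinematics()] object
#' @param meta a [trial_meta()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trial <- function(trial, meta, path) {
  rep <- validate_trial(trial, meta)
  if (!rep$ok) {
    stop("refusing to write invalid trial: ",
         paste(rep$issues$code, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  kv <- c(player_id = meta$player_id, sex = meta$sex, task = meta$task,
          cut_limb = meta$cut_limb, injured_limb = meta$injured_limb,
          trial_index = meta$trial_index,
          sample_rate = format(trial$sample_rate, digits = 15))
  if (is.finite(meta$age)) kv <- c(kv, age = meta$age)
  if (is.finite(meta$months_post_surgery))
    kv <- c(kv, months_post_surgery = meta$months_post_surgery)
  writeLines(paste0("# ", names(kv), "=", kv), con)
  df <- trial$data
  writeLines(paste(names(df), collapse = ","), con)
  mat <- vapply(df, function(col) sprintf("%.15g", col), character(nrow(df)))
  writeLines(apply(mat, 1, paste, collapse = ","), con)
  invisible(path)
}
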