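## Per-player six-section report and cohort aggregation. The machine-
## readable JSON document is the acceptance surface: every number in the
## human-readable HTML rendering comes from it, and rendering never alters a
## number. Stance curves are time-normalized to 101 points (0-100% stance)
## before averaging.

REPORT_SCHEMA_VERSION <- "1.0"

# resample a window of a signal to 101 points (0..100% stance)
resample_stance <- function(x, win) {
  seg <- x[win]
  if (length(seg) == 1) return(rep(seg, 101))
  stats::approx(seq(0, 100, length.out = length(seg)), seg,
                xout = 0:100)$y
}

# run the per-trial chain; returns either the full analysis or a failure
# record carrying the stage name
analyze_trial <- function(trial, meta, config = default_config()) {
  res <- list(meta = meta)
  tryCatch({
    vrep <- validate_trial(trial, meta, config)
    if (!vrep$ok)
      stop("validation: ", paste(vrep$issues$code, collapse = ", "))
    contacts <- detect_foot_contacts(trial, config)
    ca <- compute_cut_angle(trial, contacts, config)
    window <- locate_fc_window(trial, contacts, ca$final_sample,
                               meta$cut_limb, config)
    perf <- extract_performance(trial, window, config)
    fv <- list(IC = extract_factor_values(trial, window, "IC", config),
               pKF = extract_factor_values(trial, window, "pKF", config))
    res$ok <- TRUE
    res$trial <- trial
    res$contacts <- contacts
    res$cut <- ca
    res$window <- window
    res$performance <- perf
    res$factor_values <- fv
    res
  }, error = function(e) {
    res$ok <- FALSE
    res$failure <- conditionMessage(e)
    res
  })
}

#' Build the six-section report for one player
#'
#' Runs the full chain (events, cut angle, FC window, performance,
#' asymmetry, risk classification) on every trial of one player and
#' aggregates the results. Trials failing any stage are listed in section 1
#' with the failure message and excluded from sections 2-5.
#'
#' @param trials list of lists with elements `trial` and `meta`, all for one
#'   player
#' @param thresholds a `threshold_library` (e.g. [bundled_table1()])
#' @param norms optional normative statistics from [derive_norms()] (NULL
#'   leaves z-scores/dials and extreme flags unset)
#' @param config pipeline configuration
#' @return object of class `player_report` (a nested list; see the package
#'   vignette for the schema)
#' @export
build_player_report <- function(trials, thresholds, norms = NULL,
                                config = default_config()) {
  stopifnot(length(trials) >= 1)
  metas <- lapply(trials, `[[`, "meta")
  pid <- unique(vapply(metas, `[[`, character(1), "player_id"))
  if (length(pid) != 1) stop("trials belong to more than one player")
  sex <- metas[[1]]$sex
  injured <- metas[[1]]$injured_limb

  analyzed <- lapply(trials, function(tw)
    analyze_trial(tw$trial, tw$meta, config))
  ok <- vapply(analyzed, `[[`, logical(1), "ok")
  if (!any(ok)) stop("report error: no analyzable trial for player ", pid)

  trial_label <- function(m) sprintf("%s_%s_%02d", m$task, m$cut_limb,
                                     m$trial_index)
  failures <- lapply(analyzed[!ok], function(a)
    list(trial = trial_label(a$meta), failure = a$failure))
  good <- analyzed[ok]
  tasks <- sort(unique(vapply(good, function(a) a$meta$task, character(1))))

  section1 <- list(
    player_id = pid, sex = sex, injured_limb = injured,
    age = metas[[1]]$age,
    months_post_surgery = metas[[1]]$months_post_surgery,
    n_trials_total = length(trials),
    n_trials_analyzed = length(good),
    trials_per_task_side = count_task_side(metas),
    excluded_trials = failures)

  per_task <- stats::setNames(lapply(tasks, function(task) {
    sub <- Filter(function(a) a$meta$task == task, good)
    build_task_section(sub, task, sex, injured, thresholds, norms, config)
  }), tasks)

  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    section1_personal = section1,
    section2_cod = lapply(per_task, `[[`, "cod"),
    section3_performance = lapply(per_task, `[[`, "performance"),
    section4_kinematics = lapply(per_task, `[[`, "kinematics"),
    section5_risk = lapply(per_task, `[[`, "risk"),
    section6_remarks = ""),
    class = "player_report")
}

count_task_side <- function(metas) {
  df <- data.frame(task = vapply(metas, `[[`, character(1), "task"),
                   limb = vapply(metas, `[[`, character(1), "cut_limb"))
  as.list(table(paste(df$task, df$limb, sep = "_")))
}

build_task_section <- function(analyzed, task, sex, injured, thresholds,
                               norms, config) {
  labels <- vapply(analyzed, function(a)
    sprintf("%s_%s_%02d", a$meta$task, a$meta$cut_limb, a$meta$trial_index),
    character(1))
  injured_flags <- vapply(analyzed, function(a)
    a$meta$cut_limb == injured, logical(1))

  ## section 2: change of direction
  angles <- vapply(analyzed, function(a) a$cut$final_angle_deg, numeric(1))
  durs <- vapply(analyzed, function(a) a$window$duration_s, numeric(1))
  cod <- list(
    trials = data.frame(trial = labels, cut_angle_deg = angles,
                        fc_duration_s = durs, stringsAsFactors = FALSE),
    mean_cut_angle_deg = mean(angles),
    sd_cut_angle_deg = if (length(angles) > 1) stats::sd(angles) else 0)

  ## section 3: performance with dials
  pkey <- paste(sex, task, sep = "|")
  pnorms <- norms$performance[[pkey]]
  perf_rows <- lapply(seq_along(analyzed), function(i) {
    p <- score_performance(analyzed[[i]]$performance, pnorms)
    c(list(trial = labels[i]),
      p[PERF_METRICS],
      stats::setNames(p$z, paste0("z_", PERF_METRICS)),
      stats::setNames(p$dial, paste0("dial_", PERF_METRICS)))
  })
  performance <- list(trials = perf_rows)

  ## section 4: asymmetry + normalized stance curves
  tw <- lapply(analyzed, function(a) list(trial = a$trial,
                                          window = a$window))
  both_limbs <- length(unique(vapply(tw, function(x) x$window$stance_limb,
                                     character(1)))) == 2
  kinematics <- list(asymmetry = NULL, curves = NULL)
  if (both_limbs) {
    kinematics$asymmetry <- analyze_asymmetry(
      tw, injured, norms$asymmetry[[pkey]], config)
    inj_limb <- if (injured == "none") "left" else injured
    kinematics$curves <- stance_curves(tw, inj_limb,
                                       norms$curves[[pkey]])
  }

  ## section 5: risk factors per frame
  risk <- stats::setNames(lapply(c("IC", "pKF"), function(frame) {
    tset <- threshold_set(thresholds, sex, task, frame)
    frs <- lapply(analyzed, function(a)
      classify_factors(a$factor_values[[frame]], tset))
    summ <- player_summary(frs, labels, injured_flags)
    list(
      per_trial = lapply(seq_along(frs), function(i)
        c(list(trial = labels[i]),
          list(table = as.data.frame(frs[[i]])),
          list(n_factors_at_risk = trial_risk(frs[[i]])$n_factors_at_risk,
               overall_at_risk = trial_risk(frs[[i]])$overall_at_risk))),
      summary = list(
        factors = summ$factors,
        n_trials = summ$n_trials,
        n_overall_at_risk = summ$n_overall_at_risk,
        n_overall_injured = summ$n_overall_injured,
        n_overall_noninjured = summ$n_overall_noninjured,
        category_pct_trials = as.list(summ$category_pct_trials),
        category_red = as.list(summ$category_red)))
  }), c("IC", "pKF"))

  list(cod = cod, performance = performance, kinematics = kinematics,
       risk = risk)
}

# time-normalized (0-100% stance) mean curves per joint for injured and
# non-injured limbs, plus the normative band when available
stance_curves <- function(trials_windows, injured_limb, curve_norms = NULL) {
  other <- if (injured_limb == "left") "right" else "left"
  one_limb <- function(limb) {
    use <- Filter(function(x) x$window$stance_limb == limb, trials_windows)
    lapply(stats::setNames(nm = names(ASYM_JOINTS)), function(joint) {
      mat <- vapply(use, function(x) {
        resample_stance(limb_signal(x$trial, ASYM_JOINTS[[joint]], limb),
                        seq(x$window$start, x$window$end - 1L))
      }, numeric(101))
      rowMeans(matrix(mat, nrow = 101))
    })
  }
  out <- list(injured = one_limb(injured_limb), noninjured = one_limb(other))
  if (!is.null(curve_norms)) out$normative = curve_norms
  out
}

#' Derive normative statistics from a control cohort
#'
#' Runs the pipeline on healthy-control trials and summarizes, per
#' sex-by-task stratum: performance metrics (mean/SD across trials),
#' inter-limb asymmetry percentages (left vs right, mean/SD across players),
#' and time-normalized stance curves (mean/SD band per joint).
#'
#' @param cohort list of lists with `trial` and `meta` elements (e.g. from
#'   [generate_control_cohort()])
#' @param config pipeline configuration
#' @return nested list with elements `performance`, `asymmetry`, `curves`,
#'   each keyed by `"<sex>|<task>"`
#' @export
derive_norms <- function(cohort, config = default_config()) {
  analyzed <- lapply(cohort, function(tw)
    analyze_trial(tw$trial, tw$meta, config))
  analyzed <- Filter(function(a) a$ok, analyzed)
  if (length(analyzed) < 2) stop("too few analyzable control trials")
  keys <- vapply(analyzed, function(a)
    paste(a$meta$sex, a$meta$task, sep = "|"), character(1))
  out <- list(performance = list(), asymmetry = list(), curves = list())
  for (key in unique(keys)) {
    sub <- analyzed[keys == key]
    sx <- strsplit(key, "|", fixed = TRUE)[[1]]
    ## performance
    out$performance[[key]] <- lapply(
      stats::setNames(nm = PERF_METRICS), function(m) {
        x <- vapply(sub, function(a) a$performance[[m]], numeric(1))
        norm_stats(m, mean(x), stats::sd(x), length(x),
                   sex = sx[1], task = sx[2])
      })
    ## asymmetry: per player left vs right (controls have no injured limb)
    pids <- vapply(sub, function(a) a$meta$player_id, character(1))
    pcts <- lapply(unique(pids), function(pid) {
      tws <- lapply(sub[pids == pid], function(a)
        list(trial = a$trial, window = a$window))
      limbs <- vapply(tws, function(x) x$window$stance_limb, character(1))
      if (length(unique(limbs)) < 2) return(NULL)
      l <- limb_summary(tws, "left"); r <- limb_summary(tws, "right")
      vapply(names(ASYM_JOINTS), function(j)
        asymmetry_percent(l[[j]], r[[j]], config)$pct, numeric(1))
    })
    pcts <- Filter(Negate(is.null), pcts)
    if (length(pcts) >= 2) {
      mat <- do.call(rbind, pcts)
      out$asymmetry[[key]] <- lapply(
        stats::setNames(nm = names(ASYM_JOINTS)), function(j)
          norm_stats(paste0("asym_", j), mean(mat[, j]), stats::sd(mat[, j]),
                     nrow(mat), sex = sx[1], task = sx[2]))
    }
    ## curves: pooled over trials and limbs
    out$curves[[key]] <- lapply(
      stats::setNames(nm = names(ASYM_JOINTS)), function(joint) {
        mat <- vapply(sub, function(a) {
          resample_stance(
            limb_signal(a$trial, ASYM_JOINTS[[joint]],
                        a$window$stance_limb),
            seq(a$window$start, a$window$end - 1L))
        }, numeric(101))
        mat <- matrix(mat, nrow = 101)
        list(mean = rowMeans(mat), sd = apply(mat, 1, stats::sd))
      })
  }
  out
}

#' Render a player report to files
#'
#' Writes (a) `report.json`, the machine-readable document containing every
#' number, and (b) optionally `report.html`, a standalone human-readable
#' page with speedometer dials, asymmetry bars, per-factor risk wheels and
#' the category dashboard, all drawn from the JSON content.
#'
#' @param report a `player_report` from [build_player_report()]
#' @param out_dir output directory (created if needed)
#' @param formats subset of c("json", "html")
#' @return named character vector of written paths, invisibly
#' @export
render_report <- function(report, out_dir, formats = c("json", "html")) {
  bad <- setdiff(formats, c("json", "html"))
  if (length(bad)) stop("unknown format key(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pid <- report$section1_personal$player_id
  written <- character(0)
  if ("json" %in% formats) {
    path <- file.path(out_dir, paste0(pid, "_report.json"))
    writeLines(report_json(report), path)
    written["json"] <- path
  }
  if ("html" %in% formats) {
    path <- file.path(out_dir, paste0(pid, "_report.html"))
    writeLines(render_html(report), path)
    written["html"] <- path
  }
  invisible(written)
}

# canonical JSON serialization: fixed digits => byte-identical for equal
# inputs
report_json <- function(report) {
  jsonlite::toJSON(unclass(report), digits = I(10), auto_unbox = TRUE,
                   pretty = TRUE, na = "null", null = "null",
                   dataframe = "rows")
}

#' Read back a machine-readable report
#'
#' @param path path to a `*_report.json` file written by [render_report()]
#' @return nested list mirroring the `player_report` structure
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full pipeline over a directory of trial files
#'
#' Reads every `*.csv` trial in `data_dir`, groups trials by player, builds
#' one report per player and a cohort summary. Per-trial read or analysis
#' failures are logged, not fatal.
#'
#' @param data_dir directory of trial CSV files (see [read_trial()])
#' @param thresholds a `threshold_library`
#' @param norms optional normative statistics from [derive_norms()]
#' @param out_dir optional output directory; when given, every player report
#'   is rendered there plus `cohort_report.json`
#' @param formats formats for [render_report()]
#' @param config pipeline configuration
#' @return list with `reports` (per player), `cohort` (see
#'   [build_cohort_report()]), and `log` (character vector)
#' @export
run_pipeline <- function(data_dir, thresholds = bundled_table1(),
                         norms = NULL, out_dir = NULL,
                         formats = c("json", "html"),
                         config = default_config()) {
  files <- sort(list.files(data_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("input error: no trial files in ", data_dir)
  log <- character(0)
  loaded <- list()
  for (f in files) {
    r <- tryCatch(read_trial(f), error = function(e) e)
    if (inherits(r, "error")) {
      log <- c(log, sprintf("SKIP %s: %s", basename(f), conditionMessage(r)))
    } else {
      log <- c(log, sprintf("READ %s: player=%s task=%s", basename(f),
                            r$meta$player_id, r$meta$task))
      loaded[[length(loaded) + 1L]] <- r
    }
  }
  if (length(loaded) == 0) stop("input error: no readable trials")
  pids <- vapply(loaded, function(x) x$meta$player_id, character(1))
  reports <- list()
  for (pid in unique(pids)) {
    rep <- tryCatch(
      build_player_report(loaded[pids == pid], thresholds, norms, config),
      error = function(e) e)
    if (inherits(rep, "error")) {
      log <- c(log, sprintf("FAIL player %s: %s", pid, conditionMessage(rep)))
    } else {
      reports[[pid]] <- rep
      nfail <- length(rep$section1_personal$excluded_trials)
      log <- c(log, sprintf("REPORT player %s (%d trials, %d excluded)", pid,
                            rep$section1_personal$n_trials_analyzed, nfail))
      if (!is.null(out_dir)) render_report(rep, out_dir, formats)
    }
  }
  cohort <- build_cohort_report(reports)
  if (!is.null(out_dir)) {
    writeLines(jsonlite::toJSON(cohort, digits = I(10), auto_unbox = TRUE,
                                pretty = TRUE, na = "null",
                                dataframe = "rows"),
               file.path(out_dir, "cohort_report.json"))
  }
  list(reports = reports, cohort = cohort, log = log)
}

#' Aggregate player reports into a cohort report
#'
#' Per task and frame: counts of players per traffic-light color bin for
#' each factor (rows partition the player set), and overall-risk trial
#' counts split by injured / non-injured limb.
#'
#' @param reports named list of `player_report` objects
#' @return nested list keyed task, then frame, with `factor_bin_counts` and
#'   `overall_risk` counts
#' @export
build_cohort_report <- function(reports) {
  tasks <- unique(unlist(lapply(reports, function(r)
    names(r$section5_risk))))
  out <- list(n_players = length(reports))
  for (task in tasks) {
    out[[task]] <- list()
    for (frame in c("IC", "pKF")) {
      bins <- c("green", "yellow", "orange", "red")
      fd <- factor_defs()
      counts <- matrix(0L, nrow(fd), 4, dimnames = list(fd$factor_id, bins))
      n_trials <- 0L; n_risk <- 0L; n_inj <- 0L; n_non <- 0L
      for (r in reports) {
        s5 <- r$section5_risk[[task]]
        if (is.null(s5)) next
        summ <- s5[[frame]]$summary
        for (j in seq_len(nrow(summ$factors))) {
          counts[summ$factors$factor_id[j], summ$factors$color_bin[j]] <-
            counts[summ$factors$factor_id[j], summ$factors$color_bin[j]] + 1L
        }
        n_trials <- n_trials + summ$n_trials
        n_risk <- n_risk + summ$n_overall_at_risk
        n_inj <- n_inj + summ$n_overall_injured
        n_non <- n_non + summ$n_overall_noninjured
      }
      out[[task]][[frame]] <- list(
        factor_bin_counts = data.frame(factor_id = rownames(counts), counts,
                                       row.names = NULL,
                                       stringsAsFactors = FALSE),
        overall_risk = list(n_trials = n_trials, n_at_risk = n_risk,
                            n_at_risk_injured = n_inj,
                            n_at_risk_noninjured = n_non))
    }
  }
  out
}
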