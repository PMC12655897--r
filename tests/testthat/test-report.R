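# build a small player's trial set: n trials, alternating limbs
player_trials <- function(pid = "ACLR04", n = 4, angle = 66, seed0 = 500,
                          noise = 0.05, injured = "left", task = "AGTT") {
  lapply(seq_len(n), function(k) {
    syn <- generate_cut_trial(synth_params(
      cut_angle_deg = angle, noise_sd = noise, seed = seed0 + k,
      player_id = pid, task = task,
      cut_limb = if (k %% 2 == 1) "left" else "right",
      injured_limb = injured, trial_index = k))
    list(trial = syn$trial, meta = syn$meta)
  })
}

test_that("report aggregates known cut angles", {
  trials <- player_trials(n = 6, angle = 66, noise = 0)
  rep <- build_player_report(trials, bundled_table1())
  expect_equal(rep$section2_cod$AGTT$mean_cut_angle_deg, 66, tolerance = 1)
  expect_lt(rep$section2_cod$AGTT$sd_cut_angle_deg, 1)
  expect_equal(rep$section1_personal$n_trials_analyzed, 6)
  expect_identical(rep$section6_remarks, "")
})

test_that("failed trials are excluded and logged in section 1", {
  trials <- player_trials(n = 3, noise = 0)
  # straight-run trial: no cut to detect
  tr <- flat_trial(duration_s = 6)
  tr$data$pelvis_vel_z <- -0.4 * cos(2 * pi * 3 * tr$data$time)
  trials[[4]] <- list(trial = tr,
                      meta = trial_meta("ACLR04", "male", "AGTT", "right",
                                        "left", 4L))
  rep <- build_player_report(trials, bundled_table1())
  expect_equal(rep$section1_personal$n_trials_analyzed, 3)
  excl <- rep$section1_personal$excluded_trials
  expect_length(excl, 1)
  expect_match(excl[[1]]$failure, "no-cut|no local maximum")
})

test_that("machine-readable report is byte-identical across runs", {
  trials <- player_trials(n = 4)
  ctrl <- generate_control_cohort(4, seed = 3, trials_per_player = 2)
  norms <- derive_norms(ctrl)
  r1 <- build_player_report(trials, bundled_table1(), norms)
  r2 <- build_player_report(trials, bundled_table1(), norms)
  expect_identical(cutrisk:::report_json(r1), cutrisk:::report_json(r2))
})

test_that("rendered outputs carry the report's numbers", {
  trials <- player_trials(n = 4)
  rep <- build_player_report(trials, bundled_table1())
  out <- withr::local_tempdir()
  paths <- render_report(rep, out, formats = c("json", "html"))
  back <- read_report(paths[["json"]])
  expect_equal(back$section2_cod$AGTT$mean_cut_angle_deg,
               rep$section2_cod$AGTT$mean_cut_angle_deg)
  expect_equal(back$schema_version, rep$schema_version)
  html <- paste(readLines(paths[["html"]]), collapse = "\n")
  # the mean cut angle as displayed must appear in the page
  expect_match(html, formatC(rep$section2_cod$AGTT$mean_cut_angle_deg,
                             format = "f", digits = 1), fixed = TRUE)
  expect_match(html, "6. Final remarks")
  expect_error(render_report(rep, out, formats = "pdf"), "unknown format")
})

test_that("run_pipeline processes a folder and survives a corrupt file", {
  dir <- withr::local_tempdir()
  for (pid in c("P01", "P02")) {
    for (tw in player_trials(pid = pid, n = 2, seed0 = match(pid, c("P01", "P02")) * 50))
      write_trial(tw$trial, tw$meta,
                  file.path(dir, sprintf("%s_%d.csv", pid, tw$meta$trial_index)))
  }
  writeLines("garbage,not,a,trial", file.path(dir, "corrupt.csv"))
  out <- withr::local_tempdir()
  res <- run_pipeline(dir, bundled_table1(), out_dir = out,
                      formats = "json")
  expect_length(res$reports, 2)
  expect_true(any(grepl("SKIP corrupt.csv", res$log)))
  expect_true(file.exists(file.path(out, "P01_report.json")))
  expect_true(file.exists(file.path(out, "cohort_report.json")))
  # cohort counts partition players
  counts <- res$cohort$AGTT$IC$factor_bin_counts
  expect_true(all(rowSums(counts[, c("green", "yellow", "orange", "red")])
                  == 2))
  expect_error(run_pipeline(withr::local_tempdir()), "input error")
})

test_that("asymmetry and curves appear when both limbs are present", {
  trials <- player_trials(n = 4, noise = 0)
  rep <- build_player_report(trials, bundled_table1())
  kin <- rep$section4_kinematics$AGTT
  expect_named(kin$asymmetry, c("hip", "knee", "ankle"))
  expect_length(kin$curves$injured$knee, 101)
  # symmetric generator defaults: near-zero asymmetry
  expect_lt(kin$asymmetry$knee$pct, 5)
})

test_that("CLI synth and cutangle subcommands work end to end", {
  dir <- withr::local_tempdir()
  cutrisk_main(c("synth", "--out", dir, "--n", "2", "--seed", "5",
                 "--noise", "0"))
  files <- list.files(dir, pattern = "\\.csv$")
  expect_length(files, 2)
  out <- file.path(dir, "angles.csv")
  cutrisk_main(c("cutangle", "--data", dir, "--out", out))
  tab <- utils::read.csv(out)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$final_angle_deg, c(75, 75), tolerance = 2)
})
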