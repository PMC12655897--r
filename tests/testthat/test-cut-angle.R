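test_that("straight-line path yields only near-zero candidates", {
  tr <- flat_trial(duration_s = 6)
  # hand-made contacts every 0.33 s
  fc <- structure(list(contact_samples = as.integer(seq(40, 560, by = 33)),
                       source_signal = "test"), class = "foot_contacts")
  cand <- candidate_angles(segment_steps(fc, tr), tr)
  expect_true(all(cand$angle_deg < 1))
})

test_that("candidate at the cut step recovers the true angle", {
  syn <- clean_trial(angle = 90, seed = 2)
  fc <- detect_foot_contacts(syn$trial)
  cand <- candidate_angles(segment_steps(fc, syn$trial), syn$trial)
  at_cut <- cand[abs(cand$sample - syn$truth$cut_sample) <= 2, ]
  expect_equal(at_cut$angle_deg[1], 90, tolerance = 2)
})

test_that("direction reversal gives a ~180 degree candidate", {
  fs <- 100; n <- 600
  tt <- (seq_len(n) - 1) / fs
  x <- ifelse(tt < 3, 5 * tt, 15 - 5 * (tt - 3))
  df <- data.frame(time = tt, pelvis_pos_x = x, pelvis_pos_y = 0,
                   pelvis_pos_z = 1, pelvis_vel_x = c(diff(x), 0) * fs,
                   pelvis_vel_y = 0, pelvis_vel_z = 0)
  for (col in setdiff(cutrisk:::trial_columns(FALSE), names(df)))
    df[[col]] <- 0
  tr <- trial_kinematics(df, fs)
  fc <- structure(list(contact_samples = as.integer(seq(35, 565, by = 33)),
                       source_signal = "test"), class = "foot_contacts")
  cand <- candidate_angles(segment_steps(fc, tr), tr)
  expect_gt(max(cand$angle_deg), 175)
})

test_that("insufficient steps raise an error", {
  tr <- flat_trial()
  fc <- structure(list(contact_samples = as.integer(seq(40, 300, by = 33)),
                       source_signal = "test"), class = "foot_contacts")
  expect_error(candidate_angles(segment_steps(fc, tr), tr),
               "insufficient steps")
})

test_that("plausibility filter keeps [10, 110] inclusive", {
  cand <- data.frame(step_index = 1:5, sample = 1:5,
                     angle_deg = c(5, 45, 120, 10, 110))
  kept <- plausibility_filter(cand)
  expect_equal(kept$angle_deg, c(45, 10, 110))
  expect_equal(nrow(plausibility_filter(cand[0, ])), 0)
})

test_that("velocity filter keeps the cut candidate and errors on monotone speed", {
  syn <- clean_trial(seed = 3)
  fc <- detect_foot_contacts(syn$trial)
  cand <- candidate_angles(segment_steps(fc, syn$trial), syn$trial)
  vel <- velocity_interval_filter(plausibility_filter(cand), syn$trial)
  expect_true(any(abs(vel$sample - syn$truth$cut_sample) <= 2))
  # strictly increasing speed: no interior maximum
  fs <- 100; n <- 400
  tt <- (seq_len(n) - 1) / fs
  df <- data.frame(time = tt, pelvis_pos_x = tt + tt^2, pelvis_pos_y = 0,
                   pelvis_pos_z = 1, pelvis_vel_x = 1 + 2 * tt,
                   pelvis_vel_y = 0, pelvis_vel_z = 0)
  for (col in setdiff(cutrisk:::trial_columns(FALSE), names(df)))
    df[[col]] <- 0
  mono <- trial_kinematics(df, fs)
  expect_error(velocity_interval_filter(cand, mono), "no local maximum")
})

test_that("derivative window retains only candidates within 250 ms", {
  syn <- clean_trial(seed = 4)
  fc <- detect_foot_contacts(syn$trial)
  cand <- candidate_angles(segment_steps(fc, syn$trial), syn$trial)
  vel <- velocity_interval_filter(plausibility_filter(cand), syn$trial)
  der <- derivative_window_filter(vel, syn$trial)
  m <- attr(der, "derivative_peak_sample")
  expect_true(all(abs(der$sample - m) <= 25))
  dropped <- vel[!vel$sample %in% der$sample, ]
  if (nrow(dropped)) expect_true(all(abs(dropped$sample - m) > 25))
})

test_that("compute_cut_angle recovers task-typical angles", {
  # pre-planned 90-degree-drill-like cut
  agtt <- clean_trial(angle = 75, seed = 11, task = "AGTT")
  fc <- detect_foot_contacts(agtt$trial)
  r <- compute_cut_angle(agtt$trial, fc)
  expect_equal(r$final_angle_deg, 75, tolerance = 5)
  # shallower unplanned cut
  fsd <- clean_trial(angle = 33, seed = 12, task = "FS",
                     exit_speed = 4.2)
  fc <- detect_foot_contacts(fsd$trial)
  r <- compute_cut_angle(fsd$trial, fc)
  expect_equal(r$final_angle_deg, 33, tolerance = 5)
})

test_that("filters only remove (subset chain) and bounds hold", {
  syn <- generate_cut_trial(synth_params(noise_sd = 0.05, seed = 13))
  fc <- detect_foot_contacts(syn$trial)
  r <- compute_cut_angle(syn$trial, fc)
  expect_true(all(r$plausible$sample %in% r$candidates$sample))
  expect_true(all(r$velocity_eligible$sample %in% r$plausible$sample))
  expect_true(all(r$derivative_eligible$sample %in% r$velocity_eligible$sample))
  expect_gte(r$final_angle_deg, 10)
  expect_lte(r$final_angle_deg, 110)
  expect_equal(r$final_angle_deg, max(r$derivative_eligible$angle_deg))
})

test_that("straight run reports no cut", {
  fs <- 100; n <- 700
  tt <- (seq_len(n) - 1) / fs
  # straight path with realistic speed bump and step oscillation
  speed <- 4 + 0.5 * sin(2 * pi * tt / 7)
  px <- cumsum(speed) / fs
  vz <- -0.4 * cos(2 * pi * 3 * (tt - 0.5))
  df <- data.frame(time = tt, pelvis_pos_x = px, pelvis_pos_y = 0,
                   pelvis_pos_z = 1, pelvis_vel_x = speed, pelvis_vel_y = 0,
                   pelvis_vel_z = vz)
  for (col in setdiff(cutrisk:::trial_columns(FALSE), names(df)))
    df[[col]] <- 20
  tr <- trial_kinematics(df, fs)
  fc <- detect_foot_contacts(tr)
  expect_error(compute_cut_angle(tr, fc), "no-cut-detected")
})

test_that("candidate angles are rotation invariant", {
  syn <- clean_trial(seed = 14)
  fc <- detect_foot_contacts(syn$trial)
  cand1 <- candidate_angles(segment_steps(fc, syn$trial), syn$trial)
  phi <- 37 * pi / 180
  d <- syn$trial$data
  x <- d$pelvis_pos_x * cos(phi) - d$pelvis_pos_y * sin(phi)
  y <- d$pelvis_pos_x * sin(phi) + d$pelvis_pos_y * cos(phi)
  d$pelvis_pos_x <- x; d$pelvis_pos_y <- y
  tr2 <- trial_kinematics(d, syn$trial$sample_rate)
  cand2 <- candidate_angles(segment_steps(fc, tr2), tr2)
  expect_equal(cand1$angle_deg, cand2$angle_deg, tolerance = 1e-6)
})
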