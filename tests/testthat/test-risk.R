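male_agtt_ic <- function() threshold_set(bundled_table1(), "male", "AGTT", "IC")

# a factor-value vector violating no male/AGTT/IC threshold
safe_vals <- function(frame = "IC") {
  factor_values(frame, HK = 0.5, HF = 40, KF = 35, AF = -8, KV = 1.5,
                HA = 2, HI = 10, TIB = 8, TCR = 5)
}

test_that("planted factor targets are extracted at both frames", {
  tg <- c("KF@IC" = 30, "KV@IC" = 3.0, "KF@pKF" = 68, "KV@pKF" = 4.2)
  syn <- generate_cut_trial(synth_params(noise_sd = 0, seed = 9,
                                         factor_targets = tg))
  fc <- detect_foot_contacts(syn$trial)
  w <- locate_fc_window(syn$trial, fc, syn$truth$cut_sample,
                        syn$meta$cut_limb)
  ic <- extract_factor_values(syn$trial, w, "IC")
  pkf <- extract_factor_values(syn$trial, w, "pKF")
  expect_equal(ic$KF, 30, tolerance = 0.1)
  expect_equal(ic$KV, 3.0, tolerance = 0.1)
  expect_equal(pkf$KF, 68, tolerance = 0.3)
  expect_equal(pkf$KV, 4.2, tolerance = 0.3)
})

test_that("HK ratio of constant signals is the plain ratio", {
  tr <- flat_trial(duration_s = 5, angles = 0)
  tr$data$knee_flex_r[] <- 50
  tr$data$hip_flex_r[] <- 40
  w <- structure(list(start = 300L, end = 330L, ic = 300L, pkf = 315L,
                      stance_limb = "right", duration_s = 0.3),
                 class = "fc_window")
  expect_equal(extract_factor_values(tr, w, "IC")$HK, 1.25)
  expect_equal(extract_factor_values(tr, w, "pKF")$HK, 1.25)
})

test_that("mirrored trials give identical factor values", {
  tg <- c("KF@IC" = 31, "KV@pKF" = 4)
  run <- function(limb) {
    syn <- generate_cut_trial(synth_params(noise_sd = 0, seed = 10,
                                           cut_limb = limb,
                                           factor_targets = tg))
    fc <- detect_foot_contacts(syn$trial)
    w <- locate_fc_window(syn$trial, fc, syn$truth$cut_sample, limb)
    extract_factor_values(syn$trial, w, "IC")
  }
  left <- run("left"); right <- run("right")
  for (fid in cutrisk:::FACTOR_IDS)
    expect_equal(left[[fid]], right[[fid]], label = fid)
})

test_that("classification matches the published directional rules", {
  ts <- male_agtt_ic()
  v <- safe_vals()
  expect_false(any(classify_factors(v, ts)$at_risk))
  # KF below 32.2 is at risk
  v$KF <- 30
  fr <- classify_factors(v, ts)
  expect_true(fr$at_risk[fr$factor_id == "KF"])
  # KV exactly double its 2.3 threshold: deviation 100%, not yet "extreme"
  v <- safe_vals(); v$KV <- 4.6
  fr <- classify_factors(v, ts)
  kv <- fr[fr$factor_id == "KV", ]
  expect_true(kv$at_risk)
  expect_equal(kv$deviation_pct, 100)
  expect_false(kv$extreme)
  # beyond double -> extreme
  v$KV <- 4.7
  fr <- classify_factors(v, ts)
  expect_true(fr[fr$factor_id == "KV", "extreme"])
  # HA at risk through the adduction bound
  v <- safe_vals(); v$HA <- -9.0
  fr <- classify_factors(v, ts)
  ha <- fr[fr$factor_id == "HA", ]
  expect_true(ha$at_risk)
  expect_equal(ha$threshold, -7.8)
})

test_that("zero threshold reports absolute deviation, never extreme", {
  ts <- threshold_set(bundled_table1(), "male", "FS", "IC")  # HK > 0.0
  v <- safe_vals(); v$frame <- "IC"
  v$HK <- 0.4
  fr <- classify_factors(v, ts)
  hk <- fr[fr$factor_id == "HK", ]
  expect_true(hk$at_risk)
  expect_true(is.na(hk$deviation_pct))
  expect_equal(hk$deviation_abs, 0.4)
  expect_false(hk$extreme)
})

test_that("frame mismatch between values and thresholds errors", {
  expect_error(classify_factors(safe_vals("pKF"), male_agtt_ic()),
               "stratum mismatch")
})

test_that("overall risk needs at least four factors", {
  ts <- male_agtt_ic()
  v <- safe_vals()
  # violate thresholds one factor at a time: KF low, HF high, KV high, HI high
  risky <- list(KF = 30, HF = 45, KV = 3, HI = 16, TIB = 12)
  for (k in 0:5) {
    vv <- v
    for (f in names(risky)[seq_len(k)]) vv[[f]] <- risky[[f]]
    tr <- trial_risk(classify_factors(vv, ts))
    expect_identical(tr$n_factors_at_risk, k)
    expect_identical(tr$overall_at_risk, k >= 4)
  }
})

test_that("category flags require every factor of the category", {
  ts <- male_agtt_ic()
  v <- safe_vals()
  v$TIB <- 12; v$TCR <- 8  # both TPI factors
  tr <- trial_risk(classify_factors(v, ts))
  expect_true(tr$category_at_risk[["TPI"]])
  expect_false(tr$category_at_risk[["SKL"]])
  v$TCR <- 5  # only one TPI factor
  tr <- trial_risk(classify_factors(v, ts))
  expect_false(tr$category_at_risk[["TPI"]])
})

test_that("classification agrees with a brute-force oracle", {
  lib <- bundled_table1()
  withr::with_seed(77, {
    for (i in 1:200) {
      frame <- sample(c("IC", "pKF"), 1)
      sex <- sample(c("male", "female"), 1)
      task <- sample(c("AGTT", "FS"), 1)
      fv <- random_factor_values(frame)
      got <- classify_factors(fv, threshold_set(lib, sex, task, frame))
      want <- oracle_classify(fv, sex, task, frame)
      expect_identical(stats::setNames(got$at_risk, got$factor_id), want)
    }
  })
})

test_that("raising knee valgus never lowers the at-risk count", {
  ts <- male_agtt_ic()
  withr::with_seed(88, {
    for (i in 1:20) {
      fv <- random_factor_values("IC")
      kvs <- sort(runif(5, -5, 10))
      counts <- vapply(kvs, function(kv) {
        fv$KV <- kv
        trial_risk(classify_factors(fv, ts))$n_factors_at_risk
      }, integer(1))
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("player summary bins percentages per the pie-chart rules", {
  ts <- male_agtt_ic()
  mk <- function(kv) {
    v <- safe_vals(); v$KV <- kv
    classify_factors(v, ts)
  }
  # 4 of 6 trials at risk for KV -> 66.7% -> orange
  frs <- lapply(c(3, 3, 3, 3, 1, 1), mk)
  ps <- player_summary(frs, injured_flags = rep(c(TRUE, FALSE), 3))
  kv <- ps$factors[ps$factors$factor_id == "KV", ]
  expect_equal(kv$pct_trials_at_risk, 400 / 6, tolerance = 1e-9)
  expect_identical(kv$color_bin, "orange")
  expect_true(kv$majority_flag)
  # 0 of 6 -> green; 5 of 6 -> red
  ps0 <- player_summary(lapply(rep(1, 6), mk))
  expect_identical(ps0$factors[ps0$factors$factor_id == "KV", "color_bin"],
                   "green")
  ps5 <- player_summary(lapply(c(3, 3, 3, 3, 3, 1), mk))
  expect_identical(ps5$factors[ps5$factors$factor_id == "KV", "color_bin"],
                   "red")
  expect_error(player_summary(list()), "zero analyzed trials")
})

test_that("color_bin edges: 50 stays yellow, 70 stays orange", {
  expect_identical(color_bin(0), "green")
  expect_identical(color_bin(19.9), "green")
  expect_identical(color_bin(20), "yellow")
  expect_identical(color_bin(50), "yellow")
  expect_identical(color_bin(50.1), "orange")
  expect_identical(color_bin(70), "orange")
  expect_identical(color_bin(70.1), "red")
  expect_identical(color_bin(100), "red")
})

test_that("cohort counts partition the player set", {
  ts <- male_agtt_ic()
  mk_player <- function(n_risky) {
    frs <- lapply(seq_len(6), function(i) {
      v <- safe_vals()
      if (i <= n_risky) v$KV <- 5
      classify_factors(v, ts)
    })
    player_summary(frs)
  }
  summaries <- lapply(c(0, 2, 4, 5, 6), mk_player)
  cs <- cohort_summary(summaries)
  expect_true(all(rowSums(cs[, c("green", "yellow", "orange", "red")]) == 5))
  kv <- cs[cs$factor_id == "KV", ]
  # 0/6 green; 2/6 yellow; 4/6, 5/6 red? 4/6=66.7 orange, 5/6=83.3 red, 6/6 red
  expect_equal(kv$green, 1)
  expect_equal(kv$yellow, 1)
  expect_equal(kv$orange, 1)
  expect_equal(kv$red, 2)
})
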