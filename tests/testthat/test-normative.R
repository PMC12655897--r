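test_that("bundled library spot values match the published table", {
  lib <- bundled_table1()
  ts <- threshold_set(lib, "male", "AGTT", "IC")
  expect_equal(cutrisk:::threshold_value(ts, "KF"), 32.2)
  expect_equal(ts$table["KF", "direction"], "below")
  expect_equal(cutrisk:::threshold_value(ts, "HAbd"), 10.3)
  expect_equal(cutrisk:::threshold_value(ts, "HAdd"), -7.8)
  ts <- threshold_set(lib, "female", "FS", "pKF")
  expect_equal(cutrisk:::threshold_value(ts, "KV"), 3.2)
  expect_equal(ts$table["KV", "direction"], "above")
  # the "> -0.0" oddity is carried as 0.0
  ts <- threshold_set(lib, "female", "FS", "IC")
  expect_identical(cutrisk:::threshold_value(ts, "HK"), 0)
})

test_that("bundled library re-serializes byte-identically", {
  lib <- bundled_table1()
  path <- withr::local_tempfile(fileext = ".csv")
  write_thresholds(lib, path)
  ref <- system.file("extdata", "table1_thresholds.csv", package = "cutrisk")
  expect_identical(readLines(path), readLines(ref))
  # and round-trips through the reader
  expect_identical(read_thresholds(path)$table$value, lib$table$value)
})

test_that("library covers all 8 strata x 10 rows", {
  lib <- bundled_table1()
  tab <- lib$table
  strata <- unique(tab[c("sex", "task", "frame")])
  expect_equal(nrow(strata), 8)
  counts <- table(paste(tab$sex, tab$task, tab$frame))
  expect_true(all(counts == 10))
})

mk_vals <- function(n, gen) {
  keys <- apply(cutrisk:::ALL_STRATA, 1, paste, collapse = "|")
  keys <- gsub(" ", "", keys)
  out <- lapply(keys, function(k)
    lapply(stats::setNames(nm = cutrisk:::FACTOR_IDS), function(f) gen(n)))
  stats::setNames(out, keys)
}

test_that("derived threshold follows mu +/- 1.05 sigma", {
  vals <- mk_vals(2, function(n) c(35, 45))
  lib <- derive_thresholds(vals, tolerance_pct = 5)
  mu <- 40; sg <- stats::sd(c(35, 45))
  ts <- threshold_set(lib, "male", "AGTT", "IC")
  expect_equal(cutrisk:::threshold_value(ts, "KF"), mu - 1.05 * sg)
  expect_equal(cutrisk:::threshold_value(ts, "HF"), mu + 1.05 * sg)
  expect_equal(cutrisk:::threshold_value(ts, "HAbd"), mu + 1.05 * sg)
  expect_equal(cutrisk:::threshold_value(ts, "HAdd"), mu - 1.05 * sg)
  # hand value: mu = 40, sigma = 5, tol 5% -> below threshold 34.75
  vals5 <- mk_vals(2, identity)
  for (k in names(vals5)) vals5[[k]] <- lapply(vals5[[k]], function(.)
    c(40 - 5 / sqrt(2) * sqrt(1), 40 + 5 / sqrt(2)))  # sd exactly 5
  lib5 <- derive_thresholds(vals5, tolerance_pct = 5)
  ts5 <- threshold_set(lib5, "male", "AGTT", "IC")
  expect_equal(cutrisk:::threshold_value(ts5, "KF"), 34.75)
})

test_that("derived thresholds are consistent on large cohorts", {
  withr::with_seed(21, {
    vals <- mk_vals(200, function(n) rnorm(n, 40, 5))
    lib <- derive_thresholds(vals)
    # within 3 standard errors of mu - 1.05 sigma (se ~ sigma*sqrt(1/n + 1.05^2/(2n)))
    se <- 5 * sqrt(1 / 200 + 1.05^2 / (2 * 200))
    ts <- threshold_set(lib, "female", "FS", "pKF")
    expect_lt(abs(cutrisk:::threshold_value(ts, "KF") - (40 - 1.05 * 5)),
              3 * se)
    expect_lt(abs(cutrisk:::threshold_value(ts, "HI") - (40 + 1.05 * 5)),
              3 * se)
  })
})

test_that("wider tolerance never increases at-risk classifications", {
  withr::with_seed(31, {
    vals <- mk_vals(50, function(n) rnorm(n, 20, 6))
    lib1 <- derive_thresholds(vals, tolerance_pct = 5)
    lib2 <- derive_thresholds(vals, tolerance_pct = 15)
    for (i in 1:50) {
      fv <- random_factor_values("IC")
      ts1 <- threshold_set(lib1, "male", "AGTT", "IC")
      ts2 <- threshold_set(lib2, "male", "AGTT", "IC")
      n1 <- sum(classify_factors(fv, ts1)$at_risk)
      n2 <- sum(classify_factors(fv, ts2)$at_risk)
      expect_lte(n2, n1)
    }
  })
})

test_that("missing stratum or factor raises insufficient-data errors", {
  vals <- mk_vals(5, function(n) rnorm(n, 10, 2))
  vals[["male|AGTT|IC"]] <- NULL
  expect_error(derive_thresholds(vals), "insufficient-data")
  vals2 <- mk_vals(5, function(n) rnorm(n, 10, 2))
  vals2[["male|FS|pKF"]]$KV <- numeric(0)
  expect_error(derive_thresholds(vals2), "KV")
})
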