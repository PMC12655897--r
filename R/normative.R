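## Risk-factor definitions and normative threshold libraries.
##
## Nine factors in three categories:
##   SKL (sagittal knee loading): HK (hip/knee flexion ratio, defined as the
##       median knee-flexion angle over the first quartile of the hip-flexion
##       angle in a 100 ms sub-window), HF (hip flexion), KF (knee flexion),
##       AF (ankle flexion; plantarflexion negative);
##   KVC (knee valgus collapse): KV (knee valgus), HA (hip abd/adduction,
##       the single two-sided factor), HI (hip internal rotation);
##   TPI (trunk-pelvis imbalance): TIB (trunk ipsilateral bending),
##       TCR (trunk contralateral rotation).
## Thresholds are directional ("above" risky, "below" risky, or "outside"
## both bounds for HA) and stratified by sex x task x frame (8 strata). A
## published reference library is bundled; alternatively thresholds are
## derived from a healthy control cohort as mean +/- 1.05 sigma (one SD
## inflated by the 5% conservative tolerance).

#' Risk-factor definitions
#'
#' @return data.frame with one row per factor: `factor_id`, `category`
#'   (SKL/KVC/TPI), `direction` ("above", "below", or "outside" for the
#'   two-sided HA factor), `units`
#' @export
factor_defs <- function() {
  data.frame(
    factor_id = c("HK", "HF", "KF", "AF", "KV", "HA", "HI", "TIB", "TCR"),
    category = c("SKL", "SKL", "SKL", "SKL", "KVC", "KVC", "KVC",
                 "TPI", "TPI"),
    direction = c("above", "above", "below", "below", "above", "outside",
                  "above", "above", "above"),
    units = c("ratio", rep("degrees", 8)),
    stringsAsFactors = FALSE)
}

ALL_STRATA <- expand.grid(sex = c("male", "female"), task = c("AGTT", "FS"),
                          frame = c("IC", "pKF"), stringsAsFactors = FALSE)

# 10 threshold rows per stratum: HA appears as HAbd (upper) + HAdd (lower)
THRESH_ROW_IDS <- c("HK", "HF", "KF", "AF", "KV", "HAbd", "HAdd", "HI",
                    "TIB", "TCR")

new_threshold_library <- function(table, provenance) {
  stopifnot(all(c("sex", "task", "frame", "factor", "direction", "value")
                %in% names(table)))
  for (i in seq_len(nrow(ALL_STRATA))) {
    sub <- table[table$sex == ALL_STRATA$sex[i] &
                 table$task == ALL_STRATA$task[i] &
                 table$frame == ALL_STRATA$frame[i], ]
    missing <- setdiff(THRESH_ROW_IDS, sub$factor)
    if (length(missing))
      stop(sprintf("threshold library incomplete for (%s, %s, %s): missing %s",
                   ALL_STRATA$sex[i], ALL_STRATA$task[i], ALL_STRATA$frame[i],
                   paste(missing, collapse = ", ")))
  }
  structure(list(table = table, provenance = provenance),
            class = "threshold_library")
}

#' @export
print.threshold_library <- function(x, ...) {
  cat(sprintf("<threshold_library> %s: %d strata x %d thresholds\n",
              x$provenance, nrow(unique(x$table[c("sex", "task", "frame")])),
              length(THRESH_ROW_IDS)))
  invisible(x)
}

#' The bundled published threshold library
#'
#' Sex- x task- x frame-specific directional thresholds for the nine factors
#' (10 values per stratum counting the two hip abd/adduction bounds), as
#' published from a matched healthy-control cohort of young competitive
#' footballers.
#'
#' @return a `threshold_library` with provenance `"bundled_table1"`
#' @export
#' @examples
#' lib <- bundled_table1()
#' threshold_set(lib, "male", "AGTT", "IC")
bundled_table1 <- function() {
  path <- system.file("extdata", "table1_thresholds.csv", package = "cutrisk")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_threshold_library(tab, "bundled_table1")
}

#' Extract one stratum's threshold set
#'
#' @param library a `threshold_library`
#' @param sex,task,frame stratum selectors
#' @return object of class `threshold_set`: the stratum labels plus a
#'   threshold table with rows HK, HF, KF, AF, KV, HAbd, HAdd, HI, TIB, TCR
#' @export
threshold_set <- function(library, sex, task, frame) {
  sub <- library$table[library$table$sex == sex & library$table$task == task &
                       library$table$frame == frame, ]
  if (nrow(sub) == 0)
    stop(sprintf("no thresholds for stratum (%s, %s, %s)", sex, task, frame))
  rownames(sub) <- sub$factor
  structure(list(sex = sex, task = task, frame = frame,
                 table = sub[THRESH_ROW_IDS, ]),
            class = "threshold_set")
}

threshold_value <- function(tset, factor) tset$table[factor, "value"]

#' Derive thresholds from healthy-control factor values
#'
#' Per stratum and factor the threshold is the control mean plus (direction
#' "above") or minus (direction "below") one standard deviation inflated by
#' the conservative tolerance: `mu +/- (1 + tolerance_pct/100) * sigma`. The
#' two-sided HA factor gets both bounds from its single distribution. The
#' tolerance acts on sigma rather than on the threshold because several
#' published thresholds sit at or near zero, where a percent-of-threshold
#' band degenerates.
#'
#' @param control_factor_values named list keyed `"<sex>|<task>|<frame>"`,
#'   each element a named list mapping the row ids HK, HF, KF, AF, KV, HA,
#'   HI, TIB, TCR to numeric vectors of per-trial control values (>= 2 each)
#' @param tolerance_pct conservative tolerance in percent (default 5)
#' @return a `threshold_library` with provenance `"cohort_derived"`
#' @export
#' @examples
#' vals <- list("male|AGTT|IC" = c(list(HK = rnorm(50, 0.5, 0.1)),
#'   lapply(stats::setNames(nm = c("HF","KF","AF","KV","HA","HI","TIB","TCR")),
#'          function(f) rnorm(50, 10, 3))))
#' # a full library needs all 8 strata; see derive_thresholds tests
derive_thresholds <- function(control_factor_values, tolerance_pct = 5) {
  fd <- factor_defs()
  infl <- 1 + tolerance_pct / 100
  rows <- list()
  for (i in seq_len(nrow(ALL_STRATA))) {
    sex <- ALL_STRATA$sex[i]; task <- ALL_STRATA$task[i]
    frame <- ALL_STRATA$frame[i]
    key <- paste(sex, task, frame, sep = "|")
    vals <- control_factor_values[[key]]
    if (is.null(vals))
      stop("insufficient-data error: no control observations for stratum (",
           sex, ", ", task, ", ", frame, ")")
    for (j in seq_len(nrow(fd))) {
      fid <- fd$factor_id[j]
      x <- vals[[fid]]
      if (is.null(x) || length(x) < 2)
        stop(sprintf(
          "insufficient-data error: stratum (%s, %s, %s), factor %s",
          sex, task, frame, fid))
      mu <- mean(x); sg <- stats::sd(x)
      if (sg <= 0)
        stop("derive_thresholds: zero variance for factor ", fid)
      add <- function(factor, direction, value) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sex = sex, task = task, frame = frame, factor = factor,
          direction = direction, value = value, stringsAsFactors = FALSE)
      }
      if (fd$direction[j] == "above") add(fid, "above", mu + infl * sg)
      else if (fd$direction[j] == "below") add(fid, "below", mu - infl * sg)
      else {  # HA: two bounds
        add("HAbd", "above", mu + infl * sg)
        add("HAdd", "below", mu - infl * sg)
      }
    }
  }
  new_threshold_library(do.call(rbind, rows), "cohort_derived")
}

#' Collect per-stratum factor values from a control cohort
#'
#' Runs the event-detection, cut-angle and extraction stages on every trial
#' and groups the nine factor values by sex x task x frame, in the structure
#' [derive_thresholds()] consumes.
#'
#' @param cohort list of lists with `trial` and `meta` elements
#' @param config pipeline configuration
#' @return named list keyed `"<sex>|<task>|<frame>"` of named lists of
#'   numeric vectors (one value per analyzable trial)
#' @export
collect_factor_values <- function(cohort, config = default_config()) {
  out <- list()
  for (tw in cohort) {
    a <- analyze_trial(tw$trial, tw$meta, config)
    if (!a$ok) next
    for (frame in c("IC", "pKF")) {
      key <- paste(a$meta$sex, a$meta$task, frame, sep = "|")
      fv <- a$factor_values[[frame]]
      if (is.null(out[[key]])) out[[key]] <- list()
      for (fid in FACTOR_IDS) {
        out[[key]][[fid]] <- c(out[[key]][[fid]], fv[[fid]])
      }
    }
  }
  out
}

#' Write a threshold library as a flat delimited table
#'
#' @param library a `threshold_library`
#' @param path output path (CSV: sex, task, frame, factor, direction, value)
#' @return `path`, invisibly
#' @export
write_thresholds <- function(library, path) {
  tab <- library$table
  tab$value <- vapply(tab$value, function(v) {
    if (v == floor(v) && abs(v) < 100) sprintf("%.1f", v)
    else format(v, digits = 10)
  }, character(1))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a threshold library from a flat delimited table
#'
#' @param path CSV path with columns sex, task, frame, factor, direction,
#'   value
#' @return a `threshold_library` with provenance `"file"`
#' @export
read_thresholds <- function(path) {
  new_threshold_library(utils::read.csv(path, stringsAsFactors = FALSE),
                        "file")
}
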