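# shared fixtures: small clean trials and a minimal hand-built trial

clean_trial <- function(seed = 1, angle = 75, ...) {
  generate_cut_trial(synth_params(cut_angle_deg = angle, noise_sd = 0,
                                  seed = seed, ...))
}

# constant-velocity straight-line trial built by hand (no generator), with
# flat joint angles; used where generator machinery must not be involved
flat_trial <- function(duration_s = 4, fs = 100, vx = 5, angles = 10) {
  n <- duration_s * fs
  tt <- (seq_len(n) - 1) / fs
  df <- data.frame(time = tt, pelvis_pos_x = vx * tt, pelvis_pos_y = 0,
                   pelvis_pos_z = 1, pelvis_vel_x = vx, pelvis_vel_y = 0,
                   pelvis_vel_z = 0)
  for (col in setdiff(cutrisk:::trial_columns(FALSE),
                      c(names(df)))) df[[col]] <- angles
  trial_kinematics(df, fs)
}

meta_stub <- function(...) {
  trial_meta(player_id = "P01", sex = "male", task = "AGTT",
             cut_limb = "right", ...)
}

# independent brute-force factor classifier: reads the bundled CSV directly
# and compares value vs threshold with plain arithmetic (no pipeline code)
oracle_classify <- function(vals, sex, task, frame) {
  tab <- utils::read.csv(system.file("extdata", "table1_thresholds.csv",
                                     package = "cutrisk"))
  tab <- tab[tab$sex == sex & tab$task == task & tab$frame == frame, ]
  thr <- stats::setNames(tab$value, tab$factor)
  c(HK = vals$HK > thr[["HK"]],
    HF = vals$HF > thr[["HF"]],
    KF = vals$KF < thr[["KF"]],
    AF = vals$AF < thr[["AF"]],
    KV = vals$KV > thr[["KV"]],
    HA = vals$HA > thr[["HAbd"]] || vals$HA < thr[["HAdd"]],
    HI = vals$HI > thr[["HI"]],
    TIB = vals$TIB > thr[["TIB"]],
    TCR = vals$TCR > thr[["TCR"]])
}

random_factor_values <- function(frame) {
  factor_values(frame,
                HK = stats::runif(1, -0.5, 1.5),
                HF = stats::runif(1, 10, 70),
                KF = stats::runif(1, 0, 100),
                AF = stats::runif(1, -40, 10),
                KV = stats::runif(1, -5, 10),
                HA = stats::runif(1, -20, 20),
                HI = stats::runif(1, -5, 25),
                TIB = stats::runif(1, -5, 20),
                TCR = stats::runif(1, -5, 15))
}
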