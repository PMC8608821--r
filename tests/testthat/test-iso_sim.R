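test_that("cycle kinematics follow the raised-cosine bell", {
  cfg <- sim_config(pace_cpm = 60)
  cyc <- simulate_kinematics(cfg, 1)
  expect_equal(length(cyc$time_s), 1500)           # 1 s at 1.5 kHz
  expect_equal(cyc$angle_deg[1], 80)
  expect_equal(cyc$angle_deg[751], 130)            # t = 0.5 s
  expect_equal(cyc$angle_deg[1500], 80, tolerance = 1e-4)
  # one positive and one negative velocity lobe
  expect_true(all(cyc$velocity_deg_s[2:750] > 0))
  expect_true(all(cyc$velocity_deg_s[752:1500] < 0))
  # instantaneous power identity: 100 N·m at 90 deg/s is 157.08 W
  expect_equal(compute_power(100, 90), 100 * 90 * pi / 180)
  # second repetition continues the time axis
  cyc2 <- simulate_kinematics(cfg, 2)
  expect_equal(cyc2$time_s[1], 1)
})

test_that("concentric velocity integral equals the ROM span", {
  # fundamental theorem of calculus on the angle bell
  cfg <- sim_config(fs_hz = 15000)                  # fine grid: 1e-6 relative
  cyc <- simulate_kinematics(cfg, 1)
  half <- length(cyc$time_s) / 2
  integral <- sum(cyc$velocity_deg_s[1:half]) / 15000
  expect_equal(integral, 50, tolerance = 1e-6)
  cfg2 <- sim_config()                              # acquisition grid
  cyc2 <- simulate_kinematics(cfg2, 1)
  expect_equal(sum(cyc2$velocity_deg_s[1:750]) / 1500, 50, tolerance = 1e-5)
})

test_that("power decay reproduces the calibrated endurance ratio", {
  p <- simulate_power_decay(sim_config(noise_cv = 0))
  expect_equal(mean(tail(p, 5)) / mean(head(p, 5)), 388.73 / 629.62,
               tolerance = 1e-10)
  expect_true(all(diff(p) < 0))
  # degenerate: no decay, no noise
  p0 <- simulate_power_decay(sim_config(noise_cv = 0, decay_frac = 0))
  expect_equal(p0, rep(629.62, length(p0)))
  # linear arithmetic
  p1 <- simulate_power_decay(sim_config(noise_cv = 0, decay_frac = 0.4,
                                        baseline_peak_power_w = 600,
                                        n_reps = 50))
  expect_equal(p1[50], 360)
  expect_equal(p1[1], 600)
})

test_that("noise keeps the imposed decay on average", {
  ratios <- vapply(1:40, function(s) {
    p <- simulate_power_decay(sim_config(seed = s))
    mean(tail(p, 5)) / mean(head(p, 5))
  }, numeric(1))
  expect_equal(mean(ratios), 388.73 / 629.62, tolerance = 0.02)
})

test_that("termination rule matches hand-computed indices", {
  # baseline 100 from the two cycles inside the first 5 s
  expect_identical(
    apply_termination_rule(c(100, 100, 80, 74, 74, 74), (1:6) * 2.5), 5L)
  # never triggers: returns series length
  expect_identical(apply_termination_rule(rep(100, 8), 1:8), 8L)
  # no two consecutive sub-threshold cycles
  expect_identical(
    apply_termination_rule(c(100, 70, 100, 70, 100), (1:5) * 2.5), 5L)
  # immediate trigger
  expect_identical(
    apply_termination_rule(c(100, 100, 60, 60, 90), (1:5) * 2.5), 4L)
  expect_error(apply_termination_rule(numeric(0), numeric(0)), "non-empty")
})

test_that("termination rule is order-exact beyond the trigger point", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    p <- 100 * exp(-cumsum(runif(n, 0, 0.1))) + rnorm(n, sd = 2)
    times <- seq_len(n) * 2.5
    k <- apply_termination_rule(p, times)
    if (k < n - 1) {
      tail_idx <- (k + 1):n
      p2 <- p
      p2[tail_idx] <- p[sample(tail_idx)]
      expect_identical(apply_termination_rule(p2, times), k)
    }
  }
})

test_that("simulated trials are deterministic and internally consistent", {
  cfg <- sim_config(n_reps = 8, seed = 5)
  tr1 <- simulate_trial(cfg)
  tr2 <- simulate_trial(cfg)
  expect_identical(tr1$emg$samples, tr2$emg$samples)
  expect_identical(tr1$mech$power_W, tr2$mech$power_W)
  tru <- tr1$truth
  expect_equal(length(tru$peak_power_w), tru$termination_rep)
  expect_equal(length(tru$mnf_hz), tru$termination_rep)
  expect_equal(length(tru$rms_scale), tru$termination_rep)
  expect_lte(tru$termination_rep, cfg$n_max)
  # n_max caps the voluntary stop
  capped <- simulate_trial(sim_config(n_reps = 30, n_max = 12, seed = 2))
  expect_equal(capped$truth$termination_rep, 12)
})

test_that("measured spectral centroid tracks the imposed trajectory", {
  # disturbance-free world isolates the shaping machinery
  first_rep_mnf <- vapply(1:10, function(s) {
    tr <- simulate_trial(sim_config(n_reps = 2, seed = s,
                                    emg_disturbance_frac = 0))
    idx <- (tr$segments$start_idx[1] + 1):tr$segments$end_idx[1]
    spectral_features(bandpass_emg(tr$emg)$samples[idx], 1500)[["MNF"]]
  }, numeric(1))
  expect_equal(mean(first_rep_mnf), 110, tolerance = 0.05)

  # slope of measured on imposed centroid over a 50-seed ensemble
  imposed <- c()
  measured <- c()
  for (s in 1:50) {
    tr <- simulate_trial(sim_config(n_reps = 6, seed = s,
                                    emg_disturbance_frac = 0))
    bp <- bandpass_emg(tr$emg)
    for (i in seq_len(nrow(tr$segments))) {
      idx <- (tr$segments$start_idx[i] + 1):tr$segments$end_idx[i]
      measured <- c(measured,
                    spectral_features(bp$samples[idx], 1500)[["MNF"]])
      imposed <- c(imposed, tr$truth$mnf_hz[i])
    }
  }
  slope <- coef(stats::lm(measured ~ imposed))[[2]]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("sEMG amplitude grows by the imposed fraction", {
  # Monte-Carlo over 50 seeds with the amplitude wander disabled
  ratios <- vapply(1:50, function(s) {
    tr <- simulate_trial(sim_config(n_reps = 8, seed = s,
                                    emg_amp_noise_sd = 0))
    seg_rms <- vapply(c(1, 8), function(i) {
      idx <- (tr$segments$start_idx[i] + 1):tr$segments$end_idx[i]
      rms(tr$emg$samples[idx])
    }, numeric(1))
    seg_rms[2] / seg_rms[1]
  }, numeric(1))
  expect_equal(mean(ratios), 1.2, tolerance = 0.02)
})

test_that("rest intervals carry low-level baseline activity", {
  tr <- simulate_trial(sim_config(n_reps = 3, seed = 4))
  npc <- 1500
  rest_idx <- (npc / 2 + 1):npc                     # eccentric half of cycle 1
  burst_idx <- 1:(npc / 2)
  expect_lt(rms(tr$emg$samples[rest_idx]), 0.1 * rms(tr$emg$samples[burst_idx]))
  expect_gt(rms(tr$emg$samples[rest_idx]), 0)
})

test_that("config validation rejects out-of-protocol settings", {
  expect_error(sim_config(rom_deg = c(130, 80)), "end > start")
  expect_error(sim_config(rom_deg = c(10, 130)), "protocol range")
  expect_error(sim_config(pace_cpm = 30), "45")
  expect_error(sim_config(emg_mnf_start_hz = 80, emg_mnf_end_hz = 110),
               "emg_mnf_end_hz")
  expect_error(sim_config(decay_frac = 1.2), "decay_frac")
  expect_error(sim_config(fs_hz = 400), "fs_hz")
  # imposed centroid pushing the shaping band beyond Nyquist
  cfg <- sim_config(fs_hz = 510, emg_mnf_start_hz = 220,
                    emg_mnf_end_hz = 200)
  expect_error(simulate_trial(cfg), "Nyquist")
})

test_that("cohort simulation writes three reproducible files per subject", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfgs <- cohort_configs(3, master_seed = 11, n_reps = 6)
  files <- simulate_cohort(cfgs, dir1)
  expect_equal(nrow(files), 3)
  expect_equal(length(list.files(dir1)), 9)
  simulate_cohort(cfgs, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  expect_error(simulate_cohort(list(cfgs[[1]], cfgs[[1]]), dir1), "distinct")
  # repetition counts stay in the plausible tens for a protocol-scale cohort
  big <- cohort_configs(12, master_seed = 3)
  reps <- vapply(big, function(cfg) cfg$n_reps, integer(1))
  expect_true(all(reps >= 10 & reps <= 80))
  expect_true(mean(reps) > 30 && mean(reps) < 75)
})
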