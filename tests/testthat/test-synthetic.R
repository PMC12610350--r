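test_that("zero-amplitude, zero-noise trials are pure gravity", {
  cfg <- cohort_config(n_participants = 2, gyro_noise_sd = 0,
                       accel_noise_sd = 0)
  prof <- task_profile("still", gyro_amp = c(0, 0, 0), period = 1,
                       accel_amp = c(0, 0, 0), gravity = c(0, 0, 9.81))
  tr <- generate_trial(prof, reps = 10, config = cfg)
  expect_true(all(tr$stream$gyro_x == 0))
  expect_true(all(tr$stream$gyro_y == 0))
  expect_true(all(tr$stream$gyro_z == 0))
  expect_true(all(tr$stream$accel_x == 0))
  expect_true(all(tr$stream$accel_z == 9.81))
})

test_that("trial duration follows the reps/period/gap arithmetic", {
  cfg <- cohort_config(n_participants = 2)
  prof <- task_profile("gap", gyro_amp = c(50, 0, 0), period = 1.0, gap = 0.5)
  tr <- generate_trial(prof, reps = 10, config = cfg)
  expect_equal(tr$truth$duration_s, 10 * 1.0 + 9 * 0.5)
  # stream covers the trial at the sampling rate
  expect_equal(nrow(tr$stream), round(14.5 * 62))
  # 5 vs 20 reps at the same pace: duration ratio (5P+4g)/(20P+19g)
  e5 <- expected_trial_measures(prof, 5, config = cfg)
  e20 <- expected_trial_measures(prof, 20, config = cfg)
  expect_equal(e5$duration_s / e20$duration_s, (5 + 4 * 0.5) / (20 + 19 * 0.5))
})

test_that("mean rectified half-sine matches the 2A/pi closed form at 62 Hz", {
  cfg <- cohort_config(n_participants = 2, gyro_noise_sd = 0,
                       accel_noise_sd = 0)
  A <- 80
  prof <- task_profile("onexis", gyro_amp = c(A, 0, 0), period = 2,
                       accel_amp = c(0, 0, 0))
  tr <- generate_trial(prof, reps = 10, config = cfg)
  measured <- mean(abs(tr$stream$gyro_x))
  expect_lt(abs(measured / (2 * A / pi) - 1), 0.01)
})

test_that("empirical zero-noise measures match the analytic expectations", {
  cfg <- cohort_config(n_participants = 2, gyro_noise_sd = 0,
                       accel_noise_sd = 0)
  profs <- default_task_profiles()
  gapped <- task_profile("gapped", gyro_amp = c(60, 30, 15), period = 1.5,
                         gap = 0.6, accel_amp = c(1.2, 1.2, 1.2))
  cases <- list(
    list(p = profs$cup, reps = 5, pace = "comfortable"),
    list(p = profs$writing, reps = 10, pace = "fast"),
    list(p = gapped, reps = 10, pace = "comfortable"),
    list(p = gapped, reps = 5, pace = "fast")
  )
  for (cs in cases) {
    tr <- generate_trial(cs$p, cs$reps, cs$pace, config = cfg)
    exp <- expected_trial_measures(cs$p, cs$reps, cs$pace, config = cfg)
    win <- list(start_s = tr$stream$t[1], stop_s = tr$stream$t[1] + exp$duration_s)
    m <- trial_measures(tr$stream, win)
    expect_lt(abs(m$avg_total_ang_vel_dps / exp$avg_total_ang_vel_dps - 1),
              0.01)
    expect_lt(abs(m$total_sd_accel_ms2 / exp$total_sd_accel_ms2 - 1), 0.01)
  }
})

test_that("expected measures scale with pace and are invariant to reps", {
  cfg <- cohort_config(n_participants = 2, pace_multiplier_fast = 1.4)
  prof <- default_task_profiles()$cup
  e5 <- expected_trial_measures(prof, 5, config = cfg)
  e10 <- expected_trial_measures(prof, 10, config = cfg)
  e20 <- expected_trial_measures(prof, 20, config = cfg)
  # duration strictly increasing in reps, velocity/acceleration invariant
  expect_true(e5$duration_s < e10$duration_s && e10$duration_s < e20$duration_s)
  expect_equal(e5$avg_total_ang_vel_dps, e20$avg_total_ang_vel_dps)
  expect_equal(e5$total_sd_accel_ms2, e20$total_sd_accel_ms2)
  # fast pace: velocity and acceleration SD scale by m, duration by 1/m
  f10 <- expected_trial_measures(prof, 10, "fast", config = cfg)
  expect_equal(f10$avg_total_ang_vel_dps / e10$avg_total_ang_vel_dps, 1.4)
  expect_equal(f10$total_sd_accel_ms2 / e10$total_sd_accel_ms2, 1.4)
  expect_equal(f10$duration_s / e10$duration_s, 1 / 1.4)
})

test_that("a session has 20 ground-truth windows and quiet rests", {
  cfg <- cohort_config(n_participants = 2, seed = 3)
  set.seed(3)
  s <- generate_session("P01", cfg)
  expect_equal(nrow(s$truth), 20L)
  expect_equal(nrow(s$manifest), 20L)
  # windows strictly increasing and non-overlapping, duration = stop - start
  expect_true(all(diff(s$truth$start_s) > 0))
  expect_true(all(s$truth$start_s[-1] >= s$truth$stop_s[-20]))
  expect_equal(s$truth$duration_s, s$truth$stop_s - s$truth$start_s)
  # every task appears under every condition exactly once
  expect_equal(as.integer(table(s$manifest$task)), rep(5L, 4))
  expect_equal(as.integer(table(s$manifest$condition)), rep(4L, 5))
  # rest segments are noise only: folded-normal mean of |V| total is
  # 3 * sd * sqrt(2/pi) < 3 * sd
  rect <- rectify(s$stream)
  in_rest <- rect$t < s$truth$start_s[1] - 0.5
  expect_lte(mean(rect$v_total[in_rest]), 3 * cfg$gyro_noise_sd)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_participants = 3, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$sessions$P01$stream, c2$sessions$P01$stream)
  expect_identical(c1$truth_table, c2$truth_table)
  expect_identical(c1$effects, c2$effects)
})

test_that("measure-level cohorts reproduce the rendered cohort's truth", {
  cfg <- cohort_config(n_participants = 3, seed = 9)
  full <- generate_cohort(cfg, render_streams = TRUE)
  fast <- generate_cohort(cfg, render_streams = FALSE)
  expect_null(fast$sessions$P01$stream)
  expect_equal(fast$truth_table[, c("participant", "task", "condition",
                                    "avg_total_ang_vel_dps")],
               full$truth_table[, c("participant", "task", "condition",
                                    "avg_total_ang_vel_dps")])
})

test_that("the variance-ratio true ICC follows the configured components", {
  expect_equal(cohort_config(n_participants = 2, between_subject_sd = 0.4,
                             within_subject_sd = 0.2)$true_icc, 0.8)
  # degenerate: no within-subject noise implies perfect reliability
  cfg0 <- cohort_config(n_participants = 6, within_subject_sd = 0, seed = 2)
  expect_equal(cfg0$true_icc, 1)
  co <- generate_cohort(cfg0, render_streams = FALSE)
  tm <- truth_measure_table(co)
  v10 <- tm$avg_total_ang_vel_dps[tm$condition == "c10"]
  v10r <- tm$avg_total_ang_vel_dps[tm$condition == "c10r"]
  ord <- order(tm$participant[tm$condition == "c10"])
  ordr <- order(tm$participant[tm$condition == "c10r"])
  expect_equal(v10[ord], v10r[ordr], tolerance = 1e-12)
})

test_that("estimated ICC converges to the configured true ICC", {
  # Monte-Carlo recovery at measure level; log scale, where the
  # multiplicative model's variance-ratio ICC holds exactly
  set.seed(404)
  ests <- replicate(12, {
    cfg <- cohort_config(n_participants = 60, between_subject_sd = 0.4,
                         within_subject_sd = 0.2,
                         seed = sample.int(1e6, 1))
    tm <- truth_measure_table(generate_cohort(cfg, render_streams = FALSE))
    sub <- tm[tm$task == "cup" & tm$condition %in% c("c10", "c10r"), ]
    mat <- cbind(log(sub$avg_total_ang_vel_dps[sub$condition == "c10"]),
                 log(sub$avg_total_ang_vel_dps[sub$condition == "c10r"]))
    icc_agreement(mat, "single")$estimate
  })
  expect_lt(abs(mean(ests) - 0.8), 0.05)
})

test_that("invalid generator configurations are rejected", {
  expect_error(task_profile("bad", c(-1, 0, 0), 1), "non-negative")
  expect_error(task_profile("bad", c(1, 1, 1), 0), "period")
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(n_participants = 5, pace_multiplier_fast = 1),
               "pace_multiplier_fast")
  expect_error(cohort_config(n_participants = 5, between_subject_sd = -0.1),
               "standard deviations")
})
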