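test_that("simulated sessions are deterministic in the seed", {
  prof <- impairment_profile(tracking_noise_sd = 4, trunk_sway_amp = 2)
  a <- simulate_session("ankle_L", profile = prof, seed = 12)
  b <- simulate_session("ankle_L", profile = prof, seed = 12)
  expect_identical(a$truth$angles, b$truth$angles)
  expect_identical(lapply(a$streams, `[[`, "a"),
                   lapply(b$streams, `[[`, "a"))
  c <- simulate_session("ankle_L", profile = prof, seed = 13)
  expect_false(identical(a$truth$angles, c$truth$angles))
})

test_that("a null impairment profile moves only the target joint", {
  ses <- simulate_session("knee_R", profile = impairment_profile(), seed = 2)
  ang <- ses$truth$angles
  for (ch in setdiff(colnames(ang), "knee_R")) {
    expect_equal(diff(range(ang[, ch])), 0)
  }
  expect_gt(diff(range(ang[, "knee_R"])), 20)
})

test_that("unit mirror coupling copies the target derivative exactly", {
  prof <- impairment_profile(mirror_gain = 1)
  ses <- simulate_session("ankle_L", profile = prof, seed = 5)
  d_t <- diff(ses$truth$angles[, "ankle_L"])
  d_m <- diff(ses$truth$angles[, "ankle_R"])
  expect_equal(d_m, d_t, tolerance = 1e-12)

  half <- simulate_session("ankle_L",
                           profile = impairment_profile(mirror_gain = 0.5),
                           seed = 5)
  expect_equal(diff(half$truth$angles[, "ankle_R"]), 0.5 * d_t,
               tolerance = 1e-12)
})

test_that("the quasi-static sensor model points gravity correctly", {
  # hanging rest posture: every sample near (0, -1, 0)
  rest <- simulate_session("ankle_L",
                           profile = impairment_profile(), seed = 3,
                           path = generate_target_path(
                             waypoints = data.frame(time_s = 0, percent = 50)),
                           calibration = structure(
                             list(joint = "ankle_L", raw_min = -20,
                                  raw_max = 20, arom_min = -15, arom_max = 15,
                                  capped = FALSE, playable = TRUE,
                                  reason = NA_character_),
                             class = "arom_calibration"),
                           noise_sd = 0)
  # constant path at 50% of a symmetric range holds the target at 0 deg
  for (s in rest$streams) {
    expect_lt(max(abs(s$a[, 1] - 0)), 1e-9)
    expect_lt(max(abs(s$a[, 2] + 1)), 1e-9)
  }

  # a segment at a constant 90 degrees puts gravity fully on the sine axis
  truth <- rest$truth
  truth$angles[, "hip_flexion_L"] <- 90
  streams <- kinematics_to_accel(truth, noise_sd = 0, seed = 1)
  thigh <- streams[["thigh_L"]]
  expect_lt(max(abs(thigh$a[, 3] + 1)), 1e-9)  # zy plane: sine axis is z
  expect_lt(max(abs(thigh$a[, 2])), 1e-9)
})

test_that("timestamps mix 29 and 58 Hz segments near the 70/30 time split", {
  set.seed(44)
  fracs <- replicate(8, {
    ts <- svmcgame:::irregular_timestamps(120)
    dt <- diff(ts)
    fast <- abs(dt - 1 / 58) < 1e-6
    sum(dt[fast]) / sum(dt)
  })
  expect_gt(mean(fracs), 0.2)
  expect_lt(mean(fracs), 0.4)
})

test_that("rigid whole-body compensation does not leak into joint channels", {
  ses <- simulate_session("ankle_L", seed = 9, noise_sd = 0)
  sway <- list(zy = 4 * sin(2 * pi * 0.2 * ses$truth$t),
               xy = 3 * cos(2 * pi * 0.15 * ses$truth$t))
  set.seed(1); plain <- kinematics_to_accel(ses$truth, noise_sd = 0)
  set.seed(1); swayed <- kinematics_to_accel(ses$truth, noise_sd = 0,
                                             compensation = sway)
  c1 <- compute_joint_channels(plain, "LE")
  c2 <- compute_joint_channels(swayed, "LE")
  for (ch in names(c1$channels)) {
    rms <- sqrt(mean((c1$channels[[ch]]$angle - c2$channels[[ch]]$angle)^2))
    expect_lt(rms, 0.3)
  }
})

test_that("cohort simulation feeds the scorer end to end", {
  adults <- simulate_cohort(5, "NIA", seed = 19)
  sessions <- lapply(adults, process_session)
  ref <- build_reference(sessions)
  expect_true(all(ref$sigma_path >= ref$sd_floor))
  expect_true(all(vapply(ref$channels, function(c) all(c$sigma >= 0.5),
                         logical(1))))
  # adult scores on their own reference stay small and finite
  sc <- score_session(sessions[[1]], ref)
  expect_lt(sc$accuracy, 3)
  expect_lt(sc$involuntary, 3)

  # patients with strong mirror coupling separate from adults
  pats <- simulate_cohort(5, "P", seed = 23)
  inv_p <- vapply(pats, function(s)
    score_session(process_session(s), ref)$involuntary, numeric(1))
  inv_a <- vapply(sessions, function(s)
    score_session(s, ref)$involuntary, numeric(1))
  expect_gt(mean(inv_p), mean(inv_a))
})

test_that("NIC mirror gain decreases with age and shows in the scores", {
  kids <- simulate_cohort(14, "NIC", seed = 29)
  ages <- vapply(kids, function(s) s$meta$age, numeric(1))
  gains <- vapply(kids, function(s) s$profile$mirror_gain, numeric(1))
  expect_lt(cor(ages, gains, method = "spearman"), 0)

  ref <- make_reference(n_adults = 4, seed = 30)
  inv <- vapply(kids, function(s)
    score_session(process_session(s), ref)$involuntary, numeric(1))
  expect_lt(cor(ages, inv, method = "spearman"), 0)
})

test_that("UE sessions run through the same pipeline", {
  ses <- simulate_session("elbow_L", extremity = "UE",
                          profile = impairment_profile(mirror_gain = 0.6,
                                                       trunk_sway_amp = 2),
                          seed = 37)
  expect_length(ses$streams, 12)
  cs <- compute_joint_channels(ses$streams, "UE")
  expect_length(cs$channels, 12)  # 10 limb + 2 trunk
  ps <- process_session(ses)
  expect_equal(length(ps$t), 725)
})
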