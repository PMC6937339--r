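test_that("reference statistics: degenerate, two-point and Gaussian cohorts", {
  n_t <- 200
  mk_session <- function(dev, derivs = NULL) {
    d <- if (is.null(derivs)) {
      matrix(0, n_t, 1, dimnames = list(NULL, "knee_R"))
    } else derivs
    structure(list(t = (0:(n_t - 1)) / 29, rate_hz = 29, extremity = "LE",
                   target_joint = "ankle_L",
                   avatar_p = 50 + dev, p_star = rep(50, n_t),
                   derivs = d, missing = character(), meta = list()),
              class = "svmc_session")
  }
  # adults exactly on the path: SD floored
  ref0 <- build_reference(list(mk_session(0), mk_session(0)))
  expect_true(all(ref0$sigma_path == 0.5))
  expect_true(all(ref0$channels$knee_R$sigma == 0.5))

  # symmetric two-adult deviations: sample SD = |d| * sqrt(2)
  d <- 3 * sin((1:n_t) / 10)
  ref2 <- build_reference(list(mk_session(d), mk_session(-d)))
  expect_equal(ref2$sigma_path, pmax(abs(d) * sqrt(2), 0.5))

  # 30 adults with i.i.d. Gaussian deviations, sigma = 4%
  set.seed(11)
  sessions <- lapply(1:30, function(i) mk_session(rnorm(n_t, 0, 4)))
  ref30 <- build_reference(sessions)
  inside <- mean(ref30$sigma_path >= 3 & ref30$sigma_path <= 5)
  expect_gte(inside, 0.95)

  expect_error(build_reference(sessions[1]), "at least 2")
  bad <- mk_session(0)
  bad$p_star <- rep(40, n_t)
  expect_error(build_reference(list(mk_session(0), bad)),
               "different paths")
})

test_that("accuracy score standardizes deviation from the path", {
  n <- 100
  expect_equal(accuracy_score(rep(50, n), rep(50, n), rep(3, n)), 0)
  expect_equal(accuracy_score(rep(56, n), rep(50, n), rep(3, n)), 2)
  # scale equivariance in the deviation
  set.seed(2)
  p <- 50 + rnorm(n)
  ps <- rep(50, n)
  s <- runif(n, 2, 5)
  expect_equal(accuracy_score(50 + 3 * (p - 50), ps, s),
               3 * accuracy_score(p, ps, s))
  expect_error(accuracy_score(p, ps[-1], s), "different grids")
})

test_that("involuntary channel error is centred on the adult mean", {
  n <- 150
  mu <- sin((1:n) / 7) * 5
  sg <- runif(n, 1, 3)
  # perfectly physiological co-movement scores zero
  expect_equal(involuntary_channel_error(mu, mu, sg), 0)
  # one adult SD away everywhere scores exactly one
  expect_equal(involuntary_channel_error(mu + sg, mu, sg), 1)
  expect_error(involuntary_channel_error(mu, mu[-1], sg), "different grids")
})

test_that("vectorized scores equal an independent scalar-loop oracle", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    p <- runif(n, 0, 100); ps <- runif(n, 5, 95); sg <- runif(n, 0.5, 6)
    loop_acc <- 0
    for (k in seq_len(n)) loop_acc <- loop_acc + abs(p[k] - ps[k]) / sg[k]
    expect_equal(accuracy_score(p, ps, sg), loop_acc / n, tolerance = 1e-10)

    d <- rnorm(n, 0, 10); mu <- rnorm(n); s2 <- runif(n, 0.5, 4)
    loop_inv <- 0
    for (k in seq_len(n)) loop_inv <- loop_inv + abs(d[k] - mu[k]) / s2[k]
    expect_equal(involuntary_channel_error(d, mu, s2), loop_inv / n,
                 tolerance = 1e-10)
  }
})

test_that("two-level aggregation reproduces the ankle-target example", {
  e <- c(trunk_lateral = 1, trunk_ventral = 3,
         hip_flexion_L = 2, hip_rotation_L = 2,
         hip_flexion_R = 0, hip_rotation_R = 4,
         knee_L = 5, knee_R = 1, ankle_R = 6)
  agg <- aggregate_involuntary(e, "LE", "ankle_L")
  expect_equal(unname(agg$per_unit[c("trunk", "hip_L", "hip_R", "knee_L",
                                     "knee_R", "ankle_R")]),
               c(2, 2, 2, 5, 1, 6))
  expect_equal(agg$score, 3)
  expect_length(agg$per_unit, 6)

  # constant inputs survive any averaging
  e2 <- e; e2[] <- 1.7
  expect_equal(aggregate_involuntary(e2, "LE", "ankle_L")$score, 1.7)

  # the target channel never contributes
  e3 <- c(e, ankle_L = 1e6)
  expect_equal(aggregate_involuntary(e3, "LE", "ankle_L")$score, 3)
})

test_that("missing-channel policy: drop averages over what is left, fail stops", {
  e <- c(trunk_lateral = 1, hip_flexion_L = 2)
  expect_identical(handle_missing_channels(e), e)

  # trunk_ventral missing under drop: trunk unit = trunk_lateral alone
  e4 <- c(trunk_lateral = 4, hip_flexion_L = 2, hip_rotation_L = 2,
          hip_flexion_R = 2, hip_rotation_R = 2, knee_L = 2, knee_R = 2,
          ankle_R = 2)
  ok <- handle_missing_channels(e4, missing = "trunk_ventral")
  agg <- aggregate_involuntary(ok, "LE", "ankle_L")
  expect_equal(unname(agg$per_unit["trunk"]), 4)

  expect_error(handle_missing_channels(e, missing = "knee_L",
                                       strategy = "fail"), "knee_L")
  # the imputation hook fills before the policy applies
  filled <- handle_missing_channels(e, missing = "knee_L", strategy = "fail",
                                    imputed = c(knee_L = 9))
  expect_equal(unname(filled["knee_L"]), 9)
  expect_error(aggregate_involuntary(c(ankle_L = 1), "LE", "ankle_L"),
               "no aggregation unit")
})

test_that("session scoring ties the pieces together and validates grids", {
  ref <- make_reference(n_adults = 4, seed = 15)
  ses <- make_patient_session(seed = 16)
  sc <- score_session(ses, ref)
  expect_s3_class(sc, "svmc_scores")
  expect_gte(sc$accuracy, 0)
  expect_gte(sc$involuntary, 0)
  expect_equal(sc$involuntary, mean(sc$per_unit), tolerance = 1e-12)
  expect_length(sc$per_unit, 6)
  expect_false("ankle_L" %in% names(sc$per_channel))

  other <- process_session(simulate_session("knee_L", seed = 3))
  expect_error(score_session(other, ref), "does not match")
})

test_that("age normalization builds the right peer groups and z direction", {
  cohort <- data.frame(
    age = c(6.5, 7.9, 8.2, 10.4, 30, 40, 25, 9.1),
    group = c("NIC", "NIC", "NIC", "NIC", "NIA", "NIA", "NIA", "P"),
    score = c(1, 2, 3, 9, 1, 2, 3, 5))
  # participant aged 7.2: peers are the intact children with integer ages
  # 6, 7, 8 (scores 1, 2, 3) - not the 10-year-old
  r <- age_normalize(2, 7.2, "P", cohort)
  expect_equal(r$peer_n, 3)
  expect_equal(r$peer_mean, 2)
  expect_equal(r$z, 0)
  # one peer SD worse is z = +1 (positive = worse)
  r2 <- age_normalize(2 + r$peer_sd, 7.2, "P", cohort)
  expect_equal(r2$z, 1)

  # adults use the whole adult group, no subgrouping
  ra <- age_normalize(2, 47, "NIA", cohort)
  expect_equal(ra$peer_n, 3)
  expect_equal(ra$z, 0)

  # too few peers / zero SD are reported, not fabricated
  r3 <- age_normalize(1, 17.5, "NIC", cohort)
  expect_true(is.na(r3$z))
  expect_match(r3$reason, "peer group")
  degen <- data.frame(age = c(7, 7, 7), group = rep("NIC", 3),
                      score = c(2, 2, 2))
  r4 <- age_normalize(2, 7.1, "NIC", degen)
  expect_true(is.na(r4$z))
  expect_match(r4$reason, "zero")
})

test_that("z-scores of a shared peer group have mean 0 and SD 1", {
  set.seed(6)
  df <- data.frame(age = runif(12, 7.0, 7.9), group = "NIC",
                   score = NA, accuracy = rnorm(12, 2, 0.5),
                   involuntary = rnorm(12, 1, 0.3))
  z <- add_z_scores(df)
  expect_equal(mean(z$z_accuracy), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_accuracy), 1, tolerance = 1e-12)
  expect_equal(mean(z$z_involuntary), 0, tolerance = 1e-12)
  expect_equal(sd(z$z_involuntary), 1, tolerance = 1e-12)
})
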