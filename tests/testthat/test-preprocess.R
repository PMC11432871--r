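test_that("smoothing configuration enforces its invariants", {
  expect_error(smoothing_config(savgol_window = 10), "odd")
  expect_error(smoothing_config(savgol_window = 3, savgol_polyorder = 3), "exceed")
  expect_error(smoothing_config(hr_ma_window = 4), "odd")
  cfg <- smoothing_config(savgol_polyorder = 9, savgol_window = 11)
  expect_equal(cfg$savgol_passes, 3L)
})

test_that("Savitzky-Golay filter reproduces polynomials up to its order", {
  t <- seq(0, 1, length.out = 60)
  y <- 2 - t + 3 * t^2 - 0.5 * t^3
  sm <- smooth_vo2(y, smoothing_config(savgol_polyorder = 3, savgol_window = 11))
  expect_lt(max(abs(sm - y)), 1e-8)
  expect_length(sm, length(y))
})

test_that("three passes equal composing the single-pass filter three times", {
  set.seed(1)
  y <- cumsum(rnorm(80))
  cfg1 <- smoothing_config(savgol_passes = 1L)
  once <- function(v) smooth_vo2(v, cfg1)
  expect_equal(smooth_vo2(y, smoothing_config(savgol_passes = 3L)),
               once(once(once(y))))
  expect_error(smooth_vo2(y[1:5], smoothing_config()), "shorter")
})

test_that("smoothing reduces noise on a slow oscillation", {
  set.seed(21)
  t <- seq(0, 60, by = 0.5)
  clean <- sin(2 * pi * t / 60)
  noisy <- clean + rnorm(length(t), 0, 0.3)
  sm <- smooth_vo2(noisy, smoothing_config(savgol_window = 11))
  expect_lt(mean((sm - clean)^2), mean((noisy - clean)^2))
})

test_that("moving-average smoothing handles edges and degenerate windows", {
  expect_identical(smooth_hr(c(4, 2, 9), 1L), c(4, 2, 9))
  expect_equal(smooth_hr(c(1, 2, 3), 3L)[2], 2)
  const <- rep(7, 20)
  expect_equal(smooth_hr(const, 5L), const)
  expect_length(smooth_hr(rnorm(10), 3L), 10)
  expect_error(smooth_hr(1:10, 2L), "odd")
  # edge handling: first value averages the shrunk symmetric window
  expect_equal(smooth_hr(c(1, 2, 3, 4), 3L)[1], 1)
  expect_equal(smooth_hr(c(1, 2, 3, 4), 3L)[2], 2)
})

test_that("cross-correlation offset estimation recovers constructed shifts", {
  t <- 0:999
  base <- sin(2 * pi * t / 120) + 0.5 * sin(2 * pi * t / 47)
  vo2 <- data.frame(t = t, vo2 = base)
  hr <- data.frame(t = t, hr = base)
  expect_equal(estimate_offset(vo2, hr), 0)
  for (k in c(-40, -7, 13, 60)) {
    shifted <- data.frame(t = t + k, vo2 = base)   # clock runs ahead by k
    expect_equal(estimate_offset(shifted, hr), k)
  }
  # equivariance: shifting both streams leaves the estimate unchanged
  v2 <- data.frame(t = t + 500, vo2 = base)
  h2 <- data.frame(t = t + 500, hr = base)
  expect_equal(estimate_offset(v2, h2), 0)
  expect_error(estimate_offset(data.frame(t = t, vo2 = rep(1, 1000)), hr),
               "zero-variance")
  expect_error(estimate_offset(vo2[1:100, ], hr[1:100, ]), "overlap")
})

test_that("alignment resamples onto step times and drops gap-affected steps", {
  set.seed(14)
  prof <- fixed_profile()
  sess <- simulate_session(prof, build_protocol(3), noise = FALSE)
  out <- align_and_resample(sess, offset = 0)
  expect_s3_class(out, "aligned_steps")
  expect_equal(nrow(out), nrow(sess$step_stream))
  expect_true(all(diff(out$t) > 0))
  expect_false(anyNA(out))

  # constant VO2 stream interpolates to that constant
  sess2 <- sess
  sess2$vo2_stream$vo2 <- rep(12, nrow(sess2$vo2_stream))
  out2 <- align_and_resample(sess2, 0)
  expect_true(all(out2$vo2 == 12))

  # spirometer gap: steps needing interpolation across the gap are dropped
  gap <- inject_artifacts(sess, artifact_scenario("spirometer_gap",
                                                  gap_start_s = 1000,
                                                  gap_length_s = 90))
  outg <- align_and_resample(gap, 0)
  expect_false(any(outg$t > 1000 & outg$t < 1085))
  expect_lt(nrow(outg), nrow(out))
  expect_true(all(outg$t %in% out$t))
})

test_that("session preprocessing recovers the injected clock offset", {
  set.seed(15)
  sess <- simulate_session(fixed_profile(), build_protocol(4))
  out <- preprocess_session(sess)
  expect_lt(abs(attr(out, "offset_est") - sess$true_offset_s), 2)
})

test_that("attribute encoding follows the categorical table", {
  p <- fixed_profile()
  p$age <- 24; p$bmi <- 21.5; p$sex <- "female"; p$fitness <- "untrained"
  expect_equal(unname(encode_attributes(p)), c(0L, 0L, 0L, 0L))
  p$age <- 27; p$bmi <- 23; p$sex <- "male"; p$fitness <- "trained"
  expect_equal(unname(encode_attributes(p)), c(1L, 1L, 1L, 1L))
  p$age <- 31; p$bmi <- 26
  expect_equal(unname(encode_attributes(p))[1:2], c(2L, 2L))
  p$age <- 25; p$bmi <- 22
  expect_equal(unname(encode_attributes(p))[1:2], c(0L, 1L))
  p$age <- 30; p$bmi <- 25
  expect_equal(unname(encode_attributes(p))[1:2], c(2L, 1L))
})

test_that("normalization statistics standardize and record provenance", {
  steps <- rbind(as.data.frame(fake_steps(100, 1)), as.data.frame(fake_steps(80, 2)))
  class(steps) <- c("aligned_steps", "data.frame")
  st <- fit_normalization(steps, c(1, 2))
  normed <- apply_normalization(steps, st)
  for (f in c("speed", "heart_rate")) {
    expect_lt(abs(mean(normed[[f]])), 1e-12)
    expect_equal(sd(normed[[f]]), 1)
  }
  # provenance: held-out subject never enters the statistics
  st1 <- fit_normalization(steps, 1)
  expect_equal(st1$subject_ids, 1)
  steps_mut <- steps
  steps_mut[steps_mut$subject_id == 2, "speed"] <- 999
  class(steps_mut) <- c("aligned_steps", "data.frame")
  st1b <- fit_normalization(steps_mut, 1)
  expect_identical(st1$mean, st1b$mean)
  # scaling a feature by c scales the fitted SD by c
  steps_sc <- steps
  steps_sc$speed <- steps_sc$speed * 3
  class(steps_sc) <- c("aligned_steps", "data.frame")
  expect_equal(fit_normalization(steps_sc, c(1, 2))$sd[["speed"]],
               3 * st$sd[["speed"]])
  const <- steps; const$speed <- 1
  class(const) <- c("aligned_steps", "data.frame")
  expect_error(fit_normalization(const, c(1, 2)), "zero-variance")
})

test_that("windowing produces correctly aligned many-to-one samples", {
  s <- fake_steps(250)
  expect_equal(n_samples(window_sequences(s, 250L)), 1L)
  w <- window_sequences(s, 200L, 1L)
  expect_equal(n_samples(w), 51L)
  expect_equal(dim(w$x), c(51L, 5L, 200L))
  # target of the k-th sample is the VO2 at step k+L-1
  for (k in c(1L, 17L, 51L)) {
    expect_equal(w$target[k], s$vo2[k + 200L - 1L])
    expect_equal(w$x[k, 5, 200], s$heart_rate[k + 200L - 1L])
    expect_equal(w$x[k, 1, 1], s$speed[k])
  }
  # stride reduces the count per the floor formula
  w4 <- window_sequences(s, 200L, 4L)
  expect_equal(n_samples(w4), floor((250 - 200) / 4) + 1)
  expect_error(window_sequences(fake_steps(10), 50L), "shorter")
})

test_that("windows never cross subject boundaries", {
  a <- fake_steps(60, 1, vo2 = rep(10, 60))
  b <- fake_steps(60, 2, vo2 = rep(40, 60))
  both <- rbind(as.data.frame(a), as.data.frame(b))
  class(both) <- c("aligned_steps", "data.frame")
  w <- window_sequences(both, 50L, 1L)
  expect_equal(n_samples(w), 2L * (60L - 50L + 1L))
  expect_true(all(w$target[w$subject_id == 1] == 10))
  expect_true(all(w$target[w$subject_id == 2] == 40))
  # attribute attachment maps subject ids to profiles
  p1 <- fixed_profile(1, sex = "female", fitness = "untrained")
  p2 <- fixed_profile(2, sex = "male", fitness = "trained")
  w2 <- attach_attributes(w, list(p1, p2))
  expect_equal(dim(w2$attrs), c(n_samples(w), 4L))
  expect_true(all(w2$attrs[w2$subject_id == 1, 3] == 0))
  expect_true(all(w2$attrs[w2$subject_id == 2, 3] == 1))
})

test_that("aligned step series survive a CSV round-trip", {
  s <- fake_steps(40, 3)
  path <- file.path(tempdir(), "steps.csv")
  write_aligned_steps(s, path)
  back <- read_aligned_steps(path)
  expect_s3_class(back, "aligned_steps")
  expect_equal(back$vo2, s$vo2)
  expect_equal(back$subject_id, s$subject_id)
  unlink(path)
})
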