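test_that("cohort attribute distributions match the target population", {
  set.seed(42)
  pop <- vo2_population()
  n <- 10000
  ages <- numeric(n)
  heights <- numeric(n)
  sexes <- character(n)
  fits <- character(n)
  for (i in seq_len(n)) {
    p <- sample_subject_profile(pop, i)
    ages[i] <- p$age; heights[i] <- p$height
    sexes[i] <- p$sex; fits[i] <- p$fitness
  }
  # analytic mean of a truncated normal
  tmean <- function(mu, s, a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    mu + s * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
  }
  # pooled expectations of the truncated fitness-mixture; the printed cohort
  # means (27.5 yr, 175.3 cm) are recovered up to the small truncation shift
  exp_age <- 10 / 16 * tmean(28.1, 3.7, 18, 35) + 6 / 16 * tmean(26.5, 3.1, 18, 35)
  exp_height <- 10 / 16 * tmean(177.6, 6.4, 150, 205) +
    6 / 16 * tmean(171.5, 10.59, 150, 205)
  expect_lt(abs(mean(ages) - exp_age), 3 * 3.5 / sqrt(n))
  expect_lt(abs(mean(heights) - exp_height), 3 * 8.4 / sqrt(n))
  expect_lt(abs(mean(ages) - 27.5), 0.3)
  expect_lt(abs(mean(heights) - 175.3), 0.5)
  expect_lt(abs(mean(sexes == "female") - 0.5), 3 * 0.5 / sqrt(n))
  expect_lt(abs(mean(fits == "trained") - 10 / 16), 3 * 0.5 / sqrt(n))
  expect_true(all(ages >= 18 & ages <= 35))
})

test_that("profiles satisfy their physiological invariants", {
  set.seed(7)
  for (i in 1:50) {
    p <- sample_subject_profile()
    expect_equal(p$bmi, p$body_mass / (p$height / 100)^2)
    expect_lt(p$hr_rest, 220 - p$age)
    expect_gt(p$tau_on, 0)
    expect_gt(p$tau_off, 0)
    expect_true(all(p$noise_scales >= 0))
  }
})

test_that("zero-SD population collapses each subgroup to its means", {
  pop <- zero_sd_population()
  set.seed(1)
  ps <- replicate(20, sample_subject_profile(pop), simplify = FALSE)
  tr <- Filter(function(p) p$fitness == "trained", ps)
  ages <- vapply(tr, function(p) p$age, 0)
  expect_true(all(ages == 28.1))
  heights <- vapply(tr, function(p) p$height, 0)
  expect_true(all(heights == 177.6))
})

test_that("profile sampling is deterministic under a fixed seed", {
  set.seed(123); a <- sample_subject_profile()
  set.seed(123); b <- sample_subject_profile()
  expect_identical(a, b)
})

test_that("negative population SDs are rejected", {
  pop <- vo2_population()
  pop$attributes$trained$age[2] <- -1
  expect_error(sample_subject_profile(pop), "non-negative")
})

test_that("protocol starts at 1.0 m/s and permutes the study speeds", {
  set.seed(5)
  p <- build_protocol(8)
  expect_equal(p$segment_speeds[1], 1.0)
  expect_setequal(p$segment_speeds, c(1.0, 1.3, 1.5, 2.2, 2.5, 2.8, 3.1, 3.3))
  expect_equal(p$rest_initial_s, 300)
  expect_equal(p$segment_duration_s, 300)
  expect_equal(p$rest_between_s, 300)
  p1 <- build_protocol(1)
  expect_equal(p1$segment_speeds, 1.0)
  expect_error(build_protocol(0))
  expect_error(build_protocol(9))
  pe <- build_protocol(8, extra_speed = TRUE)
  expect_equal(pe$segment_speeds[9], 3.6)
})

test_that("speed permutations are uniform (position-2 frequencies)", {
  set.seed(11)
  n <- 5000
  second <- replicate(n, build_protocol(8)$segment_speeds[2])
  tab <- table(second)
  expect_equal(length(tab), 7L)
  p <- 1 / 7
  se <- sqrt(p * (1 - p) / n)
  for (f in as.vector(tab) / n) expect_lt(abs(f - p), 3 * se)
})

test_that("steady-state targets are correct and monotone", {
  prof <- fixed_profile()
  ss0 <- steady_state_targets(0, prof)
  expect_equal(ss0$vo2_ss, prof$vo2_rest)
  expect_equal(ss0$hr_ss, prof$hr_rest)
  prof$vo2_rest <- 5; prof$vo2_gain_linear <- 10; prof$vo2_gain_quadratic <- 0
  expect_equal(steady_state_targets(2, prof)$vo2_ss, 25)
  set.seed(3)
  for (i in 1:20) {
    p <- sample_subject_profile()
    v <- steady_state_targets(c(1.0, 1.5, 2.2, 3.3), p)$vo2_ss
    expect_true(all(diff(v) >= 0))
    h <- steady_state_targets(c(1.0, 3.3), p)$hr_ss
    expect_lte(h[2], 220 - p$age)
  }
  expect_error(steady_state_targets(-1, prof), "non-negative")
})

test_that("noiseless kinetics match the piecewise-exponential closed form", {
  prof <- fixed_profile()
  set.seed(2)
  proto <- build_protocol(3)
  sess <- simulate_session(prof, proto, noise = FALSE)
  # independent closed-form reconstruction, segment by segment
  segs <- data.frame(start = 300 * 0, end = 300, speed = 0)
  t <- 300
  for (v in proto$segment_speeds) {
    segs <- rbind(segs, data.frame(start = t, end = t + 300, speed = v)); t <- t + 300
    segs <- rbind(segs, data.frame(start = t, end = t + 300, speed = 0)); t <- t + 300
  }
  x <- prof$vo2_rest
  expected <- numeric(t + 1)
  expected[1] <- x
  for (i in seq_len(nrow(segs))) {
    xss <- steady_state_targets(segs$speed[i], prof)$vo2_ss
    tau <- if (xss > x) prof$tau_on else prof$tau_off
    tt <- seq_len(segs$end[i] - segs$start[i])
    expected[segs$start[i] + 1 + tt] <- xss + (x - xss) * exp(-tt / tau)
    x <- expected[segs$end[i] + 1]
  }
  span <- diff(range(expected))
  expect_lt(max(abs(sess$truth$vo2 - expected)), 1e-3 * span)
  # VO2 relaxes back toward rest by the end of the rest period that follows
  # the first activity bout
  rest_end <- sess$truth$vo2[sess$truth$t == segs$end[3]]
  expect_lt(abs(rest_end - prof$vo2_rest), 0.05 * span)
})

test_that("session streams have the nominal sampling rates", {
  set.seed(4)
  sess <- simulate_session(fixed_profile(), build_protocol(2))
  expect_true(all(abs(diff(sess$vo2_stream$t) - 5) < 1e-9))
  expect_true(all(abs(diff(sess$hr_stream$t) - 1) < 1e-9))
  expect_lte(abs(sess$true_offset_s), 30)
  # recorded step durations agree with start-time differences within active
  # segments (measurement noise only)
  st <- sess$step_stream
  act <- st[st$speed > 0.5, ]
  d <- diff(act$t)
  same_seg <- d < 2             # not spanning a rest break
  expect_lt(max(abs(d[same_seg] - act$step_duration[-nrow(act)][same_seg])), 0.05)
})

test_that("artifact injection deletes exactly what it says", {
  set.seed(8)
  sess <- simulate_session(fixed_profile(), build_protocol(6))
  same <- inject_artifacts(sess, artifact_scenario("none"))
  expect_identical(same$vo2_stream, sess$vo2_stream)
  expect_identical(same$hr_stream, sess$hr_stream)

  gap <- inject_artifacts(sess, artifact_scenario("spirometer_gap"))
  expect_equal(nrow(sess$vo2_stream) - nrow(gap$vo2_stream), 18L)
  # surviving records bit-identical, spacing preserved away from the gap
  expect_true(all(gap$vo2_stream$vo2 %in% sess$vo2_stream$vo2))
  d <- diff(gap$vo2_stream$t)
  expect_true(all(abs(d - 5) < 1e-9 | abs(d - 95) < 1e-9))

  hr <- inject_artifacts(sess, artifact_scenario("hr_partial", gap_start_s = 1000,
                                                 gap_length_s = 600))
  expect_equal(nrow(sess$hr_stream) - nrow(hr$hr_stream), 600L)
  expect_true(all(hr$hr_stream$t < 1000 | hr$hr_stream$t >= 1600))

  tr <- inject_artifacts(sess, artifact_scenario("early_termination",
                                                 cycles_retained = 5))
  t_cut <- 300 + 5 * 600
  expect_lt(max(tr$step_stream$t), 300 + 6 * 600 - 300)  # before cycle 6 starts
  expect_lte(max(tr$hr_stream$t), t_cut)
  expect_equal(tr$protocol$n_cycles_completed, 5L)
  expect_error(inject_artifacts(sess, artifact_scenario("spirometer_gap",
                                                        gap_start_s = 1e6)),
               "outside")
})

test_that("cohort generation is reproducible and applies default artifacts", {
  a <- generate_cohort(12, seed = 9)
  kinds <- vapply(a$sessions, function(s) s$artifact$kind, "")
  expect_equal(sum(kinds != "none"), 3L)
  expect_equal(kinds[1], "hr_partial")
  expect_equal(kinds[2], "spirometer_gap")
  expect_equal(kinds[10], "early_termination")
  b <- generate_cohort(12, seed = 9)
  expect_identical(a$sessions[[3]]$vo2_stream, b$sessions[[3]]$vo2_stream)
  expect_identical(a$profiles, b$profiles)
  one <- generate_cohort(1, seed = 2)
  expect_equal(one$sessions[[1]]$artifact$kind, "hr_partial")
  clean <- generate_cohort(1, seed = 2, artifacts = FALSE)
  expect_equal(clean$sessions[[1]]$artifact$kind, "none")
})

test_that("cohort CSV/JSON round-trip preserves the streams byte-for-byte", {
  dir1 <- file.path(tempdir(), "coh1"); dir2 <- file.path(tempdir(), "coh2")
  coh <- generate_cohort(2, seed = 33)
  write_cohort(coh, dir1)
  write_cohort(generate_cohort(2, seed = 33), dir2)
  f1 <- file.path(dir1, "subject_01", "steps.csv")
  f2 <- file.path(dir2, "subject_01", "steps.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_cohort(dir1)
  expect_equal(back$sessions[[2]]$vo2_stream$vo2, coh$sessions[[2]]$vo2_stream$vo2)
  expect_equal(back$profiles[[1]]$age, coh$profiles[[1]]$age)
  expect_equal(back$provenance$seed, 33)
  unlink(c(dir1, dir2), recursive = TRUE)
})
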