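# Small fixtures shared across test files; everything is generated in code.

# a degenerate population whose every SD is zero (attribute draws collapse)
zero_sd_population <- function() {
  pop <- vo2_population()
  for (g in names(pop$attributes)) {
    for (a in names(pop$attributes[[g]])) pop$attributes[[g]][[a]][2] <- 0
  }
  for (a in names(pop$latent)) pop$latent[[a]][2] <- 0
  pop
}

# deterministic profile for session-level tests
fixed_profile <- function(subject_id = 1L, sex = "male", fitness = "trained") {
  prof <- list(
    subject_id = as.integer(subject_id),
    age = 27, height = 176, body_mass = 71,
    bmi = 71 / 1.76^2, sex = sex, fitness = fitness,
    hr_rest = 56, vo2_rest = 5, hr_gain = 34,
    vo2_gain_linear = 9.5, vo2_gain_quadratic = 1.0,
    tau_on = 30, tau_off = 45,
    cadence_base = if (sex == "male") 1.75 else 1.9,
    cadence_slope = if (sex == "male") 0.32 else -0.15,
    osc_walk = 0.033, osc_run = 0.095,
    noise_scales = vo2_population()$noise_scales,
    osc_spike = c(p = 0.03, mean = 0.5)
  )
  class(prof) <- "subject_profile"
  prof
}

# synthetic aligned step series with fully controlled columns
fake_steps <- function(n, subject_id = 1L, vo2 = NULL) {
  d <- data.frame(
    subject_id = subject_id,
    t = cumsum(rep(0.5, n)),
    speed = seq(1, 3, length.out = n),
    speed_change = rep(0.2, n) + seq_len(n) * 1e-4,
    step_duration = rep(0.5, n) + seq_len(n) * 1e-5,
    vertical_oscillation = seq(0.03, 0.09, length.out = n),
    heart_rate = seq(60, 170, length.out = n),
    vo2 = if (is.null(vo2)) seq(5, 45, length.out = n) else vo2
  )
  class(d) <- c("aligned_steps", "data.frame")
  d
}

# tiny raw sample set for training tests (learnable linear map of HR)
toy_samples <- function(n = 32L, L = 10L, seed = 1L, subjects = 1L) {
  set.seed(seed)
  x <- array(stats::rnorm(n * 5 * L, mean = 1, sd = 0.5), c(n, 5L, L))
  target <- 10 + 6 * x[, 5, L] + 2 * x[, 1, L]
  out <- list(x = x, target = target,
              subject_id = rep_len(subjects, n),
              t_end = seq_len(n), L = L, stride = 1L, normalized = FALSE)
  class(out) <- "vo2_samples"
  out
}
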