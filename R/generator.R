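# ---- truncated normal ----------------------------------------------------

#' Draw from a truncated normal distribution
#'
#' Simple inverse-CDF sampler used for all bounded physiological quantities.
#' With `sd = 0` the mean is returned (degenerate distribution), clamped to
#' the bounds.
#'
#' @param n number of draws
#' @param mean,sd distribution parameters; `sd >= 0`
#' @param lower,upper truncation bounds
#' @return numeric vector of length `n`
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper)
}

# ---- population parameters ----------------------------------------------

#' Default cohort population parameters
#'
#' Attribute distributions follow the published cohort statistics of the
#' 16-participant field study this generator emulates: fitness-specific
#' means/SDs for age, height and body mass (trained: age 28.1 +/- 3.7 yr,
#' height 177.6 +/- 6.4 cm, mass 70.8 +/- 11.4 kg; untrained: 26.5 +/- 3.1 yr,
#' 171.5 +/- 10.59 cm, 73.3 +/- 16.1 kg), a 10/16 trained proportion and a
#' balanced female/male split within each fitness group (5/10 and 3/6), so
#' that pooled expectations match the printed cohort (age 27.5, height 175.3,
#' mass 71.8, 8 females). The latent physiological parameters (resting values,
#' steady-state gains, on/off time constants, cadence and vertical-oscillation
#' regimes) are generator-owned: the emulated study measured rather than
#' modelled them, so realistic exercise-physiology ranges are used, with
#' fitness lowering resting heart rate and shortening the on-transient.
#'
#' Each attribute entry is `c(mean, sd, lower, upper)`.
#'
#' @return nested list of population parameters, class `vo2_population`
#' @export
vo2_population <- function() {
  pop <- list(
    p_trained = 10 / 16,
    p_female  = c(trained = 0.5, untrained = 0.5),
    attributes = list(
      trained = list(
        age    = c(28.1, 3.7, 18, 35),
        height = c(177.6, 6.4, 150, 205),
        mass   = c(70.8, 11.4, 45, 110)
      ),
      untrained = list(
        age    = c(26.5, 3.1, 18, 35),
        height = c(171.5, 10.59, 150, 205),
        mass   = c(73.3, 16.1, 45, 110)
      )
    ),
    latent = list(
      vo2_rest          = c(5.0, 0.5, 3.5, 6.5),     # ml/min/kg
      vo2_gain_linear   = c(9.5, 1.0, 7, 12),        # ml/min/kg per m/s
      vo2_gain_quadratic= c(1.0, 0.3, 0.3, 1.8),     # ml/min/kg per (m/s)^2
      hr_rest_trained   = c(55, 5, 40, 70),          # bpm
      hr_rest_untrained = c(67, 6, 50, 85),
      hr_gain           = c(34, 4, 25, 45),          # bpm per m/s
      tau_on_trained    = c(28, 4, 18, 45),          # s
      tau_on_untrained  = c(40, 6, 25, 60),
      tau_off           = c(45, 8, 30, 75),
      cadence_base_male   = c(1.75, 0.08, 1.5, 2.2), # steps/s at 1 m/s
      cadence_base_female = c(1.90, 0.08, 1.6, 2.3),
      cadence_slope_male   = c(0.32, 0.05, 0.15, 0.50),  # steps/s per m/s
      cadence_slope_female = c(-0.15, 0.04, -0.28, -0.05),
      osc_walk = c(0.033, 0.004, 0.020, 0.050),      # m
      osc_run  = c(0.095, 0.008, 0.070, 0.120)
    ),
    # observation-noise SDs; the emulated sensors quote accuracies of
    # ~0.05 m/s (speed), ~1 cm (oscillation), ~10 ms (step duration),
    # interpreted as 2-sigma bounds; HR/VO2 levels are documented guesses.
    noise_scales = c(
      speed = 0.025, speed_change = 0.025, step_duration = 0.005,
      vertical_oscillation = 0.005, heart_rate = 2, vo2 = 1.5
    ),
    # heavy-tailed spike component of the vertical-oscillation measurement
    # (occasional INS integration-drift artifacts): probability per step and
    # mean spike amplitude (m). Rank statistics are immune to these; linear
    # correlation is not.
    osc_spike = c(p = 0.03, mean = 0.5)
  )
  class(pop) <- "vo2_population"
  pop
}

#' Sample one subject profile
#'
#' Draws observable attributes (age, height, body mass; BMI derived) from
#' truncated normal distributions matching the cohort statistics, assigns sex
#' and fitness with the cohort proportions, and draws the latent physiological
#' parameters governing the simulated session. Uses the current R RNG stream;
#' seed with [set.seed()] (or use [generate_cohort()]).
#'
#' @param population population parameters, see [vo2_population()]
#' @param subject_id integer identifier stored in the profile
#' @return object of class `subject_profile`
#' @export
sample_subject_profile <- function(population = vo2_population(), subject_id = 1L) {
  stopifnot(inherits(population, "vo2_population") || is.list(population))
  for (grp in population$attributes) for (a in grp) {
    if (!all(is.finite(a[1:2]))) stop("population means/SDs must be finite")
    if (a[2] < 0) stop("population SDs must be non-negative")
  }
  fitness <- if (stats::runif(1) < population$p_trained) "trained" else "untrained"
  sex <- if (stats::runif(1) < population$p_female[[fitness]]) "female" else "male"
  at <- population$attributes[[fitness]]
  age    <- rtruncnorm(1, at$age[1], at$age[2], at$age[3], at$age[4])
  height <- rtruncnorm(1, at$height[1], at$height[2], at$height[3], at$height[4])
  mass   <- rtruncnorm(1, at$mass[1], at$mass[2], at$mass[3], at$mass[4])
  lt <- population$latent
  draw <- function(nm) rtruncnorm(1, lt[[nm]][1], lt[[nm]][2], lt[[nm]][3], lt[[nm]][4])
  hr_rest <- draw(paste0("hr_rest_", fitness))
  hr_rest <- min(hr_rest, 220 - age - 1e-6)
  prof <- list(
    subject_id = as.integer(subject_id),
    age = age, height = height, body_mass = mass,
    bmi = mass / (height / 100)^2,
    sex = sex, fitness = fitness,
    hr_rest = hr_rest,
    vo2_rest = draw("vo2_rest"),
    hr_gain = draw("hr_gain"),
    vo2_gain_linear = draw("vo2_gain_linear"),
    vo2_gain_quadratic = draw("vo2_gain_quadratic"),
    tau_on = draw(paste0("tau_on_", fitness)),
    tau_off = draw("tau_off"),
    cadence_base = draw(paste0("cadence_base_", sex)),
    cadence_slope = draw(paste0("cadence_slope_", sex)),
    osc_walk = draw("osc_walk"),
    osc_run = draw("osc_run"),
    noise_scales = population$noise_scales,
    osc_spike = population$osc_spike
  )
  class(prof) <- "subject_profile"
  prof
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("Subject %d: %s, %s, %.1f yr, %.1f cm, %.1f kg (BMI %.1f)\n",
              x$subject_id, x$sex, x$fitness, x$age, x$height, x$body_mass, x$bmi))
  cat(sprintf("  rest: HR %.0f bpm, VO2 %.1f ml/min/kg; tau on/off %.0f/%.0f s\n",
              x$hr_rest, x$vo2_rest, x$tau_on, x$tau_off))
  invisible(x)
}

# ---- protocol ------------------------------------------------------------

#' Study speeds (m/s): three walking, five running
#' @keywords internal
study_speeds <- function() c(1.0, 1.3, 1.5, 2.2, 2.5, 2.8, 3.1, 3.3)

#' Build a randomized session protocol
#'
#' The protocol is 5 min of initial seated rest, then `n_cycles` cycles of
#' 5 min walking/running followed by 5 min seated rest. The first speed is
#' always 1.0 m/s; the remaining speeds are a uniformly random permutation of
#' the other seven study speeds, truncated to `n_cycles - 1`. Uses the current
#' RNG stream.
#'
#' @param n_cycles number of walk/run cycles, 1..8
#' @param extra_speed if `TRUE`, append an additional 3.6 m/s cycle (the one
#'   participant in the emulated study who also ran at 3.6 m/s)
#' @return object of class `protocol_spec`
#' @export
build_protocol <- function(n_cycles = 8L, extra_speed = FALSE) {
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L || n_cycles > 8L) stop("n_cycles must be in 1..8")
  rest <- study_speeds()[-1]
  speeds <- c(1.0, sample(rest)[seq_len(n_cycles - 1L)])
  if (extra_speed) speeds <- c(speeds, 3.6)
  proto <- list(
    rest_initial_s = 300, segment_speeds = speeds,
    segment_duration_s = 300, rest_between_s = 300,
    n_cycles_completed = length(speeds)
  )
  class(proto) <- "protocol_spec"
  proto
}

#' Steady-state targets for a given speed
#'
#' VO2 steady state is quadratic in speed
#' (`vo2_rest + a * v + b * v^2`); heart-rate steady state is linear
#' (`hr_rest + hr_gain * v`), capped at `220 - age`. At speed 0 the resting
#' values are returned. Both are monotone non-decreasing in speed.
#'
#' @param speed speed in m/s, `>= 0` (vectorized)
#' @param profile a [subject_profile][sample_subject_profile]
#' @return list with `vo2_ss` (ml/min/kg) and `hr_ss` (bpm)
#' @export
steady_state_targets <- function(speed, profile) {
  if (any(speed < 0)) stop("speed must be non-negative")
  vo2 <- ifelse(speed > 0,
                profile$vo2_rest + profile$vo2_gain_linear * speed +
                  profile$vo2_gain_quadratic * speed^2,
                profile$vo2_rest)
  hr <- ifelse(speed > 0, profile$hr_rest + profile$hr_gain * speed, profile$hr_rest)
  hr <- pmin(hr, 220 - profile$age)
  list(vo2_ss = vo2, hr_ss = hr)
}

# segment table for a protocol: start, end, speed (rest speed = 0)
protocol_segments <- function(protocol) {
  segs <- data.frame(start = 300 * 0, end = protocol$rest_initial_s, speed = 0)
  t <- protocol$rest_initial_s
  for (v in protocol$segment_speeds) {
    segs <- rbind(segs, data.frame(start = t, end = t + protocol$segment_duration_s, speed = v))
    t <- t + protocol$segment_duration_s
    segs <- rbind(segs, data.frame(start = t, end = t + protocol$rest_between_s, speed = 0))
    t <- t + protocol$rest_between_s
  }
  segs
}

# exact discrete first-order kinetics on a 1 Hz grid:
# X[t+1] = Xss + (X[t] - Xss) * exp(-1/tau), tau = tau_on when rising else tau_off.
# Within a constant-speed segment the approach is monotone so tau is constant,
# allowing a vectorized recursive filter per segment.
simulate_kinetics <- function(segs, x_rest, ss_fun, tau_on, tau_off) {
  t_end <- segs$end[nrow(segs)]
  out <- numeric(t_end + 1)        # values at t = 0..t_end
  x <- x_rest
  out[1] <- x
  for (i in seq_len(nrow(segs))) {
    n <- segs$end[i] - segs$start[i]
    xss <- ss_fun(segs$speed[i])
    tau <- if (xss > x) tau_on else tau_off
    a <- exp(-1 / tau)
    vals <- stats::filter(rep((1 - a) * xss, n), a, method = "recursive", init = x)
    out[segs$start[i] + 1 + seq_len(n)] <- vals
    x <- vals[n]
  }
  out
}

# ---- session simulation --------------------------------------------------

#' Simulate one raw multi-rate session
#'
#' Integrates first-order on/off kinetics for VO2 and heart rate at 1 Hz over
#' the protocol (`dX/dt = (X_ss - X)/tau`, `tau_on` when rising, `tau_off`
#' when falling, exact exponential discretization), then emits three sensor
#' streams: VO2 every 5 s (with a uniformly drawn +/-`max_offset_s` clock
#' offset added to its timestamps, kept in `true_offset_s` for oracle checks),
#' heart rate at 1 Hz, and per-step gait features during active segments
#' (speed, peak-to-peak speed change, step duration, vertical oscillation).
#' Sparse low-amplitude "shuffle" steps are emitted during seated rests so the
#' step series also covers the resting VO2 range at near-zero oscillation.
#'
#' Vertical oscillation follows two regimes: a walking level (<= 1.5 m/s) with
#' a mild positive slope, and a running level with a negative within-regime
#' slope, so that pooled against VO2 the relation is strongly monotone in rank
#' but almost uncorrelated linearly.
#'
#' @param profile a [subject_profile][sample_subject_profile]
#' @param protocol a [protocol_spec][build_protocol]
#' @param noise logical; `FALSE` zeroes all observation noise and the clock
#'   offset (used by the kinetics oracle)
#' @param max_offset_s clock-offset bound (s)
#' @return object of class `raw_session`: `vo2_stream` (`t`, `vo2`),
#'   `hr_stream` (`t`, `hr`), `step_stream` (one row per step),
#'   `true_offset_s`, and the noiseless 1 Hz `truth` trajectories
#' @export
simulate_session <- function(profile, protocol, noise = TRUE, max_offset_s = 30) {
  stopifnot(inherits(profile, "subject_profile"), inherits(protocol, "protocol_spec"))
  segs <- protocol_segments(protocol)
  ns <- if (noise) profile$noise_scales else profile$noise_scales * 0
  vo2_true <- simulate_kinetics(
    segs, profile$vo2_rest,
    function(v) steady_state_targets(v, profile)$vo2_ss,
    profile$tau_on, profile$tau_off)
  hr_true <- simulate_kinetics(
    segs, profile$hr_rest,
    function(v) steady_state_targets(v, profile)$hr_ss,
    profile$tau_on, profile$tau_off)
  t_end <- segs$end[nrow(segs)]
  tt <- 0:t_end

  offset <- if (noise) stats::runif(1, -max_offset_s, max_offset_s) else 0
  vo2_t <- seq(0, t_end, by = 5)
  vo2_stream <- data.frame(
    t = vo2_t + offset,
    vo2 = vo2_true[vo2_t + 1] + stats::rnorm(length(vo2_t), 0, ns[["vo2"]]))
  hr_stream <- data.frame(
    t = tt,
    hr = hr_true + stats::rnorm(length(tt), 0, ns[["heart_rate"]]))

  # per-step gait features
  steps <- list()
  for (i in seq_len(nrow(segs))) {
    v <- segs$speed[i]
    dur_total <- segs$end[i] - segs$start[i]
    if (v > 0) {
      cadence <- max(profile$cadence_base + profile$cadence_slope * (v - 1), 0.8)
      d0 <- 1 / cadence
      n <- floor(dur_total / d0) - 1L
      if (n < 1) next
      durs <- rep(d0, n)
      starts <- segs$start[i] + cumsum(c(0, durs[-n]))
      if (v <= 1.5) {
        osc <- profile$osc_walk + 0.004 * (v - 1.0)
        spch <- 0.10 + 0.08 * (v - 1.0)
      } else {
        osc <- profile$osc_run - 0.022 * (v - 2.2)
        spch <- 0.30 + 0.22 * (v - 2.2)
      }
      osc_obs <- pmax(osc + stats::rnorm(n, 0, ns[["vertical_oscillation"]]), 0)
      if (noise && profile$osc_spike[["p"]] > 0) {
        sp <- stats::runif(n) < profile$osc_spike[["p"]]
        osc_obs[sp] <- osc_obs[sp] + stats::rexp(sum(sp), 1 / profile$osc_spike[["mean"]])
      }
      steps[[length(steps) + 1]] <- data.frame(
        t = starts,
        speed = v + stats::rnorm(n, 0, ns[["speed"]]),
        speed_change = pmax(spch + stats::rnorm(n, 0, ns[["speed_change"]]), 0),
        step_duration = durs + stats::rnorm(n, 0, ns[["step_duration"]]),
        vertical_oscillation = osc_obs)
    } else {
      # sparse postural shuffle bouts while seated: ~3 steps every ~20 s
      bout_starts <- seq(segs$start[i] + 5, segs$end[i] - 10, by = 20)
      for (b in bout_starts) {
        n <- 3L
        durs <- rep(0.56, n)
        starts <- b + cumsum(c(0, durs[-n]))
        steps[[length(steps) + 1]] <- data.frame(
          t = starts,
          speed = pmax(0.04 + stats::rnorm(n, 0, ns[["speed"]]), 0),
          speed_change = pmax(0.05 + stats::rnorm(n, 0, ns[["speed_change"]]), 0),
          step_duration = durs + stats::rnorm(n, 0, ns[["step_duration"]]),
          vertical_oscillation = pmax(0.004 + stats::rnorm(n, 0, ns[["vertical_oscillation"]]), 0))
      }
    }
  }
  step_stream <- do.call(rbind, steps)
  step_stream <- step_stream[order(step_stream$t), , drop = FALSE]
  rownames(step_stream) <- NULL

  session <- list(
    vo2_stream = vo2_stream, hr_stream = hr_stream, step_stream = step_stream,
    true_offset_s = offset,
    truth = data.frame(t = tt, vo2 = vo2_true, hr = hr_true),
    subject_id = profile$subject_id, protocol = protocol
  )
  class(session) <- "raw_session"
  session
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("Raw session (subject %s): %d VO2 samples (5 s), %d HR samples (1 Hz), %d steps\n",
              x$subject_id, nrow(x$vo2_stream), nrow(x$hr_stream), nrow(x$step_stream)))
  cat(sprintf("  clock offset %.1f s, %d walk/run cycles\n",
              x$true_offset_s, x$protocol$n_cycles_completed))
  invisible(x)
}

# ---- artifacts -----------------------------------------------------------

#' Construct an artifact scenario
#'
#' The three data defects documented in the emulated study: partially missing
#' heart-rate data (`hr_partial`), a ~90 s spirometer gap (`spirometer_gap`),
#' and early termination after a given cycle count (`early_termination`).
#'
#' @param kind one of `"none"`, `"hr_partial"`, `"spirometer_gap"`,
#'   `"early_termination"`
#' @param gap_start_s start of the deleted span (s); for `spirometer_gap`
#'   snapped to the 5 s sampling grid
#' @param gap_length_s length of the deleted span (s)
#' @param cycles_retained cycles kept for `early_termination`
#' @return object of class `artifact_scenario`
#' @export
artifact_scenario <- function(kind = c("none", "hr_partial", "spirometer_gap",
                                       "early_termination"),
                              gap_start_s = NULL, gap_length_s = NULL,
                              cycles_retained = 5L) {
  kind <- match.arg(kind)
  sc <- list(kind = kind, gap_start_s = gap_start_s, gap_length_s = gap_length_s,
             cycles_retained = as.integer(cycles_retained))
  class(sc) <- "artifact_scenario"
  sc
}

#' Inject a data-defect scenario into a raw session
#'
#' Surviving records are bit-identical; only deletions/truncations occur, so
#' the sampling spacing of surviving records is unchanged.
#'
#' @param session a [raw_session][simulate_session]
#' @param scenario an [artifact_scenario()]
#' @return the modified session, with the scenario recorded in `$artifact`
#' @export
inject_artifacts <- function(session, scenario) {
  stopifnot(inherits(session, "raw_session"), inherits(scenario, "artifact_scenario"))
  t_end <- max(session$hr_stream$t)
  if (scenario$kind == "none") {
    session$artifact <- scenario
    return(session)
  }
  if (scenario$kind == "hr_partial") {
    len <- if (is.null(scenario$gap_length_s)) 1200 else scenario$gap_length_s
    start <- if (is.null(scenario$gap_start_s)) round(t_end * 0.35) else scenario$gap_start_s
    if (start < 0 || start + len > t_end) stop("gap outside session span")
    keep <- session$hr_stream$t < start | session$hr_stream$t >= start + len
    session$hr_stream <- session$hr_stream[keep, , drop = FALSE]
    scenario$gap_start_s <- start; scenario$gap_length_s <- len
  } else if (scenario$kind == "spirometer_gap") {
    len <- if (is.null(scenario$gap_length_s)) 90 else scenario$gap_length_s
    start <- if (is.null(scenario$gap_start_s)) round(t_end * 0.5 / 5) * 5 else scenario$gap_start_s
    if (start < 0 || start + len > t_end) stop("gap outside session span")
    # deletion on the stream's own (offset) clock, half-open [start, start+len)
    tt <- session$vo2_stream$t - session$true_offset_s
    keep <- tt < start | tt >= start + len
    session$vo2_stream <- session$vo2_stream[keep, , drop = FALSE]
    scenario$gap_start_s <- start; scenario$gap_length_s <- len
  } else if (scenario$kind == "early_termination") {
    nc <- scenario$cycles_retained
    if (nc < 1 || nc > session$protocol$n_cycles_completed)
      stop("cycles_retained outside session span")
    t_cut <- session$protocol$rest_initial_s +
      nc * (session$protocol$segment_duration_s + session$protocol$rest_between_s)
    session$vo2_stream <- session$vo2_stream[
      session$vo2_stream$t - session$true_offset_s <= t_cut, , drop = FALSE]
    session$hr_stream <- session$hr_stream[session$hr_stream$t <= t_cut, , drop = FALSE]
    session$step_stream <- session$step_stream[session$step_stream$t <= t_cut, , drop = FALSE]
    session$truth <- session$truth[session$truth$t <= t_cut, , drop = FALSE]
    session$protocol$segment_speeds <- session$protocol$segment_speeds[seq_len(nc)]
    session$protocol$n_cycles_completed <- nc
  }
  session$artifact <- scenario
  session
}

# ---- cohort --------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` independent profiles and sessions. With
#' `artifacts = TRUE` (default) subjects 1, 2 and 10 carry the three
#' documented data defects: partial heart-rate data, a ~90 s spirometer gap,
#' and termination after the fifth cycle. Fully reproducible from `seed`:
#' per-subject sub-seeds are derived from the top-level seed so each subject's
#' data is independent of cohort size.
#'
#' @param n_subjects number of subjects (default 16, as in the emulated study)
#' @param seed integer seed
#' @param artifacts apply the default artifact scenarios
#' @param n_cycles walk/run cycles per protocol (default 8)
#' @param population see [vo2_population()]
#' @return object of class `vo2_cohort`: list with `profiles`, `sessions`,
#'   and a `provenance` record (seed, parameters)
#' @export
generate_cohort <- function(n_subjects = 16L, seed = 1L, artifacts = TRUE,
                            n_cycles = 8L, population = vo2_population()) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  profiles <- vector("list", n_subjects)
  sessions <- vector("list", n_subjects)
  scen_for <- function(i) {
    if (!artifacts) return(artifact_scenario("none"))
    if (i == 1L) artifact_scenario("hr_partial")
    else if (i == 2L) artifact_scenario("spirometer_gap")
    else if (i == 10L) artifact_scenario("early_termination", cycles_retained = 5L)
    else artifact_scenario("none")
  }
  for (i in seq_len(n_subjects)) {
    set.seed(sub_seeds[i])
    prof <- sample_subject_profile(population, subject_id = i)
    proto <- build_protocol(n_cycles)
    sess <- simulate_session(prof, proto)
    sess <- inject_artifacts(sess, scen_for(i))
    profiles[[i]] <- prof
    sessions[[i]] <- sess
  }
  cohort <- list(
    profiles = profiles, sessions = sessions,
    provenance = list(seed = seed, n_subjects = n_subjects,
                      artifacts = artifacts, n_cycles = n_cycles,
                      sub_seeds = sub_seeds,
                      generated = "vo2net::generate_cohort")
  )
  class(cohort) <- "vo2_cohort"
  cohort
}

#' @export
print.vo2_cohort <- function(x, ...) {
  n <- length(x$profiles)
  art <- vapply(x$sessions, function(s) s$artifact$kind, "")
  cat(sprintf("Synthetic cohort: %d subjects (seed %d), artifacts: %s\n",
              n, x$provenance$seed,
              if (all(art == "none")) "none" else
                paste(sprintf("subject %d %s", which(art != "none"), art[art != "none"]),
                      collapse = ", ")))
  invisible(x)
}

# ---- cohort I/O ----------------------------------------------------------

#' Write a cohort to per-subject CSV streams plus a JSON manifest
#'
#' Layout: `subject_<id>/vo2.csv` (`t_s`, `vo2_ml_min_kg`), `hr.csv`
#' (`t_s`, `hr_bpm`), `steps.csv` (`t_s`, `speed_m_s`, `speed_change_m_s`,
#' `step_duration_s`, `vertical_oscillation_m`), and `manifest.json` with
#' profiles, scenarios and the generating seed.
#'
#' @param cohort a [vo2_cohort][generate_cohort]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vo2_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    sd <- file.path(dir, sprintf("subject_%02d", s$subject_id))
    dir.create(sd, showWarnings = FALSE)
    vo2 <- s$vo2_stream; names(vo2) <- c("t_s", "vo2_ml_min_kg")
    hr <- s$hr_stream; names(hr) <- c("t_s", "hr_bpm")
    st <- s$step_stream
    names(st) <- c("t_s", "speed_m_s", "speed_change_m_s", "step_duration_s",
                   "vertical_oscillation_m")
    utils::write.csv(vo2, file.path(sd, "vo2.csv"), row.names = FALSE)
    utils::write.csv(hr, file.path(sd, "hr.csv"), row.names = FALSE)
    utils::write.csv(st, file.path(sd, "steps.csv"), row.names = FALSE)
  }
  manifest <- list(
    provenance = cohort$provenance,
    profiles = lapply(cohort$profiles, function(p) unclass(p)),
    scenarios = lapply(cohort$sessions, function(s)
      list(subject_id = s$subject_id, kind = s$artifact$kind,
           true_offset_s = s$true_offset_s,
           protocol = unclass(s$protocol)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json` and per-subject folders
#' @return a `vo2_cohort` (without the noiseless truth trajectories)
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  n <- length(man$profiles)
  profiles <- vector("list", n)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    p <- man$profiles[[i]]
    p$noise_scales <- unlist(p$noise_scales)
    p$osc_spike <- unlist(p$osc_spike)
    class(p) <- "subject_profile"
    profiles[[i]] <- p
    sd <- file.path(dir, sprintf("subject_%02d", p$subject_id))
    vo2 <- utils::read.csv(file.path(sd, "vo2.csv")); names(vo2) <- c("t", "vo2")
    hr <- utils::read.csv(file.path(sd, "hr.csv")); names(hr) <- c("t", "hr")
    st <- utils::read.csv(file.path(sd, "steps.csv"))
    names(st) <- c("t", "speed", "speed_change", "step_duration", "vertical_oscillation")
    sc <- man$scenarios[[i]]
    proto <- sc$protocol
    class(proto) <- "protocol_spec"
    sess <- list(vo2_stream = vo2, hr_stream = hr, step_stream = st,
                 true_offset_s = sc$true_offset_s, truth = NULL,
                 subject_id = p$subject_id, protocol = proto,
                 artifact = artifact_scenario(sc$kind))
    class(sess) <- "raw_session"
    sessions[[i]] <- sess
  }
  cohort <- list(profiles = profiles, sessions = sessions,
                 provenance = man$provenance)
  class(cohort) <- "vo2_cohort"
  cohort
}
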