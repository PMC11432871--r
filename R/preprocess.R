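# ---- smoothing -----------------------------------------------------------

#' Smoothing configuration
#'
#' Savitzky-Golay settings for the VO2 stream and moving-average window for
#' heart rate. Defaults: polynomial order 3, window 11, 3 sequential passes
#' for VO2 (order 9 is the documented alternative for unusually noisy
#' spirometer data, window must then still exceed the order); window 3 for HR
#' (5 for noisy HR).
#'
#' @param savgol_polyorder polynomial order (default 3)
#' @param savgol_window odd window length, `> savgol_polyorder`
#' @param savgol_passes number of sequential filter applications (default 3)
#' @param hr_ma_window odd moving-average window for heart rate (default 3)
#' @return object of class `smoothing_config`
#' @export
smoothing_config <- function(savgol_polyorder = 3L, savgol_window = 11L,
                             savgol_passes = 3L, hr_ma_window = 3L) {
  savgol_window <- as.integer(savgol_window)
  if (savgol_window %% 2L == 0L) stop("savgol_window must be odd")
  if (savgol_window <= savgol_polyorder) stop("savgol_window must exceed savgol_polyorder")
  if (savgol_passes < 1L || hr_ma_window < 1L) stop("windows and passes must be >= 1")
  if (hr_ma_window %% 2L == 0L) stop("hr_ma_window must be odd")
  cfg <- list(savgol_polyorder = as.integer(savgol_polyorder),
              savgol_window = savgol_window,
              savgol_passes = as.integer(savgol_passes),
              hr_ma_window = as.integer(hr_ma_window))
  class(cfg) <- "smoothing_config"
  cfg
}

#' Savitzky-Golay smoothing of a VO2 series
#'
#' Applies `signal::sgolayfilt` `savgol_passes` times sequentially. Length is
#' preserved; a polynomial of degree `<= savgol_polyorder` passes through
#' unchanged.
#'
#' @param x numeric vector (sampled VO2 values)
#' @param cfg a [smoothing_config()]
#' @return smoothed vector, same length
#' @export
smooth_vo2 <- function(x, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  if (length(x) < cfg$savgol_window) stop("series shorter than savgol_window")
  for (i in seq_len(cfg$savgol_passes)) {
    x <- signal::sgolayfilt(x, p = cfg$savgol_polyorder, n = cfg$savgol_window)
  }
  x
}

#' Centered moving-average smoothing of a heart-rate series
#'
#' Edges are handled by symmetrically shrinking the window, so length is
#' preserved and a constant series is unchanged.
#'
#' @param x numeric vector
#' @param window odd window length
#' @return smoothed vector, same length
#' @export
smooth_hr <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (length(x) < window) stop("series shorter than window")
  if (window == 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  h <- pmin(seq_len(n) - 1L, n - seq_len(n), half)  # symmetric shrink at edges
  lo <- seq_len(n) - h
  hi <- seq_len(n) + h
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# ---- synchronization -----------------------------------------------------

#' Estimate the clock offset between the VO2 and heart-rate streams
#'
#' Both streams are linearly interpolated onto a common 1 Hz grid over their
#' overlap, standardized to zero mean and unit variance, and cross-correlated
#' over integer lags within `+/- max_lag_s`. The lag with the highest
#' correlation is returned; ties break toward the smallest absolute lag. A
#' positive return value means the VO2 stream's clock runs ahead of the
#' heart-rate clock by that many seconds (subtract it from the VO2 timestamps
#' to align).
#'
#' @param vo2_stream data frame with columns `t`, `vo2`
#' @param hr_stream data frame with columns `t`, `hr`
#' @param max_lag_s search half-window in seconds (default 120)
#' @return estimated offset in seconds
#' @export
estimate_offset <- function(vo2_stream, hr_stream, max_lag_s = 120L) {
  t0 <- max(min(vo2_stream$t), min(hr_stream$t))
  t1 <- min(max(vo2_stream$t), max(hr_stream$t))
  if (t1 - t0 < 2 * max_lag_s) stop("stream overlap shorter than twice the search window")
  grid <- seq(ceiling(t0), floor(t1), by = 1)
  v <- stats::approx(vo2_stream$t, vo2_stream$vo2, grid)$y
  h <- stats::approx(hr_stream$t, hr_stream$hr, grid)$y
  if (stats::sd(v) == 0 || stats::sd(h) == 0) stop("zero-variance input")
  v <- (v - mean(v)) / stats::sd(v)
  h <- (h - mean(h)) / stats::sd(h)
  n <- length(grid)
  lags <- -max_lag_s:max_lag_s
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- v[(1 + k):n]; b <- h[1:(n - k)]
    } else {
      a <- v[1:(n + k)]; b <- h[(1 - k):n]
    }
    sum(a * b) / length(a)
  }, 0)
  best <- max(cc)
  cand <- lags[cc >= best - 1e-12]
  cand[which.min(abs(cand))]
}

# ---- alignment and resampling --------------------------------------------

# indices of query times that fall inside a well-sampled region of (t, spacing)
interp_ok <- function(sample_t, query_t, nominal_dt) {
  if (length(sample_t) < 2) return(rep(FALSE, length(query_t)))
  i <- findInterval(query_t, sample_t)
  ok <- i >= 1 & i < length(sample_t)
  gap <- rep(Inf, length(query_t))
  gap[ok] <- sample_t[i[ok] + 1L] - sample_t[i[ok]]
  ok & gap <= 1.5 * nominal_dt
}

#' Align streams and resample onto step times
#'
#' Shifts the VO2 timestamps by `-offset`, then linearly interpolates the
#' (already smoothed) VO2 and heart-rate streams onto the step start times.
#' Steps whose interpolation window falls outside stream coverage or spans a
#' deleted-data gap (sample spacing more than 1.5x the nominal rate) are
#' dropped rather than imputed.
#'
#' @param session a [raw_session][simulate_session] whose stream values have
#'   been smoothed
#' @param offset clock offset in seconds, see [estimate_offset()]
#' @return data frame of class `aligned_steps`: one row per surviving step
#'   with columns `subject_id`, `t`, `speed`, `speed_change`, `step_duration`,
#'   `vertical_oscillation`, `heart_rate`, `vo2`
#' @export
align_and_resample <- function(session, offset = 0) {
  stopifnot(inherits(session, "raw_session"))
  st <- session$step_stream
  vt <- session$vo2_stream$t - offset
  ok <- interp_ok(vt, st$t, 5) & interp_ok(session$hr_stream$t, st$t, 1)
  if (!any(ok)) stop("empty overlap after alignment")
  st <- st[ok, , drop = FALSE]
  vo2 <- stats::approx(vt, session$vo2_stream$vo2, st$t)$y
  hr <- stats::approx(session$hr_stream$t, session$hr_stream$hr, st$t)$y
  out <- data.frame(
    subject_id = session$subject_id,
    t = st$t,
    speed = st$speed,
    speed_change = st$speed_change,
    step_duration = st$step_duration,
    vertical_oscillation = st$vertical_oscillation,
    heart_rate = hr,
    vo2 = vo2
  )
  stopifnot(all(diff(out$t) > 0), !anyNA(out))
  class(out) <- c("aligned_steps", "data.frame")
  out
}

#' Preprocess one session: smooth, synchronize, resample
#'
#' Applies [smooth_vo2()] and [smooth_hr()] to the stream values, estimates
#' the VO2/HR clock offset with [estimate_offset()], and resamples onto step
#' times with [align_and_resample()].
#'
#' @param session a [raw_session][simulate_session]
#' @param cfg a [smoothing_config()]
#' @return an `aligned_steps` data frame; the estimated offset is stored in
#'   attribute `offset_est`
#' @export
preprocess_session <- function(session, cfg = smoothing_config()) {
  s <- session
  s$vo2_stream$vo2 <- smooth_vo2(s$vo2_stream$vo2, cfg)
  s$hr_stream$hr <- smooth_hr(s$hr_stream$hr, cfg$hr_ma_window)
  off <- estimate_offset(s$vo2_stream, s$hr_stream)
  out <- align_and_resample(s, off)
  attr(out, "offset_est") <- off
  out
}

#' Preprocess a whole cohort
#'
#' @param cohort a [vo2_cohort][generate_cohort]
#' @param cfg a [smoothing_config()]
#' @return an `aligned_steps` data frame pooled over subjects; estimated
#'   offsets per subject in attribute `offsets`
#' @export
preprocess_cohort <- function(cohort, cfg = smoothing_config()) {
  stopifnot(inherits(cohort, "vo2_cohort"))
  parts <- lapply(cohort$sessions, preprocess_session, cfg = cfg)
  offs <- vapply(parts, attr, 0, "offset_est")
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("aligned_steps", "data.frame")
  attr(out, "offsets") <- offs
  out
}

# ---- aligned-series I/O --------------------------------------------------

#' Write/read an aligned step series as CSV
#'
#' One row per step; columns carry SI units in their names
#' (`t_s`, `speed_m_s`, `speed_change_m_s`, `step_duration_s`,
#' `vertical_oscillation_m`, `heart_rate_bpm`, `vo2_ml_min_kg`).
#'
#' @param steps an `aligned_steps` data frame
#' @param path CSV file path
#' @return `path` invisibly (write); the `aligned_steps` table (read)
#' @export
write_aligned_steps <- function(steps, path) {
  stopifnot(inherits(steps, "aligned_steps"))
  out <- as.data.frame(steps)
  names(out) <- c("subject_id", "t_s", "speed_m_s", "speed_change_m_s",
                  "step_duration_s", "vertical_oscillation_m",
                  "heart_rate_bpm", "vo2_ml_min_kg")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aligned_steps
#' @export
read_aligned_steps <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- c("subject_id", "t", "speed", "speed_change", "step_duration",
                "vertical_oscillation", "heart_rate", "vo2")
  class(d) <- c("aligned_steps", "data.frame")
  d
}

# ---- attribute encoding --------------------------------------------------

#' Encode participant attributes as category codes
#'
#' Age: `<= 25` -> 0, 26-29 -> 1, `>= 30` -> 2. BMI: `< 22` -> 0, 22-25 -> 1,
#' `> 25` -> 2. Sex: female 0, male 1. Fitness: untrained 0, trained 1.
#'
#' @param profile a [subject_profile][sample_subject_profile]
#' @return integer vector `c(age, bmi, sex, fitness)` of category codes
#' @export
encode_attributes <- function(profile) {
  age_code <- if (profile$age <= 25) 0L else if (profile$age < 30) 1L else 2L
  bmi_code <- if (profile$bmi < 22) 0L else if (profile$bmi <= 25) 1L else 2L
  sex_code <- if (profile$sex == "male") 1L else 0L
  fit_code <- if (profile$fitness == "trained") 1L else 0L
  c(age = age_code, bmi = bmi_code, sex = sex_code, fitness = fit_code)
}

# ---- normalization -------------------------------------------------------

vo2_feature_names <- function() {
  c("speed", "speed_change", "step_duration", "vertical_oscillation", "heart_rate")
}

#' Fit per-feature normalization statistics on training subjects
#'
#' Means and standard deviations of the five input features, computed over
#' the listed subjects only; the subject-ID provenance is stored with the
#' statistics so leakage can be audited.
#'
#' @param steps an `aligned_steps` data frame
#' @param subject_ids subjects whose rows enter the statistics
#' @return object of class `normalization_stats` with `mean`, `sd`,
#'   `subject_ids`
#' @export
fit_normalization <- function(steps, subject_ids) {
  stopifnot(inherits(steps, "aligned_steps"))
  rows <- steps$subject_id %in% subject_ids
  if (!any(rows)) stop("no data for the given training subjects")
  feats <- as.matrix(steps[rows, vo2_feature_names(), drop = FALSE])
  m <- colMeans(feats)
  s <- apply(feats, 2, stats::sd)
  if (any(s == 0)) stop("zero-variance feature")
  st <- list(mean = m, sd = s, subject_ids = sort(unique(steps$subject_id[rows])))
  class(st) <- "normalization_stats"
  st
}

#' Apply normalization statistics
#'
#' Standardizes the five input features of an `aligned_steps` table or the
#' feature rows of a `vo2_samples` set.
#'
#' @param x an `aligned_steps` data frame or a `vo2_samples` object
#' @param stats a [normalization_stats][fit_normalization]
#' @return `x` with standardized features
#' @export
apply_normalization <- function(x, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  if (inherits(x, "aligned_steps")) {
    for (f in vo2_feature_names()) x[[f]] <- (x[[f]] - stats$mean[[f]]) / stats$sd[[f]]
    return(x)
  }
  if (inherits(x, "vo2_samples")) {
    for (i in seq_along(vo2_feature_names())) {
      x$x[, i, ] <- (x$x[, i, ] - stats$mean[[i]]) / stats$sd[[i]]
    }
    x$normalized <- TRUE
    return(x)
  }
  stop("unsupported input")
}

# ---- windowing -----------------------------------------------------------

#' Cut an aligned step series into training sequences
#'
#' Sliding windows of `L` consecutive steps at the given stride, never
#' crossing subject boundaries. Each sample is a 5-by-`L` feature matrix
#' (rows: speed, speed change, step duration, vertical oscillation, heart
#' rate) with the VO2 at the window's final step as target (many-to-one).
#'
#' @param steps an `aligned_steps` data frame (one or several subjects)
#' @param L window length in steps (the emulated study used 50 and 200)
#' @param stride window stride in steps (default 1, maximally overlapping)
#' @return object of class `vo2_samples`: list with `x` (array `N x 5 x L`),
#'   `target` (VO2 at window end), `subject_id`, `t_end`
#' @export
window_sequences <- function(steps, L, stride = 1L) {
  stopifnot(inherits(steps, "aligned_steps"))
  L <- as.integer(L); stride <- as.integer(stride)
  if (L < 1L || stride < 1L) stop("L and stride must be >= 1")
  sids <- unique(steps$subject_id)
  xs <- list(); targ <- list(); sub <- list(); tend <- list()
  feats <- vo2_feature_names()
  for (sid in sids) {
    d <- steps[steps$subject_id == sid, , drop = FALSE]
    n <- nrow(d)
    if (n < L) {
      if (length(sids) == 1L) stop("series shorter than L")
      next
    }
    starts <- seq.int(1L, n - L + 1L, by = stride)
    K <- length(starts)
    idx <- outer(starts, 0:(L - 1L), "+")
    arr <- array(0, dim = c(K, 5L, L))
    for (f in seq_along(feats)) {
      v <- d[[feats[f]]]
      arr[, f, ] <- v[idx]
    }
    xs[[length(xs) + 1]] <- arr
    targ[[length(targ) + 1]] <- d$vo2[starts + L - 1L]
    sub[[length(sub) + 1]] <- rep(sid, K)
    tend[[length(tend) + 1]] <- d$t[starts + L - 1L]
  }
  if (!length(xs)) stop("series shorter than L")
  ktot <- sum(vapply(xs, function(a) dim(a)[1], 0L))
  x <- array(0, dim = c(ktot, 5L, L))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[1]
    x[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out <- list(x = x, target = unlist(targ), subject_id = unlist(sub),
              t_end = unlist(tend), L = L, stride = stride, normalized = FALSE)
  class(out) <- "vo2_samples"
  out
}

#' Attach encoded participant attributes to a sample set
#'
#' @param samples a `vo2_samples` object
#' @param profiles list of [subject_profile][sample_subject_profile]s covering
#'   every subject present in `samples`
#' @return `samples` with an `attrs` matrix (`N x 4` category codes)
#' @export
attach_attributes <- function(samples, profiles) {
  stopifnot(inherits(samples, "vo2_samples"))
  ids <- vapply(profiles, function(p) p$subject_id, 0L)
  codes <- t(vapply(profiles, encode_attributes, integer(4)))
  m <- match(samples$subject_id, ids)
  if (anyNA(m)) stop("missing profile for some subjects")
  samples$attrs <- codes[m, , drop = FALSE]
  samples
}

#' Subset a sample set
#'
#' @param x a `vo2_samples` object
#' @param i sample indices (logical or integer)
#' @param ... unused
#' @return the subset, a `vo2_samples` object
#' @export
`[.vo2_samples` <- function(x, i, ...) {
  out <- x
  out$x <- x$x[i, , , drop = FALSE]
  out$target <- x$target[i]
  out$subject_id <- x$subject_id[i]
  out$t_end <- x$t_end[i]
  if (!is.null(x$attrs)) out$attrs <- x$attrs[i, , drop = FALSE]
  out
}

#' @export
print.vo2_samples <- function(x, ...) {
  cat(sprintf("vo2_samples: %d samples of 5 x %d (stride %d), %d subject(s)%s%s\n",
              dim(x$x)[1], x$L, x$stride, length(unique(x$subject_id)),
              if (isTRUE(x$normalized)) ", normalized" else "",
              if (!is.null(x$attrs)) ", with attributes" else ""))
  invisible(x)
}

#' Number of samples in a `vo2_samples` set
#' @param samples a `vo2_samples` object
#' @return integer count
#' @export
n_samples <- function(samples) dim(samples$x)[1]
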