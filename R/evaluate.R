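# ---- split plans ---------------------------------------------------------

#' Intra-subject random splits
#'
#' For each subject, samples are divided randomly into training (70%),
#' validation (15%) and test (15%) sets; the division is repeated
#' `repetitions` times with sub-seeds derived from `seed`.
#'
#' @param samples a `vo2_samples` set
#' @param seed integer seed
#' @param repetitions number of repeated random divisions (default 5)
#' @return object of class `split_plan` (`mode = "intra"`): list of folds,
#'   each with `subject`, `repetition`, and `train`/`val`/`test` sample
#'   indices
#' @export
make_intra_splits <- function(samples, seed = 1L, repetitions = 5L) {
  stopifnot(inherits(samples, "vo2_samples"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, repetitions)
  sids <- sort(unique(samples$subject_id))
  folds <- list()
  for (r in seq_len(repetitions)) {
    set.seed(rep_seeds[r])
    for (sid in sids) {
      idx <- which(samples$subject_id == sid)
      n <- length(idx)
      if (n < 10L) stop("fewer than 10 samples for subject ", sid)
      n_tr <- floor(0.70 * n)
      n_va <- floor(0.15 * n)
      perm <- sample(idx)
      folds[[length(folds) + 1]] <- list(
        subject = sid, repetition = r,
        train = sort(perm[seq_len(n_tr)]),
        val = sort(perm[n_tr + seq_len(n_va)]),
        test = sort(perm[(n_tr + n_va + 1L):n]))
    }
  }
  plan <- list(mode = "intra", folds = folds, seed = seed,
               repetitions = repetitions)
  class(plan) <- "split_plan"
  plan
}

#' Leave-one-subject-out split plan
#'
#' For each held-out test subject and each repetition, two validation
#' subjects are drawn at random from the remaining subjects and the rest
#' train. The held-out subject never appears in its folds' training or
#' validation sets.
#'
#' @param subject_ids subject identifiers (>= 4 subjects)
#' @param seed integer seed
#' @param repetitions repetitions per held-out subject (default 5)
#' @return object of class `split_plan` (`mode = "loso"`): folds with
#'   `test_subject`, `val_subjects`, `train_subjects`, `repetition`
#' @export
make_loso_plan <- function(subject_ids, seed = 1L, repetitions = 5L) {
  subject_ids <- sort(unique(subject_ids))
  if (length(subject_ids) < 4L) stop("LOSO requires at least 4 subjects")
  set.seed(seed)
  folds <- list()
  for (sid in subject_ids) {
    rest <- setdiff(subject_ids, sid)
    for (r in seq_len(repetitions)) {
      val <- sample(rest, 2L)
      folds[[length(folds) + 1]] <- list(
        test_subject = sid, repetition = r,
        val_subjects = sort(val),
        train_subjects = sort(setdiff(rest, val)))
    }
  }
  plan <- list(mode = "loso", folds = folds, seed = seed,
               repetitions = repetitions)
  class(plan) <- "split_plan"
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("%s split plan: %d folds (%d repetitions, seed %d)\n",
              x$mode, length(x$folds), x$repetitions, x$seed))
  invisible(x)
}

# ---- error metrics -------------------------------------------------------

#' Root-mean-square error
#'
#' @param estimates,references equal-length numeric vectors (ml/min/kg)
#' @return RMSE in the input units
#' @export
rmse <- function(estimates, references) {
  if (length(estimates) != length(references)) stop("length mismatch")
  if (!length(estimates)) stop("empty input")
  sqrt(mean((estimates - references)^2))
}

#' Aggregate per-fold RMSEs
#'
#' @param fold_rmses numeric vector of per-(subject, repetition) RMSEs
#' @return list with `mean` and `sd` (sample standard deviation)
#' @export
aggregate_rmse <- function(fold_rmses) {
  if (!length(fold_rmses)) stop("empty input")
  if (length(fold_rmses) < 2L) stop("need at least 2 folds")
  list(mean = mean(fold_rmses), sd = stats::sd(fold_rmses))
}

#' Percent change of a value relative to a reference
#'
#' `100 * (new - reference) / reference`, full precision (round only when
#' reporting).
#'
#' @param new_value,reference_value numeric; `reference_value != 0`
#' @return percent change
#' @export
percent_change <- function(new_value, reference_value) {
  if (any(reference_value == 0)) stop("zero reference")
  100 * (new_value - reference_value) / reference_value
}

# ---- Bland-Altman --------------------------------------------------------

#' Bland-Altman agreement analysis
#'
#' Differences `d = estimate - reference`; bias is their mean, the 95% limits
#' of agreement are `bias +/- 1.96 * SD(d)` and the reported `loa_halfwidth`
#' is the half-width `1.96 * SD(d)`. Percentage fields are relative to an
#' assumed peak VO2 (default 50 ml/min/kg).
#'
#' @param estimates,references equal-length vectors (ml/min/kg)
#' @param peak assumed peak VO2 (> 0)
#' @return object of class `bland_altman`: `bias`, `sd_diff`,
#'   `loa_halfwidth`, `bias_pct_peak`, `loa_pct_peak`, `peak_assumed`, and a
#'   `points` data frame (`mean`, `difference`) for plotting
#' @export
bland_altman <- function(estimates, references, peak = 50) {
  if (length(estimates) != length(references)) stop("length mismatch")
  if (!length(estimates)) stop("empty input")
  if (peak <= 0) stop("peak must be positive")
  d <- estimates - references
  bias <- mean(d)
  sd_diff <- if (length(d) > 1) stats::sd(d) else 0
  res <- list(bias = bias, sd_diff = sd_diff,
              loa_halfwidth = 1.96 * sd_diff,
              bias_pct_peak = 100 * bias / peak,
              loa_pct_peak = 100 * 1.96 * sd_diff / peak,
              peak_assumed = peak,
              points = data.frame(mean = (estimates + references) / 2,
                                  difference = d))
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f ml/min/kg (%.4f%% of peak %.0f), LoA +/- %.4f (%.4f%%)\n",
              x$bias, x$bias_pct_peak, x$peak_assumed, x$loa_halfwidth, x$loa_pct_peak))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x a [bland_altman()] result
#' @param ... passed to [graphics::plot()]
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$mean, x$points$difference,
                 xlab = "mean of estimate and reference (ml/min/kg)",
                 ylab = "estimate - reference (ml/min/kg)",
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.4), ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = x$bias + c(-1, 1) * x$loa_halfwidth, lty = 2)
  invisible(x)
}

# ---- correlation report --------------------------------------------------

#' Pearson/Spearman correlation report
#'
#' Correlates each of the five input features with VO2 over the pooled data
#' and within sex and fitness subgroups. Constant series yield `NA`
#' coefficients (undefined, not zero).
#'
#' @param steps an `aligned_steps` data frame
#' @param profiles list of subject profiles (for subgroup membership)
#' @return data frame of class `correlation_report`: columns `group`,
#'   `feature`, `pearson`, `spearman`
#' @export
correlation_report <- function(steps, profiles) {
  stopifnot(inherits(steps, "aligned_steps"))
  ids <- vapply(profiles, function(p) p$subject_id, 0L)
  sex <- vapply(profiles, function(p) p$sex, "")
  fit <- vapply(profiles, function(p) p$fitness, "")
  groups <- list(
    all = ids,
    female = ids[sex == "female"], male = ids[sex == "male"],
    untrained = ids[fit == "untrained"], trained = ids[fit == "trained"])
  out <- list()
  for (g in names(groups)) {
    rows <- steps$subject_id %in% groups[[g]]
    if (sum(rows) < 3L) next
    y <- steps$vo2[rows]
    for (f in vo2_feature_names()) {
      v <- steps[[f]][rows]
      r <- if (stats::sd(v) == 0 || stats::sd(y) == 0) NA_real_ else
        stats::cor(v, y)
      rho <- if (stats::sd(v) == 0 || stats::sd(y) == 0) NA_real_ else
        stats::cor(v, y, method = "spearman")
      out[[length(out) + 1]] <- data.frame(group = g, feature = f,
                                           pearson = r, spearman = rho)
    }
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("correlation_report", "data.frame")
  rep
}

#' Correlation heatmap
#'
#' Displays the Pearson and Spearman coefficients of a
#' [correlation_report()] as a colour matrix (features x groups).
#'
#' @param x a `correlation_report`
#' @param method `"pearson"` or `"spearman"`
#' @param ... unused
#' @export
plot.correlation_report <- function(x, method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  d <- as.data.frame(x)
  groups <- unique(d$group)
  feats <- unique(d$feature)
  m <- matrix(NA_real_, length(feats), length(groups),
              dimnames = list(feats, groups))
  for (i in seq_len(nrow(d))) m[d$feature[i], d$group[i]] <- d[[method]][i]
  op <- graphics::par(mar = c(6, 9, 3, 1)); on.exit(graphics::par(op))
  graphics::image(seq_along(groups), seq_along(feats), t(m),
                  zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(21, "Blue-Red", rev = TRUE),
                  main = sprintf("%s correlation with VO2", method))
  graphics::axis(1, seq_along(groups), groups, las = 2)
  graphics::axis(2, seq_along(feats), feats, las = 1)
  for (i in seq_along(groups)) for (j in seq_along(feats)) {
    if (!is.na(m[j, i])) graphics::text(i, j, sprintf("%.2f", m[j, i]))
  }
  invisible(x)
}

# ---- configuration ranking -----------------------------------------------

#' Rank network configurations by mean RMSE
#'
#' Ascending sort by mean RMSE; ties break by RMSE standard deviation, then
#' by configuration name (stable, documented tie-break).
#'
#' @param results data frame with columns `network_type`, `rmse_mean`,
#'   `rmse_std`, `part_spec`, `seq_len`, `model_config` (see
#'   [evaluate_loso()]), or a list of such rows
#' @return the table with a leading `rank` column, class `ranking_table`
#' @export
rank_configurations <- function(results) {
  if (!is.data.frame(results)) results <- do.call(rbind, lapply(results, as.data.frame))
  if (!nrow(results)) stop("no results to rank")
  ord <- order(results$rmse_mean, results$rmse_std, results$model_config,
               results$network_type)
  out <- results[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

# ---- LOSO evaluation driver ----------------------------------------------

#' Evaluate one configuration under the LOSO protocol
#'
#' For every fold of the plan: windows from the fold's training subjects form
#' the training set, the two validation subjects the validation set, and the
#' held-out subject the test set; the network is trained from scratch
#' ([vo2net_fit()]) and its test RMSE recorded, together with the RMSE of the
#' trivial mean predictor (predicting the training-target mean everywhere)
#' as a floor reference.
#'
#' @param samples raw `vo2_samples` over all subjects (attributes attached if
#'   the configuration needs them)
#' @param config a [model_config()]
#' @param plan a LOSO [split_plan][make_loso_plan]
#' @param policy a [training_policy()] (default [policy_intersubject()])
#' @param seed integer seed; per-fold sub-seeds are derived from it
#' @param keep_predictions keep per-fold test predictions (for Bland-Altman)
#' @param verbose print per-fold progress
#' @return object of class `evaluation_result`: per-fold records
#'   (`fold_records`), aggregates, and optionally pooled predictions
#' @export
evaluate_loso <- function(samples, config, plan, policy = policy_intersubject(),
                          seed = 1L, keep_predictions = FALSE, verbose = FALSE) {
  stopifnot(inherits(plan, "split_plan"), plan$mode == "loso")
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(plan$folds))
  recs <- list()
  preds <- list()
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    tr <- samples[samples$subject_id %in% f$train_subjects]
    va <- samples[samples$subject_id %in% f$val_subjects]
    te <- samples[samples$subject_id == f$test_subject]
    set.seed(fold_seeds[k])
    model <- vo2net_fit(tr, va, config, policy)
    est <- predict(model, te)
    base <- rep(mean(tr$target), n_samples(te))
    rec <- data.frame(
      config = config_label(config), test_subject = f$test_subject,
      repetition = f$repetition,
      rmse = rmse(est, te$target),
      rmse_baseline = rmse(base, te$target),
      stop_reason = model$stop_reason, epochs = nrow(model$history))
    recs[[k]] <- rec
    if (keep_predictions) {
      preds[[k]] <- data.frame(test_subject = f$test_subject,
                               repetition = f$repetition,
                               estimate = est, reference = te$target)
    }
    if (verbose) {
      message(sprintf("fold %d/%d subject %d rep %d: RMSE %.3f (baseline %.3f)",
                      k, length(plan$folds), f$test_subject, f$repetition,
                      rec$rmse, rec$rmse_baseline))
    }
  }
  fold_records <- do.call(rbind, recs)
  agg <- aggregate_rmse(fold_records$rmse)
  res <- list(
    config = config, fold_records = fold_records,
    rmse_mean = agg$mean, rmse_sd = agg$sd,
    baseline_mean = mean(fold_records$rmse_baseline),
    predictions = if (keep_predictions) do.call(rbind, preds) else NULL,
    provenance = list(seed = seed, plan_seed = plan$seed,
                      policy = unclass(policy)))
  class(res) <- "evaluation_result"
  res
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Evaluation of %s over %d folds:\n  RMSE %.4f +/- %.4f ml/min/kg (mean predictor: %.4f)\n",
              config_label(x$config), nrow(x$fold_records),
              x$rmse_mean, x$rmse_sd, x$baseline_mean))
  invisible(x)
}

#' Summary row for ranking tables
#'
#' @param result an `evaluation_result`
#' @return one-row data frame matching the ranking-table column layout
#' @export
as_ranking_row <- function(result) {
  cfg <- result$config
  data.frame(
    network_type = cfg$family,
    rmse_mean = result$rmse_mean,
    rmse_std = result$rmse_sd,
    part_spec = cfg$use_participant_features,
    seq_len = cfg$seq_len,
    model_config = config_label(cfg))
}
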