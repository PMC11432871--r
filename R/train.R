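# ---- training policy -----------------------------------------------------

#' Training policy
#'
#' Optimizer, learning-rate schedule and termination rules for network
#' training. Three presets cover the studied settings:
#' [policy_intersubject()] (AdamW, cosine schedule 1e-3 -> 1e-5, 100 epochs,
#' batch 64), [policy_baseline_lstm()] (Adam, constant 0.005, 1000 epochs)
#' and [policy_modified_lstm()] (Adam, initial 0.005 decreased by factor 0.2
#' after 25 non-improving epochs down to 1e-6, early-exit rule enabled).
#'
#' @param optimizer `"adam"` or `"adamw"`
#' @param lr_initial,lr_final initial/final learning rate (`lr_final <=
#'   lr_initial`; `lr_final` is reached at the last epoch of the cosine
#'   schedule)
#' @param schedule `"constant"`, `"cosine"` or `"plateau_decay"`
#' @param plateau_factor,plateau_patience,lr_min plateau-decay parameters
#' @param max_epochs training epochs (upper bound)
#' @param batch_size minibatch size
#' @param early_exit enable the early-exit termination rule
#' @param early_exit_window,early_exit_run_length see
#'   [early_exit_should_stop()]
#' @param weight_decay decoupled weight decay (AdamW only)
#' @return object of class `training_policy`
#' @export
training_policy <- function(optimizer = c("adamw", "adam"),
                            lr_initial = 1e-3, lr_final = 1e-5,
                            schedule = c("cosine", "constant", "plateau_decay"),
                            plateau_factor = 0.2, plateau_patience = 25L,
                            lr_min = 1e-6, max_epochs = 100L, batch_size = 64L,
                            early_exit = FALSE, early_exit_window = 20L,
                            early_exit_run_length = 3L, weight_decay = 0.01) {
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  if (lr_final > lr_initial) stop("lr_final must not exceed lr_initial")
  if (schedule == "plateau_decay" && plateau_patience >= max_epochs)
    stop("plateau_patience must be < max_epochs")
  pol <- list(optimizer = optimizer, lr_initial = lr_initial, lr_final = lr_final,
              schedule = schedule, plateau_factor = plateau_factor,
              plateau_patience = as.integer(plateau_patience), lr_min = lr_min,
              max_epochs = as.integer(max_epochs),
              batch_size = as.integer(batch_size),
              early_exit = early_exit,
              early_exit_window = as.integer(early_exit_window),
              early_exit_run_length = as.integer(early_exit_run_length),
              weight_decay = weight_decay, loss = "mse")
  class(pol) <- "training_policy"
  pol
}

#' @rdname training_policy
#' @param max_epochs training epochs
#' @param batch_size minibatch size
#' @export
policy_intersubject <- function(max_epochs = 100L, batch_size = 64L) {
  training_policy("adamw", 1e-3, 1e-5, "cosine", max_epochs = max_epochs,
                  batch_size = batch_size)
}

#' @rdname training_policy
#' @export
policy_baseline_lstm <- function(max_epochs = 1000L, batch_size = 64L) {
  training_policy("adam", 0.005, 0.005, "constant", max_epochs = max_epochs,
                  batch_size = batch_size)
}

#' @rdname training_policy
#' @export
policy_modified_lstm <- function(max_epochs = 1000L, batch_size = 64L) {
  training_policy("adam", 0.005, 1e-6, "plateau_decay", plateau_factor = 0.2,
                  plateau_patience = 25L, lr_min = 1e-6, max_epochs = max_epochs,
                  batch_size = batch_size, early_exit = TRUE)
}

# ---- training loop -------------------------------------------------------

# mean and sd of training targets; predictions are trained on the
# standardized scale and unscaled at prediction time
target_stats <- function(y) {
  s <- stats::sd(y)
  list(mean = mean(y), sd = if (is.finite(s) && s > 0) s else 1)
}

# samples are held internally as [N, L, C] so that a batch row-slice flattens
# directly into the channels-last sequence layout with no transposes
prep_x <- function(samples) aperm(samples$x, c(1, 3, 2))

batch_seq <- function(xa, idx) {
  d <- dim(xa)
  xb <- xa[idx, , , drop = FALSE]
  dim(xb) <- c(length(idx) * d[2], d[3])
  as_seq(xb, length(idx), d[2])
}

eval_loss <- function(model, xa, attrs, y_std, batch_size = 256L) {
  n <- length(y_std)
  sse <- 0
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    idx <- lo:hi
    ab <- if (is.null(attrs)) NULL else attrs[idx, , drop = FALSE]
    p <- model_forward(model, batch_seq(xa, idx), ab, training = FALSE)
    sse <- sse + sum((p - y_std[idx])^2)
  }
  sse / n
}

#' Train a network
#'
#' Minimizes mean-squared error on standardized targets with the policy's
#' optimizer and learning-rate schedule, evaluating the validation loss each
#' epoch. The parameters of the best-validation epoch are restored at the
#' end. With `early_exit` enabled, training stops once the trailing window of
#' train/validation loss gaps shows no strictly decreasing run (see
#' [early_exit_should_stop()]). Inputs must already be normalized;
#' [vo2net_fit()] is the higher-level entry point that handles normalization
#' and target scaling.
#'
#' @param model a `vo2net_model` from [assemble_model()]
#' @param policy a [training_policy()]
#' @param train_samples,val_samples `vo2_samples` (normalized features, with
#'   attributes attached if the model uses them)
#' @param verbose print per-epoch progress
#' @return the model (trained in place), with `model$history` a data frame of
#'   per-epoch training loss, validation loss and learning rate, plus
#'   `stop_reason` and `best_epoch`
#' @export
train_network <- function(model, policy, train_samples, val_samples,
                          verbose = FALSE) {
  stopifnot(inherits(model, "vo2net_model"), inherits(policy, "training_policy"))
  n <- n_samples(train_samples)
  if (n < 1L || n_samples(val_samples) < 1L) stop("empty sample set")
  ts <- model$target_stats
  if (is.null(ts)) stop("model has no target statistics; use vo2net_fit()")
  y_tr <- (train_samples$target - ts$mean) / ts$sd
  y_va <- (val_samples$target - ts$mean) / ts$sd
  xa_tr <- prep_x(train_samples)
  xa_va <- prep_x(val_samples)
  refs <- model_param_refs(model)
  opt <- new_optimizer(refs, policy$optimizer, weight_decay = policy$weight_decay)
  lr <- policy$lr_initial
  hist_epoch <- integer(0); hist_train <- numeric(0)
  hist_val <- numeric(0); hist_lr <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; best_state <- NULL
  since_improve <- 0L
  stop_reason <- "max_epochs"
  for (epoch in seq_len(policy$max_epochs)) {
    if (policy$schedule == "cosine") {
      lr <- cosine_lr(epoch, policy$lr_initial, policy$lr_final, policy$max_epochs)
    }
    ord <- sample.int(n)
    tot <- 0
    for (lo in seq(1L, n, by = policy$batch_size)) {
      hi <- min(lo + policy$batch_size - 1L, n)
      idx <- ord[lo:hi]
      B <- length(idx)
      xb <- batch_seq(xa_tr, idx)
      ab <- if (is.null(train_samples$attrs)) NULL else
        train_samples$attrs[idx, , drop = FALSE]
      model_zero_grads(model)
      p <- model_forward(model, xb, ab, training = TRUE)
      err <- p - y_tr[idx]
      loss <- sum(err^2) / B
      if (!is.finite(loss)) {
        stop(structure(class = c("vo2net_divergence", "error", "condition"),
                       list(message = sprintf("training diverged at epoch %d", epoch),
                            call = sys.call())))
      }
      model_backward(model, 2 * err / B)
      optimizer_step(opt, lr)
      tot <- tot + loss * B
    }
    train_loss <- tot / n
    val_loss <- eval_loss(model, xa_va, val_samples$attrs, y_va)
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, train_loss)
    hist_val <- c(hist_val, val_loss)
    hist_lr <- c(hist_lr, lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, train_loss, val_loss, lr))
    }
    if (val_loss < best_val) {
      best_val <- val_loss
      best_epoch <- epoch
      best_state <- lapply(model_layers(model), nn_get_state)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    if (policy$schedule == "plateau_decay" && since_improve >= policy$plateau_patience) {
      lr <- max(lr * policy$plateau_factor, policy$lr_min)
      since_improve <- 0L
    }
    if (policy$early_exit && epoch >= policy$early_exit_window) {
      gaps <- abs(hist_train - hist_val)
      if (early_exit_should_stop(gaps, policy$early_exit_window,
                                 policy$early_exit_run_length)) {
        stop_reason <- "early_exit"
        break
      }
    }
  }
  if (!is.null(best_state)) {
    lys <- model_layers(model)
    for (i in seq_along(lys)) nn_set_state(lys[[i]], best_state[[i]])
  }
  model$history <- data.frame(epoch = hist_epoch, train_loss = hist_train,
                              val_loss = hist_val, lr = hist_lr)
  model$stop_reason <- stop_reason
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_val
  model$trained <- TRUE
  model
}

# ---- S3 front end --------------------------------------------------------

# per-feature mean/sd over a sample tensor
sample_feature_stats <- function(samples) {
  m <- numeric(5L); s <- numeric(5L)
  for (i in 1:5) {
    v <- samples$x[, i, ]
    m[i] <- mean(v)
    s[i] <- stats::sd(as.vector(v))
    if (!is.finite(s[i]) || s[i] == 0) stop("zero-variance feature")
  }
  names(m) <- names(s) <- vo2_feature_names()
  list(mean = m, sd = s, subject_ids = sort(unique(samples$subject_id)))
}

standardize_samples <- function(samples, fs) {
  if (isTRUE(samples$normalized)) return(samples)
  for (i in 1:5) samples$x[, i, ] <- (samples$x[, i, ] - fs$mean[i]) / fs$sd[i]
  samples$normalized <- TRUE
  samples
}

#' Fit a VO2 regression network
#'
#' The modelling front end: assembles the configured network, fits feature
#' normalization statistics and target scaling on the training samples only
#' (their subject-ID provenance is stored for leakage audits), trains under
#' the policy, and returns a fitted model object with the usual methods
#' (`print`, `summary`, `predict`, `plot`, `residuals`).
#'
#' @param train_samples,val_samples raw (un-normalized) `vo2_samples`, with
#'   attributes attached if the configuration uses participant features
#' @param config a [model_config()]
#' @param policy a [training_policy()]; default chosen from the family
#' @param verbose print per-epoch progress
#' @return a fitted `vo2net_model`
#' @export
vo2net_fit <- function(train_samples, val_samples, config,
                       policy = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(policy)) {
    policy <- switch(config$family,
                     baseline_lstm = policy_baseline_lstm(),
                     modified_lstm = policy_modified_lstm(),
                     policy_intersubject())
  }
  if (config$use_participant_features &&
      (is.null(train_samples$attrs) || is.null(val_samples$attrs)))
    stop("configuration uses participant features but samples have no attributes")
  model <- assemble_model(config)
  model$feature_stats <- sample_feature_stats(train_samples)
  model$target_stats <- target_stats(train_samples$target)
  tr <- standardize_samples(train_samples, model$feature_stats)
  va <- standardize_samples(val_samples, model$feature_stats)
  train_network(model, policy, tr, va, verbose = verbose)
  model$policy <- policy
  model
}

#' Predict VO2 for new samples
#'
#' @param object a fitted `vo2net_model`
#' @param newdata raw `vo2_samples`; the model's stored normalization is
#'   applied
#' @param batch_size forward-pass batch size
#' @param ... unused
#' @return numeric vector of VO2 estimates (ml/min/kg)
#' @export
predict.vo2net_model <- function(object, newdata, batch_size = 256L, ...) {
  if (!isTRUE(object$trained)) stop("model is not trained")
  nd <- standardize_samples(newdata, object$feature_stats)
  n <- n_samples(nd)
  xa <- prep_x(nd)
  out <- numeric(n)
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(lo + batch_size - 1L, n)
    idx <- lo:hi
    ab <- if (is.null(nd$attrs)) NULL else nd$attrs[idx, , drop = FALSE]
    p <- model_forward(object, batch_seq(xa, idx), ab, training = FALSE)
    out[idx] <- p
  }
  out * object$target_stats$sd + object$target_stats$mean
}

#' @export
print.vo2net_model <- function(x, ...) {
  cat(sprintf("vo2net model: %s (%d parameters)%s\n",
              config_label(x$cfg), n_params(x),
              if (isTRUE(x$trained)) "" else " [untrained]"))
  if (isTRUE(x$trained)) {
    cat(sprintf("  trained %d epochs (%s), best epoch %d, val RMSE %.4f ml/min/kg\n",
                nrow(x$history), x$stop_reason, x$best_epoch,
                sqrt(x$best_val_loss) * x$target_stats$sd))
  }
  invisible(x)
}

#' @export
summary.vo2net_model <- function(object, ...) {
  print(object)
  if (isTRUE(object$trained)) {
    h <- object$history
    cat(sprintf("  final train loss %.4f, val loss %.4f (standardized scale)\n",
                h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
    cat(sprintf("  learning rate %.2e -> %.2e\n", h$lr[1], h$lr[nrow(h)]))
    cat(sprintf("  normalization fit on subjects: %s\n",
                paste(object$feature_stats$subject_ids, collapse = ", ")))
  }
  invisible(object)
}

#' Plot training history
#'
#' @param x a fitted `vo2net_model`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.vo2net_model <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is not trained")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "MSE (standardized)",
                    main = config_label(x$cfg), ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' Stores the parameter state (including batch-norm running statistics), the
#' configuration, the normalization and target statistics and the training
#' history in R's standard serialization container, and rebuilds the model on
#' load.
#'
#' @param model a fitted `vo2net_model`
#' @param path checkpoint file (`.rds`)
#' @return `path` invisibly (save); the restored `vo2net_model` (load)
#' @export
save_vo2net_model <- function(model, path) {
  stopifnot(inherits(model, "vo2net_model"))
  obj <- list(
    cfg = model$cfg,
    state = lapply(model_layers(model), nn_get_state),
    feature_stats = model$feature_stats,
    target_stats = model$target_stats,
    history = model$history,
    stop_reason = model$stop_reason,
    best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss,
    trained = model$trained
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_vo2net_model
#' @export
load_vo2net_model <- function(path) {
  obj <- readRDS(path)
  model <- assemble_model(obj$cfg)
  lys <- model_layers(model)
  for (i in seq_along(lys)) nn_set_state(lys[[i]], obj$state[[i]])
  for (nm in c("feature_stats", "target_stats", "history", "stop_reason",
               "best_epoch", "best_val_loss", "trained")) {
    assign(nm, obj[[nm]], envir = model)
  }
  model
}

#' Residuals of a fitted model on a sample set
#'
#' @param object a fitted `vo2net_model`
#' @param samples raw `vo2_samples` with reference targets
#' @param ... unused
#' @return numeric vector `estimate - reference` (ml/min/kg)
#' @export
residuals.vo2net_model <- function(object, samples, ...) {
  predict(object, samples) - samples$target
}
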