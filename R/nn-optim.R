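# ---- optimizers ----------------------------------------------------------

# Adam / AdamW over a flat list of (env, name) parameter references.
# AdamW applies decoupled weight decay (the decay step is taken directly on
# the weights, scaled by the current learning rate, not added to the
# gradient); biases and batch-norm parameters are not decayed.
new_optimizer <- function(refs, kind = c("adam", "adamw"),
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          weight_decay = 0.01) {
  kind <- match.arg(kind)
  st <- new.env(parent = emptyenv())
  st$refs <- refs
  st$m <- lapply(refs, function(r) r$env[[r$name]] * 0)
  st$v <- lapply(refs, function(r) r$env[[r$name]] * 0)
  st$t <- 0L
  st$kind <- kind
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$wd <- if (kind == "adamw") weight_decay else 0
  # decay only weight matrices (dim >= 2)
  st$decay <- vapply(refs, function(r) !is.null(dim(r$env[[r$name]])), TRUE)
  class(st) <- "nn_optimizer"
  st
}

optimizer_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$env[[paste0("g_", r$name)]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    w <- r$env[[r$name]]
    if (opt$wd > 0 && opt$decay[i]) w <- w - lr * opt$wd * w
    w <- w - lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    assign(r$name, w, envir = r$env)
  }
  invisible(NULL)
}

# ---- learning-rate schedules ---------------------------------------------

# cosine annealing from lr_initial (epoch 1) to lr_final (epoch max_epochs)
cosine_lr <- function(epoch, lr_initial, lr_final, max_epochs) {
  if (max_epochs <= 1) return(lr_initial)
  frac <- (epoch - 1) / (max_epochs - 1)
  lr_final + 0.5 * (lr_initial - lr_final) * (1 + cos(pi * frac))
}

# ---- early-exit rule -----------------------------------------------------

#' Early-exit training-termination rule
#'
#' Monitors the per-epoch difference between training and validation loss (the
#' generalization gap). Training stops when the last `window` gap values
#' contain no run of `run_length` consecutive epochs with strictly decreasing
#' gap, i.e. no index i with `g[i] > g[i+1] > g[i+2]` for the default run
#' length 3.
#'
#' @param gap_history numeric vector of per-epoch `|train - validation|` loss
#'   gaps, oldest first
#' @param window trailing window length in epochs (default 20)
#' @param run_length required strictly decreasing run (default 3)
#' @return `TRUE` if training should stop
#' @export
early_exit_should_stop <- function(gap_history, window = 20L, run_length = 3L) {
  if (length(gap_history) < window) stop("gap history shorter than window")
  g <- utils::tail(gap_history, window)
  dec <- diff(g) < 0
  if (run_length < 2L) return(!any(dec))
  need <- run_length - 1L
  run <- 0L
  for (d in dec) {
    run <- if (d) run + 1L else 0L
    if (run >= need) return(FALSE)
  }
  TRUE
}
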