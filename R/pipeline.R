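# ---- configuration grid --------------------------------------------------

#' The studied configuration grid
#'
#' Declarative description of the full 60-configuration sweep: every family's
#' own options crossed with sequence length {50, 200} and participant
#' features on/off. Xception: n_f {8,16} x c_out {16,32} (16 configurations);
#' ResNet: two kernel-size options (8); CNN: c_out {16,32} (8); recurrent:
#' {rnn,lstm,gru} x {one-,bi-directional} (24); DenseNet: one option (4).
#'
#' @return a list grid specification for [expand_config_grid()]
#' @export
paper_grid <- function() {
  list(
    seq_len = c(50L, 200L),
    use_participant_features = c(FALSE, TRUE),
    families = list(
      xception = list(n_f = c(8L, 16L), c_out = c(16L, 32L)),
      resnet = list(kernel_sizes = list(c(3L, 3L, 3L), c(7L, 5L, 3L))),
      cnn = list(c_out = c(16L, 32L)),
      rnn = list(bidirectional = c(FALSE, TRUE)),
      lstm = list(bidirectional = c(FALSE, TRUE)),
      gru = list(bidirectional = c(FALSE, TRUE)),
      densenet = list()
    )
  )
}

#' Expand a grid specification into model configurations
#'
#' Cartesian expansion of family-specific options with the shared axes
#' (sequence length, participant features), deduplicated and in a
#' deterministic order. The default grid expands to the studied 60
#' configurations.
#'
#' @param grid a grid specification, see [paper_grid()]
#' @return list of [model_config()] objects
#' @export
expand_config_grid <- function(grid = paper_grid()) {
  cfgs <- list()
  for (fam in names(grid$families)) {
    opts <- grid$families[[fam]]
    opt_rows <- if (length(opts)) {
      do.call(expand.grid, c(lapply(opts, seq_along), KEEP.OUT.ATTRS = FALSE))
    } else {
      data.frame(row.names = 1)
    }
    for (L in grid$seq_len) for (pf in grid$use_participant_features) {
      for (r in seq_len(nrow(opt_rows))) {
        args <- list(family = fam, seq_len = L, use_participant_features = pf)
        for (o in names(opts)) {
          val <- opts[[o]][[opt_rows[r, o]]]
          args[[o]] <- val
        }
        cfgs[[length(cfgs) + 1]] <- do.call(model_config, args)
      }
    }
  }
  labs <- vapply(cfgs, config_label, "")
  cfgs[!duplicated(labs)]
}

# ---- config serialization ------------------------------------------------

#' Write/read model configurations and training policies
#'
#' Serializes to YAML (`.yml`/`.yaml`) or JSON (anything else) with fixed key
#' names matching the constructor arguments.
#'
#' @param x a `model_config` or `training_policy`
#' @param path output file
#' @return `path` (write) or the reconstructed object (read), invisibly for
#'   write
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, "model_config") || inherits(x, "training_policy"))
  obj <- c(list(.type = class(x)[1]), unclass(x))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  type <- obj$.type
  obj$.type <- NULL
  obj$hidden_join_dim <- NULL   # derived
  obj$loss <- NULL
  if (identical(type, "model_config")) {
    do.call(model_config, obj)
  } else if (identical(type, "training_policy")) {
    do.call(training_policy, obj)
  } else {
    stop("unrecognized config file")
  }
}

# ---- end-to-end pipeline -------------------------------------------------

#' Run configuration for the end-to-end pipeline
#'
#' @param n_subjects cohort size
#' @param seed top-level seed; stage seeds are derived from it
#' @param artifacts inject the documented data-defect scenarios
#' @param n_cycles walk/run cycles per session
#' @param seq_len window length L
#' @param stride window stride
#' @param smoothing a [smoothing_config()]
#' @param configs list of [model_config()]s to evaluate
#' @param repetitions LOSO repetitions
#' @param policy a [training_policy()]
#' @param out_dir output directory (`NULL`: nothing written)
#' @return object of class `run_config`
#' @export
run_config <- function(n_subjects = 16L, seed = 1L, artifacts = TRUE,
                       n_cycles = 8L, seq_len = 50L, stride = 1L,
                       smoothing = smoothing_config(),
                       configs = list(model_config("xception", seq_len = 50L)),
                       repetitions = 5L, policy = policy_intersubject(),
                       out_dir = NULL) {
  rc <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
             artifacts = artifacts, n_cycles = as.integer(n_cycles),
             seq_len = as.integer(seq_len), stride = as.integer(stride),
             smoothing = smoothing, configs = configs,
             repetitions = as.integer(repetitions), policy = policy,
             out_dir = out_dir)
  class(rc) <- "run_config"
  rc
}

#' Run the full pipeline: simulate, preprocess, evaluate, report
#'
#' Generates a synthetic cohort, preprocesses it into windowed samples,
#' evaluates every configuration under the LOSO protocol, and assembles the
#' ranking table plus a correlation report. All stage seeds derive from the
#' top-level seed, so rerunning with the same configuration reproduces every
#' numeric output. When `out_dir` is set, per-fold records, the ranking table
#' and a JSON manifest (configuration, seed, timestamps, stage record counts)
#' are written there.
#'
#' @param rc a [run_config()]
#' @param verbose print stage progress
#' @return list with `cohort`, `steps`, `samples`, `results` (one
#'   `evaluation_result` per configuration), `ranking`, `correlations`, and
#'   the run `manifest`
#' @export
run_pipeline <- function(rc, verbose = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  if (!is.null(rc$out_dir) && !dir.exists(dirname(rc$out_dir)) && dirname(rc$out_dir) != ".")
    stop("output directory parent does not exist")
  t0 <- Sys.time()
  set.seed(rc$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  log_info <- function(...) if (verbose) message(sprintf(...))

  log_info("simulate: %d subjects (seed %d)", rc$n_subjects, stage_seeds[1])
  cohort <- generate_cohort(rc$n_subjects, seed = stage_seeds[1],
                            artifacts = rc$artifacts, n_cycles = rc$n_cycles)

  log_info("preprocess: smoothing + synchronization + windowing (L=%d, stride=%d)",
           rc$seq_len, rc$stride)
  steps <- preprocess_cohort(cohort, rc$smoothing)
  samples <- window_sequences(steps, rc$seq_len, rc$stride)
  samples <- attach_attributes(samples, cohort$profiles)
  log_info("preprocess: %d aligned steps -> %d samples", nrow(steps),
           n_samples(samples))

  plan <- make_loso_plan(unique(samples$subject_id), seed = stage_seeds[2],
                         repetitions = rc$repetitions)
  results <- list()
  for (i in seq_along(rc$configs)) {
    cfg <- rc$configs[[i]]
    log_info("evaluate %d/%d: %s", i, length(rc$configs), config_label(cfg))
    results[[i]] <- evaluate_loso(samples, cfg, plan, rc$policy,
                                  seed = stage_seeds[3] + i - 1L,
                                  verbose = verbose)
  }
  ranking <- rank_configurations(lapply(results, as_ranking_row))
  correlations <- correlation_report(steps, cohort$profiles)

  manifest <- list(
    seed = rc$seed, stage_seeds = stage_seeds,
    n_subjects = rc$n_subjects, n_cycles = rc$n_cycles,
    seq_len = rc$seq_len, stride = rc$stride,
    repetitions = rc$repetitions,
    configs = vapply(rc$configs, config_label, ""),
    n_steps = nrow(steps), n_samples = n_samples(samples),
    started = format(t0), finished = format(Sys.time()),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(rc$out_dir)) {
    dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(do.call(rbind, lapply(results, function(r) r$fold_records)),
                     file.path(rc$out_dir, "fold_records.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ranking),
                     file.path(rc$out_dir, "ranking.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(correlations),
                     file.path(rc$out_dir, "correlations.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(rc$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, steps = steps, samples = samples, results = results,
       ranking = ranking, correlations = correlations, manifest = manifest)
}
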