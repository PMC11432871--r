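# Architecture contracts: printed widths, branch wiring, and training
# behaviour of the model front end.

forward_once <- function(cfg, B = 3L, training = FALSE) {
  set.seed(11)
  x <- array(rnorm(B * 5 * cfg$seq_len), c(B, 5, cfg$seq_len))
  a <- matrix(sample(0:2, B * 4, TRUE), B, 4)
  m <- assemble_model(cfg)
  list(model = m, y = vo2net:::model_forward(m, x, a, training), x = x, a = a)
}

test_that("every family builds and forwards at both sequence lengths", {
  fams <- c("xception", "resnet", "cnn", "rnn", "lstm", "gru", "densenet")
  for (L in c(50L, 200L)) for (fam in fams) for (pf in c(FALSE, TRUE)) {
    cfg <- model_config(fam, seq_len = L, use_participant_features = pf)
    out <- forward_once(cfg)
    expect_equal(dim(out$y), c(3L, 1L))
    expect_true(all(is.finite(out$y)),
                label = sprintf("%s L=%d pf=%s finite", fam, L, pf))
  }
})

test_that("head output widths match the printed architecture", {
  expect_equal(build_cnn_head(16L, 50L)$out_dim, 16L)
  expect_equal(build_cnn_head(32L, 50L)$out_dim, 32L)
  expect_equal(build_resnet_head(c(3, 3, 3))$out_dim, 16L)
  expect_equal(build_xception_head(16L, 16L)$out_dim, 16L)
  expect_equal(build_xception_head(8L, 32L)$out_dim, 32L)
  expect_equal(build_rnn_head("gru", FALSE)$out_dim, 128L)
  expect_equal(build_rnn_head("lstm", TRUE)$out_dim, 256L)
  expect_error(build_resnet_head(c(5, 5, 5)), "kernel_sizes")
})

test_that("the resnet blocks use the printed filter progression", {
  set.seed(1)
  hb <- build_resnet_head(c(3, 3, 3))
  blocks <- hb$head$children[1:3]
  # last batch-norm of each block's main path carries the block's filter count
  widths <- vapply(blocks, function(b) {
    bns <- vo2net:::nn_collect_layers(b$children[[1]], "ly_bn1d")
    bns[[length(bns)]]$c_in
  }, 0L)
  expect_equal(widths, c(24L, 48L, 48L))
})

test_that("densenet reaches 280 channels before the reduction convolutions", {
  set.seed(2)
  hb <- build_densenet_head(200L)
  convs <- vo2net:::nn_collect_layers(hb$head, "ly_conv1d")
  cins <- vapply(convs, function(l) l$c_in, 0L)
  expect_true(280L %in% cins)   # first reduction convolution consumes 280
  red <- convs[[which(cins == 280L)[1]]]
  expect_equal(red$c_out, 32L)
  # initial convolution halves the temporal length: L=200 -> 100
  first <- hb$head$children[[1]]
  x <- vo2net:::as_seq(matrix(rnorm(2 * 200 * 5), 400, 5), 2L, 200L)
  y <- vo2net:::nn_fwd(first, x, FALSE)
  expect_equal(attr(y, "seq_dims")[2], 100L)
  # dense blocks grow channels by 64 each
  blocks <- vo2net:::nn_collect_layers(hb$head, "ly_dense_block")
  expect_equal(vapply(blocks, function(b) b$c_in, 0L), c(24L, 88L, 152L, 216L))
})

test_that("the attribute head is a 4->2 ReLU map with 10 parameters", {
  set.seed(3)
  fh <- build_feature_head()
  expect_equal(vo2net:::nn_n_params(fh), 10)
  y <- vo2net:::nn_fwd(fh, matrix(0, 4, 4), FALSE)
  expect_equal(dim(y), c(4L, 2L))
  expect_true(all(y >= 0))
  y2 <- vo2net:::nn_fwd(fh, matrix(rnorm(40), 10, 4), FALSE)
  expect_true(all(y2 >= 0))
})

test_that("the join layer follows the family-specific wiring", {
  cfg_rnn <- model_config("gru", seq_len = 50L)
  m <- assemble_model(cfg_rnn)
  expect_equal(cfg_rnn$hidden_join_dim, 0L)
  expect_length(m$join$children, 1L)          # single affine layer, no hidden
  cfg_d <- model_config("densenet", seq_len = 50L)
  expect_equal(cfg_d$hidden_join_dim, 4L)
  md <- assemble_model(cfg_d)
  expect_equal(md$join$children[[1]]$d_out, 4L)
  for (fam in c("resnet", "xception")) {
    cfg <- model_config(fam, seq_len = 50L)
    expect_equal(cfg$hidden_join_dim, 16L)
    mm <- assemble_model(cfg)
    expect_equal(mm$join$children[[1]]$d_out, 16L)
  }
  # participant branch widens the join input by the 2-unit attribute output
  cfg_pf <- model_config("xception", seq_len = 50L, use_participant_features = TRUE)
  mpf <- assemble_model(cfg_pf)
  expect_equal(mpf$join$children[[1]]$d_in, mpf$head_dim + 2L)
})

test_that("intra-subject LSTM models have the printed hidden widths", {
  set.seed(4)
  mb <- assemble_model(model_config("baseline_lstm", seq_len = 50L))
  expect_equal(mb$head$H, 150L)
  mm <- assemble_model(model_config("modified_lstm", seq_len = 50L))
  expect_equal(mm$head$H, 100L)
  set.seed(9); m1 <- assemble_model(model_config("baseline_lstm", seq_len = 50L))
  set.seed(9); m2 <- assemble_model(model_config("baseline_lstm", seq_len = 50L))
  expect_identical(m1$head$Wx, m2$head$Wx)
})

test_that("configuration validation rejects off-grid options", {
  expect_error(model_config("xception", n_f = 12L), "n_f")
  expect_error(model_config("resnet", c_out = 32L), "c_out")
  expect_error(model_config("cnn", c_out = 8L), "c_out")
  expect_error(model_config("resnet", kernel_sizes = c(5, 5, 5)), "kernel_sizes")
  expect_error(model_config("cnn", bidirectional = TRUE), "recurrent")
  expect_error(model_config("baseline_lstm", use_participant_features = TRUE))
})

test_that("a zeroed residual block reduces to its shortcut path", {
  set.seed(12)
  blk <- vo2net:::resnet_block(5L, 24L, c(3L, 3L, 3L))
  x <- vo2net:::as_seq(matrix(rnorm(4 * 20 * 5), 80, 5), 4L, 20L)
  main <- blk$children[[1]]; short <- blk$children[[2]]
  for (cv in vo2net:::nn_collect_layers(main, "ly_conv1d")) {
    cv$W <- cv$W * 0; cv$b <- cv$b * 0
  }
  y <- vo2net:::nn_fwd(blk, x, training = FALSE)
  ys <- vo2net:::nn_fwd(short, x, training = FALSE)
  expect_equal(unclass(y), unclass(pmax(ys, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("one training step reaches every trainable tensor (gradient flow)", {
  set.seed(13)
  B <- 8L; L <- 50L
  x <- array(rnorm(B * 5 * L), c(B, 5, L))
  a <- matrix(sample(0:2, B * 4, TRUE), B, 4)
  y <- rnorm(B)
  fams <- c("xception", "resnet", "cnn", "rnn", "lstm", "gru", "densenet",
            "baseline_lstm", "modified_lstm")
  for (fam in fams) {
    pf <- !fam %in% c("baseline_lstm", "modified_lstm")
    cfg <- model_config(fam, seq_len = L, use_participant_features = pf)
    m <- assemble_model(cfg)
    vo2net:::model_zero_grads(m)
    p <- vo2net:::model_forward(m, x, if (pf) a else NULL, training = TRUE)
    vo2net:::model_backward(m, 2 * (p - y) / B)
    refs <- vo2net:::model_param_refs(m)
    dead <- vapply(refs, function(r) all(r$env[[paste0("g_", r$name)]] == 0), TRUE)
    expect_false(any(dead), label = sprintf("dead tensors in %s: %d", fam, sum(dead)))
  }
})

test_that("training records the schedule and is reproducible", {
  tr <- toy_samples(64, seed = 1)
  va <- toy_samples(32, seed = 2)
  cfg <- model_config("cnn", seq_len = 10L)
  pol <- policy_intersubject(max_epochs = 5L)
  set.seed(20)
  m1 <- vo2net_fit(tr, va, cfg, pol)
  expect_equal(m1$history$lr[1], 1e-3)
  expect_equal(m1$history$lr[5], 1e-5)
  expect_equal(nrow(m1$history), 5L)
  set.seed(20)
  m2 <- vo2net_fit(toy_samples(64, seed = 1), toy_samples(32, seed = 2), cfg, pol)
  # reproducible to numerical identity (BLAS kernels may differ in the last
  # bit depending on buffer alignment)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_equal(predict(m1, toy_samples(16, seed = 3)),
               predict(m2, toy_samples(16, seed = 3)), tolerance = 1e-12)
})

test_that("networks can overfit a tiny sample set (capacity sanity)", {
  tr <- toy_samples(32, seed = 5)
  target_sd <- sd(tr$target)
  for (cfg in list(model_config("xception", seq_len = 10L, n_f = 8L),
                   model_config("modified_lstm", seq_len = 10L))) {
    pol <- if (cfg$family == "modified_lstm") {
      training_policy("adam", 0.005, 1e-6, "plateau_decay", max_epochs = 200L,
                      batch_size = 32L)
    } else {
      training_policy("adamw", 1e-2, 1e-4, "cosine", max_epochs = 200L,
                      batch_size = 32L)
    }
    set.seed(21)
    m <- vo2net_fit(tr, tr, cfg, pol)
    train_rmse <- rmse(predict(m, tr), tr$target)
    expect_lt(train_rmse, 0.05 * target_sd,
              label = sprintf("%s overfit RMSE", cfg$family))
  }
})

test_that("the fitted model exposes the usual S3 surface", {
  tr <- toy_samples(48, seed = 8)
  va <- toy_samples(24, seed = 9)
  set.seed(22)
  m <- vo2net_fit(tr, va, model_config("cnn", seq_len = 10L),
                  policy_intersubject(max_epochs = 3L))
  expect_output(print(m), "cnn")
  expect_output(summary(m), "normalization fit on subjects")
  r <- residuals(m, va)
  expect_length(r, 24L)
  expect_equal(r, predict(m, va) - va$target)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
  expect_gt(n_params(m), 0)
})

test_that("plateau decay lowers the learning rate after stalled validation", {
  # constant targets make validation loss stall immediately
  tr <- toy_samples(32, seed = 30)
  va <- toy_samples(16, seed = 31)
  va$target <- rep(20, 16)
  pol <- training_policy("adam", 0.005, 1e-6, "plateau_decay",
                         plateau_patience = 3L, max_epochs = 12L,
                         batch_size = 32L)
  set.seed(32)
  m <- vo2net_fit(tr, va, model_config("modified_lstm", seq_len = 10L), pol)
  expect_true(any(abs(m$history$lr - 0.001) < 1e-12))
  expect_true(all(m$history$lr >= 1e-6))
})

test_that("model checkpoints restore identical predictions", {
  tr <- toy_samples(48, seed = 40)
  va <- toy_samples(24, seed = 41)
  set.seed(42)
  m <- vo2net_fit(tr, va, model_config("xception", seq_len = 10L, n_f = 8L),
                  policy_intersubject(max_epochs = 3L))
  te <- toy_samples(16, seed = 43)
  path <- file.path(tempdir(), "model.rds")
  save_vo2net_model(m, path)
  m2 <- load_vo2net_model(path)
  expect_identical(predict(m2, te), predict(m, toy_samples(16, seed = 43)))
  expect_equal(m2$history, m$history)
  unlink(path)
})
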