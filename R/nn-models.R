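# ---- model configuration -------------------------------------------------

#' Network configuration
#'
#' Describes one network in the studied grid. Families: `baseline_lstm` and
#' `modified_lstm` (single-branch many-to-one LSTM regressors used for
#' intra-subject estimation); `rnn`, `lstm`, `gru` (three stacked recurrent
#' layers of 128 units, optionally bidirectional); `cnn` (three 1D
#' convolutions with 32/64/32 filters, kernel 3); `resnet` (three residual
#' blocks, filters 24/48/48, kernels `c(3,3,3)` or `c(7,5,3)`, output 16);
#' `densenet` (four dense blocks with positional encoding, growth 16, 280
#' channels before the reduction convolutions); `xception` (stacked modules
#' of three depthwise-separable convolutions plus a max-pooling path with
#' residual connections, `n_f` in {8, 16}, output width `c_out` in {16, 32}).
#'
#' The width of the fully connected hidden layer joining the regression and
#' attribute branches is family-fixed: 0 (none) for the recurrent and plain
#' convolutional families, 4 for `densenet`, 16 for `resnet` and `xception`.
#'
#' @param family network family, see Details
#' @param seq_len input sequence length L (50 or 200 in the emulated study)
#' @param use_participant_features attach the categorical attribute branch
#' @param bidirectional recurrent families only
#' @param n_f filter-count parameter (xception: 8 or 16; resnet: 24)
#' @param c_out output-vector width (16 or 32 where the family allows a choice)
#' @param kernel_sizes resnet kernel sizes, `c(3,3,3)` or `c(7,5,3)`
#' @param n_modules number of Xception modules (default 3)
#' @return object of class `model_config`
#' @export
model_config <- function(family = c("xception", "resnet", "cnn", "rnn", "lstm",
                                    "gru", "densenet", "baseline_lstm",
                                    "modified_lstm"),
                         seq_len = 50L, use_participant_features = FALSE,
                         bidirectional = FALSE, n_f = NULL, c_out = NULL,
                         kernel_sizes = c(3L, 3L, 3L), n_modules = 3L) {
  family <- match.arg(family)
  seq_len <- as.integer(seq_len)
  if (seq_len < 1L) stop("seq_len must be >= 1")
  recurrent <- family %in% c("rnn", "lstm", "gru")
  if (family == "xception") {
    if (is.null(n_f)) n_f <- 16L
    if (is.null(c_out)) c_out <- 16L
    if (!n_f %in% c(8L, 16L)) stop("xception n_f must be 8 or 16")
    if (!c_out %in% c(16L, 32L)) stop("xception c_out must be 16 or 32")
  } else if (family == "resnet") {
    if (is.null(n_f)) n_f <- 24L
    if (is.null(c_out)) c_out <- 16L
    if (n_f != 24L) stop("resnet n_f is fixed at 24")
    if (c_out != 16L) stop("resnet c_out is fixed at 16")
    if (!(identical(as.integer(kernel_sizes), c(3L, 3L, 3L)) ||
          identical(as.integer(kernel_sizes), c(7L, 5L, 3L))))
      stop("resnet kernel_sizes must be c(3,3,3) or c(7,5,3)")
  } else if (family == "cnn") {
    if (is.null(c_out)) c_out <- 16L
    if (!c_out %in% c(16L, 32L)) stop("cnn c_out must be 16 or 32")
  } else if (family == "densenet") {
    if (seq_len < 16L) stop("densenet requires seq_len >= 16")
  }
  if (bidirectional && !recurrent) stop("bidirectional applies to recurrent families only")
  if (family %in% c("baseline_lstm", "modified_lstm") && use_participant_features)
    stop("the intra-subject LSTM models have no attribute branch")
  hidden_join_dim <- switch(family,
                            densenet = 4L, resnet = 16L, xception = 16L, 0L)
  cfg <- list(family = family, seq_len = seq_len,
              use_participant_features = use_participant_features,
              bidirectional = bidirectional, n_f = n_f, c_out = c_out,
              kernel_sizes = as.integer(kernel_sizes),
              n_modules = as.integer(n_modules),
              hidden_join_dim = hidden_join_dim)
  class(cfg) <- "model_config"
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat(config_label(x), "\n")
  invisible(x)
}

#' Short human-readable configuration label
#' @param cfg a [model_config()]
#' @return character scalar
#' @export
config_label <- function(cfg) {
  extra <- switch(cfg$family,
    xception = sprintf("n_f=%d, c_out=%d", cfg$n_f, cfg$c_out),
    resnet = sprintf("n_f=%d, c_out=%d, kss=[%s]", cfg$n_f, cfg$c_out,
                     paste(cfg$kernel_sizes, collapse = ",")),
    cnn = sprintf("c_out=%d", cfg$c_out),
    rnn = , lstm = , gru = if (cfg$bidirectional) "bidirectional" else "one-directional",
    "")
  sprintf("%s L=%d part=%s%s", cfg$family, cfg$seq_len,
          if (cfg$use_participant_features) "TRUE" else "FALSE",
          if (nzchar(extra)) paste0(" ", extra) else "")
}

# ---- head builders -------------------------------------------------------

# depthwise separable convolution: per-channel depthwise then 1x1 pointwise
sep_conv <- function(c_in, c_out, k) {
  nn_seq(ly_dwconv1d(c_in, k), ly_conv1d(c_in, c_out, 1L),
         ly_bn1d(c_out), ly_relu())
}

#' Attribute-branch head: 4 category codes to a 2-unit representation
#'
#' A single fully connected layer from the 4-dimensional attribute vector to
#' 2 units followed by a rectified-linear activation (10 parameters). The
#' bias is initialized slightly positive so neither unit starts dead behind
#' the ReLU (the category codes are non-negative and the branch is only two
#' units wide).
#'
#' @return an `nn_layer`
#' @export
build_feature_head <- function() {
  d <- ly_dense(4L, 2L)
  d$b <- rep(0.1, 2L)
  nn_seq(d, ly_relu())
}

#' Recurrent regression head
#'
#' Three stacked recurrent layers of 128 units each (per direction when
#' bidirectional); the output is the final-time-step top-layer state, width
#' 128 (one-directional) or 256 (bidirectional). No hidden join layer follows
#' this family.
#'
#' @param cell `"rnn"`, `"lstm"` or `"gru"`
#' @param bidirectional logical
#' @param c_in input channel count (5 temporal features)
#' @return list with the layer (`head`) and its output width (`out_dim`)
#' @export
build_rnn_head <- function(cell = c("rnn", "lstm", "gru"), bidirectional = FALSE,
                           c_in = 5L) {
  cell <- match.arg(cell)
  H <- 128L
  mk <- function(d_in, return_seq) {
    if (bidirectional) ly_bidir(d_in, H, cell, return_seq)
    else ly_rnn(d_in, H, cell, return_seq)
  }
  w <- if (bidirectional) 2L * H else H
  head <- nn_seq(mk(c_in, TRUE), mk(w, TRUE), mk(w, FALSE))
  list(head = head, out_dim = w)
}

#' Plain convolutional regression head
#'
#' Three 1D convolutions (kernel 3, filters 32/64/32), each followed by batch
#' normalization and ReLU, then a fully connected layer from the flattened
#' feature map to `out_dim`.
#'
#' @param out_dim output width, 16 or 32
#' @param L input sequence length
#' @param c_in input channel count
#' @return list with `head` and `out_dim`
#' @export
build_cnn_head <- function(out_dim = 16L, L = 50L, c_in = 5L) {
  stopifnot(out_dim %in% c(16L, 32L))
  head <- nn_seq(
    ly_conv1d(c_in, 32L, 3L), ly_bn1d(32L), ly_relu(),
    ly_conv1d(32L, 64L, 3L), ly_bn1d(64L), ly_relu(),
    ly_conv1d(64L, 32L, 3L), ly_bn1d(32L), ly_relu(),
    ly_flatten(), ly_dense(32L * L, out_dim))
  list(head = head, out_dim = as.integer(out_dim))
}

resnet_block <- function(c_in, f, ks) {
  main <- nn_seq(
    ly_conv1d(c_in, f, ks[1]), ly_bn1d(f), ly_relu(),
    ly_conv1d(f, f, ks[2]), ly_bn1d(f), ly_relu(),
    ly_conv1d(f, f, ks[3]), ly_bn1d(f))
  shortcut <- if (c_in == f) ly_identity() else
    nn_seq(ly_conv1d(c_in, f, 1L), ly_bn1d(f))
  ly_parallel_add(list(main, shortcut), post_relu = TRUE)
}

#' Residual regression head
#'
#' Three residual blocks of three 1D convolutions each (kernels
#' `kernel_sizes` within every block, filters 24/48/48 across blocks), with
#' additive shortcuts (1x1 projection on channel mismatch), global average
#' pooling and a fully connected layer to width 16.
#'
#' @param kernel_sizes `c(3,3,3)` or `c(7,5,3)`
#' @param n_f first-block filter count (24)
#' @param c_in input channel count
#' @return list with `head` and `out_dim`
#' @export
build_resnet_head <- function(kernel_sizes = c(3L, 3L, 3L), n_f = 24L, c_in = 5L) {
  ks <- as.integer(kernel_sizes)
  if (!(identical(ks, c(3L, 3L, 3L)) || identical(ks, c(7L, 5L, 3L))))
    stop("kernel_sizes must be c(3,3,3) or c(7,5,3)")
  head <- nn_seq(
    resnet_block(c_in, n_f, ks),
    resnet_block(n_f, 2L * n_f, ks),
    resnet_block(2L * n_f, 2L * n_f, ks),
    ly_gap1d(), ly_dense(2L * n_f, 16L))
  list(head = head, out_dim = 16L)
}

# one dense module: 1x1 conv then kernel-3 conv (16 filters each), batch norm
# + ReLU, with an additive 1x1-projected shortcut
dense_module <- function(c_in, growth = 16L) {
  main <- nn_seq(
    ly_conv1d(c_in, growth, 1L), ly_bn1d(growth), ly_relu(),
    ly_conv1d(growth, growth, 3L), ly_bn1d(growth))
  ly_parallel_add(list(main, nn_seq(ly_conv1d(c_in, growth, 1L), ly_bn1d(growth))),
                  post_relu = TRUE)
}

# dense block: positional encoding, four dense modules with dense
# connectivity (each module sees the block input and every earlier module
# output; the block emits their full concatenation, +64 channels), then an
# optional halving max pool
ly_dense_block <- function(c_in, growth = 16L, n_modules = 4L, pool = TRUE) {
  mods <- lapply(seq_len(n_modules), function(i)
    dense_module(c_in + (i - 1L) * growth, growth))
  new_layer("dense_block",
            fields = list(c_in = c_in, growth = growth, n_modules = n_modules),
            children = c(list(ly_posenc()), mods,
                         if (pool) list(ly_maxpool1d(2L, 2L)) else list()))
}

#' @export
nn_fwd.ly_dense_block <- function(layer, x, training = FALSE) {
  pe <- layer$children[[1]]
  x0 <- nn_fwd(pe, x, training)
  sd <- seq_dims(x0); B <- sd[1]; L <- sd[2]
  g <- layer$growth
  n <- layer$n_modules
  cat_mat <- matrix(0, B * L, layer$c_in + n * g)
  cat_mat[, seq_len(layer$c_in)] <- x0
  cur_c <- layer$c_in
  for (i in seq_len(n)) {
    inp <- as_seq(cat_mat[, seq_len(cur_c), drop = FALSE], B, L)
    o <- nn_fwd(layer$children[[1L + i]], inp, training)
    cat_mat[, cur_c + seq_len(g)] <- o
    cur_c <- cur_c + g
  }
  out <- as_seq(cat_mat, B, L)
  if (length(layer$children) > 1L + n) {
    out <- nn_fwd(layer$children[[length(layer$children)]], out, training)
  }
  layer$B <- B; layer$L <- L
  out
}

#' @export
nn_bwd.ly_dense_block <- function(layer, gy) {
  n <- layer$n_modules
  g <- layer$growth
  B <- layer$B; L <- layer$L
  if (length(layer$children) > 1L + n) {
    gy <- nn_bwd(layer$children[[length(layer$children)]], gy)
  }
  # gy is the gradient of the full concatenation [B*L, c_in + n*g]
  gacc <- gy
  for (i in rev(seq_len(n))) {
    cur_c <- layer$c_in + (i - 1L) * g
    go <- as_seq(gacc[, cur_c + seq_len(g), drop = FALSE], B, L)
    gin <- nn_bwd(layer$children[[1L + i]], go)
    gacc <- gacc[, seq_len(cur_c), drop = FALSE] + gin
  }
  nn_bwd(layer$children[[1]], as_seq(gacc, B, L))
}

#' Densely connected regression head
#'
#' An initial stride-2 convolution produces a 24-channel feature map at half
#' the input length; four dense blocks follow (positional encoding, four
#' dense modules of growth 16, +64 channels per block), with halving max
#' pools after the first three blocks so the final map is at ~1/16 of the
#' input length with 24 + 4*64 = 280 channels. Two 1x1 convolutions reduce
#' the channels 280 -> 32 -> 16 and the result is flattened into the output
#' vector.
#'
#' @param L input sequence length (>= 16)
#' @param c_in input channel count
#' @return list with `head` and `out_dim`
#' @export
build_densenet_head <- function(L = 200L, c_in = 5L) {
  L <- as.integer(L)
  if (L < 16L) stop("densenet requires L >= 16")
  l2 <- ceiling(L / 2)
  l16 <- floor(floor(floor(l2 / 2) / 2) / 2)
  head <- nn_seq(
    ly_conv1d(c_in, 24L, 7L, stride = 2L), ly_bn1d(24L), ly_relu(),
    ly_dense_block(24L, pool = TRUE),    # -> 88 channels
    ly_dense_block(88L, pool = TRUE),    # -> 152
    ly_dense_block(152L, pool = TRUE),   # -> 216
    ly_dense_block(216L, pool = FALSE),  # -> 280
    ly_conv1d(280L, 32L, 1L), ly_bn1d(32L), ly_relu(),
    ly_conv1d(32L, 16L, 1L), ly_bn1d(16L), ly_relu(),
    ly_flatten())
  list(head = head, out_dim = 16L * l16)
}

xception_module <- function(c_in, n_f) {
  pathA <- nn_seq(sep_conv(c_in, n_f, 3L), sep_conv(n_f, n_f, 5L),
                  sep_conv(n_f, n_f, 7L))
  pathB <- nn_seq(ly_maxpool1d(3L, 1L, padding = "same"),
                  ly_conv1d(c_in, n_f, 1L), ly_bn1d(n_f))
  shortcut <- if (c_in == n_f) ly_identity() else
    nn_seq(ly_conv1d(c_in, n_f, 1L), ly_bn1d(n_f))
  ly_parallel_add(list(pathA, pathB, shortcut), post_relu = TRUE)
}

#' Xception-style regression head
#'
#' Stacked modules, each combining a path of three depthwise-separable 1D
#' convolutions (kernels 3/5/7, `n_f` filters, batch norm + ReLU) with a
#' stride-1 max-pooling path, joined by additive residual connections (1x1
#' projection on channel mismatch). Adaptive average pooling to 4 bins and a
#' fully connected layer produce the `c_out`-wide output vector.
#'
#' @param n_f module filter count, 8 or 16
#' @param c_out output width, 16 or 32
#' @param n_modules number of modules (default 3)
#' @param c_in input channel count
#' @return list with `head` and `out_dim`
#' @export
build_xception_head <- function(n_f = 16L, c_out = 16L, n_modules = 3L, c_in = 5L) {
  stopifnot(n_f %in% c(8L, 16L), c_out %in% c(16L, 32L))
  mods <- list(xception_module(c_in, n_f))
  for (i in seq_len(n_modules - 1L)) mods <- c(mods, list(xception_module(n_f, n_f)))
  head <- nn_seq(c(mods, list(ly_adaptpool1d(4L), ly_flatten(),
                              ly_dense(4L * n_f, c_out))))
  list(head = head, out_dim = as.integer(c_out))
}

# ---- assembled model -----------------------------------------------------

#' Assemble a regression network from a configuration
#'
#' Builds the dual-branch architecture: the family's regression head, the
#' optional 2-unit attribute head, and the joining layers (a ReLU hidden
#' layer of the family's `hidden_join_dim` when nonzero, then a final affine
#' layer to the scalar VO2 estimate). The intra-subject families
#' (`baseline_lstm`: LSTM with 150 hidden units; `modified_lstm`: 100) are a
#' single many-to-one LSTM layer with a dense output layer.
#'
#' Parameter initialization uses the current RNG stream; seed with
#' [set.seed()] for reproducible builds.
#'
#' @param cfg a [model_config()]
#' @return object of class `vo2net_model` (untrained)
#' @export
assemble_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$family %in% c("baseline_lstm", "modified_lstm")) {
    H <- if (cfg$family == "baseline_lstm") 150L else 100L
    head <- ly_rnn(5L, H, "lstm", return_seq = FALSE)
    hb <- list(head = head, out_dim = H)
  } else {
    hb <- switch(cfg$family,
      rnn = , lstm = , gru = build_rnn_head(cfg$family, cfg$bidirectional),
      cnn = build_cnn_head(cfg$c_out, cfg$seq_len),
      resnet = build_resnet_head(cfg$kernel_sizes, cfg$n_f),
      densenet = build_densenet_head(cfg$seq_len),
      xception = build_xception_head(cfg$n_f, cfg$c_out, cfg$n_modules))
  }
  feature_head <- if (cfg$use_participant_features) build_feature_head() else NULL
  join_in <- hb$out_dim + if (cfg$use_participant_features) 2L else 0L
  join <- if (cfg$hidden_join_dim > 0L) {
    nn_seq(ly_dense(join_in, cfg$hidden_join_dim), ly_relu(),
           ly_dense(cfg$hidden_join_dim, 1L))
  } else {
    nn_seq(ly_dense(join_in, 1L))
  }
  m <- new.env(parent = emptyenv())
  m$head <- hb$head
  m$head_dim <- hb$out_dim
  m$feature_head <- feature_head
  m$join <- join
  m$cfg <- cfg
  m$trained <- FALSE
  class(m) <- "vo2net_model"
  m
}

model_layers <- function(model) {
  ls <- list(model$head, model$join)
  if (!is.null(model$feature_head)) ls <- c(ls, list(model$feature_head))
  ls
}

model_param_refs <- function(model) {
  do.call(c, lapply(model_layers(model), nn_param_refs))
}

model_zero_grads <- function(model) {
  for (l in model_layers(model)) nn_zero_grads(l)
}

#' Number of trainable parameters of a model
#' @param model a `vo2net_model`
#' @return integer count
#' @export
n_params <- function(model) {
  sum(vapply(model_layers(model), nn_n_params, 0))
}

# convert a [B, 5, L] sample array to the channels-last internal layout
to_seq_tensor <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(1, 3, 2))
  dim(xm) <- c(d[1] * d[3], d[2])
  as_seq(xm, d[1], d[3])
}

# forward to the scalar output (standardized target scale during training)
model_forward <- function(model, x, attrs = NULL, training = FALSE) {
  if (is.array(x) && length(dim(x)) == 3L) x <- to_seq_tensor(x)
  h <- nn_fwd(model$head, x, training)
  if (!is.null(model$feature_head)) {
    if (is.null(attrs)) stop("model expects participant attributes")
    f <- nn_fwd(model$feature_head, attrs, training)
    z <- cbind(h, f)
  } else {
    z <- h
  }
  nn_fwd(model$join, z, training)
}

model_backward <- function(model, gy) {
  gz <- nn_bwd(model$join, gy)
  if (!is.null(model$feature_head)) {
    d <- model$head_dim
    gh <- gz[, seq_len(d), drop = FALSE]
    gf <- gz[, d + 1:2, drop = FALSE]
    nn_bwd(model$feature_head, gf)
  } else {
    gh <- gz
  }
  nn_bwd(model$head, gh)
  invisible(NULL)
}
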