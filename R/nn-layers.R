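# Minimal layer-based neural-network engine.
#
# Layers are environments of class c("ly_<type>", "nn_layer") holding
# parameters (named arrays), their gradients (prefixed "g_"), and forward
# caches. nn_fwd()/nn_bwd() dispatch on the layer class; containers recurse.
#
# Sequence tensors use a channels-last flat layout: a matrix [B*L, C] whose
# rows are ordered batch-fastest (row (t-1)*B + b is time step t of sequence
# b), carrying attr "seq_dims" = c(B, L). In this layout an im2col patch for
# convolution tap j is a contiguous row block, so convolutions reduce to
# block copies plus one BLAS product, with no transposes. Vector data is a
# plain matrix [B, features]. Gradients are verified against finite
# differences in the test suite.

new_layer <- function(type, fields = list(), params = character(),
                      children = list()) {
  e <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$param_names <- params
  e$children <- children
  for (nm in params) assign(paste0("g_", nm), e[[nm]] * 0, envir = e)
  class(e) <- c(paste0("ly_", type), "nn_layer")
  e
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# fast column-wise ops (x is [n, C]; v length C); attributes of x survive
addc <- function(x, v) x + rep(v, each = nrow(x))
subc <- function(x, v) x - rep(v, each = nrow(x))
mulc <- function(x, v) x * rep(v, each = nrow(x))

seq_dims <- function(x) {
  sd <- attr(x, "seq_dims")
  if (is.null(sd)) stop("input is not a sequence tensor")
  sd
}

as_seq <- function(m, B, L) {
  attr(m, "seq_dims") <- c(B, L)
  m
}

#' Forward pass through a layer
#' @param layer an `nn_layer`
#' @param x input (sequence tensor or plain matrix)
#' @param training logical; training mode (batch-norm statistics, caches)
#' @return layer output
#' @keywords internal
nn_fwd <- function(layer, x, training = FALSE) UseMethod("nn_fwd")

#' Backward pass through a layer
#' @param layer an `nn_layer`
#' @param gy gradient of the loss w.r.t. the layer output
#' @return gradient w.r.t. the layer input; parameter gradients are
#'   accumulated in the layer
#' @keywords internal
nn_bwd <- function(layer, gy) UseMethod("nn_bwd")

# flat list of (env, name) parameter references
nn_param_refs <- function(layer) {
  refs <- lapply(layer$param_names, function(nm) list(env = layer, name = nm))
  for (ch in layer$children) refs <- c(refs, nn_param_refs(ch))
  refs
}

nn_zero_grads <- function(layer) {
  for (r in nn_param_refs(layer)) {
    assign(paste0("g_", r$name), r$env[[r$name]] * 0, envir = r$env)
  }
  invisible(NULL)
}

nn_n_params <- function(layer) {
  own <- if (!is.null(layer$n_free)) layer$n_free else
    sum(vapply(layer$param_names, function(nm) length(layer[[nm]]), 0))
  own + sum(vapply(layer$children, nn_n_params, 0))
}

nn_get_state <- function(layer) {
  refs <- nn_param_refs(layer)
  state <- lapply(refs, function(r) r$env[[r$name]])
  # batch-norm running statistics are part of the model state
  bns <- nn_collect_layers(layer, "ly_bn1d")
  list(params = state,
       bn = lapply(bns, function(b) list(rm = b$running_mean, rv = b$running_var)))
}

nn_set_state <- function(layer, state) {
  refs <- nn_param_refs(layer)
  for (i in seq_along(refs)) {
    assign(refs[[i]]$name, state$params[[i]], envir = refs[[i]]$env)
  }
  bns <- nn_collect_layers(layer, "ly_bn1d")
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn[[i]]$rm
    bns[[i]]$running_var <- state$bn[[i]]$rv
  }
  invisible(NULL)
}

nn_collect_layers <- function(layer, cls) {
  out <- if (inherits(layer, cls)) list(layer) else list()
  for (ch in layer$children) out <- c(out, nn_collect_layers(ch, cls))
  out
}

# ---- dense ---------------------------------------------------------------

ly_dense <- function(d_in, d_out) {
  new_layer("dense",
            fields = list(W = glorot(d_in, d_out, c(d_in, d_out)),
                          b = numeric(d_out), d_in = d_in, d_out = d_out),
            params = c("W", "b"))
}

#' @export
nn_fwd.ly_dense <- function(layer, x, training = FALSE) {
  layer$x <- x
  addc(x %*% layer$W, layer$b)
}

#' @export
nn_bwd.ly_dense <- function(layer, gy) {
  layer$g_W <- layer$g_W + crossprod(layer$x, gy)
  layer$g_b <- layer$g_b + colSums(gy)
  gy %*% t(layer$W)
}

# ---- relu ----------------------------------------------------------------

ly_relu <- function() new_layer("relu")

#' @export
nn_fwd.ly_relu <- function(layer, x, training = FALSE) {
  layer$mask <- x > 0
  x * layer$mask
}

#' @export
nn_bwd.ly_relu <- function(layer, gy) gy * layer$mask

# ---- 1D convolution (channels-last im2col) -------------------------------

conv_pad <- function(L, k, stride) {
  Lout <- as.integer(ceiling(L / stride))
  total <- max((Lout - 1L) * stride + k - L, 0L)
  c(left = total %/% 2L, right = total - total %/% 2L, Lout = Lout)
}

# row indices of tap j in the padded matrix (stride s, Lout outputs, batch B)
tap_rows <- function(j, s, Lout, B) {
  if (s == 1L) return(((j - 1L) * B + 1L):((j - 1L + Lout) * B))
  tt <- (seq_len(Lout) - 1L) * s + j
  rep((tt - 1L) * B, each = B) + seq_len(B)
}

# weight matrix rows are ordered channel-fastest within tap: row (j-1)*C + c
ly_conv1d <- function(c_in, c_out, k, stride = 1L) {
  new_layer("conv1d",
            fields = list(W = glorot(c_in * k, c_out, c(c_in * k, c_out)),
                          b = numeric(c_out), c_in = c_in, c_out = c_out,
                          k = as.integer(k), stride = as.integer(stride)),
            params = c("W", "b"))
}

#' @export
nn_fwd.ly_conv1d <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  C <- layer$c_in; k <- layer$k; s <- layer$stride
  p <- conv_pad(L, k, s); Lout <- p[["Lout"]]
  Lp <- L + p[["left"]] + p[["right"]]
  Xpad <- matrix(0, B * Lp, C)
  Xpad[p[["left"]] * B + seq_len(B * L), ] <- x
  Xc <- matrix(0, B * Lout, C * k)
  for (j in seq_len(k)) {
    Xc[, (j - 1L) * C + seq_len(C)] <- Xpad[tap_rows(j, s, Lout, B), ]
  }
  y <- addc(Xc %*% layer$W, layer$b)
  layer$Xc <- Xc; layer$B <- B; layer$L <- L; layer$pad <- p
  as_seq(y, B, Lout)
}

#' @export
nn_bwd.ly_conv1d <- function(layer, gy) {
  B <- layer$B; L <- layer$L
  C <- layer$c_in; k <- layer$k; s <- layer$stride
  p <- layer$pad; Lout <- p[["Lout"]]
  layer$g_W <- layer$g_W + crossprod(layer$Xc, gy)
  layer$g_b <- layer$g_b + colSums(gy)
  gXc <- gy %*% t(layer$W)
  Lp <- L + p[["left"]] + p[["right"]]
  gXpad <- matrix(0, B * Lp, C)
  for (j in seq_len(k)) {
    rows <- tap_rows(j, s, Lout, B)
    gXpad[rows, ] <- gXpad[rows, , drop = FALSE] +
      gXc[, (j - 1L) * C + seq_len(C), drop = FALSE]
  }
  as_seq(gXpad[p[["left"]] * B + seq_len(B * L), , drop = FALSE], B, L)
}

# ---- depthwise 1D convolution (stride 1, same padding) -------------------

# A standard convolution whose weight matrix is constrained to the
# per-channel block pattern (tap row (j-1)*C + c connects only to output
# channel c); the gradient is masked after each backward pass so off-block
# entries stay exactly zero. The free-parameter count (c_in * k weights +
# c_in biases) is reported instead of the dense matrix size.
ly_dwconv1d <- function(c_in, k) {
  ly <- ly_conv1d(c_in, c_in, k)
  row_channel <- rep(seq_len(c_in), times = k)
  mask <- outer(row_channel, seq_len(c_in), "==") * 1
  ly$W <- glorot(k, k, c(c_in * k, c_in)) * mask
  ly$mask <- mask
  ly$n_free <- c_in * k + c_in
  class(ly) <- c("ly_dwconv1d", class(ly))
  ly
}

#' @export
nn_bwd.ly_dwconv1d <- function(layer, gy) {
  gx <- NextMethod()
  layer$g_W <- layer$g_W * layer$mask
  gx
}

# ---- batch normalization (per channel) -----------------------------------

# works on sequence tensors [B*L, C] and plain matrices [B, C] alike
ly_bn1d <- function(c_in, momentum = 0.1, eps = 1e-5) {
  new_layer("bn1d",
            fields = list(gamma = rep(1, c_in), beta = numeric(c_in),
                          running_mean = numeric(c_in), running_var = rep(1, c_in),
                          momentum = momentum, eps = eps, c_in = c_in),
            params = c("gamma", "beta"))
}

#' @export
nn_fwd.ly_bn1d <- function(layer, x, training = FALSE) {
  n <- nrow(x)
  if (training) {
    m <- colMeans(x)
    xc <- subc(x, m)
    v <- colSums(xc * xc) / n
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * m
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v * n / max(n - 1, 1)
  } else {
    m <- layer$running_mean
    v <- layer$running_var
    xc <- subc(x, m)
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- mulc(xc, istd)
  y <- addc(mulc(xhat, layer$gamma), layer$beta)
  layer$xhat <- xhat; layer$istd <- istd
  layer$train_mode <- training; layer$n <- n
  y
}

#' @export
nn_bwd.ly_bn1d <- function(layer, gy) {
  n <- layer$n
  ggamma <- colSums(gy * layer$xhat)
  gbeta <- colSums(gy)
  layer$g_gamma <- layer$g_gamma + ggamma
  layer$g_beta <- layer$g_beta + gbeta
  if (layer$train_mode) {
    gx <- subc(gy, gbeta / n) - mulc(layer$xhat, ggamma / n)
    gx <- mulc(gx, layer$gamma * layer$istd)
  } else {
    gx <- mulc(gy, layer$gamma * layer$istd)
  }
  gx
}

# ---- pooling -------------------------------------------------------------

ly_maxpool1d <- function(size, stride = size, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  new_layer("maxpool1d", fields = list(size = as.integer(size),
                                       stride = as.integer(stride),
                                       padding = padding))
}

#' @export
nn_fwd.ly_maxpool1d <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  C <- ncol(x); k <- layer$size; s <- layer$stride
  if (layer$padding == "same") {
    p <- conv_pad(L, k, s)
  } else {
    p <- c(left = 0L, right = 0L, Lout = (L - k) %/% s + 1L)
  }
  Lout <- p[["Lout"]]
  Lp <- L + p[["left"]] + p[["right"]]
  Xpad <- matrix(-Inf, B * Lp, C)
  Xpad[p[["left"]] * B + seq_len(B * L), ] <- x
  best <- Xpad[tap_rows(1L, s, Lout, B), , drop = FALSE]
  argj <- matrix(1L, B * Lout, C)
  if (k > 1) for (j in 2:k) {
    cur <- Xpad[tap_rows(j, s, Lout, B), , drop = FALSE]
    mask <- cur > best
    best[mask] <- cur[mask]
    argj[mask] <- j
  }
  layer$argj <- argj; layer$B <- B; layer$L <- L; layer$pad <- p
  as_seq(best, B, Lout)
}

#' @export
nn_bwd.ly_maxpool1d <- function(layer, gy) {
  B <- layer$B; L <- layer$L
  C <- ncol(gy); k <- layer$size; s <- layer$stride
  p <- layer$pad; Lout <- p[["Lout"]]
  Lp <- L + p[["left"]] + p[["right"]]
  gXpad <- matrix(0, B * Lp, C)
  for (j in seq_len(k)) {
    rows <- tap_rows(j, s, Lout, B)
    gXpad[rows, ] <- gXpad[rows, , drop = FALSE] + gy * (layer$argj == j)
  }
  as_seq(gXpad[p[["left"]] * B + seq_len(B * L), , drop = FALSE], B, L)
}

# global average pooling over time: [B*L, C] -> [B, C]
ly_gap1d <- function() new_layer("gap1d")

#' @export
nn_fwd.ly_gap1d <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  layer$B <- B; layer$L <- L
  rowsum(x, rep_len(seq_len(B), nrow(x)), reorder = TRUE) / L
}

#' @export
nn_bwd.ly_gap1d <- function(layer, gy) {
  B <- layer$B; L <- layer$L
  as_seq(gy[rep_len(seq_len(B), B * L), , drop = FALSE] / L, B, L)
}

# adaptive average pooling to a fixed number of time bins
ly_adaptpool1d <- function(out_len) {
  new_layer("adaptpool1d", fields = list(out_len = as.integer(out_len)))
}

#' @export
nn_fwd.ly_adaptpool1d <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  o <- layer$out_len
  bin <- floor((seq_len(L) - 1L) * o / L) + 1L   # bin of each time step
  w <- tabulate(bin, o)                          # bin widths
  grp <- rep((bin - 1L) * B, each = B) + seq_len(B)
  y <- rowsum(x, grp, reorder = TRUE) / rep(w, each = B)
  layer$B <- B; layer$L <- L; layer$grp <- grp; layer$w <- w
  as_seq(y, B, o)
}

#' @export
nn_bwd.ly_adaptpool1d <- function(layer, gy) {
  B <- layer$B; L <- layer$L
  gyn <- gy / rep(layer$w, each = B)
  as_seq(gyn[layer$grp, , drop = FALSE], B, L)
}

# ---- flatten: [B*L, C] -> [B, L*C] ---------------------------------------

ly_flatten <- function() new_layer("flatten")

#' @export
nn_fwd.ly_flatten <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  layer$B <- B; layer$L <- L; layer$C <- ncol(x)
  y <- x
  attr(y, "seq_dims") <- NULL
  dim(y) <- c(B, L * ncol(x))
  y
}

#' @export
nn_bwd.ly_flatten <- function(layer, gy) {
  dim(gy) <- c(layer$B * layer$L, layer$C)
  as_seq(gy, layer$B, layer$L)
}

# ---- fixed sinusoidal positional encoding --------------------------------

ly_posenc <- function() new_layer("posenc")

posenc_matrix <- function(C, L) {
  pe <- matrix(0, L, C)
  t <- seq_len(L) - 1L
  for (c in seq_len(C)) {
    i <- (c - 1L) %/% 2L
    w <- 1 / 10000^(2 * i / C)
    pe[, c] <- if (c %% 2L == 1L) sin(w * t) else cos(w * t)
  }
  pe
}

#' @export
nn_fwd.ly_posenc <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]; C <- ncol(x)
  key <- paste(B, L, C)
  if (!identical(layer$key, key)) {
    layer$pe_rows <- posenc_matrix(C, L)[rep(seq_len(L), each = B), , drop = FALSE]
    layer$key <- key
  }
  x + layer$pe_rows
}

#' @export
nn_bwd.ly_posenc <- function(layer, gy) gy

# ---- containers ----------------------------------------------------------

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !inherits(layers[[1]], "nn_layer")) {
    layers <- layers[[1]]
  }
  new_layer("seq", children = layers)
}

#' @export
nn_fwd.ly_seq <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- nn_fwd(ch, x, training)
  x
}

#' @export
nn_bwd.ly_seq <- function(layer, gy) {
  for (ch in rev(layer$children)) gy <- nn_bwd(ch, gy)
  gy
}

# sum of parallel paths (residual connections), optional trailing ReLU
ly_parallel_add <- function(paths, post_relu = TRUE) {
  new_layer("parallel_add", fields = list(post_relu = post_relu), children = paths)
}

#' @export
nn_fwd.ly_parallel_add <- function(layer, x, training = FALSE) {
  y <- NULL
  for (ch in layer$children) {
    yi <- nn_fwd(ch, x, training)
    y <- if (is.null(y)) yi else y + yi
  }
  if (layer$post_relu) {
    layer$mask <- y > 0
    y <- y * layer$mask
  }
  y
}

#' @export
nn_bwd.ly_parallel_add <- function(layer, gy) {
  if (layer$post_relu) gy <- gy * layer$mask
  gx <- NULL
  for (ch in layer$children) {
    gi <- nn_bwd(ch, gy)
    gx <- if (is.null(gx)) gi else gx + gi
  }
  gx
}

ly_identity <- function() new_layer("identity")

#' @export
nn_fwd.ly_identity <- function(layer, x, training = FALSE) x

#' @export
nn_bwd.ly_identity <- function(layer, gy) gy
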