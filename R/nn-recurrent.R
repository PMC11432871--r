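# Recurrent layers with backpropagation through time.
#
# Input is a channels-last sequence tensor [B*L, C] (batch fastest); the time
# slice of step t is the contiguous row block (t-1)*B + 1:B. Output is either
# the full hidden sequence (same layout, H channels) or the final hidden
# state [B, H]. Gate layouts follow the usual conventions: LSTM gates
# (i, f, g, o) with forget-gate bias initialized to 1; GRU gates (r, z, n)
# with separate input/hidden biases so the reset gate acts inside the
# candidate as in standard implementations. The input projection for all
# time steps is computed in a single matrix product; only the hidden-to-
# hidden part stays in the time loop.

sigmoid <- function(x) 1 / (1 + exp(-x))

ly_rnn <- function(c_in, H, cell = c("rnn", "lstm", "gru"), return_seq = FALSE) {
  cell <- match.arg(cell)
  G <- switch(cell, rnn = 1L, lstm = 4L, gru = 3L)
  b <- numeric(G * H)
  if (cell == "lstm") b[H + seq_len(H)] <- 1   # forget gate
  fields <- list(
    Wx = glorot(c_in, G * H, c(c_in, G * H)),
    Wh = glorot(H, G * H, c(H, G * H)),
    b = b,
    c_in = c_in, H = H, cell = cell, G = G, return_seq = return_seq
  )
  params <- c("Wx", "Wh", "b")
  if (cell == "gru") {
    fields$bh <- numeric(G * H)
    params <- c(params, "bh")
  }
  new_layer(paste0("rnn_", cell), fields = fields, params = params)
}

rnn_forward_generic <- function(layer, x, training) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  H <- layer$H
  AX <- addc(x %*% layer$Wx, layer$b)   # [B*L, G*H]
  h <- matrix(0, B, H)
  cst <- matrix(0, B, H)
  cache <- vector("list", L)
  Hs <- if (layer$return_seq) matrix(0, B * L, H) else NULL
  iH <- seq_len(H)
  for (t in seq_len(L)) {
    rows <- (t - 1L) * B + seq_len(B)
    axt <- AX[rows, , drop = FALSE]
    if (layer$cell == "rnn") {
      a <- axt + h %*% layer$Wh
      hprev <- h
      h <- tanh(a)
      cache[[t]] <- list(hprev = hprev, h = h)
    } else if (layer$cell == "lstm") {
      z <- axt + h %*% layer$Wh
      i <- sigmoid(z[, iH, drop = FALSE])
      f <- sigmoid(z[, H + iH, drop = FALSE])
      g <- tanh(z[, 2 * H + iH, drop = FALSE])
      o <- sigmoid(z[, 3 * H + iH, drop = FALSE])
      cprev <- cst; hprev <- h
      cst <- f * cprev + i * g
      tc <- tanh(cst)
      h <- o * tc
      cache[[t]] <- list(hprev = hprev, cprev = cprev,
                         i = i, f = f, g = g, o = o, tc = tc)
    } else { # gru
      ah <- addc(h %*% layer$Wh, layer$bh)
      r <- sigmoid(axt[, iH, drop = FALSE] + ah[, iH, drop = FALSE])
      zg <- sigmoid(axt[, H + iH, drop = FALSE] + ah[, H + iH, drop = FALSE])
      hn_h <- ah[, 2 * H + iH, drop = FALSE]
      n <- tanh(axt[, 2 * H + iH, drop = FALSE] + r * hn_h)
      hprev <- h
      h <- (1 - zg) * n + zg * hprev
      cache[[t]] <- list(hprev = hprev, r = r, z = zg, n = n, hn_h = hn_h)
    }
    if (layer$return_seq) Hs[rows, ] <- h
  }
  layer$cache <- cache
  layer$x_in <- x
  layer$B <- B; layer$L <- L
  if (layer$return_seq) as_seq(Hs, B, L) else h
}

rnn_backward_generic <- function(layer, gy) {
  B <- layer$B; L <- layer$L
  H <- layer$H
  G <- layer$G
  iH <- seq_len(H)
  gh <- matrix(0, B, H)
  gc <- matrix(0, B, H)
  gWh <- layer$g_Wh * 0
  if (layer$cell == "gru") gbh <- layer$g_bh * 0
  GZ <- matrix(0, B * L, G * H)   # per-step pre-activation grads (x side)
  seq_out <- layer$return_seq
  for (t in rev(seq_len(L))) {
    rows <- (t - 1L) * B + seq_len(B)
    ca <- layer$cache[[t]]
    gh_t <- gh + if (seq_out) gy[rows, , drop = FALSE] else
      if (t == L) gy else matrix(0, B, H)
    if (layer$cell == "rnn") {
      ga <- gh_t * (1 - ca$h^2)
      GZ[rows, ] <- ga
      gWh <- gWh + crossprod(ca$hprev, ga)
      gh <- ga %*% t(layer$Wh)
    } else if (layer$cell == "lstm") {
      go <- gh_t * ca$tc
      gc_t <- gc + gh_t * ca$o * (1 - ca$tc^2)
      gi <- gc_t * ca$g
      gf <- gc_t * ca$cprev
      gg <- gc_t * ca$i
      gc <- gc_t * ca$f
      gz <- cbind(gi * ca$i * (1 - ca$i),
                  gf * ca$f * (1 - ca$f),
                  gg * (1 - ca$g^2),
                  go * ca$o * (1 - ca$o))
      GZ[rows, ] <- gz
      gWh <- gWh + crossprod(ca$hprev, gz)
      gh <- gz %*% t(layer$Wh)
    } else { # gru
      gz_gate <- gh_t * (ca$hprev - ca$n)
      gn <- gh_t * (1 - ca$z)
      gh_direct <- gh_t * ca$z
      gan <- gn * (1 - ca$n^2)         # pre-activation of candidate
      gr <- gan * ca$hn_h
      gax <- cbind(gr * ca$r * (1 - ca$r),
                   gz_gate * ca$z * (1 - ca$z),
                   gan)
      gah <- cbind(gax[, iH, drop = FALSE],
                   gax[, H + iH, drop = FALSE],
                   gan * ca$r)
      GZ[rows, ] <- gax
      gWh <- gWh + crossprod(ca$hprev, gah)
      gbh <- gbh + colSums(gah)
      gh <- gh_direct + gah %*% t(layer$Wh)
    }
  }
  layer$g_Wx <- layer$g_Wx + crossprod(layer$x_in, GZ)
  layer$g_Wh <- layer$g_Wh + gWh
  layer$g_b <- layer$g_b + colSums(GZ)
  if (layer$cell == "gru") layer$g_bh <- layer$g_bh + gbh
  as_seq(GZ %*% t(layer$Wx), B, L)
}

#' @export
nn_fwd.ly_rnn_rnn <- function(layer, x, training = FALSE) rnn_forward_generic(layer, x, training)
#' @export
nn_fwd.ly_rnn_lstm <- function(layer, x, training = FALSE) rnn_forward_generic(layer, x, training)
#' @export
nn_fwd.ly_rnn_gru <- function(layer, x, training = FALSE) rnn_forward_generic(layer, x, training)
#' @export
nn_bwd.ly_rnn_rnn <- function(layer, gy) rnn_backward_generic(layer, gy)
#' @export
nn_bwd.ly_rnn_lstm <- function(layer, gy) rnn_backward_generic(layer, gy)
#' @export
nn_bwd.ly_rnn_gru <- function(layer, gy) rnn_backward_generic(layer, gy)

# ---- bidirectional wrapper ----------------------------------------------

# time-reversal row permutation for a [B*L, C] tensor
rev_rows <- function(B, L) rep((rev(seq_len(L)) - 1L) * B, each = B) + seq_len(B)

# Runs a forward-direction and a backward-direction copy of the same cell and
# concatenates along channels; with return_seq = FALSE the output is the
# concatenation of the two final states (the backward direction's final state
# corresponds to the start of the sequence, the standard convention).
ly_bidir <- function(c_in, H, cell, return_seq = FALSE) {
  fwd <- ly_rnn(c_in, H, cell, return_seq)
  bwd <- ly_rnn(c_in, H, cell, return_seq)
  new_layer("bidir", fields = list(H = H, return_seq = return_seq),
            children = list(fwd, bwd))
}

#' @export
nn_fwd.ly_bidir <- function(layer, x, training = FALSE) {
  sd <- seq_dims(x); B <- sd[1]; L <- sd[2]
  rr <- rev_rows(B, L)
  layer$B <- B; layer$L <- L
  y1 <- nn_fwd(layer$children[[1]], x, training)
  xr <- as_seq(x[rr, , drop = FALSE], B, L)
  y2 <- nn_fwd(layer$children[[2]], xr, training)
  if (layer$return_seq) {
    y2 <- y2[rr, , drop = FALSE]
    as_seq(cbind(y1, y2), B, L)
  } else {
    cbind(y1, y2)
  }
}

#' @export
nn_bwd.ly_bidir <- function(layer, gy) {
  H <- layer$H
  B <- layer$B; L <- layer$L
  rr <- rev_rows(B, L)
  g1 <- gy[, seq_len(H), drop = FALSE]
  g2 <- gy[, H + seq_len(H), drop = FALSE]
  if (layer$return_seq) {
    g1 <- as_seq(g1, B, L)
    g2 <- as_seq(g2[rr, , drop = FALSE], B, L)
  }
  gx1 <- nn_bwd(layer$children[[1]], g1)
  gx2 <- nn_bwd(layer$children[[2]], g2)
  gx1 + gx2[rr, , drop = FALSE]
}
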