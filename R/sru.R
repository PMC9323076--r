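# Simple recurrent unit (SRU) and its attention-augmented variant (SRU++).
#
# The SRU recurrence, per time step t with elementwise products:
#   f_t = sigmoid(Wf x_t + vf * c_{t-1} + bf)        (forget gate)
#   c_t = f_t * c_{t-1} + (1 - f_t) * (W x_t)        (internal state)
#   r_t = sigmoid(Wr x_t + vr * c_{t-1} + br)        (reset gate)
#   h_t = r_t * c_t + (1 - r_t) * x_t                (highway output)
# Only the elementwise recurrence is sequential: the three input projections
# are batched across all time steps as U = rbind(W, Wf, Wr) %*% X. SRU++
# replaces that linear projection with scaled-dot-product self-attention
# followed by a projection with layer normalization.

#' Parameters of one SRU cell
#'
#' @param W,Wf,Wr Weight matrices, each `hidden x input`.
#' @param vf,vr,bf,br Parameter vectors of length `hidden` (elementwise state
#'   weights and gate biases).
#' @param Wx Optional `hidden x input` projection for the highway term when
#'   the input and hidden sizes differ; when `NULL`, the highway uses the
#'   input directly (requires `input == hidden`).
#' @return An `sru_cell_params` object.
#' @export
sru_cell_params <- function(W, Wf, Wr, vf, vr, bf, br, Wx = NULL) {
  W <- as.matrix(W); Wf <- as.matrix(Wf); Wr <- as.matrix(Wr)
  h <- nrow(W)
  d <- ncol(W)
  if (!all(dim(Wf) == c(h, d)) || !all(dim(Wr) == c(h, d))) {
    vib_abort("W, Wf, Wr must share dimensions", "vib_invalid_parameter")
  }
  for (v in list(vf, vr, bf, br)) {
    if (length(v) != h) vib_abort("vf, vr, bf, br must have length hidden",
                                  "vib_invalid_parameter")
  }
  if (is.null(Wx) && d != h) {
    vib_abort("highway term needs input == hidden or an explicit Wx projection",
              "vib_invalid_parameter")
  }
  if (!is.null(Wx) && !all(dim(as.matrix(Wx)) == c(h, d))) {
    vib_abort("Wx must be hidden x input", "vib_invalid_parameter")
  }
  out <- list(W = W, Wf = Wf, Wr = Wr, vf = as.numeric(vf),
              vr = as.numeric(vr), bf = as.numeric(bf), br = as.numeric(br))
  if (!is.null(Wx)) out$Wx <- as.matrix(Wx)
  structure(out, class = "sru_cell_params")
}

#' Randomly initialized SRU cell parameters
#' @param input,hidden Input and hidden sizes.
#' @return An [sru_cell_params()] object (biases start at zero).
#' @export
init_sru_cell <- function(input, hidden) {
  sc <- sqrt(1 / input)
  m <- function() matrix(stats::runif(hidden * input, -sc, sc), hidden, input)
  sru_cell_params(m(), m(), m(),
                  vf = stats::runif(hidden, -sc, sc),
                  vr = stats::runif(hidden, -sc, sc),
                  bf = numeric(hidden), br = numeric(hidden),
                  Wx = if (input != hidden) m() else NULL)
}

#' One SRU time step
#'
#' @param x_t Input vector at time t.
#' @param c_prev Previous internal state vector (length `hidden`).
#' @param params An [sru_cell_params()].
#' @return A list with the output `h`, new state `c`, and a `trace` holding
#'   the forget gate `f`, reset gate `r`, output `h`, and projection rows `u`
#'   (gate values lie strictly in (0, 1)).
#' @examples
#' p <- sru_cell_params(W = matrix(1), Wf = matrix(0), Wr = matrix(0),
#'                      vf = 0, vr = 0, bf = 0, br = 0)
#' sru_cell_step(1, 0, p)$h  # 0.75
#' @export
sru_cell_step <- function(x_t, c_prev, params) {
  if (!inherits(params, "sru_cell_params")) {
    vib_abort("`params` must be sru_cell_params", "vib_invalid_parameter")
  }
  x_t <- as.numeric(x_t)
  c_prev <- as.numeric(c_prev)
  if (length(x_t) != ncol(params$W) || length(c_prev) != nrow(params$W)) {
    vib_abort("dimension mismatch in sru_cell_step", "vib_invalid_parameter")
  }
  u_w <- drop(params$W %*% x_t)
  u_f <- drop(params$Wf %*% x_t)
  u_r <- drop(params$Wr %*% x_t)
  f <- sigmoid(u_f + params$vf * c_prev + params$bf)
  c_t <- f * c_prev + (1 - f) * u_w
  r <- sigmoid(u_r + params$vr * c_prev + params$br)
  xh <- if (is.null(params$Wx)) x_t else drop(params$Wx %*% x_t)
  h <- r * c_t + (1 - r) * xh
  list(h = h, c = c_t, trace = list(f = f, r = r, h = h, u = c(u_w, u_f, u_r)))
}

# Shared elementwise recurrence given the precomputed projections. u is a
# 3h x T matrix (blocks: W-, Wf-, Wr-projections); xh is the highway input.
sru_recurrence_forward <- function(u, xh, c0, vf, vr, bf, br) {
  h <- nrow(xh)
  T <- ncol(xh)
  u_w <- u[seq_len(h), , drop = FALSE]
  u_f <- u[(h + 1L):(2L * h), , drop = FALSE]
  u_r <- u[(2L * h + 1L):(3L * h), , drop = FALSE]
  Fm <- matrix(0, h, T); Rm <- matrix(0, h, T)
  Cm <- matrix(0, h, T + 1L)
  Hm <- matrix(0, h, T)
  Cm[, 1L] <- c0
  for (t in seq_len(T)) {
    cp <- Cm[, t]
    f <- sigmoid(u_f[, t] + vf * cp + bf)
    ct <- f * cp + (1 - f) * u_w[, t]
    r <- sigmoid(u_r[, t] + vr * cp + br)
    Fm[, t] <- f; Rm[, t] <- r; Cm[, t + 1L] <- ct
    Hm[, t] <- r * ct + (1 - r) * xh[, t]
  }
  list(H = Hm, cache = list(F = Fm, R = Rm, C = Cm, u_w = u_w, u_f = u_f,
                            u_r = u_r, xh = xh))
}

# Backward through the recurrence. Returns gradients w.r.t. u (3h x T), the
# highway input xh, and the elementwise parameters.
sru_recurrence_backward <- function(dH, cache, vf, vr) {
  h <- nrow(dH)
  T <- ncol(dH)
  Fm <- cache$F; Rm <- cache$R; Cm <- cache$C
  du_w <- matrix(0, h, T); du_f <- matrix(0, h, T); du_r <- matrix(0, h, T)
  dxh <- matrix(0, h, T)
  dvf <- numeric(h); dvr <- numeric(h); dbf <- numeric(h); dbr <- numeric(h)
  dc_next <- numeric(h)
  for (t in rev(seq_len(T))) {
    f <- Fm[, t]; r <- Rm[, t]
    cp <- Cm[, t]; ct <- Cm[, t + 1L]
    dh <- dH[, t]
    dr <- dh * (ct - cache$xh[, t])
    dc <- dh * r + dc_next
    dxh[, t] <- dh * (1 - r)
    dpre_r <- dr * r * (1 - r)
    du_r[, t] <- dpre_r
    dvr <- dvr + dpre_r * cp
    dbr <- dbr + dpre_r
    dcp <- dpre_r * vr
    df <- dc * (cp - cache$u_w[, t])
    du_w[, t] <- dc * (1 - f)
    dcp <- dcp + dc * f
    dpre_f <- df * f * (1 - f)
    du_f[, t] <- dpre_f
    dvf <- dvf + dpre_f * cp
    dbf <- dbf + dpre_f
    dcp <- dcp + dpre_f * vf
    dc_next <- dcp
  }
  list(du = rbind(du_w, du_f, du_r), dxh = dxh,
       dvf = dvf, dvr = dvr, dbf = dbf, dbr = dbr, dc0 = dc_next)
}

#' Run an SRU layer over a sequence
#'
#' Computes the batched projection `U = rbind(W, Wf, Wr) %*% X` once for the
#' whole sequence, then runs the elementwise recurrence; the result is
#' identical (to rounding) to iterating [sru_cell_step()] over time.
#'
#' @param X Input sequence as an `input x T` matrix (columns are time steps).
#' @param params An [sru_cell_params()].
#' @param c0 Initial state (default zero).
#' @return A `hidden x T` matrix of outputs.
#' @export
sru_layer_forward <- function(X, params, c0 = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) vib_abort("empty sequence", "vib_invalid_parameter")
  h <- nrow(params$W)
  if (nrow(X) != ncol(params$W)) {
    vib_abort("input dimension mismatch", "vib_invalid_parameter")
  }
  if (is.null(c0)) c0 <- numeric(h)
  u <- rbind(params$W, params$Wf, params$Wr) %*% X
  xh <- if (is.null(params$Wx)) X else params$Wx %*% X
  sru_recurrence_forward(u, xh, c0, params$vf, params$vr,
                         params$bf, params$br)$H
}

# ---- SRU++ ------------------------------------------------------------------

#' Parameters of one SRU++ layer
#'
#' The input projection of the SRU is replaced by single-head scaled-dot-
#' product self-attention: `Q = Wq X`, `K = Wk Q`, `V = Wv Q`, attention
#' output `A`, and `U = Wo layernorm(Q + alpha * A)`, where `alpha` is a
#' learnable scalar initialized at zero (so a fresh layer starts as a plain
#' linear projection, independent of `Wk` and `Wv`).
#'
#' @param input Input size d.
#' @param hidden Hidden size.
#' @param attention_dim Attention dimension d', strictly smaller than the
#'   input; `Wk` and `Wv` are d' x d'. Default `max(1, hidden / 4)`.
#' @return An `srupp_layer_params` object with randomly initialized weights,
#'   zero biases, and `alpha = 0`.
#' @export
init_srupp_layer <- function(input, hidden, attention_dim = NULL) {
  if (is.null(attention_dim)) attention_dim <- max(1L, hidden %/% 4L)
  if (attention_dim >= input) {
    vib_abort("attention_dim must be smaller than the input size",
              "vib_configuration_error")
  }
  sc <- sqrt(1 / input)
  sca <- sqrt(1 / attention_dim)
  out <- structure(list(
    Wq = matrix(stats::runif(attention_dim * input, -sc, sc), attention_dim, input),
    Wk = matrix(stats::runif(attention_dim^2, -sca, sca), attention_dim, attention_dim),
    Wv = matrix(stats::runif(attention_dim^2, -sca, sca), attention_dim, attention_dim),
    Wo = matrix(stats::runif(3L * hidden * attention_dim, -sca, sca),
                3L * hidden, attention_dim),
    ln_gain = rep(1, attention_dim),
    ln_bias = numeric(attention_dim),
    alpha = 0,
    vf = stats::runif(hidden, -sc, sc),
    vr = stats::runif(hidden, -sc, sc),
    bf = numeric(hidden), br = numeric(hidden)
  ), class = "srupp_layer_params")
  if (input != hidden) {
    out$Wx <- matrix(stats::runif(hidden * input, -sc, sc), hidden, input)
  }
  out
}

#' SRU++ self-attention block
#'
#' @param X Input sequence, `input x T` matrix.
#' @param params An [init_srupp_layer()] parameter set.
#' @return A list with `U` (the `3 * hidden x T` projected matrix feeding the
#'   SRU recurrence) and `trace` (Q, K, V, the attention output A, the
#'   softmax weights S whose rows sum to 1, U, and X).
#' @export
srupp_attention <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) vib_abort("empty sequence", "vib_invalid_parameter")
  dpr <- nrow(params$Wq)
  if (dpr >= nrow(X)) {
    vib_abort("attention_dim must be smaller than the input size",
              "vib_configuration_error")
  }
  att <- srupp_attention_forward(X, params)
  list(U = att$U, trace = att[c("Q", "K", "V", "A", "S", "U")])
}

srupp_attention_forward <- function(X, params) {
  Q <- params$Wq %*% X                       # d' x T
  K <- params$Wk %*% Q
  V <- params$Wv %*% Q
  dpr <- nrow(Q)
  scores <- crossprod(Q, K) / sqrt(dpr)      # T x T
  S <- softmax_rows(scores)
  A <- t(S %*% t(V))                         # d' x T
  Z <- Q + params$alpha * A
  ln <- layernorm_forward(Z, params$ln_gain, params$ln_bias)
  U <- params$Wo %*% ln$out
  list(U = U, Q = Q, K = K, V = V, S = S, A = A, ln = ln, X = X)
}

srupp_attention_backward <- function(dU, cache, params) {
  Q <- cache$Q; K <- cache$K; V <- cache$V; S <- cache$S; A <- cache$A
  dpr <- nrow(Q)
  dWo <- dU %*% t(cache$ln$out)
  dln_out <- crossprod(params$Wo, dU)
  lnb <- layernorm_backward(dln_out, cache$ln, params$ln_gain)
  dZ <- lnb$dx
  dalpha <- sum(dZ * A)
  dA <- params$alpha * dZ
  dQ <- dZ                                   # residual path
  # attention path: A = V %*% t(S)
  dV <- dA %*% S
  dS <- crossprod(dA, V)                     # T x T
  dscores <- (dS - rowSums(dS * S)) * S
  dQ <- dQ + K %*% t(dscores) / sqrt(dpr)
  dK <- Q %*% dscores / sqrt(dpr)
  dQ <- dQ + crossprod(params$Wk, dK) + crossprod(params$Wv, dV)
  dWk <- dK %*% t(Q)
  dWv <- dV %*% t(Q)
  dWq <- dQ %*% t(cache$X)
  dX <- crossprod(params$Wq, dQ)
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo,
       dln_gain = lnb$dgain, dln_bias = lnb$dbias, dalpha = dalpha)
}

#' Run an SRU++ layer over a sequence
#'
#' The attention block produces the projection matrix U, and the SRU
#' elementwise recurrence runs over it; output length equals input length.
#'
#' @inheritParams srupp_attention
#' @param c0 Initial internal state (default zero).
#' @return A `hidden x T` matrix of outputs.
#' @export
srupp_layer_forward <- function(X, params, c0 = NULL) {
  srupp_layer_forward_cached(X, params, c0)$H
}

srupp_layer_forward_cached <- function(X, params, c0 = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) vib_abort("empty sequence", "vib_invalid_parameter")
  h <- length(params$vf)
  if (is.null(c0)) c0 <- numeric(h)
  att <- srupp_attention_forward(X, params)
  xh <- if (is.null(params$Wx)) X else params$Wx %*% X
  rec <- sru_recurrence_forward(att$U, xh, c0, params$vf, params$vr,
                                params$bf, params$br)
  list(H = rec$H, cache = list(att = att, rec = rec$cache, X = X))
}

srupp_layer_backward <- function(dH, cache, params) {
  rb <- sru_recurrence_backward(dH, cache$rec, params$vf, params$vr)
  ab <- srupp_attention_backward(rb$du, cache$att, params)
  dX <- ab$dX
  dWx <- NULL
  if (is.null(params$Wx)) {
    dX <- dX + rb$dxh
  } else {
    dWx <- rb$dxh %*% t(cache$X)
    dX <- dX + crossprod(params$Wx, rb$dxh)
  }
  dparams <- list(Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv, Wo = ab$dWo,
                  ln_gain = ab$dln_gain, ln_bias = ab$dln_bias,
                  alpha = ab$dalpha, vf = rb$dvf, vr = rb$dvr,
                  bf = rb$dbf, br = rb$dbr)
  if (!is.null(dWx)) dparams$Wx <- dWx
  list(dX = dX, dparams = dparams)
}

# ---- plain SRU layer with cache (for training when seq_module = "sru") -----

sru_layer_forward_cached <- function(X, params, c0 = NULL) {
  h <- nrow(params$W)
  if (is.null(c0)) c0 <- numeric(h)
  u <- rbind(params$W, params$Wf, params$Wr) %*% X
  xh <- if (is.null(params$Wx)) X else params$Wx %*% X
  rec <- sru_recurrence_forward(u, xh, c0, params$vf, params$vr,
                                params$bf, params$br)
  list(H = rec$H, cache = list(rec = rec$cache, X = X))
}

sru_layer_backward <- function(dH, cache, params) {
  h <- nrow(params$W)
  rb <- sru_recurrence_backward(dH, cache$rec, params$vf, params$vr)
  du_w <- rb$du[seq_len(h), , drop = FALSE]
  du_f <- rb$du[(h + 1L):(2L * h), , drop = FALSE]
  du_r <- rb$du[(2L * h + 1L):(3L * h), , drop = FALSE]
  X <- cache$X
  dX <- crossprod(params$W, du_w) + crossprod(params$Wf, du_f) +
    crossprod(params$Wr, du_r)
  dWx <- NULL
  if (is.null(params$Wx)) {
    dX <- dX + rb$dxh
  } else {
    dWx <- rb$dxh %*% t(X)
    dX <- dX + crossprod(params$Wx, rb$dxh)
  }
  dparams <- list(W = du_w %*% t(X), Wf = du_f %*% t(X), Wr = du_r %*% t(X),
                  vf = rb$dvf, vr = rb$dvr, bf = rb$dbf, br = rb$dbr)
  if (!is.null(dWx)) dparams$Wx <- dWx
  list(dX = dX, dparams = dparams)
}

# ---- LSTM baseline ----------------------------------------------------------

init_lstm_layer <- function(input, hidden) {
  sc <- sqrt(1 / input)
  sch <- sqrt(1 / hidden)
  list(Wi = matrix(stats::runif(4L * hidden * input, -sc, sc), 4L * hidden, input),
       Uh = matrix(stats::runif(4L * hidden * hidden, -sch, sch), 4L * hidden, hidden),
       b = numeric(4L * hidden))
}

lstm_layer_forward_cached <- function(X, params) {
  h <- nrow(params$Uh) %/% 4L
  T <- ncol(X)
  pre_x <- params$Wi %*% X + params$b
  Hm <- matrix(0, h, T)
  cache <- list(I = matrix(0, h, T), F = matrix(0, h, T), G = matrix(0, h, T),
                O = matrix(0, h, T), C = matrix(0, h, T + 1L),
                TC = matrix(0, h, T), Hprev = matrix(0, h, T + 1L), X = X)
  for (t in seq_len(T)) {
    pre <- pre_x[, t] + params$Uh %*% cache$Hprev[, t]
    i <- sigmoid(pre[seq_len(h)])
    f <- sigmoid(pre[(h + 1L):(2L * h)])
    g <- tanh(pre[(2L * h + 1L):(3L * h)])
    o <- sigmoid(pre[(3L * h + 1L):(4L * h)])
    ct <- f * cache$C[, t] + i * g
    tc <- tanh(ct)
    Hm[, t] <- o * tc
    cache$I[, t] <- i; cache$F[, t] <- f; cache$G[, t] <- g; cache$O[, t] <- o
    cache$C[, t + 1L] <- ct; cache$TC[, t] <- tc
    cache$Hprev[, t + 1L] <- Hm[, t]
  }
  list(H = Hm, cache = cache)
}

lstm_layer_backward <- function(dH, cache, params) {
  h <- nrow(dH)
  T <- ncol(dH)
  dpre_all <- matrix(0, 4L * h, T)
  dh_next <- numeric(h)
  dc_next <- numeric(h)
  for (t in rev(seq_len(T))) {
    dh <- dH[, t] + dh_next
    i <- cache$I[, t]; f <- cache$F[, t]; g <- cache$G[, t]; o <- cache$O[, t]
    tc <- cache$TC[, t]
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g
    dg <- dc * i
    df <- dc * cache$C[, t]
    dc_next <- dc * f
    dpre <- c(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2),
              do_ * o * (1 - o))
    dpre_all[, t] <- dpre
    dh_next <- drop(crossprod(params$Uh, dpre))
  }
  dX <- crossprod(params$Wi, dpre_all)
  dWi <- dpre_all %*% t(cache$X)
  dUh <- dpre_all %*% t(cache$Hprev[, seq_len(T), drop = FALSE])
  list(dX = dX, dparams = list(Wi = dWi, Uh = dUh, b = rowSums(dpre_all)))
}
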