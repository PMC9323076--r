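# Low-level neural-network operations on channels-by-time matrices, each with
# an explicit backward pass. Convolutions go through im2col so the heavy
# lifting is BLAS matrix multiplication.

# Patch matrix: rows are (k-1)*C_in + c_in, columns are output time steps.
im2col <- function(x, kernel, stride) {
  c_in <- nrow(x)
  t_in <- ncol(x)
  t_out <- (t_in - kernel) %/% stride + 1L
  if (t_out < 1L) vib_abort("input shorter than kernel", "vib_invalid_parameter")
  starts <- seq(1L, by = stride, length.out = t_out)
  col <- matrix(0, c_in * kernel, t_out)
  for (k in seq_len(kernel)) {
    col[((k - 1L) * c_in + 1L):(k * c_in), ] <- x[, starts + k - 1L, drop = FALSE]
  }
  col
}

col2im <- function(dcol, c_in, t_in, kernel, stride) {
  t_out <- ncol(dcol)
  starts <- seq(1L, by = stride, length.out = t_out)
  dx <- matrix(0, c_in, t_in)
  for (k in seq_len(kernel)) {
    cols <- starts + k - 1L
    dx[, cols] <- dx[, cols] + dcol[((k - 1L) * c_in + 1L):(k * c_in), , drop = FALSE]
  }
  dx
}

# Strided 1-D convolution. weight: C_out x (C_in * kernel); bias: C_out.
conv1d_forward <- function(x, weight, bias, kernel, stride) {
  col <- im2col(x, kernel, stride)
  out <- weight %*% col + bias
  list(out = out, col = col)
}

conv1d_backward <- function(dout, cache_col, x_dim, weight, kernel, stride) {
  dweight <- dout %*% t(cache_col)
  dbias <- rowSums(dout)
  dcol <- crossprod(weight, dout)
  dx <- col2im(dcol, x_dim[1], x_dim[2], kernel, stride)
  list(dx = dx, dweight = dweight, dbias = dbias)
}

# Transposed 1-D convolution (the adjoint of conv1d). weight layout matches
# conv1d: C_out x (C_in * kernel); output length (T_in - 1) * stride + kernel.
tconv1d_forward <- function(x, weight, bias, kernel, stride) {
  c_out <- nrow(weight)
  c_in <- nrow(x)
  t_in <- ncol(x)
  t_out <- (t_in - 1L) * stride + kernel
  out <- matrix(0, c_out, t_out)
  starts <- seq(1L, by = stride, length.out = t_in)
  for (k in seq_len(kernel)) {
    wk <- weight[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
    cols <- starts + k - 1L
    out[, cols] <- out[, cols] + wk %*% x
  }
  out + bias
}

tconv1d_backward <- function(dout, x, weight, kernel, stride) {
  c_in <- nrow(x)
  t_in <- ncol(x)
  starts <- seq(1L, by = stride, length.out = t_in)
  dweight <- matrix(0, nrow(weight), ncol(weight))
  dx <- matrix(0, c_in, t_in)
  for (k in seq_len(kernel)) {
    cols <- starts + k - 1L
    dslice <- dout[, cols, drop = FALSE]
    wk <- weight[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
    dweight[, ((k - 1L) * c_in + 1L):(k * c_in)] <- dslice %*% t(x)
    dx <- dx + crossprod(wk, dslice)
  }
  list(dx = dx, dweight = dweight, dbias = rowSums(dout))
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, mask) dout * mask

# Gated linear unit over the channel dimension: the first half of the
# channels is the value path, the second half the sigmoid gate.
glu_forward <- function(x) {
  c2 <- nrow(x)
  if (c2 %% 2L != 0L) vib_abort("GLU needs an even channel count", "vib_invalid_parameter")
  h <- c2 %/% 2L
  a <- x[seq_len(h), , drop = FALSE]
  g <- sigmoid(x[(h + 1L):c2, , drop = FALSE])
  list(out = a * g, a = a, g = g)
}

glu_backward <- function(dout, cache) {
  da <- dout * cache$g
  dg <- dout * cache$a * cache$g * (1 - cache$g)
  rbind(da, dg)
}

# Layer normalization over rows (features), independently per column (time
# step), with learnable gain and bias.
layernorm_forward <- function(x, gain, bias, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2L, inv_sd, "*")
  list(out = xn * gain + bias, xn = xn, inv_sd = inv_sd)
}

layernorm_backward <- function(dout, cache, gain) {
  xn <- cache$xn
  d <- nrow(xn)
  dgain <- rowSums(dout * xn)
  dbias <- rowSums(dout)
  dxn <- dout * gain
  # per-column: dx = inv_sd * (dxn - mean(dxn) - xn * mean(dxn * xn))
  m1 <- colMeans(dxn)
  m2 <- colMeans(dxn * xn)
  dx <- sweep(dxn, 2L, m1) - sweep(xn, 2L, m2, "*")
  dx <- sweep(dx, 2L, cache$inv_sd, "*")
  list(dx = dx, dgain = dgain, dbias = dbias)
}

# Row-wise softmax with max subtraction.
softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# Kaiming-style fan-in initialization.
init_weight <- function(n_out, n_in, fan_in = n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / fan_in)), n_out, n_in)
}
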