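test_that("hand-evaluated scalar SRU step matches the recurrence equations", {
  p <- sru_cell_params(W = matrix(1), Wf = matrix(0), Wr = matrix(0),
                       vf = 0, vr = 0, bf = 0, br = 0)
  st <- sru_cell_step(1, 0, p)
  expect_equal(st$trace$f, 0.5)
  expect_equal(st$c, 0.5)
  expect_equal(st$trace$r, 0.5)
  expect_equal(st$h, 0.75)
  # zero fixed point
  z <- sru_cell_step(0, 0, p)
  expect_equal(z$h, 0)
  expect_equal(z$c, 0)
})

test_that("a saturated forget gate carries the state unchanged", {
  p <- sru_cell_params(W = matrix(1), Wf = matrix(0), Wr = matrix(0),
                       vf = 0, vr = 0, bf = 50, br = 0)
  st <- sru_cell_step(1, 0.7, p)
  expect_equal(st$trace$f, 1, tolerance = 1e-12)
  expect_equal(st$c, 0.7, tolerance = 1e-10)
})

test_that("batched layer forward equals the step-by-step oracle on 100 random instances", {
  worst <- 0
  vibdenoise:::with_seed(123, {
    for (rep in 1:100) {
      d <- sample(1:8, 1)
      len <- sample(1:32, 1)
      p <- init_sru_cell(d, d)
      X <- matrix(stats::rnorm(d * len), d, len)
      H <- sru_layer_forward(X, p)
      c_prev <- numeric(d)
      Hs <- matrix(0, d, len)
      for (t in seq_len(len)) {
        st <- sru_cell_step(X[, t], c_prev, p)
        Hs[, t] <- st$h
        c_prev <- st$c
      }
      worst <- max(worst, max(abs(H - Hs)))
      # gates bounded in (0, 1)
      expect_true(all(st$trace$f > 0 & st$trace$f < 1))
      expect_true(all(st$trace$r > 0 & st$trace$r < 1))
    }
  })
  expect_lt(worst, 1e-5)
})

test_that("length-1 sequences and all-zero parameters behave as limits", {
  p <- vibdenoise:::with_seed(4, init_sru_cell(3, 3))
  x <- c(0.3, -0.2, 0.9)
  expect_equal(drop(sru_layer_forward(matrix(x, 3, 1), p)),
               sru_cell_step(x, numeric(3), p)$h)
  pz <- sru_cell_params(matrix(0, 3, 3), matrix(0, 3, 3), matrix(0, 3, 3),
                        numeric(3), numeric(3), numeric(3), numeric(3))
  X <- matrix(stats::rnorm(9), 3, 3)
  # u = 0 everywhere -> c stays 0; h = (1 - r) * x with r = 0.5
  expect_equal(sru_layer_forward(X, pz), 0.5 * X)
  expect_error(sru_layer_forward(matrix(numeric(0), 3, 0), p),
               class = "vib_invalid_parameter")
})

test_that("SRU++ attention with alpha = 0 ignores Wk and Wv", {
  p <- vibdenoise:::with_seed(6, init_srupp_layer(8, 8, attention_dim = 2))
  X <- vibdenoise:::with_seed(7, matrix(stats::rnorm(80), 8, 10))
  U1 <- srupp_attention(X, p)$U
  p2 <- p
  p2$Wk <- matrix(stats::rnorm(4), 2, 2)
  p2$Wv <- matrix(stats::rnorm(4), 2, 2)
  expect_identical(U1, srupp_attention(X, p2)$U)
})

test_that("SRU++ attention normalizes: length-1 softmax gives A = V, rows sum to 1", {
  p <- vibdenoise:::with_seed(8, init_srupp_layer(6, 6, attention_dim = 3))
  p$alpha <- 0.5
  att1 <- srupp_attention(matrix(stats::rnorm(6), 6, 1), p)
  expect_equal(att1$trace$A, att1$trace$V)
  att <- srupp_attention(vibdenoise:::with_seed(9, matrix(stats::rnorm(60), 6, 10)), p)
  expect_equal(rowSums(att$trace$S), rep(1, 10), tolerance = 1e-6)
})

test_that("attention matches a direct loop transcription of its equations", {
  p <- vibdenoise:::with_seed(10, init_srupp_layer(5, 4, attention_dim = 2))
  p$alpha <- 0.8
  X <- vibdenoise:::with_seed(11, matrix(stats::rnorm(5 * 7), 5, 7))
  U <- srupp_attention(X, p)$U
  # explicit loops: Q = Wq X; K = Wk Q; V = Wv Q; softmax per query row;
  # residual + layer norm per time step; final projection
  dpr <- nrow(p$Wq)
  L <- ncol(X)
  Q <- matrix(0, dpr, L); K <- matrix(0, dpr, L); V <- matrix(0, dpr, L)
  for (t in 1:L) Q[, t] <- p$Wq %*% X[, t]
  for (t in 1:L) K[, t] <- p$Wk %*% Q[, t]
  for (t in 1:L) V[, t] <- p$Wv %*% Q[, t]
  A <- matrix(0, dpr, L)
  for (t in 1:L) {
    scores <- numeric(L)
    for (s in 1:L) scores[s] <- sum(Q[, t] * K[, s]) / sqrt(dpr)
    w <- exp(scores - max(scores))
    w <- w / sum(w)
    for (s in 1:L) A[, t] <- A[, t] + w[s] * V[, s]
  }
  U_ref <- matrix(0, nrow(p$Wo), L)
  for (t in 1:L) {
    z <- Q[, t] + p$alpha * A[, t]
    zn <- (z - mean(z)) / sqrt(mean((z - mean(z))^2) + 1e-5)
    U_ref[, t] <- p$Wo %*% (zn * p$ln_gain + p$ln_bias)
  }
  expect_lt(max(abs(U - U_ref)), 1e-6)
})

test_that("with alpha = 0 and a fitted output projection, SRU++ equals plain SRU", {
  d <- 4
  # layer norm maps each time step to a zero-mean vector, so its image has
  # dimension attention_dim - 1; the output projection is solvable only for
  # sequence lengths up to that
  L <- 2
  vibdenoise:::with_seed(12, {
    cell <- init_sru_cell(d, d)
    pp <- init_srupp_layer(d, d, attention_dim = 3)
    X <- matrix(stats::rnorm(d * L), d, L)
  })
  pp$alpha <- 0
  pp$vf <- cell$vf; pp$vr <- cell$vr; pp$bf <- cell$bf; pp$br <- cell$br
  # target projection rows: U_sru = rbind(W, Wf, Wr) %*% X
  B <- rbind(cell$W, cell$Wf, cell$Wr) %*% X
  Q <- pp$Wq %*% X
  ln <- vibdenoise:::layernorm_forward(Q, pp$ln_gain, pp$ln_bias)
  M <- ln$out
  P <- solve(crossprod(M) + diag(1e-12, L)) %*% t(M)  # P %*% t? right inverse
  pp$Wo <- B %*% P  # P is a left inverse of M, so Wo %*% M = B
  expect_lt(max(abs(pp$Wo %*% M - B)), 1e-6)
  expect_equal(srupp_layer_forward(X, pp), sru_layer_forward(X, cell),
               tolerance = 1e-8)
})

test_that("SRU++ layers preserve sequence length and propagate gradients when stacked", {
  p <- vibdenoise:::with_seed(13, init_srupp_layer(6, 6, attention_dim = 2))
  p$alpha <- 0.3
  for (len in c(1, 7, 64)) {
    X <- vibdenoise:::with_seed(len, matrix(stats::rnorm(6 * len), 6, len))
    expect_equal(dim(srupp_layer_forward(X, p)), c(6L, len))
  }
  # two stacked layers: gradient w.r.t. the first layer's input is nonzero
  p2 <- vibdenoise:::with_seed(14, init_srupp_layer(6, 6, attention_dim = 2))
  X <- vibdenoise:::with_seed(15, matrix(stats::rnorm(6 * 10), 6, 10))
  f1 <- vibdenoise:::srupp_layer_forward_cached(X, p)
  f2 <- vibdenoise:::srupp_layer_forward_cached(f1$H, p2)
  b2 <- vibdenoise:::srupp_layer_backward(matrix(1, 6, 10), f2$cache, p2)
  b1 <- vibdenoise:::srupp_layer_backward(b2$dX, f1$cache, p)
  expect_gt(max(abs(b1$dX)), 0)
})

test_that("attention dimension must stay below the input size", {
  expect_error(init_srupp_layer(4, 4, attention_dim = 4),
               class = "vib_configuration_error")
  p <- vibdenoise:::with_seed(16, init_srupp_layer(8, 8, attention_dim = 2))
  expect_error(srupp_attention(matrix(0, 2, 3), p),
               class = "vib_configuration_error")
})
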