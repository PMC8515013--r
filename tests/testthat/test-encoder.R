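test_that("parametric softplus matches its closed form and asymptote", {
  expect_equal(parametric_softplus(0, 1, 1), log(2), tolerance = 1e-12)
  expect_equal(parametric_softplus(2, 2, 0.5), 2 * log(1 + exp(1)),
               tolerance = 1e-12)
  # linear asymptote: relative error < 1e-6 at beta*x = 50
  x <- 50; a <- 1.3; b <- 1
  expect_lt(abs(parametric_softplus(x, a, b) - a * b * x) / (a * b * x), 1e-6)
  # overflow-safe far beyond double exp range
  expect_equal(parametric_softplus(500, 2, 2), 2000, tolerance = 1e-9)
  expect_true(all(parametric_softplus(rnorm(100)) > 0))
  expect_error(parametric_softplus(1, -1, 1), "positive")
})

test_that("a conv stage equals hand-computed valid cross-correlation", {
  # zero weights and bias give an all-zero output
  x <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  z <- conv_stage_forward(x, array(0, c(2, 1, 2, 2)), c(0, 0))
  expect_true(all(z == 0))

  # 1x1 identity kernel in eval mode is ReLU(input)
  k1 <- array(1, c(1, 1, 1, 1))
  out <- conv_stage_forward(x, k1)
  expect_equal(out[, 1, , ], pmax(x[, 1, , ], 0))

  # hand-set 2x2 kernel on a 3x3 input: direct summation oracle
  xin <- array(0, c(1, 1, 3, 3)); xin[1, 1, , ] <- matrix(1:9, 3, byrow = TRUE)
  ker <- array(0, c(1, 1, 2, 2)); ker[1, 1, , ] <- matrix(c(1, -1, 2, 0.5), 2)
  got <- conv_stage_forward(xin, ker)[1, 1, , ]
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    oracle[i, j] <- sum(xin[1, 1, i:(i + 1), j:(j + 1)] * ker[1, 1, , ])
  expect_equal(got, pmax(oracle, 0), tolerance = 1e-12)
  expect_error(conv_stage_forward(x, array(1, c(1, 1, 4, 4))), "larger")
})

# independent scalar-loop oracles for the recurrent steps
scalar_rnn <- function(h, x, W, U, b) {
  out <- numeric(length(h))
  for (i in seq_along(h)) {
    acc <- b[i]
    for (j in seq_along(x)) acc <- acc + W[i, j] * x[j]
    for (j in seq_along(h)) acc <- acc + U[i, j] * h[j]
    out[i] <- tanh(acc)
  }
  out
}
sig <- function(v) 1 / (1 + exp(-v))
lincomb <- function(W, x, U, h, b) {
  out <- numeric(nrow(W))
  for (i in seq_len(nrow(W))) {
    acc <- b[i]
    for (j in seq_along(x)) acc <- acc + W[i, j] * x[j]
    for (j in seq_along(h)) acc <- acc + U[i, j] * h[j]
    out[i] <- acc
  }
  out
}

test_that("rnn_step matches a scalar-loop oracle and its fixed points", {
  set.seed(10)
  W <- matrix(rnorm(6), 2); U <- matrix(rnorm(4), 2); b <- rnorm(2)
  h <- c(0.3, -0.2); x <- rnorm(3)
  got <- rnn_step(list(h = h), x, list(W = W, U = U, b = b))$h
  expect_equal(got, scalar_rnn(h, x, W, U, b), tolerance = 1e-12)
  expect_true(all(abs(got) < 1))
  # zero parameters give h = 0
  z <- rnn_step(list(h = h), x, list(W = 0 * W, U = 0 * U, b = 0 * b))$h
  expect_equal(z, c(0, 0))
  # W = 0, U = I: repeated tanh contraction, magnitude non-increasing
  hh <- c(0.9, -0.5)
  for (k in 1:5) {
    nh <- rnn_step(list(h = hh), x, list(W = 0 * W[, 1:3], U = diag(2),
                                         b = c(0, 0)))$h
    expect_true(all(abs(nh) <= abs(hh) + 1e-15))
    hh <- nh
  }
})

test_that("gru_step matches a scalar-loop oracle and gate limits", {
  set.seed(11)
  p <- list(Wz = matrix(rnorm(6), 2), Uz = matrix(rnorm(4), 2), bz = rnorm(2),
            Wr = matrix(rnorm(6), 2), Ur = matrix(rnorm(4), 2), br = rnorm(2),
            Wh = matrix(rnorm(6), 2), Uh = matrix(rnorm(4), 2), bh = rnorm(2))
  h <- c(0.4, -0.7); x <- rnorm(3)
  got <- gru_step(list(h = h), x, p)$h
  z <- sig(lincomb(p$Wz, x, p$Uz, h, p$bz))
  r <- sig(lincomb(p$Wr, x, p$Ur, h, p$br))
  hh <- tanh(lincomb(p$Wh, x, p$Uh, r * h, p$bh))
  expect_equal(got, (1 - z) * h + z * hh, tolerance = 1e-12)
  # zero parameters: z = r = 0.5, candidate 0, so h -> h/2
  p0 <- lapply(p, function(m) m * 0)
  expect_equal(gru_step(list(h = h), x, p0)$h, h / 2, tolerance = 1e-12)
  # large negative update-gate bias freezes the state (memory hold)
  pz <- p; pz$bz <- c(-50, -50); pz$Wz <- 0 * p$Wz; pz$Uz <- 0 * p$Uz
  expect_equal(gru_step(list(h = h), x, pz)$h, h, tolerance = 1e-8)
})

test_that("lstm_step matches a scalar-loop oracle and fixed points", {
  set.seed(12)
  p <- list(Wf = matrix(rnorm(6), 2), Uf = matrix(rnorm(4), 2), bf = rnorm(2),
            Wi = matrix(rnorm(6), 2), Ui = matrix(rnorm(4), 2), bi = rnorm(2),
            Wo = matrix(rnorm(6), 2), Uo = matrix(rnorm(4), 2), bo = rnorm(2),
            Wc = matrix(rnorm(6), 2), Uc = matrix(rnorm(4), 2), bc = rnorm(2))
  st <- list(h = c(0.2, -0.4), c = c(0.6, -0.1)); x <- rnorm(3)
  # 5 chained steps against the scalar oracle
  st_o <- st
  for (k in 1:5) {
    x_k <- rnorm(3)
    st <- lstm_step(st, x_k, p)
    f <- sig(lincomb(p$Wf, x_k, p$Uf, st_o$h, p$bf))
    i <- sig(lincomb(p$Wi, x_k, p$Ui, st_o$h, p$bi))
    o <- sig(lincomb(p$Wo, x_k, p$Uo, st_o$h, p$bo))
    ch <- tanh(lincomb(p$Wc, x_k, p$Uc, st_o$h, p$bc))
    cc <- f * st_o$c + i * ch
    st_o <- list(h = o * tanh(cc), c = cc)
    expect_equal(st$h, st_o$h, tolerance = 1e-12)
    expect_equal(st$c, st_o$c, tolerance = 1e-12)
  }
  # zero params, zero state: fixed point at 0
  p0 <- lapply(p, function(m) m * 0)
  z <- lstm_step(list(h = c(0, 0), c = c(0, 0)), x, p0)
  expect_equal(z$h, c(0, 0)); expect_equal(z$c, c(0, 0))
  # zero params, c0 = c: c1 = c/2, h1 = tanh(c/2)/2
  cval <- c(0.8, -1.2)
  z <- lstm_step(list(h = c(0, 0), c = cval), x, p0)
  expect_equal(z$c, cval / 2, tolerance = 1e-12)
  expect_equal(z$h, 0.5 * tanh(cval / 2), tolerance = 1e-12)
})

test_that("encoder forward composes the layer primitives", {
  spec <- model_spec(c(4, 6, 6), conv1 = list(n = 3, hw = 4),
                     conv2 = list(n = 2, hw = 2), n_outputs = 2,
                     noise_sigma = 0)
  m <- init_encoder(spec, seed = 1)
  clip <- generate_white_noise(23, 6, 6, seed = 2)
  ws <- make_windows(clip, 4)

  # constant head: zero dense weights, alpha = beta = 1 gives log 2
  m0 <- m
  m0$par$dense.W[] <- 0; m0$par$dense.b[] <- 0
  out <- encoder_forward(m0, ws)
  expect_equal(as.numeric(out$rates), rep(log(2), length(out$rates)),
               tolerance = 1e-12)

  # full model vs composition of conv_stage_forward + dense + softplus
  # (batchnorm disabled so the standalone stage and the model agree exactly)
  spec_nb <- model_spec(c(4, 6, 6), conv1 = list(n = 3, hw = 4),
                        conv2 = list(n = 2, hw = 2), n_outputs = 2,
                        noise_sigma = 0, batchnorm = FALSE)
  mnb <- init_encoder(spec_nb, seed = 3)
  out <- encoder_forward(mnb, ws)
  xin <- array((ws$windows - 0.5) * 2, dim(ws$windows))   # standardized
  k1 <- array(0, c(3, 4, 4, 4))
  for (k in 1:3) k1[k, , , ] <- array(mnb$par$conv1.W[k, ], c(4, 4, 4))
  a1 <- conv_stage_forward(xin, k1, mnb$par$conv1.b)
  k2 <- array(0, c(2, 3, 2, 2))
  for (k in 1:2) k2[k, , , ] <- array(mnb$par$conv2.W[k, ], c(3, 2, 2))
  a2 <- conv_stage_forward(a1, k2, mnb$par$conv2.b)
  feat <- matrix(a2, dim(a2)[1])        # n x (K*oh*ow), channel fastest
  zd <- sweep(feat %*% t(mnb$par$dense.W), 2, mnb$par$dense.b, "+")
  oracle <- parametric_softplus(zd, mnb$par$alpha, mnb$par$beta)
  expect_equal(out$rates, t(oracle), tolerance = 1e-9)

  # outputs strictly positive and finite; eval mode deterministic
  expect_true(all(out$rates > 0), all(is.finite(out$rates)))
  expect_identical(encoder_forward(m, ws)$rates, encoder_forward(m, ws)$rates)
})

test_that("a CRNN with dead recurrence reduces to the softplus of its bias", {
  spec <- model_spec(c(3, 4, 4), conv1 = list(n = 2, hw = 3),
                     conv2 = list(n = 2, hw = 2),
                     recurrent = list(unit_type = "lstm", hidden_size = 3,
                                      sequence_len = 5),
                     n_outputs = 2, noise_sigma = 0)
  m <- init_encoder(spec, seed = 4)
  for (nm in grep("^rec\\.", names(m$par), value = TRUE)) m$par[[nm]][] <- 0
  clip <- generate_white_noise(12, 4, 4, seed = 5)
  ws <- make_windows(clip, 3)   # 10 windows = 2 sequences of 5
  out <- encoder_forward(m, ws)
  expect_equal(as.numeric(out$rates),
               rep(parametric_softplus(m$par$dense.b, 1, 1),
                   times = ncol(out$rates)),
               tolerance = 1e-12)
  # too few windows for one sequence is an error
  short <- make_windows(generate_white_noise(6, 4, 4, seed = 6), 3)
  expect_error(encoder_forward(m, short), "sequence_len")
})
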