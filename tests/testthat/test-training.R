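test_that("poisson loss has the right value, minimum and gradient", {
  ones <- matrix(1, 2, 5)
  expect_equal(poisson_loss(ones, ones), 1, tolerance = 1e-12)

  # for fixed y the data term is minimized at yhat = y elementwise
  y <- matrix(c(0.5, 2, 3, 1), 2)
  at <- function(s) poisson_loss(y * s, y)
  expect_lt(at(1), at(0.8))
  expect_lt(at(1), at(1.2))
  expect_error(poisson_loss(matrix(0, 1, 2), matrix(1, 1, 2)), "positive")

  # analytic gradients vs central finite differences on a small toy model
  spec <- model_spec(c(1, 1, 1), conv1 = list(n = 1, hw = 1),
                     conv2 = list(n = 1, hw = 1), n_outputs = 1,
                     noise_sigma = 0, batchnorm = FALSE)
  m <- init_encoder(spec, seed = 2)
  # move biases off 0 so no ReLU pre-activation sits exactly at its kink
  # (finite differences are ill-defined there)
  m$par$conv1.b[] <- 0.31; m$par$conv2.b[] <- -0.12; m$par$dense.b[] <- 0.2
  set.seed(3)
  X <- matrix(rnorm(9), 9)
  Y <- matrix(rexp(9), 9)
  lg <- retinacoder:::.encoder_loss_grad(m, X, Y)
  for (nm in names(lg$grads)) {
    for (idx in seq_along(m$par[[nm]])) {
      h <- 1e-6
      mp <- m; mp$par[[nm]][idx] <- mp$par[[nm]][idx] + h
      mm <- m; mm$par[[nm]][idx] <- mm$par[[nm]][idx] - h
      fd <- (retinacoder:::.encoder_loss_grad(mp, X, Y)$loss -
               retinacoder:::.encoder_loss_grad(mm, X, Y)$loss) / (2 * h)
      expect_lt(abs(lg$grads[[nm]][idx] - fd), 1e-5)
    }
  }

  # regularization terms only ever increase the total loss
  big <- init_encoder(model_spec(c(2, 3, 3), conv1 = list(n = 2, hw = 2),
                                 conv2 = list(n = 2, hw = 2), n_outputs = 1),
                      seed = 4)
  yh <- matrix(rexp(6) + 0.1, 1)
  expect_gte(poisson_loss(yh, yh, model = big), poisson_loss(yh, yh))
})

test_that("training is a no-op at 0 epochs and reduces the loss on a toy", {
  spec <- model_spec(c(2, 3, 3), conv1 = list(n = 2, hw = 3),
                     conv2 = list(n = 2, hw = 1), n_outputs = 1,
                     noise_sigma = 0)
  m <- init_encoder(spec, seed = 5)
  clip <- generate_white_noise(101, 3, 3, seed = 6)
  ws <- make_windows(clip, 2)
  targ <- matrix(rexp(100) + 0.2, 1)

  fit0 <- suppressWarnings(train(m, ws, targ, train_config(max_epochs = 0)))
  expect_identical(fit0$model$par, m$par)

  fit <- train(m, ws, targ, train_config(max_epochs = 12, lr = 5e-3,
                                         batch_size = 100))
  expect_equal(fit$report$epochs, 12)
  # loss decreases over the first 10 epochs of full-batch training
  expect_lt(fit$report$loss_history[10], fit$report$loss_history[1])
  expect_true(all(diff(fit$report$loss_history[1:10]) < 1e-3))
})

test_that("dead first-layer kernels are detected and revived", {
  spec <- model_spec(c(2, 3, 3), conv1 = list(n = 3, hw = 3),
                     conv2 = list(n = 2, hw = 1), n_outputs = 1,
                     noise_sigma = 0)
  m <- init_encoder(spec, seed = 7)
  # kill kernel 2: zero weights and a batchnorm shift far below the ReLU
  m$par$conv1.W[2, ] <- 0
  m$par$bn1.gamma[2] <- 0
  m$par$bn1.beta[2] <- -5
  clip <- generate_white_noise(201, 3, 3, seed = 8)
  ws <- make_windows(clip, 2)
  targ <- matrix(rexp(200) + 0.2, 1)
  expect_message(
    fit <- train(m, ws, targ, train_config(max_epochs = 10, lr = 1e-3,
                                           batch_size = 200,
                                           revive_dead = TRUE, verbose = 1)),
    "revived dead kernel")
  expect_gt(sum(abs(fit$model$par$conv1.W[2, ])), 0)
  # without revival the kernel stays dead
  fit0 <- train(m, ws, targ, train_config(max_epochs = 10, lr = 1e-3,
                                          batch_size = 200))
  expect_equal(fit0$model$par$bn1.gamma[2], 0, tolerance = 1e-6)
})

test_that("correlation metrics match hand computation and edge rules", {
  # hand Pearson: r = 11 / sqrt(5 * 26)
  expect_equal(cc_per_cell(matrix(1:4, 1), matrix(c(2, 4, 5, 9), 1)),
               11 / sqrt(130), tolerance = 1e-12)
  x <- matrix(rexp(20), 2)
  expect_equal(cc_per_cell(x, x), c(1, 1), tolerance = 1e-12)
  expect_equal(cc_per_cell(-x + 3, x), c(-1, -1), tolerance = 1e-12)
  # invariance to positive affine rescaling
  expect_equal(cc_per_cell(2.5 * x + 1, x), c(1, 1), tolerance = 1e-12)
  expect_warning(got <- cc_per_cell(matrix(1, 1, 4), matrix(1:4, 1)),
                 "constant")
  expect_equal(got, 0)

  # population CC: single cell reduces to cc_per_cell; two-cell hand oracle
  expect_equal(population_cc(x[1, , drop = FALSE], 2 * x[1, , drop = FALSE]),
               cc_per_cell(x[1, , drop = FALSE], 2 * x[1, , drop = FALSE]))
  y <- matrix(rexp(20), 2)
  expect_equal(population_cc(x, y), cor(colMeans(x), colMeans(y)),
               tolerance = 1e-12)
  expect_error(cc_per_cell(x, y[, 1:5]), "mismatch")
})

test_that("spike binning counts, averages and drops out-of-range times", {
  z <- bin_spikes(list(numeric(0)), 33, 4)
  expect_equal(z$rates, matrix(0, 1, 4))
  one <- bin_spikes(list(c(10, 40)), 33, 4)
  expect_equal(one$rates, matrix(c(1, 1, 0, 0), 1))
  # k identical trials average to the single-trial rate
  rep5 <- bin_spikes(list(rep(list(c(10, 40, 100)), 5)[[1]],
                          c(10, 40, 100), c(10, 40, 100)), 33, 4)
  expect_equal(rep5$rates, bin_spikes(list(c(10, 40, 100)), 33, 4)$rates)
  expect_message(oob <- bin_spikes(list(c(10, 500)), 33, 4), "dropped")
  expect_equal(sum(oob$rates), 1)
})
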