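# CNN / CRNN encoding models.
#
# Layout conventions (column-major throughout):
#  - a batch of stimulus windows is a matrix n x (C*H*W), columns ordered
#    (channel, row, col) with channel fastest; for the first layer the
#    window's temporal frames are the channels (oldest frame first), which
#    makes every first-layer kernel genuinely spatiotemporal.
#  - inside a layer, activations are (n*P) x K matrices (P = spatial
#    positions, K = kernels), rows ordered (sample, position) with sample
#    fastest; batch normalization acts per column (= per channel).

BN_EPS <- 1e-5

#' Architecture specification for an encoder
#'
#' @param input_shape integer triple (depth, height, width) of one stimulus
#'   window; the first conv layer's kernels span the full temporal depth.
#' @param conv1 list \code{(n, hw)}: kernel count and square spatial size of
#'   the first (spatiotemporal) convolutional layer.
#' @param conv2 list \code{(n, hw)}: kernel count and spatial size of the
#'   second (spatial) convolutional layer.
#' @param recurrent \code{NULL} for the CNN, or list
#'   \code{(unit_type, hidden_size, sequence_len)} with unit_type one of
#'   \code{"rnn"}, \code{"gru"}, \code{"lstm"} for the CRNN.
#' @param n_outputs number of model cells (dense-layer neurons).
#' @param noise_sigma std of Gaussian noise injected after batch
#'   normalization during training (0 disables).
#' @param reg list \code{(l2, l1_conv1, l1_activity)} of penalty weights.
#' @param readout \code{"per_bin"} (one rate per bin from each hidden state)
#'   or \code{"flat"} (the whole hidden-state sequence is flattened into a
#'   single readout per sequence); CRNN only.
#' @param batchnorm logical; disable only for pedagogical toy models.
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(input_shape,
                       conv1 = list(n = 8L, hw = 8L),
                       conv2 = list(n = 8L, hw = 1L),
                       recurrent = NULL,
                       n_outputs = 2L,
                       noise_sigma = 0.1,
                       reg = list(l2 = 1e-3, l1_conv1 = 5e-4,
                                  l1_activity = 1e-3),
                       readout = c("per_bin", "flat"),
                       batchnorm = TRUE) {
  readout <- match.arg(readout)
  d <- as.integer(input_shape)
  if (length(d) != 3L || any(d < 1L)) stop_bad_arg("bad input_shape")
  o1 <- d[2:3] - conv1$hw + 1L
  if (any(o1 < 1L)) stop_bad_arg("conv1 kernel larger than input")
  o2 <- o1 - conv2$hw + 1L
  if (any(o2 < 1L)) stop_bad_arg("conv2 kernel larger than conv1 output")
  if (!is.null(recurrent)) {
    recurrent$unit_type <- match.arg(recurrent$unit_type,
                                     c("lstm", "gru", "rnn"))
    recurrent$hidden_size <- as.integer(recurrent$hidden_size %||% 32L)
    recurrent$sequence_len <- as.integer(recurrent$sequence_len %||% 64L)
    if (recurrent$hidden_size < 1L) stop_bad_arg("hidden_size must be >= 1")
  }
  structure(list(
    input_shape = d, conv1 = conv1, conv2 = conv2, recurrent = recurrent,
    n_outputs = as.integer(n_outputs), noise_sigma = noise_sigma, reg = reg,
    readout = readout, batchnorm = isTRUE(batchnorm),
    oh1 = o1[1], ow1 = o1[2], P1 = prod(o1),
    oh2 = o2[1], ow2 = o2[2], P2 = prod(o2),
    n_features = conv2$n * prod(o2)), class = "model_spec")
}

#' Initialize an encoder with random weights
#'
#' Gaussian fan-in scaled weights, unit batchnorm gains, softplus
#' parameters alpha = beta = 1.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param seed integer seed for the weight draw.
#' @return object of class \code{encoder_model} with fields \code{spec},
#'   \code{par} (named list of arrays) and \code{mask} (first-layer kernel
#'   mask used by pruning, all ones initially).
#' @export
init_encoder <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  d <- spec$input_shape
  k1 <- spec$conv1; k2 <- spec$conv2
  fan1 <- d[1] * k1$hw^2
  fan2 <- k1$n * k2$hw^2
  par <- list(
    conv1.W = matrix(stats::rnorm(k1$n * fan1, sd = 1 / sqrt(fan1)),
                     k1$n, fan1, byrow = TRUE),
    conv1.b = numeric(k1$n),
    conv2.W = matrix(stats::rnorm(k2$n * fan2, sd = 1 / sqrt(fan2)),
                     k2$n, fan2, byrow = TRUE),
    conv2.b = numeric(k2$n))
  if (spec$batchnorm) {
    par$bn1.gamma <- rep(1, k1$n); par$bn1.beta <- numeric(k1$n)
    par$bn2.gamma <- rep(1, k2$n); par$bn2.beta <- numeric(k2$n)
  }
  feat <- spec$n_features
  if (!is.null(spec$recurrent)) {
    H <- spec$recurrent$hidden_size
    gates <- switch(spec$recurrent$unit_type,
                    rnn = "", gru = c("z", "r", "h"),
                    lstm = c("f", "i", "o", "c"))
    for (g in gates) {
      par[[paste0("rec.W", g)]] <-
        matrix(stats::rnorm(H * feat, sd = 1 / sqrt(feat)), H, feat)
      par[[paste0("rec.U", g)]] <-
        matrix(stats::rnorm(H * H, sd = 1 / sqrt(H)), H, H)
      par[[paste0("rec.b", g)]] <- numeric(H)
    }
    din <- if (spec$readout == "per_bin") H else H * spec$recurrent$sequence_len
  } else {
    din <- feat
  }
  par$dense.W <- matrix(stats::rnorm(spec$n_outputs * din,
                                     sd = 0.1 / sqrt(din)),
                        spec$n_outputs, din)
  par$dense.b <- numeric(spec$n_outputs)
  par$alpha <- 1; par$beta <- 1
  bn_stats <- if (spec$batchnorm)
    list(bn1.rm = numeric(k1$n), bn1.rv = rep(1, k1$n),
         bn2.rm = numeric(k2$n), bn2.rv = rep(1, k2$n)) else list()
  structure(list(spec = spec, par = par, bn_stats = bn_stats,
                 mask = rep(1, k1$n)),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  s <- x$spec
  arch <- if (is.null(s$recurrent)) "CNN"
          else sprintf("CRNN/%s(h=%d,L=%d)", s$recurrent$unit_type,
                       s$recurrent$hidden_size, s$recurrent$sequence_len)
  cat(sprintf("<encoder_model> %s: in %s, conv1 %dx%d^2, conv2 %dx%d^2, %d cells\n",
              arch, paste(s$input_shape, collapse = "x"),
              s$conv1$n, s$conv1$hw, s$conv2$n, s$conv2$hw, s$n_outputs))
  invisible(x)
}

# ---- im2col / col2im -------------------------------------------------------

# X: n x (C*H*W) matrix, columns (c,y,x) with c fastest.
# Returns (n*P) x (C*kh*kw), rows (i, oy, ox) sample-fastest,
# columns (c, dy, dx) with c fastest.
.im2col <- function(X, C, H, W, kh, kw) {
  n <- nrow(X)
  oh <- H - kh + 1L; ow <- W - kw + 1L
  if (kh == H && kw == W) return(X)       # full-field kernel: identity layout
  A <- array(X, c(n, C, H, W))
  M <- matrix(0, n * oh * ow, C * kh * kw)
  for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    sub <- A[, , dy:(dy + oh - 1L), dx:(dx + ow - 1L), drop = FALSE]
    # rows (i, oy, ox), columns c
    block <- matrix(aperm(sub, c(1, 3, 4, 2)), n * oh * ow, C)
    cols <- (((dx - 1L) * kh + (dy - 1L)) * C) + seq_len(C)
    M[, cols] <- block
  }
  M
}

# adjoint of .im2col: scatter-add dM back to dX (n x C*H*W)
.col2im <- function(dM, n, C, H, W, kh, kw) {
  oh <- H - kh + 1L; ow <- W - kw + 1L
  if (kh == H && kw == W) return(dM)
  dA <- array(0, c(n, C, H, W))
  for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    cols <- (((dx - 1L) * kh + (dy - 1L)) * C) + seq_len(C)
    block <- array(dM[, cols], c(n, oh, ow, C))
    dA[, , dy:(dy + oh - 1L), dx:(dx + ow - 1L)] <-
      dA[, , dy:(dy + oh - 1L), dx:(dx + ow - 1L), drop = FALSE] +
      aperm(block, c(1, 4, 2, 3))
  }
  matrix(dA, n, C * H * W)
}

# (n*P) x K layer output -> n x (K*oh*ow) input matrix for the next layer
.to_channel_major <- function(Y, n, oh, ow) {
  K <- ncol(Y)
  A <- array(Y, c(n, oh, ow, K))
  matrix(aperm(A, c(1, 4, 2, 3)), n, K * oh * ow)
}

.from_channel_major <- function(dX, n, K, oh, ow) {
  A <- array(dX, c(n, K, oh, ow))
  matrix(aperm(A, c(1, 3, 4, 2)), n * oh * ow, K)
}

# ---- elementary nonlinearities --------------------------------------------

#' Parametric softplus
#'
#' Elementwise \code{alpha * log(1 + exp(beta * x))}, overflow-safe (exact
#' linear asymptote for large \code{beta * x}).
#'
#' @param x numeric array.
#' @param alpha,beta positive scalars.
#' @return array of the same shape, strictly positive.
#' @export
parametric_softplus <- function(x, alpha = 1, beta = 1) {
  if (alpha <= 0 || beta <= 0) stop_bad_arg("alpha and beta must be positive")
  bx <- beta * x
  alpha * ifelse(bx > 30, bx + log1p(exp(-bx)), log1p(exp(bx)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- recurrent steps (single-state reference API) -------------------------

#' One vanilla-RNN step
#'
#' \code{h_t = tanh(W x + U h + b)}.
#'
#' @param state list with field \code{h} (hidden vector).
#' @param input input vector.
#' @param params list with \code{W} (H x F), \code{U} (H x H), \code{b} (H).
#' @return updated state list.
#' @export
rnn_step <- function(state, input, params) {
  h <- tanh(as.numeric(params$W %*% input + params$U %*% state$h + params$b))
  list(h = h)
}

#' One GRU step
#'
#' Update gate \code{z}, reset gate \code{r}, candidate \code{hhat}:
#' \code{h_t = (1-z) h + z * hhat}.
#'
#' @param state list with field \code{h}.
#' @param input input vector.
#' @param params list with \code{Wz,Uz,bz,Wr,Ur,br,Wh,Uh,bh}.
#' @return updated state list.
#' @export
gru_step <- function(state, input, params) {
  p <- params; h <- state$h
  z <- .sigmoid(as.numeric(p$Wz %*% input + p$Uz %*% h + p$bz))
  r <- .sigmoid(as.numeric(p$Wr %*% input + p$Ur %*% h + p$br))
  hh <- tanh(as.numeric(p$Wh %*% input + p$Uh %*% (r * h) + p$bh))
  list(h = (1 - z) * h + z * hh)
}

#' One LSTM step
#'
#' Forget/input/output gates and candidate cell:
#' \code{c_t = f*c + i*chat; h_t = o*tanh(c_t)}.
#'
#' @param state list with fields \code{h} and \code{c}.
#' @param input input vector.
#' @param params list with \code{Wf,Uf,bf,Wi,Ui,bi,Wo,Uo,bo,Wc,Uc,bc}.
#' @return updated state list.
#' @export
lstm_step <- function(state, input, params) {
  p <- params; h <- state$h; c0 <- state$c
  f <- .sigmoid(as.numeric(p$Wf %*% input + p$Uf %*% h + p$bf))
  i <- .sigmoid(as.numeric(p$Wi %*% input + p$Ui %*% h + p$bi))
  o <- .sigmoid(as.numeric(p$Wo %*% input + p$Uo %*% h + p$bo))
  ch <- tanh(as.numeric(p$Wc %*% input + p$Uc %*% h + p$bc))
  cc <- f * c0 + i * ch
  list(h = o * tanh(cc), c = cc)
}

# ---- standalone conv stage (reference API) --------------------------------

#' One convolutional stage: valid convolution, batchnorm, noise, ReLU
#'
#' Computes \code{ReLU(batchnorm(conv(input) + bias) + noise)} with valid
#' (no padding) cross-correlation at stride 1. Batchnorm here uses the
#' batch statistics of \code{input} itself; noise is injected only in
#' train mode.
#'
#' @param input n x C x H x W array.
#' @param kernels K x C x kh x kw array.
#' @param bias length-K vector.
#' @param batchnorm apply per-channel batch normalization.
#' @param train_mode inject Gaussian noise of sd \code{noise_sigma}.
#' @param noise_sigma noise std.
#' @return n x K x oh x ow array, elementwise nonnegative.
#' @export
conv_stage_forward <- function(input, kernels, bias = NULL, batchnorm = FALSE,
                               train_mode = FALSE, noise_sigma = 0) {
  di <- dim(input); dk <- dim(kernels)
  if (length(di) != 4L || length(dk) != 4L || di[2] != dk[2])
    stop_bad_arg("input must be n x C x H x W and kernels K x C x kh x kw")
  n <- di[1]; C <- di[2]; H <- di[3]; W <- di[4]
  K <- dk[1]; kh <- dk[3]; kw <- dk[4]
  if (kh > H || kw > W) stop_bad_arg("kernel larger than input")
  oh <- H - kh + 1L; ow <- W - kw + 1L
  X <- matrix(aperm(input, c(1, 2, 3, 4)), n, C * H * W)
  M <- .im2col(X, C, H, W, kh, kw)
  Wmat <- matrix(aperm(kernels, c(1, 2, 3, 4)), K, C * kh * kw)
  Z <- M %*% t(Wmat)
  if (!is.null(bias)) Z <- sweep(Z, 2, bias, "+")
  if (batchnorm) {
    mu <- colMeans(Z)
    v <- colMeans(sweep(Z, 2, mu)^2)
    Z <- sweep(sweep(Z, 2, mu), 2, sqrt(v + BN_EPS), "/")
  }
  if (train_mode && noise_sigma > 0)
    Z <- Z + stats::rnorm(length(Z), sd = noise_sigma)
  A <- pmax(Z, 0)
  aperm(array(A, c(n, oh, ow, K)), c(1, 4, 2, 3))
}
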