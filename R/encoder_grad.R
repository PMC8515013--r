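# Forward pass with caching, analytic backprop (including BPTT for the
# recurrent layer) and the Poisson training objective. All gradients are
# exact; they are validated against central finite differences in the
# test suite.

# standardize [0,1] pixel windows to +-1 drive and flatten to n x (d*h*w)
.windows_to_matrix <- function(windows) {
  w <- if (inherits(windows, "window_set")) windows$windows else windows
  n <- dim(w)[1]
  matrix((w - 0.5) * 2, nrow = n)
}

.stable_softplus <- function(bx) ifelse(bx > 30, bx + log1p(exp(-bx)),
                                        log1p(exp(bx)))

# core forward. mode: "train" = batch stats + optional noise,
# "eval" = running bn stats, no noise. Returns list(yhat, cache).
# X is either a n x (d*h*w) window matrix, or list(Xt = <(d*h*w) x n>)
# (transposed storage; column gathers are much cheaper than row gathers,
# so the training loop uses this form).
.encoder_forward_core <- function(model, X, mode = "eval",
                                  noise = TRUE, keep_cache = FALSE) {
  s <- model$spec; p <- model$par
  d <- s$input_shape
  full_field <- s$P1 == 1L           # conv1 kernel covers the whole frame
  Xt <- NULL
  if (is.list(X)) {
    if (full_field) Xt <- X$Xt else X <- t(X$Xt)
  }
  n <- if (is.null(Xt)) nrow(X) else ncol(Xt)
  train <- identical(mode, "train")
  cache <- list()

  conv_block <- function(Z, b, bnp, layer) {
    Z <- sweep(Z, 2, b, "+")
    if (s$batchnorm) {
      if (train) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
      } else {
        mu <- model$bn_stats[[paste0(layer, ".rm")]]
        v <- model$bn_stats[[paste0(layer, ".rv")]]
      }
      istd <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(sweep(Z, 2, mu), 2, istd, "*")
      Y <- sweep(sweep(xhat, 2, p[[paste0(layer, ".gamma")]], "*"),
                 2, p[[paste0(layer, ".beta")]], "+")
    } else {
      xhat <- NULL; istd <- NULL; mu <- NULL; v <- NULL
      Y <- Z
    }
    if (train && noise && s$noise_sigma > 0)
      Y <- Y + stats::rnorm(length(Y), sd = s$noise_sigma)
    A <- pmax(Y, 0)
    list(A = A, Y = Y, xhat = xhat, istd = istd, mu = mu, v = v)
  }

  if (is.null(Xt)) {
    M1 <- .im2col(X, d[1], d[2], d[3], s$conv1$hw, s$conv1$hw)
    Z1 <- M1 %*% t(p$conv1.W)
  } else {
    M1 <- NULL
    Z1 <- crossprod(Xt, t(p$conv1.W))
  }
  b1 <- conv_block(Z1, p$conv1.b, NULL, "bn1")
  A1 <- sweep(b1$A, 2, model$mask, "*")
  Am1 <- .to_channel_major(A1, n, s$oh1, s$ow1)
  M2 <- .im2col(Am1, s$conv1$n, s$oh1, s$ow1, s$conv2$hw, s$conv2$hw)
  b2 <- conv_block(M2 %*% t(p$conv2.W), p$conv2.b, NULL, "bn2")
  Feat <- .to_channel_major(b2$A, n, s$oh2, s$ow2)

  rec_cache <- NULL
  if (is.null(s$recurrent)) {
    Zd <- sweep(Feat %*% t(p$dense.W), 2, p$dense.b, "+")
    Din <- Feat
  } else {
    L <- s$recurrent$sequence_len
    if (n %% L != 0L || n < L)
      stop_bad_arg("window count must be a positive multiple of sequence_len")
    nseq <- n %/% L
    Hd <- s$recurrent$hidden_size
    idx <- function(t) t + L * (0:(nseq - 1L))
    rc <- .recurrent_forward(s$recurrent$unit_type, p, Feat, idx, L, nseq, Hd)
    if (s$readout == "per_bin") {
      Zd <- matrix(0, n, s$n_outputs)
      for (t in seq_len(L))
        Zd[idx(t), ] <- sweep(rc$H[[t]] %*% t(p$dense.W), 2, p$dense.b, "+")
      Din <- NULL
    } else {
      Hcat <- do.call(cbind, rc$H)             # nseq x (Hd*L), t-major blocks
      Zd <- sweep(Hcat %*% t(p$dense.W), 2, p$dense.b, "+")
      Din <- Hcat
    }
    rec_cache <- c(rc, list(L = L, nseq = nseq, idx = idx))
  }
  Svec <- .stable_softplus(p$beta * Zd)
  yhat <- p$alpha * Svec
  if (keep_cache)
    cache <- list(M1 = M1, Xt = Xt, b1 = b1, A1 = A1, M2 = M2, b2 = b2,
                  Feat = Feat, Zd = Zd, S = Svec, Din = Din, rec = rec_cache,
                  n = n)
  list(yhat = yhat, cache = cache)
}

# gate order per unit type (suffixes of rec.W*/rec.U*/rec.b*)
.gate_names <- function(type)
  switch(type, lstm = c("f", "i", "o", "c"), gru = c("z", "r", "h"),
         rnn = "")

# fused input projection: all gates for all windows in two big matmuls
.rec_fused <- function(type, p) {
  gn <- .gate_names(type)
  list(W = do.call(rbind, lapply(gn, function(g) p[[paste0("rec.W", g)]])),
       U = do.call(rbind, lapply(gn, function(g) p[[paste0("rec.U", g)]])),
       b = unlist(lapply(gn, function(g) p[[paste0("rec.b", g)]])),
       gn = gn)
}

.recurrent_forward <- function(type, p, Feat, idx, L, nseq, Hd) {
  fz <- .rec_fused(type, p)
  XW <- sweep(Feat %*% t(fz$W), 2, fz$b, "+")   # n x (n_gates*Hd)
  H <- vector("list", L)
  hp <- matrix(0, nseq, Hd)
  g1 <- seq_len(Hd)
  if (type == "lstm") {
    Fg <- Ig <- Og <- Cg <- Cs <- vector("list", L)
    cp <- matrix(0, nseq, Hd)
    Ut <- t(fz$U)
    for (t in seq_len(L)) {
      G <- XW[idx(t), , drop = FALSE] + hp %*% Ut
      f <- .sigmoid(G[, g1, drop = FALSE])
      i <- .sigmoid(G[, g1 + Hd, drop = FALSE])
      o <- .sigmoid(G[, g1 + 2L * Hd, drop = FALSE])
      ch <- tanh(G[, g1 + 3L * Hd, drop = FALSE])
      cs <- f * cp + i * ch
      hp <- o * tanh(cs)
      Fg[[t]] <- f; Ig[[t]] <- i; Og[[t]] <- o; Cg[[t]] <- ch; Cs[[t]] <- cs
      H[[t]] <- hp
      cp <- cs
    }
    list(H = H, Fg = Fg, Ig = Ig, Og = Og, Cg = Cg, Cs = Cs)
  } else if (type == "gru") {
    Zg <- Rg <- Hh <- vector("list", L)
    Uzr_t <- t(fz$U[seq_len(2L * Hd), , drop = FALSE])
    Uh_t <- t(p$rec.Uh)
    for (t in seq_len(L)) {
      Gzr <- XW[idx(t), seq_len(2L * Hd), drop = FALSE] + hp %*% Uzr_t
      z <- .sigmoid(Gzr[, g1, drop = FALSE])
      r <- .sigmoid(Gzr[, g1 + Hd, drop = FALSE])
      hh <- tanh(XW[idx(t), g1 + 2L * Hd, drop = FALSE] + (r * hp) %*% Uh_t)
      hp <- (1 - z) * hp + z * hh
      Zg[[t]] <- z; Rg[[t]] <- r; Hh[[t]] <- hh
      H[[t]] <- hp
    }
    list(H = H, Zg = Zg, Rg = Rg, Hh = Hh)
  } else {
    Ut <- t(fz$U)
    for (t in seq_len(L)) {
      hp <- tanh(XW[idx(t), , drop = FALSE] + hp %*% Ut)
      H[[t]] <- hp
    }
    list(H = H)
  }
}

#' Run an encoder on a set of stimulus windows
#'
#' Evaluation mode is fully deterministic (running batchnorm statistics,
#' no noise injection); train mode uses batch statistics and injects
#' Gaussian noise after batch normalization.
#'
#' @param model an \code{\link{encoder_model}}.
#' @param windows a \code{\link{make_windows}} result (or bare 4-D array).
#'   For a CRNN the window count must be a multiple of the sequence length.
#' @param train_mode logical.
#' @return a \code{rate_matrix} (n_cells x n_bins, strictly positive).
#' @export
encoder_forward <- function(model, windows, train_mode = FALSE) {
  stopifnot(inherits(model, "encoder_model"))
  X <- .windows_to_matrix(windows)
  exp_cols <- prod(model$spec$input_shape)
  if (ncol(X) != exp_cols)
    stop_bad_arg("window shape does not match model input_shape")
  out <- .encoder_forward_core(model, X,
                               mode = if (train_mode) "train" else "eval")
  al <- if (inherits(windows, "window_set")) windows$alignment else NULL
  bin_ms <- if (inherits(windows, "window_set")) windows$bin_ms else NA_real_
  if (!is.null(model$spec$recurrent) && model$spec$readout == "flat")
    al <- NULL   # one output per sequence, not per bin
  structure(list(rates = t(out$yhat), bin_ms = bin_ms, alignment = al),
            class = "rate_matrix")
}

# ---- loss & gradients ------------------------------------------------------

.weight_par_names <- function(par)
  grep("\\.(W|U)[a-z]?$", names(par), value = TRUE)

# full objective and exact gradients for one batch.
# X: standardized window matrix; Y: n x n_cells target matrix.
.encoder_loss_grad <- function(model, X, Y, reg = NULL, noise = TRUE) {
  s <- model$spec; p <- model$par
  reg <- reg %||% s$reg
  fw <- .encoder_forward_core(model, X, mode = "train", noise = noise,
                              keep_cache = TRUE)
  yhat <- fw$yhat; ch <- fw$cache
  if (!is.null(s$recurrent) && s$readout == "flat") {
    L <- s$recurrent$sequence_len
    Y <- Y[seq(L, nrow(Y), by = L), , drop = FALSE]  # target = sequence end
  }
  Nel <- length(yhat)
  data_loss <- mean(yhat - Y * log(pmax(yhat, 1e-300)))
  pen <- reg$l1_activity * mean(yhat)
  wn <- .weight_par_names(p)
  for (nm in wn) pen <- pen + reg$l2 * sum(p[[nm]]^2)
  pen <- pen + reg$l1_conv1 * sum(abs(p$conv1.W))
  loss <- data_loss + pen

  g <- vector("list", length(p)); names(g) <- names(p)

  dy <- (1 - Y / pmax(yhat, 1e-300)) / Nel + reg$l1_activity / Nel
  sig <- .sigmoid(p$beta * ch$Zd)
  dZd <- dy * (p$alpha * p$beta * sig)
  g$alpha <- sum(dy * ch$S)
  g$beta <- sum(dy * p$alpha * ch$Zd * sig)

  n <- ch$n
  if (is.null(s$recurrent)) {
    g$dense.W <- t(dZd) %*% ch$Feat
    g$dense.b <- colSums(dZd)
    dFeat <- dZd %*% p$dense.W
  } else {
    rc <- ch$rec; L <- rc$L; nseq <- rc$nseq; idx <- rc$idx
    Hd <- s$recurrent$hidden_size
    g$dense.b <- colSums(dZd)
    dH <- vector("list", L)
    if (s$readout == "per_bin") {
      g$dense.W <- matrix(0, nrow(p$dense.W), ncol(p$dense.W))
      for (t in seq_len(L)) {
        dZt <- dZd[idx(t), , drop = FALSE]
        g$dense.W <- g$dense.W + t(dZt) %*% rc$H[[t]]
        dH[[t]] <- dZt %*% p$dense.W
      }
    } else {
      g$dense.W <- t(dZd) %*% ch$Din
      dHcat <- dZd %*% p$dense.W
      for (t in seq_len(L))
        dH[[t]] <- dHcat[, (t - 1L) * Hd + seq_len(Hd), drop = FALSE]
    }
    bp <- .recurrent_backward(s$recurrent$unit_type, p, ch$Feat, rc, dH,
                              idx, L, nseq, Hd)
    for (nm in names(bp$g)) g[[nm]] <- bp$g[[nm]]
    dFeat <- bp$dFeat
  }

  # conv2 backward
  dA2 <- .from_channel_major(dFeat, n, s$conv2$n, s$oh2, s$ow2)
  dZ2 <- .conv_block_backward(dA2, ch$b2, p, g, "bn2", s$batchnorm)
  g <- dZ2$g
  g$conv2.W <- crossprod(dZ2$dZ, ch$M2)
  g$conv2.b <- colSums(dZ2$dZ)
  dM2 <- dZ2$dZ %*% p$conv2.W
  dAm1 <- .col2im(dM2, n, s$conv1$n, s$oh1, s$ow1, s$conv2$hw, s$conv2$hw)
  dA1 <- .from_channel_major(dAm1, n, s$conv1$n, s$oh1, s$ow1)
  dA1 <- sweep(dA1, 2, model$mask, "*")
  dZ1 <- .conv_block_backward(dA1, ch$b1, p, g, "bn1", s$batchnorm)
  g <- dZ1$g
  g$conv1.W <- if (is.null(ch$M1)) t(ch$Xt %*% dZ1$dZ)
               else crossprod(dZ1$dZ, ch$M1)
  g$conv1.b <- colSums(dZ1$dZ)

  # regularization gradients
  for (nm in wn) g[[nm]] <- g[[nm]] + 2 * reg$l2 * p[[nm]]
  g$conv1.W <- g$conv1.W + reg$l1_conv1 * sign(p$conv1.W)

  list(loss = loss, data_loss = data_loss, grads = g, yhat = yhat,
       act1 = colMeans(ch$A1),      # per-kernel mean activation (dead-unit
                                    # monitoring in the training loop)
       bn = list(bn1.mu = ch$b1$mu, bn1.v = ch$b1$v,
                 bn2.mu = ch$b2$mu, bn2.v = ch$b2$v))
}

# relu + batchnorm backward for one conv block; returns dZ and grad list
.conv_block_backward <- function(dA, blk, p, g, layer, batchnorm) {
  dY <- dA * (blk$Y > 0)
  if (batchnorm) {
    gamma <- p[[paste0(layer, ".gamma")]]
    m <- nrow(dY)
    g[[paste0(layer, ".gamma")]] <- colSums(dY * blk$xhat)
    g[[paste0(layer, ".beta")]] <- colSums(dY)
    dxhat <- sweep(dY, 2, gamma, "*")
    s1 <- colSums(dxhat) / m
    s2 <- colSums(dxhat * blk$xhat) / m
    dZ <- sweep(sweep(dxhat, 2, s1) - sweep(blk$xhat, 2, s2, "*"),
                2, blk$istd, "*")
  } else {
    dZ <- dY
  }
  list(dZ = dZ, g = g)
}

.recurrent_backward <- function(type, p, Feat, rc, dH, idx, L, nseq, Hd) {
  fz <- .rec_fused(type, p)
  nG <- length(fz$gn)
  zero <- matrix(0, nseq, Hd)
  H_at <- function(t) if (t >= 1L) rc$H[[t]] else zero
  dG <- matrix(0, nrow(Feat), nG * Hd)   # gate pre-activation grads, all bins
  dU <- matrix(0, nG * Hd, Hd)
  g1 <- seq_len(Hd)
  if (type == "lstm") {
    dc <- zero; dh <- zero
    C_at <- function(t) if (t >= 1L) rc$Cs[[t]] else zero
    for (t in rev(seq_len(L))) {
      dh <- dh + dH[[t]]
      tc <- tanh(rc$Cs[[t]])
      do <- dh * tc
      dc <- dc + dh * rc$Og[[t]] * (1 - tc^2)
      dgf <- (dc * C_at(t - 1L)) * rc$Fg[[t]] * (1 - rc$Fg[[t]])
      dgi <- (dc * rc$Cg[[t]]) * rc$Ig[[t]] * (1 - rc$Ig[[t]])
      dgo <- do * rc$Og[[t]] * (1 - rc$Og[[t]])
      dgc <- (dc * rc$Ig[[t]]) * (1 - rc$Cg[[t]]^2)
      dGt <- cbind(dgf, dgi, dgo, dgc)
      dG[idx(t), ] <- dGt
      dU <- dU + crossprod(dGt, H_at(t - 1L))
      dh <- dGt %*% fz$U
      dc <- dc * rc$Fg[[t]]
    }
  } else if (type == "gru") {
    dh <- zero
    Uzr <- fz$U[seq_len(2L * Hd), , drop = FALSE]
    for (t in rev(seq_len(L))) {
      dh <- dh + dH[[t]]
      Hp <- H_at(t - 1L)
      z <- rc$Zg[[t]]; r <- rc$Rg[[t]]; hh <- rc$Hh[[t]]
      dgh <- (dh * z) * (1 - hh^2)
      drh <- dgh %*% p$rec.Uh            # grad wrt (r * h_prev)
      dgz <- (dh * (hh - Hp)) * z * (1 - z)
      dgr <- (drh * Hp) * r * (1 - r)
      dGt <- cbind(dgz, dgr, dgh)
      dG[idx(t), ] <- dGt
      dU[seq_len(2L * Hd), ] <- dU[seq_len(2L * Hd), ] +
        crossprod(cbind(dgz, dgr), Hp)
      dU[2L * Hd + g1, ] <- dU[2L * Hd + g1, ] + crossprod(dgh, r * Hp)
      dh <- dh * (1 - z) + drh * r + cbind(dgz, dgr) %*% Uzr
    }
  } else {
    dh <- zero
    for (t in rev(seq_len(L))) {
      dh <- dh + dH[[t]]
      dGt <- dh * (1 - rc$H[[t]]^2)
      dG[idx(t), ] <- dGt
      dU <- dU + crossprod(dGt, H_at(t - 1L))
      dh <- dGt %*% fz$U
    }
  }
  dW <- crossprod(dG, Feat)
  db <- colSums(dG)
  dFeat <- dG %*% fz$W
  g <- list()
  for (k in seq_len(nG)) {
    rows <- (k - 1L) * Hd + g1
    g[[paste0("rec.W", fz$gn[k])]] <- dW[rows, , drop = FALSE]
    g[[paste0("rec.U", fz$gn[k])]] <- dU[rows, , drop = FALSE]
    g[[paste0("rec.b", fz$gn[k])]] <- db[rows]
  }
  list(g = g, dFeat = dFeat)
}

# set running batchnorm statistics to the exact statistics of a dataset,
# so that eval mode reproduces the converged train-mode behaviour.
.finalize_batchnorm <- function(model, X) {
  if (!model$spec$batchnorm) return(model)
  fw <- .encoder_forward_core(model, X, mode = "train", noise = FALSE,
                              keep_cache = TRUE)
  model$bn_stats$bn1.rm <- fw$cache$b1$mu
  model$bn_stats$bn1.rv <- fw$cache$b1$v
  # second layer statistics must be recomputed with layer-1 in eval mode
  fw2 <- .encoder_forward_core(model, X, mode = "eval", noise = FALSE,
                               keep_cache = TRUE)
  # eval mode uses running stats for bn2 too, so extract pre-bn activations:
  p <- model$par; s <- model$spec
  Z2 <- sweep(fw2$cache$M2 %*% t(p$conv2.W), 2, p$conv2.b, "+")
  model$bn_stats$bn2.rm <- colMeans(Z2)
  model$bn_stats$bn2.rv <- colMeans(sweep(Z2, 2, colMeans(Z2))^2)
  model
}
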