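# Poisson-loss training with Adam, plus the evaluation metrics.

#' Training configuration
#'
#' @param max_epochs epoch cap (default 1000).
#' @param batch_size minibatch size in windows (CNN) or in windows rounded
#'   down to whole sequences (CRNN).
#' @param lr Adam learning rate (initial value under a schedule).
#' @param lr_schedule \code{"constant"}, or \code{"cosine"} for a cosine
#'   decay from \code{lr} to \code{lr_min} over \code{max_epochs}.
#' @param lr_min floor of the cosine schedule.
#' @param warmup_epochs linear learning-rate ramp from \code{lr_min} to
#'   \code{lr} over this many initial epochs (0 disables). A gentle start
#'   protects narrow layers from early unit death under the first-layer
#'   L1 penalty.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param patience early stopping: training halts once the best epoch loss
#'   has not improved by more than \code{min_rel_improve} (relative) for
#'   this many consecutive epochs.
#' @param min_rel_improve relative improvement threshold.
#' @param reg optional override of the model's regularization weights,
#'   list \code{(l2, l1_conv1, l1_activity)}.
#' @param revive_dead monitor first-layer kernels for ReLU death (mean
#'   activation collapsing to ~0, an absorbing state under the
#'   first-layer L1 penalty) and re-initialize dead kernels together with
#'   their normalization and downstream weights. Active during the first
#'   60\% of \code{max_epochs} only, so revived kernels have time to
#'   train. Matters for narrow first layers where losing a single kernel
#'   is unrecoverable.
#' @param seed RNG seed for shuffling and noise injection.
#' @param verbose print the loss every \code{verbose} epochs (0 = silent).
#' @return object of class \code{train_config}.
#' @export
train_config <- function(max_epochs = 1000L, batch_size = 1024L, lr = 2e-3,
                         lr_schedule = c("constant", "cosine"), lr_min = 1e-4,
                         warmup_epochs = 0L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         patience = 20L, min_rel_improve = 1e-5,
                         reg = NULL, revive_dead = FALSE, seed = 1L,
                         verbose = 0L) {
  if (batch_size < 1L) stop_bad_arg("batch_size must be >= 1")
  lr_schedule <- match.arg(lr_schedule)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_schedule = lr_schedule, lr_min = lr_min,
                 warmup_epochs = as.integer(warmup_epochs),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 patience = as.integer(patience),
                 min_rel_improve = min_rel_improve,
                 reg = reg, revive_dead = isTRUE(revive_dead),
                 seed = as.integer(seed),
                 verbose = as.integer(verbose)),
            class = "train_config")
}

.as_target_matrix <- function(targets) {
  r <- if (inherits(targets, "rate_matrix")) targets$rates else as.matrix(targets)
  t(r)   # n_bins x n_cells
}

#' Poisson objective with the model's regularization
#'
#' Data term \code{mean(yhat - y * log(yhat))} over all entries, plus (when
#' a model is supplied) the squared-L2 weight penalty on every weight
#' matrix, the L1 penalty on first-layer kernels, and the L1 activity
#' penalty on the predicted rates.
#'
#' @param y_hat predicted rates (matrix or \code{rate_matrix}), all > 0.
#' @param y observed rates, same shape.
#' @param model optional \code{\link{encoder_model}} whose weights are
#'   penalized.
#' @param cfg optional \code{\link{train_config}} whose \code{reg} overrides
#'   the model's.
#' @return scalar loss.
#' @export
poisson_loss <- function(y_hat, y, model = NULL, cfg = NULL) {
  yh <- if (inherits(y_hat, "rate_matrix")) y_hat$rates else as.matrix(y_hat)
  yy <- if (inherits(y, "rate_matrix")) y$rates else as.matrix(y)
  if (!all(dim(yh) == dim(yy))) stop_bad_arg("shape mismatch")
  if (any(yh <= 0)) stop_bad_arg("predicted rates must be strictly positive")
  loss <- mean(yh - yy * log(yh))
  if (!is.null(model)) {
    reg <- (cfg$reg %||% model$spec$reg)
    for (nm in .weight_par_names(model$par))
      loss <- loss + reg$l2 * sum(model$par[[nm]]^2)
    loss <- loss + reg$l1_conv1 * sum(abs(model$par$conv1.W))
    loss <- loss + reg$l1_activity * mean(yh)
  }
  loss
}

#' Train an encoder on stimulus windows and target rates
#'
#' Minibatch Adam on the Poisson objective, with early stopping once the
#' loss stops improving and best-loss weight restoration. After training,
#' batchnorm statistics are frozen to the exact statistics of the full
#' training set so that evaluation mode is deterministic.
#'
#' @param model an \code{\link{encoder_model}} (initial weights).
#' @param windows training windows aligned with \code{targets}.
#' @param targets \code{rate_matrix} (or n_cells x n_bins matrix); column k
#'   is the response at the bin predicted by window k.
#' @param cfg a \code{\link{train_config}}.
#' @return list with \code{model} (trained) and \code{report} (class
#'   \code{eval_report}: per-cell CC on the training data, mean CC,
#'   population CC, per-epoch loss history, epochs run).
#' @export
train <- function(model, windows, targets, cfg = train_config()) {
  stopifnot(inherits(model, "encoder_model"))
  Xt <- t(.windows_to_matrix(windows))   # features x samples: cheap gathers
  Y <- .as_target_matrix(targets)
  if (nrow(Y) != ncol(Xt)) stop_bad_arg("windows and targets misaligned")
  if (ncol(Y) != model$spec$n_outputs)
    stop_bad_arg("target cell count does not match model n_outputs")
  s <- model$spec
  set.seed(cfg$seed)

  L <- if (!is.null(s$recurrent)) s$recurrent$sequence_len else 1L
  n <- ncol(Xt)
  nu <- n %/% L                      # shufflable units (sequences or windows)
  if (nu < 1L) stop_bad_arg("fewer windows than one training sequence")
  unit_rows <- function(u) if (L == 1L) u else
    rep((u - 1L) * L, each = L) + seq_len(L)
  units_per_batch <- max(1L, cfg$batch_size %/% L)

  adam_m <- list(); adam_v <- list()
  best <- Inf; best_par <- model$par; best_bn <- model$bn_stats
  wait <- 0L; hist <- numeric(0); tstep <- 0
  bn_mom <- 0.99

  # re-initialize a dead first-layer kernel, its batchnorm slot, and the
  # second-layer weights reading from it; clear their Adam moments
  revive_kernel <- function(model, k) {
    fan1 <- ncol(model$par$conv1.W)
    model$par$conv1.W[k, ] <- stats::rnorm(fan1, sd = 1 / sqrt(fan1))
    model$par$conv1.b[k] <- 0
    cols2 <- seq(k, ncol(model$par$conv2.W), by = s$conv1$n)
    model$par$conv2.W[, cols2] <-
      stats::rnorm(length(model$par$conv2.W[, cols2]),
                   sd = 1 / sqrt(ncol(model$par$conv2.W)))
    if (s$batchnorm) {
      model$par$bn1.gamma[k] <- 1; model$par$bn1.beta[k] <- 0
      model$bn_stats$bn1.rm[k] <- 0; model$bn_stats$bn1.rv[k] <- 1
    }
    adam_m$conv1.W[k, ] <<- 0; adam_v$conv1.W[k, ] <<- 0
    adam_m$conv1.b[k] <<- 0; adam_v$conv1.b[k] <<- 0
    adam_m$conv2.W[, cols2] <<- 0; adam_v$conv2.W[, cols2] <<- 0
    if (s$batchnorm) {
      adam_m$bn1.gamma[k] <<- 0; adam_v$bn1.gamma[k] <<- 0
      adam_m$bn1.beta[k] <<- 0; adam_v$bn1.beta[k] <<- 0
    }
    model
  }

  for (ep in seq_len(cfg$max_epochs)) {
    wu <- cfg$warmup_epochs %||% 0L
    lr_ep <- if (ep <= wu) {
      cfg$lr_min + (cfg$lr - cfg$lr_min) * ep / (wu + 1)
    } else if (identical(cfg$lr_schedule, "cosine")) {
      cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
        (1 + cos(pi * (ep - wu - 1) / max(cfg$max_epochs - wu - 1, 1)))
    } else cfg$lr
    ord <- sample.int(nu)
    ep_loss <- 0; nb <- 0L
    act1 <- numeric(s$conv1$n)
    for (b0 in seq(1L, nu, by = units_per_batch)) {
      u <- ord[b0:min(b0 + units_per_batch - 1L, nu)]
      rows <- unit_rows(u)
      lg <- .encoder_loss_grad(model, list(Xt = Xt[, rows, drop = FALSE]),
                               Y[rows, , drop = FALSE], reg = cfg$reg)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep)
      tstep <- tstep + 1
      for (nm in names(lg$grads)) {
        gmat <- lg$grads[[nm]]
        if (is.null(adam_m[[nm]])) {
          adam_m[[nm]] <- gmat * 0; adam_v[[nm]] <- gmat * 0
        }
        adam_m[[nm]] <- cfg$beta1 * adam_m[[nm]] + (1 - cfg$beta1) * gmat
        adam_v[[nm]] <- cfg$beta2 * adam_v[[nm]] + (1 - cfg$beta2) * gmat^2
        mhat <- adam_m[[nm]] / (1 - cfg$beta1^tstep)
        vhat <- adam_v[[nm]] / (1 - cfg$beta2^tstep)
        model$par[[nm]] <- model$par[[nm]] - lr_ep * mhat / (sqrt(vhat) + cfg$eps)
      }
      model$par$alpha <- max(model$par$alpha, 1e-3)
      model$par$beta <- max(model$par$beta, 1e-3)
      if (s$batchnorm) {
        model$bn_stats$bn1.rm <- bn_mom * model$bn_stats$bn1.rm +
          (1 - bn_mom) * lg$bn$bn1.mu
        model$bn_stats$bn1.rv <- bn_mom * model$bn_stats$bn1.rv +
          (1 - bn_mom) * lg$bn$bn1.v
        model$bn_stats$bn2.rm <- bn_mom * model$bn_stats$bn2.rm +
          (1 - bn_mom) * lg$bn$bn2.mu
        model$bn_stats$bn2.rv <- bn_mom * model$bn_stats$bn2.rv +
          (1 - bn_mom) * lg$bn$bn2.v
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      act1 <- act1 + lg$act1
    }
    ep_loss <- ep_loss / nb
    hist <- c(hist, ep_loss)
    if (cfg$revive_dead && ep <= 0.6 * cfg$max_epochs) {
      act1 <- act1 / nb
      dead <- which(model$mask > 0 &
                      act1 < 0.02 * stats::median(act1[model$mask > 0]))
      if (length(dead)) {
        for (k in dead) model <- revive_kernel(model, k)
        if (cfg$verbose > 0)
          message(sprintf("epoch %d: revived dead kernel(s) %s", ep,
                          paste(dead, collapse = ", ")))
        best <- Inf; wait <- 0L   # pre-revival snapshots must not win
      }
    }
    if (cfg$verbose > 0 && ep %% cfg$verbose == 0)
      message(sprintf("epoch %d: loss %.6f", ep, ep_loss))
    if (ep_loss < best * (1 - cfg$min_rel_improve)) {
      best <- ep_loss; best_par <- model$par; best_bn <- model$bn_stats
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  model$par <- best_par; model$bn_stats <- best_bn
  nfit <- (n %/% L) * L
  Xfit <- list(Xt = Xt[, seq_len(nfit), drop = FALSE])
  if (cfg$max_epochs > 0L) model <- .finalize_batchnorm(model, Xfit)
  fin <- .encoder_forward_core(model, Xfit, mode = "eval")
  yobs <- t(Y[seq_len(nfit), , drop = FALSE])
  if (!is.null(s$recurrent) && s$readout == "flat")
    yobs <- yobs[, seq(L, nfit, by = L), drop = FALSE]
  cc <- cc_per_cell(t(fin$yhat), yobs)
  report <- structure(list(per_cell_cc = cc, mean_cc = mean(cc),
                           population_cc = population_cc(t(fin$yhat), yobs),
                           loss_history = hist, epochs = length(hist)),
                      class = "eval_report")
  list(model = model, report = report)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d epochs, final loss %.5f, mean CC %.4f, pop CC %.4f\n",
              x$epochs, utils::tail(x$loss_history, 1), x$mean_cc,
              x$population_cc))
  invisible(x)
}

#' Per-cell Pearson correlation between predicted and observed rates
#'
#' A constant row (in either input) yields 0 with a warning.
#'
#' @param pred,data n_cells x n_bins matrices (or \code{rate_matrix}).
#' @return numeric vector of length n_cells, each in \[-1, 1\].
#' @export
cc_per_cell <- function(pred, data) {
  p <- if (inherits(pred, "rate_matrix")) pred$rates else as.matrix(pred)
  d <- if (inherits(data, "rate_matrix")) data$rates else as.matrix(data)
  if (!all(dim(p) == dim(d))) stop_bad_arg("shape mismatch")
  if (ncol(p) < 2L) stop_bad_arg("need at least 2 bins")
  vapply(seq_len(nrow(p)), function(i) safe_pearson(p[i, ], d[i, ]),
         numeric(1))
}

#' Population correlation
#'
#' Pearson correlation between the across-cell mean time courses of the
#' prediction and the data.
#'
#' @inheritParams cc_per_cell
#' @return scalar in \[-1, 1\].
#' @export
population_cc <- function(pred, data) {
  p <- if (inherits(pred, "rate_matrix")) pred$rates else as.matrix(pred)
  d <- if (inherits(data, "rate_matrix")) data$rates else as.matrix(data)
  if (!all(dim(p) == dim(d))) stop_bad_arg("shape mismatch")
  safe_pearson(colMeans(p), colMeans(d))
}

#' Bin spike times into a trial-averaged rate matrix
#'
#' @param spike_times for one cell: a list of per-trial numeric vectors of
#'   spike times in ms; or a list of such lists for several cells.
#' @param bin_ms bin width in ms (default 33).
#' @param n_bins number of bins; spikes at or beyond \code{n_bins * bin_ms}
#'   (or negative) are dropped with a message.
#' @return \code{rate_matrix} of trial-averaged counts per bin.
#' @export
bin_spikes <- function(spike_times, bin_ms = 33, n_bins) {
  if (length(spike_times) && is.numeric(spike_times[[1]]))
    spike_times <- list(spike_times)
  breaks <- seq(0, n_bins * bin_ms, by = bin_ms)
  dropped <- 0L
  rates <- t(vapply(spike_times, function(trials) {
    counts <- numeric(n_bins)
    for (tr in trials) {
      keep <- tr >= 0 & tr < n_bins * bin_ms
      dropped <<- dropped + sum(!keep)
      counts <- counts + tabulate(findInterval(tr[keep], breaks), nbins = n_bins)
    }
    counts / max(length(trials), 1L)
  }, numeric(n_bins)))
  if (dropped > 0L) message(dropped, " spike(s) outside the binning range dropped")
  structure(list(rates = rates, bin_ms = bin_ms, alignment = seq_len(n_bins)),
            class = "rate_matrix")
}
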