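# Receptive-field recovery and characterization.

#' Spike-triggered average from stimulus windows
#'
#' Response-weighted average of mean-subtracted windows:
#' \code{STA = sum_t r_t (w_t - wbar) / sum_t r_t}, where \code{wbar} is the
#' across-sample mean window. Works with spike counts or continuous rates.
#'
#' @param windows a \code{\link{make_windows}} result (or 4-D array).
#' @param response nonnegative vector, one value per window.
#' @return 3-D array (depth x height x width), oldest frame first (window
#'   order), of class \code{st_filter}.
#' @export
compute_sta <- function(windows, response) {
  w <- if (inherits(windows, "window_set")) windows$windows else windows
  d <- dim(w)
  if (length(response) != d[1]) stop_bad_arg("one response value per window")
  if (any(response < 0)) stop_bad_arg("response must be nonnegative")
  tot <- sum(response)
  if (tot == 0) stop_bad_arg("all-zero response: nothing to trigger on")
  Xm <- matrix(w, nrow = d[1])
  mw <- colMeans(Xm)
  sta <- as.numeric(crossprod(Xm, response)) / tot - mw
  structure(array(sta, d[2:4]), class = "st_filter")
}

#' Rank-1 (space-time) factorization of a 3-D filter
#'
#' Reshapes the filter to depth x (height*width) and takes the leading
#' singular triplet. Raw SVD signs are arbitrary, so under the default
#' convention the spatial map is flipped to have a positive dominant lobe
#' (the temporal kernel is flipped with it, preserving the product); the
#' cell's ON/OFF polarity then shows as the sign of the temporal kernel's
#' largest-magnitude lobe.
#'
#' @param filter 3-D array (depth x height x width).
#' @param sign_convention \code{"spatial_positive"} (default) as above;
#'   \code{"none"} keeps the raw SVD signs.
#' @return object of class \code{factorized_rf}: \code{spatial} (unit-norm
#'   2-D map), \code{temporal} (unit-norm 1-D kernel, oldest bin first),
#'   \code{singular_value}, \code{polarity}, \code{var_explained}.
#' @export
factorize_rf <- function(filter,
                         sign_convention = c("spatial_positive", "none")) {
  sign_convention <- match.arg(sign_convention)
  f <- unclass(filter)
  d <- dim(f)
  if (length(d) != 3L || d[1] < 2L) stop_bad_arg("need a 3-D filter, depth >= 2")
  if (all(f == 0)) stop_bad_arg("all-zero filter")
  M <- matrix(f, d[1], d[2] * d[3])
  sv <- svd(M, nu = 1, nv = 1)
  temporal <- sv$u[, 1]; spatial <- matrix(sv$v[, 1], d[2], d[3])
  if (sign_convention == "spatial_positive" &&
      spatial[which.max(abs(spatial))] < 0) {
    temporal <- -temporal; spatial <- -spatial
  }
  polarity <- if (temporal[which.max(abs(temporal))] >= 0) "ON" else "OFF"
  structure(list(spatial = spatial, temporal = temporal,
                 singular_value = sv$d[1], polarity = polarity,
                 var_explained = sv$d[1]^2 / sum(sv$d^2)),
            class = "factorized_rf")
}

#' Fit a 2-D Gaussian to a spatial receptive-field map
#'
#' The map's polarity is normalized so its dominant peak is positive, then
#' \code{amplitude * exp(-0.5 * quadform)} is fitted by Levenberg-Marquardt
#' least squares, initialized from the peak pixel and the second moments of
#' the squared map. A map without a dominant blob (peak not above
#' \code{peak_factor} times the median absolute value), a non-converged
#' fit, or a fit explaining less than \code{min_r2} of the map variance
#' (as any noise map yields) is flagged as having no effective RF.
#'
#' @param spatial 2-D numeric map (rows = y, columns = x).
#' @param peak_factor dominance criterion (default 3).
#' @param min_r2 minimum variance explained by the fitted Gaussian.
#' @return object of class \code{gaussian_rf}: \code{center} (x, y in
#'   pixel coordinates), \code{sigma} (major, minor), \code{theta}
#'   (orientation of the major axis, radians), \code{amplitude},
#'   \code{valid} flag, and \code{residual} (RMS of the fit).
#' @export
fit_gaussian_rf <- function(spatial, peak_factor = 3, min_r2 = 0.2) {
  m <- as.matrix(spatial)
  pk <- which.max(abs(m))
  if (m[pk] < 0) m <- -m
  med <- stats::median(abs(m))
  invalid <- function(reason)
    structure(list(center = c(NA, NA), sigma = c(NA, NA), theta = NA,
                   amplitude = NA, valid = FALSE, residual = NA,
                   reason = reason), class = "gaussian_rf")
  if (med > 0 && max(m) < peak_factor * med)
    return(invalid("no dominant peak"))
  h <- nrow(m); w <- ncol(m)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  wts <- pmax(m, 0)^2; wts <- wts / sum(wts)
  cx0 <- sum(wts * xx); cy0 <- sum(wts * yy)
  sx0 <- sqrt(max(sum(wts * (xx - cx0)^2), 0.25))
  sy0 <- sqrt(max(sum(wts * (yy - cy0)^2), 0.25))
  amp0 <- max(m)
  resid_fun <- function(par) {
    cx <- par[1]; cy <- par[2]
    sx <- abs(par[3]); sy <- abs(par[4]); th <- par[5]; amp <- par[6]
    u <- cos(th) * (xx - cx) + sin(th) * (yy - cy)
    v <- -sin(th) * (xx - cx) + cos(th) * (yy - cy)
    as.numeric(amp * exp(-0.5 * ((u / sx)^2 + (v / sy)^2)) - m)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(cx0, cy0, sx0, sy0, 0, amp0), fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(invalid("fit failed"))
  par <- fit$par
  sx <- abs(par[3]); sy <- abs(par[4]); th <- par[5]
  if (sy > sx) { tmp <- sx; sx <- sy; sy <- tmp; th <- th + pi / 2 }
  th <- atan2(sin(th), cos(th))
  if (par[6] <= 0 || sx <= 0) return(invalid("degenerate fit"))
  r2 <- 1 - sum(resid_fun(par)^2) / sum((m - mean(m))^2)
  if (r2 < min_r2) return(invalid("fit explains too little variance"))
  structure(list(center = c(x = par[1], y = par[2]),
                 sigma = c(major = sx, minor = sy), theta = th,
                 amplitude = par[6], valid = TRUE,
                 residual = sqrt(mean(resid_fun(par)^2))),
            class = "gaussian_rf")
}

#' @export
print.gaussian_rf <- function(x, ...) {
  if (!x$valid) cat("<gaussian_rf> no effective RF (", x$reason, ")\n")
  else cat(sprintf("<gaussian_rf> center (%.2f, %.2f), sigma (%.2f, %.2f), theta %.2f\n",
                   x$center[1], x$center[2], x$sigma[1], x$sigma[2], x$theta))
  invisible(x)
}

# density of a fitted gaussian_rf on the pixel grid (unnormalized)
.gaussian_rf_density <- function(g, grid_hw) {
  h <- grid_hw[1]; w <- grid_hw[2]
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- cos(g$theta) * (xx - g$center[1]) + sin(g$theta) * (yy - g$center[2])
  v <- -sin(g$theta) * (xx - g$center[1]) + cos(g$theta) * (yy - g$center[2])
  exp(-0.5 * ((u / g$sigma[1])^2 + (v / g$sigma[2])^2))
}

#' Cosine distance between two fitted receptive fields
#'
#' Both Gaussian densities are evaluated on the pixel grid, vectorized,
#' and compared: \code{1 - cosine similarity}; in \[0, 1\] for the
#' nonnegative densities involved.
#'
#' @param a,b valid \code{\link{fit_gaussian_rf}} results.
#' @param grid_hw (height, width) of the evaluation grid.
#' @return scalar distance.
#' @export
rf_cosine_distance <- function(a, b, grid_hw) {
  if (!isTRUE(a$valid) || !isTRUE(b$valid))
    stop_bad_arg("both fits must be valid")
  da <- .gaussian_rf_density(a, grid_hw)
  db <- .gaussian_rf_density(b, grid_hw)
  1 - cosine_similarity(da, db)
}

#' Moran's I spatial autocorrelation of a 2-D map
#'
#' Rook (4-neighbour) binary weights:
#' \code{I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2}.
#' A constant map returns 0 with a warning.
#'
#' @param spatial 2-D numeric map, at least 2 x 2.
#' @return scalar (typically in \[-1, 1\]).
#' @export
spatial_autocorrelation <- function(spatial) {
  m <- as.matrix(spatial)
  if (nrow(m) < 2L || ncol(m) < 2L) stop_bad_arg("need at least a 2x2 map")
  z <- m - mean(m)
  denom <- sum(z^2)
  if (denom == 0) {
    warning("constant map: Moran's I undefined, returning 0")
    return(0)
  }
  # horizontal + vertical neighbour cross-products (each pair counted twice
  # in the double sum; doubling one-directional sums is equivalent)
  cross <- 2 * (sum(z[, -1] * z[, -ncol(z)]) + sum(z[-1, ] * z[-nrow(z), ]))
  n_pairs <- 2 * (nrow(m) * (ncol(m) - 1) + (nrow(m) - 1) * ncol(m))
  (length(m) / n_pairs) * cross / denom
}

#' Temporal-regularity index of a 1-D kernel
#'
#' \code{I = (1/T) * sum_i (| |w_i| - max|w| | - eps) / (||w - wbar||_2 + eps)}.
#' High values indicate a regular oscillatory (biphasic) profile with a
#' pronounced peak; a constant kernel gives exactly -1.
#'
#' @param w numeric kernel, length >= 2.
#' @param eps stabilizer (default 5e-4).
#' @param parse \code{"abs_dev"} (default) reads the numerator as the
#'   absolute deviation of each sample's magnitude from the peak magnitude;
#'   \code{"signed_dev"} drops the outer absolute value.
#' @return scalar index.
#' @export
temporal_regularity <- function(w, eps = 5e-4,
                                parse = c("abs_dev", "signed_dev")) {
  parse <- match.arg(parse)
  if (length(w) < 2L) stop_bad_arg("kernel length must be >= 2")
  dev <- abs(w) - max(abs(w))
  num <- if (parse == "abs_dev") abs(dev) - eps else dev - eps
  den <- sqrt(sum((w - mean(w))^2)) + eps
  mean(num / den)
}

#' Score first-layer kernels by both importance indices
#'
#' For each spatiotemporal kernel: factorize (SVD), then Moran's I of the
#' spatial factor (\code{spaCorr}) and the temporal-regularity index of the
#' temporal factor (\code{tCorr}).
#'
#' @param kernels list of 3-D arrays (depth x height x width), or an
#'   \code{\link{encoder_model}} whose first-layer kernels are scored.
#' @return data.frame with columns \code{kernel}, \code{spaCorr},
#'   \code{tCorr}.
#' @export
score_kernels <- function(kernels) {
  if (inherits(kernels, "encoder_model")) kernels <- conv1_kernels(kernels)
  rows <- lapply(seq_along(kernels), function(i) {
    fz <- factorize_rf(kernels[[i]])
    data.frame(kernel = i,
               spaCorr = spatial_autocorrelation(fz$spatial),
               tCorr = temporal_regularity(fz$temporal))
  })
  do.call(rbind, rows)
}

#' Extract the first-layer kernels of an encoder as 3-D arrays
#'
#' @param model an \code{\link{encoder_model}}.
#' @return list of depth x kh x kw arrays (window temporal order).
#' @export
conv1_kernels <- function(model) {
  s <- model$spec
  d <- s$input_shape[1]; k <- s$conv1$hw
  lapply(seq_len(s$conv1$n), function(i)
    array(model$par$conv1.W[i, ], c(d, k, k)))
}

#' Optimally match learned kernels to ground-truth subunits
#'
#' Sign-agnostic (absolute cosine) optimal one-to-one assignment between a
#' list of learned spatiotemporal kernels and the ground-truth subunit
#' tensors, maximizing the summed |cosine| (exact assignment, not greedy).
#'
#' @param kernels list of 3-D arrays (window temporal order), e.g.
#'   \code{\link{conv1_kernels}} output or STAs.
#' @param truth list of \code{\link{subunit_filter}} or of 3-D arrays in
#'   the same orientation.
#' @return data.frame with columns \code{subunit}, \code{kernel},
#'   \code{similarity} (absolute cosine), ordered by subunit.
#' @export
match_kernels_to_subunits <- function(kernels, truth) {
  tt <- lapply(truth, function(x)
    if (inherits(x, "subunit_filter")) subunit_window_tensor(x) else x)
  if (!length(kernels) || !length(tt)) stop_bad_arg("empty input")
  S <- matrix(0, length(tt), length(kernels))
  for (i in seq_along(tt)) for (j in seq_along(kernels))
    S[i, j] <- abs(cosine_similarity(tt[[i]], kernels[[j]]))
  S[is.na(S)] <- 0
  asg <- assign_optimal(S)
  data.frame(subunit = seq_along(tt), kernel = asg,
             similarity = S[cbind(seq_along(tt), asg)])
}
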