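# SSIM-based spatial and temporal complexity of a movie, per patch.

#' Structural similarity between two image patches
#'
#' Computed as a single global statistic per patch pair (no sliding
#' window): \code{((2 mu_p mu_q + C1)(2 cov + C2)) /
#' ((mu_p^2 + mu_q^2 + C1)(var_p + var_q + C2))} with the standard
#' stabilizers \code{C1 = (0.01 L)^2}, \code{C2 = (0.03 L)^2} and unbiased
#' (co)variances.
#'
#' @param p,q equal-shaped numeric patches.
#' @param L dynamic range of the data (1 for \[0,1\] clips).
#' @return scalar in \[-1, 1\]; 1 for identical patches; symmetric.
#' @export
ssim <- function(p, q, L = 1) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q))) stop_bad_arg("patch shapes differ")
  n <- length(p)
  if (n < 2L) stop_bad_arg("patches must have >= 2 pixels")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mp <- mean(p); mq <- mean(q)
  vp <- sum((p - mp)^2) / (n - 1); vq <- sum((q - mq)^2) / (n - 1)
  cpq <- sum((p - mp) * (q - mq)) / (n - 1)
  ((2 * mp * mq + C1) * (2 * cpq + C2)) /
    ((mp^2 + mq^2 + C1) * (vp + vq + C2))
}

# split frames into a patch grid; returns list(rows, cols, patch fn)
.patch_grid <- function(clip, patch_px) {
  d <- dim(clip$frames)
  rows <- d[2] %/% patch_px; cols <- d[3] %/% patch_px
  if (rows * cols < 2L) stop_bad_arg("need at least 2 patches per frame")
  get <- function(t, i, j)
    clip$frames[t,
                ((i - 1L) * patch_px + 1L):(i * patch_px),
                ((j - 1L) * patch_px + 1L):(j * patch_px)]
  list(rows = rows, cols = cols, get = get, n_frames = d[1])
}

.neighbours <- function(i, j, rows, cols) {
  out <- list()
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1 && ii <= rows && jj >= 1 && jj <= cols)
      out[[length(out) + 1L]] <- c(ii, jj)
  }
  out
}

#' Spatial complexity map of a movie
#'
#' For each patch: the mean SSIM to its existing neighbours (up to 8;
#' border patches use their actual neighbour count) within each frame,
#' averaged over frames, subtracted from 1. A constant movie scores
#' exactly 0 everywhere.
#'
#' @param clip a \code{\link{stimulus_clip}}; edge pixels beyond a whole
#'   number of patches are cropped.
#' @param patch_px square patch size in pixels (default 18).
#' @return matrix (patch rows x patch cols) of SC values in \[0, 2\], with
#'   attributes \code{patch_px}.
#' @export
spatial_complexity <- function(clip, patch_px = 18L) {
  g <- .patch_grid(clip, patch_px)
  sc <- matrix(0, g$rows, g$cols)
  for (i in seq_len(g$rows)) for (j in seq_len(g$cols)) {
    nb <- .neighbours(i, j, g$rows, g$cols)
    acc <- 0
    for (t in seq_len(g$n_frames)) {
      pit <- g$get(t, i, j)
      s <- vapply(nb, function(x) ssim(pit, g$get(t, x[1], x[2])), numeric(1))
      acc <- acc + mean(s)
    }
    sc[i, j] <- 1 - acc / g$n_frames
  }
  attr(sc, "patch_px") <- patch_px
  sc
}

#' Temporal complexity map of a movie
#'
#' For each patch and each frame pair (t, t+1): the average of the SSIMs
#' between the patch at t and its existing neighbours at t+1 plus the SSIM
#' to its own position at t+1, divided by (number of neighbours + 1);
#' averaged over frame pairs and subtracted from 1.
#'
#' @inheritParams spatial_complexity
#' @return matrix (patch rows x patch cols) of TC values in \[0, 2\].
#' @export
temporal_complexity <- function(clip, patch_px = 18L) {
  g <- .patch_grid(clip, patch_px)
  if (g$n_frames < 2L) stop_bad_arg("need at least 2 frames")
  tc <- matrix(0, g$rows, g$cols)
  for (i in seq_len(g$rows)) for (j in seq_len(g$cols)) {
    nb <- .neighbours(i, j, g$rows, g$cols)
    acc <- 0
    for (t in seq_len(g$n_frames - 1L)) {
      pit <- g$get(t, i, j)
      s <- vapply(nb, function(x) ssim(pit, g$get(t + 1L, x[1], x[2])),
                  numeric(1))
      acc <- acc + (sum(s) + ssim(pit, g$get(t + 1L, i, j))) / (length(nb) + 1)
    }
    tc[i, j] <- 1 - acc / (g$n_frames - 1L)
  }
  attr(tc, "patch_px") <- patch_px
  tc
}

# smallest Mahalanobis distance^2 from the RF center to the patch rectangle
# (convex box-constrained quadratic, solved with L-BFGS-B)
.min_mahal_sq <- function(g, xlim, ylim) {
  R <- matrix(c(cos(g$theta), sin(g$theta), -sin(g$theta), cos(g$theta)),
              2, 2, byrow = TRUE)
  f <- function(p) {
    uv <- R %*% (p - g$center)
    (uv[1] / g$sigma[1])^2 + (uv[2] / g$sigma[2])^2
  }
  gr <- function(p) {
    uv <- R %*% (p - g$center)
    as.numeric(2 * t(R) %*% (uv / g$sigma^2))
  }
  st <- pmin(pmax(g$center, c(xlim[1], ylim[1])), c(xlim[2], ylim[2]))
  res <- stats::optim(st, f, gr, method = "L-BFGS-B",
                      lower = c(xlim[1], ylim[1]),
                      upper = c(xlim[2], ylim[2]))
  res$value
}

#' Relate per-patch scene complexity to model performance
#'
#' Each cell is assigned to every patch its 1-sigma receptive-field
#' ellipse overlaps; the per-patch value is the mean CC of its assigned
#' cells (NA for uncovered patches).
#'
#' @param map a complexity map from \code{\link{spatial_complexity}} or
#'   \code{\link{temporal_complexity}} (only the patch geometry is used).
#' @param rf_fits list of \code{\link{fit_gaussian_rf}} results, in pixel
#'   coordinates of the movie; invalid fits are skipped.
#' @param per_cell_cc numeric vector aligned with \code{rf_fits}.
#' @return data.frame with columns \code{row}, \code{col},
#'   \code{complexity}, \code{mean_cc}, \code{n_cells}.
#' @export
complexity_vs_performance <- function(map, rf_fits, per_cell_cc) {
  if (length(rf_fits) != length(per_cell_cc))
    stop_bad_arg("rf_fits and per_cell_cc must be aligned")
  patch_px <- attr(map, "patch_px")
  rows <- nrow(map); cols <- ncol(map)
  out <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  out$complexity <- map[cbind(out$row, out$col)]
  out$mean_cc <- NA_real_; out$n_cells <- 0L
  for (r in seq_len(nrow(out))) {
    i <- out$row[r]; j <- out$col[r]
    ylim <- c((i - 1) * patch_px + 0.5, i * patch_px + 0.5)
    xlim <- c((j - 1) * patch_px + 0.5, j * patch_px + 0.5)
    ccs <- c()
    for (k in seq_along(rf_fits)) {
      g <- rf_fits[[k]]
      if (!isTRUE(g$valid)) next
      if (.min_mahal_sq(g, xlim, ylim) <= 1) ccs <- c(ccs, per_cell_cc[k])
    }
    if (length(ccs)) {
      out$mean_cc[r] <- mean(ccs); out$n_cells[r] <- length(ccs)
    }
  }
  out
}
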