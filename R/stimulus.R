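#' Stimulus clip container
#'
#' A raw grayscale movie: a 3-D array (time x height x width) of pixel
#' intensities in \[0, 1\], plus the duration of one time bin in ms.
#'
#' @param frames 3-D numeric array, time x height x width, values in \[0,1\].
#' @param bin_ms duration of one frame bin in milliseconds (default 33).
#' @return an object of class \code{stimulus_clip}.
#' @export
stimulus_clip <- function(frames, bin_ms = 33) {
  if (length(dim(frames)) != 3L)
    stop_bad_arg("frames must be a 3-D array (time x height x width)")
  if (!all(is.finite(frames)))
    stop_bad_arg("frames must be finite")
  if (min(frames) < 0 || max(frames) > 1)
    stop_bad_arg("pixel values must lie in [0, 1]")
  structure(list(frames = frames, bin_ms = bin_ms), class = "stimulus_clip")
}

#' @export
print.stimulus_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_clip> %d frames of %dx%d px, %g ms/bin\n",
              d[1], d[2], d[3], x$bin_ms))
  invisible(x)
}

#' Generate a white-noise stimulus clip
#'
#' Binary noise is i.i.d. \{0, 1\} with p = 0.5 per pixel (models standardize
#' internally); Gaussian noise is drawn N(0.5, 0.15^2) and clipped to \[0,1\].
#'
#' @param n_frames,height,width clip dimensions (all >= 1).
#' @param kind \code{"binary"} or \code{"gaussian"}.
#' @param seed integer seed; the same seed yields a bit-identical clip.
#' @param bin_ms bin duration in ms.
#' @return a \code{\link{stimulus_clip}}.
#' @export
generate_white_noise <- function(n_frames, height, width,
                                 kind = c("binary", "gaussian"),
                                 seed = 1L, bin_ms = 33) {
  kind <- match.arg(kind)
  if (n_frames < 1 || height < 1 || width < 1)
    stop_bad_arg("n_frames, height and width must all be >= 1")
  n <- n_frames * height * width
  set.seed(seed)
  x <- if (kind == "binary") {
    as.numeric(stats::runif(n) < 0.5)
  } else {
    pmin(pmax(stats::rnorm(n, mean = 0.5, sd = 0.15), 0), 1)
  }
  stimulus_clip(array(x, dim = c(n_frames, height, width)), bin_ms = bin_ms)
}

#' Spatially resample and normalize raw movie frames
#'
#' Downsamples each frame to \code{target_hw} by block (area) averaging,
#' optionally followed by a min-max rescale of the whole clip to \[0,1\].
#' A constant clip under \code{normalize = TRUE} maps to all 0.5.
#' Non-integer downsampling factors distribute pixel area fractionally
#' across target cells (exact area weighting).
#'
#' @param raw_frames 3-D numeric array (time x height x width), any scale.
#' @param target_hw integer pair (height, width), each <= the input size.
#' @param normalize rescale min -> 0, max -> 1 after resampling.
#' @param bin_ms bin duration carried into the result.
#' @return a \code{\link{stimulus_clip}}.
#' @export
preprocess_movie <- function(raw_frames, target_hw, normalize = TRUE,
                             bin_ms = 33) {
  if (length(dim(raw_frames)) != 3L)
    stop_bad_arg("raw_frames must be a 3-D array")
  d <- dim(raw_frames)
  th <- as.integer(target_hw[1]); tw <- as.integer(target_hw[2])
  if (th > d[2] || tw > d[3])
    stop_bad_arg("target size exceeds input frame size")
  out <- if (th == d[2] && tw == d[3]) {
    raw_frames
  } else {
    # area-weighted row/column pooling matrices: out = Rh %*% frame %*% t(Rw)
    Rh <- .area_pool_matrix(d[2], th)
    Rw <- .area_pool_matrix(d[3], tw)
    res <- array(0, c(d[1], th, tw))
    for (t in seq_len(d[1]))
      res[t, , ] <- Rh %*% raw_frames[t, , ] %*% t(Rw)
    res
  }
  if (normalize) {
    rng <- range(out)
    out <- if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1])
           else array(0.5, dim(out))
  } else {
    if (min(out) < 0 || max(out) > 1)
      stop_bad_arg("values outside [0,1]; use normalize = TRUE")
  }
  stimulus_clip(out, bin_ms = bin_ms)
}

# n_in x n_out fractional area weights, rows average disjoint source spans
.area_pool_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * step; b <- i * step
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      lo <- max(a, j - 1); hi <- min(b, j)
      if (hi > lo) M[i, j] <- (hi - lo) / step
    }
  }
  M
}

#' Slice a clip into sliding spatiotemporal windows
#'
#' Window k ends at bin \code{(depth-1) + (k-1)*stride} (0-based) and holds
#' that bin's frame plus the \code{depth - 1} preceding frames, as a verbatim
#' slice of the clip. \code{alignment} records the 1-based index of the bin
#' each window predicts.
#'
#' @param clip a \code{\link{stimulus_clip}}.
#' @param depth frames per window (the target bin plus depth-1 history).
#' @param stride step between consecutive windows (>= 1).
#' @return an object of class \code{window_set} with fields \code{windows}
#'   (n x depth x height x width), \code{depth}, \code{alignment}.
#' @export
make_windows <- function(clip, depth = 20L, stride = 1L) {
  stopifnot(inherits(clip, "stimulus_clip"))
  d <- dim(clip$frames)
  depth <- as.integer(depth); stride <- as.integer(stride)
  if (depth < 1 || depth > d[1])
    stop_bad_arg("depth must be in [1, clip length]")
  if (stride < 1) stop_bad_arg("stride must be >= 1")
  ends <- seq.int(depth, d[1], by = stride)
  n <- length(ends)
  w <- array(0, c(n, depth, d[2], d[3]))
  for (k in seq_len(n))
    w[k, , , ] <- clip$frames[(ends[k] - depth + 1L):ends[k], , , drop = FALSE]
  structure(list(windows = w, depth = depth, alignment = ends,
                 bin_ms = clip$bin_ms),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows of %d x %dx%d\n", d[1], d[2], d[3], d[4]))
  invisible(x)
}
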