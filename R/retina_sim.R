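# Ground-truth simulated retinal circuit: handcrafted spatiotemporal
# subunits (bipolar-cell-like filters + rectifier) pooled by model RGCs
# with a softplus output stage and Poisson spiking.

#' Construct one receptive-field subunit
#'
#' @param spatial_map 2-D numeric map; normalized internally to unit
#'   Euclidean norm.
#' @param temporal_kernel 1-D kernel over stimulus history (index 1 = most
#'   recent frame); must be biphasic (at least one sign change).
#' @param polarity \code{"ON"} or \code{"OFF"}; OFF subunits carry a negated
#'   spatial map.
#' @return object of class \code{subunit_filter}.
#' @export
subunit_filter <- function(spatial_map, temporal_kernel, polarity = "ON") {
  nrm <- sqrt(sum(spatial_map^2))
  if (nrm == 0) stop_bad_arg("spatial map must be nonzero")
  if (!(any(temporal_kernel > 0) && any(temporal_kernel < 0)))
    stop_bad_arg("temporal kernel must be biphasic (sign change required)")
  structure(list(spatial_map = spatial_map / nrm,
                 temporal_kernel = temporal_kernel,
                 polarity = match.arg(polarity, c("ON", "OFF"))),
            class = "subunit_filter")
}

# biphasic difference-of-exponentials temporal kernel; index 1 = lag 0.
# trough lobe scales with the peak latency so the rebound stays inside the
# filter depth for all catalogue latencies.
.biphasic_kernel <- function(depth, peak = 4L, trough = 1.8 * peak) {
  t <- seq_len(depth) - 1
  k <- (t / peak)^2 * exp(-t / peak) - 0.8 * (t / trough)^2 * exp(-t / trough)
  k / sqrt(sum(k^2))
}

# spatial shape primitives on an h x w grid, all unit-norm
.shape_block <- function(hw, top, left, size) {
  m <- matrix(0, hw[1], hw[2])
  m[top:(top + size - 1), left:(left + size - 1)] <- 1
  m / sqrt(sum(m^2))
}

.shape_gaussian <- function(hw, cy, cx, sy, sx, theta = 0) {
  yy <- matrix(seq_len(hw[1]), hw[1], hw[2])
  xx <- matrix(seq_len(hw[2]), hw[1], hw[2], byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  m <- exp(-0.5 * ((u / sx)^2 + (v / sy)^2))
  m / sqrt(sum(m^2))
}

.shape_bar <- function(hw, cy, cx, len, width, theta) {
  yy <- matrix(seq_len(hw[1]), hw[1], hw[2])
  xx <- matrix(seq_len(hw[2]), hw[1], hw[2], byrow = TRUE)
  u <- cos(theta) * (xx - cx) + sin(theta) * (yy - cy)
  v <- -sin(theta) * (xx - cx) + cos(theta) * (yy - cy)
  m <- exp(-0.5 * ((u / len)^2 + (v / width)^2))
  m / sqrt(sum(m^2))
}

#' Default subunit shape catalogue
#'
#' Eight entries on an 8x8 grid: four square blocks, two Gaussian blobs and
#' two oriented bars, mixing ON and OFF polarities and two temporal peak
#' latencies. The \code{"modelII"} preset swaps the first subunit for an
#' oriented Gabor-like alternative (used to probe robustness to subunit
#' shape changes).
#'
#' @param preset \code{"modelI"} (default) or \code{"modelII"}.
#' @return a list of shape-spec lists consumed by
#'   \code{\link{build_subunit_bank}}.
#' @export
subunit_catalogue <- function(preset = c("modelI", "modelII")) {
  preset <- match.arg(preset)
  cat_I <- list(
    list(fun = .shape_block,    args = list(top = 1, left = 1, size = 3),
         polarity = "ON",  peak = 3),
    list(fun = .shape_block,    args = list(top = 1, left = 5, size = 3),
         polarity = "OFF", peak = 4),
    list(fun = .shape_gaussian, args = list(cy = 6.5, cx = 2.5, sy = 1.2, sx = 1.2),
         polarity = "ON",  peak = 4),
    list(fun = .shape_bar,      args = list(cy = 6.5, cx = 6.5, len = 2.2,
                                            width = 0.8, theta = pi / 4),
         polarity = "OFF", peak = 5),
    list(fun = .shape_block,    args = list(top = 3, left = 3, size = 3),
         polarity = "ON",  peak = 5),
    list(fun = .shape_gaussian, args = list(cy = 2.5, cx = 6.5, sy = 1.0, sx = 1.6),
         polarity = "OFF", peak = 3),
    list(fun = .shape_bar,      args = list(cy = 4.5, cx = 4.5, len = 2.4,
                                            width = 0.7, theta = -pi / 3),
         polarity = "ON",  peak = 4),
    list(fun = .shape_block,    args = list(top = 5, left = 1, size = 3),
         polarity = "OFF", peak = 5))
  if (preset == "modelII") {
    cat_I[[1]] <- list(fun = .shape_bar,
                       args = list(cy = 2.0, cx = 2.0, len = 2.0, width = 0.6,
                                   theta = pi / 6),
                       polarity = "ON", peak = 3)
  }
  cat_I
}

#' Build a bank of spatiotemporal subunit filters
#'
#' @param catalogue list of shape specs (see \code{\link{subunit_catalogue}}).
#' @param n_subunits number of subunits to instantiate (recycled through the
#'   catalogue if larger).
#' @param grid_hw (height, width) of the stimulus grid.
#' @param depth temporal depth in bins.
#' @param seed reserved for catalogue entries with stochastic parameters;
#'   the default catalogue is deterministic.
#' @return list of \code{\link{subunit_filter}} objects, each with a
#'   unit-norm spatial map and a biphasic temporal kernel.
#' @export
build_subunit_bank <- function(catalogue = subunit_catalogue(),
                               n_subunits = length(catalogue),
                               grid_hw = c(8L, 8L), depth = 20L, seed = 0L) {
  if (n_subunits < 1) stop_bad_arg("n_subunits must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_subunits), function(i) {
    sp <- catalogue[[(i - 1L) %% length(catalogue) + 1L]]
    smap <- do.call(sp$fun, c(list(hw = grid_hw), sp$args))
    if (!all(dim(smap) == grid_hw))
      stop_bad_arg("catalogue shape does not fit the grid")
    subunit_filter(smap, .biphasic_kernel(depth, peak = sp$peak),
                   polarity = sp$polarity)
  })
}

#' Full spatiotemporal tensor of a subunit
#'
#' Outer product temporal x spatial as a depth x height x width array, with
#' OFF polarity applied as a sign flip. Index 1 of the temporal axis is the
#' target bin's own frame (lag 0).
#'
#' @param su a \code{\link{subunit_filter}}.
#' @return 3-D array (depth x height x width).
#' @export
subunit_tensor <- function(su) {
  sgn <- if (su$polarity == "OFF") -1 else 1
  d <- length(su$temporal_kernel)
  out <- array(0, c(d, dim(su$spatial_map)))
  for (l in seq_len(d)) out[l, , ] <- sgn * su$temporal_kernel[l] * su$spatial_map
  out
}

#' Subunit tensor in stimulus-window order
#'
#' Same as \code{\link{subunit_tensor}} but with the temporal axis ordered
#' like a stimulus window: index 1 = oldest frame, last index = the target
#' bin. This is the orientation of learned first-layer kernels and STAs.
#'
#' @param su a \code{\link{subunit_filter}}.
#' @return 3-D array (depth x height x width).
#' @export
subunit_window_tensor <- function(su) {
  f <- subunit_tensor(su)
  f[rev(seq_len(dim(f)[1])), , , drop = FALSE]
}

#' Assemble a model RGC population over a subunit bank
#'
#' The simulated cascade is: subunit linear filter -> half-wave
#' rectification (ReLU) -> nonnegative pooling -> softplus output with a
#' small baseline. This places the simulator inside the encoder model
#' family (ReLU hidden units, softplus readout), so the encoders can in
#' principle represent it exactly.
#'
#' @param subunits list of \code{\link{subunit_filter}}.
#' @param pooling n_cells x n_subunits nonnegative matrix.
#' @param baseline scalar added inside the softplus (per cell, recycled).
#' @param gain scalar multiplying the pooled drive before the softplus.
#' @return object of class \code{rgc_model}.
#' @export
rgc_model <- function(subunits, pooling, baseline = 0.1, gain = 1) {
  pooling <- as.matrix(pooling)
  if (any(pooling < 0)) stop_bad_arg("pooling weights must be nonnegative")
  if (ncol(pooling) != length(subunits))
    stop_bad_arg("pooling columns must match number of subunits")
  if (any(rowSums(pooling) == 0))
    stop_bad_arg("each RGC needs at least one subunit")
  structure(list(subunits = subunits, pooling = pooling,
                 baseline = rep_len(baseline, nrow(pooling)), gain = gain),
            class = "rgc_model")
}

#' The canonical two-RGC simulated retina
#'
#' Eight subunits on an 8x8 grid (20-bin temporal depth), pooled 4-per-cell
#' with one shared subunit per cell so the two receptive fields overlap.
#'
#' @param preset catalogue preset, \code{"modelI"} or \code{"modelII"}.
#' @param depth temporal depth in bins.
#' @return an \code{rgc_model} with 2 cells and 8 subunits.
#' @export
build_demo_retina <- function(preset = "modelI", depth = 20L) {
  bank <- build_subunit_bank(subunit_catalogue(preset), grid_hw = c(8L, 8L),
                             depth = depth)
  pool <- rbind(c(1.6, 1.4, 1.5, 1.3, 0.9, 0,   0,   0),
                c(0,   0,   0,   0.8, 1.5, 1.4, 1.6, 1.3))
  rgc_model(bank, pool, baseline = 0.2, gain = 2.5)
}

#' Simulate RGC firing rates in response to a stimulus clip
#'
#' The stimulus is mean-centred (binary \{0,1\} noise becomes ±0.5) before
#' filtering. One rate is produced per bin from \code{depth} onward, i.e.
#' one per sliding window of the clip.
#'
#' @param model an \code{\link{rgc_model}}.
#' @param clip a \code{\link{stimulus_clip}} at the model's grid size.
#' @param center value subtracted from the stimulus before filtering
#'   (default 0.5, the binary-noise mean).
#' @return object of class \code{rate_matrix}: list with \code{rates}
#'   (n_cells x n_bins, spikes/bin), \code{bin_ms}, and \code{alignment}
#'   (clip bins the columns correspond to).
#' @export
simulate_rgc_response <- function(model, clip, center = 0.5) {
  stopifnot(inherits(model, "rgc_model"), inherits(clip, "stimulus_clip"))
  depth <- length(model$subunits[[1]]$temporal_kernel)
  d <- dim(clip$frames)
  if (d[1] < depth) stop_bad_arg("clip shorter than temporal depth")
  ws <- make_windows(clip, depth = depth, stride = 1L)
  n <- dim(ws$windows)[1]
  X <- matrix(ws$windows - center, nrow = n)   # n x (depth*h*w), col-major
  drive <- vapply(model$subunits, function(su) {
    as.numeric(X %*% as.numeric(subunit_window_tensor(su)))
  }, numeric(n))                                # n x n_subunits
  act <- pmax(drive, 0)
  z <- model$gain * (act %*% t(model$pooling))  # n x n_cells
  z <- sweep(z, 2, model$baseline, "+")
  rates <- t(log1p(exp(pmin(z, 30))) + pmax(z - 30, 0))  # stable softplus
  structure(list(rates = rates, bin_ms = clip$bin_ms, alignment = ws$alignment),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d cells x %d bins, mean %.3f spikes/bin\n",
              nrow(x$rates), ncol(x$rates), mean(x$rates)))
  invisible(x)
}

#' Sample Poisson spike counts from firing rates
#'
#' Independent Poisson draws per cell, trial and bin with mean equal to the
#' rate (spikes/bin).
#'
#' @param rates a \code{rate_matrix} or a bare nonnegative matrix.
#' @param n_trials number of independent trials.
#' @param seed integer seed (same seed, same spikes).
#' @return 3-D integer array n_cells x n_trials x n_bins.
#' @export
sample_poisson_spikes <- function(rates, n_trials = 1L, seed = 1L) {
  r <- if (inherits(rates, "rate_matrix")) rates$rates else as.matrix(rates)
  if (any(r < 0) || any(!is.finite(r)))
    stop_bad_arg("rates must be finite and nonnegative")
  set.seed(seed)
  nc <- nrow(r); nb <- ncol(r)
  out <- array(0L, c(nc, n_trials, nb))
  for (tr in seq_len(n_trials))
    out[, tr, ] <- matrix(stats::rpois(nc * nb, lambda = r), nc, nb)
  out
}
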