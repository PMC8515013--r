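# Experiment orchestration: plain-text array containers, encoder
# checkpoints, fixture generation, and config-driven experiment runs.

#' Write named numeric arrays to a single plain-text container
#'
#' One JSON file holding, per array, its dimensions and flattened
#' (column-major) data at full double precision. The package-wide exchange
#' format for clips, rate matrices, filters and spike tensors.
#'
#' @param arrays named list of numeric vectors/matrices/arrays.
#' @param path output file path (conventionally \code{.arrays.json}).
#' @return \code{path}, invisibly.
#' @export
save_arrays <- function(arrays, path) {
  stopifnot(is.list(arrays), !is.null(names(arrays)))
  payload <- lapply(arrays, function(a)
    list(dim = if (is.null(dim(a))) length(a) else dim(a),
         data = as.numeric(a)))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read a \code{\link{save_arrays}} container
#'
#' @param path file written by \code{save_arrays}.
#' @return named list of arrays with their original dimensions.
#' @export
load_arrays <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(a) {
    d <- as.integer(a$dim)
    if (length(d) == 1L) as.numeric(a$data) else array(as.numeric(a$data), d)
  })
}

#' Save an encoder checkpoint (plain text)
#'
#' @param model an \code{\link{encoder_model}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
save_encoder <- function(model, path) {
  stopifnot(inherits(model, "encoder_model"))
  s <- model$spec
  meta <- list(input_shape = s$input_shape, conv1 = s$conv1, conv2 = s$conv2,
               recurrent = s$recurrent, n_outputs = s$n_outputs,
               noise_sigma = s$noise_sigma, reg = s$reg, readout = s$readout,
               batchnorm = s$batchnorm)
  arr <- function(a) list(dim = if (is.null(dim(a))) length(a) else dim(a),
                          data = as.numeric(a))
  jsonlite::write_json(list(spec = meta,
                            par = lapply(model$par, arr),
                            bn_stats = lapply(model$bn_stats, arr),
                            mask = model$mask),
                       path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load an encoder checkpoint
#'
#' @param path file written by \code{\link{save_encoder}}.
#' @return an \code{\link{encoder_model}}.
#' @export
load_encoder <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$spec
  rec <- if (!is.null(m$recurrent) && length(m$recurrent))
    list(unit_type = m$recurrent$unit_type,
         hidden_size = m$recurrent$hidden_size,
         sequence_len = m$recurrent$sequence_len) else NULL
  spec <- model_spec(m$input_shape,
                     conv1 = as.list(m$conv1), conv2 = as.list(m$conv2),
                     recurrent = rec, n_outputs = m$n_outputs,
                     noise_sigma = m$noise_sigma, reg = as.list(m$reg),
                     readout = m$readout, batchnorm = m$batchnorm)
  unarr <- function(a) {
    d <- as.integer(a$dim)
    if (length(d) == 1L) as.numeric(a$data) else array(as.numeric(a$data), d)
  }
  structure(list(spec = spec, par = lapply(x$par, unarr),
                 bn_stats = lapply(x$bn_stats, unarr),
                 mask = as.numeric(x$mask)),
            class = "encoder_model")
}

# movie-scale simulated retina: Gaussian-blob subunits scattered on the grid
.movie_retina <- function(grid_hw = c(90L, 90L), n_subunits = 8L,
                          n_cells = 4L, depth = 20L, seed = 0L) {
  set.seed(seed)
  subs <- lapply(seq_len(n_subunits), function(i) {
    cy <- stats::runif(1, 0.15, 0.85) * grid_hw[1]
    cx <- stats::runif(1, 0.15, 0.85) * grid_hw[2]
    subunit_filter(.shape_gaussian(grid_hw, cy, cx,
                                   sy = stats::runif(1, 4, 8),
                                   sx = stats::runif(1, 4, 8)),
                   .biphasic_kernel(depth, peak = sample(3:5, 1)),
                   polarity = sample(c("ON", "OFF"), 1))
  })
  pool <- matrix(0, n_cells, n_subunits)
  for (c_ in seq_len(n_cells))
    pool[c_, sample.int(n_subunits, 3)] <- stats::runif(3, 0.8, 1.6)
  rgc_model(subs, pool, baseline = 0.2, gain = 2.5)
}

# chunked rate simulation for long clips (keeps the window tensor small)
.simulate_chunked <- function(model, clip, chunk_bins = 256L) {
  depth <- length(model$subunits[[1]]$temporal_kernel)
  nT <- dim(clip$frames)[1]
  starts <- seq(depth, nT, by = chunk_bins)
  pieces <- lapply(starts, function(s0) {
    s1 <- min(s0 + chunk_bins - 1L, nT)
    sub <- stimulus_clip(clip$frames[(s0 - depth + 1L):s1, , , drop = FALSE],
                         clip$bin_ms)
    simulate_rgc_response(model, sub)$rates
  })
  structure(list(rates = do.call(cbind, pieces), bin_ms = clip$bin_ms,
                 alignment = depth:nT),
            class = "rate_matrix")
}

#' Generate a self-contained dataset fixture on disk
#'
#' \code{"whitenoise_sim"}: binary white noise shown to the canonical
#' two-RGC simulated retina (clip, rates, Poisson spikes).
#' \code{"toy_movie"}: a procedurally generated movie (drifting grating
#' plus moving Gaussian blobs, 90x90 px, 33 ms bins) with responses of a
#' movie-scale simulated RGC population.
#'
#' @param kind \code{"whitenoise_sim"} or \code{"toy_movie"}.
#' @param seed integer seed; fixtures are byte-identical per seed.
#' @param dir output directory (created if missing).
#' @param n_frames white-noise clip length.
#' @param duration_s toy-movie duration in seconds.
#' @return path of the written container file, invisibly; the container
#'   holds \code{frames}, \code{rates}, \code{alignment} and (white noise)
#'   \code{spikes}.
#' @export
make_fixture <- function(kind = c("whitenoise_sim", "toy_movie"), seed = 0L,
                         dir = tempdir(), n_frames = 2000L, duration_s = 10) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(kind, "_seed", seed, ".arrays.json"))
  if (kind == "whitenoise_sim") {
    clip <- generate_white_noise(n_frames, 8, 8, "binary", seed = seed)
    retina <- build_demo_retina()
    rates <- simulate_rgc_response(retina, clip)
    spikes <- sample_poisson_spikes(rates, n_trials = 5L, seed = seed + 1L)
    save_arrays(list(frames = clip$frames, rates = rates$rates,
                     alignment = rates$alignment, spikes = spikes,
                     bin_ms = clip$bin_ms), path)
  } else {
    bin_ms <- 33
    nT <- floor(duration_s * 1000 / bin_ms)
    hw <- c(90L, 90L)
    set.seed(seed)
    yy <- matrix(seq_len(hw[1]), hw[1], hw[2])
    xx <- matrix(seq_len(hw[2]), hw[1], hw[2], byrow = TRUE)
    frames <- array(0, c(nT, hw))
    phase <- stats::runif(1, 0, 2 * pi)
    for (t in seq_len(nT)) {
      grating <- 0.5 + 0.25 * sin(2 * pi * (xx * cos(0.4) + yy * sin(0.4)) / 22
                                  + phase + 0.35 * t)
      bx <- hw[2] * (0.5 + 0.3 * cos(2 * pi * t / 60))
      by <- hw[1] * (0.5 + 0.3 * sin(2 * pi * t / 47))
      blob <- 0.35 * exp(-(((xx - bx)^2 + (yy - by)^2) / (2 * 7^2)))
      frames[t, , ] <- pmin(pmax(grating + blob, 0), 1)
    }
    clip <- stimulus_clip(frames, bin_ms)
    retina <- .movie_retina(hw, seed = seed)
    rates <- .simulate_chunked(retina, clip)
    save_arrays(list(frames = clip$frames, rates = rates$rates,
                     alignment = rates$alignment, bin_ms = bin_ms), path)
  }
  invisible(path)
}

#' Run a configured desk-scale experiment
#'
#' Orchestrates the package's three standard experiments end-to-end and
#' writes all results (configs, metrics, checkpoints, arrays) into a
#' deterministic directory layout.
#'
#' @param cfg a list, or path to a YAML file, with fields
#'   \code{experiment} (one of \code{"subunit_recovery"},
#'   \code{"pruning_curve"}, \code{"complexity"}), \code{out_dir},
#'   \code{seed}, and experiment-specific parameters (see the methods
#'   vignette); unset parameters use desk-scale defaults.
#' @return named list of result objects (also written to \code{out_dir}).
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  exp_name <- cfg$experiment %||% stop_bad_arg("cfg$experiment missing")
  known <- c("subunit_recovery", "pruning_curve", "complexity")
  if (!exp_name %in% known)
    stop_bad_arg("unknown experiment '", exp_name, "'")
  out_dir <- cfg$out_dir %||% file.path(tempdir(), paste0("run_", exp_name))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  if (exp_name == "complexity") {
    clip <- if (!is.null(cfg$movie)) {
      arr <- load_arrays(cfg$movie)
      stimulus_clip(arr$frames, arr$bin_ms %||% 33)
    } else {
      fx <- make_fixture("toy_movie", seed = seed, dir = out_dir,
                         duration_s = cfg$duration_s %||% 3)
      arr <- load_arrays(fx)
      stimulus_clip(arr$frames, arr$bin_ms)
    }
    patch <- cfg$patch_px %||% 18L
    sc <- spatial_complexity(clip, patch)
    tc <- temporal_complexity(clip, patch)
    utils::write.csv(sc, file.path(out_dir, "spatial_complexity.csv"),
                     row.names = FALSE)
    utils::write.csv(tc, file.path(out_dir, "temporal_complexity.csv"),
                     row.names = FALSE)
    summ <- list(patch_px = patch, mean_SC = mean(sc), mean_TC = mean(tc))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(SC = sc, TC = tc, summary = summ)))
  }

  # both remaining experiments train on the white-noise fixture
  n_train <- cfg$n_train %||% 6000L
  n_test <- cfg$n_test %||% 1280L
  depth <- 20L
  retina <- build_demo_retina()
  clip <- generate_white_noise(n_train + n_test + depth - 1L, 8, 8, "binary",
                               seed = seed)
  rates <- simulate_rgc_response(retina, clip)
  ws <- make_windows(clip, depth)
  tr <- seq_len(n_train); te <- n_train + seq_len(n_test)
  arch <- cfg$arch %||% "cnn"
  spec <- model_spec(c(depth, 8L, 8L),
                     conv1 = list(n = cfg$n_kernels %||% 8L, hw = 8L),
                     conv2 = list(n = 8L, hw = 1L),
                     recurrent = if (arch == "crnn")
                       list(unit_type = cfg$unit %||% "lstm",
                            hidden_size = cfg$hidden %||% 32L,
                            sequence_len = cfg$seq_len %||% 64L) else NULL,
                     n_outputs = 2L)
  cfg_train <- train_config(max_epochs = cfg$max_epochs %||% 150L,
                            seed = seed, verbose = 0L)
  fit <- train(init_encoder(spec, seed = seed),
               ws$windows[tr, , , , drop = FALSE],
               rates$rates[, tr, drop = FALSE], cfg_train)
  pred <- encoder_forward(fit$model, ws$windows[te, , , , drop = FALSE])
  cc_test <- suppressWarnings(
    cc_per_cell(pred$rates, rates$rates[, te, drop = FALSE]))
  save_encoder(fit$model, file.path(out_dir, "checkpoint.json"))

  if (exp_name == "subunit_recovery") {
    match_tab <- match_kernels_to_subunits(conv1_kernels(fit$model),
                                           retina$subunits)
    utils::write.csv(match_tab, file.path(out_dir, "matching.csv"),
                     row.names = FALSE)
    sta <- lapply(seq_len(2), function(c_)
      compute_sta(ws$windows[te, , , , drop = FALSE], pred$rates[c_, ]))
    save_arrays(stats::setNames(lapply(sta, unclass),
                                paste0("sta_cell", 1:2)),
                file.path(out_dir, "sta.arrays.json"))
    metrics <- list(held_out_cc = cc_test, mean_cc = mean(cc_test),
                    matched = sum(match_tab$similarity >= 0.7))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(model = fit$model, matching = match_tab,
                          metrics = metrics)))
  }

  scores <- score_kernels(fit$model)
  curve <- pruning_curve(fit$model, ws$windows[te, , , , drop = FALSE],
                         rates$rates[, te, drop = FALSE], scores,
                         index = cfg$index %||% "tCorr",
                         ks = cfg$ks %||% seq_len(spec$conv1$n))
  utils::write.csv(curve, file.path(out_dir, "pruning_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(scores, file.path(out_dir, "kernel_scores.csv"),
                   row.names = FALSE)
  invisible(list(model = fit$model, scores = scores, curve = curve))
}
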