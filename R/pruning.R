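# Kernel-importance pruning: rank first-layer kernels by spaCorr or tCorr
# and evaluate reduced (masked) models, training-free.

#' Rank first-layer kernels by an importance index
#'
#' Stable descending sort by the chosen index; ties broken by kernel id
#' (ascending).
#'
#' @param scores data.frame from \code{\link{score_kernels}}.
#' @param index \code{"spaCorr"} or \code{"tCorr"}.
#' @return integer vector of kernel ids, most important first.
#' @export
rank_kernels <- function(scores, index = c("tCorr", "spaCorr")) {
  index <- match.arg(index)
  if (!nrow(scores)) stop_bad_arg("empty score table")
  ord <- order(-scores[[index]], scores$kernel)
  scores$kernel[ord]
}

#' Reduced model with a subset of first-layer kernels
#'
#' Masks (zeroes the post-normalization output of) every first-layer kernel
#' not in \code{keep_ids}. No weights are altered and nothing is retrained;
#' keeping all kernels reproduces the full model exactly.
#'
#' @param model an \code{\link{encoder_model}}.
#' @param keep_ids nonempty subset of first-layer kernel indices.
#' @return the masked \code{encoder_model}.
#' @export
prune_model <- function(model, keep_ids) {
  stopifnot(inherits(model, "encoder_model"))
  K <- model$spec$conv1$n
  keep_ids <- unique(as.integer(keep_ids))
  if (!length(keep_ids) || any(keep_ids < 1L | keep_ids > K))
    stop_bad_arg("keep_ids must be a nonempty subset of 1..", K)
  model$mask <- as.numeric(seq_len(K) %in% keep_ids)
  model
}

#' Performance-versus-kernel-count pruning curve
#'
#' For each requested kernel count k, keeps the k top-ranked kernels under
#' the chosen index, evaluates the masked model in eval mode, and records
#' the mean per-cell CC and population CC against the targets.
#'
#' @param model trained \code{\link{encoder_model}}.
#' @param windows evaluation windows.
#' @param targets matching \code{rate_matrix} (or n_cells x n_bins matrix).
#' @param scores kernel score table (\code{\link{score_kernels}}); computed
#'   from the model when \code{NULL}.
#' @param index ranking index, \code{"tCorr"} or \code{"spaCorr"}.
#' @param ks kernel counts to evaluate.
#' @param order_override optional explicit kernel order (most important
#'   first), bypassing the index ranking (used e.g. for random-order
#'   baselines).
#' @return data.frame with columns \code{index_used}, \code{kept_k},
#'   \code{mCC}, \code{popCC}, plus attribute \code{kept_ids} (list).
#' @export
pruning_curve <- function(model, windows, targets, scores = NULL,
                          index = "tCorr", ks = NULL,
                          order_override = NULL) {
  K <- model$spec$conv1$n
  ks <- if (is.null(ks)) seq_len(K) else as.integer(ks)
  if (any(ks < 1L | ks > K)) stop_bad_arg("ks must lie in 1..n_kernels")
  ord <- if (!is.null(order_override)) as.integer(order_override)
         else rank_kernels(scores %||% score_kernels(model), index)
  Y <- .as_target_matrix(targets)
  kept <- vector("list", length(ks))
  res <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    ids <- ord[seq_len(k)]
    kept[[i]] <<- ids
    pm <- prune_model(model, ids)
    pred <- encoder_forward(pm, windows)
    cc <- suppressWarnings(cc_per_cell(pred$rates, t(Y)))
    data.frame(index_used = if (is.null(order_override)) index else "custom",
               kept_k = k, mCC = mean(cc),
               popCC = suppressWarnings(population_cc(pred$rates, t(Y))))
  })
  out <- do.call(rbind, res)
  attr(out, "kept_ids") <- kept
  out
}
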