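# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

#' Cosine similarity between two numeric arrays
#'
#' Arrays are flattened; returns \code{sum(a*b) / (||a|| ||b||)}.
#' Zero-norm input gives \code{NA}.
#'
#' @param a,b numeric arrays of equal length.
#' @return scalar in \[-1, 1\], or \code{NA} for a zero-norm input.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_bad_arg("cosine_similarity: length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Pearson r that is 0 (with a warning) when either input is constant.
safe_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant sequence in correlation; returning 0")
    return(0)
  }
  stats::cor(x, y)
}

# Optimal one-to-one assignment maximizing sum of scores, exact bitmask DP.
# score: n x m matrix (n <= m). Returns integer vector: row i -> column idx.
assign_optimal <- function(score) {
  n <- nrow(score); m <- ncol(score)
  if (n > m) stop_bad_arg("assign_optimal: more rows than columns")
  if (m > 20) stop_bad_arg("assign_optimal: problem too large for exact DP")
  nstates <- bitwShiftL(1L, m)
  best <- rep(-Inf, nstates)
  choice <- matrix(NA_integer_, n, nstates)
  best[1L] <- 0
  # states with k bits set correspond to rows 1..k assigned
  for (i in seq_len(n)) {
    nxt <- rep(-Inf, nstates)
    idx <- which(is.finite(best)) - 1L
    for (s in idx) {
      base <- best[s + 1L]
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) == 0L) {
          s2 <- bitwOr(s, bit)
          v <- base + score[i, j]
          if (v > nxt[s2 + 1L]) {
            nxt[s2 + 1L] <- v
            choice[i, s2 + 1L] <- j
          }
        }
      }
    }
    best <- nxt
  }
  s <- which.max(best) - 1L
  out <- integer(n)
  for (i in rev(seq_len(n))) {
    j <- choice[i, s + 1L]
    out[i] <- j
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  out
}
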