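#' Log-normalize RNA counts
#'
#' Elementwise natural log(1 + count).  Adding 1 keeps zero counts at zero and
#' makes the transform defined everywhere; it is strictly monotone in the raw
#' counts.
#'
#' @param m features x cells count matrix.
#' @return matrix of the same shape and class family (sparsity preserved).
#' @export
logNormalize <- function(m) {
  if (any(m < 0)) stop("negative counts cannot be log-normalized")
  log1p(m)
}

#' Centred log-ratio (CLR) transform of ADT counts
#'
#' For each ADT k across cells j, computes
#' \eqn{x_{kj} = \ln((q_{kj} + c) / g_k)} where \eqn{g_k} is the geometric
#' mean of \eqn{q_{kj} + c} over cells and \eqn{c} is a pseudocount.  Each ADT
#' is centred across cells, so every output row sums to zero (to numerical
#' tolerance).  ADT counts are compositional (total tag counts per cell are
#' arbitrary), which is why a ratio transform rather than log1p is used.
#'
#' @param q features x cells ADT count matrix.
#' @param pseudocount added to all counts before the transform; must be
#'   positive when any count is zero (the raw CLR is undefined at 0).
#' @return dense numeric matrix, features x cells.
#' @export
clrTransform <- function(q, pseudocount = 1) {
  q <- as.matrix(q)
  if (any(q < 0)) stop("negative ADT counts")
  if (pseudocount <= 0 && any(q == 0))
    stop("zero counts present: the log of 0 is undefined, use pseudocount > 0")
  lg <- log(q + pseudocount)
  lg - rowMeans(lg)
}

#' MinMax rescale per feature
#'
#' Rescales each feature (row) to [0, 1] across cells:
#' \eqn{(x_{ij} - \min_i) / (\max_i - \min_i)}.  Constant rows map to 0.
#' With \code{literal_shift = TRUE} the global minimum of the input matrix is
#' added to every rescaled value; for log-normalized RNA (global minimum 0)
#' this is a no-op, while for CLR input (global minimum below 0) it shifts the
#' output out of [0, 1], so the shift is off by default.
#'
#' @param x features x cells numeric matrix.
#' @param literal_shift add the global input minimum to the rescaled values.
#' @return dense numeric matrix, features x cells.
#' @export
minMaxScale <- function(x, literal_shift = FALSE) {
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty matrix")
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  den <- hi - lo
  const <- den == 0
  den[const] <- 1
  out <- (x - lo) / den
  out[const, ] <- 0
  if (literal_shift) out <- out + min(x)
  out
}
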