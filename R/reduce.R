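#' Principal component reduction of a scaled matrix
#'
#' Treats cells as samples: features are mean-centred across cells (no unit
#' variance scaling) and decomposed by exact SVD (\code{prcomp}).  Explained
#' variances use n_samples - 1 degrees of freedom.  The sign of each component
#' is fixed deterministically by making the loading of largest absolute value
#' positive, so repeated runs are bit-identical.
#'
#' @param x features x cells numeric matrix (typically MinMax-scaled).
#' @param k number of components to keep, or \code{"all"} for every available
#'   component (min(features, cells - 1)).
#' @param seed unused by the exact solver; kept so callers can pass a seed
#'   uniformly across reduction backends.
#' @param modality recorded in the result.
#' @return a \linkS4class{LowDimRep}.
#' @export
pcaReduce <- function(x, k = "all", seed = NULL, modality = "rna") {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("PCA needs at least 2 cells")
  kmax <- min(nrow(x), ncol(x) - 1L)
  if (identical(k, "all")) k <- kmax
  if (k > nrow(x))
    stop("k (", k, ") exceeds the number of features (", nrow(x), ")")
  k <- min(k, kmax)
  if (all(apply(x, 1, stats::sd) == 0))
    stop("zero-variance input: no principal directions exist")
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sc <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  scores <- t(sc)
  rownames(scores) <- paste0("PC", seq_len(k))
  colnames(scores) <- colnames(x)
  .LowDimRep(scores, pr$sdev[seq_len(k)]^2, rot, modality)
}

#' Use the scaled ADT matrix itself as the low-dimensional representation
#'
#' For panels with few ADTs, reduction is unnecessary and every scaled ADT is
#' carried forward as one component.  Components are ordered by decreasing
#' variance (n - 1 degrees of freedom) so the representation obeys the same
#' ordering contract as a PCA result; downstream stages are invariant to row
#' order.
#'
#' @param x features x cells scaled matrix.
#' @param modality recorded in the result.
#' @return a \linkS4class{LowDimRep} whose loadings are a permutation basis.
#' @export
passthroughRep <- function(x, modality = "adt") {
  x <- as.matrix(x)
  v <- apply(x, 1, stats::var)
  ord <- order(-v, rownames(x))
  basis <- diag(nrow(x))[, ord, drop = FALSE]
  rownames(basis) <- rownames(x)
  colnames(basis) <- rownames(x)[ord]
  .LowDimRep(x[ord, , drop = FALSE], v[ord], basis, modality)
}

#' Elbow selection of the component count
#'
#' Finds the elbow of a non-increasing explained-variance curve as the point
#' of maximum perpendicular distance to the chord joining the first and last
#' points (axes normalised to [0, 1] first).  The components strictly before
#' the elbow are retained, so the returned k is (elbow index - 1), with a
#' minimum of 1; a straight-line decay has no curvature and yields k = 1.
#'
#' @param ev non-increasing numeric vector of explained variances, length >= 3.
#' @return integer k.
#' @examples
#' elbowSelect(c(50, 30, 2, 1.9, 1.8, 1.7))  # 2
#' @export
elbowSelect <- function(ev) {
  n <- length(ev)
  if (n < 3)
    stop("need at least 3 explained-variance values; set k manually")
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- max(ev) - min(ev)
  y <- if (rng > 0) (ev - min(ev)) / rng else rep(0, n)
  # distance from (x_i, y_i) to the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + x[n] * y[1] - y[n] * x[1]) / sqrt(dx^2 + dy^2)
  elbow <- which.max(d)
  max(1L, elbow - 1L)
}

#' Integrate two modality representations by a second PCA
#'
#' Each representation is MinMax-rescaled per component to [0, 1] to remove
#' the difference in score ranges between modalities, the two are stacked
#' row-wise, and PCA is applied to the stacked matrix.  The result is the
#' shared multimodal representation used for clustering and embedding.
#'
#' @param rna_rep,adt_rep \linkS4class{LowDimRep} over the same cells in the
#'   same order (checked; no silent reindexing).
#' @param k multimodal component count, or \code{"auto"} for elbow selection.
#' @param seed forwarded to \code{\link{pcaReduce}}.
#' @return a \linkS4class{LowDimRep} with modality \code{"multimodal"}.
#' @export
integrateModalities <- function(rna_rep, adt_rep, k = "auto", seed = NULL) {
  s1 <- scores(rna_rep)
  s2 <- scores(adt_rep)
  if (nrow(s2) > 0 && nrow(s1) > 0 &&
      !identical(colnames(s1), colnames(s2)))
    stop("cell order mismatch between RNA and ADT representations")
  blocks <- list()
  if (nrow(s1) > 0) blocks$rna <- minMaxScale(s1)
  if (nrow(s2) > 0) blocks$adt <- minMaxScale(s2)
  if (length(blocks) == 0) stop("both representations are empty")
  stacked <- do.call(rbind, blocks)
  rownames(stacked) <- unlist(lapply(names(blocks), function(b)
    paste0(b, "_", rownames(scores(if (b == "rna") rna_rep else adt_rep)))))
  full <- pcaReduce(stacked, k = "all", seed = seed, modality = "multimodal")
  kk <- if (identical(k, "auto")) elbowSelect(explainedVariance(full))
        else min(k, nComponents(full))
  .truncateRep(full, kk)
}
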