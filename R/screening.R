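#' Per-gene reliability statistics
#'
#' Computes the two reliability indexes used for gene screening: the total
#' expression of each gene across cells, and the sparsity, i.e. the number of
#' cells in which the gene is detected (non-zero count).
#'
#' @param m features x cells count matrix.
#' @return data.frame with columns \code{feature}, \code{total},
#'   \code{sparsity}.
#' @examples
#' m <- matrix(c(0, 2, 3), 1, 3, dimnames = list("G1", paste0("C", 1:3)))
#' geneStats(m)  # total 5, sparsity 2
#' @export
geneStats <- function(m) {
  data.frame(feature = rownames(m),
             total = as.numeric(Matrix::rowSums(m)),
             sparsity = as.integer(Matrix::rowSums(m != 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen genes by total expression and sparsity
#'
#' Keeps exactly the genes whose total expression exceeds \code{t_frac * J}
#' and whose sparsity (number of expressing cells) exceeds \code{sp_frac * J},
#' with J the number of cells and both inequalities strict.  The default
#' fractions correspond to requiring detection in more than 5\% of cells with
#' a total count above 1\% of the cell number.
#'
#' @param m features x cells count matrix (RNA).
#' @param t_frac total-expression threshold as a fraction of J, in [0, 1].
#' @param sp_frac sparsity threshold as a fraction of J, in [0, 1].
#' @param stats optional precomputed \code{\link{geneStats}} result.
#' @param keep feature ids retained regardless of the thresholds (e.g. a
#'   species pre-screen selection); unknown ids are ignored.
#' @return the screened count matrix, row order preserved.
#' @export
screenGenes <- function(m, t_frac = 0.01, sp_frac = 0.05, stats = NULL,
                        keep = character(0)) {
  stopifnot(t_frac >= 0, t_frac <= 1, sp_frac >= 0, sp_frac <= 1)
  if (is.null(stats)) stats <- geneStats(m)
  J <- ncol(m)
  pass <- stats$total > t_frac * J & stats$sparsity > sp_frac * J
  pass <- pass | rownames(m) %in% keep
  if (!any(pass))
    stop("gene screening removed all genes; relax t_frac/sp_frac")
  m[pass, , drop = FALSE]
}

#' Select the features with the largest coefficient of variation
#'
#' Among features whose id starts with \code{prefix} (a species prefix such as
#' \code{"mm10-"} for a mouse spike-in), returns the \code{n} with the largest
#' coefficient of variation across cells (sd / mean, sd with n - 1 degrees of
#' freedom).  Features with zero mean are excluded; ties are broken by
#' lexicographic feature id for determinism.
#'
#' @param m features x cells count matrix.
#' @param prefix feature-id prefix to restrict to ("" matches all features).
#' @param n number of features to return; clamped to the number available.
#' @return character vector of feature ids (possibly empty, with a warning if
#'   nothing matches the prefix).
#' @export
topCVFeatures <- function(m, prefix, n = 100) {
  stopifnot(n >= 1)
  hit <- startsWith(rownames(m), prefix)
  if (!any(hit)) {
    warning("no features match prefix '", prefix, "'")
    return(character(0))
  }
  sub <- as.matrix(m[hit, , drop = FALSE])
  mu <- rowMeans(sub)
  sd <- apply(sub, 1, stats::sd)
  cv <- ifelse(mu > 0, sd / mu, NA_real_)
  ids <- rownames(sub)[!is.na(cv)]
  cv <- cv[!is.na(cv)]
  ord <- order(-cv, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Remove contaminated ADTs by name
#'
#' Drops antibody tags flagged as contaminated (non-specific binding), e.g.
#' the CCR7/CCR5/CD10 conjugates in cord-blood CITE-seq panels.  Unknown names
#' warn in the default mode and error when \code{strict = TRUE}.
#'
#' @param q features x cells ADT count matrix.
#' @param names ADT ids to remove.
#' @param strict error (rather than warn) on unknown names.
#' @return the reduced ADT matrix.
#' @export
dropADTs <- function(q, names = character(0), strict = FALSE) {
  if (length(names) == 0) return(q)
  unknown <- setdiff(names, rownames(q))
  if (length(unknown)) {
    msg <- paste("unknown ADT name(s):", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  out <- q[!rownames(q) %in% names, , drop = FALSE]
  if (nrow(out) == 0)
    stop("dropADTs would remove every ADT")
  out
}
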