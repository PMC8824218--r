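#' Marginal high/low probabilities for one ADT in a cluster
#'
#' On MinMax-scaled ADT values in [0, 1], a cell expresses the ADT "high" when
#' its value is at or above the threshold theta (the boundary counts as high).
#' PH is the fraction of high cells in the cluster and PL = 1 - PH.
#'
#' @param values scaled ADT values for the cells of one cluster.
#' @param theta threshold in [0, 1]; default 0.5.
#' @return named numeric vector \code{c(PH = , PL = )}.
#' @export
marginalProbs <- function(values, theta = 0.5) {
  if (length(values) == 0) stop("empty cluster")
  stopifnot(theta >= 0, theta <= 1)
  ph <- mean(values >= theta)
  c(PH = ph, PL = 1 - ph)
}

#' Quadrant counts and probabilities for an ADT pair
#'
#' Splits the 2-D plane of two scaled ADTs at threshold theta into four
#' quadrants, ordered anticlockwise from the double-positive one:
#' Q1 both >= theta, Q2 adt1 < theta & adt2 >= theta, Q3 both < theta,
#' Q4 adt1 >= theta & adt2 < theta.  Probabilities are the joint cell
#' proportions per quadrant.  The product of the marginal high/low
#' probabilities is returned separately: it coincides with the joint
#' proportions only when the two ADTs are independent, so the difference
#' between the two is itself a dependence diagnostic.
#'
#' @param v1,v2 scaled values of the two ADTs over the same cells.
#' @param theta threshold in [0, 1].
#' @return list with \code{counts} (c1..c4), \code{probs} (p1..p4, joint),
#'   \code{product} (marginal-product form), \code{n}.
#' @export
quadrantProbs <- function(v1, v2, theta = 0.5) {
  if (length(v1) != length(v2))
    stop("ADT vectors differ in length")
  if (length(v1) == 0) stop("empty cluster")
  h1 <- v1 >= theta; h2 <- v2 >= theta
  counts <- c(q1 = sum(h1 & h2), q2 = sum(!h1 & h2),
              q3 = sum(!h1 & !h2), q4 = sum(h1 & !h2))
  n <- length(v1)
  ph1 <- mean(h1); ph2 <- mean(h2)
  list(counts = counts, probs = counts / n,
       product = c(q1 = ph1 * ph2, q2 = (1 - ph1) * ph2,
                   q3 = (1 - ph1) * (1 - ph2), q4 = ph1 * (1 - ph2)),
       n = n)
}

#' Co-expression entropy of a quadrant distribution
#'
#' Base-4 Shannon entropy of the four quadrant probabilities,
#' \eqn{S = -\sum_i P_i' \log_4 P_i'} with \eqn{P_i' = \max(P_i, \epsilon)}:
#' probabilities of exactly zero are replaced by a small epsilon so the
#' logarithm is defined.  S is close to 0 when the cluster sits in a single
#' quadrant (e.g. a double-positive population) and equals 1 when cells are
#' spread uniformly over all four quadrants.  Values above about 0.75 indicate
#' a diffuse pattern without an interpretable co-expression structure.
#'
#' @param p numeric vector of 4 quadrant probabilities summing to 1.
#' @param epsilon replacement for zero probabilities (default 1e-6).
#' @return entropy S in [0, 1 + 4 * epsilon * log4(1/epsilon)].
#' @examples
#' coexpressionEntropy(c(0.25, 0.25, 0.25, 0.25))  # exactly 1
#' coexpressionEntropy(c(1, 0, 0, 0))              # ~ 0
#' @export
coexpressionEntropy <- function(p, epsilon = 1e-6) {
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities must sum to 1 (got ", sum(p), ")")
  stopifnot(epsilon > 0)
  pe <- pmax(p, epsilon)
  -sum(pe * log(pe, base = 4))
}

#' Screen all ADT pairs in all clusters for concentrated co-expression
#'
#' For every cluster and every unordered pair of distinct ADTs, computes the
#' quadrant profile and co-expression entropy on the MinMax-scaled ADT values,
#' together with Pearson, Spearman and Kendall correlations of the two ADT
#' vectors within the cluster as baselines.  Rows are sorted by entropy
#' ascending, so concentrated patterns (double-positive populations and
#' single-positive/double-negative structure) surface first.
#'
#' @param x features x cells MinMax-scaled ADT matrix (values in [0, 1]).
#' @param clusters integer cluster labels, one per cell.
#' @param theta quadrant threshold in [0, 1].
#' @param epsilon zero-probability replacement for the entropy.
#' @param product_form additionally report the marginal-product quadrant
#'   probabilities (pp1..pp4).
#' @return data.frame with columns cluster, adt1, adt2, n, c1..c4, p1..p4,
#'   entropy, pearson, spearman, kendall, band.  Correlations are NA for
#'   clusters with fewer than 3 cells or constant ADT vectors.  The band
#'   annotates the entropy: "single-quadrant" (< 0.25), "two-quadrant"
#'   (0.25-0.75), "diffuse" (> 0.75).
#' @export
screenPairs <- function(x, clusters, theta = 0.5, epsilon = 1e-6,
                        product_form = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 ADTs to form pairs")
  if (ncol(x) != length(clusters))
    stop("clusters must have one label per cell")
  adts <- rownames(x)
  labs <- sort(unique(as.integer(clusters)))
  pairs <- utils::combn(adts, 2)
  rows <- vector("list", length(labs) * ncol(pairs))
  r <- 0
  for (cl in labs) {
    cells <- as.integer(clusters) == cl
    sub <- x[, cells, drop = FALSE]
    for (j in seq_len(ncol(pairs))) {
      a1 <- pairs[1, j]; a2 <- pairs[2, j]
      v1 <- sub[a1, ]; v2 <- sub[a2, ]
      qp <- quadrantProbs(v1, v2, theta)
      s <- coexpressionEntropy(qp$probs, epsilon)
      cors <- .safe_cors(v1, v2)
      row <- data.frame(cluster = cl, adt1 = a1, adt2 = a2, n = qp$n,
                        c1 = qp$counts[1], c2 = qp$counts[2],
                        c3 = qp$counts[3], c4 = qp$counts[4],
                        p1 = qp$probs[1], p2 = qp$probs[2],
                        p3 = qp$probs[3], p4 = qp$probs[4],
                        entropy = s, pearson = cors[1], spearman = cors[2],
                        kendall = cors[3],
                        band = if (s < 0.25) "single-quadrant"
                               else if (s <= 0.75) "two-quadrant"
                               else "diffuse",
                        row.names = NULL, stringsAsFactors = FALSE)
      if (product_form) {
        row$pp1 <- qp$product[1]; row$pp2 <- qp$product[2]
        row$pp3 <- qp$product[3]; row$pp4 <- qp$product[4]
      }
      r <- r + 1
      rows[[r]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$entropy, out$cluster, out$adt1, out$adt2), , drop = FALSE]
}

.safe_cors <- function(v1, v2) {
  if (length(v1) < 3 || stats::sd(v1) == 0 || stats::sd(v2) == 0)
    return(c(NA_real_, NA_real_, NA_real_))
  c(stats::cor(v1, v2, method = "pearson"),
    stats::cor(v1, v2, method = "spearman"),
    stats::cor(v1, v2, method = "kendall"))
}

#' Quadrant scatter plot for one ADT pair in one cluster
#'
#' Scatter of the two scaled ADT values with threshold gridlines and the
#' co-expression entropy annotated, mirroring how double-positive populations
#' are displayed in flow-cytometry style quadrant gating.
#'
#' @param x scaled ADT matrix (features x cells).
#' @param clusters integer labels per cell.
#' @param cluster the cluster to plot.
#' @param adt1,adt2 ADT ids.
#' @param theta threshold.
#' @param epsilon entropy epsilon.
#' @param file optional png path; when given, the plot is written there.
#' @return the entropy, invisibly.
#' @export
plotQuadrants <- function(x, clusters, cluster, adt1, adt2, theta = 0.5,
                          epsilon = 1e-6, file = NULL) {
  cells <- as.integer(clusters) == cluster
  v1 <- as.matrix(x)[adt1, cells]
  v2 <- as.matrix(x)[adt2, cells]
  s <- coexpressionEntropy(quadrantProbs(v1, v2, theta)$probs, epsilon)
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(v1, v2, xlim = c(0, 1), ylim = c(0, 1), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6),
                 xlab = adt1, ylab = adt2,
                 main = sprintf("cluster %s: En = %.2f", cluster, s))
  graphics::abline(v = theta, h = theta, lty = 2, col = "grey40")
  invisible(s)
}
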