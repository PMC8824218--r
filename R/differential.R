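#' One-vs-rest Wilcoxon differential analysis
#'
#' Tests every feature in every cluster against all remaining cells with the
#' Wilcoxon rank-sum (Mann-Whitney) test, using the normal approximation with
#' tie and continuity corrections (the behaviour of
#' \code{wilcox.test(exact = FALSE, correct = TRUE)}).  P-values are adjusted
#' by Benjamini-Hochberg across features within each cluster.  The groups
#' being compared (one cluster vs the rest) are independent samples, which is
#' why the rank-sum rather than the paired signed-rank form is used; a
#' signed-rank variant is available for genuinely paired equal-size groups.
#'
#' @param x features x cells normalized matrix (log RNA or CLR ADT values).
#' @param clusters integer cluster labels, one per cell (same order as the
#'   columns of \code{x}).
#' @param min_cells clusters below this size are skipped with a warning.
#' @param test \code{"ranksum"} (default) or \code{"signedrank"}.
#' @return data.frame with one row per (cluster, feature): \code{cluster},
#'   \code{feature}, \code{statistic} (Mann-Whitney U of the cluster group),
#'   \code{p}, \code{padj}, \code{logFC} (base-2 ratio of group means of the
#'   normalized values, pseudocount 1e-9; NA when a mean is non-positive),
#'   \code{mean_in}, \code{mean_out}; sorted by cluster, then adjusted p, then
#'   decreasing |logFC|.
#' @export
wilcoxonDE <- function(x, clusters, min_cells = 3, test = c("ranksum", "signedrank")) {
  test <- match.arg(test)
  x <- as.matrix(x)
  if (ncol(x) != length(clusters))
    stop("clusters must have one label per cell")
  labs <- sort(unique(as.integer(clusters)))
  if (length(labs) < 2)
    stop("differential analysis needs at least 2 clusters (no 'rest' group)")
  res <- list()
  for (cl in labs) {
    grp <- as.integer(clusters) == cl
    n1 <- sum(grp); n2 <- sum(!grp)
    if (n1 < min_cells) {
      warning("cluster ", cl, " has fewer than ", min_cells, " cells; skipped")
      next
    }
    if (test == "ranksum") {
      st <- .ranksum_rows(x, grp)
    } else {
      if (n1 != n2)
        stop("signedrank requires equal-size paired groups")
      st <- .signedrank_rows(x, grp)
    }
    mi <- rowMeans(x[, grp, drop = FALSE])
    mo <- rowMeans(x[, !grp, drop = FALSE])
    lfc <- rep(NA_real_, length(mi))
    ok <- mi > 0 & mo > 0
    lfc[ok] <- log2((mi[ok] + 1e-9) / (mo[ok] + 1e-9))
    df <- data.frame(cluster = cl, feature = rownames(x),
                     statistic = st$stat, p = st$p,
                     padj = stats::p.adjust(st$p, method = "BH"),
                     logFC = lfc, mean_in = mi, mean_out = mo,
                     row.names = NULL, stringsAsFactors = FALSE)
    res[[as.character(cl)]] <- df[order(df$padj, -abs(ifelse(is.na(df$logFC), 0, df$logFC))), ]
  }
  if (length(res) == 0) stop("no cluster met min_cells")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# vectorised Mann-Whitney over matrix rows; grp marks group 1
.ranksum_rows <- function(x, grp) {
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  stat <- numeric(nrow(x)); p <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    r <- rank(x[i, ])
    U <- sum(r[grp]) - n1 * (n1 + 1) / 2
    tie <- table(x[i, ])
    tiesum <- sum(tie^3 - tie)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiesum / (n * (n - 1)))
    if (sigma2 <= 0) {
      stat[i] <- U; p[i] <- 1
      next
    }
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    stat[i] <- U
    p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(stat = stat, p = p)
}

# paired signed-rank (normal approximation), pairing by position
.signedrank_rows <- function(x, grp) {
  a <- x[, grp, drop = FALSE]
  b <- x[, !grp, drop = FALSE]
  stat <- numeric(nrow(x)); p <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    wt <- suppressWarnings(stats::wilcox.test(a[i, ], b[i, ], paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    stat[i] <- unname(wt$statistic)
    p[i] <- wt$p.value
  }
  p[is.na(p)] <- 1
  list(stat = stat, p = p)
}
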