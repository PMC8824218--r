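#' Build a Jaccard-weighted k-nearest-neighbour cell graph
#'
#' Cells are connected to their \code{k_neighbors} nearest neighbours in the
#' representation space (Euclidean distance; ties broken by cell index for
#' determinism).  Each directed neighbour pair becomes an undirected edge
#' weighted by the Jaccard overlap of the two cells' neighbour sets, the
#' construction used by PhenoGraph; zero-overlap edges are pruned.  With
#' \code{jaccard = FALSE} a plain unit-weight kNN graph is returned.
#'
#' @param rep a \linkS4class{LowDimRep} or a components x cells matrix.
#' @param k_neighbors neighbours per cell; must be < number of cells.
#' @param jaccard weight edges by neighbour-set Jaccard overlap.
#' @return an undirected weighted \pkg{igraph} graph with one vertex per cell.
#' @export
buildKnnGraph <- function(rep, k_neighbors = 30, jaccard = TRUE) {
  x <- if (methods::is(rep, "LowDimRep")) t(scores(rep)) else t(as.matrix(rep))
  n <- nrow(x)
  if (k_neighbors >= n)
    stop("k_neighbors (", k_neighbors, ") must be smaller than the number of cells (", n, ")")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k_neighbors)])
  pairs <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    j <- nb[[i]]
    cbind(pmin(i, j), pmax(i, j))
  })))
  if (jaccard) {
    w <- vapply(seq_len(nrow(pairs)), function(r) {
      a <- nb[[pairs[r, 1]]]; b <- nb[[pairs[r, 2]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
  } else {
    w <- rep(1, nrow(pairs))
  }
  keep <- w > 0
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  igraph::V(g)$name <- if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(n))
  g
}

#' Leiden clustering of a cell graph
#'
#' Runs the Leiden algorithm (modularity objective) on a weighted cell graph.
#' Labels are relabelled by decreasing cluster size (ties by first occurrence)
#' into a contiguous 0..C-1 set, and the run is deterministic for a fixed
#' seed.
#'
#' @param graph an \pkg{igraph} graph from \code{\link{buildKnnGraph}}.
#' @param resolution Leiden resolution parameter (> 0).
#' @param seed RNG seed.
#' @param n_iterations Leiden refinement iterations.
#' @return named integer vector of 0-based cluster labels, one per cell, with
#'   attributes \code{resolution} and \code{seed}.
#' @export
leidenCluster <- function(graph, resolution = 1.0, seed = 0, n_iterations = 10) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  stopifnot(resolution > 0)
  labels <- withr::with_seed(seed, {
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(graph)$weight,
                                 n_iterations = n_iterations)
    igraph::membership(cl)
  })
  out <- relabelBySize(as.integer(labels))
  names(out) <- igraph::V(graph)$name
  attr(out, "resolution") <- resolution
  attr(out, "seed") <- seed
  out
}

#' Relabel cluster labels by decreasing cluster size
#'
#' @param labels integer vector of labels.
#' @return integer vector of 0-based labels, largest cluster first; ties
#'   broken by the smaller original label.
#' @export
relabelBySize <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.integer(tab), names(tab))]
  map <- stats::setNames(seq_along(ord) - 1L, ord)
  unname(map[as.character(labels)])
}

#' Merge clusters by explicit label pairs
#'
#' Applies manual merge directives (pairs of 0-based labels).  Merging is
#' never automatic; the result is relabelled by size.
#'
#' @param labels integer cluster labels.
#' @param merge list of length-2 integer vectors, each a pair to merge.
#' @return relabelled integer vector.
#' @export
mergeClusters <- function(labels, merge) {
  lab <- as.integer(labels)
  for (pair in merge) {
    stopifnot(length(pair) == 2)
    lab[lab == pair[2]] <- pair[1]
  }
  out <- relabelBySize(lab)
  names(out) <- names(labels)
  out
}

#' Shared UMAP embedding of the multimodal representation
#'
#' Computes one 2-D UMAP embedding from the multimodal representation; the
#' same coordinates are reused to display RNA, ADT and multimodal cluster
#' labels so the modalities can be compared on a common map.
#'
#' @param rep a \linkS4class{LowDimRep} with >= 2 components.
#' @param seed RNG seed (fixed seed gives reproducible coordinates).
#' @param n_neighbors UMAP neighbourhood size; must be <= number of cells.
#' @param min_dist UMAP minimum embedding distance.
#' @return cells x 2 matrix with columns \code{UMAP1}, \code{UMAP2}.
#' @export
umapEmbed <- function(rep, seed = 0, n_neighbors = 15, min_dist = 0.5) {
  if (nComponents(rep) < 2) stop("need at least 2 components to embed")
  x <- t(scores(rep))
  if (nrow(x) < n_neighbors)
    stop("fewer cells (", nrow(x), ") than n_neighbors (", n_neighbors, ")")
  coords <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                       seed = seed, n_threads = 1, n_sgd_threads = 1,
                       batch = TRUE)
  colnames(coords) <- c("UMAP1", "UMAP2")
  rownames(coords) <- rownames(x)
  coords
}
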