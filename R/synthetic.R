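#' Specification for a synthetic paired RNA/ADT experiment
#'
#' Describes the cluster structure of a simulated CITE-seq experiment: RNA
#' counts are negative-binomial with lognormal baseline means, cluster-specific
#' multiplicative marker effects and independent dropout zeroing; ADT counts
#' are rounded lognormal draws with cluster-specific location shifts (larger
#' dynamic range, no excess zeros).  Ground-truth labels are recorded so every
#' pipeline stage can be checked against the construction.
#'
#' @param n_cells_per_cluster integer vector, cells per cluster.
#' @param n_genes,n_adts feature counts.
#' @param rna_markers list (one element per cluster) of gene indices
#'   upregulated in that cluster; clusters may share a marker set.
#' @param adt_markers list (one element per cluster) of ADT indices
#'   upregulated in that cluster.
#' @param rna_fold,adt_fold multiplicative marker effect sizes.
#' @param dispersion negative-binomial size parameter for RNA.
#' @param dropout probability that an RNA count is zeroed.
#' @param base_meanlog,base_sdlog lognormal parameters for baseline RNA means.
#' @param adt_meanlog,adt_sdlog lognormal parameters for ADT counts.
#' @param species_block optional list(prefix =, n_genes =, cluster =): adds a
#'   block of genes with the given id prefix expressed only in one cluster
#'   (a second-species spike-in).
#' @param dp_pair optional c(cluster, adt1_index, adt2_index) recording which
#'   engineered pair is double-positive (metadata only; the effect itself is
#'   encoded via \code{adt_markers}).
#' @param seed RNG seed.
#' @return a \code{citeSimSpec} list.
#' @export
citeSimSpec <- function(n_cells_per_cluster, n_genes = 200, n_adts = 8,
                        rna_markers = NULL, adt_markers = NULL,
                        rna_fold = 4, adt_fold = 8, dispersion = 2,
                        dropout = 0.3, base_meanlog = log(2), base_sdlog = 0.5,
                        adt_meanlog = log(30), adt_sdlog = 0.4,
                        species_block = NULL, dp_pair = NULL, seed = 0) {
  C <- length(n_cells_per_cluster)
  if (C == 0 || any(n_cells_per_cluster <= 0))
    stop("need at least one cluster with at least one cell")
  if (is.null(rna_markers)) rna_markers <- rep(list(integer(0)), C)
  if (is.null(adt_markers)) adt_markers <- rep(list(integer(0)), C)
  stopifnot(length(rna_markers) == C, length(adt_markers) == C)
  structure(list(n_cells_per_cluster = as.integer(n_cells_per_cluster),
                 n_genes = n_genes, n_adts = n_adts,
                 rna_markers = rna_markers, adt_markers = adt_markers,
                 rna_fold = rna_fold, adt_fold = adt_fold,
                 dispersion = dispersion, dropout = dropout,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 adt_meanlog = adt_meanlog, adt_sdlog = adt_sdlog,
                 species_block = species_block, dp_pair = dp_pair,
                 seed = seed),
            class = "citeSimSpec")
}

#' Simulate a paired RNA/ADT experiment
#'
#' @param spec a \code{\link{citeSimSpec}}.
#' @return a \linkS4class{CiteExperiment} whose \code{colData} carries the
#'   0-based ground-truth labels in \code{true_label}; the generating
#'   parameters are stored in the metadata.
#' @export
simulateCiteSeq <- function(spec) {
  stopifnot(inherits(spec, "citeSimSpec"))
  withr::with_seed(spec$seed, .simulate_impl(spec))
}

.simulate_impl <- function(spec) {
  C <- length(spec$n_cells_per_cluster)
  J <- sum(spec$n_cells_per_cluster)
  labels <- rep(seq_len(C) - 1L, spec$n_cells_per_cluster)
  barcodes <- sprintf("CELL%05d", seq_len(J))

  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  base_mu <- stats::rlnorm(spec$n_genes, spec$base_meanlog, spec$base_sdlog)
  rna <- matrix(0L, spec$n_genes, J, dimnames = list(genes, barcodes))
  for (c in seq_len(C)) {
    cells <- which(labels == c - 1L)
    mu <- base_mu
    mk <- spec$rna_markers[[c]]
    mu[mk] <- mu[mk] * spec$rna_fold
    cnt <- stats::rnbinom(spec$n_genes * length(cells),
                          mu = rep(mu, times = length(cells)),
                          size = spec$dispersion)
    rna[, cells] <- matrix(cnt, spec$n_genes, length(cells))
  }
  if (spec$dropout > 0)
    rna[stats::runif(length(rna)) < spec$dropout] <- 0L

  if (!is.null(spec$species_block)) {
    sb <- spec$species_block
    sg <- sprintf("%sGENE%04d", sb$prefix, seq_len(sb$n_genes))
    blk <- matrix(0L, sb$n_genes, J, dimnames = list(sg, barcodes))
    cells <- which(labels == sb$cluster)
    blk[, cells] <- matrix(stats::rnbinom(sb$n_genes * length(cells),
                                          mu = 20, size = spec$dispersion),
                           sb$n_genes, length(cells))
    rna <- rbind(rna, blk)
  }

  adts <- sprintf("ADT%02d", seq_len(spec$n_adts))
  adt <- matrix(0L, spec$n_adts, J, dimnames = list(adts, barcodes))
  for (c in seq_len(C)) {
    cells <- which(labels == c - 1L)
    ml <- rep(spec$adt_meanlog, spec$n_adts)
    mk <- spec$adt_markers[[c]]
    ml[mk] <- ml[mk] + log(spec$adt_fold)
    v <- stats::rlnorm(spec$n_adts * length(cells),
                       meanlog = rep(ml, times = length(cells)),
                       sdlog = spec$adt_sdlog)
    adt[, cells] <- matrix(as.integer(round(v)), spec$n_adts, length(cells))
  }

  ce <- CiteExperiment(Matrix::Matrix(rna, sparse = TRUE), adt,
                       colData = S4Vectors::DataFrame(true_label = labels))
  S4Vectors::metadata(ce)$sim_spec <- spec
  ce
}

#' Built-in synthetic scenarios
#'
#' Fixed-parameter, fixed-seed presets covering the situations the analysis is
#' designed around:
#' \describe{
#'   \item{rna_only_pair}{two clusters separable only in RNA (identical ADT
#'     profiles).}
#'   \item{adt_only_pair}{two clusters separable only in five ADTs (identical
#'     RNA profiles).}
#'   \item{mixed_five}{five clusters of 100 cells: clusters 0 and 1 differ only
#'     in RNA (shared ADT markers), clusters 2 and 3 differ only in ADT (shared
#'     RNA markers), cluster 4 differs in both.  Exercises the claim that the
#'     multimodal representation resolves the union of what each single
#'     modality resolves.}
#'   \item{double_positive}{three clusters; cluster 0 is double-positive for
#'     ADT01 and ADT02 (both strongly shifted up), mimicking conjugate or
#'     DP T populations.}
#'   \item{species_spikein}{two main clusters plus a small spike-in cluster of
#'     a second species whose genes carry the \code{"mm10-"} prefix.}
#' }
#'
#' @param name preset name.
#' @return a \code{\link{citeSimSpec}}.
#' @export
citePreset <- function(name) {
  presets <- c("rna_only_pair", "adt_only_pair", "mixed_five",
               "double_positive", "species_spikein")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  switch(name,
    rna_only_pair = citeSimSpec(
      n_cells_per_cluster = c(100, 100), n_genes = 200, n_adts = 8,
      rna_markers = list(1:10, 11:20),
      adt_markers = list(integer(0), integer(0)),
      seed = 11),
    adt_only_pair = citeSimSpec(
      n_cells_per_cluster = c(100, 100), n_genes = 200, n_adts = 8,
      rna_markers = list(integer(0), integer(0)),
      adt_markers = list(integer(0), 1:5),
      seed = 12),
    mixed_five = citeSimSpec(
      n_cells_per_cluster = rep(100, 5), n_genes = 300, n_adts = 10,
      rna_markers = list(1:15, 16:30, 31:45, 31:45, 46:60),
      adt_markers = list(1:2, 1:2, 3:4, 5:6, 7:8),
      seed = 1),
    double_positive = citeSimSpec(
      n_cells_per_cluster = c(100, 100, 100), n_genes = 100, n_adts = 8,
      rna_markers = list(1:10, 11:20, 21:30),
      adt_markers = list(1:2, 3L, 4L),
      dp_pair = c(cluster = 0L, adt1 = 1L, adt2 = 2L),
      seed = 13),
    species_spikein = citeSimSpec(
      n_cells_per_cluster = c(100, 100, 20), n_genes = 200, n_adts = 8,
      rna_markers = list(1:10, 11:20, integer(0)),
      adt_markers = list(1L, 2L, integer(0)),
      species_block = list(prefix = "mm10-", n_genes = 30, cluster = 2L),
      seed = 14))
}

#' Materialize a synthetic preset to disk
#'
#' Writes the RNA matrix as an MTX trio under \code{rna/}, the ADT matrix as
#' CSV, and the ground-truth labels as CSV, so fixtures can be consumed
#' through the file readers.
#'
#' @param name preset name (see \code{\link{citePreset}}).
#' @param dir output directory.
#' @param format \code{"mtx"} or \code{"csv"} for the RNA matrix.
#' @return the \linkS4class{CiteExperiment}, invisibly.
#' @export
materializePreset <- function(name, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  ce <- simulateCiteSeq(citePreset(name))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") writeCounts(rnaCounts(ce), file.path(dir, "rna"), "mtx")
  else writeCounts(rnaCounts(ce), dir, "csv", name = "rna")
  writeCounts(adtCounts(ce), dir, "csv", name = "adt")
  utils::write.csv(data.frame(barcode = colnames(ce),
                              true_label = ce$true_label),
                   file.path(dir, "true_labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(ce)
}
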