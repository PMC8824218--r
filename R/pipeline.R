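#' Default run configuration
#'
#' All pipeline parameters with their defaults.  Presets encode the two
#' published-style analyses: \code{"cbmc_like"} (drop the CCR7/CCR5/CD10
#' contaminated ADTs, sparsity threshold 5\%, ADT passthrough instead of ADT
#' PCA, multimodal k = 15) and \code{"hbmc_like"} (keep all ADTs, sparsity
#' threshold 1\%, 30 RNA and 18 ADT components).
#'
#' @return nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    input = list(rna = NULL, adt = NULL, format = "auto",
                 orientation = "features_x_cells"),
    preset = "none",
    seed = 0,
    outdir = "citentro_out",
    figures = FALSE,
    qc = list(t_frac = 0.01, sp_frac = 0.05, drop_adts = character(0),
              species_prefix = NULL, top_cv_n = 100,
              strict_adt_names = FALSE),
    norm = list(clr_pseudocount = 1, literal_rescale = FALSE),
    reduce = list(rna_k = "auto", adt_k = "auto", multimodal_k = "auto",
                  passthrough = FALSE, seed = 0),
    cluster = list(k_neighbors = 30, resolution = 1.0, seed = 0,
                   merge = list()),
    umap = list(seed = 0, n_neighbors = 15, min_dist = 0.5),
    de = list(test = "ranksum", min_cells = 3),
    coex = list(theta = 0.5, epsilon = 1e-6, product_form = FALSE)
  )
}

.presets <- function(name) {
  switch(name,
    cbmc_like = list(qc = list(sp_frac = 0.05,
                               drop_adts = c("CCR7", "CCR5", "CD10")),
                     reduce = list(passthrough = TRUE, rna_k = 10,
                                   multimodal_k = 15)),
    hbmc_like = list(qc = list(sp_frac = 0.01),
                     reduce = list(passthrough = FALSE, rna_k = 30,
                                   adt_k = 18)),
    none = list(),
    stop("unknown preset '", name, "' (use cbmc_like, hbmc_like or none)"))
}

.merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("config key ", full, " must be a section")
      base[[key]] <- .merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Resolve and validate a run configuration
#'
#' Merges a YAML file or list over the defaults (and over the preset, when one
#' is named), rejecting unknown keys, out-of-range values and contradictory
#' settings (ADT passthrough together with a numeric ADT component count).
#'
#' @param config path to a YAML file, a named list, or NULL for pure defaults.
#' @return the resolved configuration list.
#' @export
validateConfig <- function(config = NULL) {
  user <- if (is.null(config)) list()
    else if (is.character(config)) {
      if (!file.exists(config)) stop("config file not found: ", config)
      out <- yaml::read_yaml(config)
      if (is.null(out)) list() else out
    } else config
  resolved <- defaultConfig()
  preset <- if (!is.null(user$preset)) user$preset else resolved$preset
  resolved <- .merge_config(resolved, .presets(preset))
  resolved <- .merge_config(resolved, user)
  resolved$preset <- preset
  with(resolved, {
    if (coex$theta < 0 || coex$theta > 1)
      stop("coex.theta must lie in [0, 1]")
    if (coex$epsilon <= 0) stop("coex.epsilon must be positive")
    if (qc$t_frac < 0 || qc$t_frac > 1 || qc$sp_frac < 0 || qc$sp_frac > 1)
      stop("qc.t_frac and qc.sp_frac must lie in [0, 1]")
    if (!de$test %in% c("ranksum", "signedrank"))
      stop("de.test must be ranksum or signedrank")
    if (isTRUE(reduce$passthrough) && is.numeric(reduce$adt_k))
      stop("contradiction: reduce.passthrough with a numeric reduce.adt_k")
    if (cluster$k_neighbors < 1) stop("cluster.k_neighbors must be >= 1")
  })
  resolved
}

.resolve_k <- function(rep_full, k) {
  if (identical(k, "auto")) elbowSelect(explainedVariance(rep_full))
  else min(as.integer(k), nComponents(rep_full))
}

#' Run the full multimodal pipeline
#'
#' Executes quality control, normalization, rescaling, per-modality reduction,
#' multimodal integration, clustering of all three modality views, a shared
#' UMAP embedding, one-vs-rest differential analysis of genes and ADTs against
#' the multimodal clusters, and the co-expression entropy screen.  All stage
#' outputs are written as CSV under the configured output directory together
#' with the resolved configuration and a run log recording the dimensions
#' entering and leaving each stage.
#'
#' @param config a resolved configuration (see \code{\link{validateConfig}}),
#'   a YAML path, or NULL for defaults.
#' @param experiment optionally a \linkS4class{CiteExperiment}; when NULL the
#'   matrices are read from \code{config$input}.
#' @return invisibly, a list with the screened experiment, the three
#'   representations, cluster labels per modality, the embedding, both DE
#'   tables and the co-expression table.
#' @export
runPipeline <- function(config = NULL, experiment = NULL) {
  cfg <- validateConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(cfg$outdir, "run_log.txt")
  cat("", file = logfile)
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  log("R %s, seed %d, preset %s", getRversion(), cfg$seed, cfg$preset)

  if (is.null(experiment)) {
    if (is.null(cfg$input$rna) || is.null(cfg$input$adt))
      stop("stage io: input.rna and input.adt must be set when no experiment is given")
    rna <- readCounts(cfg$input$rna, cfg$input$format, "rna", cfg$input$orientation)
    adt <- readCounts(cfg$input$adt, cfg$input$format, "adt", cfg$input$orientation)
    experiment <- CiteExperiment(rna, adt)
  }
  log("input: %d genes x %d cells, %d ADTs", nrow(experiment),
      ncol(experiment), nrow(adtCounts(experiment)))

  # QC
  rna <- rnaCounts(experiment)
  keep <- character(0)
  if (!is.null(cfg$qc$species_prefix))
    keep <- topCVFeatures(rna, cfg$qc$species_prefix, cfg$qc$top_cv_n)
  rna <- screenGenes(rna, cfg$qc$t_frac, cfg$qc$sp_frac, keep = keep)
  adt <- dropADTs(adtCounts(experiment), cfg$qc$drop_adts,
                  strict = cfg$qc$strict_adt_names)
  log("qc: kept %d genes, %d ADTs", nrow(rna), nrow(adt))

  # normalize + scale
  xr <- minMaxScale(logNormalize(rna), cfg$norm$literal_rescale)
  xa_norm <- clrTransform(adt, cfg$norm$clr_pseudocount)
  xa <- minMaxScale(xa_norm, cfg$norm$literal_rescale)
  xr_norm <- as.matrix(logNormalize(rna))

  # reduction
  rna_full <- pcaReduce(xr, "all", cfg$reduce$seed, "rna")
  rna_rep <- .truncateRep(rna_full, .resolve_k(rna_full, cfg$reduce$rna_k))
  if (isTRUE(cfg$reduce$passthrough)) {
    adt_rep <- passthroughRep(xa)
  } else {
    adt_full <- pcaReduce(xa, "all", cfg$reduce$seed, "adt")
    adt_rep <- .truncateRep(adt_full, .resolve_k(adt_full, cfg$reduce$adt_k))
  }
  log("reduce: rna k=%d, adt k=%d", nComponents(rna_rep), nComponents(adt_rep))
  log("integrate: stacked matrix has %d rows",
      nComponents(rna_rep) + nComponents(adt_rep))
  mm_rep <- integrateModalities(rna_rep, adt_rep, cfg$reduce$multimodal_k,
                                cfg$reduce$seed)
  log("integrate: multimodal k=%d", nComponents(mm_rep))

  # clustering (three modality views)
  reps <- list(rna = rna_rep, adt = adt_rep, multimodal = mm_rep)
  clusters <- lapply(reps, function(r) {
    g <- buildKnnGraph(r, min(cfg$cluster$k_neighbors, ncol(scores(r)) - 1))
    leidenCluster(g, cfg$cluster$resolution, cfg$cluster$seed)
  })
  if (length(cfg$cluster$merge))
    clusters$multimodal <- mergeClusters(clusters$multimodal, cfg$cluster$merge)
  for (m in names(clusters))
    log("cluster %s: %d clusters", m, length(unique(clusters[[m]])))

  # shared embedding
  emb <- umapEmbed(mm_rep, cfg$umap$seed,
                   min(cfg$umap$n_neighbors, ncol(experiment)),
                   cfg$umap$min_dist)

  # differential analysis against multimodal clusters
  de_genes <- wilcoxonDE(xr_norm, clusters$multimodal, cfg$de$min_cells,
                         cfg$de$test)
  de_adts <- wilcoxonDE(xa_norm, clusters$multimodal, cfg$de$min_cells,
                        cfg$de$test)
  log("de: %d gene rows, %d ADT rows", nrow(de_genes), nrow(de_adts))

  # co-expression screen on scaled ADT values
  coex <- screenPairs(xa, clusters$multimodal, cfg$coex$theta,
                      cfg$coex$epsilon, cfg$coex$product_form)
  log("coexpression: %d (cluster, pair) rows", nrow(coex))

  # outputs
  bc <- colnames(experiment)
  for (m in names(clusters))
    utils::write.csv(data.frame(barcode = bc, label = unname(clusters[[m]])),
                     file.path(cfg$outdir, sprintf("clusters_%s.csv", m)),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(barcode = bc, x = emb[, 1], y = emb[, 2]),
                   file.path(cfg$outdir, "umap.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(de_genes, file.path(cfg$outdir, "de_genes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(de_adts, file.path(cfg$outdir, "de_adts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(coex, file.path(cfg$outdir, "coexpression.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "resolved_config.yaml"))
  if (isTRUE(cfg$figures)) .write_figures(cfg$outdir, emb, clusters)
  log("done: outputs in %s", cfg$outdir)

  invisible(list(experiment = experiment, scaled_rna = xr, scaled_adt = xa,
                 reps = reps, clusters = clusters, embedding = emb,
                 de_genes = de_genes, de_adts = de_adts, coexpression = coex,
                 config = cfg))
}

.write_figures <- function(outdir, emb, clusters) {
  for (m in names(clusters)) {
    f <- file.path(outdir, sprintf("umap_%s.png", m))
    grDevices::png(f, width = 700, height = 700)
    lab <- factor(clusters[[m]])
    graphics::plot(emb, col = grDevices::rainbow(nlevels(lab))[lab], pch = 16,
                   main = sprintf("shared UMAP, %s clusters", m))
    grDevices::dev.off()
  }
}
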