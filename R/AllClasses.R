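#' @import methods
#' @importFrom SingleCellExperiment SingleCellExperiment altExp altExp<- altExpNames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData colData<-
#' @importFrom S4Vectors DataFrame
NULL

#' Paired RNA + ADT single-cell experiment
#'
#' A thin wrapper around \linkS4class{SingleCellExperiment} that holds RNA
#' counts as the main \code{counts} assay and antibody-derived-tag (ADT)
#' counts as an \code{altExp} named \code{"ADT"}.  The validity method
#' enforces the pairing contract: both modalities cover the same cell
#' barcodes in the same order, barcodes are unique, and all counts are
#' non-negative integers.
#'
#' @export
setClass("CiteExperiment", contains = "SingleCellExperiment")

.check_counts <- function(m, what) {
  v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(v) && any(v < 0)) return(sprintf("%s counts contain negative values", what))
  if (length(v) && any(v != floor(v))) return(sprintf("%s counts are not integral", what))
  NULL
}

setValidity("CiteExperiment", function(object) {
  # down-cast before using accessors: calling them on the subclass inside its
  # own validity re-enters validObject through updateObject
  o <- methods::as(object, "SingleCellExperiment")
  msgs <- character(0)
  if (!"ADT" %in% altExpNames(o))
    msgs <- c(msgs, "missing altExp 'ADT'")
  if (!"counts" %in% names(assays(o)))
    msgs <- c(msgs, "missing 'counts' assay")
  bc <- colnames(o)
  if (is.null(bc) || anyDuplicated(bc))
    msgs <- c(msgs, "cell barcodes must be present and unique")
  if (length(msgs) == 0) {
    m <- .check_counts(assay(o, "counts"), "RNA")
    if (!is.null(m)) msgs <- c(msgs, m)
    ad <- altExp(o, "ADT")
    m <- .check_counts(assay(ad, 1L), "ADT")
    if (!is.null(m)) msgs <- c(msgs, m)
    if (!identical(colnames(ad), bc))
      msgs <- c(msgs, "ADT altExp barcodes differ from RNA barcodes")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CiteExperiment from paired count matrices
#'
#' @param rna features x cells RNA count matrix (base or \pkg{Matrix} sparse),
#'   with gene ids as rownames and cell barcodes as colnames.
#' @param adt features x cells ADT count matrix over the same barcodes, in the
#'   same column order.
#' @param colData optional per-cell annotation (\code{DataFrame} or
#'   data.frame), e.g. ground-truth labels from the synthetic generator.
#' @return A \linkS4class{CiteExperiment}.
#' @examples
#' rna <- matrix(rpois(60, 2), 6, 10,
#'               dimnames = list(paste0("G", 1:6), paste0("C", 1:10)))
#' adt <- matrix(rpois(30, 20), 3, 10,
#'               dimnames = list(paste0("ADT", 1:3), paste0("C", 1:10)))
#' ce <- CiteExperiment(rna, adt)
#' @export
CiteExperiment <- function(rna, adt, colData = NULL) {
  if (is.null(rownames(rna)) || is.null(colnames(rna)))
    stop("'rna' must carry feature rownames and barcode colnames")
  if (is.null(rownames(adt)) || is.null(colnames(adt)))
    stop("'adt' must carry feature rownames and barcode colnames")
  if (!identical(colnames(rna), colnames(adt)))
    stop("RNA and ADT matrices must share the same barcodes in the same order")
  attr(rna, "modality") <- NULL
  attr(adt, "modality") <- NULL
  sce <- SingleCellExperiment(assays = list(counts = rna))
  altExp(sce, "ADT") <- SummarizedExperiment(assays = list(counts = adt))
  if (!is.null(colData)) colData(sce) <- DataFrame(colData, row.names = colnames(rna))
  out <- methods::as(sce, "CiteExperiment")
  methods::validObject(out)
  out
}

setMethod("show", "CiteExperiment", function(object) {
  cat("CiteExperiment:", nrow(object), "genes x", ncol(object), "cells;",
      nrow(altExp(object, "ADT")), "ADTs\n")
  methods::callNextMethod()
})

#' Low-dimensional representation of one modality
#'
#' Holds component scores (components x cells), the per-component explained
#' variance (computed with n_samples - 1 degrees of freedom), the projection
#' basis, and the modality the representation was derived from.  Explained
#' variances are required to be non-increasing.
#'
#' @slot scores numeric matrix, components x cells, finite.
#' @slot explainedVariance numeric vector, one value per component,
#'   non-increasing.
#' @slot loadings numeric matrix, input features x components (a permutation
#'   basis for passthrough representations).
#' @slot modality character, one of \code{"rna"}, \code{"adt"},
#'   \code{"multimodal"}.
#' @export
setClass("LowDimRep",
  representation(scores = "matrix", explainedVariance = "numeric",
                 loadings = "matrix", modality = "character"))

setValidity("LowDimRep", function(object) {
  msgs <- character(0)
  k <- nrow(object@scores)
  if (length(object@explainedVariance) != k)
    msgs <- c(msgs, "explainedVariance length must equal component count")
  if (k > 1 && any(diff(object@explainedVariance) > 1e-8 * max(object@explainedVariance, 1)))
    msgs <- c(msgs, "explainedVariance must be non-increasing")
  if (length(object@scores) && !all(is.finite(object@scores)))
    msgs <- c(msgs, "scores must be finite")
  if (!object@modality %in% c("rna", "adt", "multimodal"))
    msgs <- c(msgs, "modality must be one of rna/adt/multimodal")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "LowDimRep", function(object) {
  cat(sprintf("LowDimRep (%s): %d components x %d cells\n", object@modality,
              nrow(object@scores), ncol(object@scores)))
  if (nrow(object@scores))
    cat("  explained variance:",
        paste(signif(utils::head(object@explainedVariance, 5), 4), collapse = ", "),
        if (nrow(object@scores) > 5) "..." else "", "\n")
})

#' @rdname LowDimRep-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname LowDimRep-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname LowDimRep-accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname LowDimRep-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname LowDimRep-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Accessors for LowDimRep
#'
#' @param x a \linkS4class{LowDimRep}.
#' @return \code{scores}: components x cells matrix; \code{explainedVariance}:
#'   numeric vector; \code{loadings}: features x components matrix;
#'   \code{modality}: character; \code{nComponents}: integer.
#' @name LowDimRep-accessors
NULL

#' @rdname LowDimRep-accessors
#' @export
setMethod("scores", "LowDimRep", function(x) x@scores)
#' @rdname LowDimRep-accessors
#' @export
setMethod("explainedVariance", "LowDimRep", function(x) x@explainedVariance)
#' @rdname LowDimRep-accessors
#' @export
setMethod("loadings", "LowDimRep", function(x) x@loadings)
#' @rdname LowDimRep-accessors
#' @export
setMethod("modality", "LowDimRep", function(x) x@modality)
#' @rdname LowDimRep-accessors
#' @export
setMethod("nComponents", "LowDimRep", function(x) nrow(x@scores))

#' @rdname CiteExperiment-accessors
#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))
#' @rdname CiteExperiment-accessors
#' @export
setGeneric("adtCounts", function(x) standardGeneric("adtCounts"))

#' Accessors for CiteExperiment
#'
#' @param x a \linkS4class{CiteExperiment}.
#' @return the features x cells count matrix of the requested modality.
#' @name CiteExperiment-accessors
NULL

#' @rdname CiteExperiment-accessors
#' @export
setMethod("rnaCounts", "CiteExperiment", function(x) assay(x, "counts"))
#' @rdname CiteExperiment-accessors
#' @export
setMethod("adtCounts", "CiteExperiment", function(x) assay(altExp(x, "ADT"), 1L))

# internal constructor used by the reduction code
.LowDimRep <- function(scores, explainedVariance, loadings, modality) {
  methods::new("LowDimRep", scores = scores,
               explainedVariance = as.numeric(explainedVariance),
               loadings = loadings, modality = modality)
}

# subset a representation to its first k components
.truncateRep <- function(rep, k) {
  .LowDimRep(rep@scores[seq_len(k), , drop = FALSE],
             rep@explainedVariance[seq_len(k)],
             rep@loadings[, seq_len(k), drop = FALSE],
             rep@modality)
}
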