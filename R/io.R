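#' Read a feature x cell count matrix
#'
#' Reads a 10x-style MTX directory (matrix + features + barcodes, plain or
#' gzipped) or a dense CSV/TSV with feature ids in the first column and cell
#' barcodes in the header.  The returned matrix is always oriented
#' features x cells; a cells x features file can be declared via
#' \code{orientation}.
#'
#' @param path file (csv/tsv) or directory (mtx_dir).
#' @param format one of \code{"auto"}, \code{"mtx_dir"}, \code{"csv"},
#'   \code{"tsv"}.  \code{"auto"} picks mtx_dir for directories and decides
#'   csv/tsv from the file extension.
#' @param modality \code{"rna"} or \code{"adt"}; recorded as an attribute.
#' @param orientation on-disk layout of dense files;
#'   \code{"features_x_cells"} (default) or \code{"cells_x_features"}.
#' @return a \code{dgCMatrix} of integer counts, features x cells, with
#'   attribute \code{modality}.
#' @export
readCounts <- function(path,
                       format = c("auto", "mtx_dir", "csv", "tsv"),
                       modality = c("rna", "adt"),
                       orientation = c("features_x_cells", "cells_x_features")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.tsv(\\.gz)?$", path)) "tsv" else "csv"
  }
  m <- if (format == "mtx_dir") .read_mtx_dir(path) else
    .read_dense(path, sep = if (format == "csv") "," else "\t")
  if (orientation == "cells_x_features" && format != "mtx_dir")
    m <- Matrix::t(m)
  validateCounts(m, modality)
}

.read_mtx_dir <- function(dir) {
  pick <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      f <- file.path(dir, paste0(s, ext))
      if (file.exists(f)) return(f)
    }
    stop("missing file in MTX directory '", dir, "': expected one of ",
         paste(stems, collapse = "/"))
  }
  mtx <- pick("matrix.mtx")
  feat <- pick(c("features.tsv", "genes.tsv"))
  bc <- pick("barcodes.tsv")
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  ftab <- utils::read.table(feat, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "")
  bcs <- utils::read.table(bc, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "")[, 1]
  if (nrow(ftab) != nrow(m))
    stop("features file rows (", nrow(ftab), ") do not match matrix rows (",
         nrow(m), ")")
  if (length(bcs) != ncol(m))
    stop("barcodes file rows (", length(bcs), ") do not match matrix columns (",
         ncol(m), ")")
  rownames(m) <- ftab[, 1]
  colnames(m) <- bcs
  m
}

.read_dense <- function(path, sep) {
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0)
    stop("empty count matrix in ", path)
  nonnum <- !vapply(df, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric entries in column(s): ",
         paste(colnames(df)[nonnum], collapse = ", "))
  as(as.matrix(df), "CsparseMatrix")
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: non-negative integral values, named and
#' unique barcodes, named features, non-empty.  Returns the matrix as a sparse
#' \code{dgCMatrix} with a \code{modality} attribute.
#'
#' @param m features x cells matrix.
#' @param modality \code{"rna"} or \code{"adt"}.
#' @export
validateCounts <- function(m, modality = c("rna", "adt")) {
  modality <- match.arg(modality)
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0)
    stop("empty count matrix")
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  bad <- which(m@x < 0)
  if (length(bad)) {
    ij <- .sparse_index(m, bad[1])
    stop(sprintf("negative count at row %d, column %d", ij[1], ij[2]))
  }
  bad <- which(m@x != floor(m@x))
  if (length(bad)) {
    ij <- .sparse_index(m, bad[1])
    stop(sprintf("non-integral count at row %d, column %d", ij[1], ij[2]))
  }
  if (is.null(colnames(m)))
    colnames(m) <- paste0("CELL", seq_len(ncol(m)))
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell barcodes: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (is.null(rownames(m)))
    rownames(m) <- paste0("FEATURE", seq_len(nrow(m)))
  attr(m, "modality") <- modality
  m
}

# (row, col) of the k-th stored value of a dgCMatrix
.sparse_index <- function(m, k) {
  c(m@i[k] + 1L, sum(m@p < k))
}

#' Write a count matrix as a 10x-style MTX trio or dense CSV
#'
#' @param m features x cells count matrix.
#' @param dir output directory (created if needed).
#' @param format \code{"mtx"} writes matrix.mtx / features.tsv / barcodes.tsv;
#'   \code{"csv"} writes \code{name.csv} with barcodes in the header.
#' @param name base name for the csv variant.
#' @return the directory, invisibly.
#' @export
writeCounts <- function(m, dir, format = c("mtx", "csv"), name = "counts") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(as(as(m, "CsparseMatrix"), "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(rownames(m), rownames(m), "Expression"),
                       file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(colnames(m), file.path(dir, "barcodes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    df <- as.data.frame(as.matrix(m))
    utils::write.csv(cbind(feature = rownames(m), df),
                     file.path(dir, paste0(name, ".csv")), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(dir)
}
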