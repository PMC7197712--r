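#' Sparse UMI count matrix with feature classes and sample labels
#'
#' The central container of the pipeline: a sparse non-negative integer UMI
#' matrix (cells in rows, features in columns), a feature table that
#' partitions features into ordinary genes, mitochondrial genes and
#' transgene sequence contents, and a per-cell sample label.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells x
#'   features. Coerced to \code{dgCMatrix}.
#' @param barcodes character vector of cell barcodes, one per row. Barcodes
#'   must be unique within each sample.
#' @param features data.frame with columns \code{name} (unique feature
#'   names) and \code{class} (one of \code{"gene"}, \code{"mito"},
#'   \code{"transgene"}). An optional \code{id} column is preserved.
#' @param samples character vector of per-cell sample labels (recycled if
#'   length 1).
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{barcodes}, \code{features}, \code{samples}.
#' @export
count_matrix <- function(counts, barcodes, features, samples) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  stop_if_not(all(counts@x >= 0), "counts must be non-negative")
  stop_if_not(all(counts@x == floor(counts@x)), "counts must be integers")
  stop_if_not(length(barcodes) == nrow(counts),
              "barcodes length (%d) != number of cells (%d)",
              length(barcodes), nrow(counts))
  stop_if_not(is.data.frame(features) &&
                all(c("name", "class") %in% names(features)),
              "features must be a data.frame with columns name, class")
  stop_if_not(nrow(features) == ncol(counts),
              "feature table rows (%d) != number of features (%d)",
              nrow(features), ncol(counts))
  stop_if_not(!anyDuplicated(features$name), "duplicate feature names")
  stop_if_not(all(features$class %in% c("gene", "mito", "transgene")),
              "feature class must be gene, mito or transgene")
  if (length(samples) == 1L) samples <- rep(samples, nrow(counts))
  stop_if_not(length(samples) == nrow(counts),
              "samples length != number of cells")
  dup <- duplicated(paste(samples, barcodes, sep = "\r"))
  stop_if_not(!any(dup), "duplicate barcodes within a sample")
  rownames(counts) <- barcodes
  colnames(counts) <- features$name
  structure(list(counts = counts,
                 barcodes = as.character(barcodes),
                 features = as.data.frame(features),
                 samples = as.character(samples)),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cls <- table(factor(x$features$class,
                      levels = c("gene", "mito", "transgene")))
  cat(sprintf("count_matrix: %d cells x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  features: %d gene, %d mito, %d transgene\n",
              cls[["gene"]], cls[["mito"]], cls[["transgene"]]))
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s (%d)", names(table(x$samples)),
                            table(x$samples)), collapse = ", ")))
  cat(sprintf("  total UMIs: %.0f\n", sum(x$counts)))
  invisible(x)
}

#' Subset a count matrix by cells and/or features
#'
#' @param x a \code{count_matrix}.
#' @param cells logical, integer or character (barcode) cell selector.
#' @param features logical, integer or character (name) feature selector.
#' @return A \code{count_matrix} restricted to the selection.
#' @export
cm_subset <- function(x, cells = NULL, features = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  ci <- seq_len(nrow(x$counts))
  fi <- seq_len(ncol(x$counts))
  if (!is.null(cells)) {
    ci <- if (is.character(cells)) match(cells, x$barcodes) else ci[cells]
    stop_if_not(!anyNA(ci), "unknown barcode in cell selection")
  }
  if (!is.null(features)) {
    fi <- if (is.character(features)) match(features, x$features$name)
          else fi[features]
    stop_if_not(!anyNA(fi), "unknown feature in feature selection")
  }
  count_matrix(x$counts[ci, fi, drop = FALSE], x$barcodes[ci],
               x$features[fi, , drop = FALSE], x$samples[ci])
}

#' Per-cell number of expressed features
#'
#' A feature is "expressed" in a cell when its raw count is greater than
#' zero.
#'
#' @param x a \code{count_matrix} (raw counts).
#' @return Integer vector, one entry per cell, named by barcode.
#' @export
n_expressed_features <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  setNames(as.integer(Matrix::rowSums(x$counts > 0)), x$barcodes)
}

# Per-cell total UMIs and percent-mitochondrial, from raw counts.
cell_covariates <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  total <- Matrix::rowSums(x$counts)
  mito <- x$features$class == "mito"
  mito_umis <- if (any(mito)) Matrix::rowSums(x$counts[, mito, drop = FALSE])
               else rep(0, nrow(x$counts))
  pct_mito <- ifelse(total > 0, 100 * mito_umis / total, 0)
  data.frame(barcode = x$barcodes, total_counts = as.numeric(total),
             pct_mito = as.numeric(pct_mito), stringsAsFactors = FALSE)
}
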