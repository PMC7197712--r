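# Readers/writers for the formats the pipeline touches: 10x-style
# MatrixMarket triplets with features/barcodes side tables, GO annotation
# tables, and RGB raster images. Every writer/reader pair round-trips
# exactly; IO never mutates values.

#' Write a count matrix as a 10x-style MTX directory
#'
#' Writes \code{matrix.mtx} (MatrixMarket coordinate integer, features x
#' cells as in the 10x convention), \code{features.tsv} (id, name, class),
#' \code{barcodes.tsv} and \code{samples.tsv} (barcode, sample).
#'
#' @param matrix a \code{\link{count_matrix}}.
#' @param path output directory (created if absent).
#' @param overwrite allow overwriting existing files (default FALSE).
#' @return Invisibly, the paths written.
#' @export
write_counts_mtx <- function(matrix, path, overwrite = FALSE) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- file.path(path, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                             "samples.tsv"))
  existing <- files[file.exists(files)]
  stop_if_not(overwrite || length(existing) == 0,
              "refusing to overwrite %s (set overwrite = TRUE)",
              paste(basename(existing), collapse = ", "))
  # 10x layout stores features as rows
  m <- Matrix::t(matrix$counts)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, files[1])
  feat <- matrix$features
  id <- if ("id" %in% names(feat)) feat$id else feat$name
  utils::write.table(data.frame(id = id, name = feat$name,
                                class = feat$class),
                     files[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(matrix$barcodes, files[3])
  utils::write.table(data.frame(barcode = matrix$barcodes,
                                sample = matrix$samples),
                     files[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(files)
}

#' Read a 10x-style MTX directory into a count matrix
#'
#' Accepts two-column (id, name) or three-column (id, name, class) feature
#' tables; with two columns, feature classes are assigned by exact-name
#' match against a \code{\link{reporter_feature_map}} (transgenes) and the
#' mitochondrial name prefix, all other features being genes. Gzipped side
#' files (\code{.tsv.gz}, \code{.mtx.gz}) are accepted.
#'
#' @param path directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv} and optionally \code{samples.tsv}.
#' @param sample sample label used when no \code{samples.tsv} is present.
#' @param map reporter map for two-column feature classification.
#' @param mito_prefix mitochondrial gene-name prefix.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts_mtx <- function(path, sample = "sample1",
                            map = reporter_feature_map(),
                            mito_prefix = "mt-") {
  find <- function(base) {
    for (f in file.path(path, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop(sprintf("missing %s under %s", base, path), call. = FALSE)
  }
  m <- Matrix::readMM(find("matrix.mtx"))
  # pattern/binary MatrixMarket files come back as n[gt]TMatrix
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  stop_if_not(all(m@x == floor(m@x)) && all(m@x >= 0),
              "non-integer or negative entries in matrix.mtx")
  feat_raw <- utils::read.delim(find("features.tsv"), header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- readLines(find("barcodes.tsv"))
  stop_if_not(nrow(feat_raw) == nrow(m),
              "features.tsv rows (%d) != matrix rows (%d)",
              nrow(feat_raw), nrow(m))
  stop_if_not(length(barcodes) == ncol(m),
              "barcodes.tsv rows (%d) != matrix columns (%d)",
              length(barcodes), ncol(m))
  if (ncol(feat_raw) >= 3 &&
      all(feat_raw[[3]] %in% c("gene", "mito", "transgene"))) {
    feat <- data.frame(name = feat_raw[[2]], class = feat_raw[[3]],
                       id = feat_raw[[1]], stringsAsFactors = FALSE)
  } else {
    nm <- feat_raw[[min(2, ncol(feat_raw))]]
    cls <- ifelse(nm %in% transgene_feature_names(map), "transgene",
                  ifelse(startsWith(nm, mito_prefix), "mito", "gene"))
    feat <- data.frame(name = nm, class = cls, id = feat_raw[[1]],
                       stringsAsFactors = FALSE)
  }
  stop_if_not(!anyDuplicated(feat$name), "duplicate feature names")
  samples_file <- file.path(path, "samples.tsv")
  samples <- if (file.exists(samples_file)) {
    st <- utils::read.delim(samples_file, stringsAsFactors = FALSE)
    stop_if_not(identical(st$barcode, barcodes),
                "samples.tsv barcodes do not match barcodes.tsv")
    st$sample
  } else sample
  count_matrix(Matrix::t(m), barcodes, feat, samples)
}

#' Read a GO annotation table
#'
#' Parses a two-or-more-column delimited text file (gene, term, optional
#' term name; ZFIN-style exports fit after column selection). Duplicate
#' gene-term pairs are deduplicated. Malformed rows (fewer than two fields)
#' are reported with their line numbers.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param gene_col,term_col,name_col column indices for gene id, term id and
#'   optional term name (\code{NA} to skip names).
#' @param header whether the file has a header line.
#' @return A list: \code{terms} (named list term -> character vector of
#'   genes) and \code{term_names} (named character, possibly empty).
#' @export
read_go_table <- function(path, sep = "\t", gene_col = 1, term_col = 2,
                          name_col = 3, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines) > 0) lines <- lines[-1]
  offset <- as.integer(header)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    return(list(terms = list(), term_names = character(0)))
  }
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], sep, fixed = TRUE)
  nf <- lengths(parts)
  need <- max(gene_col, term_col)
  bad <- which(nf < need)
  if (length(bad) > 0) {
    stop(sprintf("malformed GO table rows (need >= %d fields) at line(s): %s",
                 need,
                 paste(which(keep)[bad] + offset, collapse = ", ")),
         call. = FALSE)
  }
  gene <- vapply(parts, `[[`, character(1), gene_col)
  term <- vapply(parts, `[[`, character(1), term_col)
  tn <- if (!is.na(name_col)) {
    vapply(parts, function(p) if (length(p) >= name_col) p[[name_col]]
           else NA_character_, character(1))
  } else rep(NA_character_, length(term))
  dup <- duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[!dup]; term <- term[!dup]; tn <- tn[!dup]
  terms <- split(gene, term)
  term_names <- tn[!duplicated(term)]
  names(term_names) <- term[!duplicated(term)]
  term_names <- term_names[!is.na(term_names)]
  list(terms = terms, term_names = term_names)
}

#' Read an RGB image
#'
#' Reads an 8- or 16-bit PNG into a height x width x 3 array with channel
#' order R,G,B and values rescaled to [0,1]. Grayscale input is rejected;
#' an alpha channel, if present, is dropped.
#'
#' @param path PNG file path.
#' @param mask_path optional path to a mask PNG; any nonzero pixel (first
#'   channel) is inside the mask.
#' @return A list: \code{image} (array) and \code{mask} (logical matrix or
#'   NULL).
#' @export
read_image <- function(path, mask_path = NULL) {
  img <- png::readPNG(path)
  stop_if_not(length(dim(img)) == 3 && dim(img)[3] >= 3,
              "non-RGB input: %s", path)
  img <- img[, , 1:3, drop = FALSE]
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    stop_if_not(all(dim(m) == dim(img)[1:2]),
                "mask dimensions do not match image")
    mask <- m > 0
  }
  list(image = img, mask = mask)
}

#' Write an RGB image (and optionally a mask) as PNG
#'
#' @param image height x width x 3 array in [0,1].
#' @param path output PNG path.
#' @param mask optional logical matrix written alongside as
#'   \code{<path>.mask.png}.
#' @return Invisibly, the path(s) written.
#' @export
write_image <- function(image, path, mask = NULL) {
  stop_if_not(length(dim(image)) == 3 && dim(image)[3] == 3,
              "image must be height x width x 3")
  png::writePNG(image, path)
  out <- path
  if (!is.null(mask)) {
    mp <- paste0(path, ".mask.png")
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), mp)
    out <- c(out, mp)
  }
  invisible(out)
}
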