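# Cluster x sample composition tables and the two dotplot scaling
# statistics used for marker-gene summary figures.

#' Cross-tabulate cluster labels by sample
#'
#' @param labels per-cell cluster labels.
#' @param samples per-cell sample labels (same length).
#' @return An integer matrix, clusters x samples; row and column sums equal
#'   the marginal cell counts.
#' @export
cluster_sample_counts <- function(labels, samples) {
  stop_if_not(length(labels) == length(samples),
              "labels (%d) and samples (%d) differ in length",
              length(labels), length(samples))
  if (length(labels) == 0) {
    return(matrix(integer(0), 0, 0))
  }
  tab <- table(cluster = labels, sample = samples)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Dotplot statistics, max-scaled variant
#'
#' For each gene x group: the group mean of log-normalized expression
#' divided by its maximum over groups (0 where the maximum is 0), and the
#' number of cells with a nonzero value in the group, likewise divided by
#' its maximum over groups.
#'
#' @param lognorm a \code{lognorm_matrix} or matrix, cells x genes.
#' @param genes genes to summarise (must be present).
#' @param groups per-cell group labels.
#' @return A data.frame: \code{gene}, \code{group}, \code{mean},
#'   \code{scaled_mean}, \code{n_expressing}, \code{scaled_n_expressing}.
#' @export
dotplot_stats_max_scaled <- function(lognorm, genes, groups) {
  st <- dotplot_base(lognorm, genes, groups)
  scale_max <- function(v) {
    mx <- max(v)
    if (mx > 0) v / mx else v * 0
  }
  st$scaled_mean <- ave(st$mean, st$gene, FUN = scale_max)
  st$scaled_n_expressing <- ave(as.numeric(st$n_expressing), st$gene,
                                FUN = scale_max)
  st[, c("gene", "group", "mean", "scaled_mean", "n_expressing",
         "scaled_n_expressing")]
}

#' Dotplot statistics, min-max-scaled variant
#'
#' For each gene x group: the group mean minus the minimum over groups,
#' divided by the maximum of those min-subtracted values (0 for every group
#' when the range is 0), and the fraction of cells in the group with a
#' nonzero value.
#'
#' @inheritParams dotplot_stats_max_scaled
#' @return A data.frame: \code{gene}, \code{group}, \code{mean},
#'   \code{scaled_mean}, \code{n_expressing}, \code{frac_expressing}.
#' @export
dotplot_stats_minmax <- function(lognorm, genes, groups) {
  st <- dotplot_base(lognorm, genes, groups)
  scale_minmax <- function(v) {
    v <- v - min(v)
    mx <- max(v)
    if (mx > 0) v / mx else v * 0
  }
  st$scaled_mean <- ave(st$mean, st$gene, FUN = scale_minmax)
  st$frac_expressing <- st$n_expressing / st$n_cells
  st[, c("gene", "group", "mean", "scaled_mean", "n_expressing",
         "frac_expressing")]
}

#' Dotplot statistics dispatcher
#'
#' @inheritParams dotplot_stats_max_scaled
#' @param variant \code{"max"} or \code{"minmax"}.
#' @return See \code{\link{dotplot_stats_max_scaled}} and
#'   \code{\link{dotplot_stats_minmax}}.
#' @export
dotplot_stats <- function(lognorm, genes, groups,
                          variant = c("max", "minmax")) {
  variant <- match.arg(variant)
  if (variant == "max") dotplot_stats_max_scaled(lognorm, genes, groups)
  else dotplot_stats_minmax(lognorm, genes, groups)
}

# Shared per gene x group means and expressing-cell counts.
dotplot_base <- function(lognorm, genes, groups) {
  m <- if (inherits(lognorm, "lognorm_matrix")) lognorm$values else lognorm
  stop_if_not(length(groups) == nrow(m), "groups not aligned with cells")
  missing <- setdiff(genes, colnames(m))
  stop_if_not(length(missing) == 0, "genes not present: %s",
              paste(missing, collapse = ", "))
  gl <- unique(groups)
  stop_if_not(all(table(groups)[as.character(gl)] > 0), "empty group")
  out <- expand.grid(gene = genes, group = gl, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  sub <- m[, genes, drop = FALSE]
  means <- matrix(0, length(gl), length(genes))
  nexpr <- matrix(0L, length(gl), length(genes))
  ncell <- integer(length(gl))
  for (i in seq_along(gl)) {
    rows <- groups == gl[i]
    ncell[i] <- sum(rows)
    means[i, ] <- Matrix::colSums(sub[rows, , drop = FALSE]) / ncell[i]
    nexpr[i, ] <- Matrix::colSums(sub[rows, , drop = FALSE] > 0)
  }
  gi <- match(out$gene, genes)
  si <- match(out$group, gl)
  out$mean <- means[cbind(si, gi)]
  out$n_expressing <- nexpr[cbind(si, gi)]
  out$n_cells <- ncell[si]
  out
}
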