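# Dimensionality reduction and clustering: dispersion-binned HVG selection,
# covariate regression and scaling, PCA, kNN graph, Louvain partitioning,
# UMAP embedding, and subset re-clustering.

#' Highly-variable-gene selection parameters
#'
#' Mean bounds are on the log1p of the back-transformed per-gene mean;
#' \code{min_disp} is a cutoff on the within-bin z-score of the
#' variance/mean dispersion.
#'
#' @param min_mean,max_mean open interval for log1p(mean) (defaults 0.0125
#'   and 4).
#' @param min_disp minimum normalized dispersion (default 0.5).
#' @param n_bins number of equal-width log1p-mean bins (default 20).
#' @return An \code{hvg_config} list.
#' @export
hvg_config <- function(min_mean = 0.0125, max_mean = 4, min_disp = 0.5,
                       n_bins = 20) {
  stop_if_not(min_mean < max_mean, "min_mean must be < max_mean")
  stop_if_not(n_bins >= 1, "n_bins must be >= 1")
  structure(list(min_mean = min_mean, max_mean = max_mean,
                 min_disp = min_disp, n_bins = n_bins),
            class = "hvg_config")
}

#' Clustering parameters
#'
#' @param n_pcs number of principal components (default 50; capped at the
#'   feasible rank).
#' @param knn_k nearest-neighbour count for the cell graph (default 10).
#' @param louvain_resolution Louvain modularity resolution. The analysis
#'   this package implements used 1 for all cells and 0.5, 0.6 and 0.7 for
#'   the cardiomyocyte, double-positive and double-positive-without-mutant
#'   subsets.
#' @param seed integer seed (Louvain tie-breaking and UMAP optimisation).
#' @param compute_umap whether to compute the UMAP embedding.
#' @return A \code{cluster_config} list.
#' @export
cluster_config <- function(n_pcs = 50, knn_k = 10, louvain_resolution = 1,
                           seed = 1, compute_umap = TRUE) {
  stop_if_not(n_pcs >= 1 && knn_k >= 1, "n_pcs and knn_k must be >= 1")
  stop_if_not(louvain_resolution > 0, "resolution must be > 0")
  structure(list(n_pcs = n_pcs, knn_k = knn_k,
                 louvain_resolution = louvain_resolution,
                 seed = as.integer(seed), compute_umap = compute_umap),
            class = "cluster_config")
}

# Sparse column means and variances without densifying.
sparse_col_stats <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colSums(m) / n
  sq <- Matrix::colSums(m^2)
  v <- (sq - n * mu^2) / max(1, n - 1)
  v[v < 0] <- 0
  list(mean = as.numeric(mu), var = as.numeric(v))
}

#' Select highly variable genes by binned dispersion
#'
#' Back-transforms the log-normalized values with expm1, computes per-gene
#' mean and dispersion (variance/mean), bins genes into equal-width bins of
#' log1p(mean), z-scores the dispersion within each bin (bins holding a
#' single gene, or with zero spread, get normalized dispersion 0), and
#' flags genes with \code{min_mean < log1p(mean) < max_mean} and normalized
#' dispersion \code{>= min_disp}.
#'
#' @param lognorm a \code{lognorm_matrix} (see
#'   \code{\link{normalize_and_log}}) or a log-transformed sparse/dense
#'   matrix, cells x genes.
#' @param config an \code{\link{hvg_config}}.
#' @return A data.frame with one row per gene: \code{gene}, \code{mean},
#'   \code{log1p_mean}, \code{dispersion}, \code{norm_dispersion},
#'   \code{is_hvg}.
#' @export
select_hvgs <- function(lognorm, config = hvg_config()) {
  m <- if (inherits(lognorm, "lognorm_matrix")) lognorm$values else lognorm
  stop_if_not(sum(m) > 0 || length(m) == 0, "all-zero matrix")
  x <- methods::as(m, "CsparseMatrix")
  x@x <- expm1(x@x)
  st <- sparse_col_stats(x)
  mu <- st$mean
  disp <- ifelse(mu > 0, st$var / mu, 0)
  lm <- log1p(mu)
  nb <- config$n_bins
  rng <- range(lm)
  if (diff(rng) == 0) {
    bin <- rep(1L, length(lm))
  } else {
    br <- seq(rng[1], rng[2], length.out = nb + 1)
    bin <- findInterval(lm, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  bm <- tapply(disp, bin, mean)
  bs <- tapply(disp, bin, sd)
  bn <- tapply(disp, bin, length)
  z <- (disp - bm[as.character(bin)]) / bs[as.character(bin)]
  z[bn[as.character(bin)] < 2 | !is.finite(z)] <- 0
  is_hvg <- lm > config$min_mean & lm < config$max_mean &
    z >= config$min_disp
  data.frame(gene = colnames(m), mean = mu, log1p_mean = lm,
             dispersion = disp, norm_dispersion = as.numeric(z),
             is_hvg = is_hvg, stringsAsFactors = FALSE)
}

#' Regress out covariates and scale genes
#'
#' Replaces each gene by its least-squares residual against the given
#' per-cell covariates (plus an intercept), then zero-centres and scales
#' each gene to unit variance (genes with zero residual variance are set to
#' 0 everywhere).
#'
#' @param lognorm a \code{lognorm_matrix} or matrix, cells x genes.
#' @param covariates data.frame or matrix of per-cell covariates, typically
#'   total raw counts and percent-mitochondrial UMIs (see
#'   \code{\link{cell_covariates}}).
#' @return Dense numeric matrix, cells x genes, each column zero-mean and
#'   unit variance (or all zero).
#' @export
regress_and_scale <- function(lognorm, covariates) {
  m <- if (inherits(lognorm, "lognorm_matrix")) lognorm$values else lognorm
  y <- as.matrix(m)
  cv <- as.matrix(covariates[, setdiff(colnames(covariates), "barcode"),
                             drop = FALSE])
  storage.mode(cv) <- "double"
  stop_if_not(nrow(cv) == nrow(y),
              "covariate rows (%d) != cells (%d)", nrow(cv), nrow(y))
  X <- cbind(intercept = 1, cv)
  # qr.fitted tolerates rank-deficient designs (e.g. constant covariates)
  res <- y - qr.fitted(qr(X), y)
  res <- sweep(res, 2, colMeans(res))
  s <- apply(res, 2, sd)
  res <- sweep(res, 2, ifelse(s > 0, s, 1), "/")
  res[, s == 0] <- 0
  res
}

#' PCA on a scaled matrix
#'
#' Singular value decomposition of the (already column-centred) scaled
#' matrix. Components are ordered by non-increasing explained variance and
#' their signs fixed so the largest-magnitude gene loading of each
#' component is positive, making downstream clustering reproducible.
#'
#' @param scaled dense matrix, cells x genes (typically the HVG-restricted
#'   output of \code{\link{regress_and_scale}}).
#' @param n_pcs number of components (must not exceed min(cells-1, genes)).
#' @return A list: \code{scores} (cells x n_pcs), \code{loadings} (genes x
#'   n_pcs), \code{sdev}, \code{var_explained}.
#' @export
compute_pca <- function(scaled, n_pcs = 50) {
  scaled <- as.matrix(scaled)
  maxr <- min(nrow(scaled) - 1L, ncol(scaled))
  stop_if_not(n_pcs <= maxr,
              "n_pcs (%d) exceeds feasible rank (%d)", n_pcs, maxr)
  ctr <- sweep(scaled, 2, colMeans(scaled))
  sv <- svd(ctr, nu = n_pcs, nv = n_pcs)
  d <- sv$d[seq_len(n_pcs)]
  u <- sv$u
  v <- sv$v
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, n_pcs, n_pcs)
  rownames(scores) <- rownames(scaled)
  sdev <- d / sqrt(max(1, nrow(scaled) - 1))
  tot <- sum(apply(ctr, 2, function(x) sum(x^2))) / max(1, nrow(scaled) - 1)
  list(scores = scores, loadings = v, sdev = sdev,
       var_explained = if (tot > 0) sdev^2 / tot else rep(0, n_pcs))
}

#' Exact k-nearest-neighbour graph
#'
#' Links each cell to its k Euclidean nearest neighbours (self excluded,
#' distance ties broken by index) and union-symmetrizes the result.
#'
#' @param scores numeric matrix, cells x dims (e.g. PCA scores).
#' @param k neighbours per cell (must be < number of cells).
#' @return A \code{knn_graph}: list with \code{idx} (n x k neighbour
#'   indices), \code{dist} (n x k distances), \code{adjacency} (sparse
#'   symmetric 0/1 matrix) and \code{n}.
#' @export
knn_graph <- function(scores, k = 10) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stop_if_not(k < n, "k (%d) must be < number of cells (%d)", k, n)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(scores^2)
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(s + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(scores[rows, , drop = FALSE], scores)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      d2[i, rows[i]] <- Inf
      o <- order(d2[i, ])[seq_len(k)]
      idx[rows[i], ] <- o
      dst[rows[i], ] <- sqrt(d2[i, o])
    }
  }
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                              x = 1, dims = c(n, n))
  adj <- methods::as((adj + Matrix::t(adj)) > 0, "CsparseMatrix") * 1
  structure(list(idx = idx, dist = dst, adjacency = adj, n = n),
            class = "knn_graph")
}

#' Louvain clustering of a kNN graph
#'
#' Modularity-based multi-level partitioning at the given resolution.
#' Cluster labels are integers from 0, relabelled in order of decreasing
#' cluster size (ties by smallest original label) so runs are comparable.
#'
#' @param graph a \code{\link{knn_graph}} (or square adjacency matrix).
#' @param resolution modularity resolution parameter.
#' @param seed RNG seed (Louvain vertex-order tie-breaking).
#' @return Integer vector of 0-based labels, one per cell.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 1) {
  adj <- if (inherits(graph, "knn_graph")) graph$adjacency else graph
  stop_if_not(nrow(adj) > 0, "empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  unname(relabel[as.character(memb)])
}

#' UMAP embedding of a kNN graph
#'
#' Library-backed two-dimensional embedding computed from the precomputed
#' neighbour structure; deterministic under a fixed seed (single-threaded
#' optimisation).
#'
#' @param graph a \code{\link{knn_graph}}.
#' @param seed RNG seed.
#' @return Numeric matrix, cells x 2.
#' @export
umap_embed <- function(graph, seed = 1) {
  stopifnot(inherits(graph, "knn_graph"))
  stop_if_not(graph$n > 0, "empty input")
  nn <- list(idx = cbind(seq_len(graph$n), graph$idx),
             dist = cbind(0, graph$dist))
  with_seed(seed, {
    emb <- uwot::umap(X = NULL, nn_method = nn, n_components = 2,
                      n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
    colnames(emb) <- c("UMAP1", "UMAP2")
    emb
  })
}

#' Full clustering chain on a raw count matrix
#'
#' Runs normalize/log, HVG selection, covariate regression (total counts
#' and percent-mitochondrial, from the raw matrix), per-gene scaling, PCA,
#' kNN graph, Louvain clustering and (optionally) UMAP.
#'
#' @param matrix a QC-filtered \code{\link{count_matrix}} of raw counts.
#' @param config a \code{\link{cluster_config}}.
#' @param hvg an \code{\link{hvg_config}}.
#' @param target_sum normalization total (default 10,000).
#' @return A \code{cluster_result}: list with \code{labels} (0-based,
#'   named by barcode), \code{counts} (cluster x sample table),
#'   \code{embedding} (cells x 2 or NULL), \code{hvg} (the HVG table),
#'   \code{pca}, \code{graph}, \code{samples}.
#' @export
cluster_cells <- function(matrix, config = cluster_config(),
                          hvg = hvg_config(), target_sum = 10000) {
  stopifnot(inherits(matrix, "count_matrix"))
  ln <- normalize_and_log(matrix, target_sum)
  hv <- select_hvgs(ln, hvg)
  genes <- hv$gene[hv$is_hvg]
  stop_if_not(length(genes) >= 2, "fewer than 2 highly variable genes")
  cov <- cell_covariates(matrix)
  scaled <- regress_and_scale(ln$values[, genes, drop = FALSE],
                              cov[, c("total_counts", "pct_mito")])
  n_pcs <- min(config$n_pcs, nrow(scaled) - 1L, ncol(scaled))
  pca <- compute_pca(scaled, n_pcs)
  graph <- knn_graph(pca$scores, config$knn_k)
  labels <- louvain_cluster(graph, config$louvain_resolution,
                            seed = config$seed)
  names(labels) <- matrix$barcodes
  emb <- if (config$compute_umap) {
    e <- umap_embed(graph, seed = config$seed)
    rownames(e) <- matrix$barcodes
    e
  } else NULL
  res <- list(labels = labels,
              counts = cluster_sample_counts(labels, matrix$samples),
              embedding = emb, hvg = hv, pca = pca, graph = graph,
              samples = matrix$samples)
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cells, %d clusters\n",
              length(x$labels), length(unique(x$labels))))
  print(x$counts)
  invisible(x)
}

#' Re-cluster a subset of cells
#'
#' Extracts the cells selected by a predicate and reruns the full chain
#' (HVG, regression, scaling, PCA, kNN, Louvain) on the subset with its own
#' configuration -- e.g. resolution 0.5 for a cardiomyocyte subset, 0.6 for
#' double-positive cells, 0.7 for double-positive cells excluding the
#' mutant sample.
#'
#' @param matrix a \code{\link{count_matrix}} of raw counts.
#' @param cells logical vector, barcode vector, or predicate function
#'   applied to the matrix selecting the subset.
#' @param config a \code{\link{cluster_config}}.
#' @param ... passed on to \code{\link{cluster_cells}}.
#' @return A \code{cluster_result} for the subset.
#' @export
subset_and_recluster <- function(matrix, cells, config = cluster_config(),
                                 ...) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (is.function(cells)) cells <- cells(matrix)
  sub <- cm_subset(matrix, cells = cells)
  stop_if_not(nrow(sub$counts) >= config$knn_k + 1,
              "subset too small: %d cells for k = %d",
              nrow(sub$counts), config$knn_k)
  cluster_cells(sub, config, ...)
}
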