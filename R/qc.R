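# Quality control: minimum expressed-gene filtering, a simulated-doublet
# kNN doublet scorer, per-sample doublet thresholding, gene pruning and
# library-size normalization with log transform. The stage order is fixed:
# min-genes -> doublets -> gene pruning -> normalize -> log.

#' Quality-control configuration
#'
#' @param min_genes minimum expressed features for a cell to pass (cells
#'   with strictly fewer are removed; default 100).
#' @param doublet_threshold doublet-score cutoff (cells strictly above are
#'   removed). Either a single number or a named vector keyed by sample,
#'   e.g. the per-sample values 0.3, 0.27 and 0.38 used for an uninjured,
#'   an injured and an injured-mutant 10x run.
#' @param doublet_sim_ratio simulated doublets per observed cell.
#' @param doublet_knn neighbours used by the doublet scorer.
#' @param doublet_n_pcs principal components used by the doublet scorer.
#' @param doublet_expected_rate prior doublet rate used to calibrate the
#'   neighbour fraction into a posterior score (default 0.1, a typical
#'   droplet loading rate).
#' @param target_sum per-cell total after normalization (default 10,000).
#' @param seed integer seed for the doublet simulation.
#' @return A \code{qc_config} list.
#' @export
qc_config <- function(min_genes = 100, doublet_threshold = 0.3,
                      doublet_sim_ratio = 2, doublet_knn = 30,
                      doublet_n_pcs = 30, doublet_expected_rate = 0.1,
                      target_sum = 10000, seed = 1) {
  stop_if_not(min_genes >= 1, "min_genes must be >= 1")
  stop_if_not(all(doublet_threshold >= 0 & doublet_threshold <= 1),
              "doublet thresholds must lie in [0,1]")
  stop_if_not(target_sum > 0, "target_sum must be > 0")
  stop_if_not(doublet_sim_ratio > 0 && doublet_knn >= 1 &&
                doublet_n_pcs >= 1, "invalid doublet scorer parameters")
  stop_if_not(doublet_expected_rate > 0 && doublet_expected_rate < 1,
              "doublet_expected_rate must lie in (0,1)")
  structure(list(min_genes = min_genes,
                 doublet_threshold = doublet_threshold,
                 doublet_sim_ratio = doublet_sim_ratio,
                 doublet_knn = doublet_knn, doublet_n_pcs = doublet_n_pcs,
                 doublet_expected_rate = doublet_expected_rate,
                 target_sum = target_sum, seed = as.integer(seed)),
            class = "qc_config")
}

#' Remove cells with too few expressed features
#'
#' A cell passes when it expresses (raw count > 0) at least \code{min_genes}
#' features; cells with strictly fewer are removed.
#'
#' @param matrix a \code{\link{count_matrix}} of raw counts.
#' @param min_genes threshold (default 100).
#' @return A list: \code{matrix} (filtered) and \code{removed} (barcodes of
#'   removed cells).
#' @export
filter_low_gene_cells <- function(matrix, min_genes = 100) {
  stopifnot(inherits(matrix, "count_matrix"))
  stop_if_not(min_genes >= 1, "min_genes must be >= 1")
  nexp <- n_expressed_features(matrix)
  keep <- nexp >= min_genes
  list(matrix = cm_subset(matrix, cells = keep),
       removed = matrix$barcodes[!keep])
}

#' Normalize library sizes and log-transform
#'
#' Drops features with zero total count across all cells, rescales each
#' cell so its counts sum to \code{target_sum}, and applies the natural
#' \code{log(1 + x)} transform. Cells with zero total counts are an error
#' (filter them first).
#'
#' @param matrix a \code{\link{count_matrix}} of raw counts.
#' @param target_sum per-cell total after scaling (default 10,000).
#' @return A \code{lognorm_matrix}: list with \code{values} (sparse real
#'   matrix, cells x kept features), \code{barcodes}, \code{features}
#'   (pruned feature table), \code{samples}, \code{target_sum}.
#' @export
normalize_and_log <- function(matrix, target_sum = 10000) {
  stopifnot(inherits(matrix, "count_matrix"))
  totals <- Matrix::rowSums(matrix$counts)
  stop_if_not(all(totals > 0), "cells with zero total counts present")
  keep_feat <- Matrix::colSums(matrix$counts) > 0
  m <- matrix$counts[, keep_feat, drop = FALSE]
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% m
  values <- methods::as(scaled, "CsparseMatrix")
  values@x <- log1p(values@x)
  rownames(values) <- matrix$barcodes
  structure(list(values = values, barcodes = matrix$barcodes,
                 features = matrix$features[keep_feat, , drop = FALSE],
                 samples = matrix$samples, target_sum = target_sum),
            class = "lognorm_matrix")
}

#' @export
dim.lognorm_matrix <- function(x) dim(x$values)

#' @export
print.lognorm_matrix <- function(x, ...) {
  cat(sprintf("lognorm_matrix: %d cells x %d features (target sum %g)\n",
              nrow(x$values), ncol(x$values), x$target_sum))
  invisible(x)
}

#' Score cells for doublets with simulated-doublet k-nearest neighbours
#'
#' Implements a simulated-doublet classifier in the style used for droplet
#' data: observed cells are normalized, log-transformed, restricted to
#' highly variable genes, per-gene z-scored and embedded with PCA;
#' synthetic doublets -- element-wise sums of random pairs of distinct
#' observed raw profiles -- are pushed through the same transform (using
#' the observed means and standard deviations) and projected onto the same
#' components; each observed
#' cell is scored by the fraction \eqn{q} of synthetic doublets among its
#' \code{doublet_knn} nearest neighbours (with a +1/+2 pseudocount),
#' calibrated into a posterior doublet probability
#' \deqn{score = \frac{q \rho / r}{1 - \rho - q (1 - \rho - \rho / r)}}
#' where \eqn{r} is the simulated:observed ratio and \eqn{\rho} the
#' expected doublet rate. The calibration maps an uninformative
#' neighbourhood (simulated fraction equal to the oversampling rate) to
#' roughly \eqn{\rho} and a purely simulated neighbourhood to 1, so scores
#' lie in [0,1] on the scale on which per-sample removal thresholds around
#' 0.3 are meaningful.
#'
#' @param matrix a \code{\link{count_matrix}} of raw counts (at least 2
#'   cells, more than \code{doublet_knn}).
#' @param config a \code{\link{qc_config}}.
#' @param seed RNG seed (defaults to the config seed).
#' @return Named numeric vector of scores in [0,1], one per cell.
#' @export
score_doublets <- function(matrix, config = qc_config(),
                           seed = config$seed) {
  stopifnot(inherits(matrix, "count_matrix"))
  n <- nrow(matrix$counts)
  stop_if_not(n >= 2, "need at least 2 cells")
  stop_if_not(n > config$doublet_knn,
              "need more cells than doublet_knn (%d)", config$doublet_knn)
  with_seed(seed, {
    ln <- normalize_and_log(matrix, config$target_sum)
    hv <- select_hvgs(ln)
    genes <- hv$gene[hv$is_hvg]
    if (length(genes) < 5) {
      v <- apply(as.matrix(ln$values), 2, var)
      genes <- colnames(ln$values)[v > 0]
    }
    n_sim <- ceiling(config$doublet_sim_ratio * n)
    p1 <- sample.int(n, n_sim, replace = TRUE)
    p2 <- sample.int(n, n_sim, replace = TRUE)
    same <- p1 == p2            # a doublet needs two distinct parents
    p2[same] <- (p2[same] %% n) + 1L
    sim_raw <- matrix$counts[p1, , drop = FALSE] +
      matrix$counts[p2, , drop = FALSE]
    sim_tot <- Matrix::rowSums(sim_raw)
    sim_ln <- Matrix::Diagonal(x = config$target_sum / sim_tot) %*% sim_raw
    sim_ln <- methods::as(sim_ln, "CsparseMatrix")
    sim_ln@x <- log1p(sim_ln@x)
    colnames(sim_ln) <- colnames(matrix$counts)
    if (length(genes) == 0) {
      # fully degenerate input: no informative gene, uniform zero scores
      return(setNames(rep(0, n), matrix$barcodes))
    }
    obs <- as.matrix(ln$values[, genes, drop = FALSE])
    sim <- as.matrix(sim_ln[, genes, drop = FALSE])
    # per-gene z-scoring on the observed cells sharpens the extra
    # detected-gene signal that betrays same-type doublets
    ctr <- colMeans(obs)
    sdv <- apply(obs, 2, sd)
    sdv[sdv == 0] <- 1
    obs_z <- sweep(sweep(obs, 2, ctr), 2, sdv, "/")
    sim_z <- sweep(sweep(sim, 2, ctr), 2, sdv, "/")
    n_pcs <- min(config$doublet_n_pcs, n - 1L, ncol(obs))
    sv <- svd(obs_z, nu = 0, nv = n_pcs)
    rot <- sv$v
    obs_p <- obs_z %*% rot
    sim_p <- sim_z %*% rot
    all_p <- rbind(obs_p, sim_p)
    is_sim <- c(rep(FALSE, n), rep(TRUE, n_sim))
    k <- config$doublet_knn
    # exact kNN by blocked distance computation
    q <- numeric(n)
    all_sq <- rowSums(all_p^2)
    block <- max(1L, floor(2e7 / nrow(all_p)))
    for (s in seq(1L, n, by = block)) {
      rows <- s:min(s + block - 1L, n)
      d2 <- outer(all_sq[rows], all_sq, "+") -
        2 * tcrossprod(all_p[rows, , drop = FALSE], all_p)
      for (i in seq_along(rows)) {
        d2[i, rows[i]] <- Inf  # exclude self
        nb <- order(d2[i, ])[seq_len(k)]
        q[rows[i]] <- (sum(is_sim[nb]) + 1) / (k + 2)
      }
    }
    r <- n_sim / n
    rho <- config$doublet_expected_rate
    score <- q * rho / r / (1 - rho - q * (1 - rho - rho / r))
    score[!is.finite(score)] <- 0
    score[score < 0] <- 0
    score[score > 1] <- 1
    setNames(score, matrix$barcodes)
  })
}

#' Remove cells whose doublet score exceeds a threshold
#'
#' Cells with score strictly greater than the threshold are removed. The
#' integer identity retained = passed - removed holds by construction.
#'
#' @param matrix a \code{\link{count_matrix}}.
#' @param scores named score vector aligned with the matrix barcodes.
#' @param threshold scalar cutoff, or named vector keyed by sample.
#' @return A list: \code{matrix} (filtered), \code{removed} (barcodes).
#' @export
apply_doublet_filter <- function(matrix, scores, threshold) {
  stopifnot(inherits(matrix, "count_matrix"))
  stop_if_not(length(scores) == nrow(matrix$counts),
              "scores not aligned with barcodes")
  if (!is.null(names(scores))) {
    stop_if_not(identical(names(scores), matrix$barcodes),
                "score names do not match barcodes")
  }
  thr <- if (length(threshold) == 1L && is.null(names(threshold))) {
    rep(threshold, nrow(matrix$counts))
  } else {
    stop_if_not(all(matrix$samples %in% names(threshold)),
                "no doublet threshold for some samples")
    unname(threshold[matrix$samples])
  }
  remove <- scores > thr
  list(matrix = cm_subset(matrix, cells = !remove),
       removed = matrix$barcodes[remove])
}

#' Run the full quality-control stage
#'
#' Fixed order: (1) remove cells with fewer than \code{min_genes} expressed
#' features; (2) score doublets per sample and remove cells above the
#' per-sample threshold; (3) drop non-expressed genes, normalize every cell
#' to \code{target_sum} and log-transform.
#'
#' @param matrix a \code{\link{count_matrix}} of raw counts.
#' @param config a \code{\link{qc_config}}.
#' @return A list: \code{matrix} (filtered raw counts), \code{lognorm}
#'   (a \code{lognorm_matrix}), \code{scores} (doublet scores of cells that
#'   passed the gene filter), \code{removed_low_genes},
#'   \code{removed_doublets}, and \code{report} -- a per-sample data.frame
#'   with columns \code{sample}, \code{n_input}, \code{passed},
#'   \code{doublets_removed}, \code{retained}.
#' @export
qc_pipeline <- function(matrix, config = qc_config()) {
  f1 <- filter_low_gene_cells(matrix, config$min_genes)
  passed <- f1$matrix
  samp <- unique(passed$samples)
  scores <- numeric(0)
  parts <- list()
  removed_doub <- character(0)
  for (i in seq_along(samp)) {
    sm <- cm_subset(passed, cells = passed$samples == samp[i])
    sc <- score_doublets(sm, config, seed = child_seed(config$seed, i))
    thr <- if (length(config$doublet_threshold) == 1L &&
               is.null(names(config$doublet_threshold))) {
      config$doublet_threshold
    } else {
      stop_if_not(samp[i] %in% names(config$doublet_threshold),
                  "no doublet threshold for sample '%s'", samp[i])
      config$doublet_threshold[[samp[i]]]
    }
    f2 <- apply_doublet_filter(sm, sc, thr)
    scores <- c(scores, sc)
    parts[[i]] <- f2$matrix
    removed_doub <- c(removed_doub, f2$removed)
  }
  retained <- cm_bind(parts)
  report <- do.call(rbind, lapply(seq_along(samp), function(i) {
    s <- samp[i]
    n_passed <- sum(passed$samples == s)
    n_ret <- nrow(parts[[i]]$counts)
    data.frame(sample = s, n_input = sum(matrix$samples == s),
               passed = n_passed, doublets_removed = n_passed - n_ret,
               retained = n_ret, stringsAsFactors = FALSE)
  }))
  list(matrix = retained, lognorm = normalize_and_log(retained,
                                                      config$target_sum),
       scores = scores, removed_low_genes = f1$removed,
       removed_doublets = removed_doub, report = report)
}
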