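# HVG selection, regression/scaling, PCA, kNN graph, Louvain, UMAP and
# subset re-clustering.

# Independent HVG oracle: plain loops over the definition.
hvg_oracle <- function(lognorm, min_mean = 0.0125, max_mean = 4,
                       min_disp = 0.5, n_bins = 20) {
  x <- expm1(as.matrix(lognorm))
  n <- nrow(x)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  lm <- log1p(mu)
  br <- seq(min(lm), max(lm), length.out = n_bins + 1)
  bin <- findInterval(lm, br, rightmost.closed = TRUE, all.inside = TRUE)
  z <- numeric(length(mu))
  for (b in unique(bin)) {
    in_b <- bin == b
    if (sum(in_b) < 2 || sd(disp[in_b]) == 0) {
      z[in_b] <- 0
    } else {
      z[in_b] <- (disp[in_b] - mean(disp[in_b])) / sd(disp[in_b])
    }
  }
  lm > min_mean & lm < max_mean & z >= min_disp
}

test_that("HVG selection matches an independent binning oracle", {
  set.seed(101)
  n <- 80
  m <- matrix(rpois(n * 50, rep(exp(rnorm(50, 1, 1.5)), each = n)), n)
  colnames(m) <- sprintf("g%02d", 1:50)
  m[, 1] <- 5L                      # constant nonzero: zero variance
  ln <- normalize_and_log(toy_cm(m))
  hv <- select_hvgs(ln)
  oracle <- hvg_oracle(as.matrix(ln$values))
  expect_equal(hv$is_hvg, unname(oracle))
  expect_false(hv$is_hvg[hv$gene == "g01"])
})

test_that("the mean window and dispersion cutoff behave as documented", {
  # a gene with log1p-mean above 4 is excluded however variable it is
  set.seed(7)
  m <- matrix(rpois(200 * 30, 3), 200, 30)
  m[, 1] <- rpois(200, 60) * rbinom(200, 1, 0.5) * 10  # huge mean + var
  ln <- normalize_and_log(toy_cm(m))
  hv <- select_hvgs(ln)
  expect_gt(hv$log1p_mean[1], 4)
  expect_false(hv$is_hvg[1])
  # monotonicity: raising min_disp never adds an HVG
  hv_lo <- select_hvgs(ln, hvg_config(min_disp = 0.3))
  hv_hi <- select_hvgs(ln, hvg_config(min_disp = 0.8))
  expect_true(all(hv_hi$is_hvg <= hv_lo$is_hvg))
})

test_that("covariate regression removes planted effects and centres genes", {
  set.seed(5)
  n <- 120
  cov <- data.frame(total_counts = runif(n, 500, 5000),
                    pct_mito = runif(n, 0, 20))
  y <- matrix(rnorm(n * 15), n, 15)
  y[, 1] <- y[, 1] + 0.002 * cov$total_counts       # planted linear effect
  y[, 2] <- y[, 2] + 0.3 * cov$pct_mito
  colnames(y) <- sprintf("g%02d", 1:15)
  out <- regress_and_scale(y, cov)
  expect_lt(abs(cor(out[, 1], cov$total_counts)), 1e-8)
  expect_lt(abs(cor(out[, 2], cov$pct_mito)), 1e-8)
  expect_lt(max(abs(colMeans(out))), 1e-10)
  sds <- apply(out, 2, sd)
  expect_equal(unname(sds), rep(1, 15), tolerance = 1e-8)
  # constant covariates reduce to plain centring and scaling
  cc <- data.frame(total_counts = rep(3, n), pct_mito = rep(1, n))
  out2 <- regress_and_scale(y, cc)
  manual <- scale(y)
  expect_equal(unname(out2), unname(manual[, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA matches an SVD oracle and orders variance", {
  set.seed(9)
  m <- matrix(rnorm(20 * 10), 20, 10)
  p <- compute_pca(m, 5)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  ctr <- scale(m, scale = FALSE)
  sv <- svd(ctr)
  oracle <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  for (j in 1:5) {
    expect_equal(abs(p$scores[, j]), abs(oracle[, j]), tolerance = 1e-8)
  }
  # rank-2 input has exactly 2 nonzero variances
  r2 <- outer(rnorm(15), rnorm(6)) + outer(rnorm(15), rnorm(6))
  p2 <- compute_pca(r2, 5)
  expect_equal(sum(p2$sdev > 1e-10), 2L)
  expect_error(compute_pca(m, 50), "exceeds feasible rank")
})

test_that("the kNN graph matches brute-force neighbour sets", {
  set.seed(3)
  x <- matrix(rnorm(100 * 5), 100, 5)
  g <- knn_graph(x, k = 10)
  d <- as.matrix(dist(x))
  for (i in seq_len(100)) {
    expect_equal(sort(g$idx[i, ]),
                 sort(order(d[i, -i])[1:10] + (order(d[i, -i])[1:10] >= i)))
  }
  expect_true(all(Matrix::diag(g$adjacency) == 0))
  expect_true(Matrix::isSymmetric(g$adjacency))
  # two points: a single mutual edge
  g2 <- knn_graph(matrix(c(0, 1), 2, 1), k = 1)
  expect_equal(as.matrix(g2$adjacency),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_error(knn_graph(x, k = 100), "must be <")
})

test_that("Louvain separates disconnected cliques and relabels by size", {
  adj <- matrix(0, 25, 25)
  adj[1:10, 1:10] <- 1          # 10-clique
  adj[11:25, 11:25] <- 1        # 15-clique
  diag(adj) <- 0
  lab <- louvain_cluster(Matrix::Matrix(adj, sparse = TRUE),
                         resolution = 1, seed = 4)
  expect_equal(length(unique(lab)), 2L)
  # larger community gets label 0
  expect_true(all(lab[11:25] == 0L) && all(lab[1:10] == 1L))
  lab2 <- louvain_cluster(Matrix::Matrix(adj, sparse = TRUE),
                          resolution = 1, seed = 4)
  expect_identical(lab, lab2)
})

test_that("UMAP embeds reproducibly and preserves neighbourhoods", {
  cfg <- planted_config(n_types = 3, n_per_type = 40, n_genes = 200,
                        seed = 15)
  cm <- simulate_sample(cfg, "s1")$matrix
  ln <- normalize_and_log(cm)
  hv <- select_hvgs(ln)
  scaled <- regress_and_scale(ln$values[, hv$gene[hv$is_hvg]],
                              cell_covariates(cm)[, 2:3])
  pca <- compute_pca(scaled, 20)
  g <- knn_graph(pca$scores, 10)
  e1 <- umap_embed(g, seed = 2)
  expect_equal(dim(e1), c(120L, 2L))
  expect_true(all(is.finite(e1)))
  e2 <- umap_embed(g, seed = 2)
  expect_identical(e1, e2)
  expect_gt(trustworthiness(pca$scores, e1, k = 10), 0.8)
})

test_that("subset re-clustering on all cells equals the full pipeline", {
  cfg <- planted_config(n_types = 2, n_per_type = 80, n_genes = 250,
                        seed = 33)
  cm <- simulate_sample(cfg, "s1")$matrix
  conf <- cluster_config(n_pcs = 20, seed = 5, compute_umap = FALSE)
  full <- cluster_cells(cm, conf)
  again <- subset_and_recluster(cm, rep(TRUE, nrow(cm$counts)), conf)
  expect_identical(full$labels, again$labels)
  # a single planted type re-clusters into one dominant cluster
  tr <- cfg$cell_types$type1$name
  sim <- simulate_sample(cfg, "s1")
  keep <- truth_for(sim)$cell_type == "type1"
  one <- subset_and_recluster(sim$matrix, keep,
                              cluster_config(n_pcs = 10, seed = 5,
                                             louvain_resolution = 0.5,
                                             compute_umap = FALSE))
  expect_gt(max(table(one$labels)) / length(one$labels), 0.5)
  expect_error(subset_and_recluster(sim$matrix, seq_len(5),
                                    cluster_config()), "too small")
})

test_that("the full chain recovers planted types", {
  cfg <- planted_config(n_types = 4, n_per_type = 150, n_genes = 500,
                        seed = 41)
  sim <- simulate_sample(cfg, "s1")
  res <- cluster_cells(sim$matrix,
                       cluster_config(seed = 3, compute_umap = FALSE))
  expect_gte(ari(res$labels, truth_for(sim)$cell_type), 0.9)
})
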