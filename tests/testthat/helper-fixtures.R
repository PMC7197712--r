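# Fixtures and small independent oracles shared across test files.
# All fixtures are generated in code; nothing is read from disk.

# Build a count_matrix directly from a dense matrix (features auto-classed
# as plain genes unless a class vector is given).
toy_cm <- function(m, feature_names = NULL, classes = NULL,
                   samples = "s1", barcodes = NULL) {
  if (is.null(feature_names)) {
    feature_names <- colnames(m)
    if (is.null(feature_names)) {
      feature_names <- sprintf("g%03d", seq_len(ncol(m)))
    }
  }
  if (is.null(classes)) classes <- rep("gene", ncol(m))
  if (is.null(barcodes)) barcodes <- sprintf("bc%04d", seq_len(nrow(m)))
  count_matrix(m, barcodes,
               data.frame(name = feature_names, class = classes,
                          stringsAsFactors = FALSE),
               samples)
}

# A count_matrix with the full transgene feature set plus `n_genes` plain
# genes, filled with random Poisson counts (used by gating tests).
gating_cm <- function(n_cells, n_genes = 20, lambda = 0.3, seed = 1) {
  withr::with_seed(seed, {
    map <- reporter_feature_map()
    feats <- c(map$kdrl_gene, map$runx1_gene,
               sprintf("g%03d", seq_len(n_genes)),
               transgene_feature_names(map))
    cls <- c("gene", "gene", rep("gene", n_genes),
             rep("transgene", length(transgene_feature_names(map))))
    m <- matrix(rpois(n_cells * length(feats), lambda), n_cells,
                dimnames = list(NULL, feats))
    toy_cm(m, feats, cls)
  })
}

# Independent per-cell re-evaluation of the gate rules (plain loops).
brute_force_flags <- function(cm, map = reporter_feature_map()) {
  m <- as.matrix(cm$counts)
  out <- data.frame(barcode = cm$barcodes, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    mchr <- sum(m[i, map$mcherry_features]) >= 1
    cit <- sum(m[i, map$citrine_positive_features]) >= 1
    kdrl <- m[i, map$kdrl_gene] >= 1
    runx1 <- m[i, map$runx1_gene] >= 1
    out$mChr[i] <- mchr
    out$Cit[i] <- cit
    out$kdrl[i] <- kdrl
    out$runx1[i] <- runx1
    out$kdrl_mChr[i] <- kdrl || mchr
    out$runx1_Cit[i] <- runx1 || cit
    out$double[i] <- (kdrl || mchr) && (runx1 || cit)
  }
  out
}

# A config with k well-separated planted cell types, no doublets or
# low-quality cells unless requested.
planted_config <- function(n_types = 4, n_per_type = 300, n_genes = 600,
                           seed = 1, marker_boost = 12,
                           doublet_fraction = 0, lowq_fraction = 0,
                           dispersion = 0.3, ...) {
  type_names <- paste0("type", seq_len(n_types))
  profiles <- sim_mean_profiles(n_genes, type_names,
                                marker_boost = marker_boost,
                                seed = seed + 17)
  types <- lapply(type_names, function(tn) {
    sim_cell_type(tn, n_per_type, profiles[[tn]], dispersion = dispersion)
  })
  sim_count_config(n_genes = n_genes, cell_types = types,
                   doublet_fraction = doublet_fraction,
                   lowq_fraction = lowq_fraction,
                   samples = "s1", seed = seed, ...)
}

# Align a ground-truth table to a matrix's barcode order.
truth_for <- function(sim) {
  sim$truth[match(sim$matrix$barcodes, sim$truth$barcode), ]
}

# Area under the ROC curve via the rank statistic.
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

# Mean silhouette width of a labelled point set (plain-R implementation).
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Trustworthiness of an embedding: penalises points that enter a
# k-neighbourhood in the embedding without being near in the original
# space.
trustworthiness <- function(orig, emb, k = 10) {
  n <- nrow(orig)
  do_rank <- function(x) {
    d <- as.matrix(dist(x))
    diag(d) <- Inf
    t(apply(d, 1, rank))
  }
  r_orig <- do_rank(orig)
  d_emb <- as.matrix(dist(emb))
  diag(d_emb) <- Inf
  pen <- 0
  for (i in seq_len(n)) {
    nn_emb <- order(d_emb[i, ])[seq_len(k)]
    extra <- nn_emb[r_orig[i, nn_emb] > k]
    pen <- pen + sum(r_orig[i, extra] - k)
  }
  1 - 2 * pen / (n * k * (2 * n - 3 * k - 1))
}

# Brute-force Benjamini-Hochberg step-up (independent of p.adjust).
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  run_min <- Inf
  for (i in rev(seq_len(n))) {
    run_min <- min(run_min, p[o[i]] * n / i)
    adj[o[i]] <- min(1, run_min)
  }
  adj
}

# Exhaustive hypergeometric upper tail: probability that a random n-subset
# of the universe hits at least k of the K marked elements.
hyper_tail_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}
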