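# Overestimated-variance t-test, BH adjustment, hypergeometric enrichment.

# Hand-coded statistic: both variance terms divided by the group size.
t_overestim_oracle <- function(xg, xr) {
  ng <- length(xg)
  se2 <- var(xg) / ng + var(xr) / ng
  t <- (mean(xg) - mean(xr)) / sqrt(se2)
  df <- se2^2 / ((var(xg) / ng)^2 / (ng - 1) +
                   (var(xr) / ng)^2 / (length(xr) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

t_welch_oracle <- function(xg, xr) {
  (mean(xg) - mean(xr)) /
    sqrt(var(xg) / length(xg) + var(xr) / length(xr))
}

test_that("identical groups give t = 0 and p = 1", {
  m <- rbind(matrix(1:6, 2, 3, byrow = TRUE),
             matrix(1:6, 2, 3, byrow = TRUE))
  colnames(m) <- c("a", "b", "c")
  de <- rank_genes(m, c("g", "g", "r", "r"), "g")
  expect_equal(de$t, rep(0, 3))
  expect_equal(de$p_value, rep(1, 3))
})

test_that("the statistic matches a hand-coded oracle on a 6-cell fixture", {
  set.seed(77)
  m <- matrix(rnorm(6 * 4, 2), 6, 4,
              dimnames = list(NULL, sprintf("g%d", 1:4)))
  lab <- c("a", "a", "b", "b", "b", "b")
  de <- rank_genes(m, lab, "a")
  for (g in colnames(m)) {
    o <- t_overestim_oracle(m[lab == "a", g], m[lab == "b", g])
    expect_equal(de$t[de$gene == g], o$t, tolerance = 1e-12)
    expect_equal(de$df[de$gene == g], o$df, tolerance = 1e-12)
    expect_equal(de$p_value[de$gene == g], o$p, tolerance = 1e-12)
  }
  expect_true(all(diff(de$t) <= 0))             # sorted by descending t
  expect_true(all(de$p_adj >= de$p_value - 1e-15))
})

test_that("overestimation shrinks |t| relative to Welch for small groups", {
  set.seed(13)
  for (i in 1:200) {
    ng <- sample(2:5, 1)
    nr <- ng + sample(1:10, 1)
    xg <- rnorm(ng)
    xr <- rnorm(nr)
    if (var(xg) == 0 || var(xr) == 0) next
    t_o <- t_overestim_oracle(xg, xr)$t
    t_w <- t_welch_oracle(xg, xr)
    expect_lte(abs(t_o), abs(t_w) + 1e-12)
    # and the implementation agrees with the oracle route
    m <- matrix(c(xg, xr), ncol = 1, dimnames = list(NULL, "g1"))
    de <- rank_genes(cbind(m, m), rep(c("g", "r"), c(ng, nr)), "g")
    expect_equal(de$t[1], t_o, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals brute-force step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(29)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
  # monotone: adjusted ordering preserves raw ordering
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("hypergeometric p equals exhaustive enumeration", {
  # N = 10 genes, one term of K = 4, top list of n = 3 with k = 2 hits
  universe <- sprintf("g%02d", 1:10)
  ann <- data.frame(term = "T1", gene = universe[1:4],
                    stringsAsFactors = FALSE)
  top <- c(universe[1], universe[2], universe[9])
  res <- go_enrichment(c(top, setdiff(universe, top)), ann, universe,
                       n_top = 3, min_size = 1, max_size = 10)
  expect_equal(res$overlap, 2L)
  expect_equal(res$p_value, hyper_tail_enum(10, 4, 3, 2),
               tolerance = 1e-12)
  # the enumerated pmf is a distribution
  pmf <- vapply(0:3, function(k) {
    hyper_tail_enum(10, 4, 3, k) -
      (if (k < 3) hyper_tail_enum(10, 4, 3, k + 1) else 0)
  }, numeric(1))
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # zero overlap gives p = 1 exactly
  ann2 <- data.frame(term = "T2", gene = universe[5:8],
                     stringsAsFactors = FALSE)
  res2 <- go_enrichment(c(universe[1:3], universe[-(1:3)]), ann2,
                        universe, n_top = 3, min_size = 1, max_size = 10)
  expect_identical(res2$p_value, 1)
})

test_that("term-size bounds are strict at both ends", {
  sizes <- c(5, 6, 499, 500)
  sim <- simulate_go_universe(600, sizes, seed = 8)
  ranked <- sim$universe
  res <- go_enrichment(ranked, sim$annotations, sim$universe, n_top = 50)
  expect_setequal(res$term, sprintf("GO:%07d", 2:3))
  expect_setequal(res$term_size, c(6L, 499L))
})

test_that("a term enriched by construction rises to the top", {
  sim <- simulate_go_universe(200, c(20, 30, 40), seed = 14)
  enriched_genes <- sim$annotations$gene[sim$annotations$term ==
                                           "GO:0000001"]
  ranked <- c(enriched_genes, setdiff(sim$universe, enriched_genes))
  res <- go_enrichment(ranked, sim$annotations, sim$universe, n_top = 20)
  expect_equal(res$term[1], "GO:0000001")
  expect_equal(res$overlap[res$term == "GO:0000001"], 20L)
  expect_lt(res$p_adj[1], 1e-10)
  expect_error(go_enrichment(ranked, sim$annotations, sim$universe,
                             n_top = 500), "exceeds universe")
})
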