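# The generator's planted structure is the oracle for every later stage,
# so its own guarantees are pinned down first.

test_that("degenerate fractions and zero emission rates are honoured", {
  cfg <- planted_config(n_types = 2, n_per_type = 60, n_genes = 200,
                        seed = 4, doublet_fraction = 0, lowq_fraction = 0,
                        emission = transgene_emission(0, 0, 0, 0))
  sim <- simulate_sample(cfg, "s1")
  expect_equal(sum(sim$truth$is_doublet), 0)
  expect_equal(sum(sim$truth$is_lowq), 0)
  tg <- transgene_feature_names()
  expect_equal(sum(sim$matrix$counts[, tg]), 0)
  # reporter-negative types emit nothing on any reporter feature
  expect_true(all(!sim$truth$mChr))
})

test_that("library sizes match the analytic NB expectation", {
  n_genes <- 150
  # driver-gene slots (always overridden by emission, here rate 0) stay 0
  mu <- c(0, 0, rep(2000 / (n_genes - 2), n_genes - 2))
  cfg <- sim_count_config(
    n_genes = n_genes,
    cell_types = list(sim_cell_type("t1", 500, mu, dispersion = 0.3)),
    emission = transgene_emission(0, 0, 0, 0),
    doublet_fraction = 0, lowq_fraction = 0,
    samples = "s1", singlet_min_features = 50, seed = 11)
  sim <- simulate_sample(cfg, "s1")
  lib <- Matrix::rowSums(sim$matrix$counts)
  mc_se <- sd(lib) / sqrt(length(lib))
  expect_lt(abs(mean(lib) - 2000), 3 * mc_se)
})

test_that("same config and seed reproduce byte-identical output", {
  cfg <- planted_config(n_types = 2, n_per_type = 50, n_genes = 200,
                        seed = 9, doublet_fraction = 0.1,
                        lowq_fraction = 0.05)
  a <- simulate_sample(cfg, "s1")
  b <- simulate_sample(cfg, "s1")
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth, b$truth)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("doublets are exact sums of their recorded parents", {
  cfg <- planted_config(n_types = 3, n_per_type = 60, n_genes = 200,
                        seed = 21, doublet_fraction = 0.15)
  sim <- simulate_sample(cfg, "s1")
  doub <- sim$truth[sim$truth$is_doublet, ]
  expect_gt(nrow(doub), 0)
  m <- sim$matrix$counts
  for (i in seq_len(nrow(doub))) {
    parents <- strsplit(doub$parent_barcodes[i], "|", fixed = TRUE)[[1]]
    expect_equal(as.numeric(m[doub$barcode[i], ]),
                 as.numeric(m[parents[1], ] + m[parents[2], ]))
  }
})

test_that("planted complexity classes are separated by construction", {
  cfg <- planted_config(n_types = 2, n_per_type = 120, n_genes = 300,
                        seed = 5, doublet_fraction = 0.05,
                        lowq_fraction = 0.05)
  sim <- simulate_sample(cfg, "s1")
  tr <- truth_for(sim)
  nexp <- n_expressed_features(sim$matrix)
  expect_true(all(nexp[tr$is_lowq] < 100))
  expect_true(all(nexp[!tr$is_lowq] >= 100))
})

test_that("unknown samples and empty compositions are rejected", {
  cfg <- planted_config(n_types = 2, n_per_type = 50, n_genes = 200)
  expect_error(simulate_sample(cfg, "nope"), "unknown sample")
  cfg0 <- sim_count_config(
    n_genes = 200,
    cell_types = list(sim_cell_type("t1", 0, rep(1, 200))),
    samples = "s1", singlet_min_features = 50)
  expect_error(simulate_sample(cfg0, "s1"), "zero cells")
})

test_that("AFOG images carry exact planted class areas", {
  # degenerate: all fibrin, no noise -> every wound pixel is bright red
  img1 <- simulate_afog_image(c(fibrin = 1, collagen = 0, other = 0),
                              noise_sd = 0, seed = 2)
  expect_true(all(img1$class_map[img1$mask] == 1L))
  expect_true(all(img1$image[, , 1][img1$mask] > 0.9))
  # planted counts match requested fractions up to one pixel of rounding
  fr <- c(fibrin = 0.5, collagen = 0.3, other = 0.2)
  img2 <- simulate_afog_image(fr, noise_sd = 0, seed = 3)
  area <- sum(img2$mask)
  counts <- tabulate(img2$class_map[img2$mask], 3)
  expect_true(all(abs(counts - fr * area) <= 1))
  # determinism
  img3 <- simulate_afog_image(fr, noise_sd = 0.05, seed = 3)
  img4 <- simulate_afog_image(fr, noise_sd = 0.05, seed = 3)
  expect_identical(img3$image, img4$image)
  # invalid fractions
  expect_error(simulate_afog_image(c(fibrin = 0.5, collagen = 0.5,
                                     other = 0.5)), "sum to 1")
})

test_that("nuclei tables plant the proliferation fraction", {
  all_pos <- simulate_nuclei_table(3, 50, pcna_fraction = 1, seed = 1)
  expect_true(all(all_pos$nuclei$pcna[all_pos$nuclei$mef2]))
  none <- simulate_nuclei_table(3, 50, pcna_fraction = 0, seed = 1)
  expect_false(any(none$nuclei$pcna[none$nuclei$mef2]))
  big <- simulate_nuclei_table(5, 400, pcna_fraction = 0.3, seed = 7)
  n <- sum(big$nuclei$mef2)
  phat <- mean(big$nuclei$pcna[big$nuclei$mef2])
  ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(phat - 0.3), ci)
})

test_that("GO universes carry the requested term sizes exactly", {
  sizes <- c(5, 6, 499, 500)
  sim <- simulate_go_universe(600, sizes, seed = 3)
  got <- table(sim$annotations$term)
  expect_equal(as.integer(got[sprintf("GO:%07d", 1:4)]), sizes)
  # genes within a term are distinct
  by_term <- split(sim$annotations$gene, sim$annotations$term)
  expect_true(all(vapply(by_term, anyDuplicated, integer(1)) == 0))
  # zero-size terms vanish; impossible sizes error
  empty <- simulate_go_universe(10, c(0), seed = 1)
  expect_equal(nrow(empty$annotations), 0)
  expect_error(simulate_go_universe(10, 11), "exceeds")
})
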