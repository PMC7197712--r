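# Wound morphometry formulas, AFOG decomposition, proliferation index.

regen_fixture <- function() {
  # two fish; maxima deliberately on different sections for fish f2
  section_measurements(
    fish = c("f1", "f1", "f2", "f2", "f2"),
    section = c("s1", "s2", "s1", "s2", "s3"),
    perimeter = c(1000, 800, 900, 1200, 1100),
    open_length = c(250, 300, 500, 200, 100),
    wound_area = c(20000, 15000, 10000, 42000, 30000),
    ventricle_area = c(100000, 90000, 120000, 110000, 140000))
}

test_that("open-wall percentage uses independent per-fish maxima", {
  mm <- regen_fixture()
  # f1: max open 300, max perimeter 1000 -> 30%
  expect_equal(open_wall_percentage(mm, "f1"), 30)
  # f2: max open 500 (s1), max perimeter 1200 (s2) -> 41.666%
  expect_equal(open_wall_percentage(mm, "f2"), 100 * 500 / 1200)
  # matched-section alternative: the largest-perimeter section of f2 is s2
  expect_equal(open_wall_percentage(mm, "f2", matched_section = TRUE),
               100 * 200 / 1200)
  # fully closed wall
  closed <- section_measurements("f", "s", 100, 0, 0, 10)
  expect_equal(open_wall_percentage(closed), 0)
  # a quarter-open single section
  quarter <- section_measurements("f", "s", 400, 100, 0, 10)
  expect_equal(open_wall_percentage(quarter), 25)
  none <- section_measurements("f", "s", 0, 0, 0, 10)
  expect_error(open_wall_percentage(none), "zero ventricle perimeter")
})

test_that("wound-area percentage uses independent per-fish maxima", {
  mm <- regen_fixture()
  # f1: 20000 / 100000
  expect_equal(wound_area_percentage(mm, "f1"), 20)
  # f2: max wound 42000 (s2), max ventricle 140000 (s3)
  expect_equal(wound_area_percentage(mm, "f2"), 30)
  expect_equal(wound_area_percentage(
    section_measurements("f", "s", 10, 0, 0, 50000)), 0)
  expect_equal(wound_area_percentage(
    section_measurements("f", "s", 10, 0, 5e4, 5e4)), 100)
})

test_that("measurement invariants are enforced at construction", {
  expect_error(section_measurements("f", "s", 100, 200, 0, 10),
               "open length exceeds perimeter")
  expect_error(section_measurements("f", "s", 100, 0, 20, 10),
               "wound area exceeds ventricle")
  expect_error(section_measurements("f", "s", -1, 0, 0, 10), ">= 0")
})

test_that("AFOG composition recovers planted fractions", {
  # pure saturated blue wound
  blue <- simulate_afog_image(c(fibrin = 0, collagen = 1, other = 0),
                              noise_sd = 0, seed = 2)
  comp_b <- afog_composition(blue$image, blue$mask)
  expect_equal(unname(comp_b), c(0, 100, 0))
  # noise-free planted mix: exact up to pixel rounding
  fr <- c(fibrin = 0.5, collagen = 0.3, other = 0.2)
  img <- simulate_afog_image(fr, noise_sd = 0, seed = 9)
  comp <- afog_composition(img$image, img$mask)
  area <- sum(img$mask)
  expect_lt(max(abs(comp[c("red", "blue")] - 100 * fr[1:2])),
            100 * 1 / area + 1e-9)
  # components always sum to exactly 100
  noisy <- simulate_afog_image(fr, noise_sd = 0.2, seed = 10)
  comp_n <- afog_composition(noisy$image, noisy$mask)
  expect_equal(sum(comp_n), 100, tolerance = 1e-12)
  # pixels outside the mask are irrelevant
  scrambled <- img$image
  scrambled[!array(img$mask, dim(img$image))] <-
    runif(sum(!img$mask) * 3)
  expect_equal(afog_composition(scrambled, img$mask), comp)
  expect_error(afog_composition(img$image, img$mask & FALSE),
               "empty mask")
})

test_that("overlapping channel excesses resolve to the larger one", {
  img <- array(0, c(1, 2, 3))
  img[1, 1, ] <- c(0.9, 0, 0.7)   # red excess 0.3 > blue excess 0.1
  img[1, 2, ] <- c(0.65, 0, 0.95) # blue excess wins
  mask <- matrix(TRUE, 1, 2)
  comp <- afog_composition(img, mask)
  expect_equal(unname(comp), c(50, 50, 0))
})

test_that("proliferation index recovers planted fractions", {
  all_pos <- simulate_nuclei_table(3, 40, pcna_fraction = 1, seed = 3)
  expect_equal(proliferation_index(all_pos$nuclei), 100)
  none <- simulate_nuclei_table(3, 40, pcna_fraction = 0, seed = 3)
  expect_equal(proliferation_index(none$nuclei), 0)
  big <- simulate_nuclei_table(6, 500, pcna_fraction = 0.3, seed = 17)
  idx <- proliferation_index(big$nuclei, zone = "border")
  n <- sum(big$nuclei$mef2 & big$nuclei$zone == "border")
  ci99 <- 100 * qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(idx - 30), ci99)
  # fewer than three sections warns but still computes
  two <- simulate_nuclei_table(2, 40, pcna_fraction = 0.5, seed = 4)
  expect_warning(proliferation_index(two$nuclei), "at least 3")
  # no Mef2+ nuclei in zone is an error
  nuc <- data.frame(fish = "f", section = "s", zone = "border",
                    mef2 = FALSE, pcna = FALSE)
  expect_error(suppressWarnings(proliferation_index(nuc)),
               "zero Mef2")
})

test_that("region counts tabulate double-positive cells per sample", {
  cells <- data.frame(
    sample = rep(c("wt", "mut"), each = 4),
    region = rep(c("wound", "wound", "ventricle", "ventricle"), 2),
    double = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tab <- count_region_cells(cells)
  expect_equal(tab["wound", "wt"], 2L)
  expect_equal(tab["ventricle", "wt"], 1L)
  expect_equal(sum(tab[, "mut"]), 0L)
  # all in wound leaves the ventricle row empty
  w <- data.frame(sample = "wt", region = "wound", double = TRUE)
  expect_equal(count_region_cells(w)["ventricle", "wt"], 0L)
  bad <- data.frame(sample = "wt", region = "atrium", double = TRUE)
  expect_error(count_region_cells(bad), "unknown region")
})
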