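test_that("planted fractions follow the additive logit model", {
  d <- ecm_only_design()
  m0 <- effect_model(baseline_logit = -2,
                     component_effects = c(COL1 = 0, COL4 = 0, LAM1 = 0,
                                           LAM5 = 0))
  pis <- plant_fractions(d, m0)
  expect_equal(unname(pis[["COL4"]]), 1 / (1 + exp(2)), tolerance = 1e-12)

  m5 <- effect_model(baseline_logit = 0,
                     component_effects = c(COL1 = 0, COL4 = 0, LAM1 = 0,
                                           LAM5 = 0))
  expect_equal(unname(plant_fractions(d, m5)[["COL1"]]), 0.5)

  m <- effect_model(baseline_logit = -2,
                    component_effects = c(COL1 = 1.6, COL4 = 0, LAM1 = 0,
                                          LAM5 = 0))
  pis <- plant_fractions(d, m)
  logit <- function(p) log(p / (1 - p))
  expect_equal(logit(pis[["COL1"]]) - logit(pis[["COL4"]]), 1.6,
               tolerance = 1e-12)
  expect_true(all(pis > 0 & pis < 1))

  bad <- effect_model(component_effects = c(NOTHERE = 1))
  expect_error(plant_fractions(d, bad), "unknown component")
})

test_that("degenerate spot renders are exact", {
  # effectively zero density: background + noise only
  m <- effect_model(component_effects = c(X = 0), density_mean = 1e-9,
                    noise_sd = 0, background_level = 100)
  sp <- render_spot(0.5, m, seed = 5, side = 32)
  expect_equal(nrow(sp$cells), 0)
  expect_true(all(sp$channels$dna == 100))
  expect_true(all(sp$channels$axl == 100))

  # pi = 1: every planted cell is double positive
  m2 <- effect_model(component_effects = c(X = 0), density_mean = 15,
                     noise_sd = 0)
  sp2 <- render_spot(1, m2, seed = 5, side = 64)
  expect_gt(nrow(sp2$cells), 0)
  expect_true(all(sp2$cells$state == "double_positive"))
})

test_that("same seed reproduces spot images byte for byte", {
  m <- effect_model(component_effects = c(X = 0), density_mean = 20)
  a <- render_spot(0.3, m, seed = 77, side = 64)
  b <- render_spot(0.3, m, seed = 77, side = 64)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_spot_image(a$channels$dna, f1)
  write_spot_image(b$channels$dna, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(read_spot_image(f1), a$channels$dna)
  c <- render_spot(0.3, m, seed = 78, side = 64)
  expect_false(identical(a$channels$dna, c$channels$dna))
})

test_that("noise-free marker means over the true footprint equal the drawn means", {
  m <- effect_model(component_effects = c(X = 0), density_mean = 10,
                    noise_sd = 0, background_level = 100)
  sp <- render_spot(0.5, m, seed = 21, side = 64)
  for (i in seq_len(nrow(sp$cells))) {
    r0 <- sp$cells$row[i]; c0 <- sp$cells$col[i]; r <- sp$cells$radius_px[i]
    rr <- row(sp$channels$axl) - 1; cc <- col(sp$channels$axl) - 1
    foot <- sqrt((rr - r0)^2 + (cc - c0)^2) <= r
    measured <- mean(sp$channels$axl[foot]) - 100
    expect_equal(measured, sp$cells$true_axl[i], tolerance = 0.01)
  }
})

test_that("render_array writes one image set per assigned spot, reproducibly", {
  d <- two_ecm_design()
  lay <- build_layout(d, replicates = 3, rows = 5, cols = 4, seed = 8,
                      spot_diameter_px = 48)
  m <- effect_model(component_effects = c(COL1 = 1, COL4 = 0, OPN = 0.5,
                                          IL8 = 0),
                    density_mean = 10)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  r1 <- render_array(d, lay, m, seed = 4, out_dir = dir1)
  r2 <- render_array(d, lay, m, seed = 4, out_dir = dir2)
  expect_equal(nrow(r1$manifest), 18 * 3)   # 3 channels x 18 spots
  expect_identical(r1$manifest$md5, r2$manifest$md5)
  expect_identical(r1$ground_truth, r2$ground_truth)
})

test_that("empirical double-positive fractions converge to the planted pi", {
  d <- two_ecm_design()
  m <- effect_model(baseline_logit = log(0.3 / 0.7),
                    component_effects = c(COL1 = 0, COL4 = 0, OPN = 0,
                                          IL8 = 0),
                    density_mean = 25)
  lay <- build_layout(d, replicates = 15, rows = 10, cols = 9, seed = 3)
  gt <- render_array(d, lay, m, seed = 12)$ground_truth
  # all conditions share pi = 0.3 by construction
  n <- nrow(gt)
  expect_gt(n, 2000)
  phat <- mean(gt$state == "double_positive")
  expect_lt(abs(phat - 0.3), binomial_3se(0.3, n))

  cells <- simulate_cells(d, lay, m, seed = 13)
  # simulated marker intensities: recompute state from the generating model is
  # not possible, so check the count-level generator instead
  counts <- simulate_spot_counts(d, lay, m, seed = 14)
  phat2 <- sum(counts$n_double_positive) / sum(counts$n_cells)
  expect_lt(abs(phat2 - 0.3), binomial_3se(0.3, sum(counts$n_cells)))
  # table-level generators are seed-deterministic too
  expect_identical(cells, simulate_cells(d, lay, m, seed = 13))
  expect_identical(counts, simulate_spot_counts(d, lay, m, seed = 14))
})

test_that("effect models round-trip through YAML", {
  m <- effect_model(component_effects = c(COL1 = 1.25, COL4 = 0),
                    density_mean = 33, noise_sd = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_effect_model(m, path)
  m2 <- read_effect_model(path)
  expect_equal(m2$component_effects, m$component_effects)
  expect_equal(m2$density_mean, m$density_mean)
  expect_equal(m2$intensity_params, m$intensity_params)
})

test_that("invalid effect models are rejected", {
  expect_error(effect_model(density_mean = 0), "density_mean")
  ip <- default_intensity_params()
  ip$axl$pos[["meanlog"]] <- ip$axl$neg[["meanlog"]] - 1
  expect_error(effect_model(intensity_params = ip), "meanlog")
})
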