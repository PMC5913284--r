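ref_cells <- function(axl, ckit = axl, condition = "COL4") {
  data.frame(cell_id = paste0("c", seq_along(axl)), spot_index = 0L,
             condition_id = condition, mean_axl = axl, mean_ckit = ckit,
             eccentricity = 0.1, solidity = 0.95,
             stringsAsFactors = FALSE)
}

test_that("gate thresholds are mean + k*SD of reference cells", {
  d <- ecm_only_design()
  g <- fit_gate(ref_cells(c(1, 2, 3)), d, k = 1, min_ref_cells = 3)
  expect_equal(gate_threshold <- g$threshold[g$marker == "axl"], 3.0)
  expect_equal(g$mu_ref[1], 2)
  expect_equal(g$sigma_ref[1], 1)      # sample SD, n-1 denominator

  g0 <- fit_gate(ref_cells(rep(7, 60)), d, k = 1)
  expect_equal(g0$threshold, c(7, 7))

  # 10,000 lognormal draws against the closed-form moments
  withr::with_seed(42, {
    v <- rlnorm(10000, log(200), 0.35)
    g <- fit_gate(ref_cells(v), d, k = 1)
    expected <- lognormal_mean(log(200), 0.35) + lognormal_sd(log(200), 0.35)
    expect_equal(g$threshold[1], expected, tolerance = 0.01)
  })
})

test_that("too few reference cells is an error naming the count", {
  d <- ecm_only_design()
  expect_error(fit_gate(ref_cells(1:10), d, min_ref_cells = 50),
               "only 10 reference cells")
  # cells on non-reference conditions do not count
  expect_error(fit_gate(ref_cells(1:100, condition = "COL1"), d),
               "reference cells")
})

test_that("reference selection distinguishes COL4-alone from COL4-containing", {
  d <- default_design()
  alone <- reference_conditions(d, "col4_alone")
  expect_identical(alone, "COL4")
  any4 <- reference_conditions(d, "col4_any")
  expect_true(length(any4) > 1 && "COL4|OPN" %in% any4)
  expect_error(reference_conditions(d, "NOPE"), "unknown reference")
})

test_that("positivity calls are strict and conservative at ties", {
  g <- manual_gate(100, 200)
  cells <- ref_cells(c(99, 100, 101, 250), c(250, 250, 250, 100))
  called <- call_cells(cells, g)
  expect_equal(called$axl_pos, c(FALSE, FALSE, TRUE, TRUE))  # tie -> negative
  expect_equal(called$ckit_pos, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(called$double_pos, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(mean(called$double_pos), 0.25)

  none <- call_cells(ref_cells(c(1, 2), c(3, 4)), g)
  expect_equal(sum(none$double_pos), 0)
})

test_that("planted positive fractions are recovered through the full gate", {
  # suppressive reference (COL4, pi ~ 0.03) gates a COL1 population planted
  # at pi = 0.3; well-separated markers keep misclassification negligible
  d <- two_ecm_design()
  m <- effect_model(baseline_logit = -3.5,
                    component_effects = c(COL1 = 3.5 + qlogis(0.3), COL4 = 0,
                                          OPN = 0, IL8 = 0),
                    density_mean = 250,
                    intensity_params = well_separated_params())
  lay <- build_layout(d, replicates = 14, rows = 12, cols = 7, seed = 2)
  cells <- simulate_cells(d, lay, m, seed = 31)
  g <- fit_gate(cells, d, reference = "col4_alone", k = 1)
  called <- call_cells(cells, g)
  col1 <- called[grepl("^COL1", called$condition_id), ]
  expect_gt(nrow(col1), 10000)
  phat <- mean(col1$double_pos)
  expect_lt(abs(phat - 0.3), binomial_3se(0.3, nrow(col1)))
})

test_that("raising k never increases positive fractions", {
  d <- two_ecm_design()
  m <- effect_model(component_effects = c(COL1 = 1, COL4 = 0, OPN = 0,
                                          IL8 = 0), density_mean = 60)
  lay <- build_layout(d, replicates = 3, rows = 5, cols = 4, seed = 5)
  cells <- simulate_cells(d, lay, m, seed = 8)
  fractions <- vapply(c(0, 0.5, 1, 2, 3), function(k) {
    g <- fit_gate(cells, d, k = k)
    mean(call_cells(cells, g)$double_pos)
  }, numeric(1))
  expect_true(all(diff(fractions) <= 0))
})

test_that("double-positive fraction is bounded by the marginals and factorizes under independence", {
  withr::with_seed(99, {
    n <- 20000
    axl_state <- rbinom(n, 1, 0.3)
    ckit_state <- rbinom(n, 1, 0.4)
    cells <- ref_cells(ifelse(axl_state == 1, 5000, 100),
                       ifelse(ckit_state == 1, 5000, 100))
    called <- call_cells(cells, manual_gate(1000, 1000))
    fa <- mean(called$axl_pos); fc <- mean(called$ckit_pos)
    fdp <- mean(called$double_pos)
    expect_lte(fdp, min(fa, fc))
    expect_lt(abs(fdp - 0.3 * 0.4), binomial_3se(0.12, n))
  })
})

test_that("a mean+k*SD gate on Gaussian reference intensities calls ~Phi(-k) positive", {
  d <- ecm_only_design()
  withr::with_seed(7, {
    n <- 20000
    cells <- ref_cells(rnorm(n, 500, 60), rnorm(n, 400, 40))
    g <- fit_gate(cells, d, k = 1)
    called <- call_cells(cells, g)
    expected <- pnorm(-1)
    expect_lt(abs(mean(called$axl_pos) - expected),
              binomial_3se(expected, n) + 0.005)
    expect_lt(abs(mean(called$ckit_pos) - expected),
              binomial_3se(expected, n) + 0.005)
  })
})

test_that("spot and condition summaries aggregate as documented", {
  # one spot, 10 cells, 2 double-positive
  cells <- ref_cells(c(rep(100, 8), 5000, 5000), c(rep(100, 8), 5000, 5000))
  called <- call_cells(cells, manual_gate(1000, 1000))
  sp <- summarize_spots(called)
  expect_equal(sp$n_cells, 10)
  expect_equal(sp$fraction_dp, 0.2)

  # worked 5-cell spot: subset mean over double positives only
  cells5 <- ref_cells(c(1500, 2000, 900, 100, 3000),
                      c(1200, 1800, 2000, 100, 2500))
  cells5$spot_index <- 1L
  called5 <- call_cells(cells5, manual_gate(1000, 1000))
  sp5 <- summarize_spots(called5)
  expect_equal(sp5$n_double_positive, 3)
  expect_equal(sp5$mean_axl_dp, mean(c(1500, 2000, 3000)))
  expect_equal(sp5$mean_ckit_dp, mean(c(1200, 1800, 2500)))
  expect_equal(sp5$mean_axl_all, mean(cells5$mean_axl))

  # two spots with fractions 0.1 and 0.3 -> condition mean 0.2
  mk <- function(spot, frac, n = 10) {
    x <- ref_cells(c(rep(5000, frac * n), rep(100, n - frac * n)),
                   c(rep(5000, frac * n), rep(100, n - frac * n)))
    x$spot_index <- spot
    x
  }
  called2 <- call_cells(rbind(mk(0L, 0.1), mk(1L, 0.3)), manual_gate(1000, 1000))
  conds <- summarize_conditions(summarize_spots(called2))
  expect_equal(conds$fraction_dp, 0.2)
  expect_equal(conds$usable_spots, 2)
})

test_that("empty spots are flagged, not silently dropped", {
  d <- two_ecm_design()
  lay <- build_layout(d, replicates = 1, rows = 3, cols = 2, seed = 1)
  cells <- ref_cells(c(100, 5000), c(100, 5000))
  cells$spot_index <- lay$assignments$spot_index[1]
  cells$condition_id <- lay$assignments$condition_id[1]
  called <- call_cells(cells, manual_gate(1000, 1000))
  sp <- summarize_spots(called, lay)
  expect_equal(nrow(sp), 6)
  expect_true(is.na(sp$fraction_dp[sp$n_cells == 0][1]))
  conds <- summarize_conditions(sp)
  expect_equal(attr(conds, "excluded_spots"), 5)
  flagged <- conds[conds$usable_spots == 0, ]
  expect_equal(nrow(flagged), 5)
  expect_true(all(is.na(flagged$fraction_dp)))
})

test_that("phenotype matrices exclude incomplete conditions with a message", {
  conds <- data.frame(condition_id = c("A", "B"), n_spots = 1, usable_spots = 1,
                      cells_per_spot = c(10, 12), fraction_dp = c(0.2, 0.3),
                      mean_axl_dp = c(1500, NA), mean_ckit_dp = c(1500, 1400),
                      mean_axl_all = c(500, 600), mean_ckit_all = c(450, 500),
                      mean_eccentricity = c(0.2, 0.25),
                      mean_solidity = c(0.95, 0.93))
  expect_message(m <- phenotype_matrix(conds), "excluded")
  expect_equal(rownames(m), "A")
  expect_equal(attr(m, "excluded_conditions"), "B")
})
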