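count_spots <- function(design, pis, spots_per_cond = 10, n_per_spot = 200,
                        seed = 1) {
  lay <- build_layout(design, spots_per_cond,
                      rows = nrow(design$conditions) * spots_per_cond, cols = 1,
                      seed = seed)
  m <- effect_model(component_effects = setNames(rep(0, nrow(design$components)),
                                                 design$components$name),
                    density_mean = n_per_spot)
  sp <- simulate_spot_counts(design, lay, m, seed = seed)
  # overwrite the planted fractions with the requested per-condition pis
  withr::with_seed(seed + 1, {
    sp$n_double_positive <- rbinom(nrow(sp), sp$n_cells, pis[sp$condition_id])
    sp$fraction_dp <- ifelse(sp$n_cells > 0,
                             sp$n_double_positive / sp$n_cells, NA_real_)
  })
  sp
}

test_that("the logit MLE matches a brute-force grid search on small data", {
  d <- ecm_only_design()
  d$conditions <- d$conditions[d$conditions$condition_id %in%
                                 c("COL1", "COL4"), ]
  sp <- count_spots(d, c(COL1 = 0.45, COL4 = 0.15), spots_per_cond = 4,
                    n_per_spot = 30, seed = 3)
  fit <- fit_component_glm(sp, d)
  b <- fit$coefficients$estimate
  # two-stage grid search over (intercept, COL1 effect)
  x <- as.integer(sp$condition_id == "COL1")
  nll <- function(b0, b1) {
    p <- 1 / (1 + exp(-(b0 + b1 * x)))
    -sum(dbinom(sp$n_double_positive, sp$n_cells, p, log = TRUE))
  }
  grid_opt <- function(b0s, b1s) {
    vals <- outer(b0s, b1s, Vectorize(nll))
    i <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    c(b0s[i[1]], b1s[i[2]])
  }
  coarse <- grid_opt(seq(-4, 4, by = 0.05), seq(-4, 4, by = 0.05))
  fine <- grid_opt(seq(coarse[1] - 0.06, coarse[1] + 0.06, by = 0.001),
                   seq(coarse[2] - 0.06, coarse[2] + 0.06, by = 0.001))
  expect_equal(b[1], fine[1], tolerance = 2e-3)
  expect_equal(b[2], fine[2], tolerance = 2e-3)
})

test_that("spot-level and condition-aggregated GLMs agree (binomial sufficiency)", {
  d <- ecm_only_design()
  pis <- c(COL1 = 0.4, COL4 = 0.1, LAM1 = 0.35, `LAM1+LAM5` = 0.3)
  sp <- count_spots(d, pis, spots_per_cond = 8, n_per_spot = 100, seed = 5)
  agg <- do.call(rbind, lapply(split(sp, sp$condition_id), function(g) {
    data.frame(spot_index = g$spot_index[1], condition_id = g$condition_id[1],
               n_cells = sum(g$n_cells),
               n_double_positive = sum(g$n_double_positive),
               fraction_dp = sum(g$n_double_positive) / sum(g$n_cells))
  }))
  # aggregation leaves a single "spot" per condition; relax the replicate
  # precondition by duplicating rows with zero extra information is not valid,
  # so fit the aggregate through the internal frame directly
  f1 <- fit_component_glm(sp, d)
  df2 <- memaphen:::spot_model_frame(agg, d)
  f2 <- stats::glm(cbind(n_double_positive, n_cells - n_double_positive) ~ ecm,
                   family = binomial(), data = df2)
  expect_equal(unname(coef(f1$glm)), unname(coef(f2)), tolerance = 1e-6)
})

test_that("degenerate designs are refused with informative errors", {
  d <- ecm_only_design()
  d1 <- d; d1$conditions <- d1$conditions[1, ]
  sp <- count_spots(d1, c(COL1 = 0.3), spots_per_cond = 5, seed = 2)
  expect_error(fit_component_glm(sp, d1), "2 ECM levels")
  fit <- fit_component_glm(count_spots(d, c(COL1 = 0.4, COL4 = 0.1,
                                            LAM1 = 0.3, `LAM1+LAM5` = 0.2),
                                       seed = 4), d)
  expect_error(posthoc_contrasts(structure(list(data = fit$data[0, ],
                                                method = "ml"),
                                           class = "mema_glm")))
})

test_that("complete separation triggers the bias-reduced fallback", {
  d <- ecm_only_design()
  d$conditions <- d$conditions[d$conditions$condition_id %in%
                                 c("COL1", "COL4"), ]
  sp <- count_spots(d, c(COL1 = 0.5, COL4 = 0.5), spots_per_cond = 3,
                    n_per_spot = 4, seed = 6)
  sp$n_double_positive[sp$condition_id == "COL4"] <- 0L
  sp$fraction_dp <- sp$n_double_positive / sp$n_cells
  expect_error(fit_component_glm(sp, d, method = "ml"), "firth")
  fb <- fit_component_glm(sp, d, method = "firth")
  expect_true(all(is.finite(fb$coefficients$estimate)))
  expect_true(all(abs(fb$coefficients$estimate) < 10))
})

test_that("post-hoc contrasts mirror the published table structure", {
  d <- ecm_only_design()
  pis <- c(COL1 = 0.35, COL4 = 0.1, LAM1 = 0.33, `LAM1+LAM5` = 0.28)
  sp <- count_spots(d, pis, seed = 7)
  fit <- fit_component_glm(sp, d)
  ct <- posthoc_contrasts(fit)
  expect_equal(nrow(ct), 6)      # 4 levels -> 6 pairwise rows
  expect_setequal(ct$pair, c("COL1-COL4", "COL1-LAM1", "COL1-LAM1+LAM5",
                             "COL4-LAM1", "COL4-LAM1+LAM5",
                             "LAM1-LAM1+LAM5"))
  expect_true(all(ct$adjusted_p >= 0 & ct$adjusted_p <= 1))

  # antisymmetry: reversing a pair's contrast vector flips the estimate
  K <- memaphen:::build_pairwise_K(c("COL4", "LAM1"), names(coef(fit$glm)))
  Krev <- memaphen:::build_pairwise_K(c("LAM1", "COL4"), names(coef(fit$glm)))
  est <- as.numeric(K %*% coef(fit$glm))
  est_rev <- as.numeric(Krev %*% coef(fit$glm))
  expect_equal(est, -est_rev)
  i <- match("COL4-LAM1", ct$pair)
  expect_equal(ct$estimate[i], est)

  # adjusted p decreases with |z| when SEs are comparable
  ord <- order(abs(ct$z))
  expect_true(all(diff(ct$adjusted_p[ord]) <= 1e-8))
})

test_that("null coefficients stay within 2 SE most of the time", {
  d <- ecm_only_design()
  d$conditions <- d$conditions[d$conditions$condition_id %in%
                                 c("COL1", "COL4"), ]
  inside <- vapply(1:100, function(s) {
    sp <- count_spots(d, c(COL1 = 0.15, COL4 = 0.15), spots_per_cond = 10,
                      n_per_spot = 200, seed = 1000 + s)
    fit <- fit_component_glm(sp, d)
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    all(abs(cf$estimate) <= 2 * cf$se)
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("factor effect ranking recovers planted factors and drops singletons", {
  d <- two_ecm_design()
  m <- effect_model(component_effects = c(COL1 = 1.2, COL4 = 0, OPN = 0.9,
                                          IL8 = 0),
                    density_mean = 200)
  lay <- build_layout(d, replicates = 10, rows = 10, cols = 6, seed = 3)
  sp <- simulate_spot_counts(d, lay, m, seed = 44)
  fit <- fit_component_glm(sp, d)
  rk <- rank_factor_effects(fit)
  expect_equal(rk$factor[1], "OPN")
  expect_true(rk$significant[1])
  expect_false(rk$significant[rk$factor == "IL8"])

  # a factor observed on a single spot is excluded with a warning
  sp1 <- sp[!(sp$condition_id %in% c("COL1|IL8", "COL4|IL8")) |
              sp$spot_index == sp$spot_index[sp$condition_id == "COL1|IL8"][1], ]
  expect_warning(fit1 <- fit_component_glm(sp1, d), "IL8")
  expect_false("IL8" %in% fit1$factors)
})

test_that("line comparison measures dispersion and detects interaction shifts", {
  d <- ecm_only_design()
  pis <- c(COL1 = 0.35, COL4 = 0.1, LAM1 = 0.3, `LAM1+LAM5` = 0.25)
  spA <- count_spots(d, pis, seed = 21)
  cmp_same <- compare_lines(spA, spA, d)
  expect_equal(cmp_same$dispersion, 0)
  expect_gt(cmp_same$interaction_p, 0.99)

  # a 2-logit shift on COL1 conditions only
  shift <- function(p) plogis(qlogis(p) + 2)
  pis_b <- pis; pis_b[["COL1"]] <- shift(pis[["COL1"]])
  detected <- vapply(1:5, function(s) {
    spA <- count_spots(d, pis, seed = 100 + s)
    spB <- count_spots(d, pis_b, seed = 200 + s)
    compare_lines(spA, spB, d)$interaction_p < 0.05
  }, logical(1))
  expect_true(all(detected))

  # mismatched condition sets are an error listing the difference
  spC <- spA[spA$condition_id != "COL1", ]
  expect_error(compare_lines(spA, spC, d), "COL1")
})
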