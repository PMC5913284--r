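# Shared in-code fixtures: small designs, a well-separated intensity model,
# closed-form lognormal moments, and a centroid-matching F1 score.

ecm_only_design <- function() {
  comp <- mema_components(c("COL1", "COL4", "LAM1", "LAM5"),
                          rep("ECM", 4), c(100, 100, 100, 20))
  cond <- enumerate_conditions(list("COL1", "COL4", "LAM1", c("LAM1", "LAM5")),
                               scheme = "ecm_alone", components = comp)
  mema_design(comp, cond)
}

two_ecm_design <- function() {
  comp <- mema_components(c("COL1", "COL4", "OPN", "IL8"),
                          c("ECM", "ECM", "soluble", "soluble"),
                          c(100, 100, 1, 1))
  cond <- enumerate_conditions(list("COL1", "COL4"), c("OPN", "IL8"),
                               scheme = "both", components = comp)
  mema_design(comp, cond)
}

ecm_effects <- function(col1 = 1.6, col4 = 0, lam1 = 1.5, lam5 = -0.25) {
  c(COL1 = col1, COL4 = col4, LAM1 = lam1, LAM5 = lam5)
}

# marker distributions far enough apart that gate misclassification is
# negligible (< 1e-4 in either direction)
well_separated_params <- function() {
  list(dna = list(neg = c(meanlog = log(3000), sdlog = 0.2),
                  pos = c(meanlog = log(3000), sdlog = 0.2)),
       axl = list(neg = c(meanlog = log(200), sdlog = 0.25),
                  pos = c(meanlog = log(5000), sdlog = 0.25)),
       ckit = list(neg = c(meanlog = log(200), sdlog = 0.25),
                   pos = c(meanlog = log(5000), sdlog = 0.25)))
}

lognormal_mean <- function(meanlog, sdlog) exp(meanlog + sdlog^2 / 2)
lognormal_sd <- function(meanlog, sdlog) {
  sqrt((exp(sdlog^2) - 1) * exp(2 * meanlog + sdlog^2))
}

# greedy one-to-one centroid matching within `radius`; returns precision,
# recall, F1
match_centroids <- function(det, planted, radius) {
  if (nrow(det) == 0 || nrow(planted) == 0) {
    return(list(precision = 0, recall = 0, f1 = 0))
  }
  d <- sqrt(outer(det$row, planted$row, "-")^2 +
              outer(det$col, planted$col, "-")^2)
  tp <- 0L
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > radius) break
    tp <- tp + 1L
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(!is.finite(d))) break
  }
  precision <- tp / nrow(det)
  recall <- tp / nrow(planted)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# construct a gate object directly (for tests that fix thresholds by hand)
manual_gate <- function(axl, ckit, n_ref = 100L) {
  structure(data.frame(marker = c("axl", "ckit"), mu_ref = c(axl, ckit),
                       sigma_ref = 0, k = 0, threshold = c(axl, ckit),
                       n_ref = n_ref, stringsAsFactors = FALSE),
            class = c("mema_gate", "data.frame"))
}

binomial_3se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
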