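#' Relative qPCR fold change, 2^(-ddCt)
#'
#' For every (sample, gene): `dCt = Ct(gene) - mean(Ct over control genes in
#' the same sample)`, `ddCt = dCt(sample) - dCt(control sample)`, and
#' `fold = 2^(-ddCt)`. The control sample's folds are 1 for every gene by
#' construction; adding a constant to every Ct leaves folds unchanged.
#'
#' @param ct `data.frame` with columns `sample`, `gene`, `ct` (cycles, finite
#'   and > 0; every (sample, gene) pair unique).
#' @param control_genes character vector of reference genes, each present in
#'   every sample.
#' @param control_sample id of the calibrator sample.
#' @return `data.frame` with `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`.
#' @export
fold_change <- function(ct, control_genes, control_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct) | ct$ct <= 0)) stop("Ct values must be finite and > 0")
  key <- paste(ct$sample, ct$gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, gene) pair(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  if (!control_sample %in% ct$sample) {
    stop("control sample '", control_sample, "' not present")
  }
  samples <- unique(ct$sample)
  for (s in samples) {
    have <- ct$gene[ct$sample == s]
    miss <- setdiff(control_genes, have)
    if (length(miss)) {
      stop("sample '", s, "' lacks control gene(s): ",
           paste(miss, collapse = ", "))
    }
  }
  ctrl_mean <- vapply(samples, function(s) {
    mean(ct$ct[ct$sample == s & ct$gene %in% control_genes])
  }, numeric(1))
  names(ctrl_mean) <- samples
  out <- ct
  out$delta_ct <- out$ct - ctrl_mean[out$sample]
  base <- out[out$sample == control_sample, c("gene", "delta_ct")]
  i <- match(out$gene, base$gene)
  if (anyNA(i)) {
    stop("gene(s) absent from the control sample: ",
         paste(unique(out$gene[is.na(i)]), collapse = ", "))
  }
  out$delta_delta_ct <- out$delta_ct - base$delta_ct[i]
  out$fold_change <- 2^(-out$delta_delta_ct)
  out$ct <- NULL
  out
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of `y = a + (b - a) / (1 + (x/c)^d)` with the inflection
#' dose `c` reported as the IC50. Internally the curve is parameterized in
#' log-dose (`(x/c)^d = exp(d (log x - log c))`), with starting values
#' `a = min(y)`, `b = max(y)`, `c = geometric mean dose`, `d = 1` and a small
#' multi-start ladder on failure. As `x -> 0` the curve tends to `b`, as
#' `x -> Inf` to `a` (for `d > 0`), and `y(c) = (a + b)/2` exactly.
#'
#' @param dose positive dose vector (>= 5 points).
#' @param response response vector, same length.
#' @return An object of class `mema_4pl` with elements `a`, `b`, `c`, `d`,
#'   `rss`, `converged`, `degenerate`.
#' @export
fit_4pl <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  if (length(dose) < 5) stop("need at least 5 dose points")
  if (any(!is.finite(dose) | dose <= 0)) stop("doses must be finite and > 0")
  l <- log(dose)
  degenerate <- diff(range(response)) < 1e-8 * max(abs(response), 1)
  if (degenerate) {
    fit <- list(a = mean(response), b = mean(response),
                c = exp(mean(l)), d = 0, rss = sum((response - mean(response))^2),
                converged = TRUE, degenerate = TRUE)
    return(structure(fit, class = "mema_4pl"))
  }
  df <- data.frame(l = l, y = response)
  starts <- list(c(d = 1), c(d = -1), c(d = 2))
  best <- NULL
  best_err <- NULL
  for (s in starts) {
    st <- list(a = min(response), b = max(response), lc = mean(l), d = s[["d"]])
    res <- try(minpack.lm::nlsLM(
      y ~ a + (b - a) / (1 + exp(d * (l - lc))), data = df, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
      silent = TRUE)
    if (!inherits(res, "try-error")) {
      rss <- sum(stats::residuals(res)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- stats::coef(res)
        best <- list(a = cf[["a"]], b = cf[["b"]], c = exp(cf[["lc"]]),
                     d = cf[["d"]], rss = rss, converged = TRUE,
                     degenerate = FALSE)
      }
    } else {
      best_err <- res
    }
  }
  if (is.null(best)) {
    stop("4PL fit did not converge from any start; last optimizer message: ",
         attr(best_err, "condition")$message)
  }
  if (!all(is.finite(unlist(best[c("a", "b", "c", "d")]))) || best$c <= 0) {
    stop("4PL fit produced non-finite or non-positive parameters")
  }
  structure(best, class = "mema_4pl")
}

#' @export
print.mema_4pl <- function(x, ...) {
  cat(sprintf("4PL fit: a=%.4g b=%.4g c(IC50)=%.4g d=%.4g rss=%.3g%s\n",
              x$a, x$b, x$c, x$d, x$rss,
              if (x$degenerate) " [degenerate: flat response]" else ""))
  invisible(x)
}

#' Predicted response of a 4PL fit
#'
#' @param object a `mema_4pl`.
#' @param dose doses to predict at.
#' @param ... unused.
#' @export
predict.mema_4pl <- function(object, dose, ...) {
  object$a + (object$b - object$a) / (1 + (dose / object$c)^object$d)
}

#' IC50 (inflection dose) of a 4PL fit
#'
#' @param fit a `mema_4pl`.
#' @return The dose `c` at which the response is halfway between asymptotes.
#' @export
ic50 <- function(fit) fit$c

#' The 5-point paclitaxel dose ladder
#'
#' Five log-spaced concentrations spanning 0.001-1 ug/ml, the design used for
#' the drug-tolerance IC50 measurements this package models.
#'
#' @return Numeric vector of 5 doses (ug/ml).
#' @export
paclitaxel_doses <- function() 10^seq(-3, 0, length.out = 5)

#' EdU proliferation fractions relative to a control condition
#'
#' Per replicate, `pct = 100 * positive / total`; per condition, the mean
#' percentage, its ratio to the control condition's mean, and an unpaired
#' two-sample t-test of the replicate percentages against the control's.
#'
#' @param positive,total integer vectors of EdU-positive and total cell counts
#'   per replicate (totals > 0).
#' @param condition condition label per replicate.
#' @param control control condition label (e.g. `"COL1"`).
#' @return list with `replicates` (per-replicate percentages) and `summary`
#'   (per condition: `n`, `mean_pct`, `sd_pct`, `relative`, `p_value`; the
#'   control row's p is `NA`).
#' @export
edu_tolerance <- function(positive, total, condition, control) {
  stopifnot(length(positive) == length(total),
            length(positive) == length(condition))
  if (any(total <= 0)) stop("total counts must be > 0")
  if (any(positive < 0 | positive > total)) {
    stop("positive counts must lie in [0, total]")
  }
  if (!control %in% condition) stop("control condition '", control, "' absent")
  pct <- 100 * positive / total
  reps <- data.frame(condition = condition, positive = positive, total = total,
                     pct = pct, stringsAsFactors = FALSE)
  ctrl <- pct[condition == control]
  conds <- unique(condition)
  rows <- lapply(conds, function(cn) {
    v <- pct[condition == cn]
    p <- if (cn == control || length(v) < 2 || length(ctrl) < 2) NA_real_ else
      stats::t.test(v, ctrl, var.equal = FALSE)$p.value
    data.frame(condition = cn, n = length(v), mean_pct = mean(v),
               sd_pct = if (length(v) > 1) stats::sd(v) else NA_real_,
               relative = mean(v) / mean(ctrl), p_value = p,
               stringsAsFactors = FALSE)
  })
  list(replicates = reps, summary = do.call(rbind, rows))
}
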