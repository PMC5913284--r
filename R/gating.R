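#' Reference conditions for gating
#'
#' The positivity gate is learned on cells from reference-condition spots:
#' by default the ECM backbone is COL4 printed alone (the suppressive matrix),
#' optionally any COL4-containing condition, or an explicit id set.
#'
#' @param design a `mema_design`.
#' @param reference `"col4_alone"`, `"col4_any"`, or a character vector of
#'   condition ids.
#' @return Character vector of reference condition ids.
#' @export
reference_conditions <- function(design, reference = "col4_alone") {
  cond <- design$conditions
  if (length(reference) > 1 || !reference %in% c("col4_alone", "col4_any")) {
    unknown <- setdiff(reference, cond$condition_id)
    if (length(unknown)) stop("unknown reference condition(s): ",
                              paste(unknown, collapse = ", "))
    return(reference)
  }
  has_col4 <- vapply(cond$ecm_backbone, function(b) "COL4" %in% split_set(b),
                     logical(1))
  if (reference == "col4_alone") {
    cond$condition_id[has_col4 & cond$ecm_backbone == "COL4" &
                        cond$soluble_factors == ""]
  } else {
    cond$condition_id[has_col4]
  }
}

#' Fit per-marker positivity gates from reference cells
#'
#' For each marker, the gate is `mean + k * SD` (sample SD, n-1 denominator)
#' of that marker's mean cell intensity over all reference-condition cells.
#'
#' @param cells cell table with `condition_id` and `mean_<marker>` columns.
#' @param design a `mema_design`.
#' @param reference see [reference_conditions()].
#' @param k SD multiplier (default 1).
#' @param markers marker channel names.
#' @param min_ref_cells smallest acceptable reference population.
#' @return An object of class `mema_gate`: a `data.frame` with one row per
#'   marker (`marker, mu_ref, sigma_ref, k, threshold, n_ref`).
#' @export
fit_gate <- function(cells, design, reference = "col4_alone", k = 1,
                     markers = c("axl", "ckit"), min_ref_cells = 50L) {
  ref_ids <- reference_conditions(design, reference)
  ref <- cells[cells$condition_id %in% ref_ids, , drop = FALSE]
  if (nrow(ref) < min_ref_cells) {
    stop("only ", nrow(ref), " reference cells available (need >= ",
         min_ref_cells, ")")
  }
  rows <- lapply(markers, function(m) {
    v <- ref[[paste0("mean_", m)]]
    mu <- mean(v)
    sg <- if (length(v) > 1) stats::sd(v) else 0
    data.frame(marker = m, mu_ref = mu, sigma_ref = sg, k = k,
               threshold = mu + k * sg, n_ref = length(v),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("mema_gate", "data.frame"))
}

#' @export
print.mema_gate <- function(x, ...) {
  cat("MEMA gate (mean + k*SD on", x$n_ref[1], "reference cells):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

gate_threshold <- function(gate, marker) {
  i <- match(marker, gate$marker)
  if (is.na(i)) stop("gate has no marker '", marker, "'")
  gate$threshold[i]
}

#' Call per-cell positivity against a fitted gate
#'
#' Strictly-above-threshold calls per marker; ties resolve negative.
#' `double_pos` is the conjunction over both markers.
#'
#' @param cells cell table.
#' @param gate a `mema_gate`.
#' @return `cells` with logical columns `axl_pos`, `ckit_pos`, `double_pos`.
#' @export
call_cells <- function(cells, gate) {
  for (m in gate$marker) {
    cells[[paste0(m, "_pos")]] <- cells[[paste0("mean_", m)]] > gate_threshold(gate, m)
  }
  pos_cols <- paste0(gate$marker, "_pos")
  cells$double_pos <- Reduce(`&`, cells[pos_cols])
  cells
}

#' Per-spot phenotype summaries
#'
#' One row per spot: cell counts, the double-positive fraction, mean marker
#' intensity in the double-positive subset and in the ungated population, and
#' mean morphology. Subset means are `NA` when a spot has no double-positive
#' cells; `fraction_dp` is `NA` (flagged) when a spot has no cells at all.
#'
#' @param cells called cell table from [call_cells()].
#' @param layout optional `mema_layout` used to include assigned spots that
#'   yielded no cells.
#' @return `data.frame` of spot summaries.
#' @export
summarize_spots <- function(cells, layout = NULL) {
  base <- if (!is.null(layout)) {
    layout$assignments[, c("spot_index", "condition_id")]
  } else {
    unique(cells[, c("spot_index", "condition_id")])
  }
  base <- base[order(base$spot_index), , drop = FALSE]
  mean_if <- function(v, sel) if (any(sel)) mean(v[sel]) else NA_real_
  rows <- lapply(seq_len(nrow(base)), function(i) {
    cc <- cells[cells$spot_index == base$spot_index[i], , drop = FALSE]
    n <- nrow(cc)
    ndp <- sum(cc$double_pos)
    data.frame(spot_index = base$spot_index[i],
               condition_id = base$condition_id[i],
               n_cells = n, n_double_positive = ndp,
               fraction_dp = if (n > 0) ndp / n else NA_real_,
               mean_axl_dp = mean_if(cc$mean_axl, cc$double_pos),
               mean_ckit_dp = mean_if(cc$mean_ckit, cc$double_pos),
               mean_axl_all = if (n) mean(cc$mean_axl) else NA_real_,
               mean_ckit_all = if (n) mean(cc$mean_ckit) else NA_real_,
               mean_eccentricity = if (n) mean(cc$eccentricity) else NA_real_,
               mean_solidity = if (n) mean(cc$solidity) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-condition phenotype summaries
#'
#' Unweighted means over each condition's usable spots (spots with zero cells
#' are excluded and counted in the `excluded_spots` attribute). Conditions with
#' no usable spots are kept as flagged `NA` rows, never silently dropped.
#'
#' @param spots spot summary table from [summarize_spots()].
#' @return `data.frame` with one row per condition; column `usable_spots`
#'   flags conditions with no data (0).
#' @export
summarize_conditions <- function(spots) {
  usable <- spots[!is.na(spots$fraction_dp) & spots$n_cells > 0, , drop = FALSE]
  excluded <- nrow(spots) - nrow(usable)
  ids <- unique(spots$condition_id)
  num_cols <- c("fraction_dp", "mean_axl_dp", "mean_ckit_dp", "mean_axl_all",
                "mean_ckit_all", "mean_eccentricity", "mean_solidity")
  rows <- lapply(ids, function(id) {
    u <- usable[usable$condition_id == id, , drop = FALSE]
    out <- data.frame(condition_id = id, n_spots = nrow(u),
                      usable_spots = nrow(u),
                      cells_per_spot = if (nrow(u)) mean(u$n_cells) else NA_real_,
                      stringsAsFactors = FALSE)
    for (cl in num_cols) {
      out[[cl]] <- if (nrow(u)) mean(u[[cl]], na.rm = TRUE) else NA_real_
      if (is.nan(out[[cl]])) out[[cl]] <- NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "excluded_spots") <- excluded
  res
}

#' Condition-level phenotype feature matrix
#'
#' Fixed feature order used for clustering and embedding: double-positive
#' fraction, subset and ungated marker intensities, cells per spot,
#' eccentricity, solidity. Conditions with any missing feature (e.g. no
#' double-positive cells anywhere, or no usable spots) are excluded with a
#' message and recorded in the `excluded_conditions` attribute.
#'
#' @param conditions condition summary table from [summarize_conditions()].
#' @return Numeric matrix, rownames = condition ids.
#' @export
phenotype_matrix <- function(conditions) {
  feats <- c("fraction_dp", "mean_axl_dp", "mean_ckit_dp", "mean_axl_all",
             "mean_ckit_all", "cells_per_spot", "mean_eccentricity",
             "mean_solidity")
  m <- as.matrix(conditions[, feats])
  rownames(m) <- conditions$condition_id
  bad <- rowSums(!is.finite(m)) > 0
  if (any(bad)) {
    message(sum(bad), " condition(s) excluded from the phenotype matrix ",
            "(missing features)")
  }
  out <- m[!bad, , drop = FALSE]
  attr(out, "excluded_conditions") <- rownames(m)[bad]
  out
}

#' Write fitted gates as CSV
#'
#' @param gate a `mema_gate`.
#' @param path file path.
#' @export
write_gate <- function(gate, path) {
  utils::write.csv(as.data.frame(gate), path, row.names = FALSE)
  invisible(path)
}
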