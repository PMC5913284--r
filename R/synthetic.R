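#' Condition effect model for synthetic MEMA arrays
#'
#' The generator plants a double-positive (AXL+/cKIT+) subpopulation whose
#' log-odds depend additively on the components of each microenvironment:
#' `logit(pi) = baseline_logit + sum(component_effects[components])`. Cell
#' counts per spot are Poisson; marker intensities are lognormal per state
#' (right-skewed, as fluorescence is); images add a flat background plus
#' Gaussian noise.
#'
#' Default effect sizes mirror the qualitative structure this pipeline is built
#' to recover: COL4 is the suppressive reference matrix (effect 0), COL1 the
#' strongest inducer (+1.6 logits), laminin-rich backbones intermediate, and
#' OPN, IL-8 and COL6A3 the leading positive soluble factors, with weaker
#' contributions from TGFB, lumican, leptin and hyaluronan.
#'
#' @param baseline_logit log-odds that a cell is double-positive in the
#'   reference condition.
#' @param component_effects named numeric vector of additive log-odds
#'   contributions per component name; unnamed components contribute 0.
#' @param density_mean expected cells per spot (Poisson).
#' @param intensity_params per channel (`dna`, `axl`, `ckit`), per state
#'   (`neg`, `pos`) lognormal parameters `c(meanlog, sdlog)` in arbitrary
#'   fluorescence units.
#' @param background_level flat additive background (AU).
#' @param noise_sd Gaussian pixel noise SD (AU), `>= 0`.
#' @param nucleus_radius_px nuclear radius in pixels, `>= 2`.
#' @param min_sep_factor minimum center separation between planted cells as a
#'   multiple of the radius (2.2 keeps nuclei non-touching).
#' @param overlap_fraction fraction of cells deliberately planted touching an
#'   existing cell, to exercise watershed splitting.
#' @return An object of class `mema_effect_model`.
#' @export
effect_model <- function(baseline_logit = -2.5,
                         component_effects = c(COL1 = 1.6, COL4 = 0,
                                               LAM1 = 1.5, LAM5 = -0.25,
                                               OPN = 0.9, IL8 = 0.8, COL6A3 = 0.7,
                                               TGFB = 0.25, LUM = 0.2, LEP = 0.2,
                                               HA = 0.15),
                         density_mean = 25,
                         intensity_params = default_intensity_params(),
                         background_level = 100, noise_sd = 10,
                         nucleus_radius_px = 4, min_sep_factor = 2.2,
                         overlap_fraction = 0) {
  stopifnot(density_mean > 0, noise_sd >= 0, nucleus_radius_px >= 2,
            overlap_fraction >= 0, overlap_fraction <= 1)
  for (ch in c("axl", "ckit")) {
    p <- intensity_params[[ch]]
    if (p$pos[["meanlog"]] < p$neg[["meanlog"]]) {
      stop("positive-state meanlog must be >= negative-state meanlog for ", ch)
    }
  }
  structure(list(baseline_logit = baseline_logit,
                 component_effects = component_effects,
                 density_mean = density_mean,
                 intensity_params = intensity_params,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 nucleus_radius_px = nucleus_radius_px,
                 min_sep_factor = min_sep_factor,
                 overlap_fraction = overlap_fraction),
            class = "mema_effect_model")
}

#' @rdname effect_model
#' @export
default_intensity_params <- function() {
  list(dna = list(neg = c(meanlog = log(3000), sdlog = 0.2),
                  pos = c(meanlog = log(3000), sdlog = 0.2)),
       axl = list(neg = c(meanlog = log(200), sdlog = 0.35),
                  pos = c(meanlog = log(1200), sdlog = 0.35)),
       ckit = list(neg = c(meanlog = log(200), sdlog = 0.35),
                   pos = c(meanlog = log(1000), sdlog = 0.35)))
}

#' Read / write an effect model as YAML
#'
#' Keys are exactly the `effect_model()` fields.
#'
#' @param model a `mema_effect_model`.
#' @param path file path.
#' @export
write_effect_model <- function(model, path) {
  x <- unclass(model)
  x$component_effects <- as.list(x$component_effects)
  x$intensity_params <- lapply(x$intensity_params, function(ch) {
    lapply(ch, as.list)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_effect_model
#' @export
read_effect_model <- function(path) {
  x <- yaml::read_yaml(path)
  ip <- lapply(x$intensity_params, function(ch) {
    lapply(ch, function(v) stats::setNames(as.numeric(v), c("meanlog", "sdlog")))
  })
  effect_model(baseline_logit = x$baseline_logit,
               component_effects = unlist(x$component_effects),
               density_mean = x$density_mean, intensity_params = ip,
               background_level = x$background_level, noise_sd = x$noise_sd,
               nucleus_radius_px = x$nucleus_radius_px,
               min_sep_factor = x$min_sep_factor,
               overlap_fraction = x$overlap_fraction)
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Planted double-positive probability per condition
#'
#' `pi = logistic(baseline_logit + sum of the condition's component effects)`.
#'
#' @param design a `mema_design`.
#' @param model a `mema_effect_model`. Every name in `component_effects` must
#'   exist in the design's component table.
#' @return Named numeric vector of probabilities in (0, 1), one per condition.
#' @export
plant_fractions <- function(design, model) {
  eff <- model$component_effects
  unknown <- setdiff(names(eff), design$components$name)
  if (length(unknown)) {
    stop("effect model names unknown component(s): ",
         paste(unknown, collapse = ", "))
  }
  cond <- design$conditions
  logit <- vapply(seq_len(nrow(cond)), function(i) {
    comps <- c(split_set(cond$ecm_backbone[i]), split_set(cond$soluble_factors[i]))
    model$baseline_logit + sum(eff[intersect(names(eff), comps)])
  }, numeric(1))
  stats::setNames(logistic(logit), cond$condition_id)
}

# deterministic per-spot seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

place_cells <- function(n, side, model) {
  r <- model$nucleus_radius_px
  center <- (side - 1) / 2
  rmax <- side / 2 - r - 1
  if (rmax <= 0) stop("image side ", side, " too small for spot rendering")
  dmin <- model$min_sep_factor * r
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    if (nrow(pts) > 0 && model$overlap_fraction > 0 &&
        stats::runif(1) < model$overlap_fraction) {
      # deliberately touching pair: offset from a random existing cell
      for (try in 1:50) {
        j <- sample.int(nrow(pts), 1)
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, 1.2 * r, 1.8 * r)
        p <- pts[j, ] + d * c(cos(ang), sin(ang))
        if (sqrt(sum((p - center)^2)) <= rmax) { placed <- TRUE; break }
      }
      if (placed) { pts <- rbind(pts, p); next }
    }
    for (try in 1:2000) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- rmax * sqrt(stats::runif(1))
      p <- center + rad * c(cos(ang), sin(ang))
      ok <- nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(p, nrow(pts), 2, byrow = TRUE))^2))) >= dmin
      if (ok) { pts <- rbind(pts, p); placed <- TRUE; break }
    }
    if (!placed) break  # spot saturated; keep the cells placed so far
  }
  pts
}

draw_disk <- function(img, row, col, r, value, antialias = TRUE) {
  side <- nrow(img)
  r0 <- max(1L, floor(row - r)); r1 <- min(side, ceiling(row + r + 2))
  c0 <- max(1L, floor(col - r)); c1 <- min(ncol(img), ceiling(col + r + 2))
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - 1 - row)^2, (cc - 1 - col)^2, "+"))
  cov <- if (antialias) pmin(pmax(r + 0.5 - d, 0), 1) else (d <= r) * 1
  img[rr, cc] <- pmax(img[rr, cc], value * cov)
  img
}

#' Render one synthetic MEMA spot
#'
#' Places a Poisson number of nuclei inside the spot disk (rejection sampling
#' with a minimum center separation), draws each cell's state with probability
#' `pi`, renders nuclei as anti-aliased disks in the DNA channel and marker
#' channels as the cell's drawn lognormal mean over the (binary) nuclear
#' footprint, then adds background and Gaussian noise, rounding and clipping to
#' the 16-bit range. The same seed reproduces the image exactly.
#'
#' @param pi double-positive probability for this spot's condition.
#' @param model a `mema_effect_model`.
#' @param seed integer seed.
#' @param spot_index 0-based spot index recorded in the ground truth.
#' @param side image side in pixels (>= spot diameter).
#' @return list with `channels` (named list of `side x side` integer matrices:
#'   `dna`, `axl`, `ckit`) and `cells`, the ground-truth table
#'   (`spot_index,row,col,radius_px,state,true_axl,true_ckit`; 0-based
#'   centroids).
#' @export
render_spot <- function(pi, model, seed = 1L, spot_index = 0L, side = 64L) {
  withr::with_seed(as.integer(seed), {
    n <- stats::rpois(1, model$density_mean)
    pts <- place_cells(n, side, model)
    n <- nrow(pts)
    state <- if (n) stats::rbinom(n, 1, pi) else integer(0)
    draw_int <- function(ch, st) {
      p <- model$intensity_params[[ch]][[if (st == 1) "pos" else "neg"]]
      stats::rlnorm(1, p[["meanlog"]], p[["sdlog"]])
    }
    dna <- vapply(seq_len(n), function(i) draw_int("dna", state[i]), numeric(1))
    axl <- vapply(seq_len(n), function(i) draw_int("axl", state[i]), numeric(1))
    ckit <- vapply(seq_len(n), function(i) draw_int("ckit", state[i]), numeric(1))
    r <- model$nucleus_radius_px
    chans <- list(dna = matrix(0, side, side), axl = matrix(0, side, side),
                  ckit = matrix(0, side, side))
    for (i in seq_len(n)) {
      chans$dna <- draw_disk(chans$dna, pts[i, 1], pts[i, 2], r, dna[i], TRUE)
      chans$axl <- draw_disk(chans$axl, pts[i, 1], pts[i, 2], r, axl[i], FALSE)
      chans$ckit <- draw_disk(chans$ckit, pts[i, 1], pts[i, 2], r, ckit[i], FALSE)
    }
    chans <- lapply(chans, function(m) {
      m <- m + model$background_level
      if (model$noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, model$noise_sd),
                                              nrow(m), ncol(m))
      matrix(as.integer(pmin(pmax(round(m), 0), 65535)), nrow(m), ncol(m))
    })
    cells <- data.frame(spot_index = rep(as.integer(spot_index), n),
                        row = if (n) pts[, 1] else numeric(0),
                        col = if (n) pts[, 2] else numeric(0),
                        radius_px = rep(r, n),
                        state = ifelse(state == 1, "double_positive", "negative"),
                        true_axl = axl, true_ckit = ckit,
                        stringsAsFactors = FALSE)
    list(channels = chans, cells = cells)
  })
}

#' Render a full synthetic array
#'
#' One spot image set per assigned spot of the layout, with per-spot seeds
#' derived deterministically from the master seed. When `out_dir` is given,
#' 16-bit single-channel TIFFs named `{spot_index}_{channel}.tif`, a combined
#' `ground_truth.csv` and a `manifest.csv` (file, spot_index, condition_id,
#' md5) are written.
#'
#' @param design a `mema_design`.
#' @param layout a `mema_layout`.
#' @param model a `mema_effect_model`.
#' @param seed master integer seed.
#' @param out_dir optional output directory.
#' @return Invisibly, a list with `spots` (per-spot channel/ground-truth lists,
#'   only when `out_dir` is `NULL`), `ground_truth` and `manifest`.
#' @export
render_array <- function(design, layout, model, seed = 1L, out_dir = NULL) {
  asn <- layout$assignments
  pis <- plant_fractions(design, model)
  seeds <- derive_seeds(seed, nrow(asn))
  keep <- is.null(out_dir)
  if (!keep) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spots <- list()
  gt <- vector("list", nrow(asn))
  manifest <- vector("list", nrow(asn))
  for (i in seq_len(nrow(asn))) {
    sp <- render_spot(pis[[asn$condition_id[i]]], model, seed = seeds[i],
                      spot_index = asn$spot_index[i],
                      side = layout$spot_diameter_px)
    gt[[i]] <- sp$cells
    if (keep) {
      spots[[as.character(asn$spot_index[i])]] <- sp
    } else {
      files <- vapply(names(sp$channels), function(ch) {
        f <- file.path(out_dir, paste0(asn$spot_index[i], "_", ch, ".tif"))
        write_spot_image(sp$channels[[ch]], f)
        f
      }, character(1))
      manifest[[i]] <- data.frame(file = basename(files),
                                  spot_index = asn$spot_index[i],
                                  condition_id = asn$condition_id[i],
                                  md5 = unname(tools::md5sum(files)),
                                  stringsAsFactors = FALSE)
    }
  }
  ground_truth <- do.call(rbind, gt)
  manifest <- if (!keep) do.call(rbind, manifest) else NULL
  if (!keep) {
    utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(spots = if (keep) spots else NULL,
                 ground_truth = ground_truth, manifest = manifest))
}

#' Simulate measured per-cell tables without rasterizing pixels
#'
#' Table-level counterpart of [render_array()]: the same Poisson counts, state
#' draws and lognormal marker means, emitted directly as a cell table with the
#' schema the imaging stage produces. Morphology features are drawn from
#' narrow nuisance distributions (near-circular nuclei). Used for full-scale
#' statistical work where pixel rendering adds nothing.
#'
#' @inheritParams render_array
#' @return `data.frame` with columns `cell_id, spot_index, condition_id, row,
#'   col, area_px, mean_dna, mean_axl, mean_ckit, eccentricity, solidity,
#'   neighbor_count`.
#' @export
simulate_cells <- function(design, layout, model, seed = 1L) {
  asn <- layout$assignments
  pis <- plant_fractions(design, model)
  seeds <- derive_seeds(seed, nrow(asn))
  r <- model$nucleus_radius_px
  out <- vector("list", nrow(asn))
  for (i in seq_len(nrow(asn))) {
    out[[i]] <- withr::with_seed(seeds[i], {
      n <- stats::rpois(1, model$density_mean)
      if (n == 0) return(NULL)
      state <- stats::rbinom(n, 1, pis[[asn$condition_id[i]]])
      draw <- function(ch) {
        p <- model$intensity_params[[ch]]
        ifelse(state == 1,
               stats::rlnorm(n, p$pos[["meanlog"]], p$pos[["sdlog"]]),
               stats::rlnorm(n, p$neg[["meanlog"]], p$neg[["sdlog"]]))
      }
      data.frame(cell_id = paste0("s", asn$spot_index[i], "_c", seq_len(n)),
                 spot_index = asn$spot_index[i],
                 condition_id = asn$condition_id[i],
                 row = stats::runif(n, 0, layout$spot_diameter_px - 1),
                 col = stats::runif(n, 0, layout$spot_diameter_px - 1),
                 area_px = round(pi * r^2 * stats::runif(n, 0.9, 1.1)),
                 mean_dna = draw("dna"),
                 mean_axl = draw("axl"),
                 mean_ckit = draw("ckit"),
                 eccentricity = stats::rbeta(n, 2, 18),
                 solidity = 1 - stats::rbeta(n, 2, 60),
                 neighbor_count = stats::rpois(n, 1),
                 stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate per-spot double-positive counts
#'
#' Counts-level counterpart of [render_array()]: per assigned spot, a Poisson
#' cell count and a binomial double-positive count at the condition's planted
#' probability, emitted directly as a spot summary table. This is the natural
#' input for generalized-linear-model recovery and calibration studies, where
#' neither pixels nor per-cell intensities add information.
#'
#' @inheritParams render_array
#' @return Spot summary `data.frame` (`spot_index`, `condition_id`,
#'   `n_cells`, `n_double_positive`, `fraction_dp`).
#' @export
simulate_spot_counts <- function(design, layout, model, seed = 1L) {
  asn <- layout$assignments
  pis <- plant_fractions(design, model)
  withr::with_seed(as.integer(seed), {
    n <- stats::rpois(nrow(asn), model$density_mean)
    ndp <- stats::rbinom(nrow(asn), n, pis[asn$condition_id])
    data.frame(spot_index = asn$spot_index, condition_id = asn$condition_id,
               n_cells = n, n_double_positive = ndp,
               fraction_dp = ifelse(n > 0, ndp / n, NA_real_),
               stringsAsFactors = FALSE)
  })
}

#' 16-bit single-channel TIFF I/O
#'
#' Integer intensities in `[0, 65535]` are stored losslessly.
#'
#' @param img numeric/integer matrix.
#' @param path file path.
#' @return `read_spot_image` returns an integer matrix.
#' @export
write_spot_image <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_spot_image
#' @export
read_spot_image <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(m), nrow(m), ncol(m))
}
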