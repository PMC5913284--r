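#' Histogram-mode background threshold
#'
#' The dominant histogram mode of a fluorescence channel is assumed to be
#' background; the threshold is set at twice that modal intensity. When the
#' image holds at most `n_bins` distinct values the mode is the most frequent
#' exact value; otherwise intensities are binned into `n_bins` equal-width bins
#' over `[0, max]` and the modal bin center is used. Ties break toward the
#' lower intensity (conservative threshold).
#'
#' @param img numeric matrix of non-negative intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return Threshold `T = 2 * mode`, `>= 0`.
#' @export
background_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  if (!length(v)) stop("empty image")
  if (any(!is.finite(v)) || any(v < 0)) stop("intensities must be finite and >= 0")
  if (all(v == 0)) return(0)
  u <- sort(unique(v))
  if (length(u) <= n_bins) {
    cnt <- tabulate(match(v, u))
    return(2 * u[which.max(cnt)])
  }
  br <- seq(0, max(v), length.out = n_bins + 1L)
  bin <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  i <- which.max(cnt)
  2 * (br[i] + br[i + 1L]) / 2
}

#' Clipped background subtraction
#'
#' `max(pixel - T, 0)` elementwise; shape preserved.
#'
#' @param img numeric matrix.
#' @param threshold background threshold `T >= 0`.
#' @return Corrected matrix.
#' @export
subtract_background <- function(img, threshold) {
  stopifnot(threshold >= 0)
  pmax(img - threshold, 0)
}

#' Marker-based watershed segmentation of nuclei
#'
#' Markers are local maxima of the Gaussian-smoothed, log-stabilized
#' (`log1p`), background-subtracted DNA channel, separated by at least
#' `min_distance` pixels and restricted to the foreground mask
#' (`corrected > 0`). The log transform equalizes nuclear brightness before
#' smoothing so the blur tail of a bright nucleus cannot swallow the peak of a
#' dim neighbor (peak positions are unchanged for isolated nuclei). The
#' smoothed landscape is then flooded from those markers over the mask
#' (marker-controlled region growing, which splits touching nuclei along the
#' valley between their peaks), and objects smaller than `min_area` pixels are
#' removed.
#'
#' @param corrected background-subtracted DNA channel matrix.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param min_distance minimum separation between markers (pixels); default the
#'   expected nuclear radius.
#' @param min_area smallest retained object, in pixels.
#' @param seed_centers optional two-column matrix of marker centers
#'   (0-based row, col) that replaces automatic maximum detection, e.g. when
#'   nuclei positions are known from another channel.
#' @return Integer label matrix (background 0, labels 1..k).
#' @export
segment_cells <- function(corrected, smoothing_sigma = 2, min_distance = 4L,
                          min_area = 15L, seed_centers = NULL) {
  if (all(corrected <= 0)) {
    return(matrix(0L, nrow(corrected), ncol(corrected)))
  }
  mask <- corrected > 0
  sm <- EBImage::gblur(log1p(corrected), sigma = smoothing_sigma)
  if (is.null(seed_centers)) {
    w <- 2L * as.integer(min_distance) + 1L
    mx <- EBImage::dilate(sm, EBImage::makeBrush(w, shape = "disc"))
    peaks <- (sm >= mx) & mask & (sm > 0)
    seeds <- EBImage::bwlabel(peaks)
  } else {
    seeds <- matrix(0L, nrow(corrected), ncol(corrected))
    for (i in seq_len(nrow(seed_centers))) {
      seeds[round(seed_centers[i, 1]) + 1L, round(seed_centers[i, 2]) + 1L] <- i
    }
  }
  if (max(seeds) == 0) {
    return(matrix(0L, nrow(corrected), ncol(corrected)))
  }
  labels <- EBImage::propagate(sm, seeds, mask = mask)
  labels <- as.matrix(EBImage::imageData(labels))
  sizes <- tabulate(labels[labels > 0])
  drop <- which(sizes > 0 & sizes < min_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  # relabel 1..k in raster order of first occurrence
  old <- sort(unique(labels[labels > 0]))
  lut <- integer(max(old, 0L))
  lut[old] <- seq_along(old)
  labels[labels > 0] <- lut[labels[labels > 0]]
  matrix(as.integer(labels), nrow(corrected), ncol(corrected))
}

# number of integer lattice points inside (or on) the convex hull of a pixel
# set; the hull-area denominator of solidity in pixel-count units, so a convex
# region scores exactly 1
hull_pixel_count <- function(x, y) {
  if (length(x) < 3) return(length(x))
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  gx <- seq(min(x), max(x)); gy <- seq(min(y), max(y))
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  n <- length(hx)
  jj <- c(seq_len(n)[-1], 1L)
  orient <- sum(hx * hy[jj] - hx[jj] * hy)     # signed area x 2
  for (i in seq_len(n)) {
    j <- jj[i]
    # points inside lie on a consistent side of every edge (small tolerance
    # keeps collinear boundary points)
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & if (orient >= 0) cr >= -1e-9 else cr <= 1e-9
  }
  sum(inside)
}

#' Per-cell feature measurement
#'
#' For every retained label: pixel area, intensity-unweighted centroid
#' (0-based row/col), mean background-subtracted intensity per channel over
#' the label footprint, eccentricity of the second-moment ellipse, solidity
#' (pixel area over convex-hull area, hull area corrected to pixel-count
#' scale), and the number of other cells whose centroids lie within
#' `neighbor_radius_px`. Labels smaller than 3 px are dropped and counted in
#' the `dropped_small` attribute.
#'
#' @param labels integer label matrix from [segment_cells()].
#' @param channels named list of co-registered corrected channel matrices
#'   (e.g. `dna`, `axl`, `ckit`).
#' @param spot_index,condition_id identifiers stamped on every row.
#' @param neighbor_radius_px centroid-distance neighbor rule; default
#'   3 x median equivalent nuclear radius.
#' @return `data.frame` of cell records (one row per retained label) with a
#'   `dropped_small` attribute.
#' @export
measure_cells <- function(labels, channels, spot_index = 0L,
                          condition_id = NA_character_,
                          neighbor_radius_px = NULL) {
  empty <- data.frame(cell_id = character(0), spot_index = integer(0),
                      condition_id = character(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      neighbor_count = integer(0), stringsAsFactors = FALSE)
  for (ch in names(channels)) empty[[paste0("mean_", ch)]] <- numeric(0)
  idx <- which(labels > 0)
  if (!length(idx)) { attr(empty, "dropped_small") <- 0L; return(empty) }
  lab <- labels[idx]
  area <- tabulate(lab)
  keep <- which(area >= 3L)
  dropped <- sum(area > 0 & area < 3L)
  if (!length(keep)) { attr(empty, "dropped_small") <- dropped; return(empty) }
  sel <- lab %in% keep
  idx <- idx[sel]; lab <- lab[sel]
  rc <- arrayInd(idx, dim(labels))
  r <- rc[, 1] - 1; cc <- rc[, 2] - 1
  grp <- match(lab, keep)
  n <- length(keep)
  area <- area[keep]
  cr <- as.numeric(rowsum(r, grp)) / area
  ccl <- as.numeric(rowsum(cc, grp)) / area
  mu20 <- as.numeric(rowsum((r - cr[grp])^2, grp)) / area
  mu02 <- as.numeric(rowsum((cc - ccl[grp])^2, grp)) / area
  mu11 <- as.numeric(rowsum((r - cr[grp]) * (cc - ccl[grp]), grp)) / area
  tr <- mu20 + mu02
  det2 <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det2) / 2
  l2 <- (tr - det2) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  solidity <- vapply(seq_len(n), function(i) {
    xi <- r[grp == i]; yi <- cc[grp == i]
    ha <- hull_pixel_count(xi, yi)
    min(area[i] / max(ha, area[i]), 1)
  }, numeric(1))
  nr <- neighbor_radius_px
  if (is.null(nr)) nr <- 3 * stats::median(sqrt(area / pi))
  dmat <- as.matrix(stats::dist(cbind(cr, ccl)))
  nbr <- as.integer(rowSums(dmat <= nr) - 1L)
  out <- data.frame(cell_id = paste0("s", spot_index, "_c", seq_len(n)),
                    spot_index = as.integer(spot_index),
                    condition_id = condition_id,
                    row = cr, col = ccl, area_px = as.integer(area),
                    eccentricity = ecc, solidity = solidity,
                    neighbor_count = nbr, stringsAsFactors = FALSE)
  for (ch in names(channels)) {
    out[[paste0("mean_", ch)]] <-
      as.numeric(rowsum(as.numeric(channels[[ch]][idx]), grp)) / area
  }
  attr(out, "dropped_small") <- dropped
  out
}

#' Analyze one spot image end to end
#'
#' Per channel: background threshold (twice the histogram mode) and clipped
#' subtraction; then marker-based watershed on the corrected DNA channel and
#' per-cell feature measurement on the corrected channels.
#'
#' @param channels named list of raw channel matrices; must include `dna`.
#' @param spot_index,condition_id identifiers for the output rows.
#' @param params list of imaging parameters: `n_bins`, `smoothing_sigma`,
#'   `min_distance`, `min_area`, `neighbor_radius_px`.
#' @return list with `cells` (measurement table), `labels` (label matrix) and
#'   `thresholds` (per-channel `T`).
#' @export
analyze_spot <- function(channels, spot_index = 0L,
                         condition_id = NA_character_,
                         params = list()) {
  p <- utils::modifyList(list(n_bins = 256L, smoothing_sigma = 2,
                              min_distance = 4L, min_area = 15L,
                              neighbor_radius_px = NULL), params)
  stopifnot("dna" %in% names(channels))
  thresholds <- vapply(channels, background_threshold, numeric(1),
                       n_bins = p$n_bins)
  corrected <- lapply(names(channels), function(ch) {
    subtract_background(channels[[ch]], thresholds[[ch]])
  })
  names(corrected) <- names(channels)
  labels <- segment_cells(corrected$dna, smoothing_sigma = p$smoothing_sigma,
                          min_distance = p$min_distance, min_area = p$min_area)
  cells <- measure_cells(labels, corrected, spot_index = spot_index,
                         condition_id = condition_id,
                         neighbor_radius_px = p$neighbor_radius_px)
  list(cells = cells, labels = labels, thresholds = thresholds)
}

#' Analyze a directory of rendered spot images
#'
#' Reads `{spot_index}_{channel}.tif` per assigned spot of the layout and runs
#' [analyze_spot()] on each.
#'
#' @param image_dir directory holding the per-spot TIFFs.
#' @param layout a `mema_layout`.
#' @param params imaging parameter list, see [analyze_spot()].
#' @return Combined cell table across spots, with a `dropped_small` attribute.
#' @export
analyze_array <- function(image_dir, layout, params = list()) {
  asn <- layout$assignments
  out <- vector("list", nrow(asn))
  dropped <- 0L
  for (i in seq_len(nrow(asn))) {
    chans <- lapply(c(dna = "dna", axl = "axl", ckit = "ckit"), function(ch) {
      read_spot_image(file.path(image_dir,
                                paste0(asn$spot_index[i], "_", ch, ".tif")))
    })
    res <- analyze_spot(chans, spot_index = asn$spot_index[i],
                        condition_id = asn$condition_id[i], params = params)
    dropped <- dropped + attr(res$cells, "dropped_small")
    out[[i]] <- res$cells
  }
  cells <- do.call(rbind, out)
  rownames(cells) <- NULL
  attr(cells, "dropped_small") <- dropped
  cells
}
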