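#' Pipeline run configuration
#'
#' Bundles every knob of the simulate -> segment -> gate -> stats -> embed
#' chain. `mode = "images"` renders and re-analyzes pixel data;
#' `mode = "cells"` uses the generator's table-level output (identical
#' statistical structure, no rasterization), the choice for large arrays.
#'
#' @param out_dir output directory (created).
#' @param design a `mema_design`; default [default_design()].
#' @param replicates spots per condition.
#' @param rows,cols grid size; defaults to the smallest near-square grid.
#' @param mode `"cells"` or `"images"`.
#' @param model a `mema_effect_model`.
#' @param seed global integer seed, recorded in every output's metadata.
#' @param imaging imaging parameter overrides (see [analyze_spot()]).
#' @param gating list: `k`, `reference`, `min_ref_cells`.
#' @param stats list: `alpha`, `ref_ecm`, `perplexity` (NULL = auto),
#'   `linkage`, `cluster_k`.
#' @return list of class `mema_run_config`.
#' @export
run_config <- function(out_dir, design = NULL, replicates = 10L,
                       rows = NULL, cols = NULL,
                       mode = c("cells", "images"),
                       model = effect_model(), seed = 1L,
                       imaging = list(), gating = list(), stats = list()) {
  mode <- match.arg(mode)
  if (is.null(design)) design <- default_design()
  n_spots <- nrow(design$conditions) * replicates
  if (is.null(cols)) cols <- ceiling(sqrt(n_spots))
  if (is.null(rows)) rows <- ceiling(n_spots / cols)
  structure(list(
    out_dir = out_dir, design = design, replicates = as.integer(replicates),
    rows = as.integer(rows), cols = as.integer(cols), mode = mode,
    model = model, seed = as.integer(seed),
    imaging = imaging,
    gating = utils::modifyList(list(k = 1, reference = "col4_alone",
                                    min_ref_cells = 50L), gating),
    stats = utils::modifyList(list(alpha = 0.05, ref_ecm = "COL4",
                                   perplexity = NULL, linkage = "average",
                                   cluster_k = NULL), stats)),
    class = "mema_run_config")
}

write_stage <- function(obj, path) {
  utils::write.csv(obj, path, row.names = FALSE)
  path
}

#' Run the full MEMA analysis pipeline
#'
#' Executes the stages in order -- design/layout, simulation, (for image mode)
#' segmentation and measurement, gating, component GLM with post-hoc
#' contrasts and factor ranking, z-score clustering and t-SNE embedding --
#' writing each stage's tables under `config$out_dir` plus a manifest with
#' per-file checksums. Re-running with an identical config reproduces
#' identical checksums. A stage failure stops with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config a `mema_run_config`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mema_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  stage("design", {
    res$design <- config$design
    res$layout <- build_layout(config$design, config$replicates,
                               config$rows, config$cols, seed = config$seed)
    v <- validate_design(res$design, res$layout,
                         replicate_min = config$replicates,
                         replicate_max = config$replicates)
    if (nrow(v)) stop(paste(v$message, collapse = "; "))
    files <- c(files, write_stage(res$design$conditions,
                                  file.path(out, "design.csv")),
               write_stage(res$layout$assignments,
                           file.path(out, "layout.csv")))
  })

  stage("simulate", {
    if (config$mode == "cells") {
      res$cells <- simulate_cells(config$design, res$layout, config$model,
                                  seed = config$seed)
    } else {
      img_dir <- file.path(out, "images")
      ra <- render_array(config$design, res$layout, config$model,
                         seed = config$seed, out_dir = img_dir)
      res$ground_truth <- ra$ground_truth
      files <- c(files, file.path(img_dir, "ground_truth.csv"),
                 file.path(img_dir, "manifest.csv"))
    }
  })

  stage("segment", {
    if (config$mode == "images") {
      res$cells <- analyze_array(file.path(out, "images"), res$layout,
                                 params = config$imaging)
      message("segmentation dropped ", attr(res$cells, "dropped_small"),
              " sub-minimal object(s)")
    }
    files <- c(files, write_stage(res$cells, file.path(out, "cells.csv")))
  })

  stage("gate", {
    g <- config$gating
    res$gate <- fit_gate(res$cells, res$design, reference = g$reference,
                         k = g$k, min_ref_cells = g$min_ref_cells)
    res$called <- call_cells(res$cells, res$gate)
    res$spots <- summarize_spots(res$called, res$layout)
    res$conditions <- summarize_conditions(res$spots)
    message(attr(res$conditions, "excluded_spots"),
            " empty spot(s) excluded from condition summaries")
    files <- c(files,
               write_stage(as.data.frame(res$gate), file.path(out, "gates.csv")),
               write_stage(res$spots, file.path(out, "spots.csv")),
               write_stage(res$conditions, file.path(out, "conditions.csv")))
  })

  stage("stats", {
    s <- config$stats
    res$fit <- fit_component_glm(res$spots, res$design, ref_ecm = s$ref_ecm)
    res$contrasts <- posthoc_contrasts(res$fit, alpha = s$alpha)
    res$factor_effects <- if (length(res$fit$factors)) {
      rank_factor_effects(res$fit, alpha = s$alpha)
    } else NULL
    files <- c(files,
               write_stage(res$fit$coefficients,
                           file.path(out, "glm_coefficients.csv")),
               write_stage(res$contrasts, file.path(out, "contrasts.csv")))
    if (!is.null(res$factor_effects)) {
      files <- c(files, write_stage(res$factor_effects,
                                    file.path(out, "factor_effects.csv")))
    }
  })

  stage("embed", {
    s <- config$stats
    phen <- phenotype_matrix(res$conditions)
    if (nrow(phen) >= 4) {
      cl <- zscore_cluster(phen, linkage = s$linkage, k = s$cluster_k)
      res$zscore <- cl
      zdf <- data.frame(condition_id = rownames(cl$z), cl$z,
                        stringsAsFactors = FALSE)
      files <- c(files, write_stage(zdf, file.path(out, "z_matrix.csv")))
      perp <- s$perplexity
      if (is.null(perp)) perp <- max(2, min(30, floor((nrow(phen) - 1) / 3)))
      if (nrow(phen) >= 3 * perp + 1) {
        res$embedding <- embed_conditions(phen, perplexity = perp,
                                          seed = config$seed)
        files <- c(files, write_stage(res$embedding,
                                      file.path(out, "embedding.csv")))
      } else {
        message("embedding skipped: too few conditions")
      }
    } else {
      message("clustering/embedding skipped: too few phenotype rows")
    }
  })

  info <- list(seed = config$seed, mode = config$mode,
               replicates = config$replicates,
               n_conditions = nrow(config$design$conditions),
               package_version = as.character(utils::packageVersion("memaphen")))
  jsonlite::write_json(info, file.path(out, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(out, "run_info.json"))
  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}

#' Write a self-contained synthetic fixture
#'
#' Profiles: `tiny` (6 conditions x 3 replicates, 64 px spots, images
#' included; seconds), `default` (the packaged 228-condition design x 10
#' replicates; table-level cells, no pixel rendering) and `stress`
#' (228 x 20 with rendered images; minutes). Each fixture directory holds the
#' design, layout, effect model, ground truth and (when rendered) images.
#'
#' @param profile `"tiny"`, `"default"` or `"stress"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return Invisibly, a list with `design`, `layout`, `model` and `dir`.
#' @export
make_fixture <- function(profile = c("tiny", "default", "stress"),
                         seed = 1L, dir = tempfile("mema_fixture_")) {
  profile <- match.arg(profile)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (profile == "tiny") {
    comp <- mema_components(c("COL1", "COL4", "OPN", "IL8"),
                            c("ECM", "ECM", "soluble", "soluble"),
                            c(100, 100, 1, 1))
    cond <- enumerate_conditions(list("COL1", "COL4"), c("OPN", "IL8"),
                                 scheme = "both", components = comp)
    design <- mema_design(comp, cond)
    model <- effect_model(component_effects = c(COL1 = 1.6, COL4 = 0,
                                                OPN = 0.9, IL8 = 0.8),
                          density_mean = 20)
    layout <- build_layout(design, replicates = 3L, rows = 5L, cols = 4L,
                           seed = seed, spot_diameter_px = 64L)
    render_array(design, layout, model, seed = seed,
                 out_dir = file.path(dir, "images"))
  } else {
    design <- default_design()
    reps <- if (profile == "default") 10L else 20L
    n <- nrow(design$conditions) * reps
    cols <- ceiling(sqrt(n))
    layout <- build_layout(design, replicates = reps,
                           rows = ceiling(n / cols), cols = cols, seed = seed)
    model <- effect_model(density_mean = if (profile == "stress") 60 else 25)
    if (profile == "stress") {
      render_array(design, layout, model, seed = seed,
                   out_dir = file.path(dir, "images"))
    } else {
      cells <- simulate_cells(design, layout, model, seed = seed)
      utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
    }
  }
  write_design(design, file.path(dir, "design.csv"))
  write_layout(layout, file.path(dir, "layout.csv"))
  write_effect_model(model, file.path(dir, "effect_model.yaml"))
  invisible(list(design = design, layout = layout, model = model, dir = dir))
}
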