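#' Microenvironment component table
#'
#' A component is one printed constituent of a microenvironment: either a
#' structural ECM protein (the spot "backbone") or a soluble factor co-printed
#' with it. Concentrations are carried in printing units (ug/ml).
#'
#' @param name character vector of unique component identifiers (e.g. "COL1").
#' @param class character vector, each `"ECM"` or `"soluble"`.
#' @param concentration numeric vector of printing concentrations, all `> 0`.
#' @param unit concentration unit string, recycled.
#' @return A `data.frame` with columns `name`, `class`, `concentration`, `unit`.
#' @export
mema_components <- function(name, class, concentration, unit = "ug/ml") {
  stopifnot(length(name) == length(class), length(name) == length(concentration))
  if (anyDuplicated(name)) {
    stop("duplicate component name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  if (any(!nzchar(name))) stop("component names must be non-empty")
  if (!all(class %in% c("ECM", "soluble"))) {
    stop("component class must be 'ECM' or 'soluble'")
  }
  if (any(!is.finite(concentration) | concentration <= 0)) {
    stop("component concentrations must be finite and > 0")
  }
  data.frame(name = as.character(name), class = as.character(class),
             concentration = as.numeric(concentration),
             unit = rep_len(as.character(unit), length(name)),
             stringsAsFactors = FALSE)
}

#' Construct a MEMA design
#'
#' A design couples a component table with a condition table. Every condition is
#' one printed combinatorial microenvironment: an ECM backbone (one or more ECM
#' components) plus an optional set of soluble factors. Within the condition
#' table, component name sets are ";"-joined strings and per-condition
#' concentrations are ";"-joined `"name=value unit"` entries, so the same
#' (backbone, factors) pair printed at two concentrations can appear as two
#' conditions with distinct ids.
#'
#' @param components component table from [mema_components()].
#' @param conditions `data.frame` with columns `condition_id`, `ecm_backbone`,
#'   `soluble_factors`, `concentrations`.
#' @return An object of class `mema_design`.
#' @seealso [enumerate_conditions()], [default_design()], [validate_design()]
#' @export
mema_design <- function(components, conditions) {
  stopifnot(is.data.frame(components), is.data.frame(conditions))
  need <- c("condition_id", "ecm_backbone", "soluble_factors", "concentrations")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stop("condition table lacks column(s): ", paste(miss, collapse = ", "))
  design <- structure(list(components = components, conditions = conditions),
                      class = "mema_design")
  v <- validate_design(design)
  v <- v[v$rule %in% c("duplicate_condition_id", "unknown_component", "empty_backbone",
                       "duplicate_condition"), , drop = FALSE]
  if (nrow(v)) stop("invalid design: ", paste(v$message, collapse = "; "))
  design
}

#' @export
print.mema_design <- function(x, ...) {
  cat("MEMA design:", nrow(x$conditions), "conditions,",
      nrow(x$components), "components (",
      sum(x$components$class == "ECM"), "ECM /",
      sum(x$components$class == "soluble"), "soluble )\n")
  invisible(x)
}

split_set <- function(x) if (!nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
join_set <- function(x) paste(x, collapse = ";")

#' Deterministic condition identifier
#'
#' Sorted backbone names joined by `"+"`, then `"|"` and the sorted factor
#' names joined by `"+"` (omitted when the backbone is printed alone). An
#' optional `variant` tag (e.g. a concentration series label) is appended after
#' `"@"` so that conditions differing only in concentration stay distinct.
#'
#' @param backbone character vector of ECM component names.
#' @param factors character vector of soluble factor names (may be empty).
#' @param variant optional tag string.
#' @return A single id string.
#' @export
condition_id <- function(backbone, factors = character(0), variant = NULL) {
  id <- paste(sort(backbone), collapse = "+")
  if (length(factors)) id <- paste0(id, "|", paste(sort(factors), collapse = "+"))
  if (!is.null(variant) && nzchar(variant)) id <- paste0(id, "@", variant)
  id
}

format_concentrations <- function(names, components, scale = 1) {
  i <- match(names, components$name)
  paste0(names, "=", components$concentration[i] * scale, " ", components$unit[i],
         collapse = ";")
}

#' Enumerate combinatorial microenvironment conditions
#'
#' Builds the condition table for a set of ECM backbones crossed with single
#' soluble factors. `scheme = "both"` yields each backbone alone plus each
#' backbone combined with each single factor; the other schemes yield only one
#' of those two blocks.
#'
#' @param ecm_backbones list of character vectors, each one backbone (>= 1 ECM
#'   component name).
#' @param factors character vector of soluble factor names (may be empty).
#' @param scheme `"ecm_alone"`, `"ecm_plus_single_factor"` or `"both"`.
#' @param components optional component table used to fill the concentration
#'   column; factor rows can be rescaled via `factor_scales` to build printed
#'   concentration series.
#' @param factor_scales named numeric vector of concentration multipliers; one
#'   condition block is emitted per scale, tagged with the scale's name when it
#'   is not `"" `.
#' @return `data.frame` of conditions (sorted, deduplicated, deterministic ids).
#' @export
enumerate_conditions <- function(ecm_backbones, factors = character(0),
                                 scheme = c("both", "ecm_alone", "ecm_plus_single_factor"),
                                 components = NULL,
                                 factor_scales = c(1)) {
  scheme <- match.arg(scheme)
  if (!length(ecm_backbones)) stop("at least one ECM backbone is required")
  if (!is.list(ecm_backbones)) ecm_backbones <- as.list(ecm_backbones)
  if (any(vapply(ecm_backbones, length, 1L) == 0)) stop("empty backbone set")
  all_names <- c(unlist(ecm_backbones), factors)
  if (anyDuplicated(factors)) stop("duplicate component name in factors")
  conc <- function(nm, scale = 1) {
    if (is.null(components)) "" else format_concentrations(nm, components, scale)
  }
  if (is.null(names(factor_scales))) {
    names(factor_scales) <- ifelse(seq_along(factor_scales) == 1, "",
                                   paste0("x", factor_scales))
  }
  rows <- list()
  if (scheme %in% c("both", "ecm_alone")) {
    for (b in ecm_backbones) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition_id = condition_id(b), ecm_backbone = join_set(sort(b)),
        soluble_factors = "", concentrations = conc(sort(b)),
        stringsAsFactors = FALSE)
    }
  }
  if (scheme %in% c("both", "ecm_plus_single_factor")) {
    for (s in seq_along(factor_scales)) {
      tag <- names(factor_scales)[s]
      for (b in ecm_backbones) {
        for (f in factors) {
          cc <- if (nzchar(conc(f))) {
            paste(conc(sort(b)), conc(f, factor_scales[s]), sep = ";")
          } else ""
          rows[[length(rows) + 1L]] <- data.frame(
            condition_id = condition_id(b, f, variant = tag),
            ecm_backbone = join_set(sort(b)), soluble_factors = f,
            concentrations = cc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(condition_id = character(0), ecm_backbone = character(0),
                      soluble_factors = character(0),
                      concentrations = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$condition_id), , drop = FALSE]
  out <- out[order(out$condition_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged default 228-condition design
#'
#' The study design this package targets printed 228 unique combinatorial
#' microenvironments built from 4 ECM backbones (COL1, COL4, LAM1, LAM1+LAM5)
#' and 29 soluble factors. The exact combinatorial rule behind the printed
#' total is not recoverable from the published component lists, so the packaged
#' table is a synthetic reconstruction that reaches the same total with the
#' same components: each backbone printed alone (4), each backbone crossed
#' with each single factor at its catalogued concentration (4 x 29 = 116), and
#' a 1:10 dilution series for the 27 factors printed below matrix scale
#' (4 x 27 = 108; hyaluronan and fibronectin, catalogued at 100 ug/ml, carry
#' no dilution block). Concentrations follow the published reagent table
#' (ECMs 100 ug/ml, LAM5 20 ug/ml, HA and FN1 100 ug/ml, other factors
#' 1 ug/ml).
#'
#' @return A `mema_design` with exactly 228 conditions.
#' @export
default_design <- function() {
  comp <- mema_components(
    name = c("COL1", "COL4", "LAM1", "LAM5",
             "OPN", "HA", "TNC", "FN1", "BMP2_7", "BMP4", "CEACAM6", "CEACAM8",
             "CD44", "COL23A1", "COL6A3", "ECAD", "EGF", "FGF2", "GAS6", "HGF",
             "IGF1", "IFNG", "IL1B", "IL6", "IL8", "LEP", "GRO1", "NID1",
             "LUM", "OPG", "SCF", "SDF1B", "TGFB"),
    class = c(rep("ECM", 4), rep("soluble", 29)),
    concentration = c(100, 100, 100, 20,
                      1, 100, 1, 100, rep(1, 25)))
  backbones <- list("COL1", "COL4", "LAM1", c("LAM1", "LAM5"))
  factors <- comp$name[comp$class == "soluble"]
  dilutable <- setdiff(factors, c("HA", "FN1"))
  cond <- rbind(
    enumerate_conditions(backbones, factors, scheme = "both",
                         components = comp),
    enumerate_conditions(backbones, dilutable,
                         scheme = "ecm_plus_single_factor",
                         components = comp, factor_scales = c(lo = 0.1)))
  cond <- cond[order(cond$condition_id), , drop = FALSE]
  rownames(cond) <- NULL
  mema_design(comp, cond)
}

#' Build a replicate spot layout for a design
#'
#' Assigns every condition to exactly `replicates` spots of a printed
#' `rows x cols` grid via a seeded permutation, so the same seed always yields
#' the identical layout.
#'
#' @param design a `mema_design` (or a condition `data.frame`).
#' @param replicates spots per condition.
#' @param rows,cols grid size; `rows * cols` must be at least
#'   `n_conditions * replicates`.
#' @param seed integer seed for the spot permutation.
#' @param spot_diameter_px,spot_pitch_px printed spot geometry in pixels.
#' @return An object of class `mema_layout` with 0-based row-major
#'   `spot_index` assignments.
#' @export
build_layout <- function(design, replicates, rows, cols, seed = 1L,
                         spot_diameter_px = 64L, spot_pitch_px = 72L) {
  cond <- if (inherits(design, "mema_design")) design$conditions else design
  n_need <- nrow(cond) * replicates
  if (rows * cols < n_need) {
    stop("grid too small: ", rows, "x", cols, " = ", rows * cols,
         " spots < ", n_need, " required")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  idx <- withr::with_seed(seed, sample.int(rows * cols))[seq_len(n_need)]
  assignments <- data.frame(
    spot_index = idx - 1L,
    row = (idx - 1L) %/% cols,
    col = (idx - 1L) %% cols,
    condition_id = rep(cond$condition_id, each = replicates),
    stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$spot_index), , drop = FALSE]
  rownames(assignments) <- NULL
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spot_diameter_px = as.integer(spot_diameter_px),
                 spot_pitch_px = as.integer(spot_pitch_px),
                 assignments = assignments),
            class = "mema_layout")
}

#' @export
print.mema_layout <- function(x, ...) {
  cat("MEMA layout:", x$rows, "x", x$cols, "grid,",
      nrow(x$assignments), "assigned spots,",
      length(unique(x$assignments$condition_id)), "conditions\n")
  invisible(x)
}

#' Validate a design (and optionally a layout) against its invariants
#'
#' Violations are returned as data, not thrown: unique non-empty component and
#' condition ids, resolvable component references, unique
#' (backbone, factors, concentrations) triples, layout references to known
#' conditions, and replicate counts within `[replicate_min, replicate_max]`.
#'
#' @param design a `mema_design`.
#' @param layout optional `mema_layout`.
#' @param replicate_min,replicate_max allowed replicate range per condition
#'   when a layout is given.
#' @return `data.frame` with columns `rule`, `id`, `message`; zero rows when
#'   everything holds.
#' @export
validate_design <- function(design, layout = NULL,
                            replicate_min = 5L, replicate_max = 20L) {
  viol <- function(rule, id, message) {
    data.frame(rule = rule, id = id, message = message, stringsAsFactors = FALSE)
  }
  out <- list()
  comp <- design$components
  cond <- design$conditions
  dup <- unique(comp$name[duplicated(comp$name)])
  for (d in dup) out[[length(out) + 1L]] <- viol("duplicate_component", d,
    paste0("component name '", d, "' is duplicated"))
  dup <- unique(cond$condition_id[duplicated(cond$condition_id)])
  for (d in dup) out[[length(out) + 1L]] <- viol("duplicate_condition_id", d,
    paste0("condition_id '", d, "' is duplicated"))
  for (i in seq_len(nrow(cond))) {
    bb <- split_set(cond$ecm_backbone[i])
    sf <- split_set(cond$soluble_factors[i])
    if (!length(bb)) {
      out[[length(out) + 1L]] <- viol("empty_backbone", cond$condition_id[i],
        paste0("condition '", cond$condition_id[i], "' has an empty ECM backbone"))
    }
    unknown <- setdiff(c(bb, sf), comp$name)
    for (u in unknown) out[[length(out) + 1L]] <- viol("unknown_component",
      cond$condition_id[i],
      paste0("condition '", cond$condition_id[i], "' references unknown component '", u, "'"))
  }
  key <- paste(cond$ecm_backbone, cond$soluble_factors, cond$concentrations, sep = "&")
  dup <- unique(key[duplicated(key)])
  for (d in dup) out[[length(out) + 1L]] <- viol("duplicate_condition", d,
    paste0("duplicate (backbone, factors, concentrations) combination: ", d))
  if (!is.null(layout)) {
    asn <- layout$assignments
    unknown <- setdiff(asn$condition_id, cond$condition_id)
    for (u in unknown) out[[length(out) + 1L]] <- viol("unknown_condition", u,
      paste0("layout references unknown condition '", u, "'"))
    reps <- table(asn$condition_id)
    reps <- reps[names(reps) %in% cond$condition_id]
    bad <- names(reps)[reps < replicate_min | reps > replicate_max]
    for (b in bad) out[[length(out) + 1L]] <- viol("replicate_range", b,
      paste0("condition '", b, "' has ", reps[[b]], " replicates, outside [",
             replicate_min, ", ", replicate_max, "]"))
  }
  if (!length(out)) {
    return(data.frame(rule = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a design as CSV
#'
#' The CSV carries the condition table (`condition_id`, `ecm_backbone`,
#' `soluble_factors`, `concentrations`); the component table is reconstructed
#' from the concentration entries, classifying a component as ECM when it
#' appears in any backbone. Round-tripping a design through CSV is an identity
#' on the condition table.
#'
#' @param design a `mema_design`.
#' @param path file path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `mema_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design$conditions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cond <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (cl in c("ecm_backbone", "soluble_factors", "concentrations")) {
    cond[[cl]][is.na(cond[[cl]])] <- ""
  }
  ecm_names <- unique(unlist(lapply(cond$ecm_backbone, split_set)))
  entries <- unique(unlist(lapply(cond$concentrations, split_set)))
  entries <- entries[nzchar(entries)]
  nm <- sub("=.*$", "", entries)
  val <- sub("^[^=]*=", "", entries)
  unit <- sub("^[0-9.eE+-]+ ?", "", val)
  num <- as.numeric(sub(" .*$", "", val))
  # keep the maximum printed concentration as the catalogue value per component
  ord <- order(nm, -num)
  nm <- nm[ord]; num <- num[ord]; unit <- unit[ord]
  keep <- !duplicated(nm)
  comp <- mema_components(nm[keep],
                          ifelse(nm[keep] %in% ecm_names, "ECM", "soluble"),
                          num[keep], unit[keep])
  mema_design(comp, cond)
}

#' Read / write a spot layout as CSV
#'
#' Columns: `spot_index` (0-based, row-major), `row`, `col`, `condition_id`.
#' The CSV carries only the assignment map; grid geometry is passed explicitly
#' to `read_layout` (defaulting to the smallest grid covering the stored
#' indices).
#'
#' @param layout a `mema_layout`.
#' @param path file path.
#' @param rows,cols,spot_diameter_px,spot_pitch_px geometry for `read_layout`;
#'   `rows`/`cols` default to the smallest grid covering the stored indices.
#' @return `write_layout` returns `path` invisibly; `read_layout` a
#'   `mema_layout`.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout$assignments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path, rows = NULL, cols = NULL,
                        spot_diameter_px = 64L, spot_pitch_px = 72L) {
  asn <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(cols)) cols <- max(asn$col) + 1L
  if (is.null(rows)) rows <- max(asn$row) + 1L
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 spot_diameter_px = as.integer(spot_diameter_px),
                 spot_pitch_px = as.integer(spot_pitch_px),
                 assignments = asn),
            class = "mema_layout")
}

#' Components of one condition
#'
#' @param design a `mema_design`.
#' @param id condition id.
#' @return character vector of component names (backbone then factors).
#' @keywords internal
condition_components <- function(design, id) {
  i <- match(id, design$conditions$condition_id)
  if (is.na(i)) stop("unknown condition '", id, "'")
  c(split_set(design$conditions$ecm_backbone[i]),
    split_set(design$conditions$soluble_factors[i]))
}
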