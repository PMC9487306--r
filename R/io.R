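#' Contour JSON I/O
#'
#' The internal contour interchange format: a JSON array of structures,
#' each `{"name": ..., "contours": [{"z": ..., "points": [[x, y], ...]}, ...]}`
#' (mm, patient LPS).
#'
#' @param contours A `contour_tbl`.
#' @param path File path.
#' @export
write_contours_json <- function(contours, path) {
  contours <- validate_contour_tbl(contours)
  structs <- lapply(structure_names(contours), function(nm) {
    sub <- contours[contours$structure == nm, ]
    cts <- lapply(split(sub, sub$contour), function(p) {
      list(z = p$z[1], points = unname(cbind(p$x, p$y)))
    })
    list(name = nm, contours = unname(cts))
  })
  jsonlite::write_json(structs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  structs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- bind_rows(lapply(structs, function(s) {
    bind_rows(lapply(seq_along(s$contours), function(i) {
      ct <- s$contours[[i]]
      pts <- do.call(rbind, lapply(ct$points, unlist))
      tibble(structure = s$name, contour = i, z = as.numeric(ct$z),
             x = pts[, 1], y = pts[, 2])
    }))
  }))
  validate_contour_tbl(out)
}

#' Heatmap CSV I/O
#'
#' One row per control point: first column the gantry angle, remaining
#' columns the MCI per collimator angle (named `theta_<deg>`). Values
#' round-trip to at least 1e-6.
#'
#' @param h An `mci_heatmap`.
#' @param path File path.
#' @export
write_heatmap_csv <- function(h, path) {
  stopifnot(inherits(h, "mci_heatmap"))
  df <- data.frame(gantry = h$gantry, h$values)
  names(df)[-1L] <- paste0("theta_", formatC(h$thetas, format = "g"))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @param terminal_cp See [as_mci_heatmap()].
#' @export
read_heatmap_csv <- function(path, terminal_cp = TRUE) {
  df <- data.table::fread(path)
  thetas <- as.numeric(sub("^theta_", "", names(df)[-1L]))
  as_mci_heatmap(as.matrix(df[, -1L]), df[[1L]], thetas,
                 terminal_cp = terminal_cp)
}

#' Sub-arc plan I/O
#'
#' JSON round-trips a [segment_subarcs()] plan exactly (full-precision
#' scores and attributes); the companion CSV writer gives the flat table.
#'
#' @param plan A `subarc_plan`.
#' @param path File path.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "subarc_plan"))
  payload <- list(
    subarcs = as.data.frame(plan),
    total_score = attr(plan, "total_score"),
    cp_spacing = attr(plan, "cp_spacing"),
    terminal_cp = attr(plan, "terminal_cp"),
    constraints = attr(plan, "constraints"),
    plan_string = plan_string(plan))
  # 17 significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as_tibble(p$subarcs)
  # restore canonical column types (JSON has no integer/double distinction)
  for (col in c("subarc", "cp_start", "cp_end")) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("gantry_start", "gantry_end", "span", "collimator", "score")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  if ("fs_cm2" %in% names(out)) out$fs_cm2 <- as.numeric(out$fs_cm2)
  class(out) <- c("subarc_plan", class(out))
  attr(out, "total_score") <- p$total_score
  attr(out, "n_subarcs") <- nrow(out)
  attr(out, "cp_spacing") <- p$cp_spacing
  attr(out, "terminal_cp") <- p$terminal_cp
  attr(out, "constraints") <- p$constraints
  out
}

#' @rdname write_plan_json
#' @export
write_plan_csv <- function(plan, path) {
  stopifnot(inherits(plan, "subarc_plan"))
  data.table::fwrite(as.data.frame(plan), path)
  invisible(path)
}

#' Run configuration
#'
#' Assembles and validates the full pipeline configuration. The defaults are
#' the clinical study conditions: dual 358-degree arcs (179 -> 181 CCW and
#' 181 -> 179 CW) at 2 degrees/CP, collimator angles 0-179 in 1-degree steps,
#' sub-arcs of at least 30 degrees and at most 9 per arc, SAD 1000 mm,
#' Millennium-120-class MLC, 1 mm voxels, 0.5 mm BEV pixels, 30 Gy
#' prescription.
#'
#' @param ... Overrides for any of the listed fields.
#' @return A validated list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    sad = 1000,
    arcs = list(list(start = 179, stop = 181, direction = "CCW"),
                list(start = 181, stop = 179, direction = "CW")),
    cp_spacing = 2,
    thetas = 0:179,
    min_span = 30,
    max_subarcs = 9,
    delta = 0.01,
    pixel = 0.5,
    voxel = 1,
    mode = "divergent",
    leaf_widths = c(rep(10, 10), rep(5, 40), rep(10, 10)),
    dp = 30,
    sigma = 5,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @rdname default_config
#' @param path YAML or JSON configuration file.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.data.frame(cfg$arcs)) {
    cfg$arcs <- lapply(seq_len(nrow(cfg$arcs)), function(i) as.list(cfg$arcs[i, ]))
  }
  do.call(default_config, cfg)
}

validate_config <- function(cfg) {
  geom <- linac_geometry(sad = cfg$sad)          # validates sad
  arcs <- lapply(cfg$arcs, function(a) {
    arc_spec(a$start, a$stop, a$direction, cfg$cp_spacing)
  })
  mlc <- mlc_model(cfg$leaf_widths)
  if (cfg$min_span < cfg$cp_spacing) {
    abort("min_span must be at least cp_spacing", class = "subarcvmat_config_error")
  }
  for (a in arcs) {
    if (cfg$min_span > a$total_span) {
      abort("infeasible constraints: min_span exceeds the arc span",
            class = "subarcvmat_config_error")
    }
  }
  if (cfg$max_subarcs < 1) abort("max_subarcs must be >= 1",
                                 class = "subarcvmat_config_error")
  stopifnot(cfg$pixel > 0, cfg$voxel > 0, cfg$dp > 0, cfg$sigma > 0)
  cfg$mode <- match.arg(cfg$mode, c("divergent", "parallel"))
  cfg$geom <- geom; cfg$arc_specs <- arcs; cfg$mlc <- mlc
  structure(cfg, class = "run_config")
}

#' Run the full pipeline for one case
#'
#' Builds the MCI heatmap for every configured arc, segments it into
#' sub-arcs with per-sub-arc collimator angles, computes per-sub-arc and
#' arc-weighted field sizes, and (optionally, when a dose grid is supplied
#' or `synthetic_dose = TRUE`) the plan-quality indices. When `out_dir` is
#' given, writes per-arc heatmap CSVs, plan JSON/CSV, and an indices/summary
#' JSON.
#'
#' @param x Target structures (`contour_tbl`) or a [phantom_case()] result.
#' @param config A [default_config()] list.
#' @param out_dir Optional output directory.
#' @param dose Optional [dose_grid()] for the indices report.
#' @param synthetic_dose If `TRUE` and `x` is a phantom, score a
#'   [make_synthetic_dose()] distribution.
#' @return A list: `heatmaps`, `plans` (with `fs_cm2`), `weighted_fs_cm2`,
#'   `indices` (or `NULL`), `plan_strings`.
#' @export
run_case <- function(x, config = default_config(), out_dir = NULL,
                     dose = NULL, synthetic_dose = FALSE) {
  if (!inherits(config, "run_config")) config <- do.call(default_config, config)
  is_phantom <- inherits(x, "phantom")
  targets <- if (is_phantom) target_contours(x) else validate_contour_tbl(x)
  targets <- targets[targets$structure != "BODY", ]
  heatmaps <- list(); plans <- list()
  for (ai in seq_along(config$arc_specs)) {
    h <- mci_heatmap(targets, config$arc_specs[[ai]], config$geom, config$mlc,
                     thetas = config$thetas, pixel = config$pixel,
                     mode = config$mode)
    p <- segment_subarcs(h, config$min_span, config$max_subarcs, config$delta)
    p <- subarc_field_sizes(h, p)
    heatmaps[[ai]] <- h; plans[[ai]] <- p
  }
  wfs <- vapply(plans, weighted_field_size, numeric(1))
  indices <- NULL
  if (is.null(dose) && synthetic_dose) {
    if (!is_phantom) abort("synthetic dose needs a phantom input",
                           class = "subarcvmat_config_error")
    dose <- make_synthetic_dose(x, dp = config$dp, sigma = config$sigma,
                                spacing = config$voxel)
  }
  if (!is.null(dose)) {
    indices <- plan_indices(dose, targets, target = structure_names(targets),
                            dp = config$dp)
  }
  out <- list(heatmaps = heatmaps, plans = plans,
              weighted_fs_cm2 = wfs, indices = indices,
              plan_strings = vapply(plans, plan_string, character(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ai in seq_along(plans)) {
      write_heatmap_csv(heatmaps[[ai]], file.path(out_dir, sprintf("heatmap_arc%d.csv", ai)))
      write_plan_json(plans[[ai]], file.path(out_dir, sprintf("plan_arc%d.json", ai)))
      write_plan_csv(plans[[ai]], file.path(out_dir, sprintf("plan_arc%d.csv", ai)))
    }
    report <- list(plan_strings = out$plan_strings,
                   weighted_fs_cm2 = wfs,
                   n_subarcs = vapply(plans, nrow, integer(1)))
    if (!is.null(indices)) report$indices <- as.data.frame(indices)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
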