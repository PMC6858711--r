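#' Read and write cell tables
#'
#' CSV dialect used throughout: header `x_um,y_um,marker` (an optional
#' `source` column survives a round-trip). Unknown marker labels and
#' non-numeric coordinates are rejected with the offending data line
#' number.
#'
#' @param path CSV file path.
#' @param cells a cell table.
#' @return `read_cells()` returns the cell table; `write_cells()` the path,
#'   invisibly.
#' @export
read_cells <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "marker")
  if (!all(need %in% names(df)))
    stop("cell CSV must have header x_um,y_um,marker", call. = FALSE)
  if (!nrow(df)) return(as_cell_table(NULL))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$x_um))) |
                 !is.finite(suppressWarnings(as.numeric(df$y_um))))
  if (length(bad))
    stop("malformed coordinates at data line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  bad <- which(!df$marker %in% MARKER_LEVELS)
  if (length(bad))
    stop("unknown marker '", df$marker[bad[1]], "' at data line ",
         bad[1] + 1L, " of ", path, call. = FALSE)
  df$x_um <- as.numeric(df$x_um)
  df$y_um <- as.numeric(df$y_um)
  df
}

#' @rdname read_cells
#' @export
write_cells <- function(cells, path) {
  cells <- as_cell_table(cells)
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write margin geometry
#'
#' Accepts WKT `POLYGON`/`MULTIPOLYGON` (micrometre coordinates) or GeoJSON
#' (`Polygon`/`MultiPolygon`, possibly wrapped in a Feature). Rings are
#' validated as simple polygons, so self-intersecting input (a bow-tie) is
#' rejected.
#'
#' @param path geometry file; GeoJSON is detected by a leading opening
#'   brace, anything else is parsed as WKT.
#' @param field_bounds optional field rectangle; defaults to the polygon
#'   bounding box.
#' @param geometry a [tumor_geometry()].
#' @param format `"wkt"` or `"geojson"` for writing.
#' @return `read_geometry()` a [tumor_geometry()]; `write_geometry()` the
#'   path, invisibly.
#' @export
read_geometry <- function(path, field_bounds = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- trimws(txt)
  rings <- if (startsWith(txt, "{")) geojson_rings(txt) else wkt_rings(txt)
  tumor_geometry(rings, field_bounds = field_bounds, validate = TRUE)
}

wkt_rings <- function(txt) {
  up <- toupper(txt)
  if (!grepl("^(POLYGON|MULTIPOLYGON)", up))
    stop("WKT must be POLYGON or MULTIPOLYGON", call. = FALSE)
  ring_txt <- regmatches(txt, gregexpr("\\(([^()]+)\\)", txt))[[1]]
  if (!length(ring_txt)) stop("invalid WKT: no coordinate rings", call. = FALSE)
  lapply(ring_txt, function(r) {
    r <- gsub("[()]", "", r)
    pts <- strsplit(trimws(strsplit(r, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(pts, function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) < 2L || any(!is.finite(v[1:2])))
        stop("invalid WKT coordinate: '", paste(p, collapse = " "), "'",
             call. = FALSE)
      v[1:2]
    }))
    m
  })
}

geojson_rings <- function(txt) {
  g <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (identical(g$type, "Feature")) g <- g$geometry
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]$geometry
  co <- g$coordinates
  polys <- switch(g$type %||% "", Polygon = list(co), MultiPolygon = co,
                  stop("GeoJSON must be Polygon or MultiPolygon",
                       call. = FALSE))
  unlist(lapply(polys, function(poly) lapply(poly, function(ring)
    do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2]))))),
    recursive = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path, format = c("wkt", "geojson")) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  format <- match.arg(format)
  close_ring <- function(r) rbind(r, r[1L, , drop = FALSE])
  if (format == "wkt") {
    rings <- vapply(geometry$rings, function(r) {
      r <- close_ring(r)
      paste0("(", paste(sprintf("%.15g %.15g", r[, 1], r[, 2]),
                        collapse = ", "), ")")
    }, "")
    writeLines(paste0("POLYGON (", paste(rings, collapse = ", "), ")"), path)
  } else {
    coords <- lapply(geometry$rings, function(r) {
      r <- close_ring(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    jsonlite::write_json(list(type = "Polygon", coordinates = coords), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Flat, validated key set driving [run_pipeline()]. Unknown keys are
#' rejected before any stage runs.
#'
#' @param ... overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @details Keys: `seed` (master seed; per-stage seeds derive from it),
#'   `out_dir`; scene stage -- `n_scenes`, `field_width_um`,
#'   `field_height_um`, `margin_shape`, `margin_radius_um`, `lambda_in_cd8`,
#'   `lambda_out_cd8`, `lambda_in_cd163`, `lambda_out_cd163`, `lambda_neg`,
#'   `gradient_slope_cd8`, `gradient_slope_cd163`, `run_detection`,
#'   `um_per_pixel`, `noise_sd`; profile stage -- `band_width_um`,
#'   `extent_um`, `peritumoral_extent_um`, `inside_fraction`; cohort stage
#'   -- `n_patients`; association stage -- `term`, `do_scenes`,
#'   `do_cohort`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L, out_dir = tempfile("immunomargin_run_"),
    do_scenes = TRUE, do_cohort = TRUE,
    n_scenes = 4L, field_width_um = 1500, field_height_um = 1500,
    margin_shape = "blob", margin_radius_um = 450,
    lambda_in_cd8 = 400, lambda_out_cd8 = 700,
    lambda_in_cd163 = 600, lambda_out_cd163 = 500,
    lambda_neg = 1200, gradient_slope_cd8 = 0, gradient_slope_cd163 = 0,
    run_detection = FALSE, um_per_pixel = 0.5, noise_sd = 5,
    band_width_um = 20, extent_um = 100,
    peritumoral_extent_um = 500, inside_fraction = 0,
    n_patients = 158L, term = "group")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Scene stage: simulates tissue scenes (optionally rendering and
#' re-detecting the cells), computes distance profiles and compartment
#' densities, scores each scene and writes per-scene CSVs. Cohort stage:
#' simulates a patient cohort, summarises it and fits the multivariable
#' response and survival models. A manifest (parameters, seeds, package
#' version, per-file MD5 checksums) makes runs reproducible and
#' comparable.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `scenes` (per-scene assessments),
#'   `cohort`, `models`, `summary` and `manifest`; all also written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    if (is.data.frame(obj)) write.csv(obj, p, row.names = FALSE)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    written <<- c(written, p)
    p
  }
  scenes <- NULL
  if (config$do_scenes && config$n_scenes > 0L) {
    scenes <- do.call(rbind, lapply(seq_len(config$n_scenes), function(i) {
      sc <- generate_tissue_scene(scene_config(
        field_width_um = config$field_width_um,
        field_height_um = config$field_height_um,
        margin_shape = config$margin_shape,
        margin_radius_um = config$margin_radius_um,
        lambda_in = c(CD8 = config$lambda_in_cd8,
                      CD163 = config$lambda_in_cd163,
                      NEG = config$lambda_neg),
        lambda_out = c(CD8 = config$lambda_out_cd8,
                       CD163 = config$lambda_out_cd163,
                       NEG = config$lambda_neg),
        gradient_slope = c(CD8 = config$gradient_slope_cd8,
                           CD163 = config$gradient_slope_cd163, NEG = 0),
        seed = config$seed * 1000L + i))
      cells <- sc$cells
      if (config$run_detection) {
        # one stain per slide: re-detect CD8 and CD163 from separate renders
        cells <- do.call(rbind, lapply(c("CD8", "CD163"), function(mk) {
          sub <- sc$cells[sc$cells$marker %in% c(mk, "NEG"), , drop = FALSE]
          img <- render_ihc_image(list(cells = sub, config = sc$config),
                                  um_per_pixel = config$um_per_pixel,
                                  noise_sd = config$noise_sd,
                                  seed = config$seed * 1000L + i)
          det <- detect_cells(classify_pixels(img), marker = mk)
          if (mk == "CD163") det <- det[det$marker != "NEG", , drop = FALSE]
          det
        }))
      }
      emit(cells, sprintf("scene%02d_cells.csv", i))
      write_geometry(sc$geometry,
                     file.path(config$out_dir,
                               sprintf("scene%02d_margin.wkt", i)))
      written <<- c(written, file.path(config$out_dir,
                                       sprintf("scene%02d_margin.wkt", i)))
      prof <- band_histogram(cells, sc$geometry,
                             band_width_um = config$band_width_um,
                             extent_um = config$extent_um, min_cell_um = 2)
      emit(as.data.frame(prof), sprintf("scene%02d_profile.csv", i))
      cd <- compartment_densities(cells, sc$geometry,
                                  config$peritumoral_extent_um,
                                  config$inside_fraction, min_cell_um = 2)
      cd$score <- score_density(cd$positive_fraction_pct)
      cd$dichot <- dichotomize_score(cd$score)
      cd$scene <- i
      cd
    }))
    it <- scenes[scenes$compartment == "intratumoral", ]
    grp <- vapply(split(it, it$scene), function(s)
      as.character(combine_cd8_cd163(s$dichot[s$marker == "CD8"],
                                     s$dichot[s$marker == "CD163"])), "")
    scenes_groups <- data.frame(scene = as.integer(names(grp)),
                                cd8xcd163_group = grp, row.names = NULL)
    emit(scenes, "scene_assessments.csv")
    emit(scenes_groups, "scene_groups.csv")
  }
  cohort <- models <- summary_tab <- NULL
  if (config$do_cohort) {
    cohort <- generate_cohort(cohort_config(n_patients = config$n_patients,
                                            seed = config$seed))
    emit(cohort, "cohort.csv")
    summary_tab <- cohort_summary(cohort,
                                  c("group", "stage", "treatment", "response"))
    emit(summary_tab, "cohort_summary.csv")
    models <- list(
      response = fit_response_model(cohort, term = config$term),
      pfs = fit_survival_model(cohort, "pfs", term = config$term),
      os = fit_survival_model(cohort, "os", term = config$term))
    tidy <- do.call(rbind, lapply(names(models), function(nm)
      cbind(endpoint = nm, as.data.frame(models[[nm]]))))
    emit(tidy, "model_results.csv")
    km <- km_estimate(cohort, "os", by = config$term)
    emit(km$curve, "km_os.csv")
  }
  manifest <- list(package = "immunomargin",
                   version = as.character(utils::packageVersion("immunomargin")),
                   parameters = unclass(config),
                   checksums = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scenes = scenes, cohort = cohort, models = models,
                 summary = summary_tab, manifest = manifest))
}
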