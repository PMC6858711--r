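#' Tissue-scene configuration
#'
#' Parameters of the synthetic tissue generator: a rectangular field of view
#' containing a circular or blob-shaped tumor whose invasive margin drives a
#' marked inhomogeneous Poisson process. For marker `m` the intensity at a
#' point `p` is
#' `max(0, lambda_base(m, side(p)) + gradient_slope(m) * d(p))`
#' where `d(p)` is the signed distance to the margin (negative inside the
#' tumor) and `lambda_base` is `lambda_in` inside and `lambda_out` outside.
#'
#' @param field_width_um,field_height_um field-of-view size (micrometres).
#' @param margin_shape `"circle"` or `"blob"` (radial Fourier perturbation
#'   of a circle).
#' @param margin_radius_um base radius of the margin (micrometres).
#' @param lambda_in,lambda_out named per-marker base intensities in
#'   cells/mm^2 for markers CD8, CD163, NEG (missing markers default to 0).
#' @param gradient_slope named per-marker rate of intensity change, in
#'   (cells/mm^2) per micrometre of signed distance (default 0).
#' @param margin_center_um centre of the margin; defaults to the field
#'   centre.
#' @param blob_amplitude,blob_harmonics blob-shape parameters, see
#'   [blob_margin()].
#' @param seed integer RNG seed; the generator is deterministic given the
#'   config.
#' @return an object of class `scene_config`. A margin extending beyond the
#'   field is allowed but flagged (`clipped = TRUE`, with a warning at
#'   generation time).
#' @export
scene_config <- function(field_width_um = 2000, field_height_um = 2000,
                         margin_shape = c("circle", "blob"),
                         margin_radius_um = 600,
                         lambda_in = c(CD8 = 500, CD163 = 500, NEG = 1000),
                         lambda_out = lambda_in,
                         gradient_slope = c(CD8 = 0, CD163 = 0, NEG = 0),
                         margin_center_um = NULL,
                         blob_amplitude = 0.2, blob_harmonics = 4L,
                         seed = 1L) {
  margin_shape <- match.arg(margin_shape)
  check_number(field_width_um, "field_width_um", lower = .Machine$double.eps)
  check_number(field_height_um, "field_height_um", lower = .Machine$double.eps)
  check_number(margin_radius_um, "margin_radius_um", lower = .Machine$double.eps)
  fill <- function(v, name) {
    if (is.null(names(v)) && length(v) == 1L)
      v <- setNames(rep(v, 3L), MARKER_LEVELS)
    if (is.null(names(v)) || !all(names(v) %in% MARKER_LEVELS))
      stop(sprintf("`%s` must be named with markers among %s", name,
                   paste(MARKER_LEVELS, collapse = ", ")), call. = FALSE)
    out <- setNames(numeric(3L), MARKER_LEVELS)
    out[names(v)] <- v
    if (any(!is.finite(out)))
      stop(sprintf("`%s` must be finite", name), call. = FALSE)
    out
  }
  lambda_in <- fill(lambda_in, "lambda_in")
  lambda_out <- fill(lambda_out, "lambda_out")
  gradient_slope <- fill(gradient_slope, "gradient_slope")
  if (any(lambda_in < 0) || any(lambda_out < 0))
    stop("base intensities must be >= 0", call. = FALSE)
  if (is.null(margin_center_um))
    margin_center_um <- c(field_width_um, field_height_um) / 2
  max_amp <- if (margin_shape == "blob") 1 + blob_amplitude else 1
  clipped <-
    margin_center_um[1] - margin_radius_um * max_amp < 0 ||
    margin_center_um[2] - margin_radius_um * max_amp < 0 ||
    margin_center_um[1] + margin_radius_um * max_amp > field_width_um ||
    margin_center_um[2] + margin_radius_um * max_amp > field_height_um
  structure(list(field_width_um = field_width_um,
                 field_height_um = field_height_um,
                 margin_shape = margin_shape,
                 margin_radius_um = margin_radius_um,
                 margin_center_um = margin_center_um,
                 lambda_in = lambda_in, lambda_out = lambda_out,
                 gradient_slope = gradient_slope,
                 blob_amplitude = blob_amplitude,
                 blob_harmonics = as.integer(blob_harmonics),
                 clipped = clipped, seed = as.integer(seed)),
            class = "scene_config")
}

#' Simulate a tissue scene
#'
#' Samples CD8, CD163 and marker-negative cells from independent
#' inhomogeneous Poisson processes whose intensity depends linearly on the
#' signed distance to the invasive margin (clamped at 0 where the linear
#' law goes negative), by thinning a homogeneous dominating process.
#' Deterministic given `config$seed`.
#'
#' @param config a [scene_config()].
#' @return an object of class `scene`: list with `geometry`
#'   ([tumor_geometry()]), `cells` (data.frame `x_um`, `y_um`, `marker`,
#'   `source`), and `config`.
#' @export
generate_tissue_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  w <- config$field_width_um; h <- config$field_height_um
  bounds <- c(0, 0, w, h)
  if (config$clipped)
    warning("margin extends beyond the field of view and is clipped",
            call. = FALSE)
  with_seed(config$seed, {
    ring <- switch(config$margin_shape,
      circle = circle_margin(config$margin_center_um, config$margin_radius_um),
      blob = blob_margin(config$margin_center_um, config$margin_radius_um,
                         n_harmonics = config$blob_harmonics,
                         amplitude = config$blob_amplitude, seed = NULL))
    if (config$clipped) ring <- clip_ring_rect(ring, bounds)
    if (nrow(ring) < 3L)
      stop("margin polygon collapsed after clipping to the field",
           call. = FALSE)
    geometry <- tumor_geometry(ring, bounds, validate = FALSE)
    diag_um <- sqrt(w^2 + h^2)
    cells <- do.call(rbind, lapply(MARKER_LEVELS, function(m) {
      lam_max <- max(config$lambda_in[m], config$lambda_out[m]) +
        abs(config$gradient_slope[m]) * diag_um   # dominating intensity
      if (lam_max <= 0) return(NULL)
      n_cand <- rpois(1L, lam_max * w * h / 1e6)
      if (n_cand == 0L) return(NULL)
      x <- runif(n_cand, 0, w); y <- runif(n_cand, 0, h)
      u <- runif(n_cand)
      d <- cpp_signed_distance(x, y, geometry$rings)
      base <- ifelse(d <= 0, config$lambda_in[m], config$lambda_out[m])
      lam <- pmax(0, base + config$gradient_slope[m] * d)
      keep <- u < lam / lam_max
      if (!any(keep)) return(NULL)
      data.frame(x_um = x[keep], y_um = y[keep], marker = m,
                 source = "simulated", stringsAsFactors = FALSE)
    }))
    if (is.null(cells))
      cells <- data.frame(x_um = numeric(0), y_um = numeric(0),
                          marker = character(0), source = character(0),
                          stringsAsFactors = FALSE)
    rownames(cells) <- NULL
    structure(list(geometry = geometry, cells = cells, config = config),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  tab <- table(factor(x$cells$marker, levels = MARKER_LEVELS))
  cat(sprintf("<scene> %g x %g um field, %s margin (r = %g um)%s\n",
              x$config$field_width_um, x$config$field_height_um,
              x$config$margin_shape, x$config$margin_radius_um,
              if (x$config$clipped) " [clipped]" else ""))
  cat("  cells:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}
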