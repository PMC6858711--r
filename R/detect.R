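#' Pixel-classification parameters
#'
#' Thresholds of the RGB channel-dominance classifier. A pixel is
#' `red_positive` when `R - max(G, B) > red_dominance_threshold` (fast-red
#' chromogen), else `blue_nucleus` when `B - max(R, G) >
#' blue_dominance_threshold` (hematoxylin); remaining pixels are
#' `background`, except that non-dominant pixels darker than
#' `background_luminance_min` are treated as nuclear material (dense
#' hematoxylin clumps lose channel dominance but are not background).
#' `min_cell_area_um2`/`max_cell_area_um2` bound the connected-component
#' area accepted as one cell (default 20-400 um^2, the typical
#' lymphocyte-macrophage range).
#'
#' @param red_dominance_threshold,blue_dominance_threshold dominance margins
#'   on the 0-255 intensity scale.
#' @param background_luminance_min luminance floor (0-255) below which a
#'   non-dominant pixel is not background.
#' @param min_cell_area_um2,max_cell_area_um2 component-area filter (um^2).
#' @return a `pixel_class_params` list.
#' @export
pixel_class_params <- function(red_dominance_threshold = 40,
                               blue_dominance_threshold = 40,
                               background_luminance_min = 120,
                               min_cell_area_um2 = 20,
                               max_cell_area_um2 = 400) {
  check_number(red_dominance_threshold, "red_dominance_threshold",
               lower = .Machine$double.eps)
  check_number(blue_dominance_threshold, "blue_dominance_threshold",
               lower = .Machine$double.eps)
  check_number(background_luminance_min, "background_luminance_min",
               lower = 0, upper = 255)
  check_number(min_cell_area_um2, "min_cell_area_um2", lower = 0)
  check_number(max_cell_area_um2, "max_cell_area_um2", lower = 0)
  if (min_cell_area_um2 >= max_cell_area_um2)
    stop("`min_cell_area_um2` must be < `max_cell_area_um2`", call. = FALSE)
  structure(list(red_dominance_threshold = red_dominance_threshold,
                 blue_dominance_threshold = blue_dominance_threshold,
                 background_luminance_min = background_luminance_min,
                 min_cell_area_um2 = min_cell_area_um2,
                 max_cell_area_um2 = max_cell_area_um2),
            class = "pixel_class_params")
}

#' Classify pixels of an RGB stain image
#'
#' Assigns every pixel exactly one label -- `red_positive` (1),
#' `blue_nucleus` (2) or `background` (0) -- by the channel-dominance rules
#' of [pixel_class_params()].
#'
#' @param image an `ihc_image` or a H x W x 3 array of 0-255 intensities.
#' @param um_per_pixel scale; taken from the `ihc_image` when omitted.
#' @param params a [pixel_class_params()].
#' @return integer H x W matrix of class `pixel_mask` (0 = background,
#'   1 = red_positive, 2 = blue_nucleus) with attribute `um_per_pixel`.
#' @export
classify_pixels <- function(image, um_per_pixel = NULL,
                            params = pixel_class_params()) {
  if (inherits(image, "ihc_image")) {
    if (is.null(um_per_pixel)) um_per_pixel <- image$um_per_pixel
    image <- image$img
  }
  if (is.null(um_per_pixel))
    stop("`um_per_pixel` is required for a bare array", call. = FALSE)
  check_number(um_per_pixel, "um_per_pixel", lower = .Machine$double.eps)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be a 3-channel RGB array", call. = FALSE)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  red <- R - pmax(G, B) > params$red_dominance_threshold
  blue <- !red & (B - pmax(R, G) > params$blue_dominance_threshold)
  lum <- (R + G + B) / 3
  dark <- !red & !blue & lum < params$background_luminance_min
  mask <- matrix(0L, nrow(R), ncol(R))
  mask[red] <- 1L
  mask[blue | dark] <- 2L
  structure(mask, um_per_pixel = um_per_pixel, class = "pixel_mask")
}

#' Detect cells from a labeled pixel mask
#'
#' Extracts connected components (8-connectivity) of the `red_positive` and
#' `blue_nucleus` labels, filters them by physical area, and emits centroid
#' cell records in micrometres. One stain per slide: red components receive
#' the slide's `marker`; blue components are marker-negative (`NEG`).
#'
#' @param mask a [classify_pixels()] result.
#' @param um_per_pixel scale; taken from the mask attribute when omitted.
#' @param params a [pixel_class_params()] (area filter).
#' @param marker the slide's stain, `"CD8"` or `"CD163"`.
#' @return cell table (`x_um`, `y_um`, `marker`, `source = "detected"`).
#' @export
detect_cells <- function(mask, um_per_pixel = NULL,
                         params = pixel_class_params(),
                         marker = c("CD8", "CD163")) {
  marker <- match.arg(marker)
  if (is.null(um_per_pixel)) um_per_pixel <- attr(mask, "um_per_pixel")
  check_number(um_per_pixel, "um_per_pixel", lower = .Machine$double.eps)
  m <- unclass(mask)
  comp_centroids <- function(binary, label) {
    if (!any(binary)) return(NULL)
    lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
    lab <- EBImage::imageData(lab)
    idx <- which(lab > 0)
    if (!length(idx)) return(NULL)
    id <- lab[idx]
    npx <- tabulate(id)
    area_um2 <- npx * um_per_pixel^2
    keep <- area_um2 >= params$min_cell_area_um2 &
      area_um2 <= params$max_cell_area_um2
    if (!any(keep)) return(NULL)
    # EBImage images are x-major: dim 1 is x (column), dim 2 is y (row)
    xs <- (idx - 1L) %% nrow(lab) + 1L
    ys <- (idx - 1L) %/% nrow(lab) + 1L
    cx <- rowsum(as.numeric(xs), id)[, 1] / npx
    cy <- rowsum(as.numeric(ys), id)[, 1] / npx
    data.frame(x_um = (cx[keep] - 0.5) * um_per_pixel,
               y_um = (cy[keep] - 0.5) * um_per_pixel,
               marker = label, source = "detected",
               stringsAsFactors = FALSE)
  }
  # mask is row-major (H x W); transpose into EBImage's x-major layout
  red <- comp_centroids(t(m == 1L), marker)
  blue <- comp_centroids(t(m == 2L), "NEG")
  out <- rbind(red, blue)
  if (is.null(out))
    out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      marker = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' High-power field specification
#'
#' Defaults follow the five-field read-out: `n_fields = 5` square fields of
#' `field_area_mm2 = 1e-3` (31.6 um side). `hotspot` placement greedily
#' maximises the positive-cell count per field on a 10 um candidate grid
#' (ties broken by smallest (x, y)), without overlap, mimicking the
#' pathologist's choice of densest areas; `random` and `grid` placements
#' are available for unbiased sampling.
#'
#' @param n_fields number of fields (>= 1).
#' @param field_area_mm2 area of each square field (mm^2).
#' @param placement `"hotspot"`, `"random"` or `"grid"`.
#' @param seed RNG seed for random placement.
#' @return a `field_spec` list.
#' @export
field_spec <- function(n_fields = 5L, field_area_mm2 = 1e-3,
                       placement = c("hotspot", "random", "grid"),
                       seed = NULL) {
  placement <- match.arg(placement)
  if (n_fields < 1L) stop("`n_fields` must be >= 1", call. = FALSE)
  check_number(field_area_mm2, "field_area_mm2", lower = .Machine$double.eps)
  structure(list(n_fields = as.integer(n_fields),
                 field_area_mm2 = field_area_mm2, placement = placement,
                 seed = seed), class = "field_spec")
}

#' Field densitometry
#'
#' Places `spec$n_fields` non-overlapping square high-power fields inside a
#' region, counts positive cells (marker != NEG) per field, and reports the
#' density as `mean(count) / field_area_mm2` -- the mean-of-fields read-out
#' in cells/mm^2.
#'
#' @param cells a cell table.
#' @param region a [tumor_geometry()], a single polygon matrix, or a
#'   rectangle `c(xmin, ymin, xmax, ymax)` (micrometres). A candidate field
#'   is admissible when all four corners lie in the region.
#' @param spec a [field_spec()].
#' @param grid_step_um candidate-grid pitch for placement (micrometres).
#' @return list with `density_per_mm2`, `counts` (per field), and `fields`
#'   (data.frame of field corners `x0`, `y0` and `side_um`).
#' @export
field_density <- function(cells, region, spec = field_spec(),
                          grid_step_um = 10) {
  cells <- as_cell_table(cells)
  side <- sqrt(spec$field_area_mm2 * 1e6)
  if (inherits(region, "tumor_geometry")) {
    rings <- region$rings
    bbox <- region$field_bounds
  } else if (is.matrix(region)) {
    rings <- list(region)
    bbox <- c(min(region[, 1]), min(region[, 2]),
              max(region[, 1]), max(region[, 2]))
  } else {
    stopifnot(is.numeric(region), length(region) == 4L)
    rings <- NULL
    bbox <- region
  }
  if (bbox[3] - bbox[1] < side || bbox[4] - bbox[2] < side)
    stop("region too small for the requested fields", call. = FALSE)
  x0s <- seq(bbox[1], bbox[3] - side, by = grid_step_um)
  y0s <- seq(bbox[2], bbox[4] - side, by = grid_step_um)
  cand <- expand.grid(x0 = x0s, y0 = y0s, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(rings)) {
    corner_ok <- function(x, y) {
      d <- cpp_signed_distance(x, y, rings)
      d <= 0
    }
    ok <- corner_ok(cand$x0, cand$y0) &
      corner_ok(cand$x0 + side, cand$y0) &
      corner_ok(cand$x0, cand$y0 + side) &
      corner_ok(cand$x0 + side, cand$y0 + side)
    cand <- cand[ok, , drop = FALSE]
  }
  if (nrow(cand) < spec$n_fields)
    stop("region too small for the requested fields", call. = FALSE)
  pos <- cells[cells$marker != "NEG", , drop = FALSE]
  counts_for <- function(x0, y0)
    sum(pos$x_um >= x0 & pos$x_um <= x0 + side &
          pos$y_um >= y0 & pos$y_um <= y0 + side)
  cnt <- if (nrow(pos)) {
    # accumulate per-candidate counts cell-by-cell on the aligned grid
    v <- numeric(nrow(cand))
    key <- paste(cand$x0, cand$y0)
    lut <- seq_len(nrow(cand)); names(lut) <- key
    for (i in seq_len(nrow(pos))) {
      cxs <- x0s[x0s >= pos$x_um[i] - side & x0s <= pos$x_um[i]]
      cys <- y0s[y0s >= pos$y_um[i] - side & y0s <= pos$y_um[i]]
      if (!length(cxs) || !length(cys)) next
      k <- paste(rep(cxs, times = length(cys)), rep(cys, each = length(cxs)))
      hit <- lut[k[k %in% key]]
      v[hit] <- v[hit] + 1
    }
    v
  } else numeric(nrow(cand))
  pick <- switch(spec$placement,
    hotspot = {
      chosen <- integer(0)
      avail <- rep(TRUE, nrow(cand))
      for (f in seq_len(spec$n_fields)) {
        if (!any(avail)) stop("could not place ", spec$n_fields,
                              " non-overlapping fields", call. = FALSE)
        o <- order(-cnt, cand$x0, cand$y0)
        o <- o[avail[o]]
        sel <- o[1]
        chosen <- c(chosen, sel)
        avail <- avail & !(abs(cand$x0 - cand$x0[sel]) < side &
                             abs(cand$y0 - cand$y0[sel]) < side)
      }
      chosen
    },
    random = with_seed(spec$seed, {
      chosen <- integer(0)
      avail <- rep(TRUE, nrow(cand))
      for (f in seq_len(spec$n_fields)) {
        if (!any(avail)) stop("could not place ", spec$n_fields,
                              " non-overlapping fields", call. = FALSE)
        sel <- sample(which(avail), 1L)
        chosen <- c(chosen, sel)
        avail <- avail & !(abs(cand$x0 - cand$x0[sel]) < side &
                             abs(cand$y0 - cand$y0[sel]) < side)
      }
      chosen
    }),
    grid = {
      idx <- unique(round(seq(1, nrow(cand), length.out = spec$n_fields)))
      if (length(idx) < spec$n_fields)
        stop("region too small for grid placement", call. = FALSE)
      idx
    })
  fields <- data.frame(x0 = cand$x0[pick], y0 = cand$y0[pick], side_um = side)
  counts <- vapply(seq_len(nrow(fields)), function(i)
    counts_for(fields$x0[i], fields$y0[i]), 0)
  list(density_per_mm2 = mean(counts) / spec$field_area_mm2,
       counts = counts, fields = fields)
}
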