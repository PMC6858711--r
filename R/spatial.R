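#' Signed distance to the invasive margin
#'
#' Euclidean distance from each cell to the nearest point of the margin,
#' negative inside the tumor (even-odd rule over all rings, so holes count
#' as host tissue), positive outside, 0 on the boundary. Cells outside the
#' field of view trigger a warning but still get a distance.
#'
#' @param cells a cell table (`x_um`, `y_um`, `marker`) or an n x 2 matrix
#'   of coordinates in micrometres.
#' @param geometry a [tumor_geometry()].
#' @return numeric vector of signed distances in micrometres.
#' @export
signed_distance <- function(cells, geometry) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  xy <- if (is.matrix(cells)) cells else {
    cells <- as_cell_table(cells)
    cbind(cells$x_um, cells$y_um)
  }
  if (!nrow(xy)) return(numeric(0))
  b <- geometry$field_bounds
  out_fov <- xy[, 1] < b[1] | xy[, 1] > b[3] | xy[, 2] < b[2] | xy[, 2] > b[4]
  if (any(out_fov))
    warning(sum(out_fov), " cell(s) outside the field of view; ",
            "distances computed anyway", call. = FALSE)
  cpp_signed_distance(xy[, 1], xy[, 2], geometry$rings)
}

#' Compartment assignment relative to the margin
#'
#' Intratumoral: signed distance `d <= -inside_fraction * extent` (with the
#' default `inside_fraction = 0`, all of `d <= 0`); peritumoral: the band of
#' width `peritumoral_extent_um` adjacent to the margin, by default entirely
#' on the host-tissue side, `0 < d <= 500`; outside: beyond the peritumoral
#' band. `inside_fraction` shifts part of the peritumoral band to the tumor
#' side for readings of "centered on the border".
#'
#' @inheritParams signed_distance
#' @param peritumoral_extent_um width of the peritumoral band (micrometres).
#' @param inside_fraction fraction of the band lying inside the margin.
#' @return factor with levels intratumoral, peritumoral, outside.
#' @export
assign_compartment <- function(cells, geometry, peritumoral_extent_um = 500,
                               inside_fraction = 0) {
  check_number(peritumoral_extent_um, "peritumoral_extent_um",
               lower = .Machine$double.eps)
  check_number(inside_fraction, "inside_fraction", lower = 0, upper = 1)
  d <- if (is.numeric(cells) && !is.matrix(cells)) cells
       else signed_distance(cells, geometry)
  lo <- -inside_fraction * peritumoral_extent_um
  hi <- (1 - inside_fraction) * peritumoral_extent_um
  lab <- ifelse(d <= lo, "intratumoral",
                ifelse(d <= hi, "peritumoral", "outside"))
  factor(lab, levels = c("intratumoral", "peritumoral", "outside"))
}

#' Area of a distance band
#'
#' Area (mm^2) of the region whose signed distance to the margin lies in
#' `(d_lo, d_hi]`, intersected with the field of view. Computed by adaptive
#' quadtree integration of the signed-distance field: cells provably inside
#' or outside the band (the distance field is 1-Lipschitz) are resolved
#' wholesale, boundary cells are subdivided to `min_cell_um` and finished
#' with an exact linear-cut area using the corner distances. An eroded band
#' that has collapsed (e.g. deeper than the inscribed radius) has area 0 and
#' is flagged degenerate.
#'
#' @param geometry a [tumor_geometry()].
#' @param d_lo,d_hi band edges in micrometres, `d_lo < d_hi`; `d_lo` may be
#'   `-Inf` (whole tumor interior).
#' @param min_cell_um finest quadtree cell size (micrometres).
#' @return area in mm^2, with attribute `degenerate` (TRUE when the band
#'   has collapsed to zero area).
#' @export
band_area <- function(geometry, d_lo, d_hi, min_cell_um = 1) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  if (!is.numeric(d_lo) || !is.numeric(d_hi) || d_lo >= d_hi)
    stop("`d_lo` must be < `d_hi`", call. = FALSE)
  a <- cpp_band_areas(geometry$rings, geometry$field_bounds,
                      c(d_lo, d_hi), min_cell_um)[1] / 1e6
  a <- max(a, 0)
  structure(a, degenerate = a <= 0)
}

#' Distance-class density histogram
#'
#' Bins cells into consecutive distance classes of width `band_width_um`
#' within `extent_um` of the invasive margin (negative = inside tumor) and
#' normalises counts by band area to densities in cells/mm^2. Bands are
#' half-open `(lo, hi]`; cells farther than `extent_um` from the margin are
#' excluded and reported.
#'
#' @inheritParams signed_distance
#' @param band_width_um distance-class width (micrometres, default 20).
#' @param extent_um histogram half-extent (micrometres, default 100); must
#'   be a multiple of `band_width_um`.
#' @param markers marker labels to tabulate.
#' @param min_cell_um quadtree resolution passed to [band_area()].
#' @return a `distance_profile`: data.frame with columns `band_lo_um`,
#'   `band_hi_um`, `marker`, `count`, `area_mm2`, `density_per_mm2`,
#'   `degenerate`, plus attributes `band_edges_um` and `excluded` (number of
#'   cells beyond the extent).
#' @export
band_histogram <- function(cells, geometry, band_width_um = 20,
                           extent_um = 100, markers = c("CD8", "CD163"),
                           min_cell_um = 1) {
  check_number(band_width_um, "band_width_um", lower = .Machine$double.eps)
  check_number(extent_um, "extent_um", lower = band_width_um)
  if (abs(extent_um / band_width_um - round(extent_um / band_width_um)) > 1e-9)
    stop("`extent_um` must be a multiple of `band_width_um`", call. = FALSE)
  cells <- as_cell_table(cells)
  d <- signed_distance(cells, geometry)
  edges <- seq(-extent_um, extent_um, by = band_width_um)
  nb <- length(edges) - 1L
  areas <- pmax(cpp_band_areas(geometry$rings, geometry$field_bounds,
                               edges, min_cell_um), 0) / 1e6
  if (all(areas <= 0))
    stop("all distance bands are degenerate for this geometry", call. = FALSE)
  inside <- d > edges[1] & d <= edges[nb + 1L]
  excluded <- sum(!inside)
  bin <- findInterval(d[inside], edges, left.open = TRUE, rightmost.closed = FALSE)
  mk <- factor(cells$marker[inside], levels = markers)
  tab <- table(factor(bin, levels = seq_len(nb)), mk)
  prof <- do.call(rbind, lapply(markers, function(m) {
    cnt <- as.integer(tab[, m])
    data.frame(band_lo_um = edges[-(nb + 1L)], band_hi_um = edges[-1L],
               marker = m, count = cnt, area_mm2 = areas,
               density_per_mm2 = ifelse(areas > 0, cnt / areas, NA_real_),
               degenerate = areas <= 0, stringsAsFactors = FALSE)
  }))
  structure(prof, band_edges_um = edges, excluded = excluded,
            class = c("distance_profile", "data.frame"))
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d bands x %d marker(s), %d cell(s) beyond extent\n",
              length(attr(x, "band_edges_um")) - 1L,
              length(unique(x$marker)), attr(x, "excluded")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a distance-class histogram
#'
#' Bar plot of per-band density, tumor side (negative distances) in green,
#' host side in orange, with the margin marked by a dashed red line.
#'
#' @param x a `distance_profile`.
#' @param marker which marker to plot.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_distance_profile <- function(x, marker = x$marker[1], ...) {
  stopifnot(inherits(x, "distance_profile"))
  p <- x[x$marker == marker, ]
  mid <- (p$band_lo_um + p$band_hi_um) / 2
  cols <- ifelse(mid < 0, "#2E8B57", "#E69F00")
  bp <- barplot(p$density_per_mm2, col = cols, border = NA,
                names.arg = sprintf("%g", p$band_hi_um),
                xlab = "distance to invasive margin (um)",
                ylab = "density (cells/mm^2)", main = marker, ...)
  abline(v = mean(bp[which(p$band_hi_um == 0) + 0:1]), lty = 2, col = "red")
  invisible(bp)
}

#' Compartment densities and positive-cell fractions
#'
#' Per-marker density (cells/mm^2) and positive-cell fraction (% of all
#' cells in the compartment) for the intratumoral and peritumoral
#' compartments.
#'
#' @inheritParams assign_compartment
#' @param markers positive markers to report (NEG enters denominators only).
#' @param min_cell_um quadtree resolution for the compartment areas.
#' @return data.frame with columns `marker`, `compartment`, `count`,
#'   `total_cells`, `area_mm2`, `density_per_mm2`, `positive_fraction_pct`.
#' @export
compartment_densities <- function(cells, geometry, peritumoral_extent_um = 500,
                                  inside_fraction = 0,
                                  markers = c("CD8", "CD163"),
                                  min_cell_um = 1) {
  cells <- as_cell_table(cells)
  comp <- assign_compartment(cells, geometry, peritumoral_extent_um,
                             inside_fraction)
  lo <- -inside_fraction * peritumoral_extent_um
  hi <- (1 - inside_fraction) * peritumoral_extent_um
  ar <- pmax(cpp_band_areas(geometry$rings, geometry$field_bounds,
                            c(-Inf, lo, hi), min_cell_um), 0) / 1e6
  a_it <- ar[1]; a_pt <- ar[2]
  if (a_it <= 0 || a_pt <= 0)
    stop("zero-area compartment for this geometry/field", call. = FALSE)
  areas <- c(intratumoral = a_it, peritumoral = a_pt)
  out <- do.call(rbind, lapply(c("intratumoral", "peritumoral"), function(cp) {
    in_cp <- comp == cp
    tot <- sum(in_cp)
    do.call(rbind, lapply(markers, function(m) {
      cnt <- sum(in_cp & cells$marker == m)
      data.frame(marker = m, compartment = cp, count = cnt, total_cells = tot,
                 area_mm2 = areas[[cp]], density_per_mm2 = cnt / areas[[cp]],
                 positive_fraction_pct = if (tot > 0) 100 * cnt / tot else 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
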