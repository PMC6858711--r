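#' Tumor-margin geometry
#'
#' Container for the invasive tumor margin: one or more simple polygons in
#' micrometre coordinates (image convention: origin top-left, x right,
#' y down), together with the rectangular field of view. The outer boundary
#' of each polygon is the invasive margin; a ring nested inside another is
#' treated as a hole, i.e. host tissue (even-odd rule).
#'
#' @param polygons a single n x 2 matrix, or a list of such matrices, of
#'   polygon vertices in micrometres (first vertex not repeated at the end).
#' @param field_bounds numeric `c(xmin, ymin, xmax, ymax)` in micrometres;
#'   defaults to the bounding box of the polygons.
#' @param validate check that every ring is a simple (non-self-intersecting)
#'   polygon. Skipped by the internal generators, whose star-shaped margins
#'   are simple by construction.
#' @return an object of class `tumor_geometry` with elements `rings`
#'   (list of matrices) and `field_bounds`.
#' @export
tumor_geometry <- function(polygons, field_bounds = NULL, validate = TRUE) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  if (!length(polygons)) stop("at least one polygon is required", call. = FALSE)
  rings <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p)))
      stop("each polygon must be a finite n x 2 matrix with n >= 3",
           call. = FALSE)
    # drop a duplicated closing vertex if present
    if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    dimnames(p) <- NULL
    p
  })
  if (validate) {
    for (r in rings)
      if (!is_simple_polygon(r))
        stop("polygon is not simple (self-intersecting)", call. = FALSE)
  }
  allv <- do.call(rbind, rings)
  bbox <- c(min(allv[, 1]), min(allv[, 2]), max(allv[, 1]), max(allv[, 2]))
  if (is.null(field_bounds)) field_bounds <- bbox
  field_bounds <- as.numeric(field_bounds)
  if (length(field_bounds) != 4L || field_bounds[1] >= field_bounds[3] ||
      field_bounds[2] >= field_bounds[4])
    stop("`field_bounds` must be c(xmin, ymin, xmax, ymax) with positive extent",
         call. = FALSE)
  tol <- 1e-9 + 1e-9 * max(abs(field_bounds))
  if (bbox[1] < field_bounds[1] - tol || bbox[2] < field_bounds[2] - tol ||
      bbox[3] > field_bounds[3] + tol || bbox[4] > field_bounds[4] + tol)
    stop("polygons extend beyond `field_bounds`", call. = FALSE)
  structure(list(rings = rings, field_bounds = field_bounds),
            class = "tumor_geometry")
}

#' @export
print.tumor_geometry <- function(x, ...) {
  cat(sprintf("<tumor_geometry> %d ring(s), %d vertices, area %.4f mm^2\n",
              length(x$rings), sum(vapply(x$rings, nrow, 1L)),
              geometry_area_mm2(x)))
  b <- x$field_bounds
  cat(sprintf("  field: [%g, %g] x [%g, %g] um\n", b[1], b[3], b[2], b[4]))
  invisible(x)
}

# Shoelace signed area of one ring (um^2); positive for counter-clockwise in
# a y-up frame (sign is irrelevant to callers, which take abs()).
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area of a margin geometry
#'
#' Even-odd area of the tumor region in mm^2: rings nested inside another
#' ring subtract (holes are host tissue).
#'
#' @param geometry a [tumor_geometry()].
#' @return area in mm^2.
#' @export
geometry_area_mm2 <- function(geometry) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  rings <- geometry$rings
  depth <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1L, ]
    sum(vapply(seq_along(rings), function(j) {
      j != i && point_in_ring(p[1], p[2], rings[[j]])
    }, logical(1)))
  }, integer(1))
  sum(ifelse(depth %% 2L == 0L, 1, -1) *
        vapply(rings, function(r) abs(ring_signed_area(r)), 0)) / 1e6
}

# Even-odd test for a single point against one ring.
point_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- ring[c(2:n, 1), 1]; y2 <- ring[c(2:n, 1), 2]
  cross <- (y1 > y) != (y2 > y)
  if (!any(cross)) return(FALSE)
  xint <- x1[cross] + (y - y1[cross]) / (y2[cross] - y1[cross]) *
    (x2[cross] - x1[cross])
  sum(xint > x) %% 2L == 1L
}

# O(n^2) simplicity check: no two non-adjacent edges intersect.
is_simple_polygon <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  nx <- c(2:n, 1)
  x2 <- ring[nx, 1]; y2 <- ring[nx, 2]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  if (!nrow(idx)) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d1 <- orient(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
  d2 <- orient(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- orient(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
  d4 <- orient(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' Circular and blob invasive margins
#'
#' `circle_margin()` returns a regular polygon approximating a circle.
#' `blob_margin()` perturbs the radius with a low-order random Fourier
#' series, `r(theta) = R (1 + sum_k a_k cos(k theta + phi_k))`, keeping the
#' total amplitude bounded so the curve stays star-shaped (hence simple).
#'
#' @param center numeric length 2, centre in micrometres.
#' @param radius_um base radius in micrometres.
#' @param n_vertices number of polygon vertices.
#' @param n_harmonics number of Fourier harmonics (orders 2..n_harmonics+1).
#' @param amplitude total relative radial perturbation (bounded by 0.45).
#' @param seed RNG seed for the harmonic amplitudes/phases.
#' @return an n x 2 vertex matrix (micrometres).
#' @export
circle_margin <- function(center, radius_um, n_vertices = 512L) {
  check_number(radius_um, "radius_um", lower = .Machine$double.eps)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + radius_um * cos(th), center[2] + radius_um * sin(th))
}

#' @rdname circle_margin
#' @export
blob_margin <- function(center, radius_um, n_harmonics = 4L, amplitude = 0.2,
                        n_vertices = 512L, seed = NULL) {
  check_number(radius_um, "radius_um", lower = .Machine$double.eps)
  check_number(amplitude, "amplitude", lower = 0, upper = 0.45)
  with_seed(seed, {
    k <- seq_len(n_harmonics) + 1L
    a <- runif(n_harmonics)
    a <- a / sum(a) * amplitude
    phi <- runif(n_harmonics, 0, 2 * pi)
    th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    r <- radius_um * (1 + colSums(a * cos(outer(k, th) + phi)))
    cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  })
}

# Sutherland-Hodgman clip of one ring against an axis-aligned rectangle.
clip_ring_rect <- function(ring, bounds) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (!n) return(pts)
    out <- vector("list", 2L * n)
    m <- 0L
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1L) n else i - 1L, ]
      cin <- keep(cur); pin <- keep(prv)
      if (cin) {
        if (!pin) { m <- m + 1L; out[[m]] <- intersect(prv, cur) }
        m <- m + 1L; out[[m]] <- cur
      } else if (pin) {
        m <- m + 1L; out[[m]] <- intersect(prv, cur)
      }
    }
    if (!m) return(ring[0, , drop = FALSE])
    do.call(rbind, out[seq_len(m)])
  }
  ix <- function(p, q, val, ax) {
    t <- (val - p[ax]) / (q[ax] - p[ax])
    p + t * (q - p)
  }
  pts <- ring
  pts <- clip_edge(pts, function(p) p[1] >= bounds[1],
                   function(p, q) ix(p, q, bounds[1], 1))
  pts <- clip_edge(pts, function(p) p[1] <= bounds[3],
                   function(p, q) ix(p, q, bounds[3], 1))
  pts <- clip_edge(pts, function(p) p[2] >= bounds[2],
                   function(p, q) ix(p, q, bounds[2], 2))
  pts <- clip_edge(pts, function(p) p[2] <= bounds[4],
                   function(p, q) ix(p, q, bounds[4], 2))
  if (nrow(pts)) pts[!duplicated(round(pts, 9)), , drop = FALSE] else pts
}
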