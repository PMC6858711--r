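# Shared fixtures and independent oracles, built in code at test time.

circle_geom <- function(radius = 500, field = 2000, center = c(field, field) / 2,
                        n_vertices = 512L) {
  tumor_geometry(circle_margin(center, radius, n_vertices),
                 c(0, 0, field, field), validate = FALSE)
}

blob_geom <- function(seed, radius = 500, field = 2000, amplitude = 0.25) {
  tumor_geometry(blob_margin(c(field / 2, field / 2), radius,
                             amplitude = amplitude, seed = seed),
                 c(0, 0, field, field), validate = FALSE)
}

# n points interpolated along the closed polyline of a ring (oracle helper).
boundary_points <- function(ring, n) {
  seg <- rbind(ring, ring[1L, ])
  len <- sqrt(diff(seg[, 1])^2 + diff(seg[, 2])^2)
  cum <- c(0, cumsum(len))
  s <- seq(0, cum[length(cum)], length.out = n + 1L)[-(n + 1L)]
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(len))
  t <- (s - cum[i]) / len[i]
  cbind(seg[i, 1] + t * (seg[i + 1L, 1] - seg[i, 1]),
        seg[i, 2] + t * (seg[i + 1L, 2] - seg[i, 2]))
}

# Brute-force unsigned distance: minimum over densely sampled boundary points.
brute_force_distance <- function(pts, ring, n_boundary = 1e5) {
  bp <- boundary_points(ring, n_boundary)
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((bp[, 1] - pts[i, 1])^2 + (bp[, 2] - pts[i, 2])^2))
  }, 0)
}

# A scene-like object with hand-placed cells (for the renderer/detector).
manual_scene <- function(cells, field = 500) {
  list(cells = cells,
       config = list(field_width_um = field, field_height_um = field))
}

# Non-overlapping positive cells on a jittered grid.
grid_cells <- function(n, field = 500, spacing = 60, marker = "CD8",
                       jitter = 5, seed = 1) {
  g <- expand.grid(x = seq(spacing / 2, field - spacing / 2, by = spacing),
                   y = seq(spacing / 2, field - spacing / 2, by = spacing))
  stopifnot(nrow(g) >= n)
  g <- g[seq_len(n), ]
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(data.frame(x_um = g$x + runif(n, -jitter, jitter),
                        y_um = g$y + runif(n, -jitter, jitter),
                        marker = marker, stringsAsFactors = FALSE))
}

# Greedy nearest-neighbour matching of detected to true cells within tol.
match_cells <- function(det, truth, tol_um = 5) {
  if (!nrow(det) || !nrow(truth))
    return(list(matched = 0L, precision = 0, recall = 0, max_err = NA_real_))
  d2 <- outer(det$x_um, truth$x_um, "-")^2 + outer(det$y_um, truth$y_um, "-")^2
  matched <- 0L
  errs <- numeric(0)
  for (k in seq_len(min(nrow(det), nrow(truth)))) {
    m <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    if (sqrt(d2[m[1], m[2]]) > tol_um) break
    matched <- matched + 1L
    errs <- c(errs, sqrt(d2[m[1], m[2]]))
    d2[m[1], ] <- Inf
    d2[, m[2]] <- Inf
  }
  list(matched = matched, precision = matched / nrow(det),
       recall = matched / nrow(truth),
       max_err = if (length(errs)) max(errs) else NA_real_)
}
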