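#' Render a pseudo-IHC image of a scene
#'
#' Draws every cell as a hematoxylin-blue nucleus disk and overlays a
#' fast-red disk on CD8/CD163-positive cells (red chromogen on top, as in a
#' red-developed immunostain), on a light background, with optional
#' additive Gaussian pixel noise. Pixel (i, j) covers the square centred at
#' `((j - 0.5) * um_per_pixel, (i - 0.5) * um_per_pixel)` so detected
#' centroids are directly comparable across scales.
#'
#' @param scene a [generate_tissue_scene()] result, or any list with
#'   `cells` and `config` fields.
#' @param um_per_pixel image scale (micrometres per pixel).
#' @param nucleus_radius_um,positive_radius_um disk radii in micrometres.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   0-255 intensity scale (clamped to range after addition).
#' @param seed optional RNG seed for the noise.
#' @return an object of class `ihc_image`: list with `img` (H x W x 3 array
#'   of 0-255 intensities), `um_per_pixel`, `cells` (ground truth carried
#'   along), and `palette`.
#' @export
render_ihc_image <- function(scene, um_per_pixel = 0.5, nucleus_radius_um = 4,
                             positive_radius_um = 5, noise_sd = 0,
                             seed = NULL) {
  check_number(um_per_pixel, "um_per_pixel", lower = .Machine$double.eps)
  check_number(nucleus_radius_um, "nucleus_radius_um",
               lower = .Machine$double.eps)
  check_number(positive_radius_um, "positive_radius_um",
               lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (nucleus_radius_um / um_per_pixel < 1)
    stop("`um_per_pixel` too coarse: nucleus radius is below one pixel",
         call. = FALSE)
  cells <- as_cell_table(scene$cells)
  w_um <- scene$config$field_width_um
  h_um <- scene$config$field_height_um
  W <- ceiling(w_um / um_per_pixel)
  H <- ceiling(h_um / um_per_pixel)
  palette <- list(background = c(245, 243, 240),
                  nucleus = c(60, 70, 170),
                  fast_red = c(205, 60, 90))
  img <- array(rep(palette$background, each = H * W), dim = c(H, W, 3))
  disk_pixels <- function(cx, cy, r_um) {
    # linear indices of pixels whose centre lies within r of (cx, cy)
    jc <- cx / um_per_pixel + 0.5; ic <- cy / um_per_pixel + 0.5
    rp <- r_um / um_per_pixel
    j0 <- max(1L, floor(jc - rp)); j1 <- min(W, ceiling(jc + rp))
    i0 <- max(1L, floor(ic - rp)); i1 <- min(H, ceiling(ic + rp))
    if (j0 > j1 || i0 > i1) return(integer(0))
    jj <- j0:j1; ii <- i0:i1
    inside <- outer((ii - ic)^2, (jj - jc)^2, "+") <= rp^2
    idx <- which(inside, arr.ind = TRUE)
    (jj[idx[, 2]] - 1L) * H + ii[idx[, 1]]
  }
  paint <- function(img, lin, col) {
    if (!length(lin)) return(img)
    for (ch in 1:3) img[lin + (ch - 1L) * H * W] <- col[ch]
    img
  }
  if (nrow(cells)) {
    blue <- unlist(lapply(seq_len(nrow(cells)), function(i)
      disk_pixels(cells$x_um[i], cells$y_um[i], nucleus_radius_um)))
    img <- paint(img, unique(blue), palette$nucleus)
    pos <- which(cells$marker != "NEG")
    red <- unlist(lapply(pos, function(i)
      disk_pixels(cells$x_um[i], cells$y_um[i], positive_radius_um)))
    img <- paint(img, unique(red), palette$fast_red)
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, img + rnorm(length(img), 0, noise_sd))
    img <- pmin(pmax(img, 0), 255)
  }
  structure(list(img = img, um_per_pixel = um_per_pixel, cells = cells,
                 palette = palette), class = "ihc_image")
}

#' @export
print.ihc_image <- function(x, ...) {
  cat(sprintf("<ihc_image> %d x %d px at %g um/px, %d ground-truth cell(s)\n",
              dim(x$img)[1], dim(x$img)[2], x$um_per_pixel, nrow(x$cells)))
  invisible(x)
}

#' Write / read a rendered image with its scale sidecar
#'
#' Writes PNG or TIFF plus a JSON sidecar `{"um_per_pixel": ...}` at
#' `<path>.json`; `read_image()` reverses the operation.
#'
#' @param image an `ihc_image` or a H x W x 3 array of 0-255 intensities.
#' @param path output file; extension selects the format (.png or .tif(f)).
#' @return `write_image()` returns `path` invisibly; `read_image()` an
#'   `ihc_image` (without ground-truth cells).
#' @export
write_image <- function(image, path) {
  img <- if (inherits(image, "ihc_image")) image$img else image
  upp <- if (inherits(image, "ihc_image")) image$um_per_pixel else
    attr(image, "um_per_pixel")
  if (is.null(upp)) stop("image has no `um_per_pixel` scale", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- img / 255
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path)
  else stop("unsupported image format: .", ext, call. = FALSE)
  jsonlite::write_json(list(um_per_pixel = upp), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: .", ext, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing scale sidecar: ", sidecar, call. = FALSE)
  upp <- jsonlite::read_json(sidecar)$um_per_pixel
  structure(list(img = arr * 255, um_per_pixel = upp,
                 cells = as_cell_table(NULL), palette = NULL),
            class = "ihc_image")
}
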