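#' Construct an angiography image record
#'
#' Bundles one ultra-wide-field fluorescein angiography (UWF-FA) frame with
#' its gradable-retina mask, an optional capillary non-perfusion (CNP)
#' reference mask, and the per-image calibration (fovea centre and pixels per
#' disc diameter) needed to place the concentric grading grid.
#'
#' Matrices follow the usual R image convention: rows are the vertical (y)
#' axis, columns the horizontal (x) axis, and `fovea_xy` is `c(x, y)` in
#' 1-based pixel coordinates.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (raw frames) or on
#'   an arbitrary scale after normalization.
#' @param gradable_mask Logical (or 0/1) matrix, same shape as `pixels`,
#'   marking the gradable retina.
#' @param cnp_mask Optional logical matrix of CNP pixels; must be contained
#'   in `gradable_mask` (CNP is only defined within the gradable retina).
#' @param fovea_xy Numeric length-2 vector, fovea centre as `c(x, y)` pixels.
#' @param dd_pixels Pixels per disc diameter (DD), the grid's length unit.
#' @param image_id Character identifier.
#' @return An object of class `angio_image`.
#' @export
angio_image <- function(pixels, gradable_mask, cnp_mask = NULL,
                        fovea_xy, dd_pixels, image_id = "img") {
  stopifnot(is.matrix(pixels))
  gradable_mask <- as_mask(gradable_mask)
  check_that(identical(dim(pixels), dim(gradable_mask)), "gradable_mask",
             "shape must match `pixels`")
  if (!is.null(cnp_mask)) {
    cnp_mask <- as_mask(cnp_mask)
    check_that(identical(dim(pixels), dim(cnp_mask)), "cnp_mask",
               "shape must match `pixels`")
    check_that(!any(cnp_mask & !gradable_mask), "cnp_mask",
               "CNP pixels must lie inside the gradable mask")
  }
  check_that(length(fovea_xy) == 2 && all(is.finite(fovea_xy)), "fovea_xy",
             "must be two finite pixel coordinates c(x, y)")
  fx <- round(fovea_xy[1]); fy <- round(fovea_xy[2])
  check_that(fx >= 1 && fx <= ncol(pixels) && fy >= 1 && fy <= nrow(pixels) &&
               isTRUE(gradable_mask[fy, fx]), "fovea_xy",
             "fovea must lie inside the gradable mask")
  check_that(is.numeric(dd_pixels) && length(dd_pixels) == 1 && dd_pixels > 0,
             "dd_pixels", "must be a single positive number")
  structure(list(pixels = pixels, gradable_mask = gradable_mask,
                 cnp_mask = cnp_mask, fovea_xy = as.numeric(fovea_xy),
                 dd_pixels = as.numeric(dd_pixels),
                 image_id = as.character(image_id)),
            class = "angio_image")
}

as_mask <- function(m) {
  stopifnot(is.matrix(m))
  storage.mode(m) <- "logical"
  m
}

#' @export
print.angio_image <- function(x, ...) {
  d <- dim(x$pixels)
  gf <- mean(x$gradable_mask)
  cf <- if (is.null(x$cnp_mask)) NA_real_ else
    sum(x$cnp_mask) / max(1L, sum(x$gradable_mask))
  cat(sprintf("<angio_image> %s: %dx%d px, gradable %.1f%%, CNP %s, fovea (%.0f, %.0f), %.1f px/DD\n",
              x$image_id, d[1], d[2], 100 * gf,
              if (is.na(cf)) "n/a" else sprintf("%.1f%% of gradable", 100 * cf),
              x$fovea_xy[1], x$fovea_xy[2], x$dd_pixels))
  invisible(x)
}

#' Read and write angiography images and masks
#'
#' Intensity frames are stored losslessly as 16-bit grayscale TIFF; binary
#' masks as 8-bit PNG with values {0, 255}.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param path Output file path.
#' @name angio_io
#' @return `write_*` return `path` invisibly; `read_*` return a matrix.
#' @export
write_intensity_image <- function(pixels, path) {
  tiff::writeTIFF(clamp01(pixels), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname angio_io
#' @export
read_intensity_image <- function(path) {
  x <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' @rdname angio_io
#' @param mask Logical matrix.
#' @export
write_mask_image <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname angio_io
#' @export
read_mask_image <- function(path) {
  x <- read_intensity_image(path)
  x > 0.5
}

#' Load an angiography image from a dataset manifest row
#'
#' @param record One row of a manifest `data.frame` as written by
#'   [generate_dataset()] (columns `image_id`, `image_path`, `gradable_path`,
#'   `cnp_path`, `fovea_x`, `fovea_y`, `dd_pixels`).
#' @param dir Directory the manifest's relative paths are resolved against.
#' @return An [angio_image()].
#' @export
load_angio_image <- function(record, dir = ".") {
  px <- read_intensity_image(file.path(dir, record$image_path))
  gm <- read_mask_image(file.path(dir, record$gradable_path))
  cm <- if (!is.na(record$cnp_path) && nzchar(record$cnp_path))
    read_mask_image(file.path(dir, record$cnp_path)) else NULL
  angio_image(px, gm, cm, fovea_xy = c(record$fovea_x, record$fovea_y),
              dd_pixels = record$dd_pixels, image_id = record$image_id)
}
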