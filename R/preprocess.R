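#' Crop the central region and resize to the model input size
#'
#' Extracts the central `crop_side` x `crop_side` region and resizes it to
#' `out_side` x `out_side`. The intensity image is resampled bilinearly;
#' masks use nearest-neighbour so they stay binary. Fovea coordinates and
#' the pixels-per-disc-diameter calibration are rescaled accordingly.
#'
#' @param img An [angio_image()].
#' @param crop_side Side of the central crop in pixels (default 2000).
#' @param out_side Output side in pixels (default 448).
#' @return A resized [angio_image()].
#' @export
central_crop_resize <- function(img, crop_side = 2000L, out_side = 448L) {
  d <- dim(img$pixels)
  if (d[1] < crop_side || d[2] < crop_side) {
    stop(sprintf("image is %dx%d px; the central crop needs >= %d on both axes",
                 d[1], d[2], crop_side), call. = FALSE)
  }
  oy <- floor((d[1] - crop_side) / 2)
  ox <- floor((d[2] - crop_side) / 2)
  rows <- (oy + 1):(oy + crop_side)
  cols <- (ox + 1):(ox + crop_side)
  s <- out_side / crop_side
  rs <- function(m, filter) {
    if (crop_side == out_side) return(m)
    EBImage::imageData(EBImage::resize(EBImage::Image(m), w = out_side,
                                       h = out_side, filter = filter))
  }
  px <- rs(img$pixels[rows, cols], "bilinear")
  gm <- rs(img$gradable_mask[rows, cols] * 1, "none") > 0.5
  cm <- if (is.null(img$cnp_mask)) NULL else
    rs(img$cnp_mask[rows, cols] * 1, "none") > 0.5
  new_angio_image(px, gm, cm,
                  fovea_xy = (img$fovea_xy - c(ox, oy)) * s,
                  dd_pixels = img$dd_pixels * s, image_id = img$image_id)
}

# unvalidated constructor for pipeline intermediates (augmented crops can
# push the fovea out of frame, which the validating constructor rejects)
new_angio_image <- function(pixels, gradable_mask, cnp_mask, fovea_xy,
                            dd_pixels, image_id) {
  structure(list(pixels = pixels, gradable_mask = gradable_mask,
                 cnp_mask = cnp_mask, fovea_xy = as.numeric(fovea_xy),
                 dd_pixels = as.numeric(dd_pixels),
                 image_id = as.character(image_id)),
            class = "angio_image")
}

#' Normalize pixel intensities to mean 0.5 and standard deviation 1.0
#'
#' Uses the population standard deviation over the full image (not only the
#' gradable region). A constant image has no defined scaling and is rejected.
#'
#' @param pixels Numeric intensity matrix with at least two distinct values.
#' @return Matrix with mean 0.5 and (population) standard deviation 1.0.
#' @export
normalize_image <- function(pixels) {
  m <- mean(pixels)
  s <- sqrt(mean((pixels - m)^2))
  if (!is.finite(s) || s == 0) {
    stop("constant image: standard deviation is zero, normalization undefined",
         call. = FALSE)
  }
  (pixels - m) / s + 0.5
}

#' Contrast shift about the image mean
#'
#' Maps every value `x` to `mu + gamma * (x - mu)` where `mu` is the mean of
#' the input grid; `gamma = 1` is the identity.
#'
#' @param pixels Numeric matrix.
#' @param gamma Contrast factor (training augmentation draws it uniformly
#'   from the configured range, by default `[0.8, 1.2]`).
#' @return Matrix of the same shape.
#' @export
contrast_shift <- function(pixels, gamma) {
  mu <- mean(pixels)
  mu + gamma * (pixels - mu)
}

#' Training-time augmentation configuration
#'
#' All random values are drawn from uniform distributions. Photometric
#' augmentations (contrast, brightness) apply only to the intensity image;
#' geometric augmentations (flips, shear/rotation, random crop) apply
#' identically to the image and its masks.
#'
#' @param gamma_range Contrast factor interval.
#' @param brightness_limit Brightness shift amplitude. The default
#'   ("additive") mode shifts intensities by `U(0, brightness_limit)` times
#'   the intensity range, with a random sign; the "multiplicative" mode
#'   applies the literal scaling by a random positive factor below the limit.
#' @param shear_range Interval for the two shear factors.
#' @param rotation_range Interval for the rotation angle, radians.
#' @param min_area_keep Minimum fraction of image area kept by the random
#'   crop (default 0.63).
#' @param max_axis_distortion Lowest allowed ratio between the crop's
#'   per-axis keep fractions (default 0.7), bounding aspect distortion.
#' @param brightness_mode `"additive"` or `"multiplicative"` (see above).
#' @param contrast,brightness,flip,shear,crop Logical switches enabling each
#'   augmentation.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(gamma_range = c(0.8, 1.2), brightness_limit = 0.1,
                           shear_range = c(-0.25, 0.25),
                           rotation_range = c(-0.25, 0.25),
                           min_area_keep = 0.63, max_axis_distortion = 0.7,
                           brightness_mode = c("additive", "multiplicative"),
                           contrast = TRUE, brightness = TRUE, flip = TRUE,
                           shear = TRUE, crop = TRUE) {
  check_that(all(gamma_range > 0), "gamma_range", "must be positive")
  check_that(min_area_keep > 0 && min_area_keep <= 1, "min_area_keep",
             "must be in (0, 1]")
  check_that(max_axis_distortion > 0 && max_axis_distortion <= 1,
             "max_axis_distortion", "must be in (0, 1]")
  structure(list(gamma_range = gamma_range,
                 brightness_limit = brightness_limit,
                 shear_range = shear_range, rotation_range = rotation_range,
                 min_area_keep = min_area_keep,
                 max_axis_distortion = max_axis_distortion,
                 brightness_mode = match.arg(brightness_mode),
                 contrast = contrast, brightness = brightness, flip = flip,
                 shear = shear, crop = crop),
            class = "augment_config")
}

# warp a matrix by the affine map out = A %*% (p - c) + c + t in (x, y)
# image coordinates (x = column, y = row); EBImage stores images with the
# first index horizontal, so the map is conjugated by the axis swap
warp_affine <- function(m, A, centre, t_xy = c(0, 0), filter = "bilinear",
                        bg = 0) {
  S <- matrix(c(0, 1, 1, 0), 2, 2)
  # EBImage indexes pixel centres at integer - 0.5; compensate so the map
  # is exactly out = A (p - centre) + centre + t in 1-based coordinates
  shift <- centre - A %*% centre + t_xy + (A - diag(2)) %*% c(0.5, 0.5)
  m_eb <- rbind(t(S %*% A %*% S), as.numeric(S %*% shift))
  EBImage::imageData(EBImage::affine(EBImage::Image(m), m_eb, filter = filter,
                                     bg.col = bg, antialias = FALSE))
}

#' Apply one random augmentation draw to an image
#'
#' Applies, in order: contrast shift, brightness shift, horizontal flip
#' (p = 0.5), vertical flip (p = 0.5), a shear-plus-rotation warp (bilinear
#' for the image, nearest-neighbour for masks; out-of-frame pixels are
#' filled with the image mean and marked non-gradable), and a random crop
#' keeping at least `min_area_keep` of the area, resized back to the input
#' size. Masks undergo the identical geometric transforms and no photometric
#' ones. Fully deterministic given `seed`.
#'
#' @param img An [angio_image()], already at the model input size.
#' @param cfg An [augment_config()].
#' @param seed Integer seed for this draw.
#' @return The augmented [angio_image()].
#' @export
augment_image <- function(img, cfg = augment_config(), seed = 1L) {
  with_seed(seed, {
    px <- img$pixels
    gm <- img$gradable_mask
    cm <- img$cnp_mask
    fov <- img$fovea_xy
    dd <- img$dd_pixels
    H <- nrow(px); W <- ncol(px)

    if (cfg$contrast) {
      px <- contrast_shift(px, runif(1, cfg$gamma_range[1], cfg$gamma_range[2]))
    }
    if (cfg$brightness) {
      if (cfg$brightness_mode == "additive") {
        delta <- runif(1, 0, cfg$brightness_limit) * diff(range(px))
        px <- px + sample(c(-1, 1), 1) * delta
      } else {
        px <- px * runif(1, 0, cfg$brightness_limit)
      }
    }
    if (cfg$flip) {
      if (runif(1) < 0.5) {                    # horizontal: mirror x
        px <- px[, W:1]; gm <- gm[, W:1]
        if (!is.null(cm)) cm <- cm[, W:1]
        fov[1] <- W + 1 - fov[1]
      }
      if (runif(1) < 0.5) {                    # vertical: mirror y
        px <- px[H:1, ]; gm <- gm[H:1, ]
        if (!is.null(cm)) cm <- cm[H:1, ]
        fov[2] <- H + 1 - fov[2]
      }
    }
    if (cfg$shear) {
      sx <- runif(1, cfg$shear_range[1], cfg$shear_range[2])
      sy <- runif(1, cfg$shear_range[1], cfg$shear_range[2])
      th <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
      A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
        matrix(c(1, sy, sx, 1), 2, 2)
      ctr <- c((W + 1) / 2, (H + 1) / 2)
      px <- warp_affine(px, A, ctr, filter = "bilinear", bg = mean(px))
      gm <- warp_affine(gm * 1, A, ctr, filter = "none", bg = 0) > 0.5
      if (!is.null(cm)) {
        cm <- warp_affine(cm * 1, A, ctr, filter = "none", bg = 0) > 0.5
      }
      fov <- as.numeric(A %*% (fov - ctr) + ctr)
      dd <- dd * sqrt(abs(det(A)))
    }
    if (cfg$crop) {
      repeat {
        a <- runif(1, cfg$min_area_keep, 1)
        b <- runif(1, cfg$min_area_keep, 1)
        if (a * b >= cfg$min_area_keep &&
            min(a, b) / max(a, b) >= cfg$max_axis_distortion) break
      }
      # ceiling keeps the realized pixel area at or above the sampled one
      w <- min(W, as.integer(ceiling(a * W)))
      h <- min(H, as.integer(ceiling(b * H)))
      ox <- sample.int(W - w + 1, 1) - 1L
      oy <- sample.int(H - h + 1, 1) - 1L
      rows <- (oy + 1):(oy + h); cols <- (ox + 1):(ox + w)
      rs <- function(m, filter) EBImage::imageData(
        EBImage::resize(EBImage::Image(m), w = W, h = H, filter = filter))
      px <- rs(px[rows, cols], "bilinear")
      gm <- rs(gm[rows, cols] * 1, "none") > 0.5
      if (!is.null(cm)) cm <- rs(cm[rows, cols] * 1, "none") > 0.5
      fov <- (fov - c(ox, oy)) * c(W / w, H / h)
      dd <- dd * sqrt((W / w) * (H / h))
    }
    new_angio_image(px, gm, cm, fov, dd, img$image_id)
  })
}
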