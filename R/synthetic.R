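#' Specification for a synthetic UWF-FA image
#'
#' Describes one synthetic ultra-wide-field fluorescein angiography frame:
#' a ground-glass fluorescent background, bright branching vessels radiating
#' from the optic disc, hypofluorescent capillary non-perfusion (CNP) patches
#' of varying grayness with vessels pruned at their borders, an elliptical
#' gradable region with peripheral intensity falloff, and additive sensor
#' noise. Identical specs produce bit-identical images.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param image_side Side of the square image in pixels (>= 512).
#' @param cnp_fraction Target fraction of gradable pixels covered by CNP,
#'   in `[0, 1]`. Achieved within about +/-20% relative tolerance (patch
#'   placement is random and clipped to the gradable region).
#' @param n_cnp_patches Number of CNP patches the target area is split over.
#' @param vessel_density Dimensionless >= 0; scales the number of vessel
#'   trunks leaving the disc.
#' @param gradable_axis_ratio Vertical/horizontal semi-axis ratio of the
#'   elliptical gradable region, in `(0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param dd_pixels Pixels per disc diameter; default `image_side / 30` so
#'   the 15-DD grid radius roughly spans the gradable region.
#' @param fovea_offset Fovea offset `c(dx, dy)` in pixels from image centre.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, image_side = 2048L, cnp_fraction = 0.28,
                           n_cnp_patches = 6L, vessel_density = 1,
                           gradable_axis_ratio = 0.8, noise_sd = 0.02,
                           dd_pixels = round(image_side / 30),
                           fovea_offset = c(0, 0)) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed", "must be a single integer")
  check_that(is.numeric(image_side) && length(image_side) == 1 &&
               image_side >= 512, "image_side", "must be >= 512")
  check_that(is.numeric(cnp_fraction) && length(cnp_fraction) == 1 &&
               cnp_fraction >= 0 && cnp_fraction <= 1,
             "cnp_fraction", "must be in [0, 1]")
  check_that(n_cnp_patches >= 1, "n_cnp_patches", "must be >= 1")
  check_that(vessel_density >= 0, "vessel_density", "must be >= 0")
  check_that(gradable_axis_ratio > 0 && gradable_axis_ratio <= 1,
             "gradable_axis_ratio", "must be in (0, 1]")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(dd_pixels > 0, "dd_pixels", "must be > 0")
  check_that(length(fovea_offset) == 2, "fovea_offset", "must be c(dx, dy)")
  structure(list(seed = as.integer(seed), image_side = as.integer(image_side),
                 cnp_fraction = cnp_fraction,
                 n_cnp_patches = as.integer(n_cnp_patches),
                 vessel_density = vessel_density,
                 gradable_axis_ratio = gradable_axis_ratio,
                 noise_sd = noise_sd, dd_pixels = dd_pixels,
                 fovea_offset = as.numeric(fovea_offset)),
            class = "synthetic_spec")
}

# band-limited "value noise": coarse Gaussian grids upsampled bilinearly and
# summed over octaves; mimics the ground-glass background texture
value_noise <- function(side, cells = c(6, 12, 24, 48), amp = NULL) {
  if (is.null(amp)) amp <- 1 / sqrt(seq_along(cells))
  out <- matrix(0, side, side)
  for (k in seq_along(cells)) {
    n <- cells[k]
    g <- matrix(rnorm(n * n), n, n)
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(g), w = side,
                                             h = side, filter = "bilinear"))
    out <- out + amp[k] * up
  }
  out / sqrt(sum(amp^2))
}

# low-frequency angular wobble in [-1, 1], used to un-round patch borders
angular_wobble <- function(theta, n_harmonics = 3) {
  w <- numeric(length(theta))
  for (k in seq_len(n_harmonics)) {
    w <- w + runif(1, 0.3, 1) * sin(k * theta + runif(1, 0, 2 * pi)) / k
  }
  w / 1.5
}

# stamp an elliptical, wobbled-border patch of given pixel area into `mask`
# (logical side x side); returns the updated mask
stamp_patch <- function(mask, cx, cy, area_px, wobble_amp = 0.22) {
  q <- runif(1, 0.45, 1)               # axis ratio
  a <- sqrt(area_px / (pi * q))        # semi-major in px
  b <- a * q
  phi <- runif(1, 0, pi)
  pad <- ceiling(a * (1 + wobble_amp) + 2)
  side <- nrow(mask)
  rows <- max(1, round(cy) - pad):min(side, round(cy) + pad)
  cols <- max(1, round(cx) - pad):min(side, round(cx) + pad)
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  u <- (cos(phi) * dx + sin(phi) * dy) / a
  v <- (-sin(phi) * dx + cos(phi) * dy) / b
  rho <- sqrt(u^2 + v^2)
  wob <- angular_wobble(atan2(v, u))
  mask[rows, cols] <- mask[rows, cols] | (rho < 1 + wobble_amp * wob)
  mask
}

# recursive random branching vessel tree; returns data.frame of segments
grow_vessel_tree <- function(disc_xy, dd, side, density) {
  n_trunks <- max(0L, round(6 * density))
  segs <- vector("list", 0)
  if (n_trunks == 0) {
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), w = numeric(0)))
  }
  base_ang <- seq(0, 2 * pi, length.out = n_trunks + 1)[-1] +
    runif(n_trunks, -0.3, 0.3)
  recurse <- function(p, ang, w, depth) {
    if (depth > 5 || w < 0.8) return()
    len <- dd * runif(1, 1.2, 2.2)
    p1 <- p + len * c(cos(ang), sin(ang))
    segs[[length(segs) + 1]] <<- c(p, p1, w)
    if (p1[1] < -dd || p1[1] > side + dd || p1[2] < -dd || p1[2] > side + dd)
      return()
    recurse(p1, ang + runif(1, -0.35, 0.35), w * 0.82, depth + 1)
    if (runif(1) < 0.6) {
      recurse(p1, ang + sample(c(-1, 1), 1) * runif(1, 0.35, 0.9),
              w * 0.68, depth + 1)
    }
  }
  for (i in seq_len(n_trunks)) {
    recurse(disc_xy, base_ang[i], 0.12 * dd, 1)
  }
  m <- do.call(rbind, segs)
  data.frame(x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4], w = m[, 5])
}

# rasterize vessel segments to an additive brightness field in [0, 1]
rasterize_vessels <- function(segs, side) {
  if (nrow(segs) == 0) return(matrix(0, side, side))
  wclass <- pmax(1L, pmin(9L, as.integer(round(segs$w))))
  field <- matrix(0, side, side)
  for (w in sort(unique(wclass))) {
    sk <- matrix(0L, side, side)
    sel <- which(wclass == w)
    for (i in sel) {
      len <- sqrt((segs$x1[i] - segs$x0[i])^2 + (segs$y1[i] - segs$y0[i])^2)
      np <- max(2L, ceiling(len / 0.7))
      t <- seq(0, 1, length.out = np)
      xs <- round(segs$x0[i] + t * (segs$x1[i] - segs$x0[i]))
      ys <- round(segs$y0[i] + t * (segs$y1[i] - segs$y0[i]))
      ok <- xs >= 1 & xs <= side & ys >= 1 & ys <= side
      sk[cbind(ys[ok], xs[ok])] <- 1L
    }
    if (w > 1) {
      brush <- EBImage::makeBrush(2L * floor(w / 2) + 1L, shape = "disc")
      sk <- EBImage::imageData(EBImage::dilate(EBImage::Image(sk), brush))
    }
    field <- pmax(field, sk)
  }
  EBImage::imageData(EBImage::gblur(EBImage::Image(field), sigma = 0.8))
}

#' Generate one synthetic UWF-FA image with known CNP ground truth
#'
#' Deterministically renders the frame described by a [synthetic_spec()]:
#' ground-glass background texture, elliptical gradable region with dim
#' periphery, hypofluorescent CNP patches of varying grayness (always darker
#' than the perfused background), a bright vessel tree erased inside CNP
#' patches so vessels appear pruned at patch borders, a foveal dip, and
#' Gaussian noise.
#'
#' @param spec A [synthetic_spec()].
#' @return An [angio_image()] with `cnp_mask` filled in.
#' @examples
#' img <- generate_image(synthetic_spec(seed = 1, image_side = 512))
#' mean(img$cnp_mask) # fraction of all pixels that are CNP
#' @export
generate_image <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  side <- spec$image_side
  with_seed(spec$seed, {
    ecx <- (side + 1) / 2
    ecy <- (side + 1) / 2
    sa <- 0.47 * side
    sb <- sa * spec$gradable_axis_ratio
    xs <- matrix(rep(seq_len(side), each = side), side, side)  # column = x
    ys <- matrix(rep(seq_len(side), side), side, side)         # row = y
    u <- (xs - ecx) / sa
    v <- (ys - ecy) / sb
    rho <- sqrt(u^2 + v^2)
    wob <- angular_wobble(atan2(v, u))
    gradable <- rho < 1 + 0.04 * wob

    fovea <- c(ecx, ecy) + spec$fovea_offset
    fx <- round(fovea[1]); fy <- round(fovea[2])
    check_that(fx >= 1 && fx <= side && fy >= 1 && fy <= side &&
                 gradable[fy, fx], "fovea_offset",
               "fovea must stay inside the gradable region")

    # ground-glass background
    img <- 0.55 + 0.07 * value_noise(side)

    # CNP patches sized to split the target area, clipped to gradable
    cnp <- matrix(FALSE, side, side)
    grad_px <- sum(gradable)
    target_px <- spec$cnp_fraction * grad_px
    if (target_px >= 1) {
      props <- runif(spec$n_cnp_patches)
      props <- props / sum(props)
      grad_idx <- which(gradable)
      for (ar in props * target_px) {
        ctr <- grad_idx[sample.int(length(grad_idx), 1)]
        cy <- (ctr - 1) %% side + 1
        cx <- (ctr - 1) %/% side + 1
        cnp <- stamp_patch(cnp, cx, cy, ar)
      }
      cnp <- cnp & gradable
      # overlap and boundary clipping only shrink the union; top up
      tries <- 0
      while (sum(cnp) < 0.93 * target_px && tries < 12) {
        ctr <- grad_idx[sample.int(length(grad_idx), 1)]
        cy <- (ctr - 1) %% side + 1
        cx <- (ctr - 1) %/% side + 1
        cnp <- stamp_patch(cnp, cx, cy, target_px - sum(cnp)) & gradable
        tries <- tries + 1
      }
    }

    # per-patch grayness: darkening factor field, softened at borders
    dark <- matrix(1, side, side)
    if (any(cnp)) {
      comp <- EBImage::bwlabel(EBImage::Image(cnp * 1L))
      comp <- EBImage::imageData(comp)
      for (lab in seq_len(max(comp))) {
        depth <- runif(1, 0.35, 0.75)
        dark[comp == lab] <- 1 - depth
      }
      dark <- EBImage::imageData(EBImage::gblur(EBImage::Image(dark),
                                                sigma = 2))
    }
    img <- img * dark

    # vessel tree from the disc (2.5 DD nasal of the fovea), pruned at CNP
    disc <- c(min(side - 1, fovea[1] + 2.5 * spec$dd_pixels), fovea[2])
    segs <- grow_vessel_tree(disc, spec$dd_pixels, side, spec$vessel_density)
    vess <- rasterize_vessels(segs, side)
    vess[cnp] <- 0
    img <- img + 0.30 * vess

    # foveal avascular dip
    img <- img - 0.08 * exp(-((xs - fovea[1])^2 + (ys - fovea[2])^2) /
                              (2 * (0.35 * spec$dd_pixels)^2))

    # peripheral falloff and a few bright peripheral artifacts
    dout <- EBImage::imageData(EBImage::distmap(EBImage::Image(!gradable)))
    img <- img * ifelse(gradable, 1, 0.45 * exp(-dout / (0.06 * side)))
    n_art <- sample(2:4, 1)
    out_idx <- which(!gradable & rho < 1.3)
    if (length(out_idx) > 0) {
      art <- matrix(FALSE, side, side)
      for (i in seq_len(n_art)) {
        ctr <- out_idx[sample.int(length(out_idx), 1)]
        art <- stamp_patch(art, (ctr - 1) %/% side + 1, (ctr - 1) %% side + 1,
                           (0.01 * side)^2 * pi * runif(1, 0.5, 2))
      }
      img[art] <- img[art] + 0.25
    }

    if (spec$noise_sd > 0) img <- img + rnorm(side * side, 0, spec$noise_sd)
    img <- clamp01(img)

    angio_image(img, gradable, cnp, fovea_xy = fovea,
                dd_pixels = spec$dd_pixels,
                image_id = sprintf("synth_seed%d", spec$seed))
  })
}

#' Generate a synthetic dataset on disk with a CSV manifest
#'
#' Writes `n` synthetic frames (16-bit TIFF) with gradable and CNP masks
#' (8-bit PNG) plus a `manifest.csv` holding per-image calibration and the
#' achieved CNP fraction. Per-image seeds are `base_spec$seed + index`, so
#' the same base spec always reproduces byte-identical output.
#'
#' @param n Number of images (>= 1).
#' @param base_spec A [synthetic_spec()]; its seed anchors the dataset.
#' @param out_dir Output directory (created if missing).
#' @return The manifest `data.frame`, invisibly-written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, base_spec = synthetic_spec(), out_dir) {
  check_that(n >= 1, "n", "must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$seed <- base_spec$seed + i
    img <- generate_image(sp)
    id <- sprintf("img%03d", i)
    ip <- sprintf("image_%s.tiff", id)
    gp <- sprintf("gradable_%s.png", id)
    cp <- sprintf("cnp_%s.png", id)
    write_intensity_image(img$pixels, file.path(out_dir, ip))
    write_mask_image(img$gradable_mask, file.path(out_dir, gp))
    write_mask_image(img$cnp_mask, file.path(out_dir, cp))
    rows[[i]] <- data.frame(
      image_id = id, image_path = ip, gradable_path = gp, cnp_path = cp,
      fovea_x = img$fovea_xy[1], fovea_y = img$fovea_xy[2],
      dd_pixels = img$dd_pixels,
      cnp_fraction = sum(img$cnp_mask) / sum(img$gradable_mask))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Simulate a second grader's CNP annotation
#'
#' Emulates inter-grader variability on a reference CNP mask: random small
#' patches are added and deleted, then the mask is grown or shrunk along its
#' Euclidean distance transform until its CNP fraction matches
#' `original * (1 + bias)`. The result always stays within the gradable
#' retina. With `bias = 0` and `noise = 0` the mask is returned unchanged.
#'
#' @param img An [angio_image()] with a `cnp_mask`.
#' @param bias Relative area bias of the simulated grader; e.g. `0.4` makes
#'   the grader annotate about 40% more CNP area than the reference.
#' @param seed Integer seed for the random patch events.
#' @param noise Amplitude of random patch addition/deletion, as a fraction of
#'   the image side used for patch radii (0 disables).
#' @return A logical CNP mask of the same shape.
#' @export
simulate_second_grader <- function(img, bias = 0, seed = 1L, noise = 0.05) {
  if (is.null(img$cnp_mask)) {
    stop("image has no `cnp_mask`; a reference annotation is required",
         call. = FALSE)
  }
  mask <- img$cnp_mask
  gradable <- img$gradable_mask
  if (bias == 0 && noise == 0) return(mask)
  side <- nrow(mask)
  f0 <- sum(mask) / sum(gradable)
  target <- min(0.95, f0 * (1 + bias))
  with_seed(seed, {
    if (noise > 0) {
      grad_idx <- which(gradable)
      cnp_idx <- which(mask)
      for (i in 1:3) {   # additions
        ctr <- grad_idx[sample.int(length(grad_idx), 1)]
        r <- side * noise * runif(1, 0.3, 0.8)
        mask <- stamp_patch(mask, (ctr - 1) %/% side + 1,
                            (ctr - 1) %% side + 1, pi * r^2)
      }
      if (length(cnp_idx) > 0) {
        for (i in 1:3) { # deletions
          ctr <- cnp_idx[sample.int(length(cnp_idx), 1)]
          r <- side * noise * runif(1, 0.3, 0.8)
          hole <- stamp_patch(matrix(FALSE, side, side),
                              (ctr - 1) %/% side + 1, (ctr - 1) %% side + 1,
                              pi * r^2)
          mask <- mask & !hole
        }
      }
      mask <- mask & gradable
    }
    if (f0 > 0) mask <- morph_to_fraction(mask, gradable, target)
    mask
  })
}

# grow/shrink a mask along its distance transform until it covers `target`
# fraction of the gradable region (bisection; monotone family)
morph_to_fraction <- function(mask, gradable, target) {
  gpx <- sum(gradable)
  frac <- function(m) sum(m) / gpx
  if (abs(frac(mask) - target) < 1e-4 || !any(mask)) return(mask)
  if (frac(mask) < target) {
    dto <- EBImage::imageData(EBImage::distmap(EBImage::Image(!mask)))
    fam <- function(t) (mask | dto <= t) & gradable
  } else {
    dti <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask)))
    fam <- function(t) mask & (dti > t)
  }
  lo <- 0; hi <- nrow(mask)
  # fam(t): grows with t in the dilation branch, shrinks in the erosion one
  growing <- frac(mask) < target
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    f <- frac(fam(mid))
    if ((growing && f < target) || (!growing && f > target)) lo <- mid
    else hi <- mid
  }
  fam((lo + hi) / 2)
}
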