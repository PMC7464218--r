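test_that("grid rasterization matches the template geometry", {
  t <- fixture_template()            # fovea (256,256), 16 px/DD, 15 DD radius
  ids <- rasterize_grid(t, c(512, 512))
  # 72 gradable segments plus centre and outside
  expect_setequal(setdiff(unique(as.vector(ids)), c(0L, -1L)), 1:72)
  # central circle: 1 DD diameter
  expect_equal(ids[256, 256 + round(0.4 * 16)], 0L)
  expect_equal(ids[256, 256], 0L)
  # 3 DD lies in ring 2 (ring 1 reaches 2.5 DD); right of fovea is the
  # 3 o'clock sector, the 4th clockwise from 12
  expect_equal(ids[256, 256 + 3 * 16], (2L - 1L) * 12L + 4L)
  # 12 o'clock at 1 DD: ring 1, segment 1; just anticlockwise: segment 12
  expect_equal(ids[256 - 16, 256], 1L)
  expect_equal(ids[256 - 16, 255], 12L)
  # outside the 6th ring
  expect_equal(ids[256, 256 + round(15.5 * 16)], -1L)
  expect_error(rasterize_grid(grid_template(c(600, 256), 16), c(512, 512)),
               "fovea")
})

test_that("every pixel belongs to exactly one region", {
  t <- fixture_template()
  ids <- rasterize_grid(t, c(512, 512))
  expect_true(all(ids %in% c(-1L, 0L, 1:72)))
  expect_equal(length(ids), 512L * 512L)
})

test_that("segments subtend equal 30-degree arcs", {
  t <- fixture_template()
  # walk a circle at 4 DD; the segment id must change every 30 degrees
  ang <- seq(0, 359.5, by = 0.5)
  x <- round(256 + 4 * 16 * sin(ang * pi / 180))
  y <- round(256 - 4 * 16 * cos(ang * pi / 180))
  ids <- rasterize_grid(t, c(512, 512))
  seg <- ids[cbind(y, x)] - 12L      # ring 2 -> segment number
  expected <- pmin(floor(ang / 30) + 1, 12)
  # allow rounding blur only at sector boundaries
  off_boundary <- abs(ang %% 30) > 1 & abs(ang %% 30) < 29
  expect_equal(seg[off_boundary], expected[off_boundary])
})

test_that("the 30% rule is strict and counts only gradable pixels", {
  t <- fixture_template()
  ids <- rasterize_grid(t, c(512, 512))
  gradable <- matrix(TRUE, 512, 512)
  # find a segment whose pixel count is divisible by 10 for an exact 30%
  counts <- table(ids[ids >= 1])
  seg_id <- as.integer(names(counts)[counts %% 10 == 0][1])
  n <- counts[[as.character(seg_id)]]
  px <- which(ids == seg_id)
  cnp <- matrix(FALSE, 512, 512)
  cnp[px[seq_len(0.3 * n)]] <- TRUE
  a <- assess_grid(cnp, gradable, t)
  row <- a$ring == (seg_id - 1) %/% 12 + 1 & a$segment == (seg_id - 1) %% 12 + 1
  expect_equal(as.character(a$label[row]), "P")   # exactly 30% is not "surpassed"
  expect_equal(a$cnp_ratio[row], 0.3)
  cnp[px[0.3 * n + 1]] <- TRUE
  a2 <- assess_grid(cnp, gradable, t)
  expect_equal(as.character(a2$label[row]), "N")
})

test_that("a 40% CNP segment is non-perfused and a clean image all perfused", {
  t <- fixture_template()
  ids <- rasterize_grid(t, c(512, 512))
  gradable <- matrix(TRUE, 512, 512)
  a0 <- assess_grid(matrix(FALSE, 512, 512), gradable, t)
  expect_equal(sum(a0$label == "P"), 72L)
  expect_equal(sum(a0$label != "P"), 0L)
  px <- which(ids == 20)
  cnp <- matrix(FALSE, 512, 512)
  cnp[px[seq_len(round(0.4 * length(px)))]] <- TRUE
  a <- assess_grid(cnp, gradable, t)
  expect_equal(as.character(a$label[a$ring == 2 & a$segment == 8]), "N")
})

test_that("ungradable segments follow the gradability cutoff", {
  t <- fixture_template()
  ids <- rasterize_grid(t, c(512, 512))
  gradable <- matrix(TRUE, 512, 512)
  gradable[ids == 5] <- FALSE            # fully ungradable segment
  a <- assess_grid(matrix(FALSE, 512, 512), gradable, t)
  expect_equal(as.character(a$label[a$ring == 1 & a$segment == 5]), "U")
  expect_true(is.na(a$cnp_ratio[a$ring == 1 & a$segment == 5]))
  # segments partly off the image are ungradable, not an error
  t_edge <- grid_template(fovea_xy = c(40, 256), dd_pixels = 16)
  a_edge <- assess_grid(matrix(FALSE, 512, 512), matrix(TRUE, 512, 512),
                        t_edge)
  expect_gt(sum(a_edge$label == "U"), 0)
})

test_that("adding CNP pixels never flips a segment from N to P", {
  t <- fixture_template()
  gradable <- matrix(TRUE, 512, 512)
  set.seed(31)
  cnp <- matrix(runif(512 * 512) < 0.2, 512, 512)
  a1 <- assess_grid(cnp, gradable, t)
  extra <- cnp | matrix(runif(512 * 512) < 0.15, 512, 512)
  a2 <- assess_grid(extra, gradable, t)
  was_n <- a1$label == "N"
  expect_true(all(a2$label[was_n] == "N"))
})

test_that("counts of non-perfused segments fall as the threshold rises", {
  img <- fixture_image(seed = 7, cnp_fraction = 0.28)
  t <- grid_template(img$fovea_xy, img$dd_pixels)
  ns <- vapply(c(0.30, 0.40, 0.50), function(th)
    sum(assess_grid(img$cnp_mask, img$gradable_mask, t,
                    cnp_threshold = th)$label == "N"), 0)
  expect_true(all(diff(ns) <= 0))
})

test_that("rotating the masks by one sector permutes segment labels", {
  t <- fixture_template()
  side <- 512
  xs <- matrix(rep(seq_len(side), each = side), side, side)
  ys <- matrix(rep(seq_len(side), side), side, side)
  dx <- xs - 256; dy <- ys - 256
  d_dd <- sqrt(dx^2 + dy^2) / 16
  theta <- (90 - atan2(-dy, dx) * 180 / pi) %% 360   # clockwise from 12
  # analytic CNP wedges, kept away from sector borders to avoid pixel blur
  make_cnp <- function(offset) {
    w <- (theta - offset) %% 360
    (w %% 30 > 5 & w %% 30 < 25) & (w < 90) & d_dd > 3 & d_dd < 7
  }
  gradable <- matrix(TRUE, side, side)
  a0 <- assess_grid(make_cnp(0), gradable, t)
  a1 <- assess_grid(make_cnp(30), gradable, t)
  # one-sector clockwise rotation: labels shift by one segment within rings
  for (r in 1:6) {
    l0 <- as.character(a0$label[a0$ring == r])
    l1 <- as.character(a1$label[a1$ring == r])
    expect_equal(l1, l0[c(12, 1:11)])
  }
})

test_that("ring counts conserve totals", {
  img <- fixture_image(seed = 7, cnp_fraction = 0.28)
  t <- grid_template(img$fovea_xy, img$dd_pixels)
  a <- assess_grid(img$cnp_mask, img$gradable_mask, t)
  rc <- ring_counts(a)
  expect_equal(rc$n_P + rc$n_N + rc$n_U, rep(12L, 6))
  expect_equal(sum(rc$n_N), sum(a$label == "N"))
  # one forced non-perfused segment in ring 3 under full gradability
  gradable <- matrix(TRUE, 512, 512)
  ids <- rasterize_grid(fixture_template(), c(512, 512))
  cnp <- matrix(FALSE, 512, 512)
  cnp[ids == 2 * 12 + 5] <- TRUE
  rc1 <- ring_counts(assess_grid(cnp, gradable, fixture_template()))
  expect_equal(rc1[rc1$ring == 3, c("n_P", "n_N", "n_U")],
               data.frame(n_P = 11L, n_N = 1L, n_U = 0L, row.names = 3L))
})

test_that("manual labels wrap into assessments and survive CSV round trips", {
  a <- manual_grid_from_labels(rep("P", 72))
  expect_s3_class(a, "grid_assessment")
  expect_equal(sum(a$label == "P"), 72L)
  expect_error(manual_grid_from_labels(rep("P", 71)), "72")
  expect_error(manual_grid_from_labels(c(rep("P", 71), "X")), "labels")
  set.seed(12)
  labs <- sample(c("P", "N", "U"), 72, replace = TRUE, prob = c(.7, .2, .1))
  a2 <- manual_grid_from_labels(labs, image_id = "m1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_assessment(a2, path)
  back <- read_grid_assessment(path)
  expect_equal(as.character(back$label), labs)
  expect_equal(attr(back, "image_id"), "m1")
})

test_that("the overlay colours segments by their labels", {
  img <- fixture_image(seed = 7, cnp_fraction = 0.28)
  t <- grid_template(img$fovea_xy, img$dd_pixels)
  a <- assess_grid(img$cnp_mask, img$gradable_mask, t)
  ov <- render_grid_overlay(img, a, t)
  expect_equal(dim(ov), c(512L, 512L, 3L))
  expect_true(all(ov >= 0 & ov <= 1))
  ids <- rasterize_grid(t, dim(img$pixels))
  # a non-perfused segment must gain red over green, a perfused one reverse
  if (any(a$label == "N")) {
    seg_n <- which(a$label == "N")[1]
    sel <- ids == seg_n
    expect_gt(mean(ov[, , 1][sel]), mean(ov[, , 2][sel]))
  }
  seg_p <- which(a$label == "P")[1]
  sel <- ids == seg_p
  expect_gt(mean(ov[, , 2][sel]), mean(ov[, , 1][sel]))
})
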