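#' Deterministic fold assignment for cross-validation
#'
#' @param n Number of images.
#' @param k Number of folds; must not exceed `n`.
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold ids `1..k`; folds are
#'   disjoint, cover all images, and differ in size by at most one.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k > n) stop(sprintf("k = %d folds but only %d images", k, n),
                  call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(n)
    folds <- integer(n)
    folds[perm] <- rep(seq_len(k), length.out = n)
    folds
  })
}

# preprocess one angio image to network input scale: central crop covering
# the full frame, resize, normalize
prep_for_model <- function(img, input_side) {
  side <- min(dim(img$pixels))
  out <- central_crop_resize(img, crop_side = side, out_side = input_side)
  out$pixels <- normalize_image(out$pixels)
  out
}

#' Cross-validated training and evaluation
#'
#' Splits the images into `k` seeded random folds, trains one network per
#' fold on the remaining folds, predicts the held-out images, and
#' aggregates per-fold ROC/PRC curves via [average_curves()]. Pixel-level
#' metrics at the centred operating point (threshold 0.5) are averaged over
#' all held-out images.
#'
#' @param images List of [angio_image()]s with reference CNP masks (raw
#'   scale; they are cropped, resized and normalized internally).
#' @param k Number of folds (default 5).
#' @param net_cfg A [network_config()].
#' @param tc A [train_config()].
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param out_dir Optional directory; when given, per-fold curve CSVs, the
#'   summary JSON and per-image metrics CSV are written there.
#' @return List with `folds`, `fold_curves`, `mean_curves`, `per_image`
#'   (`data.frame` of pr/rc/dsc per held-out image) and `summary`.
#' @export
run_crossval <- function(images, k = 5L, net_cfg = network_config(),
                         tc = train_config(), seed = 1L, out_dir = NULL) {
  n <- length(images)
  folds <- make_folds(n, k, seed)
  prepped <- lapply(images, prep_for_model, input_side = net_cfg$input_side)
  fold_curves <- vector("list", k)
  per_image <- list()
  for (f in seq_len(k)) {
    tr <- prepped[folds != f]
    te <- prepped[folds == f]
    tc_f <- tc
    tc_f$seed <- tc$seed + f
    net <- build_network(net_cfg, seed = seed + f)
    fit <- train_unet(tr, net, tc_f)
    probs <- lapply(te, function(im) predict_cnp(fit$net, im))
    refs <- lapply(te, function(im) im$cnp_mask)
    regions <- lapply(te, function(im) im$gradable_mask)
    fold_curves[[f]] <- roc_prc_curves(probs, refs, regions)
    for (j in seq_along(te)) {
      m <- pixel_metrics(binarize(probs[[j]]), refs[[j]], regions[[j]])
      per_image[[length(per_image) + 1]] <-
        data.frame(image_id = te[[j]]$image_id, fold = f,
                   pr = m$pr, rc = m$rc, dsc = m$dsc)
    }
  }
  per_image <- do.call(rbind, per_image)
  mean_curves <- average_curves(fold_curves)
  summary <- list(
    k = k, n_images = n, seed = seed,
    auc_mean = mean_curves$auc_mean, auc_sd = mean_curves$auc_sd,
    auprc_mean = mean_curves$auprc_mean, auprc_sd = mean_curves$auprc_sd,
    dsc_mean = mean(per_image$dsc, na.rm = TRUE),
    pr_mean = mean(per_image$pr, na.rm = TRUE),
    rc_mean = mean(per_image$rc, na.rm = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_len(k)) {
      write.csv(fold_curves[[f]]$roc,
                file.path(out_dir, sprintf("roc_fold%d.csv", f)),
                row.names = FALSE)
      write.csv(fold_curves[[f]]$prc,
                file.path(out_dir, sprintf("prc_fold%d.csv", f)),
                row.names = FALSE)
    }
    write.csv(per_image, file.path(out_dir, "per_image_metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(folds = folds, fold_curves = fold_curves, mean_curves = mean_curves,
       per_image = per_image, summary = summary)
}

#' End-to-end assessment of one calibrated image
#'
#' Runs the full two-stage pipeline on a single frame: preprocess, predict
#' the CNP probability map, binarize at the centred operating point, place
#' the fovea-centred grid using the image's calibration, and grade all
#' segments. Optionally writes the assessment CSV and a colour overlay PNG.
#'
#' @param img An [angio_image()] with fovea/DD calibration.
#' @param net A trained `cnp_unet`.
#' @param threshold Operating point for [binarize()] (default 0.5).
#' @param cnp_threshold Segment-level CNP ratio threshold (default 0.30).
#' @param out_dir Optional output directory.
#' @return List with `assessment` (a `grid_assessment`), `prob_map`, and
#'   `mask` (the binarized CNP mask, restricted to the gradable region).
#' @export
run_end_to_end <- function(img, net, threshold = 0.5, cnp_threshold = 0.30,
                           out_dir = NULL) {
  if (is.null(img$fovea_xy) || is.null(img$dd_pixels)) {
    stop("image lacks fovea/DD calibration", call. = FALSE)
  }
  prepped <- prep_for_model(img, net$cfg$input_side)
  pm <- predict_cnp(net, prepped)
  mask <- binarize(pm, threshold) & prepped$gradable_mask
  t <- grid_template(fovea_xy = prepped$fovea_xy,
                     dd_pixels = prepped$dd_pixels)
  a <- assess_grid(mask, prepped$gradable_mask, t,
                   cnp_threshold = cnp_threshold, image_id = img$image_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_grid_assessment(a, file.path(out_dir,
                                       paste0(img$image_id, "_grid.csv")))
    ov <- render_grid_overlay(prepped, a, t)
    png::writePNG(ov, file.path(out_dir, paste0(img$image_id,
                                                "_overlay.png")))
  }
  list(assessment = a, prob_map = pm, mask = mask)
}
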