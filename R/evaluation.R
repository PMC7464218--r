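#' Pixel-level segmentation metrics within a region
#'
#' Computes precision `PR = TP/(TP+FP)`, recall `RC = TP/(TP+FN)` and Dice
#' similarity `DSC = 2TP/(2TP+FP+FN)` between a predicted and a reference
#' binary mask, restricted to `region_mask` (the gradable retina; all
#' comparisons use the first grader's gradable region).
#'
#' @param pred_mask,ref_mask Logical masks of identical shape.
#' @param region_mask Logical evaluation region; defaults to all pixels.
#' @return List with `pr`, `rc`, `dsc` and `counts` (`tp`, `tn`, `fp`,
#'   `fn`). A metric with an empty denominator (e.g. precision without any
#'   positive prediction) is `NA`, not 0.
#' @export
pixel_metrics <- function(pred_mask, ref_mask, region_mask = NULL) {
  stopifnot(identical(dim(pred_mask), dim(ref_mask)))
  p <- as.vector(pred_mask)
  r <- as.vector(ref_mask)
  if (!is.null(region_mask)) {
    stopifnot(identical(dim(ref_mask), dim(region_mask)))
    keep <- as.vector(region_mask)
    p <- p[keep]; r <- r[keep]
  }
  tp <- sum(p & r); tn <- sum(!p & !r)
  fp <- sum(p & !r); fn <- sum(!p & r)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(pr = safe_div(tp, tp + fp),
       rc = safe_div(tp, tp + fn),
       dsc = safe_div(2 * tp, 2 * tp + fp + fn),
       counts = list(tp = tp, tn = tn, fp = fp, fn = fn))
}

#' ROC and precision-recall curves for one cross-validation fold
#'
#' Pools pixels over the fold's images within each image's evaluation
#' region, sweeps the discrimination threshold, and integrates the curves
#' by the trapezoidal rule.
#'
#' @param prob_maps List of probability matrices (or `probability_map`s).
#' @param ref_masks List of logical reference CNP masks.
#' @param region_masks Optional list of logical evaluation regions.
#' @param n_thresholds Number of thresholds swept uniformly over `[0, 1]`.
#' @return List with `roc` (`data.frame`: `threshold`, `fpr`, `tpr`), `prc`
#'   (`threshold`, `recall`, `precision`), `auc`, `auprc`.
#' @export
roc_prc_curves <- function(prob_maps, ref_masks, region_masks = NULL,
                           n_thresholds = 101L) {
  stopifnot(length(prob_maps) == length(ref_masks))
  scores <- numeric(0)
  labels <- logical(0)
  for (i in seq_along(prob_maps)) {
    pm <- prob_maps[[i]]
    pr <- if (inherits(pm, "probability_map")) pm$probs else pm
    s <- as.vector(pr)
    l <- as.vector(ref_masks[[i]])
    if (!is.null(region_masks)) {
      keep <- as.vector(region_masks[[i]])
      s <- s[keep]; l <- l[keep]
    }
    scores <- c(scores, s)
    labels <- c(labels, l)
  }
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) {
    stop("reference contains a single class; ROC/PRC are undefined",
         call. = FALSE)
  }
  # descending thresholds: FPR/TPR (and recall) grow monotonically along the
  # curve, so the trapezoidal rule can follow the sweep order directly
  ts <- seq(1, 0, length.out = n_thresholds)
  pos <- scores[labels]; neg <- scores[!labels]
  tp <- vapply(ts, function(t) sum(pos > t), 0)
  fp <- vapply(ts, function(t) sum(neg > t), 0)
  tpr <- tp / npos
  fpr <- fp / nneg
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  roc <- data.frame(threshold = c(Inf, ts, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- trapz_ordered(roc$fpr, roc$tpr)
  # conventional anchor at recall 0 / precision 1 so the curve spans [0, 1]
  prc <- data.frame(threshold = c(Inf, ts), recall = c(0, tpr),
                    precision = c(1, precision))
  ok <- !is.na(prc$precision)
  auprc <- trapz_ordered(prc$recall[ok], prc$precision[ok])
  list(roc = roc, prc = prc, auc = auc, auprc = auprc)
}

#' Vertically average per-fold ROC / PRC curves
#'
#' Interpolates every fold's TPR (resp. precision) onto a common FPR
#' (resp. recall) grid of 101 points spanning `[0, 1]`, and reports the
#' pointwise mean and standard deviation, the AUC of the mean curve, and
#' the mean and standard deviation of the per-fold areas.
#'
#' @param fold_curves List of results from [roc_prc_curves()], one per fold
#'   (at least 2).
#' @return List with `roc` (`fpr`, `tpr_mean`, `tpr_sd`), `prc` (`recall`,
#'   `precision_mean`, `precision_sd`), `auc_mean_curve`, `auc_mean`,
#'   `auc_sd`, `auprc_mean_curve`, `auprc_mean`, `auprc_sd`.
#' @export
average_curves <- function(fold_curves) {
  stopifnot(length(fold_curves) >= 2)
  grid <- seq(0, 1, length.out = 101)
  interp <- function(x, y, xg) {
    o <- order(x, y)
    approx(x[o], y[o], xout = xg, ties = mean, rule = 2)$y
  }
  tprs <- sapply(fold_curves, function(f) interp(f$roc$fpr, f$roc$tpr, grid))
  precs <- sapply(fold_curves, function(f) {
    ok <- !is.na(f$prc$precision)
    interp(f$prc$recall[ok], f$prc$precision[ok], grid)
  })
  aucs <- vapply(fold_curves, function(f) f$auc, 0)
  auprcs <- vapply(fold_curves, function(f) f$auprc, 0)
  roc <- data.frame(fpr = grid, tpr_mean = rowMeans(tprs),
                    tpr_sd = apply(tprs, 1, sd))
  prc <- data.frame(recall = grid, precision_mean = rowMeans(precs),
                    precision_sd = apply(precs, 1, sd))
  list(roc = roc, prc = prc,
       auc_mean_curve = trapz(roc$fpr, roc$tpr_mean),
       auc_mean = mean(aucs), auc_sd = sd(aucs),
       auprc_mean_curve = trapz(prc$recall, prc$precision_mean),
       auprc_mean = mean(auprcs), auprc_sd = sd(auprcs))
}

#' Unweighted Cohen's kappa between two grid assessments of one image
#'
#' Segments labelled ungradable by either assessment are excluded pairwise;
#' kappa is computed over the remaining P/N pairs. When both raters give
#' constant, identical labels, chance agreement equals 1 and the usual
#' formula is 0/0; observed agreement is perfect there, so kappa is defined
#' as 1 (mostly-perfused retinas otherwise read as disagreement).
#'
#' @param a1,a2 `grid_assessment`s over the same template.
#' @return Kappa in `[-1, 1]`, or `NA` when fewer than 2 segment pairs are
#'   jointly gradable.
#' @export
grid_kappa <- function(a1, a2) {
  stopifnot(nrow(a1) == nrow(a2))
  l1 <- as.character(a1$label)
  l2 <- as.character(a2$label)
  keep <- l1 != "U" & l2 != "U"
  l1 <- l1[keep]; l2 <- l2[keep]
  n <- length(l1)
  if (n < 2) return(NA_real_)
  po <- mean(l1 == l2)
  p1 <- c(P = mean(l1 == "P"), N = mean(l1 == "N"))
  p2 <- c(P = mean(l2 == "P"), N = mean(l2 == "N"))
  pe <- sum(p1 * p2)
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' Dataset-level kappa: mean and standard error over per-image kappas
#'
#' @param kappas Numeric vector of per-image kappas (from [grid_kappa()]);
#'   `NA`s (images without a defined kappa) are excluded from `n`.
#' @return List with `kappa_mean`, `kappa_se` (`sd/sqrt(n)`), `n_images`.
#' @export
dataset_kappa <- function(kappas) {
  k <- kappas[!is.na(kappas)]
  if (length(k) < 2) {
    stop("need >= 2 images with a defined kappa", call. = FALSE)
  }
  list(kappa_mean = mean(k), kappa_se = sd(k) / sqrt(length(k)),
       n_images = length(k))
}

#' Intraclass correlation ICC(2,1) with a 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' between two raters' per-image counts, with the F-distribution confidence
#' interval. This is the agreement form appropriate for comparing the
#' number of perfused (or non-perfused) segments per image between a grader
#' and the automated assessment.
#'
#' @param x,y Numeric vectors of equal length (>= 3), one value per image.
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `lower`, `upper`, `n`. When neither rater shows
#'   any variance the coefficient is undefined and all three are `NA`.
#' @export
icc_agreement <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (var(x) == 0 && var(y) == 0) {
    return(list(icc = NA_real_, lower = NA_real_, upper = NA_real_, n = n))
  }
  M <- cbind(x, y)
  k <- 2
  grand <- mean(M)
  msr <- k * sum((rowMeans(M) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(M) - grand)^2) / (k - 1)
  sse <- sum((M - outer(rowMeans(M), rep(1, k)) -
                outer(rep(1, n), colMeans(M)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (mse == 0) {
    return(list(icc = icc, lower = icc, upper = icc, n = n))
  }
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper, n = n)
}

#' Agreement report between two sources of grid assessments
#'
#' Builds one row of the standard agreement table for a set of images
#' assessed by two label sources: mean per-image unweighted kappa with its
#' standard error, and ICC(2,1) with 95% CI for the per-image counts of
#' perfused and of non-perfused segments.
#'
#' @param assessments1,assessments2 Lists of `grid_assessment`s, paired by
#'   position.
#' @param comparison Label for the pair of sources.
#' @return A one-row `data.frame` with columns `comparison`, `n_images`,
#'   `kappa`, `kappa_se`, `icc_perfused`, `icc_p_lower`, `icc_p_upper`,
#'   `icc_nonperfused`, `icc_n_lower`, `icc_n_upper`.
#' @export
agreement_report <- function(assessments1, assessments2,
                             comparison = "source1 vs source2") {
  stopifnot(length(assessments1) == length(assessments2))
  kap <- mapply(grid_kappa, assessments1, assessments2)
  dk <- dataset_kappa(kap)
  count_lab <- function(as_list, lab)
    vapply(as_list, function(a) sum(a$label == lab), 0)
  icc_p <- icc_agreement(count_lab(assessments1, "P"),
                         count_lab(assessments2, "P"))
  icc_n <- icc_agreement(count_lab(assessments1, "N"),
                         count_lab(assessments2, "N"))
  data.frame(comparison = comparison, n_images = dk$n_images,
             kappa = dk$kappa_mean, kappa_se = dk$kappa_se,
             icc_perfused = icc_p$icc, icc_p_lower = icc_p$lower,
             icc_p_upper = icc_p$upper,
             icc_nonperfused = icc_n$icc, icc_n_lower = icc_n$lower,
             icc_n_upper = icc_n$upper)
}

#' Per-ring segment-count summary and agreement between two sources
#'
#' For each ring, reports the mean (SD) number of perfused and non-perfused
#' segments per image under both label sources and the ICC(2,1) between
#' them, mirroring the standard per-ring agreement table.
#'
#' @inheritParams agreement_report
#' @return `data.frame` with one row per ring.
#' @export
ring_agreement_report <- function(assessments1, assessments2) {
  rc1 <- lapply(assessments1, ring_counts)
  rc2 <- lapply(assessments2, ring_counts)
  rings <- rc1[[1]]$ring
  rows <- lapply(rings, function(r) {
    p1 <- vapply(rc1, function(d) d$n_P[d$ring == r], 0L)
    n1 <- vapply(rc1, function(d) d$n_N[d$ring == r], 0L)
    p2 <- vapply(rc2, function(d) d$n_P[d$ring == r], 0L)
    n2 <- vapply(rc2, function(d) d$n_N[d$ring == r], 0L)
    ip <- icc_agreement(p1, p2)
    iv <- icc_agreement(n1, n2)
    data.frame(ring = r,
               p_mean_1 = mean(p1), p_sd_1 = sd(p1),
               n_mean_1 = mean(n1), n_sd_1 = sd(n1),
               p_mean_2 = mean(p2), p_sd_2 = sd(p2),
               n_mean_2 = mean(n2), n_sd_2 = sd(n2),
               icc_perfused = ip$icc, icc_p_lower = ip$lower,
               icc_p_upper = ip$upper,
               icc_nonperfused = iv$icc, icc_n_lower = iv$lower,
               icc_n_upper = iv$upper)
  })
  do.call(rbind, rows)
}
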