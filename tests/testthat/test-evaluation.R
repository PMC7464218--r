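test_that("pixel metrics follow the printed formulas", {
  # TP=2, FP=1, FN=1
  pred <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  ref <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2)
  m <- pixel_metrics(pred, ref)
  expect_equal(m$pr, 2 / 3)
  expect_equal(m$rc, 2 / 3)
  expect_equal(m$dsc, 2 / 3)
  expect_equal(m$counts, list(tp = 2L, tn = 0L, fp = 1L, fn = 1L))
  # identity and disjoint cases
  id <- pixel_metrics(ref, ref)
  expect_equal(c(id$pr, id$rc, id$dsc), c(1, 1, 1))
  dj <- pixel_metrics(matrix(c(TRUE, FALSE, FALSE, FALSE), 2),
                      matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
  expect_equal(dj$dsc, 0)
  # no positive prediction: precision undefined, not zero
  np <- pixel_metrics(matrix(FALSE, 2, 2), ref)
  expect_true(is.na(np$pr))
  # region restriction
  reg <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  mr <- pixel_metrics(pred, ref, reg)
  expect_equal(mr$counts$tp + mr$counts$tn + mr$counts$fp + mr$counts$fn, 2L)
})

test_that("Dice is the harmonic mean of precision and recall", {
  set.seed(17)
  for (i in 1:100) {
    pred <- matrix(runif(400) < runif(1, 0.05, 0.9), 20, 20)
    ref <- matrix(runif(400) < runif(1, 0.05, 0.9), 20, 20)
    m <- pixel_metrics(pred, ref)
    if (is.na(m$pr) || is.na(m$rc) || (m$pr + m$rc) == 0) next
    expect_equal(m$dsc, 2 * m$pr * m$rc / (m$pr + m$rc), tolerance = 1e-12)
  }
})

test_that("ROC and PRC behave at the extremes", {
  set.seed(21)
  ref <- matrix(runif(10000) < 0.3, 100, 100)
  perfect <- roc_prc_curves(list(matrix(as.numeric(ref), 100, 100)),
                            list(ref))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$auprc, 1)
  s <- matrix(runif(10000), 100, 100)
  a <- roc_prc_curves(list(s), list(ref))$auc
  b <- roc_prc_curves(list(1 - s), list(ref))$auc
  expect_equal(a + b, 1, tolerance = 1e-10)
  expect_error(roc_prc_curves(list(s), list(matrix(FALSE, 100, 100))),
               "single class")
})

test_that("uninformative scores give an AUC near one half", {
  set.seed(22)
  aucs <- replicate(50, {
    ref <- matrix(runif(2000) < 0.5, 40, 50)
    roc_prc_curves(list(matrix(runif(2000), 40, 50)), list(ref))$auc
  })
  expect_gt(mean(aucs), 0.49)
  expect_lt(mean(aucs), 0.51)
})

test_that("the threshold sweep reproduces an independent AUC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  s <- runif(5000)
  r <- runif(5000) < stats::plogis(3 * (s - 0.5))
  mine <- roc_prc_curves(list(matrix(s, 50, 100)), list(matrix(r, 50, 100)),
                         n_thresholds = 2001)$auc
  oracle <- as.numeric(pROC::auc(pROC::roc(r, s, quiet = TRUE)))
  expect_equal(mine, oracle, tolerance = 1e-3)
})

test_that("fold averaging interpolates onto a common grid", {
  set.seed(24)
  folds <- lapply(1:3, function(i) {
    ref <- matrix(runif(2500) < 0.3, 50, 50)
    sc <- matrix(pmin(pmax(as.numeric(ref) * 0.4 + runif(2500) * 0.6, 0), 1),
                 50, 50)
    roc_prc_curves(list(sc), list(ref))
  })
  av <- average_curves(folds)
  expect_equal(nrow(av$roc), 101L)
  expect_equal(range(av$roc$fpr), c(0, 1))
  expect_equal(av$auc_mean, mean(sapply(folds, `[[`, "auc")))
  # identical folds collapse: zero spread, mean equals each fold
  av2 <- average_curves(list(folds[[1]], folds[[1]]))
  expect_equal(max(av2$roc$tpr_sd), 0)
  expect_equal(av2$auc_sd, 0)
  expect_equal(av2$auc_mean, folds[[1]]$auc)
})

test_that("per-image kappa matches hand-computed tables", {
  # 30 both-P, 6 P/N, 6 N/P, 30 both-N: p_o = 5/6, p_e = 1/2
  l1 <- c(rep("P", 36), rep("N", 36))
  l2 <- c(rep("P", 30), rep("N", 6), rep("P", 6), rep("N", 30))
  expect_equal(grid_kappa(manual_grid_from_labels(l1),
                          manual_grid_from_labels(l2)), 2 / 3)
  # identical non-constant labels
  a <- manual_grid_from_labels(l2)
  expect_equal(grid_kappa(a, a), 1)
  # constant identical labels: perfect observed agreement
  expect_equal(grid_kappa(manual_grid_from_labels(rep("P", 72)),
                          manual_grid_from_labels(rep("P", 72))), 1)
  # ungradable segments are excluded pairwise: direct formula on the rest
  l3 <- l2; l3[1:5] <- "U"
  keep <- l3 != "U"
  po <- mean(l1[keep] == l3[keep])
  pe <- mean(l1[keep] == "P") * mean(l3[keep] == "P") +
    mean(l1[keep] == "N") * mean(l3[keep] == "N")
  expect_equal(grid_kappa(manual_grid_from_labels(l1),
                          manual_grid_from_labels(l3)),
               (po - pe) / (1 - pe), tolerance = 1e-12)
  # fewer than two jointly gradable segments
  l4 <- c("P", rep("U", 71))
  expect_true(is.na(grid_kappa(manual_grid_from_labels(l4),
                               manual_grid_from_labels(l1))))
})

test_that("independent labels give kappa centred on zero", {
  set.seed(26)
  ks <- replicate(1000, {
    l1 <- sample(c("P", "N"), 72, replace = TRUE)
    l2 <- sample(c("P", "N"), 72, replace = TRUE)
    grid_kappa(manual_grid_from_labels(l1), manual_grid_from_labels(l2))
  })
  expect_gt(mean(ks, na.rm = TRUE), -0.05)
  expect_lt(mean(ks, na.rm = TRUE), 0.05)
})

test_that("dataset kappa averages per-image values with a standard error", {
  dk <- dataset_kappa(c(0.4, 0.6))
  expect_equal(dk$kappa_mean, 0.5)
  expect_equal(dk$kappa_se, 0.1)
  expect_equal(dk$n_images, 2L)
  dk2 <- dataset_kappa(c(0.5, 0.5, 0.5, NA))
  expect_equal(dk2$kappa_se, 0)
  expect_equal(dk2$n_images, 3L)   # missing kappas excluded from n
  expect_error(dataset_kappa(c(0.4, NA)), ">= 2")
})

test_that("ICC(2,1) matches an independent reference implementation", {
  # expected values frozen from a standard two-way random-effects
  # absolute-agreement ICC implementation (single measurement)
  x <- c(1, 10, 8, 5, 5, 11, 1, 9, 2, 1, 6, 12)
  y <- c(1, 10, 8, 4, 6, 12, 1, 11, 3, 0, 7, 11)
  ic <- icc_agreement(x, y)
  expect_equal(ic$icc, 0.974039905600, tolerance = 1e-9)
  expect_equal(round(ic$lower, 2), 0.92)
  expect_equal(round(ic$upper, 2), 0.99)
  x2 <- c(3, 7, 1, 12, 5, 9, 2, 8, 6, 11, 4, 0)
  y2 <- c(6, 4, 3, 9, 10, 5, 1, 12, 2, 7, 9, 3)
  ic2 <- icc_agreement(x2, y2)
  expect_equal(ic2$icc, 0.505653812699, tolerance = 1e-9)
  expect_equal(round(ic2$lower, 2), -0.10)
  expect_equal(round(ic2$upper, 2), 0.83)
})

test_that("ICC degenerate and symmetry properties hold", {
  x <- c(4, 8, 2, 9, 5, 7, 3)
  ici <- icc_agreement(x, x)
  expect_equal(ici$icc, 1)
  # swapping raters leaves the absolute-agreement form unchanged
  y <- c(5, 7, 3, 10, 4, 6, 2)
  expect_equal(icc_agreement(x, y)$icc, icc_agreement(y, x)$icc,
               tolerance = 1e-12)
  # no variance anywhere: undefined
  flat <- icc_agreement(rep(3, 5), rep(3, 5))
  expect_true(is.na(flat$icc))
  expect_error(icc_agreement(1:2, 1:2), ">= 3")
})

test_that("heavy rater noise destroys the ICC", {
  set.seed(27)
  mean_icc <- mean(replicate(100, {
    x <- rnorm(75, 30, 3)
    y <- x + rnorm(75, 0, 30)    # noise sd far above between-image sd
    icc_agreement(x, y)$icc
  }))
  expect_lt(mean_icc, 0.2)
})

test_that("assessing a mask against itself gives perfect agreement", {
  img <- fixture_image(seed = 7, cnp_fraction = 0.28)
  t <- grid_template(img$fovea_xy, img$dd_pixels)
  a <- assess_grid(img$cnp_mask, img$gradable_mask, t)
  expect_equal(grid_kappa(a, a), 1)
})

test_that("agreement reports carry the standard table columns", {
  set.seed(28)
  as1 <- lapply(1:6, function(i) manual_grid_from_labels(
    sample(c("P", "N"), 72, TRUE, prob = c(0.7, 0.3)), image_id = i))
  as2 <- lapply(as1, function(a) {
    l <- as.character(a$label)
    flip <- sample(72, 6)
    l[flip] <- ifelse(l[flip] == "P", "N", "P")
    manual_grid_from_labels(l)
  })
  rep1 <- agreement_report(as1, as2, "grader1 vs grader2")
  expect_equal(rep1$n_images, 6L)
  expect_true(rep1$kappa > 0 && rep1$kappa <= 1)
  expect_true(rep1$icc_p_lower <= rep1$icc_perfused)
  expect_true(rep1$icc_perfused <= rep1$icc_p_upper)
  rings <- ring_agreement_report(as1, as2)
  expect_equal(rings$ring, 1:6)
  expect_true(all(rings$p_mean_1 + rings$n_mean_1 == 12))
})
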