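#' Generalized Dice loss
#'
#' The training objective is one minus the generalized Dice overlap between
#' the one-hot reference `r` and the predicted class probabilities `p`:
#' \deqn{GDL = 1 - 2 \frac{\sum_l w_l \sum_n r_{ln} p_{ln}}
#'                       {\sum_l w_l \sum_n (r_{ln} + p_{ln})},\qquad
#'       w_l = 1 / \left(\sum_n r_{ln}\right)^2}
#' The inverse-squared-size weights make the loss invariant to imbalanced
#' label distributions. When a class is absent from the reference its weight
#' is undefined (division by zero); it is then replaced by the largest
#' finite weight so the loss stays finite.
#'
#' @param reference N x L one-hot matrix (rows are pixels, columns classes).
#' @param prediction N x L matrix of class probabilities (rows sum to 1).
#' @return Scalar loss in `[0, 1]`; 0 exactly when `prediction` equals the
#'   one-hot reference.
#' @export
gdl_loss <- function(reference, prediction) {
  gdl_with_grad(reference, prediction, want_grad = FALSE)$loss
}

# loss plus dL/dp, shared by training
gdl_with_grad <- function(reference, prediction, want_grad = TRUE) {
  stopifnot(identical(dim(reference), dim(prediction)))
  sizes <- colSums(reference)
  if (all(sizes == 0)) {
    stop("reference contains no labelled pixels", call. = FALSE)
  }
  w <- ifelse(sizes > 0, 1 / sizes^2, NA_real_)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  A <- sum(w * colSums(reference * prediction))
  B <- sum(w * (colSums(reference) + colSums(prediction)))
  loss <- 1 - 2 * A / B
  if (!want_grad) return(list(loss = loss))
  # dL/dp_ln = -2 (w_l r_ln B - A w_l) / B^2
  dp <- sweep(reference, 2, w * B, "*")
  dp <- -2 * sweep(dp, 2, A * w, "-") / B^2
  list(loss = loss, dp = dp)
}
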