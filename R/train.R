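#' Training configuration
#'
#' Stochastic gradient descent with momentum and a stepped exponential
#' learning-rate decay. With batch size 1 each optimizer step samples one
#' training image; the full-scale run length of 33,000 "epochs" is read as
#' 33,000 such steps (with batch size 1 a full dataset pass is not a
#' meaningful unit at that count). Desk-scale runs simply use a smaller
#' `iterations`.
#'
#' @param iterations Number of optimizer steps (full-scale default 33000).
#' @param lr0 Initial learning rate (default 0.05).
#' @param decay Multiplicative decay factor (default 0.9).
#' @param decay_every Steps between decay applications (default 1000); the
#'   learning rate at step `s` (0-based) is
#'   `lr0 * decay^floor(s / decay_every)`.
#' @param momentum Momentum coefficient (default 0.9).
#' @param batch_size Images per step (default 1, which also acts as a
#'   regularizer).
#' @param seed Integer seed governing sampling, augmentation and dropout.
#' @param loss_region `"all_pixels"` (default) evaluates the objective over
#'   the full frame; `"gradable_only"` restricts its sums to the gradable
#'   retina.
#' @param augment `NULL` to disable augmentation, or an [augment_config()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 33000L, lr0 = 0.05, decay = 0.9,
                         decay_every = 1000L, momentum = 0.9,
                         batch_size = 1L, seed = 1L,
                         loss_region = c("all_pixels", "gradable_only"),
                         augment = augment_config()) {
  check_that(lr0 > 0, "lr0", "must be > 0")
  check_that(decay > 0 && decay <= 1, "decay", "must be in (0, 1]")
  check_that(batch_size >= 1, "batch_size", "must be >= 1")
  check_that(iterations >= 0, "iterations", "must be >= 0")
  check_that(decay_every >= 1, "decay_every", "must be >= 1")
  structure(list(iterations = as.integer(iterations), lr0 = lr0,
                 decay = decay, decay_every = as.integer(decay_every),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 loss_region = match.arg(loss_region), augment = augment),
            class = "train_config")
}

#' Learning rate at a given optimizer step
#'
#' @param step 0-based step index.
#' @param tc A [train_config()].
#' @return `lr0 * decay^floor(step / decay_every)`; e.g. with the defaults,
#'   0.05 at step 999 and 0.045 at step 1000.
#' @export
lr_at <- function(step, tc) {
  tc$lr0 * tc$decay^(step %/% tc$decay_every)
}

# one-hot (N x 2) label matrix from a CNP mask: class 1 = CNP, class 2 = rest
one_hot_cnp <- function(cnp_mask) {
  fg <- as.numeric(as.vector(cnp_mask))
  cbind(fg, 1 - fg)
}

#' Train the segmentation network
#'
#' Runs `tc$iterations` SGD-with-momentum steps. Each step samples one
#' training image uniformly, optionally applies a fresh augmentation draw,
#' computes the generalized Dice loss ([gdl_loss()]) of the softmax output
#' against the one-hot CNP reference, backpropagates, and updates all
#' parameters with learning rate [lr_at()]. Fully deterministic given
#' `tc$seed` and the initial network.
#'
#' @param images List of [angio_image()] objects, already preprocessed
#'   (cropped/resized to `net$cfg$input_side` and normalized), each with a
#'   `cnp_mask`.
#' @param net A `cnp_unet` from [build_network()].
#' @param tc A [train_config()].
#' @param verbose Print progress every 50 steps.
#' @return A list with the trained `net` and `log`, a `data.frame` of
#'   per-step `step`, `lr`, `loss`.
#' @export
train_unet <- function(images, net, tc = train_config(), verbose = FALSE) {
  if (length(images) == 0) stop("no training images", call. = FALSE)
  side <- net$cfg$input_side
  for (im in images) {
    stopifnot(inherits(im, "angio_image"), !is.null(im$cnp_mask),
              nrow(im$pixels) == side, ncol(im$pixels) == side)
  }
  vel <- lapply(net$params, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = rep(0, length(p$b))))
  log_step <- integer(tc$iterations)
  log_lr <- numeric(tc$iterations)
  log_loss <- numeric(tc$iterations)
  with_seed(tc$seed, {
    for (s in seq_len(tc$iterations)) {
      idx <- sample.int(length(images), 1)
      img <- images[[idx]]
      if (!is.null(tc$augment)) {
        img <- augment_image(img, tc$augment,
                             seed = sample.int(.Machine$integer.max, 1))
      }
      x <- matrix(as.vector(img$pixels), ncol = 1)
      ref <- one_hot_cnp(img$cnp_mask)
      out <- unet_forward(net, x, training = TRUE)
      if (tc$loss_region == "gradable_only") {
        keep <- as.vector(img$gradable_mask)
        gl <- gdl_with_grad(ref[keep, , drop = FALSE],
                            out$probs[keep, , drop = FALSE])
        dp <- matrix(0, nrow(ref), ncol(ref))
        dp[keep, ] <- gl$dp
      } else {
        gl <- gdl_with_grad(ref, out$probs)
        dp <- gl$dp
      }
      grads <- unet_backward(net, out$cache, dp)
      lr <- lr_at(s - 1L, tc)
      for (nm in names(net$params)) {
        vel[[nm]]$W <- tc$momentum * vel[[nm]]$W - lr * grads[[nm]]$W
        vel[[nm]]$b <- tc$momentum * vel[[nm]]$b - lr * grads[[nm]]$b
        net$params[[nm]]$W <- net$params[[nm]]$W + vel[[nm]]$W
        net$params[[nm]]$b <- net$params[[nm]]$b + vel[[nm]]$b
      }
      log_step[s] <- s - 1L
      log_lr[s] <- lr
      log_loss[s] <- gl$loss
      if (verbose && s %% 50 == 0) {
        message(sprintf("step %d  lr %.4f  gdl %.4f", s - 1L, lr, gl$loss))
      }
    }
  })
  list(net = net,
       log = data.frame(step = log_step, lr = log_lr, loss = log_loss))
}

#' Save or load a model checkpoint as plain text
#'
#' Serializes the network configuration and all parameters to a JSON file
#' (numbers at full precision), so trained models survive text-only
#' round-trips.
#'
#' @param net A `cnp_unet`.
#' @param path File path (`.json`).
#' @return `save_model` returns `path` invisibly; `load_model` the network.
#' @export
save_model <- function(net, path) {
  payload <- list(
    cfg = unclass(net$cfg),
    params = lapply(net$params, function(p)
      list(W = as.vector(p$W), dim = dim(p$W), b = p$b)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, payload$cfg[c(
    "depth", "base_channels", "n_classes", "dropout_rate", "input_side",
    "in_channels")])
  params <- lapply(payload$params, function(p)
    list(W = matrix(p$W, p$dim[1], p$dim[2]), b = p$b))
  structure(list(cfg = cfg, params = params), class = "cnp_unet")
}
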