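#' Encoder-decoder network configuration
#'
#' Describes a U-net style dense segmentation network: an encoder of `depth`
#' blocks (two 3x3 convolutions + 2x2 max pooling, stride 2), doubling the
#' channel count at each stage; a bridge of two 3x3 convolutions with
#' dropout; a decoder of `depth` blocks, each bilinearly upsampling by 2,
#' concatenating the corresponding encoder feature map through a skip
#' connection, and applying two 3x3 convolutions; and a final 1x1
#' convolution mapping the last `base_channels`-channel feature map to
#' `n_classes`, followed by a per-pixel softmax. All 3x3 convolutions use
#' "same" zero padding and ReLU activations, so the output retains the
#' input's spatial shape.
#'
#' @param depth Number of pooling stages (default 4).
#' @param base_channels Channels of the first encoder block (default 64).
#' @param n_classes Number of output classes (default 2: CNP, background).
#' @param dropout_rate Dropout probability in the bridge (default 0.5),
#'   active only during training.
#' @param input_side Input side in pixels; must be divisible by `2^depth`.
#' @param in_channels Input image channels (default 1, grayscale).
#' @return An object of class `network_config`.
#' @export
network_config <- function(depth = 4L, base_channels = 64L, n_classes = 2L,
                           dropout_rate = 0.5, input_side = 448L,
                           in_channels = 1L) {
  check_that(depth >= 1, "depth", "must be >= 1")
  check_that(n_classes >= 2, "n_classes", "must be >= 2")
  check_that(input_side %% 2^depth == 0, "input_side",
             sprintf("must be divisible by 2^depth = %d", 2^depth))
  check_that(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate",
             "must be in [0, 1)")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 input_side = as.integer(input_side),
                 in_channels = as.integer(in_channels)),
            class = "network_config")
}

# channel plan: encoder channels per level and bridge channels
channel_plan <- function(cfg) {
  enc <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  list(enc = enc, bridge = cfg$base_channels * 2^cfg$depth)
}

he_uniform <- function(n_in, dims) {
  lim <- sqrt(6 / n_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

init_conv <- function(c_in, c_out, k = 9L) {
  list(W = matrix(he_uniform(k * c_in, c(k * c_in, c_out)), k * c_in, c_out),
       b = rep(0, c_out))
}

#' Build (initialize) the segmentation network
#'
#' Allocates all convolution weights with He-uniform initialization and zero
#' biases, deterministically from `seed`.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnp_unet` holding `cfg` and the parameter
#'   list. Encoder feature maps have channel counts
#'   `base_channels * 2^(0:(depth-1))`; the final pre-head feature map has
#'   `base_channels` channels.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  ch <- channel_plan(cfg)
  with_seed(seed, {
    params <- list()
    c_prev <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      params[[sprintf("enc%d_conv1", i)]] <- init_conv(c_prev, ch$enc[i])
      params[[sprintf("enc%d_conv2", i)]] <- init_conv(ch$enc[i], ch$enc[i])
      c_prev <- ch$enc[i]
    }
    params$bridge_conv1 <- init_conv(c_prev, ch$bridge)
    params$bridge_conv2 <- init_conv(ch$bridge, ch$bridge)
    c_above <- ch$bridge
    for (i in rev(seq_len(cfg$depth))) {
      c_cat <- c_above + ch$enc[i]
      params[[sprintf("dec%d_conv1", i)]] <- init_conv(c_cat, ch$enc[i])
      params[[sprintf("dec%d_conv2", i)]] <- init_conv(ch$enc[i], ch$enc[i])
      c_above <- ch$enc[i]
    }
    params$head <- list(
      W = matrix(he_uniform(ch$enc[1], c(ch$enc[1], cfg$n_classes)),
                 ch$enc[1], cfg$n_classes),
      b = rep(0, cfg$n_classes))
    structure(list(cfg = cfg, params = params), class = "cnp_unet")
  })
}

#' @export
print.cnp_unet <- function(x, ...) {
  ch <- channel_plan(x$cfg)
  n_par <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf(
    "<cnp_unet> depth %d, encoder channels (%s), bridge %d, %d classes, input %dx%d, %s parameters\n",
    x$cfg$depth, paste(ch$enc, collapse = ","), ch$bridge, x$cfg$n_classes,
    x$cfg$input_side, x$cfg$input_side, format(n_par, big.mark = ",")))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. x: (H*W) x in_channels matrix (column-major pixel order).
# Returns list(probs, cache); cache holds everything backward needs.
unet_forward <- function(net, x, training = FALSE) {
  cfg <- net$cfg
  p <- net$params
  side <- cfg$input_side
  stopifnot(nrow(x) == side * side, ncol(x) == cfg$in_channels)
  cache <- list(sizes = integer(0))
  H <- side
  a <- x
  skips <- list()
  for (i in seq_len(cfg$depth)) {
    c1 <- sprintf("enc%d_conv1", i); c2 <- sprintf("enc%d_conv2", i)
    fc1 <- .conv3_fwd_cache(a, p[[c1]]$W, p[[c1]]$b, H, H)
    cache[[paste0(c1, "_xc")]] <- fc1$Xc
    cache[[paste0(c1, "_z")]] <- fc1$Y
    a1 <- relu(fc1$Y)
    fc2 <- .conv3_fwd_cache(a1, p[[c2]]$W, p[[c2]]$b, H, H)
    cache[[paste0(c2, "_xc")]] <- fc2$Xc
    cache[[paste0(c2, "_z")]] <- fc2$Y
    a2 <- relu(fc2$Y)
    skips[[i]] <- a2
    pl <- .pool2_fwd(a2, H, H)
    cache[[sprintf("pool%d_which", i)]] <- pl$which
    cache[[sprintf("pool%d_H", i)]] <- H
    a <- pl$Y
    H <- H %/% 2L
  }
  fc1 <- .conv3_fwd_cache(a, p$bridge_conv1$W, p$bridge_conv1$b, H, H)
  cache$bridge_xc1 <- fc1$Xc
  cache$bridge_z1 <- fc1$Y
  a1 <- relu(fc1$Y)
  fc2 <- .conv3_fwd_cache(a1, p$bridge_conv2$W, p$bridge_conv2$b, H, H)
  cache$bridge_xc2 <- fc2$Xc
  cache$bridge_z2 <- fc2$Y
  a2 <- relu(fc2$Y)
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    dm <- matrix(rbinom(length(a2), 1, keep) / keep, nrow(a2), ncol(a2))
    cache$dropout_mask <- dm
    a2 <- a2 * dm
  }
  a <- a2
  for (i in rev(seq_len(cfg$depth))) {
    c1 <- sprintf("dec%d_conv1", i); c2 <- sprintf("dec%d_conv2", i)
    cache[[sprintf("up%d_H", i)]] <- H
    u <- .up2_fwd(a, H, H)
    H <- H * 2L
    catm <- cbind(skips[[i]], u)
    cache[[sprintf("cat%d_nskip", i)]] <- ncol(skips[[i]])
    fc1 <- .conv3_fwd_cache(catm, p[[c1]]$W, p[[c1]]$b, H, H)
    cache[[paste0(c1, "_xc")]] <- fc1$Xc
    cache[[paste0(c1, "_z")]] <- fc1$Y
    a1 <- relu(fc1$Y)
    fc2 <- .conv3_fwd_cache(a1, p[[c2]]$W, p[[c2]]$b, H, H)
    cache[[paste0(c2, "_xc")]] <- fc2$Xc
    cache[[paste0(c2, "_z")]] <- fc2$Y
    a2 <- relu(fc2$Y)
    a <- a2
  }
  cache$head_x <- a
  z <- sweep(a %*% p$head$W, 2, p$head$b, "+")
  probs <- softmax_rows(z)
  cache$probs <- probs
  list(probs = probs, cache = cache)
}

# Backward pass from dL/dprobs; returns gradient list shaped like params.
unet_backward <- function(net, cache, dprobs) {
  cfg <- net$cfg
  p <- net$params
  probs <- cache$probs
  # softmax backward
  dz <- probs * (dprobs - rowSums(dprobs * probs))
  grads <- list()
  grads$head <- list(W = crossprod(cache$head_x, dz),
                     b = colSums(dz))
  da <- tcrossprod(dz, p$head$W)
  dskips <- vector("list", cfg$depth)
  H <- cfg$input_side
  for (i in seq_len(cfg$depth)) {
    c1 <- sprintf("dec%d_conv1", i); c2 <- sprintf("dec%d_conv2", i)
    da <- da * (cache[[paste0(c2, "_z")]] > 0)
    g2 <- .conv3_bwd(cache[[paste0(c2, "_xc")]], p[[c2]]$W, da, H, H, TRUE)
    grads[[c2]] <- list(W = g2$dW, b = as.numeric(g2$db))
    da <- g2$dX * (cache[[paste0(c1, "_z")]] > 0)
    g1 <- .conv3_bwd(cache[[paste0(c1, "_xc")]], p[[c1]]$W, da, H, H, TRUE)
    grads[[c1]] <- list(W = g1$dW, b = as.numeric(g1$db))
    nskip <- cache[[sprintf("cat%d_nskip", i)]]
    dskips[[i]] <- g1$dX[, seq_len(nskip), drop = FALSE]
    du <- g1$dX[, -seq_len(nskip), drop = FALSE]
    Hin <- cache[[sprintf("up%d_H", i)]]
    da <- .up2_bwd(du, Hin, Hin)
    H <- Hin
  }
  if (!is.null(cache$dropout_mask)) da <- da * cache$dropout_mask
  da <- da * (cache$bridge_z2 > 0)
  g <- .conv3_bwd(cache$bridge_xc2, p$bridge_conv2$W, da, H, H, TRUE)
  grads$bridge_conv2 <- list(W = g$dW, b = as.numeric(g$db))
  da <- g$dX * (cache$bridge_z1 > 0)
  g <- .conv3_bwd(cache$bridge_xc1, p$bridge_conv1$W, da, H, H, TRUE)
  grads$bridge_conv1 <- list(W = g$dW, b = as.numeric(g$db))
  da <- g$dX
  for (i in rev(seq_len(cfg$depth))) {
    c1 <- sprintf("enc%d_conv1", i); c2 <- sprintf("enc%d_conv2", i)
    Hup <- cache[[sprintf("pool%d_H", i)]]
    da <- .pool2_bwd(da, cache[[sprintf("pool%d_which", i)]], Hup, Hup)
    da <- da + dskips[[i]]
    H <- Hup
    da <- da * (cache[[paste0(c2, "_z")]] > 0)
    g2 <- .conv3_bwd(cache[[paste0(c2, "_xc")]], p[[c2]]$W, da, H, H, TRUE)
    grads[[c2]] <- list(W = g2$dW, b = as.numeric(g2$db))
    da <- g2$dX * (cache[[paste0(c1, "_z")]] > 0)
    first <- i == 1L
    g1 <- .conv3_bwd(cache[[paste0(c1, "_xc")]], p[[c1]]$W, da, H, H, !first)
    grads[[c1]] <- list(W = g1$dW, b = as.numeric(g1$db))
    if (!first) da <- g1$dX
  }
  grads
}

#' Predict a per-pixel CNP probability map
#'
#' Runs the network in inference mode (dropout disabled); deterministic
#' given the model.
#'
#' @param net A trained `cnp_unet` (see [train_unet()]).
#' @param img An [angio_image()] already at the model input size, normalized.
#' @return An object of class `probability_map`: list with `probs` (matrix
#'   of CNP-class probabilities in `[0, 1]`, same shape as the input) and
#'   `image_id`.
#' @export
predict_cnp <- function(net, img) {
  side <- net$cfg$input_side
  px <- if (inherits(img, "angio_image")) img$pixels else img
  if (nrow(px) != side || ncol(px) != side) {
    stop(sprintf("input is %dx%d px but the model expects %dx%d",
                 nrow(px), ncol(px), side, side), call. = FALSE)
  }
  x <- matrix(as.vector(px), ncol = 1)
  out <- unet_forward(net, x, training = FALSE)
  structure(list(probs = matrix(out$probs[, 1], side, side),
                 image_id = if (inherits(img, "angio_image"))
                   img$image_id else "img"),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s: %dx%d px, mean CNP prob %.3f\n",
              x$image_id, nrow(x$probs), ncol(x$probs), mean(x$probs)))
  invisible(x)
}

#' Threshold a probability map into a binary CNP mask
#'
#' Pixels with probability strictly greater than `threshold` become CNP;
#' the default 0.5 is the centred operating point at which the automated
#' segmentation is treated as an independent grader.
#'
#' @param pm A `probability_map` (or a bare numeric matrix).
#' @param threshold Probability threshold in `(0, 1)`.
#' @return Logical matrix.
#' @export
binarize <- function(pm, threshold = 0.5) {
  check_that(threshold > 0 && threshold < 1, "threshold",
             "must be in (0, 1)")
  probs <- if (inherits(pm, "probability_map")) pm$probs else pm
  probs > threshold
}
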