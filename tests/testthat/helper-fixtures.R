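# Shared fixtures are generated once per test run and memoised here; all
# synthetic frames use the small 512 px side so the suite stays fast.
.fixture_env <- new.env(parent = emptyenv())

fixture_image <- function(seed = 7, cnp_fraction = 0.28, side = 512) {
  key <- sprintf("img_%d_%g_%d", seed, cnp_fraction, side)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_image(
      synthetic_spec(seed = seed, image_side = side,
                     cnp_fraction = cnp_fraction))
  }
  .fixture_env[[key]]
}

# a small all-gradable scene with a template whose 15-DD radius fits inside
fixture_template <- function(side = 512, dd = 16) {
  grid_template(fovea_xy = c(side / 2, side / 2), dd_pixels = dd)
}

# independent brute-force evaluation of the generalized Dice loss, written
# as plain loops so it shares no code with the package implementation
brute_force_gdl <- function(ref, pred) {
  L <- ncol(ref)
  w <- numeric(L)
  for (l in seq_len(L)) {
    s <- 0
    for (n in seq_len(nrow(ref))) s <- s + ref[n, l]
    w[l] <- if (s > 0) 1 / s^2 else NA_real_
  }
  w[is.na(w)] <- max(w, na.rm = TRUE)
  num <- 0; den <- 0
  for (l in seq_len(L)) {
    si <- 0; ss <- 0
    for (n in seq_len(nrow(ref))) {
      si <- si + ref[n, l] * pred[n, l]
      ss <- ss + ref[n, l] + pred[n, l]
    }
    num <- num + w[l] * si
    den <- den + w[l] * ss
  }
  1 - 2 * num / den
}

# random one-hot reference plus probability prediction on a small grid
random_gdl_case <- function(n = 40) {
  fg <- rbinom(n, 1, runif(1, 0.1, 0.9))
  ref <- unname(cbind(fg, 1 - fg))
  p1 <- runif(n)
  pred <- unname(cbind(p1, 1 - p1))
  list(ref = ref, pred = pred)
}
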