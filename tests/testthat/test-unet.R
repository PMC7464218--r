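test_that("default architecture has four pooling stages ending in 64 channels", {
  cfg <- network_config(input_side = 64)   # default depth/channels
  net <- build_network(cfg, seed = 1)
  expect_equal(cfg$depth, 4L)
  # encoder channel sequence 64, 128, 256, 512 read off the weight shapes
  for (i in 1:4) {
    W <- net$params[[sprintf("enc%d_conv2", i)]]$W
    expect_equal(ncol(W), 64L * 2L^(i - 1L))
  }
  # final decoder block emits 64 channels into the 1x1 head
  expect_equal(ncol(net$params$dec1_conv2$W), 64L)
  expect_equal(dim(net$params$head$W), c(64L, 2L))
  # forward pass preserves the spatial shape
  x <- matrix(rnorm(64 * 64), ncol = 1)
  out <- cnpquant:::unet_forward(net, x)
  expect_equal(dim(out$probs), c(64L * 64L, 2L))
})

test_that("small configurations satisfy the output shape contract", {
  cfg <- network_config(depth = 2, base_channels = 8, input_side = 64)
  net <- build_network(cfg, seed = 2)
  x <- matrix(rnorm(64 * 64), ncol = 1)
  out <- cnpquant:::unet_forward(net, x)
  expect_equal(dim(out$probs), c(4096L, 2L))
  expect_lt(max(abs(rowSums(out$probs) - 1)), 1e-6)
  expect_true(all(out$probs >= 0 & out$probs <= 1))
  expect_error(network_config(depth = 3, input_side = 100), "input_side")
})

test_that("generalized Dice loss matches its printed form", {
  # perfect prediction
  ref <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(gdl_loss(ref, ref), 0)
  # hand-evaluated case: two pixels, uniform prediction
  r2 <- rbind(c(1, 0), c(0, 1))
  p2 <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(gdl_loss(r2, p2), 0.5)
  # symmetric under class relabelling
  set.seed(4)
  cs <- random_gdl_case(30)
  expect_equal(gdl_loss(cs$ref, cs$pred),
               gdl_loss(cs$ref[, 2:1], cs$pred[, 2:1]))
})

test_that("loss agrees with an independent brute-force evaluation", {
  set.seed(9)
  for (i in 1:20) {
    cs <- random_gdl_case(30)
    expect_equal(gdl_loss(cs$ref, cs$pred),
                 brute_force_gdl(cs$ref, cs$pred), tolerance = 1e-12)
    expect_gte(gdl_loss(cs$ref, cs$pred), 0)
    expect_lte(gdl_loss(cs$ref, cs$pred), 1)
  }
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(5)
  cs <- random_gdl_case(25)
  gl <- cnpquant:::gdl_with_grad(cs$ref, cs$pred)
  eps <- 1e-7
  for (i in c(1, 13, 40)) {
    pp <- cs$pred; pp[i] <- pp[i] + eps
    pn <- cs$pred; pn[i] <- pn[i] - eps
    num <- (gdl_loss(cs$ref, pp) - gdl_loss(cs$ref, pn)) / (2 * eps)
    expect_equal(gl$dp[i], num, tolerance = 1e-5)
  }
})

test_that("the learning-rate schedule decays stepwise", {
  tc <- train_config(iterations = 10)
  expect_identical(lr_at(0, tc), 0.05)
  expect_identical(lr_at(999, tc), 0.05)
  expect_identical(lr_at(1000, tc), 0.05 * 0.9)
  expect_identical(lr_at(2500, tc), 0.05 * 0.9^2)
})

test_that("zero training iterations leave the network at initialization", {
  img <- fixture_image(seed = 7, cnp_fraction = 0.28)
  img <- central_crop_resize(img, 512, 64)
  img$pixels <- normalize_image(img$pixels)
  cfg <- network_config(depth = 2, base_channels = 8, input_side = 64)
  net <- build_network(cfg, seed = 3)
  fit <- train_unet(list(img), net, train_config(iterations = 0))
  expect_identical(fit$net$params, net$params)
  expect_equal(nrow(fit$log), 0)
})

test_that("short training reduces the loss and logs the schedule", {
  imgs <- lapply(c(7, 8, 9), function(s) {
    im <- fixture_image(seed = s, cnp_fraction = 0.28)
    im <- central_crop_resize(im, 512, 64)
    im$pixels <- normalize_image(im$pixels)
    im
  })
  cfg <- network_config(depth = 2, base_channels = 8, input_side = 64)
  net <- build_network(cfg, seed = 3)
  tc <- train_config(iterations = 80, lr0 = 0.01, seed = 1)
  fit <- train_unet(imgs, net, tc)
  expect_equal(fit$log$lr, rep(0.01, 80))
  expect_lt(median(fit$log$loss[61:80]), median(fit$log$loss[1:20]))
  # deterministic re-run
  fit2 <- train_unet(imgs, build_network(cfg, seed = 3), tc)
  expect_identical(fit$log$loss, fit2$log$loss)
  expect_identical(fit$net$params, fit2$net$params)
  expect_error(train_unet(list(), net, tc), "no training images")
})

test_that("prediction is deterministic and respects the softmax contract", {
  img <- fixture_image(seed = 7, cnp_fraction = 0.28)
  img <- central_crop_resize(img, 512, 64)
  img$pixels <- normalize_image(img$pixels)
  cfg <- network_config(depth = 2, base_channels = 8, input_side = 64)
  net <- build_network(cfg, seed = 3)
  p1 <- predict_cnp(net, img)
  p2 <- predict_cnp(net, img)
  expect_identical(p1$probs, p2$probs)
  expect_true(all(p1$probs >= 0 & p1$probs <= 1))
  expect_equal(dim(p1$probs), dim(img$pixels))
  wrong <- fixture_image(seed = 7, cnp_fraction = 0.28)
  expect_error(predict_cnp(net, wrong), "expects")
})

test_that("binarize applies a strict threshold and is monotone", {
  p <- matrix(0.6, 4, 4)
  expect_true(all(binarize(p, 0.5)))
  expect_false(any(binarize(matrix(0.5, 4, 4), 0.5)))   # strict >
  set.seed(6)
  pm <- matrix(runif(100), 10, 10)
  m1 <- binarize(pm, 0.3)
  m2 <- binarize(pm, 0.6)
  expect_true(all(m1 | !m2))   # raising the threshold never adds pixels
})

test_that("model checkpoints round-trip through the text format", {
  cfg <- network_config(depth = 2, base_channels = 4, input_side = 32)
  net <- build_network(cfg, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(net, path)
  back <- load_model(path)
  expect_equal(back$cfg, net$cfg)
  expect_equal(back$params, net$params, tolerance = 1e-13)
  x <- matrix(rnorm(32 * 32), ncol = 1)
  expect_equal(cnpquant:::unet_forward(back, x)$probs,
               cnpquant:::unet_forward(net, x)$probs, tolerance = 1e-12)
})
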