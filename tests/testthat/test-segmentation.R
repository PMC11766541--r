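test_that("model configs validate and parameter counts order by encoder depth", {
  expect_error(seg_model_config("rn18", input_tile_px = 100), "divisible by 32")
  expect_error(seg_model_config("rn18", width_multiplier = 2), "width_multiplier")
  m18 <- build_model(seg_model_config("rn18", 0.25, 64))
  m34 <- build_model(seg_model_config("rn34", 0.25, 64))
  m50 <- build_model(seg_model_config("rn50", 0.25, 64))
  expect_gt(n_parameters(m34), n_parameters(m18))
  expect_gt(n_parameters(m50), n_parameters(m34))
})

test_that("the network maps HxWx3 to an HxW probability map through a 32x bottleneck", {
  m <- build_model(seg_model_config("rn18", 0.25, 64), seed = 2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  # trace the encoder by hand to inspect the bottleneck
  f <- function(node, v) standcount:::exec_forward(node, v, m$env, FALSE)$y
  s <- f(m$arch$stem, x)
  p <- f(m$arch$pool, s)
  e <- f(m$arch$stage4, f(m$arch$stage3, f(m$arch$stage2, f(m$arch$stage1, p))))
  expect_equal(dim(e)[1:2], c(64 / 32, 64 / 32))
  expect_equal(dim(e)[3], round(512 * 0.25))
  # at full width and a 512 px tile the same arithmetic gives 512 x 16 x 16
  full <- build_model(seg_model_config("rn18", 1, 512))
  expect_equal(dim(full$env[["par.s4.2.c2.W"]])[4], 512)
  prob <- standcount:::seg_forward(m, x)$prob
  expect_equal(dim(prob), c(64, 64, 1, 2))
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("DiceCE equals cross-entropy plus Dice complement", {
  # perfect hard prediction: loss vanishes
  t <- matrix(0, 16, 16); t[4:8, 4:8] <- 1
  expect_lt(dice_ce_loss(t, t), 1e-3)
  # uniform 0.5 prediction on empty target: BCE = ln 2, Dice term -> 1
  n <- 64 * 64
  p <- matrix(0.5, 64, 64); z <- matrix(0, 64, 64)
  closed_form <- log(2) + 1 - 1 / (0.5 * n + 1)
  expect_equal(dice_ce_loss(p, z), closed_form, tolerance = 1e-12)
  expect_equal(closed_form, 1.693, tolerance = 1e-3)
  expect_error(dice_ce_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes")
  # non-negativity and finiteness on random inputs
  set.seed(1)
  for (k in 1:200) {
    pr <- matrix(runif(64), 8, 8)
    tg <- matrix(rbinom(64, 1, 0.5), 8, 8)
    l <- dice_ce_loss(pr, tg)
    expect_true(is.finite(l) && l >= 0)
  }
})

test_that("loss gradient matches finite differences", {
  set.seed(3)
  p <- matrix(runif(25, 0.05, 0.95), 5, 5)
  t <- matrix(rbinom(25, 1, 0.4), 5, 5)
  g <- standcount:::dice_ce_grad(p, t)
  for (i in c(1, 7, 20)) {
    eps <- 1e-6
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    num <- (dice_ce_loss(pp, t) - dice_ce_loss(pm, t)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("augmentation preserves co-registration and mask values", {
  sc <- generate_field(clean_spec(128), seed = 6)
  ident <- aug_config(rotate_deg_max = 0, scale_jitter_max = 0,
                      brightness_contrast = FALSE, gamma_jitter = FALSE,
                      hflip = FALSE, vflip = FALSE)
  out <- augment(sc$image, sc$truth_mask, ident, seed = 1)
  expect_identical(out$image, sc$image)
  expect_identical(out$mask, sc$truth_mask)
  # flips preserve the foreground count exactly
  fl <- aug_config(0, 0, FALSE, FALSE, hflip = TRUE, vflip = TRUE)
  for (s in 1:5) {
    out <- augment(sc$image, sc$truth_mask, fl, seed = s)
    expect_identical(sum(out$mask > 0), sum(sc$truth_mask > 0))
  }
  # an exact 90 degree rotation of a square tile permutes pixels: area kept
  r90 <- standcount:::rotate_pair(sc$image, sc$truth_mask, 90)
  expect_lt(abs(sum(r90$mask > 0) / sum(sc$truth_mask > 0) - 1), 0.02)
  # full recipe keeps the mask two-valued and shapes co-registered
  full <- augment(sc$image, sc$truth_mask, aug_config(), seed = 11)
  expect_true(all(full$mask %in% c(0L, 255L)))
  expect_identical(dim(full$image)[1:2], dim(full$mask))
})

test_that("the linear learning-rate schedule hits its endpoints", {
  tc <- train_config(epochs = 100, lr_start = 1e-4, lr_end = 1e-6)
  expect_equal(standcount:::lr_at_epoch(tc, 0), 1e-4)
  expect_equal(standcount:::lr_at_epoch(tc, 99), 1e-6)
  tc1 <- train_config(epochs = 1)
  expect_equal(standcount:::lr_at_epoch(tc1, 0), 1e-4)
  expect_error(train_config(lr_start = 1e-6, lr_end = 1e-4), "lr_start > lr_end")
})

test_that("a small model learns a color-thresholding toy task", {
  # target = green-dominant pixels, the signal the field scenes carry
  set.seed(21)
  mk_tile <- function() {
    img <- array(runif(32 * 32 * 3, 0, 0.4), c(32, 32, 3))
    ci <- sample(8:24, 1); cj <- sample(8:24, 1)
    img[ci + (-3:3), cj + (-3:3), 2] <- 0.8
    mask <- matrix(0L, 32, 32)
    mask[ci + (-3:3), cj + (-3:3)] <- 255L
    list(img = img, mask = mask)
  }
  tiles <- replicate(16, mk_tile(), simplify = FALSE)
  ds <- tibble::tibble(image = lapply(tiles, `[[`, "img"),
                       mask = lapply(tiles, `[[`, "mask"))
  m <- build_model(seg_model_config("rn18", 0.1, 32), seed = 4)
  tc <- train_config(epochs = 10, batch_size = 8, lr_start = 1e-3, lr_end = 1e-4,
                     seed = 2, augment = NULL)
  fit <- train(m, ds, ds, tc)
  h <- tidy(fit)
  expect_equal(nrow(h), 10)
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_equal(h$lr[1], 1e-3)
  expect_s3_class(glance(fit), "tbl_df")
  expect_error(train(m, ds[0, ], ds, tc), "empty")
})

test_that("training is reproducible for a fixed seed", {
  set.seed(33)
  img <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  ds <- tibble::tibble(image = lapply(1:4, function(i) img[, , , i]),
                       mask = lapply(1:4, function(i) {
                         m <- matrix(0L, 32, 32); m[10:20, 10:20] <- 255L; m
                       }))
  tc <- train_config(epochs = 1, batch_size = 4, lr_start = 1e-3, lr_end = 1e-4,
                     seed = 9, augment = NULL)
  m <- build_model(seg_model_config("rn18", 0.1, 32), seed = 5)
  f1 <- train(m, ds, ds, tc)
  f2 <- train(m, ds, ds, tc)
  expect_equal(f1$history$train_loss[1], f2$history$train_loss[1], tolerance = 1e-6)
})

test_that("tiled prediction covers any image size and respects locality", {
  m <- build_model(seg_model_config("rn18", 0.1, 32), seed = 8)
  # force an always-background head: bias very negative
  m$env[["par.head.b"]] <- -20
  img <- array(runif(80 * 70 * 3), c(80, 70, 3))
  pm <- predict_mask(m, img, tile_px = 32, overlap = 8)
  expect_identical(dim(pm), c(80L, 70L))
  expect_true(all(pm == 0L))
  # image smaller than one tile: pad, predict, crop back
  small <- array(runif(20 * 25 * 3), c(20, 25, 3))
  expect_identical(dim(predict_mask(m, small, tile_px = 32)), c(20L, 25L))
  # regions covered by a single tile in both settings agree across overlaps
  m2 <- build_model(seg_model_config("rn18", 0.1, 32), seed = 9)
  img2 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p0 <- predict_mask(m2, img2, tile_px = 32, overlap = 0)
  p1 <- predict_mask(m2, img2, tile_px = 32, overlap = 16)
  expect_identical(p0[1:16, 1:16], p1[1:16, 1:16])
})
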