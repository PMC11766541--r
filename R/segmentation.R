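#' Segmentation model configuration
#'
#' Encoder--decoder (U-Net style) configuration. The encoder follows the
#' ResNet family: `"rn18"`/`"rn34"` use basic blocks with stage depths
#' \[2,2,2,2\] / \[3,4,6,3\]; `"rn50"` uses bottleneck blocks \[3,4,6,3\]
#' (channel expansion 4). The decoder upsamples five times with skip
#' concatenations from every encoder resolution, so the output probability
#' map matches the input spatial size. At `width_multiplier = 1` and
#' `input_tile_px = 512` the rn18 bottleneck is 512 channels at 16 x 16 —
#' the full-scale architecture; smaller multipliers shrink every stage
#' proportionally for CPU-scale work.
#'
#' @param encoder `"rn18"`, `"rn34"` or `"rn50"`.
#' @param width_multiplier channel width factor in (0, 1].
#' @param input_tile_px input tile side, divisible by 32 (default 512).
#' @return an object of class `seg_model_config`.
#' @export
seg_model_config <- function(encoder = c("rn18", "rn34", "rn50"),
                             width_multiplier = 1, input_tile_px = 512L) {
  encoder <- match.arg(encoder)
  check_number(width_multiplier, "width_multiplier", min = 1e-6, max = 1)
  check_number(input_tile_px, "input_tile_px", min = 32)
  if (input_tile_px %% 32 != 0) stopf("input_tile_px must be divisible by 32")
  structure(list(encoder = encoder, width_multiplier = width_multiplier,
                 input_tile_px = as.integer(input_tile_px)),
            class = "seg_model_config")
}

enc_depths <- function(encoder) {
  switch(encoder, rn18 = c(2L, 2L, 2L, 2L), rn34 = c(3L, 4L, 6L, 3L),
         rn50 = c(3L, 4L, 6L, 3L))
}

wch <- function(c, w) max(2L, as.integer(round(c * w)))

basic_block <- function(env, prefix, cin, cout, stride) {
  body <- node_seq(
    node_conv(env, paste0(prefix, ".c1"), cin, cout, k = 3, stride = stride),
    node_bn(env, paste0(prefix, ".b1"), cout),
    node_relu(),
    node_conv(env, paste0(prefix, ".c2"), cout, cout, k = 3),
    node_bn(env, paste0(prefix, ".b2"), cout)
  )
  shortcut <- if (stride != 1 || cin != cout) {
    node_seq(node_conv(env, paste0(prefix, ".sc"), cin, cout, k = 1, stride = stride, pad = 0),
             node_bn(env, paste0(prefix, ".sb"), cout))
  }
  node_residual(body, shortcut)
}

bottleneck_block <- function(env, prefix, cin, cmid, stride) {
  cout <- 4L * cmid
  body <- node_seq(
    node_conv(env, paste0(prefix, ".c1"), cin, cmid, k = 1, pad = 0),
    node_bn(env, paste0(prefix, ".b1"), cmid),
    node_relu(),
    node_conv(env, paste0(prefix, ".c2"), cmid, cmid, k = 3, stride = stride),
    node_bn(env, paste0(prefix, ".b2"), cmid),
    node_relu(),
    node_conv(env, paste0(prefix, ".c3"), cmid, cout, k = 1, pad = 0),
    node_bn(env, paste0(prefix, ".b3"), cout)
  )
  shortcut <- if (stride != 1 || cin != cout) {
    node_seq(node_conv(env, paste0(prefix, ".sc"), cin, cout, k = 1, stride = stride, pad = 0),
             node_bn(env, paste0(prefix, ".sb"), cout))
  }
  node_residual(body, shortcut)
}

dec_block <- function(env, prefix, cin, cout) {
  node_seq(
    node_conv(env, paste0(prefix, ".c1"), cin, cout, k = 3),
    node_bn(env, paste0(prefix, ".b1"), cout),
    node_relu(),
    node_conv(env, paste0(prefix, ".c2"), cout, cout, k = 3),
    node_bn(env, paste0(prefix, ".b2"), cout),
    node_relu()
  )
}

#' Build a segmentation model
#'
#' Constructs and He-initializes the encoder--decoder network described by a
#' [seg_model_config()]. The model maps `H x W x 3` RGB input to an
#' `H x W` plant-probability map in \[0, 1\].
#'
#' @param config a [seg_model_config()].
#' @param seed seed for weight initialization.
#' @return an object of class `seg_model`.
#' @export
build_model <- function(config, seed = 1) {
  if (!inherits(config, "seg_model_config")) stopf("`config` must be a seg_model_config")
  w <- config$width_multiplier
  depths <- enc_depths(config$encoder)
  bottle <- config$encoder == "rn50"
  base <- vapply(c(64, 64, 128, 256, 512), wch, integer(1), w = w)
  expansion <- if (bottle) 4L else 1L
  env <- new.env(parent = emptyenv())
  with_seed(seed, {
    stem <- node_seq(
      node_conv(env, "stem.c", 3L, base[1], k = 7, stride = 2, pad = 3),
      node_bn(env, "stem.b", base[1]),
      node_relu()
    )
    make_stage <- function(id, cin, cmid, stride, n_blocks) {
      blocks <- vector("list", n_blocks)
      for (b in seq_len(n_blocks)) {
        st <- if (b == 1) stride else 1L
        ci <- if (b == 1) cin else cmid * expansion
        blocks[[b]] <- if (bottle) {
          bottleneck_block(env, sprintf("s%d.%d", id, b), ci, cmid, st)
        } else {
          basic_block(env, sprintf("s%d.%d", id, b), ci, cmid, st)
        }
      }
      do.call(node_seq, blocks)
    }
    c_out <- base[2:5] * expansion
    stage1 <- make_stage(1, base[1], base[2], 1L, depths[1])
    stage2 <- make_stage(2, c_out[1], base[3], 2L, depths[2])
    stage3 <- make_stage(3, c_out[2], base[4], 2L, depths[3])
    stage4 <- make_stage(4, c_out[3], base[5], 2L, depths[4])
    dch <- vapply(c(256, 128, 64, 32, 16), wch, integer(1), w = w)
    dec1 <- dec_block(env, "d1", c_out[4] + c_out[3], dch[1])
    dec2 <- dec_block(env, "d2", dch[1] + c_out[2], dch[2])
    dec3 <- dec_block(env, "d3", dch[2] + c_out[1], dch[3])
    dec4 <- dec_block(env, "d4", dch[3] + base[1], dch[4])
    dec5 <- dec_block(env, "d5", dch[4], dch[5])
    head <- node_conv(env, "head", dch[5], 1L, k = 3, bias = TRUE)
    # prior-probability bias init: plant discs cover a few percent of a
    # field, so starting the sigmoid near that prior avoids the early
    # all-background collapse that sparse-foreground Dice training shows
    env[["par.head.b"]] <- -3
    arch <- list(stem = stem, pool = node_maxpool(3, 2, 1),
                 stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 stage4 = stage4, dec1 = dec1, dec2 = dec2, dec3 = dec3,
                 dec4 = dec4, dec5 = dec5, head = head)
    structure(list(config = config, arch = arch, env = env), class = "seg_model")
  })
}

#' Number of trainable parameters of a segmentation model
#' @param model a `seg_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(param_names(model), function(n) length(model$env[[n]]), numeric(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s encoder, width %.2f, tile %d px, %s parameters\n",
              x$config$encoder, x$config$width_multiplier, x$config$input_tile_px,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# full forward pass; x is (H, W, 3, N); returns probabilities (H, W, 1, N)
# and, when `keep_cache`, everything needed for backprop
seg_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  a <- model$arch; env <- model$env
  f <- function(node, x) exec_forward(node, x, env, train)
  r_stem <- f(a$stem, x)
  r_pool <- f(a$pool, r_stem$y)
  r_s1 <- f(a$stage1, r_pool$y)
  r_s2 <- f(a$stage2, r_s1$y)
  r_s3 <- f(a$stage3, r_s2$y)
  r_s4 <- f(a$stage4, r_s3$y)
  u1 <- upsample2_forward(r_s4$y); x1 <- concat_c(u1, r_s3$y); r_d1 <- f(a$dec1, x1)
  u2 <- upsample2_forward(r_d1$y); x2 <- concat_c(u2, r_s2$y); r_d2 <- f(a$dec2, x2)
  u3 <- upsample2_forward(r_d2$y); x3 <- concat_c(u3, r_s1$y); r_d3 <- f(a$dec3, x3)
  u4 <- upsample2_forward(r_d3$y); x4 <- concat_c(u4, r_stem$y); r_d4 <- f(a$dec4, x4)
  u5 <- upsample2_forward(r_d4$y); r_d5 <- f(a$dec5, u5)
  r_head <- f(a$head, r_d5$y)
  prob <- 1 / (1 + exp(-r_head$y))
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, cache = list(
    stem = r_stem$cache, pool = r_pool$cache, s1 = r_s1$cache, s2 = r_s2$cache,
    s3 = r_s3$cache, s4 = r_s4$cache, d1 = r_d1$cache, d2 = r_d2$cache,
    d3 = r_d3$cache, d4 = r_d4$cache, d5 = r_d5$cache, head = r_head$cache,
    nch = list(s4 = dim(r_s4$y)[3], d1 = dim(r_d1$y)[3], d2 = dim(r_d2$y)[3],
               d3 = dim(r_d3$y)[3], d4 = dim(r_d4$y)[3])
  ))
}

# backward pass from d(loss)/d(prob); accumulates gradients into `grads` env
seg_backward <- function(model, cache, prob, dprob, grads) {
  a <- model$arch; env <- model$env
  b <- function(node, cc, dy) exec_backward(node, cc, dy, env, grads)
  dlogit <- dprob * prob * (1 - prob)
  d5in <- b(a$head, cache$head, dlogit)
  du5 <- b(a$dec5, cache$d5, d5in)
  dd4 <- upsample2_backward(du5)
  dx4 <- b(a$dec4, cache$d4, dd4)
  n4 <- cache$nch$d3                        # channels of upsampled d3 part
  du4 <- dx4[, , seq_len(n4), , drop = FALSE]
  dstem_skip <- dx4[, , -seq_len(n4), , drop = FALSE]
  dd3 <- upsample2_backward(du4)
  dx3 <- b(a$dec3, cache$d3, dd3)
  n3 <- cache$nch$d2
  du3 <- dx3[, , seq_len(n3), , drop = FALSE]
  ds1_skip <- dx3[, , -seq_len(n3), , drop = FALSE]
  dd2 <- upsample2_backward(du3)
  dx2 <- b(a$dec2, cache$d2, dd2)
  n2 <- cache$nch$d1
  du2 <- dx2[, , seq_len(n2), , drop = FALSE]
  ds2_skip <- dx2[, , -seq_len(n2), , drop = FALSE]
  dd1 <- upsample2_backward(du2)
  dx1 <- b(a$dec1, cache$d1, dd1)
  n1 <- cache$nch$s4
  du1 <- dx1[, , seq_len(n1), , drop = FALSE]
  ds3_skip <- dx1[, , -seq_len(n1), , drop = FALSE]
  ds4 <- upsample2_backward(du1)
  ds3 <- b(a$stage4, cache$s4, ds4) + ds3_skip
  ds2 <- b(a$stage3, cache$s3, ds3) + ds2_skip
  ds1 <- b(a$stage2, cache$s2, ds2) + ds1_skip
  dpool <- b(a$stage1, cache$s1, ds1)
  dstem <- .maxpool_backward(dpool, cache$pool$argmax, cache$pool$xdim) + dstem_skip
  b(a$stem, cache$stem, dstem)
}

#' Combined Dice + cross-entropy segmentation loss
#'
#' `loss = BCE(pred, target) + (1 - DiceSimilarity(pred, target))` with
#' `DiceSimilarity = (2 * sum(pred*target) + eps) / (sum(pred) + sum(target)
#' + eps)` and smoothing `eps = 1`. Sums run over the full batch. The
#' cross-entropy term uses the binary (two-class) formulation, matching the
#' single-channel mask output.
#'
#' @param pred numeric array/matrix of predicted probabilities.
#' @param target mask of the same shape; any value > 0 counts as foreground.
#' @param eps Dice smoothing constant.
#' @return non-negative scalar loss.
#' @export
dice_ce_loss <- function(pred, target, eps = 1) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target))) {
    stopf("pred and target shapes differ")
  }
  t <- as.numeric(target > 0)
  p <- as.numeric(pred)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  dice <- (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  ce + (1 - dice)
}

# gradient of dice_ce_loss w.r.t. predicted probabilities
dice_ce_grad <- function(pred, target, eps = 1) {
  t <- as.numeric(target > 0)
  p <- as.numeric(pred)
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  dce <- (-(t / pc) + (1 - t) / (1 - pc)) / n
  sp <- sum(p); st <- sum(t); spt <- sum(p * t)
  denom <- (sp + st + eps)
  ddice <- -(2 * t * denom - (2 * spt + eps)) / denom^2
  g <- dce + ddice
  dim(g) <- dim(pred)
  g
}

#' Augmentation recipe
#'
#' Random geometric transforms (flips, rotation up to `rotate_deg_max`
#' degrees, scale jitter up to `scale_jitter_max`) are applied identically to
#' image and mask (bilinear vs nearest resampling, so the mask stays
#' two-valued); photometric transforms (brightness/contrast, gamma) touch the
#' image only.
#'
#' @param rotate_deg_max maximum random rotation, degrees (default 90).
#' @param scale_jitter_max maximum relative scale change (default 0.3).
#' @param brightness_contrast,gamma_jitter,hflip,vflip enable switches.
#' @param crop_px optional random-crop side applied last.
#' @return an object of class `aug_config`.
#' @export
aug_config <- function(rotate_deg_max = 90, scale_jitter_max = 0.3,
                       brightness_contrast = TRUE, gamma_jitter = TRUE,
                       hflip = TRUE, vflip = TRUE, crop_px = NULL) {
  check_number(rotate_deg_max, "rotate_deg_max", min = 0)
  check_number(scale_jitter_max, "scale_jitter_max", min = 0, max = 0.95)
  structure(list(rotate_deg_max = rotate_deg_max, scale_jitter_max = scale_jitter_max,
                 brightness_contrast = brightness_contrast, gamma_jitter = gamma_jitter,
                 hflip = hflip, vflip = vflip, crop_px = crop_px),
            class = "aug_config")
}

# rotate with clamp-to-edge sampling; bilinear (image) or nearest (mask)
rotate_pair <- function(image, mask, angle_deg) {
  H <- dim(image)[1]; W <- dim(image)[2]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ii <- matrix(seq_len(H), H, W) - cy
  jj <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  src_i <- cos(th) * ii - sin(th) * jj + cy
  src_j <- sin(th) * ii + cos(th) * jj + cx
  ni <- pmin(pmax(round(src_i), 1), H)
  nj <- pmin(pmax(round(src_j), 1), W)
  mask_out <- matrix(mask[cbind(as.vector(ni), as.vector(nj))], H, W)
  i0 <- pmin(pmax(floor(src_i), 1), H); i1 <- pmin(i0 + 1, H)
  j0 <- pmin(pmax(floor(src_j), 1), W); j1 <- pmin(j0 + 1, W)
  fi <- clip01(src_i - i0); fj <- clip01(src_j - j0)
  img_out <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3])) {
    m <- image[, , ch]
    v <- m[cbind(as.vector(i0), as.vector(j0))] * (1 - fi) * (1 - fj) +
         m[cbind(as.vector(i1), as.vector(j0))] * fi * (1 - fj) +
         m[cbind(as.vector(i0), as.vector(j1))] * (1 - fi) * fj +
         m[cbind(as.vector(i1), as.vector(j1))] * fi * fj
    img_out[, , ch] <- matrix(v, H, W)
  }
  list(image = img_out, mask = as_mask(mask_out))
}

# resize then center-crop/edge-pad back to the original size
scale_pair <- function(image, mask, factor) {
  H <- dim(image)[1]; W <- dim(image)[2]
  nh <- max(8L, as.integer(round(H * factor)))
  nw <- max(8L, as.integer(round(W * factor)))
  img <- resize_array(image, nh, nw, filter = "bilinear")
  mk <- resize_array(mask + 0, nh, nw, filter = "none")
  idx <- function(n_new, n_old) {
    off <- floor((n_new - n_old) / 2)
    pmin(pmax(seq_len(n_old) + off, 1), n_new)
  }
  ri <- idx(nh, H); ci <- idx(nw, W)
  list(image = clip01(img[ri, ci, , drop = FALSE]),
       mask = as_mask(mk[ri, ci] > 127))
}

#' Apply the augmentation recipe to a co-registered (image, mask) pair
#'
#' @param image `H x W x 3` array in \[0, 1\].
#' @param mask `H x W` mask with values \{0, 255\}.
#' @param config an [aug_config()].
#' @param seed integer seed (the draw is deterministic given the seed).
#' @return list with elements `image` and `mask`.
#' @export
augment <- function(image, mask, config = aug_config(), seed = 1) {
  mask <- as_mask(mask)
  with_seed(seed, {
    if (config$hflip && runif(1) < 0.5) {
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if (config$vflip && runif(1) < 0.5) {
      image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
      mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    }
    if (config$rotate_deg_max > 0) {
      r <- rotate_pair(image, mask, runif(1, 0, config$rotate_deg_max))
      image <- r$image; mask <- r$mask
    }
    if (config$scale_jitter_max > 0) {
      f <- 1 + runif(1, -config$scale_jitter_max, config$scale_jitter_max)
      r <- scale_pair(image, mask, f)
      image <- r$image; mask <- r$mask
    }
    if (isTRUE(config$brightness_contrast)) {
      b <- runif(1, -0.12, 0.12); cc <- 1 + runif(1, -0.2, 0.2)
      image <- clip01((image - 0.5) * cc + 0.5 + b)
    }
    if (isTRUE(config$gamma_jitter)) {
      g <- exp(runif(1, -0.3, 0.3))
      image <- clip01(image)^g
    }
    if (!is.null(config$crop_px)) {
      cp <- as.integer(config$crop_px)
      H <- dim(image)[1]; W <- dim(image)[2]
      if (cp > H || cp > W) stopf("crop_px exceeds tile size")
      r0 <- if (H > cp) sample.int(H - cp + 1, 1) - 1L else 0L
      c0 <- if (W > cp) sample.int(W - cp + 1, 1) - 1L else 0L
      image <- image[r0 + seq_len(cp), c0 + seq_len(cp), , drop = FALSE]
      mask <- mask[r0 + seq_len(cp), c0 + seq_len(cp), drop = FALSE]
    }
    list(image = image, mask = as_mask(mask))
  })
}

#' Training configuration
#'
#' Defaults mirror the reference training protocol: Adam, learning rate
#' decreasing linearly from 1e-4 to 1e-6, batch size 8, 100 epochs, best
#' model selected by validation IoU.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr_start,lr_end linear learning-rate schedule endpoints
#'   (`lr_start > lr_end > 0`).
#' @param seed training seed (shuffling, augmentation).
#' @param augment an [aug_config()], or `NULL` to disable augmentation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 8, lr_start = 1e-4,
                         lr_end = 1e-6, seed = 1, augment = aug_config()) {
  check_number(epochs, "epochs", min = 1)
  check_number(batch_size, "batch_size", min = 1)
  check_number(lr_start, "lr_start", min = 1e-12)
  check_number(lr_end, "lr_end", min = 1e-12)
  if (lr_end >= lr_start) stopf("need lr_start > lr_end > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end, seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

# learning rate at 0-based epoch e
lr_at_epoch <- function(tconfig, e) {
  if (tconfig$epochs == 1) return(tconfig$lr_start)
  tconfig$lr_start + (tconfig$lr_end - tconfig$lr_start) * e / (tconfig$epochs - 1)
}

stack_batch <- function(images, masks) {
  H <- dim(images[[1]])[1]; W <- dim(images[[1]])[2]; N <- length(images)
  x <- array(0, c(H, W, 3, N)); y <- array(0, c(H, W, 1, N))
  for (i in seq_len(N)) {
    x[, , , i] <- images[[i]]
    y[, , 1, i] <- masks[[i]] > 0
  }
  list(x = x, y = y)
}

iou_sums <- function(prob, target, threshold = 0.5) {
  p <- prob >= threshold; t <- target > 0
  c(inter = sum(p & t), union = sum(p | t))
}

eval_loss_iou <- function(model, tiles, batch_size) {
  n <- nrow(tiles)
  loss <- 0; inter <- 0; uni <- 0; npx <- 0
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(n, b0 + batch_size - 1)
    bt <- stack_batch(tiles$image[idx], tiles$mask[idx])
    pr <- seg_forward(model, bt$x, train = FALSE)$prob
    loss <- loss + dice_ce_loss(pr, bt$y) * length(idx)
    s <- iou_sums(pr, bt$y)
    inter <- inter + s["inter"]; uni <- uni + s["union"]
  }
  list(loss = loss / n, iou = if (uni > 0) inter / uni else 1)
}

#' Train a segmentation model
#'
#' Adam with a linear learning-rate decay; the combined Dice + cross-entropy
#' loss; on-the-fly augmentation of training tiles; per-epoch training and
#' validation loss/IoU history; the returned model is the epoch snapshot
#' with the highest validation IoU.
#'
#' @param model a [build_model()] output (left unmodified; training operates
#'   on an internal copy).
#' @param train_set,val_set `seg_dataset` tibbles (or any tibble with
#'   list-columns `image` and `mask`).
#' @param tconfig a [train_config()].
#' @param verbose print per-epoch progress.
#' @return an object of class `stand_count_fit`: list with elements `model`
#'   (best epoch), `history` (tibble: epoch, lr, train_loss, val_loss,
#'   train_iou, val_iou), `best_epoch`, `tconfig`.
#' @export
train <- function(model, train_set, val_set, tconfig = train_config(),
                  verbose = FALSE) {
  if (nrow(train_set) == 0 || nrow(val_set) == 0) stopf("empty training or validation set")
  model <- clone_model(model)
  opt <- adam_init(model)
  n <- nrow(train_set)
  hist <- vector("list", tconfig$epochs)
  best_iou <- -Inf; best_snap <- NULL; best_epoch <- NA_integer_
  with_seed(tconfig$seed, {
    for (e in seq_len(tconfig$epochs)) {
      lr <- lr_at_epoch(tconfig, e - 1)
      ord <- sample.int(n)
      ep_loss <- 0; inter <- 0; uni <- 0
      for (b0 in seq(1, n, by = tconfig$batch_size)) {
        idx <- ord[b0:min(n, b0 + tconfig$batch_size - 1)]
        imgs <- train_set$image[idx]; msks <- train_set$mask[idx]
        if (!is.null(tconfig$augment)) {
          seeds <- sample.int(.Machine$integer.max - 1L, length(idx))
          for (k in seq_along(idx)) {
            a <- augment(imgs[[k]], msks[[k]], tconfig$augment, seed = seeds[k])
            imgs[[k]] <- a$image; msks[[k]] <- a$mask
          }
        }
        bt <- stack_batch(imgs, msks)
        fw <- seg_forward(model, bt$x, train = TRUE, keep_cache = TRUE)
        l <- dice_ce_loss(fw$prob, bt$y)
        if (!is.finite(l)) stopf("training diverged (non-finite loss) at epoch %d", e)
        ep_loss <- ep_loss + l * length(idx)
        s <- iou_sums(fw$prob, bt$y)
        inter <- inter + s["inter"]; uni <- uni + s["union"]
        grads <- new.env(parent = emptyenv())
        seg_backward(model, fw$cache, fw$prob, dice_ce_grad(fw$prob, bt$y), grads)
        adam_step(model, grads, opt, lr)
      }
      ev <- eval_loss_iou(model, val_set, tconfig$batch_size)
      hist[[e]] <- tibble::tibble(
        epoch = e, lr = lr, train_loss = ep_loss / n,
        val_loss = ev$loss, train_iou = if (uni > 0) inter / uni else 1,
        val_iou = ev$iou
      )
      if (ev$iou > best_iou) {
        best_iou <- ev$iou; best_snap <- snapshot_params(model); best_epoch <- e
      }
      if (verbose) {
        message(sprintf("epoch %3d lr %.2e train %.4f val %.4f val IoU %.3f",
                        e, lr, ep_loss / n, ev$loss, ev$iou))
      }
    }
  })
  best <- clone_model(model)
  restore_params(best, best_snap)
  structure(list(model = best, history = dplyr::bind_rows(hist),
                 best_epoch = best_epoch, tconfig = tconfig),
            class = "stand_count_fit")
}

#' @export
print.stand_count_fit <- function(x, ...) {
  cat(sprintf("<stand_count_fit> %d epochs, best epoch %d (val IoU %.3f)\n",
              nrow(x$history), x$best_epoch, max(x$history$val_iou)))
  invisible(x)
}

#' Predict a plant mask for a whole image by tiled inference
#'
#' The image is processed in `tile_px` tiles with `overlap` px of overlap;
#' overlapping probability predictions are averaged before thresholding.
#' Images smaller than one tile are zero-padded, predicted, and cropped back.
#'
#' @param model a `seg_model` or a [train()] fit.
#' @param image an [orthomosaic()] (assumed at 1 cm/px) or `H x W x 3` array.
#' @param tile_px tile side (default: the model's configured input size).
#' @param overlap overlap between adjacent tiles in px; the default is 64,
#'   capped at half the tile side for small tiles.
#' @param threshold probability threshold for foreground (default 0.5).
#' @return integer `H x W` mask with values \{0, 255\}.
#' @export
predict_mask <- function(model, image, tile_px = NULL, overlap = NULL,
                         threshold = 0.5) {
  if (inherits(model, "stand_count_fit")) model <- model$model
  px <- if (inherits(image, "orthomosaic")) image$pixels else image
  if (inherits(image, "field_scene")) px <- image$image
  tile_px <- as.integer(tile_px %||% model$config$input_tile_px)
  overlap <- as.integer(overlap %||% min(64L, tile_px %/% 2L))
  if (overlap >= tile_px) stopf("overlap must be smaller than tile_px")
  H <- dim(px)[1]; W <- dim(px)[2]
  ph <- max(H, tile_px); pw <- max(W, tile_px)
  if (ph > H || pw > W) {
    tmp <- array(0, c(ph, pw, 3)); tmp[seq_len(H), seq_len(W), ] <- px; px <- tmp
  }
  stride <- tile_px - overlap
  r0s <- unique(c(seq(0, ph - tile_px, by = stride), ph - tile_px))
  c0s <- unique(c(seq(0, pw - tile_px, by = stride), pw - tile_px))
  acc <- matrix(0, ph, pw); cnt <- matrix(0, ph, pw)
  for (r0 in r0s) for (c0 in c0s) {
    xt <- px[r0 + seq_len(tile_px), c0 + seq_len(tile_px), , drop = FALSE]
    dim(xt) <- c(tile_px, tile_px, 3, 1)
    pr <- seg_forward(model, xt, train = FALSE)$prob[, , 1, 1]
    acc[r0 + seq_len(tile_px), c0 + seq_len(tile_px)] <-
      acc[r0 + seq_len(tile_px), c0 + seq_len(tile_px)] + pr
    cnt[r0 + seq_len(tile_px), c0 + seq_len(tile_px)] <-
      cnt[r0 + seq_len(tile_px), c0 + seq_len(tile_px)] + 1
  }
  prob <- acc / cnt
  as_mask(prob[seq_len(H), seq_len(W), drop = FALSE] >= threshold)
}
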