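#' Synthetic row-crop field specification
#'
#' Describes a seedling-stage row-crop scene on the 1 px = 1 cm grid:
#' parallel rows at `row_spacing_cm` (45 and 90 cm are typical sugar-beet and
#' potato analogues), quasi-regular in-row placement, disc-like green canopies
#' over textured soil, plus the failure modes that matter downstream —
#' missing plants, touching plants (merged contours), and off-row weed
#' distractors.
#'
#' @param width_px,height_px scene size in px (1 px = 1 cm); at least 64.
#' @param row_spacing_cm inter-row distance, cm.
#' @param in_row_spacing_cm nominal within-row plant spacing, cm.
#' @param plant_radius_cm nominal canopy radius, cm.
#' @param radius_jitter fractional sd of per-plant radius variation.
#' @param missing_rate probability that a planted slot holds no plant.
#' @param touch_rate fraction of plants duplicated at a sub-diameter offset,
#'   producing touching/merged canopies.
#' @param soil_noise amplitude in \[0, 1\] of the soil brightness texture.
#' @param weed_rate expected number of distractor blobs per 100 m^2.
#' @param row_angle_deg rotation of the row direction, degrees.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(width_px = 512, height_px = 512,
                       row_spacing_cm = 90, in_row_spacing_cm = 25,
                       plant_radius_cm = 5, radius_jitter = 0.15,
                       missing_rate = 0.05, touch_rate = 0.05,
                       soil_noise = 0.5, weed_rate = 2, row_angle_deg = 0) {
  check_number(width_px, "width_px", min = 64)
  check_number(height_px, "height_px", min = 64)
  check_number(row_spacing_cm, "row_spacing_cm", min = 1e-9)
  check_number(in_row_spacing_cm, "in_row_spacing_cm", min = 1e-9)
  check_number(plant_radius_cm, "plant_radius_cm", min = 1e-9)
  check_number(radius_jitter, "radius_jitter", min = 0)
  check_number(missing_rate, "missing_rate", min = 0, max = 1)
  check_number(touch_rate, "touch_rate", min = 0, max = 1)
  check_number(soil_noise, "soil_noise", min = 0, max = 1)
  check_number(weed_rate, "weed_rate", min = 0)
  check_number(row_angle_deg, "row_angle_deg")
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    row_spacing_cm = row_spacing_cm, in_row_spacing_cm = in_row_spacing_cm,
    plant_radius_cm = plant_radius_cm, radius_jitter = radius_jitter,
    missing_rate = missing_rate, touch_rate = touch_rate,
    soil_noise = soil_noise, weed_rate = weed_rate,
    row_angle_deg = row_angle_deg
  ), class = "field_spec")
}

# soft-edged radial blob composited over img (in place); returns modified img
blit_blob <- function(img, x, y, radius, rgb, edge_frac = 0.3) {
  H <- dim(img)[1]; W <- dim(img)[2]
  rmax <- radius * (1 + edge_frac)
  i0 <- max(1L, floor(y - rmax)); i1 <- min(H, ceiling(y + rmax))
  j0 <- max(1L, floor(x - rmax)); j1 <- min(W, ceiling(x + rmax))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  d <- sqrt(outer((ii - 0.5 - y)^2, (jj - 0.5 - x)^2, `+`))
  a <- clip01((rmax - d) / (rmax - radius + 1e-9))
  shade <- 1 - 0.35 * clip01(d / radius)^2
  for (ch in 1:3) {
    patch <- img[ii, jj, ch]
    img[ii, jj, ch] <- patch * (1 - a) + rgb[ch] * shade * a
  }
  img
}

#' Generate a synthetic field scene with exhaustive ground truth
#'
#' Deterministic for a fixed `(spec, seed)` pair. Plants are placed on rows
#' of spacing `row_spacing_cm` with jittered in-row positions, rendered as
#' green-dominant soft discs over a textured soil background; the returned
#' centers are the complete ground truth and `truth_mask` is their radius-4
#' disc rasterization.
#'
#' @param spec a [field_spec()].
#' @param seed integer seed.
#' @return an object of class \code{field_scene}: list with `image` (H x W x 3 in
#'   \[0,1\]), `centers` ([plant_annotation()]), `truth_mask`, `spec`, `seed`.
#' @export
generate_field <- function(spec, seed = 1) {
  if (!inherits(spec, "field_spec")) stopf("`spec` must be a field_spec")
  H <- spec$height_px; W <- spec$width_px
  with_seed(seed, {
    # --- plant placement on an unrotated row lattice -------------------------
    half_diag <- sqrt(H^2 + W^2) / 2
    s <- spec$row_spacing_cm; a <- spec$in_row_spacing_cm
    rot <- spec$row_angle_deg %% 360 != 0
    if (!rot) {
      row_y <- seq(s / 2, H, by = s)
      row_y <- row_y[row_y < H]
      slot_x <- seq(a / 2, W, by = a)
      slot_x <- slot_x[slot_x < W]
    } else {
      row_y <- seq(-half_diag + s / 2, half_diag, by = s)
      slot_x <- seq(-half_diag + a / 2, half_diag, by = a)
    }
    grid <- expand.grid(x = slot_x, y = row_y)
    n0 <- nrow(grid)
    x <- grid$x + rnorm(n0, 0, 0.10 * a)
    y <- grid$y + rnorm(n0, 0, 0.04 * s)
    if (rot) {
      th <- spec$row_angle_deg * pi / 180
      cx <- if (rot) 0 else W / 2; cy <- if (rot) 0 else H / 2
      xr <- cos(th) * x - sin(th) * y + W / 2
      yr <- sin(th) * x + cos(th) * y + H / 2
      x <- xr; y <- yr
      keep_fov <- x > 0 & x < W & y > 0 & y < H
      x <- x[keep_fov]; y <- y[keep_fov]
    }
    keep <- runif(length(x)) >= spec$missing_rate
    x <- x[keep]; y <- y[keep]
    r0 <- spec$plant_radius_cm
    x <- pmin(pmax(x, r0 / 2), W - r0 / 2)
    y <- pmin(pmax(y, r0 / 2), H - r0 / 2)
    # touching plants: clone at offset uniform in (0.8 r, 1.6 r)
    n <- length(x)
    if (n > 0 && spec$touch_rate > 0) {
      cl <- which(runif(n) < spec$touch_rate)
      if (length(cl) > 0) {
        ang <- runif(length(cl), 0, 2 * pi)
        dist <- runif(length(cl), 0.8 * r0, 1.6 * r0)
        xc <- pmin(pmax(x[cl] + cos(ang) * dist, r0 / 2), W - r0 / 2)
        yc <- pmin(pmax(y[cl] + sin(ang) * dist, r0 / 2), H - r0 / 2)
        x <- c(x, xc); y <- c(y, yc)
      }
    }
    n <- length(x)
    radii <- r0 * pmax(0.3, 1 + rnorm(n, 0, spec$radius_jitter))

    # --- soil background ------------------------------------------------------
    base <- c(0.45, 0.34, 0.23)
    coarse <- matrix(rnorm(ceiling(H / 16 + 2) * ceiling(W / 16 + 2)),
                     ceiling(H / 16 + 2), ceiling(W / 16 + 2))
    lowfreq <- resize_array(coarse, H, W, filter = "bilinear")
    bright <- 1 + spec$soil_noise * (0.18 * lowfreq + 0.10 * matrix(rnorm(H * W), H, W))
    img <- array(0, c(H, W, 3))
    tint <- 1 + 0.06 * lowfreq   # subtle hue drift
    img[, , 1] <- clip01(base[1] * bright * tint)
    img[, , 2] <- clip01(base[2] * bright)
    img[, , 3] <- clip01(base[3] * bright / tint)

    # --- weeds (distractors, not in ground truth) ----------------------------
    n_weed <- rpois(1, spec$weed_rate * H * W / 1e6)
    if (n_weed > 0) {
      wx <- runif(n_weed, 0, W); wy <- runif(n_weed, 0, H)
      wr <- r0 * runif(n_weed, 0.3, 0.7)
      for (k in seq_len(n_weed)) {
        col <- c(0.30, 0.42, 0.18) * (1 + rnorm(1, 0, 0.1))
        img <- blit_blob(img, wx[k], wy[k], wr[k], clip01(col))
      }
    }

    # --- plants ---------------------------------------------------------------
    if (n > 0) {
      for (k in seq_len(n)) {
        col <- c(0.13, 0.45, 0.12) * (1 + rnorm(1, 0, 0.15))
        img <- blit_blob(img, x[k], y[k], radii[k], clip01(col))
      }
    }
    centers <- plant_annotation(tibble::tibble(x_cm = x, y_cm = y), source = "synthetic")
    structure(list(
      image = img,
      centers = centers,
      truth_mask = rasterize_centers(centers, c(H, W), radius_cm = 4),
      spec = spec, seed = as.integer(seed)
    ), class = "field_scene")
  })
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene> %d x %d px, %d plants, rows %g cm (seed %d)\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$centers),
              x$spec$row_spacing_cm, x$seed))
  invisible(x)
}

#' Annotation degradation specification
#'
#' Models lower-quality markup of the kind found in heterogeneous public
#' datasets: jittered centers, dropped and spurious plants, and centers
#' quantized through intermediate bounding boxes instead of marked points.
#'
#' @param center_jitter_cm sd of the isotropic Gaussian center displacement.
#' @param drop_rate probability that a true plant is absent from the markup.
#' @param spurious_rate expected false centers per 100 m^2.
#' @param box_mode if `TRUE`, centers are first inflated to integer-cm
#'   bounding boxes and re-derived as box midpoints (quantization).
#' @return an object of class `degrade_spec`.
#' @export
degrade_spec <- function(center_jitter_cm = 0, drop_rate = 0, spurious_rate = 0,
                         box_mode = FALSE) {
  check_number(center_jitter_cm, "center_jitter_cm", min = 0)
  check_number(drop_rate, "drop_rate", min = 0, max = 1)
  check_number(spurious_rate, "spurious_rate", min = 0)
  check_flag(box_mode, "box_mode")
  structure(list(center_jitter_cm = center_jitter_cm, drop_rate = drop_rate,
                 spurious_rate = spurious_rate, box_mode = box_mode),
            class = "degrade_spec")
}

#' Degrade ground-truth annotations to emulate low-quality markup
#'
#' @param scene a [generate_field()] scene.
#' @param dspec a [degrade_spec()].
#' @param seed integer seed.
#' @return a [plant_annotation()]; `source` is `"box_derived"` when
#'   `dspec$box_mode` is set, `"synthetic"` otherwise.
#' @export
degrade_annotations <- function(scene, dspec, seed = 1) {
  if (!inherits(scene, "field_scene")) stopf("`scene` must be a field_scene")
  if (!inherits(dspec, "degrade_spec")) stopf("`dspec` must be a degrade_spec")
  H <- dim(scene$truth_mask)[1]; W <- dim(scene$truth_mask)[2]
  with_seed(seed, {
    x <- scene$centers$x_cm; y <- scene$centers$y_cm
    keep <- runif(length(x)) >= dspec$drop_rate
    x <- x[keep]; y <- y[keep]
    if (dspec$center_jitter_cm > 0 && length(x) > 0) {
      x <- x + rnorm(length(x), 0, dspec$center_jitter_cm)
      y <- y + rnorm(length(y), 0, dspec$center_jitter_cm)
    }
    n_sp <- rpois(1, dspec$spurious_rate * H * W / 1e6)
    if (n_sp > 0) {
      x <- c(x, runif(n_sp, 0, W))
      y <- c(y, runif(n_sp, 0, H))
    }
    x <- pmin(pmax(x, 0), W); y <- pmin(pmax(y, 0), H)
    if (dspec$box_mode) {
      r <- scene$spec$plant_radius_cm
      boxes <- tibble::tibble(
        x_min = round(x - r), y_min = round(y - r),
        x_max = round(x + r), y_max = round(y + r)
      )
      boxes_to_centers(boxes)
    } else {
      plant_annotation(tibble::tibble(x_cm = x, y_cm = y), source = "synthetic")
    }
  })
}

#' Generate a tiled segmentation dataset from field specifications
#'
#' Renders `n_per_spec` scenes for each spec, assigns whole scenes to
#' train/validation/test splits (splits are disjoint by scene, so no tile of
#' a validation or test scene ever leaks into training), and cuts every scene
#' into co-registered (image, mask) tiles on a non-overlapping grid.
#'
#' @param specs a [field_spec()] or list of them.
#' @param n_per_spec scenes rendered per spec.
#' @param tile_px tile side in px; must not exceed the smallest scene side.
#' @param seed integer seed.
#' @param split_frac named fractions for `train`, `val`, `test` (summing
#'   to 1).
#' @param degrade optional [degrade_spec()]: when supplied, training masks
#'   are rasterized from degraded annotations instead of ground truth
#'   (low-quality markup emulation); validation and test masks always come
#'   from ground truth.
#' @return a tibble of class `seg_dataset` with columns `scene_id`, `split`,
#'   `row0`, `col0` and list-columns `image`, `mask`; the generated scenes
#'   are attached as attribute `"scenes"`.
#' @export
generate_dataset <- function(specs, n_per_spec = 3, tile_px = 128, seed = 1,
                             split_frac = c(train = 0.6, val = 0.2, test = 0.2),
                             degrade = NULL) {
  if (inherits(specs, "field_spec")) specs <- list(specs)
  check_number(tile_px, "tile_px", min = 16)
  min_dim <- min(vapply(specs, function(s) min(s$width_px, s$height_px), numeric(1)))
  if (tile_px > min_dim) stopf("tile_px (%d) exceeds smallest scene dimension (%d)",
                               as.integer(tile_px), as.integer(min_dim))
  n_scene <- length(specs) * n_per_spec
  plan <- with_seed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n_scene)
    ord <- sample.int(n_scene)
    list(scene_seeds = scene_seeds, ord = ord)
  })
  n_tr <- max(1L, round(split_frac[["train"]] * n_scene))
  n_va <- max(1L, round(split_frac[["val"]] * n_scene))
  split <- rep("test", n_scene)
  split[plan$ord[seq_len(n_tr)]] <- "train"
  split[plan$ord[n_tr + seq_len(min(n_va, n_scene - n_tr))]] <- "val"
  grid <- tile_grid(tile_px, coverage = "drop_partial")
  scenes <- vector("list", n_scene)
  rows <- vector("list", n_scene)
  k <- 0L
  for (si in seq_along(specs)) {
    for (rep_i in seq_len(n_per_spec)) {
      k <- k + 1L
      sc <- generate_field(specs[[si]], seed = plan$scene_seeds[k])
      scenes[[k]] <- sc
      mask <- sc$truth_mask
      if (!is.null(degrade) && split[k] == "train") {
        ann <- degrade_annotations(sc, degrade, seed = plan$scene_seeds[k] %% 1000000L)
        mask <- rasterize_centers(ann, dim(sc$truth_mask), radius_cm = 4)
      }
      im_t <- tile_image(sc$image, grid)
      mk_t <- tile_image(mask, grid)
      rows[[k]] <- tibble::tibble(
        scene_id = k, spec_id = si, split = split[k],
        row0 = im_t$row0, col0 = im_t$col0,
        image = im_t$tile, mask = mk_t$tile
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scenes") <- scenes
  class(out) <- c("seg_dataset", class(out))
  out
}
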