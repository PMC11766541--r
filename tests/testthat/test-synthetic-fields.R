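test_that("field generation is deterministic and respects the row lattice", {
  spec <- clean_spec(200, rows = 90, in_row = 25)
  sc1 <- generate_field(spec, seed = 1)
  sc2 <- generate_field(spec, seed = 1)
  expect_identical(sc1$image, sc2$image)
  expect_identical(sc1$truth_mask, sc2$truth_mask)
  expect_identical(sc1$centers$x_cm, sc2$centers$x_cm)
  # 200 px tall, rows every 90 cm from 45 -> rows at 45, 135; slots every 25 cm
  expect_equal(nrow(sc1$centers), 2 * 8)
  expect_true(all(sc1$centers$x_cm >= 0 & sc1$centers$x_cm <= 200))
  expect_true(all(sc1$centers$y_cm >= 0 & sc1$centers$y_cm <= 200))
  # truth mask is exactly the radius-4 rasterization of the centers
  expect_identical(sc1$truth_mask,
                   rasterize_centers(sc1$centers, dim(sc1$truth_mask), 4))
  sc3 <- generate_field(spec, seed = 2)
  expect_false(identical(sc1$image, sc3$image))
})

test_that("missing_rate 1 yields an empty scene", {
  spec <- field_spec(128, 128, missing_rate = 1, weed_rate = 0)
  sc <- generate_field(spec, seed = 5)
  expect_equal(nrow(sc$centers), 0)
  expect_true(all(sc$truth_mask == 0L))
})

test_that("invalid field specs name the offending field", {
  expect_error(field_spec(width_px = 10), "width_px")
  expect_error(field_spec(missing_rate = 1.5), "missing_rate")
  expect_error(field_spec(row_spacing_cm = -1), "row_spacing_cm")
})

test_that("halving row spacing doubles expected plant count", {
  n45 <- n90 <- numeric(20)
  for (s in 1:20) {
    n45[s] <- nrow(generate_field(field_spec(360, 360, row_spacing_cm = 45,
                                             in_row_spacing_cm = 25, touch_rate = 0,
                                             missing_rate = 0, weed_rate = 0),
                                  seed = s)$centers)
    n90[s] <- nrow(generate_field(field_spec(360, 360, row_spacing_cm = 90,
                                             in_row_spacing_cm = 25, touch_rate = 0,
                                             missing_rate = 0, weed_rate = 0),
                                  seed = s)$centers)
  }
  expect_gt(mean(n45) / mean(n90), 2 * 0.9)
  expect_lt(mean(n45) / mean(n90), 2 * 1.1)
})

test_that("no-op degradation is the identity and full drop empties the markup", {
  sc <- generate_field(clean_spec(160), seed = 3)
  same <- degrade_annotations(sc, degrade_spec(0, 0, 0), seed = 1)
  expect_equal(same$x_cm, sc$centers$x_cm)
  expect_equal(same$y_cm, sc$centers$y_cm)
  none <- degrade_annotations(sc, degrade_spec(drop_rate = 1), seed = 1)
  expect_equal(nrow(none), 0)
})

test_that("drop_rate retains the binomially expected fraction of centers", {
  sc <- generate_field(field_spec(256, 256, row_spacing_cm = 45,
                                  in_row_spacing_cm = 15, missing_rate = 0,
                                  touch_rate = 0, weed_rate = 0), seed = 1)
  n0 <- nrow(sc$centers)
  frac <- vapply(1:50, function(s) {
    nrow(degrade_annotations(sc, degrade_spec(center_jitter_cm = 2,
                                              drop_rate = 0.1), seed = s)) / n0
  }, numeric(1))
  expect_gt(mean(frac), 0.87)
  expect_lt(mean(frac), 0.93)
})

test_that("box_mode derives centers from quantized boxes", {
  sc <- generate_field(clean_spec(160), seed = 9)
  ann <- degrade_annotations(sc, degrade_spec(box_mode = TRUE), seed = 1)
  expect_identical(attr(ann, "source"), "box_derived")
  boxes <- attr(ann, "boxes")
  expect_equal(ann$x_cm, (boxes$x_min + boxes$x_max) / 2)
  # quantization displaces each center by less than a pixel
  expect_lt(max(abs(ann$x_cm - sc$centers$x_cm)), 1)
})

test_that("generated datasets are co-registered, scene-disjoint and deterministic", {
  specs <- list(clean_spec(128, rows = 45, in_row = 20),
                clean_spec(128, rows = 90, in_row = 25))
  ds1 <- generate_dataset(specs, n_per_spec = 3, tile_px = 64, seed = 7)
  ds2 <- generate_dataset(specs, n_per_spec = 3, tile_px = 64, seed = 7)
  expect_identical(ds1$split, ds2$split)
  expect_identical(ds1$mask, ds2$mask)
  for (k in seq_len(nrow(ds1))) {
    expect_identical(dim(ds1$image[[k]])[1:2], dim(ds1$mask[[k]]))
  }
  # splits partition scenes, never tiles
  by_scene <- tapply(ds1$split, ds1$scene_id, function(s) length(unique(s)))
  expect_true(all(by_scene == 1))
  expect_setequal(unique(ds1$split), c("train", "val", "test"))
  expect_error(generate_dataset(specs, 2, tile_px = 256), "tile_px")
})

test_that("pooled mask foreground matches the areal density prediction", {
  spec <- clean_spec(192, rows = 45, in_row = 25)
  ds <- generate_dataset(list(spec), n_per_spec = 4, tile_px = 64, seed = 3)
  fg <- mean(vapply(ds$mask, function(m) mean(m > 0), numeric(1)))
  predicted <- pi * 4^2 / (45 * 25)
  expect_gt(fg, predicted * 0.7)
  expect_lt(fg, predicted * 1.3)
})

test_that("well-separated truth masks have one component per plant", {
  for (s in 1:5) {
    sc <- generate_field(clean_spec(160, rows = 45, in_row = 25), seed = s)
    expect_equal(count_plants(sc$truth_mask, count_filter_config(0)),
                 nrow(sc$centers))
  }
})

test_that("rotated rows still produce in-bounds plants at similar density", {
  straight <- generate_field(clean_spec(256, rows = 45, in_row = 20), seed = 2)
  tilted <- generate_field(field_spec(256, 256, row_spacing_cm = 45,
                                      in_row_spacing_cm = 20, missing_rate = 0,
                                      touch_rate = 0, weed_rate = 0,
                                      row_angle_deg = 30), seed = 2)
  expect_true(all(tilted$centers$x_cm >= 0 & tilted$centers$x_cm <= 256))
  expect_gt(nrow(tilted$centers), 0.7 * nrow(straight$centers))
  expect_lt(nrow(tilted$centers), 1.3 * nrow(straight$centers))
})
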