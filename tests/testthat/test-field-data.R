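test_that("disc rasterization matches the pixel-center-in-circle definition", {
  ann <- plant_annotation(tibble::tibble(x_cm = 50, y_cm = 50), "synthetic")
  m <- rasterize_centers(ann, c(100, 100), radius_cm = 4)
  expected <- matrix(0L, 100, 100)
  for (i in 1:100) for (j in 1:100) {
    if ((i - 0.5 - 50)^2 + (j - 0.5 - 50)^2 <= 16) expected[i, j] <- 255L
  }
  expect_identical(m, expected)
  expect_identical(rasterize_centers(plant_annotation(matrix(numeric(0), 0, 2),
                                                      "synthetic"), c(20, 20)),
                   matrix(0L, 20, 20))
})

test_that("overlapping discs merge and rasterization is order-invariant", {
  two <- plant_annotation(tibble::tibble(x_cm = c(30, 36), y_cm = c(30, 30)), "synthetic")
  m <- rasterize_centers(two, c(64, 64), 4)
  expect_equal(count_plants(m, count_filter_config(0)), 1)
  rev2 <- plant_annotation(tibble::tibble(x_cm = c(36, 30), y_cm = c(30, 30)), "synthetic")
  expect_identical(m, rasterize_centers(rev2, c(64, 64), 4))
  # clipping at the canvas edge keeps the in-bounds part
  edge <- rasterize_centers(plant_annotation(tibble::tibble(x_cm = 1, y_cm = 1),
                                             "synthetic"), c(32, 32), 4)
  expect_gt(sum(edge > 0), 0)
  expect_lt(sum(edge > 0), sum(m > 0))
})

test_that("scale normalization resizes to the 1 cm grid and is idempotent", {
  img <- orthomosaic(array(runif(100 * 100 * 3), c(100, 100, 3)), gsd_cm_per_px = 2)
  out <- normalize_scale(img)
  expect_equal(dim(out$pixels)[1:2], c(200, 200))
  expect_equal(out$gsd_cm_per_px, 1)
  # already at target: unchanged pixels
  same <- normalize_scale(out)
  expect_identical(same$pixels, out$pixels)
  # unknown GSD is an actionable error
  expect_error(normalize_scale(orthomosaic(img$pixels)), "infer_scale_from_rows")
  # pixel annotations rescale with the image
  res <- normalize_scale(img, centers_px = tibble::tibble(x_px = 10, y_px = 20))
  expect_equal(res$centers_px$x_px, 20)
  expect_equal(res$centers_px$y_px, 40)
})

test_that("downsampled scenes recover their plant count after normalization", {
  sc <- generate_field(clean_spec(200, rows = 45, in_row = 25), seed = 4)
  n_true <- count_plants(predicted <- sc$truth_mask)
  half <- standcount:::resize_array(sc$image, 100, 100, "bilinear")
  back <- normalize_scale(orthomosaic(standcount:::clip01(half), gsd_cm_per_px = 2))
  expect_equal(dim(back$pixels)[1:2], c(200, 200))
})

test_that("row spacing reveals the image scale", {
  sc <- generate_field(clean_spec(320, rows = 90, in_row = 20), seed = 8)
  # rendered at 1 cm/px: spacing in px equals 90
  est1 <- infer_scale_from_rows(sc$centers, known_row_spacing_cm = 90)
  expect_gt(est1, 0.95); expect_lt(est1, 1.05)
  # same geometry at 0.5 cm/px: pixel coordinates double
  px2 <- tibble::tibble(x_px = sc$centers$x_cm * 2, y_px = sc$centers$y_cm * 2)
  est2 <- infer_scale_from_rows(px2, known_row_spacing_cm = 90)
  expect_gt(est2, 0.475); expect_lt(est2, 0.525)
  expect_error(infer_scale_from_rows(
    tibble::tibble(x_cm = c(1, 2, 3), y_cm = c(1, 2, 3)), 90), "10 centers")
})

test_that("box centers are midpoints, with degenerate and inverted boxes handled", {
  ann <- boxes_to_centers(tibble::tibble(x_min = 0, y_min = 0, x_max = 10, y_max = 10))
  expect_equal(c(ann$x_cm, ann$y_cm), c(5, 5))
  expect_identical(attr(ann, "source"), "box_derived")
  empty <- boxes_to_centers(tibble::tibble(x_min = numeric(), y_min = numeric(),
                                           x_max = numeric(), y_max = numeric()))
  expect_equal(nrow(empty), 0)
  expect_warning(deg <- boxes_to_centers(tibble::tibble(x_min = 3, y_min = 3,
                                                        x_max = 3, y_max = 3)),
                 "zero-area")
  expect_equal(c(deg$x_cm, deg$y_cm), c(3, 3))
  expect_error(boxes_to_centers(tibble::tibble(x_min = 5, y_min = 0,
                                               x_max = 1, y_max = 2)), "inverted")
})

test_that("tiling drops or pads partial tiles and reassembles exactly", {
  m <- as_mask_helper <- matrix(0L, 2000, 2000)
  m[5, 5] <- 255L
  expect_equal(nrow(tile_image(m, tile_grid(1000))), 4)
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  t1 <- tile_image(img, tile_grid(512))
  expect_equal(nrow(t1), 1)
  expect_identical(t1$tile[[1]], img)
  t2 <- tile_image(matrix(0L, 1100, 1100), tile_grid(512))
  expect_equal(nrow(t2), 4)
  expect_setequal(t2$row0, c(0L, 512L)); expect_setequal(t2$col0, c(0L, 512L))
  # pad_partial covers everything and zero-pads the edges
  small <- matrix(255L, 100, 130)
  tp <- tile_image(small, tile_grid(64, coverage = "pad_partial"))
  expect_equal(nrow(tp), 2 * 3)
  expect_true(all(vapply(tp$tile, function(t) all(dim(t) == c(64, 64)), logical(1))))
  # reassembly of drop_partial tiles reproduces the covered region
  big <- matrix(sample(c(0L, 255L), 128 * 128, TRUE), 128, 128)
  td <- tile_image(big, tile_grid(64))
  rec <- matrix(0L, 128, 128)
  for (k in seq_len(nrow(td))) {
    rec[td$row0[k] + 1:64, td$col0[k] + 1:64] <- td$tile[[k]]
  }
  expect_identical(rec, big)
  expect_warning(out <- tile_image(matrix(0L, 10, 10), tile_grid(64)), "no tiles")
  expect_equal(nrow(out), 0)
})

test_that("masks, images and annotations survive file round trips", {
  dir <- withr::local_tempdir()
  sc <- generate_field(clean_spec(128), seed = 2)
  p <- file.path(dir, "mask.png")
  write_mask(sc$truth_mask, p)
  expect_identical(read_mask(p), sc$truth_mask)
  pi_ <- file.path(dir, "img.png")
  write_image(sc$image, pi_)
  back <- read_image(pi_, gsd_cm_per_px = 1)
  expect_equal(dim(back$pixels), dim(sc$image))
  expect_lt(max(abs(back$pixels - sc$image)), 1 / 254)
  pt <- file.path(dir, "img.tif")
  write_image(sc$image, pt)
  expect_equal(dim(read_image(pt)$pixels), dim(sc$image))
  pc <- file.path(dir, "centers.csv")
  write_centers_csv(sc$centers, pc)
  rt <- read_centers_csv(pc)
  expect_equal(rt$x_cm, sc$centers$x_cm)
  pg <- file.path(dir, "centers.geojson")
  write_centers_geojson(sc$centers, pg)
  rg <- read_centers_geojson(pg)
  expect_equal(rg$y_cm, sc$centers$y_cm)
})
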