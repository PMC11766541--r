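dirs8 <- standcount:::texture_directions()

test_that("GLCM matches exhaustive pair enumeration on random binary tiles", {
  set.seed(101)
  for (k in 1:40) {
    n <- sample(8:24, 1)
    tile <- matrix(sample(c(0L, 255L), n * n, TRUE), n, n)
    d <- dirs8[[sample(8, 1)]]
    M <- glcm(tile, d)
    expect_equal(unname(M$P), glcm_oracle(tile, d), tolerance = 0)
    expect_equal(sum(M$P), 1)
    f <- glcm_features(M)
    fo <- glcm_features_oracle(unname(M$P), M$levels)
    expect_equal(f$mean, fo$mean, tolerance = 1e-12)
    expect_equal(f$correlation, fo$correlation, tolerance = 1e-12)
  }
})

test_that("GLCM handles degenerate and enumerable tiles", {
  M <- glcm(matrix(7, 5, 5), c(0, 1))
  expect_equal(dim(M$P), c(1, 1)); expect_equal(M$P[1, 1], 1)
  f <- glcm_features(M)
  expect_equal(f$mean, 7)
  expect_true(is.na(f$correlation))
  # 1x2 tile [0, 255], displacement right: the single pair (0, 255)
  M2 <- glcm(matrix(c(0, 255), 1, 2), c(0, 1))
  expect_equal(M2$P["0", "255"], 1)
  expect_equal(M2$n_pairs, 1)
  expect_error(glcm(matrix(1, 1, 3), c(1, 0)), "smaller than 2")
  expect_error(glcm(matrix(1, 3, 3), c(0, 2)), "unit direction")
})

test_that("GLRM matches a line-scanning oracle exactly", {
  set.seed(202)
  for (k in 1:40) {
    n <- sample(8:24, 1)
    tile <- matrix(sample(c(0L, 255L), n * n, TRUE), n, n)
    d <- dirs8[[sample(8, 1)]]
    R <- glrm(tile, d)
    runs <- glrm_runs_oracle(tile, d)
    expect_equal(R$n_runs, nrow(runs))
    for (lev in R$levels) for (len in seq_len(ncol(R$R))) {
      expect_equal(R$R[as.character(lev), len],
                   sum(runs$value == lev & runs$length == len))
    }
    # conservation: run lengths cover the tile
    expect_equal(sum(sweep(R$R, 2, seq_len(ncol(R$R)), `*`)), n * n)
    f <- glrm_features(R)
    fo_long <- sum(runs$length^2) / nrow(runs)
    expect_equal(f$long_run, fo_long, tolerance = 1e-12)
    expect_equal(f$run_ratio, nrow(runs) / (n * n), tolerance = 1e-12)
  }
})

test_that("closed-form GLRM cases evaluate exactly", {
  row4 <- matrix(5, 1, 4)
  f <- glrm_features(glrm(row4, c(0, 1)))
  expect_equal(f$long_run, 16)
  expect_equal(f$run_ratio, 0.25)
  cb <- matrix(c(0, 255, 255, 0), 2, 2)
  fc <- glrm_features(glrm(cb, c(0, 1)))
  expect_equal(fc$long_run, 1)
  expect_equal(fc$run_ratio, 1)
  # run_ratio = 1 iff no two adjacent pixels share a value in that direction
  stripes <- matrix(rep(c(0, 255), 8), 4, 4)          # columns alternate
  expect_equal(glrm_features(glrm(stripes, c(1, 0)))$run_ratio, 1)
  expect_lt(glrm_features(glrm(stripes, c(0, 1)))$run_ratio, 1)
})

test_that("texture profiles average the 8 directions per tile", {
  sc <- generate_field(clean_spec(200, rows = 45, in_row = 20), seed = 31)
  pr <- texture_profile(sc$truth_mask, tile_grid(100))
  expect_equal(nrow(pr), 4)
  expect_true(all(pr$glrm_run_ratio > 0 & pr$glrm_run_ratio <= 1))
  expect_true(all(pr$glcm_correlation >= -1 & pr$glcm_correlation <= 1, na.rm = TRUE))
  # all-zero mask: glcm_mean 0 everywhere, constant tiles flagged
  z <- texture_profile(matrix(0L, 200, 200), tile_grid(100))
  expect_true(all(z$glcm_mean == 0))
  expect_true(all(z$constant))
  # manual cross-check of one tile against the per-direction mean
  t1 <- sc$truth_mask[1:100, 1:100]
  per_dir <- vapply(dirs8, function(d) glcm_features(glcm(t1, d))$mean, numeric(1))
  expect_equal(pr$glcm_mean[1], mean(per_dir), tolerance = 1e-12)
})

test_that("profiles are invariant under 90 degree mask rotation", {
  sc <- generate_field(clean_spec(200, rows = 45, in_row = 20), seed = 8)
  m <- sc$truth_mask
  rot <- t(m)[ncol(m):1, ]                      # exact 90 degree rotation
  p1 <- texture_profile(m, tile_grid(200))
  p2 <- texture_profile(rot, tile_grid(200))
  for (f in standcount:::texture_feature_names()) {
    expect_equal(p1[[f]], p2[[f]], tolerance = 1e-12)
  }
})

test_that("denser rows raise the GLCM mean (cropping-pattern signal)", {
  mean45 <- mean90 <- numeric(5)
  for (s in 1:5) {
    m45 <- generate_field(clean_spec(256, rows = 45, in_row = 25), seed = s)$truth_mask
    m90 <- generate_field(clean_spec(256, rows = 90, in_row = 25), seed = s)$truth_mask
    mean45[s] <- mean(texture_profile(m45, tile_grid(128))$glcm_mean)
    mean90[s] <- mean(texture_profile(m90, tile_grid(128))$glcm_mean)
  }
  expect_true(all(mean45 > mean90))
})

test_that("merged touching plants inflate the GLRM long run at equal density", {
  # same expected plant population: the touchy field clones 50% of plants at
  # sub-diameter offsets, the clean comparator packs the same count into
  # non-touching in-row slots
  long0 <- long5 <- numeric(5)
  for (s in 1:5) {
    base <- field_spec(256, 256, row_spacing_cm = 45, in_row_spacing_cm = 25 / 1.5,
                       missing_rate = 0, touch_rate = 0, weed_rate = 0)
    touchy <- field_spec(256, 256, row_spacing_cm = 45, in_row_spacing_cm = 25,
                         missing_rate = 0, touch_rate = 0.5, weed_rate = 0)
    long0[s] <- mean(texture_profile(generate_field(base, s)$truth_mask,
                                     tile_grid(128))$glrm_long_run)
    long5[s] <- mean(texture_profile(generate_field(touchy, s)$truth_mask,
                                     tile_grid(128))$glrm_long_run)
  }
  expect_gt(mean(long5), mean(long0))
})

test_that("markup comparison recovers identity and affine shifts", {
  sc <- generate_field(clean_spec(256, rows = 45, in_row = 20), seed = 77)
  pr <- texture_profile(sc$truth_mask, tile_grid(64))
  self <- compare_markups(pr, pr)
  expect_equal(self$mean_diff, rep(0, 4))
  expect_equal(self$slope, rep(1, 4))
  expect_equal(self$intercept, rep(0, 4))
  expect_equal(self$pearson_r, rep(1, 4))
  shifted <- pr
  shifted$glcm_mean <- shifted$glcm_mean + 3
  cmp <- compare_markups(pr, shifted)
  row <- cmp[cmp$feature == "glcm_mean", ]
  expect_equal(row$mean_diff, 3)
  expect_equal(row$slope, 1, tolerance = 1e-9)
  expect_equal(row$intercept, 3, tolerance = 1e-9)
  expect_lt(row$paired_test_p, 0.001)
  expect_error(compare_markups(pr[1:2, ], pr[1:2, ]), "at least 3")
  # wilcoxon alternative runs
  cmp_w <- compare_markups(pr, shifted, test = "wilcoxon")
  expect_lt(cmp_w$paired_test_p[cmp_w$feature == "glcm_mean"], 0.01)
})
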