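# GLCM / GLRM texture features of plant masks, over the 8 unit directions:
# (0,+1), (0,-1), (+1,0), (-1,0), (+1,+1), (+1,-1), (-1,+1), (-1,-1) as
# (dy, dx). Opposite displacements are both in the set, so averaging over
# directions yields the symmetric statistics without per-matrix
# symmetrization.

texture_directions <- function() {
  list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
       c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
}

check_direction <- function(d) {
  if (length(d) != 2 || !all(d %in% c(-1, 0, 1)) || all(d == 0)) {
    stopf("displacement must be one of the 8 unit directions (dy, dx)")
  }
  as.integer(d)
}

#' Gray-level co-occurrence matrix for one displacement
#'
#' `P[i, j]` is the fraction of in-bounds pixel pairs `(p, p + d)` whose
#' values are `(levels[i], levels[j])`. Gray levels are the native pixel
#' values present in the tile (for binary plant masks, \{0, 255\}), without
#' re-quantization.
#'
#' @param tile numeric/integer matrix.
#' @param displacement integer `c(dy, dx)`, one of the 8 unit directions.
#' @return an object of class `glcmatrix`: list with `levels`, `P`
#'   (levels x levels probabilities), `displacement`, `n_pairs`.
#' @export
glcm <- function(tile, displacement) {
  d <- check_direction(displacement)
  H <- nrow(tile); W <- ncol(tile)
  if ((d[1] != 0 && H < 2) || (d[2] != 0 && W < 2)) {
    stopf("tile smaller than 2 px in the displacement direction")
  }
  levels <- sort(unique(as.vector(tile)))
  nl <- length(levels)
  ri <- seq_len(H - abs(d[1])); rj <- seq_len(W - abs(d[2]))
  if (d[1] < 0) ri <- ri + abs(d[1])
  if (d[2] < 0) rj <- rj + abs(d[2])
  a <- tile[ri, rj, drop = FALSE]
  b <- tile[ri + d[1], rj + d[2], drop = FALSE]
  ca <- match(as.vector(a), levels)
  cb <- match(as.vector(b), levels)
  counts <- tabulate(ca + nl * (cb - 1L), nbins = nl * nl)
  P <- matrix(counts / sum(counts), nl, nl,
              dimnames = list(levels, levels))
  structure(list(levels = levels, P = P, displacement = d,
                 n_pairs = sum(counts)),
            class = "glcmatrix")
}

#' GLCM mean and correlation features
#'
#' `mean` is the reference-pixel marginal mean `sum_i levels[i] *
#' sum_j P[i, j]`; `correlation` is the Pearson correlation of the
#' co-occurring value pair under `P`, reported as `NA` (undefined, not 0)
#' when either marginal is degenerate (constant tile).
#'
#' @param M a [glcm()] result.
#' @return list with elements `mean` and `correlation`.
#' @export
glcm_features <- function(M) {
  if (!inherits(M, "glcmatrix")) stopf("`M` must be a glcmatrix")
  px <- rowSums(M$P); py <- colSums(M$P)
  mu_x <- sum(M$levels * px); mu_y <- sum(M$levels * py)
  sx <- sqrt(sum((M$levels - mu_x)^2 * px))
  sy <- sqrt(sum((M$levels - mu_y)^2 * py))
  corr <- if (sx * sy == 0) NA_real_ else {
    sum(outer(M$levels - mu_x, M$levels - mu_y) * M$P) / (sx * sy)
  }
  list(mean = mu_x, correlation = corr)
}

# split a matrix into scan lines for a direction: rows, columns, or diagonals
scan_lines <- function(tile, d) {
  H <- nrow(tile); W <- ncol(tile)
  if (d[1] == 0) {
    lapply(seq_len(H), function(i) tile[i, ])
  } else if (d[2] == 0) {
    lapply(seq_len(W), function(j) tile[, j])
  } else {
    ii <- matrix(seq_len(H), H, W)
    jj <- matrix(seq_len(W), H, W, byrow = TRUE)
    key <- if (d[1] == d[2]) jj - ii else jj + ii   # main vs anti diagonals
    ord <- order(as.vector(key), as.vector(ii))
    unname(split(as.vector(tile)[ord], as.vector(key)[ord]))
  }
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal runs of equal value along all scan lines in the given
#' direction; `R[level, length]` is the number of such runs. Opposite
#' directions scan the same lines and therefore share the same run set.
#'
#' @inheritParams glcm
#' @param direction integer `c(dy, dx)`, one of the 8 unit directions.
#' @return an object of class `glrmatrix`: list with `levels`, `R`
#'   (levels x max_run counts), `direction`, `n_runs`, `n_pixels`.
#' @export
glrm <- function(tile, direction) {
  d <- check_direction(direction)
  H <- nrow(tile); W <- ncol(tile)
  if (H * W == 0) stopf("empty tile")
  levels <- sort(unique(as.vector(tile)))
  runs_v <- list(); runs_l <- list()
  lines <- scan_lines(tile, d)
  for (k in seq_along(lines)) {
    r <- rle(as.vector(lines[[k]]))
    runs_v[[k]] <- r$values; runs_l[[k]] <- r$lengths
  }
  v <- unlist(runs_v); l <- unlist(runs_l)
  maxlen <- max(l)
  ci <- match(v, levels)
  counts <- tabulate(ci + length(levels) * (l - 1L), nbins = length(levels) * maxlen)
  R <- matrix(counts, length(levels), maxlen,
              dimnames = list(levels, seq_len(maxlen)))
  structure(list(levels = levels, R = R, direction = d,
                 n_runs = length(v), n_pixels = H * W),
            class = "glrmatrix")
}

#' GLRM long-run emphasis and run-ratio features
#'
#' `long_run` (long-run emphasis) weights each run by its squared length:
#' `sum(R[g, l] * l^2) / n_runs`; `run_ratio` (run percentage) is
#' `n_runs / n_pixels` — 1 for a maximally alternating image, small for
#' homogeneous elongated structure.
#'
#' @param R a [glrm()] result.
#' @return list with elements `long_run` and `run_ratio`.
#' @export
glrm_features <- function(R) {
  if (!inherits(R, "glrmatrix")) stopf("`R` must be a glrmatrix")
  if (R$n_runs < 1) stopf("no runs in tile")
  len <- seq_len(ncol(R$R))
  long_run <- sum(sweep(R$R, 2, len^2, `*`)) / R$n_runs
  list(long_run = long_run, run_ratio = R$n_runs / R$n_pixels)
}

# all four features for one tile, averaged over the 8 directions
tile_texture_features <- function(tile) {
  dirs <- texture_directions()
  gm <- gc <- gl <- gr <- numeric(length(dirs))
  for (k in seq_along(dirs)) {
    fc <- glcm_features(glcm(tile, dirs[[k]]))
    fr <- glrm_features(glrm(tile, dirs[[k]]))
    gm[k] <- fc$mean; gc[k] <- fc$correlation
    gl[k] <- fr$long_run; gr[k] <- fr$run_ratio
  }
  tibble::tibble(
    glcm_mean = mean(gm),
    glcm_correlation = if (anyNA(gc)) NA_real_ else mean(gc),
    glrm_long_run = mean(gl),
    glrm_run_ratio = mean(gr),
    constant = anyNA(gc)
  )
}

#' Per-tile texture profile of a plant mask
#'
#' Cuts the mask into non-overlapping tiles (1000 x 1000 px by default) and
#' computes the four texture features per tile, each averaged over the 8
#' directions. Constant tiles have undefined GLCM correlation and are
#' flagged.
#'
#' @param mask integer matrix with values \{0, 255\} at 1 px = 1 cm.
#' @param grid a [tile_grid()] (default 1000 px, drop_partial).
#' @return tibble of class `texture_profile` with columns `tile_id`, `row0`,
#'   `col0`, `glcm_mean`, `glcm_correlation`, `glrm_long_run`,
#'   `glrm_run_ratio`, `constant`.
#' @export
texture_profile <- function(mask, grid = tile_grid(1000)) {
  mask <- as_mask(mask)
  tiles <- tile_image(mask, grid)
  if (nrow(tiles) == 0) {
    warn("no complete tiles at this grid size")
  }
  feats <- dplyr::bind_rows(purrr::map(tiles$tile, tile_texture_features))
  out <- dplyr::bind_cols(tiles[, c("tile_id", "row0", "col0")], feats)
  class(out) <- c("texture_profile", class(out))
  out
}

texture_feature_names <- function() {
  c("glcm_mean", "glcm_correlation", "glrm_long_run", "glrm_run_ratio")
}

#' Compare texture profiles from two markups
#'
#' For each texture feature, pairs tiles shared by the two profiles and
#' reports the two means, the paired mean difference (`b - a`) with a paired
#' two-sided test, the OLS fit of `b` on `a` (slope and intercept quantify
#' systematic bias; 1 and 0 mean none), and the Pearson correlation of the
#' tile-paired values. Tiles with undefined features are dropped pairwise
#' and counted.
#'
#' @param profile_a reference (manual) [texture_profile()].
#' @param profile_b comparison (predicted) [texture_profile()].
#' @param test paired test: `"t"` (two-sided paired t-test) or `"wilcoxon"`
#'   (signed-rank).
#' @return tibble of class `markup_comparison` with one row per feature:
#'   `feature`, `n_tiles`, `n_dropped`, `mean_a`, `mean_b`, `mean_diff`,
#'   `paired_test_p`, `slope`, `intercept`, `pearson_r`. The tile-paired
#'   values are attached as attribute `"pairs"` for plotting.
#' @export
compare_markups <- function(profile_a, profile_b, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  common <- intersect(profile_a$tile_id, profile_b$tile_id)
  if (length(common) < 3) stopf("need at least 3 common tiles, got %d", length(common))
  a <- profile_a[match(common, profile_a$tile_id), ]
  b <- profile_b[match(common, profile_b$tile_id), ]
  pairs <- list()
  rows <- purrr::map(texture_feature_names(), function(f) {
    va <- a[[f]]; vb <- b[[f]]
    ok <- is.finite(va) & is.finite(vb)
    n_drop <- sum(!ok)
    va <- va[ok]; vb <- vb[ok]
    if (length(va) < 3) {
      return(tibble::tibble(feature = f, n_tiles = length(va), n_dropped = n_drop,
                            mean_a = NA_real_, mean_b = NA_real_, mean_diff = NA_real_,
                            paired_test_p = NA_real_, slope = NA_real_,
                            intercept = NA_real_, pearson_r = NA_real_))
    }
    pairs[[f]] <<- tibble::tibble(feature = f, tile_id = common[ok], a = va, b = vb)
    d <- vb - va
    # an (essentially) constant difference has no within-pair variability:
    # a zero shift is untestable (NA), a non-zero constant shift unequivocal
    const_p <- function() if (abs(mean(d)) <= 1e-12) NA_real_ else 0
    p <- if (sd(d) == 0) {
      const_p()
    } else if (test == "t") {
      tryCatch(t.test(vb, va, paired = TRUE)$p.value, error = function(e) const_p())
    } else {
      tryCatch(wilcox.test(vb, va, paired = TRUE, exact = FALSE)$p.value,
               error = function(e) const_p())
    }
    fit <- tryCatch(coef(lm(vb ~ va)), error = function(e) c(NA_real_, NA_real_))
    r <- if (sd(va) > 0 && sd(vb) > 0) cor(va, vb) else NA_real_
    tibble::tibble(feature = f, n_tiles = length(va), n_dropped = n_drop,
                   mean_a = mean(va), mean_b = mean(vb),
                   mean_diff = mean(vb - va), paired_test_p = p,
                   slope = unname(fit[2]), intercept = unname(fit[1]),
                   pearson_r = r)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pairs") <- dplyr::bind_rows(pairs)
  class(out) <- c("markup_comparison", class(out))
  out
}
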