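#' Pixel-wise intersection over union of two masks
#'
#' `|A intersect B| / |A union B|` over foreground pixel sets; defined as 1
#' when both masks are empty.
#'
#' @param mask_a,mask_b integer matrices with values \{0, 255\}, equal shape.
#' @return IoU in \[0, 1\].
#' @export
pixel_iou <- function(mask_a, mask_b) {
  mask_a <- as_mask(mask_a); mask_b <- as_mask(mask_b)
  if (!identical(dim(mask_a), dim(mask_b))) stopf("mask shapes differ")
  a <- mask_a != 0L; b <- mask_b != 0L
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Per-tile plant counts over a non-overlapping grid
#'
#' Crops the mask into grid tiles (row-major order) and counts plants in
#' each with [count_plants()]. A region straddling a tile boundary is split
#' by the crop and may be counted in more than one tile; this is the
#' documented behavior of tile-wise counting.
#'
#' @param mask integer matrix with values \{0, 255\}.
#' @param grid a [tile_grid()] (must be non-overlapping, which [tile_grid()]
#'   grids are by construction).
#' @param filter a [count_filter_config()].
#' @return integer vector of per-tile counts in row-major tile order.
#' @export
tile_counts <- function(mask, grid, filter = count_filter_config()) {
  tiles <- tile_image(as_mask(mask), grid)
  vapply(tiles$tile, count_plants, integer(1), config = filter)
}

#' Count series from two markups
#'
#' @param x per-tile counts from markup A (reference / manual).
#' @param y per-tile counts from markup B (predicted).
#' @param tile_size_m physical tile side in meters (metadata; default 20).
#' @return an object of class `count_series`.
#' @export
count_series <- function(x, y, tile_size_m = 20) {
  if (length(x) != length(y)) stopf("count series lengths differ")
  if (length(x) < 1) stopf("need at least one tile")
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x),
                 tile_size_m = tile_size_m),
            class = "count_series")
}

#' Count agreement metrics between two markups
#'
#' MAE, MAPE, Pearson r and Spearman r_s between per-tile counts of a
#' reference markup `x` and a predicted markup `y`. Note the MAPE
#' denominator: following the printed formula this package divides by the
#' *predicted* count (`mape_denominator = "predicted"`, the default), not by
#' the reference as conventional MAPE does; set `"manual"` for the
#' conventional form. Tiles where both counts are zero are kept in MAE but
#' excluded from MAPE; a remaining zero denominator makes MAPE `NA` with a
#' warning. Spearman uses average ranks for ties.
#'
#' @param series a [count_series()], or the `x` vector when `y` is given.
#' @param y optional second vector of counts.
#' @param mape_denominator `"predicted"` (the printed formula) or `"manual"`.
#' @param pixel_iou optional pixel IoU to carry into the report.
#' @return a tibble of class `eval_report` with columns `mae`, `mape_pct`,
#'   `pearson_r`, `spearman_rs`, `pixel_iou`, `n_tiles`.
#' @export
count_metrics <- function(series, y = NULL,
                          mape_denominator = c("predicted", "manual"),
                          pixel_iou = NA_real_) {
  mape_denominator <- match.arg(mape_denominator)
  if (!inherits(series, "count_series")) series <- count_series(series, y)
  x <- series$x; yv <- series$y; n <- series$n
  mae <- mean(abs(x - yv))
  denom <- if (mape_denominator == "predicted") yv else x
  use <- !(x == 0 & yv == 0)
  if (any(!use)) {
    rlang::inform(sprintf("%d tile(s) with zero counts in both markups excluded from MAPE",
                          sum(!use)))
  }
  if (any(denom[use] == 0)) {
    warn("zero denominator count in at least one tile; MAPE undefined")
    mape <- NA_real_
  } else if (sum(use) == 0) {
    mape <- NA_real_
  } else {
    mape <- 100 / sum(use) * sum(abs(x[use] - yv[use]) / denom[use])
  }
  if (n >= 2 && sd(x) > 0 && sd(yv) > 0) {
    r <- cor(x, yv)
    rs <- cor(x, yv, method = "spearman")
  } else {
    if (n >= 2) warn("zero-variance count series; correlations undefined")
    r <- NA_real_; rs <- NA_real_
  }
  out <- tibble::tibble(mae = mae, mape_pct = mape, pearson_r = r,
                        spearman_rs = rs, pixel_iou = pixel_iou,
                        n_tiles = n)
  class(out) <- c("eval_report", class(out))
  out
}

#' Evaluate a predicted mask against a reference mask
#'
#' Convenience wrapper: pixel IoU over the whole masks plus tile-wise count
#' metrics over a non-overlapping grid (the full per-markup agreement
#' report).
#'
#' @param truth_mask,pred_mask masks of equal shape.
#' @param tile_px evaluation tile side in px (2000 px = 20 m at 1 cm/px for
#'   full-scale orthomosaics; smaller for desk-scale scenes).
#' @param filter a [count_filter_config()].
#' @param mape_denominator see [count_metrics()].
#' @return an `eval_report` tibble.
#' @export
evaluate_masks <- function(truth_mask, pred_mask, tile_px = 2000,
                           filter = count_filter_config(),
                           mape_denominator = "predicted") {
  grid <- tile_grid(tile_px, coverage = "drop_partial")
  cx <- tile_counts(truth_mask, grid, filter)
  cy <- tile_counts(pred_mask, grid, filter)
  count_metrics(count_series(cx, cy, tile_size_m = tile_px / 100),
                mape_denominator = mape_denominator,
                pixel_iou = pixel_iou(truth_mask, pred_mask))
}
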