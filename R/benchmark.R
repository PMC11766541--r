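#' Bundled desk-scale benchmark
#'
#' The package ships one fixed benchmark protocol so that the end-to-end
#' pipeline (simulate, train, predict, count, evaluate, texture) can be
#' reproduced from a single seed on one CPU. It emulates the field mix the
#' method targets: three row-spacing regimes (45, 60, 90 cm), 256 x 256 px
#' scenes at 1 px = 1 cm, with small rates of missing and touching plants
#' and occasional weeds. Training uses an rn18 encoder at width 0.25 on
#' 128 px tiles for 6 epochs — a deliberately small pilot of the full-scale
#' protocol (rn18--rn50, width 1, 512 px tiles, 100 epochs).
#'
#' @param seed master seed for scene generation, weight init and training.
#' @param epochs pilot training epochs (default 6).
#' @param n_per_spec scenes per row-spacing regime (default 17, giving about
#'   200 tiles).
#' @param verbose print per-epoch progress.
#' @return list with elements `fit` (a [train()] result), `val_iou` (best
#'   validation IoU), `report` (pooled held-out `eval_report`),
#'   `per_scene` (per-scene `eval_report` rows), `texture`
#'   (a [compare_markups()] of truth vs predicted profiles on the held-out
#'   scenes), `n_train_tiles`.
#' @export
pilot_benchmark <- function(seed = 1, epochs = 6, n_per_spec = 17,
                            verbose = FALSE) {
  specs <- pilot_field_specs()
  ds <- generate_dataset(specs, n_per_spec = n_per_spec, tile_px = 128,
                         seed = seed)
  tr <- ds[ds$split == "train", ]
  va <- ds[ds$split == "val", ]
  model <- build_model(seg_model_config("rn18", width_multiplier = 0.25,
                                        input_tile_px = 128),
                       seed = seed + 1L)
  tc <- train_config(epochs = epochs, batch_size = 8, lr_start = 1e-3,
                     lr_end = 1e-5, seed = seed + 2L)
  fit <- train(model, tr, va, tc, verbose = verbose)
  scenes <- attr(ds, "scenes")[unique(ds$scene_id[ds$split == "test"])]
  grid <- tile_grid(128, coverage = "drop_partial")
  all_x <- c(); all_y <- c(); inter <- 0; uni <- 0
  per_scene <- list(); prof_a <- list(); prof_b <- list()
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    pred <- predict_mask(fit$model, sc$image, tile_px = 128)
    cx <- tile_counts(sc$truth_mask, grid)
    cy <- tile_counts(pred, grid)
    all_x <- c(all_x, cx); all_y <- c(all_y, cy)
    a <- mask_foreground(sc$truth_mask); b <- mask_foreground(pred)
    inter <- inter + sum(a & b); uni <- uni + sum(a | b)
    per_scene[[k]] <- dplyr::bind_cols(
      tibble::tibble(scene = k, row_spacing_cm = sc$spec$row_spacing_cm),
      suppressWarnings(suppressMessages(
        count_metrics(count_series(cx, cy),
                      pixel_iou = pixel_iou(sc$truth_mask, pred))))
    )
    pa <- texture_profile(sc$truth_mask, grid)
    pb <- texture_profile(pred, grid)
    pa$tile_id <- pa$tile_id + k * 1000L
    pb$tile_id <- pb$tile_id + k * 1000L
    prof_a[[k]] <- pa; prof_b[[k]] <- pb
  }
  report <- suppressMessages(count_metrics(
    count_series(all_x, all_y),
    pixel_iou = if (uni > 0) inter / uni else 1
  ))
  pa <- dplyr::bind_rows(prof_a); pb <- dplyr::bind_rows(prof_b)
  class(pa) <- class(prof_a[[1]]); class(pb) <- class(prof_b[[1]])
  tex <- tryCatch(compare_markups(pa, pb), error = function(e) NULL)
  list(fit = fit, val_iou = max(fit$history$val_iou), report = report,
       per_scene = dplyr::bind_rows(per_scene), texture = tex,
       n_train_tiles = nrow(tr))
}

#' @rdname pilot_benchmark
#' @export
pilot_field_specs <- function() {
  list(
    field_spec(256, 256, row_spacing_cm = 45, in_row_spacing_cm = 20),
    field_spec(256, 256, row_spacing_cm = 60, in_row_spacing_cm = 22),
    field_spec(256, 256, row_spacing_cm = 90, in_row_spacing_cm = 25)
  )
}
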