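#' Dataset source descriptor for experiments
#'
#' A named training/validation/test stratum: a set of field specifications,
#' a number of scenes, and an optional annotation degradation applied to the
#' markup (the low-quality-markup analogue; validation/test masks always use
#' ground truth).
#'
#' @param specs a [field_spec()] or list of them.
#' @param n_scenes scenes generated per spec.
#' @param degrade optional [degrade_spec()].
#' @return an object of class `dataset_source`.
#' @export
dataset_source <- function(specs, n_scenes = 2, degrade = NULL) {
  if (inherits(specs, "field_spec")) specs <- list(specs)
  check_number(n_scenes, "n_scenes", min = 1)
  structure(list(specs = specs, n_scenes = as.integer(n_scenes), degrade = degrade),
            class = "dataset_source")
}

#' Experiment configuration
#'
#' A reproducible manifest for one end-to-end run: which dataset strata are
#' trained on, validated on and tested on (tags must be disjoint — the
#' leakage guard), the model and training configuration, the counting
#' filter, and the tile sizes for count evaluation and texture profiling.
#'
#' @param name experiment name (e.g. `"rn18-clean"`).
#' @param datasets named list of [dataset_source()] objects.
#' @param train_sources,val_source,test_source tags into `datasets`.
#' @param model a [seg_model_config()].
#' @param train a [train_config()].
#' @param counting a [count_filter_config()].
#' @param tile_px training tile side in px.
#' @param eval_tile_px count-evaluation tile side in px.
#' @param texture_tile_px texture tile side in px.
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(name, datasets, train_sources, val_source,
                              test_source, model = seg_model_config(),
                              train = train_config(),
                              counting = count_filter_config(),
                              tile_px = 128, eval_tile_px = 128,
                              texture_tile_px = 128, seed = 1) {
  tags <- names(datasets)
  missing_tags <- setdiff(c(train_sources, val_source, test_source), tags)
  if (length(missing_tags) > 0) {
    stopf("unknown dataset tag(s) %s; available: %s",
          paste(missing_tags, collapse = ", "), paste(tags, collapse = ", "))
  }
  if (length(intersect(train_sources, c(val_source, test_source))) > 0 ||
      val_source == test_source) {
    stopf("train/val/test dataset tags must be disjoint")
  }
  structure(list(name = name, datasets = datasets, train_sources = train_sources,
                 val_source = val_source, test_source = test_source,
                 model = model, train = train, counting = counting,
                 tile_px = as.integer(tile_px), eval_tile_px = as.integer(eval_tile_px),
                 texture_tile_px = as.integer(texture_tile_px),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# render a dataset_source into scenes + co-registered (image, mask) tiles
realize_source <- function(src, tile_px, seed, degrade_masks = FALSE) {
  n_scene <- length(src$specs) * src$n_scenes
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_scene))
  scenes <- list(); rows <- list()
  grid <- tile_grid(tile_px, coverage = "drop_partial")
  k <- 0L
  for (si in seq_along(src$specs)) for (ri in seq_len(src$n_scenes)) {
    k <- k + 1L
    sc <- generate_field(src$specs[[si]], seed = scene_seeds[k])
    scenes[[k]] <- sc
    mask <- sc$truth_mask
    if (degrade_masks && !is.null(src$degrade)) {
      ann <- degrade_annotations(sc, src$degrade, seed = scene_seeds[k] %% 1000000L)
      mask <- rasterize_centers(ann, dim(mask), radius_cm = 4)
    }
    im_t <- tile_image(sc$image, grid); mk_t <- tile_image(mask, grid)
    rows[[k]] <- tibble::tibble(scene_id = k, split = NA_character_,
                                row0 = im_t$row0, col0 = im_t$col0,
                                image = im_t$tile, mask = mk_t$tile)
  }
  list(scenes = scenes, tiles = dplyr::bind_rows(rows))
}

#' Run an end-to-end stand-counting experiment
#'
#' Generates the configured synthetic datasets, trains the segmentation
#' model, predicts masks for every test scene, and reports per-scene and
#' pooled count metrics, pixel IoU, texture profiles of truth vs predicted
#' masks, and their markup comparison.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return an object of class `experiment_report`: list with `name`, `fit`
#'   (the [train()] result), `per_scene` (tibble of per-scene metrics),
#'   `pooled` (an `eval_report`), `texture` (a [compare_markups()] result),
#'   `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (!inherits(config, "experiment_config")) stopf("`config` must be an experiment_config")
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 8))
  tr_tiles <- dplyr::bind_rows(purrr::imap(
    config$datasets[config$train_sources],
    function(src, tag) realize_source(src, config$tile_px,
                                      seed = seeds[1] + match(tag, names(config$datasets)),
                                      degrade_masks = TRUE)$tiles
  ))
  val <- realize_source(config$datasets[[config$val_source]], config$tile_px,
                        seed = seeds[2])
  test <- realize_source(config$datasets[[config$test_source]], config$tile_px,
                         seed = seeds[3])
  model <- build_model(config$model, seed = seeds[4] %% 100000L)
  fit <- train(model, tr_tiles, val$tiles, config$train, verbose = verbose)
  eval_grid <- tile_grid(config$eval_tile_px, coverage = "drop_partial")
  tex_grid <- tile_grid(config$texture_tile_px, coverage = "drop_partial")
  per_scene <- list(); all_x <- c(); all_y <- c()
  prof_a <- list(); prof_b <- list(); iou_i <- 0; iou_u <- 0
  for (k in seq_along(test$scenes)) {
    sc <- test$scenes[[k]]
    pred <- predict_mask(fit$model, sc$image, tile_px = config$tile_px)
    cx <- tile_counts(sc$truth_mask, eval_grid, config$counting)
    cy <- tile_counts(pred, eval_grid, config$counting)
    all_x <- c(all_x, cx); all_y <- c(all_y, cy)
    a <- mask_foreground(sc$truth_mask); b <- mask_foreground(pred)
    iou_i <- iou_i + sum(a & b); iou_u <- iou_u + sum(a | b)
    rep_k <- suppressWarnings(suppressMessages(count_metrics(count_series(cx, cy),
                                            pixel_iou = pixel_iou(sc$truth_mask, pred))))
    per_scene[[k]] <- dplyr::bind_cols(tibble::tibble(scene = k), rep_k)
    pa <- texture_profile(sc$truth_mask, tex_grid)
    pb <- texture_profile(pred, tex_grid)
    pa$tile_id <- pa$tile_id + k * 1e6; pb$tile_id <- pb$tile_id + k * 1e6
    prof_a[[k]] <- pa; prof_b[[k]] <- pb
  }
  pooled <- suppressWarnings(suppressMessages(count_metrics(
    count_series(all_x, all_y),
    pixel_iou = if (iou_u > 0) iou_i / iou_u else 1
  )))
  pa <- dplyr::bind_rows(prof_a); pb <- dplyr::bind_rows(prof_b)
  class(pa) <- class(prof_a[[1]]); class(pb) <- class(prof_b[[1]])
  tex <- tryCatch(compare_markups(pa, pb), error = function(e) NULL)
  structure(list(name = config$name, fit = fit,
                 per_scene = dplyr::bind_rows(per_scene), pooled = pooled,
                 texture = tex, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s\n", x$name))
  cat(sprintf("  pooled: MAE %.2f, MAPE %s%%, r %s, rs %s, IoU %.3f (%d tiles)\n",
              x$pooled$mae,
              ifelse(is.na(x$pooled$mape_pct), "NA", sprintf("%.2f", x$pooled$mape_pct)),
              ifelse(is.na(x$pooled$pearson_r), "NA", sprintf("%.4f", x$pooled$pearson_r)),
              ifelse(is.na(x$pooled$spearman_rs), "NA", sprintf("%.4f", x$pooled$spearman_rs)),
              x$pooled$pixel_iou, x$pooled$n_tiles))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors the configuration objects: top-level keys `name`,
#' `train_sources`, `val_source`, `test_source`, `seed`, `tile_px`,
#' `eval_tile_px`, `texture_tile_px`, plus `datasets` (each with `n_scenes`,
#' optional `degrade`, and a list of `specs` passed to [field_spec()]),
#' `model` (passed to [seg_model_config()]) and `train` (passed to
#' [train_config()]).
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  datasets <- purrr::map(y$datasets, function(d) {
    specs <- purrr::map(d$specs, ~ do.call(field_spec, .x))
    degrade <- if (!is.null(d$degrade)) do.call(degrade_spec, d$degrade)
    dataset_source(specs, n_scenes = d$n_scenes %||% 2, degrade = degrade)
  })
  model <- do.call(seg_model_config, y$model %||% list())
  tr_args <- y$train %||% list()
  if (!is.null(tr_args$augment)) tr_args$augment <- do.call(aug_config, tr_args$augment)
  train <- do.call(train_config, tr_args)
  experiment_config(
    name = y$name %||% "experiment", datasets = datasets,
    train_sources = unlist(y$train_sources), val_source = y$val_source,
    test_source = y$test_source, model = model, train = train,
    counting = count_filter_config(y$min_area_px %||% 10),
    tile_px = y$tile_px %||% 128, eval_tile_px = y$eval_tile_px %||% 128,
    texture_tile_px = y$texture_tile_px %||% 128, seed = y$seed %||% 1
  )
}
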