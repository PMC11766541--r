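#' Orthomosaic container
#'
#' A lightweight container for an RGB field image together with its ground
#' sampling distance (GSD, cm per pixel). The GSD may be unknown (`NA`), in
#' which case it can be estimated from crop-row geometry with
#' [infer_scale_from_rows()].
#'
#' @param pixels numeric array `H x W x 3` with values in \[0, 1\].
#' @param gsd_cm_per_px ground sampling distance in cm/px, or `NA` if unknown.
#' @param crs_tag optional character tag carried through unchanged (never
#'   interpreted).
#' @return an object of class `orthomosaic`.
#' @export
orthomosaic <- function(pixels, gsd_cm_per_px = NA_real_, crs_tag = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stopf("`pixels` must be an H x W x 3 array")
  }
  if (!is.na(gsd_cm_per_px)) check_number(gsd_cm_per_px, "gsd_cm_per_px", min = 1e-9)
  structure(
    list(pixels = pixels, gsd_cm_per_px = gsd_cm_per_px, crs_tag = crs_tag),
    class = "orthomosaic"
  )
}

#' @export
print.orthomosaic <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<orthomosaic> %d x %d px, GSD %s cm/px\n", d[1], d[2],
              ifelse(is.na(x$gsd_cm_per_px), "unknown", format(x$gsd_cm_per_px))))
  invisible(x)
}

#' Plant center annotation
#'
#' A set of plant centers on the cm grid, with provenance and (optionally)
#' the bounding boxes the centers were derived from.
#'
#' @param centers data frame with columns `x_cm`, `y_cm` (or a 2-column
#'   matrix).
#' @param source one of `"manual_point"`, `"box_derived"`, `"synthetic"`.
#' @param boxes optional data frame with columns `x_min, y_min, x_max, y_max`.
#' @return a tibble of class `plant_annotation` with columns `x_cm`, `y_cm`
#'   and attributes `source` and `boxes`.
#' @export
plant_annotation <- function(centers, source = c("manual_point", "box_derived", "synthetic"),
                             boxes = NULL) {
  source <- match.arg(source)
  if (is.matrix(centers)) centers <- tibble::tibble(x_cm = centers[, 1], y_cm = centers[, 2])
  centers <- tibble::as_tibble(centers)
  if (nrow(centers) == 0) centers <- tibble::tibble(x_cm = numeric(), y_cm = numeric())
  if (!all(c("x_cm", "y_cm") %in% names(centers))) {
    stopf("`centers` needs columns x_cm and y_cm")
  }
  if (nrow(centers) && !all(is.finite(centers$x_cm) & is.finite(centers$y_cm))) {
    stopf("plant centers must be finite")
  }
  out <- centers[, c("x_cm", "y_cm")]
  attr(out, "source") <- source
  attr(out, "boxes") <- boxes
  class(out) <- c("plant_annotation", class(out))
  out
}

#' Convert bounding boxes to center-point annotations
#'
#' Plant centers are taken as the midpoints of their rectangles, the usual
#' recipe for harmonizing box-labelled public datasets with point-labelled
#' orthomosaics.
#'
#' @param boxes data frame (or 4-column matrix) with columns
#'   `x_min, y_min, x_max, y_max` in cm.
#' @return a [plant_annotation()] with `source = "box_derived"`.
#' @export
boxes_to_centers <- function(boxes) {
  if (is.matrix(boxes)) {
    boxes <- tibble::tibble(x_min = boxes[, 1], y_min = boxes[, 2],
                            x_max = boxes[, 3], y_max = boxes[, 4])
  }
  boxes <- tibble::as_tibble(boxes)
  if (nrow(boxes) == 0) {
    return(plant_annotation(tibble::tibble(x_cm = numeric(), y_cm = numeric()),
                            source = "box_derived",
                            boxes = tibble::tibble(x_min = numeric(), y_min = numeric(),
                                                   x_max = numeric(), y_max = numeric())))
  }
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(boxes))) stopf("`boxes` needs columns %s", paste(need, collapse = ", "))
  if (any(boxes$x_min > boxes$x_max | boxes$y_min > boxes$y_max)) {
    stopf("inverted box: min exceeds max on at least one axis")
  }
  if (any(boxes$x_min == boxes$x_max & boxes$y_min == boxes$y_max)) {
    warn("zero-area box(es) present; using the degenerate corner as the center")
  }
  plant_annotation(
    tibble::tibble(x_cm = (boxes$x_min + boxes$x_max) / 2,
                   y_cm = (boxes$y_min + boxes$y_max) / 2),
    source = "box_derived", boxes = boxes[, need]
  )
}

#' Rasterize plant centers into a binary disc mask
#'
#' Paints a disc of `radius_cm` around every center on the 1 px = 1 cm grid:
#' a pixel is foreground iff its center lies within `radius_cm` of some
#' annotation point. Overlapping discs merge; portions outside the canvas are
#' clipped. This is the mask convention used for network training targets
#' (white discs of radius 4 cm on black background).
#'
#' @param annotation a [plant_annotation()] or data frame with `x_cm`, `y_cm`.
#' @param shape integer vector `c(H, W)` of the output mask in px.
#' @param radius_cm disc radius in cm (default 4).
#' @return integer `H x W` matrix with values \{0, 255\}.
#' @export
rasterize_centers <- function(annotation, shape, radius_cm = 4) {
  if (length(shape) != 2 || any(shape < 1)) stopf("`shape` must be c(H, W), both >= 1")
  check_number(radius_cm, "radius_cm", min = 1e-9)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  m <- matrix(FALSE, H, W)
  if (NROW(annotation) > 0) {
    r2 <- radius_cm^2
    for (k in seq_len(NROW(annotation))) {
      x <- annotation$x_cm[k]; y <- annotation$y_cm[k]
      i0 <- max(1L, ceiling(y - radius_cm)); i1 <- min(H, ceiling(y + radius_cm) + 1L)
      j0 <- max(1L, ceiling(x - radius_cm)); j1 <- min(W, ceiling(x + radius_cm) + 1L)
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      dy2 <- (ii - 0.5 - y)^2
      dx2 <- (jj - 0.5 - x)^2
      m[ii, jj] <- m[ii, jj] | (outer(dy2, dx2, `+`) <= r2)
    }
  }
  as_mask(m)
}

#' Resample an orthomosaic to a target ground sampling distance
#'
#' All analyses in the package assume the common 1 px = 1 cm grid; this
#' resizes an image whose GSD is known to that grid (bilinear resampling).
#' Pixel-coordinate annotations passed alongside are rescaled by the same
#' factor.
#'
#' @param image an [orthomosaic()] with known `gsd_cm_per_px`.
#' @param target_cm_per_px target GSD (default 1).
#' @param centers_px optional data frame of pixel coordinates `x_px`, `y_px`
#'   in the input raster; returned rescaled to the output raster.
#' @return the resized `orthomosaic`, or (when `centers_px` is given) a list
#'   with elements `image` and `centers_px`.
#' @export
normalize_scale <- function(image, target_cm_per_px = 1.0, centers_px = NULL) {
  if (!inherits(image, "orthomosaic")) stopf("`image` must be an orthomosaic")
  if (is.na(image$gsd_cm_per_px)) {
    stopf("GSD is unknown; estimate it first with infer_scale_from_rows()")
  }
  check_number(target_cm_per_px, "target_cm_per_px", min = 1e-9)
  f <- image$gsd_cm_per_px / target_cm_per_px
  d <- dim(image$pixels)
  new_h <- max(1L, as.integer(round(d[1] * f)))
  new_w <- max(1L, as.integer(round(d[2] * f)))
  px <- if (new_h == d[1] && new_w == d[2]) image$pixels else
    clip01(resize_array(image$pixels, new_h, new_w, filter = "bilinear"))
  out <- orthomosaic(px, gsd_cm_per_px = target_cm_per_px, crs_tag = image$crs_tag)
  if (is.null(centers_px)) return(out)
  centers_px <- tibble::as_tibble(centers_px)
  centers_px$x_px <- centers_px$x_px * f
  centers_px$y_px <- centers_px$y_px * f
  list(image = out, centers_px = centers_px)
}

#' Estimate image scale from known crop-row spacing
#'
#' When a frame's GSD is unrecorded, the agronomic row spacing provides it:
#' the dominant inter-row distance is measured in pixel units from the plant
#' centers (principal-axis projection, then the dominant gap between row
#' clusters), and the scale follows as `known_row_spacing_cm / spacing_px`.
#'
#' @param annotation plant centers in *pixel* units (data frame with columns
#'   `x_cm`/`y_cm` interpreted as raw pixel coordinates, or `x_px`/`y_px`).
#' @param known_row_spacing_cm the crop's inter-row distance in cm.
#' @return estimated GSD in cm/px.
#' @export
infer_scale_from_rows <- function(annotation, known_row_spacing_cm) {
  check_number(known_row_spacing_cm, "known_row_spacing_cm", min = 1e-9)
  df <- tibble::as_tibble(annotation)
  if (all(c("x_px", "y_px") %in% names(df))) {
    pts <- cbind(df$x_px, df$y_px)
  } else {
    pts <- cbind(df$x_cm, df$y_cm)
  }
  if (nrow(pts) < 10) stopf("need at least 10 centers to detect row structure (got %d)", nrow(pts))
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  # rows cluster the projections on the across-row axis into a few tight,
  # evenly spaced groups; the along-row axis spreads them quasi-uniformly.
  # Either principal axis can be the across-row one depending on the field's
  # aspect, so score both and keep the better-separated clustering.
  cluster_axis <- function(proj) {
    proj <- sort(proj)
    gaps <- diff(proj)
    if (max(gaps) <= 0) return(NULL)
    cut <- which(gaps > max(gaps) / 2)
    bounds <- c(0, cut, length(proj))
    rows <- vapply(seq_len(length(bounds) - 1), function(k) {
      mean(proj[(bounds[k] + 1):bounds[k + 1]])
    }, numeric(1))
    if (length(rows) < 2) return(NULL)
    within_sd <- vapply(seq_len(length(bounds) - 1), function(k) {
      v <- proj[(bounds[k] + 1):bounds[k + 1]]
      if (length(v) > 1) sd(v) else 0
    }, numeric(1))
    spacing <- median(diff(rows))
    list(spacing = spacing, within_sd = max(within_sd),
         score = spacing / (max(within_sd) + 1e-9))
  }
  cands <- Filter(Negate(is.null), lapply(1:2, function(a) cluster_axis(pc$x[, a])))
  if (length(cands) == 0) stopf("no periodic row structure detected")
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "score"))]]
  if (best$spacing <= 4 * best$within_sd) {
    stopf("row spacing (%.1f px) not well separated from in-row scatter (sd %.1f px)",
          best$spacing, best$within_sd)
  }
  known_row_spacing_cm / best$spacing
}

#' Tile grid specification
#'
#' @param tile_h_px,tile_w_px tile height/width in px (`tile_w_px` defaults to
#'   `tile_h_px`).
#' @param coverage `"drop_partial"` keeps only fully interior tiles;
#'   `"pad_partial"` zero-pads edge tiles to full size.
#' @return an object of class `tile_grid`.
#' @export
tile_grid <- function(tile_h_px, tile_w_px = tile_h_px,
                      coverage = c("drop_partial", "pad_partial")) {
  coverage <- match.arg(coverage)
  check_number(tile_h_px, "tile_h_px", min = 1)
  check_number(tile_w_px, "tile_w_px", min = 1)
  structure(list(tile_h_px = as.integer(tile_h_px), tile_w_px = as.integer(tile_w_px),
                 coverage = coverage),
            class = "tile_grid")
}

#' Split an image or mask into non-overlapping tiles
#'
#' Tiles are laid on a regular grid anchored at the top-left corner, returned
#' in row-major order. Under `drop_partial` only complete tiles are returned;
#' under `pad_partial` edge tiles are zero-padded to full size.
#'
#' @param x a matrix (mask), `H x W x C` array, or [orthomosaic()].
#' @param grid a [tile_grid()].
#' @return tibble with columns `tile_id`, `row0`, `col0` (0-based offsets) and
#'   list-column `tile`.
#' @export
tile_image <- function(x, grid) {
  if (inherits(x, "orthomosaic")) x <- x$pixels
  d <- dim(x)
  H <- d[1]; W <- d[2]
  th <- grid$tile_h_px; tw <- grid$tile_w_px
  if (grid$coverage == "drop_partial") {
    nr <- H %/% th; nc <- W %/% tw
    if (nr < 1 || nc < 1) {
      warn("tile larger than image under drop_partial; returning no tiles")
      return(tibble::tibble(tile_id = integer(), row0 = integer(), col0 = integer(),
                            tile = list()))
    }
  } else {
    nr <- ceiling(H / th); nc <- ceiling(W / tw)
  }
  offs <- expand.grid(col0 = (seq_len(nc) - 1L) * tw, row0 = (seq_len(nr) - 1L) * th)
  offs <- offs[order(offs$row0, offs$col0), ]
  crop <- function(r0, c0) {
    i1 <- min(H, r0 + th); j1 <- min(W, c0 + tw)
    t_ <- if (length(d) == 3) x[(r0 + 1):i1, (c0 + 1):j1, , drop = FALSE]
          else x[(r0 + 1):i1, (c0 + 1):j1, drop = FALSE]
    if (grid$coverage == "pad_partial" && (i1 - r0 < th || j1 - c0 < tw)) {
      full <- if (length(d) == 3) array(if (is.integer(x)) 0L else 0, c(th, tw, d[3]))
              else matrix(if (is.integer(x)) 0L else 0, th, tw)
      if (length(d) == 3) full[seq_len(i1 - r0), seq_len(j1 - c0), ] <- t_
      else full[seq_len(i1 - r0), seq_len(j1 - c0)] <- t_
      t_ <- full
    }
    t_
  }
  tiles <- purrr::map2(offs$row0, offs$col0, crop)
  tibble::tibble(tile_id = seq_along(tiles),
                 row0 = as.integer(offs$row0), col0 = as.integer(offs$col0),
                 tile = tiles)
}

# ---- file IO -----------------------------------------------------------------

#' Read / write rasters and annotations
#'
#' Masks are written as single-channel 8-bit PNG with foreground 255; RGB
#' images as 8-bit PNG or TIFF (chosen by file extension); centers as CSV with
#' columns `x_cm,y_cm` or as a GeoJSON FeatureCollection of Points.
#'
#' @param path file path.
#' @param mask integer matrix with values \{0, 255\}.
#' @name standcount-io
NULL

#' @rdname standcount-io
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname standcount-io
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  as_mask(m >= 0.5)
}

#' @rdname standcount-io
#' @param image an [orthomosaic()] or `H x W x 3` array in \[0, 1\].
#' @param gsd_cm_per_px GSD to attach when reading.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "orthomosaic")) image$pixels else image
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(px, path, bits.per.sample = 8L)
  } else {
    png::writePNG(px, path)
  }
  invisible(path)
}

#' @rdname standcount-io
#' @export
read_image <- function(path, gsd_cm_per_px = NA_real_) {
  px <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(px)) == 3 && dim(px)[3] > 3) px <- px[, , 1:3]
  orthomosaic(px, gsd_cm_per_px = gsd_cm_per_px)
}

#' @rdname standcount-io
#' @param annotation a [plant_annotation()].
#' @export
write_centers_csv <- function(annotation, path) {
  write.csv(as.data.frame(annotation)[, c("x_cm", "y_cm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname standcount-io
#' @param source annotation provenance tag used when reading.
#' @export
read_centers_csv <- function(path, source = "manual_point") {
  plant_annotation(read.csv(path), source = source)
}

#' @rdname standcount-io
#' @export
write_centers_geojson <- function(annotation, path) {
  feats <- purrr::map2(annotation$x_cm, annotation$y_cm, function(x, y) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Point", coordinates = c(x, y)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname standcount-io
#' @export
read_centers_geojson <- function(path, source = "manual_point") {
  g <- jsonlite::read_json(path)
  xy <- purrr::map(g$features, ~ unlist(.x$geometry$coordinates))
  plant_annotation(tibble::tibble(x_cm = purrr::map_dbl(xy, 1),
                                  y_cm = purrr::map_dbl(xy, 2)),
                   source = source)
}
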