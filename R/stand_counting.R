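#' Count filter configuration
#'
#' Connected regions smaller than `min_area_px` are discarded as noise
#' before counting. Foreground connectivity is 8-connected throughout.
#'
#' @param min_area_px minimum region area in px (default 10, about 20% of a
#'   radius-4 disc).
#' @return an object of class `count_filter_config`.
#' @export
count_filter_config <- function(min_area_px = 10L) {
  check_number(min_area_px, "min_area_px", min = 0)
  structure(list(min_area_px = as.integer(min_area_px), connectivity = 8L),
            class = "count_filter_config")
}

# Moore-neighbor boundary tracing (8-connected outer contour), clockwise.
# Returns a matrix of 1-based (i, j) pixel coordinates in traversal order.
trace_contour <- function(fg, start) {
  # clockwise neighbor order starting at W: W, NW, N, NE, E, SE, S, SW
  di <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dj <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  H <- nrow(fg); W <- ncol(fg)
  inb <- function(i, j) i >= 1 && i <= H && j >= 1 && j <= W
  path <- matrix(start, ncol = 2)
  cur <- start
  dir0 <- 1L   # backtrack direction: W of the start pixel is background
  first_move <- NULL
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- ((dir0 - 1 + s) %% 8) + 1
      ni <- cur[1] + di[d]; nj <- cur[2] + dj[d]
      if (inb(ni, nj) && fg[ni, nj]) {
        move <- d
        if (all(cur == start)) {
          if (is.null(first_move)) {
            first_move <- move
          } else if (move == first_move && nrow(path) > 1) {
            return(path[-nrow(path), , drop = FALSE])
          }
        }
        cur <- c(ni, nj)
        path <- rbind(path, cur)
        # next search starts from the direction opposite the entry, plus one cw
        dir0 <- ((d + 4 - 1 + 1) %% 8) + 1
        found <- TRUE
        break
      }
    }
    if (!found) return(path)                    # isolated pixel
    if (nrow(path) > 4 * sum(fg) + 8) return(path)   # safety cap
  }
}

#' Extract plant regions from a binary mask
#'
#' Maximal 8-connected foreground components with area at least
#' `min_area_px`, sorted by centroid (y, then x). Each region carries its
#' centroid on the cm grid, pixel area, bounding box, and ordered outer
#' boundary contour.
#'
#' @param mask integer matrix with values \{0, 255\}.
#' @param config a [count_filter_config()].
#' @return tibble with columns `region_id`, `x_cm`, `y_cm`, `area_px`,
#'   `x_min`, `y_min`, `x_max`, `y_max` and list-column `contour` (n x 2
#'   matrices of (i, j) pixel coordinates).
#' @export
extract_plants <- function(mask, config = count_filter_config()) {
  mask <- as_mask(mask)
  lab <- .label_components8(mask)
  n_lab <- max(lab)
  empty <- tibble::tibble(region_id = integer(), x_cm = numeric(), y_cm = numeric(),
                          area_px = integer(), x_min = numeric(), y_min = numeric(),
                          x_max = numeric(), y_max = numeric(), contour = list())
  if (n_lab == 0) return(empty)
  idx <- which(lab > 0)
  ii <- ((idx - 1) %% nrow(lab)) + 1
  jj <- ((idx - 1) %/% nrow(lab)) + 1
  ll <- lab[idx]
  area <- tabulate(ll, nbins = n_lab)
  keep <- which(area >= config$min_area_px)
  if (length(keep) == 0) return(empty)
  cy <- unname(rowsum(ii - 0.5, ll)[, 1] / area)  # pixel centers: (j-0.5, i-0.5) cm
  cx <- unname(rowsum(jj - 0.5, ll)[, 1] / area)
  bx0 <- unname(tapply(jj, ll, min)) - 1; bx1 <- unname(tapply(jj, ll, max))
  by0 <- unname(tapply(ii, ll, min)) - 1; by1 <- unname(tapply(ii, ll, max))
  out <- tibble::tibble(
    label = keep,
    x_cm = cx[keep], y_cm = cy[keep], area_px = as.integer(area[keep]),
    x_min = as.numeric(bx0[keep]), y_min = as.numeric(by0[keep]),
    x_max = as.numeric(bx1[keep]), y_max = as.numeric(by1[keep])
  )
  out <- out[order(out$y_cm, out$x_cm), ]
  out$contour <- purrr::map(out$label, function(l) {
    fg <- lab == l
    first <- which(fg)[1]                     # column-major: leftmost, then top
    trace_contour(fg, c(((first - 1) %% nrow(fg)) + 1, ((first - 1) %/% nrow(fg)) + 1))
  })
  out$region_id <- seq_len(nrow(out))
  out[, c("region_id", "x_cm", "y_cm", "area_px",
          "x_min", "y_min", "x_max", "y_max", "contour")]
}

#' Count plants in a binary mask
#'
#' The number of 8-connected foreground regions surviving the area filter.
#'
#' @inheritParams extract_plants
#' @return integer count.
#' @export
count_plants <- function(mask, config = count_filter_config()) {
  mask <- as_mask(mask)
  lab <- .label_components8(mask)
  n_lab <- max(lab)
  if (n_lab == 0) return(0L)
  area <- tabulate(lab[lab > 0], nbins = n_lab)
  sum(area >= config$min_area_px)
}

#' Plant density per hectare
#'
#' @param count plant count.
#' @param area_m2 surveyed area in square meters.
#' @return plants per hectare (`count / area_m2 * 10000`).
#' @export
plant_density <- function(count, area_m2) {
  check_number(count, "count", min = 0)
  check_number(area_m2, "area_m2", min = 1e-12)
  count / area_m2 * 1e4
}
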