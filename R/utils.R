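# internal validation + small shared helpers

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na && (is.null(x) || (length(x) == 1 && is.na(x)))) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stopf("`%s` must be a single number", name)
  }
  if (x < min || x > max) {
    stopf("`%s` must be in [%s, %s], got %s", name, format(min), format(max), format(x))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) stopf("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

# integer matrix with values {0, 255}; accepts logical/numeric input
as_mask <- function(m) {
  if (is.logical(m)) {
    storage.mode(m) <- "integer"
    m <- m * 255L
  }
  if (!is.matrix(m)) stopf("a mask must be a matrix")
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 255))) {
    stopf("a mask may only contain values 0 and 255 (found %s)",
          paste(head(setdiff(u, c(0, 255)), 3), collapse = ", "))
  }
  storage.mode(m) <- "integer"
  m
}

mask_foreground <- function(mask) mask != 0L

# clamp to [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# EBImage-backed resize of a 2D matrix or H x W x C array.
# filter "bilinear" for continuous imagery, "none" (nearest) for masks/labels.
resize_array <- function(a, new_h, new_w, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  new_h <- as.integer(round(new_h)); new_w <- as.integer(round(new_w))
  if (new_h < 1 || new_w < 1) stopf("resize target must be at least 1 x 1")
  # EBImage's first array dimension is its 'w' axis, so our H maps onto w
  out <- EBImage::resize(EBImage::Image(a), w = new_h, h = new_w, filter = filter)
  out <- EBImage::imageData(out)
  dim(out) <- if (length(dim(a)) == 3) c(new_h, new_w, dim(a)[3]) else c(new_h, new_w)
  out
}
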