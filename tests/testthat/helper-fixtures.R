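# shared fixtures, built in code

# small well-separated scene: no touching, no missing, no weeds
clean_spec <- function(px = 200, rows = 90, in_row = 25) {
  field_spec(width_px = px, height_px = px, row_spacing_cm = rows,
             in_row_spacing_cm = in_row, missing_rate = 0, touch_rate = 0,
             weed_rate = 0)
}

# brute-force flood-fill labeling oracle (8-connected), queue-based
flood_fill_label <- function(mask) {
  fg <- mask != 0
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!fg[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
            fg[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# exhaustive pair-enumeration GLCM oracle
glcm_oracle <- function(tile, d) {
  levels <- sort(unique(as.vector(tile)))
  nl <- length(levels)
  P <- matrix(0, nl, nl)
  H <- nrow(tile); W <- ncol(tile)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    qi <- i + d[1]; qj <- j + d[2]
    if (qi >= 1 && qi <= H && qj >= 1 && qj <= W) {
      a <- match(tile[i, j], levels); b <- match(tile[qi, qj], levels)
      P[a, b] <- P[a, b] + 1
    }
  }
  P / sum(P)
}

# from-scratch GLCM feature oracle (double loop over the matrix)
glcm_features_oracle <- function(P, levels) {
  nl <- length(levels)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(levels * px); mu_y <- sum(levels * py)
  sx <- sqrt(sum((levels - mu_x)^2 * px)); sy <- sqrt(sum((levels - mu_y)^2 * py))
  corr <- 0
  if (sx * sy == 0) {
    corr <- NA_real_
  } else {
    for (i in seq_len(nl)) for (j in seq_len(nl)) {
      corr <- corr + (levels[i] - mu_x) * (levels[j] - mu_y) * P[i, j]
    }
    corr <- corr / (sx * sy)
  }
  list(mean = mu_x, correlation = corr)
}

# line-by-line scanning GLRM oracle: returns list(runs = data.frame(value, length))
glrm_runs_oracle <- function(tile, d) {
  H <- nrow(tile); W <- ncol(tile)
  starts <- list()
  if (d[1] == 0) {                      # horizontal lines
    lines <- lapply(seq_len(H), function(i) tile[i, ])
  } else if (d[2] == 0) {
    lines <- lapply(seq_len(W), function(j) tile[, j])
  } else {
    # walk each diagonal explicitly pixel by pixel
    lines <- list()
    seen <- matrix(FALSE, H, W)
    for (j0 in seq_len(W)) for (i0 in seq_len(H)) {
      # start pixels: those with no predecessor in direction -d
      pi <- i0 - d[1]; pj <- j0 - d[2]
      if (pi >= 1 && pi <= H && pj >= 1 && pj <= W) next
      v <- c(); i <- i0; j <- j0
      while (i >= 1 && i <= H && j >= 1 && j <= W) {
        v <- c(v, tile[i, j]); i <- i + d[1]; j <- j + d[2]
      }
      lines[[length(lines) + 1]] <- v
    }
  }
  vals <- c(); lens <- c()
  for (v in lines) {
    k <- 1
    while (k <= length(v)) {
      k2 <- k
      while (k2 < length(v) && v[k2 + 1] == v[k]) k2 <- k2 + 1
      vals <- c(vals, v[k]); lens <- c(lens, k2 - k + 1)
      k <- k2 + 1
    }
  }
  data.frame(value = vals, length = lens)
}

# count-metric formula oracles, written independently of count_metrics()
metrics_oracle <- function(x, y) {
  n <- length(x)
  mae <- sum(abs(x - y)) / n
  mape <- 100 / n * sum(abs(x - y) / y)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  mrx <- mean(rx); mry <- mean(ry)
  rs <- sum((rx - mrx) * (ry - mry)) / sqrt(sum((rx - mrx)^2) * sum((ry - mry)^2))
  list(mae = mae, mape = mape, r = r, rs = rs)
}
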