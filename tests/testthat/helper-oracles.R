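# Independent brute-force oracles used to cross-check the implementation.
# All deliberately written as explicit loops over definitions, sharing no
# code with the package internals.

# Exhaustive 256-level between-class-variance maximizer.
otsu_brute <- function(gray, exclude_zero = FALSE) {
  v <- as.integer(round(gray))
  if (exclude_zero) v <- v[v != 0L]
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:255) {
    c0 <- v[v <= t]
    c1 <- v[v > t]
    if (length(c0) == 0L || length(c1) == 0L) next
    w0 <- length(c0) / length(v)
    s <- w0 * (1 - w0) * (mean(c0) - mean(c1))^2
    if (s > best + 1e-12) {
      best <- s
      best_t <- t
    }
  }
  best_t
}

# Per-window median over valid (non-zero) pixels only.
median_smooth_brute <- function(depth, k) {
  h <- nrow(depth); w <- ncol(depth); r <- (k - 1) / 2
  out <- depth
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (depth[i, j] == 0) next
    win <- depth[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
    win <- win[win > 0]
    out[i, j] <- stats::median(win)
  }
  out
}

# Per-pixel loop version of the masked region depth average (cm).
region_mean_brute <- function(depth, mask, region) {
  h <- nrow(depth); w <- ncol(depth)
  rows <- (floor(region$row_lo * h) + 1):floor(region$row_hi * h)
  cols <- (floor(region$col_lo * w) + 1):floor(region$col_hi * w)
  acc <- 0; n <- 0L
  for (i in rows) for (j in cols) {
    if (mask[i, j] && depth[i, j] > 0) {
      acc <- acc + depth[i, j]
      n <- n + 1L
    }
  }
  list(mean_cm = acc / n / 10, n = n)
}

# Per-pixel loop confusion counts.
confusion_brute <- function(pred, truth) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] && truth[i, j]) tp <- tp + 1L
    else if (pred[i, j]) fp <- fp + 1L
    else if (truth[i, j]) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Uniform RGB image helper.
uniform_rgb <- function(r, g, b, h = 8, w = 8) {
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

# Small random 8-bit grayscale matrix with a controllable number of levels.
random_gray <- function(h, w, levels) {
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}
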