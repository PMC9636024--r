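# Small 2D filtering helpers shared by the defocus chain and the phantom
# texture generator. Edge policy: replicate for convolutions, truncation for
# windowed statistics (counts shrink at borders).

shift_clamp <- function(mat, dx, dy) {
  n <- nrow(mat); m <- ncol(mat)
  ix <- pmin(pmax(seq_len(n) + dx, 1L), n)
  iy <- pmin(pmax(seq_len(m) + dy, 1L), m)
  mat[ix, iy, drop = FALSE]
}

gauss_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicated edges
conv_sep2d <- function(mat, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(mat), ncol(mat))
  for (t in seq_along(kernel))
    out <- out + kernel[t] * shift_clamp(mat, t - 1L - r, 0L)
  res <- matrix(0, nrow(mat), ncol(mat))
  for (t in seq_along(kernel))
    res <- res + kernel[t] * shift_clamp(out, 0L, t - 1L - r)
  res
}

gauss_blur2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  conv_sep2d(mat, gauss_kernel(sigma))
}

# discrete 5-point Laplacian, replicated edges
laplacian5 <- function(mat) {
  shift_clamp(mat, -1L, 0L) + shift_clamp(mat, 1L, 0L) +
    shift_clamp(mat, 0L, -1L) + shift_clamp(mat, 0L, 1L) - 4 * mat
}

# truncated-window box sum along both axes (window 2h+1, shrinking at edges)
box_sum_trunc <- function(mat, h) {
  n <- nrow(mat); m <- ncol(mat)
  cs <- rbind(0, apply(mat, 2, cumsum))
  hi <- pmin(seq_len(n) + h, n); lo <- pmax(seq_len(n) - h, 1L)
  rowpass <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rowpass, 1, cumsum)))
  hj <- pmin(seq_len(m) + h, m); lj <- pmax(seq_len(m) - h, 1L)
  cs2[, hj + 1L, drop = FALSE] - cs2[, lj, drop = FALSE]
}

# per-pixel population standard deviation over a (2h+1)^2 truncated window
local_std <- function(mat, h) {
  n <- nrow(mat); m <- ncol(mat)
  cnt_r <- pmin(seq_len(n) + h, n) - pmax(seq_len(n) - h, 1L) + 1
  cnt_c <- pmin(seq_len(m) + h, m) - pmax(seq_len(m) - h, 1L) + 1
  cnt <- outer(cnt_r, cnt_c)
  s1 <- box_sum_trunc(mat, h)
  s2 <- box_sum_trunc(mat * mat, h)
  v <- s2 / cnt - (s1 / cnt)^2
  sqrt(pmax(v, 0))
}
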