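#' Read a landmark correspondence table
#'
#' CSV with columns sx, sy, sz, tx, ty, tz and optionally tag, in physical
#' units.
#'
#' @param path CSV file.
#' @return data.frame of landmark pairs.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sx", "sy", "sz", "tx", "ty", "tz")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(as.matrix(df[, need]))))
    stop("landmark coordinates must be finite")
  if (nrow(df) < 1) stop("no landmarks")
  df
}

#' Block grid for piecewise-affine registration
#'
#' Axis-aligned grid of blocks (default block size 42 x 28 x 2 grid units)
#' over a region of source space; each block later receives its own affine
#' fitted to landmarks in the block's surround (the block dilated by
#' \code{surround_radius}, default one block size per axis).
#'
#' @param origin length-3 lower corner of the gridded region.
#' @param block_size length-3 block extents.
#' @param n_blocks length-3 block counts.
#' @param surround_radius length-3 surround dilation; default
#'   \code{block_size}.
#' @return a \code{block_grid}.
#' @export
block_grid <- function(origin, block_size = c(42, 28, 2), n_blocks,
                       surround_radius = NULL) {
  origin <- as.numeric(origin); block_size <- as.numeric(block_size)
  n_blocks <- as.integer(n_blocks)
  stopifnot(length(origin) == 3, length(block_size) == 3,
            length(n_blocks) == 3, all(block_size > 0), all(n_blocks >= 1))
  if (is.null(surround_radius)) surround_radius <- block_size
  structure(list(origin = origin, block_size = block_size,
                 n_blocks = n_blocks,
                 surround_radius = as.numeric(surround_radius),
                 transforms = NULL, fallback = NULL, global = NULL),
            class = "block_grid")
}

affine_fit3 <- function(src, dst) {
  X <- cbind(src, 1)
  coef <- solve(crossprod(X), crossprod(X, dst))
  t(coef)   # 3 x 4
}

affine_apply3 <- function(A, pts) {
  t(A %*% t(cbind(pts, 1)))
}

source_nondegenerate <- function(src) {
  if (nrow(src) < 4) return(FALSE)
  sv <- svd(scale(src, scale = FALSE))$d
  sv[3] > 1e-9 * max(sv[1], 1)
}

block_lin <- function(grid, i, j, k) {
  i + grid$n_blocks[1] * ((j - 1L) + grid$n_blocks[2] * (k - 1L))
}

#' Fit block-wise affine transforms from landmarks
#'
#' Each block's affine is the least-squares fit to all landmark pairs whose
#' source point lies in the block's surround. Blocks with fewer than 4
#' usable (non-degenerate) points fall back to the global affine and are
#' flagged.
#'
#' @param landmarks data.frame with sx, sy, sz, tx, ty, tz.
#' @param grid \code{\link{block_grid}}.
#' @return the grid with per-block transforms, fallback flags and the
#'   global affine filled in.
#' @export
fit_blockwise_affine <- function(landmarks, grid) {
  stopifnot(inherits(grid, "block_grid"))
  if (NROW(landmarks) < 1) stop("no landmarks")
  src <- as.matrix(landmarks[, c("sx", "sy", "sz")])
  dst <- as.matrix(landmarks[, c("tx", "ty", "tz")])
  if (!source_nondegenerate(src))
    stop("landmarks are globally degenerate; cannot fit any affine")
  grid$global <- affine_fit3(src, dst)
  nb <- grid$n_blocks
  n_tot <- prod(nb)
  grid$transforms <- vector("list", n_tot)
  grid$fallback <- logical(n_tot)
  grid$n_points <- integer(n_tot)
  for (k in seq_len(nb[3])) for (j in seq_len(nb[2])) for (i in seq_len(nb[1])) {
    lo <- grid$origin + (c(i, j, k) - 1) * grid$block_size - grid$surround_radius
    hi <- grid$origin + c(i, j, k) * grid$block_size + grid$surround_radius
    sel <- src[, 1] >= lo[1] & src[, 1] < hi[1] &
      src[, 2] >= lo[2] & src[, 2] < hi[2] &
      src[, 3] >= lo[3] & src[, 3] < hi[3]
    lin <- block_lin(grid, i, j, k)
    grid$n_points[lin] <- sum(sel)
    if (sum(sel) >= 4 && source_nondegenerate(src[sel, , drop = FALSE])) {
      grid$transforms[[lin]] <- affine_fit3(src[sel, , drop = FALSE],
                                            dst[sel, , drop = FALSE])
    } else {
      grid$transforms[[lin]] <- grid$global
      grid$fallback[lin] <- TRUE
    }
  }
  grid
}

#' Map points through a fitted block grid
#'
#' Each point is mapped by the affine of its containing block; points
#' outside the gridded region use the nearest block and are flagged.
#'
#' @param grid fitted \code{\link{block_grid}}.
#' @param points n x 3 source points.
#' @return list(mapped = n x 3 matrix, outside = logical flags,
#'   block = n x 3 block indices used).
#' @export
apply_blockwise <- function(grid, points) {
  stopifnot(inherits(grid, "block_grid"))
  if (is.null(grid$transforms)) stop("block grid has not been fitted")
  points <- matrix(as.numeric(points), ncol = 3)
  raw <- sweep(sweep(points, 2, grid$origin), 2, grid$block_size, "/")
  bidx <- floor(raw) + 1
  outside <- rowSums(bidx < 1 | bidx > matrix(grid$n_blocks,
                                              nrow(points), 3,
                                              byrow = TRUE)) > 0
  bidx <- pmin(pmax(bidx, 1), matrix(grid$n_blocks, nrow(points), 3,
                                     byrow = TRUE))
  mapped <- matrix(NA_real_, nrow(points), 3)
  for (r in seq_len(nrow(points))) {
    A <- grid$transforms[[block_lin(grid, bidx[r, 1], bidx[r, 2], bidx[r, 3])]]
    mapped[r, ] <- affine_apply3(A, points[r, , drop = FALSE])
  }
  list(mapped = mapped, outside = outside, block = bidx)
}

#' Leave-one-out landmark error per block
#'
#' For every landmark, refits its containing block's affine without it and
#' records the mapping error at the held-out landmark. Landmarks whose
#' block then lacks enough points fall back to the global affine for the
#' refit.
#'
#' @param landmarks data.frame with sx..tz.
#' @param grid \code{\link{block_grid}} (unfitted is fine).
#' @return data.frame(landmark, block_i, block_j, block_k, error).
#' @export
blockwise_loo_error <- function(landmarks, grid) {
  n <- nrow(landmarks)
  out <- NULL
  full <- fit_blockwise_affine(landmarks, grid)
  src <- as.matrix(landmarks[, c("sx", "sy", "sz")])
  dst <- as.matrix(landmarks[, c("tx", "ty", "tz")])
  for (i in seq_len(n)) {
    g <- fit_blockwise_affine(landmarks[-i, , drop = FALSE], grid)
    m <- apply_blockwise(g, src[i, , drop = FALSE])
    err <- sqrt(sum((m$mapped - dst[i, ])^2))
    out <- rbind(out, data.frame(landmark = i, block_i = m$block[1, 1],
                                 block_j = m$block[1, 2],
                                 block_k = m$block[1, 3], error = err))
  }
  out
}

#' Export / import block-grid transforms as JSON
#' @param grid fitted \code{block_grid}.
#' @param path JSON file.
#' @return \code{path} invisibly (write) or a \code{block_grid} (read).
#' @export
write_block_grid <- function(grid, path) {
  stopifnot(inherits(grid, "block_grid"))
  obj <- list(origin = grid$origin, block_size = grid$block_size,
              n_blocks = grid$n_blocks,
              surround_radius = grid$surround_radius,
              global = as.vector(grid$global),
              fallback = grid$fallback,
              transforms = lapply(grid$transforms, function(m) as.vector(m)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_block_grid
#' @export
read_block_grid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- block_grid(obj$origin, obj$block_size, obj$n_blocks,
                  obj$surround_radius)
  g$global <- matrix(as.numeric(obj$global), 3, 4)
  g$fallback <- as.logical(obj$fallback)
  g$transforms <- lapply(seq_len(nrow(obj$transforms)), function(i)
    matrix(as.numeric(obj$transforms[i, ]), 3, 4))
  g
}
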