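#' Least-squares affine stage transform from point correspondences
#'
#' Fits the affine map from mask-grid (micro-CT) coordinates into stage
#' coordinates from at least 4 non-coplanar correspondences.
#'
#' @param src,dst numeric n x 3 matrices of corresponding points.
#' @return list(A = 3 x 4 affine matrix, residuals = n x 3, rmse).
#' @export
fit_stage_transform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 3, ncol(dst) == 3, nrow(src) == nrow(dst))
  if (nrow(src) < 4)
    stop("need at least 4 point correspondences")
  sv <- svd(scale(src, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate configuration: source points are (nearly) coplanar")
  X <- cbind(src, 1)
  coef <- solve(crossprod(X), crossprod(X, dst))   # 4 x 3
  A <- t(coef)                                     # 3 x 4
  res <- dst - X %*% coef
  list(A = A, residuals = res, rmse = sqrt(mean(res^2)))
}

#' Apply a stage transform
#' @param tf result of \code{\link{fit_stage_transform}}.
#' @param pts n x 3 points.
#' @return n x 3 transformed points.
#' @export
apply_stage_transform <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  t(tf$A %*% t(cbind(pts, 1)))
}

runs_of_true <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

cover_run <- function(y1, y2, y_min, y_max, overlap, lo_bound, hi_bound) {
  y1 <- unname(y1); y2 <- unname(y2)
  L <- y2 - y1 + 1L
  step <- y_max - overlap
  k <- if (L <= y_max) 1L else as.integer(ceiling((L - overlap) / step))
  tiles <- NULL
  for (t in seq_len(k)) {
    s <- y1 + (t - 1L) * step
    e <- min(s + y_max - 1L, y2)
    len <- e - s + 1L
    if (len < y_min) {            # honor the minimum tile length
      s <- max(lo_bound, e - y_min + 1L)
      e <- min(hi_bound, s + y_min - 1L)
      len <- e - s + 1L
    }
    tiles <- rbind(tiles, c(y_start = s, y_length = len))
  }
  tiles
}

#' X-ray-mask-targeted tile plan
#'
#' Computes, per section, the horizontally stacked elongated tile pattern
#' covering a binary brain mask: columns of fixed scan width step across
#' the mask's x extent (anchored at the whole-stack mask bounding box left
#' edge); within each column, each disjoint y-occupancy interval of the
#' mask is covered by one or more tiles of length in [y_min, y_max],
#' consecutive tiles overlapping by \code{overlap}. One field-of-view
#' positioning move is counted per tile.
#'
#' @param mask binary \code{vem_volume}; z indexes sections.
#' @param tile_width fixed tile width (px, x direction).
#' @param y_min,y_max allowed tile length range (px, y direction).
#' @param overlap overlap between consecutive tiles in a run (px).
#' @return a \code{tile_plan}: list(tiles = data.frame(section, x_start,
#'   x_width, y_start, y_length), totals).
#' @export
plan_tiles <- function(mask, tile_width, y_min = 1L, y_max, overlap = 0L) {
  check_binary(mask)
  tile_width <- as.integer(tile_width); y_min <- as.integer(y_min)
  y_max <- as.integer(y_max); overlap <- as.integer(overlap)
  stopifnot(tile_width > overlap, overlap >= 0, y_min <= y_max, y_min >= 1)
  d <- dim(mask$data)
  occ_any <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(occ_any) == 0) {
    plan <- list(tiles = data.frame(section = integer(0), x_start = integer(0),
                                    x_width = integer(0), y_start = integer(0),
                                    y_length = integer(0)),
                 bbox = NULL, dim = d)
    class(plan) <- "tile_plan"
    return(plan)
  }
  bbox <- apply(occ_any, 2, range)   # 2 x 3 (min/max of x,y,z), 1-based
  x0 <- bbox[1, 1]
  tiles <- NULL
  for (z in seq_len(d[3])) {
    sec <- mask$data[, , z]
    if (!any(sec != 0)) next
    xs <- which(rowSums(sec != 0) > 0)
    for (c_start in seq(x0, max(xs), by = tile_width)) {
      c_end <- min(c_start + tile_width - 1L, d[1])
      colmask <- colSums(sec[c_start:c_end, , drop = FALSE] != 0) > 0
      if (!any(colmask)) next
      for (r in seq_len(nrow(runs_of_true(colmask)))) {
        run <- runs_of_true(colmask)[r, , drop = FALSE]
        tl <- cover_run(run[1, "start"], run[1, "end"], y_min, y_max, overlap,
                        1L, d[2])
        tiles <- rbind(tiles,
                       data.frame(section = z, x_start = c_start,
                                  x_width = c_end - c_start + 1L,
                                  y_start = tl[, "y_start"],
                                  y_length = tl[, "y_length"]))
      }
    }
  }
  plan <- list(tiles = tiles, bbox = bbox, dim = d)
  class(plan) <- "tile_plan"
  plan
}

#' Coverage check of a tile plan
#'
#' @param plan \code{tile_plan}.
#' @param mask the binary mask the plan was computed for.
#' @return TRUE iff every mask voxel lies inside at least one tile.
#' @export
plan_covers_mask <- function(plan, mask) {
  d <- dim(mask$data)
  covered <- array(FALSE, d)
  t <- plan$tiles
  for (i in seq_len(NROW(t)))
    covered[t$x_start[i]:min(t$x_start[i] + t$x_width[i] - 1L, d[1]),
            t$y_start[i]:min(t$y_start[i] + t$y_length[i] - 1L, d[2]),
            t$section[i]] <- TRUE
  !any(mask$data != 0 & !covered)
}

#' Tile-plan summary
#'
#' Motor-move count (one per tile), scanned area, and the coverage fraction
#' in two variants: against the whole-stack cuboid bounding box of the mask
#' (\code{coverage_fraction_cuboid}) and against the summed per-section
#' mask bounding boxes (\code{coverage_fraction_sections}), plus a tile
#' length histogram.
#'
#' @param plan \code{tile_plan}.
#' @param mask the binary mask the plan was computed for.
#' @return list(n_tiles, n_moves, scanned_px, coverage_fraction_cuboid,
#'   coverage_fraction_sections, tile_length_summary).
#' @export
plan_summary <- function(plan, mask) {
  t <- plan$tiles
  if (NROW(t) == 0)
    return(list(n_tiles = 0L, n_moves = 0L, scanned_px = 0,
                coverage_fraction_cuboid = NA_real_,
                coverage_fraction_sections = NA_real_,
                tile_length_summary = summary(integer(0))))
  d <- plan$dim
  bb <- plan$bbox
  ## scanned area without double-counting overlaps; the coverage fractions
  ## count only scanned pixels inside the respective bounding box (tiles may
  ## overhang it), so a fraction of 1 means the box is fully scanned
  scanned <- 0
  scanned_in_cuboid <- 0
  scanned_in_sec_bbox <- 0
  sec_bbox_area <- 0
  for (z in sort(unique(t$section))) {
    covered <- matrix(FALSE, d[1], d[2])
    tz <- t[t$section == z, , drop = FALSE]
    for (i in seq_len(nrow(tz)))
      covered[tz$x_start[i]:min(tz$x_start[i] + tz$x_width[i] - 1L, d[1]),
              tz$y_start[i]:min(tz$y_start[i] + tz$y_length[i] - 1L, d[2])] <-
        TRUE
    scanned <- scanned + sum(covered)
    scanned_in_cuboid <- scanned_in_cuboid +
      sum(covered[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2]])
    sec <- mask$data[, , z]
    w <- which(sec != 0, arr.ind = TRUE)
    sb <- apply(w, 2, range)
    sec_bbox_area <- sec_bbox_area + prod(sb[2, ] - sb[1, ] + 1)
    scanned_in_sec_bbox <- scanned_in_sec_bbox +
      sum(covered[sb[1, 1]:sb[2, 1], sb[1, 2]:sb[2, 2]])
  }
  cuboid <- unname(prod(bb[2, 1:2] - bb[1, 1:2] + 1) *
                     (bb[2, 3] - bb[1, 3] + 1))
  list(n_tiles = nrow(t), n_moves = nrow(t), scanned_px = scanned,
       coverage_fraction_cuboid = unname(scanned_in_cuboid / cuboid),
       coverage_fraction_sections = unname(scanned_in_sec_bbox /
                                             sec_bbox_area),
       tile_length_summary = summary(t$y_length))
}
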