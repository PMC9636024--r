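#' Anisotropic raster volume
#'
#' The universal raster carrier of the package: a 3D array (grayscale,
#' binary or non-negative integer labels) together with its physical voxel
#' size in nm and the voxel offset of its origin in a global frame.
#' Coordinates are 0-based voxel indices in axis order (x, y, z) with
#' half-open extents; the physical position of a voxel is
#' \code{(offset + index) * voxel_size} nm. 2D data are carried as
#' single-section volumes (nz = 1).
#'
#' @param data numeric or integer array; 2D matrices are promoted to a
#'   single-section 3D array.
#' @param voxel_size numeric length-3, nm per voxel along (x, y, z); all
#'   components strictly positive.
#' @param offset integer length-3 voxel index of the origin in the global
#'   frame.
#' @param dtype storage type tag used by the container I/O, one of
#'   \code{"uint8"}, \code{"int32"}, \code{"float64"}. Defaults from the
#'   array's storage mode.
#' @return an object of class \code{vem_volume}.
#' @examples
#' v <- vem_volume(array(0L, c(4, 4, 2)), voxel_size = c(14, 14, 25))
#' dim(v$data)
#' @export
vem_volume <- function(data, voxel_size = c(1, 1, 1), offset = c(0L, 0L, 0L),
                       dtype = NULL) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 2D matrix or 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive numbers (nm)")
  offset <- as.integer(offset)
  if (length(offset) != 3L) stop("offset must have length 3")
  if (is.null(dtype))
    dtype <- if (is.integer(data)) "int32" else "float64"
  if (!dtype %in% c("uint8", "int32", "float64"))
    stop("unsupported dtype: ", dtype)
  structure(list(data = data, voxel_size = voxel_size, offset = offset,
                 dtype = dtype),
            class = "vem_volume")
}

#' @export
print.vem_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vem_volume %d x %d x %d, voxel %g x %g x %g nm, offset (%d, %d, %d), %s>\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$offset[1], x$offset[2], x$offset[3], x$dtype))
  invisible(x)
}

is_binary <- function(vol) {
  all(vol$data %in% c(0, 1))
}

check_binary <- function(vol) {
  if (!inherits(vol, "vem_volume")) stop("expected a vem_volume")
  if (!is_binary(vol)) stop("mask must be binary (values 0/1)")
  invisible(vol)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      !isTRUE(all.equal(a$voxel_size, b$voxel_size)) ||
      !identical(as.integer(a$offset), as.integer(b$offset)))
    stop("volumes are not on the same grid")
  invisible(NULL)
}

check_connectivity <- function(connectivity, d = 3L) {
  ok <- if (d == 3L) c(6L, 18L, 26L) else c(4L, 8L)
  if (!connectivity %in% ok)
    stop("connectivity must be one of ", paste(ok, collapse = ", "))
  as.integer(connectivity)
}

#' Connected components of a binary mask
#'
#' Labels the connected components of a binary volume. Background stays 0;
#' components get labels 1..K in raster-scan order of their first voxel
#' (x fastest), which makes the labeling deterministic.
#'
#' @param mask binary \code{vem_volume}.
#' @param connectivity 3D neighborhood, one of 6, 18, 26 (default 26).
#' @return label \code{vem_volume} with attribute-free integer data; the
#'   number of components is attached as attribute \code{n_components}.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  check_binary(mask)
  connectivity <- check_connectivity(connectivity, 3L)
  lab <- cpp_label_components(as.integer(mask$data), dim(mask$data),
                              connectivity)
  k <- attr(lab, "n_components")
  out <- vem_volume(array(as.integer(lab), dim(mask$data)),
                    voxel_size = mask$voxel_size, offset = mask$offset,
                    dtype = "int32")
  attr(out, "n_components") <- k
  out
}

#' Binary erosion with a digitized ball
#'
#' Erodes a binary mask with the digitized Euclidean ball of the given
#' radius. By default the radius is in voxels and the ball is isotropic in
#' index space; with \code{metric = "nm"} the ball respects the volume's
#' anisotropic voxel size and the radius is in nm. Voxels outside the array
#' count as background.
#'
#' @param mask binary \code{vem_volume}.
#' @param radius non-negative radius; voxels (default) or nm.
#' @param metric \code{"voxel"} or \code{"nm"}.
#' @return binary \code{vem_volume}; always a subset of the input.
#' @export
erode_ball <- function(mask, radius, metric = c("voxel", "nm")) {
  check_binary(mask)
  metric <- match.arg(metric)
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("radius must be a single non-negative number")
  scale <- if (metric == "voxel") c(1, 1, 1) else mask$voxel_size
  out <- cpp_morph_ball(as.integer(mask$data), dim(mask$data),
                        as.numeric(radius), scale, dilate = FALSE)
  vem_volume(array(as.integer(out), dim(mask$data)),
             voxel_size = mask$voxel_size, offset = mask$offset,
             dtype = "int32")
}

#' Binary dilation with a digitized ball
#'
#' Counterpart of \code{\link{erode_ball}}; used e.g. to find cells within a
#' physical distance of a synaptic cleft.
#'
#' @inheritParams erode_ball
#' @return binary \code{vem_volume}; always a superset of the input.
#' @export
dilate_ball <- function(mask, radius, metric = c("voxel", "nm")) {
  check_binary(mask)
  metric <- match.arg(metric)
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("radius must be a single non-negative number")
  scale <- if (metric == "voxel") c(1, 1, 1) else mask$voxel_size
  out <- cpp_morph_ball(as.integer(mask$data), dim(mask$data),
                        as.numeric(radius), scale, dilate = TRUE)
  vem_volume(array(as.integer(out), dim(mask$data)),
             voxel_size = mask$voxel_size, offset = mask$offset,
             dtype = "int32")
}

#' Area-averaged in-plane downsampling
#'
#' Downsamples a 2D plane by an integer factor, each output pixel being the
#' arithmetic mean of its factor x factor block; edge blocks average over
#' the pixels that exist.
#'
#' @param img numeric matrix (one in-plane section).
#' @param factor integer >= 1.
#' @return numeric matrix of dimension \code{ceiling(dim(img) / factor)}.
#' @export
downsample_area <- function(img, factor) {
  if (!is.matrix(img)) stop("img must be a matrix")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(img)
  gx <- ((seq_len(nrow(img)) - 1L) %/% factor) + 1L
  gy <- ((seq_len(ncol(img)) - 1L) %/% factor) + 1L
  sums <- rowsum(t(rowsum(img, gx)), gy)          # block sums, transposed
  cnts <- tcrossprod(tabulate(gy), tabulate(gx))  # block pixel counts
  out <- t(sums / cnts)
  dimnames(out) <- NULL
  out
}

# ---- container I/O ---------------------------------------------------------
# Minimal chunk-free directory store: <path>/<dataset>/ holds meta.json
# (shape, dtype, voxel_size, offset, byte order) and data.bin, raw
# little-endian values in column-major (x fastest) order.

dtype_bytes <- c(uint8 = 1L, int32 = 4L, float64 = 8L)

#' Write a volume to a directory-store container
#'
#' Stores the array plus its voxel size (nm) and offset so that a
#' read/write round trip is bit-exact.
#'
#' @param vol \code{vem_volume}.
#' @param path container directory (created if missing).
#' @param dataset dataset name within the container.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, dataset = "volume") {
  if (!inherits(vol, "vem_volume")) stop("expected a vem_volume")
  dsdir <- file.path(path, dataset)
  dir.create(dsdir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(shape = dim(vol$data), dtype = vol$dtype,
               voxel_size = vol$voxel_size, offset = vol$offset,
               order = "F", endian = "little")
  jsonlite::write_json(meta, file.path(dsdir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dsdir, "data.bin"), "wb")
  on.exit(close(con))
  vals <- as.vector(vol$data)
  if (vol$dtype == "float64") {
    writeBin(as.numeric(vals), con, size = 8L, endian = "little")
  } else {
    writeBin(as.integer(vals), con, size = dtype_bytes[[vol$dtype]],
             endian = "little")
  }
  invisible(path)
}

#' Read a volume from a directory-store container
#'
#' @param path container directory.
#' @param dataset dataset name within the container.
#' @return \code{vem_volume}.
#' @export
read_volume <- function(path, dataset = "volume") {
  dsdir <- file.path(path, dataset)
  metafile <- file.path(dsdir, "meta.json")
  if (!file.exists(metafile))
    stop("dataset '", dataset, "' not found in container ", path)
  meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(file.path(dsdir, "data.bin"), "rb")
  on.exit(close(con))
  vals <- if (meta$dtype == "float64") {
    readBin(con, "double", n = n, size = 8L, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = dtype_bytes[[meta$dtype]],
            endian = "little", signed = meta$dtype != "uint8")
  }
  if (length(vals) != n) stop("truncated data.bin for dataset ", dataset)
  vem_volume(array(vals, shape), voxel_size = as.numeric(meta$voxel_size),
             offset = as.integer(meta$offset), dtype = meta$dtype)
}

#' Physical nm position of voxel indices
#'
#' @param vol \code{vem_volume}.
#' @param index integer matrix (n x 3) of 0-based voxel indices.
#' @return numeric n x 3 matrix of nm positions in the global frame.
#' @export
voxel_to_nm <- function(vol, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index, 2, vol$offset, "+"), 2, vol$voxel_size, "*")
}

#' Voxel index containing physical nm positions
#'
#' @param vol \code{vem_volume}.
#' @param pos numeric matrix (n x 3) of nm positions.
#' @return integer n x 3 matrix of 0-based voxel indices.
#' @export
nm_to_voxel <- function(vol, pos) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  idx <- sweep(sweep(pos, 2, vol$voxel_size, "/"), 2, vol$offset, "-")
  matrix(as.integer(floor(idx + 1e-9)), ncol = 3)
}
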