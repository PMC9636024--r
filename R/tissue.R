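#' Defocus-detector parameters
#'
#' The published filter chain: Gaussian (sigma 1), discrete 5-point
#' Laplacian, per-pixel standard deviation over a centered 21 x 21 window,
#' 128x in-plane area-averaged downsampling, and a strict \code{< 57}
#' threshold on the 8-bit intensity scale.
#'
#' @param gaussian_sigma Gaussian sigma in px.
#' @param std_window odd window width for the local standard deviation.
#' @param downsample_factor in-plane area-averaging factor.
#' @param threshold sites with value strictly below are defocused.
#' @return a \code{defocus_params} list.
#' @export
defocus_params <- function(gaussian_sigma = 1, std_window = 21L,
                           downsample_factor = 128L, threshold = 57) {
  stopifnot(gaussian_sigma > 0, std_window >= 1, std_window %% 2 == 1,
            downsample_factor >= 1, threshold > 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 std_window = as.integer(std_window),
                 downsample_factor = as.integer(downsample_factor),
                 threshold = threshold), class = "defocus_params")
}

#' Defocus mask of an image stack
#'
#' Runs the defocus filter chain plane by plane on a contrast-normalized
#' 8-bit stack and returns the binary defocus mask at the 128x-downsampled
#' in-plane resolution. Input planes are expected already normalized; an
#' optional built-in CLAHE pass (8-bit, 64 x 64 tiles, clip limit 2.0, via
#' EBImage) can be applied first.
#'
#' @param stack 8-bit grayscale \code{vem_volume}.
#' @param params \code{\link{defocus_params}}.
#' @param clahe apply the built-in CLAHE normalization first.
#' @return list(mask = binary \code{vem_volume} at downsampled in-plane
#'   resolution (1 = defocused), values = the downsampled std map).
#' @export
defocus_mask <- function(stack, params = defocus_params(), clahe = FALSE) {
  stopifnot(inherits(stack, "vem_volume"), inherits(params, "defocus_params"))
  d <- dim(stack$data)
  f <- params$downsample_factor
  h <- (params$std_window - 1L) %/% 2L
  nxo <- ceiling(d[1] / f); nyo <- ceiling(d[2] / f)
  vals <- array(0, c(nxo, nyo, d[3]))
  for (z in seq_len(d[3])) {
    plane <- matrix(as.numeric(stack$data[, , z]), d[1], d[2])
    if (clahe) {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("CLAHE normalization needs the EBImage package")
      plane <- round(255 * EBImage::clahe(EBImage::Image(plane / 255),
                                          nx = 64, ny = 64, limit = 2))
      plane <- matrix(pmin(pmax(as.numeric(plane), 0), 255), d[1], d[2])
    }
    g <- gauss_blur2d(plane, params$gaussian_sigma)
    l <- laplacian5(g)
    sd_map <- local_std(l, h)
    vals[, , z] <- downsample_area(sd_map, f)
  }
  mask <- array(as.integer(vals < params$threshold), dim(vals))
  vs <- stack$voxel_size * c(f, f, 1)
  list(mask = vem_volume(mask, voxel_size = vs, dtype = "int32"),
       values = vals)
}

#' Soma-candidate parameters
#'
#' @param exclusion_classes class names zeroed before component analysis.
#' @param erosion_radius radius (voxels) of the anti-merger erosion.
#' @param min_volume retained objects must have strictly more voxels than
#'   this (at the grid of the nucleus prediction).
#' @return a \code{soma_params} list.
#' @export
soma_params <- function(exclusion_classes = c("nonneuropil", "soma"),
                        erosion_radius = 5, min_volume = 1000) {
  stopifnot(erosion_radius >= 0, min_volume >= 0)
  structure(list(exclusion_classes = exclusion_classes,
                 erosion_radius = erosion_radius,
                 min_volume = min_volume), class = "soma_params")
}

#' Soma candidates from a binarized nucleus prediction
#'
#' Zeroes voxels of the exclusion classes, computes 3D connected
#' components, erodes with a digitized ball to break false mergers,
#' recomputes components, and keeps objects with volume strictly greater
#' than \code{min_volume} voxels.
#'
#' @param nucleus_pred binary \code{vem_volume} (binarized classifier
#'   output).
#' @param class_maps named list of binary \code{vem_volume}s, one per
#'   predicted class; entries named in \code{params$exclusion_classes} are
#'   zeroed out of the nucleus mask.
#' @param params \code{\link{soma_params}}.
#' @param connectivity component connectivity (default 26).
#' @return list(labels = label \code{vem_volume}, table = data.frame(id,
#'   volume_voxels, cx_nm, cy_nm, cz_nm) sorted by id).
#' @export
soma_candidates <- function(nucleus_pred, class_maps = list(),
                            params = soma_params(), connectivity = 26L) {
  check_binary(nucleus_pred)
  stopifnot(inherits(params, "soma_params"))
  mask <- nucleus_pred$data
  for (cls in params$exclusion_classes) {
    if (!cls %in% names(class_maps)) next
    cm <- class_maps[[cls]]
    check_same_grid(nucleus_pred, cm)
    mask[cm$data != 0] <- 0L
  }
  vol <- vem_volume(array(as.integer(mask), dim(mask)),
                    voxel_size = nucleus_pred$voxel_size,
                    offset = nucleus_pred$offset, dtype = "int32")
  cc1 <- connected_components(vol, connectivity)   # initial segmentation
  eroded <- erode_ball(vem_volume(array(as.integer(cc1$data > 0), dim(mask)),
                                  voxel_size = vol$voxel_size,
                                  offset = vol$offset, dtype = "int32"),
                       params$erosion_radius)
  cc2 <- connected_components(eroded, connectivity)
  labs <- cc2$data
  ids <- sort(unique(labs[labs > 0]))
  keep <- integer(0)
  rows <- NULL
  new_id <- 0L
  out <- array(0L, dim(mask))
  for (id in ids) {
    w <- which(labs == id)
    if (length(w) <= params$min_volume) next
    new_id <- new_id + 1L
    out[w] <- new_id
    co <- arrayInd(w, dim(mask)) - 1L               # 0-based voxel indices
    cen <- colMeans(voxel_to_nm(vol, co))
    rows <- rbind(rows, data.frame(id = new_id,
                                   volume_voxels = length(w),
                                   cx_nm = cen[1], cy_nm = cen[2],
                                   cz_nm = cen[3]))
  }
  table <- if (is.null(rows))
    data.frame(id = integer(0), volume_voxels = integer(0),
               cx_nm = numeric(0), cy_nm = numeric(0), cz_nm = numeric(0))
  else rows[order(rows$id), , drop = FALSE]
  list(labels = vem_volume(out, voxel_size = vol$voxel_size,
                           offset = vol$offset, dtype = "int32"),
       table = table)
}
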