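#' Surface mesh of a voxel object
#'
#' Triangulated iso-surface (marching tetrahedra at iso 0.5 on the binary
#' mask, padded so the surface closes) at physical scale: vertex
#' coordinates are nm in the volume's global frame. Duplicate vertices are
#' welded and the mesh is smoothed with Taubin's low-shrinkage lambda/mu
#' filter to remove the voxel staircase, which would otherwise bias
#' surface areas upward.
#'
#' @param mask binary \code{vem_volume}.
#' @param smooth_iterations Taubin smoothing iterations (0 = raw
#'   iso-surface).
#' @return list(vertices = n x 3 nm, triangles = m x 3 vertex indices).
#' @export
mesh_from_mask <- function(mask, smooth_iterations = 20L) {
  check_binary(mask)
  d <- dim(mask$data)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask$data
  origin <- (mask$offset - 1) * mask$voxel_size
  mesh <- cpp_marching_tetra(as.numeric(padded), dim(padded), 0.5,
                             mask$voxel_size, origin)
  mesh <- weld_mesh(mesh)
  if (smooth_iterations > 0) mesh <- taubin_smooth(mesh, smooth_iterations)
  mesh
}

## merge vertices that coincide (marching tetrahedra emits a triangle soup)
weld_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  if (nrow(v) == 0) return(mesh)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  list(vertices = v[uk, , drop = FALSE],
       triangles = matrix(map[mesh$triangles], ncol = 3))
}

## Taubin lambda/mu smoothing: alternating positive and negative Laplacian
## steps, which smooths without the shrinkage of plain Laplacian filtering
taubin_smooth <- function(mesh, iterations = 20L, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (nrow(v) == 0 || nrow(tr) == 0) return(mesh)
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  deg <- tabulate(e[, 1], nbins = nrow(v))
  step <- function(v, f) {
    nb <- rowsum(v[e[, 2], , drop = FALSE], e[, 1])
    v + f * (nb / deg - v)
  }
  for (i in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  list(vertices = v, triangles = tr)
}

mesh_area_nm2 <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (NROW(tr) == 0) return(0)
  a <- v[tr[, 1], , drop = FALSE]
  ab <- v[tr[, 2], , drop = FALSE] - a
  ac <- v[tr[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Contact area of a voxel object
#'
#' Meshes the object and reports its contact area in square micrometers.
#' By convention the reported area is half the closed-mesh surface area: a
#' synaptic contact annotation is a thin slab whose mesh has two faces, so
#' the full mesh area would double-count the contact. The accuracy of this
#' convention degrades for compact (non-slab-like) objects, where the side
#' walls contribute; the full mesh area is always reported alongside.
#'
#' @param mask binary \code{vem_volume} holding one connected object.
#' @param half_surface report half the closed-mesh area (default) or the
#'   full mesh area.
#' @return list(area_um2, full_area_um2, mesh, empty = flag).
#' @export
contact_area <- function(mask, half_surface = TRUE) {
  check_binary(mask)
  if (!any(mask$data != 0))
    return(list(area_um2 = 0, full_area_um2 = 0, mesh = NULL, empty = TRUE))
  mesh <- mesh_from_mask(mask)
  full <- mesh_area_nm2(mesh) / 1e6
  list(area_um2 = if (half_surface) full / 2 else full,
       full_area_um2 = full, mesh = mesh, empty = FALSE)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh list(vertices, triangles).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6g %.6g %.6g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  invisible(path)
}

## Feret diameter of a set of 2D pixel centers, with end-cap correction:
## the caliper length along the maximizing direction includes the half-pixel
## footprint at both ends, so axis-aligned runs measure count * pitch exactly.
feret_diameter <- function(pts, pitch) {
  n <- nrow(pts)
  if (n == 1) return(max(pitch))
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  best <- 0
  for (i in seq_len(nrow(hp))) for (j in seq_len(nrow(hp))) {
    if (j <= i) next
    dv <- hp[j, ] - hp[i, ]
    dd <- sqrt(sum(dv^2))
    if (dd == 0) next
    u <- abs(dv) / dd
    cand <- dd + u[1] * pitch[1] + u[2] * pitch[2]
    if (cand > best) best <- cand
  }
  if (best == 0) max(pitch) else best
}

#' Per-section 2D profile lengths of an object
#'
#' Slices the object along one cardinal axis at the dataset resolution and
#' measures, for each section intersecting it, the Feret diameter (maximum
#' pairwise caliper distance, end-capped by the pixel footprint) of the
#' largest in-plane connected component, in nm. A single-voxel slice
#' reports the larger in-plane pitch.
#'
#' @param mask binary \code{vem_volume}.
#' @param axis slicing axis, "x", "y" or "z".
#' @param connectivity in-plane connectivity, 4 or 8 (default 8).
#' @return data.frame(section = 0-based section index, length_nm).
#' @export
profile_lengths <- function(mask, axis = c("z", "x", "y"),
                            connectivity = 8L) {
  check_binary(mask)
  axis <- match.arg(axis)
  connectivity <- check_connectivity(connectivity, 2L)
  ax <- match(axis, c("x", "y", "z"))
  inplane <- setdiff(1:3, ax)
  pitch <- mask$voxel_size[inplane]
  d <- dim(mask$data)
  out <- NULL
  for (s in seq_len(d[ax])) {
    sl <- switch(axis,
                 x = mask$data[s, , ],
                 y = mask$data[, s, ],
                 z = mask$data[, , s])
    sl <- matrix(as.integer(sl), d[inplane[1]], d[inplane[2]])
    if (!any(sl != 0)) next
    lab <- array(cpp_label_components(as.integer(sl), c(dim(sl), 1L),
                                      connectivity), dim(sl))
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)        # ties: smallest label
    w <- which(lab == big, arr.ind = TRUE)
    pts <- cbind((w[, 1] - 1) * pitch[1], (w[, 2] - 1) * pitch[2])
    out <- rbind(out, data.frame(section = s - 1L,
                                 length_nm = feret_diameter(pts, pitch)))
  }
  if (is.null(out)) data.frame(section = integer(0), length_nm = numeric(0))
  else out
}

#' Sampled medians of contact area and profile length per region
#'
#' Draws a reproducible random sample of contact objects per region
#' (default 100) and reports the median contact area over sampled objects
#' and the median of their pooled per-section profile lengths.
#'
#' @param object_table data.frame(id, region, area_um2).
#' @param lengths_by_object named list: object id -> numeric vector of
#'   per-section lengths (nm), typically pooled over the slicing axes of
#'   interest.
#' @param n sample size per region.
#' @param seed RNG seed.
#' @return data.frame(region, n_objects, n_sampled, median_area_um2,
#'   median_length_nm, flag_empty).
#' @export
contact_sample_report <- function(object_table, lengths_by_object,
                                  n = 100L, seed = 1L) {
  stopifnot(all(c("id", "region", "area_um2") %in% names(object_table)))
  regions <- sort(unique(object_table$region))
  with_seed(seed, {
    rows <- lapply(regions, function(r) {
      ids <- object_table$id[object_table$region == r]
      if (length(ids) == 0)
        return(data.frame(region = r, n_objects = 0L, n_sampled = 0L,
                          median_area_um2 = NA_real_,
                          median_length_nm = NA_real_, flag_empty = TRUE))
      sel <- if (length(ids) <= n) ids else sample(ids, n)
      areas <- object_table$area_um2[match(sel, object_table$id)]
      lens <- unlist(lengths_by_object[as.character(sel)], use.names = FALSE)
      data.frame(region = r, n_objects = length(ids), n_sampled = length(sel),
                 median_area_um2 = stats::median(areas),
                 median_length_nm = if (length(lens)) stats::median(lens)
                                    else NA_real_,
                 flag_empty = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Vesicle-cloud volume fraction of a region
#'
#' @param vesicle_mask binary \code{vem_volume} of predicted vesicle-cloud
#'   voxels.
#' @param region_mask binary \code{vem_volume} of the region, same grid.
#' @return percent of region voxels predicted as vesicle cloud; NA with a
#'   warning for an empty region.
#' @export
vesicle_fraction <- function(vesicle_mask, region_mask) {
  check_binary(vesicle_mask); check_binary(region_mask)
  check_same_grid(vesicle_mask, region_mask)
  denom <- sum(region_mask$data != 0)
  if (denom == 0) {
    warning("empty region; vesicle fraction undefined")
    return(NA_real_)
  }
  100 * sum(vesicle_mask$data != 0 & region_mask$data != 0) / denom
}

#' Object-wise precision and recall
#'
#' Matches predicted objects to ground-truth objects greedily by
#' descending overlap voxel count (any overlap counts; ties by smaller id
#' pair), one-to-one. Matched predictions are true positives, unmatched
#' predictions false positives, unmatched truth objects false negatives.
#'
#' @param pred,truth label \code{vem_volume}s on one grid.
#' @return list(tp, fp, fn, precision, recall, matches data.frame,
#'   undefined flags).
#' @export
objectwise_pr <- function(pred, truth) {
  stopifnot(inherits(pred, "vem_volume"), inherits(truth, "vem_volume"))
  check_same_grid(pred, truth)
  p <- as.integer(pred$data); t_ <- as.integer(truth$data)
  both <- p > 0 & t_ > 0
  pred_ids <- sort(unique(p[p > 0])); truth_ids <- sort(unique(t_[t_ > 0]))
  ov <- if (any(both)) {
    tab <- table(pred = p[both], truth = t_[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq > 0, ]
    df$pred <- as.integer(df$pred); df$truth <- as.integer(df$truth)
    df[order(-df$Freq, df$pred, df$truth), ]
  } else data.frame(pred = integer(0), truth = integer(0), Freq = integer(0))
  used_p <- integer(0); used_t <- integer(0)
  matches <- NULL
  for (i in seq_len(nrow(ov))) {
    if (ov$pred[i] %in% used_p || ov$truth[i] %in% used_t) next
    used_p <- c(used_p, ov$pred[i]); used_t <- c(used_t, ov$truth[i])
    matches <- rbind(matches, data.frame(pred = ov$pred[i],
                                         truth = ov$truth[i],
                                         overlap = ov$Freq[i]))
  }
  tp <- length(used_p)
  fp <- length(pred_ids) - tp
  fn <- length(truth_ids) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision_undefined = tp + fp == 0,
       recall_undefined = tp + fn == 0,
       matches = matches %||% data.frame(pred = integer(0),
                                         truth = integer(0),
                                         overlap = integer(0)))
}
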