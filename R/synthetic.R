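#' Phantom specification
#'
#' Parameters of the synthetic phantom volume: neurite tubes running along x
#' in parallel rows, somata with a nucleus strictly inside, synaptic clefts
#' in the gap between adjacent tubes with a vesicle cloud in the designated
#' presynaptic tube. Defaults emulate the structures the pipeline assumes:
#' neurites down to 50 nm, vesicle-scale texture, postsynaptic-density-scale
#' cleft slabs (25--50 nm thick), on a 14 x 14 x 25 nm grid.
#'
#' @param shape volume extent in voxels (x, y, z).
#' @param voxel_size nm per voxel.
#' @param n_neurites number of neurite tubes.
#' @param neurite_radius_nm radius range sampled per tube, nm.
#' @param n_somata number of somata (each with one nucleus).
#' @param soma_radius_nm soma radius range, nm.
#' @param nucleus_radius_nm nucleus radius range, nm (kept strictly inside).
#' @param n_synapses number of synaptic clefts planted between adjacent tubes.
#' @param cleft_thickness_nm cleft slab thickness, nm.
#' @param vesicle_cloud_radius_nm radius of the presynaptic vesicle cloud, nm.
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return a \code{phantom_spec} list.
#' @export
phantom_spec <- function(shape = c(512L, 512L, 128L),
                         voxel_size = c(14, 14, 25),
                         n_neurites = 8L,
                         neurite_radius_nm = c(50, 150),
                         n_somata = 0L,
                         soma_radius_nm = c(900, 1400),
                         nucleus_radius_nm = c(400, 650),
                         n_synapses = 4L,
                         cleft_thickness_nm = 30,
                         vesicle_cloud_radius_nm = 150,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
               n_neurites = as.integer(n_neurites),
               neurite_radius_nm = as.numeric(neurite_radius_nm),
               n_somata = as.integer(n_somata),
               soma_radius_nm = as.numeric(soma_radius_nm),
               nucleus_radius_nm = as.numeric(nucleus_radius_nm),
               n_synapses = as.integer(n_synapses),
               cleft_thickness_nm = as.numeric(cleft_thickness_nm),
               vesicle_cloud_radius_nm = as.numeric(vesicle_cloud_radius_nm),
               seed = as.integer(seed))
  stopifnot(all(spec$shape > 0), all(spec$voxel_size > 0),
            spec$n_neurites >= 0, spec$n_somata >= 0, spec$n_synapses >= 0,
            all(spec$neurite_radius_nm > 0), spec$cleft_thickness_nm > 0)
  class(spec) <- "phantom_spec"
  spec
}

# ellipse cross-section offsets for a tube of voxel radii (ry, rz)
ellipse_offsets <- function(ry, rz) {
  dy <- rep(seq(-ry, ry), times = 2 * rz + 1)
  dz <- rep(seq(-rz, rz), each = 2 * ry + 1)
  keep <- (dy / ry)^2 + (dz / rz)^2 <= 1 + 1e-9
  cbind(dy = dy[keep], dz = dz[keep])
}

# smooth random in-row jitter path over x (integer voxel offsets)
smooth_path <- function(nx, amplitude) {
  if (amplitude <= 0) return(rep(0L, nx))
  raw <- cumsum(stats::rnorm(nx))
  k <- gauss_kernel(max(2, nx / 16))
  pad <- length(k)
  padded <- c(rep(raw[1], pad), raw, rep(raw[nx], pad))
  sm <- stats::filter(padded, k, sides = 2)
  sm <- as.numeric(sm[(pad + 1):(pad + nx)])
  sm <- sm - mean(sm)
  if (max(abs(sm)) > 0) sm <- sm / max(abs(sm)) * amplitude
  as.integer(round(sm))
}

#' Generate a phantom volume
#'
#' Builds the ground-truth label volume, centerline skeletons, cleft and
#' vesicle-cloud label volumes and the cleft-to-partner map described by a
#' \code{\link{phantom_spec}}. Neurite tubes run along x in rows; tubes that
#' are neighbors within a row are separated by a constant surface gap equal
#' to the cleft thickness, so clefts planted in that gap touch exactly the
#' two neighboring cells. Identical seeds give bit-identical output.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with elements \code{truth}, \code{cleft_labels},
#'   \code{vesicle_labels} (label \code{vem_volume}s), \code{skeletons}
#'   (named list of \code{\link{skeleton}}s, one per neurite),
#'   \code{cleft_to_pair} (data.frame cleft/pre/post),
#'   \code{adjacent_pairs} (data.frame of neighboring tube pairs with a
#'   contact voxel), \code{objects} (per-label bookkeeping) and
#'   \code{synapses} (per-cleft geometry).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, make_phantom_impl(spec))
}

make_phantom_impl <- function(spec) {
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  vs <- spec$voxel_size
  truth <- array(0L, spec$shape)
  cleft <- array(0L, spec$shape)
  vesic <- array(0L, spec$shape)

  gap_vox <- max(1L, as.integer(round(spec$cleft_thickness_nm / vs[2])))
  margin_x <- 3L
  x_span <- seq(margin_x + 1L, nx - margin_x)
  if (length(x_span) < 8L && spec$n_neurites > 0)
    stop("infeasible packing: volume too small along x")

  ## --- neurite rows --------------------------------------------------------
  r_nm <- if (spec$n_neurites > 0)
    stats::runif(spec$n_neurites, spec$neurite_radius_nm[1],
                 spec$neurite_radius_nm[2]) else numeric(0)
  ry <- pmax(1L, as.integer(round(r_nm / vs[2])))
  rz <- pmax(1L, as.integer(round(r_nm / vs[3])))
  jitter_amp <- 2L
  margin_y <- 2L + jitter_amp

  rows <- list()          # per row: tube indices
  tube_y <- integer(spec$n_neurites); tube_zrow <- integer(spec$n_neurites)
  cur_row <- integer(0)
  y_cur <- NA_integer_
  z_cur <- NA_integer_
  z_next_free <- 2L + jitter_amp + (if (spec$n_neurites > 0) max(rz) else 0L)
  for (i in seq_len(spec$n_neurites)) {
    start_new <- length(cur_row) == 0L ||
      (y_cur + ry[cur_row[length(cur_row)]] + gap_vox + 2L * ry[i] + margin_y > ny)
    if (start_new) {
      if (length(cur_row) > 0) {
        rows[[length(rows) + 1L]] <- cur_row
        z_next_free <- z_cur + max(rz[cur_row]) + 4L + jitter_amp + max(rz[i], 1L)
      }
      cur_row <- integer(0)
      z_cur <- z_next_free
      if (z_cur + max(rz[i], 1L) + jitter_amp > nz)
        stop("infeasible packing: not enough room for requested neurites")
      y_cur <- margin_y + ry[i]
    } else {
      y_cur <- y_cur + ry[cur_row[length(cur_row)]] + gap_vox + ry[i]
    }
    cur_row <- c(cur_row, i)
    tube_y[i] <- y_cur
    tube_zrow[i] <- z_cur
  }
  if (length(cur_row) > 0) rows[[length(rows) + 1L]] <- cur_row
  z_tubes_max <- if (spec$n_neurites > 0)
    max(tube_zrow + rz + jitter_amp) else 0L

  ## rasterize tubes; row-shared smooth jitter keeps in-row gaps exact
  skeletons <- list()
  path_y <- vector("list", length(rows)); path_z <- vector("list", length(rows))
  for (r in seq_along(rows)) {
    path_y[[r]] <- smooth_path(length(x_span), jitter_amp)
    path_z[[r]] <- smooth_path(length(x_span), jitter_amp)
  }
  row_of <- integer(spec$n_neurites)
  for (r in seq_along(rows)) row_of[rows[[r]]] <- r
  for (i in seq_len(spec$n_neurites)) {
    r <- row_of[i]
    yc <- tube_y[i] + path_y[[r]]
    zc <- tube_zrow[i] + path_z[[r]]
    off <- ellipse_offsets(ry[i], rz[i])
    coords <- cbind(
      x = rep(x_span, each = nrow(off)),
      y = rep(yc, each = nrow(off)) + rep(off[, 1], length(x_span)),
      z = rep(zc, each = nrow(off)) + rep(off[, 2], length(x_span)))
    truth[coords] <- i
    nodes <- data.frame(id = seq_along(x_span),
                        x = (x_span - 1) * vs[1],
                        y = (yc - 1) * vs[2],
                        z = (zc - 1) * vs[3],
                        radius = r_nm[i],
                        type = 0L)
    edges <- cbind(seq_len(length(x_span) - 1L), seq(2L, length(x_span)))
    skeletons[[paste0("cell", i)]] <-
      skeleton(nodes, edges, compartment = rep("axon", nrow(nodes)))
  }

  ## adjacent pairs: consecutive tubes within a row
  ap <- do.call(rbind, lapply(rows, function(rw) {
    if (length(rw) < 2L) return(NULL)
    cbind(a = rw[-length(rw)], b = rw[-1])
  }))
  adjacent_pairs <- if (is.null(ap)) {
    data.frame(a = integer(0), b = integer(0), x_contact = integer(0))
  } else {
    ## contact x positions cycle along the tube axis so that merge windows
    ## of pairs sharing a tube never overlap
    xi_lo <- min(x_span) + 8L; xi_hi <- max(x_span) - 8L
    slots_x <- seq(xi_lo, xi_hi,
                   by = max(12L, (xi_hi - xi_lo) %/% 4L))
    data.frame(a = ap[, 1], b = ap[, 2],
               x_contact = slots_x[((seq_len(nrow(ap)) - 1L) %%
                                      length(slots_x)) + 1L])
  }

  ## --- synapses ------------------------------------------------------------
  syn <- data.frame(cleft = integer(0), a = integer(0), b = integer(0),
                    pre = integer(0), post = integer(0), x0 = integer(0))
  if (spec$n_synapses > 0) {
    if (nrow(adjacent_pairs) == 0L)
      stop("infeasible packing: synapses requested but no adjacent tube pair")
    wx <- 2L
    ## synapses in one row stay well separated along x, so one synapse's
    ## vesicle cloud cannot sit inside another cleft's partner neighborhood
    sep <- max(2L * max(pmax(1L, as.integer(
      round(spec$vesicle_cloud_radius_nm / vs[1])))) + 6L, 2L * wx + 6L)
    ## visit pairs round-robin across rows and hand out slot positions from
    ## a per-row shuffled grid, so capacity is extent / separation exactly
    pair_rows <- row_of[adjacent_pairs$a]
    pair_order <- order(stats::ave(pair_rows, pair_rows,
                                   FUN = seq_along), pair_rows)
    xi_lo <- min(x_span) + 8L; xi_hi <- max(x_span) - 8L
    pools <- lapply(seq_along(rows), function(r)
      sample(seq(xi_lo, xi_hi, by = sep + 1L)))
    for (k in seq_len(spec$n_synapses)) {
      p <- pair_order[((k - 1L) %% nrow(adjacent_pairs)) + 1L]
      rw <- row_of[adjacent_pairs$a[p]]
      if (length(pools[[rw]]) == 0L)
        stop("infeasible packing: could not place synapse ", k,
             " (row ", rw, " has no free slot along x)")
      x0 <- pools[[rw]][1L]
      pools[[rw]] <- pools[[rw]][-1L]
      a <- adjacent_pairs$a[p]; b <- adjacent_pairs$b[p]
      pre <- if (stats::runif(1) < 0.5) a else b
      post <- if (pre == a) b else a
      syn <- rbind(syn, data.frame(cleft = k, a = a, b = b, pre = pre,
                                   post = post, x0 = x0))
    }
    for (k in seq_len(nrow(syn))) {
      a <- syn$a[k]; b <- syn$b[k]; x0 <- syn$x0[k]
      r <- row_of[a]
      xi <- match(x0, x_span)
      xwin <- x0 + seq(-wx, wx)
      ya_s <- tube_y[a] + path_y[[r]][xi + seq(-wx, wx)] + ry[a]   # surface of a
      yb_s <- tube_y[b] + path_y[[r]][xi + seq(-wx, wx)] - ry[b]   # surface of b
      zc <- tube_zrow[a] + path_z[[r]][xi + seq(-wx, wx)]
      for (t in seq_along(xwin)) {
        ys <- seq(ya_s[t] + 1L, yb_s[t] - 1L)
        cleft[cbind(xwin[t], ys, zc[t])] <- k
      }
      ## vesicle cloud inside the presynaptic tube near the cleft
      rvx <- pmax(1L, as.integer(round(spec$vesicle_cloud_radius_nm / vs)))
      cx <- x0; cy <- tube_y[syn$pre[k]] + path_y[[r]][xi]
      cz <- tube_zrow[syn$pre[k]] + path_z[[r]][xi]
      xr <- seq(max(1L, cx - rvx[1]), min(nx, cx + rvx[1]))
      yr <- seq(max(1L, cy - rvx[2]), min(ny, cy + rvx[2]))
      zr <- seq(max(1L, cz - rvx[3]), min(nz, cz + rvx[3]))
      gg <- expand.grid(x = xr, y = yr, z = zr)
      d2 <- ((gg$x - cx) / rvx[1])^2 + ((gg$y - cy) / rvx[2])^2 +
        ((gg$z - cz) / rvx[3])^2
      gg <- gg[d2 <= 1, , drop = FALSE]
      gm <- as.matrix(gg)
      inside <- truth[gm] == syn$pre[k]
      vesic[gm[inside, , drop = FALSE]] <- k
    }
  }

  ## --- somata --------------------------------------------------------------
  objects <- data.frame(label = seq_len(spec$n_neurites),
                        kind = rep("neurite", spec$n_neurites),
                        partner = rep(NA_integer_, spec$n_neurites))
  soma_info <- data.frame(soma_label = integer(0), nucleus_label = integer(0),
                          cx = integer(0), cy = integer(0), cz = integer(0),
                          r_soma_vox = integer(0), r_nuc_vox = integer(0))
  if (spec$n_somata > 0) {
    next_label <- spec$n_neurites
    placed_centers <- NULL
    for (s in seq_len(spec$n_somata)) {
      rs_nm <- stats::runif(1, spec$soma_radius_nm[1], spec$soma_radius_nm[2])
      rn_nm <- stats::runif(1, spec$nucleus_radius_nm[1],
                            min(spec$nucleus_radius_nm[2], rs_nm * 0.7))
      rs <- pmax(2L, as.integer(round(rs_nm / vs)))
      rn <- pmax(1L, pmin(as.integer(round(rn_nm / vs)), rs - 2L))
      zlo <- z_tubes_max + rs[3] + 2L
      if (rs[1] + 1L > nx - rs[1] || rs[2] + 1L > ny - rs[2] ||
          zlo > nz - rs[3])
        stop("infeasible packing: soma of radius ", max(rs),
             " voxels does not fit the free region")
      ok <- FALSE
      for (try in 1:200) {
        cx <- sample(seq(rs[1] + 1L, nx - rs[1]), 1L)
        cy <- sample(seq(rs[2] + 1L, ny - rs[2]), 1L)
        cz <- sample(seq(zlo, nz - rs[3]), 1L)
        if (is.null(placed_centers) ||
            all(sqrt(rowSums(sweep(placed_centers[, 1:3, drop = FALSE], 2,
                                   c(cx, cy, cz))^2)) >
                rs[2] + placed_centers[, 4] + 2)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("infeasible packing: could not place soma ", s)
      placed_centers <- rbind(placed_centers, c(cx, cy, cz, max(rs)))
      soma_lab <- next_label + 1L; nuc_lab <- next_label + 2L
      next_label <- next_label + 2L
      for (lab in c(soma_lab, nuc_lab)) {
        rr <- if (lab == soma_lab) rs else rn
        xr <- seq(cx - rr[1], cx + rr[1]); yr <- seq(cy - rr[2], cy + rr[2])
        zr <- seq(cz - rr[3], cz + rr[3])
        gg <- expand.grid(x = xr, y = yr, z = zr)
        d2 <- ((gg$x - cx) / rr[1])^2 + ((gg$y - cy) / rr[2])^2 +
          ((gg$z - cz) / rr[3])^2
        truth[as.matrix(gg[d2 <= 1 + 1e-9, ])] <- lab
      }
      objects <- rbind(objects,
                       data.frame(label = c(soma_lab, nuc_lab),
                                  kind = c("soma", "nucleus"),
                                  partner = c(nuc_lab, soma_lab)))
      soma_info <- rbind(soma_info,
                         data.frame(soma_label = soma_lab,
                                    nucleus_label = nuc_lab, cx = cx, cy = cy,
                                    cz = cz, r_soma_vox = max(rs),
                                    r_nuc_vox = max(rn)))
    }
  }

  mk <- function(arr) vem_volume(arr, voxel_size = vs, dtype = "int32")
  list(truth = mk(truth), cleft_labels = mk(cleft), vesicle_labels = mk(vesic),
       skeletons = skeletons,
       cleft_to_pair = data.frame(cleft = syn$cleft, pre = syn$pre,
                                  post = syn$post),
       adjacent_pairs = adjacent_pairs, objects = objects,
       synapses = syn, soma_info = soma_info,
       tube_geom = list(tube_y = tube_y, tube_zrow = tube_zrow, ry = ry,
                        rz = rz, row_of = row_of, path_y = path_y,
                        path_z = path_z, x_span = x_span))
}

#' Point pairs across adjacent phantom neurites
#'
#' One point pair per adjacent tube pair, the two points sitting on the two
#' tube centerlines just either side of the pair's contact x position --
#' the phantom analogue of manually annotated "adjacent but different
#' neurite" point pairs used for merge screening.
#'
#' @param phantom result of \code{\link{make_phantom}}.
#' @param dx voxel offset along x between the two points of a pair.
#' @return data.frame with voxel coordinates px,py,pz,qx,qy,qz and the two
#'   true labels.
#' @export
phantom_point_pairs <- function(phantom, dx = 2L) {
  ap <- phantom$adjacent_pairs
  g <- phantom$tube_geom
  if (nrow(ap) == 0L)
    return(data.frame(px = integer(0), py = integer(0), pz = integer(0),
                      qx = integer(0), qy = integer(0), qz = integer(0),
                      label_p = integer(0), label_q = integer(0)))
  out <- lapply(seq_len(nrow(ap)), function(i) {
    a <- ap$a[i]; b <- ap$b[i]; x0 <- ap$x_contact[i]
    r <- g$row_of[a]
    xi <- match(x0, g$x_span)
    ## 0-based voxel coordinates (package convention)
    data.frame(px = x0 + dx - 1L,
               py = g$tube_y[a] + g$path_y[[r]][xi + dx] - 1L,
               pz = g$tube_zrow[a] + g$path_z[[r]][xi + dx] - 1L,
               qx = x0 - dx - 1L,
               qy = g$tube_y[b] + g$path_y[[r]][xi - dx] - 1L,
               qz = g$tube_zrow[b] + g$path_z[[r]][xi - dx] - 1L,
               label_p = a, label_q = b)
  })
  do.call(rbind, out)
}

#' Oversegmentation error specification
#'
#' @param split_rate probability that a true object is cut at a random plane.
#' @param merge_rate probability that an adjacent true object pair shares a
#'   supervoxel.
#' @param seed RNG seed.
#' @return an \code{error_spec} list.
#' @export
error_spec <- function(split_rate = 0, merge_rate = 0, seed = 1L) {
  stopifnot(split_rate >= 0, split_rate <= 1, merge_rate >= 0, merge_rate <= 1)
  structure(list(split_rate = split_rate, merge_rate = merge_rate,
                 seed = as.integer(seed)), class = "error_spec")
}

#' Plant split and merge errors into a ground-truth segmentation
#'
#' Produces a supervoxel volume from a truth labeling: selected objects are
#' cut at a random x plane (splits); selected adjacent object pairs get a
#' shared supervoxel spanning both objects around their contact position
#' (mergers). With zero rates the output equals the truth. The true
#' agglomeration graph (supervoxel pairs belonging to one true object) and
#' the planted errors are returned for bookkeeping.
#'
#' @param truth label \code{vem_volume}.
#' @param err \code{\link{error_spec}}.
#' @param adjacent_pairs data.frame (a, b, x_contact) of adjacent object
#'   pairs eligible for mergers (e.g. from \code{\link{make_phantom}}).
#' @param merge_pairs optional integer vector of row indices into
#'   \code{adjacent_pairs} to merge deterministically (overrides the rate).
#' @param split_labels optional labels to split deterministically.
#' @param merge_halfwidth x half-width of the shared supervoxel window.
#' @return list(supervoxels, true_graph, planted_merges, planted_splits).
#' @export
make_oversegmentation <- function(truth, err = error_spec(),
                                  adjacent_pairs = NULL, merge_pairs = NULL,
                                  split_labels = NULL, merge_halfwidth = 4L) {
  stopifnot(inherits(truth, "vem_volume"), inherits(err, "error_spec"))
  with_seed(err$seed, {
    arr <- truth$data
    labs <- sort(unique(arr[arr > 0]))
    sv <- arr
    next_id <- if (length(labs)) max(labs) else 0L

    if (is.null(split_labels))
      split_labels <- labs[stats::runif(length(labs)) < err$split_rate]
    planted_splits <- data.frame(label = integer(0), part = integer(0),
                                 x_cut = integer(0))
    for (lab in split_labels) {
      w <- which(arr == lab)
      xs <- ((w - 1L) %% dim(arr)[1]) + 1L
      xr <- range(xs)
      if (diff(xr) < 2L) next
      cut <- sample(seq(xr[1] + 1L, xr[2] - 1L), 1L)
      next_id <- next_id + 1L
      sv[w[xs > cut]] <- next_id
      planted_splits <- rbind(planted_splits,
                              data.frame(label = lab, part = next_id,
                                         x_cut = cut))
    }

    planted_merges <- data.frame(a = integer(0), b = integer(0),
                                 shared = integer(0), x0 = integer(0))
    if (!is.null(adjacent_pairs) && nrow(adjacent_pairs) > 0) {
      if (is.null(merge_pairs))
        merge_pairs <- which(stats::runif(nrow(adjacent_pairs)) < err$merge_rate)
      for (p in merge_pairs) {
        a <- adjacent_pairs$a[p]; b <- adjacent_pairs$b[p]
        x0 <- adjacent_pairs$x_contact[p]
        wa <- which(arr == a); wb <- which(arr == b)
        xa <- ((wa - 1L) %% dim(arr)[1]) + 1L
        xb <- ((wb - 1L) %% dim(arr)[1]) + 1L
        sel_a <- wa[abs(xa - x0) <= merge_halfwidth]
        sel_b <- wb[abs(xb - x0) <= merge_halfwidth]
        if (!length(sel_a) || !length(sel_b)) next
        next_id <- next_id + 1L
        sv[sel_a] <- next_id; sv[sel_b] <- next_id
        planted_merges <- rbind(planted_merges,
                                data.frame(a = a, b = b, shared = next_id,
                                           x0 = x0))
      }
    }

    ## true graph: supervoxel pairs sharing a true object
    tg <- NULL
    for (lab in labs) {
      ids <- sort(unique(sv[arr == lab]))
      if (length(ids) > 1L) {
        cmb <- utils::combn(ids, 2L)
        tg <- rbind(tg, t(cmb))
      }
    }
    true_graph <- if (is.null(tg))
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b")))
    else matrix(as.integer(tg), ncol = 2, dimnames = list(NULL, c("a", "b")))

    list(supervoxels = vem_volume(sv, voxel_size = truth$voxel_size,
                                  offset = truth$offset, dtype = "int32"),
         true_graph = true_graph, planted_merges = planted_merges,
         planted_splits = planted_splits)
  })
}

#' Synthetic sharp/defocused image stack
#'
#' Generates an 8-bit grayscale stack whose texture is binary band-pass
#' granular noise at membrane scale (full 0/255 contrast, the regime a
#' contrast-normalized EM plane occupies); regions listed as defocused are
#' the same texture convolved with a Gaussian of the stated sigma. A
#' per-voxel ground-truth focus mask is returned.
#'
#' @param shape stack extent (x, y, z) in voxels.
#' @param blur_sigmas numeric vector of per-region Gaussian sigmas (px);
#'   sigma 0 means in focus.
#' @param region_mask integer array of \code{shape} with values indexing
#'   \code{blur_sigmas}; default: all voxels in region 1.
#' @param seed RNG seed.
#' @return list(stack = uint8 \code{vem_volume}, focus_mask = logical array,
#'   region_mask = integer array).
#' @export
make_focus_stack <- function(shape, blur_sigmas = c(0, 8), region_mask = NULL,
                             seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0), all(blur_sigmas >= 0))
  if (is.null(region_mask)) region_mask <- array(1L, shape)
  stopifnot(identical(dim(region_mask), shape),
            all(region_mask %in% seq_along(blur_sigmas)))
  with_seed(seed, {
    stack <- array(0L, shape)
    for (z in seq_len(shape[3])) {
      n1 <- gauss_blur2d(matrix(stats::rnorm(shape[1] * shape[2]),
                                shape[1], shape[2]), 1)
      tex <- 255 * (n1 - gauss_blur2d(n1, 2) > 0)
      plane <- matrix(0, shape[1], shape[2])
      for (r in seq_along(blur_sigmas)) {
        sel <- region_mask[, , z] == r
        if (!any(sel)) next
        pr <- if (blur_sigmas[r] > 0) gauss_blur2d(tex, blur_sigmas[r]) else tex
        plane[sel] <- pr[sel]
      }
      stack[, , z] <- as.integer(pmin(pmax(round(plane), 0), 255))
    }
    focus_mask <- array(blur_sigmas[region_mask] == 0, shape)
    list(stack = vem_volume(stack, dtype = "uint8"),
         focus_mask = focus_mask, region_mask = region_mask)
  })
}
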