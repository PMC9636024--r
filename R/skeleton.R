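#' Neuron skeleton
#'
#' A skeleton is a set of nodes with nm positions and an undirected edge
#' list forming a forest, plus optional per-node annotations (branch point,
#' synapse in/out, soma seed) and a compartment assignment (axon, dendrite,
#' soma, unassigned). This is both the ground-truth substrate for
#' segmentation evaluation and the carrier of morphometry.
#'
#' @param nodes data.frame with columns id, x, y, z (nm) and optionally
#'   radius and type.
#' @param edges two-column matrix of node ids (undirected).
#' @param annotations optional data.frame (id, tag); multiple tags per node
#'   allowed as extra rows. Recognized tags include "branch", "synapse_in",
#'   "synapse_out", "soma_seed".
#' @param compartment optional character vector per node, one of axon,
#'   dendrite, soma, unassigned.
#' @return object of class \code{vem_skeleton}.
#' @export
skeleton <- function(nodes, edges,
                     annotations = NULL, compartment = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "x", "y", "z") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("node positions must be finite")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0 && !all(edges %in% nodes$id))
    stop("edges reference unknown node ids")
  if (is.null(compartment)) compartment <- rep("unassigned", nrow(nodes))
  stopifnot(length(compartment) == nrow(nodes))
  if (is.null(annotations))
    annotations <- data.frame(id = integer(0), tag = character(0))
  structure(list(nodes = nodes, edges = edges, annotations = annotations,
                 compartment = compartment),
            class = "vem_skeleton")
}

#' @export
print.vem_skeleton <- function(x, ...) {
  cat(sprintf("<vem_skeleton: %d nodes, %d edges, %.1f um path length>\n",
              nrow(x$nodes), nrow(x$edges), path_length(x)))
  invisible(x)
}

node_index <- function(skel, ids) match(ids, skel$nodes$id)

node_degree <- function(skel) {
  deg <- integer(nrow(skel$nodes))
  if (nrow(skel$edges) > 0) {
    t1 <- tabulate(node_index(skel, skel$edges[, 1]), nbins = nrow(skel$nodes))
    t2 <- tabulate(node_index(skel, skel$edges[, 2]), nbins = nrow(skel$nodes))
    deg <- t1 + t2
  }
  deg
}

edge_lengths_nm <- function(skel) {
  if (nrow(skel$edges) == 0) return(numeric(0))
  p <- as.matrix(skel$nodes[, c("x", "y", "z")])
  i <- node_index(skel, skel$edges[, 1]); j <- node_index(skel, skel$edges[, 2])
  sqrt(rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2))
}

#' Skeleton path length
#'
#' Sum of Euclidean edge lengths, optionally restricted to a compartment.
#' An edge counts toward a compartment when both endpoints belong to it.
#'
#' @param skel \code{vem_skeleton}.
#' @param compartment optional compartment name filter.
#' @return path length in micrometers.
#' @export
path_length <- function(skel, compartment = NULL) {
  stopifnot(inherits(skel, "vem_skeleton"))
  len <- edge_lengths_nm(skel)
  if (!is.null(compartment) && nrow(skel$edges) > 0) {
    ci <- skel$compartment[node_index(skel, skel$edges[, 1])]
    cj <- skel$compartment[node_index(skel, skel$edges[, 2])]
    len <- len[ci == compartment & cj == compartment]
  }
  sum(len) / 1000
}

branch_point_ids <- function(skel) {
  ann <- skel$annotations
  if (nrow(ann) > 0 && any(ann$tag == "branch"))
    return(sort(unique(ann$id[ann$tag == "branch"])))
  skel$nodes$id[node_degree(skel) >= 3L]
}

#' Morphometric summary of one skeleton
#'
#' Path length per compartment, branch-point count and density, synapse
#' counts (from "synapse_in"/"synapse_out" annotations) and densities.
#' Branch points are nodes of graph degree >= 3 unless explicit "branch"
#' annotations exist, which win. Densities are per micrometer of the
#' relevant compartment length; a zero-length compartment with a nonzero
#' count is flagged and its density set to NA.
#'
#' @param skel \code{vem_skeleton}.
#' @param cell_id identifier copied into the row.
#' @return one-row data.frame.
#' @export
densities <- function(skel, cell_id = NA) {
  stopifnot(inherits(skel, "vem_skeleton"))
  total_um <- path_length(skel)
  axon_um <- path_length(skel, "axon")
  dend_um <- path_length(skel, "dendrite")
  bp <- branch_point_ids(skel)
  ann <- skel$annotations
  syn_out <- sum(ann$tag == "synapse_out")
  syn_in <- sum(ann$tag == "synapse_in")
  dens <- function(count, len) {
    if (len > 0) count / len else if (count == 0) 0 else NA_real_
  }
  out <- data.frame(cell = cell_id, path_um = total_um, axon_um = axon_um,
                    dendrite_um = dend_um,
                    n_branch = length(bp),
                    branch_per_um = dens(length(bp), total_um),
                    n_syn_out = syn_out,
                    syn_out_per_axon_um = dens(syn_out, axon_um),
                    n_syn_in = syn_in,
                    syn_in_per_dendrite_um = dens(syn_in, dend_um))
  out$flag_zero_length <- is.na(out$branch_per_um) ||
    is.na(out$syn_out_per_axon_um) || is.na(out$syn_in_per_dendrite_um)
  out
}

#' Region-wise branch-point profile
#'
#' Counts branch points falling in each region mask and normalizes by the
#' cell's total branch-point count; branch points in no region go to the
#' "unassigned" bin. Using branch points rather than all nodes avoids
#' counting neurites that merely pass through a region.
#'
#' @param skel \code{vem_skeleton}.
#' @param regions named list of binary \code{vem_volume} region masks on a
#'   common grid with the skeleton's nm frame.
#' @return data.frame(region, count, fraction); fractions are NA (flagged)
#'   when the cell has no branch points.
#' @export
region_branch_profile <- function(skel, regions) {
  stopifnot(inherits(skel, "vem_skeleton"), is.list(regions),
            length(regions) > 0, !is.null(names(regions)))
  bp <- branch_point_ids(skel)
  pos <- as.matrix(skel$nodes[node_index(skel, bp), c("x", "y", "z"),
                              drop = FALSE])
  counts <- integer(length(regions) + 1L)
  names(counts) <- c(names(regions), "unassigned")
  if (length(bp) > 0) {
    for (b in seq_len(nrow(pos))) {
      hit <- FALSE
      for (r in seq_along(regions)) {
        vol <- regions[[r]]
        idx <- nm_to_voxel(vol, pos[b, , drop = FALSE]) + 1L
        d <- dim(vol$data)
        if (all(idx >= 1L) && all(idx <= d) && vol$data[idx] != 0) {
          counts[r] <- counts[r] + 1L
          hit <- TRUE
          break
        }
      }
      if (!hit) counts["unassigned"] <- counts["unassigned"] + 1L
    }
  }
  data.frame(region = names(counts), count = as.integer(counts),
             fraction = if (length(bp) > 0) as.numeric(counts) / length(bp)
                        else NA_real_,
             row.names = NULL)
}

#' Consensus skeleton from redundant tracings
#'
#' Builds one consensus skeleton from 2 or more independent tracings of the
#' same cell: a node is retained iff at least \code{quorum - 1} other
#' tracings have a node within \code{tolerance_nm}; retained nodes are
#' merged by single-linkage spatial clustering at the same tolerance
#' (cluster center = mean position) and edges are induced from the
#' supporting tracings' connectivity.
#'
#' @param tracings list of \code{vem_skeleton}s (typically 3--5).
#' @param tolerance_nm spatial tolerance, nm (default 1000).
#' @param quorum number of tracings that must support a node; default
#'   majority \code{ceiling(n/2)}.
#' @return \code{vem_skeleton}; the number of connected components is
#'   attached as attribute \code{n_components}.
#' @export
consensus_skeleton <- function(tracings, tolerance_nm = 1000, quorum = NULL) {
  stopifnot(is.list(tracings), length(tracings) >= 2)
  n_tr <- length(tracings)
  if (is.null(quorum)) quorum <- ceiling(n_tr / 2)
  pts <- do.call(rbind, lapply(seq_len(n_tr), function(t) {
    s <- tracings[[t]]
    cbind(tracing = t, id = s$nodes$id,
          as.matrix(s$nodes[, c("x", "y", "z")]))
  }))
  n_pts <- nrow(pts)
  xyz <- pts[, c("x", "y", "z"), drop = FALSE]
  ## support: number of distinct tracings (incl. own) with a node in range
  support <- integer(n_pts)
  for (i in seq_len(n_pts)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    near <- d2 <= tolerance_nm^2
    support[i] <- length(unique(pts[near, "tracing"]))
  }
  keep <- support >= quorum
  kept <- which(keep)
  if (length(kept) == 0)
    return(skeleton(data.frame(id = integer(0), x = numeric(0),
                               y = numeric(0), z = numeric(0)),
                    matrix(integer(0), 0, 2)))
  ## single-linkage clustering of kept nodes at tolerance
  uf_n <- length(kept)
  parent <- seq_len(uf_n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  kxyz <- xyz[kept, , drop = FALSE]
  for (i in seq_len(uf_n)) {
    d2 <- rowSums(sweep(kxyz, 2, kxyz[i, ])^2)
    for (j in which(d2 <= tolerance_nm^2)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(uf_n), find, integer(1))
  cl <- match(root, sort(unique(root)))
  centers <- apply(kxyz, 2, function(v) tapply(v, cl, mean))
  centers <- matrix(centers, ncol = 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  ## map (tracing, node id) -> cluster for kept points
  key <- paste(pts[kept, "tracing"], pts[kept, "id"])
  cl_of <- stats::setNames(cl, key)
  edges <- NULL
  for (t in seq_len(n_tr)) {
    e <- tracings[[t]]$edges
    if (nrow(e) == 0) next
    c1 <- cl_of[paste(t, e[, 1])]
    c2 <- cl_of[paste(t, e[, 2])]
    ok <- !is.na(c1) & !is.na(c2) & c1 != c2
    if (any(ok)) edges <- rbind(edges, cbind(pmin(c1[ok], c2[ok]),
                                             pmax(c1[ok], c2[ok])))
  }
  edges <- if (is.null(edges)) matrix(integer(0), 0, 2) else unique(edges)
  out <- skeleton(data.frame(id = seq_len(nrow(centers)),
                             x = centers[, 1], y = centers[, 2],
                             z = centers[, 3]),
                  edges)
  part <- cpp_uf_partition(nrow(centers),
                           as.integer(edges[, 1]), as.integer(edges[, 2]))
  attr(out, "n_components") <- length(unique(part))
  out
}

#' Random skeleton fragments
#'
#' Samples locations uniformly along a compartment's path length and
#' extracts, for each, the sub-skeleton within a physical radius of the
#' location -- the fragment-sampling scheme used for local neurite diameter
#' measurement (defaults: 200 locations, 750 nm radius).
#'
#' @param skel \code{vem_skeleton} with compartments assigned.
#' @param n samples per compartment.
#' @param radius_nm fragment radius, nm.
#' @param compartments compartments to sample (default axon and dendrite).
#' @param seed RNG seed.
#' @return list of fragments, each a list(compartment, center (nm),
#'   skeleton); reproducible for a fixed seed. If a compartment has zero
#'   length, it is skipped with a warning.
#' @export
sample_fragments <- function(skel, n = 200L, radius_nm = 750,
                             compartments = c("axon", "dendrite"),
                             seed = 1L) {
  stopifnot(inherits(skel, "vem_skeleton"))
  if (n == 0L) return(list())
  with_seed(seed, {
    p <- as.matrix(skel$nodes[, c("x", "y", "z")])
    out <- list()
    for (comp in compartments) {
      ci <- skel$compartment[node_index(skel, skel$edges[, 1])]
      cj <- skel$compartment[node_index(skel, skel$edges[, 2])]
      eidx <- which(ci == comp & cj == comp)
      if (length(eidx) == 0) next
      len <- edge_lengths_nm(skel)[eidx]
      if (sum(len) <= 0) { warning("zero-length compartment ", comp); next }
      ecum <- cumsum(len)
      s <- stats::runif(n, 0, ecum[length(ecum)])
      for (k in seq_len(n)) {
        e <- findInterval(s[k], ecum, left.open = TRUE) + 1L
        t0 <- (s[k] - c(0, ecum)[e]) / len[e]
        i <- node_index(skel, skel$edges[eidx[e], 1])
        j <- node_index(skel, skel$edges[eidx[e], 2])
        center <- p[i, ] + t0 * (p[j, ] - p[i, ])
        keep <- sqrt(rowSums(sweep(p, 2, center)^2)) <= radius_nm
        ids <- skel$nodes$id[keep]
        sub_e <- skel$edges[skel$edges[, 1] %in% ids &
                              skel$edges[, 2] %in% ids, , drop = FALSE]
        frag <- skeleton(skel$nodes[keep, , drop = FALSE], sub_e,
                         compartment = skel$compartment[keep])
        out[[length(out) + 1L]] <- list(compartment = comp, center = center,
                                        skeleton = frag)
      }
    }
    out
  })
}

# ---- SWC I/O ---------------------------------------------------------------
# SWC columns: id type x y z radius parent. Structure type carries the
# compartment (1 soma, 2 axon, 3 dendrite, 0 undefined).

swc_type_of <- c(soma = 1L, axon = 2L, dendrite = 3L, unassigned = 0L)

#' Write a skeleton as SWC
#'
#' @param skel \code{vem_skeleton}; positions are written in nm.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_swc <- function(skel, path) {
  stopifnot(inherits(skel, "vem_skeleton"))
  n <- nrow(skel$nodes)
  parent <- rep(-1L, n)
  if (nrow(skel$edges) > 0) {
    ## orient edges away from the first node of each component
    adj <- split(
      c(node_index(skel, skel$edges[, 2]), node_index(skel, skel$edges[, 1])),
      c(node_index(skel, skel$edges[, 1]), node_index(skel, skel$edges[, 2])))
    visited <- logical(n)
    for (root in seq_len(n)) {
      if (visited[root]) next
      queue <- root; visited[root] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (nb in adj[[as.character(cur)]] %||% integer(0)) {
          if (!visited[nb]) {
            visited[nb] <- TRUE
            parent[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  radius <- if ("radius" %in% names(skel$nodes)) skel$nodes$radius else 1
  df <- data.frame(id = seq_len(n),
                   type = swc_type_of[skel$compartment],
                   x = skel$nodes$x, y = skel$nodes$y, z = skel$nodes$z,
                   radius = radius,
                   parent = ifelse(parent > 0, parent, -1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC skeleton, positions in nm", con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an SWC skeleton
#'
#' @param path SWC file; positions are taken as nm.
#' @return \code{vem_skeleton} with compartments mapped from the SWC
#'   structure type.
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  comp <- names(swc_type_of)[match(df$type, swc_type_of)]
  comp[is.na(comp)] <- "unassigned"
  e <- df[df$parent > 0, c("parent", "id")]
  skeleton(df[, c("id", "x", "y", "z", "radius")],
           as.matrix(e), compartment = comp)
}
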