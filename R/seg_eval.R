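#' Skeleton-based edge accuracy of a segmentation
#'
#' Classifies every ground-truth skeleton edge against a candidate
#' segmentation: an edge is \emph{omitted} if either endpoint falls on
#' background, \emph{split} if its endpoints carry different nonzero
#' labels, \emph{merged} if the shared label also contains nodes of a
#' different skeleton, and \emph{correct} otherwise. Accuracy is the
#' correct fraction over pooled edges; per-skeleton means are also
#' reported.
#'
#' @param skeletons list of \code{\link{skeleton}}s with nm positions.
#' @param seg label \code{vem_volume}.
#' @param snap_nodes if TRUE, nodes on background snap to a nonzero
#'   26-neighbor one voxel away (mimics human tracing tolerance);
#'   default off.
#' @param merged_witness "node" (default): a merged label is one holding
#'   nodes of 2+ skeletons; "component": the witness node must additionally
#'   lie in the same spatial connected component of that label's mask.
#' @return list with \code{accuracy}, \code{per_edge} (data.frame skeleton,
#'   class), \code{per_skeleton} (data.frame) and the class \code{counts}.
#' @export
edge_accuracy <- function(skeletons, seg, snap_nodes = FALSE,
                          merged_witness = c("node", "component")) {
  merged_witness <- match.arg(merged_witness)
  stopifnot(inherits(seg, "vem_volume"), is.list(skeletons),
            length(skeletons) > 0)
  d <- dim(seg$data)
  node_lab <- vector("list", length(skeletons))
  node_vox <- vector("list", length(skeletons))
  for (s in seq_along(skeletons)) {
    sk <- skeletons[[s]]
    idx <- nm_to_voxel(seg, as.matrix(sk$nodes[, c("x", "y", "z")])) + 1L
    bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
      idx[, 3] < 1 | idx[, 3] > d[3]
    if (any(bad))
      stop("skeleton ", s, " has nodes outside the volume: node ids ",
           paste(sk$nodes$id[bad], collapse = ", "))
    lab <- seg$data[idx]
    if (snap_nodes && any(lab == 0)) {
      for (i in which(lab == 0)) {
        best <- 0L; bestd <- Inf
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
          p <- idx[i, ] + c(dx, dy, dz)
          if (any(p < 1) || any(p > d)) next
          v <- seg$data[matrix(p, 1)]
          dd <- dx^2 + dy^2 + dz^2
          if (v != 0 && dd < bestd) { best <- v; bestd <- dd }
        }
        lab[i] <- best
      }
    }
    node_lab[[s]] <- lab
    node_vox[[s]] <- idx
  }
  ## labels holding nodes of 2+ skeletons
  lab_owner <- unique(do.call(rbind, lapply(seq_along(skeletons), function(s) {
    labs <- node_lab[[s]][node_lab[[s]] > 0]
    if (length(labs)) data.frame(label = labs, skel = rep(s, length(labs)))
    else NULL
  })))
  if (is.null(lab_owner))
    lab_owner <- data.frame(label = integer(0), skel = integer(0))
  contaminated <- unique(lab_owner$label[
    lab_owner$label %in% lab_owner$label[duplicated(lab_owner$label)]])
  comp_id <- NULL
  if (merged_witness == "component" && length(contaminated)) {
    comp_id <- cpp_label_components_multi(as.integer(seg$data), d, 26L)
  }
  per_edge <- NULL
  for (s in seq_along(skeletons)) {
    sk <- skeletons[[s]]
    if (nrow(sk$edges) == 0) next
    i <- node_index(sk, sk$edges[, 1]); j <- node_index(sk, sk$edges[, 2])
    li <- node_lab[[s]][i]; lj <- node_lab[[s]][j]
    cls <- ifelse(li == 0 | lj == 0, "omitted",
                  ifelse(li != lj, "split", NA))
    same <- which(is.na(cls))
    for (e in same) {
      lab <- li[e]
      merged <- lab %in% contaminated
      if (merged && merged_witness == "component") {
        vi <- node_vox[[s]][i[e], ]
        lin <- vi[1] + d[1] * ((vi[2] - 1) + d[2] * (vi[3] - 1))
        own_comp <- comp_id[lin]
        merged <- FALSE
        for (t in seq_along(skeletons)) {
          if (t == s) next
          w <- which(node_lab[[t]] == lab)
          if (!length(w)) next
          vt <- node_vox[[t]][w, , drop = FALSE]
          lint <- vt[, 1] + d[1] * ((vt[, 2] - 1) + d[2] * (vt[, 3] - 1))
          if (any(comp_id[lint] == own_comp)) { merged <- TRUE; break }
        }
      }
      cls[e] <- if (merged) "merged" else "correct"
    }
    per_edge <- rbind(per_edge, data.frame(skeleton = s, class = cls))
  }
  if (is.null(per_edge))
    per_edge <- data.frame(skeleton = integer(0), class = character(0))
  counts <- table(factor(per_edge$class,
                         levels = c("correct", "split", "merged", "omitted")))
  accuracy <- if (nrow(per_edge) > 0)
    as.numeric(counts["correct"]) / nrow(per_edge) else NA_real_
  per_skel <- if (nrow(per_edge) > 0) {
    agg <- tapply(per_edge$class == "correct", per_edge$skeleton, mean)
    data.frame(skeleton = as.integer(names(agg)), accuracy = as.numeric(agg))
  } else data.frame(skeleton = integer(0), accuracy = numeric(0))
  list(accuracy = accuracy, counts = counts, per_edge = per_edge,
       per_skeleton = per_skel)
}

#' Count separated point pairs
#'
#' For point pairs placed in different but adjacent neurites, counts how
#' many pairs carry two distinct nonzero segment ids in a candidate
#' segmentation -- the merge-screening statistic. Pairs with equal nonzero
#' labels are merged; pairs touching background are uninformative and
#' reported separately.
#'
#' @param seg label \code{vem_volume}.
#' @param pairs data.frame with 0-based voxel coordinates px, py, pz, qx,
#'   qy, qz (e.g. from \code{\link{phantom_point_pairs}}).
#' @return list(n_separated, n_merged, n_uninformative, detail data.frame).
#' @export
pair_separation_count <- function(seg, pairs) {
  stopifnot(inherits(seg, "vem_volume"))
  d <- dim(seg$data)
  pi_ <- as.matrix(pairs[, c("px", "py", "pz")]) + 1L
  qi <- as.matrix(pairs[, c("qx", "qy", "qz")]) + 1L
  if (any(pi_ < 1) || any(qi < 1) || any(t(t(pi_) > d)) || any(t(t(qi) > d)))
    stop("point pair outside volume")
  lp <- seg$data[pi_]; lq <- seg$data[qi]
  status <- ifelse(lp == 0 | lq == 0, "uninformative",
                   ifelse(lp != lq, "separated", "merged"))
  detail <- data.frame(pairs, label_p_seg = lp, label_q_seg = lq,
                       status = status)
  list(n_separated = sum(status == "separated"),
       n_merged = sum(status == "merged"),
       n_uninformative = sum(status == "uninformative"),
       detail = detail)
}

#' Oversegmentation consensus of two segmentations
#'
#' A voxel is foreground iff it is nonzero in both inputs; output segments
#' are connected components of constant (labelA, labelB) pairs, labeled
#' deterministically in first-encounter raster order. The consensus refines
#' both inputs (it never joins voxels that either input separates).
#'
#' @param segA,segB label \code{vem_volume}s on one grid.
#' @param connectivity component connectivity (default 26).
#' @return label \code{vem_volume}.
#' @export
oversegmentation_consensus <- function(segA, segB, connectivity = 26L) {
  stopifnot(inherits(segA, "vem_volume"), inherits(segB, "vem_volume"))
  check_same_grid(segA, segB)
  a <- as.numeric(segA$data); b <- as.numeric(segB$data)
  fg <- a > 0 & b > 0
  key <- numeric(length(a))
  key[fg] <- a[fg] * (max(b) + 1) + b[fg]   # exact below 2^53
  uk <- sort(unique(key[fg]))
  dense <- integer(length(key))
  dense[fg] <- match(key[fg], uk)
  lab <- cpp_label_components_multi(dense, dim(segA$data),
                                    check_connectivity(connectivity))
  out <- vem_volume(array(as.integer(lab), dim(segA$data)),
                    voxel_size = segA$voxel_size, offset = segA$offset,
                    dtype = "int32")
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

array_border_mask <- function(d) {
  m <- array(FALSE, d)
  m[c(1, d[1]), , ] <- TRUE
  m[, c(1, d[2]), ] <- TRUE
  m[, , c(1, d[3])] <- TRUE
  m
}

#' Post-process a segmentation
#'
#' Two cleanups applied iteratively to a fixpoint: (1) background
#' components not reachable from the volume border (6-connectivity) whose
#' surrounding voxels all carry one label are filled with that label;
#' (2) a segment completely contained within another segment -- every
#' outside-adjacent voxel belongs to that one other segment and the segment
#' touches neither border nor background -- is absorbed into it. The
#' operation is idempotent.
#'
#' @param seg label \code{vem_volume}.
#' @return label \code{vem_volume}.
#' @export
postprocess_segments <- function(seg) {
  stopifnot(inherits(seg, "vem_volume"))
  arr <- seg$data
  d <- dim(arr)
  border <- array_border_mask(d)
  repeat {
    changed <- FALSE
    ## (1) fill interior background
    bg <- array(as.integer(arr == 0), d)
    if (any(bg == 1)) {
      bglab <- array(cpp_label_components(as.integer(bg), d, 6L), d)
      border_comps <- unique(bglab[border & bg == 1])
      interior <- setdiff(unique(bglab[bglab > 0]), border_comps)
      if (length(interior)) {
        tmp <- arr
        tmp[bglab > 0] <- -as.integer(bglab[bglab > 0])
        adj <- cpp_label_adjacency(as.integer(tmp), d)
        for (comp in interior) {
          nb <- adj[adj[, 1] == -comp, 2]
          nb <- nb[nb > 0]
          if (length(unique(nb)) == 1L) {
            arr[bglab == comp] <- nb[1]
            changed <- TRUE
          }
        }
      }
    }
    ## (2) absorb completely contained segments
    adj <- cpp_label_adjacency(as.integer(arr), d)
    border_labels <- unique(arr[border])
    labs <- sort(unique(arr[arr > 0]))
    for (b in labs) {
      if (b %in% border_labels) next
      nb <- adj[adj[, 1] == b, 2]
      if (length(nb) == 1L && nb != 0) {
        arr[arr == b] <- nb
        adj[adj == b] <- nb          # keep adjacency usable this sweep
        adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vem_volume(arr, voxel_size = seg$voxel_size, offset = seg$offset,
             dtype = "int32")
}

#' Select the checkpoint pair forming the base segmentation
#'
#' Given candidate segmentations with edge accuracies and a merge-screening
#' point-pair set: keep the top-k candidates by accuracy (ties by input
#' order), compute the oversegmentation consensus of every unordered pair
#' among them, and return the pair whose consensus separates the most point
#' pairs (ties by lexicographic candidate indices), with its consensus.
#'
#' @param segs list of label \code{vem_volume}s.
#' @param accuracies numeric vector, one per candidate.
#' @param pairs point-pair data.frame (see
#'   \code{\link{pair_separation_count}}).
#' @param k number of top candidates screened (default 7).
#' @return list(pair = integer(2) original indices, consensus, n_separated,
#'   screened = data.frame over all screened pairs).
#' @export
select_checkpoint_pair <- function(segs, accuracies, pairs, k = 7L) {
  stopifnot(is.list(segs), length(segs) == length(accuracies))
  if (length(segs) < 2) stop("need at least 2 candidate segmentations")
  ord <- order(-accuracies)            # stable: ties keep input order
  top <- sort(ord[seq_len(min(k, length(segs)))])
  best <- NULL; best_n <- -1L
  screened <- NULL
  for (ii in seq_along(top)) for (jj in seq_along(top)) {
    if (jj <= ii) next
    i <- top[ii]; j <- top[jj]
    cons <- oversegmentation_consensus(segs[[i]], segs[[j]])
    n <- pair_separation_count(cons, pairs)$n_separated
    screened <- rbind(screened, data.frame(i = i, j = j, n_separated = n))
    if (n > best_n) { best_n <- n; best <- list(pair = c(i, j), consensus = cons) }
  }
  list(pair = best$pair, consensus = best$consensus, n_separated = best_n,
       screened = screened)
}
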