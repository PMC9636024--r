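# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain-R union-find, all-pairs scans, exhaustive
# enumeration) so that implementation and check stay decoupled.

# plain union-find over 1..n; returns min-id representative per node
uf_oracle <- function(n, ea, eb) {
  ea <- as.integer(ea); eb <- as.integer(eb)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (i in seq_along(ea)) {
    ra <- find(ea[i]); rb <- find(eb[i])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

# neighbor voxel pairs of a 3D mask under 6- or 26-connectivity, as linear
# indices; enumerated by explicit offset shifting, not via package code
mask_neighbor_pairs <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    m <- abs(dx) + abs(dy) + abs(dz)
    if (connectivity == 6 && m > 1) next
    # record each unordered pair once
    if (dx < 0 || (dx == 0 && dy < 0) || (dx == 0 && dy == 0 && dz < 0)) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  w <- which(mask != 0, arr.ind = TRUE)
  pairs <- NULL
  for (o in offs) {
    nb <- sweep(w, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb <- nb[ok, , drop = FALSE]
    src <- w[ok, , drop = FALSE]
    nb_lin <- nb[, 1] + d[1] * ((nb[, 2] - 1) + d[2] * (nb[, 3] - 1))
    src_lin <- src[, 1] + d[1] * ((src[, 2] - 1) + d[2] * (src[, 3] - 1))
    keep <- mask[nb_lin] != 0
    pairs <- rbind(pairs, cbind(src_lin[keep], nb_lin[keep]))
  }
  pairs
}

# partition of mask voxels by union-find over neighbor pairs
mask_partition_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  n <- prod(d)
  pairs <- mask_neighbor_pairs(mask, connectivity)
  rep_ <- uf_oracle(n, pairs[, 1], pairs[, 2])
  rep_[as.vector(mask) == 0] <- 0L
  rep_
}

# two labelings partition the foreground identically?
same_partition <- function(a, b) {
  fa <- a != 0; fb <- b != 0
  if (!identical(fa, fb)) return(FALSE)
  if (!any(fa)) return(TRUE)
  ka <- a[fa]; kb <- b[fa]
  tab <- table(ka, kb)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# random connected-ish binary mask
random_mask <- function(d, density = 0.4) {
  array(as.integer(stats::runif(prod(d)) < density), d)
}

# random label volume with spatially coherent blobs
random_labels <- function(d, n_seeds = 8) {
  arr <- array(0L, d)
  cen <- cbind(sample(d[1], n_seeds, TRUE), sample(d[2], n_seeds, TRUE),
               sample(d[3], n_seeds, TRUE))
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  r <- stats::runif(n_seeds, 2, max(d) / 2)
  for (s in seq_len(n_seeds)) {
    inside <- rowSums(sweep(co, 2, cen[s, ])^2) <= r[s]^2
    arr[co[inside, , drop = FALSE]] <- s
  }
  arr
}

# exhaustive maximum bipartite matching size on an overlap incidence matrix
max_matching_oracle <- function(inc) {
  np <- nrow(inc)
  best <- 0L
  rec <- function(i, used_t, count) {
    if (count + (np - i + 1L) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    rec(i + 1L, used_t, count)            # skip pred i
    for (t in which(inc[i, ] & !used_t)) {
      used_t[t] <- TRUE
      rec(i + 1L, used_t, count + 1L)
      used_t[t] <- FALSE
    }
  }
  rec(1L, rep(FALSE, ncol(inc)), 0L)
  best
}

# exhaustive elementary-cycle enumeration by permutation scan (small n)
cycles_oracle <- function(edges, nodes) {
  has_edge <- function(a, b) any(edges$pre == a & edges$post == b)
  found <- list()
  for (k in seq_along(nodes)) {
    for (sub in utils::combn(nodes, k, simplify = FALSE)) {
      perms <- if (k == 1) list(sub) else {
        # permutations fixing the first (smallest) element
        rest <- sub[-1]
        pr <- if (length(rest) <= 1) list(rest) else {
          out <- list()
          gen <- function(prefix, left) {
            if (!length(left)) { out[[length(out) + 1]] <<- prefix; return() }
            for (i in seq_along(left)) gen(c(prefix, left[i]), left[-i])
          }
          gen(integer(0), rest)
          out
        }
        lapply(pr, function(p) c(sub[1], p))
      }
      for (p in perms) {
        ok <- TRUE
        for (i in seq_along(p)) {
          if (!has_edge(p[i], p[(i %% length(p)) + 1])) { ok <- FALSE; break }
        }
        if (ok) found[[length(found) + 1]] <- p
      }
    }
  }
  found
}

canon_cycles <- function(cys) {
  if (!length(cys)) return(character(0))
  sort(vapply(cys, function(cy) paste(cy, collapse = "-"), character(1)))
}

# straight-tube phantom tailored for pair-separation tests
tube_bundle_spec <- function(n_neurites, n_synapses = 0, shape, seed = 1) {
  phantom_spec(shape = shape, n_neurites = n_neurites,
               n_synapses = n_synapses, n_somata = 0,
               neurite_radius_nm = c(50, 90), seed = seed)
}

# digitized ball mask centered in an array
ball_mask <- function(d, center, r) {
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  arr <- array(0L, d)
  arr[co[rowSums(sweep(co, 2, center)^2) <= r^2, , drop = FALSE]] <- 1L
  arr
}
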