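#' Assign synaptic partners to detected clefts
#'
#' For every cleft component: the cells of the agglomerated segmentation
#' with voxels within \code{dilation_nm} of the cleft are ranked by contact
#' voxel count; the top two (ties by smaller cell id) are the candidate
#' partners. The presynaptic cell is the candidate with the larger
#' vesicle-cloud overlap inside the same dilated neighborhood -- the
#' automatic counterpart of the "vesicle cloud seen in the axon" criterion.
#' If vesicle evidence is absent or tied, both partners are recorded but
#' the direction is left unset and flagged; clefts touching fewer than two
#' cells are flagged unpaired.
#'
#' @param cleft_labels label \code{vem_volume} of cleft components.
#' @param vesicle_labels label (or binary) \code{vem_volume} of vesicle
#'   clouds.
#' @param seg agglomerated cell label \code{vem_volume}.
#' @param dilation_nm physical search radius around the cleft (default 100,
#'   about cleft plus membrane thickness).
#' @return data.frame, one row per cleft: cleft, pre, post, cell_a, cell_b,
#'   contact_a, contact_b, vesicle_a, vesicle_b, directed, unpaired.
#' @export
assign_partners <- function(cleft_labels, vesicle_labels, seg,
                            dilation_nm = 100) {
  stopifnot(inherits(cleft_labels, "vem_volume"),
            inherits(vesicle_labels, "vem_volume"),
            inherits(seg, "vem_volume"))
  check_same_grid(cleft_labels, seg)
  check_same_grid(cleft_labels, vesicle_labels)
  d <- dim(seg$data)
  vs <- seg$voxel_size
  marg <- pmax(1L, as.integer(ceiling(dilation_nm / vs)))
  ids <- sort(unique(cleft_labels$data[cleft_labels$data > 0]))
  rows <- lapply(ids, function(k) {
    w <- which(cleft_labels$data == k, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - marg, 1L)
    hi <- pmin(apply(w, 2, max) + marg, d)
    sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    cl <- array(as.integer(sub(cleft_labels$data) == k),
                hi - lo + 1L)
    dil <- cpp_morph_ball(as.integer(cl), dim(cl), dilation_nm, vs,
                          dilate = TRUE)
    near <- array(dil == 1L, dim(cl))
    sl <- sub(seg$data); vl <- sub(vesicle_labels$data)
    contact <- table(sl[near & sl > 0])
    if (length(contact) < 2) {
      top <- if (length(contact) == 1) as.integer(names(contact)) else NA
      return(data.frame(cleft = k, pre = NA_integer_, post = NA_integer_,
                        cell_a = top[1], cell_b = NA_integer_,
                        contact_a = if (length(contact)) as.integer(contact[1])
                                    else NA_integer_,
                        contact_b = NA_integer_, vesicle_a = NA_integer_,
                        vesicle_b = NA_integer_, directed = FALSE,
                        unpaired = TRUE))
    }
    cdf <- data.frame(cell = as.integer(names(contact)),
                      n = as.integer(contact))
    cdf <- cdf[order(-cdf$n, cdf$cell), ]
    a <- cdf$cell[1]; b <- cdf$cell[2]
    ves_a <- sum(near & sl == a & vl > 0)
    ves_b <- sum(near & sl == b & vl > 0)
    if (ves_a == ves_b) {
      pre <- NA_integer_; post <- NA_integer_; directed <- FALSE
    } else if (ves_a > ves_b) {
      pre <- a; post <- b; directed <- TRUE
    } else {
      pre <- b; post <- a; directed <- TRUE
    }
    data.frame(cleft = k, pre = pre, post = post, cell_a = a, cell_b = b,
               contact_a = cdf$n[1], contact_b = cdf$n[2],
               vesicle_a = ves_a, vesicle_b = ves_b, directed = directed,
               unpaired = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(cleft = integer(0), pre = integer(0), post = integer(0),
                  cell_a = integer(0), cell_b = integer(0),
                  contact_a = integer(0), contact_b = integer(0),
                  vesicle_a = integer(0), vesicle_b = integer(0),
                  directed = logical(0), unpaired = logical(0))
}

#' Build the connectome edge list and address book
#'
#' Groups directed synapse assignments by (pre, post) cell pair into
#' connectome edges with synapse counts; assignments without direction and
#' unpaired clefts are listed separately, so total synapse count is
#' conserved.
#'
#' @param assignments data.frame from \code{\link{assign_partners}}.
#' @return list(edges = data.frame(pre, post, count, clefts),
#'   undirected, unpaired, address_book = data.frame(cell, n_out, n_in)).
#' @export
build_edges <- function(assignments) {
  a <- assignments
  directed <- a[a$directed %in% TRUE, , drop = FALSE]
  undirected <- a[!a$directed & !a$unpaired, , drop = FALSE]
  unpaired <- a[a$unpaired %in% TRUE, , drop = FALSE]
  edges <- if (nrow(directed)) {
    sp <- split(directed, list(directed$pre, directed$post), drop = TRUE)
    do.call(rbind, lapply(sp, function(g)
      data.frame(pre = g$pre[1], post = g$post[1], count = nrow(g),
                 clefts = paste(sort(g$cleft), collapse = ";"))))
  } else data.frame(pre = integer(0), post = integer(0), count = integer(0),
                    clefts = character(0))
  edges <- edges[order(edges$pre, edges$post), , drop = FALSE]
  rownames(edges) <- NULL
  cells <- sort(unique(c(directed$pre, directed$post,
                         undirected$cell_a, undirected$cell_b)))
  address_book <- data.frame(
    cell = cells,
    n_out = vapply(cells, function(cl) sum(directed$pre == cl), integer(1)),
    n_in = vapply(cells, function(cl) sum(directed$post == cl), integer(1)))
  list(edges = edges, undirected = undirected, unpaired = unpaired,
       address_book = address_book)
}

#' Recurrency check of a wiring diagram
#'
#' Detects directed cycles among a cell subset of the connectome and lists
#' every elementary cycle (canonical form: smallest cell first) plus all
#' bidirectionally connected pairs.
#'
#' @param edges data.frame(pre, post) or the edges element of
#'   \code{\link{build_edges}}.
#' @param cells optional cell subset to restrict to.
#' @return list(has_cycle, cycles = list of cell vectors,
#'   bidirectional = data.frame(a, b)).
#' @export
recurrency_check <- function(edges, cells = NULL) {
  e <- unique(data.frame(pre = edges$pre, post = edges$post))
  if (!is.null(cells)) e <- e[e$pre %in% cells & e$post %in% cells, ]
  nodes <- sort(unique(c(e$pre, e$post)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    sort(e$post[e$pre == v]))
  cycles <- list()
  ## enumerate elementary cycles: DFS from each start, visiting only
  ## nodes >= start, so each cycle is found once with its smallest node first
  for (s in nodes) {
    stack_path <- s
    dfs <- function(v) {
      for (w in adj[[as.character(v)]]) {
        if (w == s && length(stack_path) >= 1) {
          cycles[[length(cycles) + 1L]] <<- stack_path
        } else if (w > s && !(w %in% stack_path)) {
          stack_path <<- c(stack_path, w)
          dfs(w)
          stack_path <<- stack_path[-length(stack_path)]
        }
      }
    }
    dfs(s)
  }
  bi <- e[paste(e$post, e$pre) %in% paste(e$pre, e$post) & e$pre < e$post, ]
  bidirectional <- data.frame(a = bi$pre, b = bi$post)
  list(has_cycle = length(cycles) > 0, cycles = cycles,
       bidirectional = bidirectional)
}

#' Shared partner fraction of two cells
#'
#' Fraction of X's synaptic partners (in the given direction) that are also
#' partners of Y; the symmetric (Jaccard) variant is reported alongside.
#'
#' @param edges edge data.frame(pre, post).
#' @param cellX,cellY cell ids.
#' @param direction "out" (partners = postsynaptic targets) or "in"
#'   (partners = presynaptic sources).
#' @return list(fraction, jaccard, partners_x, partners_y, undefined).
#' @export
shared_partner_fraction <- function(edges, cellX, cellY,
                                    direction = c("out", "in")) {
  direction <- match.arg(direction)
  partners <- function(cl) {
    if (direction == "out") unique(edges$post[edges$pre == cl])
    else unique(edges$pre[edges$post == cl])
  }
  px <- partners(cellX); py <- partners(cellY)
  if (length(px) == 0) {
    warning("cell ", cellX, " has no ", direction, " partners")
    return(list(fraction = NA_real_, jaccard = NA_real_, partners_x = px,
                partners_y = py, undefined = TRUE))
  }
  list(fraction = length(intersect(px, py)) / length(px),
       jaccard = length(intersect(px, py)) / length(union(px, py)),
       partners_x = px, partners_y = py, undefined = FALSE)
}
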