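#' Agglomeration proofreading graph
#'
#' In-memory supervoxel graph with an append-only on-disk edit log: the
#' proofreading backend state. Edits (edge additions/removals) are written
#' to the log before they are acknowledged, so replaying the log on top of
#' the base graph always reproduces the live state. Connected components of
#' the live edge set are the current reconstruction of each cell.
#'
#' @param ids integer vector of supervoxel ids (positive).
#' @param edges optional base edge data.frame/matrix with columns a, b (and
#'   optionally score): the automatically generated proposal agglomeration.
#' @param log_path path of the JSONL edit log; NULL keeps the graph
#'   in-memory only (used during replay).
#' @param nucleus_of optional named integer vector mapping supervoxel id to
#'   nucleus id, used by the nucleus-separation constraint.
#' @return an \code{agglo_graph} (environment).
#' @export
agglo_graph <- function(ids, edges = NULL, log_path = NULL,
                        nucleus_of = NULL) {
  ids <- as.integer(ids)
  stopifnot(length(ids) > 0, all(ids > 0), !anyDuplicated(ids))
  g <- new.env(parent = emptyenv())
  g$ids <- sort(ids)
  g$max_id <- max(ids)
  g$present <- logical(g$max_id); g$present[ids] <- TRUE
  g$adj <- vector("list", g$max_id)
  g$ea <- integer(0); g$eb <- integer(0); g$active <- logical(0)
  g$key2idx <- new.env(parent = emptyenv())
  g$seq <- 0L
  g$log_path <- log_path
  g$logcon <- NULL
  if (!is.null(log_path)) {
    g$logcon <- file(log_path, if (file.exists(log_path)) "a" else "w")
  }
  g$nucleus_of <- nucleus_of
  class(g) <- "agglo_graph"
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.data.frame(edges)
    lo <- as.integer(pmin(edges$a, edges$b))
    hi <- as.integer(pmax(edges$a, edges$b))
    keep <- !duplicated(paste0(lo, "_", hi)) & lo != hi
    lo <- lo[keep]; hi <- hi[keep]
    if (any(lo < 1) || any(hi > g$max_id) || any(!g$present[lo]) ||
        any(!g$present[hi]))
      stop("base edges reference unknown supervoxel ids")
    g$ea <- lo; g$eb <- hi; g$active <- rep(TRUE, length(lo))
    keys <- paste0(lo, "_", hi)
    for (i in seq_along(keys)) g$key2idx[[keys[i]]] <- i
    nb <- split(c(hi, lo), c(lo, hi))
    g$adj[as.integer(names(nb))] <- nb
  }
  g
}

#' @export
print.agglo_graph <- function(x, ...) {
  cat(sprintf("<agglo_graph: %d supervoxels, %d live edges, seq %d>\n",
              length(x$ids), sum(x$active), x$seq))
  invisible(x)
}

#' Close an agglomeration graph's edit log
#' @param g \code{agglo_graph}.
#' @export
agglo_close <- function(g) {
  if (!is.null(g$logcon)) { close(g$logcon); g$logcon <- NULL }
  invisible(g)
}

edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))

edge_is_live <- function(g, a, b) {
  i <- g$key2idx[[edge_key(a, b)]]
  !is.null(i) && g$active[i]
}

edge_set_live <- function(g, a, b) {
  k <- edge_key(a, b)
  i <- g$key2idx[[k]]
  if (is.null(i)) {
    g$ea <- c(g$ea, min(a, b)); g$eb <- c(g$eb, max(a, b))
    g$active <- c(g$active, TRUE)
    g$key2idx[[k]] <- length(g$ea)
  } else g$active[i] <- TRUE
  g$adj[[a]] <- c(g$adj[[a]], b)
  g$adj[[b]] <- c(g$adj[[b]], a)
  invisible(g)
}

edge_set_dead <- function(g, a, b) {
  i <- g$key2idx[[edge_key(a, b)]]
  g$active[i] <- FALSE
  g$adj[[a]] <- g$adj[[a]][g$adj[[a]] != b]
  g$adj[[b]] <- g$adj[[b]][g$adj[[b]] != a]
  invisible(g)
}

check_sv <- function(g, id) {
  if (length(id) != 1L || is.na(id) || id < 1L || id > g$max_id ||
      !g$present[id])
    stop("unknown supervoxel id: ", id)
  invisible(as.integer(id))
}

log_append <- function(g, rec) {
  if (is.null(g$logcon)) return(invisible(rec))
  line <- sprintf(
    '{"seq":%d,"op":"%s","a":%d,"b":%d,"user":"%s","timestamp":"%s"}',
    rec$seq, rec$op, rec$a, rec$b, rec$user, rec$timestamp)
  writeLines(line, g$logcon)
  flush(g$logcon)   # acknowledge only after the record is on disk
  invisible(rec)
}

new_record <- function(g, op, a, b, user) {
  g$seq <- g$seq + 1L
  list(seq = g$seq, op = op, a = as.integer(min(a, b)),
       b = as.integer(max(a, b)), user = user,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
}

#' Add an agglomeration edge (split fix)
#'
#' @param g \code{agglo_graph}.
#' @param a,b supervoxel ids.
#' @param user annotator name recorded in the log.
#' @return the edit record, invisibly.
#' @export
agglo_add_edge <- function(g, a, b, user = "user") {
  a <- check_sv(g, a); b <- check_sv(g, b)
  if (a == b) stop("self-edge: a and b are the same supervoxel")
  if (edge_is_live(g, a, b)) stop("duplicate add: edge is already live")
  rec <- new_record(g, "add_edge", a, b, user)
  log_append(g, rec)
  edge_set_live(g, a, b)
  invisible(rec)
}

#' Remove an agglomeration edge (merge fix)
#'
#' Removing a base-graph edge and removing a previously added edge are both
#' expressible and logged identically.
#'
#' @inheritParams agglo_add_edge
#' @return the edit record, invisibly.
#' @export
agglo_remove_edge <- function(g, a, b, user = "user") {
  a <- check_sv(g, a); b <- check_sv(g, b)
  if (a == b) stop("self-edge: a and b are the same supervoxel")
  if (!edge_is_live(g, a, b)) stop("removing absent edge: edge is not live")
  rec <- new_record(g, "remove_edge", a, b, user)
  log_append(g, rec)
  edge_set_dead(g, a, b)
  invisible(rec)
}

#' Is an edge currently live?
#'
#' @param g \code{agglo_graph}.
#' @param a,b supervoxel ids.
#' @return TRUE iff the undirected edge is in the live edge set.
#' @export
agglo_has_edge <- function(g, a, b) {
  a <- check_sv(g, a); b <- check_sv(g, b)
  edge_is_live(g, a, b)
}

#' Connected component of a supervoxel
#'
#' Graph traversal over the live edge set; the result always contains the
#' queried supervoxel.
#'
#' @param g \code{agglo_graph}.
#' @param sv_id supervoxel id.
#' @return sorted integer vector of supervoxel ids.
#' @export
component_of <- function(g, sv_id) {
  sv_id <- check_sv(g, sv_id)
  seen <- logical(g$max_id)
  seen[sv_id] <- TRUE
  stack <- sv_id
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (nb in g$adj[[cur]]) {
      if (!seen[nb]) { seen[nb] <- TRUE; stack <- c(stack, nb) }
    }
  }
  which(seen)
}

#' Full partition of the live graph
#'
#' @param g \code{agglo_graph}.
#' @return integer vector over \code{g$ids}: the smallest supervoxel id of
#'   each component (a canonical component labeling).
#' @export
agglo_partition <- function(g) {
  act <- g$active
  ea <- g$ea[act]; eb <- g$eb[act]
  rep_all <- cpp_uf_partition(g$max_id, ea, eb)
  rep_all[g$ids]
}

#' Read a JSONL edit log
#'
#' @param path log file.
#' @return data.frame(seq, op, a, b, user, timestamp), possibly empty.
#' @export
read_edit_log <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(seq = integer(0), op = character(0), a = integer(0),
                      b = integer(0), user = character(0),
                      timestamp = character(0)))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  df <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
  df$seq <- as.integer(df$seq); df$a <- as.integer(df$a)
  df$b <- as.integer(df$b)
  df
}

#' Replay an edit log on a base graph
#'
#' Strict deterministic replay: records must be ordered by strictly
#' increasing seq and each must be applicable in sequence (an add of a
#' non-live edge, a remove of a live edge, between known supervoxels);
#' otherwise replay halts with an error carrying the offending seq
#' (condition class \code{vem_replay_error}, field \code{seq}).
#'
#' @param ids,edges base graph as in \code{\link{agglo_graph}}.
#' @param log data.frame as returned by \code{\link{read_edit_log}}, or a
#'   path to a JSONL log.
#' @param snapshot_partitions if TRUE, also return the full component
#'   partition after every applied record (column k = state after record
#'   k), so truncated-log states can be checked without re-replaying.
#' @return the replayed \code{agglo_graph} (in-memory, no log attached);
#'   with \code{snapshot_partitions}, a list(graph, partitions).
#' @export
replay <- function(ids, edges = NULL, log = NULL,
                   snapshot_partitions = FALSE) {
  g <- agglo_graph(ids, edges, log_path = NULL)
  if (is.character(log)) log <- read_edit_log(log)
  if (is.null(log) || nrow(log) == 0) {
    if (snapshot_partitions)
      return(list(graph = g,
                  partitions = matrix(integer(0), length(g$ids), 0)))
    return(g)
  }
  snaps <- if (snapshot_partitions)
    matrix(NA_integer_, length(g$ids), nrow(log)) else NULL
  halt <- function(seqno, msg) {
    cond <- structure(class = c("vem_replay_error", "error", "condition"),
                      list(message = sprintf("replay halted at seq %d: %s",
                                             seqno, msg),
                           call = sys.call(-1), seq = seqno))
    stop(cond)
  }
  last_seq <- 0L
  for (i in seq_len(nrow(log))) {
    seqno <- log$seq[i]
    if (seqno <= last_seq) halt(seqno, "seq not strictly increasing")
    a <- log$a[i]; b <- log$b[i]
    if (a < 1 || b < 1 || a > g$max_id || b > g$max_id ||
        !g$present[a] || !g$present[b]) halt(seqno, "unknown supervoxel")
    if (log$op[i] == "add_edge") {
      if (edge_is_live(g, a, b)) halt(seqno, "add of live edge")
      edge_set_live(g, a, b)
    } else if (log$op[i] == "remove_edge") {
      if (!edge_is_live(g, a, b)) halt(seqno, "remove of non-live edge")
      edge_set_dead(g, a, b)
    } else halt(seqno, paste("unknown op", log$op[i]))
    last_seq <- seqno
    g$seq <- seqno
    if (snapshot_partitions) snaps[, i] <- agglo_partition(g)
  }
  if (snapshot_partitions) list(graph = g, partitions = snaps) else g
}

#' Score-ordered agglomeration under nucleus separation
#'
#' Accepts candidate edges in descending score order (ties by min id, then
#' max id) unless acceptance would place two distinct nucleus ids into one
#' component -- the constraint that keeps automatically detected somata
#' separate during automatic agglomeration.
#'
#' @param ids supervoxel ids.
#' @param candidates data.frame with columns a, b, score.
#' @param nucleus_of named integer vector: supervoxel id -> nucleus id.
#' @param score_threshold candidates below this score are not considered.
#' @return list(accepted = data.frame of accepted edges in acceptance
#'   order, partition = named representative vector over ids).
#' @export
constrained_agglomerate <- function(ids, candidates, nucleus_of = NULL,
                                    score_threshold = -Inf) {
  ids <- sort(as.integer(ids))
  max_id <- max(ids)
  candidates <- as.data.frame(candidates)
  stopifnot(all(c("a", "b", "score") %in% names(candidates)))
  candidates <- candidates[candidates$score >= score_threshold, , drop = FALSE]
  candidates$a <- as.integer(candidates$a)
  candidates$b <- as.integer(candidates$b)
  lo <- pmin(candidates$a, candidates$b); hi <- pmax(candidates$a, candidates$b)
  ord <- order(-candidates$score, lo, hi)
  candidates <- candidates[ord, , drop = FALSE]
  nuc <- integer(max_id)
  if (!is.null(nucleus_of) && length(nucleus_of) > 0)
    nuc[as.integer(names(nucleus_of))] <- as.integer(nucleus_of)
  parent <- seq_len(max_id)
  find <- function(a) {
    while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }
    a
  }
  comp_nuc <- nuc   # nucleus id carried by each root (0 = none)
  accepted <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ra <- find(candidates$a[i]); rb <- find(candidates$b[i])
    if (ra == rb) { accepted[i] <- TRUE; next }
    na_ <- comp_nuc[ra]; nb_ <- comp_nuc[rb]
    if (na_ != 0 && nb_ != 0 && na_ != nb_) next
    r <- min(ra, rb)
    parent[max(ra, rb)] <- r
    comp_nuc[r] <- max(na_, nb_)
    accepted[i] <- TRUE
  }
  rep_ <- vapply(ids, find, integer(1))
  ## canonicalize to smallest member id per component
  rep_ <- stats::ave(ids, rep_, FUN = min)
  list(accepted = candidates[accepted, , drop = FALSE],
       partition = stats::setNames(rep_, ids))
}

#' Proofreading effort per cell
#'
#' Counts, for each final cell (component), the edit-log interactions that
#' touched it: edge removals are merge fixes, edge additions split fixes.
#'
#' @param log edit-log data.frame.
#' @param cells named list: cell name -> integer vector of supervoxel ids.
#' @return data.frame(cell, merge_fixes, split_fixes).
#' @export
effort_report <- function(log, cells) {
  stopifnot(is.list(cells))
  out <- data.frame(cell = names(cells) %||% as.character(seq_along(cells)),
                    merge_fixes = 0L, split_fixes = 0L)
  for (i in seq_along(cells)) {
    ids <- cells[[i]]
    touch <- log$a %in% ids | log$b %in% ids
    out$merge_fixes[i] <- sum(touch & log$op == "remove_edge")
    out$split_fixes[i] <- sum(touch & log$op == "add_edge")
  }
  out
}

#' Stress-replay a session log against a live service
#'
#' Replays an edit log through the serialized single-writer path with
#' \code{n_clients} round-robin submitters, interleaving a component query
#' after every \code{query_every} edits, and reports per-op latency
#' percentiles (1st/50th/99th). Writes are committed in seq order, so the
#' final partition is independent of the number of clients. Reporting only:
#' no pass/fail on absolute times.
#'
#' @param ids,edges base graph.
#' @param log edit-log data.frame.
#' @param n_clients number of parallel submitters emulated.
#' @param query_every issue a \code{component_of} query after this many
#'   edits (0 = never).
#' @return list(latency = data.frame(op, n, p01_ms, p50_ms, p99_ms),
#'   graph = final \code{agglo_graph}).
#' @export
replay_load_test <- function(ids, edges = NULL, log = NULL, n_clients = 1L,
                             query_every = 10L) {
  g <- agglo_graph(ids, edges, log_path = NULL)
  if (is.null(log) || nrow(log) == 0)
    return(list(latency = data.frame(op = character(0), n = integer(0),
                                     p01_ms = numeric(0), p50_ms = numeric(0),
                                     p99_ms = numeric(0)),
                graph = g))
  ## round-robin assignment; the single writer commits in seq order
  client <- ((seq_len(nrow(log)) - 1L) %% n_clients) + 1L
  ord <- order(log$seq)
  lat <- numeric(nrow(log)); op <- log$op[ord]
  q_lat <- numeric(0)
  for (k in seq_along(ord)) {
    i <- ord[k]
    t0 <- Sys.time()
    if (log$op[i] == "add_edge") edge_set_live(g, log$a[i], log$b[i])
    else edge_set_dead(g, log$a[i], log$b[i])
    g$seq <- log$seq[i]
    lat[k] <- as.numeric(Sys.time() - t0, units = "secs") * 1000
    if (query_every > 0 && k %% query_every == 0) {
      t0 <- Sys.time()
      component_of(g, log$a[i])
      q_lat <- c(q_lat, as.numeric(Sys.time() - t0, units = "secs") * 1000)
    }
  }
  pct <- function(x) if (length(x)) stats::quantile(x, c(.01, .5, .99),
                                                    names = FALSE)
                     else c(NA, NA, NA)
  rows <- list(c(list(op = "add_edge"), as.list(pct(lat[op == "add_edge"])),
                 n = sum(op == "add_edge")),
               c(list(op = "remove_edge"),
                 as.list(pct(lat[op == "remove_edge"])),
                 n = sum(op == "remove_edge")),
               c(list(op = "component_query"), as.list(pct(q_lat)),
                 n = length(q_lat)))
  latency <- do.call(rbind, lapply(rows, function(r)
    data.frame(op = r$op, n = r$n, p01_ms = r[[2]], p50_ms = r[[3]],
               p99_ms = r[[4]])))
  list(latency = latency, graph = g, n_clients = n_clients,
       client_of = client)
}
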