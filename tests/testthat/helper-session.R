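# Proofreading session driver: random base graph, random valid edit
# sequence through the service API, with the full partition recorded after
# every edit (the live reference the replay must reproduce).
random_session <- function(n_sv, n_base, n_edits, seed,
                           log_path = tempfile(fileext = ".jsonl")) {
  set.seed(seed)
  a <- sample(n_sv, n_base, TRUE); b <- sample(n_sv, n_base, TRUE)
  keep <- a != b
  base <- unique(data.frame(a = pmin(a, b)[keep], b = pmax(a, b)[keep]))
  g <- agglo_graph(seq_len(n_sv), base, log_path = log_path)
  snaps <- matrix(NA_integer_, n_sv, n_edits)
  for (i in seq_len(n_edits)) {
    if (stats::runif(1) < 0.6) {
      repeat {
        x <- sample.int(n_sv, 2)
        if (!agglo_has_edge(g, x[1], x[2])) break
      }
      agglo_add_edge(g, x[1], x[2])
    } else {
      live <- which(g$active)
      e <- live[sample.int(length(live), 1)]
      agglo_remove_edge(g, g$ea[e], g$eb[e])
    }
    snaps[, i] <- agglo_partition(g)
  }
  agglo_close(g)
  list(base = base, graph = g, snaps = snaps, log_path = log_path)
}
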