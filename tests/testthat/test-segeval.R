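two_tube_phantom <- function(seed = 7, n = 4) {
  make_phantom(phantom_spec(shape = c(128, 64, 48), n_neurites = n,
                            n_synapses = 0, n_somata = 0, seed = seed))
}

test_that("edge accuracy is 1 on truth, 0 on background, merged when fused", {
  ph <- two_tube_phantom()
  expect_equal(edge_accuracy(ph$skeletons, ph$truth)$accuracy, 1)
  bg <- vem_volume(array(0L, dim(ph$truth$data)),
                   voxel_size = ph$truth$voxel_size)
  ea <- edge_accuracy(ph$skeletons, bg)
  expect_equal(ea$accuracy, 0)
  expect_equal(sum(ea$counts) , as.numeric(ea$counts["omitted"]))
  one <- vem_volume(array(1L, dim(ph$truth$data)),
                    voxel_size = ph$truth$voxel_size)
  em <- edge_accuracy(ph$skeletons, one)
  expect_equal(em$accuracy, 0)
  expect_equal(sum(em$counts), as.numeric(em$counts["merged"]))
  ## brute-force per-edge classification oracle for the fused case:
  ## every edge maps to one label holding other skeletons' nodes
  expect_equal(as.numeric(em$counts["merged"]),
               sum(vapply(ph$skeletons, function(s) nrow(s$edges),
                          integer(1))))
  ## node outside volume errors with the node listed
  sk_bad <- ph$skeletons[[1]]
  sk_bad$nodes$x[3] <- 1e9
  expect_error(edge_accuracy(c(ph$skeletons, list(sk_bad)), ph$truth),
               "outside")
})

test_that("pair separation counts match hand enumeration", {
  arr <- array(0L, c(4, 1, 1))
  arr[1, 1, 1] <- 1L; arr[2, 1, 1] <- 2L; arr[3, 1, 1] <- 4L
  seg <- vem_volume(arr)
  pairs <- data.frame(px = c(0, 2, 3), py = 0, pz = 0,
                      qx = c(1, 2, 0), qy = 0, qz = 0)
  ## labels: (1,2) separated, (4,4) merged, (0,1) uninformative
  r <- pair_separation_count(seg, pairs)
  expect_equal(r$n_separated, 1L)
  expect_equal(r$n_merged, 1L)
  expect_equal(r$n_uninformative, 1L)
  expect_error(pair_separation_count(seg, data.frame(px = 9, py = 0, pz = 0,
                                                     qx = 0, qy = 0, qz = 0)),
               "outside")
})

test_that("consensus equals the brute-force pair-intersection oracle", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (i in 1:10) {
    d <- c(16, 16, 8)
    A <- random_labels(d, 5); B <- random_labels(d, 5)
    cons <- oversegmentation_consensus(vem_volume(A), vem_volume(B))$data
    ## oracle: graph over foreground voxels, edges when 26-adjacent with
    ## equal (a, b) pair; components via igraph
    fg <- A > 0 & B > 0
    key <- ifelse(fg, paste(A, B), "")
    keyarr <- array(match(key, unique(key[fg])), d)
    keyarr[!fg] <- 0L
    allp <- mask_neighbor_pairs(array(as.integer(fg), d), 26)
    pairs <- allp[keyarr[allp[, 1]] == keyarr[allp[, 2]], , drop = FALSE]
    n <- prod(d)
    gr <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
    memb <- igraph::components(gr)$membership
    want <- ifelse(as.vector(fg), memb, 0)
    expect_true(same_partition(as.vector(cons), want), label = paste("vol", i))
    ## refinement: consensus never joins voxels either input separates
    cfg <- cons[fg]
    expect_true(all(tapply(A[fg], cfg, function(v) length(unique(v))) == 1))
    expect_true(all(tapply(B[fg], cfg, function(v) length(unique(v))) == 1))
  }
})

test_that("consensus with itself reproduces the partition; splits refine", {
  ph <- two_tube_phantom(seed = 3, n = 3)
  cons <- oversegmentation_consensus(ph$truth, ph$truth)
  expect_true(same_partition(as.vector(cons$data), as.vector(ph$truth$data)))
  ## one tube cut in two in B: consensus has the cut
  ov <- make_oversegmentation(ph$truth, error_spec(0, 0), split_labels = 1L)
  cons2 <- oversegmentation_consensus(ph$truth, ov$supervoxels)
  expect_true(same_partition(as.vector(cons2$data),
                             as.vector(ov$supervoxels$data)))
})

test_that("postprocessing fills interior holes and absorbs nested segments", {
  ## interior background voxel filled
  arr <- array(0L, c(7, 7, 7)); arr[2:6, 2:6, 2:6] <- 1L
  arr[4, 4, 4] <- 0L
  pp <- postprocess_segments(vem_volume(arr))
  expect_equal(pp$data[4, 4, 4], 1L)
  ## nested cube absorbed
  arr2 <- array(0L, c(9, 9, 9)); arr2[2:8, 2:8, 2:8] <- 1L
  arr2[4:6, 4:6, 4:6] <- 2L
  pp2 <- postprocess_segments(vem_volume(arr2))
  expect_true(all(pp2$data[arr2 == 2] == 1L))
  ## nested cube with a background tunnel to the border is NOT absorbed
  arr3 <- array(0L, c(9, 9, 9)); arr3[2:8, 2:8, 2:8] <- 1L
  arr3[4:6, 4:6, 4:6] <- 2L
  arr3[5, 5, 1:3] <- 0L                     # tunnel from border to B
  pp3 <- postprocess_segments(vem_volume(arr3))
  expect_true(any(pp3$data == 2L))
  ## flood-fill oracle agreement: tunnel voxels stay background
  expect_true(all(pp3$data[5, 5, 1:3] == 0L))
  ## idempotence
  for (v in list(arr, arr2, arr3)) {
    p1 <- postprocess_segments(vem_volume(v))
    expect_identical(postprocess_segments(p1)$data, p1$data)
  }
})

test_that("checkpoint-pair selection maximizes separated pairs", {
  ph <- make_phantom(phantom_spec(shape = c(96, 128, 48), n_neurites = 12,
                                  n_synapses = 0, n_somata = 0, seed = 31))
  pp <- phantom_point_pairs(ph)
  np <- nrow(pp)
  expect_gte(np, 6)
  ## candidates with different planted merger patterns
  mk <- function(mp) make_oversegmentation(ph$truth, error_spec(0, 0),
                                           ph$adjacent_pairs,
                                           merge_pairs = mp)$supervoxels
  segs <- list(mk(1:3), mk(1:2), mk(c(2, 4)), mk(integer(0)))
  acc <- vapply(segs, function(s) edge_accuracy(ph$skeletons, s)$accuracy,
                numeric(1))
  sel <- select_checkpoint_pair(segs, acc, pp, k = 4)
  ## exhaustive enumeration oracle over all C(4,2) pairs
  best <- -1; best_pair <- NULL
  for (i in 1:3) for (j in (i + 1):4) {
    n <- pair_separation_count(oversegmentation_consensus(segs[[i]],
                                                          segs[[j]]),
                               pp)$n_separated
    if (n > best) { best <- n; best_pair <- c(i, j) }
  }
  expect_equal(sel$pair, best_pair)
  expect_equal(sel$n_separated, best)
  ## with 2 candidates only, that pair is chosen
  sel2 <- select_checkpoint_pair(segs[1:2], acc[1:2], pp)
  expect_equal(sel2$pair, c(1L, 2L))
  expect_error(select_checkpoint_pair(segs[1], acc[1], pp), "at least 2")
})

test_that("consensus never separates fewer informative pairs than inputs", {
  ph <- make_phantom(phantom_spec(shape = c(96, 128, 48), n_neurites = 12,
                                  n_synapses = 0, n_somata = 0, seed = 33))
  pp <- phantom_point_pairs(ph)
  mk <- function(mp) make_oversegmentation(ph$truth, error_spec(0, 0),
                                           ph$adjacent_pairs,
                                           merge_pairs = mp)$supervoxels
  A <- mk(1:2); B <- mk(c(3, 4))
  cons <- oversegmentation_consensus(A, B)
  rc <- pair_separation_count(cons, pp)
  expect_gte(rc$n_separated + rc$n_uninformative,
             max(pair_separation_count(A, pp)$n_separated,
                 pair_separation_count(B, pp)$n_separated))
})
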