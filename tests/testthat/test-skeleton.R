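straight_skel <- function(n, step_nm = 1000, comp = "axon") {
  skeleton(data.frame(id = seq_len(n), x = seq(0, by = step_nm,
                                               length.out = n),
                      y = 0, z = 0),
           cbind(seq_len(n - 1), seq(2, n)),
           compartment = rep(comp, n))
}

test_that("path length sums Euclidean edge lengths per compartment", {
  sk <- straight_skel(11)                      # 10 edges of 1 um
  expect_equal(path_length(sk), 10)
  expect_equal(path_length(sk, "axon"), 10)
  expect_equal(path_length(sk, "dendrite"), 0)  # empty filter match
  ## additivity and reindexing invariance
  set.seed(71)
  nodes <- data.frame(id = sample(100:199), x = runif(100, 0, 5e4),
                      y = runif(100, 0, 5e4), z = runif(100, 0, 5e4))
  edges <- cbind(nodes$id[1:99], nodes$id[2:100])
  sk2 <- skeleton(nodes, edges)
  ## per-edge summation oracle
  want <- sum(sqrt(rowSums((as.matrix(nodes[1:99, c("x", "y", "z")]) -
                              as.matrix(nodes[2:100, c("x", "y", "z")]))^2)))
  expect_equal(path_length(sk2), want / 1000)
  perm <- sample(100)
  sk3 <- skeleton(nodes[perm, ], edges)
  expect_equal(path_length(sk3), path_length(sk2))
})

test_that("densities follow counts over compartment lengths", {
  ## Y tree: 3 edges of 1 um, one degree-3 node
  nodes <- data.frame(id = 1:4, x = c(0, 1000, 2000, 1000),
                      y = c(0, 0, 0, 1000), z = 0)
  sk <- skeleton(nodes, rbind(c(1, 2), c(2, 3), c(2, 4)),
                 compartment = rep("axon", 4))
  row <- densities(sk, "cell")
  expect_equal(row$n_branch, 1L)
  expect_equal(row$branch_per_um, 1 / 3)
  ## 4 synapses on a 20 um axon -> 0.2 per um
  sk2 <- straight_skel(21)
  sk2$annotations <- data.frame(id = c(3, 8, 13, 18),
                                tag = rep("synapse_out", 4))
  expect_equal(densities(sk2)$syn_out_per_axon_um, 0.2)
  ## explicit branch annotations win over degree
  sk3 <- straight_skel(5)
  sk3$annotations <- data.frame(id = 2, tag = "branch")
  expect_equal(densities(sk3)$n_branch, 1L)
  ## zero-length compartment with nonzero count is flagged
  sk4 <- straight_skel(5, comp = "dendrite")
  sk4$annotations <- data.frame(id = 2, tag = "synapse_out")
  expect_true(densities(sk4)$flag_zero_length)
})

test_that("phantom cell morphometry matches generator ground truth", {
  ph <- make_phantom(phantom_spec(shape = c(128, 64, 48), n_neurites = 3,
                                  n_synapses = 0, n_somata = 0, seed = 72))
  for (nm in names(ph$skeletons)) {
    sk <- ph$skeletons[[nm]]
    ## centerline of a tube: n nodes, n-1 edges, no branch points
    expect_equal(nrow(sk$edges), nrow(sk$nodes) - 1L)
    expect_equal(densities(sk)$n_branch, 0L)
    expect_equal(path_length(sk),
                 sum(sqrt(rowSums((as.matrix(sk$nodes[-1, c("x", "y", "z")]) -
                                     as.matrix(sk$nodes[-nrow(sk$nodes),
                                                        c("x", "y", "z")]))^2)))
                 / 1000)
  }
})

test_that("region branch profiles normalize over branch points", {
  ## two regions splitting 10 branch points 7/3
  nodes <- data.frame(id = 1:30, x = c(seq(500, by = 1000, length.out = 10),
                                       runif(20, 0, 2e4)),
                      y = 500, z = 500)
  edges <- NULL
  for (b in 1:10) {
    edges <- rbind(edges, c(b, 10 + 2 * b - 1), c(b, 10 + 2 * b))
    if (b > 1) edges <- rbind(edges, c(b - 1, b))
  }
  sk <- skeleton(nodes, edges)
  expect_equal(length(vemtools:::branch_point_ids(sk)), 10L)
  vsz <- c(1000, 1000, 1000)
  rA <- array(0L, c(20, 1, 1)); rA[1:7, 1, 1] <- 1L
  rB <- array(0L, c(20, 1, 1)); rB[8:20, 1, 1] <- 1L
  regions <- list(A = vem_volume(rA, voxel_size = vsz),
                  B = vem_volume(rB, voxel_size = vsz))
  prof <- region_branch_profile(sk, regions)
  expect_equal(prof$fraction[prof$region == "A"], 0.7)
  expect_equal(prof$fraction[prof$region == "B"], 0.3)
  expect_equal(sum(prof$fraction), 1)
  ## all in one region
  prof2 <- region_branch_profile(sk, regions["B"])
  expect_equal(prof2$fraction[prof2$region == "unassigned"], 0.7)
  ## no branch points: flagged NA fractions
  lin <- straight_skel(5)
  prof3 <- region_branch_profile(lin, regions)
  expect_true(all(is.na(prof3$fraction)))
})

test_that("consensus keeps supported structure and drops lone branches", {
  base <- straight_skel(12)
  jit <- function(s, d) { s$nodes$y <- s$nodes$y + d; s }
  cs <- consensus_skeleton(list(base, jit(base, 80), jit(base, -80)),
                           tolerance_nm = 300, quorum = 2)
  expect_equal(nrow(cs$nodes), 12L)
  expect_equal(nrow(cs$edges), 11L)
  expect_equal(attr(cs, "n_components"), 1L)
  ## a distant false branch in one tracing disappears at quorum 2
  rogue <- base
  rogue$nodes <- rbind(rogue$nodes,
                       data.frame(id = 99, x = 5000, y = 5e4, z = 0))
  rogue$edges <- rbind(rogue$edges, c(6, 99))
  rogue$compartment <- c(base$compartment, "axon")
  cs2 <- consensus_skeleton(list(base, jit(base, 80), rogue),
                            tolerance_nm = 300, quorum = 2)
  expect_false(any(cs2$nodes$y > 1e4))
  ## monotone in quorum: raising k never adds nodes
  cs3 <- consensus_skeleton(list(base, jit(base, 80), rogue),
                            tolerance_nm = 300, quorum = 3)
  expect_lte(nrow(cs3$nodes), nrow(cs2$nodes))
  ## tolerance 0 on jittered copies: (near-)empty consensus
  cs0 <- consensus_skeleton(list(jit(base, 1), jit(base, -1)),
                            tolerance_nm = 0, quorum = 2)
  expect_equal(nrow(cs0$nodes), 0L)
  expect_error(consensus_skeleton(list(base)), "length")
})

test_that("fragment sampling is reproducible and radius-bounded", {
  ax <- straight_skel(201)                       # 200 um axon
  fr <- sample_fragments(ax, n = 10, radius_nm = 750, seed = 5)
  expect_length(fr, 10L)
  for (f in fr) {
    p <- as.matrix(f$skeleton$nodes[, c("x", "y", "z")])
    expect_true(all(sqrt(rowSums(sweep(p, 2, f$center)^2)) <= 750))
    ## a straight axon fragment spans at most ~1.5 um
    expect_lte(max(p[, 1]) - min(p[, 1]), 1500)
  }
  expect_identical(sample_fragments(ax, n = 10, radius_nm = 750, seed = 5),
                   fr)
  expect_length(sample_fragments(ax, n = 0), 0L)
})

test_that("SWC files round-trip nodes, edges and compartments", {
  nodes <- data.frame(id = 1:5, x = c(0, 1000, 2000, 1000, 3000),
                      y = c(0, 0, 0, 1000, 0), z = 0, radius = c(5, 4, 3, 3, 2))
  sk <- skeleton(nodes, rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5)),
                 compartment = c("soma", "axon", "axon", "dendrite", "axon"))
  f <- tempfile(fileext = ".swc")
  write_swc(sk, f)
  sk2 <- read_swc(f)
  expect_equal(nrow(sk2$nodes), 5L)
  expect_equal(nrow(sk2$edges), 4L)
  expect_equal(sort(sk2$compartment), sort(sk$compartment))
  expect_equal(path_length(sk2), path_length(sk))
})
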