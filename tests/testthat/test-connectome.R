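test_that("phantom partners and directions are recovered from vesicles", {
  ph <- make_phantom(phantom_spec(shape = c(256, 96, 48), n_neurites = 6,
                                  n_synapses = 5, n_somata = 0, seed = 11))
  asg <- assign_partners(ph$cleft_labels, ph$vesicle_labels, ph$truth,
                         dilation_nm = 60)
  expect_true(all(asg$directed))
  m <- merge(asg, ph$cleft_to_pair, by = "cleft")
  expect_equal(m$pre.x, m$pre.y)
  expect_equal(m$post.x, m$post.y)
  ## relabeling invariance: permuting cell ids permutes partnerships
  perm <- c(4L, 6L, 1L, 3L, 5L, 2L)
  seg2 <- ph$truth
  seg2$data[seg2$data > 0] <- perm[seg2$data[seg2$data > 0]]
  asg2 <- assign_partners(ph$cleft_labels, ph$vesicle_labels, seg2,
                          dilation_nm = 60)
  expect_equal(asg2$pre, perm[asg$pre])
  expect_equal(asg2$post, perm[asg$post])
})

test_that("missing vesicle evidence leaves direction null but paired", {
  ph <- make_phantom(phantom_spec(shape = c(192, 64, 32), n_neurites = 2,
                                  n_synapses = 1, n_somata = 0, seed = 13))
  empty_ves <- vem_volume(array(0L, dim(ph$truth$data)),
                          voxel_size = ph$truth$voxel_size)
  asg <- assign_partners(ph$cleft_labels, empty_ves, ph$truth,
                         dilation_nm = 60)
  expect_false(asg$directed)
  expect_true(is.na(asg$pre))
  expect_setequal(c(asg$cell_a, asg$cell_b), 1:2)
  expect_false(asg$unpaired)
})

test_that("the two largest contacts become the candidate partners", {
  ## cleft bar with three touching cells of contact 50/40/5 voxels
  d <- c(60, 9, 9)
  seg <- array(0L, d)
  seg[3:52, 2, 5] <- 1L       # 50 voxels adjacent to the cleft
  seg[3:42, 6, 5] <- 2L       # 40 voxels
  seg[3:7, 4, 2] <- 3L        #  5 voxels, adjacent from z side
  cleft <- array(0L, d)
  cleft[3:52, 4, 5] <- 1L
  ves <- array(0L, d)
  ves[3:52, 2, 5] <- 1L       # vesicle cloud inside cell 1
  vs <- c(14, 14, 25)
  asg <- assign_partners(vem_volume(cleft, voxel_size = vs),
                         vem_volume(ves, voxel_size = vs),
                         vem_volume(seg, voxel_size = vs),
                         dilation_nm = 45)
  expect_setequal(c(asg$cell_a, asg$cell_b), c(1, 2))
  expect_equal(asg$pre, 1L)
  expect_equal(asg$post, 2L)
  ## contact voxel counts match a brute-force count oracle
  expect_equal(asg$contact_a, 50L)
  expect_equal(asg$contact_b, 40L)
  ## cleft touching fewer than two cells is unpaired and flagged
  seg1 <- array(0L, d); seg1[3:52, 2, 5] <- 1L
  asg1 <- assign_partners(vem_volume(cleft, voxel_size = vs),
                          vem_volume(ves, voxel_size = vs),
                          vem_volume(seg1, voxel_size = vs),
                          dilation_nm = 45)
  expect_true(asg1$unpaired)
})

test_that("edge building groups, conserves counts and lists exceptions", {
  asg <- data.frame(cleft = 1:6,
                    pre = c(1, 1, 1, 2, NA, NA),
                    post = c(2, 2, 2, 3, NA, NA),
                    cell_a = c(1, 1, 1, 2, 4, 9),
                    cell_b = c(2, 2, 2, 3, 5, NA),
                    directed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    unpaired = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  be <- build_edges(asg)
  expect_equal(nrow(be$edges), 2L)
  expect_equal(be$edges$count[be$edges$pre == 1], 3L)
  expect_equal(be$edges$clefts[be$edges$pre == 1], "1;2;3")
  ## conservation: directed + undirected + unpaired = all clefts
  expect_equal(sum(be$edges$count) + nrow(be$undirected) + nrow(be$unpaired),
               nrow(asg))
  expect_equal(be$address_book$n_out[be$address_book$cell == 1], 3L)
  expect_equal(be$address_book$n_in[be$address_book$cell == 2], 3L)
  ## empty input
  be0 <- build_edges(asg[0, ])
  expect_equal(nrow(be0$edges), 0L)
})

test_that("phantom connectome edges equal generator ground truth", {
  ph <- make_phantom(phantom_spec(shape = c(320, 220, 64), n_neurites = 20,
                                  n_synapses = 12, n_somata = 0, seed = 17))
  asg <- assign_partners(ph$cleft_labels, ph$vesicle_labels, ph$truth,
                         dilation_nm = 60)
  be <- build_edges(asg)
  want <- ph$cleft_to_pair
  want_edges <- stats::aggregate(cleft ~ pre + post, want, length)
  got <- be$edges[order(be$edges$pre, be$edges$post), ]
  want_edges <- want_edges[order(want_edges$pre, want_edges$post), ]
  expect_equal(got$pre, want_edges$pre)
  expect_equal(got$post, want_edges$post)
  expect_equal(got$count, want_edges$cleft)
  expect_equal(sum(got$count) + nrow(be$undirected) + nrow(be$unpaired),
               length(unique(ph$cleft_labels$data[ph$cleft_labels$data > 0])))
})

test_that("recurrency check flags cycles exactly", {
  ## planted feedforward DAG of 11 cells
  dag <- data.frame(pre = c(1, 1, 2, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                    post = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 11, 11))
  rc <- recurrency_check(dag)
  expect_false(rc$has_cycle)
  expect_length(rc$cycles, 0L)
  ## one back edge creates exactly the expected cycle
  rc2 <- recurrency_check(rbind(dag, data.frame(pre = 11, post = 1)))
  expect_true(rc2$has_cycle)
  expect_true(any(vapply(rc2$cycles, function(cy) cy[1] == 1 && 11 %in% cy,
                         logical(1))))
  ## bidirectional pairs
  rc3 <- recurrency_check(data.frame(pre = c(1, 2, 2, 3),
                                     post = c(2, 1, 3, 4)))
  expect_equal(rc3$bidirectional, data.frame(a = 1, b = 2))
  ## random small graphs vs exhaustive permutation oracle
  set.seed(81)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    ne <- sample(3:10, 1)
    e <- unique(data.frame(pre = sample(n, ne, TRUE),
                           post = sample(n, ne, TRUE)))
    e <- e[e$pre != e$post, ]
    got <- recurrency_check(e)
    want <- cycles_oracle(e, seq_len(n))
    expect_equal(canon_cycles(got$cycles), canon_cycles(want),
                 label = paste("graph", i))
  }
})

test_that("has_cycle agrees with an acyclicity oracle on larger graphs", {
  skip_if_not_installed("igraph")
  set.seed(82)
  for (i in 1:20) {
    n <- 12
    e <- unique(data.frame(pre = sample(n, 14, TRUE),
                           post = sample(n, 14, TRUE)))
    e <- e[e$pre != e$post, ]
    got <- recurrency_check(e)$has_cycle
    g <- igraph::graph_from_data_frame(e, vertices = data.frame(name = 1:n))
    expect_equal(got, !igraph::is_dag(g), label = paste("digraph", i))
  }
})

test_that("shared partner fractions follow set arithmetic", {
  e <- data.frame(pre = c(rep(1, 20), rep(2, 20)),
                  post = c(1:20 + 100, c(101, 102, 103, 204:220)))
  r <- shared_partner_fraction(e, 1, 2, "out")
  expect_equal(r$fraction, 3 / 20)
  same <- data.frame(pre = c(1, 1, 2, 2), post = c(10, 11, 10, 11))
  expect_equal(shared_partner_fraction(same, 1, 2, "out")$fraction, 1)
  disj <- data.frame(pre = c(1, 2), post = c(10, 11))
  expect_equal(shared_partner_fraction(disj, 1, 2, "out")$fraction, 0)
  expect_warning(r0 <- shared_partner_fraction(disj, 9, 2, "out"), "no")
  expect_true(r0$undefined)
})
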