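test_that("contact areas match analytic slab and sphere values", {
  ## empty mask
  e <- contact_area(vem_volume(array(0L, c(4, 4, 4))))
  expect_equal(e$area_um2, 0)
  expect_true(e$empty)
  ## 1-voxel-thick slab, 10 x 10 px at 14 x 14 nm: half-surface ~ face area
  arr <- array(0L, c(20, 20, 5)); arr[6:15, 6:15, 3] <- 1L
  ca <- contact_area(vem_volume(arr, voxel_size = c(14, 14, 25)))
  expect_equal(ca$area_um2, (10 * 14)^2 / 1e6, tolerance = 0.2)
  expect_equal(ca$full_area_um2 / ca$area_um2, 2)
  ## digitized spheres: half-surface ~ 2 pi r^2 within 10% for r >= 10
  for (r in c(10, 13)) {
    d <- rep(2 * r + 7, 3)
    v <- vem_volume(ball_mask(d, rep(r + 4, 3), r))
    ca <- contact_area(v)
    expect_equal(ca$area_um2 * 1e6, 2 * pi * r^2, tolerance = 0.1)
  }
})

test_that("contact area scales quadratically and ignores axis permutation", {
  r <- 8
  d <- rep(2 * r + 5, 3)
  m <- ball_mask(d, rep(r + 3, 3), r)
  a1 <- contact_area(vem_volume(m, voxel_size = c(10, 10, 10)))$area_um2
  a2 <- contact_area(vem_volume(m, voxel_size = c(20, 20, 20)))$area_um2
  expect_equal(a2 / a1, 4, tolerance = 1e-6)
  ap <- contact_area(vem_volume(aperm(m, c(3, 1, 2)),
                                voxel_size = c(10, 10, 10)))$area_um2
  expect_equal(ap, a1, tolerance = 1e-6)
})

test_that("profile lengths are exact for axis-aligned slabs", {
  ## slab 10 px in x, 1 px in y, 4 sections in z
  arr <- array(0L, c(20, 10, 8)); arr[6:15, 5, 3:6] <- 1L
  v <- vem_volume(arr, voxel_size = c(14, 14, 25))
  pz <- profile_lengths(v, "z")
  expect_equal(nrow(pz), 4L)
  expect_true(all(pz$length_nm == 10 * 14))
  ## slicing along x: slice is 1 px x 4 sections -> length 4 * 25
  px <- profile_lengths(v, "x")
  expect_true(all(px$length_nm == 4 * 25))
  ## single-voxel object: in-plane pitch convention
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  p1 <- profile_lengths(vem_volume(one, voxel_size = c(14, 14, 25)), "z")
  expect_equal(p1$length_nm, 14)
  p2 <- profile_lengths(vem_volume(one, voxel_size = c(14, 14, 25)), "x")
  expect_equal(p2$length_nm, 25)   # in-plane pitches are (14, 25)
})

test_that("Feret lengths agree with the all-pairs oracle on random shapes", {
  set.seed(61)
  for (i in 1:50) {
    sl <- matrix(0L, 20, 20)
    n_blob <- sample(1:3, 1)
    for (b in seq_len(n_blob)) {
      cx <- sample(4:16, 1); cy <- sample(4:16, 1); r <- sample(2:5, 1)
      co <- as.matrix(expand.grid(1:20, 1:20))
      sel <- (co[, 1] - cx)^2 + (co[, 2] - cy)^2 <= r^2
      sl[co[sel, , drop = FALSE]] <- 1L
    }
    pitch <- c(14, 14)
    arr <- array(sl, c(20, 20, 1))
    got <- profile_lengths(vem_volume(arr, voxel_size = c(pitch, 25)), "z")
    ## oracle: largest 8-connected component by an independent flood fill,
    ## then brute-force max over ALL pixel pairs with the end-cap formula
    lab <- array(0L, dim(sl)); nxt <- 0L
    for (jj in 1:20) for (ii in 1:20) {
      if (sl[ii, jj] == 0 || lab[ii, jj] != 0) next
      nxt <- nxt + 1L
      queue <- list(c(ii, jj)); lab[ii, jj] <- nxt
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (dx in -1:1) for (dy in -1:1) {
          p <- cur + c(dx, dy)
          if (any(p < 1) || any(p > 20)) next
          if (sl[p[1], p[2]] != 0 && lab[p[1], p[2]] == 0) {
            lab[p[1], p[2]] <- nxt
            queue <- c(queue, list(p))
          }
        }
      }
    }
    sizes <- tabulate(lab[lab > 0])
    w <- which(lab == which.max(sizes), arr.ind = TRUE)
    pts <- cbind((w[, 1] - 1) * pitch[1], (w[, 2] - 1) * pitch[2])
    best <- max(pitch)
    if (nrow(pts) > 1) {
      for (a in 1:(nrow(pts) - 1)) for (b in (a + 1):nrow(pts)) {
        dv <- pts[b, ] - pts[a, ]
        dd <- sqrt(sum(dv^2))
        if (dd == 0) next
        u <- abs(dv) / dd
        best <- max(best, dd + u[1] * pitch[1] + u[2] * pitch[2])
      }
    }
    expect_equal(got$length_nm, best, tolerance = 1e-9,
                 label = paste("shape", i))
  }
})

test_that("sampled medians match the full population on known objects", {
  set.seed(62)
  tab <- data.frame(id = 1:40,
                    region = rep(c("tectum", "thalamus"), each = 20),
                    area_um2 = c(seq(0.05, 0.24, 0.01), seq(0.1, 0.48, 0.02)))
  lens <- stats::setNames(lapply(1:40, function(i) rep(i * 10, 3)),
                          as.character(1:40))
  rep_ <- contact_sample_report(tab, lens, n = 100, seed = 9)
  ## n exceeds population: medians are exact population medians
  expect_equal(rep_$median_area_um2[rep_$region == "tectum"],
               stats::median(tab$area_um2[tab$region == "tectum"]))
  expect_equal(rep_$median_length_nm[rep_$region == "thalamus"],
               stats::median(unlist(lens[21:40])))
  ## single object: medians equal that object's values
  rep1 <- contact_sample_report(tab[1, ], lens[1], n = 100, seed = 9)
  expect_equal(rep1$median_area_um2, tab$area_um2[1])
  ## reproducible sampling
  r1 <- contact_sample_report(tab, lens, n = 5, seed = 4)
  r2 <- contact_sample_report(tab, lens, n = 5, seed = 4)
  expect_identical(r1, r2)
})

test_that("vesicle fractions are exact voxel-count ratios", {
  set.seed(63)
  d <- c(20, 20, 10)
  region <- array(0L, d); region[1:10, , ] <- 1L
  ves <- array(0L, d); ves[1:5, , ] <- 1L
  expect_equal(vesicle_fraction(vem_volume(ves), vem_volume(region)), 50)
  empty <- array(0L, d)
  expect_equal(vesicle_fraction(vem_volume(empty), vem_volume(region)), 0)
  expect_warning(
    out <- vesicle_fraction(vem_volume(ves), vem_volume(empty)), "empty")
  expect_true(is.na(out))
  rnd <- array(as.integer(runif(prod(d)) < 0.1), d)
  expect_equal(vesicle_fraction(vem_volume(rnd), vem_volume(region)),
               100 * sum(rnd[1:10, , ]) / sum(region))
})

test_that("object-wise PR matches analytic counts and optimal matching", {
  d <- c(30, 30, 6)
  truth <- array(0L, d)
  truth[3:6, 3:6, 2:4] <- 1L; truth[12:15, 12:15, 2:4] <- 2L
  truth[22:25, 22:25, 2:4] <- 3L
  tv <- vem_volume(truth)
  expect_equal(objectwise_pr(tv, tv)$precision, 1)
  expect_equal(objectwise_pr(tv, tv)$recall, 1)
  ## one spurious blob: precision n/(n+1), recall 1
  pred <- truth
  pred[3:5, 22:24, 2:4] <- 4L
  pr <- objectwise_pr(vem_volume(pred), tv)
  expect_equal(pr$precision, 3 / 4)
  expect_equal(pr$recall, 1)
  ## empty prediction: recall 0, precision undefined
  pr0 <- objectwise_pr(vem_volume(array(0L, d)), tv)
  expect_equal(pr0$recall, 0)
  expect_true(pr0$precision_undefined)
  ## greedy equals exhaustive optimal matching on detector-like instances:
  ## scattered truth blobs, predictions jittered / dropped / with spurious
  set.seed(64)
  for (i in 1:15) {
    dd <- c(40, 40, 6)
    t_ <- array(0L, dd); p <- array(0L, dd)
    nt <- sample(4:8, 1)
    grid_xy <- as.matrix(expand.grid(seq(5, 33, by = 7), seq(5, 33, by = 7)))
    cen <- cbind(grid_xy[sample(nrow(grid_xy), nt), , drop = FALSE],
                 sample(2:5, nt, TRUE))
    for (b in seq_len(nrow(cen))) {
      bx <- cen[b, 1]; by <- cen[b, 2]; bz <- cen[b, 3]
      t_[max(1, bx - 1):min(dd[1], bx + 1),
         max(1, by - 1):min(dd[2], by + 1), bz] <- b
      if (runif(1) < 0.85) {   # detected, with jitter
        jx <- bx + sample(-1:1, 1); jy <- by + sample(-1:1, 1)
        p[max(1, jx - 1):min(dd[1], jx + 1),
          max(1, jy - 1):min(dd[2], jy + 1), bz] <- b
      }
    }
    if (runif(1) < 0.5) p[37:39, 37:39, 6] <- max(cen[, 1]) + 50L
    res <- objectwise_pr(vem_volume(p), vem_volume(t_))
    pid <- sort(unique(p[p > 0])); tid <- sort(unique(t_[t_ > 0]))
    inc <- matrix(FALSE, length(pid), length(tid))
    for (a in seq_along(pid)) for (b in seq_along(tid))
      inc[a, b] <- any(p == pid[a] & t_ == tid[b])
    expect_equal(res$tp, max_matching_oracle(inc), label = paste("inst", i))
  }
})
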