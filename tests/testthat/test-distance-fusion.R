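test_that("signed distances match brute-force search over the border set", {
  g <- image_grid(c(9, 9, 9))
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  d <- signed_distance(binary_mask(g, m))
  expect_equal(d$values[5, 5, 5], 0)
  expect_equal(d$values[6, 5, 5], 1)
  expect_equal(d$values[6, 6, 5], sqrt(2))
  expect_equal(d$values[6, 6, 6], sqrt(3))
  set.seed(41)
  ga <- image_grid(c(8, 7, 6), c(2, 2, 3))
  for (rep in 1:8) {
    b <- random_blob(ga, 2)
    if (!any(b$inside) || all(b$inside)) next
    dm <- signed_distance(b)
    oracle <- edt_oracle(surface_oracle(b$inside), ga)
    oracle[as.vector(b$inside)] <- -oracle[as.vector(b$inside)]
    oracle[as.vector(surface_oracle(b$inside))] <- 0
    expect_equal(as.vector(dm$values), oracle, tolerance = 1e-9)
  }
})

test_that("a solid sphere's center depth approximates its radius", {
  g <- image_grid(c(24, 24, 18), c(2, 2, 3))
  s <- sphere_mask(g, c(23, 23, 25.5), 10)
  d <- signed_distance(s)
  center_val <- d$values[13, 13, 10] # voxel nearest (24, 24, 27)
  expect_lt(abs(center_val + 10), sqrt(sum(g$spacing^2))) # within one diagonal
})

test_that("sign round-trip recovers the mask and the Lipschitz bound holds", {
  set.seed(43)
  g <- image_grid(c(10, 10, 8), c(2, 2, 3))
  for (rep in 1:50) {
    b <- random_blob(g, sample(1:3, 1))
    if (!any(b$inside) || all(b$inside)) next
    d <- signed_distance(b)
    expect_identical(extract_segmentation(d)$inside, b$inside)
    # single-map fusion round trip
    expect_identical(extract_segmentation(fuse_distance_maps(list(d), 1))$inside,
                     b$inside)
  }
  b <- random_blob(g, 3)
  d <- signed_distance(b)
  pts <- grid_points(g)
  v <- as.vector(d$values)
  i1 <- sample(length(v), 400, replace = TRUE)
  i2 <- sample(length(v), 400, replace = TRUE)
  sep <- sqrt(rowSums((pts[i1, ] - pts[i2, ])^2))
  expect_true(all(abs(v[i1] - v[i2]) <= sep + 1e-9))
  expect_error(signed_distance(binary_mask(g, array(FALSE, g$shape))), "empty")
})

test_that("weighted fusion is idempotent and places boundaries at weighted means", {
  g <- image_grid(c(16, 12, 10), c(1, 1, 1))
  s1 <- slab_mask(g, 1, 0, 5)
  s2 <- slab_mask(g, 1, 4, 9) # faces offset by 4 mm
  d1 <- signed_distance(s1); d2 <- signed_distance(s2)
  f <- fuse_distance_maps(list(d1, d2), c(0.3, 0.7))
  same <- fuse_distance_maps(list(d1, d1), c(0.3, 0.7))
  expect_equal(same$values, d1$values, tolerance = 1e-12)
  # equal weights: the x-face boundary sits midway between the two faces
  feq <- extract_segmentation(fuse_distance_maps(list(d1, d2), c(1, 1)))
  xmax <- max(grid_points(g)[as.vector(feq$inside), 1])
  expect_equal(xmax, 7) # faces at 5 and 9 mm -> mean 7
  expect_error(fuse_distance_maps(list(d1, d2), c(0, 0)), "positive sum")
  expect_error(fuse_distance_maps(list(), numeric(0)), "at least one")
})

test_that("fusing concentric spheres yields a sphere of weight-averaged radius", {
  g <- image_grid(c(32, 32, 32), c(1.5, 1.5, 1.5))
  c0 <- c(23.25, 23.25, 23.25)
  maps <- lapply(c(8, 10, 12), function(r) signed_distance(sphere_mask(g, c0, r)))
  fused <- extract_segmentation(fuse_distance_maps(maps, c(1, 1, 1)))
  # mean of signed radial ramps has zero level at the mean radius (10 mm)
  target <- sphere_mask(g, c0, 10)
  expect_gt(dsc(fused, target), 0.9) # half-voxel border discretization
  vol_r <- (3 * mask_volume(fused) * prod(g$spacing) / (4 * pi))^(1 / 3)
  expect_lt(abs(vol_r - 10), 1.5) # within one voxel of the weighted-mean radius
})

test_that("raising an atlas weight pulls the fused boundary toward that atlas", {
  g <- image_grid(c(32, 32, 32), c(1.5, 1.5, 1.5))
  c0 <- c(23.25, 23.25, 23.25)
  small <- sphere_mask(g, c0, 7)
  big <- sphere_mask(g, c0, 13)
  maps <- list(signed_distance(small), signed_distance(big))
  ds <- vapply(c(0.2, 1, 5), function(w)
    dsc(extract_segmentation(fuse_distance_maps(maps, c(w, 1))), small),
    numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("majority vote matches per-voxel counting and equal-weight fusion approaches it", {
  set.seed(47)
  g <- image_grid(c(8, 8, 6), c(2, 2, 3))
  masks <- lapply(1:5, function(i) random_mask(g, 0.4))
  mv <- majority_vote(masks)
  counts <- Reduce(`+`, lapply(masks, function(m) m$inside + 0L))
  expect_identical(mv$inside, counts > 2.5)
  expect_identical(majority_vote(list(masks[[1]], masks[[1]]))$inside,
                   masks[[1]]$inside)
  # k identical spheres plus one outlier: fusion approaches the majority shape
  gs <- image_grid(c(24, 24, 24), c(2, 2, 2))
  c0 <- c(23, 23, 23)
  consensus <- sphere_mask(gs, c0, 10)
  outlier <- sphere_mask(gs, c0 + c(8, 0, 0), 6)
  # the outlier pull scales with its distance map, so it fades like 1/k; the
  # limit shape is the consensus interior (border voxels sit exactly at
  # distance zero, so any positive contribution excludes that shell)
  ds <- vapply(c(2, 8, 32), function(k) {
    ms <- c(replicate(k, consensus, simplify = FALSE), list(outlier))
    dsc(fuse_masks(ms), majority_vote(ms))
  }, numeric(1))
  expect_true(all(diff(ds) >= 0))
  interior <- binary_mask(gs, signed_distance(consensus)$values < 0)
  expect_gte(ds[3], dsc(interior, consensus) - 0.01)
})

test_that("empty masks are dropped from fusion with a warning", {
  g <- image_grid(c(8, 8, 6), c(2, 2, 3))
  s <- sphere_mask(g, c(7, 7, 7.5), 5)
  empty <- binary_mask(g, array(FALSE, g$shape))
  expect_warning(f <- fuse_masks(list(s, empty), c(1, 1)), "empty")
  expect_identical(f$inside, s$inside)
})
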