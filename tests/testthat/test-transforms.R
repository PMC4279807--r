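test_that("cubic B-spline basis partitions unity and zero coefficients give the identity", {
  set.seed(7)
  g <- image_grid(c(12, 12, 10), c(2, 2, 3))
  t0 <- bspline_transform(g, 8)
  pts <- grid_points(g)
  expect_equal(transform_points(t0, pts), pts)
  # constant coefficients translate every in-domain point by that constant:
  # only true because the basis weights sum to one everywhere
  tc <- bspline_transform(g, 8)
  tc$coefficients <- matrix(rep(c(1.5, -2, 3), each = nrow(tc$coefficients)), ncol = 3)
  d <- transform_points(tc, pts) - pts
  expect_lt(max(abs(sweep(d, 2, c(1.5, -2, 3)))), 1e-12)
  # random interior points too (partition of unity off the voxel lattice)
  ext <- grid_extent(g)
  rp <- cbind(runif(2000, ext[1, 1], ext[2, 1]),
              runif(2000, ext[1, 2], ext[2, 2]),
              runif(2000, ext[1, 3], ext[2, 3]))
  d2 <- transform_points(tc, rp) - rp
  expect_lt(max(abs(sweep(d2, 2, c(1.5, -2, 3)))), 1e-12)
})

test_that("B-spline evaluation matches a naive per-point basis expansion", {
  set.seed(11)
  g <- image_grid(c(10, 10, 8), c(2, 2, 3))
  t <- bspline_transform(g, 8)
  t$coefficients <- matrix(rnorm(length(t$coefficients), 0, 2), ncol = 3)
  ext <- grid_extent(g)
  pts <- cbind(runif(60, ext[1, 1], ext[2, 1]),
               runif(60, ext[1, 2], ext[2, 2]),
               runif(60, ext[1, 3], ext[2, 3]))
  expect_equal(transform_displacement(t, pts), bspline_oracle(t, pts),
               tolerance = 1e-10)
})

test_that("composition of translations adds and identity composes neutrally", {
  g <- image_grid(c(8, 8, 6), c(2, 2, 3))
  tr <- function(v) {
    t <- bspline_transform(g, 8)
    t$coefficients <- matrix(rep(v, each = nrow(t$coefficients)), ncol = 3)
    t
  }
  f12 <- compose_transforms(tr(c(1, 0, 2)), tr(c(0.5, 1, -1)), g)
  # exact in the interior; at the domain edge the inner translation maps
  # points beyond the outer lattice support (documented zero-outside rule)
  pts <- grid_points(g)
  ext <- grid_extent(g)
  inner_ok <- pts[, 1] + 0.5 <= ext[2, 1] & pts[, 2] + 1 <= ext[2, 2] &
    pts[, 3] - 1 >= ext[1, 3]
  v <- matrix(f12$vectors, ncol = 3)
  expect_lt(max(abs(sweep(v[inner_ok, ], 2, c(1.5, 1, 1)))), 1e-12)
  t <- tr(c(2, -1, 0.5))
  fid <- compose_transforms(t, displacement_field(g), g) # identity applied first
  expect_equal(pts + array(fid$vectors, c(prod(g$shape), 3)),
               transform_points(t, pts), tolerance = 1e-12)
})

test_that("field composition tracks exact functional composition of smooth warps", {
  set.seed(3)
  g <- image_grid(c(20, 20, 16), c(2, 2, 3))
  mk <- function() {
    t <- bspline_transform(g, 12)
    t$coefficients <- matrix(rnorm(length(t$coefficients), 0, 1.2), ncol = 3)
    t
  }
  A <- mk(); B <- mk()
  fAB <- compose_transforms(A, B, g) # materialized on the voxel lattice
  # exact oracle: functional composition evaluated at off-grid points
  ext <- grid_extent(g)
  pr <- cbind(runif(1000, ext[1, 1], ext[2, 1]),
              runif(1000, ext[1, 2], ext[2, 2]),
              runif(1000, ext[1, 3], ext[2, 3]))
  exact <- transform_points(A, transform_points(B, pr))
  viaField <- transform_points(fAB, pr) # trilinear resample of the field
  # discrepancy bounded by field curvature over one voxel
  expect_lt(max(abs(exact - viaField)), 0.5)
  expect_lt(mean(abs(exact - viaField)), 0.05)
  # associativity of materialized composition within the same tolerance
  C <- mk()
  left <- compose_transforms(compose_transforms(A, B, g), C, g)
  right <- compose_transforms(A, compose_transforms(B, C, g), g)
  expect_lt(max(abs(left$vectors - right$vectors)), 0.35)
})

test_that("chains of identities and translations collapse correctly", {
  g <- image_grid(c(8, 8, 6), c(2, 2, 3))
  id3 <- transform_chain(displacement_field(g), displacement_field(g),
                         displacement_field(g))
  expect_equal(id3$n_links, 2L)
  f <- compose_chain(id3, g)
  expect_true(all(f$vectors == 0))
  mkt <- function(v) displacement_field(g, array(rep(v, each = prod(g$shape)),
                                                 c(g$shape, 3)))
  ch <- transform_chain(mkt(c(1, 0, 0)), mkt(c(0, 2, 0)), mkt(c(0, 0, 3)))
  fc <- compose_chain(ch, g)
  pts <- grid_points(g)
  inner <- pts[pts[, 1] > 2 & pts[, 1] < 12 & pts[, 2] > 3 & pts[, 2] < 12 &
                 pts[, 3] > 3 & pts[, 3] < 12, ]
  expect_equal(transform_points(fc, inner), sweep(inner, 2, c(1, 2, 3), "+"),
               tolerance = 1e-12)
  expect_error(transform_chain(), "at least one")
})

test_that("warp_image reproduces the input under identity and matches a per-voxel oracle", {
  set.seed(5)
  g <- image_grid(c(10, 10, 8), c(2, 2, 3))
  img <- scalar_image(g, array(rnorm(prod(g$shape), 50, 20), g$shape))
  expect_equal(warp_image(img, displacement_field(g), g, "linear")$values,
               img$values)
  # whole-voxel translation shifts values in the interior
  tx <- displacement_field(g, array(rep(c(2, 0, 0), each = prod(g$shape)),
                                    c(g$shape, 3)))
  w <- warp_image(img, tx, g, "linear")
  expect_equal(w$values[1:9, , ], img$values[2:10, , ], tolerance = 1e-12)
  # random smooth warp vs direct per-voxel trilinear interpolation oracle
  t <- bspline_transform(g, 10)
  t$coefficients <- matrix(rnorm(length(t$coefficients), 0, 1), ncol = 3)
  wr <- warp_image(img, t, g, "linear")
  pts <- grid_points(g)
  mapped <- transform_points(t, pts)
  oracle <- apply(mapped, 1, function(p) {
    u <- pmin(pmax((p - g$origin) / g$spacing, 0), g$shape - 1)
    i0 <- pmin(floor(u), g$shape - 2); f <- u - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wgt <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      acc <- acc + wgt * img$values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  })
  expect_equal(as.vector(wr$values), oracle, tolerance = 1e-10)
})

test_that("warp_mask is exact for identity and whole-voxel shifts, and tracks volume under smooth warps", {
  set.seed(9)
  g <- image_grid(c(20, 20, 16), c(2, 2, 3))
  m <- sphere_mask(g, c(19, 19, 22), 10)
  expect_identical(warp_mask(m, displacement_field(g), g)$inside, m$inside)
  tx <- displacement_field(g, array(rep(c(2, 0, 0), each = prod(g$shape)),
                                    c(g$shape, 3)))
  w <- warp_mask(m, tx, g)
  expect_identical(w$inside[1:19, , ], m$inside[2:20, , ])
  # smooth warp: voxel count approximates the Jacobian-scaled volume
  t <- bspline_transform(g, 14)
  t$coefficients <- matrix(rnorm(length(t$coefficients), 0, 1.5), ncol = 3)
  wm <- warp_mask(m, t, g)
  pts <- grid_points(g)[as.vector(wm$inside), , drop = FALSE]
  jac <- vapply(seq_len(nrow(pts)), function(i) {
    J <- diag(3)
    for (a in 1:3) {
      e <- rep(0, 3); e[a] <- 0.5
      J[, a] <- J[, a] + as.vector(
        transform_displacement(t, matrix(pts[i, ] + e, 1)) -
          transform_displacement(t, matrix(pts[i, ] - e, 1)))
    }
    det(J)
  }, numeric(1))
  # pull-back: warped region volume ~ integral of |J| over the warped support
  expect_lt(abs(sum(jac) - mask_volume(m)) / mask_volume(m), 0.1)
})

test_that("composing independent noisy perturbations accumulates mapping error", {
  set.seed(21)
  g <- image_grid(c(16, 16, 12), c(2, 2, 3))
  pts <- grid_points(g)
  interior <- pts[pts[, 1] > 6 & pts[, 1] < 24 & pts[, 2] > 6 & pts[, 2] < 24 &
                    pts[, 3] > 6 & pts[, 3] < 27, ]
  rms <- vapply(1:5, function(n) {
    errs <- replicate(8, {
      ts <- lapply(seq_len(n), function(i) random_ffd(g, 1, 8, check_jacobian = FALSE))
      mapped <- transform_points(transform_chain(ts), interior)
      sqrt(mean(rowSums((mapped - interior)^2)))
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("composed-field mask warps agree with exact functional composition", {
  set.seed(13)
  g <- image_grid(c(20, 20, 16), c(2, 2, 3))
  m <- sphere_mask(g, c(19, 19, 22), 10)
  mk <- function() {
    t <- bspline_transform(g, 12)
    t$coefficients <- matrix(rnorm(length(t$coefficients), 0, 1), ncol = 3)
    t
  }
  A <- mk(); B <- mk()
  viaField <- warp_mask(m, compose_transforms(A, B, g), g)
  viaExact <- warp_mask(m, transform_chain(B, A), g) # chain evaluates exactly
  expect_gt(dsc(viaField, viaExact), 0.99)
})
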