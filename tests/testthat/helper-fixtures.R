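# Shared fixtures: small analytic shapes, random blobs, and a lazily built
# miniature atlas population reused across test files.

sphere_mask <- function(grid, center, radius) {
  pts <- grid_points(grid)
  inside <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2 <= radius^2
  binary_mask(grid, array(inside, grid$shape))
}

slab_mask <- function(grid, axis, lo, hi) {
  pts <- grid_points(grid)
  inside <- pts[, axis] >= lo & pts[, axis] <= hi
  binary_mask(grid, array(inside, grid$shape))
}

# random connected-ish blob: union of a few random spheres
random_blob <- function(grid, n_spheres = 3, r_range = c(2, 5)) {
  ext <- grid_extent(grid)
  acc <- array(FALSE, grid$shape)
  for (i in seq_len(n_spheres)) {
    c0 <- runif(3, ext["lo", ] + r_range[2], ext["hi", ] - r_range[2])
    acc <- acc | sphere_mask(grid, c0, runif(1, r_range[1], r_range[2]))$inside
  }
  binary_mask(grid, acc)
}

random_mask <- function(grid, p = 0.3) {
  binary_mask(grid, array(runif(prod(grid$shape)) < p, grid$shape))
}

# miniature phantom: 24x24x18 voxels at 2x2x3 mm (46x46x51 mm extent)
tiny_phantom_spec <- function(noise_sd = 3) {
  g <- image_grid(c(24, 24, 18), c(2, 2, 3))
  organs <- list(
    list(name = "gland_l", shape = "ellipsoid", center = c(14, 16, 18),
         radii = c(7, 8, 9), intensity = 70),
    list(name = "gland_r", shape = "ellipsoid", center = c(32, 16, 18),
         radii = c(7, 8, 9), intensity = 70),
    list(name = "cord", shape = "tube", center = c(23, 33, 25),
         radii = c(5, 5, 18), intensity = 40))
  phantom_spec(g, organs, background = 20, noise_sd = noise_sd)
}

# cached tiny population (3 subjects) shared across tests
.fixture_env <- new.env(parent = emptyenv())

tiny_population <- function() {
  if (is.null(.fixture_env$pop)) {
    template <- make_template(tiny_phantom_spec(), seed = 42)
    .fixture_env$pop <- make_population(
      template,
      population_spec(n_atlases = 3, deform_amplitude = 1.2,
                      error_amplitude = 1.5, seed = 42))
  }
  .fixture_env$pop
}

# brute-force 6-connected surface oracle (explicit neighbor scan)
surface_oracle <- function(inside) {
  d <- dim(inside)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!inside[i, j, k]) next
    nb <- c(
      if (i > 1) inside[i - 1, j, k] else FALSE,
      if (i < d[1]) inside[i + 1, j, k] else FALSE,
      if (j > 1) inside[i, j - 1, k] else FALSE,
      if (j < d[2]) inside[i, j + 1, k] else FALSE,
      if (k > 1) inside[i, j, k - 1] else FALSE,
      if (k < d[3]) inside[i, j, k + 1] else FALSE)
    out[i, j, k] <- any(!nb)
  }
  out
}

# brute-force min Euclidean distance (mm) from every voxel to a feature set
edt_oracle <- function(feature, grid) {
  pts <- grid_points(grid)
  fpts <- pts[as.vector(feature), , drop = FALSE]
  apply(pts, 1, function(p) sqrt(min(colSums((t(fpts) - p)^2))))
}

# naive per-point cubic B-spline expansion (independent of the C++ path)
bspline_oracle <- function(t, pts) {
  b3 <- function(u) {
    w <- numeric(4)
    w[1] <- (1 - u)^3 / 6
    w[2] <- (3 * u^3 - 6 * u^2 + 4) / 6
    w[3] <- (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6
    w[4] <- u^3 / 6
    w
  }
  sh <- t$ctrl_shape
  coef <- t$coefficients
  out <- matrix(0, nrow(pts), 3)
  for (p in seq_len(nrow(pts))) {
    u <- (pts[p, ] - t$ctrl_origin) / t$ctrl_spacing
    i0 <- floor(u)
    wx <- b3(u[1] - i0[1]); wy <- b3(u[2] - i0[2]); wz <- b3(u[3] - i0[3])
    acc <- c(0, 0, 0)
    for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
      ix <- i0[1] - 1 + a; iy <- i0[2] - 1 + b; iz <- i0[3] - 1 + cc
      if (ix < 0 || ix >= sh[1] || iy < 0 || iy >= sh[2] || iz < 0 || iz >= sh[3])
        next
      lin <- 1 + ix + sh[1] * (iy + sh[2] * iz)
      acc <- acc + wx[a + 1] * wy[b + 1] * wz[cc + 1] * coef[lin, ]
    }
    out[p, ] <- acc
  }
  out
}

# cached standard study population (seed 1) and its experiment tables,
# shared by the acceptance-level tests
standard_fixture <- function() {
  if (is.null(.fixture_env$std)) {
    pop <- standard_population(seed = 1)
    .fixture_env$std <- list(pop = pop,
                             provider = population_transform_provider(pop))
  }
  .fixture_env$std
}

standard_experiment <- function() {
  if (is.null(.fixture_env$std_tab)) {
    fx <- standard_fixture()
    .fixture_env$std_tab <- run_experiment(
      fx$pop$atlases, fx$provider, links = 0:4,
      n_samples = c(120, 30, 30, 30), seed = 1)
  }
  .fixture_env$std_tab
}
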