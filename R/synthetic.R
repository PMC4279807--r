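#' Phantom specification
#'
#' Describes a CT-like head-and-neck phantom: a raster grid plus a list of
#' organs, each a geometric primitive (`ellipsoid`, `tube` or `arc`) with a
#' center, radii and intensity. The default organ set mirrors a
#' head-and-neck structure set: paired gland-like ellipsoids (parotid and
#' submandibular analogues), a mandible-like arc, a medulla-like tube and
#' two slab-like nodal levels.
#'
#' Shapes (all sizes in mm, world coordinates):
#' * `ellipsoid`: semi-axes `radii[1:3]` about `center`.
#' * `tube`: elliptical cylinder along z, cross-section radii `radii[1:2]`,
#'   half-length `radii[3]`.
#' * `arc`: a torus section in the `z = center[3]` plane with major radius
#'   `radii[1]` and tube radius `radii[2]`, restricted to polar angles
#'   (degrees, about the center) in `angles`.
#'
#' @param grid [image_grid()], default 64 x 64 x 48 voxels at 2 x 2 x 3 mm.
#' @param organs list of organs, each `list(name, shape, center, radii,
#'   intensity, angles = NULL)`; `NULL` selects the default set.
#' @param background background intensity (arbitrary CT-like units).
#' @param noise_sd additive Gaussian intensity noise (image only; labels are
#'   noise-free).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = image_grid(c(64, 64, 48), c(2, 2, 3)),
                         organs = NULL, background = 20, noise_sd = 5) {
  if (is.null(organs)) organs <- default_organs()
  for (o in organs) {
    stopifnot(all(c("name", "shape", "center", "radii", "intensity") %in% names(o)))
    if (any(o$radii <= 0)) stop(sprintf("organ %s has non-positive radii", o$name))
    ext <- grid_extent(grid)
    r <- switch(o$shape,
                ellipsoid = o$radii[1:3],
                tube = c(o$radii[1:2], o$radii[3]),
                arc = rep(o$radii[1] + o$radii[2], 3),
                stop(sprintf("unknown organ shape '%s'", o$shape)))
    if (any(o$center - r < ext["lo", ]) || any(o$center + r > ext["hi", ]))
      stop(sprintf("organ %s extends outside the grid", o$name))
  }
  structure(list(grid = grid, organs = organs, background = background,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

default_organs <- function() {
  list(
    list(name = "parotid_l", shape = "ellipsoid", center = c(32, 64, 96),
         radii = c(10, 12, 15), intensity = 60),
    list(name = "parotid_r", shape = "ellipsoid", center = c(94, 64, 96),
         radii = c(10, 12, 15), intensity = 60),
    list(name = "submandibular_l", shape = "ellipsoid", center = c(45, 48, 54),
         radii = c(8, 8, 9), intensity = 70),
    list(name = "submandibular_r", shape = "ellipsoid", center = c(81, 48, 54),
         radii = c(8, 8, 9), intensity = 70),
    list(name = "mandible", shape = "arc", center = c(63, 58, 72),
         radii = c(28, 6), intensity = 400, angles = c(180, 360)),
    list(name = "medulla", shape = "tube", center = c(63, 88, 70),
         radii = c(6, 6, 55), intensity = 40),
    list(name = "node_level_l", shape = "ellipsoid", center = c(36, 84, 72),
         radii = c(10, 14, 28), intensity = 50),
    list(name = "node_level_r", shape = "ellipsoid", center = c(90, 84, 72),
         radii = c(10, 14, 28), intensity = 50))
}

rasterize_organ <- function(o, X, Y, Z) {
  if (o$shape == "ellipsoid") {
    ((X - o$center[1]) / o$radii[1])^2 + ((Y - o$center[2]) / o$radii[2])^2 +
      ((Z - o$center[3]) / o$radii[3])^2 <= 1
  } else if (o$shape == "tube") {
    (((X - o$center[1]) / o$radii[1])^2 + ((Y - o$center[2]) / o$radii[2])^2 <= 1) &
      abs(Z - o$center[3]) <= o$radii[3]
  } else { # arc
    rr <- sqrt((X - o$center[1])^2 + (Y - o$center[2])^2)
    ang <- atan2(Y - o$center[2], X - o$center[1]) * 180 / pi
    ang <- (ang + 360) %% 360
    a <- o$angles %||% c(0, 360)
    inside_ang <- if (a[1] <= a[2]) ang >= a[1] & ang <= a[2]
                  else ang >= a[1] | ang <= a[2]
    ((rr - o$radii[1])^2 + (Z - o$center[3])^2 <= o$radii[2]^2) & inside_ang
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a phantom template
#'
#' Builds the template intensity image (organs over background, additive
#' Gaussian noise) and its noise-free label map. Deterministic per seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the intensity noise.
#' @return List with `image` ([scalar_image()]) and `labels` ([label_map()]).
#' @export
make_template <- function(spec = phantom_spec(), seed = 1) {
  g <- spec$grid
  pts <- grid_points(g)
  X <- array(pts[, 1], g$shape)
  Y <- array(pts[, 2], g$shape)
  Z <- array(pts[, 3], g$shape)
  img <- array(spec$background, g$shape)
  lab <- array(0L, g$shape)
  nm <- character(0)
  for (i in seq_along(spec$organs)) {
    o <- spec$organs[[i]]
    sel <- rasterize_organ(o, X, Y, Z)
    img[sel] <- o$intensity
    lab[sel] <- i
    nm[as.character(i)] <- o$name
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), g$shape)
  list(image = scalar_image(g, img), labels = label_map(g, lab, nm))
}

# RMS displacement magnitude of iid unit-sd cubic B-spline coefficients,
# estimated on a coarse point sample; used to scale coefficients to a target
# field amplitude
ffd_unit_rms <- function(t0, npts = 2000) {
  ext <- grid_extent(t0$domain)
  u <- matrix(stats::runif(3 * npts), ncol = 3)
  pts <- sweep(sweep(u, 2, ext["hi", ] - ext["lo", ], "*"), 2, ext["lo", ], "+")
  d <- transform_displacement(t0, pts)
  sqrt(mean(rowSums(d^2)))
}

#' Random smooth free-form deformation
#'
#' Draws iid Normal B-spline coefficients and rescales them so the
#' displacement field has the requested RMS magnitude over the domain.
#' Optionally rejects and regenerates fields whose numerical Jacobian
#' determinant is not safely positive on a sample grid (folding), so the
#' field is invertible in practice.
#'
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param domain [image_grid()].
#' @param amplitude target RMS displacement magnitude in mm (0 gives the
#'   identity).
#' @param control_spacing lattice spacing in mm.
#' @param check_jacobian reject folding fields and regenerate.
#' @param max_tries regeneration attempts before failing.
#' @return A [bspline_transform()].
#' @export
random_ffd <- function(domain, amplitude, control_spacing = 8,
                       check_jacobian = TRUE, max_tries = 25) {
  t0 <- bspline_transform(domain, control_spacing)
  if (amplitude == 0) return(t0)
  n_ctrl <- nrow(t0$coefficients)
  for (try in seq_len(max_tries)) {
    coefs <- matrix(stats::rnorm(n_ctrl * 3), n_ctrl, 3)
    t1 <- bspline_transform(domain, control_spacing, coefs)
    scale <- amplitude / ffd_unit_rms(t1)
    t1$coefficients <- t1$coefficients * scale
    if (!check_jacobian || min_jacobian(t1) > 0.05) return(t1)
  }
  stop("could not generate an invertible deformation; lower the amplitude")
}

# minimum numerical Jacobian determinant of x -> x + d(x) on a coarse sample
min_jacobian <- function(t, step = 1, n_side = 12) {
  ext <- grid_extent(t$domain)
  ax <- lapply(1:3, function(a) seq(ext["lo", a], ext["hi", a], length.out = n_side))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  J <- array(0, c(nrow(pts), 3, 3))
  for (a in 1:3) {
    e <- rep(0, 3); e[a] <- step
    dp <- transform_displacement(t, sweep(pts, 2, e, "+"))
    dm <- transform_displacement(t, sweep(pts, 2, e, "-"))
    J[, , a] <- (dp - dm) / (2 * step)
    J[, a, a] <- J[, a, a] + 1
  }
  dets <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
          J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
          J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  min(dets)
}

# numerically invert a transform: dense field g on `grid` with
# x + g(x) ~ t^{-1}(x), by fixed-point iteration g <- -d(x + g)
invert_transform <- function(t, grid, tol = 0.01, max_iter = 60) {
  pts <- grid_points(grid)
  g <- -transform_displacement(t, pts)
  for (it in seq_len(max_iter)) {
    gnew <- -transform_displacement(t, pts + g)
    delta <- max(abs(gnew - g))
    g <- gnew
    if (delta < tol) break
  }
  displacement_field(grid, array(g, c(grid$shape, 3L)))
}

#' Population specification
#'
#' Parameters of the synthetic atlas population: the number of subjects, the
#' amplitude and smoothness of the inter-subject deformations relating each
#' subject to the template, and the amplitude of the random error fields that
#' corrupt the otherwise exact pairwise registrations.
#'
#' @param n_atlases number of subjects, `>= 2`.
#' @param deform_amplitude inter-subject deformation RMS magnitude (mm).
#' @param control_spacing B-spline lattice spacing (mm) for both
#'   deformations and error fields.
#' @param error_amplitude registration-error RMS magnitude (mm).
#' @param seed integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_atlases = 6, deform_amplitude = 1.5,
                            control_spacing = 8, error_amplitude = 2,
                            seed = 1) {
  stopifnot(n_atlases >= 2, deform_amplitude >= 0, error_amplitude >= 0,
            control_spacing > 0)
  structure(list(n_atlases = n_atlases, deform_amplitude = deform_amplitude,
                 control_spacing = control_spacing,
                 error_amplitude = error_amplitude, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic atlas population
#'
#' Each subject is the template warped by a random smooth B-spline
#' deformation `H_i` (pull-back: subject intensities are template
#' intensities sampled at `H_i(x)`), with labels warped consistently by
#' nearest neighbor. The generating transforms are retained as ground truth
#' together with their numerically inverted dense fields, from which exact
#' pairwise registrations can be composed.
#'
#' @param template list with `image` and `labels` from [make_template()].
#' @param pop a [population_spec()].
#' @return List of class `atlas_population`: elements `atlases` (each
#'   `list(image, labels, to_template, from_template)`), `grid`, `spec`.
#' @export
make_population <- function(template, pop = population_spec()) {
  g <- template$labels$grid
  old <- .Random.seed_exists()
  set.seed(pop$seed)
  on.exit(.restore_seed(old), add = TRUE)
  atlases <- vector("list", pop$n_atlases)
  for (i in seq_len(pop$n_atlases)) {
    H <- random_ffd(g, pop$deform_amplitude, pop$control_spacing)
    atlases[[i]] <- list(
      image = warp_image(template$image, H, g, "linear"),
      labels = warp_labels(template$labels, H, g),
      to_template = H,
      from_template = if (pop$deform_amplitude > 0) invert_transform(H, g)
                      else displacement_field(g))
  }
  structure(list(atlases = atlases, grid = g, spec = pop),
            class = "atlas_population")
}

#' Synthetic pairwise registration transform
#'
#' The exact transform mapping fixed-atlas coordinates to moving-atlas
#' coordinates (composed through the template frame from the ground-truth
#' generating deformations), optionally corrupted by an independent random
#' smooth error field of given RMS magnitude applied in the fixed frame.
#' Error fields are independent across ordered pairs and deterministic per
#' `(seed, fixed, moving)`.
#'
#' @param population an `atlas_population` from [make_population()].
#' @param fixed,moving atlas indices (distinct).
#' @param error_amplitude RMS error magnitude (mm); `NULL` uses the
#'   population spec value, 0 gives the exact transform.
#' @param seed base seed; `NULL` uses the population spec seed.
#' @return A [displacement_field()] on the population grid.
#' @export
make_pairwise_transform <- function(population, fixed, moving,
                                    error_amplitude = NULL, seed = NULL) {
  stopifnot(inherits(population, "atlas_population"), fixed != moving)
  err <- error_amplitude %||% population$spec$error_amplitude
  seed <- seed %||% population$spec$seed
  g <- population$grid
  exact <- compose_transforms(population$atlases[[moving]]$from_template,
                              population$atlases[[fixed]]$to_template, g)
  if (err == 0) return(exact)
  old <- .Random.seed_exists()
  set.seed((seed * 1009L + fixed * 131071L + moving * 524287L) %% 2147483647L)
  on.exit(.restore_seed(old), add = TRUE)
  E <- random_ffd(g, err, population$spec$control_spacing,
                  check_jacobian = FALSE)
  # perturb the fixed-frame sampling points, then apply the exact map
  compose_transforms(exact, E, g)
}

#' Transform provider for [run_experiment()]
#'
#' Returns a closure `function(fixed, moving)` materializing (and caching)
#' the synthetic pairwise transform for each ordered atlas pair.
#'
#' @param population an `atlas_population`.
#' @param error_amplitude,seed forwarded to [make_pairwise_transform()].
#' @return A function usable as `transform_provider`.
#' @export
population_transform_provider <- function(population, error_amplitude = NULL,
                                          seed = NULL) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(fixed, moving) {
    key <- paste0(fixed, "_", moving)
    if (is.null(cache[[key]]))
      cache[[key]] <- make_pairwise_transform(population, fixed, moving,
                                              error_amplitude, seed)
    cache[[key]]
  }
}

#' Simulate a (similarity, quality) sample from the linear weighting model
#'
#' Draws similarities uniformly on `sim_range` and qualities from
#' `DSC = intercept + k * SIM + eps`, `eps ~ Normal(0, s^2)`, the generative
#' model underlying the regression parameterization of the fusion weights.
#' Qualities are clipped to \[0, 1\]; the number of clipped values is
#' attached as attribute `n_clipped` and reported via a message.
#'
#' @param n sample size, `>= 2`.
#' @param k true slope.
#' @param s residual standard deviation, `>= 0`.
#' @param seed integer seed.
#' @param intercept intercept of the linear model.
#' @param sim_range interval for the uniform similarity draw.
#' @return Data frame with columns `sim` and `dsc`.
#' @export
simulate_sim_dsc <- function(n, k, s, seed = 1, intercept = 0.2,
                             sim_range = c(0.2, 0.8)) {
  stopifnot(n >= 2, s >= 0)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  sim <- stats::runif(n, sim_range[1], sim_range[2])
  d <- intercept + k * sim + stats::rnorm(n, 0, s)
  n_clipped <- sum(d < 0 | d > 1)
  if (n_clipped > 0)
    message(sprintf("%d of %d simulated DSC values clipped to [0, 1]",
                    n_clipped, n))
  out <- data.frame(sim = sim, dsc = pmin(pmax(d, 0), 1))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' The standard synthetic study population
#'
#' Convenience constructor of the default experimental conditions: a
#' 64 x 64 x 48 phantom at 2 x 2 x 3 mm voxels, six subjects, and 2 mm RMS
#' registration error.
#'
#' @param seed integer seed.
#' @param n_atlases number of subjects.
#' @param error_amplitude registration-error RMS magnitude (mm).
#' @return An `atlas_population`.
#' @export
standard_population <- function(seed = 1, n_atlases = 6, error_amplitude = 2) {
  template <- make_template(phantom_spec(), seed = seed)
  make_population(template,
                  population_spec(n_atlases = n_atlases,
                                  error_amplitude = error_amplitude,
                                  seed = seed))
}
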