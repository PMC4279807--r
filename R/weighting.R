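#' Structure-local similarity region from a signed distance map
#'
#' The cut-off region contains every voxel whose signed distance to the
#' structure border is at most `r` mm: the structure interior plus an outer
#' margin of width `r`. With `r = 0` the region is exactly the structure
#' (interior plus border). Sharp-boundary structures (mandible-like) are well
#' served by `r = 0`; softer structures typically benefit from a band of
#' about 10 mm.
#'
#' @param structure_map a `signed_distance_map` (see [signed_distance()]).
#' @param r band radius in mm, `>= 0`.
#' @return A [binary_mask()] of the region.
#' @export
band_region <- function(structure_map, r) {
  stopifnot(inherits(structure_map, "signed_distance_map"), r >= 0)
  binary_mask(structure_map$grid, structure_map$values <= r)
}

#' Normalized cross correlation over a region
#'
#' Pearson-type similarity between two images restricted to a voxel region,
#' with means taken over the region: invariant to affine intensity rescaling
#' and bounded in \[-1, 1\].
#'
#' @param f,m [scalar_image()] objects on the region's grid.
#' @param region [binary_mask()] with at least 2 voxels.
#' @return NCC value in \[-1, 1\].
#' @export
ncc <- function(f, m, region) {
  stopifnot(inherits(f, "scalar_image"), inherits(m, "scalar_image"),
            inherits(region, "binary_mask"))
  stop_if_grid_mismatch(f$grid, region$grid, "image and region")
  stop_if_grid_mismatch(m$grid, region$grid, "image and region")
  sel <- region$inside
  if (sum(sel) < 2) stop("region must contain at least 2 voxels")
  x <- f$values[sel]
  y <- m$values[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("NCC undefined: zero intensity variance over the region")
  stats::cor(x, y)
}

#' Probabilistic fusion weight from a similarity deficit
#'
#' Maps the gap between an atlas's similarity and the best similarity in the
#' set to a fusion weight,
#' `w_i = (1 - erf(k_over_s / sqrt(2) * (sim_best - sim_i))) / 2`,
#' i.e. the upper standard-normal tail probability at `k_over_s * gap`. The
#' best atlas always receives 0.5; weights decrease strictly with the gap
#' when `k_over_s > 0`, and `k_over_s = 0` gives every atlas 0.5 (equal
#' weighting).
#'
#' @param sim_i similarity of the atlas (vectorized).
#' @param sim_best maximum similarity over all atlases; must be `>= sim_i`.
#' @param k_over_s non-negative control ratio: the slope of the
#'   similarity-to-quality regression divided by the residual spread.
#' @return Weight(s) in (0, 0.5].
#' @examples
#' probabilistic_weight(0.8, 0.9, 10)  # pnorm(-1) ~ 0.1587
#' @export
probabilistic_weight <- function(sim_i, sim_best, k_over_s) {
  if (k_over_s < 0) stop("k_over_s must be non-negative")
  if (any(sim_best < sim_i - 1e-12))
    stop("sim_best must be the maximum similarity")
  gap <- pmax(sim_best - sim_i, 0)
  stats::pnorm(-k_over_s * gap)
}

#' Control ratio k/s from a regression-slope angle
#'
#' Parameterizes the weight control ratio by the angle `theta` (degrees) of a
#' line through a (similarity, quality) sample: with slope `tan(theta)`, the
#' residual spread about the best-intercept line of that slope is
#' `sqrt((ss_yy + ss_xx tan^2(theta) - 2 ss_xy tan(theta)) / N)`, and
#' `k/s = sqrt(N) tan(theta) / sqrt(ss_yy + ss_xx tan^2(theta) - 2 ss_xy tan(theta))`
#' where `x` is the similarity (SIM), `y` the quality score (DSC) and the
#' `ss` terms are centered sums of squares/products over the sample of size
#' `N`. At the ordinary-least-squares angle this equals the fitted slope
#' divided by the residual standard deviation.
#'
#' @param theta angle in degrees, within (-90, 90).
#' @param sims numeric vector of similarity values.
#' @param dscs numeric vector of quality values, same length (`N >= 2`).
#' @return The ratio `k/s` (same sign as `tan(theta)`).
#' @export
k_over_s_from_theta <- function(theta, sims, dscs) {
  if (abs(theta) >= 90) stop("theta must lie within (-90, 90) degrees")
  n <- length(sims)
  if (n < 2 || length(dscs) != n)
    stop("sims and dscs must have equal length >= 2")
  ss_xx <- sum((sims - mean(sims))^2)
  ss_yy <- sum((dscs - mean(dscs))^2)
  ss_xy <- sum((sims - mean(sims)) * (dscs - mean(dscs)))
  tt <- tan(theta * pi / 180)
  rad <- ss_yy + ss_xx * tt^2 - 2 * ss_xy * tt
  if (rad <= 0) stop("degenerate sample: non-positive residual sum of squares")
  sqrt(n) * tt / sqrt(rad)
}

#' Per-case fusion weights from similarity records
#'
#' @param sims numeric vector of per-atlas similarities for one case.
#' @param k_over_s control ratio; a negative ratio inverts the preference
#'   (up-weights less similar atlases), which the calibration sweep explores
#'   through negative angles.
#' @return Weights in (0, 1), the maximum-similarity atlas(es) at 0.5.
#' @export
fusion_weights <- function(sims, k_over_s) {
  stats::pnorm(-k_over_s * (max(sims) - sims))
}

#' Rank candidate intermediate atlases by similarity
#'
#' Orders candidates by decreasing similarity (ties broken by atlas id), the
#' strategy of picking the intermediate (hub) atlas after a fast global
#' registration: more similar images make better hubs.
#'
#' @param sims data frame with columns `atlas` and `sim` (one row per
#'   candidate), or a named numeric vector of similarities.
#' @return Atlas ids in decreasing-similarity order.
#' @export
rank_intermediates <- function(sims) {
  if (is.data.frame(sims)) {
    ids <- sims$atlas
    s <- sims$sim
  } else {
    ids <- names(sims)
    if (is.null(ids)) ids <- seq_along(sims)
    s <- as.numeric(sims)
  }
  ids[order(-s, ids)]
}

#' Calibrate the weight control ratio by a theta sweep
#'
#' For each angle in `theta_grid`, computes `k/s` from the pooled
#' (similarity, quality) sample of the supplied leave-one-out cases, derives
#' per-case weights, fuses each case's atlas masks by weighted
#' signed-distance averaging, scores the consensus against the case's
#' reference mask with DSC, and averages over cases. Returns the full sweep
#' curve and the best angle; since `theta = 0` (equal weighting) is usually
#' in the grid, the optimum can only match or beat equal weights on the
#' calibration cases.
#'
#' Each case is a list with elements `reference` (a [binary_mask()]),
#' `masks` (list of per-atlas [binary_mask()]) and `sims` (numeric vector of
#' per-atlas similarities). The pooled regression sample pairs each atlas
#' mask's individual DSC against the reference with its similarity.
#'
#' @param cases list of cases as described above.
#' @param theta_grid angles in degrees, default -89..89 in 1 degree steps.
#' @return A list of class `weight_calibration` with elements `curve` (data
#'   frame: `theta`, `k_over_s`, `mean_dsc`), `best_theta`, `best_k_over_s`,
#'   `best_mean_dsc`.
#' @export
calibrate_weights <- function(cases, theta_grid = seq(-89, 89, by = 1)) {
  if (length(theta_grid) < 1) stop("theta_grid must be nonempty")
  if (length(cases) < 1) stop("at least one case is required")
  # pooled (SIM, DSC) sample over all cases and atlases
  sims <- numeric(0)
  dscs <- numeric(0)
  case_maps <- vector("list", length(cases))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    nonempty <- vapply(cs$masks, function(m) any(m$inside), logical(1))
    if (!any(nonempty)) stop(sprintf("case %d has no nonempty atlas masks", ci))
    ds <- vapply(cs$masks[nonempty], function(m) dsc(m, cs$reference), numeric(1))
    sims <- c(sims, cs$sims[nonempty])
    dscs <- c(dscs, ds)
    case_maps[[ci]] <- list(maps = lapply(cs$masks[nonempty], signed_distance),
                            sims = cs$sims[nonempty],
                            reference = cs$reference)
  }
  curve <- data.frame(theta = theta_grid, k_over_s = NA_real_,
                      mean_dsc = NA_real_)
  for (ti in seq_along(theta_grid)) {
    # a single pooled observation cannot define a regression line; the
    # weights then cancel in the fusion anyway
    ks <- if (length(sims) < 2) 0 else
      k_over_s_from_theta(theta_grid[ti], sims, dscs)
    vals <- vapply(case_maps, function(cm) {
      w <- fusion_weights(cm$sims, ks)
      fused <- extract_segmentation(fuse_distance_maps(cm$maps, w))
      dsc(fused, cm$reference)
    }, numeric(1))
    curve$k_over_s[ti] <- ks
    curve$mean_dsc[ti] <- mean(vals)
  }
  best <- which.max(curve$mean_dsc)
  structure(list(curve = curve,
                 best_theta = curve$theta[best],
                 best_k_over_s = curve$k_over_s[best],
                 best_mean_dsc = curve$mean_dsc[best]),
            class = "weight_calibration")
}

#' Structure-local similarity of a registered atlas
#'
#' Convenience wrapper computing the NCC between the fixed image and a
#' registered atlas image over the band region of the atlas's warped
#' structure, everything expressed on the fixed grid.
#'
#' @param fixed [scalar_image()] (the target/fixed image).
#' @param registered [scalar_image()] (atlas image warped to the fixed grid).
#' @param warped_mask [binary_mask()] (atlas structure warped to the fixed
#'   grid); must be nonempty.
#' @param r band radius in mm.
#' @return NCC value.
#' @export
structure_similarity <- function(fixed, registered, warped_mask, r = 10) {
  region <- band_region(signed_distance(warped_mask), r)
  ncc(fixed, registered, region)
}
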