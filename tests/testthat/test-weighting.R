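test_that("band regions grow the structure by the cut-off radius", {
  g <- image_grid(c(32, 32, 32), c(1.5, 1.5, 1.5))
  c0 <- c(23.25, 23.25, 23.25)
  s <- sphere_mask(g, c0, 10)
  d <- signed_distance(s)
  expect_identical(band_region(d, 0)$inside, s$inside) # r = 0: the object itself
  grown <- band_region(d, 10)
  vol_r <- (3 * mask_volume(grown) * prod(g$spacing) / (4 * pi))^(1 / 3)
  expect_lt(abs(vol_r - 20), 2)
  expect_true(all(band_region(d, 1e6)$inside)) # r -> infinity: whole image
  expect_error(band_region(d, -1))
})

test_that("NCC is affine-invariant and detects anticorrelation", {
  set.seed(51)
  g <- image_grid(c(8, 8, 6), c(2, 2, 3))
  f <- scalar_image(g, array(rnorm(prod(g$shape), 100, 30), g$shape))
  region <- random_mask(g, 0.5)
  expect_equal(ncc(f, f, region), 1)
  m2 <- scalar_image(g, 3.7 * f$values + 12)
  expect_equal(ncc(f, m2, region), 1, tolerance = 1e-10)
  m3 <- scalar_image(g, -f$values)
  expect_equal(ncc(f, m3, region), -1, tolerance = 1e-10)
  flat <- scalar_image(g, array(5, g$shape))
  expect_error(ncc(f, flat, region), "variance")
  # independent oracle: the explicit normalized cross-correlation sums
  m4 <- scalar_image(g, array(rnorm(prod(g$shape), 80, 25), g$shape))
  x <- f$values[region$inside]; y <- m4$values[region$inside]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ncc(f, m4, region), oracle, tolerance = 1e-12)
})

test_that("probabilistic weights honor the error-function form", {
  expect_equal(probabilistic_weight(0.7, 0.7, 5), 0.5)
  expect_equal(probabilistic_weight(0.2, 0.9, 0), 0.5) # k/s = 0: equal weights
  expect_equal(probabilistic_weight(0.8, 0.9, 10), pnorm(-1)) # ~0.1587
  # strict monotone decrease in the similarity gap
  gaps <- seq(0, 0.5, by = 0.05)
  w <- probabilistic_weight(0.9 - gaps, 0.9, 8)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 0.5))
  expect_error(probabilistic_weight(0.95, 0.9, 5), "maximum")
  expect_error(probabilistic_weight(0.5, 0.9, -1), "non-negative")
  # series-expansion oracle for the underlying error function
  erf_series <- function(x) {
    k <- 0:60
    2 / sqrt(pi) * sum((-1)^k * x^(2 * k + 1) / (factorial(k) * (2 * k + 1)))
  }
  for (x in seq(0.05, 2, length.out = 20)) {
    w_pkg <- probabilistic_weight(0, x * sqrt(2), 1) # gap*k/s = x*sqrt(2)
    expect_equal(w_pkg, 0.5 * (1 - erf_series(x)), tolerance = 1e-12)
  }
})

test_that("the theta parameterization reduces to slope over residual spread", {
  set.seed(53)
  sims <- runif(40, 0.3, 0.9)
  dscs <- 0.2 + 0.6 * sims + rnorm(40, 0, 0.05)
  expect_equal(k_over_s_from_theta(0, sims, dscs), 0)
  # theta -> 90 limit: sqrt(N / ss_xx)
  lim <- sqrt(length(sims) / sum((sims - mean(sims))^2))
  expect_equal(k_over_s_from_theta(89, sims, dscs), lim, tolerance = 0.02)
  expect_equal(k_over_s_from_theta(-89, sims, dscs), -lim, tolerance = 0.02)
  # at the OLS angle the ratio equals fitted slope / residual sd (N denominator)
  sm <- simulate_sim_dsc(500, 0.6, 0.08, seed = 5, intercept = 0.1,
                         sim_range = c(0.3, 0.9))
  fit <- lm(dsc ~ sim, data = sm)
  slope <- unname(coef(fit)["sim"])
  s_hat <- sqrt(sum(residuals(fit)^2) / nrow(sm))
  theta_hat <- atan(slope) * 180 / pi
  expect_equal(k_over_s_from_theta(theta_hat, sm$sim, sm$dsc), slope / s_hat,
               tolerance = 0.01)
  expect_error(k_over_s_from_theta(90, sims, dscs), "within")
  expect_error(k_over_s_from_theta(10, c(1, 1), c(0.5, 0.5)), "degenerate")
})

test_that("k/s estimated by regression recovers the generating ratio", {
  set.seed(59)
  k_true <- 0.5; s_true <- 0.05
  est <- replicate(100, {
    sm <- simulate_sim_dsc(1000, k_true, s_true, seed = sample.int(1e6, 1),
                           intercept = 0.25, sim_range = c(0.3, 0.9))
    fit <- lm(dsc ~ sim, data = sm)
    unname(coef(fit)["sim"]) / sqrt(sum(residuals(fit)^2) / nrow(sm))
  })
  expect_lt(abs(mean(est) / (k_true / s_true) - 1), 0.05)
})

test_that("intermediate ranking sorts by similarity with id tie-breaks", {
  df <- data.frame(atlas = c(1, 2, 3), sim = c(0.9, 0.7, 0.8))
  expect_equal(rank_intermediates(df), c(1, 3, 2))
  ties <- data.frame(atlas = c(3, 1, 2), sim = c(0.5, 0.5, 0.5))
  expect_equal(rank_intermediates(ties), c(1, 2, 3))
  set.seed(61)
  for (rep in 1:20) {
    s <- runif(6)
    df <- data.frame(atlas = 1:6, sim = s)
    expect_equal(rank_intermediates(df), order(-s))
  }
})

test_that("calibration rewards informative similarity and is flat when it cannot help", {
  g <- image_grid(c(20, 20, 20), c(2, 2, 2))
  c0 <- c(19, 19, 19)
  ref <- sphere_mask(g, c0, 10)
  good1 <- sphere_mask(g, c0, 9.5)
  good2 <- sphere_mask(g, c0 + c(1, 0, 0), 10)
  bad <- sphere_mask(g, c0 + c(10, 4, 0), 8)
  # similarity ranks exactly as quality does: one clearly bad atlas
  cases <- list(list(reference = ref, masks = list(good1, good2, bad),
                     sims = c(0.95, 0.9, 0.3)))
  cal <- calibrate_weights(cases, theta_grid = seq(-80, 80, by = 10))
  eq <- cal$curve$mean_dsc[cal$curve$theta == 0]
  expect_gte(cal$best_mean_dsc, eq)
  expect_gt(cal$best_k_over_s, 0)
  # a single atlas: weights cancel in the fusion, the sweep is flat
  cases1 <- list(list(reference = ref, masks = list(good2), sims = 0.8))
  cal1 <- calibrate_weights(cases1, theta_grid = c(-45, 0, 45))
  expect_equal(diff(range(cal1$curve$mean_dsc)), 0)
})

test_that("similarity unrelated to quality gives no calibration gain beyond noise", {
  set.seed(67)
  g <- image_grid(c(16, 16, 16), c(2, 2, 2))
  c0 <- c(15, 15, 15)
  ref <- sphere_mask(g, c0, 9)
  cases <- lapply(1:6, function(i) {
    masks <- lapply(1:4, function(j)
      sphere_mask(g, c0 + rnorm(3, 0, 1.5), 9 + rnorm(1, 0, 0.8)))
    list(reference = ref, masks = masks, sims = runif(4, 0.4, 0.9)) # independent
  })
  cal <- calibrate_weights(cases, theta_grid = seq(-60, 60, by = 15))
  eq <- cal$curve$mean_dsc[cal$curve$theta == 0]
  expect_lt(cal$best_mean_dsc - eq, 0.02)
})
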