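# Oracle tolerances: extremum depths must match the analytic oracle within
# one sample step. Inflection-derived thicknesses additionally absorb the
# moving-quadratic smoothing bias, which the second oracle quantifies by
# applying the same-width smoother to the analytic function on a fine grid.

smoothed_oracle <- function(f, width, L = 10, step = 1e-3) {
  g <- function(d) {
    vapply(d, function(x) {
      lo <- max(0, x - width / 2); hi <- min(L, x + width / 2)
      xs <- seq(lo, hi, length.out = 51)
      cf <- stats::lm.fit(cbind(1, xs - x, (xs - x)^2), f(xs))$coefficients
      cf[[1]]
    }, numeric(1))
  }
  profile_landmark_oracle(g, L = L, step = step)
}

test_that("landmarks on the two-Gaussian profile match the numerical oracle", {
  cfg <- morphometry_config()
  d <- seq(0, 10, by = cfg$sample_step)
  res <- locate_landmarks(as_average_profile(d, gaussmix_profile(d)), cfg)

  oracle <- profile_landmark_oracle(gaussmix_profile)
  expect_lt(abs(res$ps_depth - oracle$ps_depth), cfg$sample_step)
  expect_lt(abs(res$ss_depth - oracle$ss_depth), cfg$sample_step)
  expect_lt(res$ps_value, res$ss_value)
  # dip inflections sit near center +/- sigma (shifted slightly by the
  # overlapping bump): width 2 * 0.4 mm within one sample step
  expect_lt(abs(oracle$ps_thickness - 0.8), cfg$sample_step)

  sm <- smoothed_oracle(gaussmix_profile, cfg$smoothing_window)
  expect_lt(abs(res$ps_thickness - sm$ps_thickness), cfg$sample_step)
  expect_lt(abs(res$ss_thickness - sm$ss_thickness), 2 * cfg$sample_step)
  expect_equal(res$total_thickness, res$ps_thickness + res$ss_thickness)
})

test_that("degenerate profiles raise landmark errors naming the landmark", {
  cfg <- morphometry_config()
  d <- seq(0, 10, by = cfg$sample_step)
  expect_error(locate_landmarks(as_average_profile(d, 100 - 3 * d), cfg),
               "primary spongiosa minimum")
  # dip with no subsequent maximum: monotone rise to a plateau below start
  v <- 90 - 30 * exp(-(d - 2)^2 / (2 * 0.5^2))
  v[d > 2] <- 90 - 30 * exp(-(d[d > 2] - 2)^2 / (2 * 4^2))
  expect_error(locate_landmarks(as_average_profile(d, v), cfg),
               "secondary spongiosa maximum")
  expect_error(locate_landmarks(as_average_profile(d, rep(55, length(d))), cfg),
               "constant")
})

test_that("mature-metaphysis window past the profile end is advised against", {
  cfg <- morphometry_config(profile_length = 10)
  d <- seq(0, 10, by = cfg$sample_step)
  v <- 90 - 30 * exp(-(d - 2.0)^2 / (2 * 0.4^2)) +
    20 * exp(-(d - 4.5)^2 / (2 * 0.6^2))
  # ps at 2.0, ss at 4.5 -> window center at 12 mm, beyond the grid
  expect_error(locate_landmarks(as_average_profile(d, v), cfg),
               "profile_length")
})

test_that("control-pattern phantom reproduces the expected ordering", {
  ph <- generate_phantom(phantom_preset("control", "T2", seed = 7))
  map <- interpolate_map(fit_monoexponential(ph$series$T2), 3)
  res <- measure_femoral_head(map, ph$truth$boundary)
  expect_gt(res$ps_depth, 0)
  expect_gt(res$ss_depth, res$ps_depth)
  expect_lt(res$ps_value, res$mm_value)
  expect_lt(res$mm_value, res$ss_value)
})

test_that("phantom secondary-spongiosa thickness is recovered within 15%", {
  # single realizations at SNR 50 carry noise in the landmark positions, so
  # the 15% claim is asserted on the median over five seeded phantoms
  rel_err <- vapply(1:5, function(seed) {
    ph <- generate_phantom(phantom_preset("control", "T2", seed = seed))
    map <- interpolate_map(fit_monoexponential(ph$series$T2), 3)
    res <- measure_femoral_head(map, ph$truth$boundary)
    abs(res$ss_thickness - ph$truth$true_ss_thickness) /
      ph$truth$true_ss_thickness
  }, numeric(1))
  expect_lt(median(rel_err), 0.15)
})

test_that("landmark depths agree between factor-1 and factor-3 analyses", {
  ph <- generate_phantom(phantom_spec(seed = 5, snr = Inf))
  fit <- fit_monoexponential(ph$series$T2)
  cfg1 <- morphometry_config(sample_step = 0.52)
  res1 <- measure_femoral_head(fit, ph$truth$boundary, cfg1)
  res3 <- measure_femoral_head(interpolate_map(fit, 3), ph$truth$boundary)
  expect_lt(abs(res1$ps_depth - res3$ps_depth), 0.52)
  expect_lt(abs(res1$ss_depth - res3$ss_depth), 0.52)
})

test_that("constant maps cannot be measured", {
  map <- plain_map(matrix(70, 80, 80), pixel_spacing = 0.17)
  b <- growth_plate_boundary(cbind(c(3, 6, 9), 1.5), c(0, 1))
  expect_error(measure_femoral_head(map, b), "landmark detection")
})

test_that("measurements are equivariant under exact rigid motions", {
  ph <- generate_phantom(phantom_spec(seed = 21, snr = Inf))
  map <- interpolate_map(fit_monoexponential(ph$series$T2), 3)
  res <- measure_femoral_head(map, ph$truth$boundary)

  # translation: pad 6 fine pixels of NA on top, shift boundary down
  shift <- 6 * map$pixel_spacing
  pad <- matrix(NA_real_, 6, ncol(map$values))
  tmap <- relaxation_map(rbind(pad, map$values), rbind(pad, map$s0),
                         rbind(pad, map$rsq), map$pixel_spacing, "T2")
  tb <- growth_plate_boundary(
    cbind(ph$truth$boundary$points[, 1],
          ph$truth$boundary$points[, 2] + shift), c(0, 1))
  tres <- measure_femoral_head(tmap, tb)
  for (f in MORPHOMETRY_METRICS)
    expect_equal(tres[[f]], res[[f]], tolerance = 1e-6)

  # rotation by 90 degrees: exact on the raster
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  H <- nrow(map$values) * map$pixel_spacing
  rmap <- relaxation_map(rot(map$values), rot(map$s0), rot(map$rsq),
                         map$pixel_spacing, "T2")
  rb <- growth_plate_boundary(
    cbind(H - ph$truth$boundary$points[, 2], ph$truth$boundary$points[, 1]),
    c(-1, 0))
  rres <- measure_femoral_head(rmap, rb)
  for (f in MORPHOMETRY_METRICS)
    expect_equal(rres[[f]], res[[f]], tolerance = 1e-6)
})

test_that("scaling the map scales values and leaves geometry unchanged", {
  ph <- generate_phantom(phantom_preset("control", "T2", seed = 9))
  map <- interpolate_map(fit_monoexponential(ph$series$T2), 3)
  res <- measure_femoral_head(map, ph$truth$boundary)
  c0 <- 2.5
  smap <- relaxation_map(map$values * c0, map$s0, map$rsq,
                         map$pixel_spacing, "T2")
  sres <- measure_femoral_head(smap, ph$truth$boundary)
  for (f in c("ps_value", "ss_value", "mm_value"))
    expect_equal(sres[[f]], c0 * res[[f]], tolerance = 1e-9)
  for (f in c("ps_depth", "ss_depth", "ps_thickness", "ss_thickness"))
    expect_equal(sres[[f]], res[[f]], tolerance = 1e-9)
})

test_that("corrupting 5% of lines moves the landmark values by under 2%", {
  ph <- generate_phantom(phantom_preset("control", "T2", seed = 13))
  map <- interpolate_map(fit_monoexponential(ph$series$T2), 3)
  cfg <- morphometry_config(clip_sigma = 3)
  set <- extract_line_profiles(map, ph$truth$boundary, cfg)
  res <- locate_landmarks(average_profiles(set, cfg), cfg)
  n_bad <- floor(0.05 * set$n_lines)
  set.seed(99)
  bad <- sample(set$n_lines, n_bad)
  set$profiles[bad, ] <- 900
  res2 <- locate_landmarks(average_profiles(set, cfg), cfg)
  expect_lt(abs(res2$ps_value - res$ps_value) / res$ps_value, 0.02)
  expect_lt(abs(res2$ss_value - res$ss_value) / res$ss_value, 0.02)
})
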