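test_that("a 10.2 mm straight boundary yields 60 vertical lines", {
  # value varies linearly with y so the sampled profile reveals direction
  sp <- 0.17
  vals <- outer(seq_len(120), seq_len(120), function(i, j) 50 + (i - 0.5) * sp)
  map <- plain_map(vals, pixel_spacing = sp)
  y0 <- 3
  b <- growth_plate_boundary(cbind(c(4, 9.1, 14.2), y0), distal_hint = c(0, 1))
  set <- extract_line_profiles(map, b)
  expect_equal(set$n_lines, 60L)
  expect_true(all(abs(set$line_origins[, 2] - y0) < 1e-9))
  # moving distally means increasing y, so value 50 + y = 50 + y0 + depth
  for (i in c(1, 30, 60))
    expect_equal(set$profiles[i, ], 50 + y0 + set$depths, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("profiles over a constant map are constant", {
  map <- plain_map(matrix(77, 90, 90), pixel_spacing = 0.17)
  b <- growth_plate_boundary(cbind(c(3, 6, 9), 2), distal_hint = c(0, 1))
  set <- extract_line_profiles(map, b)
  expect_equal(set$profiles, matrix(77, set$n_lines, length(set$depths)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(any(set$truncated))
})

test_that("arc boundary on a radially banded map reproduces the radial profile", {
  sp <- 0.17
  n <- 220
  cx <- n * sp / 2
  cy <- -12
  f <- function(r) 80 + 20 * sin(r / 2.5)
  vals <- outer(seq_len(n), seq_len(n), function(i, j) {
    f(sqrt(((j - 0.5) * sp - cx)^2 + ((i - 0.5) * sp - cy)^2))
  })
  map <- plain_map(vals, pixel_spacing = sp)
  r0 <- 16
  th <- seq(-0.35, 0.35, length.out = 41)
  b <- growth_plate_boundary(cbind(cx + r0 * sin(th), cy + r0 * cos(th)),
                             distal_hint = c(0, 1))
  cfg <- morphometry_config(profile_length = 8)
  set <- extract_line_profiles(map, b, cfg)
  truth <- f(r0 + set$depths)
  rms <- apply(set$profiles, 1, function(p)
    sqrt(mean((p - truth)^2)) / sqrt(mean(truth^2)))
  expect_lt(max(rms), 0.02)
})

test_that("degenerate geometry and out-of-map boundaries error", {
  map <- plain_map(matrix(60, 30, 30), pixel_spacing = 0.17)
  expect_error(
    extract_line_profiles(map, growth_plate_boundary(
      cbind(c(1, 30, 60), 2), c(0, 1))),
    "outside the map")
  expect_error(
    extract_line_profiles(map, growth_plate_boundary(
      cbind(c(1, 1.3, 1.6), 0.5), c(0, 1))),
    "fewer than 10 usable")
})

test_that("boundary validation enforces the polyline invariants", {
  expect_error(growth_plate_boundary(cbind(1:2, 1), c(0, 1)), "n >= 3")
  expect_error(growth_plate_boundary(cbind(c(1, 1, 2), c(1, 1, 1)), c(0, 1)),
               "distinct")
  bow <- rbind(c(0, 0), c(4, 0), c(4, 2), c(2, -1), c(0, 2))
  expect_error(growth_plate_boundary(bow, c(0, 1)), "simple")
  expect_error(growth_plate_boundary(cbind(1:3, 1), c(0, 0)), "non-zero")
})

test_that("sigma-clipped averaging equals the plain mean on identical profiles", {
  depths <- seq(0, 10, by = 0.17)
  prof <- matrix(rep(sin(depths) + 60, each = 20), nrow = 20)
  set <- structure(list(depths = depths, profiles = prof, n_lines = 20L,
                        line_origins = cbind(1:20, 1),
                        truncated = logical(20)),
                   class = "line_profile_set")
  avg <- average_profiles(set)
  expect_equal(avg$values, sin(depths) + 60, ignore_attr = TRUE)
  expect_true(all(avg$n_contributing == 20L))
})

test_that("a single gross outlier among 100 lines is fully rejected", {
  depths <- seq(0, 10, by = 0.17)
  prof <- rbind(matrix(50, 99, length(depths)),
                matrix(500, 1, length(depths)))
  set <- structure(list(depths = depths, profiles = prof, n_lines = 100L,
                        line_origins = cbind(1:100, 1),
                        truncated = logical(100)),
                   class = "line_profile_set")
  avg <- average_profiles(set, morphometry_config(clip_sigma = 3))
  expect_equal(avg$values, rep(50, length(depths)), ignore_attr = TRUE)
  expect_true(all(avg$n_contributing == 99L))
})

test_that("clipped mean of clean normal draws stays within 3 standard errors", {
  set.seed(42)
  depths <- seq(0, 10, by = 0.17)
  mu <- 80; sdev <- 6; n <- 80
  prof <- matrix(rnorm(n * length(depths), mu, sdev), nrow = n)
  set <- structure(list(depths = depths, profiles = prof, n_lines = n,
                        line_origins = cbind(seq_len(n), 1),
                        truncated = logical(n)),
                   class = "line_profile_set")
  avg <- average_profiles(set)
  se <- sdev / sqrt(n)
  expect_true(all(abs(avg$values - mu) < 3 * se))
})

test_that("depths with fewer than 3 contributing values warn and go NA", {
  depths <- seq(0, 1, by = 0.17)
  prof <- matrix(60, 12, length(depths))
  prof[3:12, length(depths)] <- NA
  set <- structure(list(depths = depths, profiles = prof, n_lines = 12L,
                        line_origins = cbind(1:12, 1),
                        truncated = logical(12)),
                   class = "line_profile_set")
  expect_warning(avg <- average_profiles(set), "fewer than 3")
  expect_true(is.na(avg$values[length(depths)]))
  expect_true(all(is.finite(avg$values[-length(depths)])))
})
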