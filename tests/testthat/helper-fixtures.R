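# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# A length-n vector with exactly the requested sample mean and SD, by
# affine-standardizing a fixed base vector.
moments_vector <- function(mean, sd, n = 10) {
  base <- seq_len(n)
  mean + sd * (base - mean(base)) / stats::sd(base)
}

# A map_series where every pixel decays exactly as S0 * exp(-t / T).
exact_series <- function(Tmap, S0 = 100, prep_times = c(0, 20, 40, 60, 80),
                         pixel_spacing = 0.52, contrast = "T2") {
  if (!is.matrix(Tmap)) Tmap <- matrix(Tmap, 1, 1)
  if (!is.matrix(S0)) S0 <- matrix(S0, nrow(Tmap), ncol(Tmap))
  imgs <- lapply(prep_times, function(tt) S0 * exp(-tt / Tmap))
  map_series(imgs, prep_times, pixel_spacing, contrast)
}

# Exhaustive grid-search least-squares oracle for the mono-exponential fit
# of a single pixel: profiles the SSE over T with the optimal S0 closed-form
# per candidate.
grid_search_T <- function(signal, prep_times, grid = seq(0.01, 500, by = 0.01)) {
  E <- exp(-outer(prep_times, 1 / grid))
  s0 <- colSums(E * signal) / colSums(E * E)
  sse <- colSums((signal - E * rep(s0, each = length(prep_times)))^2)
  grid[which.min(sse)]
}

# A relaxation_map with given value matrix and trivial diagnostics.
plain_map <- function(values, pixel_spacing = 0.52 / 3, contrast = "T2") {
  ones <- matrix(1, nrow(values), ncol(values))
  relaxation_map(values, ones * 100, ones, pixel_spacing, contrast)
}

# Analytic two-Gaussian depth profile: a dip (primary spongiosa) followed by
# a bump (secondary spongiosa) on a flat background.
gaussmix_profile <- function(d) {
  90 - 30 * exp(-(d - 1.5)^2 / (2 * 0.4^2)) +
    20 * exp(-(d - 3.0)^2 / (2 * 0.6^2))
}

# Fine-grid numerical oracle for extrema and inflection points of f on
# [0, L]; step defaults to 1e-4 mm.
profile_landmark_oracle <- function(f, L = 10, step = 1e-4) {
  d <- seq(0, L, by = step)
  v <- f(d)
  n <- length(v)
  interior <- 2:(n - 1)
  mins <- interior[v[interior] < v[interior - 1] & v[interior] <= v[interior + 1]]
  ps_i <- mins[1]
  maxs <- interior[v[interior] > v[interior - 1] & v[interior] >= v[interior + 1]]
  maxs <- maxs[maxs > ps_i]
  ss_i <- maxs[1]
  d2 <- diff(diff(v)) / step^2
  s <- sign(d2)
  cross_i <- which(s[-1] * s[-length(s)] < 0) + 1L   # index into v
  cross_d <- d[cross_i]
  left <- max(cross_d[cross_d < d[ps_i]])
  right <- min(cross_d[cross_d > d[ps_i] & cross_d < d[ss_i]])
  list(ps_depth = d[ps_i], ps_value = v[ps_i],
       ss_depth = d[ss_i], ss_value = v[ss_i],
       infl_left = left, infl_right = right,
       ps_thickness = right - left,
       ss_thickness = 2 * (d[ss_i] - right))
}

# Build an average_profile object directly from values on a depth grid.
as_average_profile <- function(depths, values) {
  structure(list(depths = depths, values = values,
                 n_contributing = rep(99L, length(depths))),
            class = "average_profile")
}

# Manifest rows for a synthetic paired study written under `dir`.
phantom_manifest <- function(dir, n_subjects, contrasts = "T2",
                             seed_base = 100L, snr = 50) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (side in c("control", "ischemic")) {
      for (ct in contrasts) {
        seed <- seed_base + 1000L * (side == "ischemic") + 10L * s +
          match(ct, CONTRASTS)
        spec <- phantom_preset(side, ct, seed = seed, snr = snr)
        sub_dir <- file.path(dir, sprintf("S%02d_%s_%s", s, side, ct))
        rows[[length(rows) + 1L]] <-
          write_phantom(spec, sub_dir, subject_id = sprintf("S%02d", s),
                        side = side)
      }
    }
  }
  do.call(rbind, rows)
}
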