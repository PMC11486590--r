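#' Per-femoral-head morphometry result
#'
#' The six measurements of one femoral head on one contrast: relaxation
#' times at the primary-spongiosa minimum, secondary-spongiosa maximum and
#' the mature-metaphysis window, and the three thicknesses. The total
#' thickness is the sum of the primary and secondary thicknesses by
#' construction.
#'
#' @param ps_value,ss_value,mm_value relaxation times, ms.
#' @param ps_depth,ss_depth landmark depths from the growth-plate boundary, mm.
#' @param ps_thickness,ss_thickness spongiosa thicknesses, mm.
#' @param contrast_label one of [CONTRASTS].
#' @return An object of class `morphometry_result`.
#' @export
morphometry_result <- function(ps_value, ps_depth, ss_value, ss_depth,
                               mm_value, ps_thickness, ss_thickness,
                               contrast_label) {
  if (!(ps_depth > 0 && ss_depth > ps_depth))
    stop("expected 0 < ps_depth < ss_depth", call. = FALSE)
  if (!(ps_value < ss_value))
    stop("primary-spongiosa value must be below secondary-spongiosa value",
         call. = FALSE)
  if (!(ps_thickness > 0 && ss_thickness > 0))
    stop("thicknesses must be positive", call. = FALSE)
  contrast_label <- match.arg(contrast_label, CONTRASTS)
  structure(list(ps_value = ps_value, ps_depth = ps_depth,
                 ss_value = ss_value, ss_depth = ss_depth,
                 mm_value = mm_value,
                 ps_thickness = ps_thickness, ss_thickness = ss_thickness,
                 total_thickness = ps_thickness + ss_thickness,
                 contrast_label = contrast_label),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf(
    paste0("<morphometry_result> %s\n",
           "  primary spongiosa:   %.1f ms at %.2f mm, thickness %.2f mm\n",
           "  secondary spongiosa: %.1f ms at %.2f mm, thickness %.2f mm\n",
           "  mature metaphysis:   %.1f ms; total thickness %.2f mm\n"),
    x$contrast_label, x$ps_value, x$ps_depth, x$ps_thickness,
    x$ss_value, x$ss_depth, x$ss_thickness, x$mm_value, x$total_thickness))
  invisible(x)
}

#' @export
as.data.frame.morphometry_result <- function(x, ...) {
  data.frame(contrast = x$contrast_label,
             ps_value = x$ps_value, ss_value = x$ss_value,
             mm_value = x$mm_value,
             ps_thickness = x$ps_thickness, ss_thickness = x$ss_thickness,
             total_thickness = x$total_thickness,
             ps_depth = x$ps_depth, ss_depth = x$ss_depth)
}

#' Names of the six morphometric metrics
#' @export
MORPHOMETRY_METRICS <- c("ps_value", "ss_value", "mm_value",
                         "ps_thickness", "ss_thickness", "total_thickness")

# Moving quadratic (Savitzky-Golay) smoother. Fits a local order-2
# polynomial over a window of half-width h samples; at the edges the window
# shrinks asymmetrically. Returns the smoothed value and second derivative.
savgol_quadratic <- function(v, step, h) {
  n <- length(v)
  sm <- numeric(n)
  d1 <- numeric(n)
  d2 <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    idx <- lo:hi
    if (length(idx) < 3L) { sm[i] <- v[i]; d1[i] <- 0; d2[i] <- 0; next }
    x <- (idx - i) * step
    cf <- stats::lm.fit(cbind(1, x, x^2), v[idx])$coefficients
    sm[i] <- cf[1]
    d1[i] <- cf[2]
    d2[i] <- 2 * cf[3]
  }
  list(smooth = sm, deriv1 = d1, deriv2 = d2)
}

# Inflection point of the limb between two indices: the zero crossing of the
# smoothed second derivative anchored at the steepest point of the limb
# (extremum of the smoothed first derivative). Hunting for the crossing near
# the steepest slope, rather than taking the first crossing in the interval,
# keeps noise-induced sign flips of the second derivative from hijacking the
# landmark.
limb_inflection <- function(d, sg, from, to, rising) {
  idx <- from:to
  if (length(idx) < 3L) return(NA_real_)
  steep <- idx[if (rising) which.max(sg$deriv1[idx])
               else which.min(sg$deriv1[idx])]
  y <- sg$deriv2
  # nearest sign change of d2 around the steepest sample
  for (off in 0:(length(idx))) {
    for (j in unique(c(steep - off, steep + off))) {
      if (j < from || j >= to) next
      if (sign(y[j]) * sign(y[j + 1L]) < 0)
        return(d[j] + (d[j + 1L] - d[j]) * y[j] / (y[j] - y[j + 1L]))
      if (y[j] == 0) return(d[j])
    }
  }
  NA_real_
}

# Topographic prominence of the peak at index i of v (for minima pass -v):
# height above the higher of the two key saddles toward the nearest
# higher ground (or the profile ends).
peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]
  j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) { left_min <- min(left_min, v[j]); j <- j - 1L }
  if (j >= 1L) left_base <- left_min else left_base <- min(v[1:i])
  right_min <- v[i]
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) { right_min <- min(right_min, v[j]); j <- j + 1L }
  if (j <= n) right_base <- right_min else right_base <- min(v[i:n])
  v[i] - max(left_base, right_base)
}

# Interior local extrema indices; on plateaus the shallowest index wins.
local_extrema <- function(v, kind = c("min", "max")) {
  kind <- match.arg(kind)
  s <- if (kind == "min") -v else v
  n <- length(s)
  out <- integer(0)
  for (i in 2:(n - 1L)) {
    # strictly above the previous distinct value and not below the next
    j <- i - 1L
    while (j >= 1L && s[j] == s[i]) j <- j - 1L
    if (j < 1L || s[j] >= s[i]) next
    k <- i + 1L
    while (k <= n && s[k] == s[i]) k <- k + 1L
    if (k > n || s[k] >= s[i]) next
    out <- c(out, i)
  }
  out
}

# Quadratic refinement of an extremum through the 3 samples around index i.
refine_extremum <- function(d, v, i) {
  n <- length(v)
  if (i <= 1L || i >= n) return(list(depth = d[i], value = v[i]))
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom == 0) return(list(depth = d[i], value = v[i]))
  off <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  off <- max(min(off, 0.5), -0.5)
  step <- d[2] - d[1]
  val <- v[i] - 0.25 * (v[i - 1L] - v[i + 1L]) * off
  list(depth = d[i] + off * step, value = val)
}

landmark_error <- function(which, detail) {
  stop(sprintf("landmark detection failed (%s): %s", which, detail),
       call. = FALSE)
}

#' Locate spongiosa landmarks and thicknesses on an average profile
#'
#' Smooths the profile with a moving quadratic filter of width
#' `config$smoothing_window`, then finds: the primary spongiosa (PS) as the
#' first local minimum whose prominence reaches
#' `config$min_prominence` of the profile's dynamic range; the secondary
#' spongiosa (SS) as the first qualifying local maximum after it; both
#' refined by a quadratic fit through the three samples around the discrete
#' extremum. Inflection points are the zero crossings of the smoothed second
#' derivative flanking the PS minimum; the PS thickness is the distance
#' between them, the SS thickness twice the distance from the PS-SS
#' inflection to the SS maximum, and the total their sum. The
#' mature-metaphysis value is the unweighted mean of the (unsmoothed)
#' profile over a `config$mm_window` wide interval centered at
#' `ps_depth + config$mm_offset_factor * (ss_depth - ps_depth)`; the profile
#' beyond that window is unused.
#'
#' @param profile an `average_profile`, finite over its full grid.
#' @param config a [morphometry_config()].
#' @param contrast_label contrast carried into the result.
#' @return A [morphometry_result()].
#' @export
locate_landmarks <- function(profile, config = morphometry_config(),
                             contrast_label = "T2") {
  stopifnot(inherits(profile, "average_profile"),
            inherits(config, "morphometry_config"))
  d <- profile$depths
  v <- profile$values
  if (!all(is.finite(v)))
    stop("average profile must be finite over the full depth grid",
         call. = FALSE)
  step <- d[2] - d[1]
  # half-width in samples of a window spanning smoothing_window mm
  h <- max(1L, round((config$smoothing_window / step - 1) / 2))
  sg <- savgol_quadratic(v, step, h)
  vs <- sg$smooth
  rng <- diff(range(vs))
  if (rng <= 1e-9 * max(1, abs(mean(vs))))
    landmark_error("primary spongiosa minimum", "profile is constant")
  thr <- config$min_prominence * rng

  mins <- local_extrema(vs, "min")
  mins <- mins[vapply(mins, function(i) peak_prominence(-vs, i), numeric(1)) >= thr]
  if (!length(mins))
    landmark_error("primary spongiosa minimum",
                   "no interior minimum with sufficient prominence")
  ips <- mins[1]
  ps <- refine_extremum(d, vs, ips)

  maxs <- local_extrema(vs, "max")
  maxs <- maxs[maxs > ips]
  maxs <- maxs[vapply(maxs, function(i) peak_prominence(vs, i), numeric(1)) >= thr]
  if (!length(maxs))
    landmark_error("secondary spongiosa maximum",
                   "no maximum after the primary spongiosa with sufficient prominence")
  iss <- maxs[1]
  ss <- refine_extremum(d, vs, iss)

  infl_left <- limb_inflection(d, sg, 1L, ips, rising = FALSE)
  infl_right <- limb_inflection(d, sg, ips, iss, rising = TRUE)
  if (!is.finite(infl_left))
    landmark_error("proximal inflection point",
                   "no second-derivative zero crossing before the primary spongiosa")
  if (!is.finite(infl_right))
    landmark_error("primary/secondary inflection point",
                   "no second-derivative zero crossing between the spongiosa landmarks")

  ps_th <- infl_right - infl_left
  ss_th <- 2 * (ss$depth - infl_right)

  mm_center <- ps$depth + config$mm_offset_factor * (ss$depth - ps$depth)
  lo <- mm_center - config$mm_window / 2
  hi <- mm_center + config$mm_window / 2
  if (hi > max(d) + step / 2)
    stop("mature-metaphysis window (", sprintf("%.2f-%.2f", lo, hi),
         " mm) exceeds the profile end; increase `profile_length`",
         call. = FALSE)
  in_win <- d >= lo & d <= hi
  if (!any(in_win))
    stop("mature-metaphysis window contains no samples", call. = FALSE)
  mm_value <- mean(v[in_win])

  morphometry_result(ps_value = ps$value, ps_depth = ps$depth,
                     ss_value = ss$value, ss_depth = ss$depth,
                     mm_value = mm_value,
                     ps_thickness = ps_th, ss_thickness = ss_th,
                     contrast_label = contrast_label)
}

#' Measure one femoral head: extract, average, locate
#'
#' Composition of [extract_line_profiles()], [average_profiles()] and
#' [locate_landmarks()]. Provenance (number of lines, configuration) is
#' attached as attributes.
#'
#' @inheritParams extract_line_profiles
#' @return A [morphometry_result()] with attributes `n_lines` and `config`.
#' @export
measure_femoral_head <- function(map, boundary, config = morphometry_config()) {
  set <- extract_line_profiles(map, boundary, config)
  avg <- average_profiles(set, config)
  res <- locate_landmarks(avg, config, contrast_label = map$contrast_label)
  attr(res, "n_lines") <- set$n_lines
  attr(res, "config") <- config
  res
}
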