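#' Allowed relaxation-contrast labels
#'
#' The four magnetization-prepared contrasts the pipeline understands:
#' transverse relaxation (T2), rotating-frame relaxation (T1rho) and the
#' adiabatic variants (aT1rho, aT2rho).
#'
#' @export
CONTRASTS <- c("T2", "T1rho", "aT1rho", "aT2rho")

#' Magnetization-prepared image series
#'
#' Bundles one 2D image per preparation time with the acquisition metadata
#' needed for relaxometry: the preparation times themselves and the
#' (isotropic, in-plane) pixel spacing.
#'
#' @param images list of numeric matrices, one per preparation time, all of
#'   identical dimension; arbitrary signal units.
#' @param prep_times numeric vector of preparation times in ms, strictly
#'   increasing, non-negative; same length as `images`.
#' @param pixel_spacing in-plane pixel size in mm (scalar, > 0).
#' @param contrast_label one of [CONTRASTS].
#' @return An object of class `map_series`.
#' @export
map_series <- function(images, prep_times, pixel_spacing, contrast_label) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(images, is.matrix, logical(1))))
    stop("every element of `images` must be a matrix", call. = FALSE)
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images must share an identical shape", call. = FALSE)
  if (length(prep_times) != length(images))
    stop("number of images (", length(images), ") must equal number of ",
         "prep_times (", length(prep_times), ")", call. = FALSE)
  if (any(prep_times < 0) || any(diff(prep_times) <= 0))
    stop("`prep_times` must be non-negative and strictly increasing",
         call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive number", call. = FALSE)
  contrast_label <- match.arg(contrast_label, CONTRASTS)
  structure(
    list(images = lapply(images, function(m) {storage.mode(m) <- "double"; m}),
         prep_times = as.numeric(prep_times),
         pixel_spacing = as.numeric(pixel_spacing),
         contrast_label = contrast_label),
    class = "map_series")
}

#' @export
print.map_series <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "<map_series> %s: %d x %d px @ %.3g mm, prep times (ms): %s\n",
    x$contrast_label, d[1], d[2], x$pixel_spacing,
    paste(x$prep_times, collapse = ", ")))
  invisible(x)
}

#' Fit configuration for mono-exponential relaxometry
#'
#' @param method `"nonlinear_ls"` (default; signal-domain least squares
#'   seeded by the log-linear solution) or `"log_linear"` (ordinary least
#'   squares on log-signal).
#' @param min_signal samples at or below this floor are excluded from the
#'   fit. Default 0: only non-positive signals are excluded.
#' @param max_T cap on the reported relaxation time in ms. Keeps flat decays
#'   from producing runaway values. Default 1000 ms, far above any plausible
#'   metaphyseal relaxation time at 3 T.
#' @param min_valid_samples minimum number of usable prep-time points a pixel
#'   needs for a fit (>= 2).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(method = c("nonlinear_ls", "log_linear"),
                       min_signal = 0, max_T = 1000,
                       min_valid_samples = 2L) {
  method <- match.arg(method)
  if (min_valid_samples < 2L)
    stop("`min_valid_samples` must be >= 2", call. = FALSE)
  if (!is.numeric(max_T) || max_T <= 0)
    stop("`max_T` must be > 0", call. = FALSE)
  if (!is.numeric(min_signal) || min_signal < 0)
    stop("`min_signal` must be >= 0", call. = FALSE)
  structure(list(method = method, min_signal = min_signal, max_T = max_T,
                 min_valid_samples = as.integer(min_valid_samples)),
            class = "fit_config")
}

#' Fitted relaxation-time map
#'
#' Constructor used internally by [fit_monoexponential()] and the I/O layer.
#'
#' @param values matrix of relaxation times, ms; `NA` where the fit failed.
#' @param s0 matrix of fitted zero-prep-time signal.
#' @param rsq matrix of coefficients of determination in `[0, 1]`.
#' @param pixel_spacing mm.
#' @param contrast_label one of [CONTRASTS].
#' @return An object of class `relaxation_map`.
#' @export
relaxation_map <- function(values, s0, rsq, pixel_spacing, contrast_label) {
  stopifnot(is.matrix(values), identical(dim(values), dim(s0)),
            identical(dim(values), dim(rsq)))
  fin <- is.finite(values)
  if (any(values[fin] <= 0))
    stop("relaxation times must be > 0 wherever finite", call. = FALSE)
  if (any(rsq[fin] < 0 | rsq[fin] > 1, na.rm = TRUE))
    stop("rsq must lie in [0, 1] wherever values are finite", call. = FALSE)
  contrast_label <- match.arg(contrast_label, CONTRASTS)
  structure(list(values = values, s0 = s0, rsq = rsq,
                 pixel_spacing = as.numeric(pixel_spacing),
                 contrast_label = contrast_label),
            class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  d <- dim(x$values)
  fin <- is.finite(x$values)
  cat(sprintf(
    "<relaxation_map> %s: %d x %d px @ %.4g mm, %d fitted px, median T %.3g ms\n",
    x$contrast_label, d[1], d[2], x$pixel_spacing, sum(fin),
    stats::median(x$values[fin])))
  invisible(x)
}
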