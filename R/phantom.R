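#' Band labels of the femoral-head phantom, proximal to distal
#' @export
PHANTOM_BANDS <- c("epiphysis", "growth_plate", "primary_spongiosa",
                   "secondary_spongiosa", "mature_metaphysis")

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Default band relaxation times, ms. Primary/secondary spongiosa and mature
# metaphysis come from the reference cohort summaries; growth-plate and
# epiphysis values are NOT tabulated there (epiphysis is out of scope) and
# are set qualitatively: growth-plate cartilage above the secondary
# spongiosa (it is the hyperintense band), epiphysis near the mature
# metaphysis.
default_band_T <- function(contrast_label, condition = c("control", "ischemic")) {
  condition <- match.arg(condition)
  ref <- reference_effects()
  pick <- function(metric) {
    r <- ref[ref$metric == metric & ref$contrast == contrast_label, ]
    if (condition == "control") r$control_mean else r$ischemic_mean
  }
  gp <- c(T2 = 120, T1rho = 190, aT1rho = 380, aT2rho = 160)[[contrast_label]]
  epi <- c(T2 = 70, T1rho = 110, aT1rho = 250, aT2rho = 95)[[contrast_label]]
  stats::setNames(c(epi, gp, pick("ps_value"), pick("ss_value"),
                    pick("mm_value")), PHANTOM_BANDS)
}

#' Femoral-head phantom specification
#'
#' A banded phantom emulating the proximal-to-distal anatomy seen on
#' relaxation-weighted images of the developing femoral head: epiphysis,
#' hyperintense growth plate, hypointense primary spongiosa, hyperintense
#' secondary spongiosa, mature metaphysis. Bands are straight (stacked along
#' image rows) or concentric arcs (for curvature testing), blended by a
#' Gaussian transition, imaged at the contrast's preparation times with
#' Rician magnitude noise.
#'
#' @param geometry `"straight_bands"` or `"arc_bands"`.
#' @param contrasts contrast labels to emit, subset of [CONTRASTS].
#' @param band_widths named widths in mm for [PHANTOM_BANDS]; the last band
#'   extends to the image edge if the image is taller than the band stack.
#' @param band_T named list (per contrast) of relaxation times per band, ms;
#'   defaults from [reference_effects()] control columns (see
#'   `condition`).
#' @param band_S0 zero-prep-time signal per band, arbitrary units.
#' @param condition `"control"` or `"ischemic"`; selects default `band_T`
#'   (and, via [phantom_preset()], band widths).
#' @param transition_sigma Gaussian blur between bands, mm.
#' @param image_shape c(rows, cols); default accommodates the band stack at
#'   `pixel_spacing` with enough width for 60-100 line profiles.
#' @param pixel_spacing acquisition pixel size, mm (default 0.52).
#' @param snr ratio of mean S0 to the Rician noise sigma; `Inf` disables
#'   noise.
#' @param arc_radius radius of the growth-plate arc for `arc_bands`, mm.
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("straight_bands", "arc_bands"),
                         contrasts = "T2",
                         band_widths = NULL, band_T = NULL,
                         band_S0 = c(epiphysis = 450, growth_plate = 550,
                                     primary_spongiosa = 380,
                                     secondary_spongiosa = 520,
                                     mature_metaphysis = 430),
                         condition = c("control", "ischemic"),
                         transition_sigma = 0.3,
                         image_shape = c(46L, 28L), pixel_spacing = 0.52,
                         snr = 50, arc_radius = 30, seed = 1L) {
  geometry <- match.arg(geometry)
  condition <- match.arg(condition)
  contrasts <- match.arg(contrasts, CONTRASTS, several.ok = TRUE)
  ref <- reference_effects()
  if (is.null(band_widths)) {
    r <- ref[ref$contrast == contrasts[1], ]
    col <- if (condition == "control") "control_mean" else "ischemic_mean"
    band_widths <- c(epiphysis = 6, growth_plate = 1,
                     primary_spongiosa = r[r$metric == "ps_thickness", col],
                     secondary_spongiosa = r[r$metric == "ss_thickness", col],
                     mature_metaphysis = 13)
  }
  if (!identical(sort(names(band_widths)), sort(PHANTOM_BANDS)))
    stop("`band_widths` must be named by PHANTOM_BANDS", call. = FALSE)
  band_widths <- band_widths[PHANTOM_BANDS]
  if (any(band_widths <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (is.null(band_T))
    band_T <- stats::setNames(
      lapply(contrasts, default_band_T, condition = condition), contrasts)
  if (!all(contrasts %in% names(band_T)))
    stop("`band_T` must provide every requested contrast", call. = FALSE)
  for (ct in contrasts) {
    bt <- band_T[[ct]][PHANTOM_BANDS]
    if (any(!is.finite(bt)) || any(bt <= 0))
      stop("band relaxation times must be positive for ", ct, call. = FALSE)
    if (bt["growth_plate"] <= bt["primary_spongiosa"])
      stop("growth-plate T must exceed primary-spongiosa T (control pattern)",
           call. = FALSE)
    band_T[[ct]] <- bt
  }
  if (!(is.numeric(snr) && length(snr) == 1L && !is.na(snr) && snr > 0))
    stop("`snr` must be > 0 (Inf allowed)", call. = FALSE)
  extent_y <- image_shape[1] * pixel_spacing
  if (sum(band_widths) > extent_y + pixel_spacing / 2)
    stop("bands exceed the image extent (", round(sum(band_widths), 2),
         " mm > ", round(extent_y, 2), " mm)", call. = FALSE)
  structure(list(geometry = geometry, contrasts = contrasts,
                 band_widths = band_widths, band_T = band_T,
                 band_S0 = band_S0[PHANTOM_BANDS], condition = condition,
                 transition_sigma = transition_sigma,
                 image_shape = as.integer(image_shape),
                 pixel_spacing = pixel_spacing, snr = snr,
                 arc_radius = arc_radius, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Control / ischemic phantom presets
#'
#' Control preset: band widths and relaxation times at the control-arm
#' reference means. Ischemic preset: thinned primary and secondary
#' spongiosa and the ischemic-arm relaxation times.
#'
#' @param condition `"control"` or `"ischemic"`.
#' @param contrast one contrast label.
#' @param seed integer seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(condition = c("control", "ischemic"),
                           contrast = "T2", seed = 1L, ...) {
  condition <- match.arg(condition)
  phantom_spec(contrasts = contrast, condition = condition, seed = seed, ...)
}

# Analytic Gaussian blending of per-band values along the band-normal depth
# coordinate: the piecewise-constant band profile convolved with a Gaussian
# of SD `sigma`, evaluated exactly via error functions. Band edges therefore
# sit at their true sub-pixel positions instead of being rasterized to the
# acquisition grid.
blend_bands <- function(depth, band_values, edges, sigma) {
  if (sigma <= 0) {
    idx <- findInterval(depth, edges) + 1L
    idx[idx > length(band_values)] <- length(band_values)
    return(array(band_values[idx], dim = dim(depth)))
  }
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  out <- array(0, dim = dim(depth))
  for (b in seq_along(band_values)) {
    w <- stats::pnorm((depth - lo[b]) / sigma) -
      stats::pnorm((depth - hi[b]) / sigma)
    out <- out + band_values[b] * w
  }
  out
}

#' Generate a femoral-head phantom
#'
#' Builds the band label image, assigns per-band relaxation time and S0
#' fields, blurs both with `transition_sigma`, and emits one magnitude image
#' per preparation time per contrast:
#' `sqrt((S0 * exp(-t/T) + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)` and
#' `sigma = mean(S0) / snr` (Rician noise; exact noiseless signal when
#' `snr = Inf`). Deterministic for a fixed spec and seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `series` (named list of [map_series()], one per
#'   contrast) and `truth` (class `phantom_truth`: `region_mask`,
#'   `boundary`, `true_ps_thickness`, `true_ss_thickness`, `true_band_T`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  sp <- spec$pixel_spacing
  xc <- (seq_len(nc) - 0.5) * sp
  yc <- (seq_len(nr) - 0.5) * sp
  edges <- cumsum(spec$band_widths)

  if (spec$geometry == "straight_bands") {
    depth <- matrix(yc, nr, nc)                 # distance from proximal edge
  } else {
    cx <- nc * sp / 2
    cy <- spec$band_widths[["epiphysis"]] - spec$arc_radius
    R <- sqrt(outer(yc - cy, xc - cx, function(a, b) a^2 + b^2))
    depth <- R - spec$arc_radius + spec$band_widths[["epiphysis"]]
  }
  label <- matrix(findInterval(depth, edges[-length(edges)]) + 1L, nr, nc)
  label[label > length(PHANTOM_BANDS)] <- length(PHANTOM_BANDS)
  label[label < 1L] <- 1L

  inner_edges <- edges[-length(edges)]
  S0f <- blend_bands(depth, unname(spec$band_S0), inner_edges,
                     spec$transition_sigma)
  sigma <- mean(S0f) / spec$snr

  boundary <- phantom_boundary(spec)
  series <- with_seed(spec$seed, {
    out <- list()
    for (ct in spec$contrasts) {
      Tf <- blend_bands(depth, unname(spec$band_T[[ct]]), inner_edges,
                        spec$transition_sigma)
      tps <- prep_times_for(ct)
      imgs <- lapply(tps, function(tt) {
        s <- S0f * exp(-tt / Tf)
        if (is.infinite(spec$snr)) s
        else sqrt((s + matrix(stats::rnorm(nr * nc, 0, sigma), nr, nc))^2 +
                  matrix(stats::rnorm(nr * nc, 0, sigma), nr, nc)^2)
      })
      out[[ct]] <- map_series(imgs, tps, sp, ct)
    }
    out
  })

  truth <- structure(list(
    region_mask = matrix(factor(PHANTOM_BANDS[label], levels = PHANTOM_BANDS),
                         nr, nc),
    boundary = boundary,
    true_ps_thickness = unname(spec$band_widths[["primary_spongiosa"]]),
    true_ss_thickness = unname(spec$band_widths[["secondary_spongiosa"]]),
    true_band_T = spec$band_T), class = "phantom_truth")
  list(series = series, truth = truth)
}

# Proximal growth-plate edge of the phantom, with a 1.5 mm lateral margin so
# all profiles stay inside the map.
phantom_boundary <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  sp <- spec$pixel_spacing
  margin <- 1.5
  x <- seq(margin, nc * sp - margin, length.out = 25)
  y0 <- spec$band_widths[["epiphysis"]]
  if (spec$geometry == "straight_bands") {
    pts <- cbind(x, y0)
  } else {
    cx <- nc * sp / 2
    cy <- y0 - spec$arc_radius
    th_max <- asin((nc * sp / 2 - margin) / spec$arc_radius)
    th <- seq(-th_max, th_max, length.out = 41)
    pts <- cbind(cx + spec$arc_radius * sin(th),
                 cy + spec$arc_radius * cos(th))
  }
  growth_plate_boundary(pts, distal_hint = c(0, 1))
}

#' Synthetic paired-cohort specification
#'
#' @param n_subjects number of paired subjects (>= 2).
#' @param control_means,control_sds named per-metric control-arm parameters.
#' @param diff_means,diff_sds named per-metric paired-difference parameters
#'   (ischemic minus control); names must match `control_means`.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, control_means, control_sds,
                        diff_means, diff_sds, seed = 1L) {
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  nm <- names(control_means)
  if (is.null(nm) ||
      !identical(nm, names(control_sds)) ||
      !identical(nm, names(diff_means)) ||
      !identical(nm, names(diff_sds)))
    stop("all parameter vectors must share identical metric names",
         call. = FALSE)
  if (any(control_sds < 0) || any(diff_sds < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 control_means = control_means, control_sds = control_sds,
                 diff_means = diff_means, diff_sds = diff_sds,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic paired cohort table
#'
#' Per subject and metric, the control value is drawn
#' `Normal(control_mean, control_sd)` and the ischemic value is the control
#' plus an independent `Normal(diff_mean, diff_sd)` difference.
#'
#' @param spec a [cohort_spec()].
#' @return A long-format data.frame: `subject_id`, `metric`, `control`,
#'   `ischemic`.
#' @export
generate_paired_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  metrics <- names(spec$control_means)
  with_seed(spec$seed, {
    rows <- lapply(metrics, function(m) {
      ctrl <- stats::rnorm(spec$n_subjects, spec$control_means[[m]],
                           spec$control_sds[[m]])
      isch <- ctrl + stats::rnorm(spec$n_subjects, spec$diff_means[[m]],
                                  spec$diff_sds[[m]])
      data.frame(subject_id = sprintf("S%02d", seq_len(spec$n_subjects)),
                 metric = m, control = ctrl, ischemic = isch)
    })
    do.call(rbind, rows)
  })
}

#' Assemble a paired cohort object from a long cohort table
#'
#' @param table data.frame with columns `subject_id`, `metric`, `control`,
#'   `ischemic` (as produced by [generate_paired_cohort()]).
#' @param contrast_label contrast the measurements belong to.
#' @return A [paired_cohort()].
#' @export
as_paired_cohort <- function(table, contrast_label = "T2") {
  ids <- unique(table$subject_id)
  one_side <- function(col) {
    lapply(ids, function(id) {
      sub <- table[table$subject_id == id, ]
      stats::setNames(sub[[col]], sub$metric)
    })
  }
  paired_cohort(ids, one_side("control"), one_side("ischemic"),
                contrast_label)
}
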