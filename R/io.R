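#' Read and write magnetization-prepared series as text + JSON sidecar
#'
#' The on-disk container is deliberately plain text so it survives
#' source-only environments: one headerless CSV matrix per preparation time
#' plus a JSON sidecar `{prep_times_ms, pixel_spacing_mm, contrast_label,
#' files}`. NIfTI volumes convert to this layout with one `nibabel` or
#' `RNifti` call per slice (see README).
#'
#' @param series a [map_series()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return `write_map_series()` returns the sidecar path invisibly;
#'   `read_map_series()` returns a [map_series()].
#' @export
write_map_series <- function(series, dir, prefix = series$contrast_label) {
  stopifnot(inherits(series, "map_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_t%02d.csv", prefix, seq_along(series$prep_times) - 1L)
  for (i in seq_along(files))
    utils::write.table(series$images[[i]], file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  sidecar <- file.path(dir, paste0(prefix, "_series.json"))
  jsonlite::write_json(
    list(prep_times_ms = series$prep_times,
         pixel_spacing_mm = series$pixel_spacing,
         contrast_label = series$contrast_label, files = files),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @param sidecar path to a `*_series.json` sidecar.
#' @rdname write_map_series
#' @export
read_map_series <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  imgs <- lapply(meta$files, function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = ",")))
  imgs <- lapply(imgs, unname)
  map_series(imgs, meta$prep_times_ms, meta$pixel_spacing_mm,
             meta$contrast_label)
}

#' Read and write fitted relaxation maps
#'
#' Same text container as the series: `values`, `s0` and `rsq` CSV matrices
#' plus a JSON sidecar.
#'
#' @param map a [relaxation_map()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `write_relaxation_map()` returns the sidecar path invisibly;
#'   `read_relaxation_map()` returns a [relaxation_map()].
#' @export
write_relaxation_map <- function(map, dir,
                                 prefix = paste0(map$contrast_label, "_map")) {
  stopifnot(inherits(map, "relaxation_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("values", "s0", "rsq")
  files <- stats::setNames(sprintf("%s_%s.csv", prefix, parts), parts)
  for (p in parts)
    utils::write.table(map[[p]], file.path(dir, files[[p]]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(pixel_spacing_mm = map$pixel_spacing,
         contrast_label = map$contrast_label, files = as.list(files)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @param sidecar path to a map sidecar JSON.
#' @rdname write_relaxation_map
#' @export
read_relaxation_map <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  rd <- function(f) unname(as.matrix(utils::read.table(file.path(dir, f),
                                                       sep = ",")))
  relaxation_map(rd(meta$files[["values"]]), rd(meta$files[["s0"]]),
                 rd(meta$files[["rsq"]]), meta$pixel_spacing_mm,
                 meta$contrast_label)
}

#' Read and write growth-plate boundary CSVs
#'
#' Boundary files are two-column CSVs with header `x_mm,y_mm`; the distal
#' hint travels alongside (in a config or as arguments) because it is a
#' property of how the boundary was traced, not of the curve itself.
#'
#' @param boundary a [growth_plate_boundary()].
#' @param path CSV path.
#' @return `read_boundary_csv()` returns a [growth_plate_boundary()].
#' @export
write_boundary_csv <- function(boundary, path) {
  stopifnot(inherits(boundary, "growth_plate_boundary"))
  utils::write.csv(data.frame(x_mm = boundary$points[, 1],
                              y_mm = boundary$points[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @param distal_hint length-2 vector toward the metaphysis.
#' @rdname write_boundary_csv
#' @export
read_boundary_csv <- function(path, distal_hint = c(0, 1)) {
  df <- utils::read.csv(path)
  growth_plate_boundary(cbind(df$x_mm, df$y_mm), distal_hint)
}

#' Write a morphometry result as one-row CSV and JSON
#'
#' @param result a [morphometry_result()].
#' @param path_base path without extension; `.csv` and `.json` are added.
#' @return Invisibly, the two paths.
#' @export
write_morphometry_result <- function(result, path_base) {
  df <- as.data.frame(result)
  utils::write.csv(df, paste0(path_base, ".csv"), row.names = FALSE)
  jsonlite::write_json(as.list(df), paste0(path_base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(path_base, c(".csv", ".json")))
}

#' Write a line-profile set as a long-format table
#'
#' Columns `line_id`, `depth_mm`, `value_ms`.
#'
#' @param set a `line_profile_set`.
#' @param path CSV path.
#' @export
write_profile_table <- function(set, path) {
  stopifnot(inherits(set, "line_profile_set"))
  df <- data.frame(
    line_id = rep(seq_len(set$n_lines), times = length(set$depths)),
    depth_mm = rep(set$depths, each = set$n_lines),
    value_ms = as.vector(set$profiles))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert a measurements table to paired cohorts
#'
#' @param df data.frame with columns `subject_id`, `side`
#'   (`"control"`/`"ischemic"`), `contrast`, `metric`, `value` — the cohort
#'   CSV layout.
#' @return A list of [paired_cohort()], one per contrast present.
#' @export
measurements_to_cohorts <- function(df) {
  need <- c("subject_id", "side", "contrast", "metric", "value")
  if (!all(need %in% names(df)))
    stop("measurements need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$contrast), function(sub) {
    ids <- sort(unique(sub$subject_id))
    side_vecs <- function(side) {
      lapply(ids, function(id) {
        rows <- sub[sub$subject_id == id & sub$side == side, ]
        stats::setNames(rows$value, rows$metric)
      })
    }
    paired_cohort(ids, side_vecs("control"), side_vecs("ischemic"),
                  sub$contrast[1])
  })
}
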