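# CSV round-tripping for cohort tables and polar-map rasters.
# Dialect: UTF-8, comma separated, header row, '.' decimal; floating-point
# columns written with 6 significant digits so identical inputs always
# serialize to identical bytes.

#' Write / read a cohort profile table
#'
#' Columns: `subject_id`, `population`, `sex`, `phase`, optional `label`
#' and `hmr`, then `seg01`..`seg17`. Numeric columns are serialized with 6
#' significant digits.
#'
#' @param cohort Cohort data frame.
#' @param path CSV file path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns the cohort data frame.
#' @export
write_profiles <- function(cohort, path) {
  invisible(profile_matrix(cohort))  # validates segment columns
  keep <- intersect(c("subject_id", "population", "sex", "phase", "label",
                      "hmr", seg_cols()), names(cohort))
  out <- cohort[, keep, drop = FALSE]
  for (col in keep)
    if (is.numeric(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 6, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  invisible(profile_matrix(df))
  df
}

#' Write / read a polar-map raster as a plain-matrix CSV
#'
#' One row per raster row, no header; masked-out pixels are written as-is
#' (the centered-disc mask is reconstructed on read).
#'
#' @param raster A [polar_map_raster()].
#' @param path CSV file path.
#' @param phase Phase assigned on read.
#' @return `write_raster_csv()` returns `path` invisibly;
#'   `read_raster_csv()` returns a [polar_map_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "polar_map_raster"))
  utils::write.table(raster$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path, phase = "late") {
  grid <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(grid) <- NULL
  polar_map_raster(grid, phase = phase)
}

#' Export a polar-map raster as an 8-bit grayscale PNG
#'
#' For visual inspection only: masked values are scaled linearly so the
#' maximum maps to white (255) and clipped at 0; out-of-mask pixels are
#' black. Requires the `png` package.
#'
#' @param raster A [polar_map_raster()] (or bare matrix, e.g. a planar
#'   image).
#' @param path Output PNG file.
#' @param max_value Count mapped to white; default the in-mask maximum.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path, max_value = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("PNG export needs the 'png' package", call. = FALSE)
  if (inherits(raster, "polar_map_raster")) {
    grid <- raster$grid
    grid[!raster$mask] <- 0
  } else grid <- as.matrix(raster)
  if (is.null(max_value)) max_value <- max(grid)
  if (max_value <= 0) max_value <- 1
  png::writePNG(pmin(pmax(grid / max_value, 0), 1), path)
  invisible(path)
}
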