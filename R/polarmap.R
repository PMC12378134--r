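#' Polar-map raster container
#'
#' A square grid of non-negative counts sampled over the left ventricle,
#' apex at the center and base at the rim, with a centered circular mask of
#' in-map pixels.
#'
#' @param grid Square numeric matrix of counts; values outside the mask are
#'   ignored.
#' @param phase Imaging phase, `"early"` or `"late"`.
#' @param mask Optional logical matrix of in-map pixels; defaults to the
#'   centered disc of radius `nrow(grid) / 2`.
#' @return An object of class `polar_map_raster` with elements `grid`,
#'   `mask` and `phase`.
#' @export
polar_map_raster <- function(grid, phase = c("late", "early"), mask = NULL) {
  phase <- match.arg(phase)
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid))
    stop("polar-map grid must be square", call. = FALSE)
  pc <- raster_polar_coords(nrow(grid))
  default_mask <- matrix(FALSE, nrow(grid), ncol(grid))
  default_mask[cbind(pc$i, pc$j)] <- pc$mask
  if (is.null(mask)) mask <- default_mask
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(grid)))
    stop("mask must have the same dimensions as the grid", call. = FALSE)
  v <- grid[mask]
  if (any(!is.finite(v)) || any(v < 0))
    stop("masked polar-map values must be finite and non-negative",
         call. = FALSE)
  structure(list(grid = grid, mask = mask, phase = phase),
            class = "polar_map_raster")
}

#' @export
print.polar_map_raster <- function(x, ...) {
  cat(sprintf("polar_map_raster: %d x %d, %s phase, %d in-map pixels\n",
              nrow(x$grid), ncol(x$grid), x$phase, sum(x$mask)))
  invisible(x)
}

#' Segmental uptake profile for one subject and phase
#'
#' The atomic measurement: 17 segmental uptake values following AHA
#' numbering (1-6 basal, 7-12 mid, 13-16 apical, 17 apex), either raw
#' segment mean counts or normalized percent-of-reference.
#'
#' @param values Numeric vector of exactly 17 finite, non-negative values.
#' @param phase `"early"` or `"late"`.
#' @param subject_id,sex,population Subject metadata; `sex` is `"M"`, `"F"`
#'   or `NA`.
#' @return An object of class `segment_profile`.
#' @export
segment_profile <- function(values, phase = c("late", "early"),
                            subject_id = NA_character_, sex = NA_character_,
                            population = NA_character_) {
  phase <- match.arg(phase)
  values <- as.numeric(values)
  if (length(values) != 17L)
    stop("a segment profile has exactly 17 values", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("segment values must be finite and non-negative", call. = FALSE)
  if (!is.na(sex) && !sex %in% c("M", "F"))
    stop("sex must be 'M', 'F' or NA", call. = FALSE)
  structure(list(values = values, phase = phase,
                 subject_id = as.character(subject_id),
                 sex = as.character(sex),
                 population = as.character(population)),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile: subject %s (%s, %s), %s phase\n",
              x$subject_id, x$population, x$sex, x$phase))
  print(round(stats::setNames(x$values, sprintf("seg%02d", 1:17)), 2))
  invisible(x)
}

#' Extract segment mean counts from a polar-map raster
#'
#' Assigns every in-map pixel to its AHA segment and averages the counts
#' per segment. Values are raw means (not yet normalized); apply
#' [normalize_profile()] for percent-of-reference units.
#'
#' @param raster A [polar_map_raster()].
#' @param geometry A [segment_geometry()].
#' @inheritParams segment_profile
#' @return A [segment_profile()] of raw per-segment mean counts.
#' @export
profile_from_raster <- function(raster, geometry = segment_geometry(),
                                subject_id = NA_character_,
                                sex = NA_character_,
                                population = NA_character_) {
  stopifnot(inherits(raster, "polar_map_raster"))
  pc <- raster_polar_coords(nrow(raster$grid))
  keep <- raster$mask[cbind(pc$i, pc$j)]
  seg <- segment_of_pixel(pmax(pc$radius[keep], 1e-9), pc$angle[keep],
                          geometry)
  counts <- raster$grid[cbind(pc$i[keep], pc$j[keep])]
  n_per_seg <- tabulate(seg, nbins = 17L)
  if (any(n_per_seg == 0L))
    stop("degenerate geometry: segment(s) ",
         paste(which(n_per_seg == 0L), collapse = ", "),
         " receive no pixels at this resolution", call. = FALSE)
  means <- as.numeric(tapply(counts, factor(seg, levels = 1:17), mean))
  segment_profile(means, phase = raster$phase, subject_id = subject_id,
                  sex = sex, population = population)
}

#' Render a segment profile as a piecewise-constant polar-map raster
#'
#' Inverse of [profile_from_raster()] for piecewise-constant maps: every
#' pixel of a segment takes that segment's value, so the round trip
#' `profile_from_raster(raster_from_profile(p))` reproduces `p` exactly.
#'
#' @param profile A [segment_profile()] (or bare numeric vector of 17
#'   values).
#' @param geometry A [segment_geometry()].
#' @param resolution Side length of the square raster, default 128.
#' @return A [polar_map_raster()].
#' @export
raster_from_profile <- function(profile, geometry = segment_geometry(),
                                resolution = 128L) {
  values <- if (inherits(profile, "segment_profile")) profile$values
            else as.numeric(profile)
  phase <- if (inherits(profile, "segment_profile")) profile$phase else "late"
  if (length(values) != 17L || any(!is.finite(values)))
    stop("profile must hold 17 finite values", call. = FALSE)
  n <- as.integer(resolution)
  pc <- raster_polar_coords(n)
  grid <- matrix(0, n, n)
  keep <- pc$mask
  seg <- segment_of_pixel(pmax(pc$radius[keep], 1e-9), pc$angle[keep],
                          geometry)
  if (length(unique(seg)) < 17L)
    stop("degenerate geometry: resolution ", n,
         " too small to cover all 17 segments", call. = FALSE)
  grid[cbind(pc$i[keep], pc$j[keep])] <- values[seg]
  polar_map_raster(grid, phase = phase)
}

#' Normalize a segment profile to percent of reference
#'
#' Rescales raw segment means linearly so the reference maps to 100%. The
#' default reference is the highest-valued segment, a deterministic and
#' noise-tolerant choice at the segment level; an explicit reference value
#' (e.g. the mean of the brightest pixels of the raster) can be supplied
#' instead.
#'
#' @param profile A [segment_profile()] or bare numeric vector of 17 raw
#'   values.
#' @param reference `"max_segment"` (default) or `"value"`.
#' @param ref_value Reference count mapped to 100% when
#'   `reference = "value"`; must be positive.
#' @return Same type as the input, values in percent units.
#' @export
normalize_profile <- function(profile, reference = c("max_segment", "value"),
                              ref_value = NULL) {
  reference <- match.arg(reference)
  values <- if (inherits(profile, "segment_profile")) profile$values
            else as.numeric(profile)
  ref <- if (reference == "max_segment") max(values) else as.numeric(ref_value)
  if (!length(ref) || !is.finite(ref) || ref <= 0)
    stop("normalization reference must be a positive finite value ",
         "(all-zero profiles cannot be normalized)", call. = FALSE)
  out <- values / ref * 100
  if (inherits(profile, "segment_profile")) {
    profile$values <- out
    profile
  } else out
}
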