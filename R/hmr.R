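#' Heart and mediastinum region-of-interest pair
#'
#' A circular heart ROI and a rectangular upper-mediastinal ROI on a planar
#' count image, in pixel coordinates (`row` increases downwards from the
#' top of the image, `col` rightwards).
#'
#' @param heart_center Numeric `(row, col)` of the heart-ROI center.
#' @param heart_radius Heart-ROI radius in pixels.
#' @param med_origin Numeric `(row, col)` of the mediastinal box's top-left
#'   corner.
#' @param med_width,med_height Box size in pixels (columns, rows).
#' @return An object of class `roi_pair`.
#' @export
roi_pair <- function(heart_center, heart_radius, med_origin, med_width,
                     med_height) {
  if (heart_radius <= 0 || med_width < 1 || med_height < 1)
    stop("ROIs must each cover at least one pixel", call. = FALSE)
  structure(list(heart_center = as.numeric(heart_center),
                 heart_radius = as.numeric(heart_radius),
                 med_origin = as.numeric(med_origin),
                 med_width = as.numeric(med_width),
                 med_height = as.numeric(med_height)),
            class = "roi_pair")
}

roi_masks <- function(image, rois) {
  stopifnot(inherits(rois, "roi_pair"))
  image <- as.matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  heart <- (rows - rois$heart_center[1])^2 +
           (cols - rois$heart_center[2])^2 <= rois$heart_radius^2
  med <- rows >= rois$med_origin[1] &
         rows < rois$med_origin[1] + rois$med_height &
         cols >= rois$med_origin[2] &
         cols < rois$med_origin[2] + rois$med_width
  if (!sum(heart) || !sum(med))
    stop("ROI error: each ROI must cover at least one pixel inside the ",
         "image", call. = FALSE)
  hc <- rois$heart_center
  if (hc[1] - rois$heart_radius < 1 || hc[1] + rois$heart_radius > nr ||
      hc[2] - rois$heart_radius < 1 || hc[2] + rois$heart_radius > nc ||
      rois$med_origin[1] < 1 || rois$med_origin[2] < 1 ||
      rois$med_origin[1] + rois$med_height - 1 > nr ||
      rois$med_origin[2] + rois$med_width - 1 > nc)
    stop("ROI error: ROI extends outside the image", call. = FALSE)
  if (any(heart & med))
    stop("ROI error: heart and mediastinum ROIs overlap", call. = FALSE)
  list(heart = heart, med = med)
}

#' Heart-to-mediastinum average count ratio
#'
#' The planar MIBG index: mean counts within the cardiac ROI divided by
#' mean counts within the upper-mediastinal ROI. Invariant to global
#' intensity scaling of the image.
#'
#' @param image Numeric matrix of non-negative planar counts.
#' @param rois An [roi_pair()].
#' @return The raw HMR (positive scalar).
#' @export
compute_hmr <- function(image, rois) {
  image <- as.matrix(image)
  if (any(!is.finite(image)) || any(image < 0))
    stop("planar counts must be finite and non-negative", call. = FALSE)
  masks <- roi_masks(image, rois)
  med_mean <- mean(image[masks$med])
  if (med_mean <= 0)
    stop("division error: mediastinal ROI mean count is zero",
         call. = FALSE)
  mean(image[masks$heart]) / med_mean
}

#' Standardize an HMR across collimator conditions
#'
#' Phantom cross-calibration between collimator/camera conditions is linear
#' with a fixed point at HMR = 1 (pure background):
#' `HMR_std = c * (HMR_raw - 1) + 1`. With `c = 1` the conversion is the
#' identity; composing two conversions multiplies their coefficients. The
#' package ships no numeric constants -- the coefficient for a given
#' camera/collimator pair comes from the user's calibration.
#'
#' @param hmr Raw HMR value(s). Values below 1 are allowed (flagged with a
#'   warning) since noisy low-uptake studies can dip below the fixed point.
#' @param coefficient Positive conversion coefficient to the target
#'   condition (default 1, e.g. when data are already in medium-energy
#'   general-purpose units).
#' @param source,target Optional condition labels recorded in the result.
#' @return An object of class `hmr_result` (fields `raw`, `standardized`,
#'   `coefficient`, `source`, `target`); use `$standardized` for the
#'   converted value. Vectorized over `hmr`.
#' @export
standardize_hmr <- function(hmr, coefficient = 1, source = "acquisition",
                            target = "MEGP") {
  hmr <- as.numeric(hmr)
  if (any(!is.finite(hmr)) || any(hmr <= 0))
    stop("raw HMR must be positive and finite", call. = FALSE)
  if (!is.finite(coefficient) || coefficient <= 0)
    stop("calibration error: conversion coefficient must be positive",
         call. = FALSE)
  if (any(hmr < 1))
    warning("HMR value(s) below 1 encountered; standardized anyway",
            call. = FALSE)
  structure(list(raw = hmr,
                 standardized = coefficient * (hmr - 1) + 1,
                 coefficient = coefficient,
                 source = source, target = target),
            class = "hmr_result")
}

#' @export
print.hmr_result <- function(x, ...) {
  cat(sprintf("hmr_result (%s -> %s, c = %g):\n", x$source, x$target,
              x$coefficient))
  print(data.frame(raw = round(x$raw, 3),
                   standardized = round(x$standardized, 3)),
        row.names = FALSE)
  invisible(x)
}
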