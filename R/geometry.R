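#' AHA 17-segment polar-map geometry
#'
#' Defines the partition of the polar map (bullseye) into the 17 segments of
#' the American Heart Association left-ventricular model: 6 basal, 6 mid,
#' 4 apical sectors plus a central apex disc. Rings are equal-width fractions
#' of the map radius; basal/mid sectors are 60 degrees wide and apical
#' sectors 90 degrees wide, each ring's first sector centered on the anterior
#' wall.
#'
#' The angular coordinate is measured in degrees from the anterior wall (the
#' top of the map as displayed), increasing towards the septum, so that
#' segments within each ring follow AHA numbering (anterior, anteroseptal,
#' inferoseptal, inferior, inferolateral, anterolateral for the basal and mid
#' rings; anterior, septal, inferior, lateral for the apical ring).
#'
#' @param ring_bounds Outer radial bound (fraction of map radius) of the apex
#'   disc, apical, mid and basal rings. Must be strictly increasing, positive,
#'   ending at 1.
#' @return An object of class `segment_geometry`.
#' @examples
#' geo <- segment_geometry()
#' segment_of_pixel(0.1, 123, geo)   # apex disc
#' segment_of_pixel(0.9, 0, geo)     # basal anterior
#' @export
segment_geometry <- function(ring_bounds = c(0.25, 0.5, 0.75, 1)) {
  if (length(ring_bounds) != 4L || any(!is.finite(ring_bounds)))
    stop("ring_bounds must be four finite values", call. = FALSE)
  if (any(diff(ring_bounds) <= 0) || ring_bounds[1] <= 0 ||
      abs(ring_bounds[4] - 1) > 1e-12)
    stop("ring_bounds must be strictly increasing in (0, 1] and end at 1",
         call. = FALSE)
  structure(list(ring_bounds = as.numeric(ring_bounds)),
            class = "segment_geometry")
}

#' Map polar coordinates to an AHA segment index
#'
#' @param radius Radius as a fraction of the map radius, in (0, 1].
#' @param angle Angle in degrees from the anterior wall (see
#'   [segment_geometry()]); any real value, reduced modulo 360.
#' @param geometry A [segment_geometry()] object.
#' @return Integer vector of segment indices in 1..17 (17 is the apex).
#' @export
segment_of_pixel <- function(radius, angle, geometry = segment_geometry()) {
  if (length(radius) != length(angle))
    stop("radius and angle must have equal length", call. = FALSE)
  if (any(!is.finite(radius)) || any(radius <= 0) || any(radius > 1 + 1e-12))
    stop("radius outside (0, 1]: pixel is outside the polar map",
         call. = FALSE)
  radius <- pmin(radius, 1)
  theta <- angle %% 360
  # ring 0 = apex disc, 1 = apical, 2 = mid, 3 = basal
  ring <- findInterval(radius, geometry$ring_bounds, left.open = TRUE)
  sec6 <- as.integer(floor(((theta + 30) %% 360) / 60)) + 1L
  sec4 <- as.integer(floor(((theta + 45) %% 360) / 90)) + 1L
  out <- integer(length(radius))
  out[ring == 0L] <- 17L
  out[ring == 1L] <- 12L + sec4[ring == 1L]
  out[ring == 2L] <- 6L + sec6[ring == 2L]
  out[ring == 3L] <- sec6[ring == 3L]
  out
}

#' Human-readable AHA segment names
#'
#' @return Character vector of length 17 in AHA order.
#' @export
segment_names <- function() {
  c("basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior", "apical lateral",
    "apex")
}

#' Coronary-territory segment assignment
#'
#' Standard AHA mapping of the 17 segments onto the three coronary
#' territories, used by the focal-defect (CAD) simulator.
#'
#' @param territory One of `"LAD"`, `"RCA"`, `"LCx"`.
#' @return Integer vector of segment indices belonging to the territory.
#' @export
territory_segments <- function(territory = c("LAD", "RCA", "LCx")) {
  territory <- match.arg(territory)
  switch(territory,
         LAD = c(1L, 2L, 7L, 8L, 13L, 14L, 17L),
         RCA = c(3L, 4L, 9L, 10L, 15L),
         LCx = c(5L, 6L, 11L, 12L, 16L))
}

# Polar coordinates (radius fraction, angle in degrees from anterior,
# increasing towards the septum) of every pixel of an n x n raster whose
# in-map disc is centered with radius n/2. Column 1 of the matrix is the
# septal side as displayed; row 1 is the anterior (top) side.
raster_polar_coords <- function(n) {
  c0 <- (n + 1) / 2
  rmax <- n / 2
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  dx <- ij$j - c0          # towards the lateral wall
  dy_up <- c0 - ij$i       # towards the anterior wall
  r <- sqrt(dx^2 + dy_up^2) / rmax
  theta <- (atan2(dy_up, dx) * 180 / pi - 90) %% 360
  list(i = ij$i, j = ij$j, radius = r, angle = theta, mask = r <= 1)
}
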