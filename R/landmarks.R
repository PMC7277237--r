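#' Landmark pair: occlusal midpoint + pulp-chamber floor
#'
#' Two reference points that seed the initial axis estimate.  For mandibular
#' teeth the occlusal surface lies above the pulp floor in image
#' coordinates, so `occlusal_midpoint` must have the smaller y.
#'
#' @param occlusal_midpoint,pulp_floor numeric `(x, y)` in px.
#' @return list of class `landmark_pair`.
#' @export
landmark_pair <- function(occlusal_midpoint, pulp_floor) {
  occ <- as.numeric(occlusal_midpoint); pulp <- as.numeric(pulp_floor)
  if (length(occ) != 2 || length(pulp) != 2 || any(!is.finite(c(occ, pulp))))
    stop("landmarks must be finite (x, y) pairs")
  if (occ[2] >= pulp[2])
    stop("occlusal midpoint must lie above the pulp floor (smaller y)")
  structure(list(occlusal_midpoint = c(x = occ[1], y = occ[2]),
                 pulp_floor = c(x = pulp[1], y = pulp[2])),
            class = "landmark_pair")
}

#' Estimate landmarks from mask geometry
#'
#' A geometric stand-in for learned landmark prediction: the occlusal
#' midpoint is the centroid of foreground pixels in the top 5% of the
#' mask's occupied rows, and the pulp-chamber floor the centroid of the
#' row band at 35-45% of the occupied height from the top (the pulp floor
#' sits just below the crown, roughly at the cervix).  The resulting axis
#' only needs to be a coarse seed; [refine_orientation()] does the rest.
#'
#' @param mask a nonempty [binary_mask()].
#' @return A [landmark_pair()].
#' @export
estimate_landmarks <- function(mask) {
  if (is_empty_mask(mask)) stop("empty mask")
  xy <- mask_coords(mask)
  rows <- sort(unique(xy[, 2]))
  if (length(rows) < 3)
    stop("degenerate mask: fewer than 3 occupied rows")
  rmin <- min(rows); rmax <- max(rows)
  h <- rmax - rmin + 1
  off <- xy[, 2] - rmin
  band_centroid <- function(lo, hi) {
    sel <- off >= lo & off < hi
    if (!any(sel)) {     # pick the nearest occupied row to the band center
      target <- rmin + (lo + hi) / 2
      nearest <- rows[which.min(abs(rows - target))]
      sel <- xy[, 2] == nearest
    }
    c(mean(xy[sel, 1]), mean(xy[sel, 2]))
  }
  occ <- band_centroid(0, max(1, 0.05 * h))
  pulp <- band_centroid(0.35 * h, 0.45 * h)
  landmark_pair(occ, pulp)
}

#' Initial axis angle from a landmark pair
#'
#' The seed orientation is the direction from the pulp floor up to the
#' occlusal midpoint: `atan2(x_occ - x_pulp, y_pulp - y_occ)` in degrees.
#' 0 means image-vertical; positive means the occlusal point lies to the
#' right of the pulp point.
#'
#' @param landmarks a [landmark_pair()].
#' @return Signed angle in degrees.
#' @export
initial_axis_angle <- function(landmarks) {
  occ <- landmarks$occlusal_midpoint; pulp <- landmarks$pulp_floor
  dx <- occ[["x"]] - pulp[["x"]]
  dy <- pulp[["y"]] - occ[["y"]]
  if (dx == 0 && dy == 0) stop("coincident landmarks: axis undefined")
  rad2deg(atan2(dx, dy))
}
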