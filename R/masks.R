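#' Binary tooth mask
#'
#' A `binary_mask` is a logical matrix (rows = y, columns = x) marking the
#' pixels of one tooth instance.  The coordinate convention is fixed
#' throughout the package: x rightward, y downward, 0-based, coordinates
#' refer to pixel centers (pixel `[r, c]` of the matrix sits at
#' `(x = c - 1, y = r - 1)`).
#'
#' @param pixels logical (or coercible) matrix, rows = y, columns = x.
#' @return A logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(m)) stop("mask contains NA")
  class(m) <- c("binary_mask", class(m))
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

mask_area <- function(mask) sum(mask)

is_empty_mask <- function(mask) !any(mask)

# foreground pixel centers as an n x 2 matrix, columns x, y (0-based)
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

mask_centroid <- function(mask) {
  xy <- mask_coords(mask)
  c(x = mean(xy[, 1]), y = mean(xy[, 2]))
}

#' Extract the boundary pixels of a mask
#'
#' A foreground pixel is a boundary pixel when at least one of its
#' 4-neighbors is background; the image border counts as background.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @return Matrix with columns `x`, `y`: 0-based centers of the boundary
#'   pixels (row-major order, not a traced contour; see
#'   [mask_to_polygon()] for an ordered contour).
#' @export
mask_to_boundary <- function(mask) {
  if (is_empty_mask(mask)) stop("empty mask: no boundary to extract")
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(as.logical(mask), h, w)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  up    <- pad[1:h,       2:(w + 1)]
  down  <- pad[3:(h + 2), 2:(w + 1)]
  left  <- pad[2:(h + 1), 1:w]
  right <- pad[2:(h + 1), 3:(w + 2)]
  boundary <- m & !(up & down & left & right)
  idx <- which(boundary, arr.ind = TRUE)
  cbind(x = unname(idx[, 2]) - 1, y = unname(idx[, 1]) - 1)
}

#' Tooth label (position, side, FDI code)
#'
#' Mandibular molars only: FDI 36/37/38 are the left first/second/third
#' molars, 46/47/48 the right ones.
#'
#' @param fdi_code integer FDI code in 36:38 or 46:48.
#' @return list with `position` ("M1"/"M2"/"M3"), `side` ("left"/"right")
#'   and `fdi_code`, of class `tooth_label`.
#' @export
tooth_label <- function(fdi_code) {
  fdi_code <- as.integer(fdi_code)
  if (!fdi_code %in% c(36L, 37L, 38L, 46L, 47L, 48L))
    stop(sprintf("FDI code %d is not a mandibular molar (36-38, 46-48)", fdi_code))
  side <- if (fdi_code %/% 10L == 3L) "left" else "right"
  position <- paste0("M", fdi_code %% 10L - 5L)
  structure(list(position = position, side = side, fdi_code = fdi_code),
            class = "tooth_label")
}

#' Single tooth instance: label + mask + optional landmarks
#'
#' @param label a [tooth_label()] or FDI code.
#' @param mask a nonempty [binary_mask()].
#' @param landmarks optional [landmark_pair()]; when present it must lie
#'   within the mask bounding box expanded by 5 px.
#' @param source_image_id character id of the source image.
#' @return list of class `tooth_instance`.
#' @export
tooth_instance <- function(label, mask, landmarks = NULL,
                           source_image_id = "") {
  if (!inherits(label, "tooth_label")) label <- tooth_label(label)
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  if (is_empty_mask(mask)) stop("tooth instance requires a nonempty mask")
  if (!is.null(landmarks)) {
    xy <- mask_coords(mask)
    lo <- c(min(xy[, 1]), min(xy[, 2])) - 5
    hi <- c(max(xy[, 1]), max(xy[, 2])) + 5
    pts <- rbind(landmarks$occlusal_midpoint, landmarks$pulp_floor)
    if (any(pts[, 1] < lo[1] | pts[, 1] > hi[1] |
            pts[, 2] < lo[2] | pts[, 2] > hi[2]))
      stop("landmarks fall outside the mask bounding box (+5 px)")
  }
  structure(list(label = label, mask = mask, landmarks = landmarks,
                 source_image_id = source_image_id),
            class = "tooth_instance")
}

#' A scene: up to six molar instances sharing one image frame
#'
#' @param image_id character id.
#' @param instances list of [tooth_instance()]; at most one per FDI code.
#' @param height,width image dimensions in px.
#' @return list of class `molar_scene`.
#' @export
molar_scene <- function(image_id, instances, height, width) {
  fdi <- vapply(instances, function(i) i$label$fdi_code, integer(1))
  if (anyDuplicated(fdi))
    stop("scene contains more than one instance for FDI code(s): ",
         paste(unique(fdi[duplicated(fdi)]), collapse = ", "))
  structure(list(image_id = image_id, instances = instances,
                 height = as.integer(height), width = as.integer(width)),
            class = "molar_scene")
}

#' @export
print.molar_scene <- function(x, ...) {
  cat(sprintf("<molar_scene '%s' %dx%d px, %d instance(s): %s>\n",
              x$image_id, x$height, x$width, length(x$instances),
              paste(vapply(x$instances, function(i) i$label$fdi_code,
                           integer(1)), collapse = ",")))
  invisible(x)
}

scene_fdi <- function(scene)
  vapply(scene$instances, function(i) i$label$fdi_code, integer(1))
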