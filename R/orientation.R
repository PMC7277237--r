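#' Configuration for the iterative orientation refinement
#'
#' @param n_iterations number of refinement iterations (default 10; ten
#'   iterations are ample for convergence on clean contours).
#' @param band_top_frac,band_bottom_frac the retained fraction of the
#'   upright contour's vertical extent after censoring the occlusal surface
#'   (top) and the roots (bottom).  Defaults `[0.15, 0.55]` keep a section
#'   of crown and cervix.
#' @param early_stop_tol_deg stop early when the per-iteration correction
#'   falls below this (degrees); 0 disables early stopping.
#' @param min_band_rows minimum number of distinct contour rows the
#'   censored band must retain.
#' @return list of class `orientation_config`.
#' @export
orientation_config <- function(n_iterations = 10L,
                               band_top_frac = 0.15,
                               band_bottom_frac = 0.55,
                               early_stop_tol_deg = 0,
                               min_band_rows = 8L) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (!(band_top_frac >= 0 && band_top_frac < band_bottom_frac &&
        band_bottom_frac <= 1))
    stop("need 0 <= band_top_frac < band_bottom_frac <= 1")
  if (early_stop_tol_deg < 0) stop("early_stop_tol_deg must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 band_top_frac = band_top_frac,
                 band_bottom_frac = band_bottom_frac,
                 early_stop_tol_deg = early_stop_tol_deg,
                 min_band_rows = as.integer(min_band_rows)),
            class = "orientation_config")
}

#' Rotate contour coordinates to the upright frame
#'
#' Rigid rotation by `-angle_deg` about `pivot`, so that a shape whose long
#' axis sits at `angle_deg` (package sign convention) becomes vertical.
#'
#' @param points n x 2 matrix of `(x, y)` coordinates.
#' @param angle_deg the current axis-angle estimate, degrees.
#' @param pivot `(x, y)` rotation center.
#' @return Rotated n x 2 matrix.
#' @export
to_upright <- function(points, angle_deg, pivot) {
  pts <- as_point_matrix(points)
  th <- deg2rad(angle_deg)
  dx <- pts[, 1] - pivot[1]; dy <- pts[, 2] - pivot[2]
  cbind(x = pivot[1] + cos(th) * dx + sin(th) * dy,
        y = pivot[2] - sin(th) * dx + cos(th) * dy)
}

# inverse of to_upright: carries an upright shape to axis angle angle_deg
rotate_points <- function(points, angle_deg, pivot) {
  to_upright(points, -angle_deg, pivot)
}

# resample a closed polyline at roughly `step` px spacing so that, after
# any rotation, every integer row crossed by the contour holds points from
# both sides of the shape
densify_closed_polyline <- function(pts, step = 0.25) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  seg_len <- sqrt(rowSums((nxt - pts)^2))
  pieces <- lapply(seq_len(n), function(i) {
    k <- max(1L, ceiling(seg_len[i] / step))
    t <- (seq_len(k) - 1) / k
    cbind(pts[i, 1] + t * (nxt[i, 1] - pts[i, 1]),
          pts[i, 2] + t * (nxt[i, 2] - pts[i, 2]))
  })
  out <- do.call(rbind, pieces)
  colnames(out) <- c("x", "y")
  out
}

#' Censor roots and occlusal surface from an upright contour
#'
#' Keeps the points whose relative height
#' `(y - y_min) / (y_max - y_min)` lies in
#' `[band_top_frac, band_bottom_frac]`, i.e. a section of crown and cervix.
#'
#' @param points upright contour coordinates (n x 2).
#' @param config an [orientation_config()].
#' @return The retained coordinates.
#' @export
censor_band <- function(points, config = orientation_config()) {
  pts <- as_point_matrix(points)
  ymin <- min(pts[, 2]); ymax <- max(pts[, 2])
  if (ymax == ymin) stop("censor error: contour has no vertical extent")
  rel <- (pts[, 2] - ymin) / (ymax - ymin)
  keep <- rel >= config$band_top_frac & rel <= config$band_bottom_frac
  kept <- pts[keep, , drop = FALSE]
  if (length(unique(round(kept[, 2]))) < config$min_band_rows)
    stop(sprintf("censor error: band retains %d distinct rows (< %d)",
                 length(unique(round(kept[, 2]))), config$min_band_rows))
  kept
}

#' Split a censored contour into its left and right side chains
#'
#' For each occupied row (y rounded to integer) the leftmost point goes to
#' the left chain and the rightmost to the right chain; single-point rows
#' contribute to both.  After upright rotation these are the mesial and
#' distal surfaces (which is which depends on the tooth's side).
#'
#' @param points retained upright coordinates (n x 2).
#' @return list with `left` and `right` n x 2 matrices.
#' @export
split_sides <- function(points) {
  pts <- as_point_matrix(points)
  row <- round(pts[, 2])
  if (length(unique(row)) < 2)
    stop("split error: fewer than 2 distinct rows")
  ord <- order(row, pts[, 1])
  pts <- pts[ord, , drop = FALSE]; row <- row[ord]
  first <- !duplicated(row)
  last <- !duplicated(row, fromLast = TRUE)
  list(left = pts[first, , drop = FALSE],
       right = pts[last, , drop = FALSE])
}

#' Least-squares line through a near-vertical side chain
#'
#' Fits `x = a + b * y` (x regressed on y, well conditioned because the
#' sides are near-vertical after upright rotation).  `angle_deg` is
#' `atan(b)` in degrees — the line's signed deviation from vertical in
#' slope terms; note its sign is opposite to the package axis-angle
#' convention (see [refine_orientation()]).
#'
#' @param chain n x 2 matrix of `(x, y)` points, n >= 2, with at least two
#'   distinct y values.
#' @return list of class `regression_line`: `intercept_x`, `slope_dx_dy`,
#'   `angle_deg`, `n_points`.
#' @export
fit_side_line <- function(chain) {
  pts <- as_point_matrix(chain)
  if (nrow(pts) < 2) stop("fit error: need at least 2 points")
  y <- pts[, 2]; x <- pts[, 1]
  if (max(y) == min(y)) stop("fit error: all y identical")
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((y - mean(y))^2)
  a <- mean(x) - b * mean(y)
  structure(list(intercept_x = a, slope_dx_dy = b,
                 angle_deg = rad2deg(atan(b)), n_points = nrow(pts)),
            class = "regression_line")
}

#' Iteratively refine a molar's orientation by contour-side regression
#'
#' The long-axis angle is estimated by repeating, for `n_iterations`
#' (default 10): rotate the tooth contour upright by the current estimate,
#' censor roots and occlusal surface, split the remaining crown/cervix band
#' into its two side chains, fit a least-squares line to each, and correct
#' the estimate by the mean orientation of the two lines.  The initial
#' estimate comes from the landmark pair (supplied on the instance or
#' estimated via [estimate_landmarks()]).
#'
#' The correction applied is `-(angle_left + angle_right) / 2`: a side line
#' with slope `dx/dy = b` deviates from vertical by `atan(b)` but its axis
#' orientation in the package sign convention (positive = top toward +x) is
#' `-atan(b)`, because y grows downward.
#'
#' @param instance a [tooth_instance()] (or bare [binary_mask()]).
#' @param config an [orientation_config()].
#' @return list of class `orientation_result`: `initial_angle_deg`, `trace`
#'   (per-iteration angle estimates), `final_angle_deg`,
#'   `final_magnitude_deg`, `left_line`/`right_line` (final iteration,
#'   [fit_side_line()] objects), `mesial_line`/`distal_line` (the same two,
#'   named using the tooth's side when known), `converged`, `n_iterations`.
#' @export
refine_orientation <- function(instance, config = orientation_config()) {
  if (inherits(instance, "binary_mask") || is.matrix(instance))
    instance <- tooth_instance(36L, instance)
  mask <- instance$mask
  if (is_empty_mask(mask)) stop("empty mask")
  if (mask_area(mask) < 200)
    warning("mask has fewer than 200 foreground px; angle may be unreliable")
  contour <- densify_closed_polyline(mask_to_polygon(mask))
  pivot <- c(mean(contour[, 1]), mean(contour[, 2]))
  lm <- instance$landmarks
  if (is.null(lm)) lm <- estimate_landmarks(mask)
  theta <- initial_axis_angle(lm)
  initial <- theta
  trace <- numeric(0)
  converged <- FALSE
  left_fit <- right_fit <- NULL
  for (k in seq_len(config$n_iterations)) {
    up <- to_upright(contour, theta, pivot)
    kept <- tryCatch(censor_band(up, config),
                     error = function(e) stop("iteration ", k, ": ",
                                              conditionMessage(e)))
    # band-edge hygiene: a row only partially covered by the censor band can
    # hold points from just one side, which would contaminate the other
    # side's chain; keep only rows whose full [r-0.5, r+0.5] span is in-band
    ymin <- min(up[, 2]); ext <- max(up[, 2]) - ymin
    lo <- ymin + config$band_top_frac * ext
    hi <- ymin + config$band_bottom_frac * ext
    row <- round(kept[, 2])
    full <- row - 0.5 >= lo & row + 0.5 <= hi
    if (length(unique(row[full])) >= config$min_band_rows)
      kept <- kept[full, , drop = FALSE]
    sides <- tryCatch(split_sides(kept),
                      error = function(e) stop("iteration ", k, ": ",
                                               conditionMessage(e)))
    left_fit <- tryCatch(fit_side_line(sides$left),
                         error = function(e) stop("iteration ", k, ": ",
                                                  conditionMessage(e)))
    right_fit <- tryCatch(fit_side_line(sides$right),
                          error = function(e) stop("iteration ", k, ": ",
                                                   conditionMessage(e)))
    delta <- -(left_fit$angle_deg + right_fit$angle_deg) / 2
    theta <- theta + delta
    trace <- c(trace, theta)
    if (config$early_stop_tol_deg > 0 && abs(delta) < config$early_stop_tol_deg) {
      converged <- TRUE
      break
    }
  }
  if (config$early_stop_tol_deg == 0) converged <- abs(delta) < 0.1
  side <- instance$label$side
  mesial <- if (identical(side, "right")) left_fit else right_fit
  distal <- if (identical(side, "right")) right_fit else left_fit
  structure(list(initial_angle_deg = initial,
                 trace = trace,
                 final_angle_deg = theta,
                 final_magnitude_deg = abs(theta),
                 left_line = left_fit, right_line = right_fit,
                 mesial_line = mesial, distal_line = distal,
                 converged = converged,
                 n_iterations = length(trace)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf(paste0("<orientation_result: initial %.2f deg -> final %.2f deg ",
                     "(|angle| %.2f deg) in %d iteration(s)%s>\n"),
              x$initial_angle_deg, x$final_angle_deg, x$final_magnitude_deg,
              x$n_iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Measure all instances of a scene
#'
#' Runs [refine_orientation()] on every tooth of a scene and returns the
#' angle table in the package CSV dialect.  Per-instance failures do not
#' abort the batch: the failing tooth gets NA angles and its error message
#' is attached as the `errors` attribute.
#'
#' @param scene a [molar_scene()].
#' @param config an [orientation_config()].
#' @return data.frame with columns image_id, fdi, position, side,
#'   angle_signed_deg, angle_magnitude_deg, n_iterations, converged.
#' @export
measure_scene <- function(scene, config = orientation_config()) {
  rows <- list(); errs <- character(0)
  for (inst in scene$instances) {
    res <- tryCatch(refine_orientation(inst, config), error = identity)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("%s/%d: %s", scene$image_id,
                              inst$label$fdi_code, conditionMessage(res)))
      rows[[length(rows) + 1]] <- data.frame(
        image_id = scene$image_id, fdi = inst$label$fdi_code,
        position = inst$label$position, side = inst$label$side,
        angle_signed_deg = NA_real_, angle_magnitude_deg = NA_real_,
        n_iterations = NA_integer_, converged = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        image_id = scene$image_id, fdi = inst$label$fdi_code,
        position = inst$label$position, side = inst$label$side,
        angle_signed_deg = res$final_angle_deg,
        angle_magnitude_deg = res$final_magnitude_deg,
        n_iterations = res$n_iterations, converged = res$converged)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), fdi = integer(0),
               position = character(0), side = character(0),
               angle_signed_deg = numeric(0), angle_magnitude_deg = numeric(0),
               n_iterations = integer(0), converged = logical(0))
  attr(out, "errors") <- errs
  out
}
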