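#' Rasterize a polygon to a binary mask
#'
#' A pixel is foreground iff its center `(x = col, y = row)` (0-based) lies
#' inside the polygon or on its boundary (even-odd rule).  The polygon may
#' be non-convex but must be simple.
#'
#' @param points numeric n x 2 matrix (or list of `c(x, y)` pairs) of
#'   polygon vertices, at least 3.
#' @param height,width raster dimensions in px.
#' @return A [binary_mask()] of size `height` x `width`.
#' @export
polygon_to_mask <- function(points, height, width) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 3) stop("polygon needs at least 3 points")
  if (polygon_self_intersects(pts))
    stop("self-intersecting polygon is not supported")
  if (abs(pracma::polyarea(pts[, 1], pts[, 2])) < 1e-9)
    stop("degenerate polygon: vertices are collinear or coincident")
  mask <- matrix(FALSE, height, width)
  # evaluate only inside the bounding box
  cs <- max(0, floor(min(pts[, 1]))):min(width - 1, ceiling(max(pts[, 1])))
  rs <- max(0, floor(min(pts[, 2]))):min(height - 1, ceiling(max(pts[, 2])))
  if (length(cs) == 0 || length(rs) == 0) return(binary_mask(mask))
  grid <- expand.grid(x = cs, y = rs)
  inside <- pracma::inpolygon(grid$x, grid$y, pts[, 1], pts[, 2],
                              boundary = TRUE)
  mask[cbind(grid$y + 1, grid$x + 1)] <- inside
  binary_mask(mask)
}

# default image ids drop the file extension so PNG and JSON annotations of
# the same scene share one id
strip_ext <- function(x) sub("\\.[A-Za-z0-9]+$", "", x)

as_point_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, points)
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must be (x, y) pairs")
  storage.mode(pts) <- "double"
  if (any(!is.finite(pts))) stop("non-finite polygon coordinates")
  colnames(pts) <- c("x", "y")
  pts
}

# O(n^2) proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1), , drop = FALSE]
  seg_cross <- function(p1, p2, p3, p4) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    for (j in js) {
      if (seg_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Trace the outer contour of a mask as an ordered polygon
#'
#' Returns the ordered boundary-pixel-center polygon of the largest
#' connected foreground component (contour tracing via EBImage).
#'
#' @param mask a nonempty [binary_mask()].
#' @return n x 2 matrix of ordered `(x, y)` vertices, 0-based pixel centers.
#' @export
mask_to_polygon <- function(mask) {
  if (is_empty_mask(mask)) stop("empty mask: no contour to trace")
  img <- EBImage::Image(t(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  # label connected components first: contour tracing needs one object per
  # label, and noisy masks may carry small satellite components
  lab <- EBImage::bwlabel(img)
  areas <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  comp <- EBImage::Image(as.numeric(lab == which.max(areas)), dim = dim(lab))
  oc <- EBImage::ocontour(comp)
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  if (nrow(pts) < 3)
    stop("degenerate mask: traced contour has fewer than 3 points")
  colnames(pts) <- c("x", "y")
  pts
}

default_label_table <- function() setNames(c(36L, 37L, 38L, 46L, 47L, 48L), 1:6)

#' Read a label-map PNG into a scene
#'
#' The PNG must be single-channel 8-bit; index 0 is background and nonzero
#' indices map to FDI codes through `label_table`.
#'
#' @param path PNG file path.
#' @param label_table named integer vector mapping label index (name) to
#'   FDI code; default maps 1..6 to 36,37,38,46,47,48.
#' @param image_id id stored on the scene (default: file name).
#' @return A [molar_scene()].
#' @export
read_label_map <- function(path, label_table = default_label_table(),
                           image_id = NULL) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] > 1 && !all(raw[, , 1] == raw[, , 2]))
      stop("label-map PNG must be single-channel 8-bit")
    raw <- raw[, , 1]
  }
  idx <- round(raw * 255)
  if (max(abs(raw * 255 - idx)) > 1e-6)
    stop("label-map PNG must be 8-bit (indices 0-255)")
  present <- sort(unique(as.vector(idx)))
  present <- present[present != 0]
  instances <- list()
  for (v in present) {
    fdi <- label_table[as.character(v)]
    if (is.na(fdi) || is.null(fdi))
      stop(sprintf("unknown label index %d (not in label table)", v))
    instances[[length(instances) + 1]] <-
      tooth_instance(tooth_label(fdi), binary_mask(idx == v),
                     source_image_id = if (is.null(image_id)) strip_ext(basename(path)) else image_id)
  }
  molar_scene(if (is.null(image_id)) strip_ext(basename(path)) else image_id,
              instances, nrow(idx), ncol(idx))
}

#' Write a scene as a label-map PNG
#'
#' Inverse of [read_label_map()]: each instance's mask is painted with its
#' label index.  Masks are expected to be disjoint; later instances win on
#' overlap.
#'
#' @param scene a [molar_scene()].
#' @param path output PNG path.
#' @param label_table named integer vector, label index -> FDI code.
#' @export
write_label_map <- function(scene, path, label_table = default_label_table()) {
  fdi_to_idx <- setNames(as.integer(names(label_table)), label_table)
  img <- matrix(0L, scene$height, scene$width)
  for (inst in scene$instances) {
    v <- fdi_to_idx[as.character(inst$label$fdi_code)]
    if (is.na(v)) stop("FDI code ", inst$label$fdi_code, " not in label table")
    img[inst$mask] <- v
  }
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a key=value label-table file ("1=36" per line)
#'
#' @param path text file path; blank lines and `#` comments ignored.
#' @return named integer vector, index -> FDI code.
#' @export
read_label_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed label-table line: ", lines[bad][1])
  setNames(as.integer(vapply(kv, `[`, "", 2)),
           trimws(vapply(kv, `[`, "", 1)))
}

#' @rdname read_label_table
#' @param label_table named vector to write.
#' @export
write_label_table <- function(label_table, path) {
  writeLines(paste0(names(label_table), "=", label_table), path)
  invisible(path)
}

#' Read a LabelMe-style polygon annotation into a scene
#'
#' Expects top-level `imageHeight`, `imageWidth` and `shapes`; each shape
#' must be a polygon (>= 3 points) whose `label` is an FDI code.  Each
#' polygon is rasterized with [polygon_to_mask()].  When polygons overlap,
#' later shapes win per pixel (a warning is raised).
#'
#' @param path JSON file path.
#' @param image_id id stored on the scene (default: file name).
#' @return A [molar_scene()].  Optional per-shape landmarks (keys
#'   `occlusal`, `pulp_floor`) are attached when present.
#' @export
read_labelme <- function(path, image_id = NULL) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (k in c("imageHeight", "imageWidth", "shapes"))
    if (is.null(js[[k]])) stop("LabelMe JSON missing key '", k, "'")
  h <- as.integer(js$imageHeight); w <- as.integer(js$imageWidth)
  id <- if (is.null(image_id)) strip_ext(basename(path)) else image_id
  instances <- list()
  claimed <- matrix(FALSE, h, w)
  for (shape in js$shapes) {
    st <- if (is.null(shape$shape_type)) "polygon" else shape$shape_type
    if (!identical(st, "polygon"))
      stop("unsupported shape_type '", st, "' (only polygons are supported)")
    fdi <- suppressWarnings(as.integer(shape$label))
    if (is.na(fdi)) stop("cannot parse shape label '", shape$label,
                         "' as an FDI code")
    pts <- as_point_matrix(lapply(shape$points, function(p) c(p[[1]], p[[2]])))
    if (nrow(pts) < 3) stop("polygon for label ", fdi, " has < 3 points")
    mask <- polygon_to_mask(pts, h, w)
    if (any(mask & claimed)) {
      warning("overlapping polygons: later shape (label ", fdi,
              ") wins per pixel")
      for (i in seq_along(instances)) {
        prev <- instances[[i]]
        newmask <- prev$mask & !mask
        instances[[i]] <- tooth_instance(prev$label, binary_mask(newmask),
                                         prev$landmarks, prev$source_image_id)
      }
    }
    claimed <- claimed | mask
    lm <- NULL
    if (!is.null(shape$occlusal) && !is.null(shape$pulp_floor))
      lm <- landmark_pair(unlist(shape$occlusal), unlist(shape$pulp_floor))
    instances[[length(instances) + 1]] <-
      tooth_instance(tooth_label(fdi), mask, lm, source_image_id = id)
  }
  molar_scene(id, instances, h, w)
}

#' Write polygons as a LabelMe-style JSON annotation
#'
#' @param polygons named list: FDI code (as name) -> n x 2 vertex matrix.
#' @param height,width image dimensions.
#' @param path output JSON path.
#' @export
write_labelme <- function(polygons, height, width, path) {
  shapes <- lapply(names(polygons), function(lab) {
    pts <- as_point_matrix(polygons[[lab]])
    list(label = lab,
         points = lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
         shape_type = "polygon")
  })
  jsonlite::write_json(
    list(imageHeight = height, imageWidth = width, shapes = shapes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

angle_csv_columns <- c("image_id", "fdi", "position", "side",
                       "angle_signed_deg", "angle_magnitude_deg",
                       "n_iterations", "converged")

#' Write / read the per-tooth angle CSV table
#'
#' Columns: image_id, fdi, position, side, angle_signed_deg,
#' angle_magnitude_deg, n_iterations, converged.  Comma-separated, UTF-8,
#' "." decimal separator; lines starting with `#` are treated as comments
#' on read (used to record the generator seed).
#'
#' @param records data.frame with the columns above.
#' @param path CSV path.
#' @param comment optional character vector written as `#`-prefixed header
#'   lines (e.g. `"seed=7"`).
#' @export
write_angle_csv <- function(records, path, comment = NULL) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(angle_csv_columns, names(records))
  if (length(missing_cols))
    stop("angle records missing column(s): ", paste(missing_cols, collapse = ", "))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(records[, angle_csv_columns, drop = FALSE], con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_angle_csv
#' @export
read_angle_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
           fileEncoding = "UTF-8")
}
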