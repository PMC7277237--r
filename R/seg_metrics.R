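#' Pixel-wise confusion counts between two masks
#'
#' @param pred,ref [binary_mask()]s of identical dimensions.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref)))
    stop("shape error: masks have different dimensions")
  p <- as.logical(pred); r <- as.logical(ref)
  structure(list(tp = sum(p & r), fp = sum(p & !r),
                 fn = sum(!p & r), tn = sum(!p & !r)),
            class = "confusion_counts")
}

metric_ratio <- function(num, den, name) {
  if (den == 0) {
    warning(name, " undefined (zero denominator); returning NaN")
    return(NaN)
  }
  num / den
}

#' Segmentation overlap metrics from confusion counts
#'
#' IoU = TP/(TP+FP+FN), precision = TP/(TP+FP), recall = TP/(TP+FN).
#' A zero denominator yields NaN with a warning rather than an error, so
#' batch evaluation continues.
#'
#' @param counts a [confusion_counts()].
#' @return numeric scalar.
#' @export
iou <- function(counts)
  metric_ratio(counts$tp, counts$tp + counts$fp + counts$fn, "IoU")

#' @rdname iou
#' @export
precision <- function(counts)
  metric_ratio(counts$tp, counts$tp + counts$fp, "precision")

#' @rdname iou
#' @export
recall <- function(counts)
  metric_ratio(counts$tp, counts$tp + counts$fn, "recall")

# max over rows of the min distance to any point of b (directed Hausdorff)
directed_hausdorff <- function(a, b) {
  # chunk rows of a to bound the distance-matrix size
  step <- max(1L, floor(4e6 / nrow(b)))
  worst <- 0
  for (i0 in seq(1, nrow(a), by = step)) {
    idx <- i0:min(i0 + step - 1, nrow(a))
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Hausdorff distance between two masks (boundary point sets)
#'
#' The symmetric Hausdorff distance (default) is the larger of the two
#' directed max-min Euclidean distances between the boundary pixel sets of
#' the masks (see [mask_to_boundary()]), in px.
#'
#' @param pred,ref nonempty [binary_mask()]s.
#' @param directed if `TRUE`, return only the pred-to-ref directed
#'   distance.
#' @return distance in px.
#' @export
hausdorff <- function(pred, ref, directed = FALSE) {
  if (is_empty_mask(pred) || is_empty_mask(ref))
    stop("empty mask: Hausdorff distance undefined")
  a <- mask_to_boundary(pred); b <- mask_to_boundary(ref)
  d_ab <- directed_hausdorff(a, b)
  if (directed) return(d_ab)
  max(d_ab, directed_hausdorff(b, a))
}

#' Score all matched teeth of a predicted scene against a reference
#'
#' Teeth are matched by FDI code.  Unmatched reference teeth are reported
#' as missing and excluded from the means.
#'
#' @param pred,ref [molar_scene()]s over the same image frame.
#' @return list of class `scene_score`: `per_tooth` data.frame (fdi,
#'   position, side, iou, precision, recall, hausdorff_px), `by_position`
#'   mean metrics per M1/M2/M3 with counts, `overall` one-row means,
#'   `missing_in_pred` / `extra_in_pred` FDI vectors.
#' @export
score_scene <- function(pred, ref) {
  if (pred$height != ref$height || pred$width != ref$width)
    stop("shape error: scenes have different image dimensions")
  pf <- scene_fdi(pred); rf <- scene_fdi(ref)
  common <- intersect(rf, pf)
  rows <- lapply(common, function(f) {
    p <- pred$instances[[match(f, pf)]]; r <- ref$instances[[match(f, rf)]]
    cc <- confusion_counts(p$mask, r$mask)
    data.frame(fdi = f, position = r$label$position, side = r$label$side,
               iou = iou(cc), precision = precision(cc), recall = recall(cc),
               hausdorff_px = hausdorff(p$mask, r$mask))
  })
  per_tooth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fdi = integer(0), position = character(0), side = character(0),
               iou = numeric(0), precision = numeric(0), recall = numeric(0),
               hausdorff_px = numeric(0))
  metrics <- c("iou", "precision", "recall", "hausdorff_px")
  by_position <- if (nrow(per_tooth)) {
    agg <- aggregate(per_tooth[metrics], by = list(position = per_tooth$position),
                     FUN = mean)
    agg$n <- as.vector(table(per_tooth$position)[agg$position])
    agg
  } else NULL
  overall <- if (nrow(per_tooth))
    as.data.frame(c(lapply(per_tooth[metrics], mean), list(n = nrow(per_tooth))))
  else NULL
  structure(list(per_tooth = per_tooth, by_position = by_position,
                 overall = overall,
                 missing_in_pred = setdiff(rf, pf),
                 extra_in_pred = setdiff(pf, rf)),
            class = "scene_score")
}

#' @export
print.scene_score <- function(x, ...) {
  cat("Per-tooth segmentation scores:\n")
  print(x$per_tooth, row.names = FALSE)
  if (!is.null(x$by_position)) {
    cat("\nMeans by position:\n")
    print(x$by_position, row.names = FALSE)
  }
  if (length(x$missing_in_pred))
    cat("\nMissing in prediction (excluded from means):",
        paste(x$missing_in_pred, collapse = ", "), "\n")
  invisible(x)
}
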