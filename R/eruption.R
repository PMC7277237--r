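#' Eruption rule for third molars
#'
#' A third molar angled above the critical angle (27.0 degrees by default)
#' is unlikely to reach functional eruption; angles within the borderline
#' interval `[24.5, 29.5]` around the critical angle are flagged as
#' borderline calls.
#'
#' @param critical_angle_deg critical angle, degrees (default 27.0).
#' @param borderline_low,borderline_high borderline interval bounds
#'   (defaults 24.5 and 29.5); must bracket the critical angle.
#' @return list of class `eruption_rule`.
#' @export
eruption_rule <- function(critical_angle_deg = 27.0,
                          borderline_low = 24.5,
                          borderline_high = 29.5) {
  if (!(borderline_low <= critical_angle_deg &&
        critical_angle_deg <= borderline_high))
    stop("borderline interval must contain the critical angle")
  structure(list(critical_angle_deg = critical_angle_deg,
                 borderline_low = borderline_low,
                 borderline_high = borderline_high),
            class = "eruption_rule")
}

#' Classify third-molar eruption potential from the angle magnitude
#'
#' Verdict is `"unfavorable"` iff the angle strictly exceeds the critical
#' angle (an angle of exactly 27.0 degrees is favorable); the borderline
#' flag is set when the angle falls inside the borderline interval
#' (inclusive), independently of the verdict.
#'
#' @param angle_deg unsigned angle magnitude in `[0, 90]`.
#' @param rule an [eruption_rule()].
#' @param stage optional Demirjian letter (A-H) recorded on the call.
#' @return list of class `eruption_call`: `verdict`, `borderline`,
#'   `angle_deg`, `stage_class`.
#' @export
classify_eruption <- function(angle_deg, rule = eruption_rule(),
                              stage = NULL) {
  if (!is.finite(angle_deg) || angle_deg < 0 || angle_deg > 90)
    stop("domain error: angle must lie in [0, 90] degrees")
  structure(list(
    verdict = if (angle_deg > rule$critical_angle_deg) "unfavorable" else "favorable",
    borderline = angle_deg >= rule$borderline_low &
      angle_deg <= rule$borderline_high,
    angle_deg = angle_deg,
    stage_class = if (is.null(stage)) "unknown" else shorten_demirjian(stage)),
    class = "eruption_call")
}

#' Shortened Demirjian development-stage classes
#'
#' Maps the A-H Demirjian stages to three classes: follicles without root
#' formation (A-D), starting root bifurcation (E), and root length equal
#' to or greater than the crown height (F-H).
#'
#' @param stage a single letter A-H, or `"unknown"`.
#' @return `"no_roots"`, `"bifurcation"`, `"developed_roots"` or
#'   `"unknown"`.
#' @export
shorten_demirjian <- function(stage) {
  if (identical(stage, "unknown") || is.null(stage) || is.na(stage))
    return("unknown")
  stage <- toupper(as.character(stage))
  if (!stage %in% LETTERS[1:8])
    stop("stage error: '", stage, "' is not a Demirjian stage (A-H)")
  if (stage %in% LETTERS[1:4]) "no_roots"
  else if (stage == "E") "bifurcation"
  else "developed_roots"
}

#' Eruption calls for an angle table
#'
#' Applies [classify_eruption()] to every third molar of an angle table
#' (package CSV dialect).  In `"absolute"` mode the measured M3 magnitude
#' is used directly; in `"relative"` mode the angle is the magnitude of the
#' difference between the M3 and the ipsilateral M2 signed angles (the M2
#' long axis as the clinical reference axis).
#'
#' @param angles data.frame as produced by [measure_scene()] /
#'   [read_angle_csv()].
#' @param rule an [eruption_rule()].
#' @param mode `"absolute"` or `"relative"`.
#' @param stages optional data.frame (image_id, fdi, stage) with Demirjian
#'   letters.
#' @return data.frame: image_id, fdi, mode, angle_deg, verdict, borderline,
#'   stage_class.
#' @export
classify_eruption_table <- function(angles, rule = eruption_rule(),
                                    mode = c("absolute", "relative"),
                                    stages = NULL) {
  mode <- match.arg(mode)
  m3 <- angles[angles$position == "M3" & !is.na(angles$angle_magnitude_deg), ,
               drop = FALSE]
  rows <- lapply(seq_len(nrow(m3)), function(i) {
    r <- m3[i, ]
    ang <- if (mode == "absolute") r$angle_magnitude_deg else {
      m2 <- angles[angles$image_id == r$image_id &
                     angles$position == "M2" & angles$side == r$side, ]
      if (nrow(m2) != 1 || is.na(m2$angle_signed_deg)) return(NULL)
      abs(r$angle_signed_deg - m2$angle_signed_deg)
    }
    stage <- NULL
    if (!is.null(stages)) {
      s <- stages[stages$image_id == r$image_id & stages$fdi == r$fdi, ]
      if (nrow(s) == 1) stage <- s$stage
    }
    call <- classify_eruption(min(ang, 90), rule, stage)
    data.frame(image_id = r$image_id, fdi = r$fdi, mode = mode,
               angle_deg = call$angle_deg, verdict = call$verdict,
               borderline = call$borderline, stage_class = call$stage_class)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), fdi = integer(0), mode = character(0),
               angle_deg = numeric(0), verdict = character(0),
               borderline = logical(0), stage_class = character(0))
}
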