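#' Paired angle measurements (reference vs test)
#'
#' @param reference,test numeric vectors of equal length (>= 2), degrees.
#' @param ids optional parallel labels.
#' @return list of class `paired_angles`.
#' @export
paired_angles <- function(reference, test, ids = NULL) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length")
  if (length(reference) < 2) stop("need at least 2 pairs")
  if (any(!is.finite(reference)) || any(!is.finite(test)))
    stop("angles must be finite")
  if (is.null(ids)) ids <- as.character(seq_along(reference))
  structure(list(reference = as.numeric(reference), test = as.numeric(test),
                 ids = ids),
            class = "paired_angles")
}

#' Fraction of measurements within an error interval
#'
#' For each half-width `d` (degrees), the fraction of pairs with
#' `|test - reference| <= d` (inclusive).  The conventional reporting grid
#' is +/-1, +/-2.5 and +/-5 degrees.
#'
#' @param pairs a [paired_angles()].
#' @param half_widths positive half-widths, degrees.
#' @return named numeric vector of fractions.
#' @export
accuracy_within <- function(pairs, half_widths = c(1, 2.5, 5)) {
  if (any(half_widths <= 0)) stop("half_widths must be > 0")
  d <- abs(pairs$test - pairs$reference)
  setNames(vapply(half_widths, function(hw) mean(d <= hw), numeric(1)),
           paste0("within_", half_widths))
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented test - reference, so a negative bias means the
#' test method underestimates.  Limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (sample SD, n-1 denominator).
#'
#' @param pairs a [paired_angles()].
#' @return list of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `frac_within_loa` (inclusive bounds), `n`,
#'   plus the per-pair `means` and `diffs` used for plotting.
#' @export
bland_altman <- function(pairs) {
  diffs <- pairs$test - pairs$reference
  n <- length(diffs)
  bias <- mean(diffs)
  sdd <- sd(diffs)
  loa <- c(bias - 1.96 * sdd, bias + 1.96 * sdd)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = loa[1], loa_high = loa[2],
                 frac_within_loa = mean(diffs >= loa[1] & diffs <= loa[2]),
                 n = n,
                 means = (pairs$test + pairs$reference) / 2,
                 diffs = diffs),
            class = "bland_altman_result")
}

#' Bland-Altman plot (base graphics)
#'
#' Differences against pair means, with solid bias line and dashed limits
#' of agreement.
#'
#' @param res a [bland_altman()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot_bland_altman <- function(res, ...) {
  graphics::plot(res$means, res$diffs,
                 xlab = "Mean of methods (deg)",
                 ylab = "Difference test - reference (deg)", ...)
  graphics::abline(h = res$bias, lty = 1)
  graphics::abline(h = c(res$loa_low, res$loa_high), lty = 2)
  invisible(res)
}

#' Intraclass correlation: two-way random effects, absolute agreement,
#' single measurement
#'
#' The standard inter-observer reliability index (ICC(2,1) in the
#' Shrout-Fleiss taxonomy, ICC(A,1) in McGraw-Wong): subjects and raters
#' are both random effects and systematic rater differences count as
#' disagreement.  Computed from the two-way mean squares; the 95% CI uses
#' the McGraw-Wong F-distribution formulation.
#'
#' @param ratings numeric matrix or data.frame, subjects x raters,
#'   complete (no missing cells), >= 5 subjects and >= 2 raters.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model` (`"ICC(2,1) absolute agreement"`), `n_subjects`, `n_raters`.
#' @export
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("missing-data error: ratings table must be complete")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("need at least 5 subjects")
  if (k < 2) stop("need at least 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)            # subjects
  msc <- n * sum((col_m - grand)^2) / (k - 1)            # raters
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 model = "ICC(2,1) absolute agreement",
                 n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s: %.4f (95%% CI %.4f-%.4f), %d subjects x %d raters\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Summarize manual refinements to automatic angle measurements
#'
#' Descriptive statistics of the corrections `refined - original`, grouped
#' by tooth position, with counts of edits exceeding 5 and 10 degrees.
#'
#' @param original,refined numeric angle vectors (degrees), parallel.
#' @param labels position labels (e.g. "M1"), parallel.
#' @return list: `by_position` data.frame (position, n, mean, sd, min,
#'   max), `n_edits_over_5`, `n_edits_over_10`.
#' @export
refinement_summary <- function(original, refined, labels) {
  if (length(original) != length(refined) ||
      length(original) != length(labels))
    stop("original, refined and labels must be parallel")
  edit <- refined - original
  groups <- split(edit, labels)
  by_position <- do.call(rbind, lapply(names(groups), function(g) {
    e <- groups[[g]]
    data.frame(position = g, n = length(e), mean = mean(e),
               sd = if (length(e) > 1) sd(e) else 0,
               min = min(e), max = max(e))
  }))
  list(by_position = by_position,
       n_edits_over_5 = sum(abs(edit) > 5),
       n_edits_over_10 = sum(abs(edit) > 10))
}
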