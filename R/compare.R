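# Relating the physiological wind effects to the UTCI wind effect at the
# experimental conditions: rank correlation and binary classification of
# heating events.

# bilinear interpolation of a matrix field z[ta, pa] at arbitrary points;
# NA if any of the four surrounding nodes is NA or the point is outside
.bilinear <- function(ta_axis, pa_axis, z, ta, pa) {
  n <- length(ta)
  out <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (ta[k] < ta_axis[1L] || ta[k] > ta_axis[length(ta_axis)] ||
        pa[k] < pa_axis[1L] || pa[k] > pa_axis[length(pa_axis)]) next
    i <- findInterval(ta[k], ta_axis, rightmost.closed = TRUE)
    j <- findInterval(pa[k], pa_axis, rightmost.closed = TRUE)
    i <- min(i, length(ta_axis) - 1L); j <- min(j, length(pa_axis) - 1L)
    x1 <- ta_axis[i]; x2 <- ta_axis[i + 1L]
    y1 <- pa_axis[j]; y2 <- pa_axis[j + 1L]
    q <- z[i:(i + 1L), j:(j + 1L)]
    if (anyNA(q)) next
    wx <- (ta[k] - x1) / (x2 - x1); wy <- (pa[k] - y1) / (y2 - y1)
    out[k] <- q[1L, 1L] * (1 - wx) * (1 - wy) + q[2L, 1L] * wx * (1 - wy) +
      q[1L, 2L] * (1 - wx) * wy + q[2L, 2L] * wx * wy
  }
  out
}

.surface_matrix <- function(surface, col = "delta", supported_only = TRUE) {
  ta_axis <- attr(surface, "ta_axis"); pa_axis <- attr(surface, "pa_axis")
  z <- matrix(NA_real_, length(ta_axis), length(pa_axis))
  keep <- if (supported_only) surface$supported else rep(TRUE, nrow(surface))
  i <- match(surface$ta_C, ta_axis); j <- match(surface$pa_kPa, pa_axis)
  z[cbind(i[keep], j[keep])] <- surface[[col]][keep]
  list(ta_axis = ta_axis, pa_axis = pa_axis, z = z)
}

#' Pair UTCI and physiological wind effects at experimental conditions
#'
#' Interpolates both the UTCI wind-effect field and a fitted physiological
#' difference surface bilinearly at the given temperature-humidity
#' conditions. Conditions falling outside either support are dropped with
#' a warning.
#'
#' @param conditions Data frame with columns \code{ta_C}, \code{pa_kPa}
#'   (e.g. the experimental conditions of a trial table).
#' @param surface A \code{\link{delta_surface}}.
#' @param field A \code{\link{delta_v_field}} result.
#' @param significant_only If TRUE, keep only conditions where the
#'   physiological wind effect is pointwise significant.
#' @return Data frame of class \code{"effect_pairs"} with columns
#'   \code{ta_C}, \code{pa_kPa}, \code{delta_utci}, \code{delta_physio},
#'   \code{response}.
#' @export
pair_effects <- function(conditions, surface, field,
                         significant_only = FALSE) {
  stopifnot(all(c("ta_C", "pa_kPa") %in% names(conditions)),
            inherits(surface, "delta_surface"),
            inherits(field, "wind_effect_field"))
  sm <- .surface_matrix(surface)
  du <- .bilinear(field$grid$ta_axis, field$grid$pa_axis, field$delta,
                  conditions$ta_C, conditions$pa_kPa)
  dp <- .bilinear(sm$ta_axis, sm$pa_axis, sm$z,
                  conditions$ta_C, conditions$pa_kPa)
  keep <- !is.na(du) & !is.na(dp)
  if (significant_only) {
    sg <- .surface_matrix(surface, "significant")
    sig <- .bilinear(sg$ta_axis, sg$pa_axis, sg$z,
                     conditions$ta_C, conditions$pa_kPa)
    keep <- keep & !is.na(sig) & sig == 1
  }
  if (any(!keep))
    warning(sum(!keep), " condition(s) outside the common support were dropped")
  out <- data.frame(ta_C = conditions$ta_C[keep],
                    pa_kPa = conditions$pa_kPa[keep],
                    delta_utci = du[keep], delta_physio = dp[keep],
                    response = attr(surface, "response"))
  class(out) <- c("effect_pairs", "data.frame")
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using mid-ranks for ties, with a two-sided p-value
#' from the t approximation t = r * sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), or \code{x} an
#'   \code{"effect_pairs"} frame (then \code{delta_utci} vs
#'   \code{delta_physio} is used).
#' @return List with \code{r_s}, \code{p}, \code{n}.
#' @export
spearman_correlation <- function(x, y = NULL) {
  if (inherits(x, "effect_pairs")) {
    y <- x$delta_physio; x <- x$delta_utci
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r_s = r, p = p, n = n)
}

#' Classification metrics for heating wind effects
#'
#' Treats a physiological wind effect Delta_v > 0 (strictly) as the truth
#' "heating" class and Delta_v UTCI > 0 as the prediction, and reports the
#' confusion counts with sensitivity, specificity and overall accuracy.
#' Exact zeros fall in the non-heating class. With no positive truth case,
#' sensitivity is undefined and reported as NA.
#'
#' @param pairs An \code{"effect_pairs"} frame (or data frame with columns
#'   \code{delta_utci}, \code{delta_physio}).
#' @return List with \code{TP}, \code{FP}, \code{TN}, \code{FN},
#'   \code{sensitivity}, \code{specificity}, \code{accuracy}, \code{n}.
#' @export
heating_classification <- function(pairs) {
  stopifnot(all(c("delta_utci", "delta_physio") %in% names(pairs)))
  ok <- stats::complete.cases(pairs$delta_utci, pairs$delta_physio)
  truth <- pairs$delta_physio[ok] > 0
  pred <- pairs$delta_utci[ok] > 0
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       n = tp + fp + tn + fn)
}

#' Compare UTCI and physiological wind effects for all four responses
#'
#' Convenience wrapper: pairs the UTCI wind-effect field with each fitted
#' response surface at the experimental conditions and computes the
#' Spearman correlation and heating classification metrics.
#'
#' @param trials Trial table (conditions are taken from it).
#' @param surfaces Named list of \code{\link{delta_surface}} objects
#'   (names hr, tre, tsk, sr or any subset).
#' @param field A \code{\link{delta_v_field}} result.
#' @param significant_only Restrict to pointwise-significant conditions.
#' @return List per response with \code{pairs}, \code{spearman},
#'   \code{classification}.
#' @export
compare_effects <- function(trials, surfaces, field,
                            significant_only = FALSE) {
  conditions <- unique(trials[, c("ta_C", "pa_kPa")])
  out <- lapply(surfaces, function(s) {
    pr <- pair_effects(conditions, s, field,
                       significant_only = significant_only)
    list(pairs = pr, spearman = spearman_correlation(pr),
         classification = heating_classification(pr))
  })
  names(out) <- names(surfaces)
  out
}
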