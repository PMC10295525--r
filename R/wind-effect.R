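#' Build a psychrometric evaluation grid
#'
#' Rectangular lattice of air temperature x water vapor pressure with a
#' relative-humidity mask: cells with \code{p_vap} above the saturation
#' pressure at \code{t_air} (rH > 100 %) or above the 5 kPa UTCI validity
#' limit are masked out. Mean radiant temperature is carried as a constant
#' radiant excess \code{dT_mrt} above air temperature.
#'
#' @param ta_range Air temperature range, degC; default \code{c(25, 50)}.
#' @param pa_range Vapor pressure range, kPa; default \code{c(0.1, 5)}.
#' @param steps Grid steps \code{c(ta_step, pa_step)}; default
#'   \code{c(0.5, 0.1)}.
#' @param dT_mrt Radiant excess T_mrt - T_a, K; default 0.
#' @return Object of class \code{"psychro_grid"}: list with \code{ta_axis},
#'   \code{pa_axis}, logical \code{mask} (TRUE = cell inside the rH <= 100%
#'   and p_vap <= 5 kPa region; rows index \code{ta_axis}), and
#'   \code{dT_mrt}.
#' @export
build_grid <- function(ta_range = c(25, 50), pa_range = c(0.1, 5),
                       steps = c(0.5, 0.1), dT_mrt = 0) {
  stopifnot(length(ta_range) == 2L, length(pa_range) == 2L,
            length(steps) == 2L, all(steps > 0), length(dT_mrt) == 1L)
  if (diff(ta_range) <= 0 || diff(pa_range) <= 0)
    stop("empty grid range")
  ta_axis <- seq(ta_range[1L], ta_range[2L], by = steps[1L])
  pa_axis <- seq(pa_range[1L], pa_range[2L], by = steps[2L])
  psat <- saturation_vapor_pressure(ta_axis)
  mask <- outer(psat, pa_axis, function(ps, pa) pa <= ps & pa <= 5)
  structure(list(ta_axis = ta_axis, pa_axis = pa_axis, mask = mask,
                 dT_mrt = dT_mrt),
            class = "psychro_grid")
}

#' @export
print.psychro_grid <- function(x, ...) {
  cat(sprintf(
    "psychrometric grid: %d x %d (Ta %g..%g degC, pa %g..%g kPa), dT_mrt = %g K, %d cells inside rH mask\n",
    length(x$ta_axis), length(x$pa_axis), min(x$ta_axis), max(x$ta_axis),
    min(x$pa_axis), max(x$pa_axis), x$dT_mrt, sum(x$mask)))
  invisible(x)
}

# Continuous wind-effect function underlying a field; used for contour
# refinement and crossing checks.
.delta_fun <- function(v10_hi, v10_ref, dT_mrt) {
  function(ta, pa) {
    hi <- thermal_condition(ta, pa, ta + dT_mrt, v10_hi)
    rf <- thermal_condition(ta, pa, ta + dT_mrt, v10_ref)
    utci(hi, check = FALSE) - utci(rf, check = FALSE)
  }
}

#' Wind effect on UTCI over a psychrometric grid
#'
#' Computes the cellwise UTCI difference between an elevated wind speed and
#' a reference wind speed (default 0.5 m/s at 10 m), all other inputs held
#' fixed: delta_v UTCI = UTCI(..., v10_hi) - UTCI(..., v10_ref). Negative
#' values indicate wind cooling, positive values wind heating.
#'
#' @param grid A \code{\link{build_grid}} result.
#' @param v10_hi Elevated 10 m wind speed, m/s.
#' @param v10_ref Reference 10 m wind speed, m/s; default 0.5.
#' @return Object of class \code{"wind_effect_field"}: the grid plus
#'   \code{delta} (matrix, K; NA outside the mask), \code{rh} (relative
#'   humidity, percent), and the wind pair.
#' @export
delta_v_field <- function(grid, v10_hi, v10_ref = 0.5) {
  stopifnot(inherits(grid, "psychro_grid"))
  for (v in c(v10_hi, v10_ref))
    if (v < 0.5 || v > 17) stop("wind speed outside UTCI validity (0.5..17 m/s)")
  nt <- length(grid$ta_axis); np <- length(grid$pa_axis)
  cells <- which(grid$mask, arr.ind = TRUE)
  ta <- grid$ta_axis[cells[, 1L]]
  pa <- grid$pa_axis[cells[, 2L]]
  f <- .delta_fun(v10_hi, v10_ref, grid$dT_mrt)
  delta <- matrix(NA_real_, nt, np)
  delta[cells] <- f(ta, pa)
  rh <- matrix(NA_real_, nt, np)
  rh[cells] <- 100 * pa / saturation_vapor_pressure(ta)
  structure(list(grid = grid, delta = delta, rh = rh,
                 v10_hi = v10_hi, v10_ref = v10_ref),
            class = "wind_effect_field")
}

#' @export
print.wind_effect_field <- function(x, ...) {
  q <- stats::quantile(x$delta, c(0, .5, 1), na.rm = TRUE)
  cat(sprintf(
    "wind-effect field: %g vs %g m/s (10 m), dT_mrt = %g K; delta range %.2f .. %.2f K (median %.2f)\n",
    x$v10_hi, x$v10_ref, x$grid$dT_mrt, q[1L], q[3L], q[2L]))
  invisible(x)
}

#' Convert a wind-effect field to a long-format data frame
#'
#' @param x A \code{"wind_effect_field"}.
#' @param ... Unused.
#' @return Data frame with columns \code{ta_C}, \code{pa_kPa},
#'   \code{rh_pct}, \code{delta_K}, unmasked cells only.
#' @export
as.data.frame.wind_effect_field <- function(x, ...) {
  cells <- which(x$grid$mask, arr.ind = TRUE)
  out <- data.frame(ta_C = x$grid$ta_axis[cells[, 1L]],
                    pa_kPa = x$grid$pa_axis[cells[, 2L]],
                    rh_pct = x$rh[cells],
                    delta_K = x$delta[cells])
  out[order(out$ta_C, out$pa_kPa), , drop = FALSE]
}

#' Zero-effect contour of a wind-effect field
#'
#' Extracts the delta_v = 0 polyline separating wind cooling from wind
#' heating by marching squares with linear interpolation
#' (\code{grDevices::contourLines}), then refines each vertex by 1-D
#' bisection of the continuous UTCI difference until |delta| < \code{tol}.
#' A field without sign change yields an empty contour.
#'
#' @param field A \code{\link{delta_v_field}} result.
#' @param refine Bisect vertices against the continuous function
#'   (default TRUE).
#' @param tol Refinement tolerance, K; default 0.01.
#' @return Object of class \code{"zero_contour"}: data frame with columns
#'   \code{t_air}, \code{p_vap}, \code{piece} (contour segment id).
#' @export
zero_effect_contour <- function(field, refine = TRUE, tol = 0.01) {
  stopifnot(inherits(field, "wind_effect_field"))
  g <- field$grid
  cl <- grDevices::contourLines(g$ta_axis, g$pa_axis, field$delta,
                                levels = 0)
  if (length(cl) == 0L) {
    out <- data.frame(t_air = numeric(0), p_vap = numeric(0),
                      piece = integer(0))
    class(out) <- c("zero_contour", "data.frame")
    return(out)
  }
  f <- .delta_fun(field$v10_hi, field$v10_ref, g$dT_mrt)
  dt <- diff(g$ta_axis[1:2]); dp <- diff(g$pa_axis[1:2])
  refine_vertex <- function(ta, pa) {
    # bisect along the axis that brackets a sign change around the vertex
    for (axis in c("pa", "ta")) {
      if (axis == "pa") {
        lo <- max(pa - dp, min(g$pa_axis)); hi <- min(pa + dp, max(g$pa_axis))
        flo <- f(ta, lo); fhi <- f(ta, hi)
        if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0) {
          r <- stats::uniroot(function(p) f(ta, p), c(lo, hi),
                              tol = 1e-6)$root
          return(c(ta, r))
        }
      } else {
        lo <- max(ta - dt, min(g$ta_axis)); hi <- min(ta + dt, max(g$ta_axis))
        flo <- f(lo, pa); fhi <- f(hi, pa)
        if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0) {
          r <- stats::uniroot(function(t) f(t, pa), c(lo, hi),
                              tol = 1e-6)$root
          return(c(r, pa))
        }
      }
    }
    c(ta, pa)  # no bracket within one step (flat spot); keep vertex
  }
  pieces <- lapply(seq_along(cl), function(i) {
    ta <- cl[[i]]$x; pa <- cl[[i]]$y
    if (refine) {
      v <- t(mapply(refine_vertex, ta, pa))
      ta <- v[, 1L]; pa <- v[, 2L]
    }
    data.frame(t_air = ta, p_vap = pa, piece = i)
  })
  out <- do.call(rbind, pieces)
  class(out) <- c("zero_contour", "data.frame")
  out
}

#' Zero-crossing temperature of the wind effect at fixed humidity
#'
#' Finds the air temperature at which the UTCI wind effect changes sign for
#' a fixed vapor pressure, by bisection of the continuous UTCI difference.
#'
#' @param pa Vapor pressure, kPa.
#' @param v10_hi,v10_ref Wind pair, m/s at 10 m.
#' @param dT_mrt Radiant excess, K.
#' @param ta_range Search interval, degC.
#' @return Crossing temperature in degC, or NA if the sign does not change
#'   on the interval.
#' @export
zero_crossing_temperature <- function(pa, v10_hi = 3, v10_ref = 0.5,
                                      dT_mrt = 0, ta_range = c(25, 50)) {
  f <- .delta_fun(v10_hi, v10_ref, dT_mrt)
  tg <- seq(ta_range[1L], ta_range[2L], by = 0.25)
  vapply(pa, function(p) {
    v <- f(tg, p)
    i <- which(v[-length(v)] * v[-1L] <= 0 & v[-length(v)] != 0)
    if (length(i) == 0L) return(NA_real_)
    # first crossing (cooling-to-heating transition)
    stats::uniroot(function(t) f(t, p), tg[c(i[1L], i[1L] + 1L)],
                   tol = 1e-6)$root
  }, numeric(1))
}

#' Percentile summary of a wind-effect field
#'
#' The five order statistics P0 (minimum), P25, P50 (median), P75, and P100
#' (maximum) of delta_v UTCI over the unmasked grid cells.
#'
#' @param field A \code{\link{delta_v_field}} result.
#' @return Named numeric vector \code{P0, P25, P50, P75, P100} with
#'   attributes \code{v10_hi} and \code{dT_mrt}.
#' @export
percentile_summary <- function(field) {
  stopifnot(inherits(field, "wind_effect_field"))
  x <- field$delta[field$grid$mask]
  if (length(x) == 0L) stop("empty unmasked region")
  q <- stats::quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
  structure(q, names = c("P0", "P25", "P50", "P75", "P100"),
            v10_hi = field$v10_hi, dT_mrt = field$grid$dT_mrt)
}

#' Sweep of wind effects over wind speeds and radiant heat loads
#'
#' Evaluates delta_v UTCI fields for each combination of elevated wind
#' speed and radiant excess, summarizes each by its percentiles, and
#' reports the mean UTCI rise per +10 K radiant excess at reference wind.
#'
#' @param winds Elevated 10 m wind speeds, m/s; default \code{c(3, 4, 6)}.
#' @param radiant Radiant excesses dT_mrt, K; default \code{c(0, 10, 20, 30)}.
#' @param v10_ref Reference wind, m/s; default 0.5.
#' @param ta_range,pa_range,steps Grid specification, see
#'   \code{\link{build_grid}}.
#' @return Object of class \code{"wind_effect_sweep"}: list with
#'   \code{summary} (data frame: v10_hi, dT_mrt, P0..P100), \code{fields}
#'   (the underlying wind-effect fields), and \code{radiant_slope_K}
#'   (mean cellwise UTCI(dT_mrt = 10) - UTCI(dT_mrt = 0) at reference wind).
#' @export
wind_effect_sweep <- function(winds = c(3, 4, 6), radiant = c(0, 10, 20, 30),
                              v10_ref = 0.5, ta_range = c(25, 50),
                              pa_range = c(0.1, 5), steps = c(0.5, 0.1)) {
  combos <- expand.grid(v10_hi = winds, dT_mrt = radiant,
                        KEEP.OUT.ATTRS = FALSE)
  fields <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    g <- build_grid(ta_range, pa_range, steps, dT_mrt = combos$dT_mrt[i])
    fields[[i]] <- delta_v_field(g, combos$v10_hi[i], v10_ref)
    q <- percentile_summary(fields[[i]])
    rows[[i]] <- data.frame(v10_hi = combos$v10_hi[i],
                            dT_mrt = combos$dT_mrt[i], t(q))
  }
  g0 <- build_grid(ta_range, pa_range, steps, dT_mrt = 0)
  cells <- which(g0$mask, arr.ind = TRUE)
  ta <- g0$ta_axis[cells[, 1L]]; pa <- g0$pa_axis[cells[, 2L]]
  u0 <- utci(thermal_condition(ta, pa, ta, v10_ref), check = FALSE)
  u10 <- utci(thermal_condition(ta, pa, ta + 10, v10_ref), check = FALSE)
  structure(list(summary = do.call(rbind, rows), fields = fields,
                 radiant_slope_K = mean(u10 - u0)),
            class = "wind_effect_sweep")
}

#' @export
print.wind_effect_sweep <- function(x, ...) {
  cat("wind-effect sweep over", nrow(x$summary), "wind x radiant combinations\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat(sprintf("mean UTCI rise per +10 K dT_mrt at reference wind: %.2f K\n",
              x$radiant_slope_K))
  invisible(x)
}
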