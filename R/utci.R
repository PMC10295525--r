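#' Saturation water vapor pressure over liquid water
#'
#' Evaluates the ITS-90-based formulation of Hardy used by the UTCI
#' operational procedure. Input temperatures are restricted to -50 to +60
#' degC, which covers the whole UTCI operational range.
#'
#' @param t_air Air temperature in degC (vectorized).
#' @return Saturation vapor pressure in kPa.
#' @examples
#' saturation_vapor_pressure(25) # about 3.17 kPa
#' @export
saturation_vapor_pressure <- function(t_air) {
  if (!is.numeric(t_air) || anyNA(t_air))
    stop("'t_air' must be numeric without missing values")
  if (any(t_air < -50 | t_air > 60))
    stop("'t_air' outside the supported range -50..60 degC")
  tk <- t_air + 273.15
  g <- c(-2.8365744e3, -6.028076559e3, 1.954263612e1, -2.737830188e-2,
         1.6261698e-5, 7.0229056e-10, -1.8680009e-13)
  lnp <- 2.7150305 * log(tk)
  for (i in 1:7) lnp <- lnp + g[i] * tk^(i - 3)
  exp(lnp) / 1000  # Pa -> kPa
}

#' Convert 10 m wind speed to person level (1 m)
#'
#' Logarithmic wind-profile conversion between the meteorological 10 m
#' measurement height and the 1 m person level with roughness length 0.01 m:
#' v1 = v10 * log(1/0.01) / log(10/0.01) = v10 / 1.5.
#'
#' @param v10 Wind speed 10 m above ground, m/s (vectorized).
#' @return Wind speed at 1 m, m/s.
#' @examples
#' wind_10m_to_person(3)   # 2 m/s
#' wind_10m_to_person(0.5) # 1/3 m/s, reported as 0.3
#' @export
wind_10m_to_person <- function(v10) {
  if (!is.numeric(v10) || anyNA(v10)) stop("'v10' must be numeric")
  if (any(v10 < 0)) stop("'v10' must be non-negative")
  v10 * (log(1 / 0.01) / log(10 / 0.01))
}

#' Angle-averaged relative air velocity of a walking person
#'
#' For a person walking with speed \code{v_walk} through air moving at
#' \code{v1} (person level), the relative air speed depends on the angle
#' alpha between walking and wind direction,
#' sqrt((v_walk - v1 cos(alpha))^2 + (v1 sin(alpha))^2). Since no specific
#' angle is assumed, the value is averaged over alpha in [0, 2*pi) by
#' fixed-grid trapezoidal quadrature (3600 points). The average equals
#' (2/pi) * sqrt(A + B) * E(k) with A = v_walk^2 + v1^2, B = 2 v_walk v1,
#' k^2 = 2B/(A + B) and E the complete elliptic integral of the second
#' kind, which serves as an independent cross-check.
#'
#' @param v1 Air speed at person level, m/s (vectorized).
#' @param v_walk Walking speed, m/s; default 1.1 (4 km/h).
#' @return Angle-averaged relative air velocity, m/s.
#' @examples
#' relative_air_velocity(0)    # 1.1, the walking speed itself
#' relative_air_velocity(2)    # HiWind person-level speed
#' @export
relative_air_velocity <- function(v1, v_walk = 1.1) {
  if (!is.numeric(v1) || anyNA(v1) || any(v1 < 0))
    stop("'v1' must be numeric and non-negative")
  if (!is.numeric(v_walk) || length(v_walk) != 1L || v_walk < 0)
    stop("'v_walk' must be a single non-negative number")
  n <- 3600L
  alpha <- seq(0, 2 * pi, length.out = n + 1L)
  vapply(v1, function(v) {
    f <- sqrt((v_walk - v * cos(alpha))^2 + (v * sin(alpha))^2)
    # trapezoid on a periodic integrand: end points carry half weight
    sum((f[-1L] + f[-(n + 1L)]) / 2) * (2 * pi / n) / (2 * pi)
  }, numeric(1))
}

#' Construct a thermal environment condition
#'
#' Bundles the four UTCI inputs: air temperature, ambient water vapor
#' pressure, mean radiant temperature, and wind speed 10 m above ground.
#'
#' @param t_air Air temperature, degC.
#' @param p_vap Water vapor pressure, kPa.
#' @param t_mrt Mean radiant temperature, degC; defaults to \code{t_air}.
#' @param v10 Wind speed at 10 m, m/s.
#' @return A data frame of class \code{"thermal_condition"} with columns
#'   \code{t_air}, \code{p_vap}, \code{t_mrt}, \code{v10} (inputs recycled
#'   to a common length).
#' @export
thermal_condition <- function(t_air, p_vap, t_mrt = t_air, v10) {
  cond <- data.frame(t_air = t_air, p_vap = p_vap, t_mrt = t_mrt, v10 = v10)
  if (any(cond$p_vap < 0)) stop("'p_vap' must be non-negative")
  class(cond) <- c("thermal_condition", "data.frame")
  cond
}

# UTCI polynomial validity window (operational procedure):
# Ta in [-50, 50] degC, v10 in [0.5, 17] m/s, Tmrt - Ta in [-30, 70] K,
# p_vap in [0, 5] kPa.
.check_utci_validity <- function(cond, enforce_rh = TRUE) {
  bad <- function(flag, what) {
    if (any(flag)) {
      i <- which(flag)[1L]
      stop(sprintf(
        "condition outside UTCI validity (%s) at row %d: t_air=%g, p_vap=%g, t_mrt=%g, v10=%g",
        what, i, cond$t_air[i], cond$p_vap[i], cond$t_mrt[i], cond$v10[i]),
        call. = FALSE)
    }
  }
  bad(cond$t_air < -50 | cond$t_air > 50, "t_air beyond -50..50 degC")
  bad(cond$v10 < 0.5 | cond$v10 > 17, "v10 beyond 0.5..17 m/s")
  d <- cond$t_mrt - cond$t_air
  bad(d < -30 | d > 70, "t_mrt - t_air beyond -30..70 K")
  bad(cond$p_vap < 0 | cond$p_vap > 5, "p_vap beyond 0..5 kPa")
  if (enforce_rh)
    bad(cond$p_vap > saturation_vapor_pressure(cond$t_air) + 1e-9,
        "relative humidity above 100%")
  invisible(TRUE)
}

#' Universal Thermal Climate Index (operational polynomial)
#'
#' Evaluates the sixth-order regression polynomial of the UTCI operational
#' procedure: UTCI = Ta + offset(Ta, va10, Tmrt - Ta, pa), with the offset
#' a full degree-6 polynomial in the four inputs (210 coefficients).
#' Conditions outside the validity window (Ta -50..50 degC, v10 0.5..17
#' m/s, Tmrt - Ta within -30..70 K, pa <= 5 kPa, rH <= 100 %) raise an
#' error; values are never silently clamped.
#'
#' @param cond A \code{\link{thermal_condition}} (or data frame with columns
#'   \code{t_air}, \code{p_vap}, \code{t_mrt}, \code{v10}).
#' @param check If \code{FALSE}, skip validity checking (internal use on
#'   pre-validated grids).
#' @return Numeric vector of UTCI equivalent temperatures, degC.
#' @examples
#' utci(thermal_condition(t_air = 30, p_vap = 1.5, v10 = 0.5))
#' @export
utci <- function(cond, check = TRUE) {
  stopifnot(all(c("t_air", "p_vap", "t_mrt", "v10") %in% names(cond)))
  if (check) .check_utci_validity(cond)
  ta <- cond$t_air
  va <- cond$v10
  dt <- cond$t_mrt - cond$t_air
  pa <- cond$p_vap
  n <- length(ta)
  pow <- function(x) outer(x, 0:6, `^`)  # n x 7
  tp <- pow(ta); vp <- pow(va); dp <- pow(dt); pp <- pow(pa)
  e <- .utci_poly_exponents
  X <- tp[, e[, "t"] + 1L, drop = FALSE] *
    vp[, e[, "v"] + 1L, drop = FALSE] *
    dp[, e[, "d"] + 1L, drop = FALSE] *
    pp[, e[, "p"] + 1L, drop = FALSE]
  ta + drop(X %*% .utci_poly_coef)
}

#' Heat-stress category of a UTCI value
#'
#' Heat-side classification with category upper limits at 26 degC (no
#' thermal stress), 32 (moderate), 38 (strong), and 46 (very strong);
#' values above 46 degC are extreme heat stress. Upper limits are
#' inclusive. Cold-stress classes are out of scope; everything at or below
#' 26 degC is reported as "no thermal stress".
#'
#' @param u UTCI values, degC (vectorized).
#' @return Ordered factor with levels "no thermal stress" < "moderate" <
#'   "strong" < "very strong" < "extreme".
#' @examples
#' utci_category(c(26, 39, 55))
#' @export
utci_category <- function(u) {
  if (!is.numeric(u)) stop("'u' must be numeric")
  cut(u, breaks = c(-Inf, 26, 32, 38, 46, Inf),
      labels = c("no thermal stress", "moderate", "strong", "very strong",
                 "extreme"),
      right = TRUE, ordered_result = TRUE)
}
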