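# Shared fixtures, built in code. One canonical seed pins the synthetic
# dataset and fits reused across test files; objects are memoized so the
# expensive GAM fits run once per test session.

canonical_seed <- 1L

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, expr, .fixture_env)
  get(key, .fixture_env)
}

canonical_config <- function() memo("config", generator_config())

canonical_trials <- function()
  memo("trials", generate_trials(canonical_config(), canonical_seed))

canonical_fit <- function(response = "hr")
  memo(paste0("fit_", response),
       fit_strain_gam(canonical_trials(), response))

canonical_surface <- function(response = "hr")
  memo(paste0("surface_", response),
       delta_surface(canonical_fit(response)))

canonical_field <- function()
  memo("field", delta_v_field(build_grid(), v10_hi = 3, v10_ref = 0.5))

# closed form of the angle-averaged relative speed via the complete
# elliptic integral of the second kind: (2/pi) sqrt(A+B) E(m),
# A = vw^2 + v1^2, B = 2 vw v1, m = 2B/(A+B)
relative_speed_elliptic <- function(v1, v_walk = 1.1) {
  vapply(v1, function(v) {
    if (v == 0) return(v_walk)
    A <- v_walk^2 + v^2
    B <- 2 * v_walk * v
    m <- 2 * B / (A + B)
    E <- if (requireNamespace("pracma", quietly = TRUE)) {
      pracma::ellipke(m)$e
    } else {
      stats::integrate(function(th) sqrt(1 - m * sin(th)^2), 0, pi / 2,
                       rel.tol = 1e-12)$value
    }
    (2 / pi) * sqrt(A + B) * E
  }, numeric(1))
}

# scaled distance (tolerances 2 degC / 0.5 kPa = 1 unit) from points to the
# generator's L-shaped wind-effect zero curve for a response
truth_curve_distance <- function(ta, pa, config, response) {
  pthr <- config$pa_thr[[response]]
  tthr <- config$ta_thr
  curve_t <- c(rep(tthr, 400L),
               seq(tthr, config$ta_range[2L], length.out = 400L))
  curve_p <- c(seq(config$pa_range[1L], pthr, length.out = 400L),
               rep(pthr, 400L))
  vapply(seq_along(ta), function(i) {
    min(pmax(abs(ta[i] - curve_t) / 2, abs(pa[i] - curve_p) / 0.5))
  }, numeric(1))
}
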