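# Synthetic climate-chamber trial generator.
#
# Emulates the statistical structure of the study database: 5 acclimated
# young males walking 4 km/h, 10 series (subject x wind condition), 198
# trials (97 RefWind / 101 HiWind), conditions quasi-uniform over Ta
# 25-55 degC x pa 0.5-5.3 kPa with rH <= 100%, smooth temperature-humidity
# response surfaces with a wind-interaction surface crossing zero along a
# configurable threshold curve, random subject intercepts, Gaussian noise,
# and premature aborts once rectal temperature exceeds 38.5 degC.

# run expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Du Bois body surface area
#'
#' BSA = 0.007184 * weight^0.425 * (100 * height)^0.725.
#'
#' @param height Body height, m.
#' @param weight Body weight, kg.
#' @return Body surface area, m^2.
#' @examples
#' dubois_bsa(1.87, 70.5) # about 1.94 m^2
#' @export
dubois_bsa <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive")
  0.007184 * weight^0.425 * (100 * height)^0.725
}

# Site weights of the weighted mean skin temperature
.tsk_weights <- c(head = 0.05, chest = 0.20, back = 0.15,
                  arm = 0.20, thigh = 0.25, leg = 0.15)

#' Weighted mean skin temperature from six sites
#'
#' T_sk = 0.05 head + 0.20 chest + 0.15 back + 0.20 arm + 0.25 thigh +
#' 0.15 leg. The weights sum to one.
#'
#' @param head,chest,back,arm,thigh,leg Local skin temperatures, degC
#'   (vectorized).
#' @return Mean skin temperature, degC.
#' @examples
#' mean_skin_temperature(36, 35, 35, 34, 34, 33) # 34.40
#' @export
mean_skin_temperature <- function(head, chest, back, arm, thigh, leg) {
  sites <- list(head, chest, back, arm, thigh, leg)
  if (any(vapply(sites, function(s) !is.numeric(s) || anyNA(s), logical(1))))
    stop("all six site temperatures must be finite numerics")
  w <- unname(.tsk_weights)
  w[1L] * head + w[2L] * chest + w[3L] * back +
    w[4L] * arm + w[5L] * thigh + w[6L] * leg
}

#' Configuration of the synthetic trial generator
#'
#' Defaults reproduce the study conditions: 5 subjects, 97 RefWind and 101
#' HiWind trials in 10 series of 16-25 trials, conditions on Ta 25-55 degC x
#' pa 0.5-5.3 kPa (rH <= 100%), response noise SDs of 7.6 bpm (HR), 0.2 degC
#' (T_re), 0.4 degC (T_sk) and 120.1 g/h (SR), and population response
#' means of 102.5 bpm, 37.6 degC, 35.5 degC and 744.4 g/h. Each noise-free
#' response is an intercept plus a logistic ramp in the heat-load score
#' h = Ta + 3 * pa, plus (under HiWind) a wind-effect surface
#' M * tanh(min((Ta - ta_thr)/ta_scale, (pa_thr - pa)/pa_scale)) that is
#' positive (heating) only for hot-dry conditions Ta > ta_thr and
#' pa < pa_thr, and crosses zero exactly on the boundary of that region.
#'
#' @param n_subjects Number of participants; default 5.
#' @param n_ref,n_hi Trial totals per wind condition; defaults 97 and 101.
#' @param series_range Allowed trials per series; default \code{c(16, 25)}.
#' @param ta_range,pa_range Condition ranges, degC and kPa.
#' @param means Named response means (intercepts).
#' @param amplitudes Named full ranges of the heat-load ramp.
#' @param noise_sd Named residual SDs.
#' @param subject_sd Named SDs of the random subject intercepts.
#' @param wind_effect Named wind-effect magnitudes M (response units);
#'   set to 0 for a null wind effect.
#' @param ta_thr Threshold air temperature of the wind-effect zero curve,
#'   degC; default 35.
#' @param pa_thr Named threshold vapor pressures, kPa; defaults 2 (HR,
#'   T_re) and 3 (T_sk, SR).
#' @param ta_scale,pa_scale Softness of the wind-effect ramp, degC and kPa.
#' @param heat_load_coef Humidity weight in the heat-load score, degC/kPa.
#' @param h0,hw Center and width of the logistic heat-load ramp.
#' @param dropout_prob Independent missingness probability for HR, T_sk,
#'   SR; default 0.02.
#' @param abort_tre Abort threshold for rectal temperature, degC.
#' @return List of class \code{"generator_config"}.
#' @export
generator_config <- function(n_subjects = 5L, n_ref = 97L, n_hi = 101L,
                             series_range = c(16L, 25L),
                             ta_range = c(25, 55), pa_range = c(0.5, 5.3),
                             means = c(hr = 102.5, tre = 37.6, tsk = 35.5,
                                       sr = 744.4),
                             amplitudes = c(hr = 45, tre = 1.4, tsk = 4,
                                            sr = 700),
                             noise_sd = c(hr = 7.6, tre = 0.2, tsk = 0.4,
                                          sr = 120.1),
                             subject_sd = c(hr = 2, tre = 0.15, tsk = 0.3,
                                            sr = 80),
                             wind_effect = c(hr = 12, tre = 0.25, tsk = 1.5,
                                             sr = 250),
                             ta_thr = 35,
                             pa_thr = c(hr = 2, tre = 2, tsk = 3, sr = 3),
                             ta_scale = 5, pa_scale = 1,
                             heat_load_coef = 3, h0 = 48, hw = 6,
                             dropout_prob = 0.02, abort_tre = 38.5) {
  resp <- c("hr", "tre", "tsk", "sr")
  for (v in list(means, amplitudes, noise_sd, subject_sd, wind_effect, pa_thr))
    stopifnot(all(resp %in% names(v)))
  if (any(noise_sd < 0) || any(subject_sd < 0))
    stop("noise and subject-intercept SDs must be non-negative")
  if (n_subjects * series_range[1L] > min(n_ref, n_hi) ||
      n_subjects * series_range[2L] < max(n_ref, n_hi))
    stop("infeasible per-series trial counts for the requested totals")
  cfg <- list(n_subjects = as.integer(n_subjects), n_ref = as.integer(n_ref),
              n_hi = as.integer(n_hi), series_range = as.integer(series_range),
              ta_range = ta_range, pa_range = pa_range, means = means[resp],
              amplitudes = amplitudes[resp], noise_sd = noise_sd[resp],
              subject_sd = subject_sd[resp], wind_effect = wind_effect[resp],
              ta_thr = ta_thr, pa_thr = pa_thr[resp], ta_scale = ta_scale,
              pa_scale = pa_scale, heat_load_coef = heat_load_coef,
              h0 = h0, hw = hw, dropout_prob = dropout_prob,
              abort_tre = abort_tre)
  # centering constant of the logistic ramp so that the population mean of
  # each truth surface over the design region equals `means`
  ta <- seq(ta_range[1L], ta_range[2L], by = 0.25)
  pa <- seq(pa_range[1L], pa_range[2L], by = 0.05)
  g <- expand.grid(ta = ta, pa = pa)
  g <- g[g$pa <= saturation_vapor_pressure(g$ta), ]
  h <- g$ta + heat_load_coef * g$pa
  cfg$ramp_center <- mean(stats::plogis((h - h0) / hw))
  class(cfg) <- "generator_config"
  cfg
}

#' Sample the experimental design of a synthetic study
#'
#' Allocates trials to series (one series per subject x wind condition)
#' with per-series counts inside the configured range, and draws the
#' temperature-humidity conditions uniformly over the design region
#' (rejection sampling under rH <= 100%).
#'
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @return Data frame with columns \code{subject_id}, \code{series_id},
#'   \code{wind} (factor ref/hi), \code{ta_C}, \code{pa_kPa}.
#' @export
sample_design <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(seed, {
    counts_for <- function(total) {
      lo <- config$series_range[1L]; hi <- config$series_range[2L]
      for (i in 1:10000) {
        x <- sample(lo:hi, config$n_subjects, replace = TRUE)
        if (sum(x) == total) return(x)
      }
      stop("could not allocate per-series counts in range after 10000 draws")
    }
    n_ref <- counts_for(config$n_ref)
    n_hi <- counts_for(config$n_hi)
    rows <- list()
    sid <- 0L
    for (w in c("ref", "hi")) {
      nn <- if (w == "ref") n_ref else n_hi
      for (s in seq_len(config$n_subjects)) {
        sid <- sid + 1L
        rows[[sid]] <- data.frame(
          subject_id = sprintf("S%02d", s),
          series_id = sprintf("R%02d", sid),
          wind = w, n = nn[s])
      }
    }
    des <- do.call(rbind, rows)
    des <- des[rep(seq_len(nrow(des)), des$n), c("subject_id", "series_id",
                                                 "wind")]
    n <- nrow(des)
    ta <- numeric(n); pa <- numeric(n); got <- 0L
    while (got < n) {
      m <- 2L * (n - got)
      cta <- stats::runif(m, config$ta_range[1L], config$ta_range[2L])
      cpa <- stats::runif(m, config$pa_range[1L], config$pa_range[2L])
      ok <- cpa <= saturation_vapor_pressure(cta)
      k <- min(sum(ok), n - got)
      if (k > 0L) {
        ta[got + seq_len(k)] <- cta[ok][seq_len(k)]
        pa[got + seq_len(k)] <- cpa[ok][seq_len(k)]
        got <- got + k
      }
    }
    des$ta_C <- ta
    des$pa_kPa <- pa
    des$wind <- factor(des$wind, levels = c("ref", "hi"))
    rownames(des) <- NULL
    des
  })
}

# wind-effect truth surface: positive (heating) inside the hot-dry region
# Ta > ta_thr & pa < pa_thr, zero exactly on its boundary
.wind_effect_truth <- function(ta, pa, config, response) {
  d <- pmin((ta - config$ta_thr) / config$ta_scale,
            (config$pa_thr[[response]] - pa) / config$pa_scale)
  config$wind_effect[[response]] * tanh(d)
}

#' Noise-free response surfaces of the generator
#'
#' Evaluates the configured truth: intercept + amplitude * centered
#' logistic ramp of the heat-load score h = Ta + c * pa, plus (HiWind only)
#' the wind-effect surface, plus optional subject intercepts.
#'
#' @param ta,pa Conditions (vectorized), degC and kPa.
#' @param wind Character or factor, "ref" or "hi" (recycled).
#' @param config A \code{\link{generator_config}}.
#' @param subject_effects Optional named list with per-response numeric
#'   vectors of subject intercepts to add (same length as \code{ta}).
#' @return Data frame with columns \code{hr}, \code{tre}, \code{tsk},
#'   \code{sr}.
#' @export
true_response <- function(ta, pa, wind, config, subject_effects = NULL) {
  stopifnot(inherits(config, "generator_config"))
  wind <- as.character(wind)
  if (!all(wind %in% c("ref", "hi"))) stop("wind must be 'ref' or 'hi'")
  h <- ta + config$heat_load_coef * pa
  ramp <- stats::plogis((h - config$h0) / config$hw) - config$ramp_center
  hiw <- as.numeric(wind == "hi")
  out <- lapply(c("hr", "tre", "tsk", "sr"), function(r) {
    y <- config$means[[r]] + config$amplitudes[[r]] * ramp +
      hiw * .wind_effect_truth(ta, pa, config, r)
    if (!is.null(subject_effects)) y <- y + subject_effects[[r]]
    y
  })
  names(out) <- c("hr", "tre", "tsk", "sr")
  as.data.frame(out)
}

#' Generate a synthetic trial table
#'
#' Draws the design, subject profiles and intercepts, adds Gaussian noise
#' to the truth surfaces, constructs six local skin temperatures whose
#' weighted mean equals the generated T_sk, and applies the censoring
#' rules: trials whose rectal temperature exceeds the abort threshold are
#' flagged aborted with HR, T_sk and SR recorded as missing (T_re itself
#' stays observed, as the probe records continuously), and a small
#' independent dropout adds further missingness to HR, T_sk and SR.
#'
#' @param config A \code{\link{generator_config}}.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return Data frame with one row per trial: \code{subject_id},
#'   \code{series_id}, \code{ta_C}, \code{pa_kPa}, \code{wind},
#'   \code{hr_bpm}, \code{tre_C}, \code{tsk_C}, \code{sr_gph}, six
#'   \code{tsk_*_C} site columns and \code{aborted}. Carries the subject
#'   profile table as attribute \code{"subjects"}.
#' @export
generate_trials <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  des <- sample_design(config, seed)
  .with_seed(seed + 1L, {
    ns <- config$n_subjects
    subjects <- data.frame(
      subject_id = sprintf("S%02d", seq_len(ns)),
      age_yr = round(stats::rnorm(ns, 20.1, 0.9), 1),
      height_m = round(stats::rnorm(ns, 1.87, 0.02), 2),
      weight_kg = round(stats::rnorm(ns, 70.5, 2.1), 1),
      vo2max = round(stats::rnorm(ns, 47.9, 6.4), 1))
    subjects$bsa_m2 <- dubois_bsa(subjects$height_m, subjects$weight_kg)
    resp <- c("hr", "tre", "tsk", "sr")
    intercepts <- sapply(resp, function(r)
      stats::rnorm(ns, 0, config$subject_sd[[r]]))
    rownames(intercepts) <- subjects$subject_id
    idx <- match(des$subject_id, subjects$subject_id)
    subj_eff <- lapply(resp, function(r) intercepts[idx, r])
    names(subj_eff) <- resp
    truth <- true_response(des$ta_C, des$pa_kPa, des$wind, config, subj_eff)
    n <- nrow(des)
    obs <- lapply(resp, function(r)
      truth[[r]] + stats::rnorm(n, 0, config$noise_sd[[r]]))
    names(obs) <- resp
    # six local skin temperatures: site pattern + noise, recentered so the
    # weighted mean reproduces tsk exactly
    site_pattern <- c(head = 0.6, chest = 0.4, back = 0.3, arm = -0.2,
                      thigh = -0.3, leg = -0.7)
    dev <- sapply(names(.tsk_weights), function(s)
      site_pattern[[s]] + stats::rnorm(n, 0, 0.6))
    dev <- dev - drop(dev %*% .tsk_weights)  # weighted mean now zero
    sites <- dev + obs$tsk
    colnames(sites) <- paste0("tsk_", names(.tsk_weights), "_C")
    aborted <- obs$tre > config$abort_tre
    out <- data.frame(des, hr_bpm = obs$hr, tre_C = obs$tre,
                      tsk_C = obs$tsk, sr_gph = obs$sr, sites,
                      aborted = aborted)
    drop_na <- function(col) {
      miss <- aborted | stats::runif(n) < config$dropout_prob
      out[[col]][miss] <<- NA_real_
    }
    for (col in c("hr_bpm", "tsk_C", "sr_gph")) drop_na(col)
    miss_sites <- is.na(out$tsk_C)
    out[miss_sites, colnames(sites)] <- NA_real_
    attr(out, "subjects") <- subjects
    attr(out, "truth") <- truth
    rownames(out) <- NULL
    out
  })
}
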