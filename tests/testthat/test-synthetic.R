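test_that("Du Bois surface area reproduces the cohort mean", {
  # formula value 1.9451 m^2; the cohort's printed mean is 1.94 +/- 0.02
  expect_equal(dubois_bsa(1.87, 70.5), 1.9451, tolerance = 1e-4)
  expect_lt(abs(dubois_bsa(1.87, 70.5) - 1.94), 0.02)
  expect_equal(dubois_bsa(1.80, 70.0), 1.89, tolerance = 0.005)
  expect_gt(dubois_bsa(1.90, 70.5), dubois_bsa(1.87, 70.5))
  expect_gt(dubois_bsa(1.87, 73), dubois_bsa(1.87, 70.5))
  expect_error(dubois_bsa(0, 70), "positive")
})

test_that("mean skin temperature is the stated six-site weighted average", {
  expect_equal(sum(heatwind:::.tsk_weights), 1)
  expect_equal(mean_skin_temperature(35, 35, 35, 35, 35, 35), 35)
  # 0.05*36 + 0.2*35 + 0.15*35 + 0.2*34 + 0.25*34 + 0.15*33 = 34.30
  expect_equal(mean_skin_temperature(36, 35, 35, 34, 34, 33), 34.30)
  expect_error(mean_skin_temperature(36, 35, NA, 34, 34, 33), "finite")
})

test_that("sampled design reproduces the study layout", {
  des <- sample_design(canonical_config(), canonical_seed)
  expect_equal(nrow(des), 198L)
  expect_equal(as.vector(table(des$wind)), c(97L, 101L))
  counts <- table(des$series_id)
  expect_length(counts, 10L)
  expect_true(all(counts >= 16 & counts <= 25))
  expect_true(all(des$pa_kPa <= saturation_vapor_pressure(des$ta_C)))
  expect_true(all(des$ta_C >= 25 & des$ta_C <= 55))
  expect_identical(des, sample_design(canonical_config(), canonical_seed))
})

test_that("wind-effect truth crosses zero exactly on its threshold curve", {
  cfg <- canonical_config()
  # on the curve: vertical branch at 35 degC, horizontal branch at pa_thr
  on_curve <- true_response(c(35, 35, 40, 50), c(1, 1.5, 2, 2),
                            "hi", cfg)
  off_ref <- true_response(c(35, 35, 40, 50), c(1, 1.5, 2, 2),
                           "ref", cfg)
  expect_equal(on_curve$hr, off_ref$hr)
  expect_equal(on_curve$tre, off_ref$tre)
  # humid heat: cooling for all four responses
  hi <- true_response(45, 4.5, "hi", cfg)
  rf <- true_response(45, 4.5, "ref", cfg)
  expect_true(all(unlist(hi) < unlist(rf)))
  # sign field matches the configured region on an evaluation grid
  g <- expand.grid(ta = seq(25, 55, 1), pa = seq(0.5, 5, 0.25))
  dv <- true_response(g$ta, g$pa, "hi", cfg)$hr -
    true_response(g$ta, g$pa, "ref", cfg)$hr
  inside <- g$ta > 35 & g$pa < cfg$pa_thr[["hr"]]
  expect_equal(dv > 0, inside)
})

test_that("generator population means approximate the configured intercepts", {
  cfg <- canonical_config()
  des <- sample_design(cfg, canonical_seed)
  truth <- true_response(des$ta_C, des$pa_kPa, "ref", cfg)
  expect_equal(mean(truth$hr), cfg$means[["hr"]], tolerance = 0.02)
  expect_equal(mean(truth$tre), cfg$means[["tre"]], tolerance = 0.005)
  expect_equal(mean(truth$sr), cfg$means[["sr"]], tolerance = 0.05)
})

test_that("zero-noise generation returns the truth surfaces exactly", {
  cfg <- generator_config(noise_sd = c(hr = 0, tre = 0, tsk = 0, sr = 0),
                          subject_sd = c(hr = 0, tre = 0, tsk = 0, sr = 0),
                          dropout_prob = 0)
  tr <- generate_trials(cfg, 5)
  truth <- true_response(tr$ta_C, tr$pa_kPa, tr$wind, cfg)
  keep <- !tr$aborted
  expect_equal(tr$hr_bpm[keep], truth$hr[keep])
  expect_equal(tr$tre_C, truth$tre)
  expect_equal(tr$sr_gph[keep], truth$sr[keep])
})

test_that("generated noise matches the configured residual scale", {
  tr <- canonical_trials()
  truth <- attr(tr, "truth")
  sd_hr <- stats::sd(tr$hr_bpm - truth$hr, na.rm = TRUE)
  expect_equal(sd_hr, 7.6, tolerance = 0.15)
  sd_tre <- stats::sd(tr$tre_C - truth$tre, na.rm = TRUE)
  expect_equal(sd_tre, 0.2, tolerance = 0.15)
})

test_that("censoring and skin-temperature identities hold", {
  tr <- canonical_trials()
  expect_equal(nrow(tr), 198L)
  # abort rule: no unaborted trial above the rectal threshold
  expect_true(all(tr$tre_C[!tr$aborted] <= 38.5))
  expect_true(all(is.na(tr$hr_bpm[tr$aborted])))
  # weighted six-site mean reproduces tsk exactly
  ok <- !is.na(tr$tsk_C)
  chk <- mean_skin_temperature(tr$tsk_head_C[ok], tr$tsk_chest_C[ok],
                               tr$tsk_back_C[ok], tr$tsk_arm_C[ok],
                               tr$tsk_thigh_C[ok], tr$tsk_leg_C[ok])
  expect_equal(chk, tr$tsk_C[ok])
  # bit-identical regeneration
  expect_identical(tr, generate_trials(canonical_config(), canonical_seed))
})

test_that("empirical moments converge at large trial counts", {
  cfg <- generator_config(n_ref = 2500, n_hi = 2500,
                          series_range = c(400, 600))
  tr <- generate_trials(cfg, 9)
  truth <- attr(tr, "truth")
  expect_equal(stats::sd(tr$hr_bpm - truth$hr, na.rm = TRUE), 7.6,
               tolerance = 0.05)
  expect_equal(stats::sd(tr$sr_gph - truth$sr, na.rm = TRUE), 120.1,
               tolerance = 0.05)
  # some premature aborts occur under extreme heat at this scale
  expect_gt(sum(tr$aborted), 0)
  ref <- tr$wind == "ref"
  expect_equal(mean(tr$tre_C[ref]), cfg$means[["tre"]], tolerance = 0.005)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_ref = 500), "infeasible")
  expect_error(generator_config(noise_sd = c(hr = -1, tre = 0.2, tsk = 0.4,
                                             sr = 120)), "non-negative")
})
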