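test_that("design matrices follow the difference-smooth coding", {
  tr <- canonical_trials()
  des <- build_design(tr, "hr")
  # tensor rank 81; one sum-to-zero constraint absorbed for the main
  # smooth, no centering for the wind-difference smooth
  expect_length(des$term_index$te, 80L)
  expect_length(des$term_index$te_dv, 81L)
  expect_length(des$term_index$subject, 5L)
  # RefWind rows carry no wind-difference basis
  refrows <- des$frame$windhi == 0
  expect_true(all(des$X[refrows, des$term_index$te_dv] == 0))
  expect_true(any(des$X[!refrows, des$term_index$te_dv] != 0))
  # penalties are symmetric positive semi-definite
  for (S in des$penalties) {
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("noiseless data are recovered essentially perfectly", {
  cfg <- generator_config(n_ref = 500, n_hi = 500,
                          series_range = c(80, 125),
                          noise_sd = c(hr = 0, tre = 0, tsk = 0, sr = 0),
                          dropout_prob = 0)
  tr <- generate_trials(cfg, 21)
  m <- fit_strain_gam(tr, "hr")
  expect_gt(m$summary$r2_adj_pct, 99)
})

test_that("fit recovers the generator's noise level and intercept", {
  m <- canonical_fit("hr")
  expect_equal(m$summary$resid_sd, 7.6, tolerance = 0.15)
  expect_lt(abs(m$summary$intercept - 102.5), 2 * m$summary$intercept_se)
  expect_equal(m$summary$r2_adj_pct, 78, tolerance = 0.1)
})

test_that("single wind level or single subject is rejected", {
  tr <- canonical_trials()
  expect_error(fit_strain_gam(tr[tr$wind == "ref", ], "hr"),
               "wind levels")
  expect_error(fit_strain_gam(tr[tr$subject_id == "S01", ], "hr"),
               "subjects")
})

test_that("delta surface equals the HiWind-minus-RefWind prediction", {
  m <- canonical_fit("hr")
  s <- canonical_surface("hr")
  pick <- s[s$supported, ][c(1, 50, 500), ]
  lev <- levels(m$model$model$subject)[1L]
  ph <- predict(m$model, data.frame(ta = pick$ta_C, pa = pick$pa_kPa,
                                    windhi = 1, subject = lev))
  pr <- predict(m$model, data.frame(ta = pick$ta_C, pa = pick$pa_kPa,
                                    windhi = 0, subject = lev))
  expect_equal(pick$delta, as.numeric(ph - pr), tolerance = 1e-10)
  expect_true(all(s$p >= 0 & s$p <= 1))
  expect_equal(s$significant, s$p <= 0.05)
})

test_that("significant cells recover the sign of the true wind effect", {
  cfg <- canonical_config()
  s <- canonical_surface("hr")
  sig <- s[s$supported & s$significant, ]
  dv <- true_response(sig$ta_C, sig$pa_kPa, "hi", cfg)$hr -
    true_response(sig$ta_C, sig$pa_kPa, "ref", cfg)$hr
  agree <- mean(sign(sig$delta) == sign(dv))
  expect_gte(agree, 0.9)
})

test_that("estimated zero contour tracks the configured threshold curve", {
  s <- canonical_surface("hr")
  ct <- attr(s, "contour")
  expect_gt(nrow(ct), 5L)
  d <- truth_curve_distance(ct$t_air, ct$p_vap, canonical_config(), "hr")
  # median deviation along the contour within 2 degC / 0.5 kPa
  expect_lte(stats::median(d), 1)
})

test_that("smooth-term tests flag the injected wind interaction", {
  tt <- term_tests(canonical_fit("hr"))
  expect_setequal(tt$term, c("s(ID)", "te(Ta,pa)", "te_dv(Ta,pa)"))
  expect_lt(tt$p_value[tt$term == "te(Ta,pa)"], 1e-4)
  expect_lt(tt$p_value[tt$term == "te_dv(Ta,pa)"], 0.001)
  # permuting the wind labels destroys the interaction
  tr <- canonical_trials()
  set.seed(99)
  ps <- replicate(5, {
    trp <- tr
    trp$wind <- sample(trp$wind)
    ttp <- term_tests(fit_strain_gam(trp, "hr"))
    ttp$p_value[ttp$term == "te_dv(Ta,pa)"]
  })
  expect_gte(sum(ps > 0.01), 4)
})

test_that("null subject effects shrink the subject term toward zero", {
  cfg <- generator_config(subject_sd = c(hr = 0, tre = 0, tsk = 0, sr = 0))
  tr <- generate_trials(cfg, 17)
  tt <- term_tests(fit_strain_gam(tr, "tre"))
  edf_null <- tt$edf[tt$term == "s(ID)"]
  # far below both the term rank (4 effective) and the edf under real
  # subject heterogeneity
  expect_lt(edf_null, 1.5)
  tt_real <- term_tests(canonical_fit("tre"))
  expect_lt(edf_null, tt_real$edf[tt_real$term == "s(ID)"] / 2)
})

test_that("penalized fit equals the ridge normal-equations solve", {
  tr <- canonical_trials()
  tr50 <- tr[c(1:25, 101:125), ]
  sp <- c(1, 2, 0.5, 1.5, 3)
  m <- fit_strain_gam(tr50, "hr", sp = sp)
  fit <- m$model
  X <- predict(fit, type = "lpmatrix")
  p <- ncol(X)
  Sfull <- matrix(0, p, p)
  k <- 0L
  for (sm in fit$smooth) for (j in seq_along(sm$S)) {
    k <- k + 1L
    idx <- sm$first.para:sm$last.para
    Sfull[idx, idx] <- Sfull[idx, idx] + sp[k] * sm$S[[j]]
  }
  beta <- solve(crossprod(X) + Sfull, crossprod(X, fit$y))
  expect_lt(max(abs(beta - coef(fit))) / max(abs(coef(fit))), 1e-8)
})
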