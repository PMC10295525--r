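# Penalized tensor-product spline (GAM) estimation of the heat-strain
# response surfaces and of the wind-effect difference surface.
#
# Model per response: E[Y] = mu + s(ID) + te(Ta, pa) + te_dv(Ta, pa), with
# te() a tensor product of two cubic regression spline bases of rank 9
# (total rank 81), te_dv() the same tensor basis active only on HiWind
# rows (factor smooth interaction in difference coding, so its evaluation
# IS the HiWind-minus-RefWind difference), and s(ID) a random subject
# intercept (ridge-penalized indicators, rank = number of subjects).
# Smoothing parameters are selected by maximum likelihood.

.response_cols <- c(hr = "hr_bpm", tre = "tre_C", tsk = "tsk_C",
                    sr = "sr_gph")

#' Spline basis specification for the strain GAMs
#'
#' @param tensor_rank Marginal basis dimension of each tensor smooth;
#'   default 9 (total tensor rank 81).
#' @param subject_rank Basis dimension of the subject effect; default 5.
#' @param method Smoothing-parameter selection criterion, "ML" (default)
#'   or "REML".
#' @return List of class \code{"spline_spec"}.
#' @export
spline_spec <- function(tensor_rank = 9L, subject_rank = 5L,
                        method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(tensor_rank >= 3L, subject_rank >= 2L)
  structure(list(tensor_rank = as.integer(tensor_rank),
                 subject_rank = as.integer(subject_rank), method = method),
            class = "spline_spec")
}

# assemble the modelling frame for one response; drops incomplete cases
.gam_frame <- function(trials, response) {
  response <- match.arg(response, names(.response_cols))
  col <- .response_cols[[response]]
  need <- c("subject_id", "ta_C", "pa_kPa", "wind", col)
  if (!all(need %in% names(trials)))
    stop("trials table lacks columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  d <- data.frame(y = trials[[col]], ta = trials$ta_C, pa = trials$pa_kPa,
                  windhi = as.numeric(as.character(trials$wind) == "hi"),
                  subject = factor(trials$subject_id))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$windhi)) < 2L)
    stop("both wind levels are required; the wind effect is unidentifiable")
  if (nlevels(droplevels(d$subject)) < 2L)
    stop("at least two subjects are required")
  d$subject <- droplevels(d$subject)
  d
}

#' Design matrices and penalties of the strain GAM
#'
#' Constructs the penalized-regression representation of the model:
#' intercept, sum-to-zero-constrained tensor smooth te(Ta, pa) (rank 81,
#' 80 columns after the constraint), the wind-difference tensor smooth
#' te_dv(Ta, pa) multiplied by the HiWind indicator (81 columns, zero on
#' RefWind rows), and ridge-penalized subject indicators. Each tensor
#' smooth carries two marginal penalty matrices.
#'
#' @param trials Trial table (see \code{\link{generate_trials}}).
#' @param response One of "hr", "tre", "tsk", "sr".
#' @param spec A \code{\link{spline_spec}}.
#' @return List with \code{X} (design matrix), \code{y}, \code{penalties}
#'   (list of full-size PSD matrices), and \code{term_index} (named list of
#'   column ranges).
#' @export
build_design <- function(trials, response = "hr", spec = spline_spec()) {
  d <- .gam_frame(trials, response)
  k <- spec$tensor_rank
  sm_main <- mgcv::smoothCon(
    mgcv::te(ta, pa, k = c(k, k), bs = "cr"), data = d,
    absorb.cons = TRUE)[[1L]]
  sm_diff <- mgcv::smoothCon(
    mgcv::te(ta, pa, k = c(k, k), bs = "cr", by = windhi), data = d,
    absorb.cons = TRUE)[[1L]]
  Z <- stats::model.matrix(~ subject - 1, d)
  X <- cbind(`(Intercept)` = 1, sm_main$X, sm_diff$X, Z)
  idx <- list(intercept = 1L,
              te = 1L + seq_len(ncol(sm_main$X)),
              te_dv = 1L + ncol(sm_main$X) + seq_len(ncol(sm_diff$X)),
              subject = 1L + ncol(sm_main$X) + ncol(sm_diff$X) +
                seq_len(ncol(Z)))
  embed <- function(S, cols) {
    M <- matrix(0, ncol(X), ncol(X))
    M[cols, cols] <- S
    (M + t(M)) / 2
  }
  penalties <- c(lapply(sm_main$S, embed, cols = idx$te),
                 lapply(sm_diff$S, embed, cols = idx$te_dv),
                 list(embed(diag(ncol(Z)), idx$subject)))
  names(penalties) <- c("te_ta", "te_pa", "te_dv_ta", "te_dv_pa", "subject")
  list(X = X, y = d$y, penalties = penalties, term_index = idx, frame = d)
}

#' Fit the penalized tensor-spline model for one heat-strain response
#'
#' Fits E[Y] = mu + s(ID) + te(Ta, pa) + te_dv(Ta, pa) by penalized least
#' squares with smoothing parameters chosen by maximum likelihood
#' (Gaussian errors), using \code{mgcv::gam}. Rows with a missing response
#' are dropped (complete-case analysis per response).
#'
#' @param trials Trial table with columns \code{subject_id}, \code{ta_C},
#'   \code{pa_kPa}, \code{wind} and the response column.
#' @param response One of "hr", "tre", "tsk", "sr".
#' @param spec A \code{\link{spline_spec}}.
#' @param sp Optional fixed smoothing-parameter vector (length 5), mainly
#'   for validation against a direct penalized least-squares solve.
#' @return Object of class \code{"strain_gam"}: list with the fitted
#'   \code{model} (a \code{gam} object), \code{response}, \code{spec},
#'   \code{n}, \code{design_points}, and a \code{summary} list
#'   (r2_adj_pct, resid_sd, intercept, intercept_se).
#' @export
fit_strain_gam <- function(trials, response = "hr", spec = spline_spec(),
                           sp = NULL) {
  response <- match.arg(response, names(.response_cols))
  d <- .gam_frame(trials, response)
  k <- spec$tensor_rank
  form <- y ~ te(ta, pa, k = c(k, k), bs = "cr") +
    te(ta, pa, k = c(k, k), bs = "cr", by = windhi) +
    s(subject, bs = "re", k = spec$subject_rank)
  fit <- mgcv::gam(form, data = d, method = spec$method, sp = sp)
  if (!fit$converged)
    stop("GAM smoothing-parameter optimization did not converge; sp = ",
         paste(signif(fit$sp, 4), collapse = ", "))
  sm <- summary(fit)
  res <- structure(list(
    model = fit, response = response, spec = spec, n = nrow(d),
    design_points = d[, c("ta", "pa", "windhi")],
    summary = list(r2_adj_pct = 100 * sm$r.sq,
                   resid_sd = sqrt(fit$sig2),
                   intercept = unname(stats::coef(fit)[1L]),
                   intercept_se = unname(sqrt(fit$Vp[1L, 1L])))),
    class = "strain_gam")
  res
}

#' @export
print.strain_gam <- function(x, ...) {
  cat(sprintf(
    "strain GAM for %s: n = %d, adj. R2 = %.1f%%, residual SD = %.3g, intercept = %.4g +/- %.2g\n",
    x$response, x$n, x$summary$r2_adj_pct, x$summary$resid_sd,
    x$summary$intercept, x$summary$intercept_se))
  print(term_tests(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Wald tests for the smooth terms of a strain GAM
#'
#' Per-term effective degrees of freedom, reference degrees of freedom,
#' F statistic and p-value, from the Wald-type test on the penalized
#' coefficients.
#'
#' @param model A \code{\link{fit_strain_gam}} result.
#' @return Data frame with columns \code{term}, \code{edf}, \code{ref_df},
#'   \code{F}, \code{p_value}.
#' @export
term_tests <- function(model) {
  stopifnot(inherits(model, "strain_gam"))
  st <- summary(model$model)$s.table
  lab <- rownames(st)
  term <- ifelse(grepl("^s\\(subject\\)", lab), "s(ID)",
                 ifelse(grepl(":windhi", lab, fixed = TRUE), "te_dv(Ta,pa)",
                        "te(Ta,pa)"))
  data.frame(term = term, edf = st[, "edf"], ref_df = st[, "Ref.df"],
             F = st[, "F"], p_value = st[, "p-value"], row.names = NULL)
}

# scaled distance (in grid-step units) from points to the convex hull
# boundary of the design points; 0 inside the hull
.hull_distance <- function(ta, pa, hx, hy, step_ta, step_pa) {
  px <- ta / step_ta; py <- pa / step_pa
  qx <- hx / step_ta; qy <- hy / step_pa
  m <- length(qx)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- qx[j] - qx[i]; ey <- qy[j] - qy[i]
    tt <- ((px - qx[i]) * ex + (py - qy[i]) * ey) / (ex^2 + ey^2)
    tt <- pmin(pmax(tt, 0), 1)
    dd <- sqrt((px - (qx[i] + tt * ex))^2 + (py - (qy[i] + tt * ey))^2)
    dmin <- pmin(dmin, dd)
  }
  dmin
}

#' Estimated wind-effect difference surface
#'
#' Evaluates the fitted wind effect Delta_v (HiWind-minus-RefWind predicted
#' difference) over a temperature-humidity grid, with pointwise standard
#' errors from the coefficient covariance, two-sided Wald p-values for
#' Delta_v = 0, a significance mask at the given level, a support flag
#' (convex hull of the observed design points dilated by one grid step),
#' and the estimated zero contour over supported cells.
#'
#' @param model A \code{\link{fit_strain_gam}} result.
#' @param grid A \code{\link{build_grid}} result, or NULL to build one
#'   spanning the observed design points with the given steps.
#' @param steps Grid steps when \code{grid} is NULL.
#' @param alpha Pointwise significance level; default 0.05. No multiplicity
#'   correction is applied.
#' @return Object of class \code{"delta_surface"}: data frame with columns
#'   \code{ta_C}, \code{pa_kPa}, \code{delta}, \code{se}, \code{p},
#'   \code{significant}, \code{supported}; attributes \code{ta_axis},
#'   \code{pa_axis}, \code{response}, \code{contour}.
#' @export
delta_surface <- function(model, grid = NULL, steps = c(0.5, 0.1),
                          alpha = 0.05) {
  stopifnot(inherits(model, "strain_gam"))
  dp <- model$design_points
  if (is.null(grid)) {
    ta_range <- range(dp$ta); pa_range <- range(dp$pa)
    grid <- build_grid(ta_range, pa_range, steps)
  }
  stopifnot(inherits(grid, "psychro_grid"))
  cells <- which(grid$mask, arr.ind = TRUE)
  ta <- grid$ta_axis[cells[, 1L]]
  pa <- grid$pa_axis[cells[, 2L]]
  subj <- model$design_points
  lev <- levels(model$model$model$subject)[1L]
  nd_hi <- data.frame(ta = ta, pa = pa, windhi = 1, subject = lev)
  nd_ref <- data.frame(ta = ta, pa = pa, windhi = 0, subject = lev)
  Xd <- stats::predict(model$model, nd_hi, type = "lpmatrix") -
    stats::predict(model$model, nd_ref, type = "lpmatrix")
  est <- drop(Xd %*% stats::coef(model$model))
  se <- sqrt(pmax(rowSums((Xd %*% model$model$Vp) * Xd), 0))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  # support: convex hull of design points, dilated by one grid step
  hull <- grDevices::chull(dp$ta, dp$pa)
  hx <- dp$ta[hull]; hy <- dp$pa[hull]
  inside <- mgcv::in.out(cbind(c(hx, hx[1L]), c(hy, hy[1L])),
                         cbind(ta, pa))
  dist <- .hull_distance(ta, pa, hx, hy, diff(grid$ta_axis[1:2]),
                         diff(grid$pa_axis[1:2]))
  supported <- inside | dist <= 1
  out <- data.frame(ta_C = ta, pa_kPa = pa, delta = est, se = se, p = p,
                    significant = p <= alpha, supported = supported)
  # zero contour over supported cells
  zmat <- matrix(NA_real_, length(grid$ta_axis), length(grid$pa_axis))
  zmat[cells] <- ifelse(supported, est, NA_real_)
  cl <- grDevices::contourLines(grid$ta_axis, grid$pa_axis, zmat, levels = 0)
  contour <- if (length(cl) == 0L)
    data.frame(t_air = numeric(0), p_vap = numeric(0), piece = integer(0))
  else do.call(rbind, lapply(seq_along(cl), function(i)
    data.frame(t_air = cl[[i]]$x, p_vap = cl[[i]]$y, piece = i)))
  structure(out, ta_axis = grid$ta_axis, pa_axis = grid$pa_axis,
            response = model$response, contour = contour, alpha = alpha,
            class = c("delta_surface", "data.frame"))
}

#' @export
print.delta_surface <- function(x, ...) {
  sup <- x[x$supported, ]
  cat(sprintf(
    "wind-effect surface for %s: %d grid cells (%d supported), delta range %.3g .. %.3g, %.1f%% significant at alpha = %g\n",
    attr(x, "response"), nrow(x), nrow(sup), min(sup$delta), max(sup$delta),
    100 * mean(sup$significant), attr(x, "alpha")))
  invisible(x)
}
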