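#' Decay-corrected fractional uptake
#'
#' Converts physical (measurement-time) activities into percent of the
#' administered activity, decay-corrected to injection time:
#' `100 * activity / decay_factor(t) / administered`.
#'
#' @param samples data.frame with columns `t_h`, `activity_MBq`.
#' @param administered_MBq administered activity, MBq (> 0).
#' @param nuclide a [radionuclide].
#' @return data.frame with columns `t_h`, `fraction_pct`.
#' @export
fractional_uptake <- function(samples, administered_MBq,
                              nuclide = iodine124()) {
  if (!is.numeric(administered_MBq) || administered_MBq <= 0)
    stop("'administered_MBq' must be > 0")
  data.frame(
    t_h = samples$t_h,
    fraction_pct = 100 * samples$activity_MBq /
      decay_factor(samples$t_h, nuclide) / administered_MBq
  )
}

#' Fit a two-phase time-activity curve
#'
#' The default `"smooth"` model least-squares fits the physical activity
#' `A(t) = C * (1 - exp(-k_u t)) * exp(-(k_b + lambda_p) t)` with the
#' physical decay constant fixed; its rising and falling phases are the
#' uptake and outflow pieces of the classical two-component description.
#' The `"piecewise"` alternative uses a linear rise from the origin to the
#' maximal sample and a log-linear fit of the effective decay on the
#' samples at and after the maximum.
#'
#' @param samples data.frame with columns `t_h`, `activity_MBq`.
#' @param method `"smooth"` or `"piecewise"`.
#' @param nuclide a [radionuclide] fixing `lambda_p`.
#' @return An object of class `kinetic_fit`: list with `method`, `C`,
#'   `k_u`, `k_b`, `lambda_p`, `t_peak` (biological peak time, h),
#'   `residual_sse`, `degenerate` flag, and for the piecewise model
#'   `t_peak_sample` and `A_peak`.
#' @export
fit_tac <- function(samples, method = c("smooth", "piecewise"),
                    nuclide = iodine124()) {
  method <- match.arg(method)
  stopifnot(all(c("t_h", "activity_MBq") %in% names(samples)))
  t <- samples$t_h; A <- samples$activity_MBq
  lp <- nuclide$lambda_p
  if (all(A == 0)) {
    return(structure(list(method = method, C = 0, k_u = 1, k_b = 0,
                          lambda_p = lp, t_peak = NA_real_,
                          residual_sse = 0, degenerate = TRUE),
                     class = "kinetic_fit"))
  }
  if (method == "smooth") {
    if (length(unique(t)) < 3)
      stop("smooth fit needs >= 3 samples at distinct times")
    im <- which.max(A)
    # deterministic initialization from the data
    ku0 <- 1 / max(t[1], 1e-3)
    mid <- max(im, length(t) - 1L)
    kb0 <- if (t[length(t)] > t[mid] && A[length(t)] > 0 && A[mid] > 0)
      max(log(A[mid] / A[length(t)]) / (t[length(t)] - t[mid]) - lp, 1e-5)
      else 1e-3
    C0 <- max(A) / max(1 - exp(-ku0 * t[im]), 0.1)
    fit <- try(minpack.lm::nlsLM(
      activity_MBq ~ C * (1 - exp(-ku * t_h)) * exp(-(kb + lp) * t_h),
      data = data.frame(t_h = t, activity_MBq = A),
      start = list(C = C0, ku = ku0, kb = kb0),
      lower = c(C = 0, ku = 1e-4, kb = 0),
      upper = c(C = Inf, ku = 100, kb = 10),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("smooth TAC fit failed to converge: ", attr(fit, "condition")$message)
    p <- stats::coef(fit)
    tpk <- if (p[["kb"]] > 0) log(1 + p[["ku"]] / p[["kb"]]) / p[["ku"]]
           else NA_real_
    structure(list(method = "smooth", C = p[["C"]], k_u = p[["ku"]],
                   k_b = p[["kb"]], lambda_p = lp, t_peak = tpk,
                   residual_sse = sum(stats::resid(fit)^2),
                   degenerate = FALSE),
              class = "kinetic_fit")
  } else {
    im <- which.max(A)
    post <- which(t >= t[im])
    if (length(post) < 2) stop("piecewise fit needs >= 2 post-peak samples")
    lf <- stats::lm(log(A[post]) ~ t[post])
    lambda_eff <- -stats::coef(lf)[[2]]
    degenerate <- lambda_eff <= 1e-12      # flat or rising tail
    kb <- max(lambda_eff - lp, 0)
    pred <- ifelse(t <= t[im], A[im] * t / t[im],
                   A[im] * exp(-lambda_eff * (t - t[im])))
    structure(list(method = "piecewise", C = A[im], k_u = NA_real_,
                   k_b = kb, lambda_p = lp, t_peak = t[im],
                   t_peak_sample = t[im], A_peak = A[im],
                   lambda_eff = lambda_eff,
                   residual_sse = sum((A - pred)^2),
                   degenerate = degenerate),
              class = "kinetic_fit")
  }
}

#' Evaluate a fitted physical time-activity curve
#'
#' @param fit a [fit_tac()] result.
#' @param t_h times, hours.
#' @return Physical activity, MBq.
#' @export
predict_tac <- function(fit, t_h) {
  if (fit$method == "smooth") {
    fit$C * (1 - exp(-fit$k_u * t_h)) * exp(-(fit$k_b + fit$lambda_p) * t_h)
  } else {
    ifelse(t_h <= fit$t_peak_sample,
           fit$A_peak * t_h / pmax(fit$t_peak_sample, .Machine$double.eps),
           fit$A_peak * exp(-fit$lambda_eff * (t_h - fit$t_peak_sample)))
  }
}

#' Peak fractional uptake implied by a fitted curve
#'
#' Maximum of the biological (decay-corrected) curve
#' `B(t) = C (1 - exp(-k_u t)) exp(-k_b t)` as a percentage of the
#' administered activity. When the fitted clearance is zero the curve
#' saturates at `C`. For the piecewise model the peak sample itself,
#' decay-corrected, is used.
#'
#' @param fit a [fit_tac()] result.
#' @param administered_MBq administered activity, MBq (> 0).
#' @return Peak fractional uptake, percent.
#' @export
fitted_peak_fraction <- function(fit, administered_MBq) {
  if (administered_MBq <= 0) stop("'administered_MBq' must be > 0")
  bmax <- if (fit$method == "smooth") {
    if (fit$k_b > 0) {
      tp <- log(1 + fit$k_u / fit$k_b) / fit$k_u
      fit$C * (1 - exp(-fit$k_u * tp)) * exp(-fit$k_b * tp)
    } else fit$C
  } else {
    fit$A_peak / exp(-fit$lambda_p * fit$t_peak_sample)
  }
  100 * bmax / administered_MBq
}

#' Cumulated activity from a fitted curve
#'
#' Integrates the fitted PHYSICAL activity (actual decays, not the
#' decay-corrected curve) from zero to `t_max_h` (infinity by default) in
#' closed form, in MBq.s, and splits it at the curve peak into uptake and
#' outflow parts.
#'
#' Smooth model: with `le = k_b + lambda_p`,
#' `A_tilde = 3600 * C * (1/le - 1/(k_u + le))`; the partial integral to T
#' is `3600 * C * ((1 - exp(-le T))/le - (1 - exp(-(k_u+le) T))/(k_u+le))`.
#' Piecewise model: triangle area to the peak sample plus the analytic
#' exponential tail.
#'
#' @param fit a [fit_tac()] result with `k_b + lambda_p > 0`.
#' @param t_max_h upper integration limit, hours (`Inf` default).
#' @return List of class `cumulated_activity` with `a_tilde_MBqs`,
#'   `a_uptake_MBqs`, `a_outflow_MBqs`, `split_time_h`; the parts sum to
#'   the total exactly.
#' @export
cumulated_activity <- function(fit, t_max_h = Inf) {
  if (fit$C == 0)
    return(structure(list(a_tilde_MBqs = 0, a_uptake_MBqs = 0,
                          a_outflow_MBqs = 0, split_time_h = NA_real_),
                     class = "cumulated_activity"))
  if (fit$method == "smooth") {
    le <- fit$k_b + fit$lambda_p
    if (le <= 0) stop("non-integrable: k_b + lambda_p must be > 0")
    part <- function(T) {
      if (is.infinite(T)) 3600 * fit$C * (1 / le - 1 / (fit$k_u + le))
      else 3600 * fit$C * ((1 - exp(-le * T)) / le -
                           (1 - exp(-(fit$k_u + le) * T)) / (fit$k_u + le))
    }
    total <- part(t_max_h)
    # split at the physical-curve peak (argmax of A(t))
    split <- log(1 + fit$k_u / le) / fit$k_u
    split <- min(split, t_max_h)
    up <- part(split)
  } else {
    if (fit$lambda_eff <= 0)
      stop("non-integrable: effective decay constant must be > 0")
    split <- min(fit$t_peak_sample, t_max_h)
    up <- 3600 * 0.5 * fit$A_peak * split *
      (if (split < fit$t_peak_sample) split / fit$t_peak_sample else 1)
    tail_end <- t_max_h - fit$t_peak_sample
    total <- if (t_max_h <= fit$t_peak_sample) up
      else up + 3600 * fit$A_peak / fit$lambda_eff *
        (1 - if (is.infinite(tail_end)) 0 else exp(-fit$lambda_eff * tail_end))
  }
  structure(list(a_tilde_MBqs = total, a_uptake_MBqs = up,
                 a_outflow_MBqs = total - up, split_time_h = split),
            class = "cumulated_activity")
}
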