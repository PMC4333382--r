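#' Michaelis-Menten velocity
#'
#' Evaluates \eqn{v = V_{max} S / (K_M + S)}.
#'
#' @param S Substrate concentration (nM).
#' @param KM Michaelis constant (nM).
#' @param Vmax Maximal velocity (nM/min).
#' @export
mm_velocity <- function(S, KM, Vmax) Vmax * S / (KM + S)

#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Direct nonlinear fit of \eqn{v = V_{max} S / (K_M + S)} to initial
#' velocities measured across a substrate-concentration grid.  When the
#' enzyme concentration is supplied, the turnover number
#' \eqn{k_{cat} = V_{max} / E_0} (converted to 1/s) and the catalytic
#' efficiency \eqn{k_{cat} / K_M} (1/(M s)) are derived.  Both parameters
#' are constrained positive.
#'
#' @param points data.frame with columns \code{S_nM} and
#'   \code{v0_nM_per_min} (a \code{replicate} column is allowed and
#'   ignored by the fit).  At least 4 distinct substrate concentrations
#'   spanning one order of magnitude are required.
#' @param E0 Enzyme concentration in nM (optional; enables kcat and
#'   efficiency).
#' @param weighting \code{"none"} (default) or \code{"inv_v2"} for
#'   \eqn{1/v^2} weights.
#' @return Object of class \code{"mm_fit"}: \code{KM} (nM), \code{Vmax}
#'   (nM/min), \code{se}, \code{kcat} (1/s, or NA), \code{efficiency}
#'   (1/(M s), or NA), \code{E0}, \code{fit} (the underlying nls object)
#'   and \code{data}.
#' @examples
#' d <- gen_mm_velocities(spec = generator_spec(1, noise_scale = 0))
#' fit_michaelis_menten(d, E0 = 1)
#' @export
fit_michaelis_menten <- function(points, E0 = NULL,
                                 weighting = c("none", "inv_v2")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("S_nM", "v0_nM_per_min") %in% names(points)))
  S <- points$S_nM
  v <- points$v0_nM_per_min
  if (any(S <= 0) || any(v < 0))
    stop("require S > 0 and v0 >= 0", call. = FALSE)
  us <- unique(S)
  if (length(us) < 4L || max(us) / min(us) < 10)
    stop("unidentifiable design: need >= 4 distinct S spanning an order of magnitude",
         call. = FALSE)
  w <- if (weighting == "inv_v2") 1 / pmax(v, 1e-12)^2 else rep(1, length(v))
  vmax0 <- max(v) * 1.2
  km0 <- us[which.min(abs(vapply(us, function(s) mean(v[S == s]), 1) - vmax0 / 2))]
  fit <- minpack.lm::nlsLM(
    v ~ Vmax * S / (KM + S),
    data = data.frame(S = S, v = v),
    start = list(KM = max(km0, 1e-3), Vmax = vmax0),
    lower = c(0, 0), weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  KM <- unname(est["KM"]); Vmax <- unname(est["Vmax"])
  kcat <- if (!is.null(E0)) velocity_to_per_s(Vmax, E0) else NA_real_
  eff <- if (!is.null(E0)) kcat / (KM * 1e-9) else NA_real_
  structure(
    list(KM = KM, Vmax = Vmax,
         se = c(KM = unname(se["KM"]), Vmax = unname(se["Vmax"])),
         kcat = kcat, efficiency = eff, E0 = E0,
         fit = fit, data = points, weighting = weighting),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat("Michaelis-Menten fit (nonlinear least squares)\n")
  cat(sprintf("  KM   = %s nM (se %s)\n", signif(x$KM, digits),
              signif(x$se["KM"], 3)))
  cat(sprintf("  Vmax = %s nM/min (se %s)\n", signif(x$Vmax, digits),
              signif(x$se["Vmax"], 3)))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %s 1/s (E0 = %g nM)\n", signif(x$kcat, digits), x$E0))
    cat(sprintf("  kcat/KM = %s 1/(M s)\n", signif(x$efficiency, 3)))
  }
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(KM = object$KM, Vmax = object$Vmax)

#' @export
summary.mm_fit <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(coefficients = s$coefficients, kcat = object$kcat,
              efficiency = object$efficiency, E0 = object$E0,
              sigma = s$sigma, df = s$df)
  class(out) <- "summary.mm_fit"
  out
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  if (!is.na(x$kcat))
    cat(sprintf("\nkcat = %.4g 1/s at E0 = %g nM; kcat/KM = %.3g 1/(M s)\n",
                x$kcat, x$E0, x$efficiency))
  cat(sprintf("Residual standard error: %.4g on %d degrees of freedom\n",
              x$sigma, x$df[2L]))
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, S_nM = object$data$S_nM, ...) {
  mm_velocity(S_nM, object$KM, object$Vmax)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$v0_nM_per_min - predict(object)
}

#' Lineweaver-Burk double-reciprocal transformation
#'
#' Ordinary least squares on \eqn{1/v} versus \eqn{1/S}.  Retained as a
#' display diagnostic only: reciprocal transformation inflates the weight of
#' low-velocity points, so under realistic noise the implied parameters are
#' biased relative to the direct nonlinear fit, which is authoritative.
#'
#' @inheritParams fit_michaelis_menten
#' @return List with \code{slope}, \code{intercept}, \code{KM}, \code{Vmax}
#'   (implied) and the underlying \code{lm} fit; class
#'   \code{"lineweaver_burk"}.
#' @export
lineweaver_burk <- function(points) {
  stopifnot(all(c("S_nM", "v0_nM_per_min") %in% names(points)))
  if (any(points$v0_nM_per_min <= 0))
    stop("transform undefined: all velocities must be positive", call. = FALSE)
  d <- data.frame(x = 1 / points$S_nM, y = 1 / points$v0_nM_per_min)
  fit <- stats::lm(y ~ x, data = d)
  co <- stats::coef(fit)
  structure(
    list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
         KM = unname(co["x"] / co["(Intercept)"]),
         Vmax = unname(1 / co["(Intercept)"]), fit = fit,
         diagnostic_only = TRUE),
    class = "lineweaver_burk")
}

#' @export
print.lineweaver_burk <- function(x, ...) {
  cat("Lineweaver-Burk transformation (diagnostic only)\n")
  cat(sprintf("  1/v = %.4g + %.4g * (1/S)\n", x$intercept, x$slope))
  cat(sprintf("  implied KM = %.4g nM, Vmax = %.4g nM/min\n", x$KM, x$Vmax))
  invisible(x)
}

#' Linear temperature dependence of the initial velocity
#'
#' Ordinary least-squares line of initial velocity against reaction
#' temperature, with the coefficient of determination.
#'
#' @param v0_by_T data.frame with columns \code{temperature_C} and
#'   \code{v0_nM_per_min}; at least 3 temperatures.
#' @return Object of class \code{"temperature_fit"}: \code{slope}
#'   (nM/(min C)), \code{intercept} (nM/min), \code{r_squared}, \code{fit}.
#' @export
fit_temperature <- function(v0_by_T) {
  stopifnot(all(c("temperature_C", "v0_nM_per_min") %in% names(v0_by_T)))
  if (nrow(v0_by_T) < 3L)
    stop("insufficient data: need at least 3 temperatures", call. = FALSE)
  fit <- stats::lm(v0_nM_per_min ~ temperature_C, data = v0_by_T)
  co <- stats::coef(fit)
  v <- v0_by_T$v0_nM_per_min
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(co["temperature_C"]),
         intercept = unname(co["(Intercept)"]),
         r_squared = r2, fit = fit),
    class = "temperature_fit")
}

#' @export
print.temperature_fit <- function(x, ...) {
  cat(sprintf("Temperature dependence: v0 = %.4g + %.4g * T, r^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.temperature_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Fractional velocities and percent reductions across inhibitor doses
#'
#' @param v0_control Uninhibited initial velocity (nM/min), positive.
#' @param v0_by_dose data.frame with columns \code{I_nM} and
#'   \code{v0_nM_per_min}.
#' @return data.frame with \code{I_nM}, \code{fractional_velocity}
#'   (\eqn{v(I)/v(0)}) and \code{reduction_pct}.
#' @examples
#' inhibition_profile(1, data.frame(I_nM = c(1, 10),
#'                                  v0_nM_per_min = c(0.42, 0.22)))
#' @export
inhibition_profile <- function(v0_control, v0_by_dose) {
  if (v0_control <= 0)
    stop("invalid control: v0_control must be positive", call. = FALSE)
  stopifnot(all(c("I_nM", "v0_nM_per_min") %in% names(v0_by_dose)))
  if (any(v0_by_dose$I_nM < 0))
    stop("doses must be non-negative", call. = FALSE)
  fv <- v0_by_dose$v0_nM_per_min / v0_control
  data.frame(I_nM = v0_by_dose$I_nM, fractional_velocity = fv,
             reduction_pct = 100 * (1 - fv))
}

#' Partial (hyperbolic) inhibition velocity
#'
#' \eqn{v/v_0 = (K_i^{app} + \beta I) / (K_i^{app} + I)}: activity falls
#' hyperbolically with inhibitor and saturates at the residual fraction
#' \eqn{\beta} instead of zero.
#'
#' @param I Inhibitor concentration (nM).
#' @param Ki_app Apparent inhibition constant (nM).
#' @param beta Residual fractional activity at saturating inhibitor.
#' @export
partial_inhibition_velocity <- function(I, Ki_app, beta) {
  (Ki_app + beta * I) / (Ki_app + I)
}

#' Fit the partial-inhibition dose response
#'
#' Fits \eqn{v/v_0 = (K_i^{app} + \beta I)/(K_i^{app} + I)} to fractional
#' velocities.  With exactly two informative doses the model is exactly
#' identified and solved algebraically (the model is linear in
#' \eqn{(K_i^{app}, \beta)} after clearing the denominator); with more
#' doses it is fit by bounded nonlinear least squares.
#'
#' @param fractional data.frame with columns \code{I_nM} and
#'   \code{fractional_velocity} (\eqn{v/v_0 \in (0, 1]}); the \code{I = 0}
#'   anchor row is permitted and ignored by the solve.
#' @return Object of class \code{"inhibition_fit"}: \code{Ki_app} (nM),
#'   \code{beta}, \code{method} (\code{"exact"} or \code{"nls"}),
#'   \code{identifiable}, \code{data}.
#' @examples
#' fit_partial_inhibition(data.frame(I_nM = c(1, 10),
#'                                   fractional_velocity = c(0.42, 0.22)))
#' @export
fit_partial_inhibition <- function(fractional) {
  stopifnot(all(c("I_nM", "fractional_velocity") %in% names(fractional)))
  fv <- fractional$fractional_velocity
  if (any(fv > 1 + 1e-9) || any(fv <= 0))
    stop("invalid fraction: fractional velocities must lie in (0, 1]",
         call. = FALSE)
  inf <- fractional[fractional$I_nM > 0, ]
  if (nrow(inf) < 2L)
    stop("need at least 2 doses with I > 0", call. = FALSE)
  if (all(abs(inf$fractional_velocity - 1) < 1e-9)) {
    warning("no inhibition observed: Ki_app unidentifiable, beta = 1")
    out <- list(Ki_app = NA_real_, beta = 1, method = "degenerate",
                identifiable = FALSE, data = fractional)
    class(out) <- "inhibition_fit"
    return(out)
  }
  if (nrow(inf) == 2L) {
    # f (Ki + I) = Ki + beta I  =>  Ki (f - 1) - beta I = -f I
    A <- cbind(inf$fractional_velocity - 1, -inf$I_nM)
    b <- -inf$fractional_velocity * inf$I_nM
    sol <- solve(A, b)
    Ki <- sol[1L]; beta <- sol[2L]
    method <- "exact"
  } else {
    start_beta <- min(inf$fractional_velocity)
    fit <- minpack.lm::nlsLM(
      fv ~ (Ki + beta * I) / (Ki + I),
      data = data.frame(I = inf$I_nM, fv = inf$fractional_velocity),
      start = list(Ki = stats::median(inf$I_nM), beta = start_beta * 0.9),
      lower = c(0, 0), upper = c(Inf, 1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- stats::coef(fit)
    Ki <- unname(est["Ki"]); beta <- unname(est["beta"])
    method <- "nls"
  }
  if (beta < 0) {
    warning("beta estimate below 0; clamped to 0")
    beta <- 0
  }
  if (Ki <= 0)
    stop("inhibition fit failed: non-positive Ki_app", call. = FALSE)
  structure(
    list(Ki_app = Ki, beta = beta, method = method, identifiable = TRUE,
         data = fractional),
    class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Partial-inhibition fit (%s)\n", x$method))
  if (!x$identifiable) {
    cat("  unidentifiable: no inhibition observed (beta = 1)\n")
  } else {
    cat(sprintf("  Ki_app = %.4g nM\n  beta (residual activity) = %.4g\n",
                x$Ki_app, x$beta))
  }
  invisible(x)
}

#' @export
coef.inhibition_fit <- function(object, ...) {
  c(Ki_app = object$Ki_app, beta = object$beta)
}

#' @export
predict.inhibition_fit <- function(object, I_nM = object$data$I_nM, ...) {
  if (!object$identifiable) return(rep(1, length(I_nM)))
  partial_inhibition_velocity(I_nM, object$Ki_app, object$beta)
}
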