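#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Pseudo-first-order closed forms for single-site binding at constant
#' analyte concentration \code{C}: during association
#' \eqn{R(t) = R_{eq}(1 - e^{-(k_a C + k_d) t})} with
#' \eqn{R_{eq} = R_{max} k_a C / (k_a C + k_d)}; after the injection stops,
#' \eqn{R(t) = R(t_{assoc}) e^{-k_d (t - t_{assoc})}}.  These are exact for
#' the 1:1 model, so no numerical integration is used.
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd_rate Dissociation rate constant, 1/s.
#' @param Rmax Surface capacity, response units (RU).
#' @param C Analyte concentration, molar.
#' @param t_assoc Association (contact) time, s.
#' @param t_diss Dissociation time, s.
#' @param dt Sampling interval, s.
#' @return Object of class \code{"sensorgram"}: list with \code{times} (s),
#'   \code{response} (RU), \code{analyte_conc} (M), \code{t_assoc_end} (s).
#' @export
simulate_sensorgram <- function(ka, kd_rate, Rmax, C,
                                t_assoc = 60, t_diss = 600, dt = 1) {
  if (any(c(ka, kd_rate, Rmax, C, t_assoc, t_diss, dt) <= 0))
    stop("invalid parameter: all rates, concentrations and times must be positive",
         call. = FALSE)
  times <- seq(0, t_assoc + t_diss, by = dt)
  structure(
    list(times = times,
         response = langmuir_response(times, ka, kd_rate, Rmax, C, t_assoc),
         analyte_conc = C, t_assoc_end = t_assoc),
    class = "sensorgram")
}

#' @rdname simulate_sensorgram
#' @param times Times (s) at which to evaluate the response.
#' @export
langmuir_response <- function(times, ka, kd_rate, Rmax, C, t_assoc) {
  kobs <- ka * C + kd_rate
  req <- Rmax * ka * C / kobs
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(times <= t_assoc,
         req * (1 - exp(-kobs * times)),
         r_end * exp(-kd_rate * (times - t_assoc)))
}

#' Equilibrium response of the 1:1 model
#'
#' @inheritParams simulate_sensorgram
#' @export
langmuir_req <- function(ka, kd_rate, Rmax, C) Rmax * ka * C / (ka * C + kd_rate)

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram: C = %.3g nM, %d points, association ends at %g s\n",
              x$analyte_conc * 1e9, length(x$times), x$t_assoc_end))
  invisible(x)
}

#' @export
as.data.frame.sensorgram <- function(x, ...) {
  data.frame(time_s = x$times, response_RU = x$response,
             conc_nM = x$analyte_conc * 1e9,
             phase = ifelse(x$times <= x$t_assoc_end, "assoc", "diss"))
}

#' Global 1:1 Langmuir fit across analyte concentrations
#'
#' Fits a single set of rate constants (ka, kd) and a shared surface
#' capacity Rmax to a series of sensorgrams recorded at different analyte
#' concentrations, by nonlinear least squares on the stacked residuals.
#' Parameters are optimised on the log scale to enforce positivity.  The
#' equilibrium affinity is reported as \eqn{K_D = k_d / k_a}.
#'
#' @param sensorgrams List of \code{"sensorgram"} objects (at least 3
#'   distinct analyte concentrations for a well-identified fit; fewer
#'   triggers a weak-identifiability warning).
#' @param start Optional named list \code{list(ka=, kd_rate=, Rmax=)} of
#'   starting values.
#' @return Object of class \code{"langmuir_fit"}: \code{ka}, \code{kd_rate},
#'   \code{Rmax}, \code{KD} (molar, \code{= kd_rate/ka}), \code{se}
#'   (delta-method standard errors), \code{rss}, \code{sensorgrams}.
#' @export
fit_langmuir_global <- function(sensorgrams, start = NULL) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(all(vapply(sensorgrams, inherits, TRUE, "sensorgram")))
  concs <- vapply(sensorgrams, `[[`, 1, "analyte_conc")
  if (length(unique(concs)) < 3L)
    warning("fewer than 3 analyte concentrations: rate constants weakly identifiable")
  if (is.null(start)) {
    rmax0 <- max(vapply(sensorgrams, function(s) max(s$response), 1)) * 1.3
    # dissociation tail of the highest-concentration trace gives kd
    top <- sensorgrams[[which.max(concs)]]
    diss <- top$times > top$t_assoc_end & top$response > 0
    kd0 <- if (sum(diss) > 2) {
      td <- top$times[diss] - top$t_assoc_end
      max(-stats::coef(stats::lm(log(top$response[diss]) ~ td))[2L], 1e-4)
    } else 0.01
    start <- list(ka = 1e6, kd_rate = kd0, Rmax = rmax0)
  }
  resid_fn <- function(p) {
    ka <- exp(p[1L]); kd <- exp(p[2L]); rmax <- exp(p[3L])
    unlist(lapply(sensorgrams, function(s)
      s$response - langmuir_response(s$times, ka, kd, rmax,
                                     s$analyte_conc, s$t_assoc_end)))
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(start$ka, start$kd_rate, start$Rmax)),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (fit$info %in% c(0, 5))
    stop("Langmuir fit failed to converge: ", fit$message, call. = FALSE)
  est <- exp(fit$par)
  names(est) <- c("ka", "kd_rate", "Rmax")
  n <- length(fit$fvec); df <- n - 3L
  sigma2 <- sum(fit$fvec^2) / max(df, 1L)
  se_log <- tryCatch(sqrt(diag(sigma2 * solve(fit$hessian))),
                     error = function(e) rep(NA_real_, 3L))
  se <- est * se_log                       # delta method for exp transform
  names(se) <- names(est)
  structure(
    list(ka = unname(est["ka"]), kd_rate = unname(est["kd_rate"]),
         Rmax = unname(est["Rmax"]),
         KD = unname(est["kd_rate"] / est["ka"]),
         se = se, rss = sum(fit$fvec^2), n_obs = n,
         sensorgrams = sensorgrams),
    class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("Global 1:1 Langmuir fit\n")
  cat(sprintf("  ka   = %.3g 1/(M s) (se %.2g)\n", x$ka, x$se["ka"]))
  cat(sprintf("  kd   = %.3g 1/s (se %.2g)\n", x$kd_rate, x$se["kd_rate"]))
  cat(sprintf("  Rmax = %.4g RU\n", x$Rmax))
  cat(sprintf("  KD   = kd/ka = %.3g nM\n", x$KD * 1e9))
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...) {
  c(ka = object$ka, kd_rate = object$kd_rate, Rmax = object$Rmax)
}

#' @export
predict.langmuir_fit <- function(object, sensorgram = NULL, ...) {
  sg <- if (is.null(sensorgram)) object$sensorgrams[[1L]] else sensorgram
  langmuir_response(sg$times, object$ka, object$kd_rate, object$Rmax,
                    sg$analyte_conc, sg$t_assoc_end)
}

#' Fit an EMSA fraction-bound isotherm
#'
#' Under excess protein the bound fraction follows the hyperbola
#' \eqn{f = P / (P + k_d^{app})}; \code{kd_apparent} is the protein
#' concentration at half-maximal binding.  When the probe concentration is
#' comparable to the protein concentrations, set \code{depletion = TRUE}
#' and supply \code{rna_conc} to use the exact (quadratic) solution for a
#' 1:1 complex with ligand depletion.
#'
#' @param points data.frame with columns \code{conc_nM} (total protein) and
#'   \code{fraction_bound}.  At least 4 concentrations; a warning is issued
#'   unless the titration brackets the transition (one point below 0.3 and
#'   one above 0.6 bound).
#' @param depletion Use the ligand-depletion (quadratic) model.
#' @param rna_conc Probe RNA concentration in nM (required when
#'   \code{depletion = TRUE}).
#' @return Object of class \code{"emsa_fit"}: \code{kd_apparent} (nM),
#'   \code{se}, \code{model}, \code{fit}, \code{data}.
#' @export
fit_emsa_isotherm <- function(points, depletion = FALSE, rna_conc = NULL) {
  stopifnot(all(c("conc_nM", "fraction_bound") %in% names(points)))
  P <- points$conc_nM; fb <- points$fraction_bound
  if (any(fb < 0 | fb > 1))
    stop("fraction_bound must lie in [0, 1]", call. = FALSE)
  if (length(unique(P)) < 4L)
    stop("need at least 4 protein concentrations", call. = FALSE)
  if (all(fb < 0.05) || all(fb > 0.95))
    stop("unidentifiable: titration shows no binding transition", call. = FALSE)
  if (!any(fb < 0.3) || !any(fb > 0.6))
    warning("titration does not bracket the transition (want points below 0.3 and above 0.6 bound)")
  kd0 <- P[which.min(abs(fb - 0.5))]
  if (depletion) {
    if (is.null(rna_conc))
      stop("depletion model requires rna_conc (nM)", call. = FALSE)
    R <- rna_conc
    fit <- minpack.lm::nlsLM(
      fb ~ ((P + R + kd) - sqrt((P + R + kd)^2 - 4 * P * R)) / (2 * R),
      data = data.frame(P = P, fb = fb, R = R),
      start = list(kd = max(kd0, 1e-3)), lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 500))
    model <- "quadratic (ligand depletion)"
  } else {
    fit <- minpack.lm::nlsLM(
      fb ~ P / (P + kd), data = data.frame(P = P, fb = fb),
      start = list(kd = max(kd0, 1e-3)), lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 500))
    model <- "hyperbolic (excess protein)"
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  structure(
    list(kd_apparent = unname(est["kd"]), se = se, model = model,
         fit = fit, data = points, rna_conc = rna_conc),
    class = "emsa_fit")
}

#' @export
print.emsa_fit <- function(x, ...) {
  cat(sprintf("EMSA isotherm fit, %s model\n", x$model))
  cat(sprintf("  kd apparent = %.4g nM (se %.2g)\n", x$kd_apparent, x$se))
  invisible(x)
}

#' @export
coef.emsa_fit <- function(object, ...) c(kd_apparent = object$kd_apparent)

#' @export
predict.emsa_fit <- function(object, conc_nM = object$data$conc_nM, ...) {
  kd <- object$kd_apparent
  if (startsWith(object$model, "quadratic")) {
    R <- object$rna_conc; P <- conc_nM
    ((P + R + kd) - sqrt((P + R + kd)^2 - 4 * P * R)) / (2 * R)
  } else {
    conc_nM / (conc_nM + kd)
  }
}

.fit_ic50 <- function(series) {
  c0 <- series$conc_nM == 0
  if (!any(c0) || series$fraction_bound[c0][1L] <= 0)
    stop("competition series needs a positive fraction bound at competitor 0",
         call. = FALSE)
  # flat series: displacement never reaches 20% of the starting signal
  f0 <- mean(series$fraction_bound[c0])
  if (min(series$fraction_bound) > 0.8 * f0) return(NA_real_)
  fit <- minpack.lm::nlsLM(
    fb ~ F0 / (1 + conc / ic50),
    data = data.frame(conc = series$conc_nM, fb = series$fraction_bound),
    start = list(F0 = f0,
                 ic50 = max(stats::median(series$conc_nM[series$conc_nM > 0]), 1e-3)),
    lower = c(0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  unname(stats::coef(fit)["ic50"])
}

#' Relative competitor displacement efficiency
#'
#' Fits each competition series to the one-site displacement curve
#' \eqn{F(c) = F_0 / (1 + c / IC_{50})} and reports the efficiency of the
#' second (e.g. mutant) competitor relative to the first as the IC50 ratio
#' \eqn{IC_{50}^{wt} / IC_{50}^{mut}}: a competitor needing a 3.3-fold
#' higher IC50 is 30\% as efficient.
#'
#' @param wt_series,mut_series data.frames with columns \code{conc_nM}
#'   (competitor) and \code{fraction_bound}, on a shared competitor grid
#'   including 0.
#' @return List with \code{efficiency} (\code{IC50_wt / IC50_mut}, NA when
#'   either series is flat), \code{ic50_wt}, \code{ic50_mut}.
#' @export
competition_efficiency <- function(wt_series, mut_series) {
  for (s in list(wt_series, mut_series))
    stopifnot(all(c("conc_nM", "fraction_bound") %in% names(s)))
  if (!setequal(wt_series$conc_nM, mut_series$conc_nM))
    stop("series must share the same competitor grid", call. = FALSE)
  ic_wt <- .fit_ic50(wt_series)
  ic_mut <- .fit_ic50(mut_series)
  if (is.na(ic_wt) || is.na(ic_mut)) {
    warning("flat competition series: no displacement detected; efficiency undefined")
    return(list(efficiency = NA_real_, ic50_wt = ic_wt, ic50_mut = ic_mut))
  }
  list(efficiency = ic_wt / ic_mut, ic50_wt = ic_wt, ic50_mut = ic_mut)
}
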