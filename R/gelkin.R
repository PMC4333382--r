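#' Fraction of duplex unwound in a gel lane
#'
#' Densitometric definition of reaction progress in a strand-separation (or
#' annealing) assay: the product band intensity divided by the sum of product
#' and substrate band intensities in the same lane.  The ratio is invariant
#' under common rescaling of both intensities, so lanes need not be
#' cross-calibrated.
#'
#' @param product_intensity Densitometry signal of the product band
#'   (single-strand for unwinding, duplex for annealing). Non-negative.
#' @param substrate_intensity Densitometry signal of the remaining substrate
#'   band. Non-negative.
#' @return Fraction in \code{[0, 1]}. Vectorised over both arguments.
#' @examples
#' fraction_unwound(30, 70)   # 0.3
#' @export
fraction_unwound <- function(product_intensity, substrate_intensity) {
  if (any(product_intensity < 0) || any(substrate_intensity < 0))
    stop("invalid densitometry: negative band intensity", call. = FALSE)
  tot <- product_intensity + substrate_intensity
  if (any(tot == 0))
    stop("empty lane: product and substrate intensities are both zero",
         call. = FALSE)
  product_intensity / tot
}

#' Build a progress curve from a lane-intensity table
#'
#' Collapses a densitometry table (one duplex and one single-strand
#' measurement per time point) into a time-ordered reaction progress curve.
#' In \code{"unwinding"} mode the single-strand band is the product; in
#' \code{"annealing"} mode the duplex band is the product.
#'
#' @param lanes data.frame with columns \code{sample_id}, \code{time_s},
#'   \code{band} (\code{"duplex"} or \code{"single_strand"}) and
#'   \code{intensity}.
#' @param mode \code{"unwinding"} or \code{"annealing"}.
#' @param substrate_conc Substrate duplex concentration in nM; carried on the
#'   curve so velocities can be expressed in nM/min.
#' @return An object of class \code{"progress_curve"}: a list with
#'   \code{times} (s, strictly increasing), \code{fraction},
#'   \code{substrate_conc} (nM) and \code{mode}.
#' @export
build_progress_curve <- function(lanes, mode = c("unwinding", "annealing"),
                                 substrate_conc = 1) {
  mode <- match.arg(mode)
  req <- c("time_s", "band", "intensity")
  if (!all(req %in% names(lanes)))
    stop("lane table must have columns time_s, band, intensity", call. = FALSE)
  if (!all(lanes$band %in% c("duplex", "single_strand")))
    stop("band must be 'duplex' or 'single_strand'", call. = FALSE)
  times <- sort(unique(lanes$time_s))
  frac <- vapply(times, function(t) {
    sub <- lanes[lanes$time_s == t, ]
    ds <- sub$intensity[sub$band == "duplex"]
    ss <- sub$intensity[sub$band == "single_strand"]
    if (length(ds) != 1L || length(ss) != 1L)
      stop(sprintf(
        "incomplete lane at t = %g s: need exactly one duplex and one single_strand measurement",
        t), call. = FALSE)
    if (mode == "unwinding") fraction_unwound(ss, ds) else fraction_unwound(ds, ss)
  }, numeric(1))
  structure(
    list(times = times, fraction = frac,
         substrate_conc = substrate_conc, mode = mode),
    class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Progress curve (%s), %d time points, substrate %g nM\n",
              x$mode, length(x$times), x$substrate_conc))
  cat(sprintf("  t = %g..%g s, fraction %.3f..%.3f\n",
              min(x$times), max(x$times), min(x$fraction), max(x$fraction)))
  invisible(x)
}

#' @export
as.data.frame.progress_curve <- function(x, ...) {
  data.frame(time_s = x$times, fraction = x$fraction)
}

#' Initial reaction velocity from the linear range of a progress curve
#'
#' Fits an ordinary least-squares line (free intercept) through the early
#' points of the curve -- those with fraction converted at or below
#' \code{max_fraction} -- and converts the slope to a velocity in nM/min
#' using the substrate concentration carried on the curve.  Restricting to
#' low conversion is standard initial-rate practice: it bounds the
#' linearisation bias of the underlying exponential progress curve.
#'
#' @param curve A \code{"progress_curve"}.
#' @param max_fraction Upper bound of the linear range (default 0.2).
#' @param min_points Minimum number of qualifying points (default 3).
#' @return Velocity in nM/min (fraction of substrate converted per minute
#'   times substrate concentration).
#' @export
initial_velocity <- function(curve, max_fraction = 0.2, min_points = 3) {
  stopifnot(inherits(curve, "progress_curve"))
  keep <- curve$fraction <= max_fraction
  if (sum(keep) < min_points)
    stop(sprintf(
      "insufficient linear range: %d point(s) with fraction <= %g, need %d",
      sum(keep), max_fraction, min_points), call. = FALSE)
  fit <- stats::lm(f ~ t, data = data.frame(t = curve$times[keep],
                                            f = curve$fraction[keep]))
  slope_per_s <- unname(stats::coef(fit)[2L])
  slope_per_s * 60 * curve$substrate_conc
}

#' Convert a velocity in nM/min to a turnover rate in 1/s
#'
#' @param v_nM_per_min Velocity in nM/min.
#' @param E0_nM Enzyme concentration in nM.
#' @return Rate in 1/s (\code{v / 60 / E0}).
#' @export
velocity_to_per_s <- function(v_nM_per_min, E0_nM) {
  stopifnot(E0_nM > 0)
  v_nM_per_min / 60 / E0_nM
}

#' @rdname velocity_to_per_s
#' @param rate_per_s Rate in 1/s.
#' @export
per_s_to_velocity <- function(rate_per_s, E0_nM) {
  stopifnot(E0_nM > 0)
  rate_per_s * 60 * E0_nM
}

#' Fit a single-exponential annealing curve
#'
#' Strand annealing is modelled as a first-order approach to a plateau,
#' \eqn{f(t) = A_{max}(1 - e^{-k_{ann} t})}, with the plateau \code{A_max}
#' constrained to \code{[0, 1]}.  The plateau (annealing extent), not the
#' rate, is the headline quantity: it distinguishes protein-facilitated
#' annealing from the spontaneous background level.
#'
#' @param curve A \code{"progress_curve"} with \code{mode = "annealing"} and
#'   at least 4 time points.
#' @return An object of class \code{"annealing_fit"} with components
#'   \code{A_max} (plateau fraction), \code{k_ann} (1/min), \code{se}
#'   (standard errors), \code{fitted} and \code{curve}.
#' @export
fit_annealing <- function(curve) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$mode != "annealing")
    stop("fit_annealing expects an annealing-mode curve", call. = FALSE)
  if (length(curve$times) < 4L)
    stop("need at least 4 time points", call. = FALSE)
  t_min <- curve$times / 60
  f <- curve$fraction
  if (all(f < 1e-10)) {
    out <- list(A_max = 0, k_ann = NA_real_,
                se = c(A_max = NA_real_, k_ann = NA_real_),
                fitted = rep(0, length(f)), curve = curve)
    class(out) <- "annealing_fit"
    return(out)
  }
  a0 <- min(max(f), 1)
  # crude rate start: time at which half the plateau is reached
  t_half <- suppressWarnings(min(t_min[f >= a0 / 2 & t_min > 0]))
  k0 <- if (is.finite(t_half)) log(2) / t_half else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * (1 - exp(-k * tm)),
                      data = data.frame(f = f, tm = t_min),
                      start = list(A = a0, k = k0),
                      lower = c(0, 0), upper = c(1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("annealing fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA_real_, k = NA_real_))
  out <- list(A_max = unname(est["A"]), k_ann = unname(est["k"]),
              se = c(A_max = unname(se["A"]), k_ann = unname(se["k"])),
              fitted = stats::fitted(fit), curve = curve)
  class(out) <- "annealing_fit"
  out
}

#' @export
print.annealing_fit <- function(x, ...) {
  cat("Single-exponential annealing fit\n")
  cat(sprintf("  A_max (plateau extent): %.4f\n", x$A_max))
  cat(sprintf("  k_ann: %s 1/min\n",
              if (is.na(x$k_ann)) "NA" else sprintf("%.4g", x$k_ann)))
  invisible(x)
}

#' @export
coef.annealing_fit <- function(object, ...) {
  c(A_max = object$A_max, k_ann = object$k_ann)
}

#' @export
predict.annealing_fit <- function(object, times_s = object$curve$times, ...) {
  if (is.na(object$k_ann)) return(rep(object$A_max, length(times_s)))
  object$A_max * (1 - exp(-object$k_ann * times_s / 60))
}

#' Subtract a matched buffer-control curve
#'
#' Optional background correction: the net curve is sample minus control at
#' matched time points, clamped back into \code{[0, 1]}.
#'
#' @param curve,control \code{"progress_curve"} objects on the same time grid.
#' @return A corrected \code{"progress_curve"}.
#' @export
subtract_control_curve <- function(curve, control) {
  stopifnot(inherits(curve, "progress_curve"),
            inherits(control, "progress_curve"))
  if (!isTRUE(all.equal(curve$times, control$times)))
    stop("curves must share the same time grid", call. = FALSE)
  curve$fraction <- pmin(pmax(curve$fraction - control$fraction, 0), 1)
  curve
}

.rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Characterise a partial RNA duplex substrate
#'
#' Given the loaded (long) strand and the complementary short strand, finds
#' the contiguous perfectly paired region, the single-stranded overhang on
#' the long strand, and the GC content of the paired region.  The short
#' strand must be the reverse complement of one end of the long strand.
#'
#' @param long_strand,short_strand RNA sequences, 5' to 3', over A/C/G/U.
#' @return An object of class \code{"substrate_duplex"}: list with
#'   \code{long_strand}, \code{short_strand}, \code{duplex_len} (bp),
#'   \code{overhang_len} (nt), \code{overhang_end} (\code{"3prime"} or
#'   \code{"5prime"}, referring to the long strand) and \code{gc_fraction}
#'   of the paired region.
#' @examples
#' define_duplex("GCGUCGAUCCGAAACUAUACUUAAUUUUAA", "GUUUCGGAUCGACGC")
#' @export
define_duplex <- function(long_strand, short_strand) {
  for (s in c(long_strand, short_strand))
    if (!grepl("^[ACGU]+$", s))
      stop("sequences must be RNA over {A,C,G,U}", call. = FALSE)
  if (nchar(short_strand) > nchar(long_strand))
    stop("short_strand longer than long_strand", call. = FALSE)
  paired <- .rna_revcomp(short_strand)   # as read on the long strand
  n <- nchar(paired)
  len <- nchar(long_strand)
  if (substr(long_strand, 1L, n) == paired) {
    overhang_end <- "3prime"             # 5' end paired, 3' tail single-stranded
  } else if (substr(long_strand, len - n + 1L, len) == paired) {
    overhang_end <- "5prime"
  } else {
    stop("no contiguous perfect pairing between the strands", call. = FALSE)
  }
  gc <- sum(strsplit(paired, "", fixed = TRUE)[[1L]] %in% c("G", "C")) / n
  structure(
    list(long_strand = long_strand, short_strand = short_strand,
         duplex_len = n, overhang_len = len - n,
         overhang_end = overhang_end, gc_fraction = gc),
    class = "substrate_duplex")
}

#' @export
print.substrate_duplex <- function(x, ...) {
  cat(sprintf("RNA duplex: %d bp paired, %d nt %s overhang, GC %.1f%%\n",
              x$duplex_len, x$overhang_len,
              sub("prime", "'", x$overhang_end), 100 * x$gc_fraction))
  invisible(x)
}
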