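#' Spherical-cap particle volume from AFM cross-sections
#'
#' Volume of a particle modelled as a spherical cap of height \code{h} with
#' elliptical half-height widths \code{a} and \code{b} (measured along
#' perpendicular cross-sections at half the maximal height):
#' \deqn{V_c = \frac{h\pi}{6}\left(\frac{3ab}{4} + h^2\right).}
#' For \code{a = b = 2h} this reduces exactly to the hemisphere volume
#' \eqn{(2/3)\pi h^3}.
#'
#' @param h Height, nm.
#' @param a,b Widths at half-maximal height along perpendicular sections, nm.
#' @return Volume in nm^3. Vectorised.
#' @examples
#' cap_volume(3, 8, 8)     # (3*pi/6) * (48 + 9)
#' @export
cap_volume <- function(h, a, b) {
  if (any(h <= 0) || any(a <= 0) || any(b <= 0))
    stop("invalid dimension: h, a, b must all be positive", call. = FALSE)
  (h * pi / 6) * (3 * a * b / 4 + h^2)
}

#' Reference volumes (and optional masses) for the two protein species
#'
#' @param v_ewsfli1,v_rha Reference molecular volumes, nm^3.
#' @param mass_ewsfli1,mass_rha Optional reference masses, kDa (the
#'   volume-to-mass conversion requires at least one).
#' @return Object of class \code{"species_calibration"}.
#' @export
species_calibration <- function(v_ewsfli1 = 104, v_rha = 267,
                                mass_ewsfli1 = NULL, mass_rha = NULL) {
  if (v_ewsfli1 <= 0 || v_rha <= 0)
    stop("reference volumes must be positive", call. = FALSE)
  structure(
    list(volumes = c(ewsfli1 = v_ewsfli1, rha = v_rha),
         masses = c(ewsfli1 = if (is.null(mass_ewsfli1)) NA_real_ else mass_ewsfli1,
                    rha = if (is.null(mass_rha)) NA_real_ else mass_rha)),
    class = "species_calibration")
}

#' @export
print.species_calibration <- function(x, ...) {
  cat(sprintf("Species calibration: EWS-FLI1 %g nm^3, RHA %g nm^3\n",
              x$volumes["ewsfli1"], x$volumes["rha"]))
  if (any(!is.na(x$masses)))
    cat(sprintf("  masses (kDa): EWS-FLI1 %s, RHA %s\n",
                x$masses["ewsfli1"], x$masses["rha"]))
  invisible(x)
}

#' Convert particle volume to mass
#'
#' Linear-through-origin conversion using the mean mass/volume ratio of the
#' calibration references that carry masses.  When two references are
#' supplied and their implied ratios disagree, the mean ratio is used and
#' the relative spread is reported.
#'
#' @param volume Particle volume, nm^3.
#' @param calibration A \code{"species_calibration"} with at least one
#'   reference mass.
#' @return List with \code{mass_kDa}, \code{ratio_kDa_per_nm3} and
#'   \code{ratio_rel_spread} (NA with a single reference).
#' @export
mass_from_volume <- function(volume, calibration) {
  stopifnot(inherits(calibration, "species_calibration"))
  ok <- !is.na(calibration$masses)
  if (!any(ok))
    stop("calibration missing: no reference masses supplied", call. = FALSE)
  ratios <- calibration$masses[ok] / calibration$volumes[ok]
  ratio <- mean(ratios)
  spread <- if (length(ratios) > 1L) diff(range(ratios)) / ratio else NA_real_
  list(mass_kDa = volume * ratio, ratio_kDa_per_nm3 = ratio,
       ratio_rel_spread = spread)
}

.composition_grid <- function(max_i, max_j) {
  g <- expand.grid(i = 0:max_i, j = 0:max_j)
  g[g$i + g$j > 0, , drop = FALSE]
}

#' Assign a particle volume to a protein-complex stoichiometry
#'
#' Searches compositions \eqn{(i, j)} of \eqn{i} EWS-FLI1 plus \eqn{j} RHA
#' subunits and picks the one minimising the relative volume mismatch
#' \eqn{|V - (i V_{EF} + j V_{RHA})| / (i V_{EF} + j V_{RHA})}.  Ties go to
#' the composition with fewer total subunits.  A particle whose best
#' residual exceeds \code{tolerance} is left unassigned (a valid outcome,
#' not an error).
#'
#' @param volume Measured particle volume, nm^3.
#' @param calibration A \code{"species_calibration"}.
#' @param max_i,max_j Largest subunit counts searched (defaults 3 and 2).
#' @param tolerance Maximum relative residual for an assignment, in
#'   (0, 0.5] (default 0.25).
#' @param compositions Optional data.frame with columns \code{i}, \code{j}
#'   restricting the candidate compositions.  Use this when the imaged
#'   sample contains a single protein species: a deposition of pure
#'   EWS-FLI1 is classified against its own oligomers
#'   (\code{data.frame(i = 1:3, j = 0)}), since candidate volumes of the
#'   absent species would capture scatter from neighbouring oligomer
#'   classes.
#' @return Object of class \code{"particle_call"}: \code{volume}, \code{i}
#'   (EWS-FLI1 count), \code{j} (RHA count), \code{residual},
#'   \code{assigned}.
#' @export
classify_particle <- function(volume, calibration = species_calibration(),
                              max_i = 3, max_j = 2, tolerance = 0.25,
                              compositions = NULL) {
  stopifnot(inherits(calibration, "species_calibration"),
            tolerance > 0, tolerance <= 0.5, max_i >= 1, max_j >= 1)
  g <- if (is.null(compositions)) .composition_grid(max_i, max_j)
  else {
    stopifnot(all(c("i", "j") %in% names(compositions)),
              all(compositions$i >= 0), all(compositions$j >= 0),
              all(compositions$i + compositions$j > 0))
    data.frame(i = as.integer(compositions$i),
               j = as.integer(compositions$j))
  }
  vref <- g$i * calibration$volumes[["ewsfli1"]] +
    g$j * calibration$volumes[["rha"]]
  res <- abs(volume - vref) / vref
  # residuals equal up to rounding count as tied; ties go to fewer subunits
  near <- which(res <= min(res) + 1e-9)
  best <- near[order(g$i[near] + g$j[near], res[near])][1L]
  assigned <- res[best] <= tolerance
  structure(
    list(volume = volume,
         i = if (assigned) g$i[best] else NA_integer_,
         j = if (assigned) g$j[best] else NA_integer_,
         residual = res[best], assigned = assigned),
    class = "particle_call")
}

#' @export
print.particle_call <- function(x, ...) {
  if (x$assigned) {
    cat(sprintf("Particle %.1f nm^3 -> (EWS-FLI1)%d(RHA)%d, residual %.3f\n",
                x$volume, x$i, x$j, x$residual))
  } else {
    cat(sprintf("Particle %.1f nm^3 -> unassigned (best residual %.3f)\n",
                x$volume, x$residual))
  }
  invisible(x)
}

#' Stoichiometry distribution of an AFM particle population
#'
#' Computes each particle's cap volume from its measured dimensions,
#' assigns a composition with \code{\link{classify_particle}}, and reports
#' per-composition counts and fractions over the assigned particles, with
#' Clopper-Pearson binomial confidence intervals.
#'
#' @param particles data.frame with columns \code{particle_id}, \code{h_nm},
#'   \code{a_nm}, \code{b_nm} (an \code{on_rna} column is carried through if
#'   present).
#' @param calibration A \code{"species_calibration"}.
#' @param max_i,max_j,tolerance,compositions Passed to
#'   \code{\link{classify_particle}}.
#' @param conf_level Confidence level for the binomial intervals.
#' @return Object of class \code{"stoichiometry_distribution"}: a table
#'   with columns \code{i_ewsfli1}, \code{j_rha}, \code{count},
#'   \code{fraction}, \code{ci_lo}, \code{ci_hi}; plus \code{n_assigned},
#'   \code{n_unassigned} and the per-particle \code{calls} data.frame.
#' @export
stoichiometry_distribution <- function(particles,
                                       calibration = species_calibration(),
                                       max_i = 3, max_j = 2,
                                       tolerance = 0.25,
                                       compositions = NULL,
                                       conf_level = 0.95) {
  stopifnot(all(c("h_nm", "a_nm", "b_nm") %in% names(particles)),
            nrow(particles) >= 1L)
  vols <- cap_volume(particles$h_nm, particles$a_nm, particles$b_nm)
  calls <- lapply(vols, classify_particle, calibration = calibration,
                  max_i = max_i, max_j = max_j, tolerance = tolerance,
                  compositions = compositions)
  calls_df <- data.frame(
    particle_id = if ("particle_id" %in% names(particles))
      particles$particle_id else seq_along(vols),
    volume_nm3 = vols,
    i_ewsfli1 = vapply(calls, `[[`, 1L, "i"),
    j_rha = vapply(calls, `[[`, 1L, "j"),
    residual = vapply(calls, `[[`, 1, "residual"),
    assigned = vapply(calls, `[[`, TRUE, "assigned"))
  ok <- calls_df[calls_df$assigned, ]
  if (nrow(ok) == 0L)
    stop("empty distribution: every particle exceeded the assignment tolerance",
         call. = FALSE)
  key <- paste(ok$i_ewsfli1, ok$j_rha, sep = ":")
  tab <- table(key)
  n <- nrow(ok)
  comps <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  dist <- data.frame(
    i_ewsfli1 = as.integer(comps[, 1L]),
    j_rha = as.integer(comps[, 2L]),
    count = as.integer(tab),
    fraction = as.integer(tab) / n)
  ci <- t(vapply(dist$count, function(k)
    stats::binom.test(k, n, conf.level = conf_level)$conf.int,
    numeric(2)))
  dist$ci_lo <- ci[, 1L]; dist$ci_hi <- ci[, 2L]
  dist <- dist[order(-dist$fraction), ]
  rownames(dist) <- NULL
  structure(
    list(distribution = dist, n_assigned = n,
         n_unassigned = sum(!calls_df$assigned), calls = calls_df,
         conf_level = conf_level),
    class = "stoichiometry_distribution")
}

#' @export
print.stoichiometry_distribution <- function(x, ...) {
  cat(sprintf("AFM stoichiometry distribution: %d assigned, %d unassigned\n",
              x$n_assigned, x$n_unassigned))
  d <- x$distribution
  for (r in seq_len(nrow(d)))
    cat(sprintf("  (EWS-FLI1)%d(RHA)%d: %d (%.1f%%, %d%% CI %.1f-%.1f%%)\n",
                d$i_ewsfli1[r], d$j_rha[r], d$count[r], 100 * d$fraction[r],
                round(100 * x$conf_level), 100 * d$ci_lo[r], 100 * d$ci_hi[r]))
  invisible(x)
}

#' @export
as.data.frame.stoichiometry_distribution <- function(x, ...) x$distribution
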