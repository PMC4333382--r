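#' Seeded generator specification
#'
#' Bundles the random seed and the noise model used by every synthetic-data
#' generator.  An identical spec produces bit-identical output; the caller's
#' random-number state is saved and restored around each generator call.
#'
#' Noise models: \code{"gaussian_abs"} adds Gaussian noise with absolute
#' standard deviation \code{noise_scale} (in the output's own units);
#' \code{"gaussian_prop"} adds Gaussian noise with standard deviation
#' \code{noise_scale} times the signal; \code{"negative_binomial"} draws
#' counts with mean equal to the signal and dispersion (size)
#' \code{nb_size}.
#'
#' @param seed Integer seed.
#' @param noise_model One of \code{"gaussian_abs"}, \code{"gaussian_prop"},
#'   \code{"negative_binomial"}.
#' @param noise_scale Non-negative noise scale (0 = noiseless).
#' @param nb_size Negative-binomial dispersion parameter.
#' @return Object of class \code{"generator_spec"}.
#' @export
generator_spec <- function(seed = 1L,
                           noise_model = c("gaussian_prop", "gaussian_abs",
                                           "negative_binomial"),
                           noise_scale = 0, nb_size = 10) {
  noise_model <- match.arg(noise_model)
  stopifnot(noise_scale >= 0, nb_size > 0)
  structure(list(seed = as.integer(seed), noise_model = noise_model,
                 noise_scale = noise_scale, nb_size = nb_size),
            class = "generator_spec")
}

# run expr with the spec's seed, restoring the caller's RNG state
.with_seed <- function(spec, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  expr
}

.add_noise <- function(x, spec) {
  if (spec$noise_scale == 0) return(x)
  switch(spec$noise_model,
         gaussian_abs = x + stats::rnorm(length(x), 0, spec$noise_scale),
         gaussian_prop = x * (1 + stats::rnorm(length(x), 0, spec$noise_scale)),
         negative_binomial = stop("negative_binomial noise applies to count generators",
                                  call. = FALSE))
  }

#' Generate a lane-intensity table for an unwinding progress curve
#'
#' Emulates densitometry of a single-exponential unwinding reaction,
#' \eqn{f(t) = 1 - e^{-rate \cdot t}}: each lane carries a duplex and a
#' single-strand band whose intensities sum to \code{total_intensity}
#' before noise.
#'
#' @param true_rate Unwinding rate constant, 1/s.
#' @param substrate_conc Substrate duplex concentration, nM.
#' @param times Sampling times, s.
#' @param spec A \code{\link{generator_spec}}.
#' @param total_intensity Per-lane total band intensity before noise.
#' @param sample_id Sample identifier written into the table.
#' @return data.frame with columns \code{sample_id}, \code{time_s},
#'   \code{band}, \code{intensity}, and attribute \code{truth} (the
#'   generating parameters).
#' @export
gen_progress_curves <- function(true_rate, substrate_conc = 1,
                                times = seq(0, 600, by = 30),
                                spec = generator_spec(),
                                total_intensity = 100,
                                sample_id = "synthetic") {
  stopifnot(true_rate > 0, length(times) > 0)
  .with_seed(spec, {
    f <- 1 - exp(-true_rate * times)
    ds <- .add_noise(total_intensity * (1 - f), spec)
    ss <- .add_noise(total_intensity * f, spec)
    out <- data.frame(
      sample_id = sample_id,
      time_s = rep(times, 2L),
      band = rep(c("duplex", "single_strand"), each = length(times)),
      intensity = pmax(c(ds, ss), 0))
    attr(out, "truth") <- list(rate = true_rate,
                               substrate_conc = substrate_conc,
                               initial_velocity_nM_per_min =
                                 true_rate * 60 * substrate_conc)
    out
  })
}

#' Generate Michaelis-Menten velocity points
#'
#' @param KM Michaelis constant, nM.
#' @param Vmax Maximal velocity, nM/min.  The default corresponds to a
#'   turnover number of 0.69 1/s at 1 nM enzyme.
#' @param S_grid Substrate grid, nM (default two-fold series 0.125-32 nM).
#' @param replicates Replicates per concentration.
#' @param spec A \code{\link{generator_spec}}.
#' @return data.frame with columns \code{S_nM}, \code{v0_nM_per_min},
#'   \code{replicate}; attribute \code{truth}.
#' @export
gen_mm_velocities <- function(KM = 44, Vmax = 0.69 * 60,
                              S_grid = 0.125 * 2^(0:8), replicates = 1,
                              spec = generator_spec()) {
  stopifnot(KM > 0, Vmax > 0, all(S_grid > 0), replicates >= 1)
  .with_seed(spec, {
    S <- rep(S_grid, each = replicates)
    v <- pmax(.add_noise(mm_velocity(S, KM, Vmax), spec), 0)
    out <- data.frame(S_nM = S, v0_nM_per_min = v,
                      replicate = rep(seq_len(replicates), length(S_grid)))
    attr(out, "truth") <- list(KM = KM, Vmax = Vmax)
    out
  })
}

# defaults for the inhibition generator: exact solve of the two-dose
# 58%/78% reduction system
.default_inhibition_params <- function() {
  fit <- fit_partial_inhibition(
    data.frame(I_nM = c(1, 10), fractional_velocity = c(0.42, 0.22)))
  c(Ki_app = fit$Ki_app, beta = fit$beta)
}

#' Generate a partial-inhibition dose series
#'
#' Fractional velocities from
#' \eqn{v/v_0 = (K_i^{app} + \beta I)/(K_i^{app} + I)} over an inhibitor
#' grid, with the \eqn{I = 0} anchor included.  Defaults reproduce the
#' two-dose reduction pattern (58\% at 1 nM, 78\% at 10 nM).
#'
#' @param Ki_app Apparent inhibition constant, nM.
#' @param beta Residual fractional activity at saturating inhibitor.
#' @param I_grid Inhibitor doses, nM.
#' @param spec A \code{\link{generator_spec}}.
#' @return data.frame with columns \code{I_nM}, \code{fractional_velocity};
#'   attribute \code{truth}.
#' @export
gen_inhibition_series <- function(Ki_app = NULL, beta = NULL,
                                  I_grid = c(0.5, 1, 2, 5, 10),
                                  spec = generator_spec()) {
  if (is.null(Ki_app) || is.null(beta)) {
    p <- .default_inhibition_params()
    if (is.null(Ki_app)) Ki_app <- unname(p["Ki_app"])
    if (is.null(beta)) beta <- unname(p["beta"])
  }
  stopifnot(Ki_app > 0, beta >= 0, beta < 1, all(I_grid > 0))
  .with_seed(spec, {
    fv <- .add_noise(partial_inhibition_velocity(I_grid, Ki_app, beta), spec)
    out <- data.frame(I_nM = c(0, I_grid),
                      fractional_velocity = c(1, pmin(pmax(fv, 1e-6), 1)))
    attr(out, "truth") <- list(Ki_app = Ki_app, beta = beta)
    out
  })
}

#' Generate a concentration series of 1:1 Langmuir sensorgrams
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd_rate Dissociation rate constant, 1/s.
#' @param Rmax Surface capacity, RU.
#' @param C_list Analyte concentrations, molar (default the two-fold
#'   series 24 down to 0.375 nM).
#' @param t_assoc,t_diss,dt Injection timing, s.
#' @param spec A \code{\link{generator_spec}}; for \code{"gaussian_abs"}
#'   the noise scale is in RU.
#' @return List of \code{"sensorgram"} objects; attribute \code{truth}.
#' @export
gen_sensorgrams <- function(ka = 3.5e6, kd_rate = 0.030, Rmax = 1800,
                            C_list = c(24, 12, 6, 3, 1.5, 0.75, 0.375) * 1e-9,
                            t_assoc = 60, t_diss = 600, dt = 1,
                            spec = generator_spec()) {
  .with_seed(spec, {
    out <- lapply(C_list, function(C) {
      sg <- simulate_sensorgram(ka, kd_rate, Rmax, C, t_assoc, t_diss, dt)
      sg$response <- .add_noise(sg$response, spec)
      sg
    })
    attr(out, "truth") <- list(ka = ka, kd_rate = kd_rate, Rmax = Rmax)
    out
  })
}

#' Generate an EMSA fraction-bound titration
#'
#' @param kd Apparent dissociation constant, nM.
#' @param P_grid Protein concentrations, nM (default two-fold 0.5-64 nM).
#' @param spec A \code{\link{generator_spec}}; for \code{"gaussian_abs"}
#'   the noise scale is in fraction-bound units.
#' @return data.frame with columns \code{conc_nM}, \code{fraction_bound};
#'   attribute \code{truth}.
#' @export
gen_emsa <- function(kd = 30, P_grid = 0.5 * 2^(0:7),
                     spec = generator_spec()) {
  stopifnot(kd > 0, all(P_grid > 0))
  .with_seed(spec, {
    fb <- .add_noise(P_grid / (P_grid + kd), spec)
    out <- data.frame(conc_nM = P_grid,
                      fraction_bound = pmin(pmax(fb, 0), 1))
    attr(out, "truth") <- list(kd = kd)
    out
  })
}

#' Generate an AFM particle population with planted stoichiometries
#'
#' Samples a composition for each particle from \code{mix}, draws its true
#' volume \eqn{i V_{EF} + j V_{RHA}} with lognormal scatter of the given
#' coefficient of variation, and inverts the cap-volume formula under the
#' hemispherical aspect model \eqn{a = b = 2h} to emit measurable
#' dimensions.
#'
#' @param mix Named numeric vector of composition fractions; names are
#'   \code{"i:j"} (EWS-FLI1 count : RHA count), values sum to 1.  Default
#'   is the RNA-bound EWS-FLI1 population: 44\% monomer, 39\% dimer, 17\%
#'   trimer.
#' @param volume_cv Coefficient of variation of the lognormal volume
#'   scatter.
#' @param n Number of particles.
#' @param calibration A \code{\link{species_calibration}}.
#' @param spec A \code{\link{generator_spec}} (only the seed is used; the
#'   scatter model is the lognormal CV).
#' @return data.frame with columns \code{particle_id}, \code{h_nm},
#'   \code{a_nm}, \code{b_nm}, \code{on_rna}; attribute \code{truth} holds
#'   the planted mix and per-particle compositions.
#' @export
gen_afm_population <- function(mix = c("1:0" = 0.44, "2:0" = 0.39,
                                       "3:0" = 0.17),
                               volume_cv = 0.10, n = 500,
                               calibration = species_calibration(),
                               spec = generator_spec()) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, volume_cv >= 0, n >= 1)
  comps <- do.call(rbind, strsplit(names(mix), ":", fixed = TRUE))
  ij <- cbind(as.integer(comps[, 1L]), as.integer(comps[, 2L]))
  .with_seed(spec, {
    idx <- sample.int(length(mix), n, replace = TRUE, prob = mix)
    v_true <- ij[idx, 1L] * calibration$volumes[["ewsfli1"]] +
      ij[idx, 2L] * calibration$volumes[["rha"]]
    if (volume_cv > 0) {
      sdlog <- sqrt(log(1 + volume_cv^2))
      v <- v_true * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    } else v <- v_true
    h <- (3 * v / (2 * pi))^(1 / 3)        # a = b = 2h inverts cap_volume
    out <- data.frame(particle_id = sprintf("p%04d", seq_len(n)),
                      h_nm = h, a_nm = 2 * h, b_nm = 2 * h, on_rna = TRUE)
    attr(out, "truth") <- list(mix = mix, composition = names(mix)[idx],
                               volume = v_true)
    out
  })
}

#' Generate a planted RIP-seq library set
#'
#' Builds eight libraries (control/treated x RHA/EWS-FLI1 x
#' unblocked/blocked) over a transcript universe.  Planted RIP transcripts
#' receive high counts, background transcripts low counts; blocked
#' libraries receive background everywhere plus a configurable nonspecific
#' subset (which the blocked-antibody subtraction removes).  The treated
#' libraries realise a planted four-way partition of the control-common
#' transcripts.  FPKM values are computed from negative-binomial (or
#' noiseless expected) counts through \code{\link{fpkm}} with 1-kb
#' transcripts and a fixed library total.
#'
#' @param n_transcripts Universe size.
#' @param n_common Control-common planted transcripts.
#' @param n_rha_only,n_ef_only Planted transcripts unique to each control
#'   IP.
#' @param partition Named counts (\code{retained}, \code{ef_only},
#'   \code{rha_only}, \code{lost}) summing to \code{n_common}; defaults to
#'   the 46/23/18/13\% split of \code{n_common} with the remainder going to
#'   \code{retained}.
#' @param n_nonspecific Transcripts planted in both the unblocked and
#'   blocked libraries of each antibody.
#' @param planted_fpkm,background_fpkm Expected FPKM of planted and
#'   background transcripts.
#' @param library_total Total mapped fragments per library.
#' @param transcript_length Transcript length, bp.
#' @param spec A \code{\link{generator_spec}}; noise model
#'   \code{"negative_binomial"} with \code{noise_scale > 0} draws counts
#'   from a negative binomial with the expected mean and size
#'   \code{spec$nb_size}, otherwise counts are the noiseless expectations.
#' @return Named list of eight \code{"rip_library"} objects; attribute
#'   \code{truth} holds the planted sets and partition.
#' @export
gen_rip_tables <- function(n_transcripts = 20000, n_common = 1345,
                           n_rha_only = 600, n_ef_only = 450,
                           partition = NULL, n_nonspecific = 150,
                           planted_fpkm = 50, background_fpkm = 0.1,
                           library_total = 1e7, transcript_length = 1000,
                           spec = generator_spec()) {
  if (is.null(partition)) {
    p <- c(ef_only = 0.23, rha_only = 0.18, lost = 0.13)
    partition <- round(p * n_common)
    partition <- c(retained = n_common - sum(partition), partition)
  }
  partition <- partition[c("retained", "ef_only", "rha_only", "lost")]
  stopifnot(sum(partition) == n_common,
            n_common + n_rha_only + n_ef_only + n_nonspecific <= n_transcripts)
  ids <- sprintf("TX%06d", seq_len(n_transcripts))
  common <- ids[seq_len(n_common)]
  rha_only <- ids[n_common + seq_len(n_rha_only)]
  ef_only <- ids[n_common + n_rha_only + seq_len(n_ef_only)]
  nonspec <- ids[n_common + n_rha_only + n_ef_only + seq_len(n_nonspecific)]
  splits <- split(common, rep(names(partition), partition))
  # expected count giving the target FPKM
  mu_of <- function(f) f * transcript_length * library_total / 1e9
  .with_seed(spec, {
    draw <- function(planted) {
      mu <- rep(mu_of(background_fpkm), n_transcripts)
      mu[ids %in% planted] <- mu_of(planted_fpkm)
      counts <- if (spec$noise_model == "negative_binomial" &&
                    spec$noise_scale > 0)
        stats::rnbinom(n_transcripts, mu = mu, size = spec$nb_size)
      else mu
      stats::setNames(fpkm(counts, transcript_length, library_total), ids)
    }
    libs <- list(
      control_rha = rip_library("ctl_RHA", "DMSO", "RHA",
                                draw(c(common, rha_only, nonspec))),
      control_fli1 = rip_library("ctl_FLI1", "DMSO", "FLI1",
                                 draw(c(common, ef_only, nonspec))),
      control_rha_block = rip_library("ctl_RHAb", "DMSO", "RHA_block",
                                      draw(nonspec)),
      control_fli1_block = rip_library("ctl_FLI1b", "DMSO", "FLI1_block",
                                       draw(nonspec)),
      treated_rha = rip_library(
        "yk_RHA", "YK4279", "RHA",
        draw(c(splits$retained, splits$rha_only, rha_only, nonspec))),
      treated_fli1 = rip_library(
        "yk_FLI1", "YK4279", "FLI1",
        draw(c(splits$retained, splits$ef_only, ef_only, nonspec))),
      treated_rha_block = rip_library("yk_RHAb", "YK4279", "RHA_block",
                                      draw(nonspec)),
      treated_fli1_block = rip_library("yk_FLI1b", "YK4279", "FLI1_block",
                                       draw(nonspec)))
    attr(libs, "truth") <- list(
      universe = ids, common = common, rha_only = rha_only,
      ef_only = ef_only, nonspecific = nonspec,
      partition_counts = vapply(splits[c("retained", "ef_only",
                                         "rha_only", "lost")], length, 1L),
      partition_members = splits)
    libs
  })
}
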