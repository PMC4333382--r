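---
title: "Models and methods behind helibind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helibind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helibind)
```

helibind implements the quantitative layer of a helicase–transcription
factor interaction study: gel-based unwinding and annealing kinetics,
steady-state enzyme kinetics and partial inhibition, surface plasmon
resonance (SPR) and electrophoretic mobility shift (EMSA) binding, atomic
force microscopy (AFM) volumetric stoichiometry, and RIP-seq set
statistics.  This vignette records the models, the assumptions they carry,
and the numerical and design choices made where the analysis was genuinely
open.

## Gel kinetics

Reaction progress in one gel lane is the product band over the lane total,
`f = P/(P + S)`.  This ratio is invariant under common rescaling of both
bands, so lanes need no cross-calibration; densitometry saturation is not
modelled and intensities are taken at face value.  Blank (no-enzyme)
correction is available as an explicit, optional step
(`subtract_control_curve`), with the net curve clamped back into [0, 1];
whether to apply it is left to the analyst because raw and blank-corrected
ratios are both defensible readings of a lane table.

**Initial velocity.** The early linear range is defined as the points with
fraction converted ≤ 0.2 (`max_fraction`), requiring at least 3 such points
(`min_points`) — standard initial-rate practice.  The slope of an ordinary
least-squares line (free intercept) is converted to nM/min via the
substrate concentration.  Because a first-order progress curve is convex,
the least-squares slope over a window [0, T] underestimates the t→0
derivative by roughly a factor e^(−kT/2); at the default window the bias is
bounded by about 5% when curves are sampled densely within the linear
range, which the recovery tests verify.  Velocities are normalised to
nM/min internally; `velocity_to_per_s`/`per_s_to_velocity` convert to
turnover units.

**Annealing.** Strand annealing is fit as a single-exponential approach to
a plateau, `f(t) = A_max(1 − e^(−k_ann t))`, with `A_max` bounded in
[0, 1].  The plateau — the annealing extent — is the headline quantity; the
simplest monotone model suffices because only extents are compared between
facilitated and spontaneous reactions.  An all-zero curve short-circuits to
`A_max = 0` with an undefined rate rather than forcing a degenerate fit.

**Substrate geometry.** `define_duplex` locates the contiguous perfectly
paired region between the loaded strand and the short strand by a reverse
complement string match against either end, and reports duplex length,
overhang length and side, and the GC fraction of the paired region.  The
shipped example is the 30-nt/15-nt substrate used throughout the assay
design (15 bp duplex, 15 nt 3′ overhang, GC 60%).  Melting-temperature
prediction is out of scope.

## Enzyme kinetics and inhibition

`fit_michaelis_menten` fits `v = V_max S/(K_M + S)` by bounded nonlinear
least squares (Levenberg–Marquardt via minpack.lm), unweighted by default
with an optional 1/v² weighting flag.  The design must contain at least 4
distinct substrate concentrations spanning an order of magnitude; anything
less is rejected as unidentifiable rather than fit badly.  With the enzyme
concentration supplied, `k_cat = V_max/(60 E_0)` (1/s) and the efficiency
`k_cat/K_M` (1/(M s)) are derived.  The Lineweaver–Burk double-reciprocal
transform is provided because the field still displays it, but it is
labelled diagnostic-only: reciprocal transformation inflates low-velocity
noise, and under heteroscedastic noise its implied parameters deviate from
the direct fit (the tests assert the deviation, not agreement).

**Partial inhibition.** The dose response of the helicase velocity under
increasing inhibitor saturates well below complete inhibition, so a
hyperbolic partial-inhibition form with residual activity is used:

v/v₀ = (K_i^app + βI)/(K_i^app + I),

where β ∈ [0, 1) is the fractional activity remaining at saturating
inhibitor.  The model is linear in (K_i^app, β) after clearing the
denominator, so with exactly two informative doses it is solved exactly as
a 2×2 linear system; with more doses it is fit by bounded nonlinear least
squares.  A flat dose response (v/v₀ ≡ 1) is flagged unidentifiable with
β = 1 rather than fit; a negative β estimate is clamped to 0 with a
warning.  The fitted curve is monotone non-increasing in dose and bounded
below by β, which the tests assert on the fitted function.

**Temperature dependence.** A straight line with r²; a constant-velocity
input returns slope 0 and r² = 0 by convention (the usual formula is 0/0).

## SPR: 1:1 Langmuir model

The pseudo-first-order closed forms are exact for 1:1 binding at constant
analyte concentration C, so no numerical integration is used:
association `R(t) = R_eq (1 − e^(−(k_a C + k_d)t))` with
`R_eq = R_max k_a C/(k_a C + k_d)`, dissociation
`R(t) = R(t_assoc) e^(−k_d (t − t_assoc))`.  The default injection design
mirrors the experimental series: seven analyte concentrations from 24 nM in
two-fold steps to 0.375 nM, 60 s contact, 600 s dissociation, ~1800 RU
surface.  `fit_langmuir_global` fits one (k_a, k_d, R_max) triple to all
traces simultaneously on the stacked residuals, optimising log-parameters
to enforce positivity; standard errors come from the Gauss–Newton
covariance with a delta-method back-transform.  Starting values are taken
from the data (R_max from the largest response, k_d from a log-linear fit
to the dissociation tail of the highest-concentration trace).  `K_D` is
reported as `k_d/k_a` exactly.  Mass-transport limitation, drift, bulk
refractive-index jumps and regeneration are not modelled.

## EMSA isotherms and competition

Under excess protein the bound fraction follows `f = P/(P + k_d^app)`.
Because the probe load in a real gel shift may violate the excess-protein
assumption, a ligand-depletion option solves the exact 1:1 quadratic given
the probe concentration.  Titrations that do not bracket the transition
(no point below 0.3 and above 0.6 bound) trigger a warning; all-unbound or
all-bound titrations are rejected as unidentifiable.  Competition is
summarised by fitting each series to `F(c) = F_0/(1 + c/IC50)` and
reporting the IC50 ratio of the two competitors — a competitor needing a
3.3-fold higher IC50 is 30% as efficient.  A series whose displacement
never reaches 20% of the starting signal is treated as flat: the ratio is
undefined and a warning is raised instead of extrapolating an IC50 far
outside the tested grid.

## AFM volumetric stoichiometry

Particle volumes come from the spherical-cap formula
`V_c = (hπ/6)(3ab/4 + h²)`, with h the background-corrected height and a, b
the perpendicular widths at half-maximal height.  At a = b = 2h this is
exactly the hemisphere volume (2/3)πh³ — the identity the tests use as a
closed-form oracle.  Reference volumes default to 104 nm³ (EWS-FLI1) and
267 nm³ (RHA); they are defaults, not constants, and reference masses are
user-supplied because the two implied mass/volume ratios of the reference
proteins disagree, so no single conversion constant is assumed.

Classification minimises the relative mismatch
`|V − (i·V_EF + j·V_RHA)|/(i·V_EF + j·V_RHA)` over candidate compositions,
by default i ≤ 3, j ≤ 2 (the largest complexes under discussion are dimers
and small heterocomplexes).  The default assignment tolerance is 25%
relative; a particle beyond it is left unassigned, a valid outcome rather
than an error.  Ties within numerical rounding go to the composition with
fewer subunits.  Classification is scale-consistent: scaling the volume and
both references together leaves the call unchanged.

When the deposited sample contains a single protein species — as in the
RNA-bound EWS-FLI1 and RNA-bound RHA imaging experiments, which image one
protein at a time — the candidate set should be that species' oligomers
(`compositions = data.frame(i = 1:3, j = 0)` and `data.frame(i = 0,
j = 1:2)` respectively).  With the full mixed grid, 10% volume scatter
around the 208 nm³ EWS-FLI1 dimer and 312 nm³ trimer leaks into the nearby
267 nm³ RHA-monomer candidate, a species known to be absent from the
deposition; restricting the candidates is the correct analysis of those
experiments, not a tuning knob, and the mixture-recovery tests use it.

Class fractions are reported over assigned particles with Clopper–Pearson
binomial intervals.

## RIP-seq set statistics

FPKM is computed by the standard formula
`count·10⁹/(length_bp · library_total)`.  Calling uses a strict threshold:
RIP means FPKM > 0.5.  The stated rule ("greater than 0.5" is RIP, "fewer
than 0.5" is non-RIP) leaves the boundary value ambiguous; the strict
inequality was chosen so the boundary case is conservative (non-RIP).
Blocked-antibody libraries act as the nonspecific filter: the blocked
call set is subtracted from the unblocked call set.  IgG libraries are
accepted in input but unused by default.  Note that while `call_rip` is
monotone in the threshold, the subtracted set is not (raising the threshold
can also shrink the blocked set), so only the subset relation
`subtract_blocked ⊆ call_rip(target)` is guaranteed.

Overlap significance is the hypergeometric upper tail
P(X ≥ k) for X ~ Hypergeometric(N, K, n), summed in log space from
log-gamma binomial coefficients with a log-sum-exp reduction.  This keeps
`log10 p` finite and accurate at survey scale (p of order 10⁻³⁰⁰ and
below), where the linear-scale probability underflows to zero.  The
universe N defaults to all transcripts in the merged quantification table
and is configurable, since a RIP experiment itself does not define its
universe.

The four-way treatment partition classifies every control-common transcript
by its presence in the two treated call sets; percentages are rounded
half-away-from-zero to integers, the rule that maps the class counts
(615, 306, 243, 181) of a 1345-transcript common set onto 46/23/18/13.
Rounded percents may sum to 100 ± 2.

## Synthetic-data generators

Each generator mirrors the experimental design of its consumer stage:
progress-curve lanes with constant per-lane total intensity and
single-exponential conversion; Michaelis–Menten velocities on the two-fold
0.125–32 nM substrate grid (defaults K_M = 44 nM, V_max set so
k_cat = 0.69 1/s at 1 nM enzyme); inhibition series whose default
(K_i^app, β) are computed at call time from the two-dose 58%/78% reduction
pattern; sensorgrams at the seven-concentration analyte series; EMSA
titrations over 0.5–64 nM in two-fold steps; AFM populations drawn from a
planted composition mix with lognormal volume scatter, inverted to (h, a, b)
under the hemispherical aspect model a = b = 2h (consistent with the
hemisphere identity of the volume formula); and RIP library sets with
planted call sets, planted four-way partition, and a nonspecific subset
that the blocked-antibody subtraction must remove.

Noise conventions: `gaussian_prop` scales with the signal (used at 5% for
velocity data), `gaussian_abs` is additive in the output's units (0.5% of
R_max, i.e. 9 RU, for sensorgrams; 0.03 fraction-bound for EMSA), and
`negative_binomial` draws counts with the target mean and dispersion
`nb_size`, converted to FPKM through the package's own `fpkm()` with 1-kb
transcripts and 10⁷ mapped fragments per library.  Generators seed a local
RNG state and restore the caller's stream, so identical `generator_spec`s
are bit-reproducible and generators never perturb surrounding code.

What the generators do **not** emulate: gel-band spillover and saturation,
baseline drift and refractive-index jumps in sensorgrams, tip-convolution
bias in AFM dimensions, positional (gene-length or GC) biases in RIP
counts, and replicate library structure.  Passing recovery tests therefore
demonstrate that the estimators invert their own generative assumptions at
realistic noise levels — not that those assumptions hold for any particular
instrument.

## Problem sizes and tolerances

The recovery studies use the sizes a bench comparison would: 500 simulated
titrations (3 replicates, 5% noise) for the K_M error distribution, 20
noisy seven-trace SPR series, 200 EMSA titrations per affinity, 50 AFM
populations of 500 particles, and a 20 000-transcript RIP universe with a
1345-transcript planted common set.  Exhaustive hypergeometric validation
runs over all (K, n, k) for several universes up to N = 25 plus randomized
checks to N = 200 against direct enumeration and `phyper`.  Noiseless fits
are required to invert their generators to a relative tolerance of 1e-6;
analytic identities (hemisphere volume, half-saturation, KD = k_d/k_a) hold
to machine precision.

## Known limitations

* Initial-velocity extraction assumes the curve was sampled inside the
  linear range; sparse sampling of a fast reaction biases the slope low.
* The partial-inhibition form is phenomenological; it does not identify
  the mechanistic binding scheme behind the residual activity.
* The global Langmuir fit assumes a shared R_max across traces and no
  mass-transport limitation; violations bias both rates.
* EMSA fitting treats free ≈ total protein unless the depletion option is
  used, and the competition metric (IC50 ratio) is one of several
  reasonable definitions of relative efficiency.
* AFM volume→mass conversion requires user-supplied reference masses; the
  package deliberately ships none.
* The hypergeometric test treats transcripts as exchangeable; it ignores
  expression-level and length biases that a permutation scheme could
  capture.
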