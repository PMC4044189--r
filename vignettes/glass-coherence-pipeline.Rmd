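---
title: "Simulating and analyzing coherence responses to polar Glass patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing coherence responses to polar Glass patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(glasscoh)
```

## The scientific problem

Polar Glass patterns are fields of dot pairs (dipoles) in which a
proportion of the pairs -- the *coherence* -- share an orientation rule
defined relative to fixation: tangential dipoles yield a circular
(rotational) percept, radial dipoles a starburst (expansion) percept. The
patterns dissociate local orientation energy, which is matched across
coherence levels, from global form structure, which grows with coherence.
They are therefore a standard probe of where in the cortical visual
hierarchy spatially pooled, complex-form-selective responses first arise.

`glasscoh` implements, end to end, a block-design fMRI experiment around
this stimulus and its analysis chain: stimulus synthesis, a first-order
counterbalanced block protocol, a node-level BOLD simulator that embodies
the statistical assumptions the analysis makes, and the analysis itself --
a prewhitened general linear model (GLM), percent-signal-change (psc)
conversion, false-discovery-rate (FDR) node selection, orthogonal
polynomial trend contrasts with within-participant permutation tests, and
a behavioral lagged-correlation control analysis. Because no participant
data are distributed, the simulator is the package's data source; it is
first-class, tested code, and the analysis is validated by parameter
recovery and null calibration against it.

## Stimulus model

A pattern is described by `glass_spec()`. Dipole centers are uniform over
a square placement field whose side equals the annulus outer diameter
(14.4 deg); the annular aperture is applied afterwards as a contrast
envelope rather than as a placement constraint, which is the simplest
geometry consistent with dots being masked at the edges. The defaults are
the experiment's values: 25 dots/deg^2, dot separation 0.14 deg within a
dipole (dots at +/-0.07 deg from the center along the orientation axis),
Gaussian dot profiles with sigma = 0.025 deg, and an annulus of 1.5 deg
inner and 14.4 deg outer diameter with 0.75 deg raised-cosine contrast
ramps. The ramp geometry is read as: envelope zero up to the 0.75 deg
inner edge radius, rising to 1 at 1.5 deg, and falling from 6.45 deg to 0
at the 7.2 deg outer radius, which keeps the stimulus extent at the
stated outer diameter.

Dot totals are forced to the nearest even number (dots come in pairs) and
signal-dipole counts use round-half-to-even, so neither rounding is
biased across coherence levels. Orientations live in `[0, pi)`: a dipole
is an unordered dot pair, so it has an axis, not a direction. Noise
dipoles draw unconstrained uniform orientations -- a noise dipole may by
chance be near-tangential, which matches the definition of coherence as
the proportion of *designated* signal dipoles. Overlapping dots
accumulate additively and the rendered image is clipped to `[0, 1]`,
emulating display saturation. Dipoles straddling an aperture edge are
attenuated by the envelope rather than re-drawn.

```{r stimulus}
spec <- glass_spec(coherence = 0.66, form = "circular")
field <- sample_dipole_field(spec)
img <- render_pattern(field, spec)
img
```

The default raster resolution (40 px/deg) puts one pixel at the dot
sigma; the renderer warns when sigma falls below one pixel. The fixation
digits of the behavioral task are not rendered -- the task is simulated
abstractly (below), which is sufficient for its analysis.

## Design

The protocol (`block_protocol()`) has four coherence conditions (0, 33,
66, 100%) in 16 s blocks. `counterbalanced_orders()` produces four
sequences per run -- a Williams-type row-complete arrangement in which
every ordered pair of distinct conditions occurs exactly once across
within-sequence adjacencies, so first-order carry-over is balanced.
Randomization relabels conditions and shuffles sequence order, preserving
the property; orders are re-randomized for every run. "Preceded by" is
interpreted as immediate stimulus-to-stimulus adjacency within a
sequence: each sequence ends in a blank block, which breaks adjacency
chains, so cross-sequence adjacency is not defined. A single Williams
square does not exist for small odd condition counts, and
`counterbalanced_orders()` refuses odd `n` rather than silently returning
an unbalanced order.

Each run is a 6 s blank, four sequences of four stimulus blocks plus one
blank block, and one appended blank: 342 s, 171 volumes at TR = 2 s.

```{r design}
tl <- build_run_timeline(block_protocol(), counterbalanced_orders(4))
tl
transition_matrix(tl)
```

## Forward model of the BOLD signal

`simulate_node()` generates one node (a cortical-surface location
carrying one timecourse) as

    baseline * (1 + sum_c amp_c/100 * x_c(t)) + drift(t) + noise(t)

where `x_c` is the condition boxcar convolved with the canonical
double-gamma hemodynamic response (peak near 5 s, undershoot at 16 s with
1/6 amplitude) and sampled at volume times, `drift` is a per-run cubic
Legendre expansion, and `noise` is ARMA(1,1). Amplitudes `amp_c` are in
psc of the baseline, so the analysis-side psc conversion is the exact
inverse of generation; noiseless simulation followed by the GLM recovers
the amplitudes to machine precision, which is the package's structural
self-test. The hemodynamic kernel is kept as the raw difference of gamma
densities, unnormalized: the same kernel is used on both sides, so
recovery is invariant to its scaling.

Defaults the experiment does not pin down were fixed once at values a
practitioner would call typical for high-field fMRI, and are all
configurable:

* baseline 1000 a.u.; ARMA(1,1) `a = 0.3`, `b = -0.1`, innovation sd 10
  (1% of baseline, i.e. temporal SNR near 100; lag-1 autocorrelation
  about 0.2);
* drift weights for Legendre degrees 1-3 drawn per run from N(0, 5 a.u.);
* six motion nuisance series simulated as smoothed, per-run-standardized
  random walks, with zero coupling by default (pure nuisance columns);
* area coherence profiles: V1 and V2 flat; V3, hMT+, DRA and VRA linear
  in coherence with full-versus-zero differences of 0.153, 0.101, 0.185
  and 0.246 psc, on a 1 psc pedestal (all areas respond to the pattern
  as such);
* per-participant, per-condition amplitude jitter with sd 0.08 psc,
  shared across an area's nodes. With six participants this puts the
  between-participant SEM of the full-versus-zero difference near 0.046
  psc, the observed scale for V3-like effects;
* 50 responsive plus 10 non-responsive nodes per area per hemisphere
  (the non-responsive fraction exercises node selection); each node gets
  a visual-field meridian distance uniform in [0, 90] deg.

`simulate_cohort()` assembles 6 participants x 12 runs of this model.
What the generator does *not* emulate: spatially correlated noise across
nodes, physiological (cardiac/respiratory) noise structure, motion
artifacts correlated with stimulation, or nonlinear hemodynamics. Tests
passing on this cohort therefore validate the estimation chain under its
own assumptions -- they do not certify behavior on real data where those
assumptions fail.

## Analysis chain

`build_design_matrix()` concatenates runs with one regressor per
condition spanning all runs, per-run Legendre blocks (degrees 0-3, zero
outside their run), and six motion columns standardized per run; the
first three volumes (6 s) of each run are censored by dropping rows from
data and design alike. For the default protocol this is the 2016 x 58
matrix (168 retained rows per run; 4 + 48 + 6 columns).

`fit_node_glm()` fits ordinary least squares, estimates ARMA(1,1) noise
coefficients from the residuals, and refits by generalized least squares
implemented as OLS on innovation-filtered data and design. The filter is
applied independently per run (`e_t = y_t - a y_{t-1} - b e_{t-1}`, first
sample passed through), so run boundaries never leak; with estimated
coefficients (0, 0) it is exactly the identity and the fit collapses to
OLS. `estimate_arma11()` maximizes the conditional Gaussian likelihood
with a moment-matched start, constrained to `|a|, |b| < 0.95`. Two
numerical choices matter: estimation is started both from the moment
estimate and from the origin, and when candidate optima are within the
chi-square(2) 95% band of the best concentrated log-likelihood the more
parsimonious one wins. This resolves the `a = -b` cancellation ridge --
every point on it is observationally white noise -- to (0, 0) instead of
an arbitrary ridge point. ARMA estimation is per node; all whitening
transforms are invertible, so betas remain unbiased regardless of the
estimate, which only affects efficiency and the responsiveness t
statistics.

Condition betas become psc by division by the node's baseline -- the mean
of the fitted drift-only timecourse, which is dominated by the per-run
intercepts and is the only reading of "the drift regressor average" that
yields a baseline in signal units -- times 100. psc is thus invariant to
rescaling the raw signal. Nodes enter an area's response if their
all-stimulus-versus-baseline contrast (unweighted sum of the four
condition betas, one-sided) survives Benjamini-Hochberg FDR at q = 0.001
computed separately within each hemisphere. Selected nodes' psc values
are averaged within participant and each participant's mean across the
four conditions is subtracted, so every row of the resulting
participant x condition matrix sums to zero.

## Inference

Coherence response functions are summarized by integer orthogonal
polynomial contrasts (`[-3, -1, +1, +3]`, `[+1, -1, -1, +1]`,
`[-1, +3, -3, +1]` for four levels). The group coefficient is the mean
over participants of the per-participant contrast (identical to the
contrast of group means for balanced data). Significance comes from a
permutation test: on each of 10^4 iterations every participant's four
condition values are independently permuted -- the literal within-
participant exchangeability implied by the null of no coherence effect --
and the group coefficient recomputed. The one-tailed p counts null values
as or more extreme (ties count, which is conservative) in the observed
direction, with the add-one correction `(1 + count)/(N + 1)` so p is
never zero; it is then doubled for two-tailedness and capped at 1. A
zero observed coefficient reports p = 1. For two or three participants
the test can enumerate all joint permutations exactly, which the test
suite uses as the oracle for the sampled version.

`binned_trend_analysis()` repeats the area-level test within bins of
meridian distance (default edges 0, 22.5, 45, 67.5, 90 deg), the control
used to show that a V3 effect is not confined to nodes bordering the
mid-level areas near the vertical meridian. A bin empty for any
participant is flagged missing rather than silently dropped.

```{r inference, eval = FALSE}
cohort <- simulate_cohort(profiles = list(area_profile("V3")),
                          nodes_per_hemi = 4, null_nodes_per_hemi = 1)
fit <- analyze_cohort(cohort)
permutation_trend_test(fit$responses$V3, orthogonal_contrasts(4)$linear)
```

## Behavioral control analysis

The fixation task presents a digit at 3 Hz; each presentation is a target
with probability 1/20 (ten digits, two polarities, two targets).
`simulate_behavior_run()` generates target and response trains (response
latency, hit rate and Poisson false alarms configurable) discretized into
100 ms bins alongside the active block condition. `lagged_correlation()`
computes the Pearson (phi) coefficient between target and lagged response
restricted to each condition's bins; the condition of a bin follows the
target bin, not the response bin. The lag grid is 15 values, 0 to 1.4 s:
a 0-1.5 s range at 0.1 s steps would give 16, and 15 levels is the
constraint we keep.

`two_way_rm_anova()` partitions the correlation table into condition,
lag, and condition x lag effects, each tested against its interaction
with the random participant factor (the standard mixed-model partition,
giving lag df 14 over lag x participant df `14 (n-1)`); a pooled-error
variant (all participant-interaction strata pooled) is also reported,
clearly labeled, since pooled denominators are common in published
tables. The partition is computed from cell means and is verified in the
tests against `stats::aov` error strata and a hand-worked toy table.

## Reproducibility and problem sizes

Every random draw descends from one master seed through named substreams
(stimulus, cohort, permutation, behavior), so changing the consumers of
one stage does not perturb the others; `run_pipeline()` writes the
config, all seeds and all tables into its output bundle and is
byte-reproducible given the same config.

The validation suite runs at desk scale, chosen to keep each check's
Monte-Carlo error well inside its decision margin: null calibration uses
500 two-run cohorts with 10 nodes per participant and 10^3 permutations
(the rejection rate at alpha = 0.05 is then measurable to +/-0.02);
parameter recovery uses replicate 12-run cohorts with 10 nodes per
participant, comparing recovered psc against each participant's known
generating amplitudes so that amplitude jitter cancels and only
estimation bias remains. The acceptance script averages the recovered
V3 full-versus-zero difference over 60 replicate cohorts for the same
reason: a single 6-participant cohort carries ~0.05 psc of sampling
spread by design, which replication reduces to below 0.01.

## Known limitations

* The simulator works on node timecourses; no image-space (voxel/NIfTI)
  data, motion correction, distortion correction or surface projection
  is modeled -- those belong to scanner-software preprocessing, upstream
  of this pipeline.
* GLS uses the conditional (first-sample-unscaled) innovation filter, not
  exact REML; the difference is a single observation's weighting per run.
* The behavioral ANOVA requires a complete balanced table; degenerate
  series (a condition with no targets) surface as missing correlations
  and must be handled by the caller, typically by simulating longer
  sessions.
* Williams counterbalancing is restricted to even condition counts.
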