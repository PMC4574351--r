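---
title: "Models and methods behind mtdynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtdynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mtdynamics` quantifies microtubule dynamic instability from length-vs-time
traces of astral microtubules (aMTs), analyses GAP-stimulated GTP hydrolysis
titrations from the malachite-green assay, and does mass bookkeeping for
chaperone complex stoichiometries. This vignette documents the underlying
models, the defaults and why they were chosen, and the limits of what the
package's recovery tests demonstrate.

## The three-state model of dynamic instability

A microtubule plus end switches stochastically between persistent assembly,
rapid disassembly, and pause. The synthetic-trace generator models a single
aMT as a continuous-time Markov chain over the states *growth* (length
increasing at `v_g` µm/min), *shrink* (decreasing at `v_s` µm/min) and
*pause* (velocity zero). Six exponential hazards (min⁻¹) govern the
transitions:

| from \ to | growth | shrink | pause |
|-----------|--------|--------|-------|
| growth    | —      | `gs`   | `gp`  |
| shrink    | `sg`   | —      | `sp`  |
| pause     | `pg`   | `ps`   | —     |

This is the minimal generative model consistent with the field's transition
definitions: a *catastrophe* is any entry into disassembly from assembly or
pause; a *rescue* is any entry into assembly from disassembly or pause.
Length is integrated exactly between events, so trajectories are piecewise
linear with no discretisation error; the sampled trace is the trajectory
evaluated every `dt` seconds (4 s default, 600 s duration, matching a
10-minute spinning-disk acquisition) plus independent Gaussian measurement
noise (`noise_sd`, default 0.05 µm — sub-pixel localisation scale; the
imaging literature gives no single figure, so this is a package choice).
Negative sampled lengths are truncated at zero.

At zero length the trajectory renucleates: a shrinking microtubule that
reaches the spindle pole immediately re-enters growth. This keeps traces
full length for statistics, as in-vivo aMTs persist; `boundary =
"terminate"` is available where outright disappearance is wanted. The
initial state is drawn from the chain's stationary occupancy by default and
can be overridden; the initial length defaults to 0.9 µm, the scale of a
typical preanaphase aMT. All randomness in a call flows through one seeded
generator, so traces are bit-reproducible.

## From reported statistics to hazards, and back

Condition-level reports give catastrophe frequency (events per minute of
assembly + pause time), rescue frequency (per minute of disassembly + pause
time) and mean phase durations. `hazards_from_summary()` inverts these into
the six hazards in the stationary regime: dwell-time targets fix each
state's total exit rate, and the two frequency constraints fix how growth
and shrink exits split between the direct switch and the pause route. The
split of pause exits between shrink and growth is not identified by these
statistics at all; the solver prefers a balanced split (`pause_split =
0.5`) and moves it only if the balanced system has no exact solution, in
which case the least-squares-closest feasible hazards are returned and
flagged. The fixed point iterates over the stationary occupancies to a
residual of 1e-8. With pause disabled the two-state closed form applies
(`gs` = catastrophe frequency, `sg` = rescue frequency).

### Why the generator is calibrated against the classifier

The published statistics are not properties of an underlying chain — they
are outputs of a measurement procedure that classifies noisy sampled traces
and censors what it cannot call. Phases whose net length change stays below
the 0.5 µm event threshold are not events; pauses shorter than four samples
are not pauses; and run-merging across brief reversals concatenates what
the chain considers separate dwells. Simulating directly from the
analytically inverted hazards and re-measuring therefore recovers the
frequencies with substantial bias (catastrophe frequency low by tens of
percent, mean pause duration high, at wild-type-like parameters).

`calibrate_generator()` closes this loop. It treats
simulate → classify → summarize as the measurement operator and adjusts the
chain-level targets (frequencies, dwell times and phase velocities) by a
damped multiplicative fixed point until the *measured* statistics match the
requested ones, using a seeded cohort of 250 traces per iteration and at
most 10 iterations. The resulting chain is not the naive one — its dwell
times are shorter and its raw switching rates higher than the reported
values — but its classified output reproduces the reported assembly and
disassembly rates, rescue frequency and pause duration to within a few
percent, and catastrophe frequency to within about ten percent, which is
where detection efficiency saturates at these parameters. The pipeline and
the recovery tests use the calibrated generator; the analytic inversion
remains available (and exactly satisfies its chain-level contract) via
`hazards_from_summary()` alone.

## The phase classifier

`classify_trace()` implements the event-classification procedure for
uniformly sampled traces:

1. consecutive inter-sample displacements of the same sign are merged into
   candidate monotone runs, absorbing single-sample reversals smaller than
   `pause_flatness` so that one noisy sample cannot split a phase;
2. a run becomes assembly or disassembly when |net change| ≥
   `min_net_change` (0.5 µm) **and** the |Pearson correlation| of length
   against time over the run is ≥ `min_fit_quality` (0.85);
3. maximal remaining stretches of ≥ `min_pause_points` (4) samples whose
   total excursion is ≤ `pause_flatness` (0.25 µm) become pauses;
4. everything else is *undetermined*;
5. catastrophes and rescues are recorded between consecutive classified
   phases, looking across undetermined gaps of up to `max_gap_points` (2)
   samples; longer gaps sever adjacency, so an unclassifiable stretch
   cannot silently carry a transition.

The 0.85 threshold is applied to the magnitude of the linear correlation of
length versus time. A conventional coefficient of variation (sd/mean) is
not a usable quality measure for a trending segment, so the config key is
named `min_fit_quality` and kept interpretation-neutral. The pause
flatness bound (0.25 µm, half the event threshold) operationalises
"without significant change"; no published number exists for it. Greedy
run-merging was chosen over global change-point optimisation for
transparency and determinism; on noiseless piecewise-linear traces with
super-threshold legs the greedy classifier recovers boundaries to within
one sample and event counts exactly, which bounds the cost of the choice.

Phases are contiguous blocks of inter-sample intervals; consecutive phases
share their boundary sample. This makes the tiling identity exact — phase
durations always sum to the trace duration — at the cost of assigning each
boundary instant to the earlier phase's end and the later phase's start.
Indices are 1-based (R convention); exchange tables carry times in seconds.

## Dynamics statistics

Per microtubule: rates are duration-weighted mean slopes over phases of a
kind; durations are plain means; mean length is the time average of all
samples (undetermined spans included); catastrophe frequency is
`n_catastrophes / (t_assembly + t_pause)` and rescue frequency
`n_rescues / (t_disassembly + t_pause)`, in min⁻¹, with undetermined time
excluded from all denominators. A zero denominator marks the frequency
undefined (`NA`) rather than zero, and such entries are dropped
per-statistic at aggregation — imputing zero would bias condition means
toward quiescence.

Per condition: mean and SEM (sd/√n) over microtubules, frequencies averaged
per-microtubule rather than pooled over events, matching how the reference
statistics were determined for individual aMTs. Cohorts from fewer than
five cells warn. Condition comparisons use the two-sided Welch
(unequal-variance) t-test per statistic — the robust default when only
"t-test" is specified and cohort sizes differ — flagged at α = 0.05 for
table-style and α = 0.01 for figure-style reports. Whether per-cell means
should be pooled before averaging is not specified in the reference
protocol; the per-microtubule grouping is primary and cell identifiers are
carried in every table so the per-cell grouping can be recomputed.

## GTPase kinetics

The malachite-green assay measures free phosphate after a 90-minute
endpoint incubation. The analysis chain is: ordinary least-squares fit of
the 0–5 µM phosphate standard line; inversion of absorbances to phosphate
(clamped at zero, clamps logged); division by the incubation time to get a
rate (assuming linear accumulation); then a Michaelis–Menten fit of
`v = Vmax·S/(Km + S)`.

The fit is nonlinear least squares, profiled: for fixed `Km` the model is
linear in `Vmax`, so `Vmax(Km)` has a closed form and the problem reduces
to a one-dimensional Brent search over `log Km` (bracket: two decades
around the substrate range, tolerance 1e-12). This removes the
starting-value failure mode of Levenberg–Marquardt-style fits, makes the
result deterministic, and gives exact scale equivariance: scaling all rates
by `c` scales `Vmax` (and `kcat = Vmax/E`) by `c` and leaves `Km`
bit-identical, because Brent's decisions depend only on scale-invariant
comparisons. Standard errors come from the local linearisation at the
optimum. Unweighted residuals are the default (no weighting is specified
for the reference analysis); a `weights` hook is exposed. The test suite
cross-checks the profiled fit against an independent Levenberg–Marquardt
implementation.

The turnover column is reported per µM enzyme with enzyme at 1 µM, so
numeric `kcat` values are plain min⁻¹; where the reference running text and
its parameter table disagree at the last digit (1.85 vs 1.88 min⁻¹ for the
fully assembled chaperone–GAP–tubulin reaction), the presets carry the
running-text values and recovery tolerances are wide enough to be agnostic.

The synthetic titration generator has two modes. `initial_rate` evaluates
the Michaelis–Menten curve and adds 3% multiplicative Gaussian noise (the
package's model of plate-reader replicate scatter). `depleting` integrates
substrate consumption over the incubation (via `deSolve`) and reports
accumulated phosphate divided by time — what an endpoint assay actually
measures. At 1 µM enzyme, `kcat` ≈ 1.9 min⁻¹ and low substrate, 90 minutes
consumes a large fraction of the pool, so the endpoint rate substantially
underestimates the initial rate; the reference analysis fits endpoint data
as if it were initial rates, and the fit stage here deliberately does not
correct for depletion either. Recovery tests default to `initial_rate`
mode; `depleting` mode quantifies the size of the linear-accumulation
assumption's error.

## Complex masses

`predicted_mass()` is exact Dalton arithmetic over integer subunit counts;
kDa rounding happens only at display. `infer_stoichiometry()` enumerates
all compositions up to `max_copies` per subunit and keeps those within
`tolerance_sd` (default 2) standard deviations of the measured mass, ranked
by absolute residual with a lexicographic tie-break. The default tolerance
accommodates the typical gap between light-scattering masses and
sequence-predicted masses (e.g. a measured 335 ± 10 kDa ternary complex
against a predicted 342 kDa). Two tubulin-dimer constants ship as presets:
the 110 kDa nominal value used in predicted sums and the 100 kDa
light-scattering value for the free dimer.

## Pipelines, seeding and reproducibility

`run_dynamics_pipeline()` and `run_kinetics_pipeline()` orchestrate
generate → classify → summarize → compare and generate → fit → compare. One
master seed is fanned out to per-condition seeds by stable hashing of the
condition label, so adding a condition never perturbs the streams of the
others; per-trace seeds fan out the same way. Outputs are plain
tab-delimited text with units in the column headers, doubles written at
full precision so tables round-trip exactly, plus a YAML manifest recording
the seed fan-out and a config hash. Reruns with the same config and seed
are bit-identical.

## Problem sizes used by the recovery tests

The package's own verification uses desk-scale simulations chosen to keep
statistical error comfortably below the tolerances being checked: 200
traces of 600 s at 4-s sampling for dynamics recovery (SEMs of a few
percent on each statistic), 250 traces per calibration iteration, 20 seeded
titrations of 10 substrate levels for kinetics recovery, 500–1000 traces
for distributional properties, and 1000 resampled null repeats for the
Welch-test size check.

## What the synthetic data does and does not show

The generator emulates: phase switching at realistic rates, constant phase
velocities, renucleation at the pole, uniform sampling at 4–5 s, and
additive localisation noise. It does not emulate: curved or foreshortened
microtubules projected into 2-D, spindle movement (lengths are measured
from a fixed origin), photobleaching or detection dropouts, variable
per-frame noise, tubulin-pool coupling between microtubules in a cell, or
any cell-to-cell heterogeneity (traces are i.i.d. given a condition).
Passing recovery tests therefore demonstrates that the analysis chain is
self-consistent — it recovers known parameters from data generated under
its own assumptions at realistic noise — not that those assumptions hold
for any particular microscope or strain. Likewise the kinetics recovery
shows correctness of the calibration-conversion-fit chain, not of the
linear-accumulation assumption itself, whose error the depleting mode makes
explicit.

## Known limitations

- Catastrophe detection efficiency at wild-type-like parameters caps the
  calibrated generator's measured catastrophe frequency roughly 10% below
  the target; the other six statistics calibrate to within a few percent.
- The classifier has no sub-interval event timing; boundaries are sample
  indices.
- No per-cell mixed-effects modelling; cells enter only as identifiers and
  a warning threshold.
- Stoichiometry inference is purely mass-based; it cannot distinguish
  compositions with coincidentally equal masses.
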