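---
title: "Stochastic modelling of mu-opioid receptor signalling with mornet"
author: "mornet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic modelling of mu-opioid receptor signalling with mornet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mornet` implements a mass-action reaction network for mu-opioid receptor
(MOR) signalling in a small membrane compartment, such as the terminal of a
sensory neuron. Eleven species are tracked as integer molecule counts:
extracellular ligand `L`, free receptor `R`, the surface receptor-ligand
complex `RL`, the internalised complex `RL_w`, the intact heterotrimeric
G-protein `aGDPbg`, free GDP- and GTP-loaded alpha subunits (`aGDP`,
`aGTP`), the free betagamma subunit `bg`, an internalisation partner `M`
(arrestin-like), and voltage-gated calcium channels in the open (`Ca_on`)
or betagamma-blocked (`Ca_off`) state. Eleven reactions connect three
cycles:

* receptor cycle — binding `L + R -> RL` (rate constant `k1`),
  internalisation `RL + M -> RL_w` (`k4`), recycling `RL_w -> R` (`k7`),
  degradation `RL_w -> 0` (`k8`);
* G-protein cycle — receptor-catalysed activation
  `RL + aGDPbg -> RL + aGTP + bg` (`k2`), hydrolysis
  `aGTP -> aGDP + M` (`k3`), reassociation
  `aGDP + Ca_off -> aGDPbg + Ca_on` (`k6`), and ligand-independent
  (constitutive) activation `R + aGDPbg -> R + aGTP + bg` (`k11`),
  the network's entry point for reactive-oxygen-species effects;
* channel cycle — betagamma block `bg + Ca_on -> Ca_off` (`k5`) and the
  reopening bundled into `k6`; auxiliary decays `M -> 0` (`k9`) and
  `L -> 0` (`k10`).

Rate constants are *stochastic* rate constants in s^-1 acting directly on
counts (`k x` for unimolecular, `k x y` for bimolecular reactions); the
compartment volume is folded into the bimolecular constants, and the
deterministic module uses unit volume so concentrations equal counts. The
state evolves as a Markov jump process whose law solves the chemical master
equation; `simulate_ssa()` draws statistically exact paths with the
Gillespie direct method (exponential waiting times at the total propensity,
reaction choice proportional to the individual propensities). The tiny
network makes approximate accelerations (tau-leaping, hybrid schemes)
pointless, so none are provided.

Three linear combinations of counts are conserved by every reaction: total
alpha subunits, total betagamma subunits, and total channels. With the
canonical initial counts (10 ligands, 20 receptors, 40 G-proteins, 80
channels; `initial_state()`) the conserved triple is (40, 40, 80). Because
each closed channel holds one betagamma subunit, at most 40 of the 80
channels can ever be closed: channel inhibition has a hard structural
ceiling of 50%. The test suite asserts the triple exactly along every
trajectory and derives the ceiling from the stoichiometry rather than from
simulation.

```{r network}
library(mornet)
net <- mor_network(mor_rates())
net
conserved_quantities(initial_state())
```

## Default parameters

`mor_rates()` carries two parameterisations: the literature-guided
*preselected* values (`preselected = TRUE`) used to initialise estimation,
and the *fitted* values (the default) that result from the FRET-based fit.
`k7 = 5e-4` and `k8 = 5e-5` s^-1 are identical in both: receptor recycling
and degradation act on a scale of tens of minutes, which a five-minute
recording cannot inform, so they are frozen during fitting. The binding
rate `k1` is the biologically interesting dial: it depends on the ligand
(fentanyl versus the pH-sensitive fentanyl derivative NFEPP) and on the
extracellular pH. `k1_reference()` returns the fitted values per condition;
`resolve_scenario()` additionally applies the radical rules (below).

Ensembles follow the study design: 500 Monte-Carlo runs over a 1200 s
horizon, recorded on a 1 s grid by last-value carry-forward (the recording
grid is an output choice, not a solver step; the jump process itself is
simulated exactly). Each run gets seed `seed_base + i - 1`, so any ensemble
is reproducible from one integer. Batch-means confidence intervals split
the runs into batches of 50, test the batch means for normality
(Anderson-Darling, skipped below 8 batches) and apply a Student-t interval
with `n_batches - 1` degrees of freedom.

## Constitutive activation and the radical scenarios

Reactive oxygen species both enable ligand-free G-protein activation and
hinder ligand binding. The scenario rules are: without radicals `k11 = 0`
and the system starts with every channel open; with radicals
`k11 = 5e-5` s^-1, and the ligand-binding rate at pH 6.5 is reduced to 80%
of its radical-free value. Under constitutive activation alone the network
relaxes to a stationary level of closed channels;
`steady_state_base_level()` estimates it as the time-and-ensemble average
of `Ca_off` over the second half of a 20000 s horizon across 100 runs
(values chosen to be comfortably past relaxation, which takes a few
thousand seconds), rounded to the nearest natural number, ties up. With
`k11 = 5e-5` this gives 5, and radical scenarios therefore start from
`initial_state(a = 5)`: five G-proteins pre-dissociated, their betagamma
subunits on channels and their alpha subunits GDP-loaded, so the conserved
triple is unchanged.

```{r scenarios}
steady_state_base_level(mor_rates(k11 = 5e-5))
resolve_scenario("NFEPP", 6.5, radicals = TRUE)
```

## Deterministic limit

`integrate_rre()` solves the reaction-rate equation — the propensity-
weighted sum of stoichiometric vectors — with a stiff-capable adaptive
integrator at `rtol = 1e-8`, `atol = 1e-10` (generous for an 11-dimensional
system; conservation drift stays below 1e-9 over 1200 s). Negative
concentrations beyond tolerance raise an error instead of being clipped:
mass action from nonnegative initial data should never need clipping, so
negativity signals a solver problem worth surfacing. A compiled
right-hand side is used by default and is cross-checked against the plain-R
implementation in the tests.

At the study's copy numbers the ensemble mean and the deterministic
solution agree only up to a finite-size correction: after the inhibition
peak the jump-process mean runs up to about 5% below the mass-action curve
(nonlinear propensities make the mean of the process differ from the
process of the means). The test suite quantifies this two ways: the mean
tracks the ODE within Monte-Carlo error plus an explicit 2-channel
finite-size allowance, and rescaling counts by a volume factor (with
bimolecular constants divided by it, `rescale_network()`) makes the
deviation shrink monotonically toward the thermodynamic limit.

## Parameter estimation from FRET data

The estimation data are FRET recordings of G-protein subunit dissociation:
one series per ligand/pH combination, expressed as percent of initial
fluorescence, flat at ~100% until the ligand is added (~20 s into the
recording) and decaying afterwards. The model quantity behind the signal is
the count of undissociated G-proteins `aGDPbg(t)`; an affine per-series
transform maps it onto the percent scale. Preprocessing
(`preprocess_fret()`) aligns each series so that model time zero is the
ligand addition, either from the annotation or by least-squares
change-point detection (flat baseline plus polynomial hinge; accurate to
about two samples at realistic noise, so the annotated offset is the
default and detection an optional mode).

`mor_fit()` estimates the rates in two stages, with the per-series affine
transform always profiled out in closed form (ordinary least squares of the
data on the model curve — this removes eight nuisance parameters from the
nonlinear search). The residual is the sum over series of the mean squared
difference between transformed model and data; `k11` is fixed at zero
because the recordings come from radical-free conditions.

* Stage one adapts the shared intracellular rates `k2..k6, k9, k10` (with
  `k7`, `k8` frozen) in log10 space with a bound-constrained quasi-Newton
  search, multi-started around the preselected values and restricted to a
  +-2-decade trust region. By default the four per-series binding rates are
  adapted *jointly* in this stage. The design was genuinely open here: the
  historical protocol fixes `k1` at its preselected value during the shared
  fit, but when the starting `k1` are several-fold off, that stage
  compensates by distorting the intracellular rates and the subsequent
  `k1` refinement cannot undo the damage; joint adaptation removes the
  distortion at no cost when the starting values are good. `joint = FALSE`
  restores the strict staging.
* Stage two (`fit_k1_per_series()`) polishes each series' `k1` by scalar
  minimisation in log10 space with everything else fixed, flagging
  series whose residual is flat in `k1` (uninformative data).

### What the data can and cannot identify

The fit observes only the G-protein pool. Rates whose effect on
`aGDPbg(t)` is strong — `k2`, `k3`, `k4`, `k9`, `k10` and the per-series
`k1` — are recovered increasingly well as noise shrinks (the round-trip
test in the suite fits data generated by the model itself). The
channel-cycle rates `k5` and `k6` are a different matter: decade-scale
changes move the fitted curves by less than typical measurement noise, as
the chunk below demonstrates, so their fitted values should be read as
"consistent with the data", not as measurements. Reported point estimates
carry no uncertainty quantification (no profile likelihood or bootstrap);
that is a deliberate non-goal.

```{r identifiability}
ds <- lapply(generate_fret_dataset(synth_spec(noise_sd = 0, seed = 1)),
             preprocess_fret)
truth <- attr(generate_fret_dataset(synth_spec(noise_sd = 0, seed = 1)),
              "truth")
k <- truth$rates
k[["k6"]] <- k[["k6"]] * 50
# residual change from a 50x change in k6, in squared-percent units:
fret_residual(do.call(mor_rates, as.list(k)), truth$k1, ds)
```

## The synthetic FRET generator

`generate_fret_dataset()` emulates the data-generating situation the
estimation assumes, so the whole pipeline is testable without laboratory
data: a flat 100% baseline before the addition time, then the affinely
transformed deterministic `aGDPbg` curve (started from the canonical state
with no base level), plus i.i.d. Gaussian noise on the percent scale.
Defaults: the four ligand/pH combinations at their reference binding
rates, 1 Hz sampling for 320 s, addition at 20 s, noise sd 1.5% — scatter
of the magnitude real recordings show after photobleaching correction, and
roughly homoscedastic. The default transform maps the initial 40
G-proteins to exactly 100%.

Real FRET data differ from this idealisation in ways the generator
deliberately does not model: noise is taken as white and Gaussian (no
autocorrelated drift, no photobleaching trend, no heteroscedasticity), the
underlying curve is the deterministic mean rather than one stochastic
realisation of the cell's own reaction noise, and the transform is exactly
affine. Passing round-trip tests therefore certify the estimation
machinery — alignment, transform profiling, optimisation — under the
model's own assumptions, not robustness to misspecified noise.

## Scenario studies

`run_ph_study()` compares the four radical-free conditions;
`run_radical_study()` pairs each ligand's healthy condition (pH 7.4, no
radicals) with progressive inflammation (pH 6.5, radicals). "Amplitude"
always means the maximum over the recording grid of the ensemble-mean
closed-channel percentage of all 80 channels — the peak of the mean, which
is what a mean time-course plot shows (the mean of per-run peaks is
systematically higher and is not used). `amplitude_vs_k1()` sweeps the
binding rate over a log-spaced grid (default 25 points across
1e-4..1e-1 s^-1) and exposes the response nonlinearity: the amplitude
climbs steeply below about 2e-3 s^-1 and saturates near the structural
ceiling above 1e-2 s^-1. `binding_event_distribution()` histograms the
per-run count of binding events, whose support cannot exceed the 10
available ligands; as `k1` decreases the distribution shifts toward zero
and its relative spread grows, which is why the weak-binding scenario
(NFEPP at pH 7.4) also shows the largest across-run variance of closed
channels: runs with zero or one binding event coexist with runs with
several.

## Numerical and testing choices

* Reaction choice inside the SSA uses a linear scan over the 11
  propensities; waiting times use the R RNG, so a seed fixes a trajectory
  bit for bit across platforms.
* A frozen system (zero total propensity) fills the remaining grid with
  the current state rather than erroring: absorbing states are legitimate.
* Rounding of the constitutive base level uses round-half-up to a natural
  number.
* The test suite runs ensembles of 40-500 runs depending on the
  discrimination the assertion needs (500 for the headline peaks, less for
  qualitative orderings), a choice balancing statistical resolution
  against suite runtime; all seeds are fixed in the tests.
* The two middle reference binding rates differ by only a factor 1.3, so
  adjacent-step assertions on histogram spread are made within an explicit
  Monte-Carlo tolerance while the overall widening across the full range
  is asserted strictly.

## Known limitations

* No spatial or compartmental structure, no receptor conformational
  states, no explicit GDP/GTP pools; `k11` lumps all
  radical-dependent constitutive activity into one constant.
* The estimation returns point estimates only, and `k5`/`k6` are
  structurally ill-determined by G-protein-pool data (see above).
* The deterministic module is a large-volume approximation used for
  fitting speed; at the study's copy numbers its curves sit a few percent
  above the true process mean after the peak.
* Laboratory-scale effects (photobleaching, cell-to-cell variability,
  patch-clamp statistics) are outside the model; comparisons with such
  data are qualitative.
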