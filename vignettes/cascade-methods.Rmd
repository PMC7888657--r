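---
title: "Modelling the dual-sensor oxygen response of Rhizobium leguminosarum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dual-sensor oxygen response of Rhizobium leguminosarum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixcascade)
```

## The biological system

*Rhizobium leguminosarum* bv. viciae 3841 (Rlv3841) must rewire its
respiration as it moves from soil (21% headspace O2) through the
microaerobic outer zones of a pea nodule into the near-anoxic nitrogen
fixing core (20-50 nM dissolved O2). Two sensors drive this transition
and form a single regulatory cascade:

* **hFixL-FxkR-FixK** — a relatively oxygen-tolerant two-component
  system. The membrane kinase hFixL autophosphorylates when O2 falls to
  roughly the 1% headspace range and transfers the phosphoryl group to the
  response regulator FxkR, which binds a K-box operator
  (`GTTACA-N4-GTTACA`) to induce the FNR-family transcription factor FixK.
* **FnrN** — an FNR-family factor with an oxygen-labile iron-sulfur
  cluster, active only near anoxia (around 0.01% headspace). FnrN and FixK
  both bind anaerobox operators (`TTGAT-N4-ATCAA`) as dimers and induce
  the same regulon, including *fixNOQP* (the high-affinity cbb3 terminal
  oxidase needed for bacteroid respiration) and *fnrN* itself.

The *fnrN* promoter carries two anaeroboxes: a distal site whose occupancy
activates transcription and a proximal site that represses it by steric
hindrance. This gives FnrN both positive and negative auto-regulation, and
lets FixK prime *fnrN* expression under mild microaerobiosis before FnrN
itself switches on.

`fixcascade` implements a five-species ODE model of this cascade, the
steady-state and bifurcation analysis of its oxygen response, calibration
of its parameters to knockout/wild-type reporter ratios, a Langevin
ensemble treatment of stochastic commitment, a synthetic reporter-assay
generator, and a promoter scanner for the two operator motifs.

## Model structure

The model tracks one copy each of hFixL (`L`), FxkR (`R`), FixK (`K`),
FnrN (`N`) and FixNOQP (`F`), in arbitrary concentration units. All
species share a first-order removal rate `delta` (dilution plus turnover);
time is nondimensionalised so `delta = 1`, i.e. one time unit is one
protein turnover time.

Oxygen enters through two transfer functions:

* hFixL active fraction: `K_L^2 / (K_L^2 + c^2)` — cooperative O2
  binding, Hill coefficient 2, half-inactivation `K_L` = 12 uM (the
  dissolved concentration in equilibrium with a 1% headspace at 1 atm,
  with a Henry constant of 1200 uM/atm; 0.01% likewise corresponds to
  120 nM).
* FnrN active fraction: `K_NO2 / (K_NO2 + c)` with `K_NO2` = 120 nM.
  Cluster destruction by O2 is modelled as first order: the cooperative
  (Hill-2) processes in this cascade are hFixL-O2 binding and the two
  DNA-dimer binding reactions, and FnrN-O2 is deliberately not among
  them.

Phosphotransfer is treated at quasi-steady state: active FxkR is
`L x R x` (hFixL active fraction). The kinase level `L` enters as a factor
so that deleting *hfixL* extinguishes signalling smoothly through protein
decay; at the wild-type steady state `L = 1`, so the expression reduces to
`R x` active-fraction. The *fixK* promoter responds to active FxkR with a
saturating first-order law (half-saturation `K_RK`) — phosphorylated
response regulators were not among the cooperative binding processes
either.

FixK and FnrN compete for each anaerobox. With propensities
`x = (K / A_K)^2` and `y = (N_active / A_N)^2`, single-box occupancies are
`x/(1+x+y)` and `y/(1+x+y)`; both factors induce identically when bound,
so promoters respond to the total occupancy. FnrN binds anaeroboxes more
tightly than FixK (`A_N < A_K`), reflecting FnrN's dominant role in the
regulon. The three regulated promoters are:

* *fixK*: `alpha_K + beta_K * h(R_active)`,
* *fnrN*: `alpha_N + beta_N * theta_dist * (1 - theta_prox)` — distal
  activation gated by the probability that the proximal, sterically
  repressing box is free; the proximal box binds both factors with
  affinities penalised by factors `rho_K`, `rho_N` > 1,
* *fixNOQP*: `alpha_F + beta_F * theta_box`, where the fixNOQP operator
  carries its own affinity pair (`A_K_fix`, `A_N_fix`). A single shared
  affinity pair cannot reproduce the knockout ratio data: the in-planta
  fnrN reporter ratio of the *hfixL* knockout fixes the mutant's FnrN
  level relative to wild type, and with shared affinities that fixes the
  occupancy ratio at every box, contradicting the observed *fixNOQP*
  ratios. Operator context plausibly modulates effective affinity; the
  second pair encodes that freedom explicitly.

Deliberate simplifications: one gene copy each (the real strain carries
two *hfixL*, two *fxkR*, three *fixK* and three *fixNOQP* homologs, but
the single-copy cascade is the modelled object); *hfixL* and *fxkR* are
constitutive — the K-box upstream of the chromosomal *fixK-hfixL* operon
and FxkR negative auto-regulation are left out of the network; no NifA or
nitrogenase (they act downstream of the modelled pathway); no
phosphatase/ATP detail. The supplementary equations of the source study
are not public, so the rate laws above are this package's own
concretisation of the stated modelling constraints; they are documented as
such and all quantitative behaviour is re-derived by the calibration
below.

## Steady states, sweeps and bistability

Because hFixL and FxkR are constitutive and FixK has no feedback, the
system is feed-forward except for FnrN auto-regulation: steady states
reduce to a one-dimensional fixed-point problem in `N`. The package
exploits this twice:

* the *reduced solver* (used by scenario evaluation and calibration)
  brackets sign changes of the FnrN fixed-point residual on a dense grid
  and polishes each root with `uniroot`;
* the *general solver* `find_steady_states()` runs damped multi-start
  Newton iteration on the full five-dimensional right-hand side (50
  Latin-hypercube starts plus the basal state and, in sweeps, the
  previous grid point's roots as continuation seeds), deduplicates roots
  at 1e-4 relative distance and verifies `|rhs| < 1e-9`.

The two routes, plus long-time integration with `deSolve::lsoda`, are
pinned against each other in the test suite. Stability is classified by
the eigenvalues of a central finite-difference Jacobian with a 1e-7
margin; borderline states are flagged and counted as unstable rather than
silently accepted. `sweep_bifurcation()` walks a descending log-spaced
oxygen grid (default 200 points from 21% to 0.001% headspace
equivalents — the direction a bacterium experiences entering a nodule),
and `detect_bistable_window()` extracts the maximal contiguous interval
with at least two stable states, refining its ends by bisection between
grid points.

With the shipped calibration the wild-type sweep is monostable
everywhere — the hFixL arm destroys the low-expression state before FnrN
auto-activation could latch — while the *hfixL* knockout leaves FnrN
auto-activation alone and opens a bistable window entirely below 120 nM,
with coexisting near-zero and high expression states.

## Scenarios, knockout ratios and the history rule

Three scenarios mirror the reporter assays: atmospheric (21% headspace),
free-living microaerobic (1%, 12 uM dissolved) and in-planta bacteroids
(30 nM dissolved, chosen inside the reported 20-50 nM range and exposed
as a parameter). Reporter readout is the instantaneous promoter
transcription rate — what a plasmid-borne transcriptional fusion reads
out in any genetic background, including strains whose own copy of the
gene is disrupted; a protein-level readout is available and is identical
up to the shared removal rate at steady state.

Where a mutant is multistable in planta, the reported state is selected
by *history*: forward evolution from that genotype's free-living steady
state, mimicking cells descending the nodule gradient from microaerobic
towards anoxic conditions. Wherever the system is monostable the rule
reduces to the unique state. Because FixK never depends on FnrN, the
reduced implementation of this rule (a one-dimensional flow in `N` at
fixed slaved variables) is exact, and it is cross-checked against full
ODE integration in the tests. For the underdeveloped nodules of *fnrN*
mutants, where oxygen is unlikely to drop as far, an elevated-oxygen
variant (300 nM) is provided but deliberately not used in calibration.

`nodule_zone_profile()` prescribes a log-linear oxygen gradient along the
nodule axis from 12 uM at the tip (anchoring hFixL activity in zone I; the
source imaging does not state zone I oxygen, so this is a package choice)
down to 30 nM in the core, applies the history rule tip-to-root, and
summarises each reporter by its onset steepness (maximum spatial
derivative of min-max-normalised expression). Reaction-diffusion transport
of oxygen is out of scope; the gradient is an input.

## Calibration

Free parameters (basal and maximal rates, `K_RK`, anaerobox affinities,
proximal penalties, and the two sensor thresholds within their stated
ranges `K_L` in 6-24 uM, `K_NO2` in 60-240 nM) are fitted by multi-start
bounded least squares (`nlminb` over Latin-hypercube starts) on
log-residuals of the built-in ratio table: seven knockout/wild-type
percentages (free-living: 25% and ~100% for *fnrN*, 17% and 73% for
*fixNOQP*; in planta: 22%, 28%, 5%, 68%) plus the wild-type *fixNOQP*
fold induction of ~5. Log scale keeps the small ratios (5%) from being
dominated by the large ones, and each row's squared residual is capped so
that an observable the model family cannot reach does not distort the
rest of the fit. Where the assays report both plasmid operons the pRL9
copy is used, because the model has a single FixNOQP species. The *fnrN*
fold induction is only printed as a bound ("more than double" the ~5-fold
of *fixNOQP*), so it enters as a one-sided barrier at 10, not a squared
term. Acetylene-reduction data are excluded: nitrogenase is downstream of
the modelled pathway.

Structural penalties keep candidate fits in the qualitative regime the
study establishes: a monostable wild type over the whole sweep,
a knockout bistable window confined below 120 nM, and a wild-type *fnrN*
branch that peaks at intermediate oxygen and declines towards anoxia
(auto-repression). A candidate minimising the residuals but violating the
monostable/bistable constraint is rejected in favour of the next-best
start. Identifiability is claimed only at the level of predictions: fits
from different seeds must agree on the nine predicted observables within
2%, not on raw parameter values. Concentration units are arbitrary; a
joint rescaling of all synthesis rates and protein half-saturation
constants (`rescale_concentration_unit()`) leaves every ratio unchanged,
which pins down why only ratios are fittable and why one rate can be
fixed to 1.

The shipped `default_params()` is the best such fit. It reproduces seven
of the nine observables within about 5% relative error — both free-living
and in-planta *fixNOQP* ratios, the *fnrN*-null controls, the in-planta
*fnrN* auto-activation ratio and the fold induction — while satisfying
every structural constraint. The two remaining observables, the *fnrN*
reporter ratios of the *hfixL* knockout (25% free-living, 28% in planta),
are under-predicted, and this is a structural property of the promoter
model rather than a fitting failure. Those two numbers jointly require
FixK input at the *fnrN* promoter to provide most of the wild-type signal
at 1% O2 yet almost none of it at 30 nM, even though the FixK level and
its DNA-binding activity both *rise* monotonically as oxygen falls; with
competitive Hill-type occupancy (and a proximal box that can only add
repression, never relieve it) no parameter assignment can make the same
input large in one condition and small in the other while FnrN
amplification and the knockout's own closure are maintained. Reproducing
them would need a mechanism outside the modelled topology — for example
the FnrN-mediated repression of *fxkR* suggested by the downstream
operator sites of the real gene cluster, which the single-pathway model
deliberately omits. The package reports what the calibrated model
actually predicts for these rows (roughly 6% and 2% of wild type) rather
than tuning them cosmetically. Parameters are stored in a flat YAML file
(`inst/extdata/params_default.yaml`) and `calibrate_cascade()`
regenerates an equivalent set from scratch in minutes.

## Stochastic commitment

In the bistable knockout regime the deterministic model cannot say *when*
a cell jumps to the high branch; the study's reading is that expression
noise drives an increasing fraction of cells across as oxygen falls and
the escape barrier shrinks. `simulate_langevin()` and
`commitment_fraction()` implement the simplest consistent treatment:
Euler-Maruyama with additive noise of shared amplitude `sigma` on each
synthesis term, reflection at zero, `dt` = 1e-3 and a horizon of 50
turnover times (long enough for slow barrier crossings, short enough that
the fraction resolves the window's interior). Cells start at the
low/basal state and are classified by the nearest stable state (in FnrN)
at the end, with a state counting as "high" if its FnrN level is at least
half the largest stable level on the grid — this keeps the
classification well defined at monostable grid points on either side of
the window. The default `sigma` (shipped in
`inst/extdata/ensemble_default.yaml`) was chosen once so the knockout
commitment curve spans roughly 5-95% across the default window. No noise
magnitude is given in the source study; all stochastic results are
illustrations of the mechanism, not quantitative predictions, and
molecule-count (master-equation) treatments are out of scope.

## Synthetic reporter data

`generate_reporter_dataset()` emulates the assays' statistical structure:
model-predicted promoter activities times lognormal noise (positive,
right-skewed, like fluorescence/OD ratios), replicated, and normalised so
each (reporter, scenario) group's wild-type mean is exactly 100%.
Defaults: cv 0.2 for plate-reader assays, 0.35 for bacteroid assays
(plant-to-plant variability); replicate-level dispersions are not printed
in the source, so these are package choices. The generator feeds
`recover_parameters()`, a round-trip harness that refits the model to
synthetic group means and compares generating and recovered predictions
row by row. What these tests demonstrate is internal consistency of the
pipeline under known noise; they do not validate the noise family against
real replicate-level data, which the package does not ship.

## Motif scanning

`scan_sequence()` does exhaustive sliding-window matching of the two
operator consensi on both strands with an exact-match default
(mismatches are a parameter). Offsets follow the operator-map convention:
position of the motif's 5'-most base on the forward strand relative to
the transcription start site, TSS = +1, negative upstream, no zero — the
convention that reproduces the mixed negative/positive published offsets
(-34 and -2 for the *fnrN* boxes, -62 for *fixK* K-boxes, +6 and +38
downstream of *fxkR*) self-consistently. Which motif base the published
table anchors is not stated; the 5'-most-base choice is a documented
package convention. The anaerobox is an exact palindrome, so coinciding
forward/reverse matches are reported once; the K-box is a direct repeat
and both strands are reported. The scanner is verified against a
brute-force regular-expression oracle on randomised planted fixtures. A
genome-wide rescan of the real Rlv3841 assembly is out of scope (it would
require the external assembly); published offsets are used as coordinate
conventions and test fixtures, not re-derived claims.

## Numerical choices and limitations

* Root tolerance 1e-9 (rhs max-norm); deduplication at 1e-4 relative;
  eigenvalue margin 1e-7; window bisection to 1e-6 in log-oxygen.
* Negative concentrations are rejected as errors, not clamped; `c = 0`
  (anoxia) is a legal input and the transfer functions are exact there.
* Default problem sizes — 200-point sweeps, 500-cell ensembles at 6-8
  oxygen levels, 100-point nodule profiles — were chosen so the full
  analysis reruns in minutes on a laptop while keeping discretisation
  error well below the tolerances above.
* The calibration fits nine observables with more free parameters than
  data; parameter values are not individually identified and should not
  be interpreted, only the predicted observables.
* The model is deterministic and well mixed per cell; it does not model
  operon duplication, plasmid copy number, growth-rate coupling, or the
  plant side of the symbiosis (the oxygen gradient is prescribed, not
  computed).

## Reproducing the shipped analysis

```{r, eval = FALSE}
params <- default_params()

# knockout ratio table at the calibrated defaults
predict_ratio_table(params)

# bifurcation structure
sw_wt <- sweep_bifurcation(params, "wt")
sw_ko <- sweep_bifurcation(params, "hfixL")
detect_bistable_window(sw_ko)
autoplot(sw_ko, "fnrN")

# stochastic commitment across the knockout window
win <- detect_bistable_window(sw_ko)
grid <- exp(seq(log(win$upper), log(win$lower), length.out = 6))
commitment_fraction(grid, params, "hfixL", n_cells = 500, seed = 1)

# refit from scratch
fit <- calibrate_cascade(seed = 1)
glance(fit)
```
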