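---
title: "The torsade metric pipeline: model, metric, uncertainty and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The torsade metric pipeline: model, metric, uncertainty and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsadeRisk)
```

## The problem

Drug-induced torsade de pointes (TdP) is driven by block of the rapid
delayed-rectifier potassium current IKr (hERG), but hERG block alone is a
poor predictor: drugs that also block inward currents (late sodium INaL,
L-type calcium ICaL) can be electrophysiologically safe despite potent
hERG affinity. This package implements a mechanistic risk pipeline: drug
effects on four currents are integrated in a paced human ventricular
myocyte simulation, summarised by a net-charge metric, propagated through
measurement uncertainty, and converted into a calibrated three-category
risk call (high / intermediate / low) with prespecified performance
statistics.

## The myocyte model

`"cipaordv1.0"` is an ORd-family endocardial ventricular cell: the full
set of ionic currents (INa, INaL, Ito, ICaL/ICaNa/ICaK, IKr, IKs, IK1,
INaCa, INaK, background and pump currents), CaMK signalling, and
four-compartment calcium handling, with the conductance rescalings of the
CiPA-optimised variant (IKs x1.87, IK1 x1.698, INaL x2.661, ICaL x1.007,
and the rescaled IKr conductance 4.6585e-2 mS/uF). It is written in C
behind `deSolve`'s compiled-model interface; `lsoda` integrates the 48
stiff states with relative tolerance 1e-6 and absolute tolerance 1e-8,
chosen so that qNet moves by well under 0.1% when the tolerances are
refined further (asserted in the test suite). Pacing restarts the solver
at every stimulus so the 0.5 ms pulse can never be stepped over by the
adaptive integrator.

### The dynamic drug--hERG submodel

IKr is a nine-state Markov scheme: a conducting row C1--C2--O, an
inactivated row IC1--IC2--IO, vertical inactivation edges, and three
drug-bound states (open-bound, inactivated-open-bound and a trapped
closed-bound state). Drug association is concentration-dependent,

$$k_{on}(D) = K_{max} \, K_u \, \frac{D^{n}}{D^{n} + halfmax},$$

dissociation from the open-bound state occurs at $K_u$ (with a
microscopic-reversibility-corrected rate from the inactivated-bound
state), and bound drug becomes trapped in the closed-bound state at a
voltage-dependent rate $K_t / (1 + e^{-(V - V_{half})/6.789})$ with
$K_t = 3.5\times10^{-5}$ ms$^{-1}$. The five drug-specific parameters
($K_{max}$, $K_u$ in 1/ms, $n$, $halfmax$ in nM$^n$, $V_{half}$ in mV)
are exactly the quantities measured by the dynamic hERG voltage
protocol, and are consumed as inputs -- fitting them from raw traces is
out of scope.

The scheme's fourteen voltage-dependent rate constants follow the
published physiological-temperature parameterisation. The assignment of
the rate pairs to the seven edges was fixed, before any metric was
computed, by requiring textbook hERG macroscopic behaviour under voltage
clamp: essentially closed at rest, rapid inactivation during a
depolarising step (inactivated-open dominating open), and a resurgent
open-probability tail on repolarisation. The test suite asserts the
consequences that matter downstream: occupancies sum to one at every
output point (1e-6), zero concentration reproduces the drug-free trace
bit for bit, and increasing the concentration of a pure hERG binder never
shortens APD90 nor raises qNet.

### Non-hERG drug effects

INaL, INa and ICaL (optionally IKs, IK1, Ito) are blocked statically:
the conductance is multiplied by $1 - 1/(1 + (IC_{50}/C)^h)$. IC50s are
stored in nM; an infinite IC50 is the explicit "no measurable block"
sentinel that empty table cells map to.

### The toy model

`"toy"` is a three-variable analytic caricature (membrane potential, a
placeholder gate, and the bound fraction of a hERG-like site) whose beat
is constructed in closed form: piecewise-linear AP and current waveforms
whose integrals -- and hence qNet (`toyQnet()`) -- are known exactly, a
bound fraction that relaxes geometrically to its binding equilibrium,
and a qNet that provably and strictly decreases with binding potency
(both terms of its derivative in the bound fraction are negative by the
choice of conductances). It exists so the uncertainty-quantification and
statistics layers can be exercised at full scale in seconds; any model
that registers an initial state, a pacing step and a beat tracer through
`registerApModel()` can be swapped in, because everything downstream is
model-agnostic.

## The metric

qNet is the time integral over one paced beat of
$I_{net} = I_{CaL} + I_{NaL} + I_{Kr} + I_{Ks} + I_{K1} + I_{to}$
(trapezoidal rule on the solver's own output grid, (uA/uF)·ms scaled to
uC/uF). The *torsade metric score* of a drug is the mean of qNet over
steady-state beats at 1, 2, 3 and 4 times its free therapeutic Cmax --
integer multiples, configurable. Lower scores mean higher risk.

Defaults follow standard proarrhythmia-simulation practice: cycle length
2000 ms, stimulus -80 uA/uF for 0.5 ms, 1000 pre-pacing beats.
Endocardial parameters only; transmural heterogeneity is not modelled.
APD anchors at the time of maximum upstroke velocity; a beat whose
post-stimulus peak never exceeds 0 mV is a depolarization failure (the
threshold separates full APs cleanly from stimulus artifacts), and a
beat that never recrosses the APD level before the cycle ends is a
repolarization failure. A parameter sample whose simulation fails at any
concentration has an undefined score: it is excluded from the score
distribution and counted in `nFailures`, reported prominently, rather
than being assigned an extreme score -- assigning "worst risk" would
silently conflate sodium-channel pharmacology with hERG-mediated risk.

## Uncertainty quantification

Per-cell fractional-block measurements are fitted by least squares to
the Hill equation with the IC50 on the log scale and the Hill
coefficient constrained to (0, 5] -- unconstrained exponents on sparse
noisy patch-clamp data are unstable. Nonparametric bootstrap resamples
cells (not points) with replacement and refits, and joint per-drug
parameter samples (default 2000) pair independent draws across channels:
the channels are measured in separate experiments, so no cross-channel
correlation is imposed (a documented switch point; precomputed joint
sample files pass through unchanged). Each joint sample yields one
torsade metric score; the 2000 scores form the drug's score
distribution.

## Thresholds by ordinal regression

The training drugs' pooled score samples, each drug weighted $1/n$ so
every drug is one vote, enter a proportional-odds cumulative-logit model
with the score as single covariate (risk ordered high < intermediate <
low along increasing score). The two thresholds are the score values
where adjacent cumulative category probabilities equal 0.5, i.e. the
fitted cut points divided by the slope. Fitting is by maximum likelihood
(`MASS::polr`, convergence tolerance 1e-8) on internally standardized
scores -- the optimiser is scale-sensitive, the model is not, and the
back-transformed thresholds are exactly scale-equivariant (asserted in
the tests). Pooled-sample fitting is the default because the thresholds
are meant to cut the full distributions; fitting on per-drug medians
only is available as a switch. Boundary ties classify as intermediate, a
measure-zero convention for continuous scores.

## Performance measures

All measures resample the score distributions: per iteration one
uniform draw per drug (10,000 iterations by default, 2.5/50/97.5
percentiles reported).

* **ROC1 / ROC2 AUC** -- high-or-intermediate vs low, and high vs
  intermediate-or-low, by Mann--Whitney pair counting with ties at 0.5;
  the tests prove pair counting identical to trapezoidal integration of
  the empirical ROC curve and label-swap antisymmetry.
* **Pairwise comparison correct rate** -- concordance of all
  cross-category pairs with the risk order, no category combining.
* **LR+ / LR-** at both thresholds -- sensitivity/(1-specificity) and
  (1-sensitivity)/specificity of the threshold classification; any zero
  probability entering a ratio is replaced by 1e-6, so a perfectly
  classified panel reports a large finite LR+ (order 1e5--1e6) rather
  than infinity.
* **Mean classification error** -- the mean over drugs of the
  off-category probability mass. Per iteration every drug's
  distribution is bootstrap-resampled at its own size and its
  off-category fraction averaged over drugs. This is the formulation
  under which the measure's arithmetic behaves as expected -- a single
  drug with 75% off-category mass in a 16-drug panel contributes
  0.75/16 -- whereas summarising single draws by the median collapses
  onto multiples of 1/n.

Leave-one-out cross-validation refits the thresholds without each drug
and classifies the held-out drug with its fold's thresholds; ranking
measures, which need no thresholds, use the full panel.

## Synthetic data: what it emulates, what it does not

The fixtures module generates (i) per-cell Hill-curve responses with
truncated Gaussian noise, (ii) Gaussian score panels with closed-form
category masses, and (iii) mechanistic drug panels for the toy model in
which high-risk drugs are strong hERG binders, low-risk drugs weak
binders with protective ICaL block, and every drug carries a
cross-cutting amount of INaL block. Every generator is a pure function
of its seed. The mechanistic panel's categories are genuinely separable
by construction, so ranking measures on it saturate near their ideal
values; passing those checks demonstrates that the estimators and the
pipeline plumbing are correct, *not* that real drug panels -- where
in vitro variability, skewed score distributions and genuinely
borderline compounds produce substantial category overlap -- would be
ranked that well. Real score distributions are also skewed, which only
the full myocyte-model path exercises.

## Problem sizes

The package's own checks run at reduced sizes chosen to exercise every
code path at full fidelity: the compiled model is paced for tens of
beats from a stored paced steady state (shipped as a plain-text
initial-condition file) instead of 1000 beats from rest, uncertainty
quantification uses 200 samples where the production default is 2000,
and evaluation uses 1000 resamples where the default is 10,000. The
acceptance script (`scripts/acceptance.R`) reports the sizes it used
alongside every value.

## Known limitations

* The dynamic-hERG rate constants and their edge assignment are a
  reconstruction of a published parameterisation validated against
  macroscopic channel behaviour, not against the original code; absolute
  drugged qNet values for real compounds should be re-anchored against
  reference simulations before regulatory use.
* Early afterdepolarisation detection and other arrhythmia surrogates
  are out of scope; beats that depolarise but oscillate without
  repolarising are caught only if the APD level is never crossed.
* Single endocardial cell only; no tissue, fibre or transmural
  simulation, no temperature correction of kinetics.
* Hill fitting assumes fractional block already normalised to [0, 1];
  raw-current normalisation is upstream of this package.
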