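---
title: "Three-state folding kinetics of xrRNAs from single-molecule FRET"
author: "xrfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state folding kinetics of xrRNAs from single-molecule FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xrfret)
```

## The system and the observable

Exoribonuclease-resistant RNAs (xrRNAs) of mosquito-borne flaviviruses fold
into a ring-like pseudoknotted tertiary structure that blocks the 5'→3'
exonuclease Xrn1. In single-molecule FRET experiments a donor/acceptor pair
reports the distance between an internal loop and the 3' end, and
individual molecules interconvert among three conformations: an unfolded
low-FRET state (L, centre ≈ 0.3), a partially folded intermediate
(I, ≈ 0.5) and the natively folded high-FRET state (H, ≈ 0.9).
Magnesium shifts the ensemble towards H, and the propensity to leave H
controls how fast Xrn1 degrades the RNA. `xrfret` implements the full
analysis chain for this kind of data — and, because raw single-molecule
data sets of this type are rarely deposited, a synthetic-data generator
with exact ground truth against which every stage is validated.

## Generative model

State switching is modelled as a continuous-time Markov chain on {L, I, H}
with six rate constants `k_LI, k_LH, k_IL, k_IH, k_HL, k_HI` (s⁻¹).
`simulateStatePath()` draws exact Gillespie trajectories: the dwell in a
state is exponential with mean 1/(sum of its exit rates), and the
destination is chosen proportionally to the individual rates.

`renderTrace()` converts a path into camera frames (default 0.025 s/frame,
the usual EMCCD setting for this chemistry). Two choices matter:

* **Frame integration.** A real camera integrates over the exposure, so a
  frame containing a jump reports the occupancy-weighted mean FRET. This
  is the default. An instantaneous-sampling switch (`integrate = FALSE`)
  samples the state at the frame midpoint instead; it exists as an oracle
  mode in which estimator correctness can be tested separately from
  camera-blur effects (see *Missed-event bias* below).
* **Noise and photobleaching.** Channel noise is additive Gaussian
  (default s.d. 70 counts at a total intensity of 1000, giving ≈ 0.05
  s.d. on the FRET axis — the scatter typical of oxygen-scavenged TIRF
  data). Photobleaching is single-step and per-channel, with default
  rates 0.01 s⁻¹ (donor) and 0.005 s⁻¹ (acceptor), i.e. mean bleach times
  comfortably longer than the default 60 s observation window. Full
  photon statistics, blinking and spectral crosstalk are deliberately out
  of scope: the estimators under test are insensitive to those details at
  this noise level, and the Gaussian model keeps the ground truth exact.

The Mg²⁺ dependence of the rates (`mgRateLaw()`) is a power law — log-linear
in log concentration — applied to the two unfolding rates `k_HI` and
`k_IL` (exponents 0.5 and 0.35 at a 1 mM reference), with the folding
rates held constant. This mirrors the experimentally observed pattern in
which increasing Mg²⁺ mainly slows escape from the folded and intermediate
states; no specific functional form is established experimentally, so a
monotone two-parameter law is the simplest adequate choice.

`simulateMovie()` renders dual-channel TIRF stacks (Gaussian point-spread
spots, Poisson noise, a stored donor→acceptor channel transform) as input
for the imaging front end, and `simulateDecayTrace()` /
`simulateGuinierCurve()` provide decay and scattering fixtures.

## Imaging front end

`detectSpots()` finds local maxima and refines each by least-squares
fitting a symmetric 2D Gaussian in a 9 × 9 pixel window; spots whose
window is clipped by the frame edge are skipped, and fits with implausible
widths (outside 0.5–4 px) are dropped. The local background is the median
of the window border. `registerChannels()` treats every donor–acceptor
spot pair as a vote for a candidate translation, accumulates votes on a
0.5 px grid, takes the modal bin and refines by least squares over the
inliers — a deliberately minimal reading of Hough-style registration;
rotation refinement is off by default. `extractTrace()` refits the
Gaussian at a fixed position per frame and reports the
background-subtracted peak volume 2π·A·σ² as the intensity (per-frame
shape refit by default, frozen σ optional). `selectTraces()` keeps
molecules with signal in both channels, donor–acceptor anticorrelation
(Pearson r ≤ −0.3 over the pre-bleach segment; no community-standard value
exists, so the threshold is exposed) and at most a single bleach step.

## Trace idealization

FRET efficiency is `E = I_A / (I_A + I_D)` per frame, clipped to [0, 1],
with no gamma or donor-leakage correction (none is applied to the data
this emulates). Traces are truncated at the first detected photobleach —
a two-segment change-point on each channel that requires a sustained
collapse to background.

One Gaussian-emission hidden Markov model is fitted per condition by
Baum–Welch across all traces pooled (`fitHmm()`): histograms, transition
density plots and populations are ensemble-level quantities, so a shared
model is the consistent choice. The number of states is fixed at three by
default; `selectHmmStates()` offers BIC selection over 1–4 states for
constructs whose centres shift. Numerical choices: emission means are
initialized by k-means on a (deterministic) subsample — quantile seeding
is offered but fails when state occupancies are strongly skewed; the EM
tolerance is ΔlogL < 10⁻⁴; emission s.d. is floored at 10⁻³ so noiseless
test data cannot collapse the likelihood; states are relabelled by
ascending mean so L < I < H regardless of initialization. The
log-likelihood is asserted non-decreasing in the test suite.

Idealized paths are Viterbi decodes (posterior decoding available). At
decode time, hard zeros in the fitted initial distribution and transition
matrix are floored at 10⁻¹² — a model trained on traces that all start
unfolded would otherwise forbid a new trace from starting folded.

`fitStatePopulations()` fits a three-Gaussian mixture to the pooled FRET
values (unequal variances, falling back to equal variances if a component
collapses); the fractional population of a state is its mixture weight.
The test suite checks these weights against Viterbi frame occupancy — two
estimators of the same quantity that must agree on well-separated data.

## Dwell times, rates and energies

`extractDwells()` merges consecutive same-state frames into dwells and
counts every observed state change. The first and last dwell of each
trace are censored (their true length is unknown) and excluded from
lifetime fits — standard single-molecule practice. Lifetimes are fitted
per state from the uncensored dwell distribution; the default estimator
is the exponential MLE (τ = mean dwell), with a binned least-squares
alternative since binned fitting is common in this literature and the two
agree on clean data. Fewer than 25 uncensored dwells triggers a warning.

The six rate constants follow from the branching construction: for state
X with lifetime τ_X and exit counts n_XY, n_XZ,

    k_XY = (1 / τ_X) · n_XY / (n_XY + n_XZ)

so that `k_XY + k_XZ = 1/τ_X` holds exactly — an identity the tests
assert to machine precision. A state with no observed exits gets both
rates zero, flagged.

Relative free energies use detailed balance on rate pairs,
ΔG_b − ΔG_a = −k_BT·ln(k_ab / k_ba), with the unfolded L state as the
ground state (ΔG_L = 0) and T = 298.15 K (25 °C, k_BT = 0.5925 kcal/mol)
by default. ΔG_H can be built two ways — sequentially through I, or
directly from the H↔L pair. The sequential path is the estimate (the
folding pathway is sequential and the direct rates are poorly determined,
see below); the discrepancy between the two routes is reported as a
cycle-closure residual, which doubles as a detailed-balance diagnostic:
it vanishes (within estimation error) exactly when the generating rates
satisfy the Kolmogorov cycle condition, and both directions are tested.
Barrier heights are drawn with the convention −k_BT·ln(k) + 1.8·k_BT
(rates in s⁻¹). The offset fixes the zero of the barrier scale, so these
values are illustrative, for energy diagrams only; no barrier is drawn
for L→H, whose rate is too rarely observed to be reliable.

Transition density plots (`buildTdp()`) place one count per transition at
(mean FRET of the departing run, mean FRET of the arriving run), binned
at 0.02 on both axes and normalized by the total number of transitions;
the marginal counts agree exactly with the transition-count matrix.

## Titration analysis

Fractional populations versus Mg²⁺ are fitted with the Hill equation
f(c) = baseline + amplitude·cⁿ/(Kⁿ + cⁿ) (`fitHill()`), decreasing
titrations via negative amplitude. Only the H- and L-state fractions are
fitted — the intermediate's occupancy is not a saturating function of
Mg²⁺ and the fit is refused unless explicitly overridden. A flat
titration leaves K and n unidentifiable and is returned flagged rather
than fitted. The critical Mg²⁺ concentration — the lowest concentration
at which the fitted H fraction exceeds the L fraction — is located by
bisection on the two curves (`criticalMg()`), with boundary flags when
the curves do not cross in range.

`runTitrationAnalysis()` composes all of the above per condition and
across conditions, returns a manifest in which every number traces back
to the configuration and seed, and `validateAgainstTruth()` tabulates
recovery errors on synthetic runs.

## Xrn1 decay kinetics

Decay traces are normalized to the minus-enzyme control,
F = (F_exp,t/F_exp,0)/(F_con,t/F_con,0), which cancels any drift shared
by the two wells exactly (asserted algebraically and numerically) and
anchors F(0) = 1. The normalized curve is fitted with a single
exponential, plateau fixed at zero by default; a free-plateau mode exists
because strongly resistant constructs level off at their protected
fraction, and the fixed-plateau fit then underestimates the rate — a
documented caveat, not a default. One consequence of the t = 0 anchoring
is worth knowing: noise in the two t = 0 readings becomes a common scale
error on the whole normalized curve, so single-replicate rate estimates
scatter more than the nominal fit standard error suggests, while the
ensemble mean is unbiased — the test suite checks exactly that. Construct
rates are divided by the malachite-green-aptamer control rate at matched
Mg²⁺ (`relativeRate()`), removing the Mg²⁺ dependence of Xrn1 activity
itself. `correlateSeries()` provides the Pearson correlation reports
(optionally on log axes; linear is the default since no transform is
canonical) used to relate decay rates to H-state fractions, transition
rates, or ΔG_H across constructs.

## SAXS metrics

`guinierFit()` performs the weighted linear fit of ln I versus q² over
the largest low-q window with q·R_g ≤ 1.3 (the community convention for
folded RNA), iterated to self-consistency; R_g = √(−3·slope). The
dimensionless Kratky transform (qR_g)²·I(q)/I(0) versus qR_g is
parameter-free for an ideal Guinier curve — peak at √3, height 3/e — which
the tests assert numerically; compact folded RNA appears as a bell-shaped
peak near that point. Pair-distance distributions and ab initio shape
reconstruction are left to the dedicated external tools.

## Missed-event bias: what the recovery suite shows

With camera integration on (the realistic default), a direct L↔H jump
produces one blurred frame whose apparent FRET lies between the L and H
centres — squarely in the I emission band about half the time. The
Viterbi decode then inserts a spurious one-frame I visit, and the direct
transition is recorded as L→I→H. The four sequential-pathway rates are
recovered within the recovery suite's 15% bound, but the two rare direct
rates `k_LH` and `k_HL` are systematically undercounted well beyond it;
in the oracle (instantaneous-sampling) mode the same estimator recovers
all six rates, isolating camera blur as the cause. Correcting this
properly requires missed-event/dead-time modelling, which is out of scope
here, and naive path cleanup (merging one-frame dwells) trades the
H-side bias for corruption of the short-lived L-state statistics, so no
such heuristic is applied. Practically: dwell-based direct-transition
rates at 25 ms resolution should be treated as lower bounds, which is
also why the free-energy landscape deliberately avoids the L↔H pair.

```{r blur-study}
## the comparison the recovery suite runs, in miniature
truth <- generatorRates(kLI = 2, kLH = 0.05, kIL = 1, kIH = 0.8,
                        kHL = 0.1, kHI = 0.4)
for (mode in c(TRUE, FALSE)) {   # integrate vs instantaneous
  set.seed(42)
  traces <- lapply(1:200, function(i)
    renderTrace(simulateStatePath(truth, 60), emissionModel(),
                integrate = mode))
  fret <- Filter(function(f) length(f) >= 10, lapply(traces, computeFret))
  model <- fitHmm(fret)
  ideal <- lapply(fret, function(f) idealizeTrace(model, f))
  print(round(abs(estimateRates(ideal)@rates - truth@rates) /
                truth@rates, 3))
}
```

## Problem sizes and determinism

The test suite validates recovery at 200 traces × 60 s (25 ms/frame) for
the rate suite and 100–300 traces for population and mixture checks —
sizes comparable to a per-condition single-molecule data set and chosen
so the whole suite completes in well under a minute of simulation per
check. All generators take explicit seeds; repeated runs of
`runTitrationAnalysis()` under one seed produce bit-identical manifests.

## Known limitations

* Gaussian channel noise, not photon statistics; no blinking, crosstalk
  or gamma calibration — estimates of absolute FRET centres on real data
  inherit whatever corrections were (not) applied upstream.
* Dwell-based rates carry missed-event bias at 25 ms resolution (above);
  only the direct L↔H rates are materially affected at the default
  kinetics.
* Channel registration is translation-only by default; optical systems
  with appreciable rotation or magnification mismatch need the rotation
  refinement or an external mapping.
* The Hill model is empirical; K and n are condition summaries, not
  binding constants.
* Passing synthetic-recovery tests demonstrates estimator correctness
  under this generative model, not the absence of instrument systematics
  in any particular real data set.
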