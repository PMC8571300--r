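# xrfret

Single-molecule FRET folding kinetics and Xrn1 decay analysis for
exoribonuclease-resistant RNAs (xrRNAs).

Flaviviral xrRNAs fold into a ring-like pseudoknotted structure that
blocks the 5'→3' exonuclease Xrn1. In smFRET experiments individual
dye-labelled xrRNA molecules interconvert among three conformations —
unfolded (L, E_FRET ≈ 0.3), intermediate (I, ≈ 0.5) and natively folded
(H, ≈ 0.9) — with Mg²⁺-dependent kinetics that determine exonuclease
resistance. This package is for single-molecule biophysicists who want a
tested, end-to-end implementation of that analysis: trace extraction from
TIRF movies, hidden Markov model idealization, dwell-time kinetics,
free-energy landscapes, Mg²⁺ titration analysis, fluorescence decay-rate
fitting and minimal SAXS foldedness metrics — plus a synthetic-data
generator with exact ground truth so every estimator is verifiable.

## The core quantities

From idealized three-state trajectories, with τ_X the exponential
lifetime of state X and n_XY the number of observed X→Y transitions, the
six rate constants are

    k_XY = (1 / τ_X) · n_XY / (n_XY + n_XZ),   X, Y, Z ∈ {L, I, H}

so k_XY + k_XZ = 1/τ_X exactly. Relative free energies follow from
detailed balance on rate pairs,

    ΔG_b − ΔG_a = −k_B T · ln(k_ab / k_ba),      ΔG_L ≡ 0,

with barriers drawn as −k_B T·ln(k) + 1.8 k_B T for illustration. Decay
assays are normalized to minus-enzyme controls,
F = (F_exp,t/F_exp,0)/(F_con,t/F_con,0), and fitted with a single
exponential; titrations use the Hill equation; SAXS curves get Guinier
fits (q·R_g ≤ 1.3) and dimensionless Kratky transforms.

## Worked example

Simulate an ensemble at known rates, run the full pipeline, and compare:

```r
library(xrfret)
truth <- generatorRates(kLI = 2, kLH = 0.05, kIL = 1, kIH = 0.8,
                        kHL = 0.1, kHI = 0.4)     # s^-1
set.seed(1)
traces <- lapply(1:60, function(i)
  renderTrace(simulateStatePath(truth, 30), emissionModel(),
              id = sprintf("mol%02d", i)))
fret  <- Filter(function(f) length(f) >= 10, lapply(traces, computeFret))
model <- fitHmm(fret)
model
#> HmmModel: 3 states, logLik 81471.55 (converged)
#>   means: 0.300 0.500 0.900
#>   sds:   0.055 0.052 0.060
ideal <- lapply(fret, function(f) idealizeTrace(model, f))
rates <- estimateRates(ideal)
rates
#> RateSet (s^-1):
#>  transition      k     se
#>          LI 1.9126 0.0853
#>          LH 0.0222 0.0091
#>          IL 1.0370 0.0482
#>          IH 0.8243 0.0429
#>          HL 0.0628 0.0093
#>          HI 0.4480 0.0256
freeEnergyLandscape(rates)
#> EnergyLandscape at 298.15 K (kBT = 0.5925 kcal/mol)
#>   dG (kcal/mol): L = 0.000, I = -0.363, H = -0.724
#>   cycle-closure residual: 1.339 kcal/mol
```

The fitted emission means land on the generating centres (0.3/0.5/0.9)
and the four sequential-pathway rates match the truth within a few
percent. The two rare direct rates (k_LH, k_HL) are undercounted because
camera integration blurs direct L↔H jumps into apparent one-frame I
visits — a known missed-event effect at 25 ms resolution, analysed in the
methods vignette (`vignettes/xrfret-methods.Rmd`); the free-energy
construction therefore uses the sequential L↔I and I↔H pairs, with I and
H stabilized here by −0.36 and −0.72 kcal/mol relative to the unfolded
state. `runTitrationAnalysis()` composes the same steps across Mg²⁺
conditions and adds Hill fits and the critical Mg²⁺ concentration;
`normalizeDecay()`/`fitDecayRate()` and `guinierFit()`/
`dimensionlessKratky()` cover the decay and SAXS branches.

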