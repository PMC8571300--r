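#' @import methods
NULL

## State labels are fixed throughout: the low- (~0.3), intermediate- (~0.5)
## and high-FRET (~0.9) conformations of the xrRNA, stored internally as
## integer codes 1/2/3.
STATE_LABELS <- c("L", "I", "H")

## Ordered labels for the six allowed transitions, matching the rate symbols
## k_{L-I}, k_{L-H}, k_{I-L}, k_{I-H}, k_{H-L}, k_{H-I}.
RATE_NAMES <- c("LI", "LH", "IL", "IH", "HL", "HI")

## Boltzmann constant in kcal/(mol K)
KB_KCAL <- 1.987204259e-3

#' Ground-truth transition rate constants for the three-state model
#'
#' Holds the six rate constants (per second) governing transitions among the
#' low (L), intermediate (I) and high (H) FRET conformational states. Used
#' as the generator of synthetic state paths and as the ground-truth twin of
#' the rate constants the analysis pipeline estimates.
#'
#' @slot rates named numeric of length 6 with names
#'   \code{c("LI","LH","IL","IH","HL","HI")}, in s^-1.
#' @export
setClass("GeneratorRates", representation(rates = "numeric"))

setValidity("GeneratorRates", function(object) {
  r <- object@rates
  if (length(r) != 6L || !identical(names(r), RATE_NAMES))
    return("rates must be a named numeric of length 6 (LI, LH, IL, IH, HL, HI)")
  if (any(!is.finite(r)) || any(r < 0))
    return("all rates must be finite and >= 0")
  if (sum(r) <= 0)
    return("at least one rate must be positive")
  ## a state with zero total exit rate is allowed at construction; the
  ## simulator rejects paths that would start in (or reach) it
  TRUE
})

#' Magnesium-dependent rate law
#'
#' Power-law (log-linear in log concentration) dependence of each rate on
#' the Mg2+ concentration: k(c) = k_ref * (c / refMg)^(-exponent). Positive
#' exponents make a rate decrease with Mg2+, as observed for the unfolding
#' rates k_HI and k_IL; exponents of 0 leave a rate constant.
#'
#' @slot baseRates a \linkS4class{GeneratorRates} at the reference
#'   concentration.
#' @slot exponents named numeric of length 6 (same names as the rates).
#' @slot refMg reference Mg2+ concentration in mM.
#' @export
setClass("MgRateLaw",
         representation(baseRates = "GeneratorRates",
                        exponents = "numeric",
                        refMg = "numeric"))

setValidity("MgRateLaw", function(object) {
  if (!identical(names(object@exponents), RATE_NAMES))
    return("exponents must be named LI, LH, IL, IH, HL, HI")
  if (object@refMg <= 0) return("refMg must be > 0")
  TRUE
})

#' Camera emission model for rendering FRET traces
#'
#' @slot means per-state mean FRET efficiency, strictly increasing, in [0,1].
#' @slot totalIntensity total (donor + acceptor) intensity per frame, in
#'   arbitrary camera units.
#' @slot channelNoiseSd additive Gaussian noise s.d. per channel.
#' @slot donorBleachRate,acceptorBleachRate single-step photobleaching rates
#'   in s^-1 (0 disables bleaching of that channel).
#' @slot background per-channel background level after bleaching.
#' @export
setClass("EmissionModel",
         representation(means = "numeric", totalIntensity = "numeric",
                        channelNoiseSd = "numeric",
                        donorBleachRate = "numeric",
                        acceptorBleachRate = "numeric",
                        background = "numeric"))

setValidity("EmissionModel", function(object) {
  m <- object@means
  if (any(diff(m) <= 0)) return("state means must be strictly increasing (L < I < H)")
  if (any(m < 0 | m > 1)) return("state means must lie in [0, 1]")
  if (object@channelNoiseSd < 0) return("channelNoiseSd must be >= 0")
  if (object@totalIntensity <= 0) return("totalIntensity must be > 0")
  if (object@donorBleachRate < 0 || object@acceptorBleachRate < 0)
    return("bleach rates must be >= 0")
  TRUE
})

#' Continuous-time state path
#'
#' Exact jump trajectory from the Gillespie simulation: contiguous,
#' non-overlapping dwell segments covering [0, duration].
#'
#' @slot state integer codes (1 = L, 2 = I, 3 = H) per segment.
#' @slot entry,exit segment boundaries in seconds.
#' @slot duration total simulated time in seconds.
#' @export
setClass("StatePath",
         representation(state = "integer", entry = "numeric",
                        exit = "numeric", duration = "numeric"))

setValidity("StatePath", function(object) {
  n <- length(object@state)
  if (length(object@entry) != n || length(object@exit) != n)
    return("state, entry and exit must have equal length")
  if (n == 0L) return("path must contain at least one segment")
  if (abs(object@entry[1]) > 1e-12) return("first segment must start at 0")
  if (abs(object@exit[n] - object@duration) > 1e-9)
    return("last segment must end at duration")
  if (n > 1L) {
    if (any(abs(object@entry[-1] - object@exit[-n]) > 1e-9))
      return("segments must be contiguous")
    if (any(object@state[-1] == object@state[-n]))
      return("consecutive segments must differ in state")
  }
  if (any(object@exit <= object@entry)) return("segments must have positive length")
  TRUE
})

#' Dual-channel fluorescence trace of one molecule
#'
#' @slot time frame mid-point times in seconds (uniformly spaced).
#' @slot donor,acceptor per-frame intensities.
#' @slot frameInterval frame interval in seconds (default acquisition is
#'   0.025 s per frame).
#' @slot truthState integer ground-truth state per frame (majority-occupancy
#'   state), NA when unknown (real data).
#' @slot truthBleach named numeric: ground-truth donor/acceptor bleach times
#'   in seconds (Inf if the channel never bleached).
#' @slot id trace identifier.
#' @export
setClass("FretTrace",
         representation(time = "numeric", donor = "numeric",
                        acceptor = "numeric", frameInterval = "numeric",
                        truthState = "integer", truthBleach = "numeric",
                        id = "character"))

setValidity("FretTrace", function(object) {
  n <- length(object@time)
  if (length(object@donor) != n || length(object@acceptor) != n)
    return("time, donor and acceptor must have equal length")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  if (n > 1L) {
    dt <- diff(object@time)
    if (any(abs(dt - object@frameInterval) > 1e-6 * object@frameInterval))
      return("times must be uniformly spaced at frameInterval")
  }
  if (length(object@truthState) && length(object@truthState) != n)
    return("truthState must be empty or one value per frame")
  TRUE
})

#' Fitted Gaussian-emission hidden Markov model
#'
#' One model is shared by all traces of a condition (an ensemble-level fit).
#' States are relabelled by ascending emission mean so that state 1/2/3
#' always map to L/I/H.
#'
#' @slot nStates number of hidden states.
#' @slot means,sds per-state emission mean and s.d. on the FRET axis.
#' @slot transMat per-frame state transition probability matrix (rows sum
#'   to 1).
#' @slot initProb initial state distribution.
#' @slot logLik final log-likelihood; \code{logLikTrace} the per-iteration
#'   log-likelihoods (non-decreasing).
#' @slot converged logical; \code{flags} character vector of warnings such
#'   as degenerate (near-empty) states.
#' @export
setClass("HmmModel",
         representation(nStates = "integer", means = "numeric",
                        sds = "numeric", transMat = "matrix",
                        initProb = "numeric", logLik = "numeric",
                        logLikTrace = "numeric", converged = "logical",
                        flags = "character"))

setValidity("HmmModel", function(object) {
  K <- object@nStates
  if (length(object@means) != K || length(object@sds) != K)
    return("means and sds must have nStates entries")
  if (is.unsorted(object@means, strictly = TRUE))
    return("emission means must be sorted strictly ascending")
  if (any(object@sds <= 0)) return("emission s.d. must be > 0")
  if (!all(dim(object@transMat) == c(K, K)))
    return("transMat must be nStates x nStates")
  if (any(abs(rowSums(object@transMat) - 1) > 1e-8))
    return("transition matrix rows must sum to 1")
  TRUE
})

#' Idealized (state-labelled) trace
#'
#' @slot states per-frame Viterbi (or posterior-mode) state codes.
#' @slot fret per-frame FRET efficiency used for decoding.
#' @slot stateMeans fitted state means of the model that produced the path.
#' @slot id source trace identifier.
#' @export
setClass("IdealizedTrace",
         representation(states = "integer", fret = "numeric",
                        stateMeans = "numeric", id = "character"))

setValidity("IdealizedTrace", function(object) {
  if (length(object@states) != length(object@fret))
    return("states and fret must have equal length")
  K <- length(object@stateMeans)
  if (length(object@states) &&
      (min(object@states) < 1L || max(object@states) > K))
    return("state codes must index into stateMeans")
  TRUE
})

#' Pooled FRET histogram
#'
#' Normalized by the total number of FRET data points, so frequencies sum
#' to 1.
#'
#' @slot breaks bin edges on [0, 1].
#' @slot frequency normalized per-bin frequency.
#' @slot nMolecules,nPoints number of traces and pooled frames.
#' @export
setClass("FretHistogram",
         representation(breaks = "numeric", frequency = "numeric",
                        nMolecules = "integer", nPoints = "integer"))

setValidity("FretHistogram", function(object) {
  if (length(object@frequency) != length(object@breaks) - 1L)
    return("frequency must have one entry per bin")
  if (object@nPoints > 0L && abs(sum(object@frequency) - 1) > 1e-8)
    return("frequencies must sum to 1")
  TRUE
})

#' Gaussian-mixture state populations
#'
#' @slot centers,widths,fractions per-component Gaussian centre, s.d. and
#'   fractional population (mixture weight), centres ascending.
#' @slot condition Mg2+ concentration label in mM (NA when unspecified).
#' @slot source "mixture" or "occupancy" (frame-count fractions).
#' @slot flags degenerate-component warnings.
#' @export
setClass("StatePopulations",
         representation(centers = "numeric", widths = "numeric",
                        fractions = "numeric", condition = "numeric",
                        source = "character", flags = "character"))

setValidity("StatePopulations", function(object) {
  if (is.unsorted(object@centers)) return("centers must be ascending")
  if (abs(sum(object@fractions) - 1) > 1e-6)
    return("fractions must sum to 1 (within 1e-6)")
  TRUE
})

#' Dwell records and transition counts extracted from idealized traces
#'
#' @slot records data.frame with columns state (factor L/I/H), duration (s),
#'   traceId, censoredFirst, censoredLast. Dwells touching either end of a
#'   trace are censored and excluded from lifetime fits.
#' @slot counts 3x3 integer matrix of observed transitions (row = from,
#'   col = to, diagonal zero).
#' @slot frameInterval frame interval of the source traces (s).
#' @export
setClass("DwellSet",
         representation(records = "data.frame", counts = "matrix",
                        frameInterval = "numeric"))

setValidity("DwellSet", function(object) {
  if (!all(dim(object@counts) == c(3L, 3L)))
    return("counts must be a 3x3 matrix")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (any(diag(object@counts) != 0)) return("self-transitions are not counted")
  TRUE
})

#' State lifetimes from exponential dwell-time fits
#'
#' @slot tau lifetimes tau_L, tau_I, tau_H in seconds.
#' @slot se fit standard errors; \code{nDwells} uncensored dwells used.
#' @slot estimator "mle" (tau = mean dwell) or "binned-lsq".
#' @slot flags e.g. "resolution-limited" states.
#' @export
setClass("LifetimeSet",
         representation(tau = "numeric", se = "numeric",
                        nDwells = "integer", estimator = "character",
                        flags = "character"))

setValidity("LifetimeSet", function(object) {
  if (!identical(names(object@tau), STATE_LABELS))
    return("tau must be named L, I, H")
  if (any(!is.na(object@tau) & object@tau <= 0))
    return("lifetimes must be > 0")
  TRUE
})

#' Estimated transition rate constants
#'
#' The six rates obey the algebraic identity
#' k_XY + k_XZ = 1/tau_X exactly, by construction.
#'
#' @slot rates named numeric (LI, LH, IL, IH, HL, HI), s^-1.
#' @slot se propagated standard errors.
#' @slot lifetimes the \linkS4class{LifetimeSet} provenance.
#' @slot counts the transition-count matrix provenance.
#' @slot flags states with no observed exits, etc.
#' @export
setClass("RateSet",
         representation(rates = "numeric", se = "numeric",
                        lifetimes = "LifetimeSet", counts = "matrix",
                        flags = "character"))

setValidity("RateSet", function(object) {
  if (!identical(names(object@rates), RATE_NAMES))
    return("rates must be named LI, LH, IL, IH, HL, HI")
  if (any(!is.na(object@rates) & object@rates < 0))
    return("rates must be >= 0")
  TRUE
})

#' Relative free-energy landscape of the three conformational states
#'
#' The low-FRET (unfolded) state is the ground state, dG_L = 0. dG_I comes
#' from the L-I rate pair and dG_H is built sequentially (L-I then I-H),
#' following the sequential folding pathway; the direct H-L pair provides a
#' detailed-balance closure diagnostic.
#'
#' @slot dG named numeric (L, I, H) in kcal/mol, dG["L"] == 0.
#' @slot barriers illustrative barrier heights -kBT ln(k) + 1.8 kBT in
#'   kcal/mol for the transitions L->I, I->L, I->H, H->I, H->L (the L->H
#'   barrier is not computed; that rate is too rarely observed to be
#'   reliable).
#' @slot temperature temperature in K; \code{kBT} in kcal/mol.
#' @slot closure cycle-closure residual in kcal/mol: dG_H via the direct
#'   H-L pair minus dG_H via the sequential path.
#' @export
setClass("EnergyLandscape",
         representation(dG = "numeric", barriers = "numeric",
                        temperature = "numeric", kBT = "numeric",
                        closure = "numeric"))

setValidity("EnergyLandscape", function(object) {
  if (!identical(names(object@dG), STATE_LABELS))
    return("dG must be named L, I, H")
  if (abs(object@dG[["L"]]) > 1e-12) return("dG_L must be 0 (ground state)")
  TRUE
})

#' Transition density plot (TDP)
#'
#' 2D normalized histogram of (FRET before transition, FRET after
#' transition) over all transition events; entries sum to 1.
#'
#' @slot density matrix of fractions; \code{breaks} shared bin edges on
#'   [0,1]; \code{nTransitions} total events.
#' @export
setClass("TDP",
         representation(density = "matrix", breaks = "numeric",
                        nTransitions = "integer"))

setValidity("TDP", function(object) {
  if (object@nTransitions > 0L && abs(sum(object@density) - 1) > 1e-8)
    return("TDP entries must sum to 1")
  TRUE
})

#' Hill-equation fit of a fractional population versus Mg2+
#'
#' f(c) = baseline + amplitude * c^n / (K^n + c^n); decreasing titrations
#' are fitted with negative amplitude.
#'
#' @slot params named numeric: amplitude, K (mM), n, baseline.
#' @slot se per-parameter standard errors.
#' @slot state which state's fractions were fitted ("H" or "L").
#' @slot converged logical; \code{flags} degenerate-fit notes.
#' @export
setClass("HillFit",
         representation(params = "numeric", se = "numeric",
                        state = "character", converged = "logical",
                        flags = "character"))

setValidity("HillFit", function(object) {
  p <- object@params
  need <- c("amplitude", "K", "n", "baseline")
  if (!all(need %in% names(p))) return("params must contain amplitude, K, n, baseline")
  if (is.finite(p[["K"]]) && p[["K"]] <= 0) return("K must be > 0")
  TRUE
})

#' Xrn1 decay time course (experimental and minus-enzyme control)
#'
#' @slot time time in minutes after Xrn1 addition.
#' @slot fexp,fcon fluorescence of the +Xrn1 and -Xrn1 wells.
#' @slot condition list with entries such as construct and mg (mM).
#' @export
setClass("DecayTrace",
         representation(time = "numeric", fexp = "numeric",
                        fcon = "numeric", condition = "list"))

setValidity("DecayTrace", function(object) {
  n <- length(object@time)
  if (length(object@fexp) != n || length(object@fcon) != n)
    return("time, fexp and fcon must have equal length")
  i0 <- which.min(abs(object@time))
  if (n && (object@fexp[i0] <= 0 || object@fcon[i0] <= 0))
    return("fluorescence at t = 0 must be > 0 in both wells")
  TRUE
})

#' Single-exponential decay-rate fit
#'
#' @slot rate decay rate in min^-1; \code{se} its standard error.
#' @slot plateau fitted plateau (0 unless freed).
#' @slot r2 coefficient of determination; \code{flags} e.g. negative-rate.
#' @export
setClass("DecayFit",
         representation(rate = "numeric", se = "numeric",
                        plateau = "numeric", r2 = "numeric",
                        flags = "character"))

#' Small-angle X-ray scattering curve
#'
#' @slot q momentum transfer in inverse Angstrom, strictly ascending and
#'   positive (a leading q = 0 point is allowed for ideal curves).
#' @slot I intensity (arbitrary units); \code{sigma} uncertainties.
#' @export
setClass("ScatteringCurve",
         representation(q = "numeric", I = "numeric", sigma = "numeric"))

setValidity("ScatteringCurve", function(object) {
  if (length(object@I) != length(object@q))
    return("q and I must have equal length")
  if (any(object@q < 0) || is.unsorted(object@q, strictly = TRUE))
    return("q must be non-negative and strictly ascending")
  if (any(!is.finite(object@I))) return("intensities must be finite")
  TRUE
})

#' Guinier fit result
#'
#' @slot Rg radius of gyration (Angstrom) and \code{RgSe} its s.e.
#' @slot I0 forward scattering intensity and \code{I0Se} its s.e.
#' @slot qRange fitted q window; \code{qRgMax} q_max * Rg at the window end.
#' @slot nPoints points used.
#' @export
setClass("GuinierResult",
         representation(Rg = "numeric", RgSe = "numeric", I0 = "numeric",
                        I0Se = "numeric", qRange = "numeric",
                        qRgMax = "numeric", nPoints = "integer"))

setValidity("GuinierResult", function(object) {
  if (object@Rg <= 0) return("Rg must be > 0")
  TRUE
})

#' Dual-channel registration result
#'
#' Translation (plus optional small rotation) mapping donor-channel spot
#' positions onto the acceptor channel, with the matched spot pairs.
#'
#' @slot dx,dy translation in pixels; \code{rotation} radians.
#' @slot pairs two-column matrix of (donor index, acceptor index).
#' @slot score fraction of votes in the modal translation bin.
#' @export
setClass("ChannelTransform",
         representation(dx = "numeric", dy = "numeric", rotation = "numeric",
                        pairs = "matrix", score = "numeric"))
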