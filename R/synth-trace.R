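#' Construct a camera emission model
#'
#' Defaults reproduce the acquisition conditions the package emulates:
#' state FRET centres 0.3 / 0.5 / 0.9, and a per-channel noise level chosen
#' so that the FRET-axis scatter is about 0.05 s.d. at the default total
#' intensity.
#'
#' @param means per-state FRET efficiency (ascending, in [0,1]).
#' @param totalIntensity donor + acceptor counts per frame.
#' @param channelNoiseSd additive Gaussian noise s.d. per channel;
#'   70 counts at total 1000 gives roughly 0.05 s.d. on the FRET axis.
#' @param donorBleachRate,acceptorBleachRate single-step photobleaching
#'   rates (s^-1); 0 disables.
#' @param background post-bleach background level.
#' @return an \linkS4class{EmissionModel}.
#' @export
emissionModel <- function(means = c(0.3, 0.5, 0.9), totalIntensity = 1000,
                          channelNoiseSd = 70, donorBleachRate = 0.01,
                          acceptorBleachRate = 0.005, background = 0) {
  new("EmissionModel", means = means, totalIntensity = totalIntensity,
      channelNoiseSd = channelNoiseSd, donorBleachRate = donorBleachRate,
      acceptorBleachRate = acceptorBleachRate, background = background)
}

#' Render a fluorescence trace from a continuous state path
#'
#' Emulates camera integration: each frame reports the occupancy-weighted
#' mean FRET over the frame window (so a jump at mid-frame produces an
#' averaged, "blurred" frame), converted to donor and acceptor intensities
#' with additive Gaussian channel noise. Photobleaching is single-step:
#' after acceptor bleach the donor recovers the full intensity and the
#' acceptor drops to background; after donor bleach both channels drop to
#' background.
#'
#' @param path a \linkS4class{StatePath}.
#' @param emission an \linkS4class{EmissionModel}.
#' @param frameInterval camera frame interval in seconds (default 0.025,
#'   i.e. 25 ms/frame).
#' @param seed optional integer seed.
#' @param integrate if FALSE, sample the state instantaneously at frame
#'   mid-points instead of integrating over the frame (oracle mode).
#' @param id trace identifier.
#' @return a \linkS4class{FretTrace} with per-frame ground-truth states
#'   (majority-occupancy state) and bleach times attached.
#' @export
renderTrace <- function(path, emission, frameInterval = 0.025, seed = NULL,
                        integrate = TRUE, id = "trace") {
  stopifnot(frameInterval > 0)
  validObject(path); validObject(emission)
  if (!is.null(seed)) set.seed(seed)
  nFrames <- max(1L, floor(path@duration / frameInterval))
  dt <- frameInterval
  fStart <- (seq_len(nFrames) - 1L) * dt
  fEnd <- fStart + dt
  mid <- fStart + dt / 2

  ## per-frame occupancy of each state (seconds within the frame)
  occ <- matrix(0, nFrames, 3L)
  for (i in seq_along(path@state)) {
    a <- path@entry[i]; b <- path@exit[i]
    lo <- max(1L, 1L + floor(a / dt + 1e-12))
    hi <- min(nFrames, 1L + floor((b - 1e-12) / dt))
    if (lo > hi) next
    idx <- lo:hi
    ov <- pmin(fEnd[idx], b) - pmax(fStart[idx], a)
    occ[idx, path@state[i]] <- occ[idx, path@state[i]] + ov
  }
  occ <- occ / rowSums(occ)

  if (integrate) {
    efret <- as.vector(occ %*% emission@means)
  } else {
    atMid <- vapply(mid, function(t) {
      path@state[max(which(path@entry <= t + 1e-12))]
    }, integer(1))
    efret <- emission@means[atMid]
  }
  truthState <- max.col(occ, ties.method = "first")

  tDonor <- if (emission@donorBleachRate > 0)
    stats::rexp(1L, emission@donorBleachRate) else Inf
  tAcceptor <- if (emission@acceptorBleachRate > 0)
    stats::rexp(1L, emission@acceptorBleachRate) else Inf

  I <- emission@totalIntensity
  bg <- emission@background
  donor <- I * (1 - efret)
  acceptor <- I * efret
  aDead <- mid >= tAcceptor
  donor[aDead] <- I               # no transfer once the acceptor is gone
  acceptor[aDead] <- bg
  dDead <- mid >= tDonor
  donor[dDead] <- bg
  acceptor[dDead] <- bg
  if (emission@channelNoiseSd > 0) {
    donor <- donor + stats::rnorm(nFrames, 0, emission@channelNoiseSd)
    acceptor <- acceptor + stats::rnorm(nFrames, 0, emission@channelNoiseSd)
  }

  new("FretTrace", time = mid, donor = donor, acceptor = acceptor,
      frameInterval = dt, truthState = truthState,
      truthBleach = c(donor = tDonor, acceptor = tAcceptor), id = id)
}

#' Simulate a Mg2+ titration series of FRET traces
#'
#' For each concentration, evaluates the rate law, simulates \code{nTraces}
#' exact state paths and renders them with the emission model, keeping the
#' ground-truth rates alongside. Warns when any generating rate exceeds
#' 0.2 / frameInterval, beyond which trace idealization becomes unreliable.
#'
#' @param rateLaw an \linkS4class{MgRateLaw}, or a single
#'   \linkS4class{GeneratorRates} used for every concentration.
#' @param mgConcs Mg2+ concentrations in mM (>= 1 value).
#' @param nTraces traces per concentration (0 gives an empty set).
#' @param duration per-trace duration in seconds.
#' @param emission an \linkS4class{EmissionModel}.
#' @param frameInterval seconds per frame.
#' @param seed integer seed; the whole set is reproducible from it.
#' @return list of conditions, each a list with elements \code{mg},
#'   \code{truthRates} (\linkS4class{GeneratorRates}) and \code{traces}
#'   (list of \linkS4class{FretTrace}).
#' @export
simulateTitration <- function(rateLaw, mgConcs, nTraces = 100L,
                              duration = 60, emission = emissionModel(),
                              frameInterval = 0.025, seed = NULL) {
  stopifnot(length(mgConcs) >= 1L, nTraces >= 0L)
  if (!is.null(seed)) set.seed(seed)
  lapply(mgConcs, function(mg) {
    rts <- if (is(rateLaw, "MgRateLaw")) ratesAt(rateLaw, mg) else rateLaw
    if (any(rts@rates > 0.2 / frameInterval))
      warning(sprintf(
        "at %g mM a generating rate exceeds 0.2/frameInterval (%.3g s^-1); ",
        mg, 0.2 / frameInterval),
        "dwell-based rate estimates will be unreliable")
    traces <- if (nTraces > 0L) lapply(seq_len(nTraces), function(i) {
      p <- simulateStatePath(rts, duration)
      renderTrace(p, emission, frameInterval,
                  id = sprintf("mg%g_t%03d", mg, i))
    }) else list()
    list(mg = mg, truthRates = rts, traces = traces)
  })
}

setMethod("show", "FretTrace", function(object) {
  cat(sprintf("FretTrace '%s': %d frames at %.3g s/frame (%.3g s total)\n",
              object@id, length(object@time), object@frameInterval,
              length(object@time) * object@frameInterval))
})
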