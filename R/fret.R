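#' Detect a single-step photobleach by change-point analysis
#'
#' Scans each channel for the best two-segment constant fit (least
#' squares). A change point is called a bleach when the drop is a sustained
#' single step: the post-step mean falls below a fraction of the pre-step
#' mean (donor bleach: both channels collapse; acceptor bleach: the
#' acceptor collapses while the donor rises).
#'
#' @param trace a \linkS4class{FretTrace}.
#' @param dropFraction post/pre mean ratio below which a step counts as a
#'   bleach.
#' @param minSegment shortest segment (frames) considered on either side.
#' @return integer index of the first post-bleach frame, or NA if no
#'   bleach is detected.
#' @export
detectBleach <- function(trace, dropFraction = 0.25, minSegment = 5L) {
  n <- length(trace@time)
  if (n < 2L * minSegment) return(NA_integer_)
  total <- mean(trace@donor + trace@acceptor)

  stepDown <- function(x) {
    ## best split of x into two constant segments, via cumulative sums
    cs <- cumsum(x); cs2 <- cumsum(x^2)
    k <- minSegment:(n - minSegment)           # last index of segment 1
    m1 <- cs[k] / k
    m2 <- (cs[n] - cs[k]) / (n - k)
    sse <- (cs2[n]) - (k * m1^2 + (n - k) * m2^2)
    i <- which.min(sse)
    list(split = k[i] + 1L, pre = m1[i], post = m2[i])
  }

  candidates <- integer(0)
  for (channel in list(trace@acceptor, trace@donor)) {
    st <- stepDown(channel)
    if (st$pre > 0.1 * total &&
        st$post < dropFraction * st$pre &&
        st$post < 0.15 * total)
      candidates <- c(candidates, st$split)
  }
  if (length(candidates) == 0L) NA_integer_ else min(candidates)
}

#' Compute the FRET efficiency series of a trace
#'
#' E = I_A / (I_A + I_D) per frame, with no gamma or donor-leakage
#' corrections. Frames after the (detected or ground-truth) bleach are
#' excluded, frames whose total intensity is non-positive are masked, and
#' values are clipped to [0, 1].
#'
#' @param trace a \linkS4class{FretTrace}.
#' @param bleach "detect" (change-point, the default), "truth" (use the
#'   simulator's bleach times), or "none".
#' @return numeric vector of FRET efficiencies for the retained frames,
#'   with attributes \code{frames} (their indices in the source trace) and
#'   \code{bleachFrame} (first excluded frame, NA if none).
#' @export
computeFret <- function(trace, bleach = c("detect", "truth", "none")) {
  bleach <- match.arg(bleach)
  n <- length(trace@time)
  cut <- switch(bleach,
    detect = detectBleach(trace),
    truth = {
      tb <- min(trace@truthBleach)
      if (is.finite(tb)) which(trace@time >= tb)[1] else NA_integer_
    },
    none = NA_integer_)
  end <- if (is.na(cut)) n else cut - 1L
  if (end < 1L) stop("no frames remain before the bleach")
  idx <- seq_len(end)
  total <- trace@donor[idx] + trace@acceptor[idx]
  valid <- total > 0
  if (!any(valid)) stop("no frame with positive total intensity")
  e <- pmin(1, pmax(0, trace@acceptor[idx][valid] / total[valid]))
  structure(e, frames = idx[valid], bleachFrame = cut)
}

#' Build a pooled FRET histogram
#'
#' Per-frame FRET values from all traces are pooled and binned on [0, 1];
#' frequencies are normalized by the total number of FRET data points so
#' they sum to 1. Warns when fewer than \code{minMolecules} traces
#' contribute (ensemble histograms are conventionally built from more than
#' 200 molecules).
#'
#' @param fretSeries list of FRET series (as from \code{\link{computeFret}})
#'   or a single numeric vector.
#' @param binWidth bin width on the FRET axis (default 0.02).
#' @param minMolecules molecule-count threshold for the warning.
#' @return a \linkS4class{FretHistogram}.
#' @export
buildHistogram <- function(fretSeries, binWidth = 0.02,
                           minMolecules = 200L) {
  if (is.numeric(fretSeries)) fretSeries <- list(fretSeries)
  stopifnot(length(fretSeries) > 0L)
  pooled <- unlist(fretSeries, use.names = FALSE)
  breaks <- seq(0, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- graphics::hist(pooled, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  nm <- length(fretSeries)
  if (nm < minMolecules)
    warning(sprintf("histogram built from %d molecules (< %d)", nm,
                    minMolecules))
  new("FretHistogram", breaks = breaks, frequency = counts / sum(counts),
      nMolecules = as.integer(nm), nPoints = length(pooled))
}

setMethod("show", "FretHistogram", function(object) {
  cat(sprintf("FretHistogram: %d bins, %d molecules, %d data points\n",
              length(object@frequency), object@nMolecules, object@nPoints))
})
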