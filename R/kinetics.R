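#' Extract dwell records and transition counts from idealized traces
#'
#' Consecutive same-state runs are merged into dwells. Every observed state
#' change is recorded as one transition. The first and last dwell of each
#' trace are flagged censored (their true duration is unknown) and are
#' excluded from lifetime fits downstream.
#'
#' @param idealizedTraces list of \linkS4class{IdealizedTrace} (or one).
#' @param frameInterval seconds per frame (default 0.025).
#' @return a \linkS4class{DwellSet}.
#' @export
extractDwells <- function(idealizedTraces, frameInterval = 0.025) {
  if (is(idealizedTraces, "IdealizedTrace"))
    idealizedTraces <- list(idealizedTraces)
  stopifnot(length(idealizedTraces) > 0L)
  counts <- matrix(0L, 3L, 3L, dimnames = list(STATE_LABELS, STATE_LABELS))
  recs <- vector("list", length(idealizedTraces))
  for (i in seq_along(idealizedTraces)) {
    tr <- idealizedTraces[[i]]
    if (length(tr@states) < 1L) next
    r <- rle(tr@states)
    nRun <- length(r$lengths)
    recs[[i]] <- data.frame(
      state = factor(STATE_LABELS[r$values], levels = STATE_LABELS),
      duration = r$lengths * frameInterval,
      traceId = tr@id,
      censoredFirst = seq_len(nRun) == 1L,
      censoredLast = seq_len(nRun) == nRun)
    if (nRun > 1L) {
      from <- r$values[-nRun]; to <- r$values[-1L]
      for (j in seq_along(from))
        counts[from[j], to[j]] <- counts[from[j], to[j]] + 1L
    }
  }
  new("DwellSet", records = do.call(rbind, recs), counts = counts,
      frameInterval = frameInterval)
}

#' Fit state lifetimes from dwell-time distributions
#'
#' Exponential fit of the uncensored dwell durations per state. The default
#' estimator is maximum likelihood (tau = mean dwell, s.e. = tau / sqrt(n));
#' "binned" performs least squares on a binned dwell histogram against
#' A exp(-t / tau).
#'
#' @param dwells a \linkS4class{DwellSet}.
#' @param estimator "mle" or "binned".
#' @param minDwells per-state dwell count below which a warning is issued
#'   (the fit is still returned).
#' @param binWidth histogram bin width in seconds for the binned estimator
#'   (default 2 frames).
#' @return a \linkS4class{LifetimeSet}. A state with no uncensored dwells
#'   gets tau = NA with a flag when it has no observed exits either;
#'   if exits were counted but no uncensored dwell exists, the lifetime is
#'   undefined while the rate equations need it, and that is an error.
#' @export
fitLifetimes <- function(dwells, estimator = c("mle", "binned"),
                         minDwells = 25L, binWidth = NULL) {
  estimator <- match.arg(estimator)
  rec <- dwells@records
  dt <- dwells@frameInterval
  if (is.null(binWidth)) binWidth <- 2 * dt
  tau <- se <- rep(NA_real_, 3L)
  names(tau) <- names(se) <- STATE_LABELS
  n <- integer(3L); names(n) <- STATE_LABELS
  flags <- character(0)
  for (s in STATE_LABELS) {
    inState <- rec$state == s
    d <- rec$duration[inState & !rec$censoredFirst & !rec$censoredLast]
    n[s] <- length(d)
    if (length(d) == 0L) {
      if (sum(dwells@counts[s, ]) > 0L)
        stop("state ", s, " has no uncensored dwells: lifetime undefined")
      flags <- c(flags, paste0(s, if (any(inState))
        ": only censored dwells" else ": never observed"))
      next
    }
    if (length(d) < minDwells)
      warning(sprintf("only %d uncensored dwells for state %s (< %d)",
                      length(d), s, minDwells))
    if (estimator == "mle" || length(d) < 10L) {
      tau[s] <- mean(d)
      se[s] <- tau[s] / sqrt(length(d))
    } else {
      br <- seq(0, max(d) + binWidth, by = binWidth)
      hh <- graphics::hist(d, breaks = br, plot = FALSE)
      keep <- hh$counts > 0
      df <- data.frame(t = hh$mids[keep], y = hh$counts[keep])
      fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                               start = list(A = max(df$y), tau = mean(d)),
                               lower = c(0, dt / 10))
      co <- summary(fit)$coefficients
      tau[s] <- co["tau", "Estimate"]
      se[s] <- co["tau", "Std. Error"]
    }
    if (all(d <= dt + 1e-12))
      flags <- c(flags, paste0(s, ": resolution-limited"))
  }
  new("LifetimeSet", tau = tau, se = se, nDwells = n,
      estimator = estimator, flags = flags)
}

#' Transition rate constants from lifetimes and transition counts
#'
#' Applies the six branching equations literally: for state X with
#' lifetime tau_X and exit counts n_XY, n_XZ,
#' k_XY = (1 / tau_X) * n_XY / (n_XY + n_XZ), so that
#' k_XY + k_XZ = 1 / tau_X exactly. A state with no observed exits gets
#' both rates 0 with a flag; a missing lifetime with nonzero exit counts is
#' an error.
#'
#' @param lifetimes a \linkS4class{LifetimeSet}.
#' @param counts 3x3 transition-count matrix (as in a
#'   \linkS4class{DwellSet}), or a \linkS4class{DwellSet}.
#' @return a \linkS4class{RateSet}.
#' @export
transitionRates <- function(lifetimes, counts) {
  if (is(counts, "DwellSet")) counts <- counts@counts
  stopifnot(all(dim(counts) == c(3L, 3L)))
  dimnames(counts) <- list(STATE_LABELS, STATE_LABELS)
  k <- se <- structure(rep(NA_real_, 6L), names = RATE_NAMES)
  flags <- character(0)
  for (s in STATE_LABELS) {
    others <- setdiff(STATE_LABELS, s)
    nExit <- counts[s, others]
    tot <- sum(nExit)
    pairNames <- paste0(s, others)
    if (tot == 0L) {
      k[pairNames] <- 0; se[pairNames] <- 0
      flags <- c(flags, paste0("no exits observed from ", s))
      next
    }
    tauS <- lifetimes@tau[[s]]
    if (is.na(tauS))
      stop("lifetime of state ", s,
           " is undefined but exit counts are nonzero")
    tauSe <- lifetimes@se[[s]]
    for (j in seq_along(others)) {
      b <- nExit[j] / tot
      k[pairNames[j]] <- b / tauS
      ## delta-method: binomial branching + lifetime uncertainty
      varB <- b * (1 - b) / tot
      se[pairNames[j]] <- if (b > 0)
        k[pairNames[j]] * sqrt(varB / b^2 + (tauSe / tauS)^2) else 0
    }
  }
  new("RateSet", rates = k, se = se, lifetimes = lifetimes,
      counts = counts, flags = flags)
}

#' Estimate the six transition rates from idealized traces
#'
#' Convenience wrapper: dwell extraction, lifetime fits and the branching
#' equations in one call.
#'
#' @inheritParams extractDwells
#' @inheritParams fitLifetimes
#' @return a \linkS4class{RateSet}.
#' @export
estimateRates <- function(idealizedTraces, frameInterval = 0.025,
                          estimator = "mle", minDwells = 25L) {
  dw <- extractDwells(idealizedTraces, frameInterval)
  lt <- fitLifetimes(dw, estimator = estimator, minDwells = minDwells)
  transitionRates(lt, dw)
}

#' Build a transition density plot
#'
#' Each transition contributes one count at (mean observed FRET of the
#' departing run, mean observed FRET of the arriving run); the 2D histogram
#' is normalized by the total number of transitions. The diagonal is empty
#' by construction (self-transitions do not exist).
#'
#' @param idealizedTraces list of \linkS4class{IdealizedTrace}.
#' @param binWidth bin width on both FRET axes (default 0.02).
#' @return a \linkS4class{TDP}.
#' @export
buildTdp <- function(idealizedTraces, binWidth = 0.02) {
  if (is(idealizedTraces, "IdealizedTrace"))
    idealizedTraces <- list(idealizedTraces)
  breaks <- seq(0, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  dens <- matrix(0, nb, nb)
  nTrans <- 0L
  for (tr in idealizedTraces) {
    r <- rle(tr@states)
    nRun <- length(r$lengths)
    if (nRun < 2L) next
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-nRun] + 1L)
    runMean <- vapply(seq_len(nRun), function(i)
      mean(tr@fret[starts[i]:ends[i]]), numeric(1))
    runMean <- pmin(pmax(runMean, 0), 1)
    from <- runMean[-nRun]; to <- runMean[-1L]
    bi <- pmin(pmax(findInterval(from, breaks, rightmost.closed = TRUE), 1L), nb)
    bj <- pmin(pmax(findInterval(to, breaks, rightmost.closed = TRUE), 1L), nb)
    for (t in seq_along(bi)) dens[bi[t], bj[t]] <- dens[bi[t], bj[t]] + 1
    nTrans <- nTrans + length(bi)
  }
  if (nTrans == 0L) {
    warning("no transitions: TDP is empty")
  } else {
    dens <- dens / nTrans
  }
  new("TDP", density = dens, breaks = breaks,
      nTransitions = as.integer(nTrans))
}

#' Sum the TDP mass in a state-pair corner
#'
#' Total TDP fraction with initial FRET within \code{halfWidth} of one
#' state centre and final FRET within \code{halfWidth} of another; used to
#' quantify, e.g., how rare direct L-H transitions are.
#'
#' @param tdp a \linkS4class{TDP}.
#' @param fromCenter,toCenter state centres on the FRET axis.
#' @param halfWidth half-width of the corner window.
#' @return the summed fraction.
#' @export
tdpCornerMass <- function(tdp, fromCenter, toCenter, halfWidth = 0.1) {
  mids <- (tdp@breaks[-1] + tdp@breaks[-length(tdp@breaks)]) / 2
  i <- abs(mids - fromCenter) <= halfWidth
  j <- abs(mids - toCenter) <= halfWidth
  sum(tdp@density[i, j])
}

setMethod("show", "DwellSet", function(object) {
  cat(sprintf("DwellSet: %d dwells, %d transitions\n",
              nrow(object@records), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "LifetimeSet", function(object) {
  cat("LifetimeSet (s), estimator =", object@estimator, "\n")
  print(data.frame(state = STATE_LABELS, tau = round(object@tau, 4),
                   se = round(object@se, 4), n = object@nDwells),
        row.names = FALSE)
})

setMethod("show", "RateSet", function(object) {
  cat("RateSet (s^-1):\n")
  print(data.frame(transition = RATE_NAMES,
                   k = round(object@rates, 4), se = round(object@se, 4)),
        row.names = FALSE)
  if (length(object@flags)) cat("flags:", object@flags, "\n")
})

setMethod("show", "TDP", function(object) {
  cat(sprintf("TDP: %d transitions over %d x %d bins\n",
              object@nTransitions, nrow(object@density),
              ncol(object@density)))
})
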