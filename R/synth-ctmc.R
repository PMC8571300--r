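#' Construct a set of ground-truth transition rates
#'
#' @param kLI,kLH,kIL,kIH,kHL,kHI rate constants in s^-1 for the six
#'   transitions among the L, I and H states.
#' @return a \linkS4class{GeneratorRates} object.
#' @examples
#' generatorRates(kLI = 2, kIL = 1, kIH = 0.8, kHI = 0.4, kHL = 0.1,
#'                kLH = 0.05)
#' @export
generatorRates <- function(kLI = 0, kLH = 0, kIL = 0, kIH = 0, kHL = 0,
                           kHI = 0) {
  new("GeneratorRates",
      rates = c(LI = kLI, LH = kLH, IL = kIL, IH = kIH, HL = kHL, HI = kHI))
}

#' @describeIn generatorRates extract the named rate vector.
#' @param object a \code{GeneratorRates}.
#' @export
rates <- function(object) object@rates

#' Generator (intensity) matrix of the three-state chain
#'
#' @param rates a \linkS4class{GeneratorRates}.
#' @return 3x3 matrix Q with off-diagonal entries the rates and rows summing
#'   to zero.
#' @export
rateMatrix <- function(rates) {
  r <- rates@rates
  Q <- matrix(0, 3, 3, dimnames = list(STATE_LABELS, STATE_LABELS))
  Q["L", "I"] <- r[["LI"]]; Q["L", "H"] <- r[["LH"]]
  Q["I", "L"] <- r[["IL"]]; Q["I", "H"] <- r[["IH"]]
  Q["H", "L"] <- r[["HL"]]; Q["H", "I"] <- r[["HI"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary distribution of the generating chain
#'
#' Solves pi Q = 0, sum(pi) = 1 for the long-run occupancies of the L, I and
#' H states; the reference against which empirical fractional populations
#' are checked.
#'
#' @param rates a \linkS4class{GeneratorRates}.
#' @return named numeric of length 3 summing to 1.
#' @export
stationaryDistribution <- function(rates) {
  Q <- rateMatrix(rates)
  A <- rbind(t(Q), rep(1, 3))
  b <- c(0, 0, 0, 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0     # round-off from transient states
  names(pi) <- STATE_LABELS
  pi / sum(pi)
}

#' Simulate an exact continuous-time state path (Gillespie algorithm)
#'
#' Dwell times in state X are exponential with mean 1 / (sum of X's exit
#' rates); the destination is drawn proportionally to the individual rates.
#'
#' @param rates a \linkS4class{GeneratorRates}.
#' @param duration total simulated time in seconds.
#' @param initialState "L", "I", "H", or "stationary" to draw from the
#'   stationary distribution.
#' @param seed optional integer seed for reproducibility.
#' @return a \linkS4class{StatePath}.
#' @export
simulateStatePath <- function(rates, duration, initialState = "stationary",
                              seed = NULL) {
  stopifnot(duration > 0)
  validObject(rates)
  if (!is.null(seed)) set.seed(seed)
  Q <- rateMatrix(rates)
  exit <- -diag(Q)
  if (identical(initialState, "stationary")) {
    p <- stationaryDistribution(rates)
    s <- sample.int(3L, 1L, prob = p)
  } else {
    s <- match(initialState, STATE_LABELS)
    if (is.na(s)) stop("initialState must be 'L', 'I', 'H' or 'stationary'")
  }
  if (exit[s] <= 0)
    stop("absorbing state: all exit rates of the initial state are zero")

  state <- integer(0); entry <- numeric(0); exitT <- numeric(0)
  t <- 0
  while (t < duration) {
    dwell <- stats::rexp(1L, rate = exit[s])
    tEnd <- min(t + dwell, duration)
    state <- c(state, s); entry <- c(entry, t); exitT <- c(exitT, tEnd)
    t <- tEnd
    if (t >= duration) break
    w <- Q[s, ]; w[s] <- 0
    s <- sample.int(3L, 1L, prob = w)
    if (exit[s] <= 0) {            # absorbing destination: dwell to the end
      state <- c(state, s); entry <- c(entry, t); exitT <- c(exitT, duration)
      break
    }
  }
  new("StatePath", state = state, entry = entry, exit = exitT,
      duration = duration)
}

#' Default Mg2+ rate law mirroring the observed titration trends
#'
#' The unfolding rates k_HI and k_IL decrease with Mg2+ (log-linearly in
#' log concentration) while the folding rates are held constant, so the
#' equilibrium shifts from L towards H as Mg2+ rises.
#'
#' @param baseRates rates at \code{refMg}; the defaults give roughly
#'   second-scale dynamics with all three states populated near 1 mM Mg2+.
#' @param exponents named power-law exponents; positive = decreasing in
#'   Mg2+.
#' @param refMg reference concentration in mM.
#' @return an \linkS4class{MgRateLaw}.
#' @export
mgRateLaw <- function(baseRates = generatorRates(kLI = 2, kLH = 0.05,
                                                 kIL = 1, kIH = 0.8,
                                                 kHL = 0.1, kHI = 0.4),
                      exponents = c(LI = 0, LH = 0, IL = 0.35, IH = 0,
                                    HL = 0, HI = 0.5),
                      refMg = 1) {
  new("MgRateLaw", baseRates = baseRates, exponents = exponents,
      refMg = refMg)
}

#' Evaluate a Mg2+ rate law at a concentration
#'
#' @param law an \linkS4class{MgRateLaw}.
#' @param mg Mg2+ concentration in mM (> 0).
#' @return a \linkS4class{GeneratorRates}.
#' @export
ratesAt <- function(law, mg) {
  stopifnot(mg > 0)
  r <- law@baseRates@rates * (mg / law@refMg)^(-law@exponents)
  new("GeneratorRates", rates = r)
}

#' @describeIn simulateStatePath total time spent in each state.
#' @param path a \code{StatePath}.
#' @export
stateOccupancy <- function(path) {
  dur <- path@exit - path@entry
  occ <- vapply(1:3, function(s) sum(dur[path@state == s]), numeric(1))
  names(occ) <- STATE_LABELS
  occ / sum(occ)
}

setMethod("show", "GeneratorRates", function(object) {
  cat("GeneratorRates (s^-1):\n")
  print(round(object@rates, 4))
})

setMethod("show", "StatePath", function(object) {
  cat(sprintf("StatePath: %d segments over %.3g s; occupancy L/I/H = %s\n",
              length(object@state), object@duration,
              paste(sprintf("%.2f", stateOccupancy(object)), collapse = "/")))
})
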