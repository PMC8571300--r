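## Shared fixtures: the reference generator (sequential-pathway kinetics
## with rare direct L<->H events) and small simulated trace sets.

refRates <- function() {
  generatorRates(kLI = 2, kLH = 0.05, kIL = 1, kIH = 0.8, kHL = 0.1,
                 kHI = 0.4)
}

## noiseless, bleach-free emission model for oracle-style tests
cleanEmission <- function(noiseSd = 0) {
  emissionModel(channelNoiseSd = noiseSd, donorBleachRate = 0,
                acceptorBleachRate = 0)
}

## simulate n traces and return their FRET series plus ground truth
simulateFretSet <- function(rates, n, duration, emission, seed,
                            integrate = TRUE, frameInterval = 0.025) {
  set.seed(seed)
  traces <- lapply(seq_len(n), function(i)
    renderTrace(simulateStatePath(rates, duration), emission,
                frameInterval = frameInterval, integrate = integrate,
                id = sprintf("t%03d", i)))
  fret <- lapply(traces, computeFret, bleach = "none")
  list(traces = traces, fret = fret)
}

## independent run-length scanner: frame-by-frame loop, no rle()
oracleScanCounts <- function(states) {
  counts <- matrix(0L, 3L, 3L)
  dwells <- numeric(0)
  cur <- states[1]; len <- 1L
  if (length(states) > 1L) for (i in 2:length(states)) {
    if (states[i] == cur) {
      len <- len + 1L
    } else {
      counts[cur, states[i]] <- counts[cur, states[i]] + 1L
      dwells <- c(dwells, len)
      cur <- states[i]; len <- 1L
    }
  }
  list(counts = counts, nRuns = length(dwells) + 1L)
}
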