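mkIdeal <- function(states, fret = NULL, id = "t") {
  if (is.null(fret)) fret <- c(0.3, 0.5, 0.9)[states]
  new("IdealizedTrace", states = as.integer(states), fret = fret,
      stateMeans = c(0.3, 0.5, 0.9), id = id)
}

test_that("dwell extraction merges runs and counts transitions by hand", {
  ## L(10) I(5) L(8): censored ends, one transition each way
  id <- mkIdeal(c(rep(1, 10), rep(2, 5), rep(1, 8)))
  dw <- extractDwells(id, frameInterval = 0.025)
  expect_equal(nrow(dw@records), 3L)
  expect_equal(as.character(dw@records$state), c("L", "I", "L"))
  expect_equal(dw@records$duration, c(10, 5, 8) * 0.025)
  expect_true(dw@records$censoredFirst[1] && dw@records$censoredLast[3])
  expect_false(dw@records$censoredFirst[2] || dw@records$censoredLast[2])
  expect_equal(dw@counts["L", "I"], 1L)
  expect_equal(dw@counts["I", "L"], 1L)
  expect_equal(sum(dw@counts), 2L)

  ## constant trace: one fully censored dwell, no transitions
  dwc <- extractDwells(mkIdeal(rep(3, 20)))
  expect_equal(nrow(dwc@records), 1L)
  expect_true(dwc@records$censoredFirst && dwc@records$censoredLast)
  expect_equal(sum(dwc@counts), 0L)
})

test_that("transition counts equal an independent run-length scanner", {
  s <- simulateFretSet(refRates(), 50, 20, cleanEmission(70), seed = 91)
  m <- fitHmm(s$fret)
  ideal <- lapply(s$fret, function(f) idealizeTrace(m, f))
  dw <- extractDwells(ideal)
  oracle <- matrix(0L, 3L, 3L)
  nDwells <- 0L
  for (tr in ideal) {
    sc <- oracleScanCounts(tr@states)
    oracle <- oracle + sc$counts
    nDwells <- nDwells + sc$nRuns
  }
  expect_identical(unname(dw@counts), oracle)
  expect_identical(nrow(dw@records), nDwells)
})

test_that("lifetime estimators match their closed forms", {
  ## exponential sampling oracle
  set.seed(101)
  n <- 1e4
  d <- rexp(n, 1 / 0.5)
  rec <- data.frame(state = factor(rep("I", n + 2), levels = c("L", "I", "H")),
                    duration = c(1, d, 1), traceId = "t",
                    censoredFirst = c(TRUE, rep(FALSE, n + 1)),
                    censoredLast = c(rep(FALSE, n + 1), TRUE))
  dw <- new("DwellSet", records = rec,
            counts = matrix(0L, 3, 3,
                            dimnames = list(c("L","I","H"), c("L","I","H"))),
            frameInterval = 0.025)
  lt <- suppressWarnings(fitLifetimes(dw))
  expect_lt(abs(lt@tau[["I"]] - 0.5), 3 * 0.5 / sqrt(n))

  ## binned least squares agrees with MLE on the same sample
  ltB <- suppressWarnings(fitLifetimes(dw, estimator = "binned",
                                       binWidth = 0.05))
  expect_equal(ltB@tau[["I"]], lt@tau[["I"]], tolerance = 0.05)

  ## single uncensored dwell: MLE equals that dwell
  rec1 <- data.frame(state = factor(c("H", "L", "H"),
                                    levels = c("L", "I", "H")),
                     duration = c(1, 2.0, 1), traceId = "t",
                     censoredFirst = c(TRUE, FALSE, FALSE),
                     censoredLast = c(FALSE, FALSE, TRUE))
  dw1 <- new("DwellSet", records = rec1, counts = dw@counts,
             frameInterval = 0.025)
  lt1 <- suppressWarnings(fitLifetimes(dw1))
  expect_equal(lt1@tau[["L"]], 2.0)

  ## all dwells at one frame: resolution-limited flag
  recR <- data.frame(state = factor(rep("L", 32), levels = c("L", "I", "H")),
                     duration = rep(0.025, 32), traceId = "t",
                     censoredFirst = FALSE, censoredLast = FALSE)
  dwR <- new("DwellSet", records = recR, counts = dw@counts,
             frameInterval = 0.025)
  ltR <- fitLifetimes(dwR)
  expect_equal(ltR@tau[["L"]], 0.025)
  expect_true(any(grepl("resolution-limited", ltR@flags)))

  ## a state seen only in censored dwells is an error
  recC <- data.frame(state = factor("H", levels = c("L", "I", "H")),
                     duration = 5, traceId = "t",
                     censoredFirst = TRUE, censoredLast = TRUE)
  cWithExit <- dw@counts; cWithExit["H", "I"] <- 1L
  dwC <- new("DwellSet", records = recC, counts = cWithExit,
             frameInterval = 0.025)
  expect_error(fitLifetimes(dwC), "no uncensored dwells")
  ## without observed exits the lifetime is simply undefined, flagged
  dwC2 <- new("DwellSet", records = recC, counts = dw@counts,
              frameInterval = 0.025)
  ltC2 <- fitLifetimes(dwC2)
  expect_true(is.na(ltC2@tau[["H"]]))
  expect_true(any(grepl("censored", ltC2@flags)))
})

test_that("the six branching equations hold literally and algebraically", {
  mkLt <- function(tL = NA, tI = NA, tH = NA)
    new("LifetimeSet", tau = c(L = tL, I = tI, H = tH),
        se = c(L = 0, I = 0, H = 0), nDwells = c(L = 50L, I = 50L, H = 50L),
        estimator = "mle", flags = character(0))
  cmat <- function(...) {
    m <- matrix(as.integer(c(...)), 3, 3, byrow = TRUE,
                dimnames = list(c("L","I","H"), c("L","I","H")))
    m
  }

  ## tau_L = 1, n_LI = 10, n_LH = 0 -> k_LI = 1, k_LH = 0
  rs <- transitionRates(mkLt(tL = 1, tI = 1, tH = 1),
                        cmat(0, 10, 0, 4, 0, 4, 2, 2, 0))
  expect_equal(rs@rates[["LI"]], 1)
  expect_equal(rs@rates[["LH"]], 0)

  ## hand evaluation: tau_H = 2, n_HL = 1, n_HI = 3
  rs2 <- transitionRates(mkLt(tL = 1, tI = 1, tH = 2),
                         cmat(0, 5, 5, 5, 0, 5, 1, 3, 0))
  expect_equal(rs2@rates[["HL"]], 0.125)
  expect_equal(rs2@rates[["HI"]], 0.375)

  ## identity k_XY + k_XZ = 1/tau_X to machine precision
  expect_equal(rs2@rates[["HL"]] + rs2@rates[["HI"]], 1 / 2,
               tolerance = 1e-15)
  expect_equal(rs2@rates[["LI"]] + rs2@rates[["LH"]], 1,
               tolerance = 1e-15)

  ## no exits from a state: both rates 0 with a flag, even without tau
  rs3 <- transitionRates(mkLt(tL = 1, tI = 1),
                         cmat(0, 5, 0, 5, 0, 0, 0, 0, 0))
  expect_equal(rs3@rates[["HL"]], 0)
  expect_equal(rs3@rates[["HI"]], 0)
  expect_true(any(grepl("no exits", rs3@flags)))

  ## missing tau with nonzero exit counts is an error
  expect_error(transitionRates(mkLt(tL = 1, tI = 1),
                               cmat(0, 5, 0, 5, 0, 0, 1, 1, 0)),
               "undefined")
})

test_that("rate estimates converge to the generating CTMC rates", {
  estErr <- function(nTraces, duration, seed) {
    s <- simulateFretSet(refRates(), nTraces, duration, cleanEmission(70),
                         seed = seed, integrate = FALSE)
    m <- fitHmm(s$fret)
    ideal <- lapply(s$fret, function(f) idealizeTrace(m, f))
    rs <- suppressWarnings(estimateRates(ideal))
    abs(rs@rates - refRates()@rates) / refRates()@rates
  }
  small <- estErr(30, 15, 111)
  large <- estErr(120, 40, 112)
  expect_lt(mean(large), mean(small) + 0.02)   # error shrinks with data
  ## the rare direct rates carry the largest counting noise (~60 events)
  expect_lt(max(large), 0.4)
  expect_lt(max(large[c("LI", "IL", "IH", "HI")]), 0.1)
})

test_that("TDPs are normalized two-dimensional transition histograms", {
  ## hand count: L -> I -> L with means 0.3 / 0.5
  id <- mkIdeal(c(rep(1, 10), rep(2, 6), rep(1, 10)))
  tdp <- buildTdp(id)
  expect_equal(tdp@nTransitions, 2L)
  expect_equal(sum(tdp@density), 1)
  expect_equal(tdpCornerMass(tdp, 0.3, 0.5, halfWidth = 0.05), 0.5)
  expect_equal(tdpCornerMass(tdp, 0.5, 0.3, halfWidth = 0.05), 0.5)
  expect_equal(sum(diag(tdp@density)), 0)

  ## marginal agreement with TransitionCounts
  s <- simulateFretSet(refRates(), 20, 20, cleanEmission(70), seed = 121)
  m <- fitHmm(s$fret)
  ideal <- lapply(s$fret, function(f) idealizeTrace(m, f))
  dw <- extractDwells(ideal)
  tdp2 <- buildTdp(ideal)
  expect_identical(tdp2@nTransitions, sum(dw@counts))

  expect_warning(buildTdp(mkIdeal(rep(1, 20))), "no transitions")
})

test_that("free-energy landscapes follow detailed balance on rate pairs", {
  ## equal forward/backward rates: all dG = 0
  eq <- generatorRates(kLI = 1, kLH = 1, kIL = 1, kIH = 1, kHL = 1, kHI = 1)
  ls <- freeEnergyLandscape(eq)
  expect_equal(unname(ls@dG), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ls@closure, 0, tolerance = 1e-12)

  ## closed form: 2:1 rates at 298 K give -kBT ln 2 = -0.411 kcal/mol
  r21 <- generatorRates(kLI = 2, kIL = 1, kIH = 1, kHI = 1, kHL = 0,
                        kLH = 0)
  ls21 <- freeEnergyLandscape(r21, temperatureK = 298.15)
  expect_equal(ls21@dG[["I"]], -1.987204259e-3 * 298.15 * log(2),
               tolerance = 1e-12)
  expect_lt(abs(ls21@dG[["I"]] - (-0.411)), 2e-3)

  ## antisymmetry of the pair formula
  expect_equal(pairFreeEnergy(2, 1), -pairFreeEnergy(1, 2),
               tolerance = 1e-14)

  ## barrier convention: k = 1 s^-1 gives exactly 1.8 kBT
  expect_identical(transitionBarrier(1, kBT = 1), 1.8)
  expect_false("L->H" %in% names(ls@barriers))

  ## required rate <= 0 names the offender
  expect_error(freeEnergyLandscape(
    generatorRates(kLI = 1, kIL = 1, kIH = 0, kHI = 1, kHL = 1, kLH = 1)),
    "k_IH")
})

test_that("cycle closure vanishes iff the generator satisfies detailed balance", {
  ## Kolmogorov criterion: kLI*kIH*kHL == kLH*kHI*kIL
  balanced <- generatorRates(kLI = 2, kIL = 1, kIH = 0.8, kHI = 0.4,
                             kLH = 0.1, kHL = 0.1 * 0.4 * 1 / (2 * 0.8))
  run <- function(rts, seed) {
    s <- simulateFretSet(rts, 120, 40, cleanEmission(70), seed = seed,
                         integrate = FALSE)
    m <- fitHmm(s$fret)
    ideal <- lapply(s$fret, function(f) idealizeTrace(m, f))
    freeEnergyLandscape(suppressWarnings(estimateRates(ideal)))
  }
  lsB <- run(balanced, 131)
  expect_lt(abs(lsB@closure), 0.25)

  violating <- generatorRates(kLI = 2, kIL = 1, kIH = 0.8, kHI = 0.4,
                              kLH = 0.1, kHL = 0.5)
  lsV <- run(violating, 132)
  truthClosure <- pairFreeEnergy(0.1, 0.5) -
    (pairFreeEnergy(2, 1) + pairFreeEnergy(0.8, 0.4))
  expect_gt(abs(lsV@closure), 0.5)
  expect_equal(lsV@closure, truthClosure, tolerance = 0.35)
})

test_that("fractional populations track occupancy and the stationary law", {
  expect_equal(unname(fractionalPopulations(mkIdeal(rep(3, 30)))),
               c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(unname(fractionalPopulations(mkIdeal(c(rep(1, 10),
                                                      rep(2, 10),
                                                      rep(3, 10))))),
               rep(1 / 3, 3), ignore_attr = TRUE)

  s <- simulateFretSet(refRates(), 150, 30, cleanEmission(70), seed = 141)
  m <- fitHmm(s$fret)
  ideal <- lapply(s$fret, function(f) idealizeTrace(m, f))
  expect_equal(unname(fractionalPopulations(ideal)),
               unname(stationaryDistribution(refRates())),
               tolerance = 0.03, ignore_attr = TRUE)
})

test_that("Hill fits recover titration parameters and expose policy", {
  mg <- 10^seq(-3, 2, length.out = 10)
  f <- 0.05 + 0.9 * mg / (1.5 + mg)
  hf <- fitHill(mg, f, state = "H")
  expect_equal(hf@params[["K"]], 1.5, tolerance = 0.01)
  expect_equal(hf@params[["n"]], 1, tolerance = 0.01)
  expect_equal(hf@params[["amplitude"]], 0.9, tolerance = 0.01)
  expect_equal(hf@params[["baseline"]], 0.05, tolerance = 0.01)

  ## flat data: amplitude ~ 0, flagged unidentifiable
  hfF <- fitHill(mg, rep(0.4, 10), state = "L")
  expect_lt(abs(hfF@params[["amplitude"]]), 0.02)
  expect_true(length(hfF@flags) > 0)

  ## intermediate state refused unless overridden
  expect_error(fitHill(mg, f, state = "I"), "not fitted")
  expect_s4_class(fitHill(mg, f, state = "I", allowIntermediate = TRUE),
                  "HillFit")
})

test_that("the critical Mg2+ is the H/L crossing of the fitted curves", {
  mkHill <- function(amplitude, baseline, K, n, state)
    new("HillFit", params = c(amplitude = amplitude, K = K, n = n,
                              baseline = baseline),
        se = c(amplitude = 0, K = 0, n = 0, baseline = 0), state = state,
        converged = TRUE, flags = character(0))
  hH <- mkHill(0.8, 0, 1.5, 1, "H")
  hL <- mkHill(-0.8, 0.8, 1.5, 1, "L")
  cr <- criticalMg(hH, hL)
  expect_equal(cr$mg, 1.5, tolerance = 1e-3)
  expect_equal(cr$flag, "crossing")

  ## H above L everywhere: range minimum, flagged
  crLo <- criticalMg(mkHill(0.1, 0.8, 1, 1, "H"),
                     mkHill(0, 0.1, 1, 1, "L"))
  expect_equal(crLo$mg, 1e-3)
  expect_equal(crLo$flag, "below-range")

  ## H below L everywhere: +Inf flag
  crHi <- criticalMg(mkHill(0, 0.1, 1, 1, "H"),
                     mkHill(0, 0.8, 1, 1, "L"))
  expect_identical(crHi$mg, Inf)
  expect_equal(crHi$flag, "no-crossing")
})
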