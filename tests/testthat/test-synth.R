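test_that("Gillespie paths respect reachability and exact dwell statistics", {
  ## only L<->I connected: H must never appear
  r2 <- generatorRates(kLI = 1, kIL = 1, kIH = 0, kHI = 1, kHL = 1)
  p <- simulateStatePath(r2, 10, initialState = "L", seed = 7)
  expect_false(3L %in% p@state)

  ## exponential dwell-mean oracle: mean L dwell = 1/(kLI+kLH)
  p <- simulateStatePath(generatorRates(kLI = 2, kIL = 2, kIH = 1e-9,
                                        kHI = 1, kHL = 1),
                         1e4, initialState = "L", seed = 11)
  d <- p@exit - p@entry
  meanL <- mean(d[p@state == 1L & seq_along(d) > 1 & seq_along(d) < length(d)])
  expect_lt(abs(meanL - 0.5) / 0.5, 0.05)

  ## determinism under a fixed seed
  pa <- simulateStatePath(refRates(), 50, seed = 3)
  pb <- simulateStatePath(refRates(), 50, seed = 3)
  expect_identical(pa@state, pb@state)
  expect_identical(pa@exit, pb@exit)

  ## absorbing initial state is rejected
  expect_error(
    simulateStatePath(generatorRates(kLI = 0, kLH = 0, kIL = 1, kIH = 1,
                                     kHL = 1, kHI = 1),
                      10, initialState = "L"),
    "absorbing")
})

test_that("long-run occupancy matches the stationary distribution", {
  rts <- refRates()
  p <- simulateStatePath(rts, 2e4, seed = 5)
  expect_equal(unname(stateOccupancy(p)),
               unname(stationaryDistribution(rts)), tolerance = 0.05)
  expect_equal(sum(stationaryDistribution(rts)), 1, tolerance = 1e-12)
})

test_that("rendered traces reproduce emission physics", {
  em <- cleanEmission()
  ## constant H state: I_A = 900, I_D = 100 every frame
  pH <- new("StatePath", state = 3L, entry = 0, exit = 1, duration = 1)
  tr <- renderTrace(pH, em, frameInterval = 0.025)
  expect_equal(tr@acceptor, rep(900, 40))
  expect_equal(tr@donor, rep(100, 40))

  ## occupancy-weighted frame: L->H jump at mid-frame gives apparent E = 0.6
  pj <- new("StatePath", state = c(1L, 3L), entry = c(0, 0.0125),
            exit = c(0.0125, 0.025), duration = 0.025)
  trj <- renderTrace(pj, em, frameInterval = 0.025)
  expect_equal(trj@acceptor / (trj@acceptor + trj@donor), 0.6,
               tolerance = 1e-9)
  ## instantaneous switch samples the mid-frame state instead
  tri <- renderTrace(pj, em, frameInterval = 0.025, integrate = FALSE)
  expect_equal(tri@acceptor / (tri@acceptor + tri@donor), 0.9,
               tolerance = 1e-9)

  ## after donor bleach both channels sit at background
  emB <- emissionModel(channelNoiseSd = 0, donorBleachRate = 0.5,
                       acceptorBleachRate = 0)
  pLong <- new("StatePath", state = 3L, entry = 0, exit = 100,
               duration = 100)
  trb <- renderTrace(pLong, emB, seed = 21)
  tD <- trb@truthBleach[["donor"]]
  expect_true(is.finite(tD) && tD < 100)
  post <- trb@time >= tD
  expect_true(all(trb@acceptor[post] == 0))
  expect_true(all(trb@donor[post] == 0))
})

test_that("titration sets carry ground truth with monotone H-state bias", {
  law <- mgRateLaw()
  mg <- c(0.01, 0.1, 1, 10, 100)
  ## ground-truth equilibrium H fraction increases monotonically with Mg2+
  fH <- vapply(mg, function(c) stationaryDistribution(ratesAt(law, c))[["H"]],
               numeric(1))
  expect_true(all(diff(fH) > 0))

  sets <- simulateTitration(law, c(1), nTraces = 2L, duration = 5,
                            emission = cleanEmission(), seed = 9)
  expect_length(sets, 1L)
  expect_length(sets[[1]]$traces, 2L)
  expect_s4_class(sets[[1]]$truthRates, "GeneratorRates")

  empty <- simulateTitration(law, c(1, 10), nTraces = 0L, duration = 5,
                             seed = 9)
  expect_length(empty[[1]]$traces, 0L)

  ## reproducibility of the whole set
  a <- simulateTitration(law, c(0.1, 1), nTraces = 2L, duration = 5,
                         emission = emissionModel(), seed = 4)
  b <- simulateTitration(law, c(0.1, 1), nTraces = 2L, duration = 5,
                         emission = emissionModel(), seed = 4)
  expect_identical(a[[2]]$traces[[2]]@donor, b[[2]]$traces[[2]]@donor)

  ## rate/frame-rate guard
  fast <- generatorRates(kLI = 50, kIL = 50, kIH = 1, kHI = 1)
  expect_warning(simulateTitration(fast, 1, nTraces = 1L, duration = 1,
                                   emission = cleanEmission(), seed = 1),
                 "unreliable")
})

test_that("synthetic movies render calibrated Gaussian spots", {
  spec1 <- movieSpec(dim = c(48L, 48L), psfSigma = 1.3,
                     spots = matrix(c(23.5, 24.2), 1, 2), amplitude = 400,
                     background = 0, poissonNoise = FALSE)
  mov <- simulateMovie(spec1)
  expect_equal(sum(mov$donor[, , 1]), 2 * pi * 1.3^2 * 400,
               tolerance = 1e-4)

  ## zero spots: frames are background only
  spec0 <- movieSpec(dim = c(32L, 32L), background = 7,
                     poissonNoise = FALSE)
  mov0 <- simulateMovie(spec0)
  expect_true(all(mov0$donor == 7) && all(mov0$acceptor == 7))

  ## acceptor channel = donor positions through the stored transform
  sp <- matrix(c(10, 30, 12, 28), 2, 2)
  specT <- movieSpec(dim = c(64L, 64L), spots = sp,
                     transform = c(dx = 5, dy = -3, rotation = 0),
                     poissonNoise = FALSE)
  movT <- simulateMovie(specT)
  expect_equal(movT$truth$acceptorSpots[, 1], sp[, 1] + 5)
  expect_equal(movT$truth$acceptorSpots[, 2], sp[, 2] - 3)
})

test_that("decay and scattering generators follow their closed forms", {
  ## zero rate: experimental and control identical up to noise
  d0 <- simulateDecayTrace(0, duration = 30, noiseSd = 0)
  expect_equal(d0@fexp, d0@fcon)

  ## noiseless normalized trace is exactly exp(-rate t)
  d <- simulateDecayTrace(0.1, duration = 60, noiseSd = 0)
  nd <- normalizeDecay(d)
  expect_equal(nd$F, exp(-0.1 * nd$time), tolerance = 1e-12)

  ## Guinier curve: q -> 0 limit and direct evaluation
  cv <- simulateGuinierCurve(20, I0 = 5, qGrid = c(1e-9, 0.05))
  expect_equal(cv@I[1], 5, tolerance = 1e-6)
  expect_equal(cv@I[2], 5 * exp(-0.05^2 * 400 / 3), tolerance = 1e-12)

  ## doubling Rg at fixed q decreases I
  expect_lt(simulateGuinierCurve(40, I0 = 5, qGrid = 0.05)@I,
            simulateGuinierCurve(20, I0 = 5, qGrid = 0.05)@I)
})
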