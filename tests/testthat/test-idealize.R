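test_that("FRET efficiency follows the intensity ratio with clipping", {
  mk <- function(d, a) new("FretTrace", time = (seq_along(d) - 0.5) * 0.025,
                           donor = d, acceptor = a, frameInterval = 0.025,
                           truthState = integer(0),
                           truthBleach = c(donor = Inf, acceptor = Inf),
                           id = "t")
  expect_equal(as.numeric(computeFret(mk(rep(100, 12), rep(100, 12)),
                                      bleach = "none")),
               rep(0.5, 12))
  expect_equal(as.numeric(computeFret(mk(rep(100, 12), rep(900, 12)),
                                      bleach = "none")),
               rep(0.9, 12))
  ## negative background-subtracted acceptor clips to 0
  e <- computeFret(mk(rep(100, 12), rep(-5, 12)), bleach = "none")
  expect_equal(as.numeric(e), rep(0, 12))
  ## all-zero frames are masked
  d <- rep(100, 12); a <- rep(100, 12); d[5] <- 0; a[5] <- 0
  e2 <- computeFret(mk(d, a), bleach = "none")
  expect_length(e2, 11L)
  expect_false(5L %in% attr(e2, "frames"))
})

test_that("bleach detection truncates traces at the intensity step", {
  em <- emissionModel(channelNoiseSd = 30, donorBleachRate = 0,
                      acceptorBleachRate = 0.2)
  p <- new("StatePath", state = 3L, entry = 0, exit = 40, duration = 40)
  set.seed(17)
  tr <- renderTrace(p, em, seed = 17)
  tA <- tr@truthBleach[["acceptor"]]
  expect_true(is.finite(tA) && tA < 40)
  cut <- detectBleach(tr)
  expect_false(is.na(cut))
  expect_lt(abs(tr@time[cut] - tA), 0.5)   # within 20 frames of truth
  ## no bleach, no change point
  trN <- renderTrace(p, cleanEmission(30), seed = 18)
  expect_true(is.na(detectBleach(trN)))
})

test_that("Baum-Welch recovers emission parameters", {
  ## noiseless (instantaneous-sampling oracle): means within 1e-3
  s <- simulateFretSet(refRates(), 5, 30, cleanEmission(), seed = 51,
                       integrate = FALSE)
  m0 <- fitHmm(s$fret)
  expect_equal(m0@means, c(0.3, 0.5, 0.9), tolerance = 1e-3)

  ## noisy ensemble: means within 0.02 of the generator values
  sN <- simulateFretSet(refRates(), 60, 30, cleanEmission(70), seed = 52)
  mN <- fitHmm(sN$fret)
  expect_equal(mN@means, c(0.3, 0.5, 0.9), tolerance = 0.02)
  expect_true(mN@converged)

  ## log-likelihood is monotone non-decreasing
  expect_true(all(diff(mN@logLikTrace) > -1e-6))

  ## initialization-permutation invariance after relabeling
  mS <- fitHmm(sN$fret, initStrategy = "spread")
  expect_equal(mS@means, mN@means, tolerance = 0.01)

  ## single-state fit: closed form (sample mean / population sd)
  set.seed(53)
  x <- rnorm(4000, 0.5, 0.05)
  m1 <- fitHmm(x, nStates = 1L)
  expect_equal(m1@means, mean(x), tolerance = 1e-6)
  expect_equal(m1@sds, stats::sd(x) * sqrt((length(x) - 1) / length(x)),
               tolerance = 1e-4)

  expect_error(fitHmm(list(rnorm(5))), "at least 10 frames")
})

test_that("Viterbi idealization matches ground truth", {
  ## well-separated noiseless jumps: exact recovery
  p <- new("StatePath", state = c(1L, 2L, 3L, 2L, 1L),
           entry = c(0, 1, 2, 3, 4), exit = c(1, 2, 3, 4, 5), duration = 5)
  tr <- renderTrace(p, cleanEmission(), integrate = FALSE)
  f <- computeFret(tr, bleach = "none")
  m <- suppressWarnings(fitHmm(list(as.numeric(f))))
  id <- idealizeTrace(m, f)
  expect_identical(id@states, tr@truthState)

  ## constant series: single uniform label
  idc <- idealizeTrace(m, rep(0.9, 50))
  expect_true(all(idc@states == 3L))

  ## frame misassignment < 5% at channel noise giving ~0.05 FRET sd
  ## (instantaneous sampling: decoder accuracy, not camera blur)
  sN <- simulateFretSet(refRates(), 25, 30, cleanEmission(70), seed = 61,
                        integrate = FALSE)
  mN <- fitHmm(sN$fret)
  mis <- vapply(seq_along(sN$fret), function(i) {
    id <- idealizeTrace(mN, sN$fret[[i]])
    mean(id@states != sN$traces[[i]]@truthState)
  }, numeric(1))
  expect_lt(mean(mis), 0.05)

  ## posterior decoding agrees with Viterbi on well-separated data
  idp <- idealizeTrace(mN, sN$fret[[1]], method = "posterior")
  idv <- idealizeTrace(mN, sN$fret[[1]])
  expect_gt(mean(idp@states == idv@states), 0.98)
})

test_that("pooled histograms are normalized frequency distributions", {
  h1 <- suppressWarnings(buildHistogram(rep(0.5, 1000)))
  expect_equal(sum(h1@frequency), 1)
  expect_equal(sum(h1@frequency > 0), 1L)

  h2 <- suppressWarnings(buildHistogram(c(rep(0.31, 500), rep(0.91, 500))))
  expect_equal(sort(h2@frequency[h2@frequency > 0]), c(0.5, 0.5))

  set.seed(71)
  h3 <- suppressWarnings(buildHistogram(runif(5000)))
  expect_equal(sum(h3@frequency), 1, tolerance = 1e-12)

  expect_warning(buildHistogram(list(rep(0.5, 100))), "molecules")
})

test_that("Gaussian-mixture populations recover sampler weights", {
  set.seed(81)
  n <- 1e5
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  x <- rnorm(n, c(0.3, 0.5, 0.9)[comp], 0.05)
  sp <- fitStatePopulations(x, seed = 2)
  expect_equal(sp@fractions, c(0.2, 0.3, 0.5), tolerance = 0.02)
  expect_equal(sp@centers, c(0.3, 0.5, 0.9), tolerance = 0.02)

  ## degenerate single-mode data: no spurious outer modes appear
  set.seed(82)
  spd <- fitStatePopulations(rnorm(5000, 0.5, 0.04), seed = 2)
  expect_true(all(abs(spd@centers - 0.5) < 0.12))
  expect_equal(sum(spd@fractions * spd@centers), 0.5, tolerance = 0.01)

  ## cross-estimator consistency: mixture weights vs Viterbi occupancy
  s <- simulateFretSet(refRates(), 40, 30, cleanEmission(70), seed = 83,
                       integrate = FALSE)
  m <- fitHmm(s$fret)
  ideal <- lapply(s$fret, function(f) idealizeTrace(m, f))
  occ <- fractionalPopulations(ideal)
  mix <- fitStatePopulations(s$fret, seed = 2)
  expect_equal(unname(occ), mix@fractions, tolerance = 0.03,
               ignore_attr = TRUE)
})

test_that("BIC selection identifies the number of FRET states", {
  ## instantaneous sampling: frame blur would otherwise add pseudo-states
  s3 <- simulateFretSet(refRates(), 12, 20, cleanEmission(70), seed = 91,
                        integrate = FALSE)
  sel <- suppressWarnings(selectHmmStates(s3$fret, maxStates = 4L))
  expect_equal(sel$nStates, 3L)
  ## two-state dynamics: only L and H connected
  r2 <- generatorRates(kLI = 0, kLH = 1, kIL = 1, kIH = 1, kHL = 1,
                       kHI = 0)
  s2 <- simulateFretSet(r2, 12, 20, cleanEmission(70), seed = 92,
                        integrate = FALSE)
  sel2 <- suppressWarnings(selectHmmStates(s2$fret, maxStates = 4L))
  expect_equal(sel2$nStates, 2L)
})
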