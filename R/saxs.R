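#' Construct a scattering curve
#'
#' @param q momentum transfer in inverse Angstrom (strictly ascending).
#' @param I intensity (arbitrary units).
#' @param sigma per-point uncertainties (optional).
#' @return a \linkS4class{ScatteringCurve}.
#' @export
scatteringCurve <- function(q, I, sigma = numeric(0)) {
  new("ScatteringCurve", q = q, I = I, sigma = sigma)
}

#' Simulate an ideal Guinier scattering curve
#'
#' I(q) = I0 exp(-q^2 Rg^2 / 3) plus optional Gaussian noise; the sigma
#' column is populated with the noise level (or 1% of I for noiseless
#' curves, so weighted fits remain defined).
#'
#' @param Rg radius of gyration in Angstrom (> 0).
#' @param I0 forward scattering intensity.
#' @param qGrid positive ascending q values (1/Angstrom).
#' @param noiseSd relative noise s.d. (fraction of I).
#' @param seed optional integer seed.
#' @return a \linkS4class{ScatteringCurve}.
#' @export
simulateGuinierCurve <- function(Rg, I0 = 1, qGrid = seq(0.005, 0.3,
                                                         by = 0.002),
                                 noiseSd = 0, seed = NULL) {
  stopifnot(Rg > 0, all(qGrid >= 0))
  if (!is.null(seed)) set.seed(seed)
  I <- I0 * exp(-qGrid^2 * Rg^2 / 3)
  sigma <- pmax(noiseSd, 0.01) * I
  if (noiseSd > 0) I <- I + stats::rnorm(length(I), 0, noiseSd * I)
  scatteringCurve(qGrid, I, sigma)
}

#' Guinier fit of the low-angle region
#'
#' Weighted linear fit of ln I versus q^2 over the largest low-q window
#' satisfying q_max * Rg <= \code{qRgLimit}, iterated to self-consistency
#' (the window is re-chosen with the fitted Rg until it stabilizes).
#' Rg = sqrt(-3 * slope); I(0) = exp(intercept).
#'
#' @param curve a \linkS4class{ScatteringCurve}.
#' @param qRgLimit Guinier validity limit (community convention 1.3).
#' @param minPoints minimum number of points in the fitted window.
#' @return a \linkS4class{GuinierResult}.
#' @export
guinierFit <- function(curve, qRgLimit = 1.3, minPoints = 5L) {
  validObject(curve)
  pos <- curve@q > 0 & curve@I > 0
  q <- curve@q[pos]; I <- curve@I[pos]
  sig <- if (length(curve@sigma)) curve@sigma[pos] else rep(NA_real_, sum(pos))
  if (length(q) < minPoints) stop("fewer than ", minPoints,
                                  " usable low-q points")
  ## weights for ln I: var(ln I) ~ (sigma / I)^2
  w <- if (all(is.finite(sig)) && all(sig > 0)) (I / sig)^2 else rep(1, length(q))

  fitWindow <- function(m) {
    df <- data.frame(q2 = q[1:m]^2, lnI = log(I[1:m]))
    stats::lm(lnI ~ q2, data = df, weights = w[1:m])
  }
  m <- length(q)
  for (iter in 1:50) {
    fit <- fitWindow(m)
    slope <- stats::coef(fit)[["q2"]]
    if (slope >= 0) {
      ## shrink towards the lowest angles before giving up
      if (m > minPoints) { m <- max(minPoints, floor(m / 2)); next }
      stop("no Guinier region: non-negative low-q slope")
    }
    Rg <- sqrt(-3 * slope)
    mNew <- max(minPoints, findInterval(qRgLimit / Rg, q))
    if (mNew == m) break
    m <- mNew
  }
  fit <- fitWindow(m)
  co <- summary(fit)$coefficients
  slope <- co["q2", "Estimate"]
  if (slope >= 0) stop("no Guinier region: non-negative low-q slope")
  Rg <- sqrt(-3 * slope)
  RgSe <- 3 * co["q2", "Std. Error"] / (2 * Rg)
  I0 <- exp(co["(Intercept)", "Estimate"])
  new("GuinierResult", Rg = Rg, RgSe = RgSe, I0 = I0,
      I0Se = I0 * co["(Intercept)", "Std. Error"],
      qRange = c(q[1], q[m]), qRgMax = q[m] * Rg, nPoints = m)
}

#' Dimensionless Kratky transform
#'
#' x = q Rg, y = (q Rg)^2 I(q) / I(0). Parameter-free for an ideal Guinier
#' curve (peak at x = sqrt(3), height 3/e), bell-shaped for compactly
#' folded RNA, and invariant to global intensity rescaling.
#'
#' @param curve a \linkS4class{ScatteringCurve}.
#' @param guinier the curve's \linkS4class{GuinierResult}.
#' @return data.frame with columns x (= qRg) and y.
#' @export
dimensionlessKratky <- function(curve, guinier) {
  x <- curve@q * guinier@Rg
  y <- x^2 * curve@I / guinier@I0
  data.frame(x = x, y = y)
}

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf(
    "GuinierResult: Rg = %.2f +/- %.2f A, I(0) = %.4g (q window %.4g-%.4g, qRg_max %.2f, %d pts)\n",
    object@Rg, object@RgSe, object@I0, object@qRange[1], object@qRange[2],
    object@qRgMax, object@nPoints))
})

setMethod("show", "ScatteringCurve", function(object) {
  cat(sprintf("ScatteringCurve: %d points, q in [%.4g, %.4g] A^-1\n",
              length(object@q), min(object@q), max(object@q)))
})
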