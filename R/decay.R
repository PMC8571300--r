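#' Construct an Xrn1 decay trace
#'
#' @param time time in minutes after Xrn1 addition.
#' @param fexp,fcon fluorescence of the +Xrn1 (experimental) and -Xrn1
#'   (control) wells on the same time grid.
#' @param construct,mg condition labels.
#' @return a \linkS4class{DecayTrace}.
#' @export
decayTrace <- function(time, fexp, fcon, construct = NA_character_,
                       mg = NA_real_) {
  new("DecayTrace", time = time, fexp = fexp, fcon = fcon,
      condition = list(construct = construct, mg = mg))
}

#' Simulate an Xrn1 decay trace pair
#'
#' The experimental well decays as F0 exp(-rate t); both wells share any
#' multiplicative instrument drift, so control normalization cancels it.
#'
#' @param rate decay rate in min^-1 (>= 0).
#' @param duration assay length in minutes.
#' @param sampling sampling interval in minutes.
#' @param noiseSd multiplicative noise s.d. (0 = noiseless).
#' @param drift optional function of time (minutes) giving the shared
#'   multiplicative drift; NULL = flat.
#' @param f0 initial fluorescence.
#' @param seed optional integer seed.
#' @param construct,mg condition labels.
#' @return a \linkS4class{DecayTrace}.
#' @export
simulateDecayTrace <- function(rate, duration = 60, sampling = 1,
                               noiseSd = 0, drift = NULL, f0 = 1000,
                               seed = NULL, construct = "synthetic",
                               mg = NA_real_) {
  stopifnot(rate >= 0, duration > 0, sampling > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = sampling)
  d <- if (is.null(drift)) rep(1, length(t)) else drift(t)
  noise <- function() if (noiseSd > 0)
    1 + stats::rnorm(length(t), 0, noiseSd) else 1
  fexp <- f0 * exp(-rate * t) * d * noise()
  fcon <- f0 * d * noise()
  decayTrace(t, fexp, fcon, construct = construct, mg = mg)
}

#' Normalize a decay trace to its minus-enzyme control
#'
#' F(t) = (F_exp(t) / F_exp(0)) / (F_con(t) / F_con(0)); F(0) = 1 exactly,
#' and any drift shared by the two wells cancels. Points where the control
#' is zero are masked with a warning.
#'
#' @param trace a \linkS4class{DecayTrace}.
#' @return data.frame with columns time and F (masked points dropped).
#' @export
normalizeDecay <- function(trace) {
  validObject(trace)
  i0 <- which.min(abs(trace@time))
  e0 <- trace@fexp[i0]; c0 <- trace@fcon[i0]
  bad <- trace@fcon == 0
  if (any(bad))
    warning(sum(bad), " point(s) with zero control fluorescence masked")
  keep <- !bad
  data.frame(time = trace@time[keep],
             F = (trace@fexp[keep] / e0) / (trace@fcon[keep] / c0))
}

#' Fit a single-exponential decay rate
#'
#' Least-squares fit of F(t) = plateau + (1 - plateau) exp(-rate t) to a
#' normalized decay series. The plateau is fixed at 0 by default (a pure
#' single exponential); freeing it accommodates constructs whose
#' normalized fluorescence levels off at their resistant fraction.
#'
#' @param time time in minutes, or a data.frame from
#'   \code{\link{normalizeDecay}} (then \code{F} is taken from it).
#' @param F normalized fluorescence.
#' @param freePlateau fit the plateau as a free parameter.
#' @param tStart drop points before this time (minutes), e.g. a pre-binding
#'   window recorded before enzyme addition.
#' @return a \linkS4class{DecayFit} (rate in min^-1).
#' @export
fitDecayRate <- function(time, F = NULL, freePlateau = FALSE, tStart = 0) {
  if (is.data.frame(time)) { F <- time$F; time <- time$time }
  keep <- time >= tStart
  time <- time[keep]; F <- F[keep]
  stopifnot(length(time) >= 5L)
  df <- data.frame(t = time, y = F)

  ## an (essentially) constant series is the rate-0 limit; nonlinear
  ## least squares has a vanishing numerical gradient there
  if (stats::sd(df$y) < 1e-10 * max(abs(df$y), 1))
    return(new("DecayFit", rate = 0, se = 0,
               plateau = if (freePlateau) mean(df$y) else 0,
               r2 = NA_real_, flags = "constant series"))

  ## log-linear start (robust to noise; exact on noiseless data)
  pos <- df$y > 0
  k0 <- if (sum(pos) >= 2L)
    max(-unname(stats::coef(stats::lm(log(y) ~ t, df[pos, ]))[2]), 1e-3)
  else 0.1
  flags <- character(0)
  if (freePlateau) {
    fit <- minpack.lm::nlsLM(y ~ p + (1 - p) * exp(-k * t), data = df,
                             start = list(k = k0, p = max(min(df$y), 0)),
                             lower = c(-1, 0), upper = c(Inf, 1))
    co <- summary(fit)$coefficients
    rate <- co["k", "Estimate"]; rateSe <- co["k", "Std. Error"]
    plateau <- co["p", "Estimate"]
  } else {
    fit <- minpack.lm::nlsLM(y ~ exp(-k * t), data = df,
                             start = list(k = k0), lower = -1)
    co <- summary(fit)$coefficients
    rate <- co["k", "Estimate"]; rateSe <- co["k", "Std. Error"]
    plateau <- 0
  }
  if (rate < 0) flags <- "negative fitted rate"
  resid <- df$y - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((df$y - mean(df$y))^2)
  if (!is.finite(r2)) r2 <- NA_real_   # constant series: zero variance
  new("DecayFit", rate = rate, se = rateSe, plateau = plateau, r2 = r2,
      flags = flags)
}

#' Decay rate relative to the MG-aptamer control
#'
#' Ratio of a construct's decay rate to the rate of the malachite-green
#' aptamer control at the matched Mg2+ concentration, correcting for the
#' Mg2+ dependence of Xrn1 activity itself. Standard errors are propagated
#' in quadrature on the relative scale.
#'
#' @param constructFit,controlFit \linkS4class{DecayFit} objects.
#' @param mg Mg2+ concentration label (mM).
#' @return list with \code{relRate}, \code{se}, \code{mg}.
#' @export
relativeRate <- function(constructFit, controlFit, mg = NA_real_) {
  if (controlFit@rate <= 0)
    stop("control decay rate must be > 0")
  ratio <- constructFit@rate / controlFit@rate
  relVar <- (constructFit@se / constructFit@rate)^2 +
    (controlFit@se / controlFit@rate)^2
  se <- if (constructFit@rate > 0) abs(ratio) * sqrt(relVar) else NA_real_
  list(relRate = ratio, se = se, mg = mg)
}

#' Correlate two kinetic quantities
#'
#' Pearson correlation (two-sided test) with an ordinary least-squares
#' slope, optionally on log-transformed axes; the workhorse for
#' structure-function comparisons such as decay rate versus H-state
#' fraction or versus individual transition rates, pooled across
#' constructs.
#'
#' @param x,y paired finite values (n >= 3).
#' @param logX,logY log10-transform the respective axis (requires positive
#'   values).
#' @return list with r, p, slope, intercept, n.
#' @export
correlateSeries <- function(x, y, logX = FALSE, logY = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 3L)
  if (logX) { stopifnot(all(x > 0)); x <- log10(x) }
  if (logY) { stopifnot(all(y > 0)); y <- log10(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  co <- stats::coef(stats::lm(y ~ x))
  list(r = unname(ct$estimate), p = ct$p.value, slope = unname(co[2]),
       intercept = unname(co[1]), n = length(x))
}

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: rate = %.4g +/- %.2g min^-1 (plateau %.3f, R2 %.3f)\n",
              object@rate, object@se, object@plateau, object@r2))
})

setMethod("show", "DecayTrace", function(object) {
  cat(sprintf("DecayTrace (%s, %s mM Mg2+): %d points over %.3g min\n",
              object@condition$construct, format(object@condition$mg),
              length(object@time), max(object@time)))
})
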