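#' Fit a shared Gaussian-emission hidden Markov model
#'
#' Baum-Welch maximum-likelihood fit of one HMM across all FRET series of a
#' condition (ensemble-level, as for histograms and TDPs). The
#' log-likelihood is non-decreasing across iterations; convergence is
#' declared when its increase falls below \code{tol}. States are relabelled
#' by ascending emission mean so that 1/2/3 always map onto L/I/H.
#'
#' @param fretSeries list of numeric FRET series (each >= 10 frames), or a
#'   single numeric vector.
#' @param nStates number of hidden states (default 3; the ensembles studied
#'   here show three FRET states).
#' @param initStrategy "kmeans" (default: k-means centres on a pooled-data
#'   subsample, robust to unequal state occupancies), "quantile"
#'   (pooled-data quantiles) or "spread" (evenly spaced on the pooled
#'   range).
#' @param seed optional integer seed (initialization is deterministic, so
#'   this matters only for reproducibility bookkeeping).
#' @param maxIter,tol Baum-Welch iteration cap and log-likelihood tolerance.
#' @return an \linkS4class{HmmModel}.
#' @export
fitHmm <- function(fretSeries, nStates = 3L, initStrategy = "kmeans",
                   seed = NULL, maxIter = 200L, tol = 1e-4) {
  if (is.numeric(fretSeries)) fretSeries <- list(fretSeries)
  stopifnot(length(fretSeries) >= 1L)
  fretSeries <- lapply(fretSeries, as.numeric)
  if (any(vapply(fretSeries, length, integer(1)) < 10L))
    stop("every series must have at least 10 frames")
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(nStates)
  pooled <- unlist(fretSeries, use.names = FALSE)

  mu <- switch(initStrategy,
    kmeans = {
      ## seeded from the data size so the fit is a pure function of input
      set.seed((length(pooled) + 7L * K) %% 1000003L)
      sub <- if (length(pooled) > 2e4) sample(pooled, 2e4) else pooled
      if (K > 1L && length(unique(sub)) > K) {
        km <- stats::kmeans(sub, centers = K, nstart = 5L,
                            iter.max = 50L)
        sort(as.numeric(km$centers))
      } else as.numeric(stats::quantile(sub,
               probs = seq(0.5 / K, 1 - 0.5 / K, length.out = K)))
    },
    quantile = as.numeric(stats::quantile(pooled,
                 probs = seq(0.5 / K, 1 - 0.5 / K, length.out = K))),
    spread = seq(min(pooled), max(pooled), length.out = K + 2L)[2:(K + 1L)],
    stop("unknown initStrategy"))
  if (K > 1L && min(diff(mu)) < 1e-6)            # degenerate seeds
    mu <- mu + seq(0, 1e-3, length.out = K)
  sigma <- rep(max(stats::sd(pooled) / K, 0.02), K)
  A <- matrix(0.05 / max(K - 1L, 1L), K, K); diag(A) <- if (K > 1L) 0.95 else 1
  pi0 <- rep(1 / K, K)

  llTrace <- numeric(0)
  llPrev <- -Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    gSum <- numeric(K); gxSum <- numeric(K); gx2Sum <- numeric(K)
    xiSum <- matrix(0, K, K); g1Sum <- numeric(K)
    ll <- 0
    for (x in fretSeries) {
      fb <- .fb_gaussian(x, mu, sigma, A, pi0)
      ll <- ll + fb$loglik
      g <- fb$gamma
      gSum <- gSum + colSums(g)
      gxSum <- gxSum + colSums(g * x)
      gx2Sum <- gx2Sum + colSums(g * x^2)
      xiSum <- xiSum + fb$xi
      g1Sum <- g1Sum + fb$gamma1
    }
    llTrace <- c(llTrace, ll)
    if (is.finite(llPrev) && ll - llPrev < tol) { converged <- TRUE; break }
    llPrev <- ll
    pi0 <- g1Sum / sum(g1Sum)
    if (K > 1L) {
      rs <- rowSums(xiSum)
      A <- xiSum / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / K
    }
    mu <- gxSum / gSum
    sigma <- sqrt(pmax(gx2Sum / gSum - mu^2, 1e-6))
  }

  ## relabel by ascending mean
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]
  A <- A[ord, ord, drop = FALSE]; pi0 <- pi0[ord]
  occupancy <- gSum[ord] / sum(gSum)
  flags <- character(0)
  if (!converged) flags <- c(flags, "not converged")
  if (any(occupancy < 1e-3)) {
    flags <- c(flags, sprintf("degenerate state(s): %s",
      paste(which(occupancy < 1e-3), collapse = ",")))
    warning("HMM has degenerate state(s) with occupancy < 0.1%")
  }
  new("HmmModel", nStates = K, means = mu, sds = sigma, transMat = A,
      initProb = pi0, logLik = llTrace[length(llTrace)],
      logLikTrace = llTrace, converged = converged, flags = flags)
}

#' Idealize a FRET series with a fitted model
#'
#' Viterbi most-probable state path (the default decoding for the red
#' idealized traces overlaid on experimental ones); posterior-mode decoding
#' is available as an option.
#'
#' @param model a fitted \linkS4class{HmmModel}.
#' @param fret numeric FRET series.
#' @param method "viterbi" or "posterior".
#' @param id source trace identifier.
#' @return an \linkS4class{IdealizedTrace}.
#' @export
idealizeTrace <- function(model, fret, method = c("viterbi", "posterior"),
                          id = "trace") {
  method <- match.arg(method)
  fret <- as.numeric(fret)
  ## floor hard zeros so a state the training set never started in is
  ## still decodable at the first frame of a new trace
  pi0 <- pmax(model@initProb, 1e-12); pi0 <- pi0 / sum(pi0)
  A <- pmax(model@transMat, 1e-12); A <- A / rowSums(A)
  states <- if (method == "viterbi") {
    .viterbi_gaussian(fret, model@means, model@sds, A, pi0)
  } else {
    fb <- .fb_gaussian(fret, model@means, model@sds, A, pi0)
    max.col(fb$gamma, ties.method = "first")
  }
  new("IdealizedTrace", states = as.integer(states), fret = fret,
      stateMeans = model@means, id = id)
}

setMethod("show", "HmmModel", function(object) {
  cat(sprintf("HmmModel: %d states, logLik %.2f (%s)\n", object@nStates,
              object@logLik,
              if (object@converged) "converged" else "not converged"))
  cat("  means:", paste(sprintf("%.3f", object@means), collapse = " "), "\n")
  cat("  sds:  ", paste(sprintf("%.3f", object@sds), collapse = " "), "\n")
})

setMethod("show", "IdealizedTrace", function(object) {
  occ <- table(factor(object@states, levels = seq_along(object@stateMeans)))
  cat(sprintf("IdealizedTrace '%s': %d frames; occupancy %s\n", object@id,
              length(object@states),
              paste(sprintf("%.2f", occ / sum(occ)), collapse = "/")))
})

#' Select the number of HMM states by BIC
#'
#' Fits models with 1..\code{maxStates} states and returns the fit with the
#' lowest Bayesian information criterion. Intended for constructs whose
#' state centres shift (e.g. labeling-site variants) where three states
#' cannot be assumed.
#'
#' @inheritParams fitHmm
#' @param maxStates largest model considered (default 4).
#' @return list with \code{model} (the selected \linkS4class{HmmModel}),
#'   \code{nStates}, and \code{bic} (one value per candidate).
#' @export
selectHmmStates <- function(fretSeries, maxStates = 4L, ...) {
  if (is.numeric(fretSeries)) fretSeries <- list(fretSeries)
  nObs <- sum(vapply(fretSeries, length, integer(1)))
  fits <- lapply(seq_len(maxStates), function(K)
    suppressWarnings(fitHmm(fretSeries, nStates = K, ...)))
  nPar <- vapply(seq_len(maxStates), function(K)
    2 * K + K * (K - 1) + (K - 1), numeric(1))
  bic <- vapply(seq_len(maxStates), function(K)
    -2 * fits[[K]]@logLik + nPar[K] * log(nObs), numeric(1))
  best <- which.min(bic)
  list(model = fits[[best]], nStates = best, bic = bic)
}
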