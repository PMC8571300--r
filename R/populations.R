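#' Fit Gaussian-mixture state populations to pooled FRET data
#'
#' Fits an \code{nStates}-component Gaussian mixture (unequal variances) to
#' pooled per-frame FRET values; the fractional population of each state is
#' its mixture weight. Components are sorted by ascending centre and
#' labelled L / I / H.
#'
#' @param fretSeries list of FRET series or a single pooled numeric vector.
#' @param nStates number of components (default 3).
#' @param condition Mg2+ concentration label in mM (optional).
#' @param subsetSize k-means initialization runs on a deterministic
#'   subsample of at most this many points.
#' @param seed integer seed for the initialization subsample.
#' @return a \linkS4class{StatePopulations}.
#' @importFrom mclust em emV emE
#' @export
fitStatePopulations <- function(fretSeries, nStates = 3L,
                                condition = NA_real_, subsetSize = 5000L,
                                seed = 1L) {
  x <- unlist(fretSeries, use.names = FALSE)
  stopifnot(length(x) >= 10L * nStates)
  ## deterministic k-means seeding, then full-data EM (model "V", falling
  ## back to pooled variances if a component collapses); hierarchical
  ## initialization on a subsample is not robust to the boundary spikes
  ## that intensity-ratio clipping produces
  set.seed(seed)
  sub <- if (length(x) > subsetSize) sample(x, subsetSize) else x
  km <- stats::kmeans(sub, centers = nStates, nstart = 10L, iter.max = 50L)
  ord0 <- order(km$centers)
  mu0 <- as.numeric(km$centers)[ord0]
  w0 <- (km$size / sum(km$size))[ord0]
  var0 <- pmax(vapply(ord0, function(k)
    stats::var(sub[km$cluster == k]), numeric(1)), 1e-6)

  runEm <- function(model, sigmasq) {
    par <- list(pro = w0, mean = mu0,
                variance = list(modelName = model, d = 1, G = nStates,
                                sigmasq = sigmasq))
    tryCatch(mclust::em(modelName = model, data = x, parameters = par),
             error = function(e) NULL)
  }
  fit <- runEm("V", var0)
  if (is.null(fit) || !is.finite(fit$loglik) ||
      any(!is.finite(fit$parameters$mean)))
    fit <- runEm("E", mean(var0))
  if (is.null(fit) || !is.finite(fit$loglik))
    stop("Gaussian mixture fit did not converge for G = ", nStates)
  ord <- order(fit$parameters$mean)
  centers <- as.numeric(fit$parameters$mean[ord])
  widths <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(widths) == 1L) widths <- rep(widths, nStates)
  widths <- widths[ord]
  fractions <- fit$parameters$pro[ord]
  flags <- character(0)
  if (any(fractions < 1e-3))
    flags <- "near-empty component(s): data may not span all states"
  new("StatePopulations", centers = centers, widths = widths,
      fractions = fractions / sum(fractions), condition = condition,
      source = "mixture", flags = flags)
}

#' Fractional state populations
#'
#' The relative fraction of each FRET state, computed either as frame
#' occupancy of idealized traces or taken from a Gaussian-mixture fit.
#'
#' @param x a list of \linkS4class{IdealizedTrace} objects, a single one,
#'   or a \linkS4class{StatePopulations}.
#' @param condition optional Mg2+ label attached to the result.
#' @return named numeric (L, I, H) summing to 1, with attribute
#'   \code{source} ("occupancy" or "mixture").
#' @export
fractionalPopulations <- function(x, condition = NA_real_) {
  if (is(x, "StatePopulations")) {
    out <- x@fractions
    names(out) <- STATE_LABELS[seq_along(out)]
    return(structure(out, source = "mixture", condition = condition))
  }
  if (is(x, "IdealizedTrace")) x <- list(x)
  stopifnot(length(x) > 0L)
  K <- length(x[[1]]@stateMeans)
  counts <- numeric(K)
  for (tr in x)
    counts <- counts + tabulate(tr@states, nbins = K)
  out <- counts / sum(counts)
  names(out) <- STATE_LABELS[seq_len(K)]
  structure(out, source = "occupancy", condition = condition)
}

setMethod("show", "StatePopulations", function(object) {
  cat("StatePopulations",
      if (!is.na(object@condition)) sprintf("(%g mM Mg2+)", object@condition),
      "\n")
  df <- data.frame(state = STATE_LABELS[seq_along(object@centers)],
                   center = round(object@centers, 3),
                   width = round(object@widths, 3),
                   fraction = round(object@fractions, 3))
  print(df, row.names = FALSE)
})
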