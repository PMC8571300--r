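#' Default configuration for a titration analysis run
#'
#' @param mgConcs Mg2+ concentrations in mM.
#' @param nTraces traces per concentration.
#' @param duration per-trace duration (s).
#' @param rateLaw an \linkS4class{MgRateLaw} (synthetic mode).
#' @param emission an \linkS4class{EmissionModel}.
#' @param frameInterval seconds per frame.
#' @param nStates HMM states.
#' @param binWidth,tdpBinWidth histogram and TDP bin widths.
#' @param temperatureK temperature for the energy landscapes.
#' @param bleach bleach-handling mode passed to \code{\link{computeFret}}.
#' @param seed integer seed recorded in every output.
#' @param outputDir optional directory for artifact files.
#' @return a named list (the run configuration).
#' @export
titrationConfig <- function(mgConcs = c(0.01, 0.1, 1, 10, 100),
                            nTraces = 50L, duration = 30,
                            rateLaw = mgRateLaw(),
                            emission = emissionModel(),
                            frameInterval = 0.025, nStates = 3L,
                            binWidth = 0.02, tdpBinWidth = 0.02,
                            temperatureK = 298.15, bleach = "detect",
                            seed = 1L, outputDir = NULL) {
  list(mode = "synthetic", mgConcs = mgConcs, nTraces = nTraces,
       duration = duration, rateLaw = rateLaw, emission = emission,
       frameInterval = frameInterval, nStates = nStates,
       binWidth = binWidth, tdpBinWidth = tdpBinWidth,
       temperatureK = temperatureK, bleach = bleach, seed = seed,
       outputDir = outputDir)
}

withStage <- function(stage, condition, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s | condition %s] %s", stage, condition,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end titration analysis
#'
#' For each Mg2+ condition: simulate (or take) traces, compute FRET with
#' bleach truncation, fit one shared HMM, idealize, build the histogram,
#' mixture populations, dwells, the six transition rates, the TDP and the
#' free-energy landscape. Across conditions: occupancy fractions versus
#' Mg2+, Hill fits of the H- and L-state fractions (when >= 4
#' concentrations) and the critical Mg2+ concentration. The returned
#' manifest carries every artifact plus the configuration and seed; runs
#' are deterministic given the seed.
#'
#' @param config a list from \code{\link{titrationConfig}}. For real data
#'   set \code{mode = "traces"} and supply \code{conditions}: a list of
#'   \code{list(mg =, traces = list of FretTrace)}.
#' @return manifest list with \code{conditions} (per-condition results),
#'   \code{fractions} (state fractions by concentration), \code{hill},
#'   \code{criticalMg} and \code{config}.
#' @export
runTitrationAnalysis <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  set.seed(config$seed)
  condIn <- if (identical(config$mode, "synthetic")) {
    simulateTitration(config$rateLaw, config$mgConcs,
                      nTraces = config$nTraces,
                      duration = config$duration,
                      emission = config$emission,
                      frameInterval = config$frameInterval)
  } else config$conditions
  stopifnot(length(condIn) > 0L)

  results <- lapply(condIn, function(cond) {
    lab <- sprintf("%g mM", cond$mg)
    fret <- withStage("fret", lab,
      lapply(cond$traces, computeFret, bleach = config$bleach))
    keep <- vapply(fret, length, integer(1)) >= 10L
    fret <- fret[keep]
    usable <- cond$traces[keep]
    model <- withStage("hmm", lab,
      suppressWarnings(fitHmm(fret, nStates = config$nStates)))
    ideal <- withStage("idealize", lab,
      lapply(seq_along(fret), function(i)
        idealizeTrace(model, fret[[i]], id = usable[[i]]@id)))
    hist <- withStage("histogram", lab,
      suppressWarnings(buildHistogram(fret, binWidth = config$binWidth)))
    pops <- withStage("populations", lab,
      fitStatePopulations(fret, nStates = config$nStates,
                          condition = cond$mg, seed = config$seed))
    dwells <- withStage("dwells", lab,
      extractDwells(ideal, frameInterval = config$frameInterval))
    rateSet <- withStage("rates", lab, {
      lt <- suppressWarnings(fitLifetimes(dwells))
      transitionRates(lt, dwells)
    })
    tdp <- withStage("tdp", lab,
      suppressWarnings(buildTdp(ideal, binWidth = config$tdpBinWidth)))
    landscape <- withStage("landscape", lab, tryCatch(
      freeEnergyLandscape(rateSet, temperatureK = config$temperatureK),
      error = function(e) NULL))   # some rates may be unobserved
    list(mg = cond$mg, model = model, idealized = ideal,
         histogram = hist, populations = pops, dwells = dwells,
         rates = rateSet, tdp = tdp, landscape = landscape,
         fractions = fractionalPopulations(ideal, condition = cond$mg),
         truthRates = cond$truthRates)
  })

  mg <- vapply(results, `[[`, numeric(1), "mg")
  frac <- t(vapply(results, `[[`, numeric(3), "fractions"))
  rownames(frac) <- sprintf("%g", mg)
  hill <- NULL; crit <- NULL
  if (length(mg) >= 4L) {
    hill <- withStage("hill", "all", list(
      H = fitHill(mg, frac[, "H"], state = "H"),
      L = fitHill(mg, frac[, "L"], state = "L")))
    crit <- withStage("criticalMg", "all",
      criticalMg(hill$H, hill$L, range = range(mg)))
  }
  manifest <- list(conditions = results, fractions = frac, hill = hill,
                   criticalMg = crit,
                   config = config[setdiff(names(config),
                                           c("rateLaw", "emission"))])
  if (!is.null(config$outputDir)) writeManifest(manifest, config$outputDir)
  manifest
}

## Flat numeric summaries to disk: rates CSV, fractions CSV, landscape and
## run-metadata JSON. Kept deliberately plain-text.
writeManifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rateRows <- do.call(rbind, lapply(manifest$conditions, function(x)
    data.frame(mg = x$mg, transition = RATE_NAMES, k = x$rates@rates,
               se = x$rates@se)))
  utils::write.csv(rateRows, file.path(dir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(mg = as.numeric(rownames(manifest$fractions)),
                              manifest$fractions),
                   file.path(dir, "fractions.csv"), row.names = FALSE)
  meta <- list(seed = manifest$config$seed,
               nTraces = manifest$config$nTraces,
               duration = manifest$config$duration,
               mgConcs = manifest$config$mgConcs,
               criticalMg = manifest$criticalMg,
               landscapes = lapply(manifest$conditions, function(x)
                 if (is.null(x$landscape)) NULL else
                   list(mg = x$mg, dG = as.list(x$landscape@dG),
                        closure = x$landscape@closure)))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Compare an analysis run against the generator ground truth
#'
#' Tabulates relative errors of the estimated transition rates, state
#' emission means and fractional populations against the known generating
#' values of a synthetic run.
#'
#' @param manifest result of \code{\link{runTitrationAnalysis}} in
#'   synthetic mode.
#' @param emission the generating \linkS4class{EmissionModel} (defaults to
#'   the package default).
#' @return data.frame with columns mg, quantity, estimated, truth,
#'   relError.
#' @export
validateAgainstTruth <- function(manifest, emission = emissionModel()) {
  rows <- lapply(manifest$conditions, function(x) {
    if (is.null(x$truthRates))
      stop("condition ", x$mg, " carries no ground truth (not synthetic?)")
    truthK <- x$truthRates@rates
    est <- x$rates@rates
    statTruth <- stationaryDistribution(x$truthRates)
    rbind(
      data.frame(mg = x$mg, quantity = paste0("k_", RATE_NAMES),
                 estimated = unname(est), truth = unname(truthK)),
      data.frame(mg = x$mg, quantity = paste0("mean_", STATE_LABELS),
                 estimated = x$model@means, truth = emission@means),
      data.frame(mg = x$mg, quantity = paste0("frac_", STATE_LABELS),
                 estimated = unname(x$fractions),
                 truth = unname(statTruth)))
  })
  out <- do.call(rbind, rows)
  out$relError <- ifelse(out$truth != 0,
                         abs(out$estimated - out$truth) / abs(out$truth),
                         abs(out$estimated))
  out
}
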