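#' Hill fit of a fractional population versus Mg2+
#'
#' Least-squares fit of f(c) = baseline + amplitude * c^n / (K^n + c^n) to
#' per-concentration state fractions (linear fraction axis, concentrations
#' spanning decades). Decreasing titrations are accommodated by a negative
#' amplitude. By convention only the high- and low-FRET state fractions are
#' fitted; the intermediate state is refused unless
#' \code{allowIntermediate = TRUE}.
#'
#' @param mg Mg2+ concentrations in mM (>= 4 values).
#' @param fractions state fractions at each concentration.
#' @param state which state the fractions belong to ("H", "L" or "I").
#' @param allowIntermediate override the refusal to fit the I state.
#' @return a \linkS4class{HillFit}.
#' @export
fitHill <- function(mg, fractions, state = c("H", "L", "I"),
                    allowIntermediate = FALSE) {
  state <- match.arg(state)
  if (state == "I" && !allowIntermediate)
    stop("the intermediate-state fraction is not fitted by convention; ",
         "set allowIntermediate = TRUE to override")
  stopifnot(length(mg) == length(fractions), length(mg) >= 4L, all(mg > 0))
  df <- data.frame(c = mg, f = fractions)

  f0 <- fractions[which.min(mg)]; f1 <- fractions[which.max(mg)]
  ## a flat titration leaves K and n unidentifiable: report it, don't fit
  if (stats::sd(fractions) < 1e-8)
    return(new("HillFit",
               params = c(amplitude = 0, K = NA_real_, n = NA_real_,
                          baseline = mean(fractions)),
               se = c(amplitude = 0, K = NA_real_, n = NA_real_,
                      baseline = 0),
               state = state, converged = TRUE,
               flags = "amplitude ~ 0: K and n are unidentifiable (flat titration)"))
  start <- list(baseline = f0,
                amplitude = if (abs(f1 - f0) > 1e-3) f1 - f0 else 0.1,
                K = exp(mean(log(range(mg)))), n = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ baseline + amplitude * c^n / (K^n + c^n),
                      data = df, start = start,
                      lower = c(-1, -1, min(mg) / 100, 0.05),
                      upper = c(2, 2, max(mg) * 100, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Hill fit did not converge: ", conditionMessage(e),
           "\nlast start: ", paste(names(start), unlist(start),
                                   sep = "=", collapse = ", ")))
  co <- summary(fit)$coefficients
  params <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  ord <- c("amplitude", "K", "n", "baseline")
  flags <- character(0)
  if (abs(params[["amplitude"]]) < 0.02 ||
      abs(params[["amplitude"]]) < 2 * se[["amplitude"]])
    flags <- "amplitude ~ 0: K and n are unidentifiable (flat titration)"
  new("HillFit", params = params[ord], se = se[ord], state = state,
      converged = fit$convInfo$isConv, flags = flags)
}

#' Evaluate a fitted Hill curve
#'
#' @param fit a \linkS4class{HillFit}.
#' @param mg concentrations in mM.
#' @return fitted fractions.
#' @export
predictHill <- function(fit, mg) {
  p <- fit@params
  p[["baseline"]] + p[["amplitude"]] * mg^p[["n"]] /
    (p[["K"]]^p[["n"]] + mg^p[["n"]])
}

#' Critical Mg2+ concentration
#'
#' The lowest concentration above which the fitted H-state fraction
#' exceeds the fitted L-state fraction, located by bisection on the two
#' Hill curves over \code{range}.
#'
#' @param hillH,hillL \linkS4class{HillFit} objects for the H- and L-state
#'   fractions.
#' @param range concentration search range in mM.
#' @param tol bisection tolerance (mM).
#' @return list with \code{mg} (the crossing; the range minimum or Inf at
#'   the boundaries) and \code{flag} ("crossing", "below-range" when H > L
#'   everywhere, "no-crossing" when H < L everywhere).
#' @export
criticalMg <- function(hillH, hillL, range = c(1e-3, 100), tol = 1e-4) {
  g <- function(c) predictHill(hillH, c) - predictHill(hillL, c)
  grid <- exp(seq(log(range[1]), log(range[2]), length.out = 512L))
  v <- g(grid)
  if (v[1] > 0) return(list(mg = range[1], flag = "below-range"))
  pos <- which(v > 0)
  if (length(pos) == 0L) return(list(mg = Inf, flag = "no-crossing"))
  i <- pos[1]
  root <- stats::uniroot(g, lower = grid[i - 1L], upper = grid[i],
                         tol = tol)$root
  list(mg = root, flag = "crossing")
}

setMethod("show", "HillFit", function(object) {
  p <- object@params
  cat(sprintf(
    "HillFit (%s state): K = %.3g mM, n = %.2f, amplitude = %.3f, baseline = %.3f\n",
    object@state, p[["K"]], p[["n"]], p[["amplitude"]], p[["baseline"]]))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})
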