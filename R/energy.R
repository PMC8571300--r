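#' Illustrative transition barrier height
#'
#' The plotting convention for barrier heights: for a transition with rate
#' constant k (in s^-1), barrier = -kBT * ln(k) + 1.8 kBT. The 1.8 kBT
#' offset fixes the zero of the barrier scale; absolute values therefore
#' depend on the rate unit convention and are used for illustration only.
#'
#' @param k rate constant in s^-1 (> 0).
#' @param kBT thermal energy; pass 1 to get the barrier in units of kBT,
#'   or a value in kcal/mol for absolute units.
#' @return barrier height in the units of \code{kBT}.
#' @export
transitionBarrier <- function(k, kBT) {
  stopifnot(all(k > 0), kBT > 0)
  -kBT * log(k) + 1.8 * kBT
}

#' Free-energy landscape from transition rates
#'
#' Relative free energies from detailed balance on rate pairs:
#' dG_b - dG_a = -kBT ln(k_ab / k_ba), with the low-FRET (unfolded) state
#' as the ground state (dG_L = 0). dG_I uses the L-I pair; dG_H is built
#' sequentially as dG_I plus the I-H pair term, following the sequential
#' folding pathway L -> I -> H. The direct H-L pair gives an independent
#' estimate of dG_H whose difference from the sequential value is reported
#' as the cycle-closure (detailed-balance) residual. Barriers follow the
#' -kBT ln(k) + 1.8 kBT convention; the L -> H barrier is not computed
#' because that rate is too rarely observed to be reliable.
#'
#' @param rates a \linkS4class{RateSet} or \linkS4class{GeneratorRates};
#'   k_LI, k_IL, k_IH and k_HI must all be > 0.
#' @param temperatureK temperature in K (default 298.15, i.e. 25 C;
#'   kBT = 0.5925 kcal/mol).
#' @return an \linkS4class{EnergyLandscape} (energies in kcal/mol).
#' @export
freeEnergyLandscape <- function(rates, temperatureK = 298.15) {
  r <- rates@rates
  kBT <- KB_KCAL * temperatureK
  required <- c("LI", "IL", "IH", "HI")
  bad <- required[r[required] <= 0 | is.na(r[required])]
  if (length(bad))
    stop("rate(s) ", paste0("k_", bad, collapse = ", "),
         " must be > 0 to compute the landscape")

  dGI <- -kBT * log(r[["LI"]] / r[["IL"]])
  dGH <- dGI - kBT * log(r[["IH"]] / r[["HI"]])
  closure <- if (r[["LH"]] > 0 && r[["HL"]] > 0)
    (-kBT * log(r[["LH"]] / r[["HL"]])) - dGH
  else NA_real_

  barriers <- c(`L->I` = transitionBarrier(r[["LI"]], kBT),
                `I->L` = transitionBarrier(r[["IL"]], kBT),
                `I->H` = transitionBarrier(r[["IH"]], kBT),
                `H->I` = transitionBarrier(r[["HI"]], kBT),
                `H->L` = if (r[["HL"]] > 0)
                  transitionBarrier(r[["HL"]], kBT) else NA_real_)

  new("EnergyLandscape", dG = c(L = 0, I = dGI, H = dGH),
      barriers = barriers, temperature = temperatureK, kBT = kBT,
      closure = unname(closure))
}

#' Pairwise free-energy difference between two states
#'
#' dG_b - dG_a = -kBT ln(k_ab / k_ba); antisymmetric in (a, b).
#'
#' @param kab,kba forward and reverse rate constants (> 0).
#' @param temperatureK temperature in K.
#' @return energy difference in kcal/mol.
#' @export
pairFreeEnergy <- function(kab, kba, temperatureK = 298.15) {
  stopifnot(kab > 0, kba > 0)
  -KB_KCAL * temperatureK * log(kab / kba)
}

setMethod("show", "EnergyLandscape", function(object) {
  cat(sprintf("EnergyLandscape at %.2f K (kBT = %.4f kcal/mol)\n",
              object@temperature, object@kBT))
  cat("  dG (kcal/mol):",
      paste(sprintf("%s = %.3f", names(object@dG), object@dG),
            collapse = ", "), "\n")
  if (!is.na(object@closure))
    cat(sprintf("  cycle-closure residual: %.3f kcal/mol\n",
                object@closure))
})
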