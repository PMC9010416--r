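## Thin-film buckling mechanics of the stiff-skinned substrate.

#' Wrinkle wavelength to skin thickness ratio
#'
#' For a stiff layer (modulus \code{Ep}) on a soft elastomer (\code{Em})
#' under compression, the buckling wavelength satisfies
#' \deqn{\lambda / h = 2\pi (E_p / 3 E_m)^{1/3}.}
#'
#' @param Ep,Em skin and elastomer Young's moduli, Pa (> 0). A
#'   \linkS4class{BilayerSubstrate} may be passed as \code{Ep}.
#' @return Dimensionless wavelength ratio.
#' @seealso [stiffnessRatioFromWavelength()] for the exact inverse.
#' @export
wavelengthRatio <- function(Ep, Em) {
  if (is(Ep, "BilayerSubstrate")) { Em <- Ep@Em; Ep <- Ep@Ep }
  if (!(Ep > 0) || !(Em > 0)) wfmStop("moduli must be positive")
  2 * pi * (Ep / (3 * Em))^(1 / 3)
}

#' Stiffness ratio from an observed wavelength ratio
#'
#' Exact inversion of [wavelengthRatio()]:
#' \eqn{E_p/E_m = 3 (\lambda / 2\pi h)^3}. Observing wavelengths of a few
#' micrometres on a skin of order 100 nm (ratio near 30) implies a
#' stiffness ratio of order 300.
#'
#' @param lambdaOverH dimensionless wavelength ratio (> 0).
#' @return The stiffness ratio Ep/Em.
#' @export
stiffnessRatioFromWavelength <- function(lambdaOverH) {
  if (any(lambdaOverH <= 0)) wfmStop("lambdaOverH must be positive")
  3 * (lambdaOverH / (2 * pi))^3
}

#' Critical compressive strain for wrinkle onset
#'
#' \deqn{\varepsilon_c = -\frac{1}{4} (3 E_m / E_p)^{2/3}}
#' Always negative (compressive convention); tends to zero from below as
#' the skin stiffens.
#'
#' @inheritParams wavelengthRatio
#' @return Critical strain, dimensionless and negative.
#' @export
criticalStrain <- function(Ep, Em) {
  if (is(Ep, "BilayerSubstrate")) { Em <- Ep@Em; Ep <- Ep@Ep }
  if (!(Ep > 0) || !(Em > 0)) wfmStop("moduli must be positive")
  -(1 / 4) * (3 * Em / Ep)^(2 / 3)
}

#' Wrinkle amplitude above onset
#'
#' \deqn{A / h = (\varepsilon / \varepsilon_c - 1)^{1/2}}
#' for compression beyond the critical strain; zero below onset (the
#' sub-critical branch is flat, not complex). Both strains are carried as
#' negative numbers.
#'
#' @param strain applied compressive strain (negative).
#' @param strainCritical critical strain (negative), e.g. from
#'   [criticalStrain()].
#' @param h skin thickness; the amplitude is returned in the same units.
#' @return Wrinkle amplitude A.
#' @export
wrinkleAmplitude <- function(strain, strainCritical, h) {
  if (!(strain < 0) || !(strainCritical < 0))
    wfmStop("strains must be negative (compressive convention)")
  if (!(h > 0)) wfmStop("h must be positive")
  if (abs(strain) <= abs(strainCritical)) return(0)
  h * sqrt(strain / strainCritical - 1)
}

#' Rescale a predicted traction field to a new substrate stiffness
#'
#' When two substrates share the same skin/elastomer stiffness ratio, the
#' wrinkle-generation conditions coincide and a traction prediction made on
#' a reference substrate transfers to the new one by scaling every
#' component by \code{Enew / Eref}. The caller asserts the equal-ratio
#' condition.
#'
#' @param traction a \linkS4class{VectorField2D} in Pa.
#' @param Eref,Enew reference and new Young's moduli, Pa (> 0).
#' @return The rescaled \linkS4class{VectorField2D}.
#' @export
rescalePrediction <- function(traction, Eref, Enew) {
  stopifnot(is(traction, "VectorField2D"))
  if (!(Eref > 0) || !(Enew > 0)) wfmStop("moduli must be positive")
  s <- Enew / Eref
  VectorField2D(traction@compX * s, traction@compY * s,
                pixelSize = traction@grid@pixelSize, units = traction@units)
}
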