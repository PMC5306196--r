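#' Surface concentration of PC from the area per molecule
#'
#' `C_PC = 1 / (N_A * area)`: one lipid per `area` of outer surface.
#'
#' @param area_per_lipid Area per PC molecule, m\eqn{^2}.
#' @return Surface concentration, mol/m\eqn{^2}.
#' @export
#' @examples
#' surface_concentration_from_area(65e-20)  # ~2.555e-6 mol/m^2
surface_concentration_from_area <- function(area_per_lipid) {
  if (!is.numeric(area_per_lipid) || any(!is.finite(area_per_lipid)) ||
      any(area_per_lipid <= 0)) {
    pc_abort("`area_per_lipid` must be positive (m^2)",
             "pcion_error_invalid_input")
  }
  1 / (.pc$N_A * area_per_lipid)
}

#' Bulk H+ and OH- concentrations from pH
#'
#' pH is defined on the molar concentration scale, so the SI proton
#' concentration is `a_H = 1000 * 10^(-pH)` mol/m\eqn{^3};
#' `hydroxide_activity()` returns `Kw / a_H`. Activities are identified with
#' concentrations throughout the package.
#'
#' @param pH pH value(s), dimensionless.
#' @return Concentration(s), mol/m\eqn{^3}.
#' @export
#' @examples
#' proton_activity(7)                 # 1e-4 mol/m^3
#' hydroxide_activity(7, Kw = 1e-8)   # 1e-4 mol/m^3
proton_activity <- function(pH) 1000 * 10^(-pH)

#' @rdname proton_activity
#' @param Kw Ion product of water, (mol/m\eqn{^3})\eqn{^2}.
#' @export
hydroxide_activity <- function(pH, Kw = 1e-8) Kw / proton_activity(pH)

# shared denominators of the two binding branches:
#   A branch (phosphate):          1 + K_AH a_H + K_AMe a_Me
#   B branch (trimethylammonium):  1 + K_BOH a_OH + K_BCl a_Cl
.branch_denominators <- function(pH, constants, electrolyte) {
  a_H <- proton_activity(pH)
  a_OH <- electrolyte$Kw / a_H
  list(
    a_H = a_H, a_OH = a_OH,
    DA = 1 + constants[["K_AH"]] * a_H + constants[["K_AMe"]] * electrolyte$a_Me,
    DB = 1 + constants[["K_BOH"]] * a_OH + constants[["K_BCl"]] * electrolyte$a_Cl
  )
}

#' Surface site concentrations of the four-equilibrium model
#'
#' Solves the four association equilibria plus the two mass balances in
#' closed form. The free phosphate concentration is
#' `a_Aminus = C_PC / (1 + K_AH a_H + K_AMe a_Me)`, with the bound forms
#' `K_AH a_H` and `K_AMe a_Me` times that; the trimethylammonium family is
#' symmetric with OH- and Cl-. Both families sum to `C_PC` exactly.
#'
#' @param pH pH value(s); the result has one row per pH.
#' @param constants An [association_constants()] object.
#' @param electrolyte An [electrolyte_spec()] object.
#' @param membrane A [membrane_spec()] object.
#' @return A data.frame with columns `pH`, `a_Aminus`, `a_AH`, `a_AMe`,
#'   `a_Bplus`, `a_BOH`, `a_BCl` (all mol/m\eqn{^2}).
#' @export
site_concentrations <- function(pH, constants, electrolyte, membrane) {
  stopifnot(inherits(constants, "pcion_constants"),
            inherits(electrolyte, "pcion_electrolyte"),
            inherits(membrane, "pcion_membrane"))
  b <- .branch_denominators(pH, constants, electrolyte)
  C <- membrane$C_PC
  a_Aminus <- C / b$DA
  a_Bplus <- C / b$DB
  data.frame(
    pH = pH,
    a_Aminus = a_Aminus,
    a_AH = constants[["K_AH"]] * b$a_H * a_Aminus,
    a_AMe = constants[["K_AMe"]] * electrolyte$a_Me * a_Aminus,
    a_Bplus = a_Bplus,
    a_BOH = constants[["K_BOH"]] * b$a_OH * a_Bplus,
    a_BCl = constants[["K_BCl"]] * electrolyte$a_Cl * a_Bplus
  )
}

#' Model surface charge density versus pH
#'
#' The central closed form of the four-equilibrium model:
#' \deqn{\sigma(\mathrm{pH}) = F\left[
#'   \frac{C_{PC}}{1 + K_{BOH} a_{OH} + K_{BCl} a_{Cl}} -
#'   \frac{C_{PC}}{1 + K_{AH} a_{H} + K_{AMe} a_{Me}}\right].}
#' Equal to \eqn{F (a_{B^+} - a_{A^-})} from [site_concentrations()]; bounded
#' by \eqn{\pm F C_{PC}}; strictly decreasing in pH when all constants are
#' positive, so the isoelectric point is unique.
#'
#' @inheritParams site_concentrations
#' @return Surface charge density, C/m\eqn{^2}, same length as `pH`.
#' @export
#' @examples
#' el <- electrolyte_spec("Li", 155); mem <- membrane_spec()
#' sigma_model(3, reference_constants("LiCl"), el, mem)  # ~6.51e-3 C/m^2
sigma_model <- function(pH, constants, electrolyte, membrane) {
  stopifnot(inherits(constants, "pcion_constants"),
            inherits(electrolyte, "pcion_electrolyte"),
            inherits(membrane, "pcion_membrane"))
  b <- .branch_denominators(pH, constants, electrolyte)
  .pc$Faraday * membrane$C_PC * (1 / b$DB - 1 / b$DA)
}

#' Isoelectric point of the model membrane
#'
#' The pH at which the model surface charge density crosses zero. Setting
#' the two branch denominators equal and substituting `a_OH = Kw / a_H` gives
#' a quadratic in the proton concentration,
#' \deqn{K_{AH} a_H^2 + (K_{AMe} a_{Me} - K_{BCl} a_{Cl}) a_H - K_{BOH} K_w = 0,}
#' whose positive root is converted back to pH. When `K_AH = 0` the equation
#' is linear and is solved directly. The returned pH is verified by a sign
#' change of [sigma_model()] in a bracketing interval.
#'
#' @inheritParams site_concentrations
#' @param membrane A [membrane_spec()] object; the isoelectric point does not
#'   depend on `C_PC`, the argument exists for interface symmetry.
#' @return The isoelectric pH (a single number).
#' @export
#' @examples
#' el <- electrolyte_spec("Na", 155)
#' isoelectric_point(reference_constants("NaCl"), el)  # ~3.74
isoelectric_point <- function(constants, electrolyte,
                              membrane = membrane_spec()) {
  stopifnot(inherits(constants, "pcion_constants"),
            inherits(electrolyte, "pcion_electrolyte"))
  K_AH <- constants[["K_AH"]]; K_AMe <- constants[["K_AMe"]]
  K_BOH <- constants[["K_BOH"]]; K_BCl <- constants[["K_BCl"]]
  bcoef <- K_AMe * electrolyte$a_Me - K_BCl * electrolyte$a_Cl
  ccoef <- -K_BOH * electrolyte$Kw

  a_H <- if (K_AH > 0) {
    # numerically stable positive root of K_AH x^2 + b x + c = 0 (c <= 0)
    disc <- sqrt(bcoef^2 - 4 * K_AH * ccoef)
    if (bcoef <= 0) (-bcoef + disc) / (2 * K_AH) else 2 * (-ccoef) / (bcoef + disc)
  } else if (K_BOH > 0 && bcoef > 0) {
    -ccoef / bcoef
  } else {
    NA_real_
  }
  if (!is.finite(a_H) || a_H <= 0) {
    pc_abort("surface charge density has no zero crossing for these constants",
             "pcion_error_no_iep")
  }
  pH <- -log10(a_H / 1000)

  # confirm a genuine sign change around the root (guards the degenerate
  # sigma == 0 everywhere case, e.g. all constants zero)
  f <- function(p) sigma_model(p, constants, electrolyte, membrane)
  lo <- f(pH - 0.5); hi <- f(pH + 0.5)
  if (!(lo > 0 && hi < 0)) {
    pc_abort("surface charge density has no zero crossing for these constants",
             "pcion_error_no_iep")
  }
  pH
}
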