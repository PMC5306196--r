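#' Describe the bulk electrolyte
#'
#' Bundles everything the electrokinetic and equilibrium calculations need to
#' know about the bulk solution: a 1:1 alkali chloride at concentration
#' `c_salt`, the temperature, the ion product of water, and the solvent's
#' permittivity and viscosity. All quantities are SI: concentrations in
#' mol/m\eqn{^3} (155 mol/m\eqn{^3} is 0.155 mol/l), `Kw` in
#' (mol/m\eqn{^3})\eqn{^2} (1e-8 corresponds to the familiar 1e-14
#' (mol/l)\eqn{^2}).
#'
#' For a 1:1 salt the bulk cation and chloride concentrations both equal
#' `c_salt`, and the ionic strength defaults to `c_salt`: the H+/OH-
#' contribution is at most ~6\% at pH 2 for a 0.155 M electrolyte and is
#' excluded by default. Pass an explicit `ionic_strength`, or use
#' [ionic_strength_with_hoh()], to include it.
#'
#' @param cation Cation label, one of `"Li"`, `"Na"`, `"K"`, `"Cs"` (a label
#'   only; it carries no physics).
#' @param c_salt Bulk salt concentration, mol/m\eqn{^3}. Must be positive.
#' @param temperature Absolute temperature, K. Default 298.15.
#' @param Kw Ion product of water, (mol/m\eqn{^3})\eqn{^2}. Default 1e-8.
#' @param epsilon_r Relative permittivity of the medium. Default 78.5 (water
#'   at 25 degrees C).
#' @param eta Dynamic viscosity, Pa s. Default 8.90e-4 (water at 25 degrees C).
#' @param ionic_strength Ionic strength, mol/m\eqn{^3}; defaults to `c_salt`.
#'   Must be at least `c_salt`.
#' @return An object of class `pcion_electrolyte`.
#' @seealso [membrane_spec()], [association_constants()]
#' @export
#' @examples
#' electrolyte_spec("Li", c_salt = 155)
electrolyte_spec <- function(cation = c("Na", "Li", "K", "Cs"),
                             c_salt = 155,
                             temperature = 298.15,
                             Kw = 1e-8,
                             epsilon_r = 78.5,
                             eta = 8.90e-4,
                             ionic_strength = NULL) {
  cation <- match.arg(cation)
  if (!is.numeric(c_salt) || length(c_salt) != 1L || !is.finite(c_salt) ||
      c_salt <= 0) {
    pc_abort("`c_salt` must be a single positive number (mol/m^3)",
             "pcion_error_invalid_input")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    pc_abort("`temperature` must be positive (K)", "pcion_error_invalid_input")
  }
  if (!is.finite(Kw) || Kw <= 0) {
    pc_abort("`Kw` must be positive ((mol/m^3)^2)",
             "pcion_error_invalid_input")
  }
  if (!is.finite(epsilon_r) || epsilon_r <= 0 || !is.finite(eta) || eta <= 0) {
    pc_abort("`epsilon_r` and `eta` must be positive",
             "pcion_error_invalid_input")
  }
  if (is.null(ionic_strength)) ionic_strength <- c_salt
  if (!is.finite(ionic_strength) || ionic_strength < c_salt) {
    pc_abort("`ionic_strength` must be finite and >= `c_salt`",
             "pcion_error_invalid_input")
  }
  structure(
    list(cation = cation, c_salt = c_salt, a_Me = c_salt, a_Cl = c_salt,
         temperature = temperature, Kw = Kw, epsilon_r = epsilon_r,
         eta = eta, ionic_strength = ionic_strength),
    class = "pcion_electrolyte"
  )
}

#' @export
print.pcion_electrolyte <- function(x, ...) {
  cat(sprintf("<electrolyte> %sCl, c = %g mol/m^3 (%g mol/l), T = %g K\n",
              x$cation, x$c_salt, x$c_salt / 1000, x$temperature))
  cat(sprintf("  Kw = %g (mol/m^3)^2, eps_r = %g, eta = %g Pa s, I = %g mol/m^3\n",
              x$Kw, x$epsilon_r, x$eta, x$ionic_strength))
  invisible(x)
}

#' Ionic strength including the H+/OH- contribution
#'
#' For a 1:1 salt plus strong acid/base adjustment the ionic strength at a
#' given pH is `c_salt + (a_H + a_OH)/2` (all univalent ions). By default the
#' package excludes the H+/OH- term; this helper computes the inclusive value
#' so it can be passed back into [electrolyte_spec()] when wanted.
#'
#' @param electrolyte A [electrolyte_spec()] object.
#' @param pH pH value(s).
#' @return Ionic strength, mol/m\eqn{^3}, same length as `pH`.
#' @export
ionic_strength_with_hoh <- function(electrolyte, pH) {
  stopifnot(inherits(electrolyte, "pcion_electrolyte"))
  a_H <- proton_activity(pH)
  a_OH <- electrolyte$Kw / a_H
  electrolyte$c_salt + (a_H + a_OH) / 2
}

#' Convert mol/l to the package's internal mol/m^3
#'
#' The package works in SI concentrations (mol/m\eqn{^3}); user-facing molar
#' values (e.g. "0.155 mol/l") are converted at the boundary with this helper.
#'
#' @param x Concentration in mol/l.
#' @return Concentration in mol/m\eqn{^3} (`1000 * x`).
#' @export
#' @examples
#' molar_to_si(0.155)  # 155 mol/m^3
molar_to_si <- function(x) 1000 * x

#' Describe the membrane
#'
#' The only membrane property the model needs is the surface concentration of
#' phosphatidylcholine, `C_PC = 1 / (N_A * area_per_lipid)` (mol/m\eqn{^2}),
#' fixed by the area one PC molecule occupies in the outer leaflet. The
#' default 65 \eqn{\mbox{\AA}^2} is the standard fluid-phase PC headgroup area.
#'
#' @param area_per_lipid Area per PC molecule, m\eqn{^2}. Default 65e-20
#'   (65 \eqn{\mbox{\AA}^2}).
#' @return An object of class `pcion_membrane` with fields `area_per_lipid`
#'   and `C_PC`.
#' @export
#' @examples
#' membrane_spec()$C_PC  # ~2.555e-6 mol/m^2
membrane_spec <- function(area_per_lipid = 65e-20) {
  structure(
    list(area_per_lipid = area_per_lipid,
         C_PC = surface_concentration_from_area(area_per_lipid)),
    class = "pcion_membrane"
  )
}

#' @export
print.pcion_membrane <- function(x, ...) {
  cat(sprintf("<membrane> area/lipid = %g A^2, C_PC = %.6g mol/m^2\n",
              x$area_per_lipid * 1e20, x$C_PC))
  invisible(x)
}

#' The four association constants of the surface model
#'
#' The surface model has four binding equilibria: H+ and Me+ on the phosphate
#' group (constants `K_AH`, `K_AMe`) and OH- and Cl- on the trimethylammonium
#' group (`K_BOH`, `K_BCl`). All are surface-referenced constants in
#' m\eqn{^3}/mol: functional-group concentrations per unit outer-leaflet area,
#' ion concentrations per unit volume.
#'
#' @param K_AH Phosphate--H+ association constant, m\eqn{^3}/mol.
#' @param K_AMe Phosphate--Me+ association constant, m\eqn{^3}/mol.
#' @param K_BOH Trimethylammonium--OH- association constant, m\eqn{^3}/mol.
#' @param K_BCl Trimethylammonium--Cl- association constant, m\eqn{^3}/mol.
#' @return An object of class `pcion_constants` (a named numeric vector).
#' @export
#' @examples
#' association_constants(K_AH = 493, K_AMe = 0.342,
#'                       K_BOH = 2.78e3, K_BCl = 0.222)
association_constants <- function(K_AH, K_AMe, K_BOH, K_BCl) {
  k <- c(K_AH = unname(K_AH), K_AMe = unname(K_AMe),
         K_BOH = unname(K_BOH), K_BCl = unname(K_BCl))
  if (any(!is.finite(k)) || any(k < 0)) {
    pc_abort("association constants must be finite and >= 0",
             "pcion_error_invalid_input")
  }
  structure(k, class = "pcion_constants")
}

#' @export
print.pcion_constants <- function(x, ...) {
  cat("<association constants> (m^3/mol)\n")
  cat(sprintf("  K_AH  = %-12.6g K_AMe = %-12.6g\n", x[["K_AH"]], x[["K_AMe"]]))
  cat(sprintf("  K_BOH = %-12.6g K_BCl = %-12.6g\n", x[["K_BOH"]], x[["K_BCl"]]))
  invisible(x)
}

# column scalings of the conventional reporting table:
# K_AMe in 1e-1, K_AH in 1e2, K_BOH in 1, K_BCl in 1e-2 m^3/mol
.table_scale <- c(K_AH = 1e2, K_AMe = 1e-1, K_BOH = 1, K_BCl = 1e-2)

#' Rescale association constants between SI and reporting-table units
#'
#' Published tables of these constants conventionally report `K_AMe` in
#' 10\eqn{^{-1}} m\eqn{^3}/mol, `K_AH` in 10\eqn{^2} m\eqn{^3}/mol, `K_BOH`
#' in m\eqn{^3}/mol and `K_BCl` in 10\eqn{^{-2}} m\eqn{^3}/mol.
#' `constants_to_table()` divides SI values by those scale factors;
#' `constants_from_table()` does the inverse.
#'
#' @param constants An [association_constants()] object (SI m\eqn{^3}/mol).
#' @return `constants_to_table()`: a named numeric vector in table units.
#' @export
constants_to_table <- function(constants) {
  unclass(constants)[names(.table_scale)] / .table_scale
}

#' @rdname constants_to_table
#' @param k Named numeric vector with elements `K_AH`, `K_AMe`, `K_BOH`,
#'   `K_BCl` in table units.
#' @export
constants_from_table <- function(k) {
  k <- k[names(.table_scale)] * .table_scale
  association_constants(k[["K_AH"]], k[["K_AMe"]], k[["K_BOH"]], k[["K_BCl"]])
}

# reference constants for PC in 0.155 M alkali chlorides, SI m^3/mol
.reference_table <- list(
  Li = c(K_AH = 4.93e2, K_AMe = 3.42e-1, K_BOH = 2.78e3, K_BCl = 2.22e-1),
  Na = c(K_AH = 6.37e2, K_AMe = 2.32e-1, K_BOH = 2.58e9, K_BCl = 7.35e-2),
  K  = c(K_AH = 9.12e2, K_AMe = 3.33e-1, K_BOH = 1.52e9, K_BCl = 8.37e-2),
  Cs = c(K_AH = 7.31e2, K_AMe = 3.24e-1, K_BOH = 1.09e9, K_BCl = 6.52e-2)
)

.normalize_salt <- function(salt) {
  s <- sub("Cl$", "", as.character(salt)[1])
  if (!s %in% names(.reference_table)) {
    pc_abort(sprintf("unknown salt '%s'; expected one of LiCl, NaCl, KCl, CsCl",
                     salt),
             "pcion_error_invalid_input")
  }
  s
}

#' Reference association constants for PC in 0.155 M alkali chlorides
#'
#' Packaged per-salt association constants for phosphatidylcholine membranes
#' in 0.155 mol/l LiCl, NaCl, KCl or CsCl, in SI m\eqn{^3}/mol. These are the
#' values used by the synthetic-data fixtures ([reference_config()]) and by
#' the round-trip recovery tests.
#'
#' @param salt `"LiCl"`, `"NaCl"`, `"KCl"`, `"CsCl"` (bare cation labels
#'   `"Li"` etc. also accepted).
#' @return An [association_constants()] object.
#' @export
#' @examples
#' reference_constants("LiCl")
reference_constants <- function(salt) {
  k <- .reference_table[[.normalize_salt(salt)]]
  association_constants(k[["K_AH"]], k[["K_AMe"]], k[["K_BOH"]], k[["K_BCl"]])
}
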