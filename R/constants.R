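# CODATA-style physical constants used throughout. SI units only.
.pc <- list(
  R       = 8.314462,      # gas constant, J mol^-1 K^-1
  Faraday = 96485.33,      # Faraday constant, C mol^-1
  eps0    = 8.8541878e-12, # vacuum permittivity, F m^-1
  N_A     = 6.02214076e23  # Avogadro constant, mol^-1
)

#' Physical constants used by pcion
#'
#' Returns the fixed physical constants the package computes with: the gas
#' constant `R` (J/mol/K), the Faraday constant `Faraday` (C/mol), the vacuum
#' permittivity `eps0` (F/m) and the Avogadro constant `N_A` (1/mol).
#'
#' @return A named list of four numbers.
#' @export
#' @examples
#' physical_constants()$Faraday
physical_constants <- function() .pc

# classed error helper; every user-facing failure goes through here so that
# callers can test on condition class rather than message text
pc_abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "pcion_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}
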