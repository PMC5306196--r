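#' Configure the synthetic titration generator
#'
#' Describes one simulated microelectrophoresis titration: the generating
#' association constants, electrolyte and membrane, the pH grid, the
#' per-replicate Gaussian mobility noise, and (optionally) an artifactual
#' exponential damping of the charge above a pH threshold that mimics
#' membrane destruction in the alkaline tail of real titrations.
#'
#' Noise is applied to the mobility — the quantity the instrument actually
#' measures — and propagates to charge density through the linear
#' electrokinetic conversion. The default `noise_sd_mobility` of 4.3e-9
#' m\eqn{^2}/V/s makes the per-replicate charge scatter about 2\% of the
#' full scale `F * C_PC`, a plausible match to liposome
#' microelectrophoresis scatter.
#'
#' @param constants [association_constants()] used to generate the curve.
#' @param electrolyte [electrolyte_spec()].
#' @param membrane [membrane_spec()].
#' @param pH_min,pH_max,pH_step pH grid (default 2 to 10.5 in steps of 0.5).
#' @param noise_sd_mobility Per-replicate Gaussian SD of mobility,
#'   m\eqn{^2}/V/s (>= 0).
#' @param n_replicates Replicate mobility measurements per pH (default 6).
#' @param seed Integer seed; the dataset is bit-reproducible given it.
#' @param degrade_above Optional pH threshold above which the true charge is
#'   damped by `exp(-degrade_rate * (pH - degrade_above))`; `NULL` (default)
#'   disables the artifact.
#' @param degrade_rate Decay rate per pH unit (default 1).
#' @return An object of class `pcion_generator_config`.
#' @seealso [generate_titration()], [reference_config()]
#' @export
generator_config <- function(constants, electrolyte, membrane,
                             pH_min = 2, pH_max = 10.5, pH_step = 0.5,
                             noise_sd_mobility = 4.3e-9,
                             n_replicates = 6, seed = 1L,
                             degrade_above = NULL, degrade_rate = 1) {
  stopifnot(inherits(constants, "pcion_constants"),
            inherits(electrolyte, "pcion_electrolyte"),
            inherits(membrane, "pcion_membrane"))
  if (!(pH_min < pH_max) || pH_step <= 0) {
    pc_abort("need pH_min < pH_max and pH_step > 0",
             "pcion_error_invalid_input")
  }
  if (n_replicates < 1 || noise_sd_mobility < 0) {
    pc_abort("need n_replicates >= 1 and noise_sd_mobility >= 0",
             "pcion_error_invalid_input")
  }
  if (!is.null(degrade_above) &&
      (!is.finite(degrade_above) || !is.finite(degrade_rate) ||
       degrade_rate < 0)) {
    pc_abort("invalid degradation settings", "pcion_error_invalid_input")
  }
  structure(
    list(constants = constants, electrolyte = electrolyte,
         membrane = membrane, pH_min = pH_min, pH_max = pH_max,
         pH_step = pH_step, noise_sd_mobility = noise_sd_mobility,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         degrade_above = degrade_above, degrade_rate = degrade_rate),
    class = "pcion_generator_config"
  )
}

#' Generate a synthetic titration dataset
#'
#' For every pH on the grid: the true charge density from [sigma_model()]
#' (damped above `degrade_above` if the degradation artifact is enabled) is
#' converted to a true mobility, `n_replicates` Gaussian replicate mobilities
#' are drawn around it, and the dataset records the replicate mean mobility,
#' the derived charge density, the standard deviation of the mean on the
#' charge scale (`sd_sigma`), and the replicate count. Draws are taken in
#' fixed grid order from a single seeded stream, so the dataset is fully
#' reproducible. The generating parameters are recorded in the dataset
#' metadata.
#'
#' @param config A [generator_config()].
#' @return A [titration_dataset()].
#' @export
#' @examples
#' d <- generate_titration(reference_config("LiCl"))
#' head(d$points)
generate_titration <- function(config) {
  if (!inherits(config, "pcion_generator_config")) {
    pc_abort("`config` must be a generator_config()",
             "pcion_error_invalid_input")
  }
  pH <- seq(config$pH_min, config$pH_max, by = config$pH_step)
  sigma_true <- sigma_model(pH, config$constants, config$electrolyte,
                            config$membrane)
  if (!is.null(config$degrade_above)) {
    over <- pH > config$degrade_above
    sigma_true[over] <- sigma_true[over] *
      exp(-config$degrade_rate * (pH[over] - config$degrade_above))
  }
  u_true <- sigma_to_mobility(sigma_true, config$electrolyte)

  set.seed(config$seed)
  n <- config$n_replicates
  u_mean <- numeric(length(pH))
  sd_u_mean <- numeric(length(pH))
  for (i in seq_along(pH)) {
    reps <- u_true[i] + stats::rnorm(n, 0, config$noise_sd_mobility)
    u_mean[i] <- mean(reps)
    sd_u_mean[i] <- if (n > 1) stats::sd(reps) / sqrt(n) else 0
  }
  eta_over_d <- config$electrolyte$eta /
    diffuse_layer_thickness(config$electrolyte)
  pts <- data.frame(
    pH = pH,
    mobility = u_mean,
    sigma = mobility_to_sigma(u_mean, config$electrolyte),
    sd_sigma = eta_over_d * sd_u_mean,
    n_replicates = n
  )
  k <- unclass(config$constants)
  titration_dataset(
    pts, config$electrolyte, config$membrane,
    metadata = list(
      salt = paste0(config$electrolyte$cation, "Cl"),
      seed = config$seed,
      n_replicates = n,
      noise_sd_mobility = config$noise_sd_mobility,
      K_AH = k[["K_AH"]], K_AMe = k[["K_AMe"]],
      K_BOH = k[["K_BOH"]], K_BCl = k[["K_BCl"]],
      degrade_above = if (is.null(config$degrade_above)) NA
                      else config$degrade_above,
      degrade_rate = if (is.null(config$degrade_above)) NA
                     else config$degrade_rate
    )
  )
}

#' Ready-made generator configuration for a reference salt
#'
#' A [generator_config()] loaded with the packaged reference association
#' constants ([reference_constants()]) for one of the four alkali chlorides,
#' the standard 0.155 mol/l electrolyte, a 65 \eqn{\mbox{\AA}^2} membrane,
#' and the canonical pH 2--10.5 grid with 6 replicates per point.
#'
#' @param salt `"LiCl"`, `"NaCl"`, `"KCl"` or `"CsCl"`.
#' @param ... Overrides passed on to [generator_config()] (e.g.
#'   `noise_sd_mobility = 0`, `pH_step`, `seed`, `degrade_above`).
#' @return A `pcion_generator_config`.
#' @export
#' @examples
#' reference_config("NaCl", noise_sd_mobility = 0)
reference_config <- function(salt, ...) {
  cation <- .normalize_salt(salt)
  generator_config(
    constants = reference_constants(cation),
    electrolyte = electrolyte_spec(cation, c_salt = 155),
    membrane = membrane_spec(65e-20),
    ...
  )
}
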