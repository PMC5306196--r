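#' Assemble a titration dataset
#'
#' A titration dataset couples a table of per-pH measurements with the
#' electrolyte and membrane they were measured in. Each point needs at least
#' one of `mobility` (m\eqn{^2}/V/s) or `sigma` (C/m\eqn{^2}); the missing
#' one is filled in through the electrokinetic conversion, and when both are
#' supplied they must already agree with it to 1e-9 relative. Optional
#' columns `sd_sigma` (standard deviation of the per-point mean charge
#' density, C/m\eqn{^2}) and `n_replicates` carry replicate statistics.
#'
#' @param points A data.frame with column `pH` and one or both of `mobility`
#'   and `sigma`; optional `sd_sigma`, `n_replicates`.
#' @param electrolyte An [electrolyte_spec()] object.
#' @param membrane A [membrane_spec()] object.
#' @param metadata Named list of free-form provenance (salt label, seed,
#'   generator parameters); preserved by the CSV round trip.
#' @return An object of class `pcion_titration`: a list with elements
#'   `points`, `electrolyte`, `membrane`, `metadata`.
#' @export
titration_dataset <- function(points, electrolyte, membrane,
                              metadata = list()) {
  stopifnot(inherits(electrolyte, "pcion_electrolyte"),
            inherits(membrane, "pcion_membrane"))
  if (!is.data.frame(points) || nrow(points) == 0L) {
    pc_abort("`points` must be a non-empty data.frame",
             "pcion_error_invalid_input")
  }
  if (!"pH" %in% names(points) || any(!is.finite(points$pH))) {
    pc_abort("`points` must have a finite `pH` column",
             "pcion_error_invalid_input")
  }
  has_u <- "mobility" %in% names(points)
  has_s <- "sigma" %in% names(points)
  if (!has_u && !has_s) {
    pc_abort("`points` must have a `mobility` or a `sigma` column",
             "pcion_error_invalid_input")
  }
  if (has_u && has_s) {
    chk <- mobility_to_sigma(points$mobility, electrolyte)
    rel <- abs(chk - points$sigma) / pmax(abs(points$sigma), 1e-300)
    if (any(points$sigma != 0 & rel > 1e-9)) {
      pc_abort("`mobility` and `sigma` columns are mutually inconsistent",
               "pcion_error_invalid_input")
    }
  } else if (has_u) {
    points$sigma <- mobility_to_sigma(points$mobility, electrolyte)
  } else {
    points$mobility <- sigma_to_mobility(points$sigma, electrolyte)
  }
  if ("n_replicates" %in% names(points) &&
      any(points$n_replicates < 1, na.rm = TRUE)) {
    pc_abort("`n_replicates` must be >= 1 where given",
             "pcion_error_invalid_input")
  }
  points <- points[order(points$pH), , drop = FALSE]
  rownames(points) <- NULL
  structure(
    list(points = points, electrolyte = electrolyte, membrane = membrane,
         metadata = metadata),
    class = "pcion_titration"
  )
}

#' @export
print.pcion_titration <- function(x, ...) {
  cat(sprintf("<titration> %d points, pH %.3g..%.3g, %sCl %g mol/m^3\n",
              nrow(x$points), min(x$points$pH), max(x$points$pH),
              x$electrolyte$cation, x$electrolyte$c_salt))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Drop titration points above a pH cutoff
#'
#' Microelectrophoresis titrations of PC liposomes lose reliability above
#' pH ~8.5, where membranes begin to break down; points above the cutoff are
#' excluded before any constant estimation. The number of removed points is
#' recorded in `metadata$n_removed_above_cutoff`.
#'
#' @param dataset A [titration_dataset()].
#' @param pH_max Global cutoff; points with `pH > pH_max` are dropped.
#'   Default 8.5.
#' @return The filtered `pcion_titration`.
#' @export
apply_window <- function(dataset, pH_max = 8.5) {
  stopifnot(inherits(dataset, "pcion_titration"))
  keep <- dataset$points$pH <= pH_max
  if (!any(keep)) {
    pc_abort(sprintf("no titration points at pH <= %g", pH_max),
             "pcion_error_insufficient_data")
  }
  dataset$points <- dataset$points[keep, , drop = FALSE]
  rownames(dataset$points) <- NULL
  dataset$metadata$n_removed_above_cutoff <- sum(!keep)
  dataset$metadata$pH_max <- pH_max
  dataset
}
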