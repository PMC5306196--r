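#' Asymptotic linearization regressions
#'
#' At high proton concentration the charge-density model collapses to a
#' straight line in transformed variables,
#' \eqn{\sigma a_H / F = s \, a_H + i} with slope
#' \eqn{s = C_{PC}/(1 + K_{BCl} a_{Cl})} and intercept
#' \eqn{i = -[C_{PC} K_{BOH} K_w/(1 + K_{BCl} a_{Cl})^2 + C_{PC}/K_{AH}]};
#' at low proton concentration it collapses to
#' \eqn{\sigma/(F a_H) = s' / a_H + i'} with slope
#' \eqn{s' = -C_{PC}/(1 + K_{AMe} a_{Me})} and intercept
#' \eqn{i' = C_{PC}/(K_{BOH} K_w) + C_{PC} K_{AH}/(1 + K_{AMe} a_{Me})^2}.
#' `regress_highH()` and `regress_lowH()` fit these lines by ordinary least
#' squares over a pH window; [constants_from_coefficients()] inverts the four
#' coefficients to the four association constants.
#'
#' The lines are asymptotes, so the fitted coefficients carry a truncation
#' bias that shrinks as the window moves towards the pH extremes; the
#' default windows (pH 2--4 and 7--8.5) are the practical compromise inside
#' the usable range of a liposome titration.
#'
#' @param dataset A [titration_dataset()] (already windowed or not; these
#'   functions use exactly the points inside `window`).
#' @param window Length-2 numeric pH interval.
#' @return A list with `slope`, `intercept`, their standard errors
#'   `se_slope`, `se_intercept`, the `window` and the point count `n`.
#' @export
regress_highH <- function(dataset, window = c(2, 4)) {
  .regress_asymptote(dataset, window, side = "highH")
}

#' @rdname regress_highH
#' @export
regress_lowH <- function(dataset, window = c(7, 8.5)) {
  .regress_asymptote(dataset, window, side = "lowH")
}

.regress_asymptote <- function(dataset, window, side) {
  stopifnot(inherits(dataset, "pcion_titration"), length(window) == 2L)
  pts <- dataset$points
  inw <- pts$pH >= min(window) & pts$pH <= max(window)
  if (sum(inw) < 3L) {
    pc_abort(sprintf("need >= 3 points in pH window [%g, %g], found %d",
                     min(window), max(window), sum(inw)),
             "pcion_error_insufficient_data")
  }
  a_H <- proton_activity(pts$pH[inw])
  sigma <- pts$sigma[inw]
  if (side == "highH") {
    x <- a_H
    y <- sigma * a_H / .pc$Faraday
  } else {
    x <- 1 / a_H
    y <- sigma / (.pc$Faraday * a_H)
  }
  if (stats::var(x) <= 0) {
    pc_abort("zero variance in the regressor inside the window",
             "pcion_error_degenerate_design")
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # noiseless input is legitimate here; lm's "perfect fit" caveat about the
  # standard errors is expected and harmless
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  list(slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
       se_slope = unname(se["x"]), se_intercept = unname(se["(Intercept)"]),
       window = c(min(window), max(window)), n = sum(inw))
}

#' Association constants from linearized regression coefficients
#'
#' Inverts the two asymptote lines (see [regress_highH()]) back to the four
#' association constants. The slopes give the cross constants directly,
#' `K_BCl = (C_PC/slope_highH - 1)/a_Cl` and
#' `K_AMe = (-C_PC/slope_lowH - 1)/a_Me`. The two intercepts couple `K_AH`
#' and `K_BOH`; eliminating `K_AH` leaves a quadratic in `K_BOH`, solved in
#' closed form. The quadratic generically has two positive roots, and both
#' reproduce the asymptote coefficients exactly, so the linearized
#' coefficients alone do not identify the (`K_AH`, `K_BOH`) pair: the root
#' closer to the dominant-term approximation `K_AH = C_PC/(-intercept_highH)`,
#' `K_BOH = C_PC/(Kw * intercept_lowH)` is returned as the estimate and the
#' other is attached as `attr(, "alternate")`. [fit_linearized()]
#' disambiguates by residual sum of squares against the data.
#'
#' Slope ratios that fall below 1 by less than 1e-9 relative (pure numerical
#' noise around a zero constant) are clipped to a zero constant with a
#' recorded warning; larger violations raise a model-inconsistency error.
#'
#' @param coeffs A list with `slope_highH`, `intercept_highH`, `slope_lowH`,
#'   `intercept_lowH` (as produced by [fit_linearized()] internals).
#' @param electrolyte An [electrolyte_spec()] object.
#' @param membrane A [membrane_spec()] object.
#' @return An [association_constants()] object; any clip warnings are in
#'   `attr(, "warnings")`.
#' @export
constants_from_coefficients <- function(coeffs, electrolyte, membrane) {
  stopifnot(inherits(electrolyte, "pcion_electrolyte"),
            inherits(membrane, "pcion_membrane"))
  C <- membrane$C_PC
  Kw <- electrolyte$Kw
  warnings <- character()

  if (!is.finite(coeffs$slope_highH) || coeffs$slope_highH <= 0) {
    pc_abort("slope of the high-H+ line must be positive",
             "pcion_error_model_inconsistent")
  }
  if (!is.finite(coeffs$slope_lowH) || coeffs$slope_lowH >= 0) {
    pc_abort("slope of the low-H+ line must be negative",
             "pcion_error_model_inconsistent")
  }
  A <- -coeffs$intercept_highH   # = C*K_BOH*Kw/P^2 + C/K_AH > 0
  I_l <- coeffs$intercept_lowH   # = C/(K_BOH*Kw) + C*K_AH/M^2 > 0
  if (!is.finite(A) || A <= 0 || !is.finite(I_l) || I_l <= 0) {
    pc_abort("intercepts are inconsistent with the model (need highH < 0 < lowH)",
             "pcion_error_model_inconsistent")
  }

  ratio_clip <- function(ratio, label) {
    if (ratio < 1) {
      if (ratio > 1 - 1e-9) {
        warnings <<- c(warnings, sprintf("%s clipped to 0", label))
        ratio <- 1
      } else {
        pc_abort(sprintf("%s slope implies a negative association constant",
                         label),
                 "pcion_error_model_inconsistent")
      }
    }
    ratio
  }
  P <- ratio_clip(C / coeffs$slope_highH, "K_BCl")  # = 1 + K_BCl*a_Cl
  M <- ratio_clip(-C / coeffs$slope_lowH, "K_AMe")  # = 1 + K_AMe*a_Me
  K_BCl <- (P - 1) / electrolyte$a_Cl
  K_AMe <- (M - 1) / electrolyte$a_Me

  # Coupled intercepts. Eliminating K_AH turns the pair
  #   A   = C*K_BOH*Kw/P^2 + C/K_AH
  #   I_l = C/(K_BOH*Kw)   + C*K_AH/M^2
  # into a quadratic in y = K_BOH:
  #   q2*y^2 - q1*y + q0 = 0,
  # which generically has TWO positive roots: both reproduce the asymptote
  # coefficients exactly, so the linearized coefficients alone do not
  # identify (K_AH, K_BOH). Both candidates are returned; fit_linearized()
  # picks the one with the lower residual sum against the data.
  a_y <- C * Kw / P^2
  q2 <- I_l * Kw * a_y
  q1 <- I_l * Kw * A + C * a_y - C^2 * Kw / M^2
  q0 <- C * A
  disc <- q1^2 - 4 * q2 * q0
  if (!is.finite(disc) || disc < 0 || q1 <= 0) {
    pc_abort("intercepts admit no positive (K_AH, K_BOH) solution",
             "pcion_error_model_inconsistent")
  }
  y_big <- (q1 + sqrt(disc)) / (2 * q2)   # larger root, numerically stable
  y_small <- q0 / (q2 * y_big)            # Vieta companion
  pairs <- lapply(c(y_small, y_big), function(y) {
    den <- A - a_y * y
    if (!is.finite(y) || y <= 0 || den <= 0) return(NULL)
    c(K_AH = C / den, K_BOH = y)
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) {
    pc_abort("intercepts admit no positive (K_AH, K_BOH) solution",
             "pcion_error_model_inconsistent")
  }
  # primary root: the one closer (log scale) to the dominant-term
  # initialization K_AH = C/A, K_BOH = C/(Kw*I_l)
  init <- c(C / A, C / (Kw * I_l))
  dist <- vapply(pairs, function(p)
    sum((log10(p) - log10(init))^2), numeric(1))
  ord <- order(dist)
  primary <- pairs[[ord[1]]]

  out <- association_constants(primary[["K_AH"]], K_AMe,
                               primary[["K_BOH"]], K_BCl)
  attr(out, "warnings") <- warnings
  if (length(pairs) > 1L) {
    alt <- pairs[[ord[2]]]
    attr(out, "alternate") <- association_constants(
      alt[["K_AH"]], K_AMe, alt[["K_BOH"]], K_BCl)
  }
  out
}

# model sigma without S3 dispatch overhead; K on the natural scale
.sigma_fast <- function(a_H, a_OH, K, a_Me, a_Cl, FC) {
  FC * (1 / (1 + K[3] * a_OH + K[4] * a_Cl) -
          1 / (1 + K[1] * a_H + K[2] * a_Me))
}

.fit_weights <- function(pts) {
  if ("sd_sigma" %in% names(pts) && all(is.finite(pts$sd_sigma)) &&
      all(pts$sd_sigma > 0)) {
    1 / pts$sd_sigma^2
  } else {
    rep(1, nrow(pts))
  }
}

.new_fit <- function(dataset, constants, method, residuals, weights,
                     converged, coefficients = NULL, seed = NA_integer_,
                     condition_number = NA_real_, flags = character()) {
  structure(
    list(constants = constants, method = method,
         coefficients = coefficients,
         rss = sum(weights * residuals^2),
         residuals = residuals,
         fitted = dataset$points$sigma - residuals,
         weights = weights,
         converged = converged,
         condition_number = condition_number,
         flags = flags,
         seed = seed,
         data = dataset),
    class = "pcion_fit"
  )
}

#' @export
print.pcion_fit <- function(x, ...) {
  cat(sprintf("<fit: %s> %d points, RSS = %.6g (C/m^2)^2%s\n",
              x$method, nrow(x$data$points), x$rss,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  k <- unclass(x$constants)
  tb <- constants_to_table(x$constants)
  cat(sprintf("  K_AH  = %-11.4g m^3/mol  (%.3g x 10^2)\n", k[["K_AH"]], tb[["K_AH"]]))
  cat(sprintf("  K_AMe = %-11.4g m^3/mol  (%.3g x 10^-1)\n", k[["K_AMe"]], tb[["K_AMe"]]))
  cat(sprintf("  K_BOH = %-11.4g m^3/mol  (%.3g)\n", k[["K_BOH"]], tb[["K_BOH"]]))
  cat(sprintf("  K_BCl = %-11.4g m^3/mol  (%.3g x 10^-2)\n", k[["K_BCl"]], tb[["K_BCl"]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  if (!is.null(x$bootstrap)) print(x$bootstrap)
  invisible(x)
}

#' Fit association constants by the linearized two-window route
#'
#' Applies the global pH cutoff, runs the high-H+ and low-H+ asymptote
#' regressions ([regress_highH()], [regress_lowH()]) over their windows, and
#' inverts the coefficients with [constants_from_coefficients()]. Residuals
#' and RSS are evaluated against the full nonlinear model at the recovered
#' constants, so linearized and direct fits are directly comparable.
#'
#' The linearization assumes each window actually reaches its asymptotic
#' regime; for parameter sets where it does not (notably the LiCl-like
#' regime, where the low-H+ condition fails everywhere below the cutoff),
#' prefer [fit_direct()].
#'
#' @param dataset A [titration_dataset()].
#' @param windows List with elements `highH` and `lowH`, each a pH interval.
#' @param pH_max Global cutoff passed to [apply_window()].
#' @return A `pcion_fit` object (method `"linearized"`).
#' @export
fit_linearized <- function(dataset,
                           windows = list(highH = c(2, 4), lowH = c(7, 8.5)),
                           pH_max = 8.5) {
  dataset <- apply_window(dataset, pH_max)
  rh <- regress_highH(dataset, windows$highH)
  rl <- regress_lowH(dataset, windows$lowH)
  coeffs <- list(slope_highH = rh$slope, intercept_highH = rh$intercept,
                 se_slope_highH = rh$se_slope,
                 se_intercept_highH = rh$se_intercept,
                 window_highH = rh$window,
                 slope_lowH = rl$slope, intercept_lowH = rl$intercept,
                 se_slope_lowH = rl$se_slope,
                 se_intercept_lowH = rl$se_intercept,
                 window_lowH = rl$window)
  constants <- constants_from_coefficients(coeffs, dataset$electrolyte,
                                           dataset$membrane)
  # the intercept inversion is two-valued; keep the root that explains the
  # data better (the points outside the asymptotic windows discriminate)
  w <- .fit_weights(dataset$points)
  resid_of <- function(k) {
    dataset$points$sigma -
      sigma_model(dataset$points$pH, k, dataset$electrolyte,
                  dataset$membrane)
  }
  resid <- resid_of(constants)
  alt <- attr(constants, "alternate")
  if (!is.null(alt)) {
    resid_alt <- resid_of(alt)
    if (sum(w * resid_alt^2) < sum(w * resid^2)) {
      attr(alt, "alternate") <- association_constants(
        constants[["K_AH"]], constants[["K_AMe"]],
        constants[["K_BOH"]], constants[["K_BCl"]])
      attr(alt, "warnings") <- attr(constants, "warnings")
      constants <- alt
      resid <- resid_alt
    }
  }
  .new_fit(dataset, constants, "linearized", resid, w, converged = TRUE,
           coefficients = coeffs)
}

#' Fit association constants by direct nonlinear least squares
#'
#' Minimizes the (optionally inverse-variance weighted) sum of squared
#' charge-density residuals against the four-equilibrium model, over the
#' log10 of the four constants with bounds 1e-8..1e12 m\eqn{^3}/mol. Because
#' the constants span many orders of magnitude across salts, the search is
#' multistart: a seeded log-uniform set of starting points, plus the
#' linearized estimate when it is computable, each run through bounded
#' L-BFGS-B; the best solution is polished with Levenberg--Marquardt. The
#' result is deterministic given `seed`.
#'
#' The condition number of the residual Jacobian at the optimum is reported;
#' above 1e8 (or for a flat, identically-zero charge curve) the fit is
#' flagged non-identifiable.
#'
#' @param dataset A [titration_dataset()].
#' @param init Optional [association_constants()] starting point.
#' @param multistart Number of random starts (default 16).
#' @param seed Integer seed for the start grid.
#' @param pH_max Global cutoff passed to [apply_window()].
#' @return A `pcion_fit` object (method `"direct"`).
#' @export
#' @examples
#' cfg <- reference_config("NaCl", pH_step = 0.25, noise_sd_mobility = 0)
#' fit <- fit_direct(generate_titration(cfg), seed = 1)
#' fit$constants
fit_direct <- function(dataset, init = NULL, multistart = 16, seed = 1L,
                       pH_max = 8.5) {
  stopifnot(inherits(dataset, "pcion_titration"))
  dataset <- apply_window(dataset, pH_max)
  pts <- dataset$points
  if (nrow(pts) < 5L) {
    pc_abort("direct fitting needs at least 5 points below the cutoff",
             "pcion_error_insufficient_data")
  }
  el <- dataset$electrolyte
  a_H <- proton_activity(pts$pH)
  a_OH <- el$Kw / a_H
  FC <- .pc$Faraday * dataset$membrane$C_PC
  w <- .fit_weights(pts)
  sw <- sqrt(w)
  sigma <- pts$sigma
  lo <- -8; hi <- 12

  make_resid <- function(scale) {
    force(scale)
    function(p) {
      p <- pmin(pmax(p, lo), hi)
      scale * (sigma - .sigma_fast(a_H, a_OH, 10^p, el$a_Me, el$a_Cl, FC))
    }
  }
  resid_fn <- make_resid(sw)
  obj <- function(p) sum(resid_fn(p)^2)

  starts <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "pcion_constants"))
    starts <- c(starts, list(log10(pmax(unclass(init), 10^lo))))
  }
  lin <- tryCatch(fit_linearized(dataset, pH_max = pH_max)$constants,
                  error = function(e) NULL)
  if (!is.null(lin)) {
    starts <- c(starts, list(log10(pmax(unclass(lin), 10^lo))))
  }
  set.seed(seed)
  rand <- matrix(stats::runif(4 * multistart, min = -3, max = 10),
                 ncol = 4)
  starts <- c(starts, lapply(seq_len(multistart), function(i) rand[i, ]))

  run_stage <- function(starts, rfun) {
    objf <- function(p) sum(rfun(p)^2)
    best <- NULL
    conv <- FALSE
    for (s in starts) {
      opt <- tryCatch(
        stats::optim(s, objf, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e4, maxit = 500)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (opt$convergence == 0) conv <- TRUE
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) return(NULL)
    # Levenberg-Marquardt polish from the best start
    lm <- tryCatch(
      minpack.lm::nls.lm(par = best$par, fn = rfun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 1024)),
      error = function(e) NULL)
    if (!is.null(lm)) {
      p2 <- pmin(pmax(lm$par, lo), hi)
      if (objf(p2) <= best$value) {
        best$par <- p2
        best$value <- objf(p2)
        conv <- TRUE
      }
    }
    best$converged <- conv
    best
  }

  # with strongly unequal weights, extreme-weight points can trap every
  # random start in a spurious basin; an unweighted pre-fit supplies a
  # robust extra start for the weighted stage
  if (stats::sd(w) > 0) {
    pre <- run_stage(starts, make_resid(rep(1, length(sigma))))
    if (!is.null(pre)) starts <- c(starts, list(pre$par))
  }
  best <- run_stage(starts, resid_fn)
  if (is.null(best)) {
    pc_abort("all starts of the direct fit failed",
             "pcion_error_non_convergence")
  }
  # a solution pinned to a log10 bound usually marks a spurious basin (one
  # binding branch switched off); retry with fresh batches of starts before
  # accepting it
  at_bound <- function(p) any(p <= lo + 1e-6 | p >= hi - 1e-6)
  retries <- 0L
  while (at_bound(best$par) && retries < 3L) {
    fresh <- matrix(stats::runif(4 * multistart, min = -3, max = 10),
                    ncol = 4)
    cand <- run_stage(lapply(seq_len(multistart), function(i) fresh[i, ]),
                      resid_fn)
    if (!is.null(cand) && cand$value < best$value) best <- cand
    retries <- retries + 1L
  }
  par <- best$par
  any_conv <- best$converged

  K <- 10^par
  resid <- sigma - .sigma_fast(a_H, a_OH, K, el$a_Me, el$a_Cl, FC)

  # numeric Jacobian of residuals wrt log10 K for the identifiability guard
  J <- vapply(seq_len(4L), function(j) {
    h <- 1e-6
    pp <- par; pm <- par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }, numeric(length(sigma)))
  sv <- svd(J, nu = 0, nv = 0)$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  flags <- character()
  if (max(abs(sigma)) < 1e-12 * FC) {
    flags <- c(flags, "non-identifiable: charge curve is flat (sigma ~ 0)")
  } else if (!is.finite(cond) || cond > 1e8) {
    flags <- c(flags,
               sprintf("ill-conditioned: Jacobian condition number %.3g", cond))
  }

  constants <- association_constants(K[1], K[2], K[3], K[4])
  .new_fit(dataset, constants, "direct", resid, w, converged = any_conv,
           seed = as.integer(seed), condition_number = cond, flags = flags)
}

#' Residual-bootstrap uncertainty for fitted constants
#'
#' Resamples the fit residuals with replacement, adds them back to the
#' fitted curve, and refits (a single Levenberg--Marquardt run started at
#' the point estimate) `n_boot` times. Reports per-constant percentile
#' 2.5/97.5 intervals. For a weighted fit the residuals are standardized by
#' the per-point weights before resampling and rescaled afterwards, so
#' heteroskedastic replicate noise keeps its per-point scale; for an
#' unweighted fit this reduces to the plain residual bootstrap.
#' Deterministic given `seed`. If more than 20% of replicate refits fail,
#' the result carries a reliability warning.
#'
#' @param dataset A [titration_dataset()] (the same one the fit used; the
#'   fit's windowed copy of the data drives the resampling).
#' @param fit A converged `pcion_fit`.
#' @param n_boot Number of bootstrap replicates (>= 2; default 200).
#' @param seed Integer seed.
#' @return A `pcion_bootstrap` object: `intervals` (4 x 2 matrix, 2.5% and
#'   97.5% per constant), `estimates` (replicate matrix), `n_failed`,
#'   `reliable`, `seed`.
#' @export
bootstrap_uncertainty <- function(dataset, fit, n_boot = 200, seed = 1L) {
  stopifnot(inherits(fit, "pcion_fit"))
  if (!fit$converged) {
    pc_abort("bootstrap requires a converged fit",
             "pcion_error_invalid_input")
  }
  if (n_boot < 2) {
    pc_abort("`n_boot` must be >= 2", "pcion_error_invalid_input")
  }
  pts <- fit$data$points
  el <- fit$data$electrolyte
  a_H <- proton_activity(pts$pH)
  a_OH <- el$Kw / a_H
  FC <- .pc$Faraday * fit$data$membrane$C_PC
  sw <- sqrt(fit$weights)
  p0 <- log10(pmax(unclass(fit$constants), 1e-8))
  n <- length(fit$residuals)

  set.seed(seed)
  est <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                dimnames = list(NULL, c("K_AH", "K_AMe", "K_BOH", "K_BCl")))
  resid_std <- fit$residuals * sw   # standardized (unit variance) residuals
  for (b in seq_len(n_boot)) {
    sigma_b <- fit$fitted + sample(resid_std, n, replace = TRUE) / sw
    rf <- function(p) {
      p <- pmin(pmax(p, -8), 12)
      sw * (sigma_b - .sigma_fast(a_H, a_OH, 10^p, el$a_Me, el$a_Cl, FC))
    }
    lm <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = rf,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(lm) && all(is.finite(lm$par))) {
      est[b, ] <- 10^pmin(pmax(lm$par, -8), 12)
    }
  }
  ok <- stats::complete.cases(est)
  n_failed <- sum(!ok)
  if (sum(ok) < 2) {
    pc_abort("bootstrap: fewer than 2 successful replicates",
             "pcion_error_non_convergence")
  }
  intervals <- t(apply(est[ok, , drop = FALSE], 2, stats::quantile,
                       probs = c(0.025, 0.975), names = FALSE))
  colnames(intervals) <- c("lo", "hi")
  structure(
    list(intervals = intervals, estimates = est, n_boot = n_boot,
         n_failed = n_failed, reliable = n_failed <= 0.2 * n_boot,
         seed = as.integer(seed)),
    class = "pcion_bootstrap"
  )
}

#' @export
print.pcion_bootstrap <- function(x, ...) {
  cat(sprintf("<bootstrap> %d replicates (%d failed)%s\n", x$n_boot,
              x$n_failed,
              if (x$reliable) "" else "  [UNRELIABLE: >20% refit failures]"))
  cat("  95% percentile intervals (m^3/mol):\n")
  for (k in rownames(x$intervals)) {
    cat(sprintf("  %-6s [%.4g, %.4g]\n", k,
                x$intervals[k, "lo"], x$intervals[k, "hi"]))
  }
  invisible(x)
}
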