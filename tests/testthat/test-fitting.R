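test_that("asymptote regressions recover an exact line to machine precision", {
  el <- std_electrolyte()
  mem <- std_membrane()
  Fd <- physical_constants()$Faraday

  # data lying exactly on the high-H+ line y = s*x + i
  s <- 7e-8; i <- -5e-9
  pH <- seq(2, 3.5, by = 0.1)
  a_H <- proton_activity(pH)
  d <- titration_dataset(
    data.frame(pH = pH, sigma = Fd * (s * a_H + i) / a_H), el, mem)
  r <- regress_highH(d, c(2, 3.5))
  expect_equal(r$slope, s, tolerance = 1e-12)
  expect_equal(r$intercept, i, tolerance = 1e-12)

  # and on the low-H+ line y = s2/a_H + i2
  s2 <- -5e-8; i2 <- 0.09
  pH2 <- seq(7, 8.5, by = 0.1)
  a_H2 <- proton_activity(pH2)
  d2 <- titration_dataset(
    data.frame(pH = pH2, sigma = Fd * (s2 + i2 * a_H2)), el, mem)
  r2 <- regress_lowH(d2, c(7, 8.5))
  expect_equal(r2$slope, s2, tolerance = 1e-12)
  expect_equal(r2$intercept, i2, tolerance = 1e-12)
})

test_that("regression slopes approach the closed-form asymptote coefficients", {
  mem <- std_membrane()

  dLi <- noiseless_dataset("LiCl")
  ac <- asymptote_coefficients(reference_constants("LiCl"),
                               std_electrolyte("Li"), mem)
  r <- regress_highH(dLi, c(2, 3.5))
  expect_equal(r$slope, ac$slope_highH, tolerance = 1e-2)
  expect_equal(r$slope, 7.215e-8, tolerance = 1e-2)

  dNa <- noiseless_dataset("NaCl")
  acNa <- asymptote_coefficients(reference_constants("NaCl"),
                                 std_electrolyte("Na"), mem)
  rNa <- regress_lowH(dNa, c(7, 8.5))
  expect_equal(rNa$slope, acNa$slope_lowH, tolerance = 1e-2)
})

test_that("degenerate regression inputs raise classed errors", {
  el <- std_electrolyte(); mem <- std_membrane()
  d <- titration_dataset(data.frame(pH = c(2, 3), sigma = c(1, 2) * 1e-3),
                         el, mem)
  expect_error(regress_highH(d, c(2, 4)),
               class = "pcion_error_insufficient_data")
  ddup <- titration_dataset(
    data.frame(pH = rep(3, 4), sigma = rep(1e-3, 4)), el, mem)
  expect_error(regress_highH(ddup, c(2, 4)),
               class = "pcion_error_degenerate_design")
  d2 <- titration_dataset(data.frame(pH = 2:4, sigma = rep(1e-3, 3)), el, mem)
  expect_error(regress_lowH(d2, c(7, 8.5)),
               class = "pcion_error_insufficient_data")
})

test_that("coefficient inversion reproduces the generating constants", {
  elLi <- std_electrolyte("Li")
  mem <- std_membrane()

  # forward coefficients frozen from the closed-form asymptote formulas
  co <- list(slope_highH = 7.214559e-8, intercept_highH = -5.181954e-9,
             slope_lowH = -4.730005e-8, intercept_lowH = 9.189523e-2)
  est <- constants_from_coefficients(co, elLi, mem)
  expect_lt(max_rel_err(est, reference_constants("LiCl")), 1e-5)

  # randomized forward-then-invert round trips; the intercept pair is
  # two-valued, so the truth must be the primary or the alternate root
  set.seed(23)
  for (i in 1:40) {
    k <- association_constants(10^stats::runif(1, 0, 6),
                               10^stats::runif(1, -2, 1),
                               10^stats::runif(1, 0, 8),
                               10^stats::runif(1, -3, 0))
    ac <- asymptote_coefficients(k, elLi, mem)
    inv <- constants_from_coefficients(ac, elLi, mem)
    err <- max_rel_err(inv, k)
    alt <- attr(inv, "alternate")
    if (!is.null(alt)) err <- min(err, max_rel_err(alt, k))
    expect_lt(err, 1e-6)
  }
})

test_that("decoupled intercepts give K_AH directly from the high-H+ intercept", {
  elLi <- std_electrolyte("Li")
  mem <- std_membrane()
  k <- association_constants(493, 0.342, 1e-6, 0.222)  # negligible K_BOH
  ac <- asymptote_coefficients(k, elLi, mem)
  est <- constants_from_coefficients(ac, elLi, mem)
  expect_equal(est[["K_AH"]], mem$C_PC / (-ac$intercept_highH),
               tolerance = 1e-9)
})

test_that("model-inconsistent coefficients are rejected", {
  el <- std_electrolyte(); mem <- std_membrane()
  good <- asymptote_coefficients(reference_constants("NaCl"), el, mem)
  bad1 <- good; bad1$slope_highH <- -1e-8
  expect_error(constants_from_coefficients(bad1, el, mem),
               class = "pcion_error_model_inconsistent")
  bad2 <- good; bad2$slope_lowH <- 1e-8
  expect_error(constants_from_coefficients(bad2, el, mem),
               class = "pcion_error_model_inconsistent")
  bad3 <- good; bad3$intercept_highH <- 1e-9
  expect_error(constants_from_coefficients(bad3, el, mem),
               class = "pcion_error_model_inconsistent")
  # slope implying a strongly negative constant
  bad4 <- good; bad4$slope_highH <- mem$C_PC * 2
  expect_error(constants_from_coefficients(bad4, el, mem),
               class = "pcion_error_model_inconsistent")
})

test_that("linearized fit recovers constants where the windows are asymptotic", {
  # the default liposome windows (pH 2-4, 7-8.5) are NOT asymptotic for the
  # NaCl-like constants; with the acid window moved to pH 1-2 the slopes are
  # within their truncation bias of the closed forms and the fit recovers
  # the cross constants to ~1% and the intercept-coupled pair to ~15%
  d <- generate_titration(reference_config(
    "NaCl", pH_min = 1, pH_max = 8.5, pH_step = 0.05, noise_sd_mobility = 0))
  f <- fit_linearized(d, windows = list(highH = c(1, 2), lowH = c(7, 8.5)))
  tr <- unclass(reference_constants("NaCl"))
  est <- unclass(f$constants)
  expect_lt(abs(est[["K_AMe"]] - tr[["K_AMe"]]) / tr[["K_AMe"]], 1e-4)
  expect_lt(abs(est[["K_BCl"]] - tr[["K_BCl"]]) / tr[["K_BCl"]], 2e-2)
  expect_lt(abs(est[["K_AH"]] - tr[["K_AH"]]) / tr[["K_AH"]], 5e-2)
  expect_lt(abs(est[["K_BOH"]] - tr[["K_BOH"]]) / tr[["K_BOH"]], 2.5e-1)

  # determinism
  f2 <- fit_linearized(d, windows = list(highH = c(1, 2), lowH = c(7, 8.5)))
  expect_identical(unclass(f$constants), unclass(f2$constants))

  # no usable acid-side points
  dhigh <- apply_window(d, 8.5)
  dhigh$points <- dhigh$points[dhigh$points$pH > 6, ]
  expect_error(fit_linearized(dhigh),
               class = "pcion_error_insufficient_data")
})

test_that("direct fit recovers the generating constants from noiseless curves", {
  for (salt in c("LiCl", "NaCl", "KCl", "CsCl")) {
    f <- fit_direct(noiseless_dataset(salt, pH_step = 0.1), seed = 1)
    expect_lt(max_rel_err(f$constants, reference_constants(salt)), 5e-3)
    expect_true(f$converged)
  }
})

test_that("direct fit is deterministic given the seed and seed-robust at the optimum", {
  d <- noiseless_dataset("LiCl", pH_step = 0.25)
  f1 <- fit_direct(d, seed = 1)
  f1b <- fit_direct(d, seed = 1)
  expect_identical(unclass(f1$constants), unclass(f1b$constants))
  f2 <- fit_direct(d, seed = 2)
  expect_lt(max_rel_err(f2$constants, f1$constants), 1e-8)
})

test_that("a flat charge curve is flagged non-identifiable", {
  el <- std_electrolyte(); mem <- std_membrane()
  d <- titration_dataset(
    data.frame(pH = seq(2, 8.5, 0.5), sigma = 0), el, mem)
  f <- fit_direct(d, seed = 1)
  expect_true(any(grepl("non-identifiable", f$flags)))
  expect_lt(f$rss, 1e-12)
})

test_that("direct fit never has higher residual sum than the linearized constants", {
  # barely-noisy data: the low-H+ intercept is extremely noise-sensitive
  # (the 1/a_H transform amplifies alkaline-side scatter) and must keep its
  # sign for the linearized route to apply
  cfg <- reference_config("NaCl", pH_min = 1, pH_max = 8.5, pH_step = 0.1,
                          noise_sd_mobility = 4.3e-13, seed = 5)
  d <- generate_titration(cfg)
  fl <- fit_linearized(d, windows = list(highH = c(1, 2), lowH = c(7, 8.5)))
  fd <- fit_direct(d, seed = 1)
  expect_lte(fd$rss, fl$rss)
})

test_that("bootstrap intervals collapse on noiseless data and are seeded", {
  d <- noiseless_dataset("NaCl", pH_step = 0.25)
  f <- fit_direct(d, seed = 1)
  b <- bootstrap_uncertainty(d, f, n_boot = 50, seed = 3)
  width <- (b$intervals[, "hi"] - b$intervals[, "lo"]) / unclass(f$constants)
  expect_true(all(width < 1e-6))
  expect_equal(b$n_failed, 0)
  expect_true(b$reliable)

  b2 <- bootstrap_uncertainty(d, f, n_boot = 50, seed = 3)
  expect_identical(b$intervals, b2$intervals)

  expect_error(bootstrap_uncertainty(d, f, n_boot = 1),
               class = "pcion_error_invalid_input")
})
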