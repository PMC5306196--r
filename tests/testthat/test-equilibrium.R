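test_that("surface concentration follows 1/(N_A * area)", {
  NA_ <- physical_constants()$N_A
  expect_equal(surface_concentration_from_area(65e-20), 2.555e-6,
               tolerance = 1e-3)
  expect_identical(surface_concentration_from_area(65e-20),
                   1 / (NA_ * 65e-20))
  expect_equal(surface_concentration_from_area(100e-20), 1.6606e-6,
               tolerance = 1e-4)
  expect_equal(surface_concentration_from_area(130e-20),
               surface_concentration_from_area(65e-20) / 2)
  expect_error(surface_concentration_from_area(0),
               class = "pcion_error_invalid_input")
  expect_error(surface_concentration_from_area(-1e-20),
               class = "pcion_error_invalid_input")
})

test_that("proton and hydroxide activities follow the molar pH convention", {
  expect_equal(proton_activity(7), 1e-4)
  expect_equal(hydroxide_activity(7, Kw = 1e-8), 1e-4)
  expect_equal(proton_activity(3), 1)
  expect_equal(proton_activity(2), 10)
  expect_equal(hydroxide_activity(2, Kw = 1e-8), 1e-9)
})

test_that("site concentrations obey the closed forms and their limits", {
  el <- std_electrolyte("Li")
  mem <- std_membrane()
  C <- mem$C_PC

  k0 <- association_constants(0, 0, 0, 0)
  s0 <- site_concentrations(7, k0, el, mem)
  expect_equal(s0$a_Aminus, C)
  expect_equal(s0$a_Bplus, C)
  expect_equal(s0$a_AH + s0$a_AMe + s0$a_BOH + s0$a_BCl, 0)

  kLi <- reference_constants("LiCl")
  s7 <- site_concentrations(7, kLi, el, mem)
  expect_equal(s7$a_Aminus, 4.73e-8, tolerance = 2e-3)
  expect_equal(s7$a_Bplus, 7.16e-8, tolerance = 2e-3)

  ksat <- association_constants(1e12, 0, 0, 0)
  s3 <- site_concentrations(3, ksat, el, mem)
  expect_lt(s3$a_Aminus / C, 1e-10)
  expect_equal(s3$a_AH, C, tolerance = 1e-9)
})

test_that("mass balances hold at every pH for randomized constants", {
  el <- std_electrolyte("K")
  mem <- std_membrane()
  C <- mem$C_PC
  pH <- seq(0, 14, by = 0.5)
  set.seed(7)
  for (i in 1:50) {
    k <- random_constants()
    s <- site_concentrations(pH, k, el, mem)
    expect_true(all(abs(s$a_Aminus + s$a_AH + s$a_AMe - C) / C < 1e-12))
    expect_true(all(abs(s$a_Bplus + s$a_BOH + s$a_BCl - C) / C < 1e-12))
    expect_true(all(as.matrix(s[-1]) >= 0))
  }
})

test_that("model charge density matches examples, bounds and limits", {
  el <- std_electrolyte("Li")
  mem <- std_membrane()
  FC <- physical_constants()$Faraday * mem$C_PC
  kLi <- reference_constants("LiCl")

  expect_equal(sigma_model(3, kLi, el, mem), 6.51e-3, tolerance = 1e-3)
  expect_equal(sigma_model(seq(0, 14, 0.5), association_constants(0, 0, 0, 0),
                           el, mem),
               rep(0, 29))

  # symmetric construction is uncharged at neutrality
  ks <- association_constants(500, 0.3, 500, 0.3)
  expect_equal(sigma_model(7, ks, el, mem), 0, tolerance = 1e-20)

  set.seed(11)
  for (i in 1:20) {
    k <- random_constants()
    sg <- sigma_model(seq(-1, 15, 0.25), k, el, mem)
    expect_true(all(abs(sg) <= FC * (1 + 1e-12)))
  }

  # acid/alkaline saturation plateaus (numerically at pH -3 and 17)
  kk <- unclass(kLi)
  expect_equal(sigma_model(-3, kLi, el, mem),
               FC / (1 + kk[["K_BCl"]] * 155), tolerance = 1e-6)
  expect_equal(sigma_model(17, kLi, el, mem),
               -FC / (1 + kk[["K_AMe"]] * 155), tolerance = 1e-6)
})

test_that("charge density equals F*(a_Bplus - a_Aminus) and the brute-force solve", {
  el <- std_electrolyte("Cs")
  mem <- std_membrane()
  Fd <- physical_constants()$Faraday
  C <- mem$C_PC
  pH <- seq(0, 14, by = 0.2)
  set.seed(3)
  for (i in 1:10) {
    k <- random_constants()
    s <- site_concentrations(pH, k, el, mem)
    sg <- sigma_model(pH, k, el, mem)
    expect_true(all(abs(Fd * (s$a_Bplus - s$a_Aminus) - sg) /
                      pmax(abs(sg), Fd * C * 1e-6) < 1e-10))
    for (j in seq(1, length(pH), by = 7)) {
      x <- brute_force_sites(pH[j], k, el, mem)
      expect_lt(abs(Fd * (x[4] - x[1]) - sg[j]) /
                  max(abs(sg[j]), Fd * C * 1e-6), 1e-10)
    }
  }
})

test_that("charge density decreases strictly with pH for positive constants", {
  el <- std_electrolyte()
  mem <- std_membrane()
  pH <- seq(0, 14, by = 0.1)
  set.seed(19)
  for (i in 1:25) {
    k <- random_constants(lo = -2, hi = 8)
    sg <- sigma_model(pH, k, el, mem)
    expect_true(all(diff(sg) <= 0))
    expect_lt(sg[length(sg)], sg[1])
  }
})

test_that("isoelectric point solves the quadratic and is verified by sign change", {
  mem <- std_membrane()

  # symmetric constants put the IEP exactly at neutrality
  el <- std_electrolyte()
  ks <- association_constants(500, 0.3, 500, 0.3)
  expect_equal(isoelectric_point(ks, el, mem), 7, tolerance = 1e-9)

  elLi <- std_electrolyte("Li")
  iep_li <- isoelectric_point(reference_constants("LiCl"), elLi, mem)
  expect_equal(iep_li, 8.83, tolerance = 1e-3)
  elNa <- std_electrolyte("Na")
  iep_na <- isoelectric_point(reference_constants("NaCl"), elNa, mem)
  expect_equal(iep_na, 3.74, tolerance = 1e-3)

  # bisection on sigma_model as the independent root oracle
  for (salt in c("LiCl", "NaCl", "KCl", "CsCl")) {
    el <- std_electrolyte(sub("Cl$", "", salt))
    k <- reference_constants(salt)
    iep <- isoelectric_point(k, el, mem)
    root <- stats::uniroot(function(p) sigma_model(p, k, el, mem),
                           c(iep - 1, iep + 1), tol = 1e-12)$root
    expect_equal(iep, root, tolerance = 1e-9)
  }

  # K_AH = 0 falls back to the linear branch
  k0 <- association_constants(0, 0.3, 1e6, 0.1)
  iep0 <- isoelectric_point(k0, std_electrolyte(), mem)
  expect_equal(sigma_model(iep0, k0, std_electrolyte(), mem), 0,
               tolerance = 1e-15)

  expect_error(isoelectric_point(association_constants(0, 0, 0, 0),
                                 std_electrolyte(), mem),
               class = "pcion_error_no_iep")
})
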