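# shared builders and independent oracles used across the test files

std_electrolyte <- function(cation = "Na") electrolyte_spec(cation, c_salt = 155)
std_membrane <- function() membrane_spec(65e-20)

# noiseless model dataset on a pH grid
noiseless_dataset <- function(salt, pH_min = 2, pH_max = 8.5, pH_step = 0.05) {
  generate_titration(reference_config(
    salt, pH_min = pH_min, pH_max = pH_max, pH_step = pH_step,
    noise_sd_mobility = 0))
}

# log-uniform random association constants
random_constants <- function(lo = -3, hi = 9) {
  association_constants(10^stats::runif(1, lo, hi),
                        10^stats::runif(1, lo, hi),
                        10^stats::runif(1, lo, hi),
                        10^stats::runif(1, lo, hi))
}

# independent oracle: the four association identities plus the two mass
# balances as one six-unknown linear system, solved by generic elimination
# (row-equilibrated); returns (a_Aminus, a_AH, a_AMe, a_Bplus, a_BOH, a_BCl)
brute_force_sites <- function(pH, constants, electrolyte, membrane) {
  a_H <- proton_activity(pH)
  a_OH <- electrolyte$Kw / a_H
  C <- membrane$C_PC
  A <- matrix(0, 6, 6)
  A[1, 1] <- constants[["K_AH"]] * a_H;            A[1, 2] <- -1
  A[2, 1] <- constants[["K_AMe"]] * electrolyte$a_Me; A[2, 3] <- -1
  A[3, 4] <- constants[["K_BOH"]] * a_OH;          A[3, 5] <- -1
  A[4, 4] <- constants[["K_BCl"]] * electrolyte$a_Cl; A[4, 6] <- -1
  A[5, 1:3] <- 1
  A[6, 4:6] <- 1
  s <- pmax(1, abs(A[, 1]) + abs(A[, 4]))
  solve(A / s, c(0, 0, 0, 0, C, C) / s)
}

# closed-form asymptote coefficients of the two linearized regimes
asymptote_coefficients <- function(constants, electrolyte, membrane) {
  k <- unclass(constants)
  C <- membrane$C_PC
  Kw <- electrolyte$Kw
  P <- 1 + k[["K_BCl"]] * electrolyte$a_Cl
  M <- 1 + k[["K_AMe"]] * electrolyte$a_Me
  list(slope_highH = C / P,
       intercept_highH = -(C * k[["K_BOH"]] * Kw / P^2 + C / k[["K_AH"]]),
       slope_lowH = -C / M,
       intercept_lowH = C / (k[["K_BOH"]] * Kw) + C * k[["K_AH"]] / M^2)
}

max_rel_err <- function(est, truth) {
  max(abs(unclass(est) - unclass(truth)) / unclass(truth))
}
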