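## Internal fast paths for the right-hand sides, used by the solvers.
## The exported conversion_fluxes()/model_rhs() wrap these with state-layout
## handling; these assume a correctly ordered unnamed numeric vector.

.fluxes_raw <- function(E, M, M1, M2, params) {
  met <- 0
  if (M > 0) {
    met <- params$eta_me * M * M1^params$n /
      (M1^params$n + M / (M + params$K_M0))
    if (!is.finite(met)) met <- 0
  }
  emt <- 0
  if (E > 0) {
    Ek <- E^params$k
    emt <- params$eta_em * E * M2^params$m /
      (M2^params$m + Ek / (Ek + params$K_E0^params$k))
    if (!is.finite(emt)) emt <- 0
  }
  c(met, emt)
}

.rhs_raw <- function(s, params) {
  E <- s[1L]; M <- s[2L]; M1 <- s[3L]; M2 <- s[4L]; M0 <- s[5L]
  fl <- .fluxes_raw(E, M, M1, M2, params)
  met <- fl[1L]; emt <- fl[2L]
  growth_room <- 1 - (E + M + M1 + M2 + M0) / params$N_max
  senescence <- 1 / (1 + params$alpha * M1 / (M1 + params$K_1))
  pol1 <- params$eta_1 * E / (E + params$K_E) * M0
  pol2 <- params$eta_2 * M / (M + params$K_M) * M0
  dE <- params$lambda_E * E * growth_room * senescence + met - emt
  dM <- params$lambda_M * M * growth_room - met + emt
  if (params$variant == "III") {
    C <- s[6L]
    apoptosis <- params$beta * E * M1 / (M1 + params$K_2)
    conv_12 <- params$eta_12 * C / (C + params$K_C) * M1
    conv_21 <- params$eta_21 * M2
    c(dE - apoptosis, dM,
      pol1 - conv_12 + conv_21,
      pol2 + conv_12 - conv_21,
      -pol1 - pol2,
      apoptosis - params$beta_c * C)
  } else {
    conv_12 <- (params$eta_120 + params$eta_12 * M / (M + params$K_M)) * M1
    conv_21 <- (params$eta_210 + params$eta_21 * E / (E + params$K_E)) * M2
    c(dE, dM,
      pol1 - conv_12 + conv_21,
      pol2 + conv_12 - conv_21,
      -pol1 - pol2)
  }
}
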