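#' Macrophage-assisted phenotype conversion fluxes
#'
#' The two fluxes exchanging cells between the epithelial and mesenchymal
#' compartments.  MET (mesenchymal to epithelial) is promoted by M1
#' macrophages and resisted by the mesenchymal population itself through
#' autocrine/paracrine maintenance factors; EMT (epithelial to mesenchymal)
#' is promoted by M2 macrophages and resisted cooperatively by cell-cell
#' contact among epithelial cells:
#' \deqn{\mathrm{met} = \eta_{me}\,M\,\frac{M_1^n}{M_1^n + \frac{M}{M+K_{M0}}},\qquad
#'       \mathrm{emt} = \eta_{em}\,E\,\frac{M_2^m}{M_2^m + \frac{E^k}{E^k+K_{E0}^k}}.}
#' Each resistance term saturates to a finite value as the resisting
#' population grows, with half-saturation constants `K_M0` and `K_E0`.
#'
#' At boundary states a flux is defined as 0 whenever its leading population
#' factor (`M` for MET, `E` for EMT) is 0, evaluated before any division, so
#' indeterminate 0/0 denominators never arise: conversion is proportional to
#' the population being converted.
#'
#' @param state state vector (see [population_state()]).
#' @param params validated `emtmac_params`.
#' @return named numeric vector `c(met = , emt = )`, both nonnegative, in
#'   population fraction per hour.
#' @export
conversion_fluxes <- function(state, params) {
  s <- .as_state(state, params)
  fl <- .fluxes_raw(s[["E"]], s[["M"]], s[["M1"]], s[["M2"]], params)
  c(met = fl[1L], emt = fl[2L])
}

#' Time derivative of the co-culture state
#'
#' Evaluates the right-hand side of the selected model variant.  All variants
#' share: logistic growth of both cancer phenotypes limited by the common
#' carrying capacity (with M1-induced senescence damping
#' \eqn{1/(1+\alpha M_1/(M_1+K_1))} acting on epithelial growth only), the
#' MET/EMT [conversion_fluxes()], and saturating polarization of monocytes by
#' epithelial (`eta_1`) and mesenchymal (`eta_2`) cells.  Variant II adds
#' M1/M2 interconversion at constant rates `eta_120`/`eta_210` plus
#' cancer-cell-enhanced rates `eta_12`/`eta_21`; variant I is the special
#' case with all interconversion rates zero.  Variant III instead couples
#' M1 -> M2 conversion to an apoptotic-factor compartment `C`, which is
#' produced when M1 macrophages kill epithelial cells (rate `beta`, Michaelis
#' constant `K_2`) and decays at `beta_c`; M2 -> M1 conversion is the
#' constant-rate term `eta_21 * M2`.
#'
#' The macrophage equations sum to zero identically, so `M0 + M1 + M2` is an
#' exact invariant of every variant.
#'
#' @inheritParams conversion_fluxes
#' @return named derivative vector matching the state layout, in units of
#'   fraction per hour.
#' @export
model_rhs <- function(state, params) {
  s <- .as_state(state, params)
  out <- .rhs_raw(unname(s), params)
  names(out) <- names(s)
  out
}

#' Maximum-norm residual of the right-hand side at a state
#' @inheritParams conversion_fluxes
#' @return `max(abs(model_rhs(state, params)))`.
#' @export
rhs_residual <- function(state, params) {
  max(abs(.rhs_raw(unname(.as_state(state, params)), params)))
}
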