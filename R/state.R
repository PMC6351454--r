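#' Construct a population state vector
#'
#' The dynamical state of the co-culture: epithelial (`E`) and mesenchymal
#' (`M`) cancer-cell fractions, M1- and M2-polarized macrophage fractions,
#' monocyte fraction (`M0`), all expressed as fractions of the carrying
#' capacity, plus the apoptotic-factor level `C` (dimensionless; used only by
#' model variant III and fixed at 0 otherwise).
#'
#' @param E,M,M1,M2,M0 nonnegative population fractions.
#' @param C nonnegative apoptotic-factor level (variant III only).
#' @return a named numeric vector `c(E, M, M1, M2, M0, C)`.
#' @export
population_state <- function(E = 0, M = 0, M1 = 0, M2 = 0, M0 = 0, C = 0) {
  s <- c(E = E, M = M, M1 = M1, M2 = M2, M0 = M0, C = C)
  if (any(!is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be nonnegative")
  s
}

#' State component names used by a model variant
#'
#' Variants I and II have five dynamical components; variant III appends the
#' apoptotic-factor level `C`.
#'
#' @param variant `"I"`, `"II"` or `"III"`, or an `emtmac_params` object.
#' @return character vector of component names, in state-vector order.
#' @export
state_names <- function(variant) {
  if (inherits(variant, "emtmac_params")) variant <- variant$variant
  if (variant == "III") c("E", "M", "M1", "M2", "M0", "C") else c("E", "M", "M1", "M2", "M0")
}

## Coerce a (possibly 6-component) state to the layout of the variant,
## checking length.  Accepts unnamed vectors in canonical order.
.as_state <- function(state, params) {
  nm <- state_names(params)
  d <- length(nm)
  if (length(state) == 6L && d == 5L) state <- state[1:5]
  if (length(state) != d) {
    stop("state must have ", d, " components for variant ", params$variant)
  }
  names(state) <- nm
  state
}

#' Total macrophage fraction of a state
#'
#' `M1 + M2 + M0` is conserved along every trajectory of every model variant
#' (macrophages neither divide nor die), so this total is fixed by the initial
#' condition.
#'
#' @param state a state vector.
#' @return the scalar macrophage total.
#' @export
macrophage_total <- function(state) {
  unname(state[["M1"]] + state[["M2"]] + state[["M0"]])
}
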