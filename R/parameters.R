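#' @keywords internal
"_PACKAGE"

## Canonical default parameter values for the co-culture models.
## Rates are per hour; populations are fractions of the carrying capacity N_max.
.param_defaults <- function() {
  list(
    N_max    = 1,       # carrying capacity (normalization)
    lambda_E = 1 / 72,  # epithelial growth rate
    lambda_M = 1 / 72,  # mesenchymal growth rate
    alpha    = 100,     # strength of M1-induced senescence of epithelial cells
    K_1      = 0.1,     # half-saturation of senescence induction
    eta_me   = 1 / 120, # M1-assisted MET rate constant
    eta_em   = 1 / 72,  # M2-assisted EMT rate constant
    K_M0     = 0.1,     # half-saturation of the mesenchymal resistance to MET
    K_E0     = 0.1,     # half-saturation of the epithelial resistance to EMT
    k        = 4,       # cooperativity of the epithelial resistance
    n        = 1,       # Hill cooperativity of M1-assisted MET
    m        = 1,       # Hill cooperativity of M2-assisted EMT
    beta     = 0,       # M1-induced epithelial apoptosis rate (apoptosis variant)
    K_2      = 1,       # half-saturation of apoptosis induction
    beta_c   = 1 / 1200,# apoptotic-factor decay rate
    eta_1    = 1 / 24,  # monocyte -> M1 polarization rate
    eta_2    = 1 / 24,  # monocyte -> M2 polarization rate
    K_E      = 0.1,     # half-saturation of the epithelial polarization stimulus
    K_M      = 0.1,     # half-saturation of the mesenchymal polarization stimulus
    K_C      = 1,       # half-saturation of apoptotic-factor-driven M1 -> M2 conversion
    eta_120  = 1 / 72,  # constant M1 -> M2 conversion rate (interconversion variant)
    eta_210  = 1 / 72,  # constant M2 -> M1 conversion rate (interconversion variant)
    eta_12   = 1 / 72,  # cancer- or factor-enhanced M1 -> M2 conversion rate
    eta_21   = 1 / 72   # cancer-enhanced (variant II) or constant (variant III) M2 -> M1 rate
  )
}

.param_names <- function() names(.param_defaults())

#' Construct and validate a model parameter set
#'
#' Builds the full rate/saturation parameter set of the tumor-macrophage
#' co-culture models, filling unspecified fields with the canonical defaults.
#' Three nested model variants are supported:
#' \describe{
#'   \item{`"I"`}{monocyte polarization only; no M1/M2 interconversion.  The
#'     interconversion rates (`eta_120`, `eta_210`, `eta_12`, `eta_21`) are
#'     forced to zero.}
#'   \item{`"II"`}{adds constant (`eta_120`, `eta_210`) and cancer-cell
#'     enhanced (`eta_12`, `eta_21`) interconversion between M1 and M2.}
#'   \item{`"III"`}{adds M1-induced apoptosis of epithelial cells (rate
#'     `beta`, default 1/36 per hour) with an apoptotic-factor compartment C
#'     that drives M1 -> M2 conversion; M2 -> M1 conversion is a constant-rate
#'     therapeutic term `eta_21`.  The constant rates `eta_120`/`eta_210` of
#'     variant II are absent and forced to zero.}
#' }
#'
#' @param variant model variant, one of `"I"`, `"II"`, `"III"`.
#' @param ... named parameter overrides (see [model_parameter_names()]).
#' @return an object of class `emtmac_params`: a named list of rates and
#'   saturation constants with the variant attached, and an attribute
#'   `"modified"` naming the non-default fields.
#' @examples
#' p <- model_parameters("II", eta_me = 0.02, m = 2, n = 2)
#' attr(p, "modified")
#' @export
model_parameters <- function(variant = c("I", "II", "III"), ...) {
  variant <- match.arg(variant)
  overrides <- list(...)
  p <- .param_defaults()
  if (variant == "III" && !("beta" %in% names(overrides))) p$beta <- 1 / 36
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(overrides))) {
    stop("duplicated parameter field(s): ",
         paste(unique(names(overrides)[duplicated(names(overrides))]),
               collapse = ", "))
  }
  modified <- character(0)
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number")
    }
    if (!isTRUE(all.equal(unname(v), p[[nm]]))) modified <- c(modified, nm)
    p[[nm]] <- unname(v)
  }
  if (variant == "I") p[c("eta_120", "eta_210", "eta_12", "eta_21")] <- list(0, 0, 0, 0)
  if (variant == "III") p[c("eta_120", "eta_210")] <- list(0, 0)
  p$variant <- variant
  class(p) <- "emtmac_params"
  attr(p, "modified") <- modified
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks sign and range constraints: all rates and saturation constants must
#' be nonnegative, the Hill cooperativities `n`, `m`, `k` at least 1, and the
#' carrying capacity `N_max` strictly positive.  Called by
#' [model_parameters()]; exported so externally constructed or deserialized
#' sets can be re-checked.
#'
#' @param params an `emtmac_params` object.
#' @return `params`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending field.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "emtmac_params")) {
    stop("'params' must be created by model_parameters()")
  }
  if (!params$variant %in% c("I", "II", "III")) {
    stop("unknown model variant: ", params$variant)
  }
  for (nm in .param_names()) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' is missing or not a finite number")
    }
    if (v < 0) stop("parameter '", nm, "' must be nonnegative (got ", v, ")")
  }
  if (params$N_max <= 0) stop("parameter 'N_max' must be strictly positive")
  for (nm in c("n", "m", "k")) {
    if (params[[nm]] < 1) stop("cooperativity '", nm, "' must be >= 1")
  }
  params
}

#' Names of the model parameter fields
#' @return character vector of valid field names for [model_parameters()].
#' @export
model_parameter_names <- function() .param_names()

#' Reference parameter set for the apoptosis-mediated model
#'
#' The variant III configuration used throughout the package's critical-value
#' analyses: apoptosis rate `beta` = 1/36 per hour, apoptotic-factor decay
#' `beta_c` = 1/1200 per hour, conversion rates `eta_12` = `eta_21` = 1/72 per
#' hour, Hill cooperativities `m` = `n` = 2 and epithelial-resistance
#' cooperativity `k` = 4, all other fields at their defaults.  The associated
#' total macrophage fraction is `M_c` = 0.3 (kept in the equilibrium problem,
#' not here).
#'
#' @param ... overrides passed on to [model_parameters()].
#' @return an `emtmac_params` object of variant `"III"`.
#' @export
model3_reference_params <- function(...) {
  base <- list(beta = 1 / 36, beta_c = 1 / 1200, eta_12 = 1 / 72,
               eta_21 = 1 / 72, m = 2, n = 2, k = 4)
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(model_parameters, c(list(variant = "III"), base))
}

#' @export
print.emtmac_params <- function(x, ...) {
  cat("<emtmac_params> variant", x$variant, "\n")
  nm <- .param_names()
  v <- unlist(x[nm])
  mod <- nm %in% attr(x, "modified")
  cat(paste0(sprintf("  %-9s = %-12.6g", nm, v), ifelse(mod, " *", "")),
      sep = "\n")
  if (any(mod)) cat("  (* non-default)\n")
  invisible(x)
}

#' Update fields of an existing parameter set
#'
#' @param params an `emtmac_params` object.
#' @param ... named fields to change.
#' @return a new validated `emtmac_params` object.
#' @export
update_parameters <- function(params, ...) {
  ov <- list(...)
  unknown <- setdiff(names(ov), .param_names())
  if (length(unknown)) stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  keep <- params[.param_names()]
  keep[names(ov)] <- ov
  do.call(model_parameters, c(list(variant = params$variant), keep))
}
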