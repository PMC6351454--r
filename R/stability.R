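#' Central finite-difference Jacobian
#'
#' Differentiates an arbitrary vector field `f` at `x` with central
#' differences of relative step `step` (accuracy O(step^2)).  Where a central
#' step would take a component negative and `nonneg` is `TRUE`, one-sided
#' forward differencing is used for that column and the result is flagged via
#' the `"one_sided"` attribute (the model right-hand sides are only defined
#' on the nonnegative orthant).
#'
#' @param f function mapping a numeric vector to a numeric vector of the same
#'   length.
#' @param x evaluation point.
#' @param step relative finite-difference step (default 1e-6).
#' @param nonneg restrict evaluations to the nonnegative orthant.
#' @return the Jacobian matrix, with attribute `"one_sided"` giving the
#'   indices of columns where one-sided differencing was used.
#' @export
fd_jacobian <- function(f, x, step = 1e-6, nonneg = TRUE) {
  d <- length(x)
  fx <- NULL
  J <- matrix(0, d, d)
  one_sided <- integer(0)
  for (j in seq_len(d)) {
    h <- step * max(1, abs(x[j]))
    if (nonneg && x[j] - h < 0) {
      if (is.null(fx)) fx <- f(x)
      xp <- x; xp[j] <- x[j] + h
      xpp <- x; xpp[j] <- x[j] + 2 * h
      ## second-order one-sided stencil
      J[, j] <- (-3 * fx + 4 * f(xp) - f(xpp)) / (2 * h)
      one_sided <- c(one_sided, j)
    } else {
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      J[, j] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  attr(J, "one_sided") <- one_sided
  J
}

#' Jacobian of a model right-hand side
#'
#' @param params validated `emtmac_params`.
#' @param state nonnegative state vector (5 components for variants I/II,
#'   6 for variant III).
#' @param step relative finite-difference step.
#' @return square Jacobian matrix with state-component dimnames.
#' @export
model_jacobian <- function(params, state, step = 1e-6) {
  s <- .as_state(state, params)
  J <- fd_jacobian(function(x) .rhs_raw(x, params), unname(s),
                   step = step, nonneg = TRUE)
  dimnames(J) <- list(names(s), names(s))
  J
}

#' Eigenvalue spectrum report of an equilibrium
#'
#' Classifies a spectrum as stable/unstable/marginal after discarding
#' near-zero eigenvalues (|Re| < `zero_tol`).  Structurally, the exact
#' conservation of `M0 + M1 + M2` forces one zero eigenvalue at every
#' equilibrium of every variant; variant I equilibria carry one additional
#' neutral direction along the continuum of steady states, and fully
#' cancer-free states freeze the monocyte coordinate as well.  The number of
#' discarded eigenvalues is reported in `n_zero` so callers can check it
#' against the structural expectation.
#'
#' @param eigenvalues complex (or numeric) eigenvalue vector.
#' @param zero_tol threshold below which |Re| counts as a neutral direction
#'   (default 1e-7 per hour).
#' @return an `emtmac_spectrum` list: `eigenvalues`, `max_real_part` (over
#'   non-neutral directions; `-Inf` if none), `n_zero`,
#'   `has_complex_pair_crossing` (a complex pair with |Re| <= `zero_tol`),
#'   and `classification` (`"stable"`, `"unstable"` or `"marginal"`).
#' @export
spectrum_report <- function(eigenvalues, zero_tol = 1e-7) {
  re <- Re(eigenvalues)
  neutral <- abs(re) <= zero_tol
  kept <- re[!neutral]
  max_re <- if (length(kept)) max(kept) else -Inf
  cplx <- abs(Im(eigenvalues)) > zero_tol
  crossing <- any(cplx & abs(re) <= zero_tol)
  classification <- if (!length(kept)) {
    "marginal"
  } else if (max_re < -zero_tol) {
    "stable"
  } else if (max_re > zero_tol) {
    "unstable"
  } else {
    "marginal"
  }
  structure(list(eigenvalues = eigenvalues, max_real_part = max_re,
                 n_zero = sum(neutral), has_complex_pair_crossing = crossing,
                 classification = classification),
            class = "emtmac_spectrum")
}

#' Stability classification of a steady state
#'
#' Computes the Jacobian spectrum at an equilibrium and classifies it.  One
#' structurally zero eigenvalue (macrophage conservation) is expected and
#' discarded at every equilibrium.  For variant I, whose equilibria form a
#' continuum parameterized by the M2 level, a second neutral direction is
#' expected; it is identified as the near-zero eigenvalue whose eigenvector
#' has the largest projection onto the M1/M2 exchange direction (robust when
#' other eigenvalues are also small), and its presence is recorded as
#' `"neutral_along_continuum"`.  More near-zero eigenvalues than the
#' structural expectation yield a `"marginal"` flag for manual review.
#'
#' @param steady a [steady_state()] object, or a bare state vector.
#' @param params validated `emtmac_params`.
#' @param zero_tol neutral-direction threshold, per hour.
#' @param step finite-difference step for the Jacobian.
#' @return an `emtmac_spectrum` report with additional fields
#'   `n_zero_expected` and `continuum_direction` (variant I: projection of
#'   the neutral eigenvector onto the M1/M2 exchange direction).
#' @export
classify_stability <- function(steady, params, zero_tol = 1e-7, step = 1e-6) {
  state <- if (inherits(steady, "emtmac_steady")) steady$state else .as_state(steady, params)
  J <- model_jacobian(params, state, step = step)
  eg <- eigen(J)
  rep <- spectrum_report(eg$values, zero_tol = zero_tol)

  ## structural expectation: conservation zero everywhere; +1 continuum
  ## direction in variant I; +1 frozen monocyte direction when no cancer
  ## cells are present to polarize it.
  expected <- 1L
  if (params$variant == "I") expected <- expected + 1L
  if (state[["E"]] < 1e-9 && state[["M"]] < 1e-9) expected <- expected + 1L
  rep$n_zero_expected <- expected

  if (params$variant == "I") {
    near <- which(abs(Re(eg$values)) <= zero_tol)
    if (length(near)) {
      exch <- rep(0, length(state))
      exch[match(c("M1", "M2"), names(state))] <- c(1, -1) / sqrt(2)
      proj <- vapply(near, function(i) {
        v <- eg$vectors[, i]
        abs(sum(Conj(v) * exch)) / sqrt(sum(Mod(v)^2))
      }, numeric(1))
      rep$continuum_direction <- max(proj)
    } else {
      rep$continuum_direction <- NA_real_
    }
  }
  if (rep$n_zero > expected) rep$classification <- "marginal"
  rep
}

#' Hopf indicator: leading real part among complex eigenvalue pairs
#'
#' Along a branch of equilibria this quantity is continuous in the swept
#' parameter, and its sign change localizes a Hopf bifurcation (a complex
#' conjugate pair crossing the imaginary axis).
#'
#' @param steady a [steady_state()] object or bare state vector (ignored if
#'   `jacobian` is supplied).
#' @param params validated `emtmac_params` (ignored if `jacobian` is
#'   supplied).
#' @param im_tol minimum |Im| for an eigenvalue to count as complex.
#' @param jacobian optional square matrix whose spectrum is used directly,
#'   allowing arbitrary linearized systems to be fed through the same
#'   indicator.
#' @return the maximum real part over complex eigenvalue pairs, or `NA` with
#'   attribute `"reason" = "no complex pair"` if the spectrum is real.
#' @export
hopf_indicator <- function(steady = NULL, params = NULL, im_tol = 1e-9,
                           jacobian = NULL) {
  if (is.null(jacobian)) {
    state <- if (inherits(steady, "emtmac_steady")) steady$state else .as_state(steady, params)
    jacobian <- model_jacobian(params, state)
  }
  ev <- eigen(jacobian, only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > im_tol]
  if (!length(cplx)) {
    return(structure(NA_real_, reason = "no complex pair"))
  }
  max(Re(cplx))
}
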