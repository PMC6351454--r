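#' Integrate a model trajectory
#'
#' Solves the selected model variant with a stiff-capable solver
#' ([deSolve::ode()], `lsoda`).  Tight default tolerances keep the exact
#' macrophage conservation law satisfied to high precision over long runs.
#'
#' The derivative is evaluated on the state clamped to the nonnegative
#' orthant (the model is only defined there), and small negative undershoots
#' near the boundary (|value| < 1e-8) are clipped to zero in the returned
#' states; larger negative values signal an integrator/model inconsistency
#' and raise an error.
#'
#' @param params validated `emtmac_params`.
#' @param state0 nonnegative initial state with total population at most
#'   `N_max`.
#' @param t_end final time, hours.
#' @param rel_tol,abs_tol local error tolerances of the integrator.
#' @param n_out number of equally spaced output times (including 0).
#' @return an `emtmac_trajectory`: a data frame with column `t` and one column
#'   per state component, with attributes `params`, `converged` (final
#'   residual below 1e-8) and `final_residual` (max |derivative| at the end
#'   point).
#' @export
integrate_model <- function(params, state0, t_end, rel_tol = 1e-9,
                            abs_tol = 1e-12, n_out = 201) {
  validate_parameters(params)
  s0 <- .as_state(state0, params)
  if (any(s0 < 0)) stop("initial state must be nonnegative")
  pops <- setdiff(names(s0), "C")
  if (sum(s0[pops]) > params$N_max * (1 + 1e-9)) {
    stop("initial total population exceeds the carrying capacity")
  }
  times <- seq(0, t_end, length.out = max(2L, n_out))
  deriv <- function(t, y, parms) list(.rhs_raw(pmax(y, 0), params))
  sol <- deSolve::ode(y = s0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("integration failed at t = ", max(sol[, "time"]), " hours")
  }
  df <- as.data.frame(sol)
  names(df)[1L] <- "t"
  statecols <- names(s0)
  neg <- df[statecols] < 0
  if (any(neg & as.matrix(abs(df[statecols])) > 1e-8)) {
    stop("trajectory left the nonnegative orthant beyond round-off")
  }
  df[statecols][neg] <- 0
  final <- unlist(df[nrow(df), statecols])
  res <- rhs_residual(final, params)
  structure(df, class = c("emtmac_trajectory", "data.frame"),
            params = params, converged = res < 1e-8, final_residual = res)
}

#' Relax a state to a steady state
#'
#' Integrates in chunks until the right-hand-side residual drops below
#' `residual_tol`, returning the equilibrium point, or until `t_max` is
#' reached, returning a non-convergence report (never an error).
#'
#' @inheritParams integrate_model
#' @param residual_tol convergence threshold on max |derivative| (per hour).
#' @param t_max maximum total integration time, hours.
#' @param chunk chunk length for convergence checks, hours.
#' @return on convergence, a [steady_state()] object with provenance
#'   `"relaxation"` and the initial condition attached; otherwise a list with
#'   `converged = FALSE`, the final `state`, `residual` and `t`.
#' @export
run_to_steady <- function(params, state0, residual_tol = 1e-10,
                          t_max = 5e5, chunk = 2000) {
  validate_parameters(params)
  s <- .as_state(state0, params)
  if (rhs_residual(s, params) < residual_tol) {
    return(steady_state(s, params, provenance = "relaxation",
                        extra = list(state0 = s, t = 0)))
  }
  t <- 0
  while (t < t_max) {
    tr <- integrate_model(params, s, t_end = chunk, n_out = 2L)
    s <- unlist(tr[nrow(tr), names(s)])
    t <- t + chunk
    if (rhs_residual(s, params) < residual_tol) {
      return(steady_state(s, params, provenance = "relaxation",
                          extra = list(state0 = .as_state(state0, params), t = t)))
    }
  }
  list(converged = FALSE, state = s, residual = rhs_residual(s, params), t = t)
}

#' Perturb an equilibrium and relax back
#'
#' Applies an additive offset to a steady state (clipped to the nonnegative
#' orthant and to the carrying capacity), relaxes the perturbed state, and
#' reports whether the endpoint is the original equilibrium or a different
#' one.
#'
#' @param steady a [steady_state()] object with small residual.
#' @param delta named or positional numeric offset (components missing from
#'   the model layout are ignored).
#' @param params validated `emtmac_params`.
#' @param residual_tol relaxation tolerance, per hour.
#' @param match_tol max-norm tolerance under which two equilibria are
#'   considered identical (default 1e-6).
#' @param t_max passed to [run_to_steady()].
#' @return a list with `outcome` (`"returned_to_same"`, `"reached_other"` or
#'   `"no_convergence"`), the endpoint `state`, and for `"reached_other"` the
#'   new [steady_state()] in `other`.
#' @export
perturb_and_relax <- function(steady, delta, params, residual_tol = 1e-10,
                              match_tol = 1e-6, t_max = 5e5) {
  s0 <- steady$state
  d <- rep(0, length(s0)); names(d) <- names(s0)
  if (is.null(names(delta))) {
    d[seq_along(delta)] <- delta
  } else {
    keep <- intersect(names(delta), names(d))
    d[keep] <- delta[keep]
  }
  s <- pmax(s0 + d, 0)
  pops <- setdiff(names(s), "C")
  tot <- sum(s[pops])
  if (tot > params$N_max) s[pops] <- s[pops] * params$N_max / tot
  out <- run_to_steady(params, s, residual_tol = residual_tol, t_max = t_max)
  if (is.list(out) && isFALSE(out$converged)) {
    return(list(outcome = "no_convergence", state = out$state))
  }
  if (max(abs(out$state - s0)) < match_tol) {
    list(outcome = "returned_to_same", state = out$state)
  } else {
    list(outcome = "reached_other", state = out$state, other = out)
  }
}
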