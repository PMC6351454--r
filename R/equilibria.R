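#' Define an equilibrium-finding problem
#'
#' Bundles a parameter set with the conserved total macrophage fraction
#' `M_c = M0 + M1 + M2`, which is fixed by the initial condition and selects
#' the invariant manifold on which equilibria are sought, plus optional seed
#' states for the multi-start solver.
#'
#' @param params validated `emtmac_params`.
#' @param M_c total macrophage fraction, in `[0, N_max]`.
#' @param seeds optional list of seed state vectors; defaults to
#'   [default_seed_states()].
#' @param intermediate_frac equilibria with `E + M` below this fraction of
#'   the maximum cancer load `N_max - M_c` are categorized as low-cancer
#'   intermediate states (default 0.35).
#' @return an `emtmac_problem` list.
#' @export
equilibrium_problem <- function(params, M_c, seeds = NULL,
                                intermediate_frac = 0.35) {
  validate_parameters(params)
  if (M_c < 0 || M_c > params$N_max) stop("'M_c' must lie in [0, N_max]")
  structure(list(params = params, M_c = M_c, seeds = seeds,
                 intermediate_frac = intermediate_frac),
            class = "emtmac_problem")
}

#' Category of an equilibrium state
#'
#' Equilibria fall into four categories: `extinction` (`E + M` below 1e-6),
#' `low_cancer_intermediate` (total cancer below `intermediate_frac` of the
#' maximum cancer load), and otherwise `state_I_epithelial_dominated`
#' (`E >= M`) or `state_II_mesenchymal_dominated` (`M > E`).  Exact ties
#' `E == M` are labelled state I by convention and flagged with the
#' `"tie"` attribute.
#'
#' @param state state vector.
#' @param problem an `emtmac_problem`.
#' @return category string, possibly with attribute `tie = TRUE`.
#' @export
classify_category <- function(state, problem) {
  E <- state[["E"]]; M <- state[["M"]]
  cancer <- E + M
  cap <- problem$params$N_max - problem$M_c
  if (cancer < 1e-6) return("extinction")
  if (cancer < problem$intermediate_frac * cap) return("low_cancer_intermediate")
  if (E == M) return(structure("state_I_epithelial_dominated", tie = TRUE))
  if (E > M) "state_I_epithelial_dominated" else "state_II_mesenchymal_dominated"
}

#' Construct a steady-state object
#'
#' Attaches the residual, Jacobian spectrum, stability verdict and category
#' to an equilibrium point.
#'
#' @param state equilibrium state vector.
#' @param params validated `emtmac_params`.
#' @param problem optional `emtmac_problem` (for categorization; derived from
#'   the state's macrophage total if omitted).
#' @param provenance free-form record of which seed or branch produced the
#'   point.
#' @param zero_tol neutral-direction threshold passed to
#'   [classify_stability()].
#' @param extra optional named list merged into the result.
#' @return an `emtmac_steady` list with fields `state`, `residual`,
#'   `eigenvalues`, `spectrum`, `stability`, `category`, `provenance`.
#' @export
steady_state <- function(state, params, problem = NULL, provenance = NA_character_,
                         zero_tol = 1e-7, extra = list()) {
  s <- .as_state(state, params)
  if (is.null(problem)) {
    problem <- equilibrium_problem(params, M_c = min(macrophage_total(s), params$N_max))
  }
  spec <- classify_stability(s, params, zero_tol = zero_tol)
  ## variant I equilibria are classified transverse to their continuum (the
  ## neutral direction is discarded by the spectrum report)
  stability <- spec$classification
  out <- c(list(state = s, residual = rhs_residual(s, params),
                eigenvalues = spec$eigenvalues, spectrum = spec,
                stability = stability,
                category = classify_category(s, problem),
                provenance = provenance),
           extra)
  class(out) <- "emtmac_steady"
  out
}

#' @export
print.emtmac_steady <- function(x, ...) {
  cat("<emtmac_steady>", x$category, "(", x$stability, ")\n")
  print(round(x$state, 6))
  cat("residual:", format(x$residual, digits = 3),
      " max Re(lambda):", format(x$spectrum$max_real_part, digits = 4), "\n")
  invisible(x)
}

#' Closed-form cancer-extinction state
#'
#' With no cancer cells the apoptotic factor decays away and all M2
#' macrophages are converted back to M1 by the constant therapeutic term, so
#' the extinction state is `E = M = C = M0 = M2 = 0`, `M1 = M_c`.  Its
#' right-hand side vanishes exactly.
#'
#' @param problem an `emtmac_problem` (variant II or III; also valid for a
#'   variant I problem, where it sits on the continuum boundary).
#' @return a [steady_state()] with provenance `"closed_form_extinction"`.
#' @export
extinction_state <- function(problem) {
  params <- problem$params
  s <- population_state(E = 0, M = 0, M1 = problem$M_c, M2 = 0, M0 = 0, C = 0)
  steady_state(.as_state(s, params), params, problem,
               provenance = "closed_form_extinction")
}

## ---- Newton solver on the conservation-constrained system ----------------

## Residual with the (redundant) monocyte row replaced by the conservation
## constraint M1 + M2 + M0 = M_c, making the Jacobian nonsingular.
## Operates on unnamed vectors in canonical order (M1 = 3, M2 = 4, M0 = 5).
.constrained_residual <- function(s, params, M_c) {
  r <- .rhs_raw(s, params)
  r[5L] <- s[5L] - (M_c - s[3L] - s[4L])
  r
}

## Damped (line-searched) Newton iteration from one seed.
.newton_equilibrium <- function(seed, params, M_c, tol = 1e-12, maxit = 100L) {
  nm <- state_names(params)
  s <- unname(.as_state(seed, params))
  resf <- function(x) .constrained_residual(x, params, M_c)
  done <- function(s, conv, it) {
    names(s) <- nm
    list(state = s, converged = conv, iter = it)
  }
  for (it in seq_len(maxit)) {
    r <- resf(s)
    if (max(abs(r)) < tol) return(done(s, TRUE, it))
    J <- fd_jacobian(resf, s, step = 1e-7, nonneg = FALSE)
    d <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(d) || any(!is.finite(d))) return(done(s, FALSE, it))
    damp <- 1
    repeat {
      s_new <- s + damp * d
      if (max(abs(resf(s_new))) < max(abs(r)) || damp < 1e-6) break
      damp <- damp / 2
    }
    s <- s_new
  }
  done(s, max(abs(resf(s))) < 1e-9, maxit)
}

#' Default seed grid for the multi-start equilibrium solver
#'
#' Lattice of cancer loads `E, M` over fractions of the maximum cancer load
#' `N_max - M_c` (coarse quarters plus two low-cancer fractions, since
#' low-cancer equilibria can be narrow), M1 at 0, half and all of `M_c`,
#' monocytes at zero (equilibria with cancer present require `M0 = 0`), and
#' the apoptotic factor at its quasi-steady value
#' `C = beta * E * (M1/(M1+K_2)) / beta_c`, which is slaved to `E` and `M1`.
#'
#' @param problem an `emtmac_problem`.
#' @return list of seed state vectors.
#' @export
default_seed_states <- function(problem) {
  params <- problem$params
  cap <- params$N_max - problem$M_c
  fr <- c(0, 1/32, 1/8, 1/4, 1/2, 3/4, 1)
  m1f <- c(0, 1/2, 1)
  seeds <- list()
  for (fe in fr) for (fm in fr) {
    if (fe + fm > 1 + 1e-12) next
    E <- fe * cap; M <- fm * cap
    for (f1 in m1f) {
      M1 <- f1 * problem$M_c
      C <- if (params$variant == "III" && params$beta_c > 0) {
        params$beta * E * (M1 / (M1 + params$K_2)) / params$beta_c
      } else 0
      seeds[[length(seeds) + 1L]] <-
        .as_state(population_state(E = E, M = M, M1 = M1,
                                   M2 = problem$M_c - M1, M0 = 0, C = C),
                  params)
    }
  }
  seeds
}

#' Find all equilibria of a model by multi-start root finding
#'
#' Runs a damped Newton iteration on the right-hand side (augmented with the
#' macrophage conservation constraint) from every seed state, discards
#' non-convergent and negative solutions, deduplicates equilibria closer than
#' `dedup_tol` in max norm, verifies residuals and classifies each point.
#' The returned list is deterministic given the seeds (sorted by total
#' cancer load, then by `E`).
#'
#' For variant I the equilibria form a continuum; the problem is delegated to
#' [model1_branch()] on a uniform grid of M2 values (201 points by default).
#'
#' @param problem an `emtmac_problem`.
#' @param dedup_tol max-norm tolerance for identifying duplicates.
#' @param residual_tol acceptance threshold on max |rhs|.
#' @param m2_grid_n grid size for the variant I continuum.
#' @return list of [steady_state()] objects; if no seed converged, an empty
#'   list with attribute `"diagnostics"`.
#' @export
find_equilibria <- function(problem, dedup_tol = 1e-6, residual_tol = 1e-9,
                            m2_grid_n = 201L) {
  params <- problem$params
  if (params$variant == "I") {
    m2s <- seq(0, problem$M_c, length.out = m2_grid_n)
    return(do.call(c, lapply(m2s, function(v) model1_branch(v, problem))))
  }
  seeds <- problem$seeds
  if (is.null(seeds)) seeds <- default_seed_states(problem)
  found <- list()
  fails <- 0L
  for (i in seq_along(seeds)) {
    res <- .newton_equilibrium(seeds[[i]], params, problem$M_c)
    if (!res$converged) { fails <- fails + 1L; next }
    s <- res$state
    if (any(s < -1e-8)) next        # left the feasible orthant
    s[s < 0] <- 0                   # clip round-off undershoot
    if (rhs_residual(s, params) > residual_tol) next
    dup <- any(vapply(found, function(f) max(abs(f$state - s)) < dedup_tol,
                      logical(1)))
    if (!dup) {
      found[[length(found) + 1L]] <-
        steady_state(s, params, problem, provenance = paste0("seed_", i))
    }
  }
  if (!length(found)) {
    attr(found, "diagnostics") <- list(n_seeds = length(seeds), n_failed = fails)
    return(found)
  }
  ord <- order(vapply(found, function(f) f$state[["E"]] + f$state[["M"]], numeric(1)),
               vapply(found, function(f) f$state[["E"]], numeric(1)))
  found[ord]
}

#' Semi-analytic equilibrium branch of the polarization-only model
#'
#' In variant I the macrophage populations are frozen at steady state
#' (`M0 = 0`, `M1 + M2 = M_c` with M2 a free branch parameter) and the
#' cancer compartments saturate the remaining capacity
#' (`E + M = N_max - M_c`), so equilibria are the roots in `E` of the
#' MET/EMT flux balance on that segment.  Roots are located by a sign scan
#' over a uniform `E` grid refined with [stats::uniroot()], plus the exact
#' boundary roots at `E = 0` and `E = N_max - M_c`.
#'
#' Along the branch the reduced dynamics are gradient-like
#' (`dE/dt = met - emt`), so a root is branch-stable when the flux balance
#' changes sign from positive to negative; this is recorded as
#' `branch_stable` alongside the full Jacobian classification.
#'
#' @param M2_value M2 macrophage fraction, in `[0, M_c]`.
#' @param problem an `emtmac_problem` with a variant I parameter set.
#' @param grid_n sign-scan grid resolution (default 4001).
#' @return list of [steady_state()] objects, each with `branch_stable` and
#'   `M2_value` fields.
#' @export
model1_branch <- function(M2_value, problem, grid_n = 4001L) {
  params <- problem$params
  if (params$variant != "I") stop("model1_branch() requires a variant I parameter set")
  if (M2_value < 0 || M2_value > problem$M_c) {
    stop("'M2_value' must lie in [0, M_c]")
  }
  cap <- params$N_max - problem$M_c
  M1 <- problem$M_c - M2_value
  balance <- function(E) {
    st <- population_state(E = E, M = cap - E, M1 = M1, M2 = M2_value, M0 = 0)
    fl <- conversion_fluxes(st, params)
    fl[["met"]] - fl[["emt"]]
  }
  Es <- seq(0, cap, length.out = grid_n)
  g <- vapply(Es, balance, numeric(1))
  roots <- numeric(0)
  ## exact boundary zeros (one flux switched off entirely)
  if (abs(g[1]) < 1e-15) roots <- c(roots, 0)
  if (abs(g[grid_n]) < 1e-15) roots <- c(roots, cap)
  for (i in seq_len(grid_n - 1L)) {
    if (g[i] == 0 && Es[i] > 0 && Es[i] < cap) { roots <- c(roots, Es[i]); next }
    if (g[i] * g[i + 1L] < 0) {
      r <- stats::uniroot(balance, c(Es[i], Es[i + 1L]), tol = 1e-13)
      roots <- c(roots, r$root)
    }
  }
  roots <- sort(unique(roots))
  lapply(roots, function(E) {
    st <- population_state(E = E, M = cap - E, M1 = M1, M2 = M2_value, M0 = 0)
    eps <- cap * 1e-7
    left <- if (E - eps >= 0) balance(E - eps) else NA_real_
    right <- if (E + eps <= cap) balance(E + eps) else NA_real_
    branch_stable <- isTRUE(left > 0 || is.na(left)) && isTRUE(right < 0 || is.na(right))
    steady_state(.as_state(st, params), params, problem,
                 provenance = sprintf("branch_M2_%.6g", M2_value),
                 extra = list(branch_stable = branch_stable, M2_value = M2_value))
  })
}
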