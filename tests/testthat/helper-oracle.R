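## Symbolic oracle for the model right-hand sides: the equations are written
## out as R expressions and differentiated with stats::D(), giving a
## derivative path fully independent of the package's finite-difference
## Jacobians.  Valid at interior states (all populations > 0).

oracle_expressions <- function(variant) {
  shared <- list(
    E = quote(lambda_E * E * (1 - (E + M + M1 + M2 + M0) / N_max) /
                (1 + alpha * M1 / (M1 + K_1)) +
              eta_me * M * M1^n / (M1^n + M / (M + K_M0)) -
              eta_em * E * M2^m / (M2^m + E^k / (E^k + K_E0^k))),
    M = quote(lambda_M * M * (1 - (E + M + M1 + M2 + M0) / N_max) -
              eta_me * M * M1^n / (M1^n + M / (M + K_M0)) +
              eta_em * E * M2^m / (M2^m + E^k / (E^k + K_E0^k)))
  )
  if (variant == "III") {
    list(
      E = substitute(base - beta * E * M1 / (M1 + K_2), list(base = shared$E)),
      M = shared$M,
      M1 = quote(eta_1 * E / (E + K_E) * M0 - eta_12 * C / (C + K_C) * M1 +
                   eta_21 * M2),
      M2 = quote(eta_2 * M / (M + K_M) * M0 + eta_12 * C / (C + K_C) * M1 -
                   eta_21 * M2),
      M0 = quote(-eta_1 * E / (E + K_E) * M0 - eta_2 * M / (M + K_M) * M0),
      C = quote(beta * E * M1 / (M1 + K_2) - beta_c * C)
    )
  } else {
    c(shared, list(
      M1 = quote(eta_1 * E / (E + K_E) * M0 -
                   (eta_120 + eta_12 * M / (M + K_M)) * M1 +
                   (eta_210 + eta_21 * E / (E + K_E)) * M2),
      M2 = quote(eta_2 * M / (M + K_M) * M0 +
                   (eta_120 + eta_12 * M / (M + K_M)) * M1 -
                   (eta_210 + eta_21 * E / (E + K_E)) * M2),
      M0 = quote(-eta_1 * E / (E + K_E) * M0 - eta_2 * M / (M + K_M) * M0)
    ))
  }
}

oracle_env <- function(state, params) {
  e <- as.environment(c(as.list(state),
                        params[model_parameter_names()]))
  parent.env(e) <- baseenv()
  e
}

oracle_rhs <- function(state, params) {
  ex <- oracle_expressions(params$variant)
  env <- oracle_env(state, params)
  vapply(ex, eval, numeric(1), envir = env)
}

oracle_jacobian <- function(state, params) {
  ex <- oracle_expressions(params$variant)
  vars <- names(ex)
  env <- oracle_env(state, params)
  J <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (i in seq_along(ex)) {
    for (j in seq_along(vars)) {
      J[i, j] <- eval(stats::D(ex[[i]], vars[j]), envir = env)
    }
  }
  J
}

## random strictly interior states respecting the capacity constraint
random_interior_state <- function(params, M_c = NULL) {
  repeat {
    x <- stats::runif(5, 0.02, 0.4)
    if (!is.null(M_c)) {
      w <- stats::runif(3, 0.05, 1); w <- w / sum(w) * M_c
      x[3:5] <- w
    }
    if (sum(x) < params$N_max * 0.98) break
  }
  population_state(E = x[1], M = x[2], M1 = x[3], M2 = x[4], M0 = x[5],
                   C = if (params$variant == "III") stats::runif(1, 0.01, 0.5) else 0)
}
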