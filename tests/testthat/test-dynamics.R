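test_that("the zero state stays exactly at zero", {
  p <- model_parameters("III")
  tr <- integrate_model(p, population_state(), t_end = 1000, n_out = 11)
  expect_true(all(as.matrix(tr[state_names(p)]) == 0))
})

test_that("isolated epithelial growth follows the logistic closed form", {
  p <- model_parameters("I", eta_me = 0, eta_em = 0)
  E0 <- 0.01
  tr <- integrate_model(p, population_state(E = E0), t_end = 600, n_out = 61)
  expected <- p$N_max * E0 * exp(p$lambda_E * tr$t) /
    (p$N_max + E0 * (exp(p$lambda_E * tr$t) - 1))
  expect_equal(tr$E, expected, tolerance = 1e-6)
})

test_that("macrophage totals are conserved along long stiff trajectories", {
  p <- model3_reference_params()
  s0 <- population_state(E = 0.2, M = 0.3, M1 = 0.1, M2 = 0.05, M0 = 0.15,
                         C = 0.02)
  tr <- integrate_model(p, s0, t_end = 5000, n_out = 51)
  tot <- tr$M1 + tr$M2 + tr$M0
  expect_lt(max(abs(tot - 0.3)), 1e-8 * 0.3)
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(as.matrix(tr[state_names(p)]) >= 0))
})

test_that("run_to_steady returns an equilibrium unchanged and honors its tolerance", {
  pr <- ref3_problem()
  ext <- extinction_state(pr)
  out <- run_to_steady(pr$params, ext$state, residual_tol = 1e-10)
  expect_s3_class(out, "emtmac_steady")
  expect_identical(unname(out$state), unname(ext$state))
  ## round-trip: the endpoint's residual is below the requested tolerance
  eq <- run_to_steady(pr$params, population_state(E = 0.1, M = 0.4, M1 = 0.15,
                                                  M2 = 0.1, M0 = 0.05))
  expect_s3_class(eq, "emtmac_steady")
  expect_lt(rhs_residual(eq$state, pr$params), 1e-10)
})

test_that("far above the extinction threshold every cancer-bearing start is eliminated", {
  p <- update_parameters(model3_reference_params(), eta_me = 0.20)
  ics <- sample_initial_conditions(3, M_c = 0.3, seed = 402)
  for (s0 in ics) {
    out <- run_to_steady(p, s0, residual_tol = 1e-10)
    expect_s3_class(out, "emtmac_steady")
    expect_lt(out$state[["E"]] + out$state[["M"]], 1e-6)
  }
})

test_that("the bistable window endpoints are reached from matching initial conditions", {
  pr <- model2_problem(eta_me = 0.015)
  eqs <- stable_cancer_states(find_equilibria(pr))
  expect_gte(length(eqs), 2)
  Es <- vapply(eqs, function(e) e$state[["E"]], numeric(1))
  hi <- eqs[[which.max(Es)]]; lo <- eqs[[which.min(Es)]]
  ## epithelial-dominated start -> epithelial-rich equilibrium
  s_hi <- run_to_steady(pr$params, population_state(E = 0.6, M = 0.05,
                                                    M1 = 0.25, M2 = 0.02, M0 = 0.03))
  expect_lt(max(abs(s_hi$state - hi$state)), 1e-6)
  s_lo <- run_to_steady(pr$params, population_state(E = 0.02, M = 0.65,
                                                    M1 = 0.02, M2 = 0.25, M0 = 0.03))
  expect_lt(max(abs(s_lo$state - lo$state)), 1e-6)
})

test_that("a tiny interconversion rate collapses the continuum to one steady state", {
  ## adding eps M1<->M2 exchange to the polarization-only network makes the
  ## continuum of equilibria collapse onto a single point
  p <- model_parameters("II", eta_120 = 1e-4, eta_210 = 1e-4, eta_12 = 0,
                        eta_21 = 0)
  ics <- sample_initial_conditions(10, M_c = 0.3, cancer_total_range = c(0.3, 0.7),
                                   seed = 77)
  ends <- lapply(ics, function(s0) {
    out <- run_to_steady(p, s0, residual_tol = 1e-11, t_max = 4e6, chunk = 2e5)
    expect_s3_class(out, "emtmac_steady")
    out$state
  })
  ref <- ends[[1]]
  for (e in ends[-1]) expect_lt(max(abs(e - ref)), 1e-4)
})

test_that("perturbations distinguish the cancer and macrophage directions", {
  p <- model_parameters("I", m = 2, n = 2)
  pr <- equilibrium_problem(p, M_c = 0.3)
  roots <- model1_branch(0.12, pr)
  st <- Filter(function(r) isTRUE(r$branch_stable) &&
                 r$state[["E"]] > 0 && r$state[["M"]] > 0, roots)
  skip_if(length(st) == 0, "no interior stable root at this M2")
  eq <- st[[1]]
  ## zero perturbation is a fixed point of the procedure
  out0 <- perturb_and_relax(eq, c(E = 0, M = 0), p)
  expect_identical(out0$outcome, "returned_to_same")
  ## cancer-only perturbation (E+M preserved) relaxes back to the same point
  d <- min(0.05, eq$state[["E"]] / 2, eq$state[["M"]] / 2)
  out1 <- perturb_and_relax(eq, c(E = -d, M = d), p, match_tol = 1e-5)
  expect_identical(out1$outcome, "returned_to_same")
  ## a macrophage swap moves the system to a different point on the continuum
  out2 <- perturb_and_relax(eq, c(M1 = -0.08, M2 = 0.08), p, match_tol = 1e-5)
  expect_identical(out2$outcome, "reached_other")
  expect_lt(out2$other$residual, 1e-9)
})
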