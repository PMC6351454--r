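test_that("branch endpoints are forced by fully polarized macrophage pools", {
  p <- model_parameters("I", m = 2, n = 2)
  pr <- equilibrium_problem(p, M_c = 0.3)
  cap <- p$N_max - 0.3
  ## all macrophages M1: EMT is off, so the epithelial endpoint is a root
  r0 <- model1_branch(0, pr)
  expect_true(any(vapply(r0, function(r) abs(r$state[["E"]] - cap) < 1e-12,
                         logical(1))))
  ## all macrophages M2: MET is off, so the mesenchymal endpoint is a root
  r1 <- model1_branch(0.3, pr)
  expect_true(any(vapply(r1, function(r) r$state[["E"]] == 0, logical(1))))
  expect_error(model1_branch(0.31, pr), "M2_value")
})

test_that("branch roots match a brute-force fine-grid residual scan", {
  p <- model_parameters("I", m = 1, n = 1, k = 4)
  pr <- equilibrium_problem(p, M_c = 0.3)
  cap <- 0.7
  for (m2 in c(0.08, 0.13, 0.21)) {
    M1 <- 0.3 - m2
    balance <- function(E) {
      fl <- conversion_fluxes(population_state(E = E, M = cap - E, M1 = M1,
                                               M2 = m2, M0 = 0), p)
      fl[["met"]] - fl[["emt"]]
    }
    ## independent oracle: sign scan over a 1e-5-spaced grid + bisection
    Es <- seq(0, cap, by = 1e-5)
    g <- vapply(Es, balance, numeric(1))
    brute <- Es[abs(g) < 1e-18]
    ix <- which(g[-1] * g[-length(g)] < 0)
    for (i in ix) {
      lo <- Es[i]; hi <- Es[i + 1]
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (sign(balance(mid)) == sign(balance(lo))) lo <- mid else hi <- mid
      }
      brute <- c(brute, (lo + hi) / 2)
    }
    brute <- sort(brute)
    got <- sort(vapply(model1_branch(m2, pr), function(r) r$state[["E"]],
                       numeric(1)))
    expect_equal(length(got), length(brute))
    expect_lt(max(abs(got - brute)), 1e-8)
  }
})

test_that("branch-stability flags agree with the Jacobian classification", {
  p <- model_parameters("I", m = 2, n = 2)
  pr <- equilibrium_problem(p, M_c = 0.3)
  checked <- 0
  for (m2 in c(0.05, 0.11, 0.16, 0.22, 0.28)) {
    for (r in model1_branch(m2, pr)) {
      if (r$state[["E"]] < 1e-9 || r$state[["M"]] < 1e-9) next  # boundary roots
      expect_identical(isTRUE(r$branch_stable), r$stability == "stable")
      checked <- checked + 1
    }
  }
  expect_gte(checked, 5)
})

test_that("the closed-form extinction state has an exactly vanishing residual", {
  pr <- ref3_problem()
  ext <- extinction_state(pr)
  expect_identical(ext$residual, 0)
  expect_identical(unname(ext$state),
                   c(0, 0, 0.3, 0, 0, 0))
  ext0 <- extinction_state(equilibrium_problem(pr$params, M_c = 0))
  expect_identical(unname(ext0$state), rep(0, 6))
  expect_identical(ext0$residual, 0)
})

test_that("extinction stability flips across the computed critical MET rate", {
  ## the extinction state's leading eigenvalue along the mesenchymal
  ## direction is lambda_M (1 - M_c) - eta_me, so stability flips at
  ## eta_me = lambda_M (1 - M_c)
  pr <- ref3_problem()
  thr <- pr$params$lambda_M * (1 - 0.3)
  below <- extinction_state(.set <- equilibrium_problem(
    update_parameters(pr$params, eta_me = thr * 0.8), M_c = 0.3))
  above <- extinction_state(equilibrium_problem(
    update_parameters(pr$params, eta_me = thr * 1.2), M_c = 0.3))
  expect_identical(below$stability, "unstable")
  expect_identical(above$stability, "stable")
  expect_equal(below$spectrum$max_real_part, thr - thr * 0.8, tolerance = 1e-4)
})

test_that("multi-start search is idempotent on a list of exact equilibria", {
  pr <- model2_problem(eta_me = 0.015)
  eqs <- find_equilibria(pr)
  expect_gte(length(eqs), 3)
  pr2 <- pr
  pr2$seeds <- lapply(eqs, `[[`, "state")
  eqs2 <- find_equilibria(pr2)
  expect_equal(length(eqs2), length(eqs))
  for (i in seq_along(eqs)) {
    expect_lt(max(abs(eqs2[[i]]$state - eqs[[i]]$state)), 1e-9)
  }
})

test_that("cancer-bearing equilibria saturate the carrying capacity with no monocytes", {
  ## variants without cell death: logistic saturation forces E + M to fill
  ## the capacity left by the macrophages, and polarization empties M0
  pr <- model2_problem(eta_me = 0.015)
  for (e in stable_cancer_states(find_equilibria(pr))) {
    expect_lt(e$state[["M0"]], 1e-8)
    expect_lt(abs(e$state[["E"]] + e$state[["M"]] - 0.7), 1e-6)
  }
  p1 <- model_parameters("I", m = 2, n = 2)
  pr1 <- equilibrium_problem(p1, M_c = 0.3)
  for (r in model1_branch(0.13, pr1)) {
    expect_identical(r$state[["M0"]], 0)
    expect_lt(abs(r$state[["E"]] + r$state[["M"]] - 0.7), 1e-9)
  }
})

test_that("root finding and relaxation agree on the stable equilibria", {
  pr <- model2_problem(eta_me = 0.012)
  eqs <- find_equilibria(pr)
  stable <- Filter(function(e) e$stability == "stable", eqs)
  expect_gte(length(stable), 2)
  ## every stable root is reached by relaxation from a nearby state
  for (e in stable) {
    s0 <- pmax(e$state + c(0.005, -0.005, 0.002, -0.002, 0), 0)
    out <- run_to_steady(pr$params, s0, residual_tol = 1e-10)
    expect_s3_class(out, "emtmac_steady")
    expect_lt(max(abs(out$state - e$state)), 1e-6)
  }
  ## and relaxation from random states only lands on found stable equilibria
  ics <- sample_initial_conditions(8, M_c = 0.3, seed = 19)
  for (s0 in ics) {
    out <- run_to_steady(pr$params, s0, residual_tol = 1e-10)
    expect_s3_class(out, "emtmac_steady")
    d <- vapply(stable, function(e) max(abs(out$state - e$state)), numeric(1))
    expect_lt(min(d), 1e-5)
  }
})
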