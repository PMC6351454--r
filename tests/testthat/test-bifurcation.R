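test_that("bisection solves a synthetic linear event", {
  pr <- ref3_problem()
  cv <- critical_value(pr, "eta_me", function(p) p - 0.5, c(0, 1), tol = 1e-6)
  expect_equal(as.numeric(cv), 0.5, tolerance = 1e-5)
  expect_error(critical_value(pr, "eta_me", function(p) p + 2, c(0, 1)),
               "no sign change")
})

test_that("a single-point sweep yields a single-column diagram", {
  pr <- model2_problem(eta_me = 0.015)
  bd <- sweep_parameter(pr, "eta_me", 0.015)
  expect_true(all(bd$points$param == 0.015))
  expect_identical(anyDuplicated(bd$points$branch), 0L)
  expect_error(sweep_parameter(pr, "eta_me", numeric(0)), "non-empty")
})

test_that("sweeps stitch branches and expose the bistable window", {
  pr <- model2_problem()
  grid <- seq(0.008, 0.03, by = 0.002)
  bd <- sweep_parameter(pr, "eta_me", grid)
  pts <- bd$points[bd$points$stability == "stable" & bd$points$E + bd$points$M > 1e-6, ]
  n_stable <- table(pts$param)
  expect_gte(max(n_stable), 2)  # bistable somewhere in the window
  ## branches are continuous: consecutive points on a branch stay close
  for (b in unique(pts$branch)) {
    sub <- pts[pts$branch == b, ]
    if (nrow(sub) > 1) {
      expect_lt(max(abs(diff(sub$E))), 0.15)
    }
  }
})

test_that("overlap region trends of the polarization-only model", {
  width <- function(Mc, m, n, k) {
    p <- model_parameters("I", m = m, n = n, k = k)
    ov <- model1_overlap_region(equilibrium_problem(p, M_c = Mc),
                                m2_grid_n = 61)
    ov$overlap_width
  }
  w4 <- width(0.3, 1, 1, 4); w3 <- width(0.3, 1, 1, 3); w2 <- width(0.3, 1, 1, 2)
  expect_gt(w4, 0)
  expect_lte(w3, w4)
  expect_identical(w2, 0)              # cooperativity loss removes bistability
  expect_gt(width(0.3, 2, 2, 4), w4)   # stronger conversion cooperativity widens it
  expect_identical(width(0.6, 1, 1, 4), 0)  # high macrophage load removes it
})

test_that("threshold-versus-parameter curves handle single values and failures", {
  pr <- ref3_problem()
  out <- eta_c_vs_parameter(pr, "lambda_M", 1 / 72, bracket = c(0.01, 0.12),
                            tol = 5e-4)
  expect_identical(nrow(out), 1L)
  expect_false(is.na(out$threshold))
  ## an impossible bracket is flagged, not fatal
  bad <- eta_c_vs_parameter(pr, "lambda_M", 1 / 72, bracket = c(0.2, 0.3),
                            tol = 5e-4)
  expect_true(is.na(bad$threshold))
  expect_match(bad$note, "bracket")
})

test_that("equilibrium structure is consistent on both sides of the extinction threshold", {
  pr <- ref3_problem()
  thr <- critical_value(pr, "eta_me", "sole_extinction_threshold",
                        c(0.05, 0.15), tol = 5e-4)
  above <- find_equilibria(equilibrium_problem(
    update_parameters(pr$params, eta_me = as.numeric(thr) + 0.01), M_c = 0.3))
  stab_above <- Filter(function(e) e$stability == "stable", above)
  expect_gte(length(stab_above), 1)
  expect_true(all(vapply(stab_above, function(e)
    e$state[["E"]] + e$state[["M"]] < 1e-6, logical(1))))
  below <- find_equilibria(equilibrium_problem(
    update_parameters(pr$params, eta_me = as.numeric(thr) - 0.01), M_c = 0.3))
  expect_gte(length(stable_cancer_states(below)), 1)
})

test_that("cancer-enhanced interconversion widens the epithelial-low region", {
  ## upper end of the mesenchymal-dominated (epithelial-low) stable branch,
  ## tracked by continuation from a common starting rate
  upper_end <- function(pr) {
    eqs <- stable_cancer_states(find_equilibria(pr))
    low <- eqs[[which.min(vapply(eqs, function(e) e$state[["E"]], numeric(1)))]]
    wk <- walk_branch(pr, "eta_me", pr$params$eta_me, low$state, step = 5e-4,
                      v_max = 0.2)
    max(wk$param)
  }
  end_const <- upper_end(model2_problem(eta_me = 0.01, eta_12 = 0, eta_21 = 0))
  end_enh <- upper_end(model2_problem(eta_me = 0.01))
  expect_gt(end_enh, end_const)
})

test_that("a faster M2-to-M1 conversion lowers the onset of bistability", {
  ## lower end of the epithelial-rich stable branch, tracked downwards
  lower_end <- function(pr) {
    eqs <- stable_cancer_states(find_equilibria(pr))
    hi <- eqs[[which.max(vapply(eqs, function(e) e$state[["E"]], numeric(1)))]]
    wk <- walk_branch(pr, "eta_me", pr$params$eta_me, hi$state, step = -5e-4,
                      v_min = 1e-4)
    min(wk$param)
  }
  end_ref <- lower_end(model2_problem(eta_me = 0.02))
  end_fast <- lower_end(model2_problem(eta_me = 0.02, eta_21 = 1 / 36))
  expect_lt(end_fast, end_ref)
})
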