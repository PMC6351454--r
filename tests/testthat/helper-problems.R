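## Shared problem configurations used across test files.

ref3_problem <- function(...) {
  equilibrium_problem(model3_reference_params(...), M_c = 0.3)
}

model2_problem <- function(eta_me = 1/120, eta_12 = 1/72, eta_21 = 1/72, ...) {
  p <- model_parameters("II", m = 2, n = 2, k = 4, eta_me = eta_me,
                        eta_12 = eta_12, eta_21 = eta_21, ...)
  equilibrium_problem(p, M_c = 0.3)
}

stable_cancer_states <- function(eqs) {
  Filter(function(e) e$stability == "stable" &&
           (e$state[["E"]] + e$state[["M"]]) > 1e-6, eqs)
}
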