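## Parameter sweeps, branch tracking and critical-point location.

.set_param <- function(problem, name, value) {
  if (name == "M_c") {
    problem$M_c <- value
  } else {
    ov <- list(value); names(ov) <- name
    problem$params <- do.call(update_parameters, c(list(problem$params), ov))
  }
  problem
}

#' Sweep a parameter and assemble a bifurcation diagram
#'
#' At each grid value the equilibria are located by Newton continuation from
#' the previous grid point's equilibria, augmented with the standard seed
#' grid so branches appearing inside the sweep window are still discovered.
#' Equilibria at consecutive grid values are stitched into branches by
#' nearest-neighbour matching in state space.
#'
#' @param problem an `emtmac_problem` (variant II or III).
#' @param param_name parameter to sweep (a field of [model_parameters()], or
#'   `"M_c"`).
#' @param grid monotone numeric grid of parameter values.
#' @param match_tol max-norm distance bound for connecting consecutive branch
#'   points (default 0.15).
#' @return an `emtmac_bifurcation` list: `points` (a data frame with the
#'   parameter value, branch id, state columns, `stability`, `category`,
#'   `max_real_part`, `hopf_re`), `param_name`, `grid`, and `problem`.
#' @export
sweep_parameter <- function(problem, param_name, grid, match_tol = 0.15) {
  if (!length(grid)) stop("'grid' must be non-empty")
  if (is.unsorted(grid) && is.unsorted(rev(grid))) stop("'grid' must be monotone")
  prev <- list()
  branch_of_prev <- integer(0)
  next_branch <- 1L
  rows <- list()
  for (g in grid) {
    pr <- .set_param(problem, param_name, g)
    seeds <- c(lapply(prev, `[[`, "state"), default_seed_states(pr))
    pr$seeds <- seeds
    eqs <- find_equilibria(pr)
    ## nearest-neighbour stitching to the previous column
    branch_ids <- integer(length(eqs))
    used <- logical(length(prev))
    for (i in seq_along(eqs)) {
      if (length(prev)) {
        d <- vapply(prev, function(p) max(abs(p$state - eqs[[i]]$state)), numeric(1))
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] < match_tol) {
          branch_ids[i] <- branch_of_prev[j]
          used[j] <- TRUE
          next
        }
      }
      branch_ids[i] <- next_branch
      next_branch <- next_branch + 1L
    }
    for (i in seq_along(eqs)) {
      e <- eqs[[i]]
      hre <- suppressWarnings(hopf_indicator(e, pr$params))
      rows[[length(rows) + 1L]] <- data.frame(
        param = g, branch = branch_ids[i],
        as.list(e$state),
        stability = e$stability, category = e$category,
        max_real_part = e$spectrum$max_real_part,
        hopf_re = as.numeric(hre),
        stringsAsFactors = FALSE)
    }
    prev <- eqs
    branch_of_prev <- branch_ids
  }
  pts <- if (length(rows)) do.call(rbind, rows) else data.frame()
  structure(list(points = pts, param_name = param_name, grid = grid,
                 problem = problem),
            class = "emtmac_bifurcation")
}

## Continue a single tracked equilibrium to a new parameter value.
## Returns the refreshed steady state or NULL if continuation fails
## (Newton divergence, loss of feasibility, or a jump larger than jump_tol).
.continue_state <- function(problem, state, jump_tol = 0.1) {
  res <- .newton_equilibrium(state, problem$params, problem$M_c)
  if (!res$converged) return(NULL)
  s <- res$state
  if (any(s < -1e-8)) return(NULL)
  s[s < 0] <- 0
  if (max(abs(s - state)) > jump_tol) return(NULL)
  if (rhs_residual(s, problem$params) > 1e-9) return(NULL)
  steady_state(s, problem$params, problem, provenance = "continuation")
}

#' Locate a critical parameter value by bisection
#'
#' Refines the location of a qualitative change in the equilibrium structure
#' to a bracket of width at most `tol`.  Supported event types:
#' \describe{
#'   \item{`extinction_stabilization`}{sign change of the leading non-neutral
#'     eigenvalue real part of the closed-form extinction state.}
#'   \item{`fold`}{disappearance of a continuation-tracked branch
#'     (`track_state` gives a point on the branch at `bracket[1]`).}
#'   \item{`hopf`}{sign change of [hopf_indicator()] along a tracked branch
#'     (again starting from `track_state`).}
#'   \item{`sole_extinction_threshold`}{largest parameter value at which any
#'     stable equilibrium with `E + M > 1e-6` exists (multi-start search at
#'     every probe).}
#' }
#' Alternatively `event_type` may be a function of the parameter value
#' returning a signed indicator, whose root is then bisected (useful for
#' testing and for custom events).
#'
#' @param problem an `emtmac_problem`.
#' @param param_name swept parameter (field name or `"M_c"`).
#' @param event_type one of the strings above, or an indicator function.
#' @param bracket length-2 numeric; the event must occur inside.
#' @param tol final bracket width (default 1e-4, in the parameter's units).
#' @param track_state state vector on the tracked branch at `bracket[1]`
#'   (required for `fold` and `hopf`).
#' @return the bracket midpoint, with attributes `"bracket"` (final bracket)
#'   and `"event"`.
#' @export
critical_value <- function(problem, param_name, event_type, bracket,
                           tol = 1e-4, track_state = NULL) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  lo <- bracket[1]; hi <- bracket[2]

  if (is.function(event_type)) {
    f_lo <- event_type(lo); f_hi <- event_type(hi)
    if (sign(f_lo) == sign(f_hi)) {
      stop("no sign change in bracket: f(lo) = ", f_lo, ", f(hi) = ", f_hi)
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(event_type(mid)) == sign(f_lo)) lo <- mid else hi <- mid
    }
    return(structure((lo + hi) / 2, bracket = c(lo, hi), event = "custom"))
  }

  event_type <- match.arg(event_type,
    c("extinction_stabilization", "fold", "hopf", "sole_extinction_threshold"))

  if (event_type == "extinction_stabilization") {
    ind <- function(v) {
      pr <- .set_param(problem, param_name, v)
      extinction_state(pr)$spectrum$max_real_part
    }
    f_lo <- ind(lo); f_hi <- ind(hi)
    if (sign(f_lo) == sign(f_hi)) {
      stop("extinction state does not change stability in bracket (",
           f_lo, ", ", f_hi, ")")
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(ind(mid)) == sign(f_lo)) lo <- mid else hi <- mid
    }
    return(structure((lo + hi) / 2, bracket = c(lo, hi),
                     event = "extinction_stabilization"))
  }

  if (event_type == "sole_extinction_threshold") {
    exists_cancer <- function(v) {
      pr <- .set_param(problem, param_name, v)
      eqs <- find_equilibria(pr)
      any(vapply(eqs, function(e) {
        e$stability == "stable" && (e$state[["E"]] + e$state[["M"]]) > 1e-6
      }, logical(1)))
    }
    e_lo <- exists_cancer(lo); e_hi <- exists_cancer(hi)
    if (!e_lo || e_hi) {
      stop("bracket must contain the loss of the last stable cancer-bearing ",
           "state (exists at lo: ", e_lo, ", at hi: ", e_hi, ")")
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (exists_cancer(mid)) lo <- mid else hi <- mid
    }
    return(structure((lo + hi) / 2, bracket = c(lo, hi),
                     event = "sole_extinction_threshold"))
  }

  ## branch-tracked events: fold and hopf
  if (is.null(track_state)) {
    stop("'track_state' (a branch point at bracket[1]) is required for ",
         event_type, " events")
  }
  carry_state <- .as_state(track_state, problem$params)
  carry_v <- lo
  ## Walk the tracked branch from the carried point to a target parameter
  ## value in sub-steps, so within-branch drift stays below the jump bound
  ## and only a genuine branch loss (fold) makes the walk fail.
  walk_to <- function(v, n_sub = 8L) {
    st <- carry_state
    for (vv in seq(carry_v, v, length.out = n_sub + 1L)[-1L]) {
      res <- .continue_state(.set_param(problem, param_name, vv), st)
      if (is.null(res)) return(NULL)
      st <- res$state
    }
    steady_state(st, .set_param(problem, param_name, v)$params,
                 provenance = "continuation")
  }
  st_lo <- walk_to(lo)
  if (is.null(st_lo)) stop("tracked branch not found at bracket[1]")
  carry_state <- st_lo$state

  if (event_type == "fold") {
    if (!is.null(walk_to(hi))) {
      stop("tracked branch still exists at bracket[2]; no fold inside bracket")
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      st <- walk_to(mid)
      if (!is.null(st)) {
        lo <- mid; carry_state <- st$state; carry_v <- mid
      } else {
        hi <- mid
      }
    }
    return(structure((lo + hi) / 2, bracket = c(lo, hi), event = "fold"))
  }

  ## hopf
  h_of <- function(st, v) {
    pr <- .set_param(problem, param_name, v)
    as.numeric(suppressWarnings(hopf_indicator(st, pr$params)))
  }
  f_lo <- h_of(st_lo, lo)
  st_hi <- walk_to(hi)
  if (is.null(st_hi)) stop("tracked branch lost before bracket[2]; shrink the bracket")
  f_hi <- h_of(st_hi, hi)
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi)) {
    stop("Hopf indicator does not change sign in bracket (", f_lo, ", ", f_hi, ")")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    st <- walk_to(mid)
    if (is.null(st)) stop("tracked branch lost during Hopf bisection at ", mid)
    f_mid <- h_of(st, mid)
    if (is.na(f_mid)) stop("complex pair vanished during Hopf bisection at ", mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; carry_state <- st$state; carry_v <- mid
    } else {
      hi <- mid
    }
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), event = "hopf")
}

#' Extinction threshold as a function of a second parameter
#'
#' For each value of a secondary parameter (for example the mesenchymal
#' growth rate `lambda_M`, the EMT rate `eta_em`, the M2-to-M1 conversion
#' rate `eta_21`, or the macrophage load `M_c`), computes the MET-rate
#' threshold above which cancer extinction is the only stable outcome.
#'
#' @param problem an `emtmac_problem`.
#' @param secondary_param_name parameter varied across the curve.
#' @param values numeric vector of secondary-parameter values.
#' @param bracket bracket for the threshold in the primary parameter.
#' @param param_name primary (threshold) parameter, default `"eta_me"`.
#' @param tol bisection tolerance.
#' @return data frame with columns `value` (secondary parameter),
#'   `threshold` (`NA` where the bracket failed) and `note`.
#' @export
eta_c_vs_parameter <- function(problem, secondary_param_name, values, bracket,
                               param_name = "eta_me", tol = 1e-4) {
  rows <- lapply(values, function(v) {
    pr <- .set_param(problem, secondary_param_name, v)
    th <- tryCatch(
      as.numeric(critical_value(pr, param_name, "sole_extinction_threshold",
                                bracket, tol = tol)),
      error = function(e) structure(NA_real_, msg = conditionMessage(e)))
    data.frame(value = v, threshold = as.numeric(th),
               note = if (is.na(th)) attr(th, "msg") else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map stable-state multiplicity over a two-parameter grid
#'
#' For every cell of the grid, counts the stable equilibria and the set of
#' categories they occupy.  For variant I (a continuum of equilibria) the
#' count refers to the branch-stable state categories reached across a sweep
#' of the M2 level, which is how multistability manifests in that model.
#'
#' @param problem an `emtmac_problem`.
#' @param param1,param2 parameter names (fields or `"M_c"`).
#' @param values1,values2 numeric grids.
#' @param m2_grid_n M2 sweep resolution for variant I cells.
#' @return data frame with columns `p1`, `p2`, `n_stable`, `categories`
#'   (comma-collapsed).
#' @export
multistability_map <- function(problem, param1, values1, param2, values2,
                               m2_grid_n = 101L) {
  rows <- list()
  for (v1 in values1) for (v2 in values2) {
    pr <- .set_param(.set_param(problem, param1, v1), param2, v2)
    if (pr$params$variant == "I") {
      ov <- model1_overlap_region(pr, m2_grid_n = m2_grid_n)
      cats <- ov$categories
      n_st <- ov$n_stable_categories
    } else {
      eqs <- find_equilibria(pr)
      st <- Filter(function(e) e$stability == "stable", eqs)
      cats <- unique(vapply(st, `[[`, character(1), "category"))
      n_st <- length(st)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      p1 = v1, p2 = v2, n_stable = n_st,
      categories = paste(sort(cats), collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Bistable overlap region of the polarization-only model
#'
#' Sweeps the M2 level across `[0, M_c]` and records the branch-stable roots
#' of the flux balance at each value.  The overlap region is the interval of
#' M2 where an upper (epithelial-rich) and a lower (mesenchymal-rich) stable
#' root coexist, i.e. where the hysteresis between the two state categories
#' lives; its width shrinks with the epithelial-resistance cooperativity `k`,
#' grows with the conversion cooperativities `m`, `n`, and vanishes at high
#' macrophage loads (where absolute cancer-cell numbers are too small for the
#' cooperative epithelial resistance to act).
#'
#' @param problem a variant I `emtmac_problem`.
#' @param m2_grid_n sweep resolution.
#' @return list with `sweep` (data frame: `M2`, `n_roots`, `n_stable`,
#'   `E_hi`, `E_lo` — the extreme stable roots — and `has_state_I`,
#'   `has_state_II` category flags), `overlap` (M2 interval with at least two
#'   stable roots, or `NULL`), `overlap_width`, `categories` (stable
#'   categories seen anywhere in the sweep) and `n_stable_categories`.
#' @export
model1_overlap_region <- function(problem, m2_grid_n = 101L) {
  m2s <- seq(0, problem$M_c, length.out = m2_grid_n)
  rows <- lapply(m2s, function(v) {
    roots <- model1_branch(v, problem)
    stable <- Filter(function(r) isTRUE(r$branch_stable), roots)
    cats <- vapply(stable, `[[`, character(1), "category")
    Es <- vapply(stable, function(r) r$state[["E"]], numeric(1))
    data.frame(M2 = v, n_roots = length(roots), n_stable = length(stable),
               E_hi = if (length(Es)) max(Es) else NA_real_,
               E_lo = if (length(Es)) min(Es) else NA_real_,
               has_state_I = any(cats == "state_I_epithelial_dominated"),
               has_state_II = any(cats == "state_II_mesenchymal_dominated"))
  })
  sweep <- do.call(rbind, rows)
  both <- sweep$n_stable >= 2L
  overlap <- if (any(both)) range(sweep$M2[both]) else NULL
  cats <- character(0)
  if (any(sweep$has_state_I)) cats <- c(cats, "state_I_epithelial_dominated")
  if (any(sweep$has_state_II)) cats <- c(cats, "state_II_mesenchymal_dominated")
  list(sweep = sweep, overlap = overlap,
       overlap_width = if (is.null(overlap)) 0 else diff(overlap),
       categories = cats, n_stable_categories = length(cats))
}

#' Walk a branch of equilibria by natural-parameter continuation
#'
#' Steps a tracked equilibrium along a parameter, re-solving at each step,
#' until the branch is lost (a fold or basin jump) or a parameter bound is
#' reached.  Records the leading non-neutral eigenvalue real part and the
#' Hopf indicator at every accepted point.
#'
#' @param problem an `emtmac_problem`.
#' @param param_name continued parameter.
#' @param value0 parameter value of the starting point.
#' @param state0 equilibrium state at `value0`.
#' @param step signed parameter step.
#' @param v_min,v_max parameter bounds.
#' @param max_steps safety cap on the number of steps.
#' @return data frame with columns `param`, the state components,
#'   `max_real_part`, `hopf_re`, plus attribute `"end_reason"`
#'   (`"bound"` or `"lost"`).
#' @export
walk_branch <- function(problem, param_name, value0, state0, step,
                        v_min = -Inf, v_max = Inf, max_steps = 2000L) {
  pr0 <- .set_param(problem, param_name, value0)
  st <- .continue_state(pr0, .as_state(state0, pr0$params))
  if (is.null(st)) stop("starting point is not on a branch at value0")
  rows <- list()
  push <- function(v, st) {
    hre <- suppressWarnings(hopf_indicator(st, .set_param(problem, param_name, v)$params))
    rows[[length(rows) + 1L]] <<- data.frame(
      param = v, as.list(st$state),
      max_real_part = st$spectrum$max_real_part,
      hopf_re = as.numeric(hre), stringsAsFactors = FALSE)
  }
  push(value0, st)
  v <- value0
  end_reason <- "bound"
  for (i in seq_len(max_steps)) {
    v_next <- v + step
    if (v_next < v_min || v_next > v_max) break
    res <- .continue_state(.set_param(problem, param_name, v_next), st$state)
    if (is.null(res)) { end_reason <- "lost"; break }
    st <- res
    v <- v_next
    push(v, st)
  }
  structure(do.call(rbind, rows), end_reason = end_reason)
}

#' Catalog the critical points of a one-parameter family
#'
#' Combines the closed-form extinction state, multi-start equilibrium
#' discovery at a set of probe values, and branch walking to assemble the
#' critical points of the equilibrium structure over a parameter interval:
#' \itemize{
#'   \item `extinction_stabilization`: stability change of the cancer-free
#'     state;
#'   \item `hopf`: complex-pair crossings along low-cancer branches;
#'   \item `fold`: branch end points interior to the interval;
#'   \item `sole_extinction_threshold`: loss of the last stable
#'     cancer-bearing equilibrium.
#' }
#' All events are refined by bisection to width `tol`.
#'
#' @param problem an `emtmac_problem` (variant II or III).
#' @param param_name swept parameter (default `"eta_me"`).
#' @param bracket parameter interval searched.
#' @param probe_values parameter values at which multi-start discovery runs
#'   (default 13 equally spaced values across `bracket`).
#' @param walk_step continuation step for branch walking (default 4e-4).
#' @param tol bisection tolerance (default 1e-4).
#' @return data frame with columns `type`, `value`, `note`, sorted by value;
#'   events that could not be located are reported with `NA` and the error
#'   message in `note`.
#' @export
critical_point_catalog <- function(problem, param_name = "eta_me",
                                   bracket = c(0.002, 0.25),
                                   probe_values = NULL, walk_step = 4e-4,
                                   tol = 1e-4) {
  if (is.null(probe_values)) {
    probe_values <- seq(bracket[1], bracket[2], length.out = 13L)
  }
  events <- list()
  note_of <- function(e) conditionMessage(e)

  ## extinction stabilization
  ev <- tryCatch(
    data.frame(type = "extinction_stabilization",
               value = as.numeric(critical_value(problem, param_name,
                 "extinction_stabilization", bracket, tol = tol)),
               note = ""),
    error = function(e) data.frame(type = "extinction_stabilization",
                                   value = NA_real_, note = note_of(e)))
  events[[length(events) + 1L]] <- ev

  ## sole extinction threshold
  ev <- tryCatch(
    data.frame(type = "sole_extinction_threshold",
               value = as.numeric(critical_value(problem, param_name,
                 "sole_extinction_threshold", bracket, tol = tol)),
               note = ""),
    error = function(e) data.frame(type = "sole_extinction_threshold",
                                   value = NA_real_, note = note_of(e)))
  events[[length(events) + 1L]] <- ev

  ## walk low-cancer branches found at the probe values
  visited <- list()  # rows of (param, state) already on a walked branch
  seen <- function(v, s) {
    any(vapply(visited, function(row) {
      abs(row$param - v) <= walk_step * 1.5 && max(abs(row$state - s)) < 1e-3
    }, logical(1)))
  }
  remember <- function(df) {
    nm <- setdiff(names(df), c("param", "max_real_part", "hopf_re"))
    for (i in seq_len(nrow(df))) {
      visited[[length(visited) + 1L]] <<-
        list(param = df$param[i], state = unlist(df[i, nm]))
    }
  }
  add_walk_events <- function(wk, from_value) {
    ## Hopf: sign changes of the complex-pair indicator
    h <- wk$hopf_re
    for (i in seq_len(nrow(wk) - 1L)) {
      if (!is.na(h[i]) && !is.na(h[i + 1L]) && sign(h[i]) * sign(h[i + 1L]) < 0) {
        lo_i <- if (wk$param[i] < wk$param[i + 1L]) i else i + 1L
        hi_i <- if (lo_i == i) i + 1L else i
        st <- unlist(wk[lo_i, setdiff(names(wk), c("param", "max_real_part", "hopf_re"))])
        ev <- tryCatch(
          data.frame(type = "hopf",
                     value = as.numeric(critical_value(problem, param_name, "hopf",
                       c(wk$param[lo_i], wk$param[hi_i]), tol = tol,
                       track_state = st)),
                     note = ""),
          error = function(e) data.frame(type = "hopf", value = NA_real_,
                                         note = note_of(e)))
        events[[length(events) + 1L]] <<- ev
      }
    }
    ## fold: walk lost the branch inside the interval
    if (attr(wk, "end_reason") == "lost") {
      last <- nrow(wk)
      v_last <- wk$param[last]
      st <- unlist(wk[last, setdiff(names(wk), c("param", "max_real_part", "hopf_re"))])
      dirn <- sign(v_last - from_value)
      if (dirn == 0) dirn <- 1
      lo <- min(v_last, v_last + dirn * 3 * walk_step)
      hi <- max(v_last, v_last + dirn * 3 * walk_step)
      if (dirn > 0) {
        ev <- tryCatch(
          data.frame(type = "fold",
                     value = as.numeric(critical_value(problem, param_name, "fold",
                       c(v_last, hi), tol = tol, track_state = st)),
                     note = ""),
          error = function(e) data.frame(type = "fold", value = NA_real_,
                                         note = note_of(e)))
      } else {
        ## walking downward: reflect by tracking from the last good point
        ev <- tryCatch({
          val <- .bisect_fold_down(problem, param_name, v_last, lo, st, tol)
          data.frame(type = "fold", value = val, note = "")
        }, error = function(e) data.frame(type = "fold", value = NA_real_,
                                          note = note_of(e)))
      }
      events[[length(events) + 1L]] <<- ev
    }
  }

  for (v in probe_values) {
    pr <- .set_param(problem, param_name, v)
    eqs <- tryCatch(find_equilibria(pr), error = function(e) list())
    for (e in eqs) {
      if (e$category != "low_cancer_intermediate") next
      if (seen(v, unname(e$state))) next
      up <- walk_branch(problem, param_name, v, e$state, step = walk_step,
                        v_min = bracket[1], v_max = bracket[2])
      dn <- walk_branch(problem, param_name, v, e$state, step = -walk_step,
                        v_min = bracket[1], v_max = bracket[2])
      remember(up); remember(dn)
      add_walk_events(up, v)
      add_walk_events(dn, v)
    }
  }

  out <- do.call(rbind, events)
  ## deduplicate events of the same type closer than twice the tolerance
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i] || is.na(out$value[i])) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j] || is.na(out$value[j])) next
      if (out$type[j] == out$type[i] && abs(out$value[j] - out$value[i]) < 2 * tol) {
        keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$value, na.last = TRUE), , drop = FALSE]
}

## Bisection for a fold approached from above (branch exists at hi = v_last,
## lost somewhere in [lo, v_last]).
.bisect_fold_down <- function(problem, param_name, v_exists, v_lost, state, tol) {
  carry <- state
  carry_v <- v_exists
  lo <- v_lost; hi <- v_exists
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    st <- carry
    ok <- TRUE
    for (vv in seq(carry_v, mid, length.out = 9L)[-1L]) {
      res <- .continue_state(.set_param(problem, param_name, vv), st)
      if (is.null(res)) { ok <- FALSE; break }
      st <- res$state
    }
    if (ok) { hi <- mid; carry <- st; carry_v <- mid } else lo <- mid
  }
  (lo + hi) / 2
}

#' Four-value summary of a critical-point catalog
#'
#' Reduces a [critical_point_catalog()] to the four headline thresholds of
#' the apoptosis-model analysis: the extinction-stabilization point, the
#' first Hopf point, the first fold above the Hopf point (the fold bounding
#' the low-cancer branch pair; reported as `NA` when no Hopf point exists,
#' since the bounding fold is then not identified), and the sole-extinction
#' threshold.
#'
#' @param catalog data frame from [critical_point_catalog()].
#' @return named numeric vector with entries `extinction_stabilization`,
#'   `hopf`, `fold`, `sole_extinction_threshold` (`NA` where absent).
#' @export
summarize_critical_set <- function(catalog) {
  val <- function(type) {
    v <- catalog$value[catalog$type == type & !is.na(catalog$value)]
    if (length(v)) min(v) else NA_real_
  }
  hopf <- val("hopf")
  folds <- catalog$value[catalog$type == "fold" & !is.na(catalog$value)]
  fold <- if (!length(folds) || is.na(hopf) || !any(folds > hopf)) {
    NA_real_
  } else {
    min(folds[folds > hopf])
  }
  c(extinction_stabilization = val("extinction_stabilization"),
    hopf = hopf, fold = fold,
    sole_extinction_threshold = val("sole_extinction_threshold"))
}
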