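#' Sample an ensemble of initial conditions
#'
#' Draws random initial states on the invariant manifold of fixed total
#' macrophage fraction: the total cancer load is uniform over
#' `cancer_total_range` and split uniformly between epithelial and
#' mesenchymal cells; the macrophage total `M_c` is split over
#' (M0, M1, M2) by a uniform simplex (Dirichlet(1,1,1)) draw; the apoptotic
#' factor starts at 0.  Deterministic for a fixed seed.
#'
#' @param n_states number of states to draw.
#' @param M_c total macrophage fraction.
#' @param cancer_total_range interval for `E + M`, within
#'   `[0, N_max - M_c]`.
#' @param seed integer RNG seed (mandatory, for reproducible pipelines).
#' @param N_max carrying capacity (default 1).
#' @return list of state vectors (see [population_state()]).
#' @export
sample_initial_conditions <- function(n_states, M_c,
                                      cancer_total_range = c(0, 1 - M_c),
                                      seed, N_max = 1) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (M_c < 0 || M_c > N_max) stop("'M_c' must lie in [0, N_max]")
  lo <- cancer_total_range[1]; hi <- cancer_total_range[2]
  if (lo < 0 || hi > N_max - M_c + 1e-12 || lo > hi) {
    stop("'cancer_total_range' must lie within [0, N_max - M_c]")
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    lapply(seq_len(n_states), function(i) {
      cancer <- stats::runif(1, lo, hi)
      fe <- stats::runif(1)
      w <- -log(stats::runif(3))   # uniform simplex via normalized exponentials
      w <- w / sum(w)
      population_state(E = cancer * fe, M = cancer * (1 - fe),
                       M0 = M_c * w[1], M1 = M_c * w[2], M2 = M_c * w[3],
                       C = 0)
    })
  })
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Emulates the input of the EMT-score association stage without any external
#' data: per-sample EMT scores are drawn from a chosen distribution on
#' `[0, 2]`, and each gene is built either with a planted Pearson
#' correlation `rho` with the score (`expr = rho * z_score +
#' sqrt(1 - rho^2) * noise`, both factors standardized, then scaled by
#' `noise_sd` and shifted by `baseline`), or with a planted standardized mean
#' shift `delta` between the EMT-high and EMT-low halves of the median
#' split.  The planted truth is returned alongside for test assertions.
#'
#' @param n_genes,n_samples dataset dimensions (`n_samples >= 3`).
#' @param rho per-gene planted correlation in (-1, 1); recycled.  Exactly one
#'   of `rho`/`delta` must be given.
#' @param delta per-gene planted mean shift in units of the within-group SD;
#'   recycled.
#' @param noise_sd expression scale (SD of the noise component, default 1).
#' @param baseline mean log-expression level (default 5).
#' @param score_distribution `"uniform"` on `[0, 2]`, or `"bimodal"` (an
#'   equal mixture of truncated normals near 0.35 and 1.65, mimicking
#'   epithelial- and mesenchymal-dominated subpopulations).
#' @param seed integer RNG seed (mandatory).
#' @return list with `data` (an [expression_dataset()]) and `truth` (data
#'   frame: `gene`, `rho` or `delta`).
#' @export
generate_expression_dataset <- function(n_genes, n_samples, rho = NULL,
                                        delta = NULL, noise_sd = 1,
                                        baseline = 5,
                                        score_distribution = c("uniform", "bimodal"),
                                        seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  score_distribution <- match.arg(score_distribution)
  if (is.null(rho) == is.null(delta)) {
    stop("specify exactly one of 'rho' (planted correlation) or 'delta' (planted shift)")
  }
  if (n_samples < 3L) stop("'n_samples' must be at least 3")
  if (!is.null(rho) && any(abs(rho) >= 1)) stop("planted 'rho' must lie in (-1, 1)")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  scores <- switch(score_distribution,
    uniform = stats::runif(n_samples, 0, 2),
    bimodal = {
      comp <- stats::rbinom(n_samples, 1, 0.5)
      x <- stats::rnorm(n_samples, mean = ifelse(comp == 1, 1.65, 0.35), sd = 0.25)
      pmin(pmax(x, 0), 2)
    })

  genes <- sprintf("gene_%04d", seq_len(n_genes))
  vals <- matrix(NA_real_, n_genes, n_samples,
                 dimnames = list(genes, sprintf("sample_%04d", seq_len(n_samples))))
  if (!is.null(rho)) {
    rho <- rep_len(rho, n_genes)
    z <- as.numeric(scale(scores))
    for (i in seq_len(n_genes)) {
      eps <- stats::rnorm(n_samples)
      vals[i, ] <- baseline + noise_sd * (rho[i] * z + sqrt(1 - rho[i]^2) * eps)
    }
    truth <- data.frame(gene = genes, rho = rho, stringsAsFactors = FALSE)
  } else {
    delta <- rep_len(delta, n_genes)
    high <- scores > stats::median(scores)
    for (i in seq_len(n_genes)) {
      vals[i, ] <- baseline + noise_sd * (delta[i] * as.numeric(high) +
                                            stats::rnorm(n_samples))
    }
    truth <- data.frame(gene = genes, delta = delta, stringsAsFactors = FALSE)
  }
  list(data = expression_dataset(vals, scores), truth = truth)
}
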