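#' Bundle an expression matrix with per-sample EMT scores
#'
#' @param values numeric genes x samples matrix (log-scale expression), with
#'   rownames as gene identifiers and colnames as sample identifiers.
#' @param emt_scores numeric per-sample EMT score in `[0, 2]` (0 = fully
#'   epithelial, 2 = fully mesenchymal), one per column of `values`.  Scores
#'   are taken as given inputs; the scoring metric itself is external.
#' @return an `emtmac_expression` list with `values`, `emt_scores`, `genes`,
#'   `samples`.
#' @export
expression_dataset <- function(values, emt_scores) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  }
  if (length(emt_scores) != ncol(values)) {
    stop("'emt_scores' must have one value per sample (column)")
  }
  if (anyNA(emt_scores)) stop("'emt_scores' must not contain missing values")
  if (any(emt_scores < 0 | emt_scores > 2)) {
    stop("'emt_scores' must lie in [0, 2]")
  }
  structure(list(values = values, emt_scores = as.numeric(emt_scores),
                 genes = rownames(values), samples = colnames(values)),
            class = "emtmac_expression")
}

#' Per-gene Pearson correlation with the EMT score
#'
#' The linear correlation coefficient of each gene's expression with the
#' per-sample EMT score (the slope-sign-carrying summary of a per-gene
#' simple linear regression).  Genes with zero variance are flagged
#' (`r = NA`) rather than computed, and are excluded from downstream
#' summaries.
#'
#' @param data an [expression_dataset()].
#' @return data frame with columns `gene`, `r`, `defined`.
#' @export
gene_emt_correlation <- function(data) {
  stopifnot(inherits(data, "emtmac_expression"))
  if (ncol(data$values) < 3L) stop("at least 3 samples are required")
  v <- apply(data$values, 1L, stats::var)
  r <- rep(NA_real_, nrow(data$values))
  ok <- v > 0
  if (any(ok)) {
    r[ok] <- as.numeric(stats::cor(t(data$values[ok, , drop = FALSE]),
                                   data$emt_scores))
  }
  data.frame(gene = data$genes, r = r, defined = ok, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Median-split two-sample test of expression against EMT status
#'
#' Samples are discretized at the dataset's median EMT score: strictly above
#' the median is EMT-high, at or below is EMT-low ("higher than the median"
#' defines the high group, so exact ties go to the low group).  Each gene is
#' then tested with a two-sided unpaired t-test of EMT-high versus EMT-low
#' expression (Welch by default; pooled-variance via `var_equal = TRUE`),
#' reporting the p-value, the 95% confidence interval of the high-minus-low
#' mean difference, and the direction of the difference.
#'
#' A degenerate gene with identical values in every sample is reported with
#' difference 0, interval `[0, 0]` and `p = 1`.
#'
#' @param data an [expression_dataset()].
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return data frame with columns `gene`, `r`, `diff` (mean difference,
#'   high minus low), `p_value`, `ci_low`, `ci_high`, `direction` (+1/-1/0),
#'   `significant`; the split and test choices are attached as attributes
#'   `"n_high"`, `"n_low"`, `"welch"`.
#' @export
median_split_test <- function(data, alpha = 0.05, var_equal = FALSE,
                              conf_level = 0.95) {
  stopifnot(inherits(data, "emtmac_expression"))
  med <- stats::median(data$emt_scores)
  high <- data$emt_scores > med
  n_high <- sum(high); n_low <- sum(!high)
  if (n_high < 2L || n_low < 2L) {
    stop("median split leaves a group with fewer than 2 samples (",
         n_high, " high, ", n_low, " low)")
  }
  corr <- gene_emt_correlation(data)
  rows <- lapply(seq_len(nrow(data$values)), function(i) {
    x <- data$values[i, high]   # EMT-high
    y <- data$values[i, !high]  # EMT-low
    d <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(data.frame(gene = data$genes[i], r = corr$r[i], diff = d,
                        p_value = if (d == 0) 1 else 0,
                        ci_low = d, ci_high = d, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal, conf.level = conf_level)
    data.frame(gene = data$genes[i], r = corr$r[i], diff = d,
               p_value = tt$p.value, ci_low = tt$conf.int[1],
               ci_high = tt$conf.int[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$direction <- sign(out$diff)
  out$significant <- out$p_value < alpha
  attr(out, "n_high") <- n_high
  attr(out, "n_low") <- n_low
  attr(out, "welch") <- !var_equal
  attr(out, "alpha") <- alpha
  out
}

#' Enrichment summary of a gene set among EMT-associated genes
#'
#' Counts how many members of a gene set are significantly higher in
#' EMT-high tumors, significantly higher in EMT-low tumors, or not
#' significant, given per-gene [median_split_test()] results.  Gene-set
#' members absent from the results are reported, not fatal.
#'
#' @param results data frame from [median_split_test()].
#' @param gene_set character vector of gene identifiers.
#' @return list with `n_set`, `n_tested`, `missing`, `higher_in_emt_high`,
#'   `higher_in_emt_low`, `not_significant`, `fraction_positive` (fraction of
#'   tested members with positive direction) and `table` (the subset of
#'   `results` for the tested members).
#' @export
enrichment_summary <- function(results, gene_set) {
  if (!length(gene_set)) stop("'gene_set' must be non-empty")
  missing <- setdiff(gene_set, results$gene)
  tested <- results[results$gene %in% gene_set, , drop = FALSE]
  sig_up <- sum(tested$significant & tested$direction > 0)
  sig_dn <- sum(tested$significant & tested$direction < 0)
  list(n_set = length(gene_set),
       n_tested = nrow(tested),
       missing = missing,
       higher_in_emt_high = sig_up,
       higher_in_emt_low = sig_dn,
       not_significant = nrow(tested) - sig_up - sig_dn,
       fraction_positive = if (nrow(tested)) mean(tested$direction > 0) else NA_real_,
       table = tested)
}
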