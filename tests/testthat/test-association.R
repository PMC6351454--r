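make_dataset <- function(values, scores) expression_dataset(values, scores)

test_that("self- and anti-correlated genes give r of +1 and -1", {
  scores <- seq(0.1, 1.9, length.out = 20)
  vals <- rbind(same = scores, neg = -scores + 2)
  d <- make_dataset(vals, scores)
  out <- gene_emt_correlation(d)
  expect_equal(out$r[out$gene == "same"], 1)
  expect_equal(out$r[out$gene == "neg"], -1)
})

test_that("zero-variance genes are flagged rather than computed", {
  scores <- runif(10, 0, 2)
  vals <- rbind(flat = rep(3, 10), ok = scores + rnorm(10, sd = 0.1))
  out <- gene_emt_correlation(make_dataset(vals, scores))
  expect_true(is.na(out$r[out$gene == "flat"]))
  expect_false(out$defined[out$gene == "flat"])
  expect_true(out$defined[out$gene == "ok"])
})

test_that("a planted correlation of 0.4 is recovered at n = 500", {
  gen <- generate_expression_dataset(30, 500, rho = 0.4, seed = 101)
  out <- gene_emt_correlation(gen$data)
  expect_true(all(abs(out$r - 0.4) < 0.10))
})

test_that("null genes reject at close to the nominal level", {
  ## three-sigma binomial band around 0.05 for 1000 trials: [0.029, 0.071]
  gen <- generate_expression_dataset(1000, 200, rho = 0, seed = 2024)
  res <- median_split_test(gen$data, alpha = 0.05)
  frac <- mean(res$significant)
  expect_gte(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("null p-values are close to uniform", {
  gen <- generate_expression_dataset(2000, 100, rho = 0, seed = 7)
  res <- median_split_test(gen$data)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a one-SD shift at 143 per group is detected essentially always", {
  gen <- generate_expression_dataset(300, 286, delta = 1, seed = 55)
  res <- median_split_test(gen$data)
  expect_identical(attr(res, "n_high"), 143L)
  expect_identical(attr(res, "n_low"), 143L)
  ## closed-form power at this size is 1 - 5e-14; all genes must reject
  expect_gte(mean(res$significant & res$direction > 0), 0.995)
})

test_that("degenerate genes and the tie rule behave as specified", {
  scores <- c(0.2, 0.4, 0.6, 0.6, 1.4, 1.8)  # median 0.6, ties go low
  vals <- rbind(flat = rep(2, 6), g = c(1, 1, 1, 1, 5, 5))
  res <- median_split_test(make_dataset(vals, scores))
  expect_identical(attr(res, "n_high"), 2L)  # only the two above-median
  expect_identical(attr(res, "n_low"), 4L)
  expect_identical(res$diff[res$gene == "flat"], 0)
  expect_identical(res$ci_low[res$gene == "flat"], 0)
  expect_identical(res$ci_high[res$gene == "flat"], 0)
  expect_false(res$significant[res$gene == "flat"])
})

test_that("correlation is invariant to per-gene affine transforms, p to sample order", {
  gen <- generate_expression_dataset(20, 60, rho = 0.3, seed = 12)
  d <- gen$data
  d2 <- expression_dataset(d$values * 3.7 + 11, d$emt_scores)
  expect_equal(gene_emt_correlation(d2)$r, gene_emt_correlation(d)$r,
               tolerance = 1e-12)
  perm <- sample(ncol(d$values))
  d3 <- expression_dataset(d$values[, perm], d$emt_scores[perm])
  r1 <- median_split_test(d)
  r3 <- median_split_test(d3)
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-12)
})

test_that("enrichment summaries count directions and report missing members", {
  gen <- generate_expression_dataset(40, 300, delta = rep(c(1.2, 0), each = 20),
                                     seed = 31)
  res <- median_split_test(gen$data)
  up_set <- gen$truth$gene[gen$truth$delta > 0]
  s <- enrichment_summary(res, up_set)
  expect_identical(s$higher_in_emt_high, length(up_set))
  expect_identical(s$higher_in_emt_low, 0L)
  ## null set of 31 genes: significance count within the binomial 95% band
  null_set <- gen$truth$gene[gen$truth$delta == 0][1:20]
  gen2 <- generate_expression_dataset(31, 300, delta = 0, seed = 32)
  res2 <- median_split_test(gen2$data)
  s2 <- enrichment_summary(res2, res2$gene)
  expect_lte(s2$higher_in_emt_high + s2$higher_in_emt_low,
             qbinom(0.975, 31, 0.05))
  ## a member absent from the results is reported, not fatal
  s3 <- enrichment_summary(res, c(up_set, "not_a_gene"))
  expect_identical(s3$missing, "not_a_gene")
  expect_identical(s3$n_tested, length(up_set))
  expect_error(enrichment_summary(res, character(0)), "non-empty")
})

test_that("dataset validation enforces the score contract", {
  vals <- matrix(rnorm(20), 4, 5)
  expect_error(expression_dataset(vals, c(0.5, 0.5, 0.5)), "one value per sample")
  expect_error(expression_dataset(vals, c(0.5, NA, 0.5, 0.5, 0.5)), "missing")
  expect_error(expression_dataset(vals, c(0.5, 2.5, 0.5, 0.5, 0.5)), "\\[0, 2\\]")
})
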