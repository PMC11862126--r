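make_cohort <- function(...) simulate_cohort(n_genes = 40, seed = 5, ...)

test_that("grouping sums conserve gene totals for matched peptides", {
  sim <- make_cohort()
  values <- normalize_cohort_psms(sim$psm, sim$annotations)
  meta <- sim$psm[, c("psm_id", "peptide_id", "gene")]
  by_gene <- sum_to_grouping(values, meta, "gene")
  by_group <- sum_to_grouping(values, meta, sim$grouping)
  gene_of_group <- sim$grouping$gene[match(rownames(by_group),
                                           sim$grouping$membership)]
  rebuilt <- rowsum(by_group, gene_of_group)
  expect_equal(rebuilt, by_gene[rownames(rebuilt), ], tolerance = 1e-9)

  # each group equals the direct sum over its member peptides' PSM rows
  g0 <- rownames(by_group)[1]
  peps <- sim$grouping$peptide_id[sim$grouping$membership == g0]
  direct <- colSums(values[sim$psm$peptide_id %in% peps, , drop = FALSE])
  expect_equal(by_group[g0, ], direct, tolerance = 1e-9)

  # unknown peptides in the grouping are an error
  bad <- rbind(sim$grouping,
               data.frame(gene = "NOPE", peptide_id = "nope_p1",
                          membership = "NOPE_1"))
  expect_error(sum_to_grouping(values, meta, bad), "unknown")
})

test_that("randomized membership preserves per-gene group sizes and gene totals", {
  sim <- make_cohort()
  null_map <- randomize_membership(sim$grouping, seed = 9)
  for (g in unique(sim$grouping$gene)) {
    real_sizes <- sort(table(sim$grouping$membership[sim$grouping$gene == g]))
    null_sizes <- sort(table(null_map$membership[null_map$gene == g]))
    expect_equal(unname(real_sizes), unname(null_sizes))
  }
  # single-group genes unchanged
  singles <- names(which(tapply(sim$grouping$membership, sim$grouping$gene,
                                function(m) length(unique(m))) == 1))
  i <- sim$grouping$gene %in% singles
  expect_identical(null_map$membership[i], sim$grouping$membership[i])
  # determinism and non-triviality
  expect_identical(randomize_membership(sim$grouping, seed = 9), null_map)
  expect_false(identical(null_map$membership, sim$grouping$membership))

  # gene totals identical under real and randomized grouping
  values <- normalize_cohort_psms(sim$psm, sim$annotations)
  meta <- sim$psm[, c("psm_id", "peptide_id", "gene")]
  real <- sum_to_grouping(values, meta, sim$grouping)
  null <- sum_to_grouping(values, meta, null_map)
  gene_of <- sim$grouping$gene[match(rownames(real), sim$grouping$membership)]
  expect_equal(rowsum(real, gene_of), rowsum(null, gene_of),
               tolerance = 1e-9)
})

test_that("log median centering is idempotent with zero per-sample medians", {
  sim <- make_cohort()
  values <- normalize_cohort_psms(sim$psm, sim$annotations)
  mat <- sum_to_grouping(values, sim$psm[, c("psm_id", "peptide_id", "gene")],
                         sim$grouping)
  lg <- log_median_center(mat)
  expect_true(all(abs(apply(lg, 2, median, na.rm = TRUE)) < 1e-10))
  again <- suppressWarnings(log_median_center(2^lg))
  expect_equal(again, lg, tolerance = 1e-10)
})

test_that("variance F-test follows the F(n-1, n-1) tail with null pairing", {
  n <- 61
  # identical variances -> F = 1, p = 0.5
  set.seed(4)
  x <- matrix(rnorm(3 * n), 3, n, dimnames = list(c("a", "b", "c"), NULL))
  colnames(x) <- sprintf("P%02d", 1:n)
  res <- variance_f_test(x, x)
  expect_true(all(res$F == 1))
  expect_true(all(abs(res$p - pf(1, 60, 60, lower.tail = FALSE)) < 1e-12))

  # fourfold variance: oracle tail probability from the F distribution
  y <- x; y[1, ] <- x[1, ] * 2
  res2 <- variance_f_test(y, x)
  expect_equal(res2$F[1], 4, tolerance = 1e-12)
  expect_equal(res2$p[1], pf(4, 60, 60, lower.tail = FALSE))
  expect_lt(abs(res2$p[1] - 1.3e-7) / 1.3e-7, 0.05)

  # zero null variance is flagged conservative
  z <- x; z[2, ] <- 0
  res3 <- variance_f_test(x, z)
  expect_true(res3$flagged[2])
  expect_equal(res3$p[2], 1)
})

test_that("rank-sum treatment test is exact on the textbook case", {
  mat <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                dimnames = list("g1", sprintf("P%d", 1:6)))
  res <- wilcoxon_treatment_test(mat, treated = c("P1", "P2", "P3"),
                                 untreated = c("P4", "P5", "P6"))
  expect_equal(res$p, 0.1)
  expect_equal(res$p, wilcox_enumerate(1:3, 4:6))
  # monotone in the shift
  mat2 <- rbind(mat, g2 = c(1, 2, 3, 104, 105, 106))
  res2 <- wilcoxon_treatment_test(mat2, c("P1", "P2", "P3"),
                                  c("P4", "P5", "P6"))
  expect_equal(res2$p[2], res2$p[1])  # rank test: same ranks, same p
  expect_error(wilcoxon_treatment_test(mat, character(0), "P1"))
})

test_that("rank-sum rejection rate is calibrated under the null", {
  set.seed(7)
  n_groups <- 400
  mat <- matrix(rnorm(n_groups * 40), n_groups, 40,
                dimnames = list(sprintf("g%03d", 1:n_groups),
                                sprintf("P%02d", 1:40)))
  res <- wilcoxon_treatment_test(mat, sprintf("P%02d", 1:20),
                                 sprintf("P%02d", 21:40))
  rate <- mean(res$p < 0.05)
  band <- qbinom(c(0.025, 0.975), n_groups, 0.05) / n_groups
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("Spearman correlation and its Fisher-z interval behave", {
  x <- 1:10
  expect_equal(spearman_with_ci(x, x * 2 + 3)$rho, 1)
  expect_equal(spearman_with_ci(x, -x)$rho, -1)
  set.seed(8)
  xr <- rnorm(12); yr <- -0.8 * xr + rnorm(12, 0, 0.6)
  sc <- spearman_with_ci(xr, yr)
  z <- atanh(sc$rho); se <- sqrt(1.06 / 9)
  expect_equal(sc$ci, tanh(c(z - qnorm(0.975) * se, z + qnorm(0.975) * se)))
  tt <- sc$rho * sqrt(10 / (1 - sc$rho^2))
  expect_equal(sc$p, 2 * pt(abs(tt), 10, lower.tail = FALSE))
  # bootstrap oracle: the Fisher-z interval roughly matches resampling
  set.seed(9)
  boots <- replicate(4000, {
    i <- sample(12, replace = TRUE)
    suppressWarnings(cor(rank(xr[i]), rank(yr[i])))
  })
  bq <- quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  expect_lt(abs(bq[[1]] - sc$ci[1]), 0.2)
  expect_lt(abs(bq[[2]] - sc$ci[2]), 0.2)
  # degenerate input flagged
  expect_true(spearman_with_ci(rep(1, 6), 1:6)$flagged)
  expect_error(spearman_with_ci(1:4, 1:4), "at least 5")
})

test_that("subgroup-specific response associations are found in the right stratum", {
  sim <- simulate_cohort(n_genes = 30, n_response_groups = 1,
                         response_rho = -0.8, response_in_subgroup = TRUE,
                         subgroup_size = 20, effect_size = 0, seed = 13)
  values <- normalize_cohort_psms(sim$psm, sim$annotations)
  mat <- log_median_center(
    sum_to_grouping(values, sim$psm[, c("psm_id", "peptide_id", "gene")],
                    sim$grouping))
  res <- subgroup_analysis(mat, sim$annotations)
  expect_setequal(unique(res$stratum), c("all", "subgroup", "complement"))
  target <- sim$truth$response_groups
  sub <- res[res$stratum == "subgroup" & res$group %in% target, ]
  comp <- res[res$stratum == "complement" & res$group %in% target, ]
  expect_true(all(sub$p < 0.05))
  expect_true(all(sub$rho < 0))
  expect_true(all(comp$p > 0.01))

  # the all-patients stratum equals a direct correlation call
  g <- res$group[1]
  direct <- spearman_with_ci(mat[g, sim$annotations$patient_id],
                             sim$annotations$response)
  expect_equal(res$rho[res$stratum == "all" & res$group == g], direct$rho)

  # undersized strata are skipped with a notice
  ann2 <- sim$annotations
  ann2$subgroup <- c(rep("subgroup", 3), rep("other", nrow(ann2) - 3))
  expect_message(res2 <- subgroup_analysis(mat, ann2), "skipped")
  expect_false("subgroup" %in% res2$stratum)
})
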