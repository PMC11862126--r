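test_that("melting sigmoid fit recovers noiseless parameters", {
  temps <- seq(37, 67, length.out = 10)
  y <- tppforms:::sigmoid_ml(temps, pl = 0.08, a = 1200, b = 24)
  fit <- fit_melt_model(temps, y)
  expect_lt(fit$rss, 1e-10)
  expect_lt(abs(fit$params["pl"] - 0.08) / 0.08, 1e-3)
  expect_lt(abs(fit$params["a"] - 1200) / 1200, 1e-3)

  # degenerate all-identical input
  flat <- fit_melt_model(temps, rep(0.4, 10))
  expect_true(flat$degenerate)
  expect_equal(flat$rss, 0)

  # duplicate curves: same parameters, doubled RSS structure
  set.seed(1)
  yn <- y * exp(rnorm(10, 0, 0.02))
  f1 <- fit_melt_model(temps, yn)
  f2 <- fit_melt_model(rep(temps, 2), rep(yn, 2))
  expect_equal(unname(f2$params), unname(f1$params), tolerance = 1e-4)
  expect_equal(f2$rss, 2 * f1$rss, tolerance = 1e-6)
})

test_that("NPARC F statistic follows the residual-ratio formula", {
  fs <- nparc_f_stat(12, 6, 4, 16)
  expect_equal(fs$F, 4.0)
  expect_equal(fs$p, pf(4, 4, 16, lower.tail = FALSE))
  # null identity: no improvement, F = 0, p = 1
  expect_equal(nparc_f_stat(5, 5, 3, 10)$F, 0)
  expect_equal(nparc_f_stat(5, 5, 3, 10)$p, 1)
  # numerical inversion clamps to zero
  expect_equal(nparc_f_stat(5, 5.0001, 3, 10)$F, 0)
  # perfect alternative fit gives the p = 0 limit
  expect_equal(nparc_f_stat(1, 0, 3, 10)$p, 0)
})

test_that("identical noiseless conditions yield zero improvement", {
  temps <- seq(37, 67, length.out = 10)
  y <- tppforms:::sigmoid_ml(temps, 0.05, 1300, 26)
  r <- nparc_rss(rep(temps, 4), rep(y, 4),
                 rep(c("vehicle", "drug"), each = 20))
  expect_lt(r$rss0, 1e-10)
  expect_equal(r$rss1, min(r$rss1, r$rss0))
  expect_lt(r$rss0 - r$rss1, 1e-10)
})

test_that("effective dof estimation recovers known degrees of freedom", {
  set.seed(14)
  delta <- 3.7 * rchisq(1e5, 5)
  rss1 <- 3.7 * rchisq(1e5, 12)
  ed <- estimate_effective_dof(delta, rss1)
  expect_equal(ed$method, "moments")
  expect_lt(abs(ed$d1 - 5), 0.1)
  expect_lt(abs(ed$d2 - 12), 0.3)
  # scale invariance: doubling all RSS leaves the estimate unchanged
  ed2 <- estimate_effective_dof(2 * delta, 2 * rss1)
  expect_equal(ed2$d1, ed$d1, tolerance = 1e-10)
  expect_equal(ed2$d2, ed$d2, tolerance = 1e-10)
})

test_that("dof estimation falls back to counting dof for small sets", {
  expect_message(
    ed <- estimate_effective_dof(rchisq(10, 3), rchisq(10, 10),
                                 nominal_d1 = 3, nominal_d2 = 34),
    "nominal")
  expect_equal(ed$d1, 3)
  expect_equal(ed$d2, 34)
  expect_equal(ed$method, "nominal")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute_force(p))
  }
})

test_that("4PL fitting is exact on clean data with a sane confidence band", {
  temps <- rep(seq(37, 67, length.out = 10), 2)
  y <- four_pl_curve(temps, 0.07, 1, 51.3, 0.45)
  fit <- fit_4pl(temps, y)
  expect_lt(abs(fit$params["tm"] - 51.3), 1e-6)
  # midpoint property of the fitted curve
  mid <- predict(fit, fit$params[["tm"]])
  expect_equal(mid, (fit$params[["top"]] + fit$params[["bottom"]]) / 2,
               tolerance = 1e-8)
  # band contains the fitted curve with non-negative width
  expect_true(all(fit$band$lwr <= fit$band$fit + 1e-12))
  expect_true(all(fit$band$upr >= fit$band$fit - 1e-12))
  # per-temperature observation summaries
  expect_equal(nrow(fit$point_stats), 10)
  expect_equal(fit$point_stats$mean, y[1:10], tolerance = 1e-12)
})

test_that("complete-curve filter enforces full duplicated curves per scope", {
  sim <- simulate_tpp_experiment(n_genes = 6, seed = 17)
  pr <- melt_profiles(sim$quant)
  asn <- assign_proteoform_groups(pr, seed = 1)
  gc <- suppressWarnings(summarize_groups(sim$quant, asn))
  all_ids <- filter_complete_curves(gc)
  expect_true(length(all_ids) > 0)

  # knock out one channel of one group in one sample
  gc2 <- gc
  victim <- all_ids[1]
  gc2$curves[victim, 15] <- NA
  expect_false(victim %in% filter_complete_curves(gc2))
  # but it survives a scope that excludes the damaged sample
  damaged_sample <- gc2$layout$sample_id[15]
  rest <- setdiff(gc2$samples, damaged_sample)
  expect_true(victim %in% filter_complete_curves(gc2, rest))
})

test_that("NPARC screen flags shifted groups within a mixed set", {
  set.seed(31)
  temps <- seq(37, 67, length.out = 10)
  groups <- c(lapply(1:60, function(i) simulate_nparc_group(temps)),
              lapply(1:15, function(i) simulate_nparc_group(temps, shift = 4)))
  rss <- t(vapply(groups, function(g) {
    r <- nparc_rss(g$temperature, g$y, g$condition)
    c(r$rss0, r$rss1)
  }, numeric(2)))
  ed <- estimate_effective_dof(rss[, 1] - rss[, 2], rss[, 2])
  p <- vapply(seq_len(nrow(rss)), function(i)
    nparc_f_stat(rss[i, 1], rss[i, 2], ed$d1, ed$d2)$p, 0)
  shifted <- seq_len(75) > 60
  expect_gt(mean(p[shifted] < 0.05), 0.9)
  expect_lt(mean(p[!shifted] < 0.05), 0.2)
})
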