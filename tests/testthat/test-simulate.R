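test_that("4PL curve has midpoint, asymptotes and symmetry about Tm", {
  expect_equal(four_pl_curve(50, 0, 1, 50, 0.5), 0.5)
  expect_equal(four_pl_curve(-1e6, 0.1, 0.9, 50, 0.5), 0.9)
  expect_equal(four_pl_curve(1e6, 0.1, 0.9, 50, 0.5), 0.1)
  d <- 3.7
  expect_equal(four_pl_curve(50 - d, 0, 1, 50, 0.4) - 0.5,
               0.5 - four_pl_curve(50 + d, 0, 1, 50, 0.4))
  expect_error(four_pl_curve(50, bottom = 1, top = 0.5), "below")
  expect_error(four_pl_curve(50, tm = NaN), "finite")
})

test_that("noiseless simulation reproduces latent 4PL curves exactly and monotone", {
  sim <- simulate_tpp_experiment(n_genes = 5, noise_sd = 0,
                                 ambiguous_peptide_rate = 0, seed = 3)
  pq <- sim$quant
  grid <- pq$grid
  pf <- sim$truth$proteoforms
  tr <- sim$truth$peptides
  for (r in sample(nrow(pq$meta), 20)) {
    meta <- pq$meta[r, ]
    k <- which(tr$peptide_id == meta$peptide_id)
    pr <- pf[pf$gene == tr$gene[k] & pf$proteoform == tr$proteoform[k], ]
    tm <- pr$tm + if (pr$target && meta$condition == "drug")
      sim$truth$config$drug_delta_tm else 0
    expected <- four_pl_curve(grid$temperatures, pr$bottom, pr$top, tm,
                              pr$slope)
    ratio <- pq$intensities[r, ] / pq$intensities[r, 1]
    expect_equal(ratio, expected / expected[1], tolerance = 1e-12)
    expect_true(all(diff(pq$intensities[r, ]) <= 0))
  }
})

test_that("simulation bookkeeping matches the requested design", {
  sim <- simulate_tpp_experiment(n_genes = 100, fraction_two_proteoform = 0.3,
                                 seed = 9)
  n_forms <- table(table(sim$truth$proteoforms$gene))
  expect_equal(unname(n_forms["2"]), 30)
  expect_equal(unname(n_forms["1"]), 70)
  # truth partitions each gene's peptides
  tr <- sim$truth$peptides
  expect_false(any(duplicated(paste(tr$gene, tr$peptide_id))))
  # every peptide row appears once per sample
  expect_equal(nrow(sim$quant$meta), nrow(tr) * 8)
})

test_that("identical seeds give identical simulated experiments", {
  a <- simulate_tpp_experiment(n_genes = 10, seed = 42)
  b <- simulate_tpp_experiment(n_genes = 10, seed = 42)
  expect_identical(a$quant$intensities, b$quant$intensities)
  expect_identical(a$truth$peptides, b$truth$peptides)
  c <- simulate_tpp_experiment(n_genes = 10, seed = 43)
  expect_false(identical(a$quant$intensities, c$quant$intensities))
})

test_that("multiplicative noise magnitude matches the configured sd", {
  # many replicate observations of one peptide/temperature cell
  sim <- simulate_tpp_experiment(n_genes = 2, peptides_per_gene = 25,
                                 fraction_two_proteoform = 0,
                                 cell_lines = sprintf("L%02d", 1:25),
                                 replicates = 4, noise_sd = 0.1,
                                 ambiguous_peptide_rate = 0, seed = 5)
  pq <- sim$quant
  lg <- log(pq$intensities)
  sds <- unlist(lapply(split(seq_len(nrow(lg)), pq$meta$peptide_id),
                       function(i) apply(lg[i, , drop = FALSE], 2, sd)))
  # 50 peptides x 10 channels x 100 samples = 5e4 draws in 500 cells
  expect_lt(abs(mean(sds) - 0.1) / 0.1, 0.05)
})

test_that("cohort simulation annotates the treated-versus-control design", {
  sim <- simulate_cohort(n_patients = 68, n_treated = 4, seed = 2)
  expect_equal(sum(sim$annotations$treated), 4)
  expect_equal(sum(!sim$annotations$treated), 64)
  expect_equal(nrow(sim$annotations), 68)
  # grouping partitions each gene's peptides
  expect_false(any(duplicated(sim$grouping$peptide_id)))
  # determinism
  sim2 <- simulate_cohort(n_patients = 68, n_treated = 4, seed = 2)
  expect_identical(sim$psm, sim2$psm)
  expect_identical(sim$annotations, sim2$annotations)
})

test_that("null cohort carries no treatment effect beyond noise", {
  sim <- simulate_cohort(n_genes = 60, effect_size = 0, seed = 8)
  expect_length(sim$truth$effect_groups, 0)
  ab <- sim$truth$group_abundance
  tre <- sim$annotations$treated
  d <- rowMeans(ab[, tre, drop = FALSE]) - rowMeans(ab[, !tre, drop = FALSE])
  expect_lt(abs(mean(d)), 0.2)
})
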