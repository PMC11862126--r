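test_that("weighted melt distance follows the formula and handles missingness", {
  expect_equal(melt_distance(c(1, 0.5, 0), c(1, 0.5, 0)), 0)
  expect_equal(melt_distance(c(1, 0.5, 0), c(1, 0.4, 0.1)), sqrt(0.02))
  expect_equal(melt_distance(c(1, 0.5, 0), c(1, 0.4, 0.1), c(1, 2, 1)),
               sqrt(0.03))
  # missing positions (and their weights) are excluded pairwise
  a <- c(1, 0.5, 0, NA); b <- c(1, 0.4, 0.1, 0.2)
  expect_equal(melt_distance(a, b, c(1, 2, 1, 10)), sqrt(0.03))
  # fewer than 3 shared positions -> undefined
  expect_true(is.na(melt_distance(c(1, NA, NA, 2), c(1, 1, 1, 1))))
})

test_that("Gaussian similarity kernel is monotone with the right anchors", {
  expect_equal(similarity_from_distance(0, 1), 1)
  expect_equal(similarity_from_distance(1, 1), exp(-0.5))
  d <- seq(0, 3, by = 0.3)
  expect_true(all(diff(similarity_from_distance(d, 0.8)) < 0))
  expect_error(similarity_from_distance(1, 0), "positive")
})

test_that("gene graphs are complete with median-distance bandwidth", {
  set.seed(1)
  mat <- matrix(rnorm(12 * 20), 12, 20,
                dimnames = list(sprintf("p%02d", 1:12), NULL))
  g <- build_gene_graph(mat, weight_scheme = "uniform")
  expect_equal(sum(!is.na(g$sim[upper.tri(g$sim)])), 66)
  d <- g$dist[upper.tri(g$dist)]
  expect_equal(g$bandwidth, median(d))
})

test_that("Leiden recovers planted blocks and matches exhaustive modularity maximization", {
  # 8 vertices: exhaustive search over all 4140 partitions is feasible
  n <- 8
  adj <- matrix(0.05, n, n, dimnames = list(letters[1:n], letters[1:n]))
  adj[1:4, 1:4] <- 0.9; adj[5:8, 5:8] <- 0.9
  diag(adj) <- 0
  oracle <- best_partition_modularity(adj)
  graph <- structure(list(peptide_ids = letters[1:n], dist = NULL,
                          sim = adj, bandwidth = 1), class = "gene_graph")
  lc <- leiden_communities(graph, seed = 1)
  expect_equal(lc$modularity, oracle$modularity, tolerance = 1e-12)
  expect_equal(ari_safe(lc$membership, oracle$labels), 1)
  expect_equal(ari_safe(lc$membership, rep(1:2, each = 4)), 1)

  # spec-scale case: two 5-vertex blocks
  n <- 10
  adj <- matrix(0.05, n, n); adj[1:5, 1:5] <- 0.9; adj[6:10, 6:10] <- 0.9
  diag(adj) <- 0
  dimnames(adj) <- list(letters[1:n], letters[1:n])
  graph <- structure(list(peptide_ids = letters[1:n], sim = adj,
                          bandwidth = 1), class = "gene_graph")
  lc10 <- leiden_communities(graph, seed = 1)
  expect_equal(ari_safe(lc10$membership, rep(1:2, each = 5)), 1)

  # uniform complete graph: no structure, single community, |Q| tiny
  adj_u <- matrix(0.5, n, n); diag(adj_u) <- 0
  dimnames(adj_u) <- list(letters[1:n], letters[1:n])
  graph_u <- structure(list(peptide_ids = letters[1:n], sim = adj_u,
                            bandwidth = 1), class = "gene_graph")
  lc_u <- leiden_communities(graph_u, seed = 1)
  expect_equal(length(unique(lc_u$membership)), 1)
  expect_lt(abs(lc_u$modularity), 1e-13)

  # determinism under a fixed seed
  expect_identical(leiden_communities(graph, seed = 5)$membership,
                   leiden_communities(graph, seed = 5)$membership)
})

test_that("ambiguity ratio counts multi-gene peptides", {
  sets <- c(rep(list(c("A", "B")), 2), rep(list("A"), 6))
  expect_equal(ambiguity_ratio(sets), 0.25)
  expect_equal(ambiguity_ratio(rep(list("A"), 4)), 0)
  half <- c(rep(list(c("A", "B")), 3), rep(list("A"), 3))
  expect_equal(ambiguity_ratio(half), 0.5)
  th <- proteoform_thresholds()
  expect_false(ambiguity_ratio(half) < th$max_ambiguity)
})

test_that("assignment gates route genes to single groups with the right reason", {
  sim <- simulate_tpp_experiment(n_genes = 8, peptides_per_gene = 9,
                                 fraction_two_proteoform = 1,
                                 ambiguous_peptide_rate = 0, seed = 6)
  pr <- melt_profiles(sim$quant)
  asn <- assign_proteoform_groups(pr, seed = 1)
  # 9 peptides fail the >= 10 gate: every gene a single group
  expect_true(all(asn$reason == "below_min_peptides"))
  expect_equal(length(unique(asn$membership)), 8)

  # high-ambiguity gene is not split
  sim2 <- simulate_tpp_experiment(n_genes = 4, peptides_per_gene = 12,
                                  fraction_two_proteoform = 1,
                                  ambiguous_peptide_rate = 0.6, seed = 7)
  pr2 <- melt_profiles(sim2$quant)
  asn2 <- assign_proteoform_groups(pr2, seed = 1)
  high_amb <- unique(asn2$gene[asn2$ambiguity_ratio >= 0.5])
  for (g in high_amb) {
    expect_equal(length(unique(asn2$membership[asn2$gene == g])), 1)
    expect_true(all(asn2$reason[asn2$gene == g] %in%
                      c("high_ambiguity", "below_min_peptides")))
  }
})

test_that("clean two-proteoform genes split into the true groups, nulls do not", {
  sim <- simulate_tpp_experiment(n_genes = 10, fraction_two_proteoform = 0.5,
                                 delta_tm = 4, noise_sd = 0.05,
                                 target_fraction = 0,
                                 ambiguous_peptide_rate = 0, seed = 12)
  pr <- melt_profiles(sim$quant)
  asn <- assign_proteoform_groups(pr, seed = 3)
  tr <- sim$truth$peptides
  for (g in unique(tr$gene)) {
    sel <- asn$gene == g
    truth <- tr$proteoform[match(asn$peptide_id[sel], tr$peptide_id)]
    expect_equal(ari_safe(asn$membership[sel], truth), 1)
  }
  # partition property: each retained peptide in exactly one group per gene
  expect_false(any(duplicated(paste(asn$gene, asn$peptide_id))))
})

test_that("small communities merge instead of escaping as groups", {
  # plant a 2-peptide outlier community next to a 10-peptide block
  set.seed(30)
  k <- 10; n_samples <- 4
  curve_a <- four_pl_curve(seq(37, 67, length.out = k), 0, 1, 50, 0.5)
  curve_b <- four_pl_curve(seq(37, 67, length.out = k), 0, 1, 58, 0.5)
  mk <- function(curve, n) {
    t(sapply(seq_len(n), function(i) {
      as.vector(sapply(seq_len(n_samples), function(s)
        curve * exp(rnorm(k, 0, 0.03))))
    }))
  }
  mat <- rbind(mk(curve_a, 10), mk(curve_b, 2))
  rownames(mat) <- sprintf("p%02d", 1:12)
  # bypass gates that are not under test via a hand-built profile object
  prof <- structure(list(
    fold = mat,
    peptides = data.frame(peptide_id = rownames(mat), sequence = "X",
                          genes = "G1"),
    layout = data.frame(sample_id = rep(sprintf("s%d", 1:n_samples), each = k),
                        channel = rep(1:k, n_samples)),
    samples = sprintf("s%d", 1:n_samples),
    grid = temperature_grid()), class = "melt_profiles")
  asn <- assign_proteoform_groups(prof, seed = 2)
  sizes <- table(asn$membership)
  expect_true(all(sizes >= 3))
  merged <- asn$peptide_id[asn$reason == "small_community_merged"]
  if (length(unique(asn$membership)) == 1) {
    expect_equal(length(unique(asn$membership)), 1)
  } else {
    expect_true(all(c("p11", "p12") %in% merged))
  }
})

test_that("emitted multi-group genes always satisfy the acceptance gates", {
  sim <- simulate_tpp_experiment(n_genes = 20, fraction_two_proteoform = 0.4,
                                 seed = 19)
  pr <- melt_profiles(sim$quant)
  th <- proteoform_thresholds()
  asn <- assign_proteoform_groups(pr, th, seed = 4)
  multi <- unique(asn$gene[ave(seq_len(nrow(asn)), asn$gene, FUN = function(i)
    length(unique(asn$membership[i]))) > 1])
  for (g in multi) {
    rows <- asn[asn$gene == g, ]
    expect_gt(rows$modularity[1], th$modularity_floor)
    expect_lt(rows$ambiguity_ratio[1], th$max_ambiguity)
    expect_true(all(table(rows$membership) >= th$min_community))
  }
})

test_that("group curves sum raw member intensities before renormalization", {
  sim <- simulate_tpp_experiment(n_genes = 12, seed = 21)
  pr <- melt_profiles(sim$quant)
  asn <- assign_proteoform_groups(pr, seed = 2)
  gc <- suppressWarnings(summarize_groups(sim$quant, asn))
  k <- length(gc$grid)
  # reference channel is 1 for every retained curve
  for (s in seq_along(gc$samples)) {
    ref <- gc$curves[, (s - 1) * k + gc$grid$reference_index]
    expect_true(all(abs(ref[!is.na(ref)] - 1) < 1e-12))
  }
  expect_setequal(gc$groups$membership, unique(asn$membership))
  expect_equal(gc$groups$n_member_peptides,
               as.integer(table(asn$membership)[gc$groups$membership]))
})
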