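#' Four-parameter logistic melting curve
#'
#' Fraction non-denatured as a function of temperature,
#' `f(T) = bottom + (top - bottom) / (1 + exp(slope * (T - tm)))`.
#' With positive `slope` the curve decreases from `top` (low temperature)
#' to `bottom` (high temperature) and passes through the midpoint
#' `(top + bottom) / 2` at the melting point `tm`.
#'
#' @param temperature Numeric vector of temperatures (degrees C).
#' @param bottom Lower plateau (post-denaturation fraction), `>= 0`.
#' @param top Upper plateau (about 1 at the reference temperature).
#' @param tm Melting point (inflection), degrees C.
#' @param slope Steepness per degree C; positive for melting.
#' @return Numeric vector of fractions non-denatured.
#' @examples
#' four_pl_curve(50, bottom = 0, top = 1, tm = 50, slope = 0.5)  # 0.5
#' @export
four_pl_curve <- function(temperature, bottom = 0, top = 1, tm = 50,
                          slope = 0.5) {
  params <- c(bottom, top, tm, slope)
  if (anyNA(params) || any(!is.finite(params))) {
    stop("4PL parameters must be finite")
  }
  if (bottom >= top) stop("`bottom` must be below `top`")
  bottom + (top - bottom) / (1 + exp(slope * (temperature - tm)))
}

draw_proteoform_params <- function(tm_range = c(46, 58),
                                   slope_range = c(0.35, 0.7),
                                   bottom_range = c(0.02, 0.12)) {
  list(bottom = runif(1, bottom_range[1], bottom_range[2]),
       top = 1,
       tm = runif(1, tm_range[1], tm_range[2]),
       slope = runif(1, slope_range[1], slope_range[2]))
}

#' Simulate a TPP experiment with known proteoform structure
#'
#' Emulates a lysate TPP design: two cell lines, drug and vehicle
#' conditions in technical duplicates, a ten-point temperature gradient,
#' TMT-style reporter intensities. Each gene carries one or two latent
#' proteoforms with 4PL melting; a subset of proteoforms is thermally
#' shifted by the drug. Peptide intensities are the product of a log-normal
#' baseline abundance (spanning about three orders of magnitude, to give the
#' normalization something to do), the proteoform's condition-specific 4PL
#' curve, and multiplicative log-normal noise. A fraction of peptides is
#' made ambiguous by mapping it to a second gene (shared-peptide
#' quantification: the same intensities count for both genes).
#'
#' @param n_genes Number of simulated genes.
#' @param peptides_per_gene Peptides per gene (single number, or vector to
#'   sample from).
#' @param fraction_two_proteoform Fraction of genes with two latent
#'   proteoforms.
#' @param delta_tm Melting-point separation (degrees C) between the two
#'   proteoforms of a two-proteoform gene.
#' @param target_fraction Fraction of all proteoforms that are drug targets
#'   (shifted in the drug condition).
#' @param drug_delta_tm Drug-induced melting-point shift (degrees C) applied
#'   to target proteoforms in the drug condition.
#' @param noise_sd Standard deviation of the multiplicative noise on the
#'   natural-log intensity scale.
#' @param cell_lines Character vector of cell-line labels.
#' @param replicates Technical replicates per (cell line, condition).
#' @param grid A [temperature_grid()].
#' @param ambiguous_peptide_rate Fraction of peptides mapped to a second
#'   gene.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `quant` (a [peptide_quant()]) and `truth`, a list with
#'   `peptides` (gene, peptide_id, proteoform), `proteoforms` (per-proteoform
#'   4PL parameters and target status) and the config used.
#' @export
simulate_tpp_experiment <- function(n_genes = 100,
                                    peptides_per_gene = 12,
                                    fraction_two_proteoform = 0.3,
                                    delta_tm = 4,
                                    target_fraction = 0.2,
                                    drug_delta_tm = 3,
                                    noise_sd = 0.05,
                                    cell_lines = c("RCHACV", "SW13"),
                                    replicates = 2,
                                    grid = temperature_grid(),
                                    ambiguous_peptide_rate = 0.02,
                                    seed = 1) {
  stopifnot(n_genes >= 1, fraction_two_proteoform >= 0,
            fraction_two_proteoform <= 1, target_fraction >= 0,
            target_fraction <= 1, noise_sd >= 0, replicates >= 1)
  set.seed(as.integer(seed))
  temps <- grid$temperatures
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_two <- round(n_genes * fraction_two_proteoform)
  two_pf <- c(rep(TRUE, n_two), rep(FALSE, n_genes - n_two))

  # latent proteoforms and their vehicle-condition parameters
  pf_list <- list()
  pep_truth <- list()
  for (i in seq_len(n_genes)) {
    n_pep <- if (length(peptides_per_gene) > 1) {
      sample(peptides_per_gene, 1)
    } else peptides_per_gene
    n_forms <- if (two_pf[i]) 2L else 1L
    base <- draw_proteoform_params()
    for (k in seq_len(n_forms)) {
      p <- base
      if (k == 2L) p$tm <- p$tm + delta_tm
      pf_list[[length(pf_list) + 1L]] <-
        data.frame(gene = genes[i], proteoform = k, bottom = p$bottom,
                   top = p$top, tm = p$tm, slope = p$slope)
    }
    if (n_forms == 2L) {
      n1 <- max(3L, min(n_pep - 3L, round(n_pep * runif(1, 0.35, 0.65))))
      assign <- c(rep(1L, n1), rep(2L, n_pep - n1))
    } else {
      assign <- rep(1L, n_pep)
    }
    pep_truth[[i]] <- data.frame(
      gene = genes[i],
      peptide_id = sprintf("%s_p%02d", genes[i], seq_len(n_pep)),
      proteoform = assign)
  }
  proteoforms <- do.call(rbind, pf_list)
  peptides <- do.call(rbind, pep_truth)
  rownames(proteoforms) <- rownames(peptides) <- NULL

  n_pf <- nrow(proteoforms)
  n_targets <- round(n_pf * target_fraction)
  proteoforms$target <- FALSE
  if (n_targets > 0) {
    proteoforms$target[sample.int(n_pf, n_targets)] <- TRUE
  }

  # ambiguous peptides: map to one extra gene
  peptides$genes <- peptides$gene
  if (ambiguous_peptide_rate > 0 && n_genes > 1) {
    n_amb <- round(nrow(peptides) * ambiguous_peptide_rate)
    if (n_amb > 0) {
      idx <- sample.int(nrow(peptides), n_amb)
      extra <- vapply(peptides$gene[idx], function(g) {
        sample(setdiff(genes, g), 1)
      }, "")
      peptides$genes[idx] <- paste(peptides$gene[idx], extra, sep = ";")
    }
  }

  base_abund <- rlnorm(nrow(peptides), meanlog = log(1e6), sdlog = 1.2)

  samples <- expand.grid(replicate = seq_len(replicates),
                         condition = c("vehicle", "drug"),
                         cell_line = cell_lines,
                         stringsAsFactors = FALSE)
  pf_key <- paste(proteoforms$gene, proteoforms$proteoform)
  pep_pf <- match(paste(peptides$gene, peptides$proteoform), pf_key)

  meta <- list(); ints <- list()
  for (s in seq_len(nrow(samples))) {
    sm <- samples[s, ]
    tm_eff <- proteoforms$tm +
      ifelse(proteoforms$target & sm$condition == "drug", drug_delta_tm, 0)
    frac <- vapply(seq_len(nrow(peptides)), function(j) {
      k <- pep_pf[j]
      four_pl_curve(temps, proteoforms$bottom[k], proteoforms$top[k],
                    tm_eff[k], proteoforms$slope[k])
    }, numeric(length(temps)))
    mat <- t(frac) * base_abund
    if (noise_sd > 0) {
      mat <- mat * exp(matrix(rnorm(length(mat), 0, noise_sd), nrow(mat)))
    }
    sid <- paste(sm$cell_line, sm$condition, sm$replicate, sep = ".")
    meta[[s]] <- data.frame(
      peptide_id = peptides$peptide_id,
      sequence = paste0("PEP", peptides$peptide_id),
      genes = peptides$genes,
      cell_line = sm$cell_line, condition = sm$condition,
      replicate = sm$replicate, set_id = sid,
      stringsAsFactors = FALSE)
    ints[[s]] <- mat
  }
  quant <- peptide_quant(do.call(rbind, meta), do.call(rbind, ints), grid)
  truth <- list(peptides = peptides, proteoforms = proteoforms,
                config = list(n_genes = n_genes, delta_tm = delta_tm,
                              drug_delta_tm = drug_delta_tm,
                              noise_sd = noise_sd, seed = seed))
  list(quant = quant, truth = truth)
}

#' Simulate a patient cohort with proteoform-group abundance structure
#'
#' Emulates a deep proteomics cohort: PSM-level quantities for genes whose
#' peptides partition into proteoform groups, patients labeled by
#' treatment status and molecular subgroup, and an ex vivo drug-response
#' viability variable. Patient-to-patient variation decomposes into a
#' gene-level biological component (`noise_sd`, shared by all of a gene's
#' peptides), a peptide-level sampling component (`peptide_noise_sd`) and
#' PSM-level measurement noise (`psm_noise_sd`); with `noise_sd = 0` and
#' `effect_size = 0` the cohort is pure peptide-level noise, the condition
#' under which the randomized-membership variance screen is calibrated.
#' Designated groups receive a treatment effect in treated patients;
#' designated groups are correlated with the response (optionally only
#' within the subgroup). PSM rows per peptide and a set-wise loading
#' factor are generated so that the PSM-summation and per-set
#' normalization stages are exercised.
#'
#' @param n_patients Number of independent patients (default 68).
#' @param n_genes Number of genes.
#' @param two_group_fraction Fraction of genes split into two proteoform
#'   groups (ignored when `groups_per_gene` is given).
#' @param groups_per_gene Optional fixed number of proteoform groups for
#'   every gene.
#' @param peptides_per_group Vector to sample the per-group peptide count
#'   from.
#' @param psms_per_peptide Vector to sample the per-peptide PSM count
#'   from.
#' @param n_treated Number of treated (or pretreated) patients (default
#'   4).
#' @param effect_size Treatment effect on designated groups, log2 units.
#' @param effect_group_fraction Fraction of groups carrying the treatment
#'   effect.
#' @param n_response_groups Number of groups correlated with the
#'   response.
#' @param response_rho Target Spearman correlation between those groups
#'   and the response.
#' @param response_in_subgroup If `TRUE` the response association holds
#'   only within the molecular subgroup.
#' @param subgroup_size Number of patients in the molecular subgroup.
#' @param noise_sd Gene-level biological between-patient sd, log2 units.
#' @param peptide_noise_sd Peptide-level between-patient sd, log2 units.
#' @param psm_noise_sd PSM-level measurement noise, log2 units.
#' @param n_sets Number of TMT sets the patients are distributed over.
#' @param seed Integer seed.
#' @return List with `psm` (data frame: psm_id, peptide_id, gene,
#'   membership and one intensity column per patient), `annotations`
#'   (patient_id, treated, subgroup, set_id, response), `grouping` (gene,
#'   peptide_id, membership) and `truth` (effect groups, response groups,
#'   group abundances, config).
#' @export
simulate_cohort <- function(n_patients = 68,
                            n_genes = 100,
                            two_group_fraction = 0.5,
                            groups_per_gene = NULL,
                            peptides_per_group = 3:6,
                            psms_per_peptide = 1:3,
                            n_treated = 4,
                            effect_size = 1.5,
                            effect_group_fraction = 0.1,
                            n_response_groups = 2,
                            response_rho = -0.65,
                            response_in_subgroup = TRUE,
                            subgroup_size = 12,
                            noise_sd = 0.4,
                            peptide_noise_sd = 0.3,
                            psm_noise_sd = 0.1,
                            n_sets = 8,
                            seed = 1) {
  stopifnot(n_treated < n_patients, subgroup_size <= n_patients,
            noise_sd >= 0, peptide_noise_sd >= 0, abs(response_rho) < 1)
  set.seed(as.integer(seed))
  patients <- sprintf("P%03d", seq_len(n_patients))
  treated <- sort(sample.int(n_patients, n_treated))
  subgroup <- sort(sample.int(n_patients, subgroup_size))

  genes <- sprintf("CG%04d", seq_len(n_genes))
  if (is.null(groups_per_gene)) {
    n_two <- round(n_genes * two_group_fraction)
    n_groups_per_gene <- c(rep(2L, n_two), rep(1L, n_genes - n_two))
  } else {
    n_groups_per_gene <- rep(as.integer(groups_per_gene), n_genes)
  }

  grouping <- list(); group_ids <- character(); group_gene <- character()
  for (i in seq_len(n_genes)) {
    for (k in seq_len(n_groups_per_gene[i])) {
      gid <- sprintf("%s_%d", genes[i], k)
      group_ids <- c(group_ids, gid); group_gene <- c(group_gene, genes[i])
      n_pep <- sample(peptides_per_group, 1)
      grouping[[length(grouping) + 1L]] <- data.frame(
        gene = genes[i],
        peptide_id = sprintf("%s_k%d_p%02d", genes[i], k, seq_len(n_pep)),
        membership = gid, stringsAsFactors = FALSE)
    }
  }
  grouping <- do.call(rbind, grouping)
  n_groups <- length(group_ids)

  n_effect <- round(n_groups * effect_group_fraction)
  effect_groups <- if (effect_size != 0 && n_effect > 0) {
    sort(sample(group_ids, n_effect))
  } else character()
  response_groups <- if (n_response_groups > 0) {
    sort(sample(setdiff(group_ids, effect_groups),
                min(n_response_groups, n_groups - length(effect_groups))))
  } else character()

  # group-level true log2 abundance: gene baseline + gene-level biological
  # variation shared by the gene's groups + treatment effect
  mu_gene <- setNames(runif(n_genes, 18, 24), genes)
  gene_dev <- matrix(rnorm(n_genes * n_patients, 0, noise_sd),
                     n_genes, n_patients, dimnames = list(genes, patients))
  abund <- gene_dev[group_gene, , drop = FALSE] + mu_gene[group_gene]
  rownames(abund) <- group_ids
  if (length(effect_groups)) {
    abund[effect_groups, treated] <- abund[effect_groups, treated] +
      effect_size
  }

  # response: noisy linear readout of the mean of the response groups,
  # with noise scaled to hit the target correlation in expectation
  response <- rnorm(n_patients)
  if (length(response_groups) && response_rho != 0) {
    x <- colMeans(abund[response_groups, , drop = FALSE])
    idx <- if (response_in_subgroup) subgroup else seq_len(n_patients)
    if (sd(x[idx]) > 0) {
      xs <- scale(x[idx])[, 1]
      lambda <- sqrt(1 / response_rho^2 - 1)
      response[idx] <- sign(response_rho) * xs + lambda * rnorm(length(idx))
    }
  }
  # viability-like scale in (0, 1)
  response <- 1 / (1 + exp(-response / 2))

  # expand groups -> peptides -> PSMs, with set-wise loading factors
  set_of_patient <- rep(seq_len(n_sets), length.out = n_patients)
  set_loading <- matrix(exp(runif(n_sets * n_patients, -0.3, 0.3)),
                        n_sets, n_patients)
  pep_group <- match(grouping$membership, group_ids)
  n_psm_per_pep <- sample(psms_per_peptide, nrow(grouping), replace = TRUE)
  psm_pep <- rep(seq_len(nrow(grouping)), n_psm_per_pep)
  n_psm <- length(psm_pep)

  # peptide-level between-patient deviations (detectability noise)
  pep_dev <- matrix(rnorm(nrow(grouping) * n_patients, 0, peptide_noise_sd),
                    nrow(grouping), n_patients)

  # split abundance over PSMs with one equal share per PSM of the gene, so
  # that under a no-signal cohort every PSM of a gene is exchangeable and
  # the randomized-membership null is exact (splitting by group instead
  # would give peptides of different groups unequal shares)
  psm_group <- pep_group[psm_pep]
  psm_gene <- match(group_gene[psm_group], genes)
  psm_per_gene <- tabulate(psm_gene, nbins = n_genes)
  lin <- 2^abund
  vals <- lin[psm_group, , drop = FALSE] / psm_per_gene[psm_gene]
  vals <- vals * 2^(pep_dev[psm_pep, , drop = FALSE] +
                      matrix(rnorm(n_psm * n_patients, 0, psm_noise_sd),
                             n_psm, n_patients))
  # per-set loading: each patient's channel sits in one set
  for (p in seq_len(n_patients)) {
    vals[, p] <- vals[, p] * set_loading[set_of_patient[p], p]
  }
  colnames(vals) <- patients

  psm <- data.frame(psm_id = sprintf("psm%06d", seq_len(n_psm)),
                    peptide_id = grouping$peptide_id[psm_pep],
                    gene = grouping$gene[psm_pep],
                    membership = grouping$membership[psm_pep],
                    stringsAsFactors = FALSE)
  psm <- cbind(psm, as.data.frame(vals))

  annotations <- data.frame(
    patient_id = patients,
    treated = seq_len(n_patients) %in% treated,
    subgroup = ifelse(seq_len(n_patients) %in% subgroup, "subgroup",
                      "other"),
    set_id = paste0("set", set_of_patient),
    response = response,
    stringsAsFactors = FALSE)

  truth <- list(effect_groups = effect_groups,
                response_groups = response_groups,
                group_abundance = abund,
                config = list(n_patients = n_patients,
                              n_treated = n_treated,
                              effect_size = effect_size,
                              response_rho = response_rho,
                              noise_sd = noise_sd,
                              peptide_noise_sd = peptide_noise_sd,
                              seed = seed))
  list(psm = psm, annotations = annotations,
       grouping = grouping[, c("gene", "peptide_id", "membership")],
       truth = truth)
}
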