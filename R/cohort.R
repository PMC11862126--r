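#' Calibrate cohort PSM intensities per TMT set
#'
#' Applies the variance-stabilizing calibration ([vsn_normalize()])
#' separately within each TMT set (the patients of one plex) and returns
#' values back-transformed to the calibrated intensity scale, so that
#' member PSMs can subsequently be summed on a common linear scale.
#'
#' @param psm Data frame with identifying columns plus one intensity column
#'   per patient.
#' @param annotations Patient annotations with `patient_id` and `set_id`.
#' @param trim_fraction Passed to [vsn_normalize()].
#' @return Numeric matrix, PSMs x patients, calibrated intensity scale.
#' @export
normalize_cohort_psms <- function(psm, annotations, trim_fraction = 0.1) {
  patients <- annotations$patient_id
  stopifnot(all(patients %in% names(psm)))
  mat <- as.matrix(psm[, patients, drop = FALSE])
  out <- mat * NA_real_
  for (set in unique(annotations$set_id)) {
    cols <- patients[annotations$set_id == set]
    if (length(cols) < 2) {
      # a single-channel set has nothing to calibrate against
      out[, cols] <- mat[, cols]
      next
    }
    h <- vsn_normalize(mat[, cols, drop = FALSE],
                       trim_fraction = trim_fraction)
    # back to the scale-calibrated linear scale (offset removed) so that
    # member PSMs can be summed and log-transformed meaningfully
    out[, cols] <- sweep(sinh(h), 2, attr(h, "calibration")$a, "-")
  }
  rownames(out) <- psm$psm_id %||% rownames(mat)
  out
}

#' Sum PSM values to a grouping (gene, proteoform group, or randomized)
#'
#' @param values Numeric matrix, PSMs x patients (calibrated scale).
#' @param psm_meta Data frame aligned with `values` rows, with columns
#'   `peptide_id` and `gene`.
#' @param grouping Either `"gene"`, or a grouping map data frame with
#'   columns `gene`, `peptide_id`, `membership` (only the mapped --
#'   "matched" -- peptides are summed).
#' @return Numeric matrix, entities x patients.
#' @export
sum_to_grouping <- function(values, psm_meta, grouping = "gene") {
  stopifnot(nrow(values) == nrow(psm_meta))
  if (identical(grouping, "gene")) {
    entity <- psm_meta$gene
    keep <- rep(TRUE, nrow(values))
  } else {
    stopifnot(all(c("gene", "peptide_id", "membership") %in% names(grouping)))
    key <- paste(psm_meta$gene, psm_meta$peptide_id)
    map_key <- paste(grouping$gene, grouping$peptide_id)
    unknown <- setdiff(map_key, key)
    if (length(unknown)) {
      stop("grouping references unknown peptide(s): ", unknown[1])
    }
    idx <- match(key, map_key)
    keep <- !is.na(idx)
    entity <- grouping$membership[idx[keep]]
  }
  rowsum(values[keep, , drop = FALSE], group = entity, na.rm = TRUE)
}

#' Log-transform and median-center an abundance matrix
#'
#' `log2` of the summed calibrated intensities, then subtraction of each
#' patient column's median so that per-sample medians are exactly zero.
#' Non-positive sums cannot be log-transformed and become `NA` (warning).
#'
#' @param mat Entities x patients matrix of summed abundances.
#' @return Matrix of log2, median-centered abundances.
#' @export
log_median_center <- function(mat) {
  if (any(mat <= 0, na.rm = TRUE)) {
    warning(sprintf("%d non-positive value(s) set to NA before log",
                    sum(mat <= 0, na.rm = TRUE)))
    mat[mat <= 0] <- NA
  }
  lg <- log2(mat)
  sweep(lg, 2, apply(lg, 2, median, na.rm = TRUE), "-")
}

#' Randomize proteoform-group membership within genes
#'
#' Builds the null grouping used to benchmark proteoform-group variance:
#' within each gene, the membership labels of its matched peptides are
#' permuted uniformly at random, so group sizes per gene (and hence gene
#' totals) are exactly preserved while the peptide-to-group pairing is
#' destroyed.
#'
#' @param grouping Grouping map data frame (`gene`, `peptide_id`,
#'   `membership`).
#' @param seed Integer seed; identical seeds give identical maps.
#' @return Grouping map of the same shape with permuted memberships.
#' @export
randomize_membership <- function(grouping, seed = 1) {
  set.seed(as.integer(seed))
  out <- grouping
  for (g in unique(grouping$gene)) {
    i <- which(grouping$gene == g)
    if (length(unique(grouping$membership[i])) > 1) {
      out$membership[i] <- grouping$membership[i][sample.int(length(i))]
    }
  }
  out
}

#' Variance F-test of real proteoform groups against randomized groups
#'
#' Each real group's across-patient abundance variance is compared with the
#' variance of its size-matched randomized-membership counterpart (same
#' gene, same group-size multiset), `F = var_real / var_null`, with a
#' one-sided upper-tail p from `F(n-1, n-1)` and BH correction: significant
#' groups vary more than within-gene peptide-sampling noise explains.
#'
#' @param real Matrix, groups x patients (log scale, centered).
#' @param null Matrix with identical rownames: the randomized counterpart.
#' @param alpha Significance threshold recorded in the output.
#' @return Data frame: group, var_real, var_null, F, p, p_adj, significant,
#'   flagged (zero null variance).
#' @export
variance_f_test <- function(real, null, alpha = 0.05) {
  stopifnot(setequal(rownames(real), rownames(null)))
  null <- null[rownames(real), , drop = FALSE]
  n_r <- rowSums(!is.na(real)); n_n <- rowSums(!is.na(null))
  v_r <- apply(real, 1, var, na.rm = TRUE)
  v_n <- apply(null, 1, var, na.rm = TRUE)
  flagged <- !is.finite(v_n) | v_n <= 0
  f <- ifelse(flagged, NA_real_, v_r / v_n)
  p <- ifelse(flagged, 1,
              pf(f, n_r - 1, n_n - 1, lower.tail = FALSE))
  res <- data.frame(group = rownames(real), var_real = v_r, var_null = v_n,
                    F = f, p = p, p_adj = bh_adjust(p),
                    flagged = flagged, stringsAsFactors = FALSE)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Wilcoxon rank-sum test of treated versus untreated patients per group
#'
#' Two-sided rank-sum test per proteoform group; exact when both arms have
#' at most 10 patients and no ties, normal approximation with tie and
#' continuity correction otherwise. BH correction across groups.
#'
#' @param mat Matrix, groups x patients (log abundances).
#' @param treated Patient ids of the treated (or pretreated) arm.
#' @param untreated Patient ids of the comparison arm.
#' @param alpha Significance threshold recorded in the output.
#' @return Data frame: group, W, p, p_adj, significant, delta (treated
#'   minus untreated median difference).
#' @export
wilcoxon_treatment_test <- function(mat, treated, untreated, alpha = 0.05) {
  stopifnot(length(treated) >= 1, length(untreated) >= 1,
            all(c(treated, untreated) %in% colnames(mat)))
  rows <- lapply(rownames(mat), function(g) {
    x <- mat[g, treated]; y <- mat[g, untreated]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      return(data.frame(group = g, W = NA_real_, p = NA_real_,
                        delta = NA_real_))
    }
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                       correct = !exact))
    data.frame(group = g, W = unname(wt$statistic), p = wt$p.value,
               delta = median(x) - median(y), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Correlation on average ranks; the confidence interval comes from the
#' Fisher z-transform with variance `1.06 / (n - 3)` (the standard
#' Spearman adjustment), and the two-sided p-value from the
#' t-approximation `t = rho sqrt((n-2)/(1-rho^2))`.
#'
#' @param x,y Paired numeric vectors (at least 5 complete pairs).
#' @param level Confidence level.
#' @return List with `rho`, `ci` (length-2), `p`, `n`.
#' @export
spearman_with_ci <- function(x, y, level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n = n, flagged = TRUE))
  }
  rho <- cor(rank(x), rank(y))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt(1.06 / (n - 3))
  q <- qnorm(1 - (1 - level) / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, ci = ci, p = p, n = n, flagged = FALSE)
}

#' Response correlations within patient strata
#'
#' Runs [spearman_with_ci()] between each proteoform group's abundance and
#' the response variable within three strata: all patients, the designated
#' subgroup, and its complement. Optionally restricted to groups that
#' passed the randomized-membership variance screen.
#'
#' @param mat Matrix, groups x patients.
#' @param annotations Patient annotations with `patient_id`, `subgroup`,
#'   `response`.
#' @param subgroup_label Value of `annotations$subgroup` defining the
#'   subgroup stratum.
#' @param significant_groups Optional group ids to keep (e.g. from
#'   [variance_f_test()]).
#' @param min_n Minimum patients per stratum (smaller strata are skipped
#'   with a notice).
#' @return Data frame: stratum, group, rho, ci_lo, ci_hi, p, p_adj, n.
#' @export
subgroup_analysis <- function(mat, annotations, subgroup_label = "subgroup",
                              significant_groups = NULL, min_n = 5) {
  stopifnot(all(colnames(mat) %in% annotations$patient_id))
  ann <- annotations[match(colnames(mat), annotations$patient_id), ]
  if (!is.null(significant_groups)) {
    mat <- mat[rownames(mat) %in% significant_groups, , drop = FALSE]
  }
  strata <- list(all = rep(TRUE, ncol(mat)),
                 subgroup = ann$subgroup == subgroup_label,
                 complement = ann$subgroup != subgroup_label)
  out <- list()
  for (st in names(strata)) {
    sel <- strata[[st]]
    if (sum(sel) < min_n) {
      message(sprintf("subgroup_analysis: stratum '%s' below n=%d, skipped",
                      st, min_n))
      next
    }
    resp <- ann$response[sel]
    rows <- lapply(rownames(mat), function(g) {
      sc <- spearman_with_ci(mat[g, sel], resp)
      data.frame(stratum = st, group = g, rho = sc$rho, ci_lo = sc$ci[1],
                 ci_hi = sc$ci[2], p = sc$p, n = sc$n,
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    block$p_adj <- bh_adjust(block$p)
    out[[st]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
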