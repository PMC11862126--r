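#' Summarize PSM-level rows to peptides by summation
#'
#' Reporter intensities of PSMs belonging to the same (peptide, sample, set)
#' are summed channel by channel. Missing values are treated as absent: the
#' sum runs over the present values, and a channel missing in every PSM of a
#' group stays missing.
#'
#' @param pq A [peptide_quant()] object with PSM-level rows.
#' @return A [peptide_quant()] object with one row per (peptide, sample).
#' @export
summarize_psm_to_peptides <- function(pq) {
  stopifnot(inherits(pq, "peptide_quant"))
  key <- paste(pq$meta$peptide_id, pq$meta$sample_id, pq$meta$set_id,
               sep = "\r")
  idx <- split(seq_len(nrow(pq$meta)), key)
  first <- vapply(idx, `[[`, 1L, 1L)
  ints <- matrix(NA_real_, length(idx), length(pq$grid))
  for (i in seq_along(idx)) {
    block <- pq$intensities[idx[[i]], , drop = FALSE]
    present <- colSums(!is.na(block)) > 0
    s <- colSums(block, na.rm = TRUE)
    s[!present] <- NA_real_
    ints[i, ] <- s
  }
  meta <- pq$meta[first, setdiff(names(pq$meta), c("psm_id", "sample_id")),
                  drop = FALSE]
  rownames(meta) <- NULL
  peptide_quant(meta, ints, pq$grid, gene_delim = pq$gene_delim)
}

#' Variance-stabilizing normalization by robust arsinh calibration
#'
#' Fits, per sample (column), an affine calibration followed by the
#' inverse-hyperbolic-sine transform, `h_s(x) = arsinh(a_s + b_s x)`, so
#' that transformed feature values agree across samples and the variance of
#' transformed values is approximately constant across intensity strata
#' (arsinh behaves like a log at high intensity and stays defined near
#' zero, where additive noise dominates). The calibration is estimated by
#' iteratively minimizing, per sample, a trimmed Gaussian negative
#' log-likelihood of the transformed values around the across-sample mean
#' profile, including the transformation's log-Jacobian term (without it a
#' common affine drift of all samples is unidentifiable and distorts
#' low-intensity curves). The fit is deterministic, and invariant to
#' positive rescaling of any column (each column is pre-scaled by its
#' median before fitting, so proportional columns are literally identical
#' to the fitter).
#'
#' @param mat Numeric matrix, features x samples, non-negative, `NA`
#'   allowed.
#' @param trim_fraction Fraction of features with the largest residuals
#'   excluded from each calibration fit (default 0.1).
#' @param max_iter Maximum outer iterations.
#' @param tol Convergence tolerance on the transformed values.
#' @return Matrix of transformed values (generalized-log scale) with
#'   attribute `"calibration"`: a data frame of per-sample offset `a`,
#'   coefficient `b`, and the pre-scaling factor.
#' @export
vsn_normalize <- function(mat, trim_fraction = 0.1, max_iter = 20,
                          tol = 1e-9) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensities not allowed")
  all_missing <- colSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    stop("sample(s) with no observed values: column ",
         which(all_missing)[1])
  }
  prescale <- apply(mat, 2, function(x) {
    m <- median(x[!is.na(x) & x > 0])
    if (!is.finite(m) || m <= 0) m <- mean(x, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) m <- 1
    m
  })
  y <- sweep(mat, 2, prescale, "/")
  ns <- ncol(y)
  # stage 1: common offset and scale, fitted jointly on the whole matrix
  # (the shared calibration component is identifiable only through the
  # Jacobian term, and only in a joint fit)
  obj0 <- function(p) {
    u <- p[1] + exp(p[2]) * y
    h0 <- asinh(u)
    r2 <- sum((h0 - rowMeans(h0, na.rm = TRUE))^2, na.rm = TRUE)
    0.5 * sum(!is.na(y)) * log(r2 + 1e-12) +
      sum(0.5 * log1p(u^2) - p[2], na.rm = TRUE)
  }
  fit0 <- nlminb(c(0, 0), obj0, lower = c(0, -Inf),
                 control = list(rel.tol = 1e-12, iter.max = 200))
  a <- rep(fit0$par[1], ns); lb <- rep(fit0$par[2], ns)
  h <- asinh(sweep(y, 2, exp(lb), "*") + rep(a, each = nrow(y)))
  for (iter in seq_len(max_iter)) {
    m <- rowMeans(h, na.rm = TRUE)
    h_new <- h
    for (s in seq_len(ns)) {
      obs <- which(!is.na(y[, s]) & !is.na(m))
      ys <- y[obs, s]; ms <- m[obs]
      res <- abs(asinh(a[s] + exp(lb[s]) * ys) - ms)
      if (trim_fraction > 0 && length(obs) > 10) {
        n_keep <- max(10, ceiling((1 - trim_fraction) * length(obs)))
        keep_i <- order(res)[seq_len(n_keep)]
        ys <- ys[keep_i]; ms <- ms[keep_i]
      }
      # trimmed profile negative log-likelihood: the residual variance is
      # profiled out and the arsinh-affine log-Jacobian keeps the
      # calibration identifiable.  Only the per-sample scale is refined;
      # the offset stays shared across samples -- a free per-sample offset
      # is barely identifiable once intensities reach the log regime, and
      # its column-to-column wander would distort low-intensity curves
      fit <- nlminb(lb[s], function(p) {
        u <- a[s] + exp(p) * ys
        r2 <- sum((asinh(u) - ms)^2)
        0.5 * length(ys) * log(r2 + 1e-12) +
          sum(0.5 * log1p(u^2) - p)
      }, control = list(rel.tol = 1e-14, iter.max = 200))
      lb[s] <- fit$par[1]
      h_new[, s] <- asinh(a[s] + exp(lb[s]) * y[, s])
    }
    delta <- max(abs(h_new - h), na.rm = TRUE)
    h <- h_new
    if (delta < tol) break
  }
  dimnames(h) <- dimnames(mat)
  attr(h, "calibration") <- data.frame(
    sample = colnames(mat) %||% as.character(seq_len(ns)),
    a = a, b = exp(lb) / prescale, prescale = prescale)
  h
}

#' Convert normalized melt curves to fold changes against the reference
#'
#' Values are taken back to the calibrated intensity (ratio) scale and each
#' curve is divided by its value at the reference (lowest) temperature, so
#' every retained curve is exactly 1 at the reference channel. When
#' back-transforming from the generalized-log scale the calibration offset
#' is subtracted, so fold changes are ratios of purely scale-calibrated
#' intensities (the offset belongs to the variance-stabilized scale, not to
#' the ratio scale, where it would distort low-abundance curves). Curves
#' whose reference value is missing or not positive cannot be expressed as
#' a fraction of the reference and are dropped (all-`NA` row) with a
#' warning.
#'
#' @param x Numeric matrix, one row per curve, one column per temperature
#'   channel (grid order).
#' @param grid A [temperature_grid()].
#' @param back_transform If `TRUE`, apply `sinh` first (input on the
#'   generalized-log scale of [vsn_normalize()]).
#' @param offset Calibration offset(s) subtracted after back-transform
#'   (scalar or one per channel column).
#' @return Matrix of fold changes, same shape as `x`.
#' @export
to_fold_changes <- function(x, grid, back_transform = FALSE, offset = 0) {
  stopifnot(is.matrix(x), ncol(x) == length(grid))
  v <- if (back_transform) sweep(sinh(x), 2, offset, "-") else x
  ref <- v[, grid$reference_index]
  bad <- is.na(ref) | ref <= 0
  out <- v / ref
  if (any(bad)) {
    out[bad, ] <- NA_real_
    warning(sprintf("%d curve(s) dropped: missing or non-positive reference",
                    sum(bad)))
  }
  out
}

# wide layout: rows = peptides, columns = (sample, channel)
peptide_wide <- function(pq) {
  meta <- pq$meta
  samples <- sort(unique(meta$sample_id))
  peptides <- meta[!duplicated(meta$peptide_id),
                   c("peptide_id", "sequence", "genes"), drop = FALSE]
  rownames(peptides) <- NULL
  k <- length(pq$grid)
  layout <- data.frame(
    sample_id = rep(samples, each = k),
    channel = rep(seq_len(k), length(samples)))
  wide <- matrix(NA_real_, nrow(peptides), nrow(layout),
                 dimnames = list(peptides$peptide_id, NULL))
  row_i <- match(meta$peptide_id, peptides$peptide_id)
  col_0 <- (match(meta$sample_id, samples) - 1L) * k
  for (r in seq_len(nrow(meta))) {
    wide[row_i[r], col_0[r] + seq_len(k)] <- pq$intensities[r, ]
  }
  list(mat = wide, peptides = peptides, layout = layout, samples = samples)
}

# calibrate a wide (feature x (sample, channel)) matrix per sample: the
# columns handed to the variance-stabilizing fit are whole samples (one
# TMT set = one melt curve), with the ten channels of a sample stacked as
# rows.  Calibrating per channel instead would equalize every channel's
# intensity distribution and erase the global melt trend that the curves
# are supposed to carry.  Returns the matrix on the offset-free calibrated
# intensity scale.
calibrate_by_sample <- function(wide, n_samples, k, trim_fraction) {
  n_feat <- nrow(wide)
  stacked <- matrix(NA_real_, n_feat * k, n_samples)
  for (s in seq_len(n_samples)) {
    stacked[, s] <- as.vector(wide[, (s - 1L) * k + seq_len(k)])
  }
  h <- vsn_normalize(stacked, trim_fraction = trim_fraction)
  v <- sweep(sinh(h), 2, attr(h, "calibration")$a, "-")
  out <- wide * NA_real_
  for (s in seq_len(n_samples)) {
    out[, (s - 1L) * k + seq_len(k)] <- v[, s]
  }
  out
}

#' Build relative melt profiles from raw peptide intensities
#'
#' Runs the peptide-level preprocessing chain: arrange intensities as a
#' peptides x (sample, temperature-channel) matrix, calibrate per sample
#' with the variance-stabilizing model ([vsn_normalize()]; one melt-curve
#' set is one calibrated column, so the within-set melt trend is
#' preserved), and form per-sample fold changes relative to the lowest
#' temperature ([to_fold_changes()]). Because the calibration is per set,
#' it cancels exactly in the fold-change ratio: melt profiles are invariant
#' to per-set loading differences by construction.
#'
#' @param pq A [peptide_quant()] object (peptide-level).
#' @param trim_fraction Passed to [vsn_normalize()].
#' @return Object of class `"melt_profiles"`: list with `fold` (matrix,
#'   peptides x concatenated sample blocks), `peptides`, `layout`,
#'   `samples`, and `grid`.
#' @export
melt_profiles <- function(pq, trim_fraction = 0.1) {
  stopifnot(inherits(pq, "peptide_quant"))
  w <- peptide_wide(pq)
  k <- length(pq$grid)
  v <- calibrate_by_sample(w$mat, length(w$samples), k, trim_fraction)
  fold <- w$mat * NA_real_
  dropped <- 0L
  for (s in seq_along(w$samples)) {
    cols <- (s - 1L) * k + seq_len(k)
    fc <- withCallingHandlers(
      to_fold_changes(v[, cols, drop = FALSE], pq$grid),
      warning = function(wn) {
        dropped <<- dropped + as.integer(sub("^(\\d+) .*$", "\\1",
                                             conditionMessage(wn)))
        invokeRestart("muffleWarning")
      })
    fold[, cols] <- fc
  }
  if (dropped > 0) {
    message(sprintf("melt_profiles: dropped %d curve(s) without usable reference",
                    dropped))
  }
  structure(list(fold = fold, peptides = w$peptides, layout = w$layout,
                 samples = w$samples, grid = pq$grid),
            class = "melt_profiles")
}

#' @export
print.melt_profiles <- function(x, ...) {
  cat(sprintf("melt_profiles: %d peptides x %d samples x %d temperatures\n",
              nrow(x$fold), length(x$samples), length(x$grid)))
  invisible(x)
}
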