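sigmoid_ml <- function(temperature, pl, a, b) {
  (1 - pl) / (1 + exp(b - a / temperature)) + pl
}

#' Fit a sigmoidal melting model to (temperature, fraction) data
#'
#' Fits the three-parameter melting sigmoid
#' `f(T) = (1 - pl) / (1 + exp(b - a/T)) + pl` (plateau `pl`, scale `a`,
#' shift `b`; the reciprocal-temperature exponent is the classic melt-curve
#' form). Residuals are taken on the log scale, which is maximum
#' likelihood under the multiplicative reporter-noise model and keeps the
#' residual variance comparable along the curve and across groups (a
#' prerequisite for the pooled effective-degrees-of-freedom estimate).
#' A small multi-start grid over plausible melting points and steepnesses
#' guards against local minima; the best residual sum of squares wins.
#'
#' @param temperature Numeric vector of temperatures (degrees C).
#' @param y Fractions non-denatured (fold-change scale, positive).
#' @param starts Optional data frame of starting values with columns
#'   `pl`, `a`, `b` (overrides the built-in grid).
#' @return Object of class `"sigmoid_fit"`: list with `params`
#'   (pl, a, b), `rss` (log-scale residual sum of squares), `n_points`,
#'   `converged`, `degenerate`.
#' @export
fit_melt_model <- function(temperature, y, starts = NULL) {
  ok <- !is.na(temperature) & !is.na(y)
  temperature <- temperature[ok]; y <- y[ok]
  if (length(y) < 5) stop("need at least 5 points")
  if (sd(y) == 0) {
    return(structure(list(params = c(pl = y[1], a = 1, b = 0), rss = 0,
                          n_points = length(y), converged = TRUE,
                          degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  if (is.null(starts)) {
    pl0 <- min(max(min(y), 0), 0.95)
    mid <- (1 + pl0) / 2
    tm0 <- temperature[which.min(abs(y - mid))]
    tms <- unique(c(tm0, quantile(temperature, c(0.35, 0.65), names = FALSE)))
    slopes <- c(0.25, 0.6)
    starts <- expand.grid(tm = tms, s = slopes)
    starts <- data.frame(pl = pl0, a = starts$s * starts$tm^2,
                         b = starts$s * starts$tm)
  }
  best <- NULL
  dat <- data.frame(Tk = temperature, ly = log(pmax(y, 1e-8)))
  for (i in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      ly ~ log((1 - pl) / (1 + exp(b - a / Tk)) + pl), data = dat,
      start = list(pl = max(starts$pl[i], 1e-6), a = starts$a[i],
                   b = starts$b[i]),
      lower = c(pl = 1e-8, a = 1e-6, b = -Inf),
      upper = c(pl = 0.9999, a = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-14,
                                           ptol = 1e-12))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(params = coef(fit), rss = rss,
                   converged = fit$convInfo$isConv %||% TRUE)
    }
  }
  if (is.null(best)) {
    # fall back to direct RSS minimization
    obj <- function(p) {
      sum((dat$ly - log(pmax(sigmoid_ml(temperature,
                                        min(max(p[1], 1e-8), 0.9999),
                                        exp(p[2]), p[3]), 1e-8)))^2)
    }
    o <- optim(c(0.1, log(1000), 25), obj)
    best <- list(params = c(pl = min(max(o$par[1], 1e-8), 0.9999),
                            a = exp(o$par[2]), b = o$par[3]),
                 rss = o$value, converged = o$convergence == 0)
  }
  structure(list(params = setNames(as.numeric(best$params),
                                   c("pl", "a", "b")),
                 rss = best$rss, n_points = length(y),
                 converged = isTRUE(best$converged), degenerate = FALSE),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("sigmoid melt fit: pl=%.3f a=%.1f b=%.2f, RSS=%.4g on %d points%s\n",
              x$params["pl"], x$params["a"], x$params["b"], x$rss,
              x$n_points,
              if (x$degenerate) " (degenerate)" else if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' @export
predict.sigmoid_fit <- function(object, temperature, ...) {
  sigmoid_ml(temperature, object$params["pl"], object$params["a"],
             object$params["b"])
}

#' NPARC residual decomposition for one proteoform group
#'
#' Fits a null model (one melting sigmoid pooled over all conditions) and an
#' alternative model (independent condition-specific sigmoids) and returns
#' the two residual sums of squares. The F statistic and p-value are
#' computed afterwards, once effective degrees of freedom are available
#' (see [nparc()] and [estimate_effective_dof()]).
#'
#' @param temperature Temperatures of every observation.
#' @param y Fractions non-denatured.
#' @param condition Condition label per observation (2 or more levels).
#' @return List with `rss0`, `rss1`, `n`, `n_conditions`, `n_par` (3) and
#'   nominal degrees of freedom `d1_nominal`, `d2_nominal`.
#' @export
nparc_rss <- function(temperature, y, condition) {
  condition <- as.character(condition)
  levels <- unique(condition)
  if (length(levels) < 2) stop("need at least 2 conditions")
  fit0 <- fit_melt_model(temperature, y)
  # the pooled solution seeds each condition fit, so the alternative model
  # genuinely nests the null instead of occasionally losing to it through
  # a worse local optimum
  extra_start <- data.frame(pl = fit0$params["pl"], a = fit0$params["a"],
                            b = fit0$params["b"])
  rss1 <- 0
  for (lv in levels) {
    sel <- condition == lv
    f1 <- fit_melt_model(temperature[sel], y[sel])
    f1b <- fit_melt_model(temperature[sel], y[sel], starts = extra_start)
    rss1 <- rss1 + min(f1$rss, f1b$rss)
  }
  # the alternative model nests the null; clamp tiny numerical excess
  rss1 <- min(rss1, fit0$rss)
  n <- length(y); npar <- 3L
  list(rss0 = fit0$rss, rss1 = rss1, n = n, n_conditions = length(levels),
       n_par = npar, d1_nominal = npar * (length(levels) - 1L),
       d2_nominal = n - npar * length(levels))
}

#' F statistic and p-value from NPARC residual sums of squares
#'
#' `F = ((RSS0 - RSS1)/d1) / (RSS1/d2)` with upper-tail p from the
#' F(d1, d2) distribution. Negative numerical differences are clamped to
#' `F = 0`; `RSS1 = 0` with `RSS0 > 0` gives the `p = 0` limit.
#'
#' @param rss0,rss1 Residual sums of squares of null and alternative model.
#' @param d1,d2 (Effective) degrees of freedom.
#' @return List with `F` and `p`.
#' @export
nparc_f_stat <- function(rss0, rss1, d1, d2) {
  stopifnot(d1 > 0, d2 > 0)
  if (rss1 <= 0) {
    if (rss0 > 0) return(list(F = Inf, p = 0))
    return(list(F = 0, p = 1))
  }
  f <- max(0, ((rss0 - rss1) / d1) / (rss1 / d2))
  list(F = f, p = pf(f, d1, d2, lower.tail = FALSE))
}

#' Effective degrees of freedom by scaled chi-square moment matching
#'
#' Models each group's `RSS0 - RSS1` and `RSS1` as independent chi-squares
#' scaled by a group-specific noise level, so their ratio is free of that
#' scale: `B = (RSS0 - RSS1) / RSS0` follows `Beta(d1/2, d2/2)`. The
#' degrees of freedom are recovered by matching the empirical `B`
#' distribution to the Beta family: a first-two-moments estimate refined
#' by minimizing the Anderson-Darling distance, which keeps both tails of
#' the implied p-value distribution calibrated (matching moments per RSS
#' component instead is confounded whenever noise levels differ between
#' groups -- the ratio absorbs the scale exactly). The estimate is
#' invariant to rescaling all RSS values. With fewer than `min_groups`
#' groups, or degenerate moments, the nominal counting degrees of freedom
#' are returned with a notice.
#'
#' @param delta Vector of `RSS0 - RSS1` across groups.
#' @param rss1 Vector of `RSS1` across groups.
#' @param nominal_d1,nominal_d2 Fallback counting degrees of freedom.
#' @param min_groups Minimum number of groups for moment estimation.
#' @return List with `d1`, `d2`, `method` (`"moments"` or `"nominal"`).
#' @export
estimate_effective_dof <- function(delta, rss1, nominal_d1 = 3,
                                   nominal_d2 = NULL, min_groups = 50) {
  ok <- is.finite(delta) & is.finite(rss1) & (delta + rss1) > 0
  delta <- pmax(delta[ok], 0); rss1 <- rss1[ok]
  fallback <- function() {
    message("estimate_effective_dof: too few groups or degenerate moments; ",
            "using nominal counting degrees of freedom")
    list(d1 = nominal_d1, d2 = nominal_d2 %||% nominal_d1,
         method = "nominal")
  }
  if (length(delta) < min_groups) return(fallback())
  b <- delta / (delta + rss1)
  m <- mean(b); v <- var(b)
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1) return(fallback())
  s <- 2 * (m * (1 - m) / v - 1)
  if (!is.finite(s) || s <= 0) s <- 2 / max(v, 1e-6)
  bs <- sort(pmin(pmax(b, 1e-14), 1 - 1e-14))
  fit_ad <- function(x, start) {
    n <- length(x); i <- seq_len(n)
    dist_fn <- function(par) {
      u <- pbeta(x, exp(par[1]), exp(par[2]))
      u <- pmin(pmax(u, 1e-14), 1 - 1e-14)
      -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
    }
    try(optim(start, dist_fn), silent = TRUE)
  }
  # a real screen contains true positives whose large B values would drag
  # the null fit.  Anchor the start on the bulk (median and lower quartile
  # are insensitive to an upper-tail fraction of true positives), then
  # iterate: exclude B beyond the fitted 99.9th percentile, refit by
  # Anderson-Darling distance on what remains.
  qs <- quantile(bs, c(0.25, 0.5), names = FALSE)
  qobj <- function(par) {
    (qbeta(0.5, exp(par[1]), exp(par[2])) - qs[2])^2 +
      (qbeta(0.25, exp(par[1]), exp(par[2])) - qs[1])^2
  }
  o <- try(optim(log(c(max(m * s / 2, 1e-3), max((1 - m) * s / 2, 1e-3))),
                 qobj), silent = TRUE)
  if (inherits(o, "try-error") || !is.finite(o$value)) return(fallback())
  for (iter in 1:3) {
    thr <- qbeta(0.999, exp(o$par[1]), exp(o$par[2]))
    keep <- bs <= thr
    if (sum(keep) < min_groups) break
    o2 <- fit_ad(bs[keep], o$par)
    if (inherits(o2, "try-error") || !is.finite(o2$value)) break
    o <- o2
  }
  d1 <- 2 * exp(o$par[1]); d2 <- 2 * exp(o$par[2])
  if (!is.finite(d1) || !is.finite(d2) || d1 <= 0 || d2 <= 0) {
    return(fallback())
  }
  list(d1 = d1, d2 = d2, method = "moments")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Keep proteoform groups with full melting curves in every design cell
#'
#' A group enters a comparison only if, for every expected
#' (cell line, condition, replicate) cell among the chosen samples, its
#' curve is complete over all temperature channels. Restricting `samples`
#' to one cell line makes a group detected only there eligible for that
#' lineage's comparison while it stays excluded from the all-sample model.
#'
#' @param gc A [summarize_groups()] result.
#' @param samples Sample ids defining the comparison (default: all).
#' @return Character vector of retained group ids.
#' @export
filter_complete_curves <- function(gc, samples = NULL) {
  stopifnot(inherits(gc, "group_curves"))
  samples <- samples %||% gc$samples
  k <- length(gc$grid)
  keep <- vapply(seq_len(nrow(gc$curves)), function(gi) {
    all(vapply(samples, function(sid) {
      s <- match(sid, gc$samples)
      cols <- (s - 1L) * k + seq_len(k)
      !anyNA(gc$curves[gi, cols])
    }, TRUE))
  }, TRUE)
  rownames(gc$curves)[keep]
}

#' NPARC differential-melting screen over proteoform groups
#'
#' For each proteoform group with full duplicated melting curves in the
#' scope, fits the pooled (null) and condition-specific (alternative)
#' melting sigmoids, then converts the residual improvement into an
#' F statistic using effective degrees of freedom estimated from the
#' across-group RSS distributions, with Benjamini-Hochberg correction.
#' Group results with adjusted p below `alpha` are conventionally read as
#' likely thermally impacted; raw p below `alpha` as plausibly impacted.
#'
#' @param gc A [summarize_groups()] result (or compatible `group_curves`).
#' @param scope Label for the comparison (e.g. `"all"` or a cell line).
#' @param samples Sample ids included (default all).
#' @param dof `"effective"` (default) or `"nominal"`.
#' @param min_groups Minimum groups for effective-dof estimation.
#' @param alpha Significance level recorded in the result attributes.
#' @return Data frame of class `"nparc_result"`: group, gene, scope, rss0,
#'   rss1, d1, d2, F, p, p_adj.
#' @export
nparc <- function(gc, scope = "all", samples = NULL,
                  dof = c("effective", "nominal"), min_groups = 50,
                  alpha = 0.05) {
  dof <- match.arg(dof)
  stopifnot(inherits(gc, "group_curves"))
  samples <- samples %||% gc$samples
  k <- length(gc$grid)
  retained <- filter_complete_curves(gc, samples)
  if (!length(retained)) stop("no group passes the complete-curve filter")
  sm <- gc$sample_meta[match(samples, gc$sample_meta$sample_id), ]
  rows <- lapply(retained, function(gid) {
    gi <- match(gid, rownames(gc$curves))
    y <- numeric(0); tt <- numeric(0); cond <- character(0)
    for (s in seq_along(samples)) {
      cols <- (match(samples[s], gc$samples) - 1L) * k + seq_len(k)
      y <- c(y, gc$curves[gi, cols])
      tt <- c(tt, gc$grid$temperatures)
      cond <- c(cond, rep(sm$condition[s], k))
    }
    r <- nparc_rss(tt, y, cond)
    data.frame(group = gid, rss0 = r$rss0, rss1 = r$rss1, n = r$n,
               d1_nominal = r$d1_nominal, d2_nominal = r$d2_nominal,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$gene <- gc$groups$gene[match(res$group, gc$groups$membership)]
  if (dof == "effective") {
    ed <- estimate_effective_dof(res$rss0 - res$rss1, res$rss1,
                                 nominal_d1 = res$d1_nominal[1],
                                 nominal_d2 = median(res$d2_nominal),
                                 min_groups = min_groups)
  } else {
    ed <- list(d1 = res$d1_nominal[1], d2 = median(res$d2_nominal),
               method = "nominal")
  }
  fp <- mapply(function(r0, r1) unlist(nparc_f_stat(r0, r1, ed$d1, ed$d2)),
               res$rss0, res$rss1)
  res$scope <- scope
  res$d1 <- ed$d1; res$d2 <- ed$d2
  res$F <- fp["F", ]; res$p <- fp["p", ]
  res$p_adj <- bh_adjust(res$p)
  res <- res[, c("group", "gene", "scope", "rss0", "rss1", "d1", "d2",
                 "F", "p", "p_adj")]
  attr(res, "dof_method") <- ed$method
  attr(res, "alpha") <- alpha
  class(res) <- c("nparc_result", "data.frame")
  res
}

#' @export
summary.nparc_result <- function(object, alpha = attr(object, "alpha"), ...) {
  cat(sprintf("NPARC screen [%s]: %d groups, d1=%.2f d2=%.2f (%s dof)\n",
              object$scope[1], nrow(object), object$d1[1], object$d2[1],
              attr(object, "dof_method")))
  cat(sprintf("  p < %.3g (plausibly impacted): %d;  pAdj < %.3g (likely impacted): %d\n",
              alpha, sum(object$p < alpha, na.rm = TRUE),
              alpha, sum(object$p_adj < alpha, na.rm = TRUE)))
  invisible(object)
}

#' @export
print.nparc_result <- function(x, ...) {
  summary(x)
  print.data.frame(head(x[order(x$p), ], 10), digits = 4)
  invisible(x)
}

#' Four-parameter logistic fit with confidence band
#'
#' Least-squares 4PL fit (see [four_pl_curve()]) with a 95 percent
#' confidence band obtained by first-order propagation of the parameter
#' covariance, plus per-temperature mean and standard deviation of the
#' observations, as used for reporting proteoform-group melt curves.
#'
#' @param temperature Temperatures of all observations.
#' @param y Observed fractions non-denatured.
#' @param band_at Temperatures at which to evaluate the band (default: a
#'   fine grid over the observed range).
#' @param level Confidence level.
#' @return Object of class `"four_pl_fit"`: `params` (bottom, top, tm,
#'   slope), `rss`, `vcov`, `band` (data frame temperature/fit/lwr/upr, or
#'   `NULL` with `singular = TRUE`), `point_stats`, `converged`.
#' @export
fit_4pl <- function(temperature, y, band_at = NULL, level = 0.95) {
  ok <- !is.na(temperature) & !is.na(y)
  temperature <- temperature[ok]; y <- y[ok]
  if (length(unique(temperature)) < 5) stop("need at least 5 distinct temperatures")
  dat <- data.frame(Tk = temperature, y = y)
  tms <- quantile(temperature, c(0.3, 0.5, 0.7), names = FALSE)
  starts <- expand.grid(tm = tms, slope = c(0.2, 0.5, 1.0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(slope * (Tk - tm))),
      data = dat,
      start = list(bottom = max(min(y), 0), top = max(y),
                   tm = starts$tm[i], slope = starts$slope[i]),
      lower = c(bottom = -Inf, top = -Inf, tm = min(temperature) - 30,
                slope = 1e-4),
      upper = c(bottom = Inf, top = Inf, tm = max(temperature) + 30,
                slope = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("4PL fit failed from every start")
  pars <- coef(best$fit)
  n <- length(y)
  grad_4pl <- function(tt) {
    e <- exp(pars["slope"] * (tt - pars["tm"]))
    u <- 1 / (1 + e)
    cbind(bottom = 1 - u, top = u,
          tm = (pars["top"] - pars["bottom"]) * u^2 * e * pars["slope"],
          slope = -(pars["top"] - pars["bottom"]) * u^2 * e * (tt - pars["tm"]))
  }
  vc <- try(vcov(best$fit), silent = TRUE)
  singular <- inherits(vc, "try-error") || anyNA(vc)
  band <- NULL
  if (!singular) {
    band_at <- band_at %||% seq(min(temperature), max(temperature),
                                length.out = 100)
    J <- grad_4pl(band_at)
    se <- sqrt(pmax(rowSums((J %*% vc) * J), 0))
    fitv <- four_pl_curve(band_at, pars[["bottom"]], pars[["top"]],
                          pars[["tm"]], pars[["slope"]])
    q <- qt(1 - (1 - level) / 2, df = max(n - 4, 1))
    band <- data.frame(temperature = band_at, fit = fitv,
                       lwr = fitv - q * se, upr = fitv + q * se)
  }
  ts <- sort(unique(temperature))
  point_stats <- data.frame(
    temperature = ts,
    mean = vapply(ts, function(t0) mean(y[temperature == t0]), 0),
    sd = vapply(ts, function(t0) sd(y[temperature == t0]), 0))
  structure(list(params = setNames(as.numeric(pars),
                                   c("bottom", "top", "tm", "slope")),
                 rss = best$rss, vcov = if (singular) NULL else vc,
                 band = band, point_stats = point_stats, n = n,
                 level = level, singular = singular,
                 converged = isTRUE(best$fit$convInfo$isConv %||% TRUE)),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: Tm=%.2f degC, slope=%.3f, plateaus [%.3f, %.3f], RSS=%.4g (n=%d)%s\n",
              x$params["tm"], x$params["slope"], x$params["bottom"],
              x$params["top"], x$rss, x$n,
              if (x$singular) " [singular covariance, no band]" else ""))
  invisible(x)
}

#' @export
predict.four_pl_fit <- function(object, temperature, ...) {
  p <- object$params
  four_pl_curve(temperature, p[["bottom"]], p[["top"]], p[["tm"]],
                p[["slope"]])
}

#' Plot a fitted 4PL melt curve with its confidence band
#' @param x A [fit_4pl()] result.
#' @param ... Passed to [plot()].
#' @export
plot.four_pl_fit <- function(x, ...) {
  ps <- x$point_stats
  ylim <- range(c(ps$mean - ps$sd, ps$mean + ps$sd, x$band$lwr, x$band$upr),
                na.rm = TRUE)
  plot(ps$temperature, ps$mean, ylim = ylim,
       xlab = "Temperature (degC)", ylab = "Fraction non-denatured",
       pch = 19, ...)
  segments(ps$temperature, ps$mean - ps$sd, ps$temperature, ps$mean + ps$sd)
  if (!is.null(x$band)) {
    polygon(c(x$band$temperature, rev(x$band$temperature)),
            c(x$band$lwr, rev(x$band$upr)),
            col = adjustcolor("steelblue", 0.3), border = NA)
    lines(x$band$temperature, x$band$fit, col = "steelblue", lwd = 2)
  }
  invisible(x)
}
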