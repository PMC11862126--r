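# Shared fixtures and independent oracles used across test files.

# small peptide table written to a temporary TSV
write_toy_peptide_tsv <- function(path, n_channels = 10, genes = NULL,
                                  negative_at = NULL) {
  channels <- sprintf("channel_%02d", seq_len(n_channels))
  rows <- data.frame(
    peptide_id = c("pep1", "pep2", "pep3"),
    sequence = c("AAGCLAAK", "GSLYTR", "LLLK"),
    genes = genes %||% c("BTK", "BTK;TEC", "TEC"),
    cell_line = "RCHACV", condition = "vehicle", replicate = 1L,
    set_id = "S1", stringsAsFactors = FALSE)
  ints <- matrix(seq_len(3 * n_channels) * 10, nrow = 3)
  if (!is.null(negative_at)) ints[negative_at[1], negative_at[2]] <- -5
  colnames(ints) <- channels
  utils::write.table(cbind(rows, ints), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force BH step-up straight from the definition
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    adj[ord[i]] <- min(1, min((m / js) * p[ord[js]]))
  }
  adj
}

# exhaustive hypergeometric upper tail by enumerating all draws with combn
hyper_tail_enumerate <- function(n_universe, set_size, n_draws, overlap) {
  draws <- utils::combn(n_universe, n_draws)
  in_set <- draws <= set_size  # wlog the set occupies the first slots
  mean(colSums(in_set) >= overlap)
}

# exhaustive two-sample rank-sum p-value by enumerating label assignments
wilcox_enumerate <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  obs <- sum(rank(pooled)[seq_len(nx)])
  stats <- apply(utils::combn(n, nx), 2, function(idx) {
    sum(rank(pooled)[idx])
  })
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# exhaustive maximum-modularity partition for small weighted graphs;
# enumerates all set partitions (restricted growth strings)
best_partition_modularity <- function(adj) {
  n <- nrow(adj)
  W <- sum(adj) / 2
  strength <- rowSums(adj)
  mod_of <- function(labels) {
    q <- 0
    for (c in unique(labels)) {
      v <- labels == c
      q <- q + sum(adj[v, v]) / (2 * W) - (sum(strength[v]) / (2 * W))^2
    }
    q
  }
  best <- -Inf; best_labels <- NULL
  labels <- integer(n)
  recurse <- function(i, maxlab) {
    for (lab in seq_len(maxlab + 1)) {
      labels[i] <<- lab
      if (i == n) {
        q <- mod_of(labels)
        if (q > best) { best <<- q; best_labels <<- labels }
      } else {
        recurse(i + 1, max(maxlab, lab))
      }
    }
  }
  recurse(1, 0)
  list(modularity = best, labels = best_labels)
}

# ARI with the convention that two trivial (single-cluster) partitions agree
ari_safe <- function(a, b) {
  r <- mclust::adjustedRandIndex(a, b)
  if (is.nan(r)) 1 else r
}

# simulated NPARC group curves on the fold-change scale: duplicate design,
# multiplicative log-normal noise around condition-specific sigmoids
simulate_nparc_group <- function(temps, noise_sd = 0.03, shift = 0,
                                 replicates = 2) {
  bottom <- runif(1, 0.02, 0.12)
  tm <- runif(1, 46, 58)
  sl <- runif(1, 0.35, 0.7)
  y <- c(); tt <- c(); cond <- c()
  for (cd in c("vehicle", "drug")) {
    tmx <- tm + if (cd == "drug") shift else 0
    for (r in seq_len(replicates)) {
      f <- four_pl_curve(temps, bottom, 1, tmx, sl)
      if (noise_sd > 0) f <- f * exp(rnorm(length(temps), 0, noise_sd))
      y <- c(y, f)
      tt <- c(tt, temps)
      cond <- c(cond, rep(cd, length(temps)))
    }
  }
  list(temperature = tt, y = y, condition = cond, tm = tm)
}
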