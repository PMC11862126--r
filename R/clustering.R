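#' Weighted Euclidean distance between two melt profiles
#'
#' Computed over the positions where both profiles are observed, with the
#' supplied weights taken as-is (construct them normalized to mean 1, as
#' [build_gene_graph()] does, to keep distances comparable across genes).
#' Pairs sharing fewer than 3 positions are undefined (`NA`, no edge).
#'
#' @param a,b Numeric vectors (concatenated fold-change profiles across all
#'   samples), equal length, `NA` allowed.
#' @param weights Optional non-negative per-position weights (default
#'   uniform).
#' @return `sqrt(sum(w_i (a_i - b_i)^2))` over shared positions, or `NA` if
#'   fewer than 3 positions are shared.
#' @export
melt_distance <- function(a, b, weights = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(weights)) weights <- rep(1, length(a))
  stopifnot(length(weights) == length(a), all(weights >= 0, na.rm = TRUE))
  shared <- which(!is.na(a) & !is.na(b) & !is.na(weights))
  if (length(shared) < 3) return(NA_real_)
  sqrt(sum(weights[shared] * (a[shared] - b[shared])^2))
}

#' Gaussian similarity kernel on melt-profile distances
#'
#' @param d Non-negative distance(s).
#' @param bandwidth Kernel bandwidth `h > 0`.
#' @return `exp(-d^2 / (2 h^2))`, in `(0, 1]`; 1 at `d = 0`, strictly
#'   decreasing in `d`.
#' @export
similarity_from_distance <- function(d, bandwidth) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
    stop("`bandwidth` must be a positive scalar")
  }
  stopifnot(all(d >= 0, na.rm = TRUE))
  exp(-d^2 / (2 * bandwidth^2))
}

# per-position weights: inversely proportional to the cross-peptide
# variance at each (sample, temperature) position within the gene, which
# down-weights noisy high-temperature tails; floor keeps weights finite
position_weights <- function(mat, scheme = c("inverse_variance", "uniform")) {
  scheme <- match.arg(scheme)
  if (scheme == "uniform") return(rep(1, ncol(mat)))
  v <- apply(mat, 2, var, na.rm = TRUE)
  v[!is.finite(v)] <- NA
  floor_v <- 0.01 * median(v, na.rm = TRUE)
  if (!is.finite(floor_v) || floor_v <= 0) return(rep(1, ncol(mat)))
  w <- 1 / (v + floor_v)
  w[is.na(w)] <- 0
  w / mean(w[w > 0])
}

#' Build the complete peptide similarity graph of one gene
#'
#' Vertices are the gene's peptides; every pair is connected with a weight
#' obtained by passing the weighted Euclidean distance between their
#' concatenated fold-change profiles through a Gaussian kernel whose
#' bandwidth is the gene's median pairwise distance.
#'
#' @param profiles Numeric matrix, peptides x concatenated (sample,
#'   temperature) positions; rownames are peptide ids.
#' @param weight_scheme `"inverse_variance"` (default) or `"uniform"`
#'   per-position distance weights.
#' @return Object of class `"gene_graph"`: peptide ids, distance and
#'   similarity matrices, bandwidth.
#' @export
build_gene_graph <- function(profiles,
                             weight_scheme = c("inverse_variance", "uniform")) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  w <- position_weights(profiles, match.arg(weight_scheme))
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- melt_distance(profiles[i, ], profiles[j, ], w)
    }
  }
  finite <- d[upper.tri(d)]
  finite <- finite[!is.na(finite)]
  if (!length(finite)) stop("all pairwise distances undefined")
  bw <- median(finite)
  if (bw <= 0) bw <- max(mean(finite), .Machine$double.eps)
  sim <- similarity_from_distance(d, bw)
  diag(sim) <- 0
  sim[is.na(d)] <- NA  # no edge
  structure(list(peptide_ids = rownames(profiles), dist = d, sim = sim,
                 bandwidth = bw),
            class = "gene_graph")
}

#' Leiden community detection on a gene graph
#'
#' Maximizes weighted modularity at resolution 1.0 with a seeded RNG, and
#' reports the modularity of the returned partition.
#'
#' @param graph A [build_gene_graph()] result.
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @param resolution Modularity resolution parameter.
#' @param n_iterations Leiden iterations.
#' @return List with `membership` (integer labels named by peptide id) and
#'   `modularity`.
#' @export
leiden_communities <- function(graph, seed = 1, resolution = 1,
                               n_iterations = 10) {
  stopifnot(inherits(graph, "gene_graph"))
  adj <- graph$sim
  adj[is.na(adj)] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               weights = igraph::E(g)$weight,
                               resolution = resolution,
                               n_iterations = n_iterations)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  list(membership = setNames(as.integer(memb), graph$peptide_ids),
       modularity = q)
}

#' Peptide ambiguity ratio of a gene
#'
#' Ambiguous peptides map to more than one gene symbol;
#' `r = n_ambiguous / (n_specific + n_ambiguous)`.
#'
#' @param gene_sets List of character vectors: the gene symbols each of the
#'   gene's peptides maps to.
#' @return Ratio in `[0, 1]`.
#' @export
ambiguity_ratio <- function(gene_sets) {
  stopifnot(length(gene_sets) >= 1)
  mean(lengths(gene_sets) > 1)
}

#' Default acceptance thresholds for proteoform-group assignment
#'
#' @param min_peptides Minimum peptides per gene for graph clustering.
#' @param min_per_sample Minimum peptides observed in every sample.
#' @param min_community Minimum peptides supporting an accepted community.
#' @param modularity_floor Partitions with modularity at or below this are
#'   rejected.
#' @param max_ambiguity Genes with ambiguity ratio at or above this are not
#'   split.
#' @param n_permutations Number of sample-block permutations for the
#'   modularity reproducibility gate (0 disables it). A split is accepted
#'   only if the observed modularity exceeds every permuted one, i.e. an
#'   exact permutation test at level `1 / (n_permutations + 1)`.
#' @return Named list of thresholds.
#' @export
proteoform_thresholds <- function(min_peptides = 10, min_per_sample = 2,
                                  min_community = 3,
                                  modularity_floor = 1e-13,
                                  max_ambiguity = 0.5,
                                  n_permutations = 19) {
  stopifnot(min_peptides >= 1, min_per_sample >= 1, min_community >= 1,
            max_ambiguity > 0, n_permutations >= 0)
  list(min_peptides = min_peptides, min_per_sample = min_per_sample,
       min_community = min_community, modularity_floor = modularity_floor,
       max_ambiguity = max_ambiguity, n_permutations = n_permutations)
}

# permutation null for the modularity gate: within every sample block the
# peptide rows are shuffled independently, which preserves each sample's
# profile population but destroys any peptide grouping that reproduces
# across samples -- the defining property of a real proteoform split
permute_sample_blocks <- function(mat, k) {
  n_samples <- ncol(mat) %/% k
  out <- mat
  for (s in seq_len(n_samples)) {
    cols <- (s - 1L) * k + seq_len(k)
    out[, cols] <- mat[sample.int(nrow(mat)), cols]
  }
  out
}

# order community labels: gene_1 = largest, ties by lexicographically
# smallest member peptide id
relabel_communities <- function(membership) {
  sizes <- table(membership)
  first_pep <- vapply(names(sizes), function(l) {
    min(names(membership)[membership == l])
  }, "")
  ord <- order(-as.integer(sizes), first_pep)
  new <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(as.integer(new[as.character(membership)]), names(membership))
}

#' Assign peptides to functional proteoform groups
#'
#' Per gene: peptides passing the detection gates (at least
#' `min_peptides` peptides overall and `min_per_sample` observed in every
#' sample) are clustered by Leiden community detection on the gene's
#' similarity graph. The partition is accepted only if its modularity
#' exceeds `modularity_floor` and the gene's peptide ambiguity ratio is
#' below `max_ambiguity`; communities supported by fewer than
#' `min_community` peptides are merged into the accepted community with the
#' highest mean similarity to them, so the result is always a partition.
#' Genes failing any gate keep all peptides in a single group. Groups are
#' labeled `<gene>_1, <gene>_2, ...` by decreasing size.
#'
#' @param profiles A [melt_profiles()] object.
#' @param thresholds See [proteoform_thresholds()].
#' @param seed Integer root seed (a per-gene seed is derived from it).
#' @param weight_scheme Distance weighting, see [build_gene_graph()].
#' @return Data frame of class `"proteoform_assignments"`: one row per
#'   (gene, peptide) with `membership` (`<gene>_k`), `modularity`,
#'   `ambiguity_ratio`, `accepted`, `reason`. Gate decision counts are in
#'   `attr(, "gate_counts")`.
#' @export
assign_proteoform_groups <- function(profiles,
                                     thresholds = proteoform_thresholds(),
                                     seed = 1,
                                     weight_scheme = "inverse_variance") {
  stopifnot(inherits(profiles, "melt_profiles"))
  k <- length(profiles$grid)
  n_samples <- length(profiles$samples)
  gene_sets <- split_genes(profiles$peptides$genes)
  pep_gene <- data.frame(
    peptide_id = rep(profiles$peptides$peptide_id, lengths(gene_sets)),
    gene = unlist(gene_sets, use.names = FALSE),
    ambiguous = rep(lengths(gene_sets) > 1, lengths(gene_sets)),
    stringsAsFactors = FALSE)
  genes <- sort(unique(pep_gene$gene))
  th <- thresholds
  out <- vector("list", length(genes))
  gates <- c(clustered = 0L, below_min_peptides = 0L, low_modularity = 0L,
             high_ambiguity = 0L)

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    rows <- pep_gene[pep_gene$gene == g, ]
    ridx <- match(rows$peptide_id, rownames(profiles$fold))
    mat <- profiles$fold[ridx, , drop = FALSE]
    retained <- rowSums(!is.na(mat)) > 0
    rows <- rows[retained, , drop = FALSE]
    mat <- mat[retained, , drop = FALSE]
    if (!nrow(rows)) next
    r_amb <- mean(rows$ambiguous)

    per_sample <- vapply(seq_len(n_samples), function(s) {
      cols <- (s - 1L) * k + seq_len(k)
      sum(rowSums(!is.na(mat[, cols, drop = FALSE])) > 0)
    }, 0L)
    single <- function(reason, q = NA_real_) {
      gates[reason] <<- gates[reason] + 1L
      data.frame(gene = g, peptide_id = rows$peptide_id,
                 membership = paste0(g, "_1"), modularity = q,
                 ambiguity_ratio = r_amb, accepted = reason == "clustered",
                 reason = reason, stringsAsFactors = FALSE)
    }
    if (nrow(rows) < th$min_peptides || any(per_sample < th$min_per_sample)) {
      out[[gi]] <- single("below_min_peptides")
      next
    }
    graph <- build_gene_graph(mat, weight_scheme = weight_scheme)
    gene_seed <- stage_seed(seed, "cluster") + gi
    lc <- leiden_communities(graph, seed = gene_seed)
    if (lc$modularity <= th$modularity_floor) {
      out[[gi]] <- single("low_modularity", lc$modularity)
      next
    }
    if (length(unique(lc$membership)) > 1 && (th$n_permutations %||% 0) > 0) {
      # modularity must beat every sample-block-permuted replicate: noise
      # splits do not reproduce across samples, real proteoform splits do
      q_perm <- vapply(seq_len(th$n_permutations), function(b) {
        set.seed(gene_seed + 7919L * b)
        pm <- permute_sample_blocks(mat, k)
        leiden_communities(build_gene_graph(pm, weight_scheme = weight_scheme),
                           seed = gene_seed)$modularity
      }, 0)
      if (lc$modularity <= max(q_perm)) {
        out[[gi]] <- single("low_modularity", lc$modularity)
        next
      }
    }
    if (r_amb >= th$max_ambiguity) {
      out[[gi]] <- single("high_ambiguity", lc$modularity)
      next
    }
    memb <- lc$membership
    sizes <- table(memb)
    small <- as.integer(names(sizes)[sizes < th$min_community])
    accepted_labels <- setdiff(unique(memb), small)
    merged_from <- rep(FALSE, length(memb))
    if (length(small)) {
      if (!length(accepted_labels)) {
        # nothing accepted: collapse the gene into one group
        big <- as.integer(names(sizes)[which.max(sizes)])
        merged_from <- memb != big
        memb[] <- big
      } else {
        for (lab in small) {
          members <- which(memb == lab)
          target <- vapply(accepted_labels, function(al) {
            mean(graph$sim[members, memb == al & !seq_along(memb) %in% members,
                           drop = FALSE], na.rm = TRUE)
          }, 0)
          memb[members] <- accepted_labels[which.max(target)]
          merged_from[members] <- TRUE
        }
      }
    }
    memb <- relabel_communities(memb)
    gates["clustered"] <- gates["clustered"] + 1L
    out[[gi]] <- data.frame(
      gene = g, peptide_id = names(memb),
      membership = sprintf("%s_%d", g, memb),
      modularity = lc$modularity, ambiguity_ratio = r_amb,
      accepted = TRUE,
      reason = ifelse(merged_from, "small_community_merged", "clustered"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "gate_counts") <- gates
  attr(res, "thresholds") <- th
  class(res) <- c("proteoform_assignments", "data.frame")
  res
}

#' @export
summary.proteoform_assignments <- function(object, ...) {
  per_gene <- tapply(object$membership, object$gene,
                     function(m) length(unique(m)))
  cat(sprintf("proteoform assignments: %d genes, %d groups, %d peptide rows\n",
              length(per_gene), length(unique(object$membership)),
              nrow(object)))
  cat(sprintf("  multi-group genes: %d\n", sum(per_gene > 1)))
  gc <- attr(object, "gate_counts")
  if (!is.null(gc)) {
    cat("  gate decisions: ",
        paste(sprintf("%s=%d", names(gc), gc), collapse = ", "), "\n")
  }
  invisible(per_gene)
}

#' @export
print.proteoform_assignments <- function(x, ...) {
  summary(x)
  invisible(x)
}

tppforms_calibrate_groups <- function(raw, n_samples, k, trim_fraction) {
  calibrate_by_sample(raw, n_samples, k, trim_fraction)
}

#' Summarize peptides to proteoform-group melt curves
#'
#' Member peptides' raw (non-normalized) intensities are summed channel by
#' channel per group and sample; the summed group intensities are then
#' calibrated per sample with the variance-stabilizing model (the
#' calibration cancels in the ratio, so group curves are fractions of the
#' summed raw reference intensity) and converted to fold changes relative
#' to the lowest temperature. Groups whose summed reference intensity is
#' missing or zero in a sample lose that sample's curve (warning).
#'
#' @param pq Raw [peptide_quant()] (same peptides the assignments cover).
#' @param assignments A [assign_proteoform_groups()] result.
#' @param trim_fraction Passed to [vsn_normalize()].
#' @return Object of class `"group_curves"`: list with `curves` (matrix,
#'   groups x concatenated sample blocks of fold changes), `groups` (group
#'   id, gene, n_member_peptides), `sample_meta`, `layout`, `grid`.
#' @export
summarize_groups <- function(pq, assignments, trim_fraction = 0.1) {
  stopifnot(inherits(pq, "peptide_quant"))
  k <- length(pq$grid)
  samples <- sort(unique(pq$meta$sample_id))
  groups <- unique(assignments[, c("gene", "membership")])
  groups <- groups[order(groups$membership), ]
  n_members <- table(assignments$membership)
  rownames(groups) <- NULL

  raw <- matrix(NA_real_, nrow(groups), length(samples) * k,
                dimnames = list(groups$membership, NULL))
  key <- paste(assignments$gene, assignments$peptide_id)
  for (gi in seq_len(nrow(groups))) {
    peps <- assignments$peptide_id[assignments$membership ==
                                     groups$membership[gi]]
    sel <- pq$meta$peptide_id %in% peps
    for (s in seq_along(samples)) {
      rsel <- sel & pq$meta$sample_id == samples[s]
      if (!any(rsel)) next
      block <- pq$intensities[rsel, , drop = FALSE]
      present <- colSums(!is.na(block)) > 0
      v <- colSums(block, na.rm = TRUE)
      v[!present] <- NA_real_
      raw[gi, (s - 1L) * k + seq_len(k)] <- v
    }
  }
  v <- tppforms_calibrate_groups(raw, length(samples), k, trim_fraction)
  curves <- raw * NA_real_
  dropped <- 0L
  for (s in seq_along(samples)) {
    cols <- (s - 1L) * k + seq_len(k)
    fc <- withCallingHandlers(
      to_fold_changes(v[, cols, drop = FALSE], pq$grid),
      warning = function(wn) {
        dropped <<- dropped + as.integer(sub("^(\\d+) .*$", "\\1",
                                             conditionMessage(wn)))
        invokeRestart("muffleWarning")
      })
    curves[, cols] <- fc
  }
  if (dropped > 0) {
    warning(sprintf("summarize_groups: %d group curve(s) dropped (no usable reference)",
                    dropped))
  }
  sm <- unique(pq$meta[, c("sample_id", "cell_line", "condition",
                           "replicate")])
  sm <- sm[match(samples, sm$sample_id), ]
  rownames(sm) <- NULL
  groups$n_member_peptides <- as.integer(n_members[groups$membership])
  layout <- data.frame(sample_id = rep(samples, each = k),
                       channel = rep(seq_len(k), length(samples)))
  structure(list(curves = curves, groups = groups, sample_meta = sm,
                 layout = layout, samples = samples, grid = pq$grid),
            class = "group_curves")
}

#' @export
print.group_curves <- function(x, ...) {
  cat(sprintf("group_curves: %d proteoform groups x %d samples x %d temperatures\n",
              nrow(x$curves), length(x$samples), length(x$grid)))
  invisible(x)
}
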