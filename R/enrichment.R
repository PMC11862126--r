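#' Proteoform-aware over-representation analysis against complex sets
#'
#' Entities are proteoform-group identifiers mapped to gene symbols, so a
#' gene contributes one universe (and possibly hit) entry per proteoform
#' group, in both the hit list and the background; this prices in the
#' background chance of a gene's repeated identification. For each complex,
#' membership is the set of universe entities whose gene belongs to the
#' complex, and the upper-tail hypergeometric probability of the observed
#' hit overlap is computed. Complexes represented by fewer than `min_size`
#' distinct gene symbols in the universe are skipped; BH correction is
#' applied across the tested complexes.
#'
#' @param hits Character vector of hit entity ids (must be in `universe`).
#' @param universe Character vector of all entity ids (unique).
#' @param entity_genes Named character vector mapping entity id to gene
#'   symbol. Defaults to stripping a trailing `"_<k>"` group suffix.
#' @param complexes Named list of gene-symbol vectors (see [read_gmt()]).
#' @param min_size Minimum distinct universe genes per tested complex.
#' @param alpha Significance threshold recorded in the output.
#' @return Data frame: complex, n_universe, n_hits, set_size, overlap,
#'   expected, p, p_adj, significant.
#' @export
ora_complexes <- function(hits, universe, complexes,
                          entity_genes = setNames(sub("_[0-9]+$", "", universe),
                                                  universe),
                          min_size = 3, alpha = 0.05) {
  universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop("hit entity not in universe: ", setdiff(hits, universe)[1])
  }
  genes <- entity_genes[universe]
  n_u <- length(universe); n_h <- length(unique(hits))
  rows <- lapply(names(complexes), function(nm) {
    members <- universe[genes %in% complexes[[nm]]]
    if (length(unique(genes[universe %in% members])) < min_size) return(NULL)
    k <- length(members)
    ov <- length(intersect(hits, members))
    p <- phyper(ov - 1, k, n_u - k, n_h, lower.tail = FALSE)
    data.frame(complex = nm, n_universe = n_u, n_hits = n_h, set_size = k,
               overlap = ov, expected = n_h * k / n_u, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(complex = character(), n_universe = integer(),
                      n_hits = integer(), set_size = integer(),
                      overlap = integer(), expected = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  res[order(res$p), ]
}

#' Count flanking-motif presence in hit and background sequences
#'
#' Scores each protein sequence for the presence (not occurrence count) of
#' tripeptides in which a phospho-capable or cysteine residue is flanked by
#' glycine and leucine: GCL, GSL, GTL, GYL, and the pooled pattern
#' `G[STCY]L` ("any G*L"; set `general_gxl = TRUE` for a fully general
#' `G.L`).
#'
#' @param hit_seqs Named character vector of hit sequences (uppercase).
#' @param background_seqs Named character vector of background sequences.
#' @param patterns Specific tripeptides to score.
#' @param general_gxl If `TRUE`, "any" means `G.L` rather than `G[STCY]L`.
#' @return Data frame: pattern, hit_count, hit_total, bg_count, bg_total.
#' @export
count_flank_motifs <- function(hit_seqs, background_seqs,
                               patterns = c("GCL", "GSL", "GTL", "GYL"),
                               general_gxl = FALSE) {
  check <- function(seqs, label) {
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
    if (any(bad)) {
      warning(sprintf("%d %s sequence(s) contain non-amino-acid characters",
                      sum(bad), label))
    }
    seqs
  }
  hit_seqs <- check(toupper(hit_seqs), "hit")
  background_seqs <- check(toupper(background_seqs), "background")
  any_pat <- if (general_gxl) "G.L" else "G[STCY]L"
  pats <- c(setNames(patterns, patterns), any_GxL = any_pat)
  rows <- lapply(names(pats), function(nm) {
    fixed <- !grepl("[\\[\\.]", pats[[nm]])
    data.frame(pattern = nm,
               hit_count = sum(grepl(pats[[nm]], hit_seqs, fixed = fixed)),
               hit_total = length(hit_seqs),
               bg_count = sum(grepl(pats[[nm]], background_seqs,
                                    fixed = fixed)),
               bg_total = length(background_seqs),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-sample proportion test with Yates continuity correction
#'
#' Classic 2x2 chi-square comparison of `x1/n1` versus `x2/n2` with the
#' 0.5 continuity correction (capped so the corrected deviation cannot go
#' negative), 1 degree of freedom, two-sided.
#'
#' @param x1,n1 Successes and total in group 1.
#' @param x2,n2 Successes and total in group 2.
#' @return List with `chisq` and `p`.
#' @export
two_prop_test_yates <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  tst <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = TRUE))
  list(chisq = unname(tst$statistic), p = tst$p.value)
}

#' Replication filter for affinity-pulldown hits
#'
#' An entity is a hit only if it was detected in at least
#' `min_drug_reps` of the drug-probe preparations and in none of the
#' vehicle (DMSO) preparations; any vehicle detection excludes it.
#'
#' @param detections Data frame with columns `entity`, `drug_reps`
#'   (number of drug preparations with detection), `vehicle_reps`
#'   (number of vehicle preparations with detection).
#' @param min_drug_reps Minimum replicated drug detections (default 2
#'   of 3).
#' @return Character vector of hit entities.
#' @export
pulldown_replication_filter <- function(detections, min_drug_reps = 2) {
  stopifnot(all(c("entity", "drug_reps", "vehicle_reps") %in%
                  names(detections)))
  hit <- detections$drug_reps >= min_drug_reps & detections$vehicle_reps == 0
  detections$entity[hit]
}
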