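# Drug-target overlap testing: Fisher's exact test, STITCH-style interaction
# filtering, Tanimoto fingerprint similarity, and target-set expansion via
# structurally similar chemicals.

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for a 2x2 contingency table, with
#' the one-sided `"greater"` alternative (enrichment of the top-left cell)
#' as default. The two-sided p-value sums the probabilities of all tables
#' with the observed margins that are no more likely than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return p-value.
#' @export
fisher_exact <- function(table,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_input("`table` must be 2x2")
  if (any(table < 0) || any(table != floor(table))) {
    stop_input("`table` must contain non-negative integer counts")
  }
  a <- table[1L, 1L]
  m <- sum(table[, 1L])        # successes in population
  n <- sum(table[, 2L])        # failures in population
  kk <- sum(table[1L, ])       # draws
  if (m == 0 || n == 0 || kk == 0 || sum(table[2L, ]) == 0) return(1)
  supp <- max(0, kk - n):min(kk, m)
  dens <- dhyper(supp, m, n, kk)
  switch(alternative,
    greater = sum(dens[supp >= a]),
    less = sum(dens[supp <= a]),
    two.sided = {
      # tables no more probable than the observed one (with the usual
      # relative tolerance guarding against floating-point equality)
      sum(dens[dens <= dhyper(a, m, n, kk) * (1 + 1e-7)])
    })
}

#' Targets of a drug at a STITCH-style confidence threshold
#'
#' @param interactions data.frame(`chemical_id`, `protein_id`, `score`)
#'   with integer confidence scores on the 0-1000 scale.
#' @param drug Chemical identifier.
#' @param score_threshold Minimum score (customary values 700, 800, 900).
#' @return Character vector of protein identifiers.
#' @export
drug_targets <- function(interactions, drug, score_threshold = 700L) {
  require_columns(interactions, c("chemical_id", "protein_id", "score"),
                  "interactions")
  if (any(interactions$score < 0 | interactions$score > 1000)) {
    stop_input("interaction scores must lie in [0, 1000]")
  }
  hit <- interactions$chemical_id == drug &
    interactions$score >= score_threshold
  unique(interactions$protein_id[hit])
}

#' Test overlap between associated proteins and a drug's targets
#'
#' Fisher exact (greater) test of whether the proteins found associated
#' with a drug are enriched among the drug's interaction partners at a
#' given confidence threshold, relative to the background of all tested
#' genes.
#'
#' @param associated_proteins Proteins with an association for the drug;
#'   must be a subset of `background`.
#' @param drug Chemical identifier.
#' @inheritParams drug_targets
#' @param background All genes tested for association.
#' @return List: `overlap`, `n_targets` (targets in the background), `p`
#'   (`1` when the drug has no targets).
#' @export
target_overlap_test <- function(associated_proteins, drug, interactions,
                                score_threshold = 700L, background) {
  if (length(setdiff(associated_proteins, background)) > 0L) {
    stop_input("`associated_proteins` must be a subset of `background`")
  }
  targets <- intersect(drug_targets(interactions, drug, score_threshold),
                       background)
  a <- length(intersect(associated_proteins, targets))
  if (length(targets) == 0L) {
    return(list(overlap = 0L, n_targets = 0L, p = 1))
  }
  b <- length(associated_proteins) - a
  cc <- length(targets) - a
  d <- length(background) - length(associated_proteins) - cc
  p <- fisher_exact(matrix(c(a, cc, b, d), 2L), alternative = "greater")
  list(overlap = a, n_targets = length(targets), p = p)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|` over equal-length bit vectors; defined as 1 when
#' both fingerprints are all-zero.
#'
#' @param a,b Binary (0/1 or logical) vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop_input("fingerprints differ in length (%d vs %d)", length(a), length(b))
  }
  a <- as.logical(a)
  b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L) return(1)
  sum(a & b) / union
}

#' Expand a drug's target set via structurally similar chemicals
#'
#' Unions the targets (at `score_threshold`) of every chemical whose
#' Tanimoto similarity with the drug exceeds `tanimoto_cutoff`, always
#' including the drug's own targets.
#'
#' @param drug Chemical identifier; must have a fingerprint.
#' @param fingerprints Named list of binary fingerprint vectors, one per
#'   chemical.
#' @inheritParams drug_targets
#' @param tanimoto_cutoff Similarity above which a chemical contributes its
#'   targets (customary value 0.70; strict inequality).
#' @return Character vector of protein identifiers.
#' @export
expand_targets_by_similarity <- function(drug, fingerprints, interactions,
                                         tanimoto_cutoff = 0.70,
                                         score_threshold = 700L) {
  if (!drug %in% names(fingerprints)) {
    stop_input("no fingerprint for drug %s", drug)
  }
  fp <- fingerprints[[drug]]
  similar <- names(fingerprints)[vapply(fingerprints, function(x) {
    tanimoto(fp, x) > tanimoto_cutoff
  }, logical(1L))]
  chems <- union(drug, similar)
  sort(unique(unlist(lapply(chems, function(ch) {
    drug_targets(interactions, ch, score_threshold)
  }))))
}
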