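# Independent oracles used across the suite. These deliberately recompute
# quantities by brute force (full enumeration, closed forms) and never call
# the package functions they are used to check.

# Exact null distribution of the Mann-Whitney U statistic for group sizes
# (na, nb), by enumerating every assignment of ranks to group A.
enum_u_pmf <- function(na, nb) {
  n <- na + nb
  sets <- utils::combn(n, na)
  u <- colSums(matrix(sets, nrow = na)) - na * (na + 1) / 2
  tab <- table(u)
  list(u = as.numeric(names(tab)), prob = as.numeric(tab) / ncol(sets))
}

# Two-sided p-value from an enumerated U pmf.
enum_two_sided_p <- function(u_obs, pmf) {
  p_lo <- sum(pmf$prob[pmf$u <= u_obs])
  p_hi <- sum(pmf$prob[pmf$u >= u_obs])
  min(1, 2 * min(p_lo, p_hi))
}

# U statistic of group A computed directly from values (no ties assumed).
u_stat <- function(a, b) {
  sum(vapply(a, function(x) sum(x > b), numeric(1)))
}

# Hypergeometric pmf over the support of a 2x2 table with fixed margins,
# from binomial coefficients only.
hyper_pmf <- function(m, n, k) {
  supp <- max(0, k - n):min(k, m)
  prob <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  list(x = supp, prob = prob)
}

# A small cohort with hand-placed mutations: one gene (G1, isoform G1.1,
# 100 aa) with two regions R1 = [1, 50] and R2 = [51, 100], plus a gene G2
# with no regions. Activity values are supplied by the caller.
tiny_cohort <- function(activity, mutations) {
  isoforms <- data.frame(
    gene_id = c("G1", "G2"),
    isoform_id = c("G1.1", "G2.1"),
    sequence = c(strrep("A", 100), strrep("L", 80))
  )
  regions <- data.frame(
    region_id = c("R1", "R2"), gene_id = "G1", isoform_id = "G1.1",
    source = c("pfam", "idr"), start = c(1L, 51L), end = c(50L, 100L),
    name = c("domain", "tail")
  )
  edrug_cohort(isoforms, regions, mutations, activity)
}

mut_row <- function(sample, gene = "G1", iso = "G1.1", pos = 10L) {
  data.frame(sample_id = sample, gene_id = gene, isoform_id = iso,
             position = as.integer(pos), ref_aa = "A", alt_aa = "V")
}

activity_matrix <- function(values, samples, drugs = "d1") {
  matrix(values, nrow = length(samples),
         dimnames = list(samples, drugs))
}

# Cohort with one gene carrying two opposite planted effects of size
# `delta` on disjoint carrier groups -- the configuration in which pooling
# at the gene level cancels the region signals.
opposed_cohort <- function(seed, delta = 1.0, noise_sd = 0.5,
                           n_samples = 200L, n_carriers = 15L,
                           rate = 0.02) {
  proteome <- generate_proteome(1L, regions_per_gene = c(2L, 2L),
                                idr_prob = 0, seed = seed)
  truth <- synthetic_truth(
    data.frame(region_id = proteome$regions$region_id[1:2],
               drug_id = "d1", delta = c(delta, -delta)),
    noise_sd = noise_sd, seed = seed)
  cohort <- generate_cohort(proteome, n_samples,
                            per_sample_mutation_rate = rate, truth = truth,
                            drugs = "d1",
                            min_mutated_per_effect = n_carriers)
  list(cohort = cohort, truth = truth, regions = proteome$regions)
}
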