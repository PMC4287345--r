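# The e-Drug association engine: three-stage rank-sum testing of region
# mutation status against drug activity area.

#' Assemble a cohort dataset
#'
#' Bundles the four ingredients of an association run -- isoforms, functional
#' regions, missense mutations and the drug activity-area matrix -- after
#' validating their mutual consistency. Mutations from samples without a row
#' in the activity matrix are retained but flagged unprofiled; they are
#' excluded from all tests (attribute `n_unprofiled_mutations`).
#'
#' @param isoforms data.frame(`gene_id`, `isoform_id`, `sequence`).
#' @param regions Region table (see [assign_mutations_to_regions()]).
#' @param mutations Mutation table (`sample_id`, `gene_id`, `isoform_id`,
#'   `position`, `ref_aa`, `alt_aa`).
#' @param activity Numeric matrix of activity-area values, samples in rows
#'   (rownames = sample ids), drugs in columns (colnames = drug ids). `NA`
#'   marks a missing measurement; present values must be non-negative.
#' @return An object of class `edrug_cohort` (a list with the four
#'   components).
#' @export
edrug_cohort <- function(isoforms, regions, mutations, activity) {
  require_columns(isoforms, c("gene_id", "isoform_id", "sequence"), "isoforms")
  validate_regions(regions, isoforms)
  require_columns(mutations,
                  c("sample_id", "gene_id", "isoform_id", "position",
                    "ref_aa", "alt_aa"), "mutations")
  if (nrow(mutations) > 0L) {
    if (any(mutations$position < 1L)) {
      stop_input("mutation positions must be >= 1 (1-based residue index)")
    }
    same <- mutations$ref_aa == mutations$alt_aa
    if (any(same)) {
      stop_input("mutation with ref_aa == alt_aa (%s) is not missense",
                 mutations$ref_aa[which(same)[1L]])
    }
    # bounds against known isoforms (raises a located error)
    assign_mutations_to_regions(mutations, empty_region_table(),
                                isoforms = isoforms)
  }
  if (!is.matrix(activity) || !is.numeric(activity)) {
    stop_input("`activity` must be a numeric matrix (samples x drugs)")
  }
  if (is.null(rownames(activity)) || is.null(colnames(activity))) {
    stop_input("`activity` must carry sample rownames and drug colnames")
  }
  if (anyDuplicated(rownames(activity)) || anyDuplicated(colnames(activity))) {
    stop_input("duplicated sample or drug identifiers in activity matrix")
  }
  if (any(activity < 0, na.rm = TRUE)) {
    stop_input("activity-area values must be non-negative")
  }
  unprofiled <- sum(!(mutations$sample_id %in% rownames(activity)))
  structure(
    list(isoforms = isoforms, regions = regions, mutations = mutations,
         activity = activity),
    n_unprofiled_mutations = unprofiled,
    class = "edrug_cohort"
  )
}

#' @export
print.edrug_cohort <- function(x, ...) {
  cat(sprintf(
    "edrug cohort: %d samples x %d drugs, %d genes, %d regions, %d missense mutations\n",
    nrow(x$activity), ncol(x$activity), length(unique(x$isoforms$gene_id)),
    nrow(x$regions), nrow(x$mutations)))
  if (attr(x, "n_unprofiled_mutations") > 0L) {
    cat(sprintf("  (%d mutations from unprofiled samples excluded from testing)\n",
                attr(x, "n_unprofiled_mutations")))
  }
  invisible(x)
}

#' Significance thresholds for the three-stage filter
#'
#' @param p_stage1 Stage-I level: region-mutated vs comparison group
#'   (default 0.01).
#' @param p_gene Gene-level exclusion level: pairs whose whole-gene test
#'   falls below this are discarded as gene-level signals (default 0.01).
#' @param p_stage2 Stage-II level: region-mutated vs other-region-mutated
#'   (default 0.05; the within-gene contrast involves fewer samples and
#'   fewer tests).
#' @param min_mutated Minimum number of region-mutated, activity-profiled
#'   samples for a pair to be tested at all (default 2).
#' @return List of class `association_thresholds`.
#' @export
association_thresholds <- function(p_stage1 = 0.01, p_gene = 0.01,
                                   p_stage2 = 0.05, min_mutated = 2L) {
  for (p in c(p_stage1, p_gene, p_stage2)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
      stop_input("significance levels must lie strictly between 0 and 1")
    }
  }
  if (!is_count(min_mutated)) stop_input("`min_mutated` must be >= 1")
  structure(list(p_stage1 = p_stage1, p_gene = p_gene, p_stage2 = p_stage2,
                 min_mutated = as.integer(min_mutated)),
            class = "association_thresholds")
}

# Precompute, once per run: sample index maps, per-gene and per-region
# mutated sample sets (profiled samples only).
cohort_index <- function(dataset) {
  stopifnot(inherits(dataset, "edrug_cohort"))
  samples <- rownames(dataset$activity)
  mut <- dataset$mutations
  mut <- mut[mut$sample_id %in% samples, , drop = FALSE]
  gene_samples <- lapply(split(mut$sample_id, mut$gene_id), unique)
  asg <- assign_mutations_to_regions(mut, dataset$regions)
  region_samples <- lapply(split(asg$sample_id, asg$region_id), unique)
  list(
    samples = samples,
    gene_samples = gene_samples,
    region_samples = region_samples,
    region_gene = setNames(dataset$regions$gene_id, dataset$regions$region_id),
    region_source = setNames(dataset$regions$source, dataset$regions$region_id)
  )
}

# Core two-group contrast on one drug's activity vector.
contrast_groups <- function(act, mut_samples, comp_samples) {
  a <- act[mut_samples]
  b <- act[comp_samples]
  if (length(a) == 0L || length(b) == 0L) {
    return(list(p = NA_real_, delta_median = NA_real_,
                n_mut = length(a), n_comp = length(b)))
  }
  p <- as.numeric(rank_sum_test(a, b))
  list(p = p, delta_median = median(a) - median(b),
       n_mut = length(a), n_comp = length(b))
}

#' Stage-I test for one region-drug pair
#'
#' Compares the drug's activity area between samples carrying at least one
#' missense mutation in the region and a comparison group: by default
#' samples with no missense mutation anywhere in the gene
#' (`"gene_unmutated"`), alternatively samples with no mutation in the
#' region itself (`"region_unmutated"`). Samples lacking an activity value
#' for the drug are dropped from the contrast.
#'
#' @param region_id,drug_id Identifiers present in the cohort.
#' @param dataset An [edrug_cohort()].
#' @param comparison `"gene_unmutated"` (default) or `"region_unmutated"`.
#' @return List with `p` (two-sided rank-sum p-value), `delta_median`
#'   (median activity of region-mutated minus comparison samples), `n_mut`,
#'   `n_comp`. `p` is `NA` when either group is empty.
#' @export
stage1_test <- function(region_id, drug_id, dataset,
                        comparison = c("gene_unmutated", "region_unmutated")) {
  comparison <- match.arg(comparison)
  idx <- cohort_index(dataset)
  act <- activity_vector(dataset, drug_id)
  ok <- names(act)
  mut <- intersect(idx$region_samples[[region_id]] %||% character(), ok)
  gene <- region_gene_of(idx, region_id)
  excl <- if (comparison == "gene_unmutated") {
    idx$gene_samples[[gene]] %||% character()
  } else {
    idx$region_samples[[region_id]] %||% character()
  }
  contrast_groups(act, mut, setdiff(ok, excl))
}

#' Whole-gene association test
#'
#' Rank-sum test of samples with at least one missense mutation anywhere in
#' the gene against samples with none. Pairs whose region-level signal is
#' reproduced here are excluded by [run_edrug()]: such associations carry no
#' region-specific information.
#'
#' @inheritParams stage1_test
#' @param gene_id Gene identifier.
#' @return Two-sided p-value.
#' @export
gene_level_test <- function(gene_id, drug_id, dataset) {
  idx <- cohort_index(dataset)
  act <- activity_vector(dataset, drug_id)
  ok <- names(act)
  mut <- intersect(idx$gene_samples[[gene_id]] %||% character(), ok)
  if (length(mut) == 0L) {
    stop_input("gene-level test undefined: no profiled mutated samples for %s",
               gene_id)
  }
  res <- contrast_groups(act, mut, setdiff(ok, mut))
  res$p
}

#' Stage-II within-gene test
#'
#' Compares region-mutated samples against samples mutated elsewhere in the
#' same gene (samples mutated both inside and outside the region count as
#' region-mutated only). Returns `NA` when no sample is mutated outside the
#' region: without a within-gene contrast the pair cannot be called
#' significant.
#'
#' @inheritParams stage1_test
#' @return Two-sided p-value, or `NA` if the other-region group is empty.
#' @export
stage2_test <- function(region_id, drug_id, dataset) {
  idx <- cohort_index(dataset)
  act <- activity_vector(dataset, drug_id)
  ok <- names(act)
  mut <- intersect(idx$region_samples[[region_id]] %||% character(), ok)
  gene <- region_gene_of(idx, region_id)
  other <- setdiff(intersect(idx$gene_samples[[gene]] %||% character(), ok), mut)
  if (length(mut) == 0L || length(other) == 0L) return(NA_real_)
  contrast_groups(act, mut, other)$p
}

activity_vector <- function(dataset, drug_id) {
  if (!drug_id %in% colnames(dataset$activity)) {
    stop_input("drug %s not present in activity matrix", drug_id)
  }
  act <- dataset$activity[, drug_id]
  act[!is.na(act)]
}

region_gene_of <- function(idx, region_id) {
  if (!region_id %in% names(idx$region_gene)) {
    stop_input("region %s not present in the cohort", region_id)
  }
  unname(idx$region_gene[[region_id]])
}

#' Direction of an association
#'
#' The sign of the median activity-area difference (region-mutated minus
#' comparison) labels an association: positive differences mean mutated
#' samples respond better (`sensitizing`), negative ones mean they respond
#' worse (`resistance`), zero is `undetermined`.
#'
#' @param delta_median Numeric vector of median differences.
#' @return Character vector: `"sensitizing"`, `"resistance"`,
#'   `"undetermined"`, or `NA`.
#' @export
effect_direction <- function(delta_median) {
  out <- rep(NA_character_, length(delta_median))
  out[!is.na(delta_median) & delta_median > 0] <- "sensitizing"
  out[!is.na(delta_median) & delta_median < 0] <- "resistance"
  out[!is.na(delta_median) & delta_median == 0] <- "undetermined"
  out
}

#' Run the full three-stage association analysis
#'
#' For every (region, drug) pair the engine: (I) tests region-mutated
#' against comparison samples and requires p below `p_stage1`; excludes
#' pairs whose whole-gene test already falls below `p_gene` (the signal is
#' not region-specific); and (II) requires the region-mutated vs
#' other-region-mutated contrast to fall below `p_stage2`. Pairs with fewer
#' than `min_mutated` region-mutated profiled samples are reported with
#' status `insufficient_mutations` and are not tested.
#'
#' Raw p-values drive the decision rule; Benjamini-Hochberg q-values over
#' all stage-I tested pairs are emitted as an informational column
#' (`q_stage1`) without affecting calls.
#'
#' @inheritParams stage1_test
#' @param thresholds An [association_thresholds()] object.
#' @return data.frame (class `edrug_results`) with one row per (region,
#'   drug) pair, ordered by (`drug_id`, `region_id`): identifiers and
#'   counts, the three p-values (`p_stage1`, `p_gene`, `p_stage2`; `NA`
#'   where a stage was not reached), `q_stage1`, `delta_median`,
#'   `direction` and `status` (one of `significant`,
#'   `insufficient_mutations`, `fail_stage1`, `gene_level`, `fail_stage2`).
#' @export
run_edrug <- function(dataset, thresholds = association_thresholds(),
                      comparison = c("gene_unmutated", "region_unmutated")) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(thresholds, "association_thresholds"))
  idx <- cohort_index(dataset)
  regions <- dataset$regions
  drugs <- colnames(dataset$activity)
  n_pairs <- nrow(regions) * length(drugs)

  rows <- vector("list", n_pairs)
  k <- 0L
  for (drug in drugs) {
    act <- activity_vector(dataset, drug)
    ok <- names(act)
    gene_cache <- new.env(parent = emptyenv())
    for (ri in seq_len(nrow(regions))) {
      region <- regions$region_id[ri]
      gene <- regions$gene_id[ri]
      gene_mut <- intersect(idx$gene_samples[[gene]] %||% character(), ok)
      reg_mut <- intersect(idx$region_samples[[region]] %||% character(), ok)
      other_mut <- setdiff(gene_mut, reg_mut)
      unmut <- setdiff(ok, gene_mut)
      comp <- if (comparison == "gene_unmutated") unmut else setdiff(ok, reg_mut)

      row <- list(
        region_id = region, gene_id = gene, drug_id = drug,
        source = regions$source[ri],
        n_region_mut = length(reg_mut), n_other_mut = length(other_mut),
        n_unmut = length(unmut),
        p_stage1 = NA_real_, p_gene = NA_real_, p_stage2 = NA_real_,
        delta_median = NA_real_, direction = NA_character_,
        status = NA_character_
      )

      if (length(reg_mut) < thresholds$min_mutated || length(comp) == 0L) {
        row$status <- "insufficient_mutations"
      } else {
        s1 <- contrast_groups(act, reg_mut, comp)
        row$p_stage1 <- s1$p
        row$delta_median <- s1$delta_median
        row$direction <- effect_direction(s1$delta_median)
        pg <- get0(gene, envir = gene_cache, ifnotfound = NULL)
        if (is.null(pg)) {
          pg <- if (length(gene_mut) == 0L || length(unmut) == 0L) NA_real_
                else contrast_groups(act, gene_mut, unmut)$p
          assign(gene, pg, envir = gene_cache)
        }
        row$p_gene <- pg
        if (s1$p >= thresholds$p_stage1) {
          row$status <- "fail_stage1"
        } else if (!is.na(pg) && pg < thresholds$p_gene) {
          row$status <- "gene_level"
        } else {
          p2 <- if (length(other_mut) == 0L) NA_real_
                else contrast_groups(act, reg_mut, other_mut)$p
          row$p_stage2 <- p2
          row$status <- if (!is.na(p2) && p2 < thresholds$p_stage2)
            "significant" else "fail_stage2"
        }
      }
      k <- k + 1L
      rows[[k]] <- row
    }
  }

  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out <- out[order(out$drug_id, out$region_id), , drop = FALSE]
  out$q_stage1 <- p.adjust(out$p_stage1, method = "BH")
  out <- out[, c("region_id", "gene_id", "drug_id", "source",
                 "n_region_mut", "n_other_mut", "n_unmut",
                 "p_stage1", "p_gene", "p_stage2", "q_stage1",
                 "delta_median", "direction", "status")]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  attr(out, "comparison") <- comparison
  class(out) <- c("edrug_results", "data.frame")
  out
}
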