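# Synthetic cohorts with region-structured mutation landscapes and planted
# drug effects. Everything is driven by one explicit seed so a cohort is a
# pure function of its parameters.

AA20 <- names(KD_HYDROPATHY)

# Uniform integer draw(s) from [lo, hi]; safe when lo == hi (base sample()
# would treat a scalar as 1:n).
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Ground truth for a simulated cohort
#'
#' @param effects data.frame with columns `region_id`, `drug_id`, `delta`:
#'   the activity-area shift added to samples mutated in the region
#'   (negative = resistance). May have zero rows (a null cohort).
#' @param baseline_mean Mean activity area of unaffected (sample, drug)
#'   cells. Default 3.0, comparable to the 0-8 scale of cell-line panels.
#' @param noise_sd Gaussian noise standard deviation (default 0.5).
#' @param seed Integer seed governing every random draw.
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(effects = NULL, baseline_mean = 3.0,
                            noise_sd = 0.5, seed = 1L) {
  if (is.null(effects)) {
    effects <- data.frame(region_id = character(), drug_id = character(),
                          delta = numeric())
  }
  require_columns(effects, c("region_id", "drug_id", "delta"), "effects")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_input("`noise_sd` must be positive")
  }
  structure(list(effects = effects, baseline_mean = baseline_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a synthetic proteome with domain structure
#'
#' Draws random amino-acid sequences and places per gene a random number of
#' non-overlapping domain intervals, optionally adding one disordered-tagged
#' interval. Interval placement distributes the slack uniformly among the
#' gaps, so regions land anywhere in the protein.
#'
#' @param n_genes Number of genes (one isoform each).
#' @param regions_per_gene Length-2 integer range (inclusive) for the number
#'   of domain intervals per gene; may be `c(0, 0)`.
#' @param length_range Length-2 range of sequence lengths.
#' @param region_length_range Length-2 range of domain lengths.
#' @param idr_prob Probability that a gene receives one extra interval
#'   tagged `idr` (default 0.25).
#' @param seed Integer seed.
#' @return List with `isoforms` and `regions` tables.
#' @export
generate_proteome <- function(n_genes, regions_per_gene = c(1L, 2L),
                              length_range = c(500L, 900L),
                              region_length_range = c(90L, 160L),
                              idr_prob = 0.25, seed = 1L) {
  if (!is_count(n_genes)) stop_input("`n_genes` must be a positive integer")
  stopifnot(length(regions_per_gene) == 2L, length(length_range) == 2L)
  worst_regions <- max(regions_per_gene) + (idr_prob > 0)
  if (worst_regions * max(region_length_range) > min(length_range)) {
    stop_input(
      "infeasible packing: up to %d regions of up to %d residues cannot fit in a %d-residue protein",
      worst_regions, max(region_length_range), min(length_range))
  }
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    isoform_ids <- sprintf("%s.1", genes)
    lens <- sample_range(length_range[1L], length_range[2L], n_genes)
    sequences <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE), collapse = "")
    }, character(1L))
    isoforms <- data.frame(gene_id = genes, isoform_id = isoform_ids,
                           sequence = sequences)
    region_rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- if (regions_per_gene[2L] == 0L) 0L else
        sample_range(regions_per_gene[1L], regions_per_gene[2L])
      n_idr <- if (runif(1) < idr_prob) 1L else 0L
      total <- k + n_idr
      if (total == 0L) next
      rl <- sample_range(region_length_range[1L], region_length_range[2L],
                         total)
      slack <- lens[g] - sum(rl)
      # distribute slack over total+1 gaps
      cuts <- sort(sample(seq_len(slack + total), total))
      gaps <- diff(c(0L, cuts)) - 1L
      starts <- cumsum(gaps) + c(0L, cumsum(rl[-total])) + 1L
      ends <- starts + rl - 1L
      src <- c(rep("pfam", k), rep("idr", n_idr))
      region_rows[[g]] <- data.frame(
        region_id = sprintf("%s:R%d", genes[g], seq_len(total)),
        gene_id = genes[g], isoform_id = isoform_ids[g],
        source = src, start = as.integer(starts), end = as.integer(ends),
        name = sprintf("%s region %d", src, seq_len(total))
      )
    }
    regions <- do.call(rbind, region_rows)
    if (is.null(regions)) regions <- empty_region_table()
    rownames(regions) <- NULL
    validate_regions(regions, isoforms)
    list(isoforms = isoforms, regions = regions)
  })
}

#' Generate a synthetic cohort with planted drug effects
#'
#' Each (sample, gene) mutates independently with probability
#' `per_sample_mutation_rate`; a mutated pair receives one missense mutation
#' at a uniformly chosen residue (or, with `placement = "hotspot"`, at a
#' position drawn from a narrow window around a per-gene hotspot). Activity
#' areas are drawn from Normal(`baseline_mean`, `noise_sd`) per (sample,
#' drug); for each planted effect, samples with at least one mutation inside
#' the effect's region have `delta` added for that drug. Values are clipped
#' at zero (activity area is non-negative).
#'
#' When `min_mutated_per_effect` is positive, each planted-effect region is
#' topped up to that many mutated samples by placing additional mutations
#' (uniform within the region) in samples not yet mutated in the gene, drawn
#' from the same seeded stream. This yields designed case groups -- e.g. two
#' regions of one gene with opposite shifts and disjoint carrier sets, the
#' configuration in which gene-level pooling cancels the signal.
#'
#' @param proteome Output of [generate_proteome()].
#' @param n_samples Number of samples.
#' @param per_sample_mutation_rate Per-(sample, gene) mutation probability,
#'   in (0, 1]. Default 0.2, the regime of recurrently mutated cancer genes
#'   in pan-cancer panels, so that at desk scale typical regions carry on
#'   the order of ten mutated samples.
#' @param truth A [synthetic_truth()]; its seed drives all draws.
#' @param drugs Character vector of drug identifiers.
#' @param placement `"uniform"` (default) or `"hotspot"`.
#' @param min_mutated_per_effect Guaranteed minimum carrier count per
#'   planted-effect region (default 0 = no top-up).
#' @return An [edrug_cohort()].
#' @export
generate_cohort <- function(proteome, n_samples, per_sample_mutation_rate = 0.2,
                            truth = synthetic_truth(), drugs = c("drug1"),
                            placement = c("uniform", "hotspot"),
                            min_mutated_per_effect = 0L) {
  placement <- match.arg(placement)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is_count(n_samples)) stop_input("`n_samples` must be a positive integer")
  rate <- per_sample_mutation_rate
  if (!is.numeric(rate) || rate <= 0 || rate > 1) {
    stop_input("`per_sample_mutation_rate` must lie in (0, 1]")
  }
  isoforms <- proteome$isoforms
  regions <- proteome$regions
  unknown <- setdiff(truth$effects$region_id, regions$region_id)
  if (length(unknown) > 0L) {
    stop_input("planted effect references unknown region(s): %s",
               paste(unknown, collapse = ", "))
  }
  if (nrow(truth$effects) > 0L &&
      length(setdiff(truth$effects$drug_id, drugs)) > 0L) {
    stop_input("planted effect references a drug not in `drugs`")
  }

  with_seed(truth$seed, {
    samples <- sprintf("S%04d", seq_len(n_samples))
    lens <- setNames(nchar(isoforms$sequence), isoforms$isoform_id)
    hot <- NULL
    if (placement == "hotspot") {
      hot <- setNames(
        vapply(lens, function(L) sample.int(L, 1L), integer(1L)),
        names(lens))
    }

    mut_rows <- vector("list", nrow(isoforms))
    for (g in seq_len(nrow(isoforms))) {
      iso <- isoforms$isoform_id[g]
      carriers <- samples[runif(n_samples) < rate]
      if (length(carriers) == 0L) next
      L <- lens[[iso]]
      pos <- if (placement == "uniform") {
        sample.int(L, length(carriers), replace = TRUE)
      } else {
        pmin(L, pmax(1L, hot[[iso]] +
                       sample(-5:5, length(carriers), replace = TRUE)))
      }
      mut_rows[[g]] <- data.frame(
        sample_id = carriers, gene_id = isoforms$gene_id[g], isoform_id = iso,
        position = as.integer(pos))
    }
    mutations <- do.call(rbind, mut_rows)
    if (is.null(mutations)) {
      mutations <- data.frame(sample_id = character(), gene_id = character(),
                              isoform_id = character(), position = integer())
    }

    # Top-up planted-effect regions to a guaranteed carrier count, using
    # samples not yet mutated in the owning gene (keeps carrier sets of
    # sibling regions disjoint).
    if (min_mutated_per_effect > 0L && nrow(truth$effects) > 0L) {
      for (region in unique(truth$effects$region_id)) {
        ri <- match(region, regions$region_id)
        iso <- regions$isoform_id[ri]
        gene <- regions$gene_id[ri]
        in_region <- mutations$isoform_id == iso &
          mutations$position >= regions$start[ri] &
          mutations$position <= regions$end[ri]
        have <- unique(mutations$sample_id[in_region])
        need <- min_mutated_per_effect - length(have)
        if (need <= 0L) next
        gene_carriers <- unique(mutations$sample_id[mutations$gene_id == gene])
        pool <- setdiff(samples, gene_carriers)
        if (length(pool) < need) {
          stop_input("cannot guarantee %d carriers for %s: only %d gene-naive samples left",
                     min_mutated_per_effect, region, length(pool))
        }
        extra <- sample(pool, need)
        mutations <- rbind(mutations, data.frame(
          sample_id = extra, gene_id = gene, isoform_id = iso,
          position = as.integer(sample_range(regions$start[ri],
                                             regions$end[ri], need))))
      }
    }

    # reference/alternate residues from the sequence
    if (nrow(mutations) > 0L) {
      seq_map <- setNames(isoforms$sequence, isoforms$isoform_id)
      mutations$ref_aa <- substring(seq_map[mutations$isoform_id],
                                    mutations$position, mutations$position)
      mutations$alt_aa <- vapply(mutations$ref_aa, function(r) {
        sample(setdiff(AA20, r), 1L)
      }, character(1L), USE.NAMES = FALSE)
      mutations <- mutations[order(mutations$sample_id, mutations$gene_id,
                                   mutations$position), , drop = FALSE]
      rownames(mutations) <- NULL
    } else {
      mutations$ref_aa <- character()
      mutations$alt_aa <- character()
    }

    activity <- matrix(
      rnorm(n_samples * length(drugs), truth$baseline_mean, truth$noise_sd),
      nrow = n_samples, dimnames = list(samples, drugs))
    if (nrow(truth$effects) > 0L) {
      asg <- assign_mutations_to_regions(mutations, regions)
      for (e in seq_len(nrow(truth$effects))) {
        eff <- truth$effects[e, ]
        carriers <- unique(asg$sample_id[asg$region_id == eff$region_id])
        activity[carriers, eff$drug_id] <-
          activity[carriers, eff$drug_id] + eff$delta
      }
    }
    activity[activity < 0] <- 0

    edrug_cohort(isoforms, regions, mutations, activity)
  })
}

#' Score an association run against planted truth
#'
#' A planted (region, drug) effect counts as recovered (true positive) when
#' its pair is called `significant` with the matching direction
#' (`sensitizing` for positive delta, `resistance` for negative). Any other
#' `significant` pair -- unplanted, or planted with mismatched direction --
#' is a false positive.
#'
#' @param results An `edrug_results` table from [run_edrug()].
#' @param truth The [synthetic_truth()] used to generate the cohort.
#' @return List: `n_planted`, `n_tested` (pairs with a stage-I p-value),
#'   `tp`, `fp`, `sensitivity` (`NA` when nothing was planted),
#'   `type_i_error` (significant fraction of tested unplanted pairs) and
#'   `stage1_positive_rate` (tested pairs with stage-I p below 0.01).
#' @export
recovery_report <- function(results, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  require_columns(results, c("region_id", "drug_id", "status", "direction",
                             "p_stage1"), "results")
  eff <- truth$effects
  key <- function(r, d) paste(r, d, sep = "\r")
  planted <- key(eff$region_id, eff$drug_id)
  if (length(planted) > 0L &&
      !all(planted %in% key(results$region_id, results$drug_id))) {
    stop_input("truth references (region, drug) pairs absent from results")
  }
  res_key <- key(results$region_id, results$drug_id)
  sig <- results$status == "significant"
  planted_dir <- setNames(effect_direction(eff$delta), planted)
  is_planted <- res_key %in% planted
  matched <- sig & is_planted &
    results$direction == planted_dir[res_key]
  matched[is.na(matched)] <- FALSE
  tested <- !is.na(results$p_stage1)
  tp <- sum(matched)
  fp <- sum(sig, na.rm = TRUE) - tp
  n_tested_unplanted <- sum(tested & !is_planted)
  list(
    n_planted = length(planted),
    n_tested = sum(tested),
    tp = tp,
    fp = fp,
    sensitivity = if (length(planted) > 0L) tp / length(planted) else NA_real_,
    type_i_error = if (n_tested_unplanted > 0L)
      sum(sig & !is_planted, na.rm = TRUE) / n_tested_unplanted else NA_real_,
    stage1_positive_rate = if (sum(tested) > 0L)
      sum(results$p_stage1[tested] < 0.01) / sum(tested) else NA_real_
  )
}
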