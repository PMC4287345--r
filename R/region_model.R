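# Protein functional regions: disorder prediction, isoform selection and
# mutation-to-region assignment.
#
# Conventions used throughout the package:
#   * isoform tables:  data.frame(gene_id, isoform_id, sequence)
#   * region tables:   data.frame(region_id, gene_id, isoform_id, source,
#                                 start, end, name), 1-based inclusive
#   * mutation tables: data.frame(sample_id, gene_id, isoform_id, position,
#                                 ref_aa, alt_aa), missense only

# Kyte-Doolittle hydropathy, rescaled to [0,1] inside foldindex_profile().
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

#' Per-residue fold/unfold propensity profile
#'
#' Computes a charge/hydropathy disorder score for every residue of a protein
#' sequence, in the FoldIndex formulation: over a window centred on each
#' residue (truncated at the termini),
#' \deqn{FI = 2.785 \langle H \rangle - |\langle q \rangle| - 1.151}
#' where \eqn{\langle H \rangle} is the mean Kyte-Doolittle hydropathy
#' rescaled to \[0,1\] via \eqn{(h + 4.5)/9} and \eqn{\langle q \rangle} is
#' the mean net charge (K, R = +1; D, E = -1; all other residues 0).
#' Negative scores indicate predicted disorder; positive scores predicted
#' order.
#'
#' The 20 standard amino acids are accepted, plus `X`, which contributes a
#' neutral scaled hydropathy of 0.5 and zero charge. Any other letter is
#' rejected.
#'
#' @param sequence Single amino-acid string (one-letter code).
#' @param window Odd positive integer; the sliding-window width (default 51,
#'   the disorder predictor's customary default). Windows are truncated at
#'   the sequence termini, so every residue receives a score.
#' @return Numeric vector of length `nchar(sequence)` of unfold scores, with
#'   attribute `window`.
#' @examples
#' foldindex_profile("MKKLLILTCLVAVALA", window = 5)
#' @seealso [predict_idrs()] to extract disordered intervals from a profile.
#' @export
foldindex_profile <- function(sequence, window = 51L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) < 1L) {
    stop_input("`sequence` must be a non-empty amino-acid string")
  }
  if (!is_count(window) || window %% 2 == 0) {
    stop_input("`window` must be an odd positive integer (got %s)",
               format(window))
  }
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), c(names(KD_HYDROPATHY), "X"))
  if (length(bad) > 0L) {
    stop_input("non-standard residue(s) in sequence: %s",
               paste(bad, collapse = ", "))
  }
  # integer accumulators (hydropathy in tenths, shifted to 0..90) keep the
  # window sums exact, so reversing the sequence reverses the profile
  # bit-for-bit
  h10 <- round((unname(KD_HYDROPATHY[aa]) + 4.5) * 10)
  h10[aa == "X"] <- 45
  q <- unname(AA_CHARGE[aa])
  q[is.na(q)] <- 0

  n <- length(aa)
  half <- (window - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  width <- hi - lo + 1L
  csh <- cumsum(c(0, h10))
  csq <- cumsum(c(0, q))
  mean_h <- (csh[hi + 1L] - csh[lo]) / (90 * width)
  mean_q <- (csq[hi + 1L] - csq[lo]) / width

  scores <- 2.785 * mean_h - abs(mean_q) - 1.151
  attr(scores, "window") <- as.integer(window)
  scores
}

#' Extract intrinsically disordered regions from a disorder profile
#'
#' Returns the maximal runs of consecutive residues whose unfold score falls
#' below `threshold`, keeping only runs of at least `min_length` residues.
#' Intervals are 1-based inclusive, sorted by start, and non-overlapping by
#' construction.
#'
#' @param scores Numeric per-residue profile, e.g. from [foldindex_profile()].
#' @param threshold Scores strictly below this value count as disordered
#'   (default -0.1).
#' @param min_length Minimum run length to report (default 10 residues).
#' @return data.frame with columns `start`, `end`, `length`.
#' @export
predict_idrs <- function(scores, threshold = -0.1, min_length = 10L) {
  if (!is.numeric(scores) || length(scores) < 1L) {
    stop_input("`scores` must be a non-empty numeric profile")
  }
  if (!is_count(min_length)) stop_input("`min_length` must be a positive integer")
  below <- scores < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    length = as.integer(r$lengths[keep])
  )
}

#' Predict disordered regions for a table of isoforms
#'
#' Convenience wrapper running [foldindex_profile()] + [predict_idrs()] over
#' an isoform table and returning the intervals as a region table with
#' `source = "idr"`, ready to be combined with annotated domain intervals.
#'
#' @param isoforms data.frame with columns `gene_id`, `isoform_id`,
#'   `sequence`.
#' @inheritParams foldindex_profile
#' @inheritParams predict_idrs
#' @return A region table (`region_id`, `gene_id`, `isoform_id`, `source`,
#'   `start`, `end`, `name`). Region ids are `<isoform_id>:IDR<k>`.
#' @export
idr_regions <- function(isoforms, window = 51L, threshold = -0.1,
                        min_length = 10L) {
  require_columns(isoforms, c("gene_id", "isoform_id", "sequence"), "isoforms")
  out <- lapply(seq_len(nrow(isoforms)), function(i) {
    prof <- foldindex_profile(isoforms$sequence[i], window = window)
    runs <- predict_idrs(prof, threshold = threshold, min_length = min_length)
    if (nrow(runs) == 0L) return(NULL)
    data.frame(
      region_id = sprintf("%s:IDR%d", isoforms$isoform_id[i], seq_len(nrow(runs))),
      gene_id = isoforms$gene_id[i],
      isoform_id = isoforms$isoform_id[i],
      source = "idr",
      start = runs$start,
      end = runs$end,
      name = sprintf("IDR %d-%d", runs$start, runs$end)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- empty_region_table()
  }
  rownames(out) <- NULL
  out
}

empty_region_table <- function() {
  data.frame(
    region_id = character(), gene_id = character(), isoform_id = character(),
    source = character(), start = integer(), end = integer(),
    name = character()
  )
}

#' Pick the largest isoform of each gene
#'
#' Analyses are restricted to one isoform per gene: the one with the longest
#' sequence. Length ties break to the lexicographically smallest
#' `isoform_id`, so the choice is deterministic across input orderings.
#'
#' @param isoforms data.frame with columns `gene_id`, `isoform_id`,
#'   `sequence`. For [select_largest_isoform()] all rows must belong to one
#'   gene; [largest_isoforms()] applies the rule per gene.
#' @return One isoform row ([select_largest_isoform()]) or one row per gene
#'   ([largest_isoforms()]).
#' @export
select_largest_isoform <- function(isoforms) {
  require_columns(isoforms, c("gene_id", "isoform_id", "sequence"), "isoforms")
  if (nrow(isoforms) == 0L) stop_input("no isoforms supplied")
  if (length(unique(isoforms$gene_id)) != 1L) {
    stop_input("select_largest_isoform() expects isoforms of a single gene")
  }
  len <- nchar(isoforms$sequence)
  ord <- order(-len, isoforms$isoform_id)
  out <- isoforms[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname select_largest_isoform
#' @export
largest_isoforms <- function(isoforms) {
  require_columns(isoforms, c("gene_id", "isoform_id", "sequence"), "isoforms")
  picked <- lapply(split(isoforms, isoforms$gene_id), select_largest_isoform)
  out <- do.call(rbind, picked)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign missense mutations to functional regions
#'
#' A mutation at residue `p` of an isoform is assigned to every region of
#' that isoform whose interval covers `p`. Overlapping regions each receive
#' the mutation (regions are tested independently and are never merged).
#' Mutations covered by no region contribute to gene-level tests only.
#'
#' @param mutations Mutation table (`sample_id`, `gene_id`, `isoform_id`,
#'   `position`, ...).
#' @param regions Region table.
#' @param isoforms Optional isoform table; when supplied, any mutation whose
#'   position exceeds its isoform's length raises an error naming the record.
#' @return data.frame with one row per (mutation, covering region) pair:
#'   columns `region_id`, `gene_id`, `isoform_id`, `sample_id`, `position`.
#' @export
assign_mutations_to_regions <- function(mutations, regions, isoforms = NULL) {
  require_columns(mutations, c("sample_id", "gene_id", "isoform_id", "position"),
                  "mutations")
  require_columns(regions, c("region_id", "isoform_id", "start", "end"),
                  "regions")
  if (!is.null(isoforms)) {
    len <- setNames(nchar(isoforms$sequence), isoforms$isoform_id)
    known <- mutations$isoform_id %in% names(len)
    over <- known & mutations$position > len[mutations$isoform_id]
    if (any(over)) {
      i <- which(over)[1L]
      stop_input(
        "mutation %s:%s position %d exceeds isoform %s length %d",
        mutations$sample_id[i], mutations$gene_id[i], mutations$position[i],
        mutations$isoform_id[i], len[[mutations$isoform_id[i]]])
    }
  }
  empty <- data.frame(
    region_id = character(), gene_id = character(), isoform_id = character(),
    sample_id = character(), position = integer()
  )
  if (nrow(regions) == 0L || nrow(mutations) == 0L) return(empty)
  hit <- merge(
    mutations[, c("sample_id", "isoform_id", "position")],
    regions[, c("region_id", "gene_id", "isoform_id", "start", "end")],
    by = "isoform_id"
  )
  hit <- hit[hit$position >= hit$start & hit$position <= hit$end, , drop = FALSE]
  if (nrow(hit) == 0L) return(empty)
  out <- hit[, c("region_id", "gene_id", "isoform_id", "sample_id", "position")]
  out <- out[order(out$region_id, out$sample_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Validate a region table against its isoforms; used by readers and the
# cohort constructor. Returns the table invisibly or raises a located error.
validate_regions <- function(regions, isoforms = NULL) {
  require_columns(regions,
                  c("region_id", "gene_id", "isoform_id", "source",
                    "start", "end", "name"), "regions")
  if (nrow(regions) == 0L) return(invisible(regions))
  bad_src <- setdiff(unique(regions$source), c("pfam", "predicted_domain", "idr"))
  if (length(bad_src) > 0L) {
    stop_input("unknown region source(s): %s", paste(bad_src, collapse = ", "))
  }
  bad <- regions$start < 1L | regions$end < regions$start
  if (any(bad)) {
    stop_input("region %s has an invalid interval [%d, %d]",
               regions$region_id[which(bad)[1L]],
               regions$start[which(bad)[1L]], regions$end[which(bad)[1L]])
  }
  if (anyDuplicated(regions$region_id)) {
    stop_input("duplicated region_id: %s",
               regions$region_id[duplicated(regions$region_id)][1L])
  }
  if (!is.null(isoforms)) {
    len <- setNames(nchar(isoforms$sequence), isoforms$isoform_id)
    known <- regions$isoform_id %in% names(len)
    over <- known & regions$end > len[regions$isoform_id]
    if (any(over)) {
      i <- which(over)[1L]
      stop_input("region %s: end %d exceeds isoform %s length %d",
                 regions$region_id[i], regions$end[i], regions$isoform_id[i],
                 len[[regions$isoform_id[i]]])
    }
  }
  invisible(regions)
}
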