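# Readers and writers for the package's external formats. Every reader
# validates the invariants of the objects it produces and raises a located
# format error rather than coercing silently. TSV/CSV files carry explicit
# headers; a missing value is an empty cell ('.' is not accepted).

read_tsv_checked <- function(path, cols, what) {
  if (!file.exists(path)) stop_input("%s: file not found: %s", what, path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "", quote = "", check.names = FALSE)
  require_columns(df, cols, sprintf("%s (%s)", what, path))
  df
}

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the isoform
#' identifier. The gene identifier is taken from a `gene=<id>` attribute in
#' the header, or from a two-column isoform-to-gene TSV map
#' (`isoform_id`, `gene_id`); one of the two must provide it.
#'
#' @param path FASTA file.
#' @param gene_map Optional path to (or data.frame of) an isoform-to-gene
#'   map.
#' @return Isoform table: `gene_id`, `isoform_id`, `sequence`.
#' @export
read_fasta <- function(path, gene_map = NULL) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop_input("FASTA file %s contains no sequences", path)
  headers <- names(set)
  isoform_id <- vapply(strsplit(headers, "\\s+"), `[[`, character(1L), 1L)
  gene_id <- rep(NA_character_, length(set))
  attr_at <- regexpr("gene=[^[:space:]]+", headers)
  has_attr <- attr_at > 0L
  gene_id[has_attr] <- sub("^gene=", "", regmatches(headers, attr_at))
  if (!is.null(gene_map)) {
    map <- if (is.character(gene_map)) {
      read_tsv_checked(gene_map, c("isoform_id", "gene_id"), "gene map")
    } else gene_map
    hit <- match(isoform_id, map$isoform_id)
    gene_id[is.na(gene_id)] <- map$gene_id[hit][is.na(gene_id)]
  }
  if (anyNA(gene_id)) {
    stop_input("no gene id for isoform %s (use a gene= header attribute or a gene map)",
               isoform_id[which(is.na(gene_id))[1L]])
  }
  if (anyDuplicated(isoform_id)) {
    stop_input("duplicated isoform id in %s: %s", path,
               isoform_id[duplicated(isoform_id)][1L])
  }
  data.frame(gene_id = gene_id, isoform_id = isoform_id,
             sequence = unname(as.character(set)))
}

#' @rdname read_fasta
#' @param isoforms Isoform table to write.
#' @export
write_fasta <- function(isoforms, path) {
  require_columns(isoforms, c("gene_id", "isoform_id", "sequence"), "isoforms")
  set <- Biostrings::AAStringSet(isoforms$sequence)
  names(set) <- sprintf("%s gene=%s", isoforms$isoform_id, isoforms$gene_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read missense mutations from a MAF-subset TSV
#'
#' Requires columns `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Transcript_ID`,
#' `Protein_position`, `Reference_AA`, `Alternate_AA`,
#' `Variant_Classification`. Only `Missense_Mutation` rows are kept;
#' the number of skipped non-missense rows is reported via [message()] and
#' stored in attribute `n_skipped`. Malformed rows (non-positive or
#' non-integer positions, identical reference and alternate residues) are
#' rejected with their line numbers.
#'
#' @param path TSV file.
#' @return Mutation table: `sample_id`, `gene_id`, `isoform_id`,
#'   `position`, `ref_aa`, `alt_aa`.
#' @export
read_mutations <- function(path) {
  maf_cols <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Transcript_ID",
                "Protein_position", "Reference_AA", "Alternate_AA",
                "Variant_Classification")
  df <- read_tsv_checked(path, maf_cols, "mutations")
  missense <- df$Variant_Classification == "Missense_Mutation"
  n_skipped <- sum(!missense)
  if (n_skipped > 0L) {
    message(sprintf("read_mutations: skipped %d non-missense row(s) in %s",
                    n_skipped, path))
  }
  keep <- df[missense, , drop = FALSE]
  lines <- which(missense) + 1L  # header is line 1
  pos <- suppressWarnings(as.numeric(keep$Protein_position))
  bad <- is.na(pos) | pos < 1 | pos != floor(pos)
  if (any(bad)) {
    stop_input("%s line %d: invalid Protein_position '%s' (1-based integer required)",
               path, lines[which(bad)[1L]],
               keep$Protein_position[which(bad)[1L]])
  }
  same <- keep$Reference_AA == keep$Alternate_AA
  if (any(same)) {
    stop_input("%s line %d: Reference_AA equals Alternate_AA ('%s'): not missense",
               path, lines[which(same)[1L]], keep$Reference_AA[which(same)[1L]])
  }
  out <- data.frame(
    sample_id = keep$Tumor_Sample_Barcode, gene_id = keep$Hugo_Symbol,
    isoform_id = keep$Transcript_ID, position = as.integer(pos),
    ref_aa = keep$Reference_AA, alt_aa = keep$Alternate_AA
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' @rdname read_mutations
#' @param mutations Mutation table to write.
#' @export
write_mutations <- function(mutations, path) {
  require_columns(mutations,
                  c("sample_id", "gene_id", "isoform_id", "position",
                    "ref_aa", "alt_aa"), "mutations")
  out <- data.frame(
    Tumor_Sample_Barcode = mutations$sample_id,
    Hugo_Symbol = mutations$gene_id,
    Transcript_ID = mutations$isoform_id,
    Protein_position = mutations$position,
    Reference_AA = mutations$ref_aa,
    Alternate_AA = mutations$alt_aa,
    Variant_Classification = "Missense_Mutation"
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a functional-region table
#'
#' Region TSVs carry columns `region_id`, `gene_id`, `isoform_id`,
#' `source` (`pfam`, `predicted_domain` or `idr`), `start`, `end` (1-based
#' inclusive residue coordinates) and `name`. When an isoform table is
#' supplied, intervals are checked against sequence lengths.
#'
#' @param path TSV file.
#' @param isoforms Optional isoform table for bounds checking.
#' @return Region table.
#' @export
read_regions <- function(path, isoforms = NULL) {
  df <- read_tsv_checked(path, c("region_id", "gene_id", "isoform_id",
                                 "source", "start", "end", "name"), "regions")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$name <- as.character(df$name)
  validate_regions(df, isoforms)
  df
}

#' @rdname read_regions
#' @param regions Region table to write.
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_regions
#' @description `write_regions_bed()` exports regions as BED (0-based,
#'   half-open) over protein coordinates, with the isoform as the sequence
#'   name.
#' @export
write_regions_bed <- function(regions, path) {
  validate_regions(regions)
  bed <- data.frame(chrom = regions$isoform_id, start = regions$start - 1L,
                    end = regions$end, name = regions$region_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a drug activity-area matrix from CSV
#'
#' First column `sample_id`, one further column per drug; an empty cell is
#' a missing measurement. Values must be non-negative; duplicated sample or
#' drug identifiers are format errors.
#'
#' @param path CSV file.
#' @return Numeric matrix, samples in rows, drugs in columns.
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop_input("activity file not found: %s", path)
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                 na.strings = "", check.names = FALSE)
  require_columns(df, "sample_id", sprintf("activity (%s)", path))
  if (ncol(df) < 2L) stop_input("%s: no drug columns", path)
  if (anyDuplicated(df$sample_id)) {
    stop_input("%s: duplicated sample_id '%s'", path,
               df$sample_id[duplicated(df$sample_id)][1L])
  }
  drugs <- setdiff(names(df), "sample_id")
  if (anyDuplicated(drugs)) {
    stop_input("%s: duplicated drug column '%s'", path,
               drugs[duplicated(drugs)][1L])
  }
  vals <- df[, drugs, drop = FALSE]
  if (any(vapply(vals, function(v) any(v == ".", na.rm = TRUE), logical(1L)))) {
    stop_input("%s: '.' is not a valid missing marker (leave the cell empty)",
               path)
  }
  m <- as.matrix(as.data.frame(lapply(vals, as.numeric)))
  colnames(m) <- drugs
  rownames(m) <- df$sample_id
  if (any(m < 0, na.rm = TRUE)) {
    stop_input("%s: negative activity-area value", path)
  }
  m
}

#' @rdname read_activity
#' @param activity Matrix to write.
#' @export
write_activity <- function(activity, path) {
  df <- data.frame(sample_id = rownames(activity), activity,
                   check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read or write an association result table
#'
#' The result TSV mirrors the columns of [run_edrug()] output; missing
#' p-values (stages not reached) are empty cells. Writing is deterministic:
#' the table is emitted in its (drug, region) order with fixed column
#' order, so identical runs produce byte-identical files.
#'
#' @param results `edrug_results` table.
#' @param path TSV file.
#' @export
write_results <- function(results, path) {
  cols <- c("region_id", "gene_id", "drug_id", "source",
            "n_region_mut", "n_other_mut", "n_unmut",
            "p_stage1", "p_gene", "p_stage2", "q_stage1",
            "delta_median", "direction", "status")
  require_columns(results, cols, "results")
  out <- as.data.frame(results)[, cols]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  cols <- c("region_id", "gene_id", "drug_id", "source",
            "n_region_mut", "n_other_mut", "n_unmut",
            "p_stage1", "p_gene", "p_stage2", "q_stage1",
            "delta_median", "direction", "status")
  df <- read_tsv_checked(path, cols, "results")
  for (col in c("p_stage1", "p_gene", "p_stage2", "q_stage1", "delta_median")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("n_region_mut", "n_other_mut", "n_unmut")) {
    df[[col]] <- as.integer(df[[col]])
  }
  class(df) <- c("edrug_results", "data.frame")
  df
}

#' Read clinical records
#'
#' TSV with columns `patient_id`, `drug_id`, `time_days` (non-negative),
#' `event` (1 = death/progression observed, 0 = censored).
#'
#' @param path TSV file.
#' @return data.frame of clinical records.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, c("patient_id", "drug_id", "time_days", "event"),
                         "clinical")
  df$time_days <- as.numeric(df$time_days)
  df$event <- as.integer(df$event)
  if (any(is.na(df$time_days)) || any(df$time_days < 0)) {
    stop_input("%s: time_days must be non-negative numbers", path)
  }
  if (!all(df$event %in% c(0L, 1L))) {
    stop_input("%s: event must be 0 (censored) or 1 (observed)", path)
  }
  df
}

#' Read chemical-protein interactions (STITCH dialect)
#'
#' TSV with columns `chemical_id`, `protein_id`, `combined_score`
#' (integer, 0-1000).
#'
#' @param path TSV file.
#' @return data.frame: `chemical_id`, `protein_id`, `score`.
#' @export
read_interactions <- function(path) {
  df <- read_tsv_checked(path, c("chemical_id", "protein_id", "combined_score"),
                         "interactions")
  score <- as.integer(df$combined_score)
  if (any(is.na(score)) || any(score < 0L | score > 1000L)) {
    stop_input("%s: combined_score must be an integer in [0, 1000]", path)
  }
  data.frame(chemical_id = df$chemical_id, protein_id = df$protein_id,
             score = score)
}

#' Read chemical fingerprints
#'
#' TSV with columns `chemical_id` and `fingerprint`, the latter a
#' hex-encoded bitstring (each hex digit encodes 4 bits, most significant
#' first). All fingerprints in one file must decode to the same length.
#'
#' @param path TSV file.
#' @return Named list of logical bit vectors.
#' @export
read_fingerprints <- function(path) {
  df <- read_tsv_checked(path, c("chemical_id", "fingerprint"), "fingerprints")
  if (anyDuplicated(df$chemical_id)) {
    stop_input("%s: duplicated chemical_id", path)
  }
  fps <- lapply(df$fingerprint, hex_to_bits)
  lens <- vapply(fps, length, 1L)
  if (length(unique(lens)) > 1L) {
    stop_input("%s: fingerprints of unequal length (%s)", path,
               paste(unique(lens), collapse = ", "))
  }
  setNames(fps, df$chemical_id)
}

hex_to_bits <- function(hex) {
  chars <- strsplit(tolower(hex), "", fixed = TRUE)[[1L]]
  vals <- strtoi(chars, base = 16L)
  if (anyNA(vals)) stop_input("invalid hex fingerprint: %s", hex)
  as.logical(unlist(lapply(vals, function(v) {
    bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L
  })))
}

bits_to_hex <- function(bits) {
  bits <- as.integer(as.logical(bits))
  pad <- (4L - length(bits) %% 4L) %% 4L
  bits <- c(bits, rep(0L, pad))
  nib <- matrix(bits, nrow = 4L)
  vals <- colSums(nib * c(8L, 4L, 2L, 1L))
  paste(format.hexmode(as.integer(vals)), collapse = "")
}

#' Read gene-to-GO-term annotations
#'
#' Two-column GAF-style TSV: `gene_id`, `term_id`.
#'
#' @param path TSV file.
#' @return data.frame: `gene_id`, `term_id`.
#' @export
read_gene_annotations <- function(path) {
  read_tsv_checked(path, c("gene_id", "term_id"), "annotations")[
    , c("gene_id", "term_id")]
}

#' Run configuration
#'
#' A flat YAML key-value file holding the association thresholds, disorder
#' predictor parameters, comparison-group flag and seed. Missing keys take
#' package defaults; [write_run_config()] writes the fully resolved
#' configuration (every run echoes it next to its outputs for provenance),
#' and the pair round-trips losslessly.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  modifyList(default_run_config(), cfg %||% list())
}

#' @rdname read_run_config
#' @param config Named list as returned by [read_run_config()] or
#'   [default_run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    p_stage1 = 0.01, p_gene = 0.01, p_stage2 = 0.05, min_mutated = 2L,
    comparison = "gene_unmutated",
    foldindex_window = 51L, idr_threshold = -0.1, idr_min_length = 10L,
    seed = 1L
  )
}
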