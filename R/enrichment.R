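# GO term enrichment of gene sets against a background, via one-sided
# Fisher tests with Benjamini-Hochberg q-values.

#' GO term enrichment of a gene set
#'
#' For every term annotating at least one background gene, tests whether
#' the term's genes are over-represented in `gene_set` relative to
#' `background` with a one-sided (greater) Fisher exact test, and adjusts
#' across tested terms with Benjamini-Hochberg.
#'
#' @param gene_set Character vector; must be a subset of `background`.
#' @param annotations data.frame(`gene_id`, `term_id`); gene-to-term
#'   annotation pairs (GAF-style, one pair per row).
#' @param background Character vector of all genes considered (e.g. every
#'   gene tested for association, or the whole genome).
#' @return data.frame ordered by p: `term_id`, `count_set`, `count_bg`,
#'   `p`, `q`.
#' @export
go_enrichment <- function(gene_set, annotations, background) {
  require_columns(annotations, c("gene_id", "term_id"), "annotations")
  if (length(background) == 0L) stop_input("`background` must be non-empty")
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (length(setdiff(gene_set, background)) > 0L) {
    stop_input("`gene_set` must be a subset of `background`")
  }
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  if (nrow(ann) == 0L) {
    return(data.frame(term_id = character(), count_set = integer(),
                      count_bg = integer(), p = numeric(), q = numeric()))
  }
  term_genes <- split(ann$gene_id, ann$term_id)
  n_bg <- length(background)
  n_set <- length(gene_set)
  rows <- lapply(names(term_genes), function(term) {
    tg <- term_genes[[term]]
    a <- length(intersect(tg, gene_set))
    cc <- length(tg) - a
    p <- fisher_exact(matrix(c(a, cc, n_set - a, n_bg - n_set - cc), 2L),
                      alternative = "greater")
    data.frame(term_id = term, count_set = a, count_bg = length(tg), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
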