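#' Hypergeometric term enrichment of a gene set
#'
#' Upper-tail hypergeometric test (enrichment only) of each annotation term in
#' a gene set against a background universe, with Benjamini-Hochberg
#' correction across terms.
#'
#' @param deg_set character vector of gene ids (e.g. significant DEGs); must
#'   be a subset of the universe.
#' @param annotation data frame with columns `gene_id`, `term` (one row per
#'   gene-term pair).
#' @param universe background gene ids; defaults to all annotated genes.
#'   Annotation rows for genes outside the universe are ignored.
#' @param alpha significance level on the corrected p-value.
#' @return data frame sorted by ascending corrected p-value with columns
#'   `term`, `k` (genes with term in the set), `n` (set size), `K` (background
#'   genes with term), `N` (background size), `p_value`, `corrected_p`,
#'   `significant`.
#' @export
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   term = c("T1", "T1", "T2"))
#' hypergeom_enrich(c("g1", "g2"), ann)
hypergeom_enrich <- function(deg_set, annotation, universe = NULL,
                             alpha = 0.05) {
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "term") %in% names(annotation)))
    stop_input("annotation needs columns 'gene_id' and 'term'")
  if (any(!nzchar(annotation$term)))
    stop_input("terms must be non-empty strings")
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  universe <- unique(universe)
  deg_set <- unique(deg_set)
  missing <- setdiff(deg_set, universe)
  if (length(missing) > 0)
    stop_input("gene(s) absent from the universe: ",
               paste(head(missing, 10), collapse = ", "))
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  annotation <- unique(annotation[, c("gene_id", "term")])
  if (nrow(annotation) == 0L) stop_input("annotation is empty")

  N <- length(universe)
  n <- length(deg_set)
  term_genes <- split(annotation$gene_id, annotation$term)
  K <- vapply(term_genes, length, integer(1))
  k <- vapply(term_genes, function(g) sum(g %in% deg_set), integer(1))
  # upper tail: P[X >= k] for X ~ Hypergeometric(N, K, n)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(term_genes), k = k, n = n, K = K, N = N,
                    p_value = p, corrected_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$corrected_p <= alpha
  out[order(out$corrected_p, out$p_value, out$term), , drop = FALSE]
}
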