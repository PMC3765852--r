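#' Normalize per-gene tag counts to tags per million clean tags (TPM)
#'
#' TPM here is the classic tag-profiling unit: unambiguous tag copies per
#' million clean tags of the library. It is library-size normalization only;
#' counts are gene-length independent by design of the protocol.
#'
#' @param counts named numeric vector of unambiguous per-gene tag counts
#'   (genes with zero count may be included and are retained at 0 TPM), or a
#'   [map_tags()] result.
#' @param total_clean total clean tags of the library (> 0). Taken from the
#'   mapping result when `counts` is one.
#' @param sample_id library label.
#' @param gene_universe optional character vector of gene ids; genes absent
#'   from `counts` are filled in at count 0.
#' @return object of class `expression_profile`: data frame with columns
#'   `gene_id`, `count`, `tpm`; attributes `sample_id` and `total_clean`.
#' @export
#' @examples
#' prof <- to_tpm(c(g1 = 82, g2 = 0), total_clean = 1e6)
#' prof$tpm  # 82, 0
to_tpm <- function(counts, total_clean = NULL, sample_id = "sample",
                   gene_universe = NULL) {
  if (inherits(counts, "mapping_result")) {
    res <- counts
    if (is.null(total_clean)) total_clean <- res$total_clean
    sample_id <- res$sample_id
    counts <- setNames(res$gene_counts$copies, res$gene_counts$gene_id)
  }
  if (is.null(total_clean) || total_clean <= 0)
    stop_input("total_clean must be a positive count")
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  if (!is.null(gene_universe)) {
    full <- setNames(numeric(length(gene_universe)), gene_universe)
    full[names(counts)] <- counts
    counts <- full
  }
  out <- data.frame(gene_id = names(counts), count = unname(counts),
                    tpm = unname(counts) / total_clean * 1e6,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "total_clean") <- total_clean
  class(out) <- c("expression_profile", "data.frame")
  out
}

#' Distribution of gene expression over copy-number bins
#'
#' Histogram of genes per tag-copy bin, plus the fraction of expressed genes
#' seen in fewer than 30 copies (the low-expression share).
#'
#' @param profile an [to_tpm()] expression profile.
#' @param breaks right-open copy-number bin edges.
#' @return list with `histogram` (data frame `bin`, `n_genes`) and
#'   `frac_below_30` (fraction of genes with count in \[1, 30)).
#' @export
expression_distribution <- function(profile,
                                    breaks = c(1, 5, 10, 30, 100, 500, Inf)) {
  stopifnot(inherits(profile, "expression_profile"))
  expressed <- profile$count[profile$count > 0]
  if (length(expressed) == 0L) {
    return(list(histogram = data.frame(bin = character(0),
                                       n_genes = integer(0)),
                frac_below_30 = NA_real_))
  }
  bin <- cut(expressed, breaks = breaks, right = FALSE)
  hist <- as.data.frame(table(bin), stringsAsFactors = FALSE)
  names(hist) <- c("bin", "n_genes")
  list(histogram = hist,
       frac_below_30 = mean(expressed < 30))
}

#' Gene-detection saturation curve
#'
#' Subsamples tag copies without replacement at increasing depths (nested
#' prefixes of one seeded permutation, so the series is non-decreasing by
#' construction), maps each subsample and counts genes detected with at least
#' one unambiguous tag.
#'
#' @param lib a [clean_tags()] library.
#' @param ref a [build_virtual_library()] reference.
#' @param fractions depths as fractions of `total_clean`, in (0, 1\]; the
#'   final point should be 1 to use the full library.
#' @param seed subsampling seed.
#' @param ... passed to [map_tags()].
#' @return data frame with columns `depth`, `detected_genes`; attribute
#'   `seed`.
#' @export
saturation_curve <- function(lib, ref, fractions = seq(0.1, 1, by = 0.1),
                             seed = 1L, ...) {
  stopifnot(inherits(lib, "tag_library"))
  if (any(fractions <= 0 | fractions > 1))
    stop_input("fractions must lie in (0, 1]")
  depths <- unique(sort(pmin(ceiling(fractions * lib$total_clean),
                             lib$total_clean)))
  result <- map_tags(lib, ref, ...)
  a <- result$assignments
  gene_code <- ifelse(a$status == "unambiguous",
                      match(a$gene_id, ref$gene_ids), NA_integer_)
  per_copy <- rep(gene_code, a$count)
  perm <- with_seed(seed, sample.int(length(per_copy)))
  per_copy <- per_copy[perm]
  detected <- vapply(depths, function(d) {
    length(unique(per_copy[seq_len(d)][!is.na(per_copy[seq_len(d)])]))
  }, integer(1))
  out <- data.frame(depth = depths, detected_genes = detected)
  attr(out, "seed") <- seed
  out
}

#' Pearson correlation between two libraries
#'
#' Computed over the union of entities (distinct tags for tag libraries, the
#' default view of reproducibility; genes for expression profiles), with
#' entities absent from one library counted as 0, on TPM values.
#'
#' @param a,b two [clean_tags()] libraries or two [to_tpm()] profiles.
#' @param log correlate `log2(TPM + 1)` instead of raw TPM.
#' @return Pearson correlation coefficient.
#' @export
library_correlation <- function(a, b, log = FALSE) {
  if (inherits(a, "tag_library") && inherits(b, "tag_library")) {
    entities <- union(names(a$tag_counts), names(b$tag_counts))
    va <- numeric(length(entities)); vb <- va
    va[match(names(a$tag_counts), entities)] <- a$tag_counts
    vb[match(names(b$tag_counts), entities)] <- b$tag_counts
    va <- va / a$total_clean * 1e6
    vb <- vb / b$total_clean * 1e6
  } else if (inherits(a, "expression_profile") &&
             inherits(b, "expression_profile")) {
    entities <- union(a$gene_id, b$gene_id)
    va <- numeric(length(entities)); vb <- va
    va[match(a$gene_id, entities)] <- a$tpm
    vb[match(b$gene_id, entities)] <- b$tpm
  } else {
    stop_input("inputs must both be tag libraries or both expression profiles")
  }
  if (length(entities) < 2L)
    stop_input("correlation undefined on fewer than 2 entities")
  if (log) { va <- log2(va + 1); vb <- log2(vb + 1) }
  cor(va, vb, method = "pearson")
}
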