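#' Build the virtual reference tag library
#'
#' Scans every reference gene on the sense strand for CATG occurrences with at
#' least 17 nt downstream and indexes the 21-nt CATG+17 window under every
#' gene carrying it. Windows containing N are skipped (and counted in the
#' returned object). Input case is ignored.
#'
#' @param reference named character vector of gene sequences, or a
#'   `Biostrings::DNAStringSet`; names are gene ids and must be unique.
#' @param both_strands also index tags from the reverse-complement strand.
#'   Off by default: the protocol sequences the mRNA 3' fragment.
#' @return an object of class `virtual_tag_library`: a list with `tags`
#'   (data frame `tag`, `gene_id`, `site`, `offset`, `strand`; `offset` is the
#'   0-based position of the C of CATG), `genes_with_catg`, `canonical`
#'   (3'-most tag per gene), `n_reference_genes`, `n_reference_tags`
#'   (distinct indexed tag sequences), `gene_ids`, `n_skipped_n_windows`.
#' @export
#' @examples
#' ref <- c(g1 = paste0("AAACATG", strrep("A", 17)))
#' lib <- build_virtual_library(ref)
#' lib$n_reference_tags
build_virtual_library <- function(reference, both_strands = FALSE) {
  if (methods::is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  if (length(reference) == 0L) stop_input("empty reference")
  ids <- names(reference)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop_input("every reference gene needs a non-empty id")
  if (anyDuplicated(ids))
    stop_input("duplicate gene_id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(reference) < 1L)) stop_input("zero-length sequence in reference")
  reference <- toupper(reference)

  scan_strand <- function(seqs, strand) {
    dna <- Biostrings::DNAStringSet(seqs)
    hits <- Biostrings::vmatchPattern(TAG_ANCHOR, dna)
    rows <- lapply(seq_along(seqs), function(i) {
      st <- BiocGenerics::start(hits[[i]])
      st <- st[st + TAG_LENGTH - 1L <= nchar(seqs[i])]
      if (length(st) == 0L) return(NULL)
      tag <- substring(seqs[i], st, st + TAG_LENGTH - 1L)
      keep <- !grepl("N", tag, fixed = TRUE)
      n_skipped <- sum(!keep)
      if (!any(keep)) return(list(df = NULL, skipped = n_skipped))
      st <- st[keep]; tag <- tag[keep]
      list(df = data.frame(tag = tag, gene_id = ids[i],
                           site = seq_along(st), offset = st - 1L,
                           strand = strand, stringsAsFactors = FALSE),
           skipped = n_skipped)
    })
    rows
  }

  parts <- scan_strand(reference, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reference)))
    parts <- c(parts, scan_strand(setNames(rc, ids), "-"))
  }
  skipped <- sum(vapply(parts, function(p)
    if (is.null(p)) 0L else p$skipped, integer(1)))
  dfs <- Filter(Negate(is.null), lapply(parts, function(p) p$df))
  tags <- if (length(dfs) > 0) do.call(rbind, dfs) else
    data.frame(tag = character(0), gene_id = character(0),
               site = integer(0), offset = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  rownames(tags) <- NULL

  sense <- tags[tags$strand == "+", , drop = FALSE]
  canonical <- setNames(rep(NA_character_, length(ids)), ids)
  if (nrow(sense) > 0) {
    last <- tapply(seq_len(nrow(sense)), sense$gene_id,
                   function(i) i[which.max(sense$offset[i])])
    canonical[names(last)] <- sense$tag[unlist(last)]
  }

  structure(list(
    tags = tags,
    genes_with_catg = sort(unique(tags$gene_id)),
    canonical = canonical,
    gene_ids = ids,
    n_reference_genes = length(ids),
    n_reference_tags = length(unique(tags$tag)),
    n_skipped_n_windows = skipped
  ), class = "virtual_tag_library")
}

#' Census of a virtual tag library
#'
#' Reports the reference-level accounting: total genes, genes with at least
#' one eligible CATG site, distinct reference tags, and tags shared by more
#' than one gene.
#'
#' @param lib a [build_virtual_library()] result.
#' @return list with `n_reference_genes`, `n_genes_with_catg`,
#'   `n_reference_tags`, `n_shared_tags`.
#' @export
library_census <- function(lib) {
  stopifnot(inherits(lib, "virtual_tag_library"))
  shared <- 0L
  if (nrow(lib$tags) > 0) {
    genes_per_tag <- tapply(lib$tags$gene_id, lib$tags$tag,
                            function(g) length(unique(g)))
    shared <- sum(genes_per_tag > 1L)
  }
  list(n_reference_genes = lib$n_reference_genes,
       n_genes_with_catg = length(lib$genes_with_catg),
       n_reference_tags = lib$n_reference_tags,
       n_shared_tags = as.integer(shared))
}

#' @export
print.virtual_tag_library <- function(x, ...) {
  cen <- library_census(x)
  cat("Virtual tag library\n",
      "  reference genes:  ", cen$n_reference_genes, "\n",
      "  genes with CATG:  ", cen$n_genes_with_catg, "\n",
      "  reference tags:   ", cen$n_reference_tags, "\n",
      "  shared tags:      ", cen$n_shared_tags, "\n",
      "  N-windows skipped:", x$n_skipped_n_windows, "\n", sep = "")
  invisible(x)
}
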