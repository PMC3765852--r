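#' Map clean tags to reference genes with at most one mismatch
#'
#' A tag with one or more exact hits is resolved at distance 0 only
#' (exact-match priority); otherwise all distance-1 hits are considered. If
#' the resolved hit set touches exactly one gene the tag is `unambiguous`;
#' more than one gene, `ambiguous` (such tags are filtered from expression
#' counting); no hit, `unknown`. Ambiguity is decided at the gene level: a tag
#' hitting two sites of the same gene is unambiguous for that gene.
#'
#' @param lib a [clean_tags()] tag library.
#' @param ref a [build_virtual_library()] virtual tag library.
#' @param max_mismatch 0 or 1.
#' @param method `"index"` (default; exact hash lookup plus the 63
#'   single-substitution variants per unmatched tag, sublinear in reference
#'   size) or `"brute"` (all-pairs Hamming distance, used as a cross-check).
#' @param anchor_exact restrict mismatches to the 17-nt variable region,
#'   keeping the CATG anchor exact.
#' @return object of class `mapping_result`: list with `assignments`
#'   (data frame `tag`, `count`, `status`, `gene_id`), `gene_counts`
#'   (data frame `gene_id`, `copies`, `distinct_tags` over unambiguous tags),
#'   `genes_all_mapped` (genes touched by any mapped tag, ambiguous included),
#'   `genes_unambiguous`, and the library totals.
#' @export
map_tags <- function(lib, ref, max_mismatch = 1L,
                     method = c("index", "brute"),
                     anchor_exact = FALSE) {
  stopifnot(inherits(lib, "tag_library"), inherits(ref, "virtual_tag_library"))
  method <- match.arg(method)
  if (!max_mismatch %in% c(0L, 1L))
    stop_input("max_mismatch must be 0 or 1 (got ", max_mismatch, ")")
  qtags <- names(lib$tag_counts)
  ref_tags <- unique(ref$tags$tag)
  if (length(qtags) > 0 && length(ref_tags) > 0 &&
      any(nchar(qtags) != nchar(ref_tags[1])))
    stop_input("library tag length differs from reference tag length")

  # gene sets per distinct reference tag, as integer codes for fast unions
  gene_code <- match(ref$tags$gene_id, ref$gene_ids)
  tag_code <- match(ref$tags$tag, ref_tags)
  genes_by_tag <- split(gene_code, tag_code)  # names are tag codes

  status <- rep("unknown", length(qtags))
  gene_of <- rep(NA_character_, length(qtags))
  touched <- logical(length(ref$gene_ids))

  resolve <- function(i, gene_codes) {
    g <- unique(gene_codes)
    touched[g] <<- TRUE
    if (length(g) == 1L) {
      status[i] <<- "unambiguous"
      gene_of[i] <<- ref$gene_ids[g]
    } else {
      status[i] <<- "ambiguous"
    }
  }

  if (length(qtags) > 0 && length(ref_tags) > 0) {
    if (method == "index") {
      exact <- match(qtags, ref_tags)
      for (i in which(!is.na(exact)))
        resolve(i, genes_by_tag[[as.character(exact[i])]])
      pending <- which(is.na(exact))
      if (max_mismatch >= 1L && length(pending) > 0) {
        positions <- if (anchor_exact) 5:TAG_LENGTH else 1:TAG_LENGTH
        hit_lists <- variant_hits(qtags[pending], ref_tags, positions)
        for (j in seq_along(pending)) {
          codes <- hit_lists[[j]]
          if (length(codes) > 0)
            resolve(pending[j], unlist(genes_by_tag[as.character(codes)],
                                       use.names = FALSE))
        }
      }
    } else {
      dm <- hamming_matrix(qtags, ref_tags)
      if (anchor_exact) {
        anchor_dm <- hamming_matrix(substr(qtags, 1L, 4L),
                                    substr(ref_tags, 1L, 4L))
        dm[anchor_dm > 0L & dm == 1L] <- 2L  # anchor mismatch not allowed
      }
      for (i in seq_along(qtags)) {
        d <- dm[i, ]
        hit <- which(d == 0L)
        if (length(hit) == 0L && max_mismatch >= 1L) hit <- which(d == 1L)
        if (length(hit) > 0)
          resolve(i, unlist(genes_by_tag[as.character(hit)],
                            use.names = FALSE))
      }
    }
  }

  assignments <- data.frame(tag = qtags,
                            count = unname(lib$tag_counts),
                            status = status, gene_id = gene_of,
                            stringsAsFactors = FALSE)
  un <- assignments[assignments$status == "unambiguous", , drop = FALSE]
  gene_counts <- if (nrow(un) > 0) {
    agg_c <- tapply(un$count, un$gene_id, sum)
    agg_d <- tapply(un$count, un$gene_id, length)
    data.frame(gene_id = names(agg_c), copies = as.integer(agg_c),
               distinct_tags = as.integer(agg_d), stringsAsFactors = FALSE,
               row.names = NULL)
  } else {
    data.frame(gene_id = character(0), copies = integer(0),
               distinct_tags = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(
    assignments = assignments,
    gene_counts = gene_counts,
    genes_all_mapped = ref$gene_ids[touched],
    genes_unambiguous = sort(unique(un$gene_id)),
    sample_id = lib$sample_id,
    total_clean = lib$total_clean,
    distinct_clean = lib$distinct_clean
  ), class = "mapping_result")
}

# for each query without an exact hit, the reference-tag codes reachable by
# exactly one substitution; returns a list parallel to `queries`
variant_hits <- function(queries, ref_tags, positions) {
  nq <- length(queries)
  npos <- length(positions)
  bases <- c("A", "C", "G", "T")
  # 3 substitutions per position per query, fully vectorized
  rep_q <- rep(queries, each = npos * 3L)
  rep_pos <- rep(rep(positions, each = 3L), times = nq)
  cur <- substr(rep_q, rep_pos, rep_pos)
  alt <- bases[(match(cur, bases) + rep(1:3, npos * nq) - 1L) %% 4L + 1L]
  substr(rep_q, rep_pos, rep_pos) <- alt
  hit <- match(rep_q, ref_tags)
  origin <- rep(seq_len(nq), each = npos * 3L)
  keep <- !is.na(hit)
  out <- vector("list", nq)
  if (any(keep)) {
    found <- split(hit[keep], origin[keep])
    out[as.integer(names(found))] <- lapply(found, unique)
  }
  out[vapply(out, is.null, logical(1))] <- list(integer(0))
  out
}

#' Percentage as printed in mapping-statistics tables
#'
#' `numerator / denominator * 100`, rounded half away from zero to two
#' decimals. A zero denominator yields 0 with a warning.
#'
#' @param numerator,denominator counts.
#' @return numeric percentage.
#' @export
#' @examples
#' mapping_percent(1215015, 3366354)  # 36.09
mapping_percent <- function(numerator, denominator) {
  if (denominator == 0) {
    warning("zero denominator; reporting 0.00")
    return(0)
  }
  pct(numerator, denominator)
}

#' Mapping statistics in the style of a DGE sequencing summary table
#'
#' Counts and percentages for all-mapped, unambiguous and unknown tags (total
#' and distinct), and for tag-mapped genes (all and unambiguous) against the
#' reference gene count.
#'
#' @param result a [map_tags()] result.
#' @param ref the [build_virtual_library()] used for mapping.
#' @return object of class `mapping_stats`: a data frame with columns
#'   `section`, `metric`, `value`; percentages carry two decimals.
#' @export
mapping_stats <- function(result, ref) {
  stopifnot(inherits(result, "mapping_result"),
            inherits(ref, "virtual_tag_library"))
  a <- result$assignments
  mapped <- a$status != "unknown"
  unamb <- a$status == "unambiguous"
  tot <- result$total_clean
  dis <- result$distinct_clean
  ngene <- ref$n_reference_genes
  row <- function(section, metric, value)
    data.frame(section = section, metric = metric, value = value,
               stringsAsFactors = FALSE)
  stats <- rbind(
    row("Clean Tag", "Total number", tot),
    row("Clean Tag", "Distinct Tag number", dis),
    row("All Tag Mapping to Gene", "Total number", sum(a$count[mapped])),
    row("All Tag Mapping to Gene", "Total % of clean tag",
        mapping_percent(sum(a$count[mapped]), tot)),
    row("All Tag Mapping to Gene", "Distinct Tag number", sum(mapped)),
    row("All Tag Mapping to Gene", "Distinct Tag % of clean tag",
        mapping_percent(sum(mapped), dis)),
    row("Unambiguous Tag Mapping to Gene", "Total number",
        sum(a$count[unamb])),
    row("Unambiguous Tag Mapping to Gene", "Total % of clean tag",
        mapping_percent(sum(a$count[unamb]), tot)),
    row("Unambiguous Tag Mapping to Gene", "Distinct Tag number", sum(unamb)),
    row("Unambiguous Tag Mapping to Gene", "Distinct Tag % of clean tag",
        mapping_percent(sum(unamb), dis)),
    row("All Tag-mapped Genes", "number", length(result$genes_all_mapped)),
    row("All Tag-mapped Genes", "% of ref genes",
        mapping_percent(length(result$genes_all_mapped), ngene)),
    row("Unambiguous Tag-mapped Genes", "number",
        length(result$genes_unambiguous)),
    row("Unambiguous Tag-mapped Genes", "% of ref genes",
        mapping_percent(length(result$genes_unambiguous), ngene)),
    row("Unknown Tag", "Total number", sum(a$count[!mapped])),
    row("Unknown Tag", "Total % of clean tag",
        mapping_percent(sum(a$count[!mapped]), tot)),
    row("Unknown Tag", "Distinct Tag number", sum(!mapped)),
    row("Unknown Tag", "Distinct Tag % of clean tag",
        mapping_percent(sum(!mapped), dis))
  )
  class(stats) <- c("mapping_stats", "data.frame")
  stats
}

#' Combine per-sample mapping statistics into one table
#'
#' @param ... named [mapping_stats()] objects (names become column headers).
#' @return data frame with `section`, `metric` and one value column per
#'   sample.
#' @export
mapping_stats_table <- function(...) {
  stats <- list(...)
  if (is.null(names(stats)) || any(names(stats) == ""))
    names(stats) <- paste0("sample_", seq_along(stats))
  out <- stats[[1]][, c("section", "metric")]
  for (nm in names(stats)) out[[nm]] <- stats[[nm]]$value
  out
}
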