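#' Filter raw tag reads into a clean tag library
#'
#' Removes reads of the wrong length, reads containing N, reads with
#' non-nucleotide characters (counted as impurities) and reads matching a
#' declared adaptor prefix, then aggregates the survivors to distinct
#' (tag, count) pairs. Optionally drops copy-number-1 tags after aggregation.
#'
#' @param reads character vector of raw reads, or a data frame with columns
#'   `tag` and `count` (pre-aggregated input; the same filters apply to the
#'   tags, counts carried through).
#' @param sample_id label for the library.
#' @param adaptors character vector of adaptor sequences; a read is junk when
#'   it equals an adaptor truncated to tag length (exact prefix match).
#' @param tag_length expected tag length in nt.
#' @param drop_singletons drop tags seen exactly once (after aggregation).
#' @return object of class `tag_library`: list with `sample_id`,
#'   `tag_counts` (named integer vector, descending count then tag),
#'   `total_clean`, `distinct_clean`, `raw_total`, `raw_distinct`, and a
#'   `filtered` breakdown (wrong_length, with_n, impurity, adaptor,
#'   singletons).
#' @export
#' @examples
#' clean_tags(c(rep(paste0("CATG", strrep("A", 17)), 3),
#'              paste0("CATGNN", strrep("A", 15))), sample_id = "toy")
clean_tags <- function(reads, sample_id = "sample",
                       adaptors = DGE_ADAPTOR,
                       tag_length = TAG_LENGTH,
                       drop_singletons = FALSE) {
  if (is.data.frame(reads)) {
    if (!all(c("tag", "count") %in% names(reads)))
      stop_input("pre-aggregated input needs columns 'tag' and 'count'")
    tags <- rep(toupper(reads$tag), reads$count)
  } else {
    tags <- toupper(as.character(reads))
  }
  raw_total <- length(tags)
  raw_distinct <- length(unique(tags))
  if (raw_total == 0L) warning("empty input; returning an empty library")

  bad_len <- nchar(tags) != tag_length
  n_bad_len <- sum(bad_len)
  tags <- tags[!bad_len]

  impurity <- !grepl("^[ACGTN]*$", tags)
  n_impurity <- sum(impurity)
  tags <- tags[!impurity]

  with_n <- grepl("N", tags, fixed = TRUE)
  n_with_n <- sum(with_n)
  tags <- tags[!with_n]

  adaptor_prefixes <- unique(substr(toupper(adaptors), 1L, tag_length))
  is_adaptor <- tags %in% adaptor_prefixes
  n_adaptor <- sum(is_adaptor)
  tags <- tags[!is_adaptor]

  counts <- table(tags)
  counts <- setNames(as.integer(counts), names(counts))
  n_singletons <- 0L
  if (drop_singletons && length(counts) > 0) {
    drop <- counts == 1L
    n_singletons <- sum(drop)
    counts <- counts[!drop]
  }
  # descending count, then lexicographic tag
  if (length(counts) > 0)
    counts <- counts[order(-counts, names(counts))]

  structure(list(
    sample_id = sample_id,
    tag_counts = counts,
    total_clean = sum(counts),
    distinct_clean = length(counts),
    raw_total = raw_total,
    raw_distinct = raw_distinct,
    filtered = c(wrong_length = n_bad_len, with_n = n_with_n,
                 impurity = n_impurity, adaptor = n_adaptor,
                 singletons = n_singletons)
  ), class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Tag library '", x$sample_id, "'\n",
      "  raw:   ", x$raw_total, " total, ", x$raw_distinct, " distinct\n",
      "  clean: ", x$total_clean, " total, ", x$distinct_clean,
      " distinct\n", sep = "")
  invisible(x)
}

# bin labels follow the bracket notation of tag-abundance summaries
ABUNDANCE_BREAKS <- c(1, 2, 6, 11, 21, 51, 101, Inf)
ABUNDANCE_LABELS <- c("[1]", "[2,5]", "[6,10]", "[11,20]", "[21,50]",
                      "[51,100]", ">100")

#' Tag-abundance distribution of a clean library
#'
#' Distinct-tag and total-copy counts per copy-number category
#' (\[1\], \[2,5\], \[6,10\], \[11,20\], \[21,50\], \[51,100\], >100).
#' The two count columns sum to `distinct_clean` and `total_clean`.
#'
#' @param lib a [clean_tags()] result.
#' @return data frame with columns `category`, `distinct_tags`,
#'   `total_copies`.
#' @export
abundance_distribution <- function(lib) {
  stopifnot(inherits(lib, "tag_library"))
  bin <- cut(lib$tag_counts, breaks = ABUNDANCE_BREAKS,
             labels = ABUNDANCE_LABELS, right = FALSE)
  data.frame(
    category = ABUNDANCE_LABELS,
    distinct_tags = as.integer(tapply(lib$tag_counts, bin, length,
                                      default = 0L)[ABUNDANCE_LABELS]),
    total_copies = as.integer(tapply(lib$tag_counts, bin, sum,
                                     default = 0L)[ABUNDANCE_LABELS]),
    stringsAsFactors = FALSE
  )
}
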