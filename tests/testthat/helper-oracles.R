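# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package's own scanning/indexing paths.

# every 21-nt window starting with CATG, by a plain substring loop
oracle_scan_tags <- function(reference) {
  reference <- toupper(reference)
  rows <- list()
  for (g in names(reference)) {
    s <- reference[[g]]
    ord <- 0L
    n_win <- nchar(s) - 20L
    if (n_win < 1L) next
    for (i in seq_len(n_win)) {
      w <- substr(s, i, i + 20L)
      if (substr(w, 1L, 4L) == "CATG" && !grepl("N", w, fixed = TRUE)) {
        ord <- ord + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          tag = w, gene_id = g, site = ord, offset = i - 1L, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tag = character(0), gene_id = character(0),
                      site = integer(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# two-sided AC p-value via stats' negative-binomial distribution functions:
# y | x is NB(size = x + 1, prob = N1 / (N1 + N2)); tails taken in both
# library orientations, smallest doubled
oracle_ac_pvalue <- function(x, y, N1, N2) {
  p0 <- N1 / (N1 + N2)
  p0r <- N2 / (N1 + N2)
  t1 <- pnbinom(y, size = x + 1, prob = p0)
  t2 <- pnbinom(y - 1, size = x + 1, prob = p0, lower.tail = FALSE)
  t3 <- pnbinom(x, size = y + 1, prob = p0r)
  t4 <- pnbinom(x - 1, size = y + 1, prob = p0r, lower.tail = FALSE)
  pmin(1, 2 * pmin(t1, t2, t3, t4))
}

oracle_ac_probability <- function(x, y, N1, N2) {
  dnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
}

# upper-tail hypergeometric p by full enumeration of all size-n draws
oracle_enrich_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  special <- seq_len(K)  # wlog the first K elements carry the term
  hits <- apply(draws, 2, function(d) sum(d %in% special))
  mean(hits >= k)
}

# random 21-nt CATG-anchored tag
random_tag <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    paste0("CATG", paste(sample(c("A", "C", "G", "T"), 17, TRUE),
                         collapse = ""))
  }, character(1))
}

# mutate one position of each tag to a different random base
mutate_tag <- function(tags) {
  vapply(tags, function(s) {
    p <- sample.int(nchar(s), 1L)
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    s
  }, character(1), USE.NAMES = FALSE)
}

# sorted canonical form of a virtual library's sense-strand tag index
tag_index_key <- function(tags_df) {
  d <- tags_df[tags_df$strand == "+",
               c("tag", "gene_id", "site", "offset")]
  d <- d[order(d$gene_id, d$offset), ]
  rownames(d) <- NULL
  d
}
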