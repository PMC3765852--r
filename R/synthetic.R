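#' Configuration for the synthetic DGE data generator
#'
#' Bundles and validates every knob of the simulator: reference size and
#' composition, the heavy-tailed expression model, sequencing depth and noise,
#' and the planted differential-expression signal.
#'
#' @param n_genes number of reference genes to generate (>= 0).
#' @param length_min,length_max transcript length range in nucleotides;
#'   `length_min` must be >= 25 so at least one full CATG+17 tag fits.
#' @param gc_fraction GC content of generated sequences, in \[0, 1\].
#' @param expression_shape sigma of the log-normal relative-expression
#'   distribution (dimensionless); larger values give heavier tails, i.e. a
#'   small subset of transcripts carrying most of the tag mass.
#' @param depth total number of tag reads emitted per library (>= 1).
#' @param error_rate per-base substitution probability in \[0, 1\].
#' @param junk_fraction fraction of reads replaced by N-containing or
#'   adaptor-like junk that QC must remove, in \[0, 1\].
#' @param de_fraction fraction of expressed genes given a planted fold change.
#' @param de_log2fc absolute planted log2 fold change.
#' @param catg_fraction fraction of genes guaranteed to carry at least one
#'   eligible CATG site; the remaining holdout genes are scrubbed of CATG so
#'   the "genes with CATG sites" accounting path is exercised.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return an object of class `synthetic_config` (a validated list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 50, depth = 1000, seed = 1)
synthetic_config <- function(n_genes = 200L,
                             length_min = 200L,
                             length_max = 2000L,
                             gc_fraction = 0.45,
                             expression_shape = 1.5,
                             depth = 5e5,
                             error_rate = 0.001,
                             junk_fraction = 0.05,
                             de_fraction = 0.1,
                             de_log2fc = 2,
                             catg_fraction = 0.95,
                             seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", lo = 0, integerish = TRUE)
  assert_scalar_number(length_min, "length_min", lo = 25, integerish = TRUE)
  assert_scalar_number(length_max, "length_max", lo = length_min,
                       integerish = TRUE)
  assert_scalar_number(gc_fraction, "gc_fraction", lo = 0, hi = 1)
  assert_scalar_number(expression_shape, "expression_shape", lo = 0)
  assert_scalar_number(depth, "depth", lo = 1, integerish = TRUE)
  assert_scalar_number(error_rate, "error_rate", lo = 0, hi = 1)
  assert_scalar_number(junk_fraction, "junk_fraction", lo = 0, hi = 1)
  assert_scalar_number(de_fraction, "de_fraction", lo = 0, hi = 1)
  assert_scalar_number(de_log2fc, "de_log2fc", lo = 0)
  assert_scalar_number(catg_fraction, "catg_fraction", lo = 0, hi = 1)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  structure(list(
    n_genes = as.integer(n_genes), length_min = as.integer(length_min),
    length_max = as.integer(length_max), gc_fraction = gc_fraction,
    expression_shape = expression_shape, depth = as.integer(depth),
    error_rate = error_rate, junk_fraction = junk_fraction,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    catg_fraction = catg_fraction, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# 1-based start offsets of eligible CATG sites: anchor + 17 downstream bases
# all inside the sequence, no N in the 21-nt window
eligible_offsets <- function(sequence) {
  hits <- gregexpr(TAG_ANCHOR, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  hits <- hits[hits + TAG_LENGTH - 1L <= nchar(sequence)]
  if (length(hits) == 0L) return(integer(0))
  windows <- substring(sequence, hits, hits + TAG_LENGTH - 1L)
  hits[!grepl("N", windows, fixed = TRUE)]
}

# 3'-most eligible CATG+17 tag per gene (NA when the gene has no eligible
# site); this is the fragment NlaIII digestion retains
canonical_tags <- function(reference) {
  vapply(reference, function(s) {
    off <- eligible_offsets(s)
    if (length(off) == 0L) return(NA_character_)
    substr(s, max(off), max(off) + TAG_LENGTH - 1L)
  }, character(1))
}

#' Generate a synthetic reference transcriptome
#'
#' Sequences are i.i.d. nucleotides at the configured GC content. A
#' `catg_fraction` share of genes is guaranteed to carry at least one eligible
#' CATG site (one is planted if none arose by chance); the holdout share is
#' scrubbed of CATG occurrences entirely.
#'
#' @param config a [synthetic_config()].
#' @return named character vector of sequences (names are unique gene ids).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  if (n == 0L) return(setNames(character(0), character(0)))
  with_seed(config$seed, {
    lens <- if (config$length_min == config$length_max) {
      rep(config$length_min, n)
    } else {
      sample(seq(config$length_min, config$length_max), n, replace = TRUE)
    }
    base_prob <- c(A = (1 - config$gc_fraction) / 2,
                   C = config$gc_fraction / 2,
                   G = config$gc_fraction / 2,
                   T = (1 - config$gc_fraction) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(base_prob), L, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
    ids <- sprintf("gene_%0*d", max(4L, nchar(n)), seq_len(n))

    n_with <- round(config$catg_fraction * n)
    with_site <- logical(n)
    if (n_with > 0) with_site[sample.int(n, n_with)] <- TRUE

    for (i in seq_len(n)) {
      if (with_site[i]) {
        if (length(eligible_offsets(seqs[i])) == 0L) {
          pos <- sample.int(lens[i] - TAG_LENGTH + 1L, 1L)
          substr(seqs[i], pos, pos + 3L) <- TAG_ANCHOR
        }
      } else {
        # scrubbing one site can expose another across the seam, hence loop
        while (grepl(TAG_ANCHOR, seqs[i], fixed = TRUE)) {
          seqs[i] <- sub(TAG_ANCHOR, "CATC", seqs[i], fixed = TRUE)
        }
      }
    }
    setNames(seqs, ids)
  })
}

#' Simulate one tag library from a reference and a ground truth
#'
#' Each read is the source gene's 3'-most CATG+17 tag, the gene drawn from the
#' truth's relative-expression distribution; per-base substitution errors are
#' applied at `error_rate`, and a `junk_fraction` share of reads is replaced by
#' N-containing or adaptor-like junk. Exactly `config$depth` reads are emitted.
#'
#' @param reference named character vector of gene sequences.
#' @param truth data frame with columns `gene_id`, `level` (relative
#'   expression, summing to 1 over expressed genes), `log2fc`.
#' @param config a [synthetic_config()].
#' @param seed seed for this library's draw (defaults to `config$seed`).
#' @return character vector of tag reads, length `config$depth`.
#' @export
simulate_tag_library <- function(reference, truth, config,
                                 seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_truth(truth)
  can <- canonical_tags(reference)
  lv <- setNames(truth$level, truth$gene_id)
  expressed <- truth$gene_id[truth$level > 0]
  if (length(expressed) == 0L)
    stop_input("truth declares no expressed gene (all levels are 0)")
  missing_site <- expressed[is.na(can[expressed])]
  if (length(missing_site) > 0L)
    stop_input("expressed gene(s) without an eligible CATG site: ",
               paste(head(missing_site, 5), collapse = ", "))
  with_seed(seed, {
    n_junk <- rbinom(1L, config$depth, config$junk_fraction)
    n_real <- config$depth - n_junk
    reads <- character(0)
    if (n_real > 0) {
      gs <- sample(expressed, n_real, replace = TRUE,
                   prob = lv[expressed])
      reads <- unname(can[gs])
      if (config$error_rate > 0) {
        n_err <- rbinom(n_real, TAG_LENGTH, config$error_rate)
        for (i in which(n_err > 0L)) {
          pos <- sample.int(TAG_LENGTH, n_err[i])
          for (p in pos) {
            cur <- substr(reads[i], p, p)
            substr(reads[i], p, p) <-
              sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
          }
        }
      }
    }
    if (n_junk > 0) {
      is_n_junk <- runif(n_junk) < 0.5
      junk <- vapply(is_n_junk, function(nj) {
        if (nj) {
          s <- paste(sample(c("A", "C", "G", "T"), TAG_LENGTH, TRUE),
                     collapse = "")
          for (p in sample.int(TAG_LENGTH, sample.int(3L, 1L)))
            substr(s, p, p) <- "N"
          s
        } else {
          DGE_ADAPTOR
        }
      }, character(1))
      reads <- c(reads, junk)
    }
    reads[sample.int(length(reads))]
  })
}

#' Generate a two-library experiment with planted fold changes
#'
#' Library A's expression is a normalized heavy-tailed (log-normal) draw over
#' genes with an eligible CATG site; library B applies the planted log2 fold
#' changes (balanced up/down) to a `de_fraction` share of expressed genes and
#' renormalizes. The returned truth records the planted signal.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `reference`, `library_a`, `library_b` (read
#'   vectors) and `truth` (data frame `gene_id`, `level`, `log2fc`, with the
#'   seed as attribute `seed`).
#' @export
make_de_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  reference <- generate_transcriptome(config)
  can <- canonical_tags(reference)
  eligible <- names(can)[!is.na(can)]
  if (length(eligible) == 0L)
    stop_input("no gene in the generated reference has an eligible CATG site")
  truth <- with_seed(config$seed + 1L, {
    lv <- rlnorm(length(eligible), meanlog = 0,
                 sdlog = config$expression_shape)
    lv <- lv / sum(lv)
    n_de <- floor(config$de_fraction * length(eligible))
    if (config$de_fraction > 0 && n_de == 0L) {
      warning("de_fraction too small for this gene count; no DE genes planted")
    }
    l2fc <- setNames(numeric(length(eligible)), eligible)
    if (n_de > 0L) {
      de_genes <- sample(eligible, n_de)
      l2fc[de_genes] <- sample(rep(c(1, -1), length.out = n_de)) *
        config$de_log2fc
    }
    level <- setNames(numeric(length(reference)), names(reference))
    level[eligible] <- lv
    fc <- setNames(numeric(length(reference)), names(reference))
    fc[eligible] <- l2fc
    data.frame(gene_id = names(reference), level = unname(level),
               log2fc = unname(fc), stringsAsFactors = FALSE)
  })
  attr(truth, "seed") <- config$seed
  truth_b <- truth
  truth_b$level <- truth_levels_b(truth)
  list(
    reference = reference,
    library_a = simulate_tag_library(reference, truth, config,
                                     seed = sub_seed(config$seed, 2L)),
    library_b = simulate_tag_library(reference, truth_b, config,
                                     seed = sub_seed(config$seed, 3L)),
    truth = truth
  )
}

#' Library-B expression levels implied by a truth table
#'
#' Applies the planted log2 fold changes to the library-A levels and
#' renormalizes to a probability vector.
#'
#' @param truth truth data frame (`gene_id`, `level`, `log2fc`).
#' @return numeric vector of library-B levels, aligned with `truth$gene_id`.
#' @export
truth_levels_b <- function(truth) {
  validate_truth(truth)
  b <- truth$level * 2^truth$log2fc
  if (sum(b) > 0) b <- b / sum(b)
  b
}

validate_truth <- function(truth) {
  if (!is.data.frame(truth) ||
      !all(c("gene_id", "level", "log2fc") %in% names(truth)))
    stop_input("truth must be a data frame with gene_id, level, log2fc")
  if (any(truth$level < 0)) stop_input("truth levels must be nonnegative")
  if (abs(sum(truth$level) - 1) > 1e-9)
    stop_input("truth levels must sum to 1")
  invisible(truth)
}

# derived stream seeds stay valid 32-bit integers
sub_seed <- function(seed, k) as.integer((seed + k) %% .Machine$integer.max)
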