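## Readers and writers for the pipeline's plain-text interchange formats.
## Sequence formats go through Biostrings; tables are plain tab-delimited.

#' Read a reference transcriptome from FASTA
#'
#' @param path FASTA file (wrapped or single-line).
#' @return named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dna))  # id is the first token of the header
  setNames(toupper(as.character(dna)), ids)
}

#' Write a reference transcriptome as FASTA
#'
#' @param reference named character vector of sequences.
#' @param path output file.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  message(length(reference), " sequences written to ", path)
  invisible(path)
}

#' Write tag reads as FASTQ with dummy qualities
#'
#' @param reads character vector of reads.
#' @param path output file.
#' @export
write_tag_fastq <- function(reads, path) {
  n <- length(reads)
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- sprintf("read_%d", seq_len(n))
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  message(n, " reads written to ", path)
  invisible(path)
}

#' Read tag reads from FASTQ
#'
#' @param path FASTQ file.
#' @return character vector of reads.
#' @export
read_tag_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write a clean tag library as a tab-delimited (tag, count) table
#'
#' Rows are sorted by descending count then tag.
#'
#' @param lib a [clean_tags()] library.
#' @param path output file.
#' @export
write_tag_counts <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  df <- data.frame(tag = names(lib$tag_counts),
                   count = unname(lib$tag_counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(nrow(df), " tag records written to ", path)
  invisible(path)
}

#' Read a (tag, count) table into a tag library
#'
#' The table is taken as already clean: raw totals equal the clean totals.
#'
#' @param path tab-delimited file with columns `tag`, `count`.
#' @param sample_id library label.
#' @return a `tag_library`.
#' @export
read_tag_counts <- function(path, sample_id = basename(path)) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer"))
  clean_tags(df, sample_id = sample_id)
}

#' Write and read a synthetic-truth table
#'
#' Tab-delimited (gene_id, level, log2fc); levels are written with 17
#' significant digits so a written-then-reread truth is bit-identical.
#'
#' @param truth truth data frame from [make_de_experiment()].
#' @param path file path.
#' @return `read_truth` returns the truth data frame.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(gene_id = truth$gene_id,
                   level = format(truth$level, digits = 17),
                   log2fc = format(truth$log2fc, digits = 17))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(nrow(df), " truth records written to ", path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "numeric"))
  df
}

#' Read a two-column (gene_id, term) annotation table
#'
#' @param path tab-delimited file, one gene-term pair per row.
#' @return data frame with columns `gene_id`, `term`.
#' @export
read_annotation <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "character"))
}

#' Read a qPCR Ct table
#'
#' @param path tab-delimited file with columns `gene`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_reference`.
#' @return data frame suitable for [ddct()].
#' @export
read_ct_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a per-gene expression profile
#'
#' @param profile a [to_tpm()] profile.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(nrow(profile), " gene records written to ", path)
  invisible(path)
}

#' Write a differential-expression table
#'
#' Columns mirror the usual DEG listing: counts, TPMs, log2 ratio, p-value,
#' FDR and the up/down/ns call.
#'
#' @param results a [call_degs()] result.
#' @param path output file.
#' @export
write_deg_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(nrow(results), " DEG records written to ", path)
  invisible(path)
}
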