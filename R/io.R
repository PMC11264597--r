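# File formats: FASTA/FASTQ through Biostrings, TSV with a header row,
# UTF-8, '.' for missing values.

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write sequences as FASTQ (Sanger Phred+33)
#'
#' All bases get the constant quality 'I' (Q40); downstream stages ignore
#' quality.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTA or FASTQ into a named character vector
#'
#' @param path Input path; format inferred from the extension
#'   (`.fastq`/`.fq` vs anything else).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a TSV with header
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                    check.names = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Writes `reads.fastq` (or `.fasta`), `reference.fasta`, `taxonomy.tsv`
#' (taxon_id, semicolon-joined 7-rank lineage), `truth.tsv` (read_id,
#' taxon_id) and `metadata.tsv` (sample_id, site_label).
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reads <- unlist(unname(lapply(ds$read_sets, `[[`, "reads")))
  if (format == "fastq") {
    write_fastq(reads, file.path(dir, "reads.fastq"))
  } else {
    write_fasta(reads, file.path(dir, "reads.fasta"))
  }
  write_fasta(ref_sequences(ds$reference), file.path(dir, "reference.fasta"))
  write_tsv(data.frame(taxon_id = ds$reference$taxa$taxon_id,
                       lineage = unname(ref_lineages(ds$reference)),
                       stringsAsFactors = FALSE),
            file.path(dir, "taxonomy.tsv"))
  truth <- unlist(unname(lapply(ds$read_sets, `[[`, "truth")))
  write_tsv(data.frame(read_id = names(truth), taxon_id = unname(truth),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth.tsv"))
  write_tsv(stats::setNames(ds$metadata, c("sample_id", "site_label")),
            file.path(dir, "metadata.tsv"))
  invisible(dir)
}
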