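#' Read an assembly FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' description lines to the first whitespace-delimited token and rejects
#' duplicate contig ids.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) stop("assembly FASTA not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate contig ids in ", path, call. = FALSE)
  }
  x
}

#' Read a read set from FASTQ or FASTA
#'
#' Format is chosen by extension: `.fastq`/`.fq` (optionally `.gz`) are read
#' as FASTQ, everything else as FASTA. Qualities are ignored; the exact-match
#' criterion uses sequence only.
#'
#' @param path path to the reads file.
#' @return a [Biostrings::DNAStringSet] of reads.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path, call. = FALSE)
  fq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  Biostrings::readDNAStringSet(path, format = if (fq) "fastq" else "fasta")
}

#' Write contigs as wrapped FASTA
#'
#' @param contigs a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param width line-wrap width in bases (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 60L) {
  Biostrings::writeXStringSet(contigs, path, width = width)
  invisible(path)
}

#' Write reads as FASTQ with constant quality
#'
#' Simulated reads carry no quality model; every base is written with the
#' phred+33 quality character `"I"` (Q40).
#'
#' @param reads a named [Biostrings::DNAStringSet] (or a `sex_read_set`).
#' @param path output path; `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "sex_read_set")) reads <- reads$reads
  quals <- Biostrings::BStringSet(vapply(
    Biostrings::width(reads),
    function(w) strrep("I", w), character(1)
  ))
  Biostrings::writeXStringSet(reads, path,
    format = "fastq",
    compress = grepl("\\.gz$", path), qualities = quals
  )
  invisible(path)
}
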