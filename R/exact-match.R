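#' Build an exact-substring index over an assembly
#'
#' Prepares a contig set for whole-read, zero-mismatch matching on either
#' strand. The reverse complement of every contig is precomputed so each
#' query is answered by plus-strand scans of both orientations. Matching is
#' performed by an Aho-Corasick scan of read dictionaries
#' ([Biostrings::PDict]) over the indexed sequences; the dictionary is built
#' per read chunk at query time, which bounds memory on large read sets.
#'
#' `N` (or any non-ACGT letter) never matches anything, on either side:
#' queries containing such letters are unmatched by contract, and ambiguous
#' positions in contigs cannot be matched by an ACGT query.
#'
#' @param contigs a named [Biostrings::DNAStringSet] (or FASTA path);
#'   alphabet `{A,C,G,T,N}`; duplicate ids are rejected.
#' @return an object of class `exact_index`.
#' @seealso [count_exact_matches()], [index_query()]
#' @export
exact_index <- function(contigs) {
  if (is.character(contigs)) contigs <- read_assembly(contigs)
  stopifnot(is(contigs, "DNAStringSet"))
  if (length(contigs) == 0L) stop("no contigs to index", call. = FALSE)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must carry unique names", call. = FALSE)
  }
  # allow N but no exotic IUPAC letters beyond it
  letters_used <- colSums(Biostrings::alphabetFrequency(contigs)) > 0
  allowed <- c("A", "C", "G", "T", "N")
  if (any(letters_used[setdiff(names(letters_used), allowed)])) {
    stop("contig alphabet must be {A,C,G,T,N}", call. = FALSE)
  }
  structure(
    list(
      contigs = contigs,
      rc = Biostrings::reverseComplement(contigs),
      lengths = setNames(Biostrings::width(contigs), names(contigs))
    ),
    class = "exact_index"
  )
}

#' @export
print.exact_index <- function(x, ...) {
  cat(
    "exact_index:", length(x$contigs), "contigs,",
    sum(x$lengths), "bp (both strands searchable)\n"
  )
  invisible(x)
}

# TRUE where the query is pure ACGT (only these can ever match)
is_acgt <- function(seqs) {
  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  af[, "other"] == 0L & rowSums(af[, c("A", "C", "G", "T"), drop = FALSE]) ==
    Biostrings::width(seqs)
}

#' Query an exact index for substring membership
#'
#' @param index an [exact_index()].
#' @param queries a [Biostrings::DNAStringSet] or character vector.
#' @return logical vector: does each query occur, full-length and
#'   mismatch-free, in at least one contig on either strand?
#' @export
index_query <- function(index, queries) {
  stopifnot(inherits(index, "exact_index"))
  queries <- Biostrings::DNAStringSet(queries)
  hit <- logical(length(queries))
  ok <- which(Biostrings::width(queries) > 0L & is_acgt(queries))
  for (i in ok) {
    q <- queries[[i]]
    hit[i] <-
      sum(Biostrings::vcountPattern(q, index$contigs, fixed = TRUE)) > 0L ||
        sum(Biostrings::vcountPattern(q, index$rc, fixed = TRUE)) > 0L
  }
  hit
}

#' Count reads matching each contig under the zero-mismatch criterion
#'
#' A read increments a contig's count by exactly 1 if the full read occurs
#' at least once in that contig, on either strand, with zero mismatches and
#' no indels. Multiple occurrences within one contig still count once, but
#' a read may count once in each of several contigs. Counts are independent
#' of read order. Reads containing `N` (or other ambiguity codes) match
#' nothing but still count toward `total_reads`; empty reads are skipped
#' with a warning and excluded from the total.
#'
#' @param index an [exact_index()].
#' @param reads a [Biostrings::DNAStringSet], a `sex_read_set`, or a
#'   FASTQ/FASTA path.
#' @param chunk_size reads per Aho-Corasick dictionary (memory knob;
#'   default 500000).
#' @return an `alignment_counts` object: a `data.frame` with columns
#'   `contig_id`, `length`, `n_matched`, and attribute `total_reads`.
#' @export
count_exact_matches <- function(index, reads, chunk_size = 5e5) {
  stopifnot(inherits(index, "exact_index"))
  if (inherits(reads, "sex_read_set")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_reads(reads)
  }
  reads <- Biostrings::DNAStringSet(reads)
  if (length(reads) == 0L) stop("read set is empty", call. = FALSE)
  empty <- Biostrings::width(reads) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty read(s) skipped")
    reads <- reads[!empty]
    if (length(reads) == 0L) stop("all reads empty", call. = FALSE)
  }
  total <- length(reads)
  counts <- setNames(integer(length(index$contigs)), names(index$contigs))
  matchable <- which(is_acgt(reads))
  widths <- Biostrings::width(reads)
  # constant-width dictionaries: group reads by width, chunk within group
  for (w in unique(widths[matchable])) {
    grp <- matchable[widths[matchable] == w]
    for (chunk in split(grp, ceiling(seq_along(grp) / chunk_size))) {
      pd <- Biostrings::PDict(reads[chunk])
      fwd <- Biostrings::vwhichPDict(pd, index$contigs)
      rev <- Biostrings::vwhichPDict(pd, index$rc)
      # union per contig: once per (read, contig) regardless of strand or
      # position multiplicity
      n_hit <- mapply(
        function(f, r) length(unique.default(c(f, r))),
        fwd, rev,
        USE.NAMES = FALSE
      )
      counts <- counts + n_hit
    }
  }
  res <- data.frame(
    contig_id = names(index$contigs),
    length = as.integer(index$lengths),
    n_matched = as.integer(counts),
    stringsAsFactors = FALSE
  )
  attr(res, "total_reads") <- total
  class(res) <- c("alignment_counts", "data.frame")
  res
}

#' Write alignment counts as TSV
#'
#' Columns `contig_id  n_reads_matched  total_reads`.
#'
#' @param counts an `alignment_counts` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "alignment_counts"))
  write_tsv(
    data.frame(
      contig_id = counts$contig_id,
      n_reads_matched = counts$n_matched,
      total_reads = attr(counts, "total_reads")
    ),
    path
  )
}
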