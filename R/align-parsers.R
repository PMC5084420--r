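#' Read repeat insertion/consensus alignments (canonical TSV dialect)
#'
#' The canonical input for divergence computation: one row per TE insertion
#' with both gapped alignment rows inline. Columns (tab-separated, with
#' header): `contig_id start end te_name te_class aligned_insertion
#' aligned_consensus`; gaps are `-`; coordinates 1-based inclusive on the
#' contig.
#'
#' @param path TSV path.
#' @return a `data.frame` with those columns.
#' @seealso [repeat_divergence()], [read_rm_align()]
#' @export
read_repeat_alignments <- function(path) {
  df <- read_tsv(path)
  need <- c(
    "contig_id", "start", "end", "te_name", "te_class",
    "aligned_insertion", "aligned_consensus"
  )
  if (!all(need %in% names(df))) {
    stop(
      "TSV must carry columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(nchar(df$aligned_insertion) != nchar(df$aligned_consensus))) {
    stop("gapped rows differ in length", call. = FALSE)
  }
  df
}

#' Write repeat alignments in the canonical TSV dialect
#'
#' @param alignments `data.frame` as accepted by [repeat_divergence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_alignments <- function(alignments, path) {
  write_tsv(
    alignments[, c(
      "contig_id", "start", "end", "te_name", "te_class",
      "aligned_insertion", "aligned_consensus"
    )],
    path
  )
}

# te_class from a `name#class/subfamily` annotation token
te_class_from_label <- function(label) {
  cls <- sub("^[^#]*#", "", label)
  cls <- sub("/.*$", "", cls)
  known <- c(
    LINE = "LINE", SINE = "SINE", LTR = "LTR", DNA = "DNA", RC = "RC",
    Simple_repeat = "simple", Low_complexity = "low-complexity"
  )
  out <- unname(known[cls])
  ifelse(is.na(out), "other", out)
}

#' Best-effort parser for cross_match/RepeatMasker `.align` files
#'
#' Reads the block dialect emitted by cross_match-based repeat annotation:
#' a header line per alignment
#' (`score div del ins query qstart qend (left) [C] repeat#class ...`)
#' followed by interleaved, line-wrapped gapped sequence segments for query
#' and repeat. Segments are concatenated per block and returned in the
#' canonical columns of [read_repeat_alignments()]. Lines that do not fit
#' the dialect (matrix lines, Kimura annotations, transition markers) are
#' ignored; blocks whose two rows end up with unequal lengths are dropped
#' with a warning rather than failing the whole file.
#'
#' @param path `.align` file path.
#' @return a `data.frame` in canonical alignment columns.
#' @export
read_rm_align <- function(path) {
  if (!file.exists(path)) stop(".align file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # header: score perc_div perc_del perc_ins query begin end (left) [C] repeat
  head_re <- paste0(
    "^\\s*\\d+\\s+[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s+", # score, div, del, ins
    "(\\S+)\\s+(\\d+)\\s+(\\d+)\\s+\\(\\d+\\)\\s+(C\\s+)?(\\S+)"
  )
  seq_re <- "^\\s*(C\\s+)?(\\S+)\\s+(\\d+)\\s+([ACGTNXacgtnx-]+)\\s+(\\d+)\\s*$"
  starts <- grep(head_re, lines)
  if (length(starts) == 0L) {
    stop("no alignment headers recognized in ", path, call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  blocks <- Map(function(s, e) lines[s:e], starts, ends)
  recs <- lapply(blocks, function(bl) {
    m <- regmatches(bl[1], regexec(head_re, bl[1]))[[1]]
    query <- m[2]
    qstart <- as.integer(m[3])
    qend <- as.integer(m[4])
    label <- m[6]
    seq_lines <- grep(seq_re, bl[-1], value = TRUE)
    if (length(seq_lines) < 2L) {
      return(NULL)
    }
    parts <- regmatches(seq_lines, regexec(seq_re, seq_lines))
    ids <- vapply(parts, `[`, character(1), 3)
    seqs <- vapply(parts, `[`, character(1), 5)
    # rows alternate query / repeat; identify query rows by name match,
    # falling back to odd/even order
    is_query <- ids == query
    if (!any(is_query) || all(is_query)) {
      is_query <- seq_along(ids) %% 2L == 1L
    }
    q <- paste(seqs[is_query], collapse = "")
    r <- paste(seqs[!is_query], collapse = "")
    if (nchar(q) != nchar(r) || nchar(q) == 0L) {
      return(NA)
    }
    data.frame(
      contig_id = query, start = qstart, end = qend,
      te_name = sub("#.*$", "", label),
      te_class = te_class_from_label(label),
      aligned_insertion = q, aligned_consensus = r,
      stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(recs, function(x) identical(x, NA), logical(1)))
  if (dropped > 0L) {
    warning(dropped, " block(s) dropped: unequal gapped row lengths")
  }
  recs <- recs[vapply(recs, is.data.frame, logical(1))]
  if (length(recs) == 0L) {
    stop("no usable alignment blocks in ", path, call. = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
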