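#' Kimura 2-parameter distance
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are the
#' proportions of aligned (non-gap, non-ambiguous) columns showing a
#' transition and a transversion difference respectively. `K` estimates
#' substitutions per site, correcting the raw mismatch proportion `P + Q`
#' upward for multiple hits, with transitions and transversions allowed
#' different rates.
#'
#' Saturated inputs — `1 - 2P - Q <= 0` or `1 - 2Q <= 0`, where the
#' correction diverges — return `NA` rather than a clamped value;
#' [build_landscape()] reports them in a separate bucket.
#'
#' @param P,Q transition and transversion proportions (vectorized,
#'   recycled); each `>= 0`, `P + Q <= 1`.
#' @return numeric vector of distances (substitutions/site), `NA` where
#'   saturated.
#' @examples
#' k2p_distance(0, 0) # 0
#' k2p_distance(0.1, 0.05) # 0.17017...
#' k2p_distance(0.5, 0) # NA (saturated)
#' @export
k2p_distance <- function(P, Q) {
  n <- max(length(P), length(Q))
  P <- rep_len(as.numeric(P), n)
  Q <- rep_len(as.numeric(Q), n)
  if (any(P < 0 | Q < 0 | P + Q > 1, na.rm = TRUE)) {
    stop("P and Q must be non-negative with P + Q <= 1", call. = FALSE)
  }
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  out <- rep(NA_real_, n)
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  out[ok] <- -0.5 * log(a[ok] * sqrt(b[ok]))
  out
}

#' Count transitions and transversions in a pairwise alignment
#'
#' Takes two gapped sequences of equal length (rows of a pairwise
#' alignment). Only columns carrying a standard base (A/C/G/T) on both rows
#' are counted; gap and ambiguous (e.g. N) columns are excluded from the
#' denominator. Transitions are A<->G and C<->T; every other mismatch is a
#' transversion.
#'
#' @param insertion_seq,consensus_seq character strings (or
#'   [Biostrings::DNAString]) with `-` for gaps; equal length.
#' @return a list with `aligned_columns` (countable columns), `P` and `Q`
#'   (fractions of countable columns; `NA` when no column is countable).
#' @examples
#' count_substitutions("AGGT", "ACGT") # one G/C transversion: Q = 0.25
#' @export
count_substitutions <- function(insertion_seq, consensus_seq) {
  a <- toupper(as.character(insertion_seq))
  b <- toupper(as.character(consensus_seq))
  if (nchar(a) != nchar(b)) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  std <- c("A", "C", "G", "T")
  countable <- av %in% std & bv %in% std
  n <- sum(countable)
  if (n == 0L) {
    return(list(aligned_columns = 0L, P = NA_real_, Q = NA_real_))
  }
  av <- av[countable]
  bv <- bv[countable]
  purine <- c("A", "G")
  mism <- av != bv
  ts <- mism & ((av %in% purine) == (bv %in% purine))
  list(
    aligned_columns = n,
    P = sum(ts) / n,
    Q = sum(mism & !ts) / n
  )
}

#' Globally align a TE copy to its consensus
#'
#' Needleman-Wunsch global alignment with affine gap penalties (defaults:
#' match +2, mismatch -2, gap open -5, gap extend -1; a gap of length L
#' costs `5 + L`). This is the in-package path for computing divergence of
#' planted or user-supplied copies when no precomputed alignment file is
#' available. Alignment is delegated to [Biostrings::pairwiseAlignment()];
#' ties are broken deterministically by its fixed dynamic-programming
#' traceback order.
#'
#' @param copy_seq,consensus_seq character or [Biostrings::DNAString];
#'   non-empty.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   given as positive costs for `gap_open`/`gap_extend`).
#' @return a list with gapped strings `copy` and `consensus`, and `score`.
#' @export
align_copy_to_consensus <- function(copy_seq, consensus_seq, match = 2,
                                    mismatch = -2, gap_open = 5,
                                    gap_extend = 1) {
  copy_seq <- as.character(copy_seq)
  consensus_seq <- as.character(consensus_seq)
  if (nchar(copy_seq) == 0L || nchar(consensus_seq) == 0L) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(copy_seq, consensus_seq,
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  list(
    copy = as.character(Biostrings::alignedPattern(pa)),
    consensus = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}
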