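#' Build a table of repeat alignments with K2P divergence
#'
#' Converts parsed insertion/consensus alignment pairs into per-insertion
#' records: countable columns, transition (P) and transversion (Q)
#' proportions and the K2P divergence. Input is the canonical TSV dialect of
#' [read_repeat_alignments()] or any data.frame with the same columns.
#'
#' @param alignments `data.frame` with columns `contig_id`, `start`, `end`,
#'   `te_name`, `te_class`, `aligned_insertion`, `aligned_consensus` (gapped
#'   rows, `-` for gaps).
#' @return a `repeat_alignments` data.frame with columns `contig_id`,
#'   `start`, `end`, `te_name`, `te_class`, `aligned_columns`, `P`, `Q`,
#'   `k2p` (`NA` where saturated or uncountable).
#' @export
repeat_divergence <- function(alignments) {
  need <- c(
    "contig_id", "start", "end", "te_name", "te_class",
    "aligned_insertion", "aligned_consensus"
  )
  if (!all(need %in% names(alignments))) {
    stop(
      "alignments must carry columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(alignments$end < alignments$start)) {
    stop("alignment with end < start", call. = FALSE)
  }
  subs <- Map(
    count_substitutions,
    alignments$aligned_insertion, alignments$aligned_consensus
  )
  out <- data.frame(
    contig_id = alignments$contig_id,
    start = alignments$start,
    end = alignments$end,
    te_name = alignments$te_name,
    te_class = alignments$te_class,
    aligned_columns = vapply(subs, `[[`, integer(1), "aligned_columns"),
    P = vapply(subs, `[[`, numeric(1), "P"),
    Q = vapply(subs, `[[`, numeric(1), "Q"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$k2p <- ifelse(is.na(out$P), NA_real_, k2p_distance(out$P, out$Q))
  class(out) <- c("repeat_alignments", "data.frame")
  out
}

#' Bin repeat divergences into an accumulation landscape
#'
#' Each alignment contributes its countable aligned columns (bp) to the
#' divergence bin containing `100 * k2p`. Older insertions carry larger
#' divergence from their consensus, so the landscape reads as a (reversed)
#' time profile of TE activity. Insertions are weighted by aligned columns,
#' not genomic span, matching per-alignment divergence weighting.
#'
#' Bins of width `bin_width` partition `[0, cap)` percent; non-saturated
#' alignments at or beyond `cap` fall into one overflow bin `[cap, Inf)` so
#' that binned bp always sums to the aligned bp of defined-divergence
#' alignments. Saturated/uncountable alignments (`NA` k2p) are tallied
#' separately in attribute `saturated_bp`, never clamped into bins.
#'
#' @param alignments a `repeat_alignments` data.frame from
#'   [repeat_divergence()] (columns `te_class`, `aligned_columns`, `k2p`).
#' @param bin_width bin width in percent divergence (default 1).
#' @param cap right edge of the regular bins, percent (default 55).
#' @return a `landscape_table` data.frame with columns `te_class`,
#'   `bin_lo`, `bin_hi`, `bp`; attributes `total_bp` (binned),
#'   `saturated_bp`, `class_totals`, `bin_width`, `cap`.
#' @export
build_landscape <- function(alignments, bin_width = 1, cap = 55) {
  stopifnot(all(c("te_class", "aligned_columns", "k2p") %in% names(alignments)))
  assert_scalar_number(bin_width, "bin_width", 0, Inf, strict_lower = TRUE)
  assert_scalar_number(cap, "cap", bin_width, Inf)
  defined <- !is.na(alignments$k2p)
  sat_bp <- sum(alignments$aligned_columns[!defined])
  al <- alignments[defined, , drop = FALSE]
  edges <- seq(0, cap, by = bin_width)
  if (edges[length(edges)] < cap) edges <- c(edges, cap)
  pct <- 100 * al$k2p
  bin <- findInterval(pct, edges, rightmost.closed = FALSE)
  bin[pct >= cap] <- length(edges) # overflow bin [cap, Inf)
  lo <- c(edges[-length(edges)], cap)
  hi <- c(edges[-1], Inf)
  if (nrow(al)) {
    agg <- stats::aggregate(
      al$aligned_columns,
      by = list(te_class = al$te_class, bin = bin), FUN = sum
    )
  } else {
    agg <- data.frame(te_class = character(), bin = integer(), x = numeric())
  }
  out <- data.frame(
    te_class = agg$te_class,
    bin_lo = lo[agg$bin],
    bin_hi = hi[agg$bin],
    bp = as.numeric(agg$x),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$te_class, out$bin_lo), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("landscape_table", "data.frame")
  attr(out, "total_bp") <- sum(out$bp)
  attr(out, "saturated_bp") <- sat_bp
  attr(out, "class_totals") <- if (nrow(out)) {
    stats::aggregate(bp ~ te_class, data = out, FUN = sum)
  } else {
    data.frame(te_class = character(), bp = numeric())
  }
  attr(out, "bin_width") <- bin_width
  attr(out, "cap") <- cap
  out
}

#' Fraction of a sequence set covered by repeat annotations
#'
#' Overlapping annotation intervals on one sequence are merged before
#' summing, so nested or overlapping repeat calls are not double-counted.
#'
#' @param annotations `data.frame` with columns `contig_id`, `start`, `end`
#'   (1-based, inclusive).
#' @param sequences a named [Biostrings::DNAStringSet] — the set whose
#'   repeat fraction is wanted (e.g. all contigs, or the putative X subset).
#' @return a list with `repeat_bp`, `total_bp`, `fraction` (in [0, 1]).
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(ctg = strrep("A", 1000)))
#' ann <- data.frame(contig_id = "ctg", start = 1, end = 100)
#' repeat_fraction(ann, seqs)$fraction # 0.1
#' @export
repeat_fraction <- function(annotations, sequences) {
  stopifnot(all(c("contig_id", "start", "end") %in% names(annotations)))
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  ann <- annotations[annotations$contig_id %in% names(lens), , drop = FALSE]
  if (nrow(ann)) {
    bad <- ann$end > lens[ann$contig_id] | ann$start < 1 | ann$end < ann$start
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf(
        "annotation out of bounds: %s:%d-%d (contig length %d)",
        ann$contig_id[i], ann$start[i], ann$end[i], lens[ann$contig_id[i]]
      ), call. = FALSE)
    }
  }
  merged_bp <- 0
  if (nrow(ann)) {
    by_ctg <- split(IRanges::IRanges(ann$start, ann$end), ann$contig_id)
    merged_bp <- sum(vapply(
      by_ctg, function(ir) sum(IRanges::width(IRanges::reduce(ir))),
      numeric(1)
    ))
  }
  total <- sum(as.numeric(lens))
  list(repeat_bp = merged_bp, total_bp = total, fraction = merged_bp / total)
}

#' Write a landscape table as TSV
#'
#' Columns `te_class  bin_lo  bin_hi  bp`; totals go in the JSON run report.
#'
#' @param landscape a `landscape_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  df <- as.data.frame(landscape)
  df$bin_hi <- ifelse(is.infinite(df$bin_hi), "Inf", format(df$bin_hi))
  write_tsv(df, path)
}

#' Plot a repeat accumulation landscape
#'
#' Stacked bars of repeat bp per divergence bin, colored by TE class —
#' the standard way repeat landscapes are drawn. Requires ggplot2.
#'
#' @param landscape a `landscape_table` from [build_landscape()].
#' @return a ggplot object.
#' @export
plot_landscape <- function(landscape) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- as.data.frame(landscape)
  df <- df[is.finite(df$bin_hi), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = bin_lo, y = bp, fill = te_class)) +
    ggplot2::geom_col(width = attr(landscape, "bin_width")) +
    ggplot2::labs(
      x = "Kimura 2-parameter divergence from consensus (%)",
      y = "Repeat bp", fill = "TE class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a CQ histogram
#'
#' Distribution of per-contig chromosome quotients with the Y and X
#' decision bands marked.
#'
#' @param records a `cq_records` data.frame from [compute_cq()].
#' @param thresholds a [cq_thresholds()]; defaults to the thresholds stored
#'   on `records`.
#' @return a ggplot object.
#' @export
plot_cq <- function(records, thresholds = attr(records, "thresholds")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  thresholds <- thresholds %||% cq_thresholds()
  df <- as.data.frame(records)
  df <- df[!is.na(df$cq), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = cq)) +
    ggplot2::geom_histogram(binwidth = 0.05, fill = "grey40") +
    ggplot2::geom_vline(
      xintercept = c(thresholds$y_max, thresholds$x_min, thresholds$x_max),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "Chromosome quotient", y = "Contigs") +
    ggplot2::theme_minimal()
}
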