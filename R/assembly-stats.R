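#' Compute standard assembly statistics
#'
#' Bit-reproducible definitions of the usual draft-assembly quality table:
#'
#' * `n50`: sort contig lengths descending; N50 is the length of the contig
#'   at which the cumulative sum first reaches at least half the total
#'   (ties at the 50 % boundary resolve to the contig crossing it, the
#'   QUAST convention).
#' * `at_fraction`: percent A+T over A/C/G/T calls only — `N` is excluded
#'   from the denominator, since N counts are reported separately.
#' * `ns_per_100kb`: `1e5 * (count of N) / total_bp` (total includes N).
#'
#' @param contigs a named [Biostrings::DNAStringSet] or FASTA path.
#' @param length_floor drop contigs shorter than this many bp before
#'   computing anything (default 0; the conventional ">= 1000 bp" table row
#'   is also always reported).
#' @return an `assembly_stats` list with fields `n_contigs`, `total_bp`,
#'   `n50`, `mean_contig`, `max_contig`, `at_fraction` (percent),
#'   `n_contigs_ge_1kb`, `total_bp_ge_1kb`, `ns_per_100kb`.
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(
#'   a = strrep("AT", 20), b = strrep("GC", 15),
#'   c = strrep("AT", 10), d = strrep("GC", 5)
#' ))
#' assembly_stats(ctg)$n50 # 30
#' @export
assembly_stats <- function(contigs, length_floor = 0L) {
  if (is.character(contigs)) contigs <- read_assembly(contigs)
  stopifnot(is(contigs, "DNAStringSet"))
  length_floor <- assert_count(length_floor, "length_floor")
  contigs <- contigs[Biostrings::width(contigs) >= length_floor]
  if (length(contigs) == 0L) {
    stop("no contigs remain after applying the length floor", call. = FALSE)
  }
  lens <- Biostrings::width(contigs)
  total <- sum(as.numeric(lens))
  af <- colSums(Biostrings::alphabetFrequency(contigs, baseOnly = TRUE))
  acgt <- sum(af[c("A", "C", "G", "T")])
  n_count <- total - acgt # N and any other ambiguity call
  ge1kb <- lens >= 1000L
  out <- list(
    n_contigs = length(lens),
    total_bp = total,
    n50 = n50(lens),
    mean_contig = total / length(lens),
    max_contig = max(lens),
    at_fraction = 100 * sum(af[c("A", "T")]) / acgt,
    n_contigs_ge_1kb = sum(ge1kb),
    total_bp_ge_1kb = sum(as.numeric(lens[ge1kb])),
    ns_per_100kb = 1e5 * n_count / total
  )
  class(out) <- "assembly_stats"
  out
}

#' N50 of a length multiset
#'
#' @param lengths positive integer vector of contig lengths.
#' @return the N50 in bp.
#' @examples
#' n50(c(40, 30, 20, 10)) # 30
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths >= 1))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  contigs:           %d\n", x$n_contigs))
  cat(sprintf("  total length:      %.0f bp\n", x$total_bp))
  cat(sprintf("  N50:               %.0f bp\n", x$n50))
  cat(sprintf("  mean / max contig: %.0f / %.0f bp\n", x$mean_contig, x$max_contig))
  cat(sprintf("  %%AT (ACGT only):   %.2f\n", x$at_fraction))
  cat(sprintf(
    "  >=1 kb:            %d contigs, %.0f bp\n",
    x$n_contigs_ge_1kb, x$total_bp_ge_1kb
  ))
  cat(sprintf("  N per 100 kb:      %.2f\n", x$ns_per_100kb))
  invisible(x)
}

#' Write assembly statistics as JSON and a table-shaped TSV
#'
#' @param stats an `assembly_stats` object.
#' @param prefix output path prefix (writes `<prefix>.json` and
#'   `<prefix>.tsv`).
#' @return paths written, invisibly.
#' @export
write_assembly_stats <- function(stats, prefix) {
  stopifnot(inherits(stats, "assembly_stats"))
  js <- paste0(prefix, ".json")
  jsonlite::write_json(unclass(stats), js,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  tsv <- paste0(prefix, ".tsv")
  df <- data.frame(
    parameter = c(
      "No. of contigs", "Total length (bp)", "N50 (bp)", "Avg. contig (bp)",
      "Max. contig (bp)", "% AT", "No. of contigs (>=1000 bp)",
      "Total length (>=1000 bp)", "No. of N's per 100 kb"
    ),
    value = format(
      c(
        stats$n_contigs, stats$total_bp, stats$n50, round(stats$mean_contig, 2),
        stats$max_contig, round(stats$at_fraction, 2), stats$n_contigs_ge_1kb,
        stats$total_bp_ge_1kb, round(stats$ns_per_100kb, 2)
      ),
      trim = TRUE, scientific = FALSE
    ),
    stringsAsFactors = FALSE
  )
  write_tsv(df, tsv)
  invisible(c(js, tsv))
}
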