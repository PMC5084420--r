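#' Chromosome-quotient classification thresholds
#'
#' Defaults follow the published criterion: contigs with CQ below 0.05 are
#' putative Y, contigs with CQ between 1.9 and 2.5 (inclusive) are putative
#' X. The X band is a closed interval; the Y band is half-open `[0, y_max)`.
#' Contigs whose male alignment count falls below `min_male_hits` get no CQ
#' (an arbitrarily small denominator would otherwise flood the X band with
#' noise) and are labeled `low-evidence`.
#'
#' @param y_max upper bound (exclusive) of the Y band; default 0.05.
#' @param x_min,x_max closed X band; defaults 1.9 and 2.5.
#' @param min_male_hits minimum male count for a defined CQ; default 20.
#' @param normalize divide each count by its library total before taking the
#'   ratio (default `TRUE`); with equal per-sex sequencing effort this is a
#'   no-op, but it makes CQ portable across unequal library sizes.
#' @return an object of class `cq_thresholds`.
#' @export
cq_thresholds <- function(y_max = 0.05, x_min = 1.9, x_max = 2.5,
                          min_male_hits = 20L, normalize = TRUE) {
  assert_scalar_number(y_max, "y_max", 0, Inf, strict_lower = TRUE)
  assert_scalar_number(x_min, "x_min", y_max, Inf, strict_lower = TRUE)
  assert_scalar_number(x_max, "x_max", x_min, Inf)
  min_male_hits <- assert_count(min_male_hits, "min_male_hits")
  stopifnot(is.logical(normalize), length(normalize) == 1L)
  structure(
    list(
      y_max = y_max, x_min = x_min, x_max = x_max,
      min_male_hits = min_male_hits, normalize = normalize
    ),
    class = "cq_thresholds"
  )
}

#' Compute the chromosome quotient per contig
#'
#' CQ is the female-to-male ratio of whole-read zero-mismatch alignment
#' counts. With `normalize = TRUE` (the default),
#' `cq = (female_count / F_total) / (male_count / M_total)` where the totals
#' are the read counts of each library; with normalization off it is the
#' raw `female_count / male_count`. Contigs with `male_count <
#' min_male_hits` get `NA` CQ and label `low-evidence`; all others are
#' labeled by [classify_cq()].
#'
#' @param female,male `alignment_counts` from [count_exact_matches()], over
#'   the same contig universe.
#' @param thresholds a [cq_thresholds()].
#' @return a `cq_records` data.frame with columns `contig_id`, `length`,
#'   `female_count`, `male_count`, `cq`, `label`.
#' @export
compute_cq <- function(female, male, thresholds = cq_thresholds()) {
  stopifnot(
    inherits(female, "alignment_counts"),
    inherits(male, "alignment_counts"),
    inherits(thresholds, "cq_thresholds")
  )
  if (!identical(sort(female$contig_id), sort(male$contig_id))) {
    stop("female and male counts cover different contig universes",
      call. = FALSE
    )
  }
  m <- male[match(female$contig_id, male$contig_id), ]
  f_tot <- attr(female, "total_reads")
  m_tot <- attr(male, "total_reads")
  scale <- if (thresholds$normalize) m_tot / f_tot else 1
  defined <- m$n_matched >= thresholds$min_male_hits
  cq <- ifelse(defined, scale * female$n_matched / m$n_matched, NA_real_)
  rec <- data.frame(
    contig_id = female$contig_id,
    length = female$length,
    female_count = female$n_matched,
    male_count = m$n_matched,
    cq = cq,
    label = ifelse(defined, classify_cq(cq, thresholds), "low-evidence"),
    stringsAsFactors = FALSE
  )
  class(rec) <- c("cq_records", "data.frame")
  attr(rec, "thresholds") <- thresholds
  attr(rec, "totals") <- c(female = f_tot, male = m_tot)
  rec
}

#' Label CQ values as putative X, putative Y, or unassigned
#'
#' `Y` iff `cq < y_max`; `X` iff `x_min <= cq <= x_max`; otherwise
#' `unassigned`. `NA` CQ values pass through as `low-evidence`.
#'
#' @param cq numeric vector of chromosome quotients.
#' @param thresholds a [cq_thresholds()].
#' @return character vector of labels.
#' @examples
#' classify_cq(c(0.02, 2.0, 1.0, 1.9), cq_thresholds())
#' @export
classify_cq <- function(cq, thresholds = cq_thresholds()) {
  ifelse(is.na(cq), "low-evidence",
    ifelse(cq < thresholds$y_max, "Y",
      ifelse(cq >= thresholds$x_min & cq <= thresholds$x_max, "X",
        "unassigned"
      )
    )
  )
}

#' Summarize putative chromosome sizes
#'
#' Per-label contig counts and summed lengths ("adding the sizes of each
#' contig"), with the X minus Y size difference as an attribute — the
#' quantity comparable to cytologically measured male/female genome-size
#' differences.
#'
#' @param records a `cq_records` data.frame from [compute_cq()].
#' @return a `data.frame` with columns `label`, `n_contigs`, `total_bp`;
#'   attribute `xy_size_difference` (bp).
#' @export
summarize_chromosomes <- function(records) {
  stopifnot(is.data.frame(records), all(c("label", "length") %in% names(records)))
  labels <- c("X", "Y", "unassigned", "low-evidence")
  out <- data.frame(
    label = labels,
    n_contigs = vapply(
      labels, function(l) sum(records$label == l), integer(1)
    ),
    total_bp = vapply(
      labels, function(l) sum(as.numeric(records$length[records$label == l])),
      numeric(1)
    ),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "xy_size_difference") <-
    out$total_bp[out$label == "X"] - out$total_bp[out$label == "Y"]
  out
}

#' Write CQ records and summary
#'
#' Writes `<prefix>.cq.tsv` (columns `contig_id length female_count
#' male_count cq label`), `<prefix>.summary.json` (per-label counts and bp,
#' thresholds used), and FASTA subsets `<prefix>.X.fasta` /
#' `<prefix>.Y.fasta` when `contigs` is supplied.
#'
#' @param records a `cq_records` data.frame.
#' @param prefix output path prefix.
#' @param contigs optional [Biostrings::DNAStringSet] for FASTA subsets.
#' @return character vector of paths written, invisibly.
#' @export
write_cq <- function(records, prefix, contigs = NULL) {
  paths <- character()
  tsv <- paste0(prefix, ".cq.tsv")
  df <- as.data.frame(records)
  df$cq <- ifelse(is.na(df$cq), NA, format(df$cq, digits = 6, trim = TRUE))
  write_tsv(df, tsv)
  paths <- c(paths, tsv)
  summ <- summarize_chromosomes(records)
  js <- paste0(prefix, ".summary.json")
  jsonlite::write_json(
    list(
      labels = summ,
      xy_size_difference = attr(summ, "xy_size_difference"),
      thresholds = unclass(attr(records, "thresholds"))
    ),
    js,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  paths <- c(paths, js)
  if (!is.null(contigs)) {
    for (lab in c("X", "Y")) {
      fa <- paste0(prefix, ".", lab, ".fasta")
      write_fasta(
        contigs[names(contigs) %in% records$contig_id[records$label == lab]],
        fa
      )
      paths <- c(paths, fa)
    }
  }
  invisible(paths)
}
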