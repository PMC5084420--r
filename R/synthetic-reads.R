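#' Specify a sexed read simulation
#'
#' Reads are drawn uniformly over a copy-number-weighted template of the
#' simulated genome: per-contig weights are A = 2, X = 2, Y = 0 for a female
#' (XX) pool and A = 2, X = 1, Y = 1 for a male (XY) pool. Both sexes are
#' simulated to the same fold-coverage relative to their own copy-weighted
#' genome length, mirroring equal per-sex sequencing effort; with that
#' normalization the expected autosomal CQ is 1 and the X CQ is 2.
#'
#' @param sex `"female"` or `"male"`.
#' @param depth fold-coverage (> 0) relative to the copy-weighted haploid-
#'   equivalent genome length.
#' @param read_length read length in bp (>= 1).
#' @param substitution_error_rate per-base substitution error rate in
#'   [0, 1); substitutions only, uniform over positions and cycles.
#' @param seed integer seed.
#' @return an object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(sex = c("female", "male"), depth = 20,
                          read_length = 100L, substitution_error_rate = 0.005,
                          seed = 1L) {
  sex <- match.arg(sex)
  assert_scalar_number(depth, "depth", 0, Inf, strict_lower = TRUE)
  read_length <- assert_count(read_length, "read_length", lower = 1L)
  assert_scalar_number(substitution_error_rate, "substitution_error_rate",
    0, 1,
    strict_upper = TRUE
  )
  structure(
    list(
      sex = sex, depth = depth, read_length = read_length,
      substitution_error_rate = substitution_error_rate,
      seed = as.integer(seed)
    ),
    class = "read_sim_spec"
  )
}

# copy-number weights per contig class for each sex
copy_weights <- function(sex) {
  switch(sex,
    female = c(A = 2, X = 2, Y = 0),
    male = c(A = 2, X = 1, Y = 1)
  )
}

#' Simulate a sex-tagged read pool
#'
#' Draws single-end reads from the copy-number-weighted template described
#' in [read_sim_spec()]: contigs are chosen with probability proportional to
#' copy weight times the number of valid start positions, starts are uniform,
#' and both strands are sampled with equal probability. The read count is
#' `round(depth * W / read_length)` where `W` is the copy-weighted genome
#' length, so total sequenced bases match the requested coverage to within
#' one read. Substitution errors (to one of the three other bases) are added
#' at the specified per-base rate. Read provenance (origin contig, 1-based
#' start on the plus strand, strand) is recorded for oracle testing.
#'
#' @param genome a genome list from [simulate_genome()], or a named
#'   [Biostrings::DNAStringSet] plus `truth`.
#' @param spec a [read_sim_spec()].
#' @param truth optional truth `data.frame` overriding `genome$truth`.
#' @return an object of class `sex_read_set`: a list with
#'   \describe{
#'     \item{reads}{named [Biostrings::DNAStringSet]}
#'     \item{sex}{`"female"` or `"male"`}
#'     \item{origin}{`data.frame` with `read_id`, `contig_id`, `start`,
#'       `strand`}
#'   }
#' @export
simulate_reads <- function(genome, spec, truth = NULL) {
  stopifnot(inherits(spec, "read_sim_spec"))
  contigs <- if (is.list(genome) && !is.null(genome$contigs)) {
    genome$contigs
  } else {
    genome
  }
  truth <- truth %||% genome$truth
  stopifnot(!is.null(truth), all(names(contigs) %in% truth$contig_id))
  rl <- spec$read_length
  widths <- Biostrings::width(contigs)
  if (rl > max(widths)) {
    stop("read_length exceeds the longest contig", call. = FALSE)
  }
  cls <- truth$class[match(names(contigs), truth$contig_id)]
  w <- copy_weights(spec$sex)[cls]
  # haploid-equivalent copy-weighted genome length sets the read budget
  W <- sum(w * widths)
  n_reads <- round(spec$depth * W / rl)
  valid <- pmax(widths - rl + 1L, 0L)
  prob <- w * valid
  if (sum(prob) == 0) stop("no contig can hold a read", call. = FALSE)
  if (n_reads < 1) stop("requested depth yields zero reads", call. = FALSE)
  with_seed(spec$seed, {
    per_contig <- as.vector(stats::rmultinom(1L, n_reads, prob))
    # rep() keeps reads grouped by contig, so per-contig extraction below
    # preserves read order
    idx <- rep(seq_along(contigs), per_contig)
    starts <- floor(runif(n_reads) * valid[idx]) + 1L
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    reads <- do.call(c, lapply(which(per_contig > 0L), function(ci) {
      Biostrings::extractAt(
        contigs[[ci]],
        IRanges::IRanges(starts[idx == ci], width = rl)
      )
    }))
    minus <- which(strand == "-")
    if (length(minus)) {
      reads[minus] <- Biostrings::reverseComplement(reads[minus])
    }
    if (spec$substitution_error_rate > 0 && n_reads > 0) {
      reads <- add_substitution_errors(reads, spec$substitution_error_rate)
    }
  })
  names(reads) <- sprintf("r%07d", seq_len(n_reads))
  structure(
    list(
      reads = reads, sex = spec$sex,
      origin = data.frame(
        read_id = names(reads), contig_id = names(contigs)[idx],
        start = starts, strand = strand, stringsAsFactors = FALSE
      )
    ),
    class = "sex_read_set"
  )
}

# Uniform i.i.d. per-base substitution errors over a whole read set.
# Operates on the concatenation so one vectorized replaceLetterAt call
# handles millions of reads.
add_substitution_errors <- function(reads, rate) {
  widths <- Biostrings::width(reads)
  total <- sum(widths)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) {
    return(reads)
  }
  pos <- sort(sample.int(total, n_err))
  big <- unlist(reads)
  orig <- as.character(Biostrings::extractAt(big, IRanges::IRanges(pos, pos)))
  alt <- matrix(
    c(
      "C", "G", "T", # A ->
      "A", "G", "T", # C ->
      "A", "C", "T", # G ->
      "A", "C", "G" # T ->
    ),
    nrow = 3,
    dimnames = list(NULL, c("A", "C", "G", "T"))
  )
  pick <- sample.int(3L, n_err, replace = TRUE)
  new <- alt[cbind(pick, match(orig, colnames(alt)))]
  big <- Biostrings::replaceLetterAt(big, pos, paste(new, collapse = ""))
  ends <- cumsum(widths)
  out <- Biostrings::extractAt(
    big, IRanges::IRanges(ends - widths + 1L, ends)
  )
  names(out) <- names(reads)
  out
}

#' @export
print.sex_read_set <- function(x, ...) {
  cat(
    "sex_read_set:", length(x$reads), x$sex, "reads of length",
    paste(range(Biostrings::width(x$reads)), collapse = "-"), "bp\n"
  )
  invisible(x)
}
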