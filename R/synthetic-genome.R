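#' Specify a simulated sexed genome
#'
#' Describes a fragmented assembly containing autosomal (A), X-linked and
#' Y-linked contigs. Contigs are generated independently (the CQ method is
#' per-contig and needs no linkage), with lengths drawn uniformly from
#' `contig_length_range` and bases drawn i.i.d. at the requested GC content.
#'
#' @param n_autosomal_contigs,n_x_contigs,n_y_contigs non-negative contig
#'   counts per class; at least one contig in total.
#' @param contig_length_range integer vector `c(min, max)` of contig lengths
#'   in bp (min >= 1).
#' @param gc_content target GC fraction in (0, 1). The default 0.28 mirrors
#'   the AT-rich (72 % AT) blow fly genomes the method was developed on.
#' @param seed integer seed; all genome randomness derives from it.
#' @return an object of class `genome_spec`.
#' @seealso [simulate_genome()]
#' @export
genome_spec <- function(n_autosomal_contigs = 140L, n_x_contigs = 30L,
                        n_y_contigs = 30L,
                        contig_length_range = c(5000L, 50000L),
                        gc_content = 0.28, seed = 1L) {
  n_a <- assert_count(n_autosomal_contigs, "n_autosomal_contigs")
  n_x <- assert_count(n_x_contigs, "n_x_contigs")
  n_y <- assert_count(n_y_contigs, "n_y_contigs")
  if (n_a + n_x + n_y == 0L) {
    stop("at least one contig must be requested", call. = FALSE)
  }
  if (length(contig_length_range) != 2L || any(contig_length_range < 1) ||
    contig_length_range[1] > contig_length_range[2]) {
    stop("'contig_length_range' must be c(min, max) with 1 <= min <= max",
      call. = FALSE
    )
  }
  assert_scalar_number(gc_content, "gc_content", 0, 1,
    strict_lower = TRUE, strict_upper = TRUE
  )
  structure(
    list(
      n_autosomal_contigs = n_a, n_x_contigs = n_x, n_y_contigs = n_y,
      contig_length_range = as.integer(contig_length_range),
      gc_content = gc_content, seed = as.integer(seed)
    ),
    class = "genome_spec"
  )
}

# i.i.d. DNA at a given GC fraction, as one DNAString
random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Biostrings::DNAString(paste(
    sample(names(p), n, replace = TRUE, prob = p),
    collapse = ""
  ))
}

#' Simulate a sexed genome assembly
#'
#' Generates random contigs per [genome_spec()] and a truth table recording
#' each contig's class (A, X or Y). Deterministic for a fixed seed.
#'
#' @param spec a [genome_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{contigs}{named [Biostrings::DNAStringSet]}
#'     \item{truth}{`data.frame` with columns `contig_id`, `class`, `length`}
#'     \item{insertions}{empty insertion `data.frame`, filled by
#'       [plant_te_copies()]}
#'   }
#' @examples
#' g <- simulate_genome(genome_spec(2, 1, 1, c(1000, 2000), seed = 7))
#' table(g$truth$class)
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  classes <- rep(c("A", "X", "Y"), c(
    spec$n_autosomal_contigs, spec$n_x_contigs, spec$n_y_contigs
  ))
  n <- length(classes)
  with_seed(spec$seed, {
    lo <- spec$contig_length_range[1]
    hi <- spec$contig_length_range[2]
    lens <- lo + floor(runif(n) * (hi - lo + 1L))
    seqs <- Biostrings::DNAStringSet(lapply(
      lens, random_dna,
      gc = spec$gc_content
    ))
  })
  names(seqs) <- sprintf("ctg%05d", seq_len(n))
  truth <- data.frame(
    contig_id = names(seqs), class = classes, length = lens,
    stringsAsFactors = FALSE
  )
  list(contigs = seqs, truth = truth, insertions = empty_insertions())
}

empty_insertions <- function() {
  data.frame(
    contig_id = character(), start = integer(), end = integer(),
    consensus_id = character(), divergence = numeric(),
    p_transitions = numeric(), q_transversions = numeric(),
    stringsAsFactors = FALSE
  )
}

#' Write a simulation truth table
#'
#' Tab-separated with header `contig_id  class  length`.
#'
#' @param truth truth `data.frame` from [simulate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth[, c("contig_id", "class", "length")], path)
}

#' Write planted-insertion records
#'
#' Tab-separated, 1-based inclusive coordinates, with header
#' `contig_id  start  end  consensus_id  divergence`.
#'
#' @param insertions insertion `data.frame` from [plant_te_copies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_insertions <- function(insertions, path) {
  write_tsv(
    insertions[, c("contig_id", "start", "end", "consensus_id", "divergence")],
    path
  )
}
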