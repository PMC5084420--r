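#' Specify planted transposable-element copies
#'
#' Copies of a consensus element are written into simulated contigs after
#' evolving each copy under a Kimura 2-parameter substitution process:
#' `target_divergence` is the expected number of substitution events per
#' site, and `ts_tv_ratio` the expected ratio of transition to transversion
#' events. Multiple hits at one site are possible, so the raw mismatch
#' fraction of an old copy is below its divergence — exactly the bias the
#' K2P estimator corrects.
#'
#' @param consensus_id name of the consensus element in the library FASTA.
#' @param n_copies number of copies to plant.
#' @param target_divergence expected substitutions per site, in [0, 0.75).
#' @param ts_tv_ratio expected transitions per transversion (> 0); default 2,
#'   a typical genome-wide value.
#' @param seed integer seed.
#' @return an object of class `te_plant_spec`.
#' @export
te_plant_spec <- function(consensus_id, n_copies = 20L, target_divergence = 0.30,
                          ts_tv_ratio = 2, seed = 1L) {
  stopifnot(is.character(consensus_id), length(consensus_id) == 1L)
  n_copies <- assert_count(n_copies, "n_copies", lower = 1L)
  assert_scalar_number(target_divergence, "target_divergence", 0, 0.75,
    strict_upper = TRUE
  )
  assert_scalar_number(ts_tv_ratio, "ts_tv_ratio", 0, Inf, strict_lower = TRUE)
  structure(
    list(
      consensus_id = consensus_id, n_copies = n_copies,
      target_divergence = target_divergence, ts_tv_ratio = ts_tv_ratio,
      seed = as.integer(seed)
    ),
    class = "te_plant_spec"
  )
}

#' Expected transition/transversion proportions under the K2P process
#'
#' Closed-form per-site probabilities that a site shows a transition (P) or
#' a transversion (Q) difference from its ancestor after `d` expected
#' substitution events per site with transition:transversion event ratio
#' `ts_tv_ratio`. Plugging these into [k2p_distance()] returns `d` exactly:
#' the estimator inverts the process.
#'
#' @param d expected substitutions per site (>= 0); vectorized.
#' @param ts_tv_ratio expected transitions per transversion (> 0).
#' @return a list with numeric vectors `P` and `Q`.
#' @examples
#' pq <- k2p_expected_pq(0.3, 2)
#' k2p_distance(pq$P, pq$Q) # 0.3
#' @export
k2p_expected_pq <- function(d, ts_tv_ratio = 2) {
  stopifnot(all(d >= 0), ts_tv_ratio > 0)
  # instantaneous rates scaled to one event per site per unit time:
  # alpha (transition) + 2 beta (transversions) = 1
  alpha <- ts_tv_ratio / (ts_tv_ratio + 1)
  beta <- 1 / (2 * (ts_tv_ratio + 1))
  P <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  Q <- 0.5 - 0.5 * exp(-4 * beta * d)
  list(P = P, Q = Q)
}

# Evolve a DNAString under the K2P process: each site independently ends as
# itself, its transition partner, or one of its two transversion partners.
mutate_k2p <- function(seq, d, ts_tv_ratio) {
  pq <- k2p_expected_pq(d, ts_tv_ratio)
  n <- length(seq)
  # outcome per site: 0 same, 1 transition, 2/3 the two transversions
  outcome <- sample(0:3, n,
    replace = TRUE,
    prob = c(1 - pq$P - pq$Q, pq$P, pq$Q / 2, pq$Q / 2)
  )
  hit <- which(outcome > 0L)
  if (length(hit) == 0L) {
    return(seq)
  }
  base <- strsplit(as.character(seq), "")[[1]][hit]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  # transversion partners in fixed order (choice 2 = first, 3 = second)
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  new <- ifelse(outcome[hit] == 1L, transition[base],
    ifelse(outcome[hit] == 2L, tv1[base], tv2[base])
  )
  Biostrings::replaceLetterAt(seq, hit, paste(new, collapse = ""))
}

#' Generate a small synthetic TE consensus library
#'
#' Random consensus sequences standing in for a curated repeat library, with
#' ids of the `name#class` form used by repeat annotation tools. Default
#' families echo the superfamilies that dominate blow fly genomes (Jockey-
#' and LOA-like LINEs, Gypsy-like LTRs, Mariner-like DNA transposons,
#' Helitron-like rolling-circle elements).
#'
#' @param ids character vector of `name#class` ids.
#' @param lengths consensus lengths in bp (recycled against `ids`).
#' @param gc_content GC fraction of the random consensi.
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet].
#' @export
make_te_library <- function(ids = c(
                              "Jockey-like#LINE", "Gypsy-like#LTR",
                              "Mariner-like#DNA", "Helitron-like#RC"
                            ),
                            lengths = c(3000L, 4000L, 2000L, 2500L),
                            gc_content = 0.35, seed = 1L) {
  lengths <- rep_len(as.integer(lengths), length(ids))
  with_seed(seed, {
    lib <- Biostrings::DNAStringSet(lapply(lengths, random_dna, gc = gc_content))
  })
  names(lib) <- ids
  lib
}

#' Plant mutated TE copies into simulated contigs
#'
#' Each copy is the consensus evolved under the K2P process of
#' [te_plant_spec()], then written over a uniformly chosen, non-overlapping
#' window of a contig long enough to hold it (contig lengths are unchanged;
#' no indels). Realized transition (P) and transversion (Q) proportions and
#' the realized divergence `k2p_distance(P, Q)` are appended to the truth
#' table's insertion records.
#'
#' @param genome a genome list from [simulate_genome()] (elements `contigs`,
#'   `truth`, `insertions`).
#' @param library consensus library, a named [Biostrings::DNAStringSet] or a
#'   FASTA path.
#' @param spec a [te_plant_spec()].
#' @return the genome list with modified `contigs` and extended `insertions`.
#' @export
plant_te_copies <- function(genome, library, spec) {
  stopifnot(inherits(spec, "te_plant_spec"))
  if (is.character(library)) library <- read_assembly(library)
  if (!spec$consensus_id %in% names(library)) {
    stop("consensus '", spec$consensus_id, "' not found in library", call. = FALSE)
  }
  cons <- library[[spec$consensus_id]]
  clen <- length(cons)
  contigs <- genome$contigs
  widths <- Biostrings::width(contigs)
  eligible <- which(widths >= clen)
  if (length(eligible) == 0L) {
    stop(
      "consensus '", spec$consensus_id, "' (", clen,
      " bp) is longer than every contig", call. = FALSE
    )
  }
  occupied <- split(
    IRanges::IRanges(genome$insertions$start, genome$insertions$end),
    factor(genome$insertions$contig_id, levels = names(contigs))
  )
  recs <- vector("list", spec$n_copies)
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_copies)) {
      placed <- FALSE
      for (try in 1:100) {
        ci <- eligible[sample.int(length(eligible), 1L)]
        start <- sample.int(widths[ci] - clen + 1L, 1L)
        cand <- IRanges::IRanges(start, start + clen - 1L)
        if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0L) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place copy ", i, " without overlap after 100 tries",
          call. = FALSE
        )
      }
      occupied[[ci]] <- c(occupied[[ci]], cand)
      copy <- mutate_k2p(cons, spec$target_divergence, spec$ts_tv_ratio)
      sub <- count_substitutions(as.character(copy), as.character(cons))
      contigs[[ci]] <- Biostrings::replaceAt(
        contigs[[ci]],
        IRanges::IRanges(start, start + clen - 1L), copy
      )
      recs[[i]] <- data.frame(
        contig_id = names(contigs)[ci], start = start,
        end = start + clen - 1L, consensus_id = spec$consensus_id,
        divergence = k2p_distance(sub$P, sub$Q),
        p_transitions = sub$P, q_transversions = sub$Q,
        stringsAsFactors = FALSE
      )
    }
  })
  genome$contigs <- contigs
  genome$insertions <- rbind(genome$insertions, do.call(rbind, recs))
  genome
}
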