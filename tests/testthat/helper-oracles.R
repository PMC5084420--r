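# Independent brute-force oracles. Deliberately naive: each reimplements the
# checked quantity from first principles, sharing no code with the package.

# Reverse complement of a plain character string, base R only.
rc_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Per-contig read match counts by naive substring scan: a read counts once
# for a contig if it occurs in the contig or its reverse complement. Reads
# containing anything outside ACGT never match.
naive_match_counts <- function(contigs_chr, reads_chr) {
  counts <- setNames(integer(length(contigs_chr)), names(contigs_chr))
  rcs <- vapply(contigs_chr, rc_chr, character(1))
  for (r in reads_chr) {
    if (nchar(r) == 0 || grepl("[^ACGT]", r)) next
    hit <- grepl(r, contigs_chr, fixed = TRUE) | grepl(r, rcs, fixed = TRUE)
    counts <- counts + as.integer(hit)
  }
  counts
}

# Quadratic-space affine-gap global alignment score (Gotoh). A gap run of
# length L costs gap_open + L * gap_ext, matching the package's convention.
dp_global_score <- function(a, b, match = 2, mismatch = -2, gap_open = 5,
                            gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  Ix <- matrix(neg, n + 1, m + 1) # gap in b (consumes a)
  Iy <- matrix(neg, n + 1, m + 1) # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(
        M[i, j + 1] - gap_open - gap_ext,
        Ix[i, j + 1] - gap_ext,
        Iy[i, j + 1] - gap_open - gap_ext
      )
      Iy[i + 1, j + 1] <- max(
        M[i + 1, j] - gap_open - gap_ext,
        Iy[i + 1, j] - gap_ext,
        Ix[i + 1, j] - gap_open - gap_ext
      )
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Repeat bp by per-base bitmap marking (merge oracle).
bitmap_repeat_bp <- function(ann, contig_lengths) {
  total <- 0L
  for (ctg in unique(ann$contig_id)) {
    mask <- logical(contig_lengths[[ctg]])
    rows <- ann[ann$contig_id == ctg, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      mask[rows$start[k]:rows$end[k]] <- TRUE
    }
    total <- total + sum(mask)
  }
  total
}

# N50 by all-prefix scan over descending lengths.
brute_n50 <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) {
      return(x)
    }
  }
}

# Expected per-site transition (P) and transversion (Q) difference
# probabilities after d expected substitution events per site with
# transition:transversion event ratio R, from the Kimura model's spectral
# solution; written independently of the package's generator.
oracle_pq <- function(d, R) {
  alpha <- R / (R + 1)
  beta <- 1 / (2 * (R + 1))
  list(
    P = 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d),
    Q = 0.5 - 0.5 * exp(-4 * beta * d)
  )
}

# Random DNA as character string.
random_dna_chr <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Assemble an alignment_counts object from raw numbers (unit-test fixture).
make_counts <- function(contig_id, n_matched, total, lengths = NULL) {
  res <- data.frame(
    contig_id = contig_id,
    length = if (is.null(lengths)) rep(1000L, length(contig_id)) else lengths,
    n_matched = as.integer(n_matched),
    stringsAsFactors = FALSE
  )
  attr(res, "total_reads") <- as.integer(total)
  class(res) <- c("alignment_counts", "data.frame")
  res
}
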