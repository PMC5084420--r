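test_that("K2P distance matches independent evaluation and handles saturation", {
  expect_equal(k2p_distance(0, 0), 0)
  # -1/2 ln(0.75 * sqrt(0.90)), evaluated independently to high precision
  expect_equal(k2p_distance(0.1, 0.05), 0.170181165140347, tolerance = 1e-9)
  expect_true(is.na(k2p_distance(0.5, 0))) # 1 - 2P - Q = 0
  expect_true(is.na(k2p_distance(0.2, 0.5))) # 1 - 2Q = 0
  expect_error(k2p_distance(-0.1, 0), "non-negative")
  expect_error(k2p_distance(0.8, 0.3), "P \\+ Q")
})

test_that("K2P exceeds the raw mismatch fraction and is monotone", {
  grid <- expand.grid(P = seq(0, 0.35, by = 0.05), Q = seq(0, 0.25, by = 0.05))
  k <- k2p_distance(grid$P, grid$Q)
  ok <- !is.na(k)
  raw <- grid$P + grid$Q
  expect_true(all(k[ok] >= raw[ok]))
  expect_true(all((k[ok] == raw[ok]) == (raw[ok] == 0)))
  # strictly increasing in P for fixed Q, and in Q for fixed P
  for (q in unique(grid$Q)) {
    kk <- k2p_distance(seq(0, 0.3, by = 0.02), q)
    kk <- kk[!is.na(kk)]
    expect_true(all(diff(kk) > 0))
  }
  for (p in unique(grid$P)) {
    kk <- k2p_distance(p, seq(0, 0.24, by = 0.02))
    kk <- kk[!is.na(kk)]
    expect_true(all(diff(kk) > 0))
  }
  # Q = 0 reduces to -1/2 ln(1 - 2P); series ~ P + P^2 + ... for small P
  p <- c(0.001, 0.005, 0.01)
  expect_equal(k2p_distance(p, 0), -0.5 * log(1 - 2 * p), tolerance = 1e-12)
  expect_equal(
    k2p_distance(p, 0), p + p^2 + (4 / 3) * p^3 + 2 * p^4,
    tolerance = 1e-6
  )
})

test_that("substitution counting classifies columns like a hand tally", {
  expect_equal(
    count_substitutions("ACGT", "ACGT"),
    list(aligned_columns = 4L, P = 0, Q = 0)
  )
  # G/C: purine vs pyrimidine -> transversion
  expect_equal(
    count_substitutions("AGGT", "ACGT"),
    list(aligned_columns = 4L, P = 0, Q = 0.25)
  )
  # G/A: purine vs purine -> transition
  expect_equal(
    count_substitutions("GCGT", "ACGT"),
    list(aligned_columns = 4L, P = 0.25, Q = 0)
  )
  # gap and N columns leave the denominator
  expect_equal(
    count_substitutions("A-GNT", "ACGCT"),
    list(aligned_columns = 3L, P = 0, Q = 0)
  )
  none <- count_substitutions("---", "AAA")
  expect_equal(none$aligned_columns, 0L)
  expect_true(is.na(none$P) && is.na(none$Q))
  expect_error(count_substitutions("AC", "A"), "length")
})

test_that("global alignment matches an independent affine-gap DP on score", {
  id <- align_copy_to_consensus("ACGTACGT", "ACGTACGT")
  expect_equal(id$score, 16)
  expect_false(grepl("-", id$copy))

  one <- align_copy_to_consensus("ACGTACGT", "ACGAACGT")
  expect_equal(one$score, 7 * 2 - 2)
  expect_false(grepl("-", paste0(one$copy, one$consensus)))

  set.seed(97)
  for (i in 1:8) {
    a <- random_dna_chr(sample(40:200, 1))
    bv <- strsplit(a, "")[[1]]
    cut <- sample(length(bv), sample(1:6, 1))
    bv <- bv[-cut]
    sub <- sample(length(bv), sample(0:8, 1))
    bv[sub] <- sample(c("A", "C", "G", "T"), length(sub), replace = TRUE)
    b <- paste(bv, collapse = "")
    expect_equal(align_copy_to_consensus(a, b)$score, dp_global_score(a, b))
  }
  expect_error(align_copy_to_consensus("", "ACGT"), "non-empty")
})

test_that("landscape bins conserve aligned bp and place divergences", {
  al <- data.frame(
    te_class = c("LINE", "LINE", "LTR", "DNA"),
    aligned_columns = c(500L, 200L, 300L, 100L),
    k2p = c(0.073, 0.081, NA, 0.601) # NA: saturated; 0.601: beyond cap
  )
  land <- build_landscape(al, bin_width = 1, cap = 55)
  line7 <- land[land$te_class == "LINE" & land$bin_lo == 7, ]
  expect_equal(line7$bp, 500) # 7.3 % -> [7, 8)
  line8 <- land[land$te_class == "LINE" & land$bin_lo == 8, ]
  expect_equal(line8$bp, 200)
  over <- land[land$te_class == "DNA", ]
  expect_equal(over$bin_lo, 55)
  expect_true(is.infinite(over$bin_hi))
  expect_equal(attr(land, "total_bp"), 800) # all defined-k2p bp
  expect_equal(attr(land, "saturated_bp"), 300)

  empty <- build_landscape(al[0, ], 1)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "total_bp"), 0)
  expect_error(build_landscape(al, bin_width = 0), "bin_width")
})

test_that("landscape conservation holds on randomized alignment sets", {
  set.seed(101)
  for (w in c(0.5, 1, 2)) {
    al <- data.frame(
      te_class = sample(c("LINE", "LTR", "DNA", "RC"), 200, replace = TRUE),
      aligned_columns = sample(50:2000, 200, replace = TRUE),
      k2p = ifelse(runif(200) < 0.1, NA, runif(200, 0, 0.7))
    )
    land <- build_landscape(al, bin_width = w)
    expect_equal(
      attr(land, "total_bp"),
      sum(al$aligned_columns[!is.na(al$k2p)])
    )
    expect_equal(
      attr(land, "saturated_bp"),
      sum(al$aligned_columns[is.na(al$k2p)])
    )
    expect_equal(sum(attr(land, "class_totals")$bp), attr(land, "total_bp"))
  }
})

test_that("repeat fraction merges overlaps and matches the bitmap oracle", {
  seqs <- Biostrings::DNAStringSet(c(ctg = strrep("A", 1000)))
  expect_equal(
    repeat_fraction(
      data.frame(contig_id = "ctg", start = 1, end = 100), seqs
    )$fraction,
    0.1
  )
  two <- repeat_fraction(
    data.frame(contig_id = c("ctg", "ctg"), start = c(1, 51), end = c(100, 150)),
    seqs
  )
  expect_equal(two$repeat_bp, 150)

  set.seed(103)
  lens <- c(ctgA = 5000L, ctgB = 3000L)
  seqs2 <- Biostrings::DNAStringSet(vapply(lens, function(n) {
    strrep("T", n)
  }, character(1)))
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    ctg <- sample(names(lens), n, replace = TRUE)
    start <- vapply(ctg, function(cc) sample(lens[[cc]] - 99, 1), numeric(1))
    ann <- data.frame(
      contig_id = ctg, start = start,
      end = start + sample(10:99, n, replace = TRUE)
    )
    expect_equal(
      repeat_fraction(ann, seqs2)$repeat_bp,
      bitmap_repeat_bp(ann, as.list(lens))
    )
  }

  expect_error(
    repeat_fraction(
      data.frame(contig_id = "ctgA", start = 4990, end = 5050), seqs2
    ),
    "ctgA:4990-5050"
  )
})

test_that("canonical TSV alignments round-trip and feed divergence", {
  al <- data.frame(
    contig_id = "ctg1", start = 11L, end = 14L,
    te_name = "el", te_class = "LINE",
    aligned_insertion = "AGGT", aligned_consensus = "ACGT",
    stringsAsFactors = FALSE
  )
  tf <- tempfile(fileext = ".tsv")
  write_repeat_alignments(al, tf)
  back <- read_repeat_alignments(tf)
  expect_equal(back, al)
  div <- repeat_divergence(back)
  expect_equal(div$Q, 0.25)
  expect_equal(div$k2p, k2p_distance(0, 0.25))
  expect_error(
    repeat_divergence(al[, -1, drop = FALSE]),
    "must carry columns"
  )
})

test_that("cross_match-style .align blocks parse best-effort", {
  lines <- c(
    "239 12.50 0.00 0.00 ctg0001 101 108 (892) jockey#LINE/Jockey 1 8 (0) m_b1 1",
    "",
    "  ctg0001        101 ACGTAC 106",
    "                       i",
    "  jockey#LINE      1 ACGCAC 6",
    "",
    "  ctg0001        107 GT 108",
    "  jockey#LINE      7 GT 8",
    "",
    "Matrix = 20p43g.matrix",
    "120 5.00 0.00 0.00 ctg0002 5 10 (100) C mariner#DNA/Tc1 (0) 6 1",
    "",
    "  ctg0002          5 AACCGG 10",
    "C mariner#DNA      6 AACCGG 1",
    ""
  )
  tf <- tempfile(fileext = ".align")
  writeLines(lines, tf)
  al <- read_rm_align(tf)
  expect_equal(nrow(al), 2L)
  expect_equal(al$contig_id, c("ctg0001", "ctg0002"))
  expect_equal(al$aligned_insertion[1], "ACGTACGT")
  expect_equal(al$aligned_consensus[1], "ACGCACGT")
  expect_equal(al$te_class, c("LINE", "DNA"))
  div <- repeat_divergence(al)
  expect_equal(div$P[1], 0.125) # one T/C column: pyrimidine transition
  expect_equal(div$aligned_columns, c(8L, 6L))
})
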