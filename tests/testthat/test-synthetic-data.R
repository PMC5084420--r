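test_that("simulate_genome honors counts, lengths, labels and seed", {
  spec <- genome_spec(1, 0, 0, c(1000, 1000), seed = 3)
  g <- simulate_genome(spec)
  expect_length(g$contigs, 1L)
  expect_equal(Biostrings::width(g$contigs), 1000L)
  expect_equal(g$truth$class, "A")

  # byte-identical FASTA for identical spec + seed
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(simulate_genome(spec)$contigs, f1)
  write_fasta(simulate_genome(spec)$contigs, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(genome_spec(0, 0, 0), "at least one contig")
  expect_error(genome_spec(1, 0, 0, gc_content = 1), "gc_content")
})

test_that("simulated base composition matches the requested GC", {
  g <- simulate_genome(genome_spec(1, 0, 0, c(100000, 100000),
    gc_content = 0.5, seed = 11
  ))
  af <- Biostrings::alphabetFrequency(g$contigs[[1]], baseOnly = TRUE)
  gc <- sum(af[c("C", "G")]) / sum(af[c("A", "C", "G", "T")])
  # binomial se ~ sqrt(.25/1e5) = 0.0016; 0.01 is > 6 se
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("plant_te_copies at divergence 0 copies the consensus verbatim", {
  g <- simulate_genome(genome_spec(3, 0, 0, c(5000, 8000), seed = 2))
  lib <- Biostrings::DNAStringSet(c("cons#LINE" = random_dna_chr(2000)))
  out <- plant_te_copies(g, lib, te_plant_spec("cons#LINE",
    n_copies = 3,
    target_divergence = 0, seed = 4
  ))
  for (i in seq_len(3)) {
    ins <- out$insertions[i, ]
    planted <- as.character(Biostrings::subseq(
      out$contigs[[ins$contig_id]], ins$start, ins$end
    ))
    expect_identical(planted, as.character(lib[[1]]))
  }
  expect_equal(out$insertions$divergence, rep(0, 3))
})

test_that("planted copies realize the substitution process expectations", {
  set.seed(1)
  g <- simulate_genome(genome_spec(12, 0, 0, c(6000, 9000), seed = 21))
  lib <- Biostrings::DNAStringSet(c("cons#LINE" = random_dna_chr(5000)))

  # raw mismatch fraction at d = 0.10: multiple hits make the expectation
  # p_ts + p_tv < d; oracle gives the closed-form value (~0.0929)
  out <- plant_te_copies(g, lib, te_plant_spec("cons#LINE",
    n_copies = 1,
    target_divergence = 0.10, ts_tv_ratio = 2, seed = 31
  ))
  ins <- out$insertions[1, ]
  planted <- strsplit(as.character(Biostrings::subseq(
    out$contigs[[ins$contig_id]], ins$start, ins$end
  )), "")[[1]]
  cons <- strsplit(as.character(lib[[1]]), "")[[1]]
  raw <- mean(planted != cons)
  pq <- oracle_pq(0.10, 2)
  expected_raw <- pq$P + pq$Q
  se <- sqrt(expected_raw * (1 - expected_raw) / 5000)
  expect_lt(abs(raw - expected_raw), 4 * se)
  # and within the looser planning band around the target itself
  expect_lt(abs(raw - 0.10), 0.013)

  # pooled transition/transversion ratio over 10 copies tracks ts_tv_ratio
  out2 <- plant_te_copies(g, lib, te_plant_spec("cons#LINE",
    n_copies = 10,
    target_divergence = 0.10, ts_tv_ratio = 2, seed = 32
  ))
  ts <- 0L
  tv <- 0L
  purine <- c("A", "G")
  for (i in seq_len(nrow(out2$insertions))) {
    ins <- out2$insertions[i, ]
    planted <- strsplit(as.character(Biostrings::subseq(
      out2$contigs[[ins$contig_id]], ins$start, ins$end
    )), "")[[1]]
    mism <- planted != cons
    same_class <- (planted %in% purine) == (cons %in% purine)
    ts <- ts + sum(mism & same_class)
    tv <- tv + sum(mism & !same_class)
  }
  expect_lt(abs(ts / tv - (pq$P / pq$Q)), 0.4)
  expect_lt(abs(ts / tv - 2.0), 0.4)
})

test_that("plant_te_copies rejects a consensus longer than every contig", {
  g <- simulate_genome(genome_spec(2, 0, 0, c(500, 800), seed = 5))
  lib <- Biostrings::DNAStringSet(c("big#LTR" = random_dna_chr(2000)))
  expect_error(
    plant_te_copies(g, lib, te_plant_spec("big#LTR", n_copies = 1)),
    "longer than every contig"
  )
  expect_error(
    plant_te_copies(g, lib, te_plant_spec("absent#LTR", n_copies = 1)),
    "not found"
  )
})

test_that("error-free reads are exact substrings at the requested coverage", {
  g <- simulate_genome(genome_spec(1, 0, 0, c(10000, 10000), seed = 7))
  rs <- simulate_reads(g, read_sim_spec("female",
    depth = 10, read_length = 100,
    substitution_error_rate = 0, seed = 8
  ))
  # female autosome weight 2: W = 2 * 10000, n = 10 * 20000 / 100 = 2000
  expect_equal(length(rs$reads), 2000L)
  ctg <- as.character(g$contigs[[1]])
  rcc <- rc_chr(ctg)
  sampled <- as.character(rs$reads[sample(length(rs$reads), 200)])
  expect_true(all(vapply(
    sampled,
    function(r) grepl(r, ctg, fixed = TRUE) || grepl(r, rcc, fixed = TRUE),
    logical(1)
  )))
  # coverage conservation within one read
  expect_lte(
    abs(sum(Biostrings::width(rs$reads)) - 10 * 2 * 10000),
    100
  )
})

test_that("read origins follow the sex-specific copy-number weights", {
  g <- simulate_genome(genome_spec(4, 4, 4, c(8000, 8000), seed = 13))
  f <- simulate_reads(g, read_sim_spec("female", depth = 15, seed = 14))
  m <- simulate_reads(g, read_sim_spec("male", depth = 15, seed = 15))
  cls <- setNames(g$truth$class, g$truth$contig_id)

  # no female read originates from a Y contig
  expect_equal(sum(cls[f$origin$contig_id] == "Y"), 0L)
  # male reads do cover Y
  expect_gt(sum(cls[m$origin$contig_id] == "Y"), 0L)

  fo <- table(factor(cls[f$origin$contig_id], levels = c("A", "X")))
  mo <- table(factor(cls[m$origin$contig_id], levels = c("A", "X")))
  # per-read-budget origin fractions: female A share / male A share ~ 1,
  # female X share / male X share ~ 2
  fshare <- fo / length(f$reads)
  mshare <- mo / length(m$reads)
  expect_lt(abs(fshare[["A"]] / mshare[["A"]] - 1), 0.1)
  expect_lt(abs(fshare[["X"]] / mshare[["X"]] - 2), 0.2)
})

test_that("read simulation is deterministic per seed and validates input", {
  g <- simulate_genome(genome_spec(2, 0, 0, c(3000, 5000), seed = 1))
  s <- read_sim_spec("male", depth = 3, seed = 99)
  r1 <- simulate_reads(g, s)
  r2 <- simulate_reads(g, s)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(r1$origin, r2$origin)
  expect_error(
    simulate_reads(g, read_sim_spec("male", depth = 3, read_length = 10000)),
    "read_length"
  )
  expect_error(read_sim_spec("male", depth = 0), "depth")
  expect_error(read_sim_spec("male", substitution_error_rate = 1), "error_rate")
})

test_that("truth and insertion tables round-trip through their TSV formats", {
  g <- simulate_genome(genome_spec(2, 1, 1, c(3000, 4000), seed = 17))
  lib <- make_te_library(seed = 18)
  g <- plant_te_copies(g, lib, te_plant_spec("Mariner-like#DNA",
    n_copies = 2,
    target_divergence = 0.05, seed = 19
  ))
  tf <- tempfile()
  write_truth(g$truth, tf)
  back <- read.delim(tf)
  expect_equal(names(back), c("contig_id", "class", "length"))
  expect_equal(nrow(back), 4L)
  ti <- tempfile()
  write_insertions(g$insertions, ti)
  insb <- read.delim(ti)
  expect_equal(
    names(insb),
    c("contig_id", "start", "end", "consensus_id", "divergence")
  )
  expect_true(all(insb$start >= 1))
  lens <- setNames(g$truth$length, g$truth$contig_id)
  expect_true(all(insb$end <= lens[insb$contig_id]))
})
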