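#' Run the reference CQ recovery experiment
#'
#' Simulates the package's reference study conditions — 200 contigs of
#' 5-50 kb (140 autosomal / 30 X-linked / 30 Y-linked), female and male
#' read pools at 20x coverage with 100 bp reads and a 0.005 substitution
#' error rate — maps both pools under the zero-mismatch criterion,
#' classifies every contig with the default thresholds, and scores the
#' labels against the simulation truth.
#'
#' This is the experiment that validates the classifier: Y-linked contigs
#' receive (almost) no female reads, X-linked contigs twice the female
#' share, so default thresholds should recover nearly all planted structure.
#'
#' @param seed integer seed driving genome and read simulation.
#' @param thresholds a [cq_thresholds()].
#' @param genome,reads optional overrides of the [genome_spec()] /
#'   [read_sim_spec()] condition fields, as named lists.
#' @return a list with `records` (the labeled `cq_records`), `truth`, and
#'   `metrics`: `y_recall`, `x_recall` (fraction of true Y/X labeled so),
#'   `a_false_rate` (fraction of true autosomes labeled X or Y),
#'   `median_cq_autosomal`, `median_cq_x`, `x_bp_true`, `x_bp_labeled`,
#'   `y_bp_true`, `y_bp_labeled`.
#' @export
cq_reference_run <- function(seed = 1, thresholds = cq_thresholds(),
                             genome = list(), reads = list()) {
  gspec <- do.call(genome_spec, modifyList(
    list(
      n_autosomal_contigs = 140L, n_x_contigs = 30L, n_y_contigs = 30L,
      contig_length_range = c(5000L, 50000L), gc_content = 0.28,
      seed = derive_seed(seed, "genome")
    ),
    genome
  ))
  g <- simulate_genome(gspec)
  make_reads <- function(sex) {
    do.call(read_sim_spec, modifyList(
      list(
        sex = sex, depth = 20, read_length = 100L,
        substitution_error_rate = 0.005,
        seed = derive_seed(seed, paste0("reads-", sex))
      ),
      reads
    ))
  }
  female <- simulate_reads(g, make_reads("female"))
  male <- simulate_reads(g, make_reads("male"))
  idx <- exact_index(g$contigs)
  fc <- count_exact_matches(idx, female)
  mc <- count_exact_matches(idx, male)
  records <- compute_cq(fc, mc, thresholds)
  cls <- g$truth$class[match(records$contig_id, g$truth$contig_id)]
  is_y <- cls == "Y"
  is_x <- cls == "X"
  is_a <- cls == "A"
  metrics <- list(
    y_recall = mean(records$label[is_y] == "Y"),
    x_recall = mean(records$label[is_x] == "X"),
    a_false_rate = mean(records$label[is_a] %in% c("X", "Y")),
    median_cq_autosomal = stats::median(records$cq[is_a], na.rm = TRUE),
    median_cq_x = stats::median(records$cq[is_x], na.rm = TRUE),
    x_bp_true = sum(as.numeric(records$length[is_x])),
    x_bp_labeled = sum(as.numeric(records$length[records$label == "X"])),
    y_bp_true = sum(as.numeric(records$length[is_y])),
    y_bp_labeled = sum(as.numeric(records$length[records$label == "Y"]))
  )
  list(records = records, truth = g$truth, metrics = metrics)
}
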