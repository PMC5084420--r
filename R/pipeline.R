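#' Default run configuration
#'
#' A nested list driving [run_pipeline()]. Two modes:
#'
#' * `mode = "simulate"` — generate a sexed genome, TE plants and read
#'   pools, then run the full analysis against the simulation truth. The
#'   defaults are the package's reference study conditions: 140 autosomal /
#'   30 X / 30 Y contigs of 5-50 kb at 28 % GC, both sexes at 20x coverage
#'   with 100 bp reads and 0.005 substitution error, TE families planted at
#'   divergences 0.05 / 0.15 / 0.30.
#' * `mode = "user"` — analyze an existing assembly plus two sexed read
#'   sets, with optional repeat alignments (canonical TSV or `.align`).
#'
#' All randomness flows from the single top-level `seed` through per-stage
#' derived seeds.
#'
#' @return the default configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "cqscan-out",
    mode = "simulate",
    simulate = list(
      genome = list(
        n_autosomal = 140L, n_x = 30L, n_y = 30L,
        length_range = c(5000L, 50000L), gc_content = 0.28
      ),
      reads = list(depth = 20, read_length = 100L, error_rate = 0.005),
      te = list(
        enabled = TRUE, n_copies_per_family = 10L,
        divergences = c(0.05, 0.15, 0.30), ts_tv_ratio = 2
      ),
      write_reads = FALSE
    ),
    inputs = list(
      assembly = NULL, female_reads = NULL, male_reads = NULL,
      alignments = NULL
    ),
    thresholds = list(
      y_max = 0.05, x_min = 1.9, x_max = 2.5, min_male_hits = 20L,
      normalize = TRUE
    ),
    landscape = list(bin_width = 1, cap = 55),
    stats = list(min_length = 0L)
  )
}

#' Read / write a run configuration
#'
#' Configurations are YAML; unknown keys are rejected, missing keys take
#' defaults, and a written configuration reads back identical.
#'
#' @param path YAML path.
#' @return `read_config`: a validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  cfg <- modifyList(def, config)
  # modifyList and YAML both drop NULL-valued keys; restore them so a
  # written config reads back identical
  for (key in c("assembly", "female_reads", "male_reads", "alignments")) {
    if (is.null(cfg$inputs[[key]])) cfg$inputs[key] <- list(NULL)
  }
  if (!cfg$mode %in% c("simulate", "user")) {
    stop("mode must be 'simulate' or 'user'", call. = FALSE)
  }
  if (cfg$mode == "user") {
    for (key in c("assembly", "female_reads", "male_reads")) {
      p <- cfg$inputs[[key]]
      if (is.null(p)) {
        stop("user mode requires inputs$", key, call. = FALSE)
      }
      if (!file.exists(p)) {
        stop("inputs$", key, " does not exist: ", p, call. = FALSE)
      }
    }
    if (!is.null(cfg$inputs$alignments) &&
      !file.exists(cfg$inputs$alignments)) {
      stop("inputs$alignments does not exist: ", cfg$inputs$alignments,
        call. = FALSE
      )
    }
  }
  # constructor validation of threshold and simulation blocks
  do.call(cq_thresholds, cfg$thresholds)
  cfg
}

pipeline_log <- function(...) {
  message("[cqscan] ", ...)
}

#' Run the full CQ + repeat-landscape pipeline
#'
#' Executes simulate (optional) -> count -> CQ classify -> summarize ->
#' landscape -> assembly stats, writing every artifact plus a JSON run
#' report and a manifest (parameters, seed, package version, md5 of inputs
#' and outputs). Reruns with the same configuration and seed produce
#' byte-identical TSV/JSON outputs. Any stage failure aborts with the stage
#' name.
#'
#' @param config a configuration list (see [default_config()]), or a YAML
#'   path.
#' @return the run report, invisibly; artifacts under `config$outdir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  report <- list(mode = cfg$mode, seed = cfg$seed)
  stage <- function(name, expr) {
    pipeline_log("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  truth <- NULL
  insertions <- NULL
  alignments <- NULL

  if (cfg$mode == "simulate") {
    sim <- cfg$simulate
    genome <- stage("simulate-genome", {
      simulate_genome(genome_spec(
        sim$genome$n_autosomal, sim$genome$n_x, sim$genome$n_y,
        sim$genome$length_range, sim$genome$gc_content,
        seed = derive_seed(cfg$seed, "genome")
      ))
    })
    if (isTRUE(sim$te$enabled)) {
      genome <- stage("simulate-te", {
        lib <- make_te_library(seed = derive_seed(cfg$seed, "te-library"))
        div <- rep_len(sim$te$divergences, length(lib))
        for (i in seq_along(lib)) {
          genome <- plant_te_copies(genome, lib, te_plant_spec(
            names(lib)[i],
            n_copies = sim$te$n_copies_per_family,
            target_divergence = div[i], ts_tv_ratio = sim$te$ts_tv_ratio,
            seed = derive_seed(cfg$seed, paste0("te-", names(lib)[i]))
          ))
        }
        genome$library <- lib
        genome
      })
      alignments <- stage("align-te-copies", {
        planted_alignments(genome)
      })
    }
    contigs <- genome$contigs
    truth <- genome$truth
    insertions <- genome$insertions
    outputs <- c(
      outputs,
      write_fasta(contigs, file.path(cfg$outdir, "assembly.fasta")),
      write_truth(truth, file.path(cfg$outdir, "truth.tsv")),
      write_insertions(insertions, file.path(cfg$outdir, "insertions.tsv"))
    )
    female <- stage("simulate-reads-female", {
      simulate_reads(genome, read_sim_spec(
        "female", sim$reads$depth, sim$reads$read_length,
        sim$reads$error_rate,
        seed = derive_seed(cfg$seed, "reads-female")
      ))
    })
    male <- stage("simulate-reads-male", {
      simulate_reads(genome, read_sim_spec(
        "male", sim$reads$depth, sim$reads$read_length,
        sim$reads$error_rate,
        seed = derive_seed(cfg$seed, "reads-male")
      ))
    })
    if (isTRUE(sim$write_reads)) {
      outputs <- c(
        outputs,
        write_fastq(female, file.path(cfg$outdir, "female.fastq.gz")),
        write_fastq(male, file.path(cfg$outdir, "male.fastq.gz"))
      )
    }
    female_reads <- female$reads
    male_reads <- male$reads
  } else {
    contigs <- stage("read-assembly", read_assembly(cfg$inputs$assembly))
    female_reads <- stage("read-female", read_reads(cfg$inputs$female_reads))
    male_reads <- stage("read-male", read_reads(cfg$inputs$male_reads))
    if (!is.null(cfg$inputs$alignments)) {
      alignments <- stage("read-alignments", {
        p <- cfg$inputs$alignments
        if (grepl("\\.align$", p)) read_rm_align(p) else read_repeat_alignments(p)
      })
    }
  }

  idx <- stage("index", exact_index(contigs))
  fc <- stage("count-female", count_exact_matches(idx, female_reads))
  mc <- stage("count-male", count_exact_matches(idx, male_reads))
  outputs <- c(
    outputs,
    write_counts(fc, file.path(cfg$outdir, "counts.female.tsv")),
    write_counts(mc, file.path(cfg$outdir, "counts.male.tsv"))
  )

  thresholds <- do.call(cq_thresholds, cfg$thresholds)
  records <- stage("cq", compute_cq(fc, mc, thresholds))
  outputs <- c(
    outputs,
    stage("cq-write", write_cq(records, file.path(cfg$outdir, "cq"), contigs))
  )
  summary <- summarize_chromosomes(records)
  report$labels <- summary
  report$xy_size_difference <- attr(summary, "xy_size_difference")
  if (!is.null(truth)) {
    cm <- table(
      truth = truth$class[match(records$contig_id, truth$contig_id)],
      label = factor(records$label,
        levels = c("X", "Y", "unassigned", "low-evidence")
      )
    )
    report$confusion <- as.data.frame(cm, stringsAsFactors = FALSE)
  }

  if (!is.null(alignments)) {
    div <- stage("divergence", repeat_divergence(alignments))
    land <- stage("landscape", {
      build_landscape(div, cfg$landscape$bin_width, cfg$landscape$cap)
    })
    outputs <- c(
      outputs,
      write_landscape(land, file.path(cfg$outdir, "landscape.tsv")),
      write_repeat_alignments(
        alignments, file.path(cfg$outdir, "repeat_alignments.tsv")
      )
    )
    rf <- stage("repeat-fraction", {
      repeat_fraction(
        alignments[, c("contig_id", "start", "end")], contigs
      )
    })
    report$landscape <- list(
      total_bp = attr(land, "total_bp"),
      saturated_bp = attr(land, "saturated_bp"),
      class_totals = attr(land, "class_totals")
    )
    report$repeat_fraction <- rf
  }

  stats <- stage("stats", assembly_stats(contigs, cfg$stats$min_length))
  outputs <- c(
    outputs,
    stage("stats-write", write_assembly_stats(
      stats, file.path(cfg$outdir, "assembly_stats")
    ))
  )
  report$assembly_stats <- unclass(stats)

  report_path <- file.path(cfg$outdir, "report.json")
  jsonlite::write_json(report, report_path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "columns"
  )
  outputs <- c(outputs, report_path)

  manifest <- list(
    package = "cqscan",
    version = as.character(packageVersion("cqscan")),
    seed = cfg$seed,
    config = cfg,
    inputs = if (cfg$mode == "user") {
      as.list(md5sum(unlist(Filter(Negate(is.null), cfg$inputs))))
    } else {
      list()
    },
    outputs = as.list(md5sum(sort(unique(outputs))))
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE,
    digits = NA, pretty = TRUE
  )
  pipeline_log("done: ", length(outputs), " artifacts in ", cfg$outdir)
  invisible(report)
}

# Reconstruct gapped alignments for planted TE copies by realigning each
# planted window to its consensus (exercises the alignment path; the truth
# table's realized P/Q remain the independent oracle).
planted_alignments <- function(genome) {
  ins <- genome$insertions
  if (is.null(ins) || nrow(ins) == 0L) {
    return(NULL)
  }
  lib <- genome$library
  rows <- lapply(seq_len(nrow(ins)), function(i) {
    copy <- Biostrings::extractAt(
      genome$contigs[[ins$contig_id[i]]],
      IRanges::IRanges(ins$start[i], ins$end[i])
    )[[1]]
    al <- align_copy_to_consensus(copy, lib[[ins$consensus_id[i]]])
    data.frame(
      contig_id = ins$contig_id[i], start = ins$start[i], end = ins$end[i],
      te_name = sub("#.*$", "", ins$consensus_id[i]),
      te_class = te_class_from_label(ins$consensus_id[i]),
      aligned_insertion = al$copy, aligned_consensus = al$consensus,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
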