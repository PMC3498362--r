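# report_cli backend: orchestrate the full pipeline from a configuration and
# emit the summary tables. Each stage is also runnable standalone through
# the exported module functions; `scripts/run_pipeline.R` is a thin shell
# wrapper around run_pipeline().

#' Assemble a pipeline configuration
#'
#' Accepts either a YAML file path or a named list. Recognized fields:
#' `genome`, `annotations`, `reads_a`, `reads_b`, `mature`, `transcriptome`,
#' `degradome` (paths; stages whose inputs are missing are skipped with a
#' logged notice), module parameters (`adapter3`, `min_overlap`, `min_len`,
#' `max_len`, `known_threshold`, `novel_threshold`, `min_count`,
#' `merge_distance`, `long_flank`, `short_flank`, `max_unpaired`,
#' `max_bulge`, `target_threshold`, `gu_half`, `window`), `seed`, and
#' `labels` (display names for conditions A and B, e.g. `+N` / `-N`).
#'
#' @param config YAML path or named list.
#' @return Normalized config list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    genome = NULL, annotations = NULL, reads_a = NULL, reads_b = NULL,
    mature = NULL, transcriptome = NULL, degradome = NULL,
    adapter3 = "TGGAATTCTCGGGTGCCAAGG", adapter5 = NULL,
    min_overlap = 8L, min_len = 18L, max_len = 30L,
    length_window = c(19L, 24L),
    known_threshold = 3, novel_threshold = 2, min_count = 5L,
    merge_distance = 30L, max_nloci = 5L, long_flank = 150L,
    short_flank = 20L, max_unpaired = 4L, max_bulge = 2L,
    target_threshold = 3, gu_half = TRUE, window = 1L,
    seed = 1L, labels = c(A = "A", B = "B"))
  cfg <- utils::modifyList(defaults, config)
  cfg
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full two-condition small-RNA pipeline
#'
#' preprocess -> map -> annotate -> quant -> discover -> targets, writing
#' the class composition summary, library overlap, known-miRNA expression
#' table with response calls, novel-candidate table, precursor structures
#' and the target/degradome report into `out_dir`, together with `run.log`
#' recording every parameter.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))
  set.seed(cfg$seed)
  for (p in setdiff(names(cfg), c("labels"))) {
    log_line(logf, "param ", p, " = ",
             paste(format(cfg[[p]] %||% "NULL"), collapse = ","))
  }
  need <- function(what) {
    ok <- !is.null(cfg[[what]])
    if (!ok) log_line(logf, "notice: no ", what, " input; stage skipped")
    ok
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  results <- list(config = cfg)
  # preprocess
  if (!need("reads_a") || !need("reads_b")) stop("both read libraries are required")
  results$table <- stage("preprocess", {
    ra <- read_small_rna(cfg$reads_a)
    rb <- read_small_rna(cfg$reads_b)
    ta <- trim_reads(ra$reads, cfg$adapter3, ra$counts, cfg$adapter5,
                     cfg$min_overlap, cfg$min_len, cfg$max_len)
    tb <- trim_reads(rb$reads, cfg$adapter3, rb$counts, cfg$adapter5,
                     cfg$min_overlap, cfg$min_len, cfg$max_len)
    log_line(logf, "library A: ", sum(ta$counts), " clean reads (",
             sum(ta$rejected), " rejected)")
    log_line(logf, "library B: ", sum(tb$counts), " clean reads (",
             sum(tb$rejected), " rejected)")
    collapse_reads(ta$inserts, tb$inserts, ta$counts, tb$counts)
  })
  table <- results$table
  totals <- c(A = sum(table$count_A), B = sum(table$count_B))
  results$length_profile <- length_profile(table, window = cfg$length_window)
  # map
  if (!need("genome")) stop("a genome is required")
  results$index <- stage("map", build_index(cfg$genome))
  results$mapping <- stage("map", locate(table, results$index))
  mapped <- results$mapping$mapped
  mapped_tab <- table[table$sequence %in% mapped$sequence, , drop = FALSE]
  # annotate
  ann <- NULL
  if (need("annotations")) {
    ann <- stage("annotate", read_annotations(cfg$annotations))
  }
  results$classes <- stage("annotate", {
    if (is.null(ann)) {
      setNames(rep("other", length(unique(mapped$sequence))),
               unique(mapped$sequence))
    } else {
      classify_tags(mapped, ann)
    }
  })
  results$class_summary <- stage("annotate",
                                 class_summary(mapped_tab, results$classes))
  results$overlap <- stage("annotate", library_overlap(mapped_tab))
  # quant (known miRNAs)
  known <- character(0)
  if (need("mature")) {
    results$known <- stage("quant", quantify_known(
      mapped_tab, cfg$mature, totals, cfg$known_threshold, cfg$min_count))
    known <- results$known$sequence
  }
  # discover
  results$novel <- stage("discover", discover_mirnas(
    mapped, results$classes, mapped_tab, results$index,
    known_matures = known, merge_distance = cfg$merge_distance,
    min_count = cfg$min_count, max_nloci = cfg$max_nloci,
    long_flank = cfg$long_flank, short_flank = cfg$short_flank,
    max_unpaired = cfg$max_unpaired, max_bulge = cfg$max_bulge,
    ratio_threshold = cfg$novel_threshold))
  # targets
  if (need("transcriptome")) {
    deg <- NULL
    if (need("degradome")) deg <- read_degradome(cfg$degradome)
    mirnas <- c(
      if (!is.null(results$known))
        setNames(results$known$sequence, results$known$id),
      setNames(results$novel$sequence, results$novel$id))
    responsive <- c(
      if (!is.null(results$known))
        results$known$response %in% c("NSS", "NSI"),
      results$novel$response %in% c("NSS", "NSI"))
    mirnas <- mirnas[responsive %in% TRUE]
    results$targets <- stage("targets", predict_targets(
      mirnas, cfg$transcriptome, deg, cfg$target_threshold, cfg$gu_half,
      cfg$window))
  }
  write_pipeline_tables(results, out_dir)
  log_line(logf, "pipeline complete; tables in ", out_dir)
  invisible(results)
}

#' Write the pipeline's summary tables
#'
#' Deterministic column order and row sort; fold changes at 1 decimal and
#' composition percentages in the mixed 2/1-decimal dialect are already
#' applied by the producing modules.
#'
#' @param results Result list from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(results$table, "tag_table.tsv")
  w(results$length_profile$profile, "length_profile.tsv")
  w(results$class_summary, "class_summary.tsv")
  w(results$overlap, "library_overlap.tsv")
  if (!is.null(results$mapping$stats)) w(results$mapping$stats, "mapping_stats.tsv")
  if (!is.null(results$known)) {
    w(results$known[, c("id", "count_A", "count_B", "rpm_A", "rpm_B",
                        "log2fc", "response")], "known_mirnas.tsv")
  }
  if (!is.null(results$novel)) {
    w(results$novel[, c("id", "sequence", "length", "count_A", "count_B",
                        "log2fc", "response", "star_supported",
                        "precursor_chrom", "precursor_start0",
                        "precursor_end", "strand")], "novel_mirnas.tsv")
    if (nrow(results$novel)) {
      lines <- unlist(lapply(seq_len(nrow(results$novel)), function(i) {
        c(paste0(">", results$novel$id[i]),
          results$novel$precursor_seq[i], results$novel$structure[i], "")
      }))
      writeLines(lines, file.path(out_dir, "precursor_structures.txt"))
    }
  }
  if (!is.null(results$targets)) w(results$targets, "target_report.tsv")
  invisible(out_dir)
}
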