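# synthio: fully specified synthetic reference, two-condition small-RNA
# libraries and degradome tags, with a planted truth table so every
# downstream stage is testable without external data.
#
# Planted miRNA loci are hairpin cassettes: mature + an 8-nt A loop +
# reverse complement of the mature, followed by a purine-only spacer long
# enough to cover the precursor-extraction window. Matures are drawn from
# {C,T} with a fixed C at the 3' end. Under the deterministic pair-maximizing
# fold this construction admits no equal-scoring alternative structure that
# strips mature pairs, so every planted locus passes the hairpin criteria by
# construction (the methods vignette derives why). Decoy loci are purine-only
# blocks: they emit abundant tags but cannot base-pair internally, exercising
# the discovery filter as unstructured background.

#' Build a simulation configuration
#'
#' Defaults describe a two-condition seedling experiment scaled for fast
#' simulation: ~200k reads per library, 20 planted miRNA loci with log2
#' effects spanning -3.8 .. +2.5 (both signs and zero), negative-binomial
#' count noise with dispersion 0.1 (variance mu + alpha * mu^2), and
#' degradome tags peaking opposite miRNA position 10.
#'
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_mirna Planted miRNA loci.
#' @param n_structural Structural-RNA loci (classes cycle through rRNA,
#'   tRNA, snRNA, snoRNA).
#' @param n_decoy Unstructured background loci.
#' @param n_transcripts,transcript_length Transcriptome shape.
#' @param depth Sequencing depth (reads) per library.
#' @param dispersion NB dispersion alpha; 0 gives deterministic counts.
#' @param adapter 3' adapter appended in full to every synthetic read.
#' @param fold_palette log2 fold changes assigned cyclically to planted
#'   miRNAs; must contain positive, negative and zero values.
#' @param base_mean_range Range of per-miRNA expected counts in condition A
#'   (log-uniform draw); set both ends equal for a fixed mean.
#' @param mature_lengths Mature lengths sampled for planted miRNAs.
#' @param star_fraction Fraction of planted miRNAs that also emit miRNA*
#'   reads.
#' @param target_fraction Fraction of planted miRNAs given one target site
#'   in the transcriptome.
#' @param degradome_peak Tag count at each planted cleavage position.
#' @param degradome_noise Per-position probability of a 1-count noise tag.
#' @param truncate_adapter_fraction Fraction of reads carrying only a
#'   partial (8-nt) adapter; 0 by default so trimming tests stay separable
#'   from the min-overlap decision.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 2L, chrom_length = 60000L,
                              n_mirna = 20L, n_structural = 8L,
                              n_decoy = 10L, n_transcripts = 30L,
                              transcript_length = 1200L, depth = 200000L,
                              dispersion = 0.1,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              fold_palette = c(-3.8, -2, -1.4, 0, 0.5,
                                               1.2, 2, 2.5),
                              base_mean_range = c(50, 1000),
                              mature_lengths = c(20L, 21L, 21L, 21L, 22L,
                                                 23L, 24L),
                              star_fraction = 0.2, target_fraction = 0.4,
                              degradome_peak = 50L, degradome_noise = 0.01,
                              truncate_adapter_fraction = 0,
                              seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_mirna = as.integer(n_mirna),
              n_structural = as.integer(n_structural),
              n_decoy = as.integer(n_decoy),
              n_transcripts = as.integer(n_transcripts),
              transcript_length = as.integer(transcript_length),
              depth = as.numeric(depth), dispersion = dispersion,
              adapter = normalize_seq(adapter),
              fold_palette = fold_palette,
              base_mean_range = base_mean_range,
              mature_lengths = as.integer(mature_lengths),
              star_fraction = star_fraction,
              target_fraction = target_fraction,
              degradome_peak = as.integer(degradome_peak),
              degradome_noise = degradome_noise,
              truncate_adapter_fraction = truncate_adapter_fraction,
              seed = as.integer(seed))
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (!any(cfg$fold_palette > 0) || !any(cfg$fold_palette < 0) ||
      !any(cfg$fold_palette == 0)) {
    stop("fold_palette must include positive, negative and zero values")
  }
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# NB(mu, alpha) with variance mu + alpha mu^2; alpha = 0 is deterministic
nb_draw <- function(n, mu, alpha) {
  if (alpha == 0) return(round(mu) + integer(n))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

HAIRPIN_LOOP <- "AAAAAAAA"
SPACER_LEN <- 160L # purine spacer covering the long precursor flank

#' Generate the synthetic reference and planted truth
#'
#' Builds the genome (with planted hairpin cassettes, structural-RNA and
#' decoy loci), the structural annotations, the transcriptome (with planted
#' target sites) and the truth table that downstream tests compare against.
#' Loci are laid out on fixed non-overlapping slots, so planted classes
#' never collide.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List: `genome` (named character), `annotations`
#'   ([GenomicRanges::GRanges] with `type`), `transcriptome` (named
#'   character), `truth` (list with `mirnas`, `structural`, `decoys`,
#'   `targets`, `seed`).
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  slot <- 600L
  n_loci <- config$n_mirna + config$n_structural + config$n_decoy
  slots_per_chrom <- (config$chrom_length - 200L) %/% slot
  if (slots_per_chrom * config$n_chromosomes < n_loci) {
    stop("chromosomes too short to host the requested loci")
  }
  chroms <- lapply(seq_len(config$n_chromosomes),
                   function(i) rand_seq(config$chrom_length))
  names(chroms) <- paste0("chr", seq_len(config$n_chromosomes))
  slot_at <- function(k) { # k-th slot, round-robin over chromosomes
    ci <- ((k - 1L) %% config$n_chromosomes) + 1L
    si <- (k - 1L) %/% config$n_chromosomes
    list(chrom = ci, pos0 = 100L + si * slot)
  }
  stamp <- function(chrom_i, pos0, insert) {
    s <- chroms[[chrom_i]]
    chroms[[chrom_i]] <<- paste0(substr(s, 1L, pos0),
                                 insert,
                                 substr(s, pos0 + nchar(insert) + 1L,
                                        nchar(s)))
  }
  k <- 0L
  # planted miRNA hairpins
  mir <- list()
  n_star <- ceiling(config$star_fraction * config$n_mirna)
  for (i in seq_len(config$n_mirna)) {
    k <- k + 1L
    sl <- slot_at(k)
    L <- sample(config$mature_lengths, 1L)
    mature <- paste0(rand_seq(L - 1L, c("C", "T")), "C")
    lfc <- config$fold_palette[((i - 1L) %% length(config$fold_palette)) + 1L]
    strand <- if (i %% 2L == 0L) "-" else "+"
    spacer <- rand_seq(SPACER_LEN, c("A", "G"))
    cassette <- paste0(mature, HAIRPIN_LOOP, revcomp(mature), spacer)
    genomic <- if (strand == "+") cassette else revcomp(cassette)
    stamp(sl$chrom, sl$pos0, genomic)
    # mature locus in genome coordinates (0-based half-open)
    if (strand == "+") {
      m0 <- sl$pos0
    } else {
      m0 <- sl$pos0 + nchar(cassette) - L
    }
    # star sequence: revcomp of the mature minus its first two pairs, plus
    # the first two spacer bases (the canonical 2-nt 3' overhang register)
    star_seq <- paste0(substr(revcomp(mature), 3L, L),
                       substr(spacer, 1L, 2L))
    mir[[i]] <- data.frame(
      name = sprintf("m%02d", i), sequence = mature, length = L,
      chrom = names(chroms)[sl$chrom], start0 = m0, end = m0 + L,
      strand = strand, log2fc = lfc,
      base_mean = exp(stats::runif(1, log(config$base_mean_range[1]),
                                   log(config$base_mean_range[2]))),
      star_planted = i <= n_star, star_sequence = star_seq,
      stringsAsFactors = FALSE)
  }
  mirnas <- do.call(rbind, mir)
  # structural-RNA loci (annotation intervals over the random background)
  struct <- list()
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  for (i in seq_len(config$n_structural)) {
    k <- k + 1L
    sl <- slot_at(k)
    struct[[i]] <- data.frame(
      class = classes[((i - 1L) %% 4L) + 1L],
      feature_id = sprintf("struct%02d", i),
      chrom = names(chroms)[sl$chrom], start0 = sl$pos0,
      end = sl$pos0 + 120L, strand = if (i %% 2L == 0L) "-" else "+",
      stringsAsFactors = FALSE)
  }
  structural <- if (length(struct)) do.call(rbind, struct) else NULL
  # decoy loci: purine-only, unfoldable background
  dec <- list()
  for (i in seq_len(config$n_decoy)) {
    k <- k + 1L
    sl <- slot_at(k)
    block <- rand_seq(120L, c("A", "G"))
    stamp(sl$chrom, sl$pos0, block)
    dec[[i]] <- data.frame(
      feature_id = sprintf("decoy%02d", i),
      chrom = names(chroms)[sl$chrom], start0 = sl$pos0,
      end = sl$pos0 + 120L, strand = "+", stringsAsFactors = FALSE)
  }
  decoys <- if (length(dec)) do.call(rbind, dec) else NULL
  # transcriptome with planted target sites
  tx <- setNames(
    vapply(seq_len(config$n_transcripts),
           function(i) rand_seq(config$transcript_length), character(1)),
    sprintf("T%03d", seq_len(config$n_transcripts)))
  n_target <- min(ceiling(config$target_fraction * config$n_mirna),
                  config$n_transcripts)
  targets <- NULL
  if (n_target > 0L) {
    tg <- list()
    for (i in seq_len(n_target)) {
      L <- mirnas$length[i]
      site_start <- 200L + (i - 1L) * 25L
      stopifnot(site_start + L - 1L <= config$transcript_length - 50L)
      site <- revcomp(mirnas$sequence[i])
      s <- tx[[i]]
      tx[[i]] <- paste0(substr(s, 1L, site_start - 1L), site,
                        substr(s, site_start + L, nchar(s)))
      tg[[i]] <- data.frame(
        mirna = mirnas$name[i], transcript = names(tx)[i],
        site_start1 = site_start, site_end1 = site_start + L - 1L,
        penalty = 0, stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, tg)
  }
  ann <- if (is.null(structural)) {
    GenomicRanges::GRanges()
  } else {
    GenomicRanges::GRanges(
      seqnames = structural$chrom,
      ranges = IRanges::IRanges(start = structural$start0 + 1L,
                                end = structural$end),
      strand = structural$strand,
      type = structural$class, ID = structural$feature_id)
  }
  truth <- list(mirnas = mirnas, structural = structural, decoys = decoys,
                targets = targets, seed = config$seed)
  list(genome = unlist(chroms), annotations = ann,
       transcriptome = tx, truth = truth)
}

#' Simulate two-condition small-RNA libraries
#'
#' Per planted miRNA the expected count in condition B over condition A
#' equals `2^log2fc`; counts are negative-binomial with the configured
#' dispersion. Star reads (at ~15% of the mature mean, same fold change) are
#' emitted only for star-planted loci. Structural and decoy loci emit
#' condition-balanced background tags whose length profile is dominated by
#' 19-24 nt, filling the library to the configured depth. The 3' adapter is
#' appended in full (or truncated to 8 nt for a configurable fraction of
#' tags).
#'
#' @param truth Truth list from [make_reference()].
#' @param config The same `sim_config`.
#' @param reference The full [make_reference()] output (needed for the locus
#'   sequences); if omitted, the reference is rebuilt from `config`.
#' @return List of two data.frames `A` and `B` with columns `read` (insert +
#'   adapter) and `count`, plus `truth_counts`, the per-miRNA realized
#'   mature counts.
#' @export
simulate_libraries <- function(truth, config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth <= 0) stop("depth must be positive")
  if (is.null(reference)) reference <- make_reference(config)
  set.seed(config$seed + 1000L)
  genome <- reference$genome
  mir <- truth$mirnas
  inserts <- character(0)
  mean_a <- numeric(0)
  mean_b <- numeric(0)
  add_tag <- function(seq, ma, mb) {
    inserts <<- c(inserts, seq)
    mean_a <<- c(mean_a, ma)
    mean_b <<- c(mean_b, mb)
  }
  for (i in seq_len(nrow(mir))) {
    mu <- mir$base_mean[i]
    add_tag(mir$sequence[i], mu, mu * 2^mir$log2fc[i])
    if (mir$star_planted[i]) {
      smu <- 0.15 * mu
      add_tag(mir$star_sequence[i], smu, smu * 2^mir$log2fc[i])
    }
  }
  planted_n <- length(inserts)
  # condition-balanced background from structural + decoy loci
  bg <- rbind(
    if (!is.null(truth$structural))
      truth$structural[, c("chrom", "start0", "end", "strand")] else NULL,
    if (!is.null(truth$decoys))
      truth$decoys[, c("chrom", "start0", "end", "strand")] else NULL
  )
  if (!is.null(bg) && nrow(bg) > 0L) {
    remaining <- max(config$depth - sum(mean_a), 0)
    per_locus <- remaining / nrow(bg)
    lens <- c(18L, 19L, 20L, 21L, 22L, 23L, 24L, 25L)
    lprob <- c(0.04, 0.12, 0.18, 0.26, 0.18, 0.12, 0.06, 0.04)
    for (r in seq_len(nrow(bg))) {
      n_tags <- 25L
      w <- stats::rexp(n_tags)
      w <- w / sum(w)
      for (t in seq_len(n_tags)) {
        L <- sample(lens, 1L, prob = lprob)
        lo <- bg$start0[r]
        hi <- bg$end[r] - L
        if (hi <= lo) next
        p0 <- sample(lo:hi, 1L)
        seq <- substr(genome[[bg$chrom[r]]], p0 + 1L, p0 + L)
        if (bg$strand[r] == "-") seq <- revcomp(seq)
        if (grepl("N", seq, fixed = TRUE)) next
        mu <- per_locus * w[t]
        add_tag(seq, mu, mu)
      }
    }
  }
  count_a <- vapply(mean_a, function(m) as.numeric(nb_draw(1L, m, config$dispersion)), numeric(1))
  count_b <- vapply(mean_b, function(m) as.numeric(nb_draw(1L, m, config$dispersion)), numeric(1))
  reads <- paste0(inserts, config$adapter)
  if (config$truncate_adapter_fraction > 0) {
    tr <- stats::runif(length(reads)) < config$truncate_adapter_fraction
    reads[tr] <- paste0(inserts[tr], substr(config$adapter, 1L, 8L))
  }
  lib <- function(counts) {
    keep <- counts > 0
    agg <- tapply(counts[keep], reads[keep], sum)
    df <- data.frame(read = names(agg), count = as.integer(agg),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$read), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  truth_counts <- data.frame(
    name = mir$name, sequence = mir$sequence,
    count_A = count_a[match(mir$sequence, inserts)],
    count_B = count_b[match(mir$sequence, inserts)],
    stringsAsFactors = FALSE)
  list(A = lib(count_a), B = lib(count_b), truth_counts = truth_counts)
}

#' Simulate a degradome 5'-end tag table
#'
#' Each planted target gets a tag-count peak at the transcript position
#' paired to miRNA position 10; uniform 1-count noise is added elsewhere at
#' the configured per-position rate.
#'
#' @param truth Truth list from [make_reference()] (needs >= 1 planted
#'   target).
#' @param config The `sim_config`.
#' @return data.frame: `transcript`, `pos_1based`, `count`.
#' @export
simulate_degradome <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$targets) || nrow(truth$targets) == 0L) {
    stop("truth has no planted targets")
  }
  set.seed(config$seed + 2000L)
  tg <- truth$targets
  L <- tg$site_end1 - tg$site_start1 + 1L
  peaks <- data.frame(
    transcript = tg$transcript,
    pos_1based = cleavage_position(tg$site_start1, L),
    count = rep(config$degradome_peak, nrow(tg)),
    stringsAsFactors = FALSE)
  noise <- NULL
  if (config$degradome_noise > 0) {
    rows <- list()
    for (txn in sprintf("T%03d", seq_len(config$n_transcripts))) {
      hit <- which(stats::runif(config$transcript_length) <
                     config$degradome_noise)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = txn, pos_1based = hit, count = 1L,
          stringsAsFactors = FALSE)
      }
    }
    noise <- do.call(rbind, rows)
  }
  out <- rbind(peaks, noise)
  agg <- stats::aggregate(count ~ transcript + pos_1based, out, sum)
  agg <- agg[order(agg$transcript, agg$pos_1based), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("transcript", "pos_1based", "count")]
}

#' Write the synthetic reference to standard formats
#'
#' Genome and transcriptome as FASTA, annotations as GFF3, reads as
#' collapsed FASTA (`tag<N>-<count>` headers) or FASTQ (constant quality
#' `I`), truth and degradome as TSV.
#'
#' @param reference [make_reference()] output.
#' @param libraries [simulate_libraries()] output (optional).
#' @param degradome [simulate_degradome()] output (optional).
#' @param dir Output directory (created if needed).
#' @param reads_format `"fasta"` or `"fastq"`.
#' @return The directory, invisibly.
#' @export
write_reference <- function(reference, libraries = NULL, degradome = NULL,
                            dir, reads_format = c("fasta", "fastq")) {
  reads_format <- match.arg(reads_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$genome), file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$transcriptome),
    file.path(dir, "transcriptome.fa"))
  if (length(reference$annotations)) {
    rtracklayer::export(reference$annotations,
                        file.path(dir, "annotations.gff3"), format = "gff3")
  }
  utils::write.table(reference$truth$mirnas,
                     file.path(dir, "truth_mirnas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reference$truth$targets)) {
    utils::write.table(reference$truth$targets,
                       file.path(dir, "truth_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(libraries)) {
    for (cond in c("A", "B")) {
      df <- libraries[[cond]]
      if (reads_format == "fasta") {
        xs <- Biostrings::DNAStringSet(df$read)
        names(xs) <- sprintf("tag%06d-%d", seq_len(nrow(df)), df$count)
        Biostrings::writeXStringSet(
          xs, file.path(dir, paste0("reads_", cond, ".fa")))
      } else {
        expanded <- rep(df$read, df$count)
        xs <- Biostrings::DNAStringSet(expanded)
        names(xs) <- sprintf("read%08d", seq_along(expanded))
        Biostrings::writeXStringSet(
          xs, file.path(dir, paste0("reads_", cond, ".fq")),
          format = "fastq",
          qualities = Biostrings::BStringSet(
            vapply(nchar(expanded),
                   function(n) paste(rep("I", n), collapse = ""),
                   character(1))))
      }
    }
  }
  if (!is.null(degradome)) {
    utils::write.table(degradome, file.path(dir, "degradome.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
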