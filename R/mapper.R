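# mapper: perfect-match placement of tags on both genome strands.
#
# Coordinates are 0-based half-open internally; GFF3/BED readers and writers
# do the 1-based conversions. Only exact matches are reported (no mismatch
# mode), mirroring a perfect-match mapping policy, and a tag is counted once
# per tag downstream, not once per locus.

#' Build a genome index for exact substring lookup
#'
#' @param genome A FASTA path, a named character vector, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    nm <- names(genome)
    genome <- Biostrings::DNAStringSet(normalize_seq(genome))
    names(genome) <- nm
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop("all chromosomes must be named")
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names")
  structure(list(seqs = genome, lens = Biostrings::width(genome)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("genome_index:", length(x$seqs), "sequence(s),",
      sum(x$lens), "bp total\n")
  invisible(x)
}

# all exact hits of one pattern on the + strand of every chromosome;
# patterns containing N never match
index_hits <- function(index, pattern) {
  if (!nzchar(pattern) || grepl("N", pattern, fixed = TRUE)) {
    return(data.frame(chrom = character(0), start0 = integer(0),
                      end = integer(0)))
  }
  out <- lapply(seq_along(index$seqs), function(i) {
    m <- Biostrings::matchPattern(pattern, index$seqs[[i]], fixed = TRUE)
    if (length(m) == 0L) return(NULL)
    data.frame(chrom = names(index$seqs)[i],
               start0 = BiocGenerics::start(m) - 1L,
               end = BiocGenerics::end(m))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(0), start0 = integer(0),
                               end = integer(0)) else out
}

#' Locate tags on both strands of the genome
#'
#' Each tag is searched as-is on the + strand and as its reverse complement on
#' the − strand; every perfect-match locus is reported. Tags with no locus are
#' returned separately and are excluded from downstream analysis.
#'
#' @param table Tag table (`sequence`, `count_A`, `count_B`) or a character
#'   vector of sequences.
#' @param index A `genome_index` from [build_index()].
#' @return A list with
#'   * `mapped`: data.frame `sequence`, `chrom`, `start0`, `end`, `strand`,
#'     `n_loci` (one row per locus);
#'   * `unmapped`: character vector of unplaceable tags;
#'   * `stats`: per-library mapped read totals and fractions (when counts are
#'     available).
#' @export
locate <- function(table, index) {
  if (is.character(table)) {
    table <- data.frame(sequence = table, count_A = 1L, count_B = 0L,
                        stringsAsFactors = FALSE)
  }
  all_seqs <- normalize_seq(table$sequence)
  seqs <- unique(all_seqs) # one mapping record per distinct tag
  rc <- revcomp(seqs)
  rows <- vector("list", length(seqs))
  n_loci <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    plus <- index_hits(index, seqs[i])
    minus <- index_hits(index, rc[i])
    n <- nrow(plus) + nrow(minus)
    n_loci[i] <- n
    if (n == 0L) next
    loc <- rbind(
      if (nrow(plus)) cbind(plus, strand = "+") else NULL,
      if (nrow(minus)) cbind(minus, strand = "-") else NULL
    )
    loc$sequence <- seqs[i]
    loc$n_loci <- n
    rows[[i]] <- loc[, c("sequence", "chrom", "start0", "end", "strand", "n_loci")]
  }
  mapped <- do.call(rbind, rows)
  if (is.null(mapped)) {
    mapped <- data.frame(sequence = character(0), chrom = character(0),
                         start0 = integer(0), end = integer(0),
                         strand = character(0), n_loci = integer(0))
  }
  rownames(mapped) <- NULL
  is_mapped <- (n_loci > 0L)[match(all_seqs, seqs)]
  stats <- NULL
  if (all(c("count_A", "count_B") %in% names(table))) {
    tot_a <- sum(table$count_A); tot_b <- sum(table$count_B)
    stats <- data.frame(
      library = c("A", "B"),
      total_reads = c(tot_a, tot_b),
      mapped_reads = c(sum(table$count_A[is_mapped]),
                       sum(table$count_B[is_mapped])),
      stringsAsFactors = FALSE
    )
    stats$mapped_fraction <- ifelse(stats$total_reads > 0,
                                    stats$mapped_reads / stats$total_reads, NA)
  }
  list(mapped = mapped, unmapped = seqs[n_loci == 0L], stats = stats)
}

#' Convert mapped loci to a GRanges
#' @param mapped `mapped` data.frame from [locate()].
#' @return A [GenomicRanges::GRanges] with `sequence` and `n_loci` metadata.
#' @export
mapped_granges <- function(mapped) {
  GenomicRanges::GRanges(
    seqnames = mapped$chrom,
    ranges = IRanges::IRanges(start = mapped$start0 + 1L, end = mapped$end),
    strand = mapped$strand,
    sequence = mapped$sequence,
    n_loci = mapped$n_loci
  )
}
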