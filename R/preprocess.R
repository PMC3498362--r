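# preprocess: adapter trimming, read collapsing, length/composition profiles.
#
# The unit of all downstream analysis is the "tag table": one row per distinct
# trimmed sequence with per-library read counts.

#' Trim a 3' adapter from a single read
#'
#' Finds the leftmost occurrence of the 3' adapter — either the full adapter
#' anywhere in the read, or a prefix of the adapter of at least `min_overlap`
#' bases flush with the read's 3' end — and returns the insert preceding it.
#'
#' @param read Read sequence (DNA/RNA; normalized internally).
#' @param adapter3 3' adapter sequence.
#' @param min_overlap Minimum adapter prefix length accepted at the read end
#'   (default 8).
#' @param min_len,max_len Accepted insert length window (defaults 18 and 30).
#' @return A list with `insert` (the trimmed sequence, or `NA`) and `reason`
#'   (`"ok"`, `"empty"`, `"no_adapter"`, `"too_short"`, `"too_long"`).
#' @export
trim_adapter <- function(read, adapter3, min_overlap = 8L,
                         min_len = 18L, max_len = 30L) {
  adapter3 <- normalize_seq(adapter3)
  if (nchar(adapter3) < min_overlap || min_overlap < 1L) {
    stop("adapter must be at least min_overlap long and min_overlap >= 1")
  }
  read <- normalize_seq(read)
  if (!nzchar(read)) {
    return(list(insert = NA_character_, reason = "empty"))
  }
  cut <- trim_cut_position(read, adapter3, min_overlap)
  if (is.na(cut)) {
    return(list(insert = NA_character_, reason = "no_adapter"))
  }
  insert <- substr(read, 1L, cut - 1L)
  n <- nchar(insert)
  if (n < min_len) return(list(insert = NA_character_, reason = "too_short"))
  if (n > max_len) return(list(insert = NA_character_, reason = "too_long"))
  list(insert = insert, reason = "ok")
}

# 1-based position where the adapter match starts, or NA.
# Leftmost full occurrence wins; otherwise the longest (= leftmost-cut)
# adapter-prefix suffix of at least min_overlap bases.
trim_cut_position <- function(read, adapter3, min_overlap) {
  n <- nchar(read)
  la <- nchar(adapter3)
  full <- regexpr(adapter3, read, fixed = TRUE)
  best <- if (full > 0L) as.integer(full) else NA_integer_
  # partial adapter at the 3' end, only relevant left of any full match
  max_ov <- min(la - 1L, n)
  ov <- max_ov
  while (ov >= min_overlap) {
    p <- n - ov + 1L
    if (!is.na(best) && p >= best) break
    if (substr(read, p, n) == substr(adapter3, 1L, ov)) {
      best <- p
      break
    }
    ov <- ov - 1L
  }
  best
}

#' Trim a vector of reads
#'
#' Vectorized wrapper around [trim_adapter()] that also drops reads containing
#' the 5' adapter (two-adapter ligation artifacts) when one is supplied.
#'
#' @inheritParams trim_adapter
#' @param reads Character vector of raw reads.
#' @param counts Optional integer multiplicities (collapsed input); default 1.
#' @param adapter5 Optional 5' adapter; reads containing it are rejected with
#'   reason `"adapter5"`.
#' @return A list with `inserts` (character), `counts` (integer) for accepted
#'   reads and `rejected`, a named integer vector of read counts per rejection
#'   reason.
#' @export
trim_reads <- function(reads, adapter3, counts = NULL, adapter5 = NULL,
                       min_overlap = 8L, min_len = 18L, max_len = 30L) {
  if (is.null(counts)) counts <- rep(1L, length(reads))
  stopifnot(length(counts) == length(reads))
  reads <- normalize_seq(reads)
  keep_seq <- character(0)
  keep_n <- integer(0)
  rejected <- c(empty = 0L, no_adapter = 0L, too_short = 0L,
                too_long = 0L, adapter5 = 0L)
  for (i in seq_along(reads)) {
    if (!is.null(adapter5) &&
        grepl(normalize_seq(adapter5), reads[i], fixed = TRUE)) {
      rejected[["adapter5"]] <- rejected[["adapter5"]] + counts[i]
      next
    }
    tr <- trim_adapter(reads[i], adapter3, min_overlap, min_len, max_len)
    if (tr$reason == "ok") {
      keep_seq <- c(keep_seq, tr$insert)
      keep_n <- c(keep_n, counts[i])
    } else {
      rejected[[tr$reason]] <- rejected[[tr$reason]] + counts[i]
    }
  }
  list(inserts = keep_seq, counts = as.integer(keep_n), rejected = rejected)
}

#' Collapse trimmed inserts from two libraries into a tag table
#'
#' One row per distinct sequence with per-library multiplicities. Rows are
#' ordered by descending combined count, ties broken lexicographically, so the
#' table is deterministic.
#'
#' @param inserts_a,inserts_b Character vectors of trimmed inserts.
#' @param counts_a,counts_b Optional multiplicities (default 1 each).
#' @return A `data.frame` with columns `sequence`, `count_A`, `count_B`.
#' @export
collapse_reads <- function(inserts_a, inserts_b = character(0),
                           counts_a = NULL, counts_b = NULL) {
  tally <- function(s, n) {
    if (is.null(n)) n <- rep(1L, length(s))
    if (length(s) == 0L) return(integer(0))
    tapply(as.integer(n), s, sum)
  }
  ta <- tally(inserts_a, counts_a)
  tb <- tally(inserts_b, counts_b)
  seqs <- sort(unique(c(names(ta), names(tb))))
  tab <- data.frame(
    sequence = seqs,
    count_A = as.integer(ifelse(seqs %in% names(ta), ta[seqs], 0L)),
    count_B = as.integer(ifelse(seqs %in% names(tb), tb[seqs], 0L)),
    stringsAsFactors = FALSE
  )
  ord <- order(-(tab$count_A + tab$count_B), tab$sequence)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-length profile of a tag table
#'
#' Histograms of unique tags and total reads by insert length, per library,
#' plus the fraction of total reads inside a stated length window (the
#' "19-24 nt" style headline number).
#'
#' @param table Tag table from [collapse_reads()].
#' @param lengths Integer lengths to tabulate (default 15:35).
#' @param window Two-element window of lengths for the read fraction
#'   (default `c(19, 24)`).
#' @return A list with `profile` (data.frame: `length`, `unique_A`, `total_A`,
#'   `unique_B`, `total_B`) and `window_fraction` (named numeric: `A`, `B`,
#'   `combined`; proportions in `[0,1]`).
#' @export
length_profile <- function(table, lengths = 15:35, window = c(19L, 24L)) {
  if (nrow(table) == 0L) stop("empty_library")
  L <- nchar(table$sequence)
  prof <- data.frame(
    length = lengths,
    unique_A = vapply(lengths, function(l) sum(L == l & table$count_A > 0L), integer(1)),
    total_A = vapply(lengths, function(l) sum(table$count_A[L == l]), integer(1)),
    unique_B = vapply(lengths, function(l) sum(L == l & table$count_B > 0L), integer(1)),
    total_B = vapply(lengths, function(l) sum(table$count_B[L == l]), integer(1))
  )
  inw <- L >= window[1] & L <= window[2]
  frac <- function(cnt) if (sum(cnt) == 0L) NA_real_ else sum(cnt[inw]) / sum(cnt)
  list(
    profile = prof,
    window_fraction = c(
      A = frac(table$count_A),
      B = frac(table$count_B),
      combined = frac(table$count_A + table$count_B)
    )
  )
}

#' Read small-RNA reads from FASTA/FASTQ
#'
#' FASTQ qualities are ignored. FASTA headers of the form `name-<count>` (or a
#' bare integer count) are interpreted as collapsed multiplicities.
#'
#' @param path File path.
#' @param format `"fasta"` or `"fastq"` (guessed from the extension when
#'   missing).
#' @return List with `reads` (character) and `counts` (integer).
#' @export
read_small_rna <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  xs <- Biostrings::readDNAStringSet(path, format = format)
  reads <- as.character(xs)
  ids <- names(xs) %||% rep("", length(xs))
  counts <- rep(1L, length(reads))
  if (format == "fasta") {
    m <- regmatches(ids, regexpr("-([0-9]+)$", ids))
    has <- lengths(regmatches(ids, gregexpr("-([0-9]+)$", ids))) > 0
    counts[has] <- as.integer(sub("^-", "", m))
  }
  list(reads = unname(reads), counts = counts)
}

#' Write a tag table as TSV
#' @param table Tag table.
#' @param path Output path.
#' @export
write_tag_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
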