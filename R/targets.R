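# targets: complementarity-based target prediction and degradome (PARE)
# cleavage validation.
#
# The duplex model is ungapped and antiparallel: the miRNA 5'->3' is scored
# against the target site read 3'->5'. Watson-Crick pairs cost 0, G:U wobble
# 0.5, anything else 1 (the usual plant target-prediction convention); a
# strict mode counts wobbles as full mismatches. Sites at or below the
# penalty threshold (default 3, "three mismatches or less") are reported.

penalty_tables <- function(gu_half = TRUE) {
  # rows: miRNA base, cols: target base (both DNA codes A,C,G,T)
  P <- matrix(1, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  P["A", "T"] <- 0; P["T", "A"] <- 0
  P["C", "G"] <- 0; P["G", "C"] <- 0
  w <- if (gu_half) 0.5 else 1
  P["G", "T"] <- w # miRNA G opposite target U
  P["T", "G"] <- w # miRNA U opposite target G
  P
}

#' Score an ungapped miRNA/target-site duplex
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site Target site, transcript sense 5'->3', same length.
#' @param gu_half Score G:U wobble 0.5 (default) or as a full mismatch.
#' @return List: `penalty` and `status`, a string over `|` (match), `o`
#'   (wobble), `x` (mismatch), ordered along the miRNA.
#' @export
duplex_penalty <- function(mirna, site, gu_half = TRUE) {
  m <- strsplit(normalize_seq(mirna, allow_n = FALSE), "")[[1]]
  s <- strsplit(normalize_seq(site, allow_n = FALSE), "")[[1]]
  if (length(m) != length(s)) stop("miRNA and site lengths differ")
  P <- penalty_tables(gu_half)
  opp <- rev(s) # antiparallel: miRNA position j faces site position L+1-j
  pen <- P[cbind(m, opp)]
  status <- ifelse(pen == 0, "|", ifelse(pen < 1, "o", "x"))
  list(penalty = sum(pen), status = paste(status, collapse = ""))
}

#' Scan a transcriptome for candidate target sites
#'
#' Every window of miRNA length on every transcript is scored; windows with
#' penalty <= `threshold` are reported, sorted by penalty then coordinates.
#' Transcripts shorter than the miRNA are skipped with a notice.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcripts Named character vector, a
#'   [Biostrings::DNAStringSet], or a FASTA path (mRNA sense orientation).
#' @param threshold Max penalty (default 3).
#' @param gu_half See [duplex_penalty()].
#' @return data.frame: `transcript`, `start1`, `end1` (1-based inclusive),
#'   `penalty`, `status`.
#' @export
scan_targets <- function(mirna, transcripts, threshold = 3, gu_half = TRUE) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  }
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- setNames(as.character(transcripts),
                            sub("\\s.*$", "", names(transcripts)))
  }
  m <- strsplit(normalize_seq(mirna, allow_n = FALSE), "")[[1]]
  L <- length(m)
  P <- penalty_tables(gu_half)
  rows <- list()
  for (tx in names(transcripts)) {
    s <- strsplit(normalize_seq(transcripts[[tx]]), "")[[1]]
    n <- length(s)
    if (n < L) {
      message("transcript ", tx, " shorter than miRNA; skipped")
      next
    }
    nw <- n - L + 1L
    pen <- numeric(nw)
    for (j in seq_len(L)) {
      # miRNA position j faces site position (L + 1 - j) within each window
      cost <- P[m[j], ]
      cost[is.na(cost)] <- 1 # N in the transcript counts as a mismatch
      idx <- match(s[(L - j + 1L):(n - j + 1L)], c("A", "C", "G", "T"))
      add <- cost[idx]
      add[is.na(add)] <- 1
      pen <- pen + add
    }
    hit <- which(pen <= threshold)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript = tx, start1 = hit, end1 = hit + L - 1L,
        penalty = pen[hit], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(transcript = character(0), start1 = integer(0),
                      end1 = integer(0), penalty = numeric(0),
                      status = character(0)))
  }
  out <- out[order(out$penalty, out$transcript, out$start1), , drop = FALSE]
  out$status <- vapply(seq_len(nrow(out)), function(i) {
    duplex_penalty(mirna, substr(transcripts[[out$transcript[i]]],
                                 out$start1[i], out$end1[i]),
                   gu_half)$status
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Expected slicer cleavage position for a target site
#'
#' Cleavage occurs opposite miRNA positions 10-11; the reported coordinate is
#' the transcript position paired to miRNA position 10 (from the miRNA 5'
#' end): for a site spanning `[t1, t1 + L - 1]` that is `t1 + L - 10`.
#'
#' @param start1 Site start (1-based) on the transcript.
#' @param mirna_len Site/miRNA length (>= 10).
#' @return Transcript coordinate (1-based). Vectorized.
#' @export
cleavage_position <- function(start1, mirna_len) {
  if (any(mirna_len < 10L)) stop("miRNA shorter than 10 nt")
  start1 + mirna_len - 10L
}

#' Read a degradome 5'-end tag table
#'
#' @param path 3-column TSV: `transcript`, `pos_1based`, `count` (header
#'   optional).
#' @return data.frame with those columns.
#' @export
read_degradome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("transcript", "pos_1based", "count") %in% names(df))) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("transcript", "pos_1based", "count"))
  }
  df
}

#' Degradome evidence for a predicted target site
#'
#' Sums degradome tag counts within `window` of the expected cleavage
#' position and assigns an abundance category relative to the rest of the
#' transcript (the 5-level convention of degradome-validation tools):
#' category 0 — evidence is the unique maximum on the transcript; 1 — tied
#' maximum; 2 — above the median of nonzero positions; 3 — nonzero
#' otherwise; 4 — a single read; `"none"` — no evidence (or unknown
#' transcript).
#'
#' @param site One-row data.frame (or list) with `transcript`, `start1`,
#'   `end1`.
#' @param degradome Degradome tag table (`transcript`, `pos_1based`,
#'   `count`).
#' @param window Positional tolerance around the cleavage site (default 1,
#'   i.e. +/- 1 nt).
#' @return List: `cleavage_pos`, `evidence_count`, `max_count`, `category`.
#' @export
degradome_support <- function(site, degradome, window = 1L) {
  L <- site$end1 - site$start1 + 1L
  cpos <- cleavage_position(site$start1, L)
  tags <- degradome[degradome$transcript == site$transcript, , drop = FALSE]
  if (nrow(tags) == 0L) {
    return(list(cleavage_pos = cpos, evidence_count = 0L, max_count = 0L,
                category = "none"))
  }
  inw <- abs(tags$pos_1based - cpos) <= window
  ev <- sum(tags$count[inw])
  outside <- tags$count[!inw]
  maxout <- if (length(outside)) max(outside) else 0L
  category <- if (ev == 0L) {
    "none"
  } else if (ev == 1L) {
    "4"
  } else if (ev > maxout) {
    "0"
  } else if (ev == maxout) {
    "1"
  } else {
    med <- stats::median(tags$count[tags$count > 0L])
    if (ev > med) "2" else "3"
  }
  list(cleavage_pos = cpos, evidence_count = as.integer(ev),
       max_count = as.integer(max(tags$count)), category = category)
}

#' Predict and validate targets for a set of miRNAs
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Transcriptome (see [scan_targets()]).
#' @param degradome Optional degradome tag table; without it the degradome
#'   columns are `NA`.
#' @param threshold,gu_half,window Passed through.
#' @return data.frame: `mirna`, `transcript`, `start1`, `end1`, `penalty`,
#'   `cleavage_pos`, `evidence_count`, `category`.
#' @export
predict_targets <- function(mirnas, transcripts, degradome = NULL,
                            threshold = 3, gu_half = TRUE, window = 1L) {
  rows <- list()
  for (nm in names(mirnas)) {
    sites <- scan_targets(mirnas[[nm]], transcripts, threshold, gu_half)
    if (nrow(sites) == 0L) next
    sites$mirna <- nm
    L <- sites$end1 - sites$start1 + 1L
    sites$cleavage_pos <- cleavage_position(sites$start1, L)
    if (is.null(degradome)) {
      sites$evidence_count <- NA_integer_
      sites$category <- NA_character_
    } else {
      sup <- lapply(seq_len(nrow(sites)), function(i) {
        degradome_support(sites[i, ], degradome, window)
      })
      sites$evidence_count <- vapply(sup, `[[`, integer(1), "evidence_count")
      sites$category <- vapply(sup, `[[`, character(1), "category")
    }
    rows[[length(rows) + 1L]] <- sites
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      start1 = integer(0), end1 = integer(0),
                      penalty = numeric(0), cleavage_pos = integer(0),
                      evidence_count = integer(0), category = character(0)))
  }
  rownames(out) <- NULL
  out[, c("mirna", "transcript", "start1", "end1", "penalty", "cleavage_pos",
          "evidence_count", "category")]
}
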