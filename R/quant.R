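# quant: member-resolved known-miRNA quantification, RPM normalization,
# log2 fold change and response classification.
#
# Deep sequencing distinguishes family members differing by a single
# nucleotide, so quantification is by exact full-length sequence identity;
# members sharing an identical mature sequence are merged into one group
# (miR169d-g style).

#' Read a miRBase-style mature miRNA FASTA
#'
#' @param path FASTA path; headers are member names.
#' @return Named character vector of mature sequences (DNA alphabet).
#' @export
read_mature_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(xs))
  setNames(normalize_seq(as.character(xs)), nm)
}

# miR169d,miR169e,miR169f,miR169g -> "miR169d-g"; otherwise join with "/"
compress_member_names <- function(nms) {
  if (length(nms) == 1L) return(nms)
  nms <- sort(nms)
  m <- regmatches(nms, regexec("^(.*[0-9])([a-z])$", nms))
  if (all(lengths(m) == 3L)) {
    stem <- vapply(m, `[`, character(1), 2L)
    letters_ <- vapply(m, `[`, character(1), 3L)
    idx <- match(letters_, letters)
    if (length(unique(stem)) == 1L && all(diff(idx) == 1L)) {
      return(paste0(stem[1L], letters_[1L], "-", letters_[length(letters_)]))
    }
  }
  paste(nms, collapse = "/")
}

#' Match tags against known mature miRNAs
#'
#' A tag contributes to a member iff the tag sequence equals the mature
#' sequence exactly, full length. Members with identical mature sequences are
#' merged into one member group named by range compression (`miR169d-g`) or
#' concatenation. Members with no matching tag get zero-count records.
#'
#' @param table Tag table.
#' @param mature Named character vector (see [read_mature_fasta()]) or a
#'   FASTA path.
#' @return data.frame: `id`, `members`, `sequence`, `count_A`, `count_B`.
#' @export
match_known <- function(table, mature) {
  if (is.character(mature) && length(mature) == 1L && file.exists(mature)) {
    mature <- read_mature_fasta(mature)
  }
  if (anyDuplicated(names(mature))) stop("duplicate member names")
  mature <- setNames(normalize_seq(mature), names(mature))
  groups <- split(names(mature), unname(mature))
  seqs <- names(groups)
  ids <- vapply(groups, compress_member_names, character(1))
  hit <- match(seqs, table$sequence)
  out <- data.frame(
    id = ids,
    members = vapply(groups, function(g) paste(sort(g), collapse = ","), character(1)),
    sequence = seqs,
    count_A = ifelse(is.na(hit), 0L, table$count_A[hit]),
    count_B = ifelse(is.na(hit), 0L, table$count_B[hit]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads-per-million normalization
#'
#' @param records data.frame with `count_A`, `count_B`.
#' @param totals Numeric `c(A = , B = )` library totals (clean or mapped reads
#'   per library).
#' @return `records` with `rpm_A`, `rpm_B` added (2 decimals).
#' @export
rpm_normalize <- function(records, totals) {
  if (any(totals <= 0)) stop("library totals must be positive")
  records$rpm_A <- round_half_away(records$count_A / totals[["A"]] * 1e6, 2L)
  records$rpm_B <- round_half_away(records$count_B / totals[["B"]] * 1e6, 2L)
  records
}

#' Log2 fold change between two libraries (B over A)
#'
#' Raw mode takes the ratio of raw counts; rpm mode normalizes by library
#' totals first. If either count is zero, 1 is added to both raw counts
#' before forming the ratio, keeping the fold change finite while leaving
#' nonzero pairs untouched. Vectorized.
#'
#' @param count_a,count_b Non-negative counts.
#' @param mode `"raw"` or `"rpm"`.
#' @param totals Library totals, required for rpm mode.
#' @param digits Decimal places (half away from zero); `NULL` for unrounded.
#' @return Numeric vector of log2 fold changes; `NA` where both counts are
#'   zero (no signal).
#' @export
log2_fold_change <- function(count_a, count_b, mode = c("raw", "rpm"),
                             totals = NULL, digits = 1L) {
  mode <- match.arg(mode)
  a <- as.numeric(count_a)
  b <- as.numeric(count_b)
  none <- a == 0 & b == 0
  zero <- (a == 0 | b == 0) & !none
  a[zero] <- a[zero] + 1
  b[zero] <- b[zero] + 1
  if (mode == "rpm") {
    if (is.null(totals)) stop("rpm mode needs library totals")
    a <- a / totals[["A"]]
    b <- b / totals[["B"]]
  }
  lfc <- log2(b / a)
  lfc[none] <- NA_real_
  if (!is.null(digits)) lfc <- round_half_away(lfc, digits)
  lfc
}

#' Classify a fold change into response classes
#'
#' Induced (`NSI`) iff log2fc strictly exceeds `log2(ratio_threshold)`,
#' suppressed (`NSS`) iff strictly below the negative of it, else
#' `unchanged`. The strict inequalities implement a "greater than x-fold"
#' rule.
#'
#' @param log2fc Numeric vector (use unrounded values for classification).
#' @param ratio_threshold Fold-ratio threshold, > 1 (default 3 for known
#'   miRNAs; 2 is the usual novel-candidate rule).
#' @return Character vector in `{NSS, NSI, unchanged}`; `NA` in, `NA` out.
#' @export
classify_response <- function(log2fc, ratio_threshold = 3) {
  if (ratio_threshold <= 1) stop("ratio_threshold must exceed 1")
  cut <- log2(ratio_threshold)
  ifelse(is.na(log2fc), NA_character_,
         ifelse(log2fc > cut, "NSI",
                ifelse(log2fc < -cut, "NSS", "unchanged")))
}

#' Full known-miRNA expression table
#'
#' Matching, RPM normalization, fold change and response classification in
#' one step. Records with combined raw count below `min_count` are flagged
#' `low_count` and excluded from response calls (their response is `NA`).
#'
#' @inheritParams match_known
#' @param totals Library totals for RPM.
#' @param ratio_threshold Response threshold (default 3-fold).
#' @param min_count Minimum combined evidence for a response call (default 5).
#' @param fc_mode `"raw"` (default) or `"rpm"` fold-change mode.
#' @return data.frame with counts, rpm, `log2fc` (1 decimal), `low_count`,
#'   `response`.
#' @export
quantify_known <- function(table, mature, totals, ratio_threshold = 3,
                           min_count = 5L, fc_mode = "raw") {
  rec <- match_known(table, mature)
  rec <- rpm_normalize(rec, totals)
  raw <- log2_fold_change(rec$count_A, rec$count_B, mode = fc_mode,
                          totals = totals, digits = NULL)
  rec$log2fc <- round_half_away(raw, 1L)
  rec$low_count <- rec$count_A + rec$count_B < min_count
  rec$response <- ifelse(rec$low_count, NA_character_,
                         classify_response(raw, ratio_threshold))
  rec
}

#' Aggregate member counts into family counts
#'
#' @param records data.frame with `id`, `count_A`, `count_B`.
#' @param family Optional named vector mapping member/group id to family; by
#'   default the family is the id stripped of everything after the trailing
#'   number (`miR169d-g` -> `miR169`).
#' @return data.frame: `family`, `count_A`, `count_B`.
#' @export
family_aggregate <- function(records, family = NULL) {
  if (is.null(family)) {
    fam <- sub("^((ath-)?miR[0-9]+).*$", "\\1", records$id)
    bad <- fam == records$id & !grepl("^(ath-)?miR[0-9]+$", records$id)
    if (any(bad)) {
      stop("cannot infer family for: ", paste(records$id[bad], collapse = ", "))
    }
  } else {
    fam <- unname(family[records$id])
    if (anyNA(fam)) {
      stop("member(s) missing from family map: ",
           paste(records$id[is.na(fam)], collapse = ", "))
    }
  }
  out <- data.frame(
    family = sort(unique(fam)),
    count_A = as.integer(tapply(records$count_A, fam, sum)[sort(unique(fam))]),
    count_B = as.integer(tapply(records$count_B, fam, sum)[sort(unique(fam))]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
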