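# annotate: partition mapped tags into structural-RNA classes, produce
# composition summaries and between-library overlap statistics.

STRUCTURAL_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Read annotation intervals from GFF3
#'
#' The GFF3 `type` column carries the RNA class (`rRNA`, `tRNA`, `snRNA`,
#' `snoRNA`, `mRNA`, ...).
#'
#' @param path GFF3 file path.
#' @return A [GenomicRanges::GRanges] with a `type` metadata column.
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(gr$type)) stop("annotation file has no type column")
  gr$type <- as.character(gr$type)
  gr
}

#' Classify mapped tags into structural-RNA classes
#'
#' A tag is assigned class C if any of its loci overlaps (>= 1 bp) an
#' annotation record of class C. Overlap is strand-aware by default. When
#' several structural classes match, the fixed precedence
#' rRNA > tRNA > snRNA > snoRNA decides; tags matching none are `"other"`.
#' The precedence (not annotation order) resolves ties, so classification is
#' invariant under permutation of the annotation records.
#'
#' @param mapped `mapped` data.frame from [locate()].
#' @param annotations A `GRanges` with a `type` column (see
#'   [read_annotations()]).
#' @param strand_aware Require same-strand overlap (default `TRUE`).
#' @return Named character vector: class per distinct tag sequence.
#' @export
classify_tags <- function(mapped, annotations, strand_aware = TRUE) {
  seqs <- unique(mapped$sequence)
  cls <- setNames(rep("other", length(seqs)), seqs)
  ann <- annotations[annotations$type %in% STRUCTURAL_CLASSES]
  if (length(ann) == 0L || nrow(mapped) == 0L) return(cls)
  gr <- mapped_granges(mapped)
  hits <- GenomicRanges::findOverlaps(gr, ann, minoverlap = 1L,
                                      ignore.strand = !strand_aware)
  if (length(hits) == 0L) return(cls)
  tag_of_hit <- gr$sequence[S4Vectors::queryHits(hits)]
  class_of_hit <- ann$type[S4Vectors::subjectHits(hits)]
  rank <- match(class_of_hit, STRUCTURAL_CLASSES)
  best <- tapply(rank, tag_of_hit, min)
  cls[names(best)] <- STRUCTURAL_CLASSES[best]
  cls
}

#' Composition summary over RNA classes
#'
#' Per class and per library: unique-tag count, unique percentage, total-read
#' count, total percentage, plus a totals row. Percentages are printed in the
#' mixed dialect of deep-sequencing summary tables: two decimals below 10%,
#' one decimal at or above. The totals row equals the column sums exactly (no
#' rounding enters the counts).
#'
#' Two input forms are accepted: a tag table plus a class assignment from
#' [classify_tags()], or a pre-aggregated data.frame of per-class counts with
#' columns `class`, `unique_A`, `total_A`, `unique_B`, `total_B` (useful for
#' auditing a published table's arithmetic).
#'
#' @param x Tag table (`sequence`, `count_A`, `count_B`) or pre-aggregated
#'   class counts.
#' @param classes Named class vector (required for the tag-table form).
#' @param class_order Row order of the summary.
#' @return data.frame with one row per class plus a `total` row; columns
#'   `class`, `unique_A`, `unique_pct_A`, `total_A`, `total_pct_A` and the
#'   same for library B.
#' @export
class_summary <- function(x, classes = NULL,
                          class_order = c(STRUCTURAL_CLASSES, "other")) {
  if (is.null(classes)) {
    need <- c("class", "unique_A", "total_A", "unique_B", "total_B")
    if (!all(need %in% names(x))) {
      stop("pre-aggregated input needs columns: ", paste(need, collapse = ", "))
    }
    agg <- x[, need]
  } else {
    if (sum(x$count_A) + sum(x$count_B) == 0L) stop("empty_library")
    cl <- unname(classes[x$sequence])
    cl[is.na(cl)] <- "other"
    agg <- data.frame(
      class = class_order,
      unique_A = vapply(class_order, function(k) sum(cl == k & x$count_A > 0L), integer(1)),
      total_A = vapply(class_order, function(k) sum(x$count_A[cl == k]), integer(1)),
      unique_B = vapply(class_order, function(k) sum(cl == k & x$count_B > 0L), integer(1)),
      total_B = vapply(class_order, function(k) sum(x$count_B[cl == k]), integer(1)),
      stringsAsFactors = FALSE
    )
  }
  agg <- agg[order(match(agg$class, class_order)), , drop = FALSE]
  tot <- vapply(c("unique_A", "total_A", "unique_B", "total_B"),
                function(k) sum(as.numeric(agg[[k]])), numeric(1))
  if (any(tot[c("total_A", "total_B")] == 0)) stop("empty_library")
  out <- data.frame(
    class = c(agg$class, "total"),
    unique_A = c(agg$unique_A, tot[["unique_A"]]),
    unique_pct_A = c(format_pct(100 * agg$unique_A / tot[["unique_A"]]), 100),
    total_A = c(agg$total_A, tot[["total_A"]]),
    total_pct_A = c(format_pct(100 * agg$total_A / tot[["total_A"]]), 100),
    unique_B = c(agg$unique_B, tot[["unique_B"]]),
    unique_pct_B = c(format_pct(100 * agg$unique_B / tot[["unique_B"]]), 100),
    total_B = c(agg$total_B, tot[["total_B"]]),
    total_pct_B = c(format_pct(100 * agg$total_B / tot[["total_B"]]), 100),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Between-library overlap of tag sets
#'
#' A sequence is common iff it has reads in both libraries. Unique percentages
#' are over distinct sequences; total percentages are over combined read
#' counts (a common sequence contributes its counts from both libraries).
#'
#' @param table Tag table.
#' @return data.frame: `category` (`A_specific`, `B_specific`, `common`),
#'   `unique_pct`, `total_pct` (rounded to 2 decimals).
#' @export
library_overlap <- function(table) {
  in_a <- table$count_A > 0L
  in_b <- table$count_B > 0L
  n <- nrow(table)
  reads <- as.numeric(table$count_A + table$count_B)
  tot_reads <- sum(reads)
  cat_of <- ifelse(in_a & in_b, "common",
                   ifelse(in_a, "A_specific", "B_specific"))
  cats <- c("A_specific", "B_specific", "common")
  data.frame(
    category = cats,
    unique_pct = round_half_away(
      100 * vapply(cats, function(k) sum(cat_of == k), numeric(1)) / n, 2L),
    total_pct = round_half_away(
      100 * vapply(cats, function(k) sum(reads[cat_of == k]), numeric(1)) / tot_reads, 2L),
    stringsAsFactors = FALSE
  )
}
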