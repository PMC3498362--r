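# discover: novel miRNA candidates from unannotated mapped tags via locus
# clustering, precursor excision, structure prediction, hairpin criteria and
# miRNA* support.

#' Cluster candidate tag loci
#'
#' Only tags classified `"other"`, not identical to a known mature miRNA,
#' with combined count >= `min_count`, mature-like length, and at most
#' `max_nloci` genomic placements enter. Loci are merged per chromosome and
#' strand by single linkage within `merge_distance`. The cluster
#' representative (the mature candidate) is the highest-count tag, ties
#' broken lexicographically.
#'
#' @param mapped `mapped` data.frame from [locate()].
#' @param classes Named class vector from [classify_tags()].
#' @param table Tag table carrying the counts.
#' @param known_matures Character vector of known mature sequences to exclude.
#' @param merge_distance Max gap between loci merged into one cluster
#'   (default 30).
#' @param min_count Minimum combined read count (default 5).
#' @param max_nloci Multi-mapping cap for candidates (default 5).
#' @param mature_lengths Accepted mature lengths (default 20:24).
#' @return data.frame of clusters: `cluster_id`, `chrom`, `strand`, `start0`,
#'   `end` (merged span), `rep_sequence`, `rep_start0`, `rep_end`,
#'   `count_A`, `count_B` (representative tag counts), `n_tags`.
#' @export
cluster_loci <- function(mapped, classes, table, known_matures = character(0),
                         merge_distance = 30L, min_count = 5L, max_nloci = 5L,
                         mature_lengths = 20:24) {
  known_matures <- if (length(known_matures)) normalize_seq(known_matures) else character(0)
  cnt <- setNames(table$count_A + table$count_B, table$sequence)
  ca <- setNames(table$count_A, table$sequence)
  cb <- setNames(table$count_B, table$sequence)
  keep <- mapped[
    unname(classes[mapped$sequence]) == "other" &
      !(mapped$sequence %in% known_matures) &
      unname(cnt[mapped$sequence]) >= min_count &
      mapped$n_loci <= max_nloci &
      nchar(mapped$sequence) %in% mature_lengths, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      strand = character(0), start0 = integer(0),
                      end = integer(0), rep_sequence = character(0),
                      rep_start0 = integer(0), rep_end = integer(0),
                      count_A = integer(0), count_B = integer(0),
                      n_tags = integer(0)))
  }
  out <- list()
  for (key in unique(paste(keep$chrom, keep$strand))) {
    sub <- keep[paste(keep$chrom, keep$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start0, sub$end), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L
    grp[1L] <- g
    max_end <- sub$end[1L]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$start0[i] - max_end > merge_distance) g <- g + 1L
      grp[i] <- g
      max_end <- max(max_end, sub$end[i])
    }
    for (gi in unique(grp)) {
      cl <- sub[grp == gi, , drop = FALSE]
      comb <- unname(cnt[cl$sequence])
      rep_i <- order(-comb, cl$sequence)[1L]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cl$chrom[1L], strand = cl$strand[1L],
        start0 = min(cl$start0), end = max(cl$end),
        rep_sequence = cl$sequence[rep_i],
        rep_start0 = cl$start0[rep_i], rep_end = cl$end[rep_i],
        count_A = unname(ca[cl$sequence[rep_i]]),
        count_B = unname(cb[cl$sequence[rep_i]]),
        n_tags = length(unique(cl$sequence)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start0, out$strand), , drop = FALSE]
  out$cluster_id <- sprintf("cl%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cluster_id", "chrom", "strand", "start0", "end", "rep_sequence",
          "rep_start0", "rep_end", "count_A", "count_B", "n_tags")]
}

#' Excise candidate precursor windows around a cluster
#'
#' Two windows per cluster — long flank 5' / short flank 3' and the mirror —
#' so the mature can sit on either arm of the hairpin. Windows are clipped at
#' chromosome edges; minus-strand windows are reverse-complemented so the
#' mature reads 5'->3' within the returned precursor.
#'
#' @param cluster One row of the [cluster_loci()] output (uses the
#'   representative tag locus).
#' @param index `genome_index`.
#' @param long_flank,short_flank Flank sizes in nt (defaults 150 and 20).
#' @return List of two precursor records: `seq`, `chrom`, `start0`, `end`,
#'   `strand`, `mature_offset0` (0-based offset of the mature within `seq`),
#'   `mature_len`.
#' @export
extract_precursors <- function(cluster, index, long_flank = 150L,
                               short_flank = 20L) {
  if (long_flank <= 0L || short_flank <= 0L) stop("flanks must be positive")
  chrom <- cluster$chrom
  clen <- index$lens[match(chrom, names(index$seqs))]
  if (is.na(clen)) stop("unknown chromosome: ", chrom)
  s0 <- cluster$rep_start0
  e <- cluster$rep_end
  windows <- list(c(s0 - long_flank, e + short_flank),
                  c(s0 - short_flank, e + long_flank))
  lapply(windows, function(w) {
    ws <- max(0L, w[1L])
    we <- min(clen, w[2L])
    if (ws > s0 || we < e) stop("window fully clipped at contig edge")
    seq <- as.character(Biostrings::subseq(index$seqs[[chrom]], ws + 1L, we))
    if (cluster$strand == "-") {
      seq <- revcomp(seq)
      off <- we - e
    } else {
      off <- s0 - ws
    }
    list(seq = seq, chrom = chrom, start0 = ws, end = we,
         strand = cluster$strand, mature_offset0 = as.integer(off),
         mature_len = e - s0)
  })
}

#' Evaluate hairpin annotation criteria for a mature within a precursor
#'
#' Implements the structural side of community plant-miRNA annotation
#' criteria: the mature must lie in one arm of a stem-loop (all its pairing
#' partners on the opposite side of the terminal loop, no mature base inside
#' that loop), with at most `max_unpaired` unpaired mature bases and no
#' bulge/internal-loop run longer than `max_bulge` inside the mature-spanning
#' duplex.
#'
#' @param precursor Precursor sequence.
#' @param structure Dot-bracket string from [fold_rna()] (or a plugged-in
#'   folder) for `precursor`.
#' @param mature_offset0 0-based offset of the mature in the precursor.
#' @param mature_len Mature length.
#' @param max_unpaired Max unpaired mature bases (default 4).
#' @param max_bulge Max consecutive unpaired run inside the duplex
#'   (default 2).
#' @return List of flags and measures: `in_one_arm`, `outside_loop`,
#'   `unpaired_mature`, `max_bulge_run`, `pass`, plus `partner`, the partner
#'   vector used.
#' @export
evaluate_hairpin <- function(precursor, structure, mature_offset0, mature_len,
                             max_unpaired = 4L, max_bulge = 2L) {
  n <- nchar(precursor)
  if (nchar(structure) != n) stop("structure length != precursor length")
  if (mature_offset0 < 0L || mature_offset0 + mature_len > n) {
    stop("mature interval outside precursor")
  }
  partner <- parse_dot_bracket(structure)
  pos <- (mature_offset0 + 1L):(mature_offset0 + mature_len)
  prt <- partner[pos]
  paired <- pos[prt > 0L]
  res <- list(in_one_arm = FALSE, outside_loop = FALSE,
              unpaired_mature = sum(prt == 0L), max_bulge_run = NA_integer_,
              pass = FALSE, partner = partner)
  if (length(paired) == 0L) return(res)
  prts <- partner[paired]
  three_prime_star <- all(prts > max(pos))
  five_prime_star <- all(prts < min(pos))
  res$in_one_arm <- three_prime_star || five_prime_star
  if (!res$in_one_arm) return(res)
  # terminal loop enclosed by the innermost pair of the mature's stem
  if (three_prime_star) {
    inner <- max(paired)
    loop <- c(inner + 1L, partner[inner] - 1L)
  } else {
    inner <- min(paired)
    loop <- c(partner[inner] + 1L, inner - 1L)
  }
  res$outside_loop <- !any(pos >= loop[1L] & pos <= loop[2L])
  # longest unpaired run within the duplex on either arm
  runmax <- function(idx) {
    if (length(idx) < 2L) return(0L)
    r <- rle(partner[idx[1L]:idx[2L]] == 0L)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  arm_m <- runmax(range(paired))
  arm_s <- runmax(range(partner[paired]))
  res$max_bulge_run <- max(arm_m, arm_s)
  res$pass <- res$in_one_arm && res$outside_loop &&
    res$unpaired_mature <= max_unpaired && res$max_bulge_run <= max_bulge
  res
}

#' Derive the miRNA* sequence and its read support
#'
#' The star interval is obtained from the pairing partners of the mature's
#' ends, extrapolated linearly across unpaired end bases and shifted by 2 nt
#' so both ends of the mature/star duplex carry the canonical 2-nt 3'
#' overhang. Star support is reported, never required: a candidate is a tag
#' in the table equal to the star sequence or differing by 1 nt at either
#' end.
#'
#' @param precursor Precursor sequence.
#' @param partner Partner vector (from [fold_rna()] or
#'   [parse_dot_bracket()]).
#' @param mature_offset0,mature_len Mature placement within the precursor.
#' @param table Optional tag table used to look up star reads.
#' @return List: `star` (sequence), `star_start0` (offset in precursor),
#'   `star_supported`, `star_read_count`.
#' @export
find_star <- function(precursor, partner, mature_offset0, mature_len,
                      table = NULL) {
  n <- nchar(precursor)
  pos <- (mature_offset0 + 1L):(mature_offset0 + mature_len)
  paired <- pos[partner[pos] > 0L]
  if (length(paired) == 0L) stop("mature fully unpaired; star undefined")
  # antiparallel register: partner(p) decreases as p increases, so the
  # partner of the (possibly unpaired) mature 5' end extrapolates linearly;
  # the star 3' end sits 2 nt past it, which yields the canonical 2-nt 3'
  # overhang on both duplex ends and makes the mapping an involution
  # (deriving the mature back from the star returns the original interval)
  d5 <- min(paired) - pos[1L]
  q1 <- partner[min(paired)] + d5
  star_end <- q1 + 2L
  star_start <- star_end - mature_len + 1L
  if (star_start < 1L || star_end > n) {
    stop("star interval extends beyond precursor")
  }
  star <- substr(precursor, star_start, star_end)
  supported <- FALSE
  count <- 0L
  if (!is.null(table)) {
    variants <- character(0)
    for (d5 in -1L:1L) {
      for (d3 in -1L:1L) {
        a <- star_start + d5
        b <- star_end + d3
        if (a >= 1L && b <= n && b > a) {
          variants <- c(variants, substr(precursor, a, b))
        }
      }
    }
    hit <- table$sequence %in% unique(variants)
    supported <- any(hit)
    count <- sum(table$count_A[hit] + table$count_B[hit])
  }
  list(star = star, star_start0 = star_start - 1L,
       star_supported = supported, star_read_count = as.integer(count))
}

#' Discover novel miRNA candidates
#'
#' Runs clustering, precursor excision, folding, hairpin evaluation and star
#' lookup; of the two windows per cluster the passing one with the higher
#' pairing score wins (ties: more paired mature bases).
#'
#' @inheritParams cluster_loci
#' @param index `genome_index`.
#' @param long_flank,short_flank Precursor window flanks.
#' @param max_unpaired,max_bulge Hairpin criteria limits.
#' @param fold_fun Folding engine: a function of the precursor sequence
#'   returning `list(structure=, score=)` ([fold_rna()] by default).
#' @param ratio_threshold Fold-ratio threshold for the response call
#'   (default 2, the usual novel-candidate rule).
#' @return data.frame of candidates (`id`, `sequence`, `length`, `count_A`,
#'   `count_B`, `log2fc`, `response`, `star_supported`, `star_read_count`,
#'   `precursor_chrom`, `precursor_start0`, `precursor_end`, `strand`,
#'   `precursor_seq`, `structure`, `score`), ordered by descending combined
#'   count.
#' @export
discover_mirnas <- function(mapped, classes, table, index,
                            known_matures = character(0),
                            merge_distance = 30L, min_count = 5L,
                            max_nloci = 5L, mature_lengths = 20:24,
                            long_flank = 150L, short_flank = 20L,
                            max_unpaired = 4L, max_bulge = 2L,
                            fold_fun = fold_rna, ratio_threshold = 2) {
  clusters <- cluster_loci(mapped, classes, table, known_matures,
                           merge_distance, min_count, max_nloci,
                           mature_lengths)
  cand <- list()
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    precs <- tryCatch(
      extract_precursors(cl, index, long_flank, short_flank),
      error = function(e) NULL)
    if (is.null(precs)) next
    best <- NULL
    for (p in precs) {
      f <- fold_fun(p$seq)
      ev <- evaluate_hairpin(p$seq, f$structure, p$mature_offset0,
                             p$mature_len, max_unpaired, max_bulge)
      if (!ev$pass) next
      stem <- sum(ev$partner[(p$mature_offset0 + 1L):
                               (p$mature_offset0 + p$mature_len)] > 0L)
      if (is.null(best) || f$score > best$score ||
          (f$score == best$score && stem > best$stem)) {
        best <- list(p = p, f = f, ev = ev, score = f$score, stem = stem)
      }
    }
    if (is.null(best)) next
    star <- tryCatch(
      find_star(best$p$seq, best$ev$partner, best$p$mature_offset0,
                best$p$mature_len, table),
      error = function(e) list(star = NA_character_, star_supported = FALSE,
                               star_read_count = 0L))
    cand[[length(cand) + 1L]] <- data.frame(
      sequence = cl$rep_sequence,
      length = nchar(cl$rep_sequence),
      count_A = cl$count_A, count_B = cl$count_B,
      star_supported = star$star_supported,
      star_read_count = star$star_read_count,
      precursor_chrom = best$p$chrom,
      precursor_start0 = best$p$start0,
      precursor_end = best$p$end,
      strand = best$p$strand,
      precursor_seq = best$p$seq,
      structure = best$f$structure,
      score = best$f$score,
      stringsAsFactors = FALSE
    )
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand)) {
    return(data.frame(id = character(0), sequence = character(0),
                      length = integer(0), count_A = integer(0),
                      count_B = integer(0), log2fc = numeric(0),
                      response = character(0), star_supported = logical(0),
                      star_read_count = integer(0),
                      precursor_chrom = character(0),
                      precursor_start0 = integer(0),
                      precursor_end = integer(0), strand = character(0),
                      precursor_seq = character(0), structure = character(0),
                      score = integer(0)))
  }
  # one candidate per tag: a hairpin read maps to both arms (its reverse
  # complement is the opposite arm), producing mirror-image clusters; keep
  # the best-scoring precursor per sequence, pooling star support
  if (anyDuplicated(cand$sequence)) {
    keep <- lapply(split(seq_len(nrow(cand)), cand$sequence), function(ix) {
      best <- ix[order(-cand$score[ix], cand$precursor_chrom[ix],
                       cand$precursor_start0[ix])[1L]]
      cand$star_supported[best] <<- any(cand$star_supported[ix])
      cand$star_read_count[best] <<- max(cand$star_read_count[ix])
      best
    })
    cand <- cand[sort(unlist(keep)), , drop = FALSE]
  }
  cand <- cand[order(-(cand$count_A + cand$count_B), cand$sequence), ,
               drop = FALSE]
  cand$id <- sprintf("miRN%02d", seq_len(nrow(cand)))
  raw <- log2_fold_change(cand$count_A, cand$count_B, digits = NULL)
  cand$log2fc <- round_half_away(raw, 1L)
  cand$response <- classify_response(raw, ratio_threshold)
  rownames(cand) <- NULL
  cand[, c("id", "sequence", "length", "count_A", "count_B", "log2fc",
           "response", "star_supported", "star_read_count",
           "precursor_chrom", "precursor_start0", "precursor_end", "strand",
           "precursor_seq", "structure", "score")]
}
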