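# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force scans, exhaustive enumeration and
# position-by-position rescoring.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force perfect-match scan of both strands of a named genome
naive_scan <- function(genome, tag) {
  rows <- list()
  L <- nchar(tag)
  rct <- rc_oracle(tag)
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    n <- nchar(s)
    if (n < L || grepl("N", tag, fixed = TRUE)) next
    for (i in seq_len(n - L + 1L)) {
      w <- substr(s, i, i + L - 1L)
      if (w == tag) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = i - 1L, end = i + L - 1L, strand = "+",
          stringsAsFactors = FALSE)
      }
      if (w == rct) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start0 = i - 1L, end = i + L - 1L, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start0 = integer(0),
                      end = integer(0), strand = character(0))
  }
  out[order(out$chrom, out$start0, out$strand), , drop = FALSE]
}

# exhaustive enumeration of all nested structures with a minimum loop of 3;
# returns the maximum total pair weight (GC=3, AU=2, GU=1)
enum_fold_score <- function(seq, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  w_of <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("CG", "GC")) return(3L)
    if (p %in% c("AT", "TA")) return(2L)
    if (p %in% c("GT", "TG")) return(1L)
    0L
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    scores <- best(i + 1L, j) # i unpaired
    for (k in (i + min_loop + 1L):j) {
      w <- w_of(s[i], s[k])
      if (w > 0L) {
        scores <- c(scores, w + best(i + 1L, k - 1L) + best(k + 1L, j))
      }
    }
    max(scores)
  }
  if (length(s) < 2L) return(0L)
  best(1L, length(s))
}

# independent per-position duplex rescoring (antiparallel, ungapped)
oracle_duplex <- function(mirna, site, gu_half = TRUE) {
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])
  total <- 0
  for (i in seq_along(m)) {
    pair <- paste0(m[i], s[i])
    total <- total + if (pair %in% c("AT", "TA", "GC", "CG")) {
      0
    } else if (pair %in% c("GT", "TG")) {
      if (gu_half) 0.5 else 1
    } else {
      1
    }
  }
  total
}

# brute-force all-windows target scan
oracle_target_scan <- function(mirna, transcripts, threshold = 3) {
  L <- nchar(mirna)
  rows <- list()
  for (tx in names(transcripts)) {
    s <- transcripts[[tx]]
    n <- nchar(s)
    if (n < L) next
    for (i in seq_len(n - L + 1L)) {
      p <- oracle_duplex(mirna, substr(s, i, i + L - 1L))
      if (p <= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = tx, start1 = i, penalty = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript = character(0), start1 = integer(0),
                      penalty = numeric(0))
  }
  out[order(out$transcript, out$start1), , drop = FALSE]
}

# quadratic single-linkage clustering oracle on (start, end) intervals
oracle_single_linkage <- function(start0, end, merge_distance) {
  n <- length(start0)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (grp[i] != grp[j] &&
            max(start0[i], start0[j]) - min(end[i], end[j]) <= merge_distance) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# small synthetic scenario shared by discovery/pipeline tests
small_sim <- function(seed = 11, ...) {
  cfg <- simulation_config(n_mirna = 6L, n_structural = 4L, n_decoy = 4L,
                           n_transcripts = 10L, chrom_length = 20000L,
                           depth = 20000L, seed = seed, ...)
  ref <- make_reference(cfg)
  libs <- simulate_libraries(ref$truth, cfg, ref)
  list(cfg = cfg, ref = ref, libs = libs)
}

# trim+collapse+map+classify front end shared by several tests
run_front <- function(sim) {
  ta <- trim_reads(sim$libs$A$read, sim$cfg$adapter, sim$libs$A$count)
  tb <- trim_reads(sim$libs$B$read, sim$cfg$adapter, sim$libs$B$count)
  tab <- collapse_reads(ta$inserts, tb$inserts, ta$counts, tb$counts)
  idx <- build_index(sim$ref$genome)
  mp <- locate(tab, idx)
  cls <- classify_tags(mp$mapped, sim$ref$annotations)
  list(table = tab, index = idx, mapping = mp, classes = cls)
}
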