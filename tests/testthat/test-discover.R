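# A hand-built perfect hairpin used by several tests:
# mature (21 nt, pyrimidine-rich) + 8-nt loop + reverse complement, with
# 10-nt flanks of A on the left and purines on the right.
MATURE <- "TCTCCTTCTCCTTTCTCTTCC"
HAIRPIN <- paste0(strrep("A", 10), MATURE, "AAAAAAAA",
                  rc_oracle(MATURE), "GAGAAGGAGA")

test_that("clustering keeps only unannotated, abundant, placeable mature-length tags", {
  mapped <- data.frame(
    sequence = c("T1", "T2", "T3", "T4", "T5"),
    chrom = "chr1",
    start0 = c(100L, 130L, 400L, 700L, 1000L),
    end = c(121L, 151L, 421L, 721L, 1021L),
    strand = c("+", "+", "+", "+", "-"), n_loci = c(1L, 1L, 1L, 9L, 1L))
  mapped$sequence <- c(strrep("C", 21), strrep("CT", 10), strrep("T", 21),
                       strrep("TC", 11), strrep("TTC", 7))
  classes <- setNames(c("other", "other", "tRNA", "other", "other"),
                      mapped$sequence)
  tab <- data.frame(sequence = mapped$sequence,
                    count_A = c(10L, 5L, 50L, 50L, 2L),
                    count_B = c(5L, 3L, 50L, 50L, 1L))
  cl <- cluster_loci(mapped, classes, tab)
  # T3 excluded (tRNA), T4 excluded (n_loci > 5), T5 excluded (count < 5)
  expect_equal(nrow(cl), 1L) # T1+T2 merge within 30 nt
  expect_equal(cl$start0, 100L)
  expect_equal(cl$end, 151L)
  expect_equal(cl$rep_sequence, strrep("C", 21)) # highest count
  # known matures are excluded too
  cl2 <- cluster_loci(mapped, classes, tab, known_matures = strrep("C", 21))
  expect_equal(cl2$rep_sequence, strrep("CT", 10))
})

test_that("single-linkage clustering matches the quadratic oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 20
    start0 <- sort(sample(0:2000, n))
    end <- start0 + 21L
    seqs <- vapply(1:n, function(i) rand_dna(21, c("C", "T")), character(1))
    mapped <- data.frame(sequence = seqs, chrom = "chr1", start0 = start0,
                         end = end, strand = "+", n_loci = 1L)
    classes <- setNames(rep("other", n), seqs)
    tab <- data.frame(sequence = seqs, count_A = 5L, count_B = 5L)
    cl <- cluster_loci(mapped, classes, tab, merge_distance = 30L)
    want <- oracle_single_linkage(start0, end, 30L)
    expect_equal(nrow(cl), length(unique(want)))
    # every oracle group maps into exactly one emitted cluster
    for (g in unique(want)) {
      members <- which(want == g)
      inside <- cl$start0 <= min(start0[members]) &
        cl$end >= max(end[members])
      expect_equal(sum(inside), 1L)
    }
  }
})

test_that("precursor windows follow the flank arithmetic and orientation contract", {
  set.seed(37)
  g <- c(chr1 = rand_dna(1000))
  mature <- substr(g[["chr1"]], 501, 521)
  cluster <- data.frame(cluster_id = "cl001", chrom = "chr1", strand = "+",
                        start0 = 500L, end = 521L, rep_sequence = mature,
                        rep_start0 = 500L, rep_end = 521L)
  idx <- build_index(g)
  pr <- extract_precursors(cluster, idx, long_flank = 150L, short_flank = 20L)
  expect_equal(c(pr[[1]]$start0, pr[[1]]$end), c(350L, 541L))
  expect_equal(c(pr[[2]]$start0, pr[[2]]$end), c(480L, 671L))
  expect_equal(substr(pr[[1]]$seq, pr[[1]]$mature_offset0 + 1,
                      pr[[1]]$mature_offset0 + 21), mature)
  # minus strand: precursor carries the mature verbatim, not its complement
  clm <- cluster
  clm$strand <- "-"
  clm$rep_sequence <- rc_oracle(mature)
  prm <- extract_precursors(clm, idx)
  expect_equal(substr(prm[[1]]$seq, prm[[1]]$mature_offset0 + 1,
                      prm[[1]]$mature_offset0 + 21), rc_oracle(mature))
  # a cluster at the very contig edge with no room errors out
  edge <- cluster
  edge$rep_start0 <- edge$start0 <- 0L
  edge$rep_end <- edge$end <- 1100L
  expect_error(extract_precursors(edge, idx), "clipped")
})

test_that("hairpin criteria pass a clean stem and fail pathological matures", {
  f <- fold_rna(HAIRPIN)
  off <- 10L
  ev <- evaluate_hairpin(HAIRPIN, f$structure, off, nchar(MATURE))
  expect_true(ev$in_one_arm)
  expect_true(ev$outside_loop)
  expect_equal(ev$unpaired_mature, 0L)
  expect_lte(ev$max_bulge_run, 2L)
  expect_true(ev$pass)
  # mature placed across the terminal loop
  ev2 <- evaluate_hairpin(HAIRPIN, f$structure, off + 15L, nchar(MATURE))
  expect_false(ev2$in_one_arm || ev2$outside_loop)
  expect_false(ev2$pass)
  # more unpaired mature bases than the limit
  ev3 <- evaluate_hairpin(HAIRPIN, f$structure, off - 5L, nchar(MATURE))
  expect_gte(ev3$unpaired_mature, 5L)
  expect_false(ev3$pass)
  expect_error(evaluate_hairpin(HAIRPIN, f$structure, 100L, 21L), "outside")
})

test_that("the star interval carries 2-nt 3' overhangs on both duplex ends", {
  f <- fold_rna(HAIRPIN)
  off <- 10L
  L <- nchar(MATURE)
  star <- find_star(HAIRPIN, f$partner, off, L)
  # 3' end of the star = partner of the mature 5' end, shifted by 2
  expect_equal(star$star_start0 + L, f$partner[off + 1L] + 2L)
  expect_equal(star$star, paste0(substr(rc_oracle(MATURE), 3, L), "GA"))
  # overhang symmetry: re-deriving the mature from the star interval
  back <- find_star(HAIRPIN, f$partner, star$star_start0, L)
  expect_equal(back$star, MATURE)
  expect_equal(back$star_start0, off)
})

test_that("star support is read from the tag table with 1-nt end tolerance", {
  f <- fold_rna(HAIRPIN)
  star <- find_star(HAIRPIN, f$partner, 10L, nchar(MATURE))$star
  tab_exact <- data.frame(sequence = star, count_A = 4L, count_B = 1L)
  got <- find_star(HAIRPIN, f$partner, 10L, nchar(MATURE), tab_exact)
  expect_true(got$star_supported)
  expect_equal(got$star_read_count, 5L)
  shifted <- substr(star, 2, nchar(star)) # 1-nt 5' trim still supports
  got2 <- find_star(HAIRPIN, f$partner, 10L, nchar(MATURE),
                    data.frame(sequence = shifted, count_A = 2L, count_B = 0L))
  expect_true(got2$star_supported)
  none <- data.frame(sequence = rand_dna(21), count_A = 9L, count_B = 9L)
  expect_false(find_star(HAIRPIN, f$partner, 10L, nchar(MATURE),
                         none)$star_supported)
})

test_that("discovery recovers planted hairpins and rejects background loci", {
  sim <- small_sim(seed = 19, dispersion = 0)
  fr <- run_front(sim)
  nov <- discover_mirnas(fr$mapping$mapped, fr$classes, fr$table, fr$index)
  truth <- sim$ref$truth$mirnas
  expect_true(all(truth$sequence %in% nov$sequence))
  expect_equal(anyDuplicated(nov$sequence), 0L)
  # no candidate outside the planted set (structural loci are filtered by
  # class, decoy loci cannot fold)
  expect_equal(setdiff(nov$sequence, truth$sequence), character(0))
  # star support exactly where planted
  got <- nov$star_supported[match(truth$sequence, nov$sequence)]
  expect_equal(got, truth$star_planted)
  # with zero dispersion counts hit their expected values exactly
  ix <- match(nov$sequence, truth$sequence)
  expect_equal(nov$count_A, as.integer(round(truth$base_mean[ix])))
  expect_equal(nov$count_B,
               as.integer(round(truth$base_mean[ix] * 2^truth$log2fc[ix])))
})
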