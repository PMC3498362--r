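test_that("duplex penalty scores Watson-Crick, wobble and mismatch positions", {
  m <- "TGACATCCAGATAGAAGCTTT"
  site <- rc_oracle(m)
  d <- duplex_penalty(m, site)
  expect_equal(d$penalty, 0)
  expect_equal(d$status, strrep("|", nchar(m)))
  # one G opposite U (=T): half penalty
  m2 <- "GAAAA"
  s2 <- "TTTTT" # reversed: T faces G -> wobble; A:T elsewhere
  d2 <- duplex_penalty(m2, s2)
  expect_equal(d2$penalty, 0.5)
  expect_equal(substr(d2$status, 1, 1), "o")
  # strict mode counts wobble as mismatch
  expect_equal(duplex_penalty(m2, s2, gu_half = FALSE)$penalty, 1)
  expect_error(duplex_penalty("ACGT", "ACG"), "length")
})

test_that("duplex penalty matches independent rescoring on random pairs", {
  set.seed(41)
  for (i in 1:500) {
    L <- sample(19:24, 1)
    m <- rand_dna(L)
    s <- rand_dna(L)
    expect_equal(duplex_penalty(m, s)$penalty, oracle_duplex(m, s))
  }
})

test_that("strict-mode duplex penalty is invariant under reverse-complementing both strands", {
  # Watson-Crick matching is symmetric under complementation, so the strict
  # (Hamming) penalty is invariant when both strands are reverse-complemented
  # and swapped; wobble scoring is inherently strand-asymmetric (a G:U pair
  # complements to C:A) and is therefore excluded from this property.
  set.seed(43)
  for (i in 1:50) {
    m <- rand_dna(21)
    s <- rand_dna(21)
    expect_equal(duplex_penalty(m, s, gu_half = FALSE)$penalty,
                 duplex_penalty(rc_oracle(s), rc_oracle(m),
                                gu_half = FALSE)$penalty)
  }
})

test_that("target scanning reports windows at or below the penalty threshold", {
  set.seed(47)
  m <- rand_dna(21)
  tx <- c(T1 = paste0(rand_dna(100, c("A", "C")), rc_oracle(m),
                      rand_dna(100, c("A", "C"))))
  hits <- scan_targets(m, tx)
  expect_equal(hits$start1[1], 101)
  expect_equal(hits$penalty[1], 0)
  # a transcript shorter than the miRNA is skipped with a notice
  expect_message(scan_targets(m, c(S = "ACGT")), "skipped")
})

test_that("target scanning equals the brute-force window scan", {
  set.seed(53)
  m <- rand_dna(21)
  tx <- c(T1 = rand_dna(900), T2 = paste0(rand_dna(300), rc_oracle(m),
                                          rand_dna(200)))
  got <- scan_targets(m, tx, threshold = 8) # loose cut to exercise sorting
  want <- oracle_target_scan(m, tx, threshold = 8)
  got <- got[order(got$transcript, got$start1), ]
  expect_equal(got$transcript, want$transcript)
  expect_equal(got$start1, want$start1)
  expect_equal(got$penalty, want$penalty)
})

test_that("cleavage position is the transcript base paired to miRNA position 10", {
  expect_equal(cleavage_position(101, 21), 112)
  expect_equal(cleavage_position(1, 21), 12)
  expect_equal(cleavage_position(50, 24), 64)
  expect_error(cleavage_position(1, 9), "shorter")
})

test_that("degradome categories follow the 5-level abundance scheme", {
  site <- list(transcript = "T1", start1 = 101, end1 = 121) # cleavage at 112
  none <- data.frame(transcript = "T2", pos_1based = 5, count = 10)
  expect_equal(degradome_support(site, none)$category, "none")
  # unique maximum at the cleavage site
  peak <- data.frame(transcript = "T1", pos_1based = c(112, 300, 500),
                     count = c(40, 6, 3))
  s <- degradome_support(site, peak)
  expect_equal(s$cleavage_pos, 112)
  expect_equal(s$evidence_count, 40L)
  expect_equal(s$category, "0")
  # tied maximum elsewhere
  tie <- data.frame(transcript = "T1", pos_1based = c(112, 300),
                    count = c(40, 40))
  expect_equal(degradome_support(site, tie)$category, "1")
  # above the median of nonzero positions but below the max
  mid <- data.frame(transcript = "T1", pos_1based = c(112, 300, 400, 500),
                    count = c(10, 50, 4, 2))
  expect_equal(degradome_support(site, mid)$category, "2")
  # nonzero but at/below the median
  low <- data.frame(transcript = "T1", pos_1based = c(112, 300, 400, 500),
                    count = c(3, 50, 40, 30))
  expect_equal(degradome_support(site, low)$category, "3")
  # a single read is its own category
  single <- data.frame(transcript = "T1", pos_1based = c(112, 300),
                       count = c(1, 50))
  expect_equal(degradome_support(site, single)$category, "4")
  # the +/-1 window pools evidence around the exact coordinate
  off <- data.frame(transcript = "T1", pos_1based = c(111, 113, 300),
                    count = c(5, 6, 4))
  expect_equal(degradome_support(site, off)$evidence_count, 11L)
})

test_that("planted synthetic targets validate end to end at noise zero", {
  cfg <- simulation_config(n_mirna = 6L, n_structural = 4L, n_decoy = 4L,
                           n_transcripts = 10L, chrom_length = 20000L,
                           depth = 20000L, degradome_noise = 0, seed = 61)
  ref <- make_reference(cfg)
  deg <- simulate_degradome(ref$truth, cfg)
  tg <- ref$truth$targets
  # noise 0: tags only at planted cleavage positions
  L <- tg$site_end1 - tg$site_start1 + 1
  want <- paste(tg$transcript, cleavage_position(tg$site_start1, L))
  expect_setequal(paste(deg$transcript, deg$pos_1based), want)
  # every planted site is found with penalty 0 and category 0
  mir <- setNames(ref$truth$mirnas$sequence, ref$truth$mirnas$name)
  rep <- predict_targets(mir[tg$mirna], ref$transcriptome, deg)
  key <- paste(tg$mirna, tg$transcript, tg$site_start1)
  planted <- rep[paste(rep$mirna, rep$transcript, rep$start1) %in% key, ]
  expect_equal(nrow(planted), nrow(tg))
  expect_equal(planted$penalty, rep(0, nrow(tg)))
  expect_equal(planted$category, rep("0", nrow(tg)))
  # a penalty<=3 site on a tag-free transcript gets no degradome category
  free <- rep[!(rep$transcript %in% deg$transcript), ]
  if (nrow(free)) expect_true(all(free$category == "none"))
})
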