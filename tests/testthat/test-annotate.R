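make_ann <- function(df) {
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(df$start1, df$end1),
                         strand = df$strand, type = df$type,
                         ID = seq_len(nrow(df)))
}

test_that("classification is strand-aware with fixed class precedence", {
  ann <- make_ann(data.frame(
    chrom = "chr1", start1 = c(101, 101, 501), end1 = c(200, 200, 600),
    strand = c("+", "+", "-"), type = c("rRNA", "snoRNA", "tRNA")))
  mapped <- data.frame(
    sequence = c("S1", "S2", "S3"),
    chrom = "chr1", start0 = c(120, 120, 520), end = c(141, 141, 541),
    strand = c("+", "+", "+"), n_loci = 1L)
  mapped <- mapped[c(1, 3), ]
  cls <- classify_tags(mapped, ann)
  expect_equal(unname(cls["S1"]), "rRNA") # precedence over snoRNA
  expect_equal(unname(cls["S3"]), "other") # opposite strand tRNA
  # strandless mode picks the tRNA up
  cls2 <- classify_tags(mapped, ann, strand_aware = FALSE)
  expect_equal(unname(cls2["S3"]), "tRNA")
})

test_that("classification matches a quadratic overlap oracle and ignores record order", {
  set.seed(21)
  n_ann <- 12
  ann_df <- data.frame(
    chrom = "chr1", start1 = sample(1:900, n_ann), strand = sample(c("+", "-"), n_ann, TRUE),
    type = sample(c("rRNA", "tRNA", "snRNA", "snoRNA"), n_ann, TRUE))
  ann_df$end1 <- ann_df$start1 + sample(30:120, n_ann, TRUE)
  mapped <- data.frame(
    sequence = sprintf("T%02d", 1:50), chrom = "chr1",
    start0 = sample(0:980, 50), strand = sample(c("+", "-"), 50, TRUE),
    n_loci = 1L)
  mapped$end <- mapped$start0 + 21L
  cls <- classify_tags(mapped, make_ann(ann_df))
  prec <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  for (i in seq_len(nrow(mapped))) {
    ov <- ann_df$type[ann_df$strand == mapped$strand[i] &
                        ann_df$start1 <= mapped$end[i] &
                        ann_df$end1 >= mapped$start0[i] + 1]
    want <- if (length(ov)) prec[min(match(ov, prec))] else "other"
    expect_equal(unname(cls[mapped$sequence[i]]), want)
  }
  # permutation invariance
  perm <- sample(n_ann)
  cls2 <- classify_tags(mapped, make_ann(ann_df[perm, ]))
  expect_equal(cls, cls2[names(cls)])
})

test_that("class summary percentages follow the mixed-precision dialect and totals add up", {
  tab <- data.frame(sequence = c("AA", "CC", "GG", "TT"),
                    count_A = c(50L, 30L, 15L, 5L),
                    count_B = c(10L, 0L, 60L, 30L))
  cls <- c(AA = "rRNA", CC = "tRNA", GG = "other", TT = "other")
  cs <- class_summary(tab, cls)
  tot <- cs[cs$class == "total", ]
  expect_equal(tot$total_A, 100)
  expect_equal(tot$total_B, 100)
  expect_equal(sum(cs$total_A[cs$class != "total"]), tot$total_A)
  expect_equal(sum(cs$unique_B[cs$class != "total"]), tot$unique_B)
  expect_equal(cs$total_pct_A[cs$class == "rRNA"], 50.0)
  expect_equal(cs$total_pct_A[cs$class == "tRNA"], 30.0)
  expect_equal(cs$total_pct_B[cs$class == "rRNA"], 10.0)
  expect_equal(cs$unique_pct_A[cs$class == "rRNA"], 25.0)
  # below 10 percent prints two decimals
  expect_equal(cs$total_pct_A[cs$class == "other"], 20.0)
  tab2 <- data.frame(sequence = c("AA", "CC"), count_A = c(31L, 969L),
                     count_B = c(1L, 999L))
  cs2 <- class_summary(tab2, c(AA = "snRNA", CC = "other"))
  expect_equal(cs2$total_pct_A[cs2$class == "snRNA"], 3.1)
  expect_equal(cs2$total_pct_B[cs2$class == "snRNA"], 0.1)
  expect_error(class_summary(tab2[0, ], c(AA = "other")), "empty_library")
})

test_that("a single-class table reports 100 percent for that class", {
  tab <- data.frame(sequence = c("AA", "CC"), count_A = c(3L, 7L),
                    count_B = c(1L, 2L))
  cs <- class_summary(tab, c(AA = "tRNA", CC = "tRNA"))
  expect_equal(cs$total_pct_A[cs$class == "tRNA"], 100)
  expect_equal(cs$total_pct_A[cs$class == "rRNA"], 0)
})

test_that("library overlap splits unique and total percentages correctly", {
  # identical libraries: all common
  same <- data.frame(sequence = c("A1", "A2"), count_A = c(5L, 5L),
                     count_B = c(5L, 5L))
  ov <- library_overlap(same)
  expect_equal(ov$unique_pct[ov$category == "common"], 100)
  expect_equal(ov$total_pct[ov$category == "common"], 100)
  # disjoint with equal depth: 50/50 on totals
  disj <- data.frame(sequence = c("A1", "A2", "B1", "B2"),
                     count_A = c(6L, 4L, 0L, 0L),
                     count_B = c(0L, 0L, 3L, 7L))
  ov2 <- library_overlap(disj)
  expect_equal(ov2$total_pct[ov2$category == "A_specific"], 50)
  expect_equal(ov2$total_pct[ov2$category == "B_specific"], 50)
  expect_equal(ov2$unique_pct[ov2$category == "common"], 0)
  # hand-computed 5-sequence table
  tab <- data.frame(sequence = sprintf("S%d", 1:5),
                    count_A = c(10L, 5L, 0L, 0L, 5L),
                    count_B = c(2L, 0L, 6L, 2L, 0L))
  ov3 <- library_overlap(tab)
  expect_equal(ov3$unique_pct, c(40, 40, 20))
  expect_equal(ov3$total_pct, round(100 * c(10, 8, 12) / 30, 2))
  expect_lt(abs(sum(ov3$unique_pct) - 100), 0.05)
  expect_lt(abs(sum(ov3$total_pct) - 100), 0.05)
})

test_that("GFF3 annotations round-trip through the reader", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "ann.gff3")
  gr <- make_ann(data.frame(chrom = "chr1", start1 = 101, end1 = 200,
                            strand = "+", type = "tRNA"))
  rtracklayer::export(gr, gff, format = "gff3")
  back <- read_annotations(gff)
  expect_equal(as.character(GenomicRanges::seqnames(back)), "chr1")
  expect_equal(BiocGenerics::start(back), 101)
  expect_equal(back$type, "tRNA")
})
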