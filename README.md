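# miRstress

Two-condition small RNA-seq analysis of stress-responsive plant miRNAs.

miRstress is an R package for researchers contrasting two small-RNA
sequencing libraries — typically a control condition against a nutrient- or
stress-treated one (e.g. nitrogen-sufficient +N vs nitrogen-deficient −N
seedlings). From adapter-ligated reads, a genome, structural-RNA
annotations, a mature-miRNA catalog, a transcriptome and degradome (PARE)
tags, it produces:

* per-library RNA-class composition and between-library overlap summaries;
* member-resolved expression of known miRNAs (exact full-length matching
  distinguishes family members one nucleotide apart), with RPM
  normalization, log2 fold changes and stress-response classes;
* novel miRNA candidates from hairpin-precursor structure criteria, with
  miRNA\* (star) read support;
* complementarity-predicted target sites with degradome cleavage
  validation.

A bundled synthetic-data generator (genome + annotations + two-condition
libraries + degradome + planted truth) makes every stage testable without
external resources.

## The models in brief

**Quantification.** A tag (distinct trimmed insert with per-library counts
$n_A$, $n_B$) matches a mature miRNA only by exact identity. Fold change is
$\log_2(n_B/n_A)$ on raw counts (adding 1 to both counts only when one is
zero); a miRNA is stress-induced when $\log_2\mathrm{FC} > \log_2 r$ and
stress-suppressed when below $-\log_2 r$ (strict; $r=3$ for known miRNAs,
$r=2$ for novel candidates).

**Discovery.** Unannotated, mature-length tags are clustered (single
linkage, ≤ 30 nt, per strand), excised in 150/20-nt flanking windows, and
folded with a weighted base-pair-maximization dynamic program (GC = 3,
AU = 2, GU = 1, minimum loop 3, deterministic traceback). A candidate
passes when the mature sits in one arm of the stem-loop with ≤ 4 unpaired
bases and no bulge > 2 nt; the star interval is the mature's pairing
partner shifted for canonical 2-nt 3′ overhangs.

**Targets.** Ungapped antiparallel duplex scoring (Watson–Crick 0, G:U
wobble 0.5, mismatch 1) keeps sites with penalty ≤ 3; slicer cleavage is
expected at the transcript position paired to miRNA position 10
($t_1 + L - 10$), and degradome tag pile-ups there are categorized 0–4 by
abundance relative to the rest of the transcript.

## Worked example

Auditing a published composition table and novel-miRNA fold column from
their raw counts:

```r
library(miRstress)

counts <- read.table(system.file("extdata", "published_class_counts.tsv",
                                 package = "miRstress"),
                     header = TRUE, sep = "\t")
class_summary(counts)
#>   class unique_A unique_pct_A total_A total_pct_A ... total_B total_pct_B
#>    rRNA    18852         0.87  307668        3.18 ...  281621        2.74
#>    tRNA     6099         0.28  301115        3.11 ... 1007667        9.80
#>   snRNA     1116         0.05    2188        0.02 ...    5497        0.05
#>  snoRNA     1668         0.08    3297        0.03 ...    6236        0.06
#>   other  2131218        98.70 9067082       93.70 ... 8984342       87.40
#>   total  2158953       100.00 9681350      100.00 ...10285363      100.00
```

Library totals are exact column sums; percentages use the mixed 2/1-decimal
dialect of deep-sequencing summary tables. Under nitrogen starvation the
tRNA-derived share of reads rises from 3.11% to 9.80%.

```r
nov <- read.table(system.file("extdata", "published_novel_counts.tsv",
                              package = "miRstress"),
                  header = TRUE, sep = "\t")
lfc  <- log2_fold_change(nov$count_A, nov$count_B)        # rounded, 1 dp
resp <- classify_response(log2_fold_change(nov$count_A, nov$count_B,
                                           digits = NULL), 2)
head(data.frame(id = nov$id, nov[4:5], log2fc = lfc, response = resp), 7)
#>      id count_A count_B log2fc  response
#>  miRN01      22      18   -0.3 unchanged
#>  ...
#>  miRN05      12      28    1.2       NSI
#>  miRN07      28     153    2.5       NSI
sum(resp %in% c("NSS", "NSI"))
#> [1] 9
```

Nine of the twenty novel candidates exceed the 2-fold rule — the count a
two-condition screen of this shape reports as "significantly responsive".

A fully synthetic end-to-end run:

```r
cfg  <- simulation_config(seed = 1)
ref  <- make_reference(cfg)
libs <- simulate_libraries(ref$truth, cfg, ref)
dir  <- tempdir()
write_reference(ref, libs, simulate_degradome(ref$truth, cfg), dir)
res  <- run_pipeline(list(genome = file.path(dir, "genome.fa"),
                          annotations = file.path(dir, "annotations.gff3"),
                          reads_a = file.path(dir, "reads_A.fa"),
                          reads_b = file.path(dir, "reads_B.fa"),
                          transcriptome = file.path(dir, "transcriptome.fa"),
                          degradome = file.path(dir, "degradome.tsv")),
                     file.path(dir, "out"))
res$novel[, c("id", "length", "count_A", "count_B", "log2fc", "response")]
```

`scripts/run_pipeline.R` wraps the same entry point for shell use
(`--config config.yaml --out DIR`).

## Package layout

| Area | Functions |
| --- | --- |
| synthetic data | `simulation_config`, `make_reference`, `simulate_libraries`, `simulate_degradome`, `write_reference` |
| preprocess | `trim_adapter`, `trim_reads`, `collapse_reads`, `length_profile`, `read_small_rna` |
| mapping | `build_index`, `locate` |
| annotation | `read_annotations`, `classify_tags`, `class_summary`, `library_overlap` |
| quantification | `match_known`, `rpm_normalize`, `log2_fold_change`, `classify_response`, `family_aggregate`, `quantify_known` |
| discovery | `cluster_loci`, `extract_precursors`, `fold_rna`, `evaluate_hairpin`, `find_star`, `discover_mirnas` |
| targets | `duplex_penalty`, `scan_targets`, `cleavage_position`, `degradome_support`, `predict_targets` |
| orchestration | `run_pipeline`, `write_pipeline_tables` |

See `vignettes/mirstress-methods.Rmd` for the full account of the models,
defaults and design decisions.
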