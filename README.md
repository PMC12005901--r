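# cnvbench

Clinically oriented benchmarking of germline copy-number variant (CNV)
call sets from short-read whole-genome sequencing.

Clinical laboratories judge a CNV call by whether it disrupts coding
sequence, not by how precisely its breakpoints are drawn. `cnvbench`
therefore scores deletion (DEL) and duplication (DUP) calls against a
truth set through the **coding exons they overlap**: a query call is a
true positive iff at least one splice-padded exon (coding exon ± 15 bp
of flanking intron) that it overlaps by ≥ 1 bp is also overlapped by a
truth event of the same dosage direction (DEL↔DEL, DUP↔DUP). Queries
overlapping exons without such support are false positives; calls
touching no evaluated exon are ignored. Counting is event-level, so an
event spanning many exons is never double counted. Sensitivity and
precision follow the GA4GH benchmarking definitions, with truth-side
and query-side counts kept separate:

    sensitivity = TP_truth / (TP_truth + FN)        over truth events
    precision   = TP_query / (TP_query + FP)        over query calls

Around this matching engine the package provides:

* **Truth-set preparation** — structural-variant VCF ingestion
  (SVTYPE/END/SVLEN, symbolic alleles), reclassification of
  insertion-represented duplications by comparing the inserted sequence
  to the reference flanks (≥ 95% ungapped identity, ± 2 bp positional
  slop), and restriction to the evaluated 500 bp – 10 Mb size window.
* **Synthetic gene spiking** — planting translated copies of template
  gene models into high-confidence regions (and directly on top of
  truth duplications) so sparse truth sets gain scoreable exon
  overlaps, with an independent constraint auditor.
* **Stratified metrics** — by event type, event length (0.5–1, 1–5,
  1–10, ≥ 5, > 10 kb) and number of exons spanned (1, 2–5, > 5).
* **Artifact filtering** — a multi-rule post-caller filter (size
  window, junction-only calls over 1 Mb, assembly-gap overlap,
  reciprocal overlap ≥ 0.90 with recurrent artifacts, the latter also
  available as the two-BED min/max containment mechanism) plus a
  blacklist builder that discovers recurrent artifacts across samples
  by single-linkage clustering.
* **Seeded fixtures** — fully synthetic references, gene models, truth
  and query sets with planted TP/FP/ignored composition whose expected
  metrics are recorded at generation time, independently of the engine.

Everything is built on Bioconductor containers: events, exons and
region sets are `GRanges`; VCF, BED/BED12, GFF3 and FASTA go through
VariantAnnotation, rtracklayer and Biostrings.

## Worked example

Generate a benchmark fixture with known composition, classify the
call set, and read off stratified metrics:

```r
library(cnvbench)

case <- simulate_benchmark_case(seed = 7)
exons <- padded_exons(case$genes, pad = case$pad)
cls <- classify_calls(case$queries, case$truth, exons)
event_counts(cls)
#> $tp_query  14    $fp       6    $ignored        4
#> $tp_truth  14    $fn       4    $truth_excluded 0
cnv_metrics(cls)
#>              axis stratum tp_truth fn tp_query fp sensitivity precision
#> 1             ALL     ALL       14  4       14  6   0.778     0.700
#> 2          SVTYPE     DEL        7  3        7  4   0.700     0.636
#> 3          SVTYPE     DUP        7  1        7  2   0.875     0.778
#> 4      LENGTH_BIN 0.5-1kb        4  1        3  0   0.800     1.000
#> ...
```

Of the 24 simulated calls, 14 confirm a truth event through a shared
exon, 6 overlap exons without same-direction truth support (false
positives), and 4 intergenic calls are ignored; 14 of the 18 truth
events are detected, giving 77.8% sensitivity and 70% precision
overall, with the per-type, per-length and per-exon-count breakdown in
the remaining rows.

Filtering a high-sensitivity call set against a discovered artifact
blacklist:

```r
cohort <- simulate_artifact_cohort(seed = 4)
bl <- build_artifact_blacklist(cohort$callsets, min_recurrence = 3)
cfg <- filter_config(artifact_regions = bl)
res <- apply_cnv_filters(cohort$callsets$S01, cfg)
res$verdicts[, c("id", "kept", "failed_rules")]
```

A thin command-line front end wraps the same functions
(`inst/cli/cnvbench`; locate it with
`system.file("cli", "cnvbench", package = "cnvbench")`):

```sh
cnvbench make-fixture --seed 3 --out fx
cnvbench benchmark --query fx/query.vcf --truth fx/truth.vcf \
    --genes fx/genes.bed
cnvbench prepare-truth --vcf truth_raw.vcf --reference ref.fa
cnvbench build-blacklist --calls S1=s1.vcf,S2=s2.vcf --min-recurrence 2
cnvbench filter --vcf calls.vcf --artifact-min min.bed \
    --artifact-max max.bed --mode two-bed
```

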