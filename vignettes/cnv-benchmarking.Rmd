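---
title: "Exon-overlap benchmarking of germline CNV call sets"
author: "cnvbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-overlap benchmarking of germline CNV call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvbench)
```

## The problem and the model

Short-read WGS CNV callers are usually compared to a truth set by
breakpoint or reciprocal-overlap agreement. For clinical germline
testing that is the wrong currency: what matters is whether a reported
deletion or duplication disrupts a protein, i.e. whether it touches
coding sequence, and whether its dosage direction matches the known
event. `cnvbench` implements that evaluation directly.

The matching unit is the **splice-padded coding exon**: each coding
exon of a canonical transcript extended by `pad` bases of flanking
intron on both sides (default 15 bp), so that a call clipping a splice
junction still registers. Classification of a query call set against a
truth set is then:

* A **query** call is **TP** iff some padded exon it overlaps by at
  least 1 bp is also overlapped (≥ 1 bp) by at least one truth event of
  the same dosage direction (DEL with DEL, DUP with DUP). If it
  overlaps in-scope exons but shares none with a same-direction truth
  event it is **FP**; if it overlaps no in-scope exon it is
  **ignored** and enters no denominator.
* A **truth** event overlapping at least one in-scope exon is
  **detected** iff some same-direction query shares one of its exons,
  otherwise **FN**. Truth events touching no in-scope exon are
  excluded from the sensitivity denominator.

Note what is deliberately absent: there is no reciprocal-overlap or
breakpoint condition *between* query and truth. A call whose right
breakpoint overruns by a megabase still confirms the truth event it
shares an exon with — and becomes a false positive only if the
overrun drags in an additional exon with no truth support. This is the
behaviour a clinical reviewer applies when reading coverage plots.

Counting is **event-level** ("multi-exon adjustment"): each query
contributes exactly one TP or FP no matter how many exons it spans, and
each truth event one detected/missed unit no matter how many exons or
how many confirming calls are involved. No 1:1 assignment between
queries and truths is needed because the counts are set-based, not
matching-based: a truth event confirmed by two calls counts once on the
truth side while both calls count as TPs on the query side. Sensitivity
and precision follow the GA4GH benchmarking convention of separate
truth-side and query-side counts; a ratio with an empty denominator is
reported as `NA` (never 0), since "no evaluable events" is not "zero
performance".

Where the counting rule was open — the adjustment is stated by its
purpose (avoid double counting), not by a formula — the event-level
interpretation lives behind `event_counts()` so an exon-level variant
could be swapped in without touching the classifier.

### Panel restriction

For virtual-panel evaluation the in-scope exon set can be restricted by
gene name (`panel_genes`) or region (`restrict_to`). Off-panel calls
then become ignored rather than FP: counting them against precision
would make panel-level precision meaningless, since the rest of the
genome is typically uncharacterised in panel-annotated samples.

## Truth-set preparation

Truth sets often encode duplications as insertions of the duplicated
sequence. `verify_duplication()` decides whether an insertion is a
tandem duplication of its flank: the inserted sequence is compared to
the reference segment of the same length on each side of the insertion
point, at every positional offset in `-slop..+slop` (default ±2 bp),
and the best ungapped identity over that (flank × offset) grid is
reported. At the default threshold (identity ≥ 0.95) the accepted
insertions become DUP events spanning the **matched reference
segment** — the duplicated footprint is what downstream exon matching
needs, not the single-base insertion point. Rejected insertions are
excluded, with the grid's best score retained in an audit table.

Numerical choices: identity is Hamming-style over the aligned window
(`matches / length`), with `N` never counting as a match and all-`N`
insertions rejected outright; windows running past a contig end are
skipped. The slop is realised as an integer offset scan rather than a
gapped alignment — the tolerance being modelled is positional ("the
repeat copy may start a couple of bases away"), and a full aligner
would accept indel-containing matches the threshold is not calibrated
for. Both flanks are always scanned because a tandem duplication may be
recorded at either end of the repeat; the construction is symmetric,
and the test suite verifies that mirrored constructions are accepted
via mirrored flanks. For random inserted sequences of length ≥ 100 the
acceptance rate at 0.95 is indistinguishable from zero (0 in 1000
trials in the acceptance suite), so the threshold is conservative.

Analysis is restricted to events of 500 bp – 10 Mb (`size_filter()`,
both bounds inclusive — "from 500 bp to 10 Mb" naturally includes its
endpoints). Both bounds are configuration, not constants: smaller
events are dominated by caller noise, larger ones by reference
artifacts spanning centromeres and telomeres.

## Synthetic gene spiking

Truth sets for well-characterised reference samples overlap few coding
exons, which starves the benchmark of scoreable events. The spiking
module plants translated copies of real template gene structures:

* **general mode** scans each contig left to right and places templates
  (drawn round-robin from a seed-shuffled cycle) so that every gene
  span lies wholly inside a high-confidence region, overlaps no real
  gene span, and leaves at least `min_gap` (default 100 kb) bases
  strictly between consecutive synthetic genes;
* **on-top-of mode** anchors one template on each truth event of a
  chosen dosage type so at least one exon overlaps the event — used to
  give the sparse duplication class more exon overlaps. Event-anchored
  placements are exempt from the inter-gene gap rule, which cannot in
  general be satisfied at fixed anchor points.

Only the constraints are prescribed by the evaluation design; the
placement *algorithm* is this package's choice, and a deterministic
greedy scan was chosen over rejection sampling for reproducibility:
the same seed yields byte-identical placements. Exon structures are
exact translations of their template (all inter-exon distances
preserved). `audit_synthetic_genes()` re-checks every constraint by
direct arithmetic on the emitted placements — it shares no code with
the placer, so the acceptance suite's "50 seeds, zero violations" check
is a genuine cross-validation. Real-gene avoidance uses the full gene
span (first to last exon), the conservative reading. Strand is copied
from the template and never affects matching, which is strand-blind.

## Stratification

Metrics are reported overall and per stratum, with truth events
stratified by their own properties and query events by theirs:

* **type**: DEL, DUP;
* **length**: 0.5–1 kb, 1–5 kb, 1–10 kb, ≥ 5 kb, > 10 kb. Ranged bins
  are lower-inclusive/upper-exclusive; open-top bins follow their label
  (`≥` inclusive, `>` exclusive). These bins deliberately overlap —
  they are the unions of the reporting conventions used in genome-wide
  and panel-level CNV evaluations — so each bin is evaluated
  independently rather than as a partition, and an event may appear in
  several length strata. An event falling in no configured length bin
  still counts in `ALL` and is flagged in `attr(, "unbinned")`.
* **exons spanned**: 1, 2–5, > 5 distinct padded exons overlapped by
  the event itself.

## Artifact filtering

High-sensitivity caller modes trade precision for recall; the filter
module restores precision with rules whose footprints are observable
caller failure modes:

| rule | drops a call when |
|---|---|
| `SIZE_MIN` | length < 500 bp (dense small-call noise) |
| `SIZE_MAX` | length > 10 Mb (centromere/telomere-spanning artifacts) |
| `JUNCTION_LONG` | junction-only evidence (SVCLAIM=J) and length > 1 Mb — genuine calls that large essentially always carry depth support |
| `GAP_OVERLAP` | ≥ 1 bp overlap with the assembly gap track |
| `RECURRENT_ARTIFACT` | reciprocal overlap ≥ 0.90 with a same-type recurrent artifact |

All rules are evaluated independently and all failures reported, so
rule order can never change the kept set; a call with an unknown
evidence claim is not subject to `JUNCTION_LONG`.

The recurrent-artifact rule has two modes. The default tests reciprocal
overlap directly. The **two-BED mode** reproduces the containment
mechanism used when the downstream filtering tool can only test
interval containment: a call matches a cluster when it contains the
cluster's minimum interval (intersection of member spans) and is
contained by its maximum interval (union of member spans). The two
modes agree on calls shaped like the cluster members and diverge at the
margins — a call at exactly 0.90 reciprocal overlap that pokes beyond
the union interval is dropped by the direct mode but kept by the
containment mode — which is why both are provided and the direct mode
is the default.

`build_artifact_blacklist()` discovers the artifact regions: calls of
the same dosage type are pooled across samples and single-linkage
clustered under the relation "reciprocal overlap ≥ 0.90"; clusters
present in at least `min_recurrence` distinct samples (default 2)
become artifact regions with median-endpoint representatives. The
recurrence threshold and the type-awareness of matching are both
configuration, since neither is forced by the design; type-aware
matching is the default because dosage direction is the benchmark's
universal matching currency. Clustering is order-invariant, and the
test suite checks it against an igraph connected-components oracle on
random cohorts.

## The fixture generator

All tests run on fully synthetic, seed-reproducible fixtures — no
download, no real genome.

`simulate_benchmark_case()` places genes in **private territories**:
each gene owns a margin around its span wider than any planted event,
and territories never overlap, so an event planted on one gene cannot
interact with any other gene's exons. Within that isolation the planted
composition is exact by construction: a chosen fraction of truth events
receive a same-type confirming query (jittered but guaranteed to keep
its anchor exon), direction-mismatch FPs copy a truth span with the
opposite type, unmatched-exon FPs sit on truth-free genes, and ignored
calls fall in deep intergenic space. The generator then recomputes
every event's exon set and status with plain integer arithmetic — no
`GRanges`, no shared code with the engine — and asserts the planted
composition before emitting expectations. The acceptance suite's
"planted-metric recovery" check compares the engine's full stratified
metric table against these independently derived expectations on 100
seeds.

`simulate_reference()` embeds tandem-duplication sites whose recorded
insertion points must verify at identity 1.0 from either flank;
`simulate_artifact_cohort()` plants artifacts at chosen recurrences
with jitter bounded at 1% of event length (keeping all intra-cluster
reciprocal overlaps above 0.95, safely over the 0.90 linkage
threshold) and spaces sites 200 kb apart so clusters cannot merge;
`simulate_filter_case()` plants one call at each rule boundary (499 /
500 bp, 10 Mb / 10 Mb + 1, junction-only vs depth-supported 2 Mb,
in-gap vs near-gap, reciprocal overlaps of exactly 0.92 and 0.89).

What the fixtures do **not** emulate: read-level evidence (no
BAM/FASTQ — the toolkit consumes calls, not alignments), GC and
mappability structure, segmental duplications and paralogy (the cause
of several well-known false-positive classes), overlapping real gene
models, and multi-allelic or genotype-annotated records. Passing tests
therefore demonstrate that the *scoring machinery* is exact under its
definitions, not that any particular caller performs well on real data;
the published performance of real callers on reference cell lines
additionally depends on sequencing depth, alignment and the callers
themselves, none of which are in scope here.

## Scale and determinism

Default problem sizes are chosen so the whole suite runs in minutes on
one CPU: benchmark fixtures use 2 × 5 Mb contigs, 40 genes and ≤ 50
events; oracle-equivalence checks use 100 randomized instances of ≤ 100
events and ≤ 200 exons; identity scoring is cross-checked on 1000
random grid cases. Every generator takes an explicit seed, restores the
caller's RNG state on exit, and is byte-reproducible per seed.

Coordinates are held in Bioconductor's native 1-based closed `GRanges`
convention throughout; BED (0-based half-open) is converted at the
boundary by rtracklayer, and a VCF DEL/DUP record at `POS` with end
`END` spans `[POS, END]` with length `END − POS + 1`. Overlap always
means "at least one shared base": adjacency never matches
(`minoverlap = 1` everywhere).

## Known limitations

* Genotype/zygosity and copy-number magnitude are not compared; dosage
  direction is binary (gain vs loss).
* Insertion verification is ungapped: a true duplication whose copy
  diverged by indels can score below 0.95 and be excluded. The audit
  table makes such exclusions visible.
* Inversions, translocations and breakends are out of scope and are
  reported as skipped records on input.
* Only the first ALT allele of a multi-allelic record is considered.
* The two-BED containment mode is an approximation of reciprocal
  overlap at the cluster margins, as described above.
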