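---
title: "Triage and validation of multi-caller long-read variant calls"
author: "lrtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage and validation of multi-caller long-read variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtriage)
```

# Scope and model

A clinical long-read pipeline runs several specialised callers in
parallel and must reduce their combined output — tens of thousands of
raw calls per genome — to a short reviewable list, then prove its
detection performance on truth sets. `lrtriage` implements exactly this
integration and validation layer. The callers themselves (basecalling,
alignment, the genotyping algorithms) are out of scope; the package
consumes their VCF output through a per-caller *dialect* registry and
models their behaviour, for testing, through detection profiles.

All coordinates are hg19 and held internally as 1-based closed
`GRanges`; VCF positions and 0-based half-open BED intervals convert at
the I/O boundary. Contig names are normalized to `chr`-prefixed form on
ingest because caller dialects disagree. Strand is stored on gene
records but all overlap tests are strand-agnostic: the filters operate
on genomic coordinates only.

# The routing policy

Each caller is trusted only inside a declared size band, encoded in a
`RoutingPolicy`:

| parameter        | default | meaning                                        |
|------------------|---------|------------------------------------------------|
| `smallMaxSize`   | 50 bp   | small-variant genotyper: `|size change| < 50`  |
| `bridgeMin/Max`  | 50–100  | bridging SV caller window `[50, 100)`          |
| `svMinSize`      | 100 bp  | primary SV caller floor (inclusive)            |
| `q0Max`          | 0.5     | depth segments: low-mapQ read fraction, strict |
| `pNMax`          | 0.5     | depth segments: reference-N fraction, strict   |
| `pMax`           | 0.001   | depth segments: depth-deviation p, strict      |

The policy validates that the bridging window abuts both neighbours —
no gap and no overlap in the declared ranges — so every SV size has
exactly one trusted caller. Where the routine descriptions of the size
split are loose ("> 50 bp"), the operational statement of the bridging
policy (bridge between the 50 bp maximum of the small-variant caller
and the 100 bp floor of the primary SV caller) is taken as definitive.
Breakend calls have no length and pass the breakpoint callers'
restriction unconditionally. The two read-depth callers partition the
genome: one sees only autosomes, the other only chrX/chrY, the latter
with the three segment-quality thresholds applied strictly.
Sex-chromosome segments missing any required annotation are quarantined
into the ingest report rather than silently dropped: a clinical
pipeline must surface malformed caller output.

# The filtering cascade

`runTriage()` executes, in order: per-caller restriction, depth-segment
filtering, cross-caller merging, the mechanistic gene-impact filter,
phenotype-gene intersection, and the ordered logic rules. Each stage
logs input/output counts into a `FunnelReport`; monotonicity
(`n_out <= n_in`, chained) is enforced by the class validity.

**Gene impact.** Every call is classified against every gene it
touches, into exactly one of seven classes. The decisive design choices:

* `whole_gene_contained` requires both call endpoints strictly outside
  the gene span *and* containment of every exon. For inversions this
  class is dropped by default — a complete gene inversion with
  intergenic breakpoints leaves the transcript intact — while for
  deletions/duplications (and depth losses/gains) it is kept, because
  whole-gene dosage change is mechanistically disease-causing.
* `partial_coding_disruption` is reserved for inversions overlapping a
  *proper* subset of exons; these advance.
* `intronic_near_splice` uses a 100 bp default (`nearSpliceBp`). The
  value is chosen so that a clinically decisive intronic insertion
  sitting 49 bp from a splice boundary survives the default filter with
  margin, while deep-intronic noise does not.

The keep/drop decision is a complete matrix over (call type × impact
class), supplied by `defaultImpactRules()` and fully user-overridable;
an incomplete matrix is a configuration error at load time, never a
silent pass-through.

**Merging.** Calls of the same type from *different* callers merge when
their reciprocal overlap is at least 0.5 (single linkage); small
variants merge only on exact CHROM/POS/REF/ALT identity, breakends only
on identical breakend and mate coordinates. The 0.5 reciprocal
threshold is the field's convention for SV comparison. The merged
representative is the highest-quality member; ties break by the
caller priority order declared in the policy, then by leftmost start,
making the merge deterministic. Merging is idempotent (verified by
test).

**Logic rules.** The final step is an ordered list of declarative
predicates (size caps/floors per type, minimum caller support, quality
floors, region include/exclude lists) loaded from configuration. The
cascade's last stage is deliberately *data*, not code: the precise rule
set of a deployed pipeline is site-specific and under-specified in
public descriptions, so the shipped default reproduces only the
documented per-caller and size constraints, and every rule logs its own
funnel line for auditability.

# Concordance statistics

Truth matching is exact and genotype-blind on CHROM/POS/REF/ALT, with
each truth record matched to at most one query record. Per-stratum
detection proportions carry two-sided **Wilson score intervals**
(normal quantile at 97.5% for 95% confidence). The Wilson interval was
chosen over Wald/Clopper–Pearson because it behaves sensibly at
$\hat p \in \{0, 1\}$ — the typical regime for small clinical panels —
and because it reproduces, at printed precision, all six published
interval endpoints of the validation table this package's tests pin
(e.g. 25/26 → 0.811–0.9932; 166/167 → 0.9669–0.9989). The
implementation is closed-form; the test suite checks it against an
independent root-finding inversion of the score equation to 1e-9.

Two aggregate numbers deserve care:

* The count-weighted aggregate sensitivity
  $\sum_i s_i n_i / \sum_i n_i$ over per-type sensitivities.
* `sensitivitySpecificity()` reports specificity as
  $1 - \mathrm{extra}/(\mathrm{region\ bp} - \mathrm{truth})$ and
  always returns the denominator alongside, because a specificity
  exceeding 99.99% is meaningless without it. The evaluated-region size
  is a user input, not a constant.

The haplotype-caller filter keeps records with VAF > 0.2 and
quality > 1 (both strict); records missing either annotation are
dropped with a warning.

# Repeat typing

Tract sequences (pre-extracted spanning reads; alignment is out of
scope) are decomposed by a greedy left-to-right scan against a
priority-ordered motif list: reference motif first, then pathogenic,
then interruption motifs. At each offset, a window equal to a motif
opens or extends a run and advances one unit; otherwise one non-motif
base is emitted. Because all motifs at a locus share one unit length,
the greedy scan selects a maximum set of disjoint motif occurrences
(equal-length interval scheduling), so it minimizes non-motif bases; a
dynamic-programming oracle in the test suite verifies this equivalence
on random mosaics. Decomposition output tiles the input exactly,
byte-for-byte.

Genotyping clusters per-read total copy numbers with 1-D two-means,
deterministically initialized at the minimum and maximum observed
values; no random restarts, so results are reproducible. Clusters whose
centers end within 3 copies merge into a homozygous call; the 3-copy
merge distance and the 4-read spanning floor are conventions chosen for
desk-scale data and are both arguments. Allele copy number is the
cluster median (robust to the occasional mis-segmented read); the
dominant motif is the motif with the plurality of copies across member
reads, ties broken by the locus priority order.

Classification requires **both** size and content: `pathogenic` iff the
dominant motif is in the locus's pathogenic set *and* copies strictly
exceed the threshold; expansion without conversion is
`expanded_nonpathogenic_motif`; conversion without expansion is
`intermediate`. The truth table is total — every (motif, copies) pair
maps to exactly one class. For an RFC1/CANVAS-style locus the defaults
are normal range 11–200 copies and threshold 400; the pathogenic motif
set is configuration because the full set of pathogenic pentanucleotide
units is locus knowledge, not algorithm.

# Synthetic fixtures

`simulateTruthSet()` emulates the study conditions of a clinical
validation cohort: the default roster plants 80 SNVs, 26 indels (1–36
bp), 32 SVs cycling DEL/DUP/INS/INV/BND (spans log-uniform, 50 bp to
100 kb), and 29 repeat loci cycling CAG (with CAT interruptions), GAA,
AAAAG→AAGGG, CTG and CGG locus archetypes, on a 60-gene phenotype panel
(4–12 exons of 100–300 bp per gene). Planted variants keep at least
1 kb spacing so exact-match semantics stay unambiguous. Caller
emulation selects detected subsets (exact k-of-n by seeded shuffle for
pinned detection counts such as 27-of-29, Bernoulli draws otherwise),
adds false calls at a per-megabase rate, and never perturbs detected
coordinates. Repeat reads perturb the planted copy number with a 2%
coefficient of variation by default — the scale of length noise in
spanning long reads.

A single integer seed drives an explicit hierarchical stream (one child
seed per generator), so adding a generator never changes the output of
an existing one, and identical configurations are byte-identical.

What the fixtures do **not** emulate: base-level sequencing error,
alignment artefacts, coordinate jitter between callers describing the
same event (detected records keep truth coordinates), homopolymer
context, segmental duplications, or real pseudogene homology. Passing
tests therefore demonstrate the correctness of the routing, filtering,
merging, matching and genotyping logic under the declared conditions —
not the field performance of any external caller on real reads.

# Problem sizes and runtime choices

The test suite and the acceptance script are sized for a single CPU:
funnel fixtures use rosters of 20–50 planted variants with seeded false
calls in the thousands (the per-caller false rates are scaled from the
raw-call volumes a multi-caller pipeline produces, preserving their
relative proportions); the repeat-recovery study runs 200 seeded
replicates with planted alleles spanning 10–1,000 copies at depth 10
per allele, requiring both alleles within 5% of truth in at least 95%
of replicates; the benchmark-scale exact-match fixture uses 26,584
truth records. These sizes were chosen as the smallest that exercise
every code path and stabilise the stochastic checks.

# Degenerate inputs and edge policies

* Empty call sets, empty rosters and header-only VCFs flow through
  every stage and produce empty, valid outputs.
* Records a dialect cannot interpret (unknown symbolic ALT, missing
  SVLEN/END, non-ACGTN alleles) are quarantined into the ingest report
  with a per-record reason; structural file corruption is a parse error
  naming the line.
* `computeN50` errors on empty input; zero-run repeat reads have copy
  number 0; a CAT-only tract is all interruption.
* Genotyping below the spanning-read floor errors, naming the locus —
  a silent low-coverage genotype would be a clinical hazard.

# Known limitations

* Exact matching does not left-normalize indels against a reference
  sequence (no reference is stored); planted fixtures are constructed
  unambiguously, but real-world VCF pairs with inconsistent indel
  representations would need upstream normalization.
* SV truth comparison beyond exact coordinates/reciprocal overlap
  (distance-based or haplotype-aware matching) is out of scope.
* The two-allele clustering assumes a diploid locus; mosaicism and
  somatic length instability are not modelled.
* Depth-caller emulation generates bin-aligned segments only; the
  package does not model partial-bin events.
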