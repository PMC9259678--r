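---
title: "Methods: consolidating multi-assembler transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consolidating multi-assembler transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metamerge` consolidates the pooled output of several de novo transcriptome
assemblers into a non-redundant reference. This vignette records the
package's own account of the method: the procedure and its assumptions, the
parameters that matter, the numerical conventions, what the synthetic data
generator does and does not emulate, and the design choices made where the
method left room.

## The consolidation chain

De novo assemblies of the same RNA-seq reads by different algorithms agree
on the well-expressed transcripts and disagree on everything else. Pooling
them maximizes sensitivity at the price of severe redundancy, which this
chain removes in five stages. The order matters: expression filtering first
(it needs the original per-assembly transcript ids that quantification was
run against), then sequence-level collapse, then gene-level organisation,
then the two clean-up filters.

**Stage 1 — per-condition expression filter** (`expression_filter()`,
floor: 1 TPM). A transcript survives if *any* level of *any* declared
experimental factor has arithmetic-mean TPM at or above the floor. The
"any condition" reading is deliberate: the filter's purpose is removing
assembly artifacts, and requiring the floor in *all* conditions would
delete genuinely condition-specific transcripts (winter-only or
summer-only expression is exactly what downstream differential analyses
look for). Level aggregation is the arithmetic mean of TPM — the simplest
convention, stated so oracles are unambiguous. "At least" is boundary
inclusive. Transcripts missing from a quantification file count as 0 TPM
(assemblies and quantifications are often regenerated independently)
rather than raising an error.

**Stage 2 — greedy identity clustering** (`greedy_cluster()`, floor: 0.95).
A re-implementation of greedy incremental clustering in the CD-HIT-EST
tradition: records are visited in descending length order (ties broken by
ascending id, which makes the output invariant under input permutation);
each record joins the first cluster whose representative it reaches at the
identity floor on either strand, otherwise it founds a new cluster. The
first-hit rule is the classic greedy behaviour; `best_hit` is available as
a parameter. Because the representative is always the longest member,
every exact duplicate, mutated copy and contained fragment of an earlier,
longer record collapses here.

**Stage 3 — gene consolidation** (`consolidate_genes()`). A deliberately
simplified stand-in for coding-sequence-driven consolidators: the longest
ATG-initiated ORF (six frames, minimum CDS 90 nt) defines each
transcript's coding sequence; coding transcripts are grouped by single
linkage over CDS identity at the `altmid` floor (0.90); the group's
primary is the longest-CDS member; others are `althi` (CDS identity
at least 0.98), `altmid`, or `part` (CDS shorter than 70% of the primary
CDS — overriding the alternate labels); ORF-less transcripts are singleton
`noncoding` groups. The 0.98/0.90/0.70 defaults are explicit stand-ins
that echo the "high/medium alignment to primary" and "partial incomplete"
category semantics; no published values exist for them, and all are
parameters. `althi1` and `althi` are merged — the distinction has no
published definition. The coding flag is driven solely by ORF presence at
the minimum CDS; there is no hexamer or codon-usage model, so random
long-UTR ORFs occasionally classify a non-coding sequence as coding. The
default `select_okay_set()` profile drops nothing (filtering belongs to
stages 4-5); `drop = c("part", "noncoding")` profiles are available.

**Stage 4 — containment pruning** (`containment_prune()`, trigger:
coverage strictly above 0.90). All-vs-all matching by shared 15-mers,
chained on diagonals, verified as ungapped blocks at 95% identity,
extended while bases match, projected onto the shorter sequence and
merged; the covered fraction is the union length over the shorter length.
Any record covered for more than 90% of its length by a strictly longer
record is removed in a single pass against the original set — a fragment
contained only in another removed fragment is still removed, which is what
post-processing an all-vs-all alignment report once produces. Equal-length
mutual containments keep the lexicographically smaller id ("longer
transcript" leaves the tie undefined). The 95% block-identity floor is an
explicit assumption (the original local-alignment step published no
cutoffs) and is a parameter. There is no e-value model: at these scales a
seed-and-extend identity floor replaces alignment statistics.

**Stage 5 — mean-abundance filter** (`mean_abundance_filter()`, floor:
0.1 TPM). Mean across all samples; "below 0.1" is discarded, so exactly
0.1 survives.

**miRNA screening** (`call_candidates()`) combines an externally computed
hairpin-classifier score (lower = more hairpin-like; threshold 0.71,
inclusive) with an internally computed mature-miRNA match: every
full-length ungapped placement on either strand with Hamming distance at
most 2. At mature-miRNA lengths (~22 nt) a gapped alignment with at most
two mismatches is effectively a full-length ungapped match, and the
ungapped reading makes the matching rule exactly testable. Scoring models
are out of scope by design: the package tests the combination rule, not
the classifier.

## Alignment and identity conventions

"Identity" throughout is: matched bases of the optimal semi-global
alignment divided by the length of the shorter sequence. Semi-global means
the shorter sequence aligns end to end while the longer sequence's
leading/trailing overhangs are free — so an exact substring has identity
1.0, which is the convention nucleotide clusterers use and the reason
containment collapses into clustering when identity is high enough.

The alignment objective had to be pinned down for exact testability:
match +2, mismatch −1, linear gap −3; among equal-score alignments the one
with the most matched bases defines the identity. The implementation packs
(score, matches) into one 64-bit integer per DP cell so the lexicographic
maximum is a single comparison; an independent plain-R DP and a
general-purpose aligner corroborate it in the test suite. `N` never
matches, not even `N` vs `N`, and non-`ACGTN` characters are rejected at
ingest rather than masked, to surface upstream corruption early.

The k-mer prefilter used before any DP is a necessary-condition bound: an
alignment at identity *c* over shorter length *L* leaves at most
⌊(1−c)·L⌋ non-matching shorter positions, each destroying at most *k*
shared k-mers, so at least (valid k-mer positions) − k·⌊(1−c)·L⌋ distinct
shared k-mers must remain. Pairs below the bound are skipped. The bound is
only informative when k·(1−c) < 1 — hence word size 11 at the 0.95
clustering floor but word size 9 for the 0.90 consolidation linkage. The
argument assumes substitution-dominated divergence; long insertions in the
longer sequence could in principle evade it, and the suite asserts
prefilter-on/off equality on its fixtures rather than claiming a universal
theorem.

Other numerical conventions: N50 uses descending cumulative sums with an
"at least half" threshold, returning the length at first crossing; the
median of an even-sized length set is the mean of the two central values
(no published convention to follow); %GC excludes `N` from numerator and
denominator; ORF ties prefer the forward strand, then the smaller frame,
then the smaller forward-strand start; open-ended ORFs at contig edges are
allowed but flagged incomplete; the standard genetic code is assumed.

## What the synthetic generator emulates

`simulate_transcriptome()` builds gene families as an in-frame CDS core
(35–60% of the shortest isoform, never above the 70% `part` boundary)
flanked by isoform-specific UTRs. That geometry is the load-bearing
choice: true alternates share their CDS (so consolidation groups them and
the planted gene partition is recoverable) while differing over enough of
their length that they are neither collapsed at the 0.95 clustering floor
nor pruned at the 0.90 containment trigger. Duplicates are parent copies
mutated at 1% per base (safely inside the clustering floor); fragments are
exact contiguous substrings at 93–99% of the parent (half
reverse-complemented), so containment ground truth is analytic; the
fragment coverage is recorded to 3 decimals in the manifest. Contaminants
are independent random sequences designated unexpressed. Expression is
log-normal per transcript (baseline meanlog log 50, sdlog 1.2) with a
log-normal per-season effect (sdlog 0.5), per-sample noise (sdlog 0.3) and
10% dropout, renormalized to one million TPM per sample. Default scale is
about 2,000 records (550 genes, 1–4 isoforms each, lengths log-normal with
median ~1.2 kb truncated to 300–6,000 nt, GC target 36%) across 12 samples
structured by season, area and sex. One master seed drives derived
substreams (+1 transcriptome, +2 expression, +3 miRNA fixture), so every
artifact is byte-reproducible.

What it does *not* emulate: read-level sequencing error and coverage
dips, chimeric misassemblies, strand-specific library artifacts, paralog
families at intermediate identity, and real UTR/CDS length correlations.
Passing the planted-structure tests therefore demonstrates that the
filters implement their definitions and interact as intended — not that
the thresholds are optimal for any particular real data set.

In the miRNA fixture, hairpins are arm + loop + reverse-complemented arm
with the mature embedded at a planted mismatch count (0–3 cycled) and
synthetic scores at or below 0.71; decoys score above 0.71, half of them
with an embedded mature so the score condition is load-bearing. Scores are
synthesized stand-ins for an external hairpin classifier — the
combination rule is under test, never the classifier.

## Degenerate inputs and determinism

Empty assemblies, all-`N` sequence sets, unknown factors, samples missing
from the design, dangling representative ids, and malformed quantification
tables (missing columns, non-numeric TPM with the offending line number)
raise immediate validation errors. Writing an empty FASTA is allowed;
computing statistics on one is not. No pipeline stage draws random
numbers, so identical configurations produce byte-identical outputs; the
configured seed is echoed into every stage report purely as provenance for
simulated inputs.

## Problem sizes used by the test suite

Oracle-equivalence tests run 1,000 random length multisets against the N50
counting oracle, ~100 alignment pairs of 30–120 nt against the plain-R DP
oracle and an independent aligner, containment fixtures of up to 60
records against constructed-truth coverages, and a 50×20
transcript-by-mature grid against a sliding-window Hamming oracle.
Recovery tests run the full pipeline on the default ~2,000-record
transcriptome and assert at least 95% removal of planted fragments with
coverage above 0.92, at least 95% precision and recall on intended
survivors, and a gene-partition Rand index of at least 0.95. These sizes
were chosen as the smallest that exercise every code path with comfortable
statistical margins.

## Known limitations

The consolidation categories are CDS-identity approximations of a richer
evidence model (no UTR evidence, no protein-space clustering); containment
coverage has no alignment statistics, so very short spurious blocks at
exactly the identity floor can contribute a few covered bases; the
expression filter's "any condition" reading is a documented
interpretation, exposed as data (the level means) rather than hidden; and
the greedy clustering, like the tool it mirrors, is order-dependent by
construction — made reproducible, not order-free, by the canonical
length-then-id visiting order.
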