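# metamerge

Consolidation of de novo transcriptome meta-assemblies into a
non-redundant reference.

For organisms without a genome — the Antarctic krill *Euphausia superba* is
the motivating case — reference transcriptomes are built by running several
de novo assemblers over the same RNA-seq reads and merging their outputs.
The merged pool is heavily redundant: the same transcript reconstructed by
five assemblers, near-identical mutated copies, fragments contained inside
full-length transfrags, and unexpressed artifacts. `metamerge` implements
the consolidation strategy used to build the krill reference transcriptome
as a reusable R toolkit, for assembly bioinformaticians who need the
filtering chain without the terabyte-scale infrastructure around it.

## The method

The pipeline applies five filters in order, each with the study's
threshold:

1. **Per-condition expression filter.** With per-sample abundances
   \(x_{ts}\) (TPM, from `quant.sf`-style tables) and an experimental
   design mapping samples to levels of factors (season, area, sex), a
   transcript *t* is kept iff
   \(\max_{f,\ell}\; \mathrm{mean}_{s \in \ell}(x_{ts}) \ge 1\) TPM —
   some condition level must reach 1 TPM (boundary inclusive).
2. **Greedy identity clustering** (CD-HIT-EST-style, re-implemented).
   Transcripts are processed longest-first; each joins the first cluster
   whose representative it matches at identity \(\ge 0.95\), where
   identity = matched bases of the optimal semi-global alignment divided
   by the shorter length (both strands). A provably lossless shared-k-mer
   bound prefilters comparisons. Cluster representatives go forward.
3. **Gene consolidation** (simplified tr2aacds-style). The longest
   ATG-initiated ORF is called in all six frames; transcripts are grouped
   by single linkage over CDS identity \(\ge 0.90\) and classified as
   `main` / `noclass` (primary with/without alternates), `althi`
   (CDS identity \(\ge 0.98\) to the primary), `altmid`, `part`
   (CDS < 70% of the primary CDS) or `noncoding`. Gene ids are
   `ESG`-numbered.
4. **Containment pruning.** All-vs-all seed-and-extend matching projects
   matched blocks (ungapped identity \(\ge 0.95\)) onto the shorter
   sequence; any transcript covered for **more than** 90% of its length by
   a longer one is discarded (single pass; exactly 90.0% survives).
5. **Mean-abundance filter.** Transcripts with mean TPM across all samples
   **below** 0.1 are discarded (exactly 0.1 survives).

A separate screening rule flags microRNA precursor candidates: hairpin
classifier score \(\le 0.71\) (lower = more hairpin-like, scores consumed
as input) **and** a full-length ungapped match to a known mature miRNA with
at most two mismatches, on either strand.

Every stage writes a report (`input_n = kept_n + removed_n`, quality
statistics before/after) into a ledger, mirroring per-stage quality tables:
transcript count, %GC (N excluded), median contig length, N50, total bases.

A seeded generator (`simulate_transcriptome()`, `simulate_quant()`,
`simulate_mirna_fixture()`) produces multi-assembler pools with planted
gene families, duplicates, contained fragments and contaminants, plus a
ground-truth manifest, so the whole chain is testable offline.

## Worked example

```r
library(metamerge)

p  <- sim_params(seed = 4, n_genes = 60, contaminant_n = 15, n_samples = 6)
tr <- simulate_transcriptome(p)
qt <- simulate_quant(tr$manifest, p)
res <- run_pipeline(pipeline_config(assemblies = list(sim = tr$assembly),
                                    quant = qt$quant, design = qt$design,
                                    seed = 4))
print(res)
```

```
Consolidation pipeline result
stage                  input_n  kept_n  removed_n  n50_after  gc_after  median_after
expression_filter:sim  237      222     15         1,453      36.21     1,184
pool                   222      222     0          1,453      36.21     1,184
identity_cluster       222      148     74         1,393      36.18     1,183
consolidate            148      148     0          1,393      36.18     1,183
containment_prune      148      148     0          1,393      36.18     1,183
mean_abundance_filter  148      148     0          1,393      36.18     1,183

Final: 148 transcripts, 71 genes
```

Reading the ledger: the 15 unexpressed contaminants fall to the expression
filter; the 74 planted duplicates and contained fragments collapse into
their parents' clusters; the 148 survivors are exactly the planted primary
and alternate isoforms, grouped into the 60 planted genes plus singleton
groups for transcripts whose spurious ORFs do not link (71 recovered gene
groups here). On this fixture the later containment and abundance stages
have nothing left to remove — with fragments that survive clustering (for
example at 94% identity to a longer isoform but >90% containment) stage 5
does the work instead.

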