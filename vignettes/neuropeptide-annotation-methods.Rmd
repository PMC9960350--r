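---
title: "Methods: homology-seeded neuropeptide annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-seeded neuropeptide annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npannotate)
```

## The problem

Neuropeptide precursor genes are short, expressed in narrow spatiotemporal
windows, and therefore chronically under-represented in draft genome
annotations of non-model insects. A de novo transcriptome assembly recovers
most of them but severs the link to genomic coordinates, which downstream
expression, copy-number and regulatory analyses need. `npannotate`
implements a desk-scale version of the curation workflow that closes this
gap: known neuropeptide sequences seed homology searches across three
gene-model sets, candidates pass tiered acceptance criteria, surviving
models are verified against the genome by exact translation identity, and
the verified set is released as an augmented GFF3/FASTA and validated by
expression profiles.

## Seeds and selection rules

A *seed* for a neuropeptide is any subset of three sequence roles: mature
peptide(s), precursor protein, cDNA. Seeds come in two provenance tiers.
For a same-species seed, a gene model is accepted as a candidate when

* any mature peptide occurs **exactly** in the model's deduced protein, or
* the local precursor alignment covers at least **70%** of the seed
  precursor, or
* the local cDNA alignment covers at least **60%** of the seed cDNA.

When only another species' precursor is available, the single rule is
precursor coverage of at least **50%**. All thresholds are inclusive
(a coverage of exactly 0.70/0.60/0.50 is accepted) and configurable via
`np_config(thresholds = ...)`. When a model meets several criteria it is
called once, under the highest-priority criterion
(mature > precursor > cDNA); the priority order follows the order in which
the rules are stated, since exact mature-peptide evidence is the least
ambiguous.

**Coverage denominator.** "Alignment length ≥ X%" is computed as the
aligned query-span length divided by the seed (query) length — the BLAST
`qcovs` convention. This keeps coverage in [0, 1] even for gapped
alignments; using raw alignment columns could exceed 1 when the subject
side carries gaps.

**Minimum alignment score.** Coverage tests are only applied to alignments
scoring at least 50 (protein, BLOSUM62 units) or 60 (nucleotide). This
plays the role of an E-value cutoff in a conventional homology search: two
unrelated ~50-residue proteins routinely produce low-identity local
alignments that cover most of the query, and without a score gate those
would enter the coverage test. No E-value statistics are computed;
Karlin–Altschul calibration is out of scope and the raw-score gate is
documented here as the package's substitute, calibrated for the short
precursors (typically 40–150 aa) this pipeline handles.

## The alignment engine

Local alignment is an in-package Smith–Waterman with affine gaps (Gotoh
recurrences), implemented in C++ and used for every search stage. Defaults
mirror BLAST: BLOSUM62 with gap open 11 / extend 1 for proteins (a gap of
length *k* costs open + *k*·extend), and match +2 / mismatch −3 / gap open
5 / extend 2 for nucleotides. `N` scores as a mismatch against every base
including itself — conservative, and irrelevant for N-sparse assemblies.
Traceback prefers diagonal, then subject-gap, then query-gap moves, and the
best cell is scanned subject-major, so reported alignments are
deterministic. The test suite proves the optimal score equal to an
independent pure-R dynamic-programming oracle on hundreds of random pairs.

Genome-level search (`multi_locus_hits()`) deliberately returns **all**
loci above the score threshold, not only the best: on long-read assemblies
the same gene may occur at several loci through segmental duplication, and
all copies belong in curation. Found hits are masked with a
heavily-penalised sentinel character and the scaffold re-scanned.

## Six-frame ORF rescue

De novo transcript sets deduce proteins by a longest-ORF convention. For
short precursors this convention fails in a characteristic way: a chance
ORF in another reading frame outscores the true coding frame, the deduced
protein misses the mature peptide, yet the transcript still matches the
seed cDNA well. `frame_rescue()` re-translates such transcripts in all six
frames and returns the frame whose translation contains an exact mature
match — or, failing that, whose longest M-started ORF aligns to the seed
precursor above the tier threshold. Mature evidence outranks precursor
evidence across frames; remaining ties resolve toward positive frames,
then lower frame magnitude. If the longest-ORF frame itself qualifies the
function reports "no rescue needed", and if no frame qualifies the model
is recorded as a discrepancy — the signature of an inactivating mutation
in the underlying assembly rather than a frame artefact.

ORFs may run to the contig edge without a terminating stop
(`require_stop = FALSE` by default) because draft contigs are frequently
truncated; a flag restores the stricter convention.

## Locus assignment

A candidate model is *placed* at a spliced genomic region **iff**
translating that region (concatenate exons in genomic order,
reverse-complement for minus-strand models, translate frame +1) reproduces
the model's deduced protein residue-for-residue. There is no similarity
slack: one non-synonymous substitution unplaces a model, one synonymous
substitution does not. Two deliberate allowances: a trailing stop residue
in the genomic translation is ignored (ORF predictors omit it), and
identity is required over the full protein rather than the mapped portion
— the stricter reading, chosen because partial-identity placements are
exactly the cases that need a human curator. Spliced alignments are
consumed as input (12-column exon tables or GFF3 exon features grouped by
`Parent`); performing spliced alignment is a mapper's job, not this
package's.

Models mapping to several loci with identical translation are all
retained and flagged `multi_locus`; none is auto-chosen. Unplaced reasons
form a closed set: `no-mapping`, `translation-mismatch`, `partial-exon`
(total exon length not divisible by three).

## Annotation release

Placed models become `gene`/`mRNA`/`exon`/`CDS` features under release IDs
allocated from `GBI_30000` in steps of 100 (both configurable); a placed
model whose span overlaps an existing draft gene on the same strand is
instead attached to that gene as its next `-R<letter>` isoform. Unplaced
models are appended to the genome FASTA as new contigs named by their
release ID, carrying a single-gene annotation. Draft GFF lines are
byte-preserved; new attributes are written ID/Parent/Name first and the
rest alphabetically, which makes a second parse→write round trip
byte-identical — a property the test suite checks on thousands of random
features. Internally all coordinates are 0-based half-open; conversion to
GFF's 1-based inclusive dialect happens only at the file boundary.

## Expression validation

Annotated transcripts are validated against a TPM matrix (transcripts ×
samples; quantification itself is an input contract, not a pipeline
stage). Each row is z-scored; rows that are zero in every sample are
excluded — they cannot be scaled and correspond to unexpressed splice
variants — and constant non-zero rows are excluded by the zero-variance
guard, documented as an extension of the all-zero rule. The population
standard deviation (denominator *n*) is the default, matching common
heatmap z-scoring; `sd_type = "sample"` switches to *n* − 1. Profiles are
clustered by complete-linkage hierarchical clustering on Euclidean
distances, cut at *k* = 3 by default — the number of coarse developmental
patterns one expects to distinguish in a whole-body series (early-high,
steadily increasing, late spike). Cluster labels are renumbered in
dendrogram order so output is stable; the heatmap itself is rendered via
`pheatmap` when available and is presentation only.

## The synthetic study conditions

`default_plant_specs()` fixes the conditions every end-to-end test and the
acceptance script run under: eleven planted neuropeptide genes across four
scaffolds plus one genomic-only fragment —

* eight clean plants mixing strands, 1–4 exons, and the three annotation
  sources (draft-with-exons, reference-mapping, de novo);
* two frame-trick transcripts whose longest ORF is a decoy in another
  frame (the decoy is ten residues longer than the true precursor and the
  construction is verified at generation time);
* one 1-nt genomic deletion (the spliced aligner is assumed to pin CDS
  length, so the last exon absorbs one downstream base and verification
  fails by translation mismatch) and one non-synonymous genomic SNV —
  both with correct transcripts, emulating assembly-level mutations;
* one peptide fragment written into a scaffold with no transcript in any
  set, which must surface as a genome hit without transcript support.

Planted precursors have realistic prohormone architecture — Met start, a
signal-like stretch, dibasic-flanked mature cores with an amidation donor
glycine — so processing-site annotation is exercised; composition is
otherwise uniform-random because no composition model is claimed.
Generated scaffolds are a few kilobases and precursors ~46 residues: large
enough to make chance homology measurable, small enough that the full
suite runs in well under a minute. What passing these tests shows is that
the decision logic is correct under its stated assumptions; what they do
not show is robustness to real-data phenomena the generator does not
emulate — sequencing error, fragmented transcripts, deep paralogy,
non-canonical splice sites, or compositional bias in real precursors.

The packaged 43-row annotation ledger is transcribed from the released
cricket neuropeptide table and drives the tally checks (41 identified, 32
with locus, 9 without, 18 via the draft annotation). The identities of the
eight panel members lacking same-species seeds are not listed in the
source's main text, so panel fixtures mark eight members NO_SEED as a
documented synthetic substitution.

## Numerical and degenerate-input choices

* Thresholds compare with `>=` on exact ratios; the boundary cases
  70/100, 120/200 and 60/120 are asserted at the boundary in the tests.
* Ambiguity codes other than `N` are rejected at parse time; silent
  coercion hides corrupted input.
* Codons containing `N` translate to `X`; trailing partial codons are
  dropped; a frame with no complete codon is a degenerate-input error.
* Empty transcript sets, empty panels, and zero-model merges all produce
  valid empty outputs; a merge with zero models reproduces the draft
  files modulo one header comment.
* Reruns with the same configuration and seed are byte-identical, and
  all artifacts are plain text (TSV/GFF3/FASTA).

## Worked example

```{r example, eval = FALSE}
fx <- generate_genome(default_plant_specs(), scaffold_count = 4, seed = 42)
cfg <- np_config(registry = fx$registry, models = fx$models,
                 genome = fx$genome, alignments = fx$alignments)
run <- np_run_all(cfg)
assignments_table(c(run$placed, run$unplaced))
run$summary
```

## Known limitations

* No E-value statistics; the raw-score gate is a fixture-scale stand-in.
* Coverage uses the single best local alignment; summing multiple HSPs
  (as BLAST `qcovs` does) could rate fragmented homology higher.
* The curation alignment report uses a center-star progressive alignment,
  adequate for the ~20 short sequences it displays but not a general MSA.
* Signal peptides are not predicted, and processing-site annotation is
  confirmatory only — it never accepts or rejects a candidate, mirroring
  the expert-curation role it supports.
* The 60% cDNA rule uses the seed cDNA as denominator; if the intended
  denominator were the model transcript, long-UTR transcripts would be
  rated lower than here.
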