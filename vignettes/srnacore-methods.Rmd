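---
title: "srnacore: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnacore: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Small RNA sequencing of biofluids produces reads of roughly 10–44 nt that
mix host transcripts (miRNA, tRNA fragments, piRNA, snoRNA, Y RNA, ...),
material from microbial co-inhabitants, and reagent contamination.
Three properties make the analysis awkward:

1. **Annotation databases disagree.** miRNA, tRNA, piRNA, lncRNA and
   repeat annotations come from different curated sources whose intervals
   overlap, both within one database (fragmented or redundant entries)
   and across databases (a piRNA entry sitting inside a tRNA locus is the
   classic case). Conventional counters mark reads over such loci
   "ambiguous" and discard or multi-count them.
2. **The source organism of a read is not known in advance.** A 20-nt
   read can match many genomes; deciding whether it is host or microbial
   needs an explicit procedure, not just a best hit.
3. **Reagents contribute sequences.** A no-template control library
   ("environmental sample") captures what the extraction and library kits
   themselves contain, and those sequences must be subtracted from the
   biological samples.

`srnacore` implements the computational core that addresses these three
points: annotation harmonization with RNA-type prioritisation,
environmental filtering, two-pass BLAST-style species identification with
metagenome construction, priority-aware counting with coverage-guided
multimapper placement, and alignment-free differential expression over
exact unique sequences. A deterministic simulator generates every fixture
the test suite needs, so the whole pipeline is testable without
downloading databases or running external aligners.

# Annotation harmonization

## Within-source merging

Features from one database that overlap by at least one base on the same
strand of the same contig are fused into a union feature
(`merge_overlapping_features()`). The union spans its members, its name
joins the member names with `|` in coordinate order, and the member list
is kept in a `members` attribute. Attributes on which all members agree
(such as the `gene_id` of exons of one gene) survive the merge, which is
what lets intron spans be reconstructed afterwards.

Design choices the interval algebra leaves open:

* **Overlap means ≥ 1 shared base** in 1-based inclusive coordinates.
  Book-ended features (one ends where the next begins) do not merge.
* **Merging is strand-aware.** Small RNA identity is strand-specific: a
  read from the plus strand of a locus is a different molecule from its
  reverse complement, so features on opposite strands are never fused.
* The merge report counts a feature as "merged" iff it is a member of a
  union with at least two members, and reports the rounded percentage per
  source.

The implementation reduces intervals with `IRanges`; the test suite
checks it against an independent O(n²) overlap-closure oracle (explicit
pairwise adjacency plus connected components) on a thousand random
instances, along with idempotence and exact base-coverage conservation.

## Cross-source conflicts and the priority schema

Overlaps *across* sources are deliberately **not** merged. They are
resolved per read at counting time by an ordered RNA-type schema,
highest priority first:

```
miRNA > tRNA > rRNA > mRNA > processed_pseudogene > snRNA > snoRNA >
mtRNA > piRNA > lncRNA > vaultRNA > YRNA > other_RNA >
repeat_tRNA > repeat_rRNA > repeat_other
```

The rationale for a fixed order is curation quality: the types near the
top are the best studied, while bulk databases for some of the lower
types are known to contain mis-annotated fragments of other RNAs. Raw
type strings map onto the schema through a synonym table
(`Mt_tRNA → mtRNA`, `exon`/`protein_coding` → `mRNA`, ...); anything
unmapped falls into `other_RNA` and is logged.

## Placing FASTA databases on a genome

Sources distributed as sequence sets rather than coordinates (mature
miRNA catalogues, for instance) are placed by exact, full-length,
ungapped matching on both strands (`place_fasta_on_genome()`); sequences
are normalized to DNA (uppercase, U→T) so RNA-space records match the
genome. Queries with no exact occurrence are reported as skipped rather
than silently dropped; queries hitting more than `max_hits` loci
(default 100, a guard against repeat explosion) keep the first
`max_hits` placements in genome order and are flagged.

## tRNA fragments

tRF annotation is derived by halving each tRNA locus at
`floor(length/2)` from the 5' end, strand-aware: on the minus strand the
5' fragment occupies the higher-coordinate half. Fragment names carry
`-5p`/`-3p` suffixes. The half-split is a configurable convention — real
tRF boundaries vary — but it gives counting a 5'/3' resolution that a
single tRNA interval cannot.

# Environmental filtering

Reads shorter than 15 nt are removed first (`length_filter()`), matching
the shortest biologically interpretable small RNA at usual confidence.
The environmental index (`build_environment_index()`) holds the
deduplicated sequences of the no-template control reads, excluding
patterns below the same 15-nt floor so that a trivially short pattern
cannot wipe out a sample.

A sample read is removed iff it is **identical** to an indexed sequence
or **contains** one as a contiguous forward-strand substring
(`filter_environment()`). Containment in that direction follows from
what the control library measures: a contaminant insert observed in the
control can reappear in a sample read with extra flanking cycles, so the
contaminant is the substring. The reverse direction (sample read nested
inside a longer environmental read) is off by default and available as
`contain_both = TRUE`; reverse-complement matching is deliberately not
performed since library reads are orientation-preserving. Matching is
exact — no mismatches — which keeps the filter conservative and
reproducible.

The decisions are verified against a quadratic every-pattern ×
every-read substring scan at the 10⁴-read scale, and the filter is
checked to be a partition, idempotent, and monotone in the environment
set.

# Species identification

## Two-pass analysis of tabular hits

Species identification consumes BLAST-style tabular hits (outfmt-6 with
a subject-taxid column; rows with multi-valued `staxids` expand to one
hit per taxid). Hits are first binned into an ordered set of taxonomic
groups — host first, then Bacteria, Fungi, Viruses, Archaea, the
protist clades, and `other sequences` — by walking the taxonomy from the
hit's taxid to the root; a hit belongs to the first listed group whose
subtree contains it, and hits in no group are dropped and counted.
Hits above species rank are lifted to their nearest species-or-below
node; those with no species ancestor are counted at their own rank and
flagged.

**First pass** (`first_pass_rank()`): for each read, the *qualifying*
species are those whose hit bitscore is within a tolerance Δ of the
read's best bitscore. A species' *frequency of presence* is the number
of reads (not hits) in which it qualifies — robust against databases
holding many near-identical records of one genome. Species are ranked by
that count, ties broken by ascending taxid.

**Second pass** (`second_pass_assign()`): each read is assigned to the
candidate species (again within Δ of its best bitscore) with the best
first-pass rank. The intuition: when one read cannot distinguish two
species, the evidence accumulated over all reads can. Species absent
from the rank table count as worst rank; remaining ties break by
ascending taxid, so the output is independent of hit order.

Δ defaults to **2 bits**, additive on the bitscore. "Similar score" has
to be formalized somehow; an additive bitscore window is scale-free
across read lengths (a bitscore difference of 2 means the same evidence
ratio regardless of length), and 2 bits corresponds to roughly one
matching base of difference. At Δ = 0 the scheme degenerates to
best-bitscore assignment with rank used only at exact ties — a property
the tests assert.

Identification runs on a uniform random subset of reads (default
**200**, reproducible under a seed) — species identification does not
need every read, and the subset size is the knob trading run time for
sensitivity to rare species.

## Metagenome construction

Species covering **strictly more than 1%** of assigned reads are
selected (`select_metagenome_species()`); the strictness at exactly 1%
is asserted by tests. Their genomes are concatenated into one reference
(`build_metagenome()`) with record descriptions rewritten to
`taxid|species|original_id` — which also disambiguates record-id
collisions across assemblies — and the host genome placed first.
Missing genome files are recorded in the manifest with
`status = missing` rather than failing the run. Per-species read counts
are exportable as Krona-compatible text (count + tab-separated lineage).

# Counting

## Multimapper placement

Small RNA reads commonly map to several loci. `reassign_multimappers()`
keeps one placement per read using local coverage: a candidate's weight
is the number of already-placed read starts within ±50 nt on the same
contig and strand. Pass 1 weights by uniquely mapped reads; pass 2
recomputes weights including the pass-1 placements, letting
multimapper-only clusters attract their own members. Ties break to the
lowest (contig, coordinate), and uniquely mapped reads never move. The
window and pass count are parameters (50 nt, 2 passes by default — the
window is on the order of a small RNA locus). This is a deliberately
simple coverage-guided scheme with the contract of the established
multimapper resolvers (one placement per read, decided by local
evidence), not a reimplementation of any of them.

## Priority-aware counting

`count_with_priority()` gives each placed read to exactly one row: among
the features it overlaps (≥ 1 base, strand-aware by default), the one
whose priority class is best; within a class, the feature with the
largest overlap, ties by lowest start. Reads overlapping no feature but
lying within an mRNA gene span count as `__intronic__`; all other
unplaced reads count as `__unannotated__`. There is **no ambiguous
category by construction** — the resolution is total — and the matrix
total equaling the number of counted reads is the measurable form of
that claim (a multi-counted read would inflate it). "Intronic" is
defined here as within-gene-span-but-off-feature; callers who prefer to
pool introns with unannotated reads can sum the two reserved rows.

## Strategies

Two ways of combining host and metagenome alignments are provided
(`orchestrate_strategy()`):

* **successive** — host placements consume reads first; only reads with
  no host placement are assigned from the metagenome. Conservative
  toward the host: a read that maps to the host imperfectly but to a
  microbe perfectly stays host.
* **metagenome** — one combined placement pool; per read only the
  candidates with the fewest mismatches survive before coverage-guided
  placement. The same conflicted read goes to the microbe, because the
  competition is decided by alignment quality across all genomes at
  once.

Categories (`host_annotated`, `host_intronic`, `host_unannotated`,
`other_species`, `unidentified`, plus the upstream filtered count)
partition the input reads, and the summary row reports them as
percentages that sum to 100.

# Alignment-free differential expression

`collapse_sequences()` builds a unique-sequence × sample count matrix
directly from read strings — expression of *exactly identical*
sequences, no reference involved. The **keep-hits** filter
(`filter_keep_hits()`) keeps rows with count ≥ 2 in ≥ 2 samples by
default; the precise semantics (count `c` in at least `m` samples) are
this package's definition of the dataset-reduction knob, chosen because
it is monotone, cheap, and symmetric across groups.

`differential_expression()` fits the standard negative-binomial count
model: relative-log-expression (median-of-ratios-style) size factors,
tagwise dispersion estimation with empirical-Bayes shrinkage, an exact
NB test of the two-group effect (via edgeR), and Benjamini–Hochberg
adjustment. The engine was selected for small-sample calibration: under
a null NB simulation at the scale the tests use (2,000 rows, 5 + 5
samples, mean 100, dispersion 0.1 — a typical biological dispersion),
its raw p < 0.05 fraction sits near the nominal level, which the
acceptance tests assert together with ≥ 90% recovery of an 8-fold spike
at BH-adjusted p < 0.05. The same engine serves feature-count and
sequence-count matrices, and a unit test cross-checks its fold-change
estimates and calls against an independent DESeq2 fit. The fit path
contains no randomness: identical matrices give identical tables.

Significant sequences are capped at **1,000 per direction**
(`select_top_sequences()`), each side ordered by adjusted p (ties:
smaller |log2FC|, then lexicographic — a documented, deterministic
order). The capped set is clustered greedily
(`cluster_and_consensus()`): sequences are visited by decreasing total
count, each joining the first centroid with global-alignment identity
≥ 0.8 (identity = matches / alignment columns under unit-cost
Needleman–Wunsch with gap opening 2, extension 1), else founding a
cluster. The consensus is the per-column majority over the
centroid-anchored alignment (ties alphabetical; insertions relative to
the centroid ignored, so consensus length equals centroid length);
members below threshold identity to the final consensus are flagged
borderline rather than silently kept. Greedy centroid clustering
replaces an external multiple-alignment tool on purpose: at ≤ 2,000
capped sequences it preserves the contract (a partition plus a
consensus per cluster) without an external binary, at the cost of
order-dependence that the count-ranked visiting order makes
deterministic. Selected sequences get a preliminary source label
(`human` / `bacterial` / `other` / `unknown`) from the taxon group of
their best hit.

# The simulator

`make_toy_references()` + `simulate_reads()` +
`simulate_environment_sample()` generate everything the tests consume:

* a random host genome (default 100 kb) with four annotation sources —
  a miRNA-only source, a tRNA source, a piRNA source with several piRNAs
  **nested inside tRNA loci** (the cross-source conflict the priority
  schema exists for), and a gencode-like source with overlapping mRNA
  exons grouped into genes (so introns exist), rRNA, snoRNA and lncRNA;
* microbial genomes (default two bacterial species) and a separate
  reagent-contaminant genome behind the environment library;
* a toy taxonomy containing the default group roots that the fixtures
  exercise;
* reads: 10 samples (5 test + 5 control) × 10,000 reads by default,
  uniform lengths 10–44 nt, strand-aware, drawn from features (with a
  configurable fraction of *canonical* reads — a feature's 5' end up to
  22 nt, identical at every draw, modelling the fact that mature small
  RNAs recur as exact sequences), plus genome-background and microbial
  fractions, optional substitution errors, and a planted fold change on
  a few miRNAs so differential expression has signal;
* an environment library mixing contaminant-genome reads with planted
  exact copies and ≥ 15-nt prefixes of sample reads, so the filter has
  true positives of both removal kinds with known identity.

Truth labels ride in the read id (`species|feature|type|pos|serial`), so
evaluation needs no side lookup. Everything is deterministic under the
config seed, and sampling restores the caller's RNG state.

`naive_align()` is the in-package stand-in for an external
aligner/BLAST: an exhaustive substitution-only search (dictionary
matching with a trusted band for the exact case; per-pattern scanning
when mismatches are allowed) reporting *all* placements and a hit table
whose bitscore proxy is `2·matches − 3·mismatches` — monotone in
matches and shaped like a match/mismatch score, but not a real BLAST
bitscore. Tests pin it to a brute-force quadratic scan on 1-kb
references.

**What the simulator does not emulate** — and therefore what passing
tests do not show about real data: indels and sequencing-quality decay
(errors are substitutions only), realistic expression distributions
(feature usage is near-uniform plus planted effects), homology between
genomes (toy genomes are i.i.d. random, so cross-species false matching
is rarer than between real genomes), isomiR end-variation, and real
annotation pathologies beyond the planted overlap patterns. Species
sensitivity/specificity measured on the toy control (≥ 95% asserted for
error-free reads ≥ 18 nt) should be read as validating the assignment
logic, not as a performance claim for real databases.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere in the public data model.
* Every ranking has a total, documented tie order (taxid ascending,
  coordinate ascending, lexicographic), so all outputs are
  order-invariant and byte-reproducible; the pipeline test asserts
  byte-identical report directories for identical inputs.
* Zero annotated reads make type percentages `NA` rather than 0;
  an empty environment set makes filtering a warning-carrying no-op;
  an empty keep-hits result short-circuits the DE stage; a tRNA shorter
  than 2 nt is skipped with a warning; a species with a missing genome
  file is a manifest row, not an error.
* Subset sampling derives from a single integer seed and restores the
  caller's RNG state.

# Test problem sizes

The suite runs the full study design (10 × 10,000 reads) once for the
zero-ambiguity check, a thousand random interval sets (up to 1,000
intervals each) for the merge oracle, a 10⁴-read instance for the
environment-filter oracle, 2,000-row matrices for DE calibration and
power, and a reduced study (4 × 800 reads) for the end-to-end
determinism and recovery checks. These sizes were chosen to exercise the
asymptotics that matter (dictionary search, interval reduction,
dispersion shrinkage) while keeping the suite fast enough to run on
every change.

# Known limitations

* The environment filter is exact-match only; a contaminant read with a
  sequencing error in the sample survives the filter.
* The coverage-window multimapper scheme is intentionally simpler than
  dedicated resolvers; it has no probabilistic model of loci.
* Greedy clustering depends on the visiting order (made deterministic by
  count ranking) and anchors the consensus to the centroid length.
* The two-pass assignment operates at species level; strain-level
  resolution is out of scope.
* isomiR analysis, quality trimming, and interactive visualisation are
  outside this package; it consumes trimmed reads and emits tables.
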