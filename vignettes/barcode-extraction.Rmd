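---
title: "Extracting and error-correcting synthetic cellular barcodes with tagtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and error-correcting synthetic cellular barcodes with tagtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Synthetic DNA barcodes — lineage-tracing tags, combinatorial Pro-codes, sgRNAs —
are read out by amplicon or transcriptome sequencing and must be recovered from
raw reads before any clonal analysis can start. Two practical obstacles stand in
the way. First, the barcode has to be *located*: either by matching reads
against a list of known sequences (reference-based) or by exploiting the
construct's structure — conserved flanking sequence, a partially fixed internal
pattern, an expected length — when the inserted sequences are random
(reference-free). Second, sequencing errors scatter each true barcode into a
cloud of low-frequency variants that must be merged back before counting, or
the library complexity is overestimated by orders of magnitude.

`tagtrace` implements both extraction routes and a two-stage error-correction
algorithm, and emits per-sample (bulk) or per-cell/per-spot (single-cell,
spatial) barcode count matrices as CSV and H5AD.

## Extraction

**Reference-based.** With tolerance 0, reads are scanned for exact occurrences
of any reference with a multi-pattern automaton (constant-width references are
matched in a single pass; the leftmost hit wins). With tolerance
$t \ge 1$ each reference is aligned semi-globally — the reference spans fully,
gaps are free at both read ends — and a read is assigned to the reference with
the unique minimum edit distance $\le t$. Reads matched by two references, or
with two references tied at the minimum, are discarded as ambiguous rather than
double-counted: quantification integrity is preferred over sensitivity.
Internally the tolerant search is pruned by a pigeonhole filter: each reference
is cut into $t+1$ disjoint chunks, and since $\le t$ edits cannot touch all
$t+1$ chunks, only references with one chunk occurring exactly in the read need
full alignment. This is a pure optimisation — tests verify agreement with an
exhaustive dynamic-programming oracle.

**Reference-free.** The barcode is located from its context: a 5' and/or 3'
flank, an optional masked pattern over `{A,C,G,T,N}` (`N` = free position), and
an optional length interval. With tolerance 0 the flanks must occur verbatim;
with tolerance $\ge 1$ each flank gets its own edit budget (the budgets are per
flank, not shared, matching adapter-trimming convention) and is placed by
semi-global alignment. Among equal-distance placements the aligner prefers the
one with the fewest indels, then the innermost position: under the dominant
error process (substitutions) a boundary error can otherwise mimic a cheaper
single-indel alignment and silently shift the extracted window. The barcode is
the interval strictly between the two flank alignments; overlapping or inverted
flanks discard the read. An `N` in the extracted barcode is only accepted where
the mask itself has an `N`.

When flanks are matched with tolerance $t$, a legitimate alignment can shift
the window by up to $t$ bases; we therefore recommend a length interval of
$L \pm t$ rather than an exact length, letting the correction stage (below)
merge shifted variants. The package's own benchmark does exactly this.

## Error correction

Correction takes the per-sample tallies of distinct barcodes and a distance
threshold $K$ (plus an optional *ratio* gate) and proceeds in two stages.

**Fingerprint pre-clustering.** Each barcode of length $L$ is split into $K+1$
disjoint fingerprints of length

$$n = \lfloor L / (K+1) \rfloor,$$

taken at offsets $0, n, \dots, Kn$ (tail bases beyond $(K{+}1)n$ are ignored).
By the pigeonhole principle, $\le K$ mismatches cannot hit all $K+1$ chunks, so
two barcodes within Hamming distance $K$ always share one fingerprint at the
same offset. Barcodes are grouped into the connected components of the
"shares a fingerprint" relation — a transitive closure computed with a
union–find over offset-tagged fingerprint keys. The guarantee is one-sided by
design: pre-clustering may join barcodes farther than $K$ apart (refinement
separates them) but never splits a pair within $K$. For variable-length barcode
sets chunk offsets are not comparable across lengths, so all sliding $n$-grams
(with $n$ from the minimum length) are used instead; the pigeonhole argument
carries over to edit distance.

**Forest refinement.** Within each pre-cluster, barcodes are processed in
descending global count order (ties broken lexicographically, making the whole
procedure seed-free and permutation-invariant). The first barcode roots a tree.
Each subsequent barcode is compared to all existing roots — Hamming distance
for fixed-length sets, Levenshtein otherwise — and attached as a child of the
*nearest* root if that distance is $\le K$ and the ratio gate passes
(`root count >= ratio × candidate count`, when set); otherwise it starts a new
root. Children never become attachment targets, keeping trees single-level and
the number of comparisons small. Nearest-root ties go to the higher-count root,
then lexicographic. When the gate fails for the nearest root the candidate
becomes a new root rather than trying a farther root: the gate expresses "this
variant is too abundant to be an error of that specific parent", and falling
back to a worse parent would contradict it.

Clustering is *global* — distances and ordering use counts summed over all
samples — while count correction is per sample: within each tree every sample's
child counts are added to the root. A barcode that is locally rare in one
sample but dominant elsewhere is therefore rescued instead of being absorbed
into a neighbour, which matters most in single-cell data where per-sample
sampling is shallow. Counts are conserved per sample by construction, and
$K = 0$ is the identity transform. In UMI data, counts entering correction are
molecule counts (after UMI collapsing), not raw read counts.

Pre-clusters are disjoint, so refinement over them is order-independent; the
implementation processes them sequentially, and a determinism test verifies
invariance under permutation of the input.

## Read processing

A read passes QC when at least `min_fraction` of its bases have PHRED score
$\ge$ `phred_threshold` (bases exactly at the threshold pass). With a cell/spot
whitelist, only whitelisted cells are scanned. For UMI technologies, the
dominant barcode per (sample, cell, UMI) — highest summed read support, ties to
the lexicographically smallest — is kept as a single molecule; raw support is
retained as a diagnostic column. Exact UMIs only are collapsed; similarity-based
UMI networks are out of scope.

Two optional pre-filters remove artifacts: an absolute cutoff on (cell, UMI,
barcode) read support, applied before UMI collapsing, and a relative-abundance
cutoff over the pooled dataset. The relative filter's position is configurable
(`stage`): the default runs it before correction, but for benchmark-style data
we run it *after* correction — multi-error reads leave low-count clusters that
are only identifiable as junk once genuine 1–2-error reads have been merged
into their true barcodes, and filtering first would bias counts downward.

## Clone assignment

Cells carrying combinatorial tags are assigned to clones by comparing the set
of detected tags $D$ (count $\ge 1$ by default) against each clone's expected
set $E$ with the Jaccard index $|D \cap E| / |D \cup E|$, which penalises
dropout and spurious tags symmetrically; an overlap-over-expected alternative
($|D \cap E|/|E|$) is selectable. The best clone is assigned iff its similarity
reaches the cutoff (default 0.75, a practical balance between dropout tolerance
and misassignment risk); ties leave the cell unassigned.

## The simulator, and what it does not emulate

The simulator generates a barcode library by rejection sampling (length $L$,
minimum pairwise Hamming distance $d$), assigns per-sample abundances
(uniform with deterministic remainder, multinomial "random", sorted-normal, or
power-law $\propto \text{rank}^{-\gamma}$, all apportioned exactly by largest
remainder), optionally adds PCR chimeras (prefix of one barcode + suffix of
another at a random split, the shape of a template-switching artifact; counts
are a floored fraction of the parent's, and chimeras are exempt from the
distance constraint but flagged in the truth table), and writes
`flank5 + barcode + flank3` reads as FASTQ plus a ground-truth CSV and a
true-barcode FASTA.

Controlled mode emits error-free reads at constant Q40 for exact round-trip
validation. Empirical mode applies i.i.d. per-base substitutions across the
whole read (flanks included) and writes constant Q37 qualities. The defaults
are the package's validation conditions: 4 samples sharing 500 barcodes of
60 bp at minimum distance 6, fixed 20-bp flanks, 200 reads per barcode per
sample, substitution rate $10^{-3}$. All randomness flows from the single
config seed; identical configs give byte-identical FASTQ.

Deliberate simplifications, and hence what passing tests do *not* show about
real data: no indel errors (real flank/barcode indels are handled by the
edit-tolerant matchers but are not exercised end-to-end), no quality-score
structure (the error process is independent of the printed qualities), no
position-dependent error profile, no single-cell read architecture (cell
barcode + UMI layouts are supported in extraction but the simulator emits bulk
amplicons), and chimera structure limited to single-crossover joins. The
true-barcode FASTA is the hook for substituting an external read simulator
with a richer error model.

## Numerical and design choices

* Fingerprint division is floored; tail bases are excluded. Completeness is
  unaffected ($K$ errors still cannot hit all $K+1$ chunks).
* Hamming vs Levenshtein is auto-selected per barcode set (fixed length →
  Hamming); any length heterogeneity switches the whole set to Levenshtein.
* The ratio gate compares global totals, consistent with global clustering.
* Secondary/supplementary BAM alignments are skipped so each physical read is
  scanned once; BAM sequences are used as stored.
* PHRED encoding is fixed at +33.
* Degenerate inputs: empty FASTQ → empty stream and empty matrix with a
  warning; an empty whitelist, duplicate reference sequences/names, masks with
  characters outside ACGTN, and `min_length > max_length` are fatal.
* Which mate of a paired-end run carries the barcode is construct-specific, so
  it is a configuration option (`scan_mate`: 1, 2 or both; default both).
  Reverse-complement scanning is off by default (amplicon FASTQ is oriented).

## Validation benchmark

`benchmark_extraction()` is the package's self-contained validation: it
simulates the empirical-mode conditions above, runs reference-free extraction
(flank tolerance 2, length interval $60 \pm 2$) with correction at $K = 2$ and
a post-correction relative-abundance filter of $10^{-4}$ (true barcodes sit at
$2 \times 10^{-3}$ of the dataset, error clusters near $5 \times 10^{-6}$),
runs reference-based extraction against the true barcodes at tolerance 2, and
scores recovery and per-barcode count agreement. The problem size (500 barcodes
× 4 samples × 200 reads, 400k reads) keeps a full run under a minute on one
CPU. The same workflow backs `scripts/acceptance.R` and the acceptance tests;
the README shows a worked example with the numbers it prints.

The two workflows are not expected to agree on every read: a read with three or
more errors inside one flank is unextractable reference-free but still matches
its reference, which never sees the flanks. At error rate $10^{-3}$ this
affects on the order of one read per few hundred thousand, so count agreement
over 500 barcodes typically lands at 99–100%.

## Limitations

Split/dynamic barcode architectures (two-part tags) need two extraction passes
and are not orchestrated by the pipeline; SAM/CRAM, interleaved FASTQ and
long-read formats are unsupported; UMI collapsing is exact-sequence only; and
the whole dataset is processed in memory, so extremely complex libraries are
bounded by RAM rather than disk.
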