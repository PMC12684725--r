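# tagtrace

Extraction, error correction and quantification of synthetic cellular barcodes
from sequencing reads.

Lineage-tracing barcodes, combinatorial Pro-code tags and sgRNAs are read out
by amplicon, single-cell or spatial sequencing. Before any clonal analysis the
raw reads have to be turned into a clean barcode × sample (or barcode × cell)
count matrix: the barcode must be located inside each read, and the cloud of
sequencing-error variants around every true barcode must be merged back into
it. `tagtrace` does both, end to end:

* **Input**: FASTQ (single/paired-end, gzip) and BAM (all reads, unmapped
  only, or specific contigs; cell/UMI tags), cell/spot whitelists, reference
  lists (FASTA/CSV), YAML run configurations.
* **Reference-based extraction**: exact multi-pattern matching at tolerance 0;
  semi-global edit-tolerant alignment otherwise, with a unique-minimum rule and
  ambiguous reads discarded rather than double-counted.
* **Reference-free extraction**: barcodes located from 5'/3' flanks, an
  optional masked pattern (`N` = free position) and a length interval, with a
  per-flank edit budget.
* **Error correction**: two-stage clustering. Barcodes of length *L* are split
  into *K*+1 disjoint fingerprints of length *n* = ⌊*L*/(*K*+1)⌋; by the
  pigeonhole principle two barcodes within distance *K* always share one, so
  pre-clustering on shared fingerprints never separates true neighbours. Each
  pre-cluster is then refined into single-level trees: barcodes in descending
  global count order either attach to the nearest root within *K* (Hamming for
  fixed-length sets, Levenshtein otherwise; optional count-ratio gate) or
  become new roots. Clustering is global across samples, count correction is
  per sample.
* **Quantification**: bulk, single-cell or spatial count matrices written as
  CSV and H5AD (AnnData convention), UMI dominant-barcode collapsing, clone
  assignment from combinatorial tag sets (Jaccard similarity, default cutoff
  0.75).
* **Simulation**: ground-truthed amplicon datasets — controlled (error-free)
  or empirical (per-base substitution model) — with configurable abundance
  distributions and PCR chimeras, for validation and parameter tuning.

See `vignettes/barcode-extraction.Rmd` for the methods account.

## Worked example

Simulate a small two-sample library with sequencing errors, then recover it
reference-free:

```r
library(tagtrace)

cfg <- simulation_config(n_barcodes = 8, barcode_length = 24, min_hamming = 4,
                         n_samples = 2, reads_per_barcode = 50,
                         mode = "empirical", error_rate = 0.005, seed = 42)
sim <- synthesize_reads(cfg, "demo")

reads <- data.table::rbindlist(lapply(names(sim$fastq), function(s)
  read_fastq(sim$fastq[[s]], sample_id = s)))
reads <- filter_reads(reads, qc_params(20, 0.9))

pat <- barcode_pattern(cfg$flank5, cfg$flank3, min_length = 22, max_length = 26)
obs <- extract_tags(reads, "reference_free", pat, tolerance = 2)
corr <- correct_barcodes(tally_observations(obs), correction_params(2))
mat <- build_count_matrix(corr$tallies, "bulk")
mat
#> <tag_count_matrix> bulk: 2 row(s) x 8 barcode(s), 800 total counts
mat$counts[, 1:2]
#>          AAAACTCCATGTGTAACTCCGGAA AGTCGCCTAGAAAGGTACCGCTGG
#> sample_1                       50                       50
#> sample_2                       50                       50
```

All 800 simulated reads are recovered: reads whose barcode carries 1–2
substitutions are merged back into their true barcode by the correction stage
(`corr$assignment` maps every observed variant to its root), and the final
matrix reproduces the simulated ground truth of 50 reads per barcode per
sample exactly. `write_outputs(mat, "out")` writes `out/counts.csv` and
`out/counts.h5ad` with identical counts.

The same pipeline is available from the shell via YAML configurations:

```sh
tagtrace simulate --config sim.yaml
tagtrace extract  --config run.yaml
```

(`exec/tagtrace` in the installed package; exit status 0/1.)

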