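# sdpbench

Temporal benchmarking of sequence-based functional-residue and subfamily
detection in protein multiple sequence alignments (MSAs).

Protein families split into functional subfamilies, and two alignment
signals are classically used to predict functional sites from sequence
alone: **fully conserved positions** (entropy 0 columns) and
**specificity-determining positions** (SDPs) — columns conserved *within*
subfamilies but differing *between* them. Public databases grow
exponentially, so what these detectors report depends on *when* you ask.
`sdpbench` rebuilds that question as a reproducible pipeline for
bioinformaticians studying method behaviour:

1. **Historical snapshots** — filter a family to the sequences published by
   a cutoff year, remove redundancy at 95% identity with a greedy
   keep-first sweep, and gate on a minimum of 15 sequences
   (`snapshot_at()`, `remove_redundancy()`, `workable()`).
2. **Five detectors** applied per snapshot:
   * full conservation (entropy 0, gap fraction ≤ 10%),
   * Xdet-like: Spearman ρ between the column's residue-similarity matrix
     and the overall sequence-similarity matrix, selected at ρ ≥ 0.8,
   * Evolutionary-Trace-like: integer rank = shallowest tree-cut level at
     which the column is invariant in every group, selected at rank ≤ 2,
   * TEA-O-like: distance to the ideal SDP corner in the plane of global
     vs. mean within-group entropy, selected at ≤ 0.3,
   * S3det-like: correspondence analysis of the sequence × (column,
     residue) indicator table, k-means subfamily detection, SDPs scored by
     adjusted Rand index against the detected structure, selected at ≥ 0.8.
3. **Structural evaluation** — the *relative distance*

   `RD(S) = mean_{r in S} d(r, binding sites) / mean_{all r} d(r, binding sites)`

   with `d` the minimum distance to any binding residue; `RD < 1` means the
   prediction is closer to the binding region than chance.
4. **Temporal aggregation** — per-year counts and distances relative to a
   reference year (default 2014), as five-number summaries.

A synthetic-family generator (`simulate_benchmark_data()`) plants subfamily
structure, site classes, exponentially accumulating publication dates with
discovery bias, redundant near-clones, and a binding pocket whose rim holds
the planted functional columns — so the whole pipeline is testable offline.

## Worked example

```r
library(sdpbench)

ds    <- simulate_benchmark_data(n_families = 3, seed = 42)
bench <- run_benchmark(ds, benchmark_config(years = seq(2008, 2014, 2)))
print(bench)
#> sdp_benchmark: 3 families, years 2008-2014, 60 records
#> workable families: 0 @ 2008 -> 3 @ 2014

s <- summary(bench)
s$distance[s$distance$cutoff_year == 2014, c("method", "median", "n")]
#>        method     median n
#>  conservation 0.06974051 3
#>            et 0.10734771 3
#>         s3det 0.76326820 3
#>          teao 1.10388934 3
#>          xdet 0.14495492 3
```

Reading the numbers: in the 2014 snapshots the conserved positions sit at
7% of the chance distance to the binding pocket (they *are* the pocket in
the planted geometry), ET and Xdet selections at 10–15%, the S3det-like
selections at 76% (its selection also includes genuine subfamily-marker
columns away from the pocket), and the TEA-O-like selections are *farther*
than chance (1.10) — its entropy-corner score can only reach the 0.3
selection band for highly diverse columns, which lie far from the pocket.
The coverage table shows the 2a/2c-style series: no family is workable
(≥ 15 non-redundant sequences) in 2008, all three are by 2012.

The three shell subcommands wrap the same functions:

```sh
Rscript inst/scripts/sdpbench.R generate --config run.yaml --outdir out
Rscript inst/scripts/sdpbench.R run      --dataset out/dataset --config run.yaml --outdir out
Rscript inst/scripts/sdpbench.R summarize --records out/results/records.tsv --outdir out
```

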