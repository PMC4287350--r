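# cycleTSS

Base-pair-resolution mapping of bacterial transcription start sites (TSSs)
from differential 5' RACE read-count tracks, with cell-cycle classification
of TSS activity and promoter motif dissection. The package targets the
*Caulobacter*-style experimental design — a +TAP/−TAP library pair from an
unsynchronized culture plus eight 20-min time-point libraries across one
cell cycle — but all inputs are plain bedGraph/FASTA/GFF3, so any
organism/design with the same track structure works.

## The statistic at the core

At each genome position and strand, the TAP-enrichment statistic

θ = ln[(n₊TAP + c) / (n₋TAP + c)]

(counts normalized to library non-rRNA totals, pseudocount c = 1)
separates primary 5'-triphosphate ends (true TSSs) from processed
5'-monophosphate ends. θ at validated TSSs is approximately
Normal(1.71, 1.26) and at processing sites Normal(−0.52, 0.35); a TSS is
called when θ > 0.26 (≈ 2 sd above the negative-control mean, type-I rate
≈ 2.3%), the normalized +TAP count is ≥ 25, and RNA-seq coverage steps up
by > 35% across the position (38-bp windows). Called TSSs are then:

* categorized by genomic context — primary (P), internal (I), antisense
  (A), non-coding (N), and the overlaps IP and AP — with per-CDS
  contribution filters;
* classified as cell-cycle regulated via discrete-Fourier criteria on the
  8-point profile: coeff1/(coeff1+coeff2+coeff3+coeff4) ≥ 0.35,
  ln(a) − ln(b) ≥ 1.1, a ≥ 20;
* clustered (k-means, k = 15, ordered by peak time) and scanned for
  regulator motifs (CtrA TTAA-N7-TTAA and TTAA half sites, SciP
  GCGNC-N5-GNCGC/GCGNC, CcrM GANTC, a DnaA PWM with exact p-values) and
  ChIP fold enrichment, yielding combinatorial-control summaries.

A synthetic-data generator (`simulate_tss_dataset()`) produces a miniature
genome, annotation, and all tracks with a known truth table, so the entire
pipeline is testable end to end without external data.

## Worked example

```r
library(cycleTSS)

cfg <- generator_config(seed = 1)      # 200 kb genome, 200 TSSs, lambda 200
ds  <- simulate_tss_dataset(cfg)
res <- run_pipeline(ds)
print(res)
#> TSS analysis pipeline result
#>   called TSSs: 164 (threshold theta > 0.26)
#>   categories: P=93 IP=12 AP=5 I=18 A=28 N=8
#>   cell-cycle regulated: 52
#>   motif hits: 362 across 151 TSSs
```

Of the 200 planted TSSs, 175 pass calling (87.5%, matching the
normal-tail prediction Φ((1.71−0.26)/1.26) ≈ 0.875 — the θ threshold is
the only material loss), and the per-CDS contribution filters trim the
table to 164. Category labels agree with the planted truth exactly, all
52 regulated calls are planted-regulated (sensitivity and specificity
1.00 on this draw), and every planted motif on a called TSS is recovered
at its exact offset. `summary(res)` returns the count table;
`run_pipeline(ds, out_dir = "out")` writes `tss_table.tsv`, `tss.bed`,
`motif_hits.tsv`, `antisense_pairs.tsv`, `operon_internal.tsv`,
`cooccurrence_matrix.tsv` and `summary.tsv`.

Real data enter the same way from disk:

```r
ds  <- read_fixture("my_tracks/")   # FASTA + GFF3 + bedGraph pairs
res <- run_pipeline(ds, threshold = 0.26, out_dir = "results/")
```

A thin CLI with `simulate` / `run` / `demo` subcommands is installed at
`inst/scripts/tss-pipeline.R`.

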