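---
title: "Mapping and dissecting bacterial TSSs from differential 5' RACE tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and dissecting bacterial TSSs from differential 5' RACE tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleTSS)
```

## The measurement and the statistic

A transcript's genuine 5' end carries a triphosphate; the products of RNA
processing carry a monophosphate (or hydroxyl). Treating one aliquot of RNA
with tobacco acid pyrophosphatase (TAP) before 5' adapter ligation makes
primary 5' ends ligatable, while the untreated aliquot captures only
processed ends. Sequencing both libraries gives, at every genome position
and strand, a pair of 5'-end read counts, and the natural-log ratio

$$\theta = \ln\frac{n_{+TAP} + c}{n_{-TAP} + c}$$

(counts normalized to each library's non-rRNA total, pseudocount $c = 1$)
separates true transcription start sites (TSSs, high $\theta$) from
processing sites (low $\theta$). On control sites the two populations are
approximately normal: validated TSSs around mean 1.71 (sd 1.26) and tRNA
processing sites around mean $-0.52$ (sd 0.35), in natural-log units.
`calibrate_threshold()` reproduces the calibration: a Welch two-sample
$t$-test between the control samples and a threshold at
$\bar\theta_{neg} + z_{1-\alpha}\,s_{neg}$ with $\alpha$ defaulting to the
upper 2-sd tail (2.275%). The published operating point $\theta > 0.26$ is
accepted as an explicit override and is the package default; note that the
printed control summary statistics give $-0.52 + 2\cdot 0.35 = 0.18$, so
0.26 presumably came from unrounded control values — we compute our own
calibrated value *and* record the override rather than guessing intent.

Calling a TSS (`call_tss()`) additionally requires:

* at least 25 normalized +TAP reads (the control-matching floor is a
  separate parameter, default 30);
* a >35% step-up of RNA-seq coverage in the 38 bp downstream of the
  position versus the 38 bp upstream (`rna_seq_step_filter()`). The
  downstream window includes the TSS base itself — the TSS's own transcript
  contributes downstream coverage — and whether the windows abut the TSS or
  are offset is not specified upstream of this package, so the abutting
  choice is documented here rather than inferred;
* 5'-end positions within 5 bp are merged first (`merge_peaks()`), summing
  reads onto the member position with the most +TAP reads (ties to the
  leftmost).

## Genomic context and filters

`categorize_tss()` assigns each called TSS one of six context categories:
primary (P, within 300 bp upstream of a same-strand CDS start or on the
start codon's first base, otherwise intergenic), internal-primary (IP, in
the upstream CDS's final 30%), antisense-primary (AP, inside an
opposite-strand CDS but serving a downstream start), internal (I),
antisense (A), and non-coding (N). Where a TSS sits in the window of two
starts it is assigned to the nearer one, so contribution accounting is
unique. The source description of the IP rule repeats the same "last 30%"
clause for CDSs longer and shorter than 600 bp; since the two branches are
textually identical we implement a single last-30% rule with the fraction
configurable. N TSSs within 1 kb of a downstream start are flagged
`needs_review` (possible long-5'UTR primaries) instead of being manually
curated.

`contribution_filter()` keeps promoter-like TSSs (P/IP/AP) only if they
contribute >10% of the candidate reads assigned to their CDS on that
strand, and purely internal/antisense TSSs only above 25%; "total reads for
a CDS" is computed over the candidate TSSs assigned to that CDS, not
genome-wide. Independent read floors on the time-course levels (max over
the 8 points ≥ 2 for P/IP/AP, ≥ 10 otherwise) remove unquantifiable sites.

## Cell-cycle classification

Each TSS has 8 levels sampled every 20 min across a 160-min cycle
(t = 0…140). `fourier_coefficients()` computes the magnitudes
$|\sum_t x_t e^{-2\pi i k t/8}|$ for $k = 0..7$; a TSS is called regulated
(`is_regulated()`) iff

1. coeff1/(coeff1+coeff2+coeff3+coeff4) ≥ 0.35 — the single-peak
   (first-harmonic) shape criterion;
2. ln(a) − ln(b) ≥ 1.1, where a and b are the profile max and min — at
   least a 3-fold swing;
3. a ≥ 20 normalized reads — an expression floor, interpreted on the
   normalized-count scale since a fold-free floor of 20 only makes sense
   there.

Only magnitudes enter the criterion (the source does not distinguish real
and imaginary parts); coefficients 5–7 are computed for completeness but
are the conjugate mirrors of 3–1. A profile minimum of exactly zero would
make criterion 2 undefined; it is treated as passing provided a ≥ 20, since
a zero trough implies unbounded fold change. Criteria 1–2 are invariant
under uniform scaling of the profile; criterion 3 deliberately is not.

For visualization and clustering, profiles are log2-transformed, centered
to mean 0, and divided by the maximum absolute value
(`normalize_profile()`). The nominal "mean 0, max 1, min −1" display
constraint is over-determined for almost every profile; symmetric max-abs
scaling after centering is the resolution used here, attaining at least one
endpoint. k-means (`kmeans_profiles()`, default k = 15, 100 restarts, fixed
seed, Euclidean distance on display profiles — none of these specified
upstream, all configurable) orders clusters by their mean peak time;
`hierarchical_groups()` (average linkage) serves the coarser 3-group views.

## Promoter motifs

Motif models are supplied, not discovered (de novo discovery is a
published external tool's job and out of scope): gapped IUPAC consensus
strings such as the CtrA full palindrome TTAA-N7-TTAA, its TTAA half site,
SciP's GCGNC-N5-GNCGC and GCGNC, and the CcrM methylation target GANTC
(searched within 50 bp of the TSS; the others within 100 bp). Offsets are
reported for the motif's 5' base, negative upstream, strand-aware, with the
TSS itself at position 0 excluded from the promoter sequence.

PWMs are scored as log-odds in bits against a genome-composition
background, and p-values are exact: a dynamic program convolves the
per-column score distributions under the background. For widths ≤ 10 the
DP merges exactly equal partial sums (accumulated in the same order a word
is scored), so its distribution equals exhaustive enumeration bit for bit;
wider matrices fall back to a 1e-4-bit grid. Scanning reports hits with
p < 0.001 by default. The bundled DnaA PWM is built from the three printed
DnaA box variants (CTCCACA/ATCCACA/GTCCACA) as a synthetic stand-in for a
curated site alignment, which is not packaged.

CtrA half-site hits are classified by position: over the −10 element
([−20, −5]) as repressor-mode, near the −35 element ([−45, −25]) as
activator-mode. These bands are this package's concrete reading of
"over the −10" and "near the −35"; both are configurable.
`chip_enrichment()` flags ≥3-fold mean ChIP coverage in the 50 bp upstream
window relative to the genome-wide mean, and `cooccurrence()` tabulates
combinatorial regulator usage per promoter.

## The synthetic-data generator

`simulate_tss_dataset()` produces every input the pipeline consumes, with
known truth: an i.i.d. genome at GC 0.67, non-overlapping CDSs (some in
operons), TSSs planted to realize every context category in proportions
mirroring the emulated dataset (P 53%, A 18.5%, I 12.6%, IP 7.2%, AP 3.1%,
N 5.7%), including a gene with promoters at −120/−22 and an operon-internal
promoter; processing sites inside CDSs; exact motif instances overwritten
into promoter sequence (overwriting, not inserting, keeps all coordinates
stable); θ drawn from the two fitted normal distributions and realized as
−TAP ~ Poisson(λ) and +TAP ~ Poisson(λe^θ) with λ = 200, so the Jensen bias
of recovered θ stays below 1%.

Two generator choices deserve emphasis:

* **Library composition.** A real −TAP library is dominated by processed
  5'-monophosphate ends genome-wide. The generator reproduces this by
  raising the −TAP uniform background until both libraries have equal
  expected totals; this is also what makes total-count normalization
  composition-neutral, so planted θ survives the pipeline end to end.
  Without it, normalizing by totals would shift every θ by the log ratio
  of library compositions.
* **Time-course.** Regulated TSSs follow
  $m\,\exp[A\cos(2\pi(t-\text{phase})/160)]$ with phase a multiple of
  20 min and peak-to-trough fold $e^{2A}$ drawn log-uniformly from 4–16;
  constitutive TSSs are flat at $m$ (log-uniform 30–300). The 160-min
  period over an 8 × 20-min grid makes the first DFT harmonic dominant for
  any single-peak profile. The minimum planted fold of 4 clears the
  ln-fold criterion (needs e^1.1 ≈ 3) with a ≥ 20% margin, which is what
  the ≥ 0.95 sensitivity/specificity checks presuppose.

The background of spurious 5' ends (0.02 reads/position) is a free
parameter — no upstream value exists for it — chosen low enough not to
create calls on its own yet high enough to exercise the merging and floor
logic. RNA-seq coverage is deterministic (baseline 5, +4× baseline for
400 bp downstream of each TSS): the step filter's stochastic behaviour is
not the quantity under test. What the generator does **not** emulate:
sequence composition beyond GC content, 5'-structure-dependent ligation
bias (a known sensitivity ceiling of the assay), read-level errors, or
rRNA-depletion chemistry. Passing tests therefore certify the analysis
logic, not robustness to those real-data effects.

## What the checks verify, and at what sizes

With the default 200 kb genome, 200 TSSs and λ = 200, the θ threshold is
the only material loss mechanism, so end-to-end calling sensitivity should
match the normal-tail prediction $\Phi((1.71 - 0.26)/1.26) \approx 0.875$;
the test suite asserts agreement within 3 binomial standard errors, plus
zero false calls (processing sites fail θ and the step filter, background
fails the read floor). Monte-Carlo sizes — 10^6 draws for the threshold's
type-I rate, 10^5 sites through the Poisson layer, a 200 kb demo — run in
well under a minute each and keep every estimate's standard error far
below the tolerances asserted.

## Limitations

The package analyzes tracks, not reads: alignment and de novo motif
discovery are upstream tools' jobs. The IP rule's intended second branch
(the 600-bp split) is unrecoverable from its source and a single rule is
used. The antisense correlated/anticorrelated peak-time cutoffs (≤ 20 min
/ ≥ 40 min) are this package's definitions, not published constants. The
category-N manual curation step is replaced by a `needs_review` flag.
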