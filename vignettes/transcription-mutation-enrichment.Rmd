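---
title: "Testing transcription-associated mutation enrichment in genomic windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing transcription-associated mutation enrichment in genomic windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Transcription exposes single-stranded DNA, generates R-loops and torsional
stress, and so may elevate local mutation rates (transcription-associated
mutagenesis, TAM); at the same time RNA-polymerase stalling triggers
transcription-coupled repair (TCR), which should lower them. The net effect
is an empirical question. The design tamscan implements answers it with
mutation-accumulation (MA) data: lineages propagated through single-progeny
bottlenecks accumulate spontaneous mutations nearly neutrally, so the
genomic placement of their mutations can be compared with genome-wide
transcription measured by RNA-seq, free of most selective filtering.

The comparison is made at the level of genomic windows. The genome is cut
into sliding windows (by default 10 kb sliding in 1 kb steps, and 1 kb
sliding in 100 bp steps, so that conclusions can be checked against window
geometry), expression is quantified per window, and the windows containing
mutations are compared with all windows.

## Expression metrics

Two per-window metrics are computed from per-base read coverage
(the bedGraph output of `bedtools genomecov`):

* **depth** — the window's coverage rate, i.e. summed per-base coverage
  over its unmasked bases divided by its effective (unmasked) length,
  rescaled to transcripts per million. The normalisation universe is the
  *canonical tiling*: the non-overlapping subset of windows whose starts
  are multiples of the window size. Rates are summed over that tiling and
  each window's rate is multiplied by $10^6/\sum_j r_j$, so
  $\sum \mathrm{TPM} = 10^6$ exactly over the tiling and overlapping
  sliding windows do not double-count the library. Window-level TPM has no
  single canonical definition; this rate-based one preserves the TPM sum
  contract, is invariant to sequencing depth, and makes sliding and tiled
  configurations directly comparable.
* **breadth** — the percentage of the window's unmasked bases covered by
  at least one read. Breadth saturates for broadly expressed regions and
  is robust to coverage spikes.

Regions masked before mutation calling (repeats, low-confidence regions)
must also be excluded from expression denominators, otherwise depth is
biased in exactly the windows where mutations cannot be called; masking is
therefore applied symmetrically. Windows left with zero unmasked bases are
excluded from every statistic. Trailing windows truncated at chromosome
ends are retained (as `bedtools makewindows` retains them); their shorter
length is neutralised by the effective-length normalisation. GC content is
computed over unmasked non-N bases; a window with none has undefined GC
and drops out of GC-filtered analyses only.

Gene-level expression uses the same definitions over each gene's full
genomic span, with the TPM universe being all included genes. Full-span
(rather than exon-spliced) coordinates are used because the quantification
is genomic coverage, not transcript abundance; intron-aware quantification
is out of scope.

## The permutation test

Mutations are anchored at their VCF POS base (indels by their
leftmost-aligned anchor; a span rule would be arbitrary for the 1--3 bp
indels involved and would differ between types). A window is flagged when
at least one anchor lies in `[start, end)`.

Expression metrics are zero-inflated and heavy-tailed, and classical
nonparametric tests behave poorly at genome scale, so inference is by
resampling. With $k$ flagged included windows and observed median $m$,
each of $B$ permutations (default 10,000) draws $k$ windows uniformly
without replacement from **all** included windows and records the median
of the metric; the one-sided p-value is the fraction of permuted medians
greater than $m$. Small p means mutated windows are unusually highly
transcribed. The statistic is the median (the mean is available via
`statistic = "mean"`); the test is one-sided by construction and the
p-value depends only on ranks, so it is invariant under monotone
transforms of the metric.

Ties matter. Under the strict rule (`tie_rule = "strict_greater"`,
the default) a completely tied metric — e.g. breadth saturated at 100% —
degenerates to p = 0; `tie_rule = "greater_or_equal"` is the conservative
alternative and is what the calibration checks use, and
`add_one = TRUE` gives the bias-corrected $(b+1)/(B+1)$ estimator.
`exhaustive_pvalue()` enumerates all $\binom{n}{k}$ subsets (refusing more
than $10^6$) and serves as the exact oracle against which the Monte-Carlo
route is verified.

Controls and companions:

* **GC matching** (`gc_matched_test()`): GC content correlates with both
  transcription and mutation; the test is repeated with universe and
  flagged set restricted to windows with GC in an inclusive band, default
  30--50%, which retains the bulk of windows while equalising GC between
  the two sets.
* **Quartile enrichment** (`quartile_enrichment()`): included windows are
  ranked by depth, ties broken by a seeded random ranking so the four
  groups are equal-sized (making the uniform 0.25 null exact despite the
  many zero-TPM windows), and the fraction of mutation-containing windows
  per quartile is reported.
* **The battery** (`run_battery()`): one test per profile x genotype x
  metric (x mutation-type stratum when requested). Per-row seeds are
  derived from the master seed and the row key, so rows are independent
  and the battery is byte-reproducible. Raw p-values are primary;
  Benjamini-Hochberg adjusted values are reported alongside, never
  substituted. Significance stars use strict thresholds at
  0.05 / 0.01 / 0.001.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` generate complete datasets with the
statistical structure the analysis assumes, so every stage is testable
end to end without any download:

* genome: i.i.d. bases with per-window GC from a truncated normal
  (default mean 0.40, sd 0.05); a mask of merged fixed-length cells
  covering a set fraction (default 10%) of each chromosome;
* expression truth at tiling-window resolution: each window's rate
  $\lambda_w$ is 0 with probability 0.3 and otherwise log-normal
  (meanlog 1, sdlog 1.5) — zero-inflated and heavy-tailed like
  whole-body RNA-seq; coverage is piecewise constant in 100 bp segments,
  each Poisson with mean $\lambda_w \times$ read depth (default 30), with
  independent noise per profile around the shared truth;
* mutations: each mutation's window is drawn with probability
  $\propto \exp(\beta z_w)$ where $z_w$ is the z-score of
  $\log(1+\lambda_w)$ across included windows, then placed uniformly on
  the window's unmasked bases; $\beta = 0$ is the null. The multiplicative
  link is the simplest monotone one; it is a verification device, not a
  claim about *Daphnia* mutagenesis. REF alleles are read from the
  simulated sequence, so the VCFs round-trip exactly;
* genes: non-overlapping 2 kb intervals covering ~30% of each chromosome,
  to exercise the genic analysis.

Defaults mirror the scale of the MA design the package targets: nine
genotypes of 73 mutations each (657 total; the real design spans 39--136
per genotype) and four expression profiles, so the default battery has
36 tests. Truth ($\lambda_w$, $\beta$) is written to `truth.json` for
recovery checks. Everything derives from one master seed through
stage-keyed child seeds, so changing the read depth leaves the expression
truth untouched and two runs of one configuration are byte-identical.

What the generator does **not** emulate: linked sites and real LD,
sequence-context mutation spectra, transposable elements and
microsatellites, mappability structure in coverage, or correlated
profiles with biological (rather than sampling) variation. Passing tests
on synthetic data therefore demonstrate the statistical machinery —
calibration, power, conservation, determinism — not biological
conclusions about any real genome.

## Verification and the problem sizes used

The checks shipped in the test suite run at a deliberately desk-sized
geometry chosen to keep the full suite fast while leaving every
statistical property measurable: a 1 Mb genome with 10 kb tiling (100
windows), 100 mutations in one genotype, one profile.

* Monte-Carlo vs exact: on instances with $n \le 12$ windows and
  $k \le 4$, the 10,000-draw p lies within
  $3\sqrt{p(1-p)/10{,}000}$ of the exhaustive p.
* Calibration: over 500 null datasets ($\beta=0$, seeds 1--500) the
  rejection rate at $\alpha = 0.05$ under `greater_or_equal` falls in
  [0.03, 0.07]. (A direct window-level simulation oracle puts it at
  0.053 with standard error 0.008.)
* Power: at $\beta = 1.5$ the same oracle puts power at 1.00 (800
  replicates); the pipeline's observed power over 100 datasets is pinned
  inside the implied binomial 95% interval, and power is non-decreasing
  over $\beta \in \{0, 0.5, 1, 2\}$ (oracle: 0.05, 0.91, 1.00, 1.00).
* Conservation: TPM sums to $10^6$ over the canonical tiling to relative
  tolerance $10^{-9}$; doubling read depth moves mean per-window TPM by
  less than 2%.
* Quartiles: under $\beta = 0$ pooled flagged fractions sit inside their
  binomial 99% intervals around 0.25; under $\beta = 2$ the top quartile
  exceeds 0.25 with one-sided binomial p < 0.01.
* Determinism: identical configuration and seed give byte-identical
  battery TSV and identical output checksums.
* The interval/Rle quantification equals a per-base-array reference
  exactly on 100 kb genomes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (BED convention); VCF and
  GFF3 positions are converted at the parser boundary.
* A zero normalisation total (no coverage anywhere) yields all-zero TPM
  rather than NaN.
* `k = 0` flagged windows is an error ("no mutation-containing windows"),
  as is a flagged set outside the GC band; empty battery strata are
  recorded as skipped rows with a reason, not errors.
* Equal-length multi-base substitutions (MNPs) and symbolic/breakend
  alleles are rejected at parse time; multi-allelic records are split.
* Mutations whose only windows are fully masked are kept (with a warning)
  but contribute no included window.
* Window size must be divisible by the step so the canonical tiling is a
  subset of the sliding windows; both default geometries satisfy this.

## Limitations

The test is one-sided for elevated expression by construction and does
not estimate an effect size; the battery reports per-test p-values, not a
pooled estimate. Gene expression is full-span, not exon-aware. Strand is
ignored throughout, so strand-biased TCR signatures are invisible to this
analysis. Coverage input must already be per-base bedGraph; converting
BAM is a one-line external step
(`bedtools genomecov -bga -ibam sample.bam`).
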