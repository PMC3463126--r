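---
title: "Multiscale wavelet peak calling and the ngskit toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale wavelet peak calling and the ngskit toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngskit)
```

ngskit is a compact toolkit for next-generation sequencing analysis:
indexed random access to large text files, a schema-typed relational
Table, strand-aware interval algebra, per-base coverage with mismatch
counting, feature annotation and RPKM counting, and — its analytical
core — a ChIP-seq peak caller that detects enrichment at many length
scales simultaneously with a continuous wavelet transform and ranks
candidates by how persistently they appear across scales.

This vignette explains the models and the numerical choices.  It is a
methods document: every empirical statement here is one the package's
test suite or `scripts/acceptance.R` recomputes.

## The peak-calling model

ChIP-seq enrichment produces coverage "bumps" whose widths range from a
couple of hundred bases (point-source transcription-factor binding) to
kilobases (broad chromatin marks).  A detector tuned to one width
misses the others.  The caller therefore works in four stages.

**1. Signal preparation** (`prepareSignal`).  Coverage is summed into
bins of `binSize` bases (default 10).  Sample and control are each
normalized to reads per million (RPM), the control is subtracted and
negatives are floored at zero — enrichment below background carries no
peak information.  The result is smoothed with a kernel (default
Gaussian, sigma `bandwidth` = 40 bases; a box kernel and `none` are
available).  The pre-kernel binned values are retained alongside the
smoothed ones; the spike filter needs them (below).

**2. Multiscale transform** (`cwtScales`).  The signal is convolved
with a Ricker (Mexican-hat) wavelet at every bin position over a dyadic
scale grid, by default 2, 4, ..., 1024 bases (scales below one bin are
dropped; scales wider than the contig are skipped).  Because the
transform is dense (undecimated) it is translation invariant: shifting
the input by k bins shifts every coefficient array by exactly k bins.
Boundaries are handled by reflection, which avoids spurious edge
maxima.

The coefficient at scale $s$ is the inner product with the Ricker of
sigma $s$ bins, divided by $s$.  With this $1/s$ weighting the response
of a Gaussian bump of sigma $\sigma$ at scale $s$ is proportional to

$$R(s) \propto \frac{r^2}{(1+r^2)^{3/2}}, \qquad r = s/\sigma,$$

which peaks at $s = \sqrt{2}\,\sigma$ and, evaluated there, is
independent of $\sigma$.  Two useful consequences: the scale grid reads
directly as a bump-width axis (a bump of sigma $\sigma$ is "matched" at
scale $\sqrt{2}\sigma$), and matched coefficients are comparable across
scales, so a single coefficient threshold treats narrow and broad peaks
alike.  The tests verify both properties against the closed form.

**3. Ridge lines** (`findScaleMaxima`, `linkRidges`).  At each scale,
local maxima are found with a sliding window proportional to the scale
(width `max(3, round(minSeparationFactor * s))` bins; plateau ties go
to the leftmost bin; positions whose window would cross an edge are
ineligible).  Maxima are then linked greedily from the largest scale
down: each active ridge, in priority order (current coefficient, then
current length, then position), claims the nearest unclaimed maximum
within `positionToleranceFactor` × its current scale.  A ridge that
fails to extend accrues a gap; more than `gapTolerance` (default 2)
*consecutive* gaps terminates it — a successful link resets the
counter, the convention of standard CWT ridge linking.  Unclaimed
maxima seed new ridges, so every maximum belongs to exactly one ridge.
The test suite checks the greedy result against an exhaustive
enumeration of assignments on small instances.

A real peak produces a coherent chain of maxima across many scales; a
noise wiggle appears at one or two.  Ridge length — the number of
scales a ridge spans — is therefore the primary score, with the best
wavelet coefficient as tiebreak.  Longer ridges also indicate
isolation: a peak crowded by a neighbour loses its large-scale maxima
to the merged envelope, truncating its ridge.

**4. Peaks and filters** (`callPeaks`).  Each ridge of at least
`minRidgeLength` (default 3) scales becomes a candidate peak.  Its
summit is the ridge position at the smallest scale it reaches (the
best-localized estimate); boundaries extend to where the smoothed
signal drops below half the summit height, capped at twice the best
scale each side.  Three filters follow:

* **Low signal.**  Summits whose smoothed signal is below `minSignal`
  are dropped.  The default is adaptive — median + 5 MAD of the
  smoothed signal — rather than a fixed constant, so calls are
  invariant under rescaling of the input (a fixed default would break
  the amplitude-monotonicity property the tests assert).
* **Coefficient SNR.**  Ridges whose best coefficient is below
  `minSnr` (default 5) × the coefficient noise level are dropped and
  reported as `low_signal`.  The noise level is the median over scales
  of each scale's coefficient MAD.  The median matters: at the largest
  scales the MAD is dominated by the peaks themselves, and using it
  per scale suppresses genuine broad peaks.  This filter is what
  removes noise wiggles riding the flanks of broad peaks, which pass
  the absolute-signal test but have weak wavelet support.
* **Spikes.**  A peak whose width at half maximum on the *pre-kernel*
  binned signal is under `maxSpikeSharpness` bins (default 2) is a
  single-position artifact (e.g. a PCR tower), not a fragment-sized
  enrichment.  Sharpness must be measured pre-kernel because the
  smoother turns a one-bin spike into a kernel-width bump.

Finally, non-maximum suppression removes any candidate whose summit
lies inside a better-ranked surviving peak's interval: sub-maxima on a
peak's shoulders are part of that peak, not second peaks.

`gaussianSmoothPeaks` provides the classical single-bandwidth
comparison pipeline under the same peak contract.

## What the synthetic data emulate — and what they do not

The generators (`makeGenome`, `makeSam`, `makePeakTrack`,
`makeFeatures`, `makePeakLayout`) are first-class, seeded, pure
functions; every artifact carries its ground truth.  `makeSam` plants
mismatches at a per-base rate and short (1–2 bp) indels per read,
writing CIGAR, MD and NM tags that encode them exactly — so mismatch
recovery can be checked against planted truth rather than against
another tool.  `makePeakTrack` lays Gaussian bumps of stated amplitude
and width on a Poisson background.

The recovery experiments use 20 peaks on a 200 kb contig, sigma 50 to
1000 bases (log-uniform), amplitudes 5 to 20 reads per base over a
Poisson(1) background — amplitudes at least five background standard
deviations, the regime where a caller ought to succeed.  Under these
conditions the suite requires at least 95% of planted peaks recovered
(summit within half the planted width) and at most one false peak per
100 kb at default settings; `scripts/acceptance.R` reports the measured
rates (about 99.5% and 0.03 in typical runs).

What the fixtures do **not** model: fragment-length strand offsets,
quality-correlated sequencing errors, PCR duplicate structure, mappability
gaps, and copy-number-varying backgrounds.  Passing here shows the
algorithmic contract holds, not that defaults are tuned for any
particular antibody or organism; on real data, `binSize`, `bandwidth`
and the filters are the knobs to revisit.

## The support library

A few semantics are worth stating precisely.

* **Coordinates** are 0-based half-open everywhere internally; format
  readers convert at the boundary (BED and refGene are native; GFF and
  1-based TSV dialects are shifted on ingest).  Abutting intervals do
  not overlap; strand `'.'` matches any strand when strand matching is
  requested, so unstranded features still annotate stranded queries.
* **Line indexes** store one zero-padded 19-digit byte offset per line
  (plus a size/mtime header), so the k-th entry sits at a computable
  byte offset and lookup needs no scan.  Staleness is detected by
  source size or mtime change.  A final line without newline counts as
  a line; CR is stripped on return, so CRLF files index cleanly.
* **Tables** have a closed four-type schema (int, float, string,
  bool).  Outer joins pad missing sides with per-type sentinels (NA
  integer, NaN, `""`, `FALSE`) instead of introducing an option type;
  duplicate keys give the full Cartesian pairing; sorts are stable;
  joins go through a key→rows map built on the smaller operand.
  `lowerBound`/`upperBound` return 1-based indices, n+1 when no
  element qualifies.
* **Coverage** counts each M/=/X base of a mapped primary record on
  the strand of flag 0x10; deletion and skip gaps are not covered and
  cannot host mismatches.  "Uniquely aligning" means NH == 1 when the
  tag is present, else mapq > 0 — covering both aligner conventions.
  Records lacking NM are treated as error-free by the `maxErrors`
  filter.  Midpoint mode uses the outer reference span including
  gaps.  RPM normalization applies to depth, never to mismatch
  tallies, which remain integer evidence counts.
* **Counting** increments every feature a read overlaps (no fractional
  assignment), with RPKM $= 10^9 C/(NL)$, $N$ the number of reads
  passing filters and $L$ the summed exon length when sub-blocks are
  present.  A positive `shift` probes upstream of each feature: lower
  coordinates on `+`, higher on `-`, clamped at zero.
* **Provenance**: every tool records its command line, an ISO-8601
  timestamp and the package version as `#` lines that the TSV readers
  skip transparently; `--no-provenance` suppresses them, `--force` is
  required to overwrite an existing output, and missing inputs abort
  before any tool body runs.

## Worked example

```{r example}
layout <- makePeakLayout(100000, n = 8, seed = 7)
pt <- makePeakTrack(100000, layout, noiseRate = 1, seed = 107)
peaks <- suppressWarnings(waveletPeakCall(pt$track))
peaks[, c("chrom", "start", "end", "summit", "ridgeLength", "bestScale")]
```

Summits line up with the planted centers:

```{r check}
sapply(seq_len(nrow(layout)), function(i)
  min(abs(peaks$summit - layout$center[i])))
round(layout$width / 2)
```

## Known limitations

Ridge linking is greedy; pathological maxima configurations could be
linked differently by a global optimizer, though the enumeration tests
show agreement with the stated preference order.  The caller is
single-sample versus one control — no replicate modelling, no
differential calling, and no fragment-size estimation from paired
ends.  Peak boundaries are a half-maximum heuristic capped by scale,
not a statistical interval.  Problem sizes in the test suite (200 kb
contigs, 300-read alignment files, 500-feature annotation sets) were
chosen to exercise every code path while keeping the default test run
fast; all scale linearly.
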