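---
title: "Paralog-aware methylation quantification: models, parameters and design choices"
author: "paralogmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog-aware methylation quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogmeth)
```

## Scope and model

`paralogmeth` addresses a specific failure mode of targeted DNA methylation
assays: when the target region has a close paralog (here, the second exons
of *CDKN2A* and *CDKN2B*, ~95% identical), a single bisulfite PCR amplifies
both loci and the pyrosequencing readout mixes their methylation states.
The package models the product pool as a weighted mixture of four pure
template classes — paralog A or B, fully methylated or fully unmethylated at
each CpG — and exploits three kinds of post-conversion sequence differences:

* **paralog markers**: conversion-invariant bases private to one paralog
  (in the real assay, two C-to-A transversions). The peak fraction of the
  private base estimates that paralog's share of the pool.
* **paralog-specific CpGs**: CpGs destroyed in one paralog by a genomic
  C-to-T transition (or created by the reverse change). Their raw C/T
  fraction is diluted by the other paralog and is rescaled by the estimated
  proportion.
* **CpG shifts**: a CpG displaced by one base between the paralogs. The
  run-length structure of pyrosequencing entangles the two loci at such
  columns; they are mapped for inspection but never quantified
  (`kind = "cpg_shift"`, `usable = FALSE`). The corresponding position in
  the real assay was found unsuitable for proportion estimation, and we do
  not offer an option to re-enable it: every analysis that depends on it
  would inherit the entanglement silently.

### Raw level convention

The raw methylation at a CpG position is defined as the C signal over the
*total* signal at that column (C + T + any paralog-private base), matching
instrument behaviour. Under this convention the raw level of an A-specific
CpG in a pool with proportion $p_A$ and true level $m$ is exactly
$p_A m / 100$, so the correction $m = \mathrm{raw} \times 100 / p_A$ is
exact in the noiseless limit — this identity is what the end-to-end recovery
tests assert to $10^{-6}$.

### Proportion combination

With one marker per paralog, $p_A$ is the unweighted mean of the A-marker
fraction and the complement of the B-marker fraction. The mean is symmetric
and unbiased when both markers carry comparable noise; single-marker
estimation is available (`method = "marker_a"` / `"marker_b"`) for assays
where one marker fails quality control.

### Reporting rules and their order

Three rules are applied strictly in this order:

1. **Correction** of paralog-specific CpGs using the *raw* proportion.
2. **Reliability masking**: shared CpGs are reported only when the
   proportion exceeds 90% (`full` tier); at 80–90% (`moderate`, boundaries
   inclusive) and below 80% (`specific_only`) they are not analyzable
   because both paralogs are measured simultaneously.
3. **LOQ substitution** as the final reporting step: values ≤ 5.00% become
   2.50%, values ≥ 95.00% become 97.50%.

Applying LOQ substitution *before* correction would make the pipeline
non-invertible exactly where the assay is most informative (proportions
near 95%), so the substitution is applied to reported values only. The
reported proportion itself is computed from LOQ-substituted marker
fractions (`loq_on_markers = TRUE`, configurable), which is why a pure
methylated paralog-A standard reports $p_A = 97.5$ while the internal
estimate used for correction remains 100. Corrected values above 100
(possible under noise) are clipped and flagged, not errored.

## Pyrogram simulation

The simulator implements sequencing-by-synthesis literally: each template
holds a pointer, each dispensed nucleotide incorporates the full
homopolymer run at the pointer, and the expected peak height is the
weight-averaged incorporation. Heights are in expected-incorporation units
(1.0 = one base in every template); no light-intensity calibration is
modeled because the analysis consumes only relative peak ratios. Noise is
i.i.d. Gaussian per dispensation (clipped at zero), with an optional linear
signal decay along the dispensation index that reproduces the
quality-degradation pattern motivating a second sequencing primer in long
assays. A property suite checks the simulator against an independent
regex-based brute-force walk on hundreds of random instances.

Dispensation orders can be supplied (the real assays' orders ship with the
built-in configurations, with typographic artifacts stripped on ingest) or
auto-designed: a greedy scheduler dispenses a base needed by the
least-advanced templates, preferring one that no further-advanced template
would also incorporate. The position map records, per pure template, which
dispensation slot consumed each read column; a quantification row whose
slots also receive signal from *other* columns (an unabsorbed frameshift)
is flagged unusable rather than silently mis-quantified.

## The synthetic generator as study-condition definition

`generate_paralog_pair()` emulates the real assay's geometry with fixed
defaults: 230 bp, 95% target genomic identity, 24 CpGs in paralog A of
which four are destroyed in B by C-to-T transitions, one CpG created in B,
one conversion-invariant marker per paralog (each sitting inside a CpG of
the *other* paralog, as in the real target), one shifted CpG, and
reverse-primer mismatches on B (two B-private CpGs in the primer footprint
plus one invariant substitution, giving one mismatch for unmethylated and
three for methylated templates). This leaves 21 CpGs in the sequenced
window of B versus 24 in A. Identity tuning uses C-to-T edits at non-CpG
cytosines, which vanish after conversion — the same mechanism that makes
the real converted paralogs *more* similar than their genomic sequences.

Local contexts around engineered variable columns are fixed (a purine
before and after) so that every quantified column has run length one; the
noiseless pipeline then recovers truth to machine precision, which is the
basis of the acceptance-grade recovery tests. What the generator does *not*
emulate: indels between paralogs (the real window has none), incomplete
bisulfite conversion, PCR amplification bias between methylated and
unmethylated strands (observed in the real standards), and instrument
light-level effects. Passing tests therefore demonstrate correctness of the
quantification arithmetic and position mapping, not robustness to those
wet-lab artifacts.

Standard sets default to a 50/50 paralog ratio (both genes are present at
equal copy number in unrearranged genomes) at levels 0/25/50/75/100%,
mirroring the standard series run alongside the real assays.

## HRM quantification

Melt curves are normalized between linear baselines fitted in pre- and
post-melt windows (defaults: the outermost 1.0 °C at each end of the
acquisition range; the published protocol defers these settings to its
normalization reference, so they are declared package defaults,
configurable via `hrm_params()`). Normalization is exactly invariant under
affine transforms of the raw fluorescence. Derivatives use Savitzky–Golay
filtering with degree 3 and an 11-point window (1.1 °C at the 0.1 °C
acquisition step used by the melting program).

Calibration fits, per temperature in 79.6–81.6 °C, the unique cubic through
the four (normalized fluorescence, level) points of the 0/25/50/75%
standards — four points determine a cubic exactly, so the nodes are
reproduced to machine precision. The direction (fluorescence → methylation)
avoids numeric inversion of a fitted polynomial. Temperatures where two
standards have practically identical fluorescence (difference < 1e-9,
non-invertible) are excluded; the sample call aggregates per-temperature
estimates by the median, which tolerates a minority of poorly conditioned
temperatures. With physically mixed standards the fluorescence at each
temperature is affine in the level and held-out levels are recovered
essentially exactly; under a smoothly nonlinear response the cubic recovers
held-out levels within the node span to about ±2, while calls above the
75% node are extrapolations and carry wider error — a reason the real
calibration uses standards only up to 75% and substitutes extreme readings
via the LOQ rule. One typographic note: the published calibration range is
read as 79.6–81.6 °C.

Melt species attribution assigns each observed derivative peak to the
nearest candidate melting temperature after exclusion-based filtering
(candidates whose expected products were absent are removed first),
abstains on ties rather than guessing, and warns when the candidates' GC
ordering contradicts their temperature ordering (higher GC should melt
higher).

## Numerical and interface choices

* Positions are 1-based throughout (R convention), including CpG site
  positions, primer hit coordinates and dispensation slots.
* Primer matching is a Hamming scan (no indels) with a default budget of 3
  mismatches — the worst case the real assay tolerates; the reverse primer
  is reverse-complemented before scanning. `N` matches only `N`.
* Global alignment for identity uses match +1 / mismatch −1 / gap open 2 /
  gap extend 0.5 with end gaps penalized; identity is matches over
  alignment columns, which reproduces fixed-length no-indel comparisons
  exactly.
* The proportion-noise check asserts bounds derived from this package's
  own noise model (per-slot Gaussian, sd 0.02 → mean absolute proportion
  error ≈ 1.1 points, maximum < 5 over 100 simulations); they were computed
  from the simulation, not assumed.
* Problem sizes in the test and acceptance runs (230-bp pairs, a
  20-condition recovery grid, 200 oracle instances, ~100-seed Monte-Carlo
  loops) were chosen as the smallest sizes that exercise every engineered
  feature class; the whole suite completes in well under a minute.

## Limitations

* Deconvolution supports exactly two paralogs; a third co-amplified locus
  would require a different estimator.
* The accession validation tier (`accession_validation()`) needs
  user-supplied reference FASTA and is the only part of the package whose
  expected values come from published wet-lab characterizations rather than
  synthetic truth.
* Melting temperatures of simulated species are free parameters; the
  package makes no attempt to predict absolute Tm from sequence
  thermodynamics.
* Confidence intervals on the estimated proportion are not provided; the
  reliability tiers are the supported uncertainty statement.
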