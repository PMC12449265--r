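---
title: "Methods: quantifying chloroplast translational feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chloroplast translational feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidCES)
```

## The scientific problem

Photosynthetic complexes (PSII, PSI, cytochrome *b6f*, ATP synthase, NDH,
Rubisco) assemble from subunits encoded in two genomes. In chloroplasts the
synthesis of one subunit can be feedback-regulated by the accumulation or
assembly state of another — *control by epistasy of synthesis* (CES). To
detect such regulation one compares, between an assembly mutant and its
control, two per-gene quantities:

* **translation output (TO)** — ribosome-footprint coverage of a reading
  frame, a proxy for protein synthesis;
* **RNA** — transcript accumulation.

Their ratio of changes is the **translation efficiency (TE)** change; on the
log2 scale

$$\Delta\log_2 TE = \Delta\log_2 TO - \Delta\log_2 RNA,$$

an identity this package maintains exactly through every stage. A gene whose
TO drops while its RNA does not — and which is neither mutated itself nor
co-transcribed with the mutated gene — is a candidate for translational
feedback.

## Measurement branches

### Tiling microarrays

Footprint and RNA samples of mutant and control are co-hybridized on custom
tiling arrays (channels 635/532), one array per assay and biological
replicate. Probe processing follows the classical two-channel protocol:

1. **Spot QC** — each probe has 4 technical spots; flagged spots are
   discarded and probes with fewer than 2 good spots are dropped.
2. **Background** — local background subtraction, then the **median** of
   the good spots per probe and channel; medians at or below an intensity
   of 100 count as below background and become 0.
3. **Normalization** — one scale factor per channel anchors the mean
   CDS-probe value at 4,000. The anchor is arbitrary: every downstream
   quantity is a ratio or a self-normalized relative abundance, and the
   test suite asserts invariance to it. (The wording "normalized to the
   arbitrary value of 4,000" is ambiguous between sum and mean; the mean
   was chosen, and the invariance makes the choice immaterial.)
4. **Relative abundance** — per gene, the arithmetic mean of its probe
   values (zeros averaged in as zeros: excluding them would bias knockouts
   upward), expressed as log2 relative to the array's gene average.
5. **Fold change** — per replicate, mutant minus control relative
   abundance. Genes whose mean is 0 sit below the measurement floor; they
   are *censored* at the smallest positive gene mean of that array and the
   fold change becomes a bound (the ">8-fold reduced" reporting style), not
   a point estimate.

A probe belongs to a gene only if it lies fully inside the CDS; straddling
probes are treated as intergenic so operon neighbours are never
double-counted.

### Sequencing

Reads are assigned **sequentially** to four reference tiers — rRNA/tRNA
contaminants, chloroplast, mitochondrion, nucleus — keeping each read at the
first tier it aligns in; this prevents contaminant reads from inflating
chloroplast counts and chloroplast reads from leaking to organellar gene
copies elsewhere. Only chloroplast survivors are counted, under these rules:

* strands must match;
* the first 10 and last 30 nt of each CDS (in transcription order) are
  masked — footprints there derive from initiating/terminating ribosomes,
  whose dynamics differ from elongation. *Any* overlap with a masked window
  excludes a read (the conservative reading; a 5'-end-in-window variant
  would keep more reads but risks keeping terminating footprints);
* for footprints on intron-containing genes only the **last exon** is
  counted, because translation of unspliced mRNA can terminate inside
  introns;
* RNA-seq reads whose contiguous blocks run more than **52 nt** into an
  intron while also covering exon are excluded as unspliced mRNA. The
  overhang interpretation (rather than total junction-spanning span) is the
  one that specifically diagnoses unspliced molecules; spliced alignments
  whose gap matches the intron have overhang 0 and count. Both the mask
  semantics and the overhang rule are parameters with these documented
  defaults;
* a read overlapping the counting regions of two same-strand genes is
  ambiguous and discarded (the uniquely-assigned default of standard
  CDS counters).

Expression is RPKM over the *counted* region per million *counted
chloroplast* reads — the analysis is chloroplast-internal, mirroring the
arrays' self-normalization — with a pseudocount of 1 so knockouts stay
log-safe.

All coordinates are 0-based half-open internally (unambiguous interval
arithmetic); GFF3 input is 1-based closed and converted on load. The
plastome is circular: origin-wrapping genes may be written with
`end < start` and are unwrapped into two intervals whose junction is not an
intron.

## Statistics

Per-gene variances over 3 replicates are unstable, so significance uses the
empirical-Bayes moderated t: per assay, gene variances are shrunk toward a
prior estimated by moment matching on the log variances (digamma/trigamma
equations; trigamma inversion by Newton iteration, tolerance 1e-8). The
posterior variance is $s^2_{post} = (d_0 s_0^2 + d\,s^2)/(d_0 + d)$ and the
statistic is referred to a t distribution on $d_0 + d$ degrees of freedom.
Degenerate inputs are defined: identical variances give an infinite prior at
the common value; $d_0 = 0$ recovers the ordinary t; $d_0 = \infty$ a
fixed-variance z-like statistic. The implementation agrees with the limma
reference to numerical tolerance (asserted in the tests, where limma serves
as an independent cross-check only).

Design choices: arrays are **paired one-sample** tests on per-replicate
(mutant − control) log-ratios, because the two channels share an array;
sequencing samples are not co-hybridized, so the NGS branch is a
**two-sample** test on log2 RPKM. Whether the published NGS p-values used
the same machinery as the arrays is not stated; applying it to both is this
package's assumption. Priors are estimated within assay (TO and RNA have
different noise regimes); BH FDR adjustment runs across the chloroplast
protein-coding genes of each assay, matching the volcano gene universe.

Fold-change thresholds (2-fold for arrays, 4-fold for NGS, with adjusted p
0.05 / 0.01) are justified by the tail of the observed fold-change
distribution: `tail_cutoff()` returns $2^q$ with $q$ the 95th percentile of
|log2 FC| (type-7 linear-interpolation quantile — no quantile definition is
standard here, so one is fixed and documented).

## Classification

`classify_genes()` encodes the interpretive layer: *primary lesion* (the
engineered gene), *operon secondary* (same transcription unit — changes are
explained by the polycistron, e.g. readthrough from the selection marker,
not by feedback), *translational feedback candidate* (TO significant while
RNA is not, or a TE shift at least the fold cut-off alongside significant
TO — the latter clause keeps strong TE shifts with modest RNA changes from
being missed), *transcript-level candidate* (both significant, TE below
cut-off), else *unchanged*. Operon coupling is judged from the annotation's
transcription units; internal promoters that partially decouple downstream
genes can be modelled by splitting a transcription unit. A *cross-complex*
flag marks candidates outside every lesion gene's complex (the PSII-mutant →
PSI-genes pattern). The classifier deliberately encodes only the
annotation-driven part of the published reasoning; promoter-level expert
judgement is out of its scope.

## The synthetic test bed

The generator is first-class, tested code; its defaults define the study
conditions:

* a **miniature circular plastome** (21 named genes plus optional filler
  ORFs; 80 genes with `n_extra = 59`) with polycistrons mimicking the
  psbD/C/Z, psbB/T/H-petB/D, psaA/B-rps14 and psaI-ycf4-cemA-petA operons,
  intron-containing genes (petB, petD, ndhB), a same-strand overlapping
  pair (atpB/atpE) and an origin-wrapping gene (rpl2);
* **scenarios** describing mutant classes: knockdown (aadA antisense
  insertion; the preset injects a 0.5 RNA factor and 0.18 TE factor on the
  psbD-like gene, i.e. ~11-fold TO and ~2-fold RNA reduction, plus
  translational feedback of 0.30 on psbB and 0.45 on psaA in other
  transcription units), knockout (deletion to 1% RNA with ~7-fold psbA
  feedback), and readthrough overexpression (5-fold RNA over the
  downstream operon with 2.5-fold translational feedback on petB);
* baseline expression lognormal(meanlog = log 1000, sdlog = 1), control TE
  1, spot background Normal(200, 20) truncated at 0, gain 1 — arbitrary but
  fixed, since everything downstream is ratio-based;
* noise: multiplicative lognormal spot noise (CV 0.15, unit mean), a 2%
  bad-spot rate, Poisson counts (optional Gamma overdispersion), 10%
  unspliced RNA reads on intron genes with overhangs straddling 52 nt;
* 3 biological replicates, the study design.

Determinism is contractual: identical (scenario, seed) give identical
outputs; the truth, probe and alignment emitters use seed, seed+1 and
seed+2 so their draws do not collide.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: spatial array artifacts and dye biases (no loess
or quantile normalization exists here, by scope), sequence-dependent
coverage biases, alignment errors (alignment itself is an external
aligner's job; only the tier-assignment contract is implemented), P-site
structure or periodicity of footprints, and genuine biological covariance
between assays.

Two subtleties the oracles must respect:

* the self-normalized relative abundance measures fold changes *relative to
  the per-array gene average*, so with few genes or large lesions the
  measured log2 FC is the injected one minus the mean injected effect.
  Ground truth therefore carries both the absolute injected effects and
  the measured-scale expectation; the noiseless round-trip oracle compares
  to the latter at 1e-9, the recovery check to the former (on the 80-gene
  annotation the centring term stays ≈0.1);
* genes censored at the array floor yield bounds, not estimates; recovery
  is measured on point estimates, and bounds are checked for consistency.
  Deep knockdowns whose residual signal falls below the floor are
  quantified on the sequencing branch, which has no floor.

## Problem sizes and numerical choices

The test suite runs the noiseless round trip on a 31-gene annotation; the
counting oracle on 500 random 10-read alignment sets against a literal
per-(read, gene) rule enumeration; recovery on the 80-gene annotation at
spot CV 0.15 and ~300 reads per gene; null calibration on 200 simulations
of 80 genes (raw p < 0.05 rate within 3 binomial standard errors of 0.05);
prior recovery of d0 = 4 on 5,000 simulated variances (±20%); and the
percentile machinery on 100,000 half-normal draws (within 2% of
$2^{1.96}$). These sizes keep the whole suite to a few minutes while leaving
each check statistically meaningful.

Numerical conventions: trigamma inversion tolerance 1e-8; quantile type 7;
ties in probe medians resolved by `stats::median` (mean of the middle pair);
the below-background floor is applied after the technical-replicate median,
in the stated order of the protocol; empty counting regions flag the gene
rather than silently counting a truncated window.

## Known limitations

* The classifier cannot distinguish feedback from direct effects
  transmitted through unannotated internal promoters; that part of the
  published reasoning requires expert judgement or a refined annotation.
* Censored (below-floor) genes carry bounds; their moderated t statistics
  are computed from floor-valued ratios and should be read qualitatively.
* The calibration of moderated p-values assumes the inverse-chi-square
  variance prior is an adequate description of between-gene variance
  spread; with strongly structured variances (here: probe counts per gene)
  small deviations in either direction are expected and are measured, not
  assumed, by the acceptance checks.
* Trans-splicing is out of scope; a trans-spliced gene must be annotated
  as separate CDS parts.
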