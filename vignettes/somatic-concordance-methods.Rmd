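---
title: "Methods: cross-laboratory concordance of somatic mutation calls"
author: "SomaticConcord maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-laboratory concordance of somatic mutation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SomaticConcord)
```

## The problem

Tumor mutational burden (TMB) — the count, or per-megabase density, of
somatic non-synonymous mutations in a tumor exome — has become a treatment-
relevant biomarker, which makes it matter whether two sequencing
laboratories given the same DNA report comparable mutation sets. In
practice they often do not: capture kits, depths, callers, cutoffs and
filtering rules all differ, and self-reported mutation counts for the same
sample can differ by well over an order of magnitude. This package
implements the analysis used to quantify that problem and the remedy: (i)
harmonize per-laboratory call reports into exact mutation keys, (ii)
restrict every laboratory to a common genomic region, re-thresholded under
one rule, and (iii) measure replicate concordance, truth-set sensitivity,
cross-laboratory overlap and burden in both the as-delivered ("vendor") and
harmonized ("unified") spaces. A call-level simulator with known truth
makes every stage testable without access to any laboratory's raw data.

## Mutation identity

A mutation is identified by its genomic coordinate plus the base change:
contig, 1-based position, reference allele, one alternate allele. Equality
is exact — no position window, no allele fuzziness. Before comparison,
records are normalized:

* contig labels are funneled into one namespace (`chr` stripped, `M`/`MT`
  unified; both configurable);
* multi-allelic records are split, one key per alternate allele;
* alleles are uppercased, and redundant padding is trimmed — shared suffix
  first, then shared prefix with the position advanced, always leaving at
  least one base per allele as the indel anchor.

Trimming removes the dominant representation differences between reports
without needing a reference genome. Full reference-based left-alignment of
indels is deliberately not performed — no FASTA ships with the package —
but `normalizeCalls()` accepts a `leftAlign` hook for users who have one.
Duplicate keys within one report (a site listed per transcript, say)
collapse silently to one entry, keeping the maximum-depth annotation, with
the collapse count logged.

Records that failed the originating pipeline's FILTER are read and kept
with their status rather than dropped; whether they enter an analysis is an
explicit switch (`includeFiltered`). The originating pipelines' filtering
rules are generally undocumented, so this is the analyst's decision, not a
fact the data can settle; the default excludes them, which treats each
laboratory's report at face value.

## Region restriction

Capture kits differ, so fair comparison restricts all sets to regions every
kit targets — in the motivating study, the region spanned by a 4813-gene
clinical panel; here, any BED the user supplies (tests and the simulator use
a toy panel; no external download is required). Intervals are kept merged
and disjoint, so total size is well defined. A key is inside a 0-based
half-open interval `[start, end)` iff its 1-based position `p` satisfies
`start < p <= end` — equivalently `p - 1` is in `[start, end)`, matching
`bedtools intersect` semantics for point variants; deletions count by their
anchor base. Restriction is idempotent and composes with region
intersection, properties the test suite checks against per-base occupancy
oracles. Padded capture targets are not applied by default (padding is a
user decision at BED preparation time).

## The metrics

**Replicate concordance.** For two replicates with key sets $A$ and $B$,

$$\mathrm{concordance} = 100 \times \frac{|A \cap B|}{(|A| + |B|)/2}
 = 100 \times \frac{2|A \cap B|}{|A| + |B|},$$

the Dice coefficient as a percentage. Percentages are rounded half-up to
two decimals (display trims trailing zeros, so a table prints both `89`
and `88.52`); half-up rather than banker's rounding is what the published
tables this package validates against use. A single-replicate laboratory
yields an explicit not-available value, never zero, and two empty sets are
likewise undefined.

**Truth-set sensitivity.** Against an expected-mutation set (e.g. the 178
documented hotspot mutations of a 30/70 tumor/normal cell-line mixture),
sensitivity is detected-in-truth over truth size; display rounding is
nearest integer. Precision against truth is also computed
(`callPrecision()`) as a clearly labelled extension — it is only meaningful
for an exhaustive truth set.

**Overlap partitions.** Across laboratories, `overlapSummary()` reports
per-set totals, all pairwise intersections, the shared-by-all count and
per-set private counts, with the partition identity (private +
shared-with-at-least-one = total) verified internally.

**Burden.** Mutations per megabase of the interrogated region. The per-Mb
normalization is a convention of this package's reporting, chosen so that
burden is comparable across regions of different size; comparisons are only
meaningful over a common region, which is the point of the unified space.

## The detectability model

A tumor at purity $\rho$, copy-neutral diploid, gives an expected somatic
allele fraction $\rho/2$ for heterozygous and $\rho$ for homozygous
mutations — at 30% purity, 15% and 30%. With $K \sim
\mathrm{Binomial}(d, v)$ alternate reads at depth $d$, a caller that
requires `minAltReads` alternate reads, a `minVaf` observed fraction and a
`minDepth` site depth calls the mutation with probability

$$P\!\left(K \ge \max(\mathrm{minAlt}, \lceil \mathrm{minVaf}\cdot d\rceil)\right),$$

an exact binomial tail (zero below the depth floor). Thresholds apply to
the realized fraction $K/d$, mirroring caller behavior. Inverting the
purity model gives the minimum tumor content at which the expected VAF
reaches a cutoff: $2 \times \mathrm{minVaf}$ for heterozygous mutations —
30% tumor content for the common 15% cutoff at ~100x exome depth. The 15%
default for `minVaf` is a configurable parameter, not a law; it reflects
the cutoff at which ~100x exomes call with confidence.

Numerical care: the threshold count uses `ceiling(minVaf * d - 1e-9)`
because products like `0.05 * 100` exceed 5 in binary floating point, which
would silently shift the tail by one read.

## The simulator

The simulator operates at the call level — no reads, no alignment — because
the artifact under study is the comparison analysis, not the caller. Its
defaults define the study conditions the package is validated under:

* **Genome and panel.** A 10 Mb toy genome (two 5 Mb contigs); a 2 Mb
  common panel of 5 kb tiles standing in for a gene panel.
* **Truth.** Mutations planted uniformly without replacement genome-wide,
  alternate allele uniform over the three non-reference bases, heterozygous
  with probability `hetFraction`. Three preset samples: a purity-0.30
  mixture with 178 truth mutations (the sensitivity benchmark), a
  hypermutated sample (3000 mutations, purity 0.60), and a low-burden
  sample (500 mutations, purity 0.50). The 3000/500 genome-wide counts
  were chosen so that roughly 600 and 100 mutations fall in the 2 Mb
  panel — the scale a mismatch-repair-deficient versus a microsatellite-
  stable tumor shows over a comparable panel.
* **Laboratories.** Five profiles spanning the heterogeneity that drives
  discordance: capture = panel plus lab-specific extra tiles (0.5–2 Mb);
  mean depth 80–180x with negative-binomial per-site depth (dispersion
  3–10; a standard overdispersed coverage model — real exome coverage is
  also locally correlated, which this independent-site model ignores);
  thresholds from hyper-permissive (VAF 0.02, 2 reads) to strict (VAF
  0.10, 5 reads); artifact rates 2–60 false calls per capture Mb;
  germline-leak rates 0.002–0.05 of a 500-variant shared pool. One lab
  runs a single replicate, and is absent from the mixture sample, so the
  not-available path is always exercised. These profiles are qualitative
  gestures at the spread real vendors show, not calibrated estimates.
* **Mechanics.** Per truth mutation in capture: depth ~ NB(mean,
  dispersion), alternate reads ~ Binomial(depth, expected VAF), called iff
  the lab's thresholds pass on realized values. Sub-threshold candidates
  with at least one supporting read can be retained with FILTER
  `low_confidence`, which is how simulated studies let the unified
  analysis re-threshold under one rule. Artifact calls ~ Poisson(rate x
  capture Mb) at uniform capture positions with observed fractions drawn
  from a low range (0.02–0.25), optionally biased toward C>T/G>A changes
  (`fpTransitionBias`) to mimic FFPE-style deamination damage; they carry
  PASS because the originating pipeline believed them. Germline leaks draw
  from the shared pool at fraction 0.5/1.0. Replicate seeds are
  `masterSeed + lab seedOffset + replicate index`, so any replicate is
  regenerable in isolation and identical configurations give byte-identical
  output files.

What passing simulation-based tests shows — and what it does not: the
pipeline's algebra, thresholds and accounting are correct under a model
with independent sites, binomial sampling and representative heterogeneity.
Real data add correlated coverage, mapping artifacts, subclonality and
copy-number variation, none of which the simulator models; sensitivity
measured in the toy study also reflects the toy captures covering only part
of the toy genome, unlike real exome kits over real exonic truth sets.

Under this model the expected replicate concordance has a closed form:
with $N$ truth mutations in capture, per-mutation detection probability $p$
(binomial tail marginalized over the depth law) and $F$ expected artifact
calls per replicate (artifacts essentially never recur at the same key),

$$\mathbb{E}[\mathrm{concordance}] \approx 100 \,\frac{N p^2}{N p + F},$$

which the test suite verifies by Monte Carlo, along with the headline
qualitative pattern: re-thresholding all laboratories' candidate calls
under one harmonized cutoff and restricting to the common panel raises
median cross-laboratory concordance in essentially every seeded run.

## The two-level study pipeline

`runStudy()` reads a YAML study configuration (labs, samples, per-replicate
call files — VCF or schema-mapped delimited text — panel and capture BEDs,
optional truth VCFs) and computes both comparison levels from one pass over
the files: vendor space (PASS calls as delivered) and unified space (all
candidates, harmonized thresholds, panel-restricted). The harmonized
default, VAF ≥ 0.10 with ≥ 4 alternate reads and ≥ 14x depth, sits between
the permissive and strict ends of the preset laboratories; it is a
parameter, and any `CallerThresholds` can be supplied. Outputs are
delimited tables mirroring the published layouts plus one structured JSON
with a schema version and input checksums; reruns on identical inputs are
byte-identical, and per-stage key counts are logged so one can see where
discrepancy enters.

Problem sizes in the shipped tests were chosen to keep the full suite
comfortable on a laptop: the end-to-end study uses a 1 Mb genome with two
laboratories, the Monte Carlo checks use 2000 detection draws and 50
replicate pairs, and the vendor-versus-unified contrast runs 100 seeded
five-laboratory simulations.

## Known limitations

* No reference genome: indels are trim-normalized, not left-aligned;
  reports using different anchor representations of the same indel can
  evade key equality. The `leftAlign` hook exists for this.
* Copy-neutral purity model; no CNV, no subclonal fractions.
* The simulator's artifact and leak rates are plausible gestures, not
  estimates of any laboratory's behavior.
* Genotype-aware comparison, phasing and consequence annotation are out of
  scope; keys are site+change only.

## A worked example

```{r example, eval = FALSE}
pre <- cohortPresets(masterSeed = 1)
dir <- tempfile()
simulateStudy(pre$configs, dir)
res <- runStudy(file.path(dir, "study.yaml"),
                outputDir = file.path(dir, "results"))
res@concordance
```
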