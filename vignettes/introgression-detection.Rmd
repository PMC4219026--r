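---
title: "Detecting wild-species introgressions from windowed SNP density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting wild-species introgressions from windowed SNP density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
library(data.table)
```

## The model

A domesticated inbred resequenced against its species' reference genome
shows a very low background SNP density — the two genomes descend from the
same narrow domestication bottleneck — except where one of them carries a
segment introgressed from a wild relative. Wild-species divergence is one to
two orders of magnitude higher, so introgressed segments appear as sharply
bounded runs of SNP-dense windows. introscan formalizes this as:

* SNPs are binned into non-overlapping windows of width $W$ (default
  10 kb). Only distinct substitution keys (chromosome, position, alternate
  allele) are counted.
* A *SNP peak* is a maximal run of windows such that (i) the first and last
  window each hold at least $t$ SNPs (default $t = 10$), (ii) every maximal
  interior run of below-threshold windows spans at most $G$ (default
  40 kb), (iii) the run spans at least $S$ (default 50 kb), and (iv) it
  contains at least $S/W$ qualifying windows.

The gap allowance exists because truly introgressed sequence is *harder* to
map against the reference: read coverage collapses inside diverged regions,
producing interior windows with spuriously few called SNPs. $G$ must stay
below $S$ so a "peak" can never be mostly gap.

### Why a per-gap bound, not a gap budget

The gap rule is applied to each maximal interior run of below-threshold
windows independently — a region may contain several 40-kb gaps, but never a
single longer one. The alternative (a 40-kb *total* gap budget) reads less
naturally from the phrase "continuous gaps", makes maximal segments
non-unique (splitting a region changes how budget is spent), and couples
distant parts of a region. Under the per-gap rule, maximal valid segments
are exactly the chains of qualifying windows linked by gaps of at most
$G/W$ windows, which makes them unique, disjoint, and cheap to compute; the
test suite verifies equivalence against a brute-force enumeration of every
candidate segment.

## Threshold calibration

The per-window threshold $t$ is not arbitrary: it is chosen so that peaks
absorb a statistically significant excess of SNPs. For each candidate
$t \in \{3, 5, 10, 15, 20\}$, peaks are called and two window-count samples
are compared with a two-sample, two-sided Student's $t$-test (pooled
variance — a Welch option exists but the classical test is the default,
matching the method's published description): all windows of the genome
versus the windows outside every called peak. `recommend_threshold()`
returns the smallest candidate with genome mean above non-peak mean at
$p < \alpha$ (default 0.05).

Two subtleties, deliberately surfaced rather than hidden:

* **Direction of the rule.** The source method's results prose swaps its
  significance labels relative to its printed p-values, and its final choice
  corresponds to the smallest *non*-significant candidate. We implement the
  logic its methods section states — peaks at an acceptable threshold
  capture significantly more than background — because it is the
  self-consistent reading; on data where even $t = 3$ yields significant
  absorption, this rule recommends 3, not 10. The full calibration table is
  always returned so users can apply their own decision rule.
* **Overlapping samples.** The genome-wide sample *contains* the non-peak
  sample, as in the original procedure. The test is therefore conservative
  in the direction that matters: it only weakens the apparent excess.

When a threshold calls no peaks the two samples are identical and the row is
reported with $t = 0$, $p = 1$; when every window lands in a peak the row is
flagged degenerate with no p-value. Chromosomes whose peaks cover most of
their length can be excluded from both samples (`exclude_chroms`), the
standard practice when one or two chromosomes carry mega-introgressions that
would dominate the genome-wide mean.

## Origin classification

Against a panel of sequenced genomes — wild *donors* and an
introgression-free *heirloom* — each window of a peak "matches" an accession
when at least `match_min` SNP keys are shared (default 10, the same boundary
as the peak rule; sharing requires the same alternate allele, since
position-only coincidences are independent mutations). The peak label is:

1. `reference_introgression` if the heirloom matches at least half the
   windows. Shared divergence with a line that has no wild introgressions
   cannot come from the query: it implicates wild sequence in the reference
   assembly itself. Heirloom evidence takes precedence over donor evidence
   at equal support for the same reason — the donor that supplied the
   *reference's* segment will also match.
2. `donor:<id>` for the unique donor matching at least half the windows
   (ties → `unknown`).
3. `unknown` otherwise. Unknown peaks are still emitted: real scans leave
   many origins open, pending sequencing of more wild accessions.

The 0.5 *window-fraction* majority is a stated stand-in for an informal
"majority of SNPs shared" criterion; window fractions were chosen over SNP
fractions so that mixed peaks decompose cleanly into subsegments (maximal
runs of same-labeled windows, which tile the peak), but both metrics are
reported in the evidence table.

## Breakpoint refinement

Peak boundaries are window-aligned. For SNP-resolution boundaries the
*donor-unique* SNP set is used: keys shared by query and assigned donor,
absent from every other panel genome, with query depth strictly above 10
reads and alternate-allele fraction strictly above 0.9 (both exclusive, as
the criterion is worded). Records lacking allelic depths fail the filter —
frequency must be evidenced, not presumed. The first and last donor-unique
positions inside the peak are reported 1-based. With donor divergence rate
$r$ the expected spacing of informative SNPs is $\approx 1/r$ after filter
thinning, which bounds the expected boundary error.

## The synthetic world

The simulator emulates exactly the statistical structure the detector
exploits; its defaults are fixed, not tuned:

* **Divergence rates.** Donor defaults 3.5×10⁻³/bp (pimpinellifolium-like)
  and 10⁻²/bp (chilense-like) are the published whole-genome SNP rates of
  those wild accessions against the tomato reference. The domesticated
  background default is 3.7×10⁻⁵/bp. The published genome-wide figure for a
  resequenced inbred is 0.037% = 3.7×10⁻⁴, but that number *averages over
  the line's introgressions*, which contain the majority of its SNPs; the
  introgression-free background must sit well below it, and one tenth is the
  value the build contract itself states for the generator. At 0.37
  SNPs/window the background essentially never crosses even the smallest
  calibration candidate, so introgression-free genomes recommend no
  threshold — the property a sound calibration must have.
* **Mosaic structure.** Donors get genome-wide Poisson SNPs at their rate
  with uniformly chosen alternate alleles; reference bases at SNP positions
  are a deterministic function of (chromosome, position) so all accessions
  are consistent. The query copies the donor's records verbatim inside
  planted query segments. Inside planted *reference* segments both the query
  and the heirloom copy the donor's records — the shared-with-heirloom
  signature the classifier keys on. Elsewhere query and heirloom receive
  private background SNPs.
* **Read support.** Depths are Poisson(30); allele fractions are
  Binomial(depth, 0.99)/depth for homozygous calls, with a 2% contamination
  fraction drawn at Binomial(depth, 0.5)/depth to exercise the
  allele-fraction filter.
* **Determinism.** One master seed derives a hashed substream per
  (accession, chromosome), so outputs are byte-identical across runs and
  adding an accession never perturbs the others.
* **Default scene.** One 20-Mb chromosome; five chilense-like query
  segments of 0.1–2 Mb at deliberately non-window-aligned coordinates; two
  pimpinellifolium-like reference segments (0.45 and 0.8 Mb).

**What a green test does not establish.** The simulator omits coverage
gaps and unmappable regions (zero-coverage windows are indistinguishable
from zero-SNP windows in this input model), repeat-driven false SNP
clusters, indels, heterozygous residual segregation, and recombination
within introgressed segments. Recovery at 100% recall/precision in this
world validates the algorithmic contracts, not performance on real
resequencing data.

## Numerical and boundary choices

* Internal coordinates are 0-based half-open; VCF input (1-based) and BED
  output conversions happen only at I/O boundaries. Breakpoints are
  reported 1-based.
* All cutoffs follow their wording: peak threshold is inclusive
  ($\ge 10$ SNPs), depth and allele-fraction filters are exclusive
  ($> 10\times$, $> 0.9$), window match is inclusive ($\ge$ `match_min`).
* Multi-allelic VCF sites are split per ALT; only single-nucleotide
  REF/ALT pairs are kept. Records not passing FILTER (other than `.`) are
  dropped. Duplicate keys within one accession collapse to the
  highest-depth record.
* The final, truncated window of each chromosome is binned and compared
  like any other with no per-bp normalization (raw counts per window are
  the unit throughout); a peak ending there spans slightly less than a
  multiple of $W$.
* Array-marker mode defaults to marker clustering (consecutive polymorphic
  markers fitting in the span) rather than fixed tiling, so detection does
  not depend on window phase; tiled mode is available for comparison with
  tile-based reports.

## Known limitations

* Coverage-based evidence (read-depth dips that corroborate introgressions)
  is out of scope; only SNP density is used.
* The heirloom-precedence rule cannot distinguish a reference-genome
  introgression from a query introgression *at the same location* derived
  from the same donor haplotype.
* Student's pooled-variance t-test on overlapping, non-normal count samples
  is a pragmatic replication of the established procedure, not an exact
  test; treat calibration p-values as a ranking heuristic.
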