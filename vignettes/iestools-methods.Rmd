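---
title: "Models and methods behind iestools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind iestools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iestools)
```

# Scope and coordinate conventions

`iestools` analyzes programmed DNA elimination in ciliates from short-read
alignments to a germline-inclusive ("MAC+IES") reference: somatic
(macronuclear, MAC) sequence with the Internal Eliminated Sequences (IESs)
inserted. All internal coordinates are 0-based half-open; GFF3 input and
output convert to and from 1-based inclusive at the file boundary, so
interval arithmetic inside the package never needs ±1 corrections.

IESs in *Paramecium* are bounded by a TA dinucleotide on each side, one copy
of which is retained at the somatic junction after excision. The package
adopts the convention that the annotated interval *includes* the upstream
TA (the sequence begins `TA`) while the downstream TA sits immediately
outside the interval and is the retained copy. Under this convention the
gap opened in a correctly excised read has exactly the annotated IES
length, which keeps read-level and annotation-level length distributions on
the same axis. Published annotations do not state which flanking TA they
include; if a real annotation set follows the opposite convention its
intervals must be shifted by two bases on one side before use
(`validate_ta_boundaries()` reports per-IES pass/fail and will make the
mismatch obvious immediately).

Excision is a double-stranded event, so all events are recorded on the
forward strand; reverse-strand alignments are reduced to forward-strand
intervals before event calling. `N` bases never match `TA`.

# Retention scoring

For IES $i$, let $a$ and $b$ be the numbers of reads aligning across the
left and right boundary with at least `min_flank` (default 5) aligned bases
on each side and no gap at the boundary, and let $c$ be the number of reads
carrying a gap that matches the IES interval exactly, again with at least
`min_flank` aligned bases on each side of the junction. The retention score
is

$$\mathrm{IRS} = \frac{a + b}{a + b + 2c},$$

0 for complete excision and 1 for complete retention. The factor 2 reflects
that a retained fragment can be counted at both boundaries while an excised
fragment carries a single junction; with symmetric flank requirements the
score is an unbiased estimate of the per-molecule retention probability.
This symmetry is why $c$ is counted with the same `min_flank` rule used for
$a$ and $b$ rather than with the stricter anchors used for event *calling*
(below): mixing a 5-base flank for retention with a 10-base anchor for
excision would shrink the excision observation window by ten read positions
and bias the score upward by up to ~0.03 at intermediate retention.
`min_flank = 5` is small enough to score first-peak (26–31 bp) IESs from
short reads.

An IRS is missing (`NA`), never imputed, when $a + b + 2c = 0$; missing
values are excluded pairwise from replicate correlations
(`irs_correlation()`, ordinary Pearson). `irs_by_length()` summarizes
scores in 1-bp length bins up to 150 bp and coarser bins beyond;
`subterminal_base_frequencies()` tabulates the three bases just inside each
TA end (the right end read on the reverse complement, where the TA is its
own reverse complement), per IRS bin and optional length class.

# Excision-event detection and classification

Alignments are parsed with Rsamtools/GenomicAlignments (SAM input is
converted to BAM internally); secondary, supplementary, unmapped and
low-mapping-quality records are dropped (`min_mapq` default 10). Candidate
excisions are CIGAR `D` or `N` operations — real spliced mappers emit `N`
for large gaps — of length at least `min_gap` (default 20 bp, below the
shortest real IES peak at 26 bp but above small indel noise) flanked by at
least `min_anchor` (default 10) aligned bases on each side within the read.
A read with two qualifying gaps contributes two candidate events, since
neighboring IESs can co-occur on one fragment.

A candidate gap is accepted only if the excised segment begins with `TA`
and the reference carries another `TA` immediately downstream of the gap —
the same two-TA/one-retained structure as canonical IESs; failures are
recorded with reasons (`no-TA-left`, `no-TA-right`). Accepted gaps are
matched to the annotation by interval arithmetic: exact match → `CORRECT`;
contained in the matched IES → `ALT_INTERNAL`; containing it →
`ALT_EXTERNAL`; one-sided partial overlap → `ALT_OVERLAPPING`; no overlap →
`CRYPTIC`. When a gap overlaps several IESs the match maximizes reciprocal
overlap, with ties broken by smaller absolute length difference and then by
the leftmost IES — deterministic and purely overlap-driven. Identical gaps
are merged with read support accumulated.

Headline statistics follow read-based definitions:
$\mathrm{alt\%} = 100\,n_\mathrm{alt}/(n_\mathrm{alt} + n_\mathrm{correct})$
over excised reads, and
$\mathrm{cryptic\%} = 100\,n_\mathrm{cryptic}/n_\mathrm{all}$ over all
mapped reads. The fraction of IESs with alternative excision uses all
annotated IESs as denominator (an IES with at least `min_reads` = 1
supporting reads counts). Excised-length histograms use 1-bp bins and are
read-weighted by default (an event-weighted switch exists);
`ALT_OVERLAPPING` events enter the external histogram, since they extend
beyond the annotated interval on one side. The "forbidden peak" — the
strongly suppressed second IES length class — is quantified as histogram
mass in a fixed, configurable window, default [32, 38] bp around the ~35 bp
center, in preference to any peak-fitting: a fixed window is reproducible
and monotone in the underlying signal.

# Nucleosome-density profiling

Nucleosomal libraries are filtered to properly paired fragments with outer
distance (template length) in [100, 175] bp, inclusive on both ends — the
mononucleosome range around the 147 bp core particle. A fragment or read
counts toward an IES when at least `min_overlap` = 9 of its aligned
(non-gap) bases fall inside the interval; a read whose deletion spans the
IES contributes nothing to it. The fixed 9-bp rule is used instead of a
fractional overlap so behavior does not depend on read length. Per-IES
density is normalized against a DNA-seq library from the same developing
nuclei:

$$r_i = \frac{n_i / N}{d_i / D},$$

with $N$ and $D$ the post-filter library totals; $r_i$ is missing when
$d_i = 0$, and no parental-MAC correction is applied. Libraries of unequal
depth can be equalized with `downsample_reads()`, a pair-coherent Bernoulli
subsample (both mates share the keep decision). This reproduces the
downsampling statistically, not bit-for-bit like `samtools view -s`;
determinism comes from the function's own seed.

Densities are stratified into weakly (IRS < 0.2) and strongly (IRS ≥ 0.2)
retained IESs, overall and within length strata (defaults: first length
peak 26–31 bp; first non-periodic lengths 150–200 bp), and compared with a
two-sample Kolmogorov–Smirnov test. `ks_two_sample()` computes the exact
$D$ statistic by an ECDF sweep over the pooled unique values and the
p-value from the asymptotic Kolmogorov distribution at
$\sqrt{mn/(m+n)}\,D$; the asymptotic choice is declared rather than exact
small-sample inversion because the stratified comparisons involve hundreds
to thousands of IESs where the two agree.

# The synthetic-data generator

The generator exists so that every stage can be tested against known truth
without external downloads; it emulates the features of the organism's
germline genome that the pipeline is sensitive to, at toy scale:

* **Sequence composition**: ~72% AT, matching the organism and hence the
  natural density of TA sites that alternative excision can use.
* **IES structure**: every IES begins with `TA`, is followed by the
  retained downstream `TA`, and is separated from its neighbors by at least
  one read length of MAC-destined sequence. One extra TA site is planted
  just outside and just inside each boundary (offsets 3–4 bp), so an
  alternative TA pair always exists within ±20 bp — mirroring the
  observation that erroneous excision uses the next closest available
  sites.
* **Length model**: a mixture over periodic length peaks centered at 28,
  35, 45 and 55 bp with default weights 0.55, 0.02, 0.25, 0.18 — the ~35 bp
  second peak ("forbidden") nearly absent, as in wild-type excision.
* **Excision truth**: a fragment overlapping IES $i$ retains it with
  probability $\rho_i$; otherwise it is excised at the canonical pair with
  probability $1 - \alpha_i$, else at an alternative TA pair drawn from
  sites within ±20 bp of the canonical boundaries with geometric-by-rank
  weights favoring near offsets. Cryptic excisions between MAC-destined TA
  pairs occur at rate $\kappa$ per read per kb spanned. Gaps are emitted as
  CIGAR deletions; reads are pre-aligned (true coordinates) so no external
  mapper is needed, with FASTQ also written for real-mapper workflows.
* **Nucleosomal fragments**: midpoints drawn at rate 1 per bp over
  MAC-destined sequence and $\lambda_i$ over IES $i$; outer sizes from a
  normal (mean 147, sd 15) truncated to [80, 250] bp so the [100, 175]
  filter is exercised on both sides.

Everything is deterministic given the `sim_config()` seed (mandatory);
repeated runs are byte-identical, and per-read truth categories
(retained / correct / alternative / cryptic / non-IES) partition all reads.

## What the generator does and does not show

The simulator covers uniform substitution errors but no indel errors, PCR
duplicates, mappability artifacts, chimeric reads, or parental-MAC
contamination, and treats excision decisions as independent across
fragments. Tests passing on synthetic data therefore demonstrate the
correctness of the *computations* — counting rules, classification
geometry, normalization, statistics — not robustness to every artifact of
real libraries. The coupling between retention and nucleosome density is
deliberately a free parameter ($\rho$ and $\lambda$ set independently): the
generator does not assert a biological model linking them, only provides
the dial that stratified comparisons can then detect.

# Calibration experiments and their problem sizes

The test suite and `scripts/acceptance.R` verify parameter recovery under
fixed study conditions, chosen as what the estimators need to be
informative:

* **Retention**: 200 IESs with $\rho_i \sim U(0,1)$ at 100× depth. The
  binomial reference uses $(a+b)/2 + c$ as the per-IES sample size — the
  number of independent boundary-informative *molecules*, since a retained
  fragment spanning a short IES is counted at both boundaries.
* **Alternative excision**: $\alpha = 0.10$ at ≥ 10⁴ excision reads; the
  fraction of IESs with ≥ 1 alternative read is checked against the
  occupancy oracle $1 - (1 - \hat p)^{n_i}$.
* **Density**: multipliers $\lambda \in \{1, 2, 3\}$ over 100 IESs each,
  with IESs 2 kb long on a genome where they occupy < 10% of the sequence
  and ≥ 50 fragments per IES. Two properties of the generative model force
  these sizes: fragments whose midpoints lie in the rate-1 background but
  still overlap an IES by ≥ 9 bp dilute the per-IES contrast by a factor of
  roughly $(\lambda\ell + c)/(\ell + c)$ with $c \approx$ the mean fragment
  span minus twice the overlap threshold (~125 bp), so the IES must be long
  relative to the nucleosome footprint; and the library-total normalization
  anchors $r = 1$ at the genome-wide average rate, so IESs must be a small
  genome fraction (as they are in the real genome) for the $\lambda = 1$
  group to sit near 1. At first-peak IES lengths (26–31 bp) the footprint
  dilution dominates and per-IES $\lambda$ recovery is not achievable by
  any counting rule with a ±73 bp reach; the stratified KS comparison, not
  per-IES recovery, is the appropriate instrument there.
* **Kolmogorov–Smirnov**: $\lambda = 2$ vs $\lambda = 1$ groups of 200 IESs
  separate with $D > 0.2$ at $p < 0.01$; the $D$ statistic is verified
  against a quadratic-time ECDF oracle to 10⁻¹².

# Degenerate inputs and numerical choices

Empty alignment sets yield empty event tables and all-missing scores, not
errors. Gaps at read edges are trimmed rather than emitted as leading or
trailing deletions. An IRS, density $r$, or percentage whose denominator is
zero is `NA`. The mononucleosome bounds are inclusive on both ends (the
source methods say "between 100 and 175 bp" without stating inclusivity;
inclusive is declared here). Downsampling fractions must lie in (0, 1];
`fraction = 1` is the identity. The Kolmogorov survival series is truncated
at 100 terms and clamped to [0, 1], ample for double precision.

# Known limitations

* No realignment or left-normalization of gaps beyond TA-boundary
  canonicalization; a mapper that places a gap inconsistently between reads
  can split one event's support across coordinates.
* No base-pair-resolution nucleosome positioning or dyad calling: short
  IESs do not support it, and per-IES aggregate density is the designed
  readout.
* The criterion by which an IES counts as "sensitive" to a given knockdown
  is not modeled; the package reports score distributions and leaves
  thresholds to the analyst.
* Real-data alignment is out of scope: the package consumes SAM/BAM from
  any gapped mapper and emits FASTQ for that purpose, but never invokes
  one.
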