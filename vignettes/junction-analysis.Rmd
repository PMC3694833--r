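---
title: "Classifying and comparing NHEJ repair junctions from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and comparing NHEJ repair junctions from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhejseq)
```

## The problem

A site-specific endonuclease such as HO cuts a chromosomal locus leaving
4-nucleotide 3' overhangs. Non-homologous end joining (NHEJ) either restores
the cut site exactly (precise religation, which is re-cleavable so repeated
cutting enriches for everything else) or produces an *imprecise* joint:
partial overhang annealing followed by fill-in (duplicating unannealed
overhang bases), microhomology-mediated joining after limited resection
(deleting sequence), blunt-type joining with short non-templated insertions,
or combinations of these. Deep sequencing of a PCR amplicon spanning the cut
yields hundreds of thousands of reads per sample; the analysis task is to
enumerate every joint the two ends could form, assign each read to one
joint, summarise joint frequencies, and test which joints differ in
frequency between strains.

`nhejseq` implements that pipeline end to end, together with a synthetic
read generator that emits ground truth for every dataset so each stage is
testable without any external data.

## The joint model

All coordinates are 1-based on the reference top strand. A cut is `(t, v)`:
`t` is the position of the most distal base of the left end's overhang
region, `v` the overhang length. The single-stranded window is always
`top[t-v+1 .. t]`; a polarity flag records which fragment physically
carries the top strand of that window (3' overhangs by default, the HO
geometry; 5' overhangs and blunt cuts are the mirror/degenerate cases and
share the same product algebra).

A repair product is described by five fields:

* `L`, `R` — bases deleted from the left / right end, measured from the
  most distal base of the overhang;
* `M` — microhomologous base pairs annealed at the junction (appearing once
  in the product);
* `I` — 0–2 non-templated inserted bases, read from the top strand;
* `D` — the net size change, fixed by the others:
  `D = v - L - R - M + |I|`.

The repaired top strand is

```
product = top[1 .. t-L] + I + top[t-v+R+M+1 .. N]
```

and a joint with `M > 0` is only physical when the `M` junction bases
retained on the left equal the `M` right-end bases they stand in for
(`top[t-L-M+1 .. t-L] == top[t-v+R+1 .. t-v+R+M]`) — this is the annealing
constraint, and it is checked literally. The precise joint is
`L = R = 0, M = v, I = ""` and reproduces the reference exactly. Insertions
are restricted to `M = 0` junctions: a templated (microhomology) and a
non-templated explanation of the same bases would otherwise be
indistinguishable, and treating them as alternative joint classes keeps
joint identity well defined.

Many descriptor quadruples can generate the same product string (for
example `(L=1, M=v-1)` always reproduces the intact sequence). Enumeration
therefore deduplicates by product sequence and keeps a *canonical*
descriptor: maximum `M`, then minimum `|I|`, then minimum `L`, then minimum
`R`. The ordering is a convention — no rule is inherent in the biology —
chosen so templated explanations beat non-templated ones and identifiers
are deterministic. Identifiers render as `D{+n|-n|0}_M{m}_L{l}_R{r}` with
`_I{seq}` (lower case, the usual convention for non-templated bases)
appended for insertions, and the precise joint simply as `precise`.
Classic short aliases are available for the two simplest classes: `+XY`
for pure fill-in duplications and `-XYZ` for pure deletions whose deleted
segment cannot slide along a flanking repeat.

```{r}
loc <- dsb_locus("AAAACGTACGTTTT", cut_pos = 8, overhang_len = 4)
d <- joint_descriptor(L = 1, R = 0, M = 0, I = "", overhang_len = 4)
product_sequence(d, loc)   # fill-in duplication, D = +3
encode_joint_id(d)
```

Default enumeration limits are `L_max = R_max = 25`, `M_max = 10`,
insertions over `{A,C,G,T}` up to 2 nt — deletions are bounded only by the
requirement that the read still covers the junction (with 3 flanking
bases), since no biological bound exists.

## Read classification

Reads carry a 6-base inline sample index followed by amplicon sequence.
Demultiplexing is exact (no index mismatch tolerated; 6-mers are short, and
the bundled index sets keep pairwise Hamming distance at least 2).
Contaminant (spike-in control) reads are removed first by a self-contained
shared-k-mer filter: a read is contaminant when at least half of its
21-mers occur in the contaminant reference (both strands). Any predicate
with the same signature — for instance an aligner-based filter — can be
substituted.

Joint assignment needs no gapped alignment: insertions and deletions are
already distinct full-length read templates, so each read is compared to
every template by Hamming distance with the index masked. The nearest
template wins when its distance is within the one-mismatch tolerance
*and* no other template ties at that distance; a tie makes the read
`ambiguous`, and a minimum above the tolerance makes it `unmatched`. We
use the tie-at-minimum rule rather than "more than one template within
tolerance" because 1-nt insertion joints always have sibling templates at
Hamming distance 1: under the literal within-tolerance rule no error-free
insertion read could ever be assigned. Reads shorter than the layout are
compared over their overlap but must cover the junction ± 3 bases.
Classification is conservative by accounting: every read lands in exactly
one of joint / ambiguous / unmatched / contaminant / unassigned-index /
truncated, and the totals are checked to sum exactly.

One residual bias is worth knowing about: the joint space legitimately
contains net-zero-length junction variants (delete `n`, insert `n - v`
non-templated bases) whose products sit at Hamming distance 1–2 from the
intact sequence. An intact-allele read with one sequencing error can
therefore tie with such a variant and be dropped as ambiguous, or — when
the error lands exactly on the variant base — be assigned to it. At a
0.2% per-base error rate this depresses the recovered precise fraction by
roughly 1.5 percentage points relative to the planted truth. This
confusion between sequencing error and bona fide single-base junction
variation is irreducible for any classifier tolerating one mismatch;
fractions of strongly represented joints are otherwise recovered within
binomial sampling error.

## Summaries

Joint fractions are counts over the per-sample total of *joint* rows only;
ambiguous and unmatched reads are reported separately as fractions of all
reads (a flagged alternative would include them in the denominator, but
excluded is the default because the quantities of interest are relative
joint usages). A joint is a *major imprecise joint* when its fraction
reaches 0.1% (inclusive) in at least one sample; the remainder are
`other`, and the precise joint is its own category.

Two colony-assay calculators accompany the sequencing path, because
single-DSB plating assays summarise the same biology at colony resolution:
`precise_percent()` (re-cleavable survivors over tested survivors) and
`ade_minus_summary()`, which extrapolates junction-PCR results from a
tested subsample of marker-loss colonies to percentages of all colonies.
Both round half-up to integer percent — half-up, not banker's rounding,
because that is the convention that reproduces such printed tables
consistently.

## Differential joint frequencies

Raw counts (never fractions) enter a two-condition negative-binomial test
in the classic count-table style:

1. **Size factors** — median over joints of the ratio of each sample's
   count to the joint's geometric mean across samples.
2. **Dispersion** — per-joint method of moments on normalised counts,
   `alpha = max(0, (s^2 - mu)/mu^2)` averaged over conditions
   (`var = mu + alpha mu^2`; `alpha = 0` is Poisson). With two replicates
   per condition these estimates are very noisy, so the default blends
   them with a mean-dispersion trend — least squares of the *unclamped*
   estimates on `1/mu` over joints with mean normalised count at least 5 —
   taking per joint the maximum of fitted and individual values (floor
   `1e-8`). The maximum rule is deliberately conservative; fitting on
   unclamped estimates avoids the upward selection bias that clamping
   before fitting would introduce, and the count floor keeps
   noise-dominated joints out of the fit.
3. **Exact test** — condition on the total `k = kA + kB` of the summed
   counts per condition; each margin is NB with mean scaled by the summed
   size factors and the joint's dispersion; the p-value is the mass of all
   splits no more likely than the observed one, renormalised over all
   splits. In the `alpha -> 0` limit with equal size factors this is the
   exact binomial test. One non-obvious property: under strong
   overdispersion at low counts the conditional split distribution is
   U-shaped, so an exactly equal split can itself be the least likely
   outcome and receive p < 1.
4. **Multiplicity** — Bonferroni over all joints tested, significance at
   adjusted p < 0.005 by default, direction from the sign of the log2
   fold change (condition B over the reference A, chosen explicitly via
   `reference`).

`nhej_diff()` returns a classed data.frame with `print`, `summary` and
`plot` (MA plot) methods.

## What the synthetic generator emulates — and what it does not

`make_spectrum()` encodes the study conditions the pipeline is meant to
measure: before induction 98.5% intact cut sites; after 24 h of continuous
re-cleavage 60% precise / 40% imprecise for repair-proficient strains; 97%
precise for the ligase-null strain (dead cells contribute uncut alleles).
The imprecise mass is a seeded symmetric Dirichlet draw (concentration
0.3) over the enumerated joint space — long-tailed, with a few tens of
major joints, as such experiments show. The catalytic-mutant spectrum
shares the wild-type base profile (same seed) and plants exact 3-fold
changes on 15 increased and 16 decreased major joints; decreases are taken
from the largest joints and increases from a mass-balancing set so that
the overall major-joint frequency stays similar between strains — which is
both what the emulated experiment showed and what keeps median-of-ratios
normalisation undistorted.

`simulate_reads()` renders spectra as indexed reads with i.i.d.
substitution errors (default 0.2% per base, a typical short-read
substitution rate) over the whole read including the index, plus a
contaminant spike-in (default half of all reads, emulating a heavy control
library) drawn as random windows of either strand of a bundled synthetic
5 kb reference. Defaults: 100,000 reads per sample. That depth is a
deliberate power choice: the weakest planted major joint (~0.18%) needs
roughly 50,000 joint reads per sample for a 3-fold change to clear a
Bonferroni-adjusted 0.005 threshold over ~650 tests with 2+2 replicates —
the emulated experiment itself was sequenced far deeper. Tests and
examples scale down (1,000–12,000 reads) where only correctness, not
power, is at stake; the bundled synthetic locus is 240 bp with the cut at
position 110 and a `CACA` overhang, and simulations enumerate its joint
space with `L_max = R_max = 6`, `M_max = 4` (~650 joints) to keep template
scans cheap.

Features of real data deliberately not modelled: quality scores (the
classifier ignores them by default; methods based on this assay did not
quality-filter), sequencing indel errors (they would be confounded with
bona fide insertion joints under mismatch-only matching), PCR chimeras and
jackpot amplification, resection-mediated deletions extending beyond the
read, and templated insertions copied from distal sequence. Passing tests
therefore demonstrate correctness of the accounting, the enumeration
algebra and the statistics under substitution noise — not robustness to
indel-rich or chimeric libraries.

## Numerical and degenerate-case choices

* Rounding of colony percentages is half-up (`floor(x + 0.5)`).
* The exact test compares split likelihoods with a `1e-7` relative slack
  so ties at the observed likelihood are included despite floating-point
  noise; p-values are clamped into `(0, 1]`.
* Joints with zero counts everywhere get p = 1; zero-total samples are an
  error for fraction tables.
* `v = 0` (blunt cut) degenerates cleanly: the precise joint is the blunt
  religation, overhang strings are empty.
* Joints whose read templates are identical within the read window are
  intrinsically ambiguous; the generator never plants mass on them and
  the classifier routes their reads to `ambiguous` via the tie rule.
* All simulation entry points take a mandatory seed, restore the caller's
  RNG state, and are byte-reproducible given the seed.

## Known limitations

* The tie-at-minimum ambiguity rule and the 1.5-point precise-fraction
  bias discussed above.
* With two replicates per condition the dispersion trend dominates the
  blend; genuinely joint-specific overdispersion below the trend is
  invisible.
* The Moore–Haber alias declines to name deletions that can slide along a
  repeat; such joints keep only their descriptor identifier.
* The contaminant filter is k-mer exact; a contaminant diverging more than
  ~5% from its reference would partially escape at the default threshold.
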