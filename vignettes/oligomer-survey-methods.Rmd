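---
title: "Methods: surveying abundant mid-length oligonucleotides"
author: "oligosurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying abundant mid-length oligonucleotides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligosurvey)
```

## The problem

Prokaryotic genomes use oligonucleotides unevenly, far beyond what their
G+C content dictates. Some 8--14 bp words — notably adenine-rich homopurine
tracts and their homopyrimidine complements — recur at tens to hundreds of
copies per megabase across distant lineages. Detecting such words requires
(i) counting every overlapping window of each length on a chromosome,
(ii) an explicit null model for how often each word is *expected*, and
(iii) thresholds that separate genuinely abundant words from sampling
noise. `oligosurvey` implements that survey end to end, plus a synthetic
chromosome generator so every stage can be validated against data with a
known ground truth.

## Null models and statistics

**Zero-order model.** Each base is drawn independently with the
chromosome's mononucleotide frequencies. For a word $w$ with $a$ adenines,
$c$ cytosines, $g$ guanines and $t$ thymines in a chromosome of $N$
unambiguous bases with base proportions $A, C, G, T$:

$$\hat E_0(w) = N \, A^a C^c G^g T^t.$$

We use $N$ rather than the window count $N - k + 1$: the relative
difference at genome scale is below $10^{-5}$, and the full-size form gives
the canonical benchmark of $10^6 / 4^8 = 15.26$ expected copies of a random
octamer per megabase of sequence with equiprobable bases.

**Overrepresentation level.** The one-cell Pearson statistic

$$\chi^2 = \frac{(C_\mathrm{obs} - C_\mathrm{exp})^2}{C_\mathrm{exp}}$$

is used as a *level* of over- or underrepresentation, with direction taken
from $\mathrm{sign}(C_\mathrm{obs} - C_\mathrm{exp})$. It is deliberately
not treated as a significance test, so no multiple-testing correction is
applied; the retention thresholds below do the filtering.

**Second-order model.** Overrepresentation of a long word can be a mere
consequence of abundant embedded shorter words. Conditioning each base on
the two preceding bases factors out mono- and dinucleotide effects. The
plug-in estimator from observed trinucleotide counts $N_3$ and internal
dinucleotide counts $N_2$ is

$$\hat E_2(w) = \frac{\prod_{i=1}^{k-2} N_3(w_i w_{i+1} w_{i+2})}
                     {\prod_{i=2}^{k-2} N_2(w_i w_{i+1})},$$

which is exact for trinucleotides (the empty denominator product makes
$\hat E_2$ the observed count itself — a property the tests assert on every
run).

**Gaussian z.** Counts of frequent words are approximately normal, so the
second-order call uses $z = (C_\mathrm{obs} - \hat E_2)/\hat\sigma$. The
default variance accounts for self-overlap (clumping):

$$\hat\sigma^2 = \hat E_2 \Big[ 1 + 2 \sum_{d \in P(w)} \hat\pi_d
  - (2k - 1)\hat\mu \Big],$$

where $P(w)$ is the set of periods of $w$ (lags at which $w$ overlaps
itself), $\hat\pi_d$ the estimated probability that an occurrence is
followed by another $d$ positions later (a product of $d$ trinucleotide
transition probabilities), and $\hat\mu$ the per-window occurrence
probability. Two simplifications are documented and deliberate: indicator
covariances are truncated at lag $k$ (beyond it the order-2 chain's
correlation decays geometrically), and the parameter-estimation covariance
is neglected, which is justified whenever every trinucleotide count far
exceeds the word count — true for octamers on chromosomes of half a
megabase and up. A plain Poisson denominator
($\hat\sigma^2 = \hat E_2$) is selectable with `variance = "poisson"`.
Both modes are gated by the same normality property test: on 1 Mb i.i.d.
sequences, 256 random octamers must give $|\bar z| \le 0.15$ (pooled over
three replicates, which damps the $\pm 0.1$ replicate-to-replicate
fluctuation of the mean) and $\mathrm{sd}(z) \in [0.7, 1.3]$ per
replicate.

## Thresholds and their defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `minCpm` | 31 | copies/Mb | twice the 15.26 random-octamer expectation, rounded up (`retentionThreshold(8)`) |
| `chi2Min` | 100 | — | retention level for the zero-order call |
| `zMin` | 1.96 | — | two-sided 5% normal quantile for order-2 calls; a knob, echoed in every report header |
| `kRange` | 8--14 | bp | the mid-length range surveyed; one threshold pair applies at every k |
| `windowBp` | 50 000 | bp | resolution of the positional profile |
| `indexMode` | subtract | — | see below |

The same 31/Mb and $\chi^2 \ge 100$ pair is applied at every word length.
Under these thresholds i.i.d. genomes yield no qualifying nonamers or
longer words (their expectations fall 4-fold per added base), which the
property tests verify on synthetic cohorts.

Applying the retention thresholds per chromosome, a word's cohort summary
tallies: `n_over_0` (chromosomes where it passed the zero-order
thresholds), `n_over_2`/`n_under_2` (order-2 Gaussian calls), and an
overrepresentation index. Two readings of "overrepresented and not
underrepresented" are defensible at cohort level, so both are implemented:
`indexMode = "subtract"` uses `n_over_2 - n_under_2`; `"exclude"` uses
`n_over_2` alone (per chromosome the z call is exclusive). Neither is
asserted as canonical. Ranks sort by descending tally with lexicographic
tie-breaks; copy-number quantiles over qualifying chromosomes use linear
interpolation (`quantile` type 7) so reports are bit-reproducible.

## Counting conventions

* **Single-strand counting.** A word and its reverse complement are kept
  as distinct words; complement pairs appear as separate rows whose small
  tally differences reflect strand biases. Pooling is available via
  `bothStrands = TRUE`, recorded in report headers.
* **Overlapping occurrences all count** (the standard word-count
  convention in the Markov word-statistics literature).
* **Ambiguity codes** are retained in sequences; any window containing one
  is skipped and excluded from `usablePositions`, which therefore always
  equals the sum of counts. Copies/Mb uses the full chromosome length as
  denominator; both denominators are reported.
* **Circularity is ignored**: no wraparound windows, costing at most
  $k - 1$ windows per replicon.
* **Coordinates are 1-based closed** throughout, the
  `IRanges`/`GRanges` convention, so GFF3 imports with no conversion and
  all interval algebra goes through one well-tested code path.

## Coding localization and reading frames

An occurrence is *coding* only if fully contained in a CDS interval — a
straddling occurrence has no well-defined frame. Occurrences inside
overlapping CDS are assigned once, to the first containing CDS in
annotation order, conserving totals. The frame of an occurrence is the
offset modulo 3 of its 5' end *in coding orientation* from the CDS start
(frame 1 = in frame): on the plus strand
$((\mathrm{start} - \mathrm{cdsStart}) \bmod 3) + 1$; on the minus strand
the word's 5' end is its last base, giving
$((\mathrm{cdsEnd} - (\mathrm{start} + k - 1)) \bmod 3) + 1$. This
convention is pinned down testably: mirroring a chromosome (reverse
complement, CDS coordinates reflected, strands swapped) must leave every
frame assignment unchanged, and the suite asserts exactly that. Frame
uniformity is tested per word with a 2-df Pearson statistic against
(1/3, 1/3, 1/3).

## Positional distribution

Occurrences are binned into fixed windows (`floor((start - 1)/windowBp)`,
final partial window retained). The clustering proxy is the variance/mean
dispersion over full windows: uniform, Poisson-like spread gives values
near 1; a profile is flagged as clustered above a documented threshold of
2. A single 50-kb cluster of 60+ copies on a 2 Mb chromosome pushes the
dispersion above 5, so the detector cleanly separates even spread from
aggregation.

## The synthetic generator

`syntheticSpec()` + `generateSyntheticChromosome()` produce chromosomes
with exactly the structure the analysis assumes:

* i.i.d. background of configurable length and G+C
  ($P(G) = P(C) = \mathrm{gc}/2$);
* planted copies of chosen words at a Poisson rate per Mb, written at
  uniform non-overlapping positions, *replacing* background bases so the
  length and every downstream coordinate stay fixed (the background still
  contributes its own chance occurrences, so recovery tests use total
  counts with correspondingly widened Poisson bands);
* synthetic CDS annotation: exponential-ish gene lengths (mean 900 bp,
  multiples of 3, minimum 30 bp) on alternating strands, gaps scaled so
  coverage lands within 2 points of the target (default 86%, a typical
  prokaryotic coding density);
* a planting budget capped at 5% of the chromosome, so planting never
  dominates the base composition.

All randomness derives from one spec-level seed through fixed substream
offsets (background: `seed`; annotation: `seed + 1`; planted word $i$:
`seed + 1 + i`), so every fixture regenerates bit-exactly, and
`writeSyntheticFixture()` emits FASTA + GFF3 + a key=value provenance
sidecar.

What the generator does *not* emulate: codon usage, repeat families, GC
skew, strand-specific mutational bias, or phylogenetic correlation between
cohort members. Passing recovery tests therefore demonstrates that the
statistics behave as designed under their own model assumptions — not that
real chromosomes satisfy those assumptions. On real data the second-order
model is precisely the guard against the most common violation (abundant
embedded short words).

## Validation choices and problem sizes

The shipped validation uses: a 100-replicate control of 6 Mb i.i.d. 50%
G+C chromosomes (expecting zero qualifying octamers per replicate);
equivalence of the compiled counter with a naive window-scan oracle on
1000 random sequences up to 10 kb; trinucleotide exactness of
$\hat E_2$ and order-0/order-2 agreement within 10% on 1 Mb i.i.d.
sequences; recovery of a word planted at 60 copies/Mb in 15 of 20 one-Mb
chromosomes (`n_over_0` within 15 ± 1, rank 1 among the 512 candidates);
mirror-consistency of frame assignment plus frame uniformity at the 5%
level in at least 90% of 30 seeds; and byte-identical reports for
identical config + seed. These sizes keep a full run in a few minutes on
one core while leaving each check's expected failure probability
negligible.

## Degenerate inputs and edge rules

* A word using a base of proportion 0 (order 0), or with an internal
  dinucleotide count of 0 (order 2), gets expectation 0, an `NA`
  statistic, a `neutral` call, and `degenerate = TRUE`.
* $\chi^2$ requires a strictly positive expectation; `copiesPerMb`
  requires positive length.
* The variance estimate is floored at $0.05\,\hat E_2$ to guard against
  pathological compositions driving it nonpositive.
* CDS intervals whose width is not a multiple of 3 are retained but
  flagged (`lengthWarning`), since real annotations contain such
  exceptions. Compound GenBank locations (`join(...)`) are decomposed
  into independent parts.
* Empty position lists produce zero-filled localizations and profiles
  with `NA` dispersion, flagged by a warning rather than an error.

## Known limitations

* No compound-Poisson correction for clump *size* distributions of
  self-overlapping words; the variance handles clumping to first order
  only.
* Exact (non-asymptotic) word-count distributions are out of scope; for
  the rare-word regime the Gaussian call is conservative and the
  zero-order channel with its copies/Mb floor does the retention.
* Per-chromosome scoring only; multi-replicon organisms are summarised at
  the chromosome level.
* The command-line layer is a thin wrapper (`inst/scripts/oligosurvey.R`);
  the R API is the primary interface.
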