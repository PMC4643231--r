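---
title: "Methods: modelling degradation-driven taxonomic bias in 16S amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling degradation-driven taxonomic bias in 16S amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoamp)
```

## The problem

Taxonomic profiling of ancient microbiomes (dental calculus, coprolites)
has historically relied on PCR amplification of a 16S rRNA hypervariable
region, most often V3 (E. coli positions 341–534). Ancient DNA, however, is
highly fragmented — median fragment lengths are typically under 100 bp —
while the V3 target is 150–194 bp *including primers*, and its length
varies by clade: archaeal V3 stem-loops are the shortest, spirochaetes and
many proteobacteria among the longest. A PCR template must contain the
entire target plus both primer sites, so in a fragmented extract the
probability of being amplifiable decays with target length. The result is a
systematic, reproducible skew: short-target taxa (the archaeon
*Methanobrevibacter* above all) are grossly overrepresented and
long-target taxa (*Treponema*, *Neisseria*) drop out — a taphonomic
artifact, not biology. `paleoamp` implements the three quantitative pieces
of that argument and a synthetic data generator that lets all of them be
tested end-to-end without any external database.

## The survival model

Under random degradation, each internal phosphodiester bond breaks
independently with probability $\lambda$ (set by the sample's thermal age;
the climate modelling that produces $\lambda$ is out of scope — seven
literature-derived per-site values ship with the package,
`site_lambda_table()`). The probability that a target of $x$ bases is
present intact is

$$S(x) = e^{-\lambda x},$$

and the observed (amplicon) frequency of taxon $i$ with starting frequency
$f_i$ and primer-inclusive target length $x_i$ is predicted by

$$f'_i = \frac{f_i\,e^{-\lambda x_i}}{\sum_j f_j\,e^{-\lambda x_j}}.$$

Two consequences are checked as properties throughout the test suite:
memorylessness ($S(x_1+x_2) = S(x_1)S(x_2)$) and the bias direction — for
any two taxa with $x_a < x_b$, $f'_a/f_a \ge f'_b/f_b$ for every
$\lambda$, strictly for $\lambda > 0$. The shortest target is *always*
enriched; how much depends on $\lambda$ and the length spread.

Numerics: the weights $f_i e^{-\lambda x_i}$ are computed in log space
with max-subtraction before normalization. At the largest packaged
$\lambda$ (0.0863) and $x = 194$, $\lambda x \approx 17$; products of many
such terms would underflow naively, while log-space weights are exact to
machine precision.

Discrete versus continuous law: the simulator breaks bonds as Bernoulli
trials, so an $x$-base window survives with probability
$(1-\lambda)^{x-1}$ ($x-1$ internal bonds), while the analytic model uses
$e^{-\lambda x}$. Per bond the difference is below 0.5% for
$\lambda \le 0.09$; compounded over $x$ it matters exactly where survival
is already vanishing, and the relevant comparisons (normalized
frequencies, count expectations) agree within the sampling noise the
tests allow. Where a test compares an empirical survival directly against
the model we state which law the oracle uses.

## In-silico PCR

Primer binding is scored with a weighted penalty scheme over the best
alignment of primer and binding window with at most one gap:

| event                                  | penalty |
|----------------------------------------|---------|
| mismatch outside the 3' window         | 0.40    |
| mismatch in the 3' window (not final)  | 1.00    |
| mismatch at the final 3' base          | 3.00    |
| gap outside the 3' window              | 1.00    |
| gap in the 3' window                   | 3.00    |

The 3' window is the last five bases of the primer, with the final base
carrying its own penalty. A site passes iff its score is at most 1.00 —
so a single non-3' gap, one non-final 3' mismatch, or two non-3'
mismatches pass, while any final-base mismatch, any 3' gap, two or more
gaps, or three or more non-3' mismatches cannot. Capping the search at one
gap is exact with respect to the pass decision (two gaps already cost
2.00) and bounds the alignment enumeration, which is implemented in C++
and verified against an exhaustive enumeration oracle on random
primer/window pairs.

Conventions that the cited literature leaves open, fixed here and
documented:

* **Degenerate bases** match iff the IUPAC sets intersect; an `N` in the
  *reference* never matches (ambiguous reference bases must not inflate
  coverage).
* **Reverse primers** are scored as their reverse complement scanned on
  the sense strand, with the 3' penalty window mapped to the left end of
  the pattern. Whether the original tool scores the antisense strand
  directly is unknown; this convention is symmetric and testable.
* **Tie-breaks**: among equal-score passing sites, the forward search
  keeps the lowest start and the reverse search the highest — maximizing
  the canonical amplicon.
* **Amplicon length is primer-inclusive** (first base of the forward site
  through last base of the reverse site); amplicons longer than
  `max_len = 500` bp are discarded, matching the restriction of the
  analyses to sub-500 bp amplicons.
* **Length summaries** use the lower median (integer-valued for
  integer input) and nearest-rank percentiles; the 99% bounds
  (percentiles 0.5 and 99.5) trim outliers such as chimeras. Percentile
  trimming is the only outlier rule — no separate chimera filter.
* **OTU clustering** (`taxonomic_resolution()`) is greedy incremental:
  inputs sorted by decreasing length then lexicographic id, each sequence
  joins the first centroid whose identity (matches / shorter length, from
  a unit-cost global alignment) meets the 97% threshold. This
  approximates the behaviour of greedy centroid clusterers; reproducing
  any particular tool's OTU counts bit-for-bit is explicitly not
  promised.

## The synthetic data generator

The generator is the package's study system, not a fixture. Its defaults
encode the structure the analyses assume:

* **Templates are 1540 nt** — the approximate full 16S gene length.
* Each clade plants an **exact forward site at the pair's anchor**
  (E. coli 341 for V3) and an exact reverse-complement site positioned so
  the primer-inclusive amplicon equals the clade's target length; the
  canonical three-clade set uses 151/169/194 bp, the archaeal clade
  shortest — the observed V3 range.
* The **variable loop** between the sites is a clade consensus mutated
  per record at the clade's divergence rate (default 2%); flanks and all
  non-amplicon sequence are drawn once from the seed and shared across
  clades (conserved background).
* **Defects** (`last_base_mismatch`, `non3prime_mismatch`) let coverage
  experiments plant clades that must fail or pass degraded.
* One 16S copy per template organism — rRNA operon copy-number variation
  is deliberately ignored, as the analytic model ignores it; a real
  community adds that bias on top.
* Fragmentation draws per-bond Bernoulli breaks (geometric skip sampling
  in C++), keeps maximal unbroken runs, and discards fragments under 25
  bp, mirroring short-read filtering. PCR is **exhaustive**: every
  fragment containing the full amplicon interval yields exactly one
  amplicon — the mechanism under study is template availability, not
  polymerase kinetics. Shotgun reads are drawn uniformly over fragments
  (length-weighted sampling available behind a flag); with equal-length
  templates, per-taxon read counts then track template proportions.
* Both primer sites must sit on one surviving fragment; nicked-duplex
  rescue is not modelled.
* Deamination and read-level error models are not simulated.

What passing tests on this generator do *not* show: real 16S databases
spread sequence variation across the whole gene (so real amplicons
resolve fewer OTUs than full-length sequences, while the synthetic loop
concentrates variation inside the amplicon); real communities have copy
number variation, contamination, and damage patterns; and real per-site
$\lambda$ values are themselves model outputs. The synthetic system
isolates exactly one mechanism — length-dependent template survival — and
the tests demonstrate that mechanism, not the full taphonomy of any
archaeological sample.

## Estimating lambda from fragment lengths

`estimate_lambda()` implements the exponential moment estimator
$\hat\lambda = 1/\overline{L}$. For fragments cut from finite templates
this is biased upward: each template contributes one break-free terminal
fragment, giving $E[\hat\lambda] \approx \lambda + 1/T$ for template
length $T$ — a 13% relative bias at $\lambda = 0.005$, $T = 1540$.
Passing `template_length` switches to the exact break-fraction estimator
$\hat\lambda = (n_{frags} - n_{templates})/n_{bonds}$, which is unbiased
under the simulator's Bernoulli law but requires unfiltered
(`min_len = 1`) fragments that partition their templates. The recovery
tests use the corrected form; the naive form is retained because field
data rarely come with a known template length, and its bias is documented
rather than hidden.

## Empirical survival: fragments versus targets

Two different empirical quantities are easy to conflate:

1. the fraction of *fragments* with length $\ge x$
   (`amplifiable_fraction_empirical()`), which for finite templates has
   expectation $(1-\lambda)^{x-1}\,[\lambda(T-x-1)+1+\lambda]/[1+(T-1)\lambda]$
   — systematically *below* the geometric law, by up to ~0.02 at
   $\lambda = 0.01$, $x = 100$, $T = 1540$;
2. the fraction of *template copies* retaining a fixed intact $x$-base
   window (`window_survival_empirical()`), with expectation
   $(1-\lambda)^{x-1}$, within 0.01 of $e^{-\lambda x}$ everywhere the
   analyses go.

The model quantity $e^{-\lambda x}$ is a target survival, so the
simulator–model agreement checks use (2); (1) is tested against its own
exact finite-template expectation. Both are exposed because the
fragment-fraction is what one actually computes from sequencing data,
boundary effects included.

## Problem sizes and study conditions

The simulator–model agreement experiments use $10^5$ templates per
$\lambda$, where three-binomial-sigma bands are a fraction of a percent
for moderate $\lambda$ and the expected amplicon yield at the two highest
packaged $\lambda$ values (0.0701, 0.0863) is ~1 and ~0.05 amplicons —
at those intensities the check degenerates, correctly, to "the model also
predicts an empty library". The direction-of-bias experiment (shortest
clade enriched, longest depleted, in at least 99 of 100 seeds at
$\lambda = 0.0701$) needs a nonempty amplicon library in essentially
every seed; with an amplifiable fraction around $10^{-5}$ that requires
$1.6\times10^6$ templates per seed (expected yield ≈ 13–20 amplicons),
chosen once from this power analysis. At that scale the fragment set
(~$1.7\times10^8$ fragments per seed) is not materialised: a streaming
C++ kernel applies the identical per-bond model and returns per-record
tallies (fragments kept; fragments containing the amplicon interval),
and the shotgun draw becomes the distribution-identical multinomial over
per-taxon fragment counts. The streaming and fragment-level engines
consume the same RNG stream, so their amplicon tallies agree
bit-for-bit at equal seeds — one of the unit tests.

## Other fixed choices

* Community profiles are plain named numeric vectors normalized to sum 1;
  zero-frequency taxa are retained (dropout is the phenomenon of
  interest). Degenerate all-zero profiles are an error.
* Log fold change is base 2, with a symmetric pseudo-frequency
  $\varepsilon = 10^{-6}$; dropout taxa then have finite, large LFCs.
* Frequency predictions renormalize over **all supplied taxa**; taxa below
  a 0.01% display floor are suppressed only when rendering, never in
  computation.
* Oral/other classification matches genus labels exactly after
  whitespace/case folding.
* Unassigned taxonomy ranks are a single canonical marker (`NA`), so
  grouping is deterministic; both plain and `k__`-prefixed lineage
  dialects parse to the same representation.
* All stochastic stages take explicit seeds; composite runs derive stage
  sub-seeds deterministically from the master seed, so a run is
  reproducible from its parameter record alone.

## Limitations

The package quantifies one taphonomic mechanism. It does not model
deamination damage, polymerase kinetics, chimera formation,
contamination mixtures, or copy-number variation, and its greedy
clusterer is an approximation adequate for synthetic data with planted
structure. Conclusions about any real archaeological sample additionally
depend on inputs (per-site $\lambda$, reference databases) that are
outside the package's scope.
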