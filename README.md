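# paleoamp

Why does 16S rRNA amplicon sequencing of *ancient* microbiome samples
(archaeological dental calculus, coprolites) so often return profiles
dominated by the archaeon *Methanobrevibacter* and missing well-known
oral taxa like *Treponema*? `paleoamp` implements the quantitative
argument that this is a taphonomic artifact of DNA fragmentation — and
provides the tools to measure, predict and simulate it. It is aimed at
researchers working on ancient microbiomes or on amplicon-method
evaluation who want the mechanism as runnable, testable code.

The core model: under random degradation each internal phosphodiester
bond breaks independently with probability λ (set by the sample's
thermal age), so a PCR target of primer-inclusive length *x* survives
with probability

    S(x) = exp(-λ·x)

and a community with starting frequencies *fᵢ* and target lengths *xᵢ*
is observed, after amplification from fragmented templates, as

    f'ᵢ = fᵢ·exp(-λ·xᵢ) / Σⱼ fⱼ·exp(-λ·xⱼ).

Because the 16S V3 region (E. coli 341–534) is length-polymorphic —
151 bp in *Methanobrevibacter* up to 194 bp in *Treponema* and
*Streptococcus*, primers included — degradation alone reshapes the
profile: the shortest target is always enriched, strictly so for λ > 0.

The package has four layers, each independently usable:

* **In-silico PCR** — primer-binding scoring with a weighted
  mismatch/gap penalty scheme (non-3' mismatch 0.40, 3' mismatch 1.00,
  final-base mismatch 3.00, non-3' gap 1.00, 3' gap 3.00; pass ≤ 1.00),
  primer-inclusive amplicon extraction, per-clade length summaries with
  99% nearest-rank bounds, per-phylum taxonomic coverage, and greedy 97%
  OTU clustering for taxonomic resolution.
* **Degradation model** — survival curves, profile predictions across
  thermal-age series, fragment-length statistics, amplifiable fractions,
  and λ estimation from fragment lengths.
* **Community metrics** — oral/other classification against a membership
  list, archaeal fraction, per-taxon log2 fold changes between amplicon
  and shotgun profiles, Spearman rank correlation.
* **Synthetic data** — a generator of clade-structured 16S databases
  with planted V3-style length polymorphisms, plus a forward simulator:
  community → template pool → per-bond fragmentation → {amplicon
  dropout, shotgun sampling} → comparison, with the analytic prediction
  attached for cross-checking.

Packaged defaults (`inst/extdata`, all literature-derived and editable):
V3 U341F/534R and V4 515F/806R primer pairs with E. coli anchor
coordinates; per-site λ values for seven archaeological sites; predicted
V3 amplicon lengths and baseline oral abundances for 34 oral taxa of
interest.

## Worked example

Predict how a four-genus oral community skews at the λ of a
~4,500-year-old site (0.0149):

```r
library(paleoamp)
pred <- predict_observed_profile(
  c(Methanobrevibacter = 0.01, Anaerolinea = 0.04,
    Streptococcus = 0.55, Treponema = 0.40),
  c(Methanobrevibacter = 151, Anaerolinea = 169,
    Streptococcus = 194, Treponema = 194),
  lam = 0.0149)
print(pred, digits = 3)
#>                taxon f_in length f_pred
#> 1 Methanobrevibacter 0.01    151 0.0185
#> 2        Anaerolinea 0.04    169 0.0565
#> 3      Streptococcus 0.55    194 0.5355
#> 4          Treponema 0.40    194 0.3895
```

A 1% archaeal community member nearly doubles its apparent frequency
while every 194 bp target shrinks — purely from fragmentation. At the
highest packaged λ (0.0701, `analysis/04_amplicon_vs_shotgun.R`) the
same 1% input reaches ~15% of the amplicon library while the matched
shotgun arm still reports ~1%, reproducing the characteristic archaeal
overrepresentation in sign and magnitude.

The `analysis/` directory holds the full workflow as numbered scripts
(primer evaluation on a synthetic oral database; fragment-length
structure across the seven sites; the thermal-age prediction series; the
amplicon-vs-shotgun simulation). Each writes TSV tables under
`results/` and narrates what it finds:

```sh
Rscript analysis/01_evaluate_primers.R
Rscript analysis/02_fragmentation.R
Rscript analysis/03_predict_bias.R
Rscript analysis/04_amplicon_vs_shotgun.R
```

## Scope

λ values are inputs: converting site age and temperature history into a
scission probability is climate modelling outside this package. Likewise
out of scope: read-level error and damage models, chimera detection,
closed-reference OTU assignment against real databases, and Bayesian
source tracking. The methods vignette
(`vignettes/degradation-bias-methods.Rmd`) documents every modelling
choice, numerical convention and limitation.
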