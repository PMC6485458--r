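---
title: "Recombination rates and biased gene conversion at a poly-A hotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination rates and biased gene conversion at a poly-A hotspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombias)
library(dplyr)
```

recombias analyses single-molecule recombination products collected by
pooled sperm typing at a human recombination hotspot whose centre carries
heterozygous poly-A microsatellites — in particular an asymmetric 9A/19A
repeat close to the PRDM9 binding motif and a 6A/7A repeat further out.
The package covers the full chain from raw per-molecule genotype tables to
crossover/non-crossover (CO/NCO) rates, hotspot centres, biased-transmission
estimates and their population-genetic consequences, together with a
genome-scale poly-A run scanner and STR diversity summaries. Because the
raw molecule tables of such experiments are rarely public, the package
ships a generative model of the assay; every estimator is exercised and
validated against data with known ground truth.

## The assay and its generative model

Pooled sperm typing aliquots a few hundred to ~1,200 sperm genomes per PCR
reaction and selectively amplifies recombinant molecules with allele-specific
primers. Two reciprocal orientations exist for each product type: for COs
the two complementary exchange haplotypes (RI, RII), for NCOs the two
background homologues that can carry a conversion (NRI, NRII). Assay
efficiency is imperfect, so all rates are expressed per *amplifiable*
genome: the assayed genome count times a donor-specific correction factor,
which in published experiments falls between 0.10 and 0.35 (default 0.25
here, the mid-range).

The simulator (`simulate_experiment()`) draws, for each assay and
reciprocal, a Poisson number of collected molecules with mean
(amplifiable genomes × event rate) and constructs each molecule as follows.

* **Crossovers.** The exchange lands in an inter-marker interval with
  probability proportional to the Normal mass of the DSB position model
  (`dsb_center`, `dsb_sd`) in that interval, multiplied by the repair-win
  weights of the two alleles retained at the interval's flanks. The weight
  of an allele at a heteroduplex site is `p_strong_transmission` for a
  strong (G/C) SNP allele, `p_long_transmission_short_heterology` for the
  long allele of a 1–2 unit STR heterology, and
  `p_short_transmission_long_heterology` for the short allele of a longer
  heterology. Modelling the bias at the two mismatches flanking the
  resolved junction — rather than at every site a conversion tract happens
  to cover — reflects that the junction's neighbouring mismatches are part
  of the heteroduplex by construction, and makes the downstream estimator
  exactly calibrated. With probability `p_complex_co` one marker beyond
  the exchange flips to the other homologue, producing a complex CO with a
  discordant block.
* **Non-crossovers.** A conversion tract of geometric length
  (`tract_mean`) is centred on a Normal DSB draw. The covered heterozygous
  markers resolve as one contiguous block, either back to the background
  homologue (undetectable) or to the other homologue (a detectable
  conversion), with odds given by the product of per-site repair weights.
  With probability `p_complex_nco` the tract skips one covered internal
  marker; with `p_complex_nco = 0` conversions are always contiguous.

The geometric tract family was chosen because it is memoryless and has a
single mean parameter; empirical studies report only means (roughly 0.6 to
1.5 kb between informative-marker bounds), not a family. The Normal DSB
model matches the Normal-CDF fits used for cumulative CO curves. Both
reciprocals of a CO meiosis are generated symmetrically and the assays
sample one each, which is why per-meiosis CO rates carry a factor 2 and
NCO rates a factor 1.

Two deliberate simplifications: `p_complex` is split into a CO and an NCO
parameter (defaults 0.015 and 0.12) because the observed magnitudes differ
by an order of magnitude — complex COs are ~1.2–1.6% of COs while ~12% of
NCOs are complex; and the default `tract_mean` of 300 bp was set on the
class-mix side: at ~4 informative SNPs per kb a single geometric scale
cannot simultaneously produce the observed predominance (a large majority)
of single-SNP conversions and bound-midpoint tract summaries near 1 kb,
because the midpoint summary is dominated by the marker spacing rather than
the underlying tract.

The default map (`build_default_map()`) mimics the modelled hotspot: 12
heterozygous SNPs over ~3 kb, a 6A/7A repeat at −490 bp, the 9A/19A repeat
at −154 bp and a homozygous 23A repeat at +239 bp from the motif. One SNP
is a G/C polymorphism — phase-informative but without a strong/weak
contrast — as happens in real marker panels.

## Event classification

`call_events()` reduces each molecule to its phase vector against the map.
Crossovers need discordant flanks; the breakpoint interval runs from the
last marker of the left-flank phase to the first marker of the right-flank
phase, and any additional interior phase runs make the molecule a complex
CO. Non-crossovers need concordant flanks and at least one discordant
internal marker; they partition exactly into simple (one converted marker),
co-conversion (several converted, none skipped) and complex conversion (an
unconverted marker between converted ones). Unscorable molecules are never
dropped: they carry a reason code (`no_phase_switch`, `flank_discordant`,
`too_few_informative`, ...) so that denominators remain auditable.

Conversion-tract lengths are interval-censored: the minimum spans the
converted markers, the maximum reaches the nearest informative unconverted
flanks, and the reported "tract length" is the midpoint of the two by
default (`tract_length(, summary = "maximum")` switches to the upper
bound). The midpoint convention is a choice — the estimator behind
published per-donor means is not defined precisely enough to reproduce.

## Rates

`estimate_frequency()` divides event counts by amplifiable genomes and
attaches a Garwood (gamma-inversion) exact Poisson 95% interval. Group
comparisons (`compare_groups()`) use the conditional construction of the
exact two-sample Poisson test: given the total count, the first count is
binomial with the exposure share as null probability; the rate-ratio CI is
the Clopper–Pearson interval mapped to the ratio scale. `cm_per_mb()`
converts per-meiosis rates over an interval to cM/Mb; the default interval
is the span of the outermost informative markers.

## Hotspot centres

`cumulative_curve()` represents COs by breakpoint-interval midpoints
(intervals, not points, are observed), gives both reciprocals equal weight,
and `fit_center()` fits a Normal CDF (COs) or a 3-parameter logistic
(NCOs; the standard parameterisation `a/(1+exp(-(x-x0)/s))`). The Normal
fit maximises the grouped multinomial likelihood of the curve increments
rather than least squares on the cumulative values: cumulative residuals
are strongly serially correlated, and a naive least-squares covariance
understates the centre's standard error several-fold. The reported SE
therefore reflects true sampling variability, which the recovery tests
verify (a fitted centre within ±3 SE of the truth in ≥95% of replicates at
n = 1,000). Starting values are the median crossing for the centre and the
interquartile span divided by 1.349 for the width; non-convergence is an
error with diagnostics, never silent.

## Transmission bias

The heart of the package. For each scorable CO the transmitted allele
classes are read at the two markers flanking its breakpoint. At any given
interval the two reciprocals retain *complementary* pairs: if RI keeps a
strong/strong pair, RII keeps the weak/weak pair of the same two SNPs.
A stratum per (donor × interval) with rows = reciprocal therefore contrasts
favored-pair against disfavored-pair exchanges under the assays' own
exposures, and the positional breakpoint distribution cancels within the
stratum. Under a per-site transmission probability *f*, the favored pair
occurs with odds (f/(1−f)) at each of the two flanks, so the pooled rate
ratio estimates (f/(1−f))² — which is exactly why the transmission
fraction is recovered as

FxR = √RR / (1 + √RR),

the convention the package adopts throughout (`fx_chain()`). Single-site
designs — iBGC read at one STR, NCO conversions read per converted site —
estimate the first-power odds, for which the `convention = "linear"`
mapping RR/(1+RR) is exact; the √ convention remains the default for
comparability with published tables and is conservative for those designs.

Pooling uses Mantel–Haenszel person-time weights with a
Greenland–Robins-type variance. One subtlety is handled explicitly:
because each reciprocal's breakpoint distribution is normalised to its own
collection total, strata in which RI supplies the favored pair and strata
in which RII does carry reciprocal normalisation factors that do not cancel
individually. `cmh_rate_ratio()` therefore pools the two orientation
groups separately and combines them symmetrically on the log scale — the
estimator analogue of plotting reciprocals "normalised to equal totals".
The combination is exact (the normalisation factors cancel in the
geometric mean), reduces to the plain 2×2 ratio for a single stratum, and
swapping class labels maps RR to 1/RR to machine precision. When a pooled
margin is zero the exact conditional binomial method takes over (a zero
favored count then gives RR = 0 with an exact upper bound, the situation at
the 9A/19A repeat in NCOs, where the short allele wins essentially always).

Per-site diagnostics (`logrr_per_site()`) compare how often the two
reciprocal haplotypes carry each allele,
log[(nRI/totRI)/(nRII/totRII)], with standardized Pearson residuals and
stars at p < 0.05/0.01/0.001; zero cells get a 0.5 continuity correction
for the log ratio only, never in the pooled estimate.

The chain to population quantities takes the recombinant fraction *c*
(events per amplifiable genome, ×2 for COs since one reciprocal of two is
measured) and computes FxTotal = 0.5·(1−c) + c·FxR and b = 2·FxTotal − 1,
the selection-coefficient equivalent. The printed algebra in the source
table's footnote ("0.5·(1−FxR)+c·FxR") cannot produce values near 50% and
is treated as a typographical error for the prose definition ("sum of the
proportion of non-recombinants and proportion of FxR"); published FxTotal
values additionally used unrounded inputs and are not exactly reproducible
from the printed ratios. `li_bulmer_equilibrium()` evaluates the
equilibrium fraction 1/(1+κ·e^(−2·Ne·b)) for a mutation-bias ratio κ.

Whether *c* should carry the ×2 meiosis factor is ambiguous in the
published footnote; the package computes it with the factor (matching the
"2·CO, 1·NCO" normalisation) and `fx_chain()` accepts any `c_rate`, so the
other convention is one call away.

## Poly-A scanning and STR diversity

`find_runs()` reports maximal perfect single-base runs (default A, ≥6 bp,
case-insensitive, N breaks a run; lengths capped at 26 for class-wise
reporting). `build_zones()` pads DSB intervals by 500 bp into hotspot
zones and lays out five 1-kb flanking windows per side, left/right windows
of equal index pooled; flanks of nearby hotspots are truncated at the gap
midpoint so zones never overlap, hotspot zones taking precedence over
flanks and inner flanks over outer. A run straddling a boundary belongs to
the zone containing its start (the published analysis does not state its
straddle handling). Densities are runs (or run bases) per zone bp
(`zone_densities()`); the enrichment test is a Kruskal–Wallis rank test of
per-hotspot densities, hotspot versus pooled flanks, matching the
published test choice. A and T runs are scanned separately, as they are
reported separately.

`diversity_summary()` computes per-locus expected heterozygosity
1 − Σpᵢ², allelic asymmetry (longest − shortest), steps between successive
allele lengths and the allele count from a clean allele-length count table
(low-quality genotype filtering is upstream of this package);
`diversity_by_zone()` compares each measure between hotspot and flank loci
with the same rank test.

## What the simulator does and does not emulate

It emulates: the pooled design with amplifiable-genome correction,
reciprocal product structure, Normal breakpoint spread, heteroduplex
transmission biases at SNPs and STRs of both heterology classes,
interval-censored conversion tracts, complex events, and missing calls.

It does not emulate: PCR artefacts and contamination (published work
excluded these with negative controls), donor-to-donor rate heterogeneity
beyond the configured group difference, more than one recombinant per
positive reaction (molecules are treated independently; the published
per-pool multiplicity handling is not described), mismatch-repair pathway
choice or inter-sister repair, and linked non-B DNA or chromatin features.
Passing recovery tests therefore demonstrates the estimators' correctness
under the stated sampling model, not robustness to assay artefacts.

## Numerical choices and problem sizes

Exact intervals are Clopper–Pearson/Garwood inversions; the centre fit
uses BFGS with a log-width parameterisation and a relative tolerance of
1e-14; zone arithmetic is integer interval arithmetic; rate ratios of 0
and ∞ are representable and flow through the fx chain (FxR 0 or 1). The
validation suite runs at deliberately moderate sizes chosen to keep the
full suite in a few minutes while leaving Monte-Carlo margins: 200
replicates of 1e5-meiosis experiments for bias and rate-ratio recovery,
100 replicates of n = 1,000 for centre recovery, 200 random 100-kb
sequences for the scanner oracle, and 500 planted hotspots for enrichment
power.

```{r example}
donors <- list(donor_profile("d1", "Ht"), donor_profile("d2", "Ho"))
res <- run_hotspot_pipeline(donors, sim_params(seed = 1, n_pools_co = 60,
                                               n_pools_nco = 120))
res$bias |> select(classification, assay, rate_ratio, p_value, fx_r, b)
```
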