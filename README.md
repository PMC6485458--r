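# recombias

Analysis of meiotic recombination products at human hotspots whose centres
carry heterozygous poly-A microsatellites. The package is aimed at
researchers working with pooled sperm-typing data — single crossover (CO)
and non-crossover (NCO) molecules selectively amplified from sperm pools —
who want to quantify how a repeat-length heterology at the hotspot centre
changes recombination rates, conversion-tract structure and the direction
of biased gene conversion, and what those biases imply for sequence
evolution.

## What it computes

* **Event rates.** CO/NCO frequencies per amplifiable genome
  (count / (genomes × correction factor)) with exact Garwood Poisson
  intervals; group comparisons by the exact conditional Poisson test; map
  lengths in cM/Mb.
* **Event classes.** Per-molecule classification into CO breakpoints,
  complex COs, and simple / co- / complex conversions, with
  interval-censored tract bounds (min, max, midpoint) and explicit
  unscorable-reason codes.
* **Hotspot centres.** Normal-CDF (CO) and 3-parameter logistic (NCO)
  fits to cumulative event-frequency curves, with honest standard errors
  from a grouped-likelihood fit.
* **Transmission bias.** Stratified Mantel–Haenszel rate ratios for
  GC-biased (strong G/C vs weak A/T) and insertion-biased (long vs short)
  gene conversion, read at breakpoint-flanking sites (CO) or converted
  sites (NCO), pooled with reciprocal balancing; per-site log rate-ratio
  diagnostics with standardized Pearson residuals; and the chain

  FxR = √RR / (1 + √RR),  FxTotal = ½(1 − c) + c·FxR,  b = 2·FxTotal − 1,

  where *c* is the recombinant fraction of gametes; plus the Li–Bulmer
  equilibrium 1 / (1 + κ·e^(−2·Nₑ·b)).
* **Poly-A landscape.** A perfect mononucleotide-run scanner
  (runs ≥ 6 bp, lengths capped at 26), DSB-hotspot ± flank zone
  construction, run/base densities per zone, and Kruskal–Wallis
  hotspot-vs-flank enrichment tests; STR population-diversity summaries
  (heterozygosity 1 − Σpᵢ², allelic asymmetry, steps, allele counts) by
  zone.
* **Synthetic experiments.** A generative model of the pooled assay
  (reciprocal products, amplifiable-genome correction, Normal DSB
  positions, geometric conversion tracts, configurable per-site
  transmission biases) so every estimator can be validated against known
  ground truth. See the methods vignette
  (`vignettes/hotspot-analysis.Rmd`) for the model and all conventions.

## Worked example

Simulate a heterozygous (9A/19A) and a homozygous (19A/19A) donor under
the default study conditions and run the full pipeline:

```r
library(recombias)
donors <- list(donor_profile("d1", "Ht"), donor_profile("d2", "Ho"))
res <- run_hotspot_pipeline(donors, sim_params(seed = 1, n_pools_co = 200,
                                               n_pools_nco = 400))

res$group_comparison
#>   assay rate_ratio ci_low ci_high p_value
#> 1 CO          1.03  0.773    1.37 0.887
#> 2 NCO         1.77  1.15     2.76 0.00796

res$centers
#>   assay      model  center       se
#> 1    CO normal_cdf 6360828 25.05
#> 2   NCO  logistic3 6360716 12.26
```

With 299 collected molecules the Ht donor already shows a significant NCO
excess over the Ho donor (ratio 1.8, p = 0.008): under the default model
the long 9A/19A heterology is always resolved towards the short allele, so
conversions covering it are reliably detected on the 19A background —
the simulated analogue of a heterology shifting DSB repair towards NCO.
The fitted centres sit within ~60 bp of the configured DSB centre
(6,360,770). The transmission-fraction chain at the headline
GC-bias ratio:

```r
fx_chain(1.27, c_rate = 2.5e-3)
#>   rate_ratio      fx_r      c  fx_total           b
#> 1       1.27 0.5298416 0.0025 0.5000746 0.000149208
```

i.e. a CO rate ratio of 1.27 means 53.0% of crossovers transmit the
strong allele, a population-wide transmitted fraction just above one half,
and a selection-coefficient equivalent b ≈ 1.5 × 10⁻⁴.

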