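---
title: "Methods: scanning allele frequencies against helminth diversity"
author: "helminthscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning allele frequencies against helminth diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

The scan treats helminth diversity — the number of parasitic-worm
species/genera transmitted in a country — as a proxy for the long-term
selective pressure worms exert on human immunity. Diversity is preferred
over prevalence because prevalence surveys are patchy, recent (eradication
campaigns), and hard to combine under polyparasitism, whereas the species
composition of a region is governed by climate and is comparatively stable
over evolutionary time. The unit of observation is the *population* (a
sampled group with per-SNP reference-allele frequencies); the environmental
variable is defined per *country* and broadcast to populations, so all
populations of a country share one value. The broadcast is intentional: it
keeps the number of ties comparable across every correlation computed in
the pipeline, and the tie-corrected statistic accounts for them.

Association is measured by Kendall's tau-b,
$\tau_b = S / \sqrt{(n_0-n_1)(n_0-n_2)}$ with $S = C - D$, because only
monotone association is hypothesised (frequency clines in either direction)
and because its sampling distribution converges acceptably to a normal even
with ties once $n > 10$. The variance of $S$ under the null uses the
standard tie-adjusted formula

$$\mathrm{var}(S) = \frac{v_0 - v_t - v_u}{18} + \frac{\sum t(t-1)\sum u(u-1)}{2n(n-1)}
 + \frac{\sum t(t-1)(t-2)\sum u(u-1)(u-2)}{9n(n-1)(n-2)}$$

with $v_0 = n(n-1)(2n+5)$ and $v_t, v_u$ the analogous sums over tie blocks
of the two margins; it reduces to $n(n-1)(2n+5)/18$ without ties. No
continuity correction is applied by default (configurable), and all
p-values are two-sided — per-SNP allele orientation is arbitrary, so sign
carries no information and is reported as an orientation flag instead.

A SNP is *significant* only if it clears two gates:

* **Bonferroni**: $p < \alpha/m$ with $m$ the number of SNPs attempted
  (flagged and degenerate records included — this reproduces the convention
  under which a 660,832-SNP panel at $\alpha = 0.05$ gives the per-test
  threshold $7.6\times10^{-8}$).
* **MAF-matched empirical percentile**: $|\tau|$ strictly above the
  nearest-rank 95th percentile of $|\tau|$ among all SNPs whose MAF lies
  within $\pm 0.01$ of the SNP's own (the focal SNP included in its own
  window). MAF is the across-population unweighted mean reference-allele
  frequency folded onto $[0, 0.5]$; folding happens after averaging.

The empirical gate exists because drift and shared history inflate
correlations in a frequency-dependent way; comparing each SNP only with
MAF-similar peers removes the frequency dependence of that inflation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise rate of the Bonferroni gate (0.01 for gene-set-restricted scans) |
| `maf_window` | 0.01 | half-width of the MAF matching window (absolute frequency units) |
| `percentile` | 0.95 | empirical-null cut within the window |
| `min_n` | 11 | minimum pairwise-complete populations per SNP; below it the record is flagged and excluded from the gates (the stated validity bound of the normal approximation) |
| `upstream_bp` | 500 / 25000 | SNP-to-gene window, strand-aware, for per-SNP tables / pathway-style analyses |
| `n_bins` | 24 | SNP-count intervals for matched resampling |
| `R` | 10000 | resamples of the enrichment test |

## Design choices where the procedure was genuinely open

* **Percentile gate on |tau|.** Published scan tables report only positive
  correlations because each SNP is oriented by its positively-correlated
  allele; gating on $|\tau|$ makes the call invariant to allele labelling.
* **Strict exceedance of a nearest-rank percentile.** "Higher than the 95th
  percentile" is read literally: the window quantile is the
  $\lceil 0.95 w \rceil$-th smallest of the $w$ window values, and the focal
  SNP must strictly exceed it. A consequence worth knowing: for windows of
  $w \le 20$ the nearest-rank 95th percentile *is* the window maximum, so no
  member can pass — sparse MAF regions are conservatively silent. Windows of
  size 1 are flagged and fail.
* **Group prevalence combiner.** How member-species prevalences combine
  into a parasite-class value is unstated in the sources; the default is the
  unweighted mean over species with data (symmetric, scale-preserving), and
  the combiner is an argument.
* **Strand-aware upstream windows.** "Upstream of the transcription start
  site" is biologically strand-defined, so the window extends left of
  `tx_start` on + genes and right of `tx_end` on − genes, although published
  descriptions do not mention strand.
* **Enrichment estimator.** Empirical p-values use $(1+k)/(1+R)$, never
  zero; draws are without replacement within a resample (a "sample of
  genes" is read as distinct genes; with-replacement is behind a flag);
  target genes stay in the control pool (sampling is "from a list of all
  genes"; exclusion is behind a flag). The SNP-count comparison is
  two-sided (doubled smaller tail, capped at 1) — it is a matching
  diagnostic, not an enrichment statistic.
* **Quantile binning.** The published 24 bin edges are not available, so
  edges are type-1 count quantiles with duplicate edges merged; explicit
  edges can be supplied for exact replication.
* **Exact permutation p.** Enumerable up to $n = 10$ so that every
  correlation below the normal-approximation validity bound ($n \le 10$)
  can fall back to it; `correlate_env` does so automatically with a
  warning, and errors below 3 shared countries.
* **Nearest-gene distance.** Half-open intervals; the distance is the
  number of bases strictly between SNP and transcript boundary
  (`tx_start - pos` upstream, `pos - tx_end` downstream), ties broken by
  the lexicographically smaller gene id.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the study conditions used throughout the
tests: 10 countries × 5 populations, an integer environmental gradient
1..10 (one value per country, replicating the tie structure of a per-country
diversity count), 20,000 neutral SNPs under a Balding–Nichols hierarchy
(ancestral $p_0 \sim U(0.05, 0.95)$, country frequency Beta-distributed
around $p_0$ with $F_{country} = 0.05$, population frequency
Beta-distributed around the country value with $F_{pop} = 0.01$), and 50
planted SNPs whose country-level frequency is
$\mathrm{logit}^{-1}(a + \beta z)$ with $a \sim U(-1,1)$, $z$ the
standardised environment and $\beta = 8$. Genes (2,000 of 5–20 kb) are
packed without overlap on a 100 Mb chromosome; neutral SNPs land uniformly,
planted SNPs land inside genes, with a configurable odds ratio towards a
target gene set. One seed drives the entire generator.

Not emulated: linkage disequilibrium between SNPs (SNPs are independent
given the structure), admixture, sequence-level mutation processes, and
realistic human demography. Passing tests therefore demonstrate that the
*procedure* behaves as specified under drift plus monotone selection — not
that real panels are free of the confounders the simulator omits.

## Known limitations, stated from measurement

* **Drift makes the normal p anti-conservative.** With shared country-level
  drift, the five populations of a country are strongly correlated, so the
  effective sample size is nearer the number of countries than the number
  of populations. On the default panel about 2.4% of *neutral* SNPs survive
  the genome-wide Bonferroni threshold, and because Bonferroni survivors
  are exactly the top-$|\tau|$ SNPs they also clear the 95th-percentile
  gate. The test suite asserts this directly (null p stochastically smaller
  than uniform) and the recovery study reports it honestly: sensitivity for
  the planted SNPs is 1.0, but the truth-FDR of the call set is ~0.89 under
  these conditions. The MAF-matched gate removes the *frequency dependence*
  of the inflation, not the inflation itself; scan hits are candidates, to
  be filtered by confounder re-tests and enrichment context. A null control
  with independent populations (country-level drift removed,
  $F_{country} \to 0$, $\beta = 0$) is correctly calibrated: zero
  significant SNPs in ≥ 95% of runs.
* **The normal approximation degrades under heavy ties.** With few distinct
  values per margin (binary-like data) the mid-range two-sided p can
  deviate substantially from the exact permutation p at small n. Where
  inference actually happens — tail p with ≥ 5 distinct values per margin —
  the deviation stays below 0.05 at $n = 9$ (measured by enumeration), and
  scans never use the approximation below `min_n = 11`.
* **Discreteness of the resampling null.** The enrichment null gene-count
  is integer-valued, so the achievable type-I rate at nominal 0.05 is
  ~0.032 at the 2,000-gene / 200-target / 100-significant design (measured
  over 1,000 replicates) — conservative, never liberal.

## Study sizes used by the checks

Calibration of the normal approximation uses 10,000 draws at $n = 50$;
Kendall correctness uses 1,000 random instances ($n \le 9$) against a
pair-enumeration oracle and 150 instances ($n \le 7$) against a full
permutation oracle; recovery uses 20 seeded panels of 20,050 SNPs plus 20
independent-population null panels; enrichment calibration uses 600
replicates of 500 resamples (enough that the Monte Carlo error of the rate
estimate is well below the tolerance band) and power uses 50 seeded 3:1
plantings at 1,000 resamples. All of these run from a single passed seed.
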