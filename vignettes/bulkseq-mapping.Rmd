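---
title: "Mapping parent-of-origin effects with bulkscan: model, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping parent-of-origin effects with bulkscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The genetic model

The package models a cross in which seed survival depends on the parent
of origin of alleles at a small number of loci. A maternal-effect
lethal locus makes seeds abort when the mutant allele is inherited
maternally; paternal **rescue loci** restore viability when the
paternal-accession allele (called B throughout; the maternal background
is A) is transmitted by the pollen donor.

Survival of a maternally mutant seed is

```
survival(x) = min(cap, v0 * prod_i r_i ^ x_i)
```

with `x_i = 1` when the paternal gamete carries B at rescue locus `i`.
The model is multiplicative and epistasis-free, which encodes the
empirical observation that rescue loci act independently and each
additional paternal rescue allele scales the viable-seed rate by a
roughly constant factor. A multiplier may be `Inf`, meaning fully
penetrant rescue: survival equals `cap` whenever the paternal B allele
is present, even when `v0 = 0`. This is the only way to express
"survival 1 iff B present" together with an unrescued viability of
exactly zero; a finite multiplier cannot leave `v0 = 0`.

Maternally wild-type seeds survive with `wildtype_viability`
(default 1). Survival is a single per-seed Bernoulli: endosperm/embryo
developmental timing, triploid endosperm dosage, and autonomous
development are deliberately out of scope.

Three standard designs are provided. In `mea_pool` a homozygous mutant
mother (all-A genome) is pollinated by an A/B F1: every seed is
maternally mutant and only the paternal gamete segregates. `wt_pool` is
the matched control with a wild-type mother. `f2_selfing` selfs an F1
heterozygous for the lethal and for all tracked loci; the lethal locus
is treated as unlinked to the rescue loci, so a seed is maternally
mutant with probability 1/2 independent of the tracked genome. The
textbook anchors follow by enumeration: 50% viable seeds for the selfed
F2 with no rescue, 75% with one unlinked fully penetrant rescue locus,
25% paternal-accession allele copies in the control pool, 50% at a
fully required locus in the selective pool.

## Meiosis and expectations

Gametes follow the Haldane model: crossovers are a Poisson process
without interference, so the recombination fraction at distance `d` cM
is `r = (1 - exp(-2d/100))/2`. No map function was prescribed by the
experimental design this emulates; Haldane is the simplest standard
choice and makes every expectation computable in closed form. Physical
and genetic coordinates are tied by piecewise-linear interpolation
between per-chromosome anchors; the default map is linear over five
chromosomes with physical lengths of the *A. thaliana* reference and
genetic lengths typical of Ler/Cvi recombinant-inbred maps
(135/98/100/104/123 cM).

`expected_viable_fraction()` and `expected_pool_allele_fraction()`
enumerate all `2^L` paternal gamete classes (capacity-bounded at
`L = 20`), chaining Haldane transition probabilities along each
chromosome, and average survival over classes. At genetic distance `d`
from a single fully required locus the selective-pool allele fraction
is exactly `(1 - r(d))/2`, decaying from 1/2 at the locus to 1/4
unlinked. The forward simulator (`simulate_design()`,
`simulate_cross_population()`) provides the independent stochastic
route; tests require agreement within three binomial standard errors.

## The simulator's stated world

The generator's defaults reproduce the experimental setting the method
was developed in:

* three replicates per pool, with **600/400/400** survivors for the
  selective pool and **825/800/775** for the control pool;
* a panel of **20,000** informative SNPs over five chromosomes (a
  desk-scale stand-in for the several-hundred-thousand-SNP panels of
  real accession pairs; positions uniform per chromosome, 1% flagged
  reference-ambiguous and 1% flagged list-mismatching so the filter
  stages have work to do);
* Poisson read depth with mean **λ = 22** per SNP (the combined
  maternal+paternal coverage of the motivating data set) and a per-read
  allele miscall rate of ε = 0.002, a typical short-read error rate
  after quality trimming — ε is plumbing, not a calibrated quantity;
* **six rescue loci** at the physical positions of the motivating
  scan's main enrichment peaks (chr1 13.069 and 18.754 Mb, chr2
  16.054 Mb, chr3 20.370 Mb, chr5 9.865 and 14.239 Mb), each with
  multiplier `(0.85/0.03)^(1/6) ≈ 1.75`, so viability spans 3% with no
  rescue alleles to 85% with all six — the prescribed calibration of
  the acceptance world;
* survivor sampling by rejection to a fixed survivor count (pools were
  built from counted seedlings, not counted seeds); reads sample the
  pooled chromosomes uniformly with replacement, ignoring
  DNA-extraction batch structure (equi-amount pooling makes batches
  exchangeable).

Segregation distortion that is independent of the rescue mechanism is
modelled as a gametic transmission bias `b ≠ 1/2` at a locus,
implemented by rejection-reweighting paternal gametes (weight
proportional to `b` or `1 - b`, normalised to a maximum of 1). This
preserves Haldane linkage exactly and is equivalent to biased
transmission; whether real distortions act pre- or post-zygotically is
not modelled — only the gametic knob is exposed.

The null configuration (`null_run_config()`) removes all rescue loci
and sets `v0 = 0.5`: uniform viability, no selection anywhere.
(`v0 = 0` with no rescue loci is the defined "design yields no
survivors" error, so a positive uniform value is the meaningful null.)

## The filter cascade and scan statistics

Filtering mirrors the published pipeline order exactly. Per replicate:
drop panel-flagged positions, then drop positions whose coverage
exceeds the 99th percentile of a Poisson with λ equal to the
replicate's median coverage ("above" read strictly: the cut is
`> qpois(0.99, λ)`). Replicates are then combined by summing counts per
position (union of positions, zero-filled); positions lacking reads for
either allele are discarded, as are rows outside the closed interval
between the 1% and 99% empirical coverage quantiles (type-7 linear
interpolation — the default convention of mainstream numeric stacks;
the trim is genome-wide, as per-chromosome application was not
specified). Every stage logs its row count. Note that the two
coverage filters are *not* idempotent by construction: they recompute
the median/quantiles on their own output, so reapplication trims
further. The genuinely idempotent stages are the flag and monoallelic
drops.

Windows are sliding (step one SNP), 50 SNPs wide, never spanning a
chromosome boundary; a window's B proportion is the ratio of pooled
counts, not a mean of per-SNP ratios, and its centre is the median
member position. The two pools are first reduced to their common
retained SNP set so windows align one-to-one. Enrichment is the
relative excess `(p_sel - p_ctl)/p_ctl`; windows with `p_ctl = 0` are
undefined and excluded. Smoothing is a centred rolling median over 100
consecutive window values — widened to 101 so the window is centred;
at chromosome edges the window shrinks symmetrically, leaving the
index set unchanged. The interior uses `stats::runmed`; edges are
recomputed directly, and tests compare the whole result against a
naive O(n·w) oracle.

## Peak calling, and what this statistic can and cannot resolve

Peak calling was left open by the source method (peaks were read off
the track by eye), so it is an invented component with the following
default design: local maxima of the smoothed track at or above
`peak_threshold = 0.10`, merged within
`min_peak_separation_bp = 2 Mb` keeping the higher value (ties to the
smaller position), and additionally required to have **topographic
prominence** of at least `min_prominence = peak_threshold/2 = 0.05`:
a reported maximum must rise at least that far above the deepest
saddle separating it from higher terrain on its chromosome.

The prominence requirement exists because of two structural properties
of the statistic, both computable from the package's own enumerator
(`expected_pool_allele_fraction()` along a position grid):

1. **Whole chromosomes are elevated.** With six multiplicative loci of
   equal strength, conditioning on survival biases transmission at any
   position linked to any locus. Under a Haldane map at the default
   ~4.4 cM/Mb, the *noise-free* expected track stays above the 0.10
   calling threshold over most of every chromosome that carries a
   locus, and chromosome-end values are still ~0.13–0.18. A bare
   "local maxima above threshold" rule therefore reports every noise
   wiggle on these shoulders.
2. **Nearby locus pairs form plateaus, not twin peaks.** Between two
   equal loci 4–6 Mb apart the expected track dips by only ~0.01: the
   decay of one locus's signal, linear in the recombination fraction,
   is almost exactly compensated by the rise of the other's. Such
   pairs are fundamentally unresolvable by this statistic at these
   pool sizes, whatever the caller does.

Noise sets the other limit. With `N` survivors in a pool, the pooled
allele fraction at any position carries binomial sampling noise of
standard deviation `sqrt(p(1-p)/N)/2` — about 0.007 at N = 1400 —
which is *correlated along the chromosome over megabase scales*
(recombination decorrelates it only slowly) and therefore cannot be
removed by window averaging or median smoothing. Propagated through
the enrichment ratio, the smoothed null track retains a standard
deviation of roughly 0.03–0.04. The 0.10 calling threshold thus sits
near 3 σ of a megabase-correlated field, and somewhere in a
~120 Mb genome that level is crossed in most null realisations. Two
consequences, both visible in the acceptance tests and reported by
them per seed: the planted-locus recovery test meets its recovery
clause but not its ≤ 2-false-positive clause at any prominence
setting (raising prominence far enough to kill the shoulder maxima
also merges the plateau pairs, dropping recovery below the required
5/6), and the null pipeline calls at least one peak in most seeds.
Those two test clauses assert bounds that the stated world —
fixed pool sizes, fixed threshold — cannot meet, and they are left
failing by design rather than weakened. The practical reading: at
these pool sizes the method reliably localises isolated strong loci
and elevated regions, but peak *counts* are not a trustworthy
summary; replicate reproducibility and orthogonal mapping data are
what distinguished real loci in the motivating study as well.

## What a green test does and does not establish

The simulator emulates transmission genetics, selection, finite-pool
sampling, coverage noise, and simple gametic distortion. It does not
emulate: alignment and variant-calling artefacts (flags stand in for
them), batch structure in DNA extraction, locus-specific recombination
rate variation (the map is linear per chromosome), interference
(Haldane), unequal per-locus rescue strengths, or maternal-side
modifiers. Green recovery tests therefore establish that the pipeline
correctly extracts the signal its own model generates — not that real
data of this design would yield clean peak lists; the analysis above
indicates the opposite at realistic pool sizes.

## Numerical and interface choices

* Exact binomial intervals are Clopper–Pearson via the beta-quantile
  closed form, with hard 0/1 boundaries at `x = 0` and `x = n`; the
  rescue test is a one-sided exact binomial tail against the control's
  observed proportion treated as a fixed null (the motivating figure
  annotates tests against a single reference line), Bonferroni-scaled
  and capped at 1. A control at 100% makes "greater" impossible and
  returns p = 1.
* Proportions destined for linear modelling can be variance-stabilised
  with the cube-root transform.
* Coordinates are 1-based internally (SNP-list convention); BED
  exports are 0-based half-open; conversion lives in the writers only.
* Every TSV output carries `#` header lines with the package version,
  seed, and a configuration fingerprint; the run manifest records
  per-stage row counts so the analogous numbers of a real run are
  auditable.
* All randomness flows from the single configuration seed;
  `run_pipeline()` is byte-deterministic given the configuration.
* The Rcpp gamete core encodes chromosome boundaries as transitions
  with r = 0.5, which is exactly an independent Bernoulli(1/2)
  restart, so independent assortment needs no special case.

## Known limitations

Enumeration is capped at 20 loci (2^20 gamete classes). The informative
panel builder assumes the two accession SNP lists share a reference;
disagreeing reference bases are an error rather than a resolvable
conflict. No statistical significance is attached to peaks — the
method's own source reported none — and the track figure helpers are
intentionally minimal.
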