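---
title: "Detecting and dating introgression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating introgression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

This vignette is the package's account of the science it implements:
the models, every tunable parameter with its default and units, the
numerical conventions, the genuinely open design choices and how they
were resolved, and what the synthetic data can and cannot tell you
about real data.

## The two inference problems

**Dating an introgressed haplotype.** When a haplotype found in a
recipient species clusters inside the donor species' mtDNA variation,
the age of the transfer is bounded by the divergence of the closest
cross-species pair. Under neutrality, silent substitutions accumulate
along the two lineages as a Poisson process with mean
$\lambda = 2\mu L T$, where $\mu$ is the silent substitution rate per
site per year per lineage, $L$ the number of silent sites compared and
$T$ the divergence time in years. `divergence_point_estimate()`
returns the method-of-moments estimate $\hat T = k/(2\mu L)$;
`divergence_upper_bound()` returns the largest $T$ such that observing
no more than $k$ substitutions still has probability $\ge \alpha$,
i.e. the unique $\lambda^*$ with $P(X \le k \mid \lambda^*) = \alpha$.
The factor 2 matters: each lineage accumulates substitutions
independently for $T$ years.

**Scanning microsatellites for gene-flow outliers.** Strict isolation
since a split at time $\tau$ predicts a distribution of per-locus
differentiation. Observed loci falling below the simulated null's lower
percentile are *more similar* across species than pure drift allows
(candidate introgressors); loci above the upper cutoff are candidate
regions resistant to gene flow. The null chain is: n-coalescent under a
two-deme isolation model → infinite-sites mutations → stepwise
mutation model (SMM) conversion → the same FST/G'ST estimator applied
to the observed data. Using the identical estimator on simulated and
observed data is what makes the comparison fair.

## Parameters that matter

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `mu` | silent substitution rate | subs/site/year/lineage | 1.6e-8 | standard *Drosophila* silent-site rate |
| `L` | silent sites compared | sites | 737 | size of the concatenated mtDNA silent mask |
| `alpha` | level of the Poisson bound | — | 0.05 | one-sided 95% bound |
| `theta` | per-locus 4N₀μ | — | 4 | average of the two species' SMM-based estimates (X loci corrected by 4/3); taken as a parameter, not re-derived, because the per-species inputs are not reproducible from the summaries alone |
| `tau` | split time | 4N₀ generations | 1.25 | replicates the reference simulation command verbatim |
| `n1`, `n2` | chromosomes per deme | — | 400 total | 200 + 200 in the reference run |
| `replicates` | simulated null loci | — | 2000 (workflow), 10 000 (reference scale) | see "Problem sizes" |
| `tail_mode` | outlier mass convention | — | `central95` | see "Open choices" |
| inbred drop `replicates` | random allele-drop data sets | — | 200 | matches the reference correction |

A deliberate wrinkle: at diploid $N_0 = 10^6$ and ten generations per
year, a 250 000-year split is $\tau = 0.625$, not the 1.25 the
reference command encodes ($\tau = 1.25$ corresponds to 500 000
years). The two values cannot both be right, and nothing in the
summaries says which was intended. The simulator therefore takes
$\tau$ verbatim as a parameter and defaults to the printed command's
1.25, while `years_to_tau()` exposes the conversion so either reading
can be produced explicitly; the sensitivity grid (0.125, 1.25, 1.275)
brackets the split-time confidence interval either way.

## Time and mutation scaling

All coalescent times are in units of $4N_0$ generations (the `ms`
convention): a single pair of lineages coalesces at rate 2, so
$E[T_2] = 1/2$, the panmictic $E[\mathrm{TMRCA}]$ for $n = 4$ is
$0.75$, and the expected number of segregating sites is Watterson's
$\theta\, a_{n-1}$ with $a_{n-1} = \sum_{i=1}^{n-1} 1/i$ (for
$n = 400$, $\theta = 4$: $\approx 26.27$). The calibration tests check
exactly these identities, and the two-deme model's site-count
distribution is checked against an independent coalescent simulator
(msprime) by a Kolmogorov–Smirnov test.

## Estimator conventions

- **FST** is the Weir–Cockerham (1984) multi-allelic variance-components
  estimator applied to *allele copies*, so diploid genotypes and
  simulated haploid chromosomes are directly comparable. The reference
  tool's exact weighting for inbred-corrected data is not recoverable;
  allele-copy weighting is the recorded choice. Negative estimates are
  retained — truncation would distort the null's lower tail, which is
  precisely the region an introgression scan reads.
- **G'ST** uses unweighted $H_S$ (mean within-deme gene diversity) and
  $H_T$ from unweighted mean frequencies, with Hedrick's (2005)
  two-deme standardization $G'_{ST} = G_{ST}(1 + H_S)/(1 - H_S)$. With
  it, highly polymorphic microsatellites can reach 1, making low-end
  outliers comparable across heterozygosity levels.
- **Inbred-line correction**: every genotype of an inbred-flagged
  individual is reduced to a single uniformly chosen allele copy
  (residual heterozygosity in an isofemale line is an artefact), and
  the statistic is averaged over 200 random reductions.
- **Rarefied richness** uses the exact hypergeometric formula
  $E[A_g] = \sum_i (1 - \binom{N-N_i}{g}/\binom{N}{g})$, evaluated via
  log-binomials for numerical stability.
- **Shared-alleles distance** is defined on pooled group frequencies
  ($D = 1 - \frac1L \sum_\ell \sum_a \min(p, q)$) with pairwise
  deletion of untyped loci; the individual-level variant is out of
  scope. NJ trees come from `ape::nj`; bootstrap support resamples
  *loci* with replacement and counts recovered bipartitions.

## Numerical choices

- The Poisson bound is inverted by monotone bisection on
  $\lambda \mapsto P(X \le k \mid \lambda)$ over $[0, k + 50]$ to
  $|\Delta\lambda| < 10^{-9}$; tests cross-check against the
  gamma-quantile identity $\lambda^* = Q_{\Gamma(k+1)}(1-\alpha)$ and
  the $k = 0$ closed form $-\log\alpha$. With $L = 737$ and
  $\mu = 1.6\times10^{-8}$ the exact inversions give 328 768 years
  ($k=3$) and 127 024 years ($k=0$); published rounded figures of
  325 000 and 125 000 differ by 1–2%, consistent with rounding at some
  unstated precision, and the package reports the exact values.
- The Jukes–Cantor correction is applied to the *mean* pairwise
  p-distance, not pair by pair — this is what reproduces the worked
  divergence numbers — and raises an explicit error at saturation
  ($\bar p \ge 3/4$).
- Null cutoffs are inverse-ECDF (type-1) order statistics: unambiguous
  with thousands of draws and exactly reproducible under a fixed seed.
- Gap/N handling: any alignment column containing `-` or `N` in any
  sequence is excluded from every statistic (and haplotype identity is
  computed on the retained columns), keeping all pairwise comparisons
  on one site set.
- Monomorphic loci/replicates are `NA`/`undefined` everywhere — never
  silently dropped, never coerced to 0 — and excluded from percentile
  computation with their rate reported.
- All randomness flows through R's global RNG; `run_pipeline()`
  derives per-stage seeds from one top-level integer so a single
  number reproduces a whole run.

## Open choices and how they were resolved

- **Outlier tail mass.** "Outside the 95 percentile" with an
  expectation of "no more than one extreme locus among 24" implies a
  *total* 5% rate, i.e. 2.5% per tail; but the accompanying figure
  shades 5% per tail. Both are implemented (`central95`, `tail5`);
  `central95` is the default because it matches the stated expectation
  under the null.
- **SMM step convention.** The historical infinite-sites→SMM
  conversion script's sign rule is undocumented; each mutation is an
  independent equiprobable ±1 repeat-unit step under the run's seed.
  Step magnitude is fixed at one (strict single-step model);
  multi-step and asymmetric variants are out of scope.
- **Silent-site classification.** The helper `silent_site_mask()`
  admits third codon positions that are ≥2-fold degenerate for every
  observed codon, but any caller-supplied mask is accepted — the
  original analyses do not state their classifier, so per-fragment
  silent-site counts are not treated as reproducible targets.

## What the synthetic data emulate — and what they do not

`synth_spec()` reproduces the *structure* of the study: 125 recipient
+ 15 donor individuals; 25 loci on X/2nd/3rd/4th chromosomes with the
4th-chromosome locus fixed in both species; 30% of recipient
individuals flagged as inbred lines; five introgressed loci simulated
with both samples drawn from one pool (split effectively at
$\tau = 0$), which yields genuinely reduced differentiation rather
than copied alleles; and an mtDNA haplogroup plan planting *exact*
silent-substitution counts on a star-like scaffold with disjoint
substitution sites (the introgressed class: one haplotype at 3
substitutions from its nearest donor, one at 0, five apart from each
other, matching the published pair counts). Haplotype classes are
planted deterministically rather than simulated under a substitution
process, because the dating checks need exact counts.

What passing tests on these data show: the estimators, the simulator
and the scan machinery are internally correct and calibrated against
independent oracles. What they do not show: robustness to features of
real data the generator omits — heteroplasmy, genotyping dropout
beyond the inbred mechanism, mutation-rate heterogeneity across loci
and lineages, selection (including endosymbiont-driven sweeps),
population structure within species, and recurrent mutation at silent
sites. Real-data outlier counts therefore need not match the synthetic
ones.

## Problem sizes

The bundled workflow and tests use deliberately reduced Monte-Carlo
sizes chosen so that sampling error is small relative to the effects
tested: 2 000-replicate nulls (cutoff standard error ≈ 0.01 at the
2.5% quantile), 5 000 replicates for the Watterson calibration
(≈ 0.1 sites standard error on a mean of 26.3), 3 000 + 3 000 draws
for the cross-simulator comparison, 1 000 loci for the nominal-rate
check. The reference-scale run (10 000 null replicates) is a single
argument change and scales linearly in time.

## Known limitations

- The isolation model has no migration after the split, no population
  size changes, and exactly two demes; the scan's null is only as good
  as those assumptions.
- The Poisson dating treats $\mu$ as known; rate uncertainty is not
  propagated (the point and bound scale as $1/\mu$, so readers can
  rescale).
- FST/G'ST are two-deme only; hierarchical sampling (collections
  within species) enters only through the shared-alleles tree.
- X-linked loci are simulated with the same effective size as
  autosomes; the 4/3 correction is assumed to have been applied when
  choosing `theta`.
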