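# introscan

Detecting and dating interspecific introgression from multilocus
population data.

Closely related species — the motivating system is the *Drosophila
simulans* / *D. mauritiana* pair — can exchange mitochondria and nuclear
alleles long after they split. Two signals betray such gene flow:

1. **mtDNA haplotypes that are "too similar" across the species
   boundary.** If a recipient-species haplotype sits only *k* silent
   substitutions from its closest donor-species relative over *L* silent
   sites, and silent substitutions accumulate at rate μ per site per
   year on each of the two lineages, the expected divergence is
   E[k] = 2μLT. The mean divergence time is therefore

   T̂ = k / (2μL),

   and the largest T still compatible with observing no more than k
   substitutions at level α solves P(X ≤ k) = α for X ~ Poisson(2μLT)
   (one-sided upper bound, inverted exactly by bisection).

2. **Microsatellites that are less differentiated than drift under
   strict isolation allows.** Each observed locus' Weir–Cockerham FST
   (or Hedrick's standardized G′ST) is compared against the null
   distribution of that statistic across loci simulated under a
   two-population isolation model: an n-coalescent with a population
   join at τ (in 4N₀ generations), infinite-sites mutations at rate
   θ = 4N₀μ per locus, converted to repeat-number alleles under the
   strict single-step stepwise mutation model. Loci below the lower
   percentile cutoff are candidate introgressors; loci above the upper
   cutoff are candidate barriers to gene flow.

The package implements both analyses end to end, together with the
supporting statistics (DnaSP-style diversity summaries, rarefied
allelic richness, inbred-line allele-drop correction,
proportion-of-shared-alleles NJ trees with locus bootstraps) and a
synthetic-data generator that reproduces the study structure — 125 + 15
individuals, 25 microsatellites, mtDNA haplogroups with exact planted
silent-substitution counts — so the whole workflow runs without any
external data deposit.

## Worked example

```r
library(introscan)

# dating: 3 silent substitutions over 737 silent sites at 1.6e-8
divergence_point_estimate(3, 737, 1.6e-8)
#> [1] 127204.9
divergence_upper_bound(3, 737, 1.6e-8, alpha = 0.05)$t_upper
#> [1] 328767.7

# how likely is a haplotype at frequency 4/125 to be missed in a
# survey of 345 individuals?
prob_unsampled_haplotype(4/125, 345)
#> [1] 1.339671e-05

# outlier scan on a synthetic two-species microsatellite panel
set.seed(1)
gt  <- gen_genotype_table(synth_spec())
obs <- locus_stats(gt)
null <- build_null(isolation_model(250, 30, 4, 1.25), 2000, "fst")
classify_loci(obs, null)
#> outlier scan (fst, central95, tau=1.25): 5 low, 0 high, 19 none, 1 undefined
```

The point estimate says the introgressed haplotype pair diverged about
127 000 years ago; the bound says anything older than about 329 000
years is incompatible (at α = 0.05) with seeing only three
substitutions. The non-sampling probability ~1.3 × 10⁻⁵ rules out the
haplotype simply having been missed by earlier surveys. In the scan,
the loci flagged `low` are exactly the ones the generator simulated
with both species' lineages drawn from a single pool (introgression);
the single `undefined` locus is the 4th-chromosome marker fixed for the
same allele in both species, which carries no information about
differentiation.

## The analysis workflow

The `analysis/` scripts run the full study pipeline over a generated
data set, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_synthesize_data.R` | generate genotypes, mtDNA alignment, silent mask |
| `02_sequence_diversity.R` | per-haplogroup n, S, h, Hd, π and between-species F, S*, Ks |
| `03_date_introgression.R` | closest donor pairs, Poisson dates and bounds |
| `04_null_outlier_scan.R` | inbred-corrected FST, coalescent null, outlier calls, τ sensitivity grid |
| `05_shared_alleles_tree.R` | rarefied richness and bootstrapped shared-alleles NJ tree |

`run_pipeline(run_config(out_dir, seed))` performs the same stages in
one call and writes a JSON manifest (config, derived per-stage seeds,
timings) from which a run is reproducible bit for bit.

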