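# phylosucc

Phylogenetic turnover of staged (chronosequence) communities: who assembles
with whom, at which phylogenetic depth, and does it track the environment?

`phylosucc` is for community ecologists analysing plot networks that span
successional stages — e.g. secondary forest mosaics — together with a dated
phylogeny of the regional species pool. It decomposes phylogenetic turnover
into spatial (within-stage) and temporal (between-stage) components with
the Hardy–Senterre statistics

* **Π<sub>ST</sub>** `= 1 − Δ^P_w / Δ^P_a` (presence/absence) and
* **B<sub>ST</sub>** `= 1 − Δ*^P_w / Δ*^P_a` (abundance-weighted),

where `Δ_w` / `Δ_a` are mean cophenetic distances between distinct species
(or individuals of distinct species) within and across plots. Π/B > 0 means
co-occurring species are more related than species from different plots
(clustering); < 0 means overdispersion. Around these it provides:

* tip-shuffling null models over the regional pool, with exact rank
  p-values, SES, and null 95% intervals;
* depth profiles: turnover restricted to species pairs younger than a
  divergence-time threshold, tested with clade-restricted partial
  randomizations (default grid 30–128 Myr in 11 steps);
* per-node clade enrichment per plot ("nodesig"), with both Monte Carlo
  and exact hypergeometric modes;
* turnover–environment permutation regressions on PCA-based environmental
  distances, with spatial-distance partialling and equal-sample-size
  resampling;
* phylogenetic signal in trait panels (Blomberg's K, Pagel's λ,
  Abouheif/Moran's I);
* a synthetic chronosequence generator with named scenarios (neutral,
  conserved-niche filtering, late-stage deep filtering, overdispersion,
  dominance shift) used as the package's own test harness.

Everything takes and returns plain tibbles (trees are `ape::phylo`), fits
pipes, has `autoplot()` methods for the main result types, and
`tidy()`/`glance()` for fitted objects.

## Worked example

```r
library(phylosucc)

# a late-stage deep-filtering community: 27 plots in stages 5/4/5/6/7,
# 143 species from a 410-species pool, 128 Myr root
bundle <- simulate_bundle(scenario_config("deep_filtering_late"), seed = 1)

pairs <- pairwise_turnover(bundle, "presence")
grouped_turnover(pairs, "spatial_temporal")
#> # A tibble: 2 × 6
#>   group   mean_stat      se pooled_stat n_pairs n_undefined
#>   <chr>       <dbl>   <dbl>       <dbl>   <int>       <int>
#> 1 between    0.0417 0.00248      0.0444     289           0
#> 2 within     0.0543 0.00954      0.0503      62           0

turnover_null_test(bundle, "presence", scopes = c("within", "4", "5"),
                   R = 999, seed = 2)[, c("scope", "observed", "ses", "p_two")]
#> # A tibble: 3 × 4
#>   scope  observed   ses p_two
#>   <chr>     <dbl> <dbl> <dbl>
#> 1 within   0.0543  32.6 0.002
#> 2 4        0.0912  28.2 0.002
#> 3 5        0.0941  30.2 0.002
```

Within-stage turnover is far above the tip-shuffling null (SES ≈ 28–33,
p = 0.002 at R = 999): plots hold clusters of close relatives, here because
the two daughter clades of a ~100 Myr split were sorted to opposite ends of
the environmental gradient in stages 4–5. The depth profile localizes that
signal:

```r
dp <- depth_profile(bundle, "presence", scopes = "5", R = 199, seed = 3)
dp[dp$threshold >= 90, c("threshold", "ses", "p_two")]
#> # A tibble: 5 × 3
#>   threshold    ses p_two
#>       <dbl>  <dbl> <dbl>
#> 1        90 -1.47   0.04
#> 2       100 -0.330  0.09
#> 3       110 23.8    0.01
#> 4       120 34.6    0.01
#> 5       128 35.5    0.01
autoplot(dp)
```

No positive signal at or below the planted split (~102 Myr in this data
set), strong positive SES only at deeper thresholds — clustering that lives
deep in the phylogeny. The environmental regression ties it to the
gradient:

```r
stagewise_association(bundle, "presence", n_perm = 5000,
                      seed = 4)[4:8, c("scope", "r_squared", "p_value")]
#> # A tibble: 5 × 3
#>   scope r_squared p_value
#>   <chr>     <dbl>   <dbl>
#> 1 1        0.0338  0.602
#> 2 2        0.707   0.049
#> 3 3        0.0955  0.376
#> 4 4        0.835   0.0002
#> 5 5        0.810   0.0002
```

The association is decisive only in the filtered late stages (R² ≈ 0.8,
p = 2e-4); stage 2's marginal negative slope (6 pairs, p = 0.049) is the
kind of nominal hit a 5% test produces — the calibration and recovery
experiments in the test suite quantify exactly this behaviour across 100
simulated data sets.

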