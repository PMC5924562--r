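# tempogen

Temporal mitogenome diversity, serially sampled coalescent simulation, and
approximate Bayesian demographic inference.

## What it is for

Conservation datasets increasingly pair **historical** sequences (museum
skins, decades to centuries old) with **modern** ones from the surviving
population. For a non-recombining, maternally inherited locus — a complete
mitochondrial genome — `tempogen` answers three questions:

1. **How much diversity was lost between layers?** Per-layer haplotype
   diversity (Hd), nucleotide diversity (π), segregating sites, mean
   pairwise differences, Tajima's D and Fu's Fs, plus fold-change reports.
2. **What demographic history explains the data?** Model choice and
   parameter estimation by approximate Bayesian computation (ABC) over
   piecewise-constant haploid demographies (constant size, postglacial
   expansion, expansion + recent anthropogenic bottlenecks), with
   local-linear regression adjustment, logistic model choice, and
   pod-based type I/II error rates.
3. **How do the haplotypes relate across time?** Temporal sharing counts and
   a minimum-spanning haplotype network (union of all minimum spanning
   trees over Hamming distances).

The statistics at the core, in standard notation:

* Tajima's **D** = (k − S/a₁) / √(e₁S + e₂S(S−1)), with k the mean pairwise
  differences, S the segregating sites and a₁, e₁, e₂ the usual constants —
  negative under expansion, positive after a bottleneck.
* Fu's **Fs** = ln(S′/(1−S′)) with S′ = P(K ≥ h) = Σⱼ₌ₕⁿ |s(n,j)| θʲ / (θ)ₙ
  under the Ewens sampling formula at θ = k. The unsigned Stirling numbers
  of the first kind |s(n,j)| reach ~10¹¹⁵ at n = 79, so `tempogen` evaluates
  them **exactly** in arbitrary-precision integer arithmetic.
* The heterochronous coalescent: lineages activate at their layer's age;
  k active lineages in an epoch of haploid size N coalesce at rate
  k(k−1)/(2N), truncated at epoch boundaries.
* ABC: normalized Euclidean distances on the per-layer feature vector
  (h, S, k, D), rejection of all but the closest fraction, Epanechnikov
  kernel weights, weighted local-linear regression adjustment on a
  logit-bounded scale, and kernel-weighted multinomial logistic model
  choice.

## Worked example

Simulate a study-shaped dataset (39 historical sequences at age 5
generations + 79 modern at age 0, 16,588 bp, 2% missing data in the
historical layer) under a severe recent bottleneck, then recover the
diversity contrast:

```r
library(tempogen)

spec <- dataset_spec("bottleneck_eu",
                     params = list(ne_modern = 3, ne_pre_european = 5.67e5,
                                   ne_pre_glaciation = 3.9e3,
                                   t_bottleneck_eu = 4.47,
                                   t_post_glaciation = 600, mu = 6.45e-8))
ds <- generate_dataset(spec, seed = 1)
stats <- layer_stats(ds$alignment)
stats[, c("layer", "n", "h", "S", "Hd", "pi", "D", "Fs")]
fold_change_report(stats)
temporal_shared(collapse_haplotypes(ds$alignment))$n_shared
```

```
#> # A tibble: 2 × 8
#>   layer          n     h     S    Hd       pi     D    Fs
#>   <chr>      <int> <int> <int> <dbl>    <dbl> <dbl> <dbl>
#> 1 modern        79     1     0 0     0        NA    NA
#> 2 historical    39    17    22 0.881 0.000446 -1.18 -6.63
#> # A tibble: 2 × 4
#>   metric    older newer fold_loss
#>   <chr>     <dbl> <dbl>     <dbl>
#> 1 Hd     0.881        0       Inf
#> 2 pi     0.000446     0       Inf
#> Warning: newer-layer diversity is zero; fold loss reported as Inf
#> [1] 1
```

The historical layer is diverse (17 haplotypes among 39 birds, Hd ≈ 0.88,
negative Tajima's D and Fu's Fs — the footprint of postglacial expansion)
while the modern layer, sampled after a crash to a haploid effective size of
3 some 4.5 generations ago, has collapsed to a single matriline: Hd = 0,
Tajima's D not computable (S = 0), fold losses reported as infinite with a
warning, and exactly one haplotype shared across the two time layers.
Gentler bottlenecks (say `ne_modern = 17.6`) leave several deeply divergent
matrilines instead, with strongly *positive* modern-layer D — the classic
intermediate-frequency signature. Real datasets of this shape sit in
between (the published study reports a ~30-fold Hd and ~11-fold π loss);
per-dataset values vary with the generating parameters and seed.

ABC model choice and estimation on the same alignment:

```r
ref <- build_reference_table(c("bottleneck_eu", "bottleneck_pol"),
                             n_sims_per_model = 10000, seed = 2)
fit <- abc_fit(ref, layer_stats(ds$alignment), accept_fraction = 0.01)
glance(fit)   # chosen scenario and its posterior probability
tidy(fit)     # posterior mode and 90% bounds per parameter
autoplot(fit) # posterior densities
```

Haplotype networks and temporal sharing:

```r
ht  <- collapse_haplotypes(ds$alignment)
temporal_shared(ht)$n_shared
net <- min_spanning_network(ht)
autoplot(net)
```

Or run everything (stats → network → ABC → pods) with one seeded, logged
call that writes TSV/JSON/GraphML outputs and a run manifest:

```r
res <- run_pipeline(run_config(synthetic_scenario = "bottleneck_eu",
                               scenarios = c("bottleneck_eu", "bottleneck_pol"),
                               n_sims = 10000, accept_fraction = 0.01,
                               seed = 1, out_dir = "run1"))
```

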