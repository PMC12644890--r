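# microsucc

Statistical analysis of soil microbial communities along
grassland-to-forest land-abandonment gradients, built for paired-site
designs: each grassland (managed, recently abandoned, or late successional)
is paired with an adjacent forest representing its successional endpoint.

The package asks, and answers quantitatively, the questions such designs
raise: does taxonomic (OTU) diversity fall while functional-gene (C-N-P
cycling) diversity rises? Do gene repertoires specialize — declining Levin's
niche overlap — as succession proceeds? Does the community trade functional
redundancy for functional diversity, and does that shift track carbon
degradation capacity?

## The core statistics

* **Diversity:** Shannon `H' = -Σ p ln p`, Simpson dominance `D = Σ p²`,
  Bray–Curtis distances, PCoA, and a seeded one-factor perMANOVA
  (pseudo-F on the standard partition of squared distances, p-value
  `(1 + #{F* ≥ F}) / (1 + n_perm)`, optional within-pair strata).
* **Paired effect sizes:** partial omega-squared
  `ω²p = (SS_eff − df·MS_err) / (SS_eff + (N − df)·MS_err)` from a
  pair-blocked two-way ANOVA with a pair-bootstrap CI; bias-corrected
  Hedges' g for substrate-wise respiration contrasts.
* **Niche metrics:** Levin's breadth `B = 1/Σ p²` and directional overlap
  `O_fg = Σ f g / Σ g²` of gene families across the samples of each
  land-use stage, with a limit-of-quantification (mean ≥ 1.65 × SE) screen
  applied within each stage and stages balanced to equal sample counts.
* **Redundancy framework:** per-stage min–max-scaled trait distances
  (Euclidean, divided by the stage maximum), Rao's quadratic entropy
  `Q = Σᵢ Σⱼ pᵢ pⱼ dᵢⱼ`, and the exact ternary closure
  `D + Q + R = 1` with uniqueness `U = Q / (1 − D)`; decoupling
  regressions of functional on taxonomic diversity per ecosystem with a
  slope-difference F-test.
* **Degradation:** substrate-induced respiration processing
  (`MSIR = Σ (rate − basal)` over glucose, glycine, oxalic acid, yeast,
  lignin, chitin) and MSIR-on-diversity regressions.
* **Normalization:** scaling with ranked subsampling (SRS, deterministic
  tie-breaks), seeded rarefaction, relative abundances.
* **Synthetic data:** a paired-site generator (generalist/specialist gene
  repertoires, Gaussian pH filtering, threshold/linear/unimodal covariate
  shapes, gene tables as counts × copies, diversity-coupled SIR) with
  ground truth, used by the test suite for calibration and
  parameter-recovery validation.

## Worked example

```r
library(microsucc)
library(dplyr)

sim <- simulate_dataset(sim_config(n_pairs = 20, seed = 1))

otu_n <- srs_normalize(sim$otu, normalization_spec("srs", cmin = min(colSums(sim$otu))))
div <- diversity_profile(otu_n) |>
  left_join(select(sim$sf, sample_id, stage, ecosystem), by = "sample_id")
div |> group_by(ecosystem) |> summarise(mean_H = mean(shannon_H), n = n())
#>   ecosystem mean_H     n
#> 1 forest      3.24    20
#> 2 grassland   3.82    20

coords <- ternary_coordinates(otu_n, sim$traits, sim$sf)
coords |> group_by(ecosystem) |> summarise(D = mean(D), Q = mean(Q), R = mean(R))
#>   ecosystem      D     Q     R
#> 1 forest    0.0607 0.425 0.514
#> 2 grassland 0.0395 0.380 0.580

glance(ternary_group_test(coords, n_perm = 9999, seed = 1))
#>   pseudo_F    R2      p partial_omega_sq permutations     n degenerate
#> 1     41.7 0.523 0.0001            0.504         9999    40 FALSE

ov <- stage_overlap_summary(to_relative(sim$gene), sim$sf)
ov$summary |> group_by(stage) |> summarise(overlap = mean(mean_overlap, na.rm = TRUE))
#>   stage   overlap
#> 1 managed   0.923
#> 2 recent    0.812
#> 3 late      0.847
#> 4 forest    0.703
```

Read: the simulated forest communities lose taxonomic diversity
(H' 3.82 → 3.24) while their functional diversity Q rises and redundancy R
falls — the ternary perMANOVA separates the ecosystems (p = 1e-4) — and the
niche overlap of gene families declines from managed grassland (0.92)
to forest (0.70): community-wide specialization. These are exactly the
contrasts the generator programs, which is what makes them useful test
fixtures.

`run_pipeline(run_config(simulate = list(n_pairs = 20), seed = 1))` runs the
whole chain (simulate → normalize → diversity → niche → redundancy → SIR →
report) and writes TSV outputs, a markdown report and a JSON manifest with
config, seeds and file checksums; identical config + seed reproduces every
file byte for byte. Real study tables (OTU/gene TSVs, sample metadata, SIR
measurements) can be substituted for the simulated inputs via
`run_config(inputs = list(...))`.

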