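# castguild

Comparative life-history analysis for guilds of parasitic castrators
("body snatchers") and their uninfected host.

## The problem

Life-history theory predicts that higher extrinsic mortality selects for
less allocation to growth and more to current reproduction.  A guild of
trematode parasitic castrators sharing a single snail host species is a
natural cross-species test bed: each castrator commandeers a host body and
grows and survives with the *same* physiological machinery as every other
guild member, while the guild's within-host dominance hierarchy (dominant
species kill subordinate species in co-infections) hands each species a
different, quantifiable extrinsic mortality.  Uninfected male and female
snails join the comparison with castration itself as their reproductive
death risk.

`castguild` is for ecologists and parasitologists who have (or want to
simulate) mark-recapture shell-growth data, site-level infection
prevalences and a dominance hierarchy, and who want the full analysis
chain with validated estimators.

## What it computes

* **Shell geometry** — growth volume `V_g = pi (w/4)^2 (d/360)` from final
  width `w` and degrees of new whorl `d`; cone-approximated standing
  volume; the cube-root scaling `V^(1/3) = 0.326 L + 0.497` and its
  inverse (`growth_volume()`, `initial_volume()`, `fit_scaling()`).
* **Growth model** — quasi-Poisson log-link GLM of individual growth on
  species group x initial size plus nested site/habitat/estuary and
  growing-time factors; size-specific growth curves standardized to a
  reference site and period; total growth allocation as the definite
  integral of the curve; all pairwise group contrasts with
  Benjamini-Hochberg FDR control (`fit_growth()`, `growth_curve()`,
  `total_growth_allocation()`, `pairwise_contrasts()`).
* **Differential extrinsic mortality** — the prevalence-transfer
  estimator: apply the focal species' prevalence among dominant-free
  snails to the snails carrying a dominant, subtract observed
  co-infections, divide by estimated total recruitment; site estimates
  pooled by prevalence-weighted mean; castration risk for uninfected
  snails; a gender-susceptibility logistic regression (`site_mortality()`,
  `pooled_mortality()`, `castration_risk()`).
* **Reproductive allocation** — gonadosomatic indices (including the
  combined female index: ovary + accessory tissues) and relative
  reproductive allocation, GSI / proportional growth = reproductive mass /
  new growth mass (`combined_female_gsi()`,
  `relative_reproductive_allocation()`, `build_allocation_table()`).
* **Comparative inference** — two-tailed randomization correlation tests,
  a two-stage randomization guard against the growth-in-the-denominator
  artifact, standard major axes, regression through the origin,
  Felsenstein independent contrasts on a unit-branch tree, and a
  site-level plasticity F-test (`randomization_correlation()`,
  `two_stage_randomization()`, `sma_fit()`, `independent_contrasts()`,
  `plasticity_test()`).
* **Synthetic worlds** — `generate_world()` builds datasets with the
  study's structure (17 sites / 3 estuaries, 8 castrators + 2 uninfected
  groups, hierarchical within-host killing, gamma-mixed Poisson growth)
  and returns the latent pre-kill recruitment, so every estimator can be
  checked against ground truth.

## Worked example

```r
library(castguild)

w   <- generate_world(default_world_config(n_per_site = 80), seed = 3)
tr  <- read_tree(system.file("extdata", "guild_tree_synthetic.nwk",
                             package = "castguild"))
res <- run_pipeline(w, tree = tr, B = 2000, seed = 7)
print(res)
```

```
Filter report: 1360 records in, 1346 retained
  excluded: 14 mixed, 0 undetermined, 0 outlier, 0 rare (rule: flagged, threshold > 20)
Growth model dispersion: 3.91
Comparative tests:
                         test statistic df      p    B seed
          growth_vs_mortality    -0.976 NA 0.0005 2000    7
             rra_vs_mortality     0.913 NA 0.0015 2000    8
             gsi_vs_mortality     0.506 NA 0.1400 2000    9
   two_stage_rra_vs_mortality     0.913 NA 0.0005 2000   10
                 plasticity_F     1.600  9 0.1240   NA   NA
 contrast_growth_vs_mortality    -0.973  8 0.0005 2000   11
    contrast_rra_vs_mortality     0.712  8 0.0260 2000   12
```

Reading this: the 14 mixed-species infections were excluded before
fitting; the quasi-Poisson dispersion (3.91) sits near the generating
factor of 4.  Total growth allocation falls steeply with differential
mortality (r = -0.976, randomization p = 0.0005 at B = 2000, the
attainable minimum), while relative reproductive allocation rises with it
(r = 0.913) — and the two-stage guard confirms the positive association is
not an artifact of growth sitting in the RRA denominator.  The raw
gonadosomatic index shows no significant association, the plasticity
F-test finds no within-species response to local risk (p = 0.124), and
both associations survive phylogenetically independent contrasts
(9 contrasts, origin-regression df = 8).  `res$allocation` holds the
10-row comparative table behind these tests, and
`res$fit$terms` the GLM term statistics.

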