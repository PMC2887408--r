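---
title: "Methods: growth, mortality and reproductive allocation in a castrator guild"
author: "castguild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth, mortality and reproductive allocation in a castrator guild}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castguild)
```

## The scientific problem

Life-history theory predicts that higher extrinsic mortality — the
probability of being killed by external factors — selects for reduced
allocation to growth and increased reproductive effort.  A guild of
trematode parasitic castrators sharing one snail host species offers an
unusually clean cross-species test.  Each castrator takes over ("snatches")
a host body and runs it with the same physiological machinery as every
other guild member; what differs between species is the extrinsic mortality
imposed by the guild's within-host dominance hierarchy, in which dominant
species kill subordinate species in co-infections.  Uninfected male and
female snails slot into the same comparison: for them, castration *is*
reproductive death, so their "differential mortality" is the risk of
becoming infected at all.

`castguild` implements the full analysis chain on mark-recapture shell
data: measured growth increments, a generalized linear growth model,
a prevalence-based mortality estimator, reproductive-allocation indices,
and the comparative inference layer (randomization tests, standard major
axes, regression through the origin, phylogenetically independent
contrasts), together with a synthetic-data generator that carries latent
ground truth so that every estimator can be validated against a known
answer.

## Shell geometry

Growth of a marked snail appears as paint-free shell deposited beyond the
mark, quantified as degrees of new whorl around the columellar axis.  The
volume of new growth is the aperture area times the grown fraction of a
turn,

$$V_g = \pi \left(\tfrac{w}{4}\right)^2 \cdot \frac{d}{360},$$

with $w$ the shell width (mm; the final width, since the new aperture
belongs to the new shell) and $d$ the degrees of growth.  Degrees may
exceed 360 for fast growers adding more than one whorl and are never
reduced modulo 360.  Standing shell volume is approximated by a cone; the
cone's base radius is taken as half the shell width (the shell's maximal
radius), a reading we make configurable through `radius_fraction` because
the aperture-circle convention above uses a quarter of the width while a
cone over the full basal width is the natural solid approximation.  Length
and volume interconvert through the cube-root scaling relation
$V^{1/3} = 0.326\,L + 0.497$, fit by ordinary least squares
(`fit_scaling()`).  Note a wrinkle worth keeping visible: inverting this
relation at 705 mm$^3$ gives 25.78 mm, slightly below the conventional
"~25.9 mm" pairing for the mean-sized snail; the package inverts the
printed relation and does not force agreement.

## The growth model

Individual growth in mm$^3$ is strongly overdispersed — many snails grow
little or not at all while some grow a great deal — so the model is a
log-link GLM with Poisson variance inflated by a multiplicative
overdispersion parameter (quasi-Poisson).  The design is: species group
(eight castrators plus uninfected males and females), initial size
(volume), their interaction, estuary, habitat nested in estuary, site
nested in estuary and habitat, and growing time nested in estuary (sites
are deliberately *fixed* effects: the model only controls for site
variation, it does not generalize over sites).  Quasi-likelihood point
estimates coincide with plain Poisson maximum likelihood; the Pearson
$\chi^2/\mathrm{df}$ dispersion estimate scales all uncertainties, and
per-term likelihood-ratio statistics are sequential deviance drops divided
by that dispersion.  A negative-binomial-style alternative is not needed
for the tested properties because the generator draws growth from a
gamma-mixed Poisson with variance $\varphi\mu$, which is exactly the
quasi-Poisson variance function — the fit is correctly specified by
construction.

Predictions are standardized to one reference site and the first growing
period (configurable; the default is the first site level), mirroring the
convention of reporting growth standardized to a fixed growing context.
`growth_curve()` evaluates expected growth along initial size; its nominal
domain is the group's sampled size range, evaluation is permitted within
the pooled sampled range, and extrapolation beyond that errors.  Total
growth allocation is the definite integral of the curve between common
limits — by default the minimum- and maximum-sized snail averaged across
groups — computed by adaptive quadrature with absolute tolerance
$10^{-8}$ times the curve scale.  Pairwise group comparisons at a common
size are Wald contrasts on the log scale (45 of them for 10 groups) with
Benjamini–Hochberg control of the false discovery rate at 0.05.

## Differential extrinsic mortality

For a focal species at one site, the estimator transfers the focal's
prevalence among *dominant-free* snails (snails carrying no species that
dominates the focal — not snails free of all trematodes, since the focal's
undisturbed prevalence is what is needed) onto the portion of the
population carrying a dominant:

* $p$ = focal prevalence among dominant-free snails,
* $E = p \times$ (snails carrying a dominant of the focal) — the expected
  doomed recruits,
* $K = E -$ (observed co-infections of the focal with a dominant),
* $R$ = (observed focal in dominant-free snails) $+ E$ — total estimated
  recruitment,

and the site-level differential mortality is $K/R$.  Negative values are
meaningful (facilitation: co-occurrence above chance); values are
truncated to $[-1, 1]$ since a species cannot lose more than all of its
recruits — in randomized stress tables the raw ratio can drop below $-1$
through sampling noise, and the truncation keeps the estimate
interpretable as a proportion.  Sites with no dominant-free snails or zero
estimated recruitment are skipped with a warning, never zero-filled.
Site estimates are pooled by a weighted mean with weights equal to the
focal's observed site prevalence; the weights are normalized within the
species across its sites (site sample size enters only through the
prevalence itself, the plainest reading of "weighting by observed
prevalence").  Dominance exceptions — tissue-refuge species tolerated by
some ranks — are represented simply by omitting edges; dominance is
deterministic, never probabilistic.

For uninfected snails the analogue of differential mortality is the
gender-specific trematode prevalence averaged (unweighted by default)
across sites.  A logistic regression of infection on gender, controlling
for site, growing time and size, tests gender differences in
susceptibility with a 1-df likelihood-ratio statistic.

## Reproductive allocation

For a castrator, reproduction is what the parasite tissue is for, so the
mass of trematode tissue over total infected-snail tissue mass is a
gonadosomatic index (GSI).  The female snail index adds accessory
reproductive tissues to the ovary fraction (7.7% + 7.2% = 14.9%,
standard errors combining in quadrature).  Because the GSI is a
standing-stock measure, the package also computes *relative reproductive
allocation* (RRA): GSI divided by the proportional allocation to growth at
the mean-sized snail, which algebraically simplifies to reproductive
tissue mass over new growth mass.  Both routes are implemented
(`relative_reproductive_allocation()`, `rra_from_masses()`) and tested for
equality.  The mass bridge from volume uses a single density constant
(default 1 mg/mm$^3$) — the module's main free constant — which cancels
out of all cross-species correlations.  GSI and RRA need not rank species
the same way, and in generated default worlds they do not: uninfected
snails combine middling GSI with very low growth and hence high RRA.

## Comparative inference

Correlation significance uses randomization tests: the observed Pearson r
against the null built by permuting one variable, two-tailed, with
$p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(B+1)$.  The production default
is $B = 100{,}000$ iterations; validation suites in this package run
scaled-down $B$ (typically 2,000) chosen so that 500-seed calibration
studies complete quickly while leaving Monte-Carlo error far below the
decision thresholds.  Because growth appears in the denominator of RRA, a
strong growth–mortality correlation could manufacture an RRA–mortality
association; the *two-stage randomization guard* permutes growth across
groups, rebuilds pseudo-RRA from the fixed GSIs, and correlates the
pseudo-RRA with the unpermuted mortalities.  This permutation scheme is
this package's own construction of the guard, designed to target exactly
the denominator artifact; it is documented as such rather than asserted to
match any external implementation.  Scatters are summarized by standard
major axes (appropriate when both variables carry error), and contrast
relationships are confirmed by regression through the origin
($\mathrm{df} = n - 1$).

Plasticity versus adaptation is separated by a site-level test: within
each species, does site-mean growth decline with the local risk of being
killed?  Local risk for a trematode is the site prevalence of its
dominants; for uninfected snails it is overall trematode prevalence.  The
test is a general linear model of site-mean growth on group and
group-specific risk slopes, reporting the joint F for the slopes.

Phylogenetically independent contrasts use Felsenstein's pruning with the
branch-extension term, on a user-supplied rooted bifurcating tree with
unit branch lengths (we do not know how evolution proceeds along these
lineages).  Polytomies are rejected rather than arbitrarily resolved — an
arbitrary resolution with unit branches changes the contrasts — though an
explicit `resolve = TRUE` flag performs a documented split-and-floor
resolution.  Uninfected male and female are included as sister tips, a
deliberate and acknowledged abuse (genders are not independent lineages)
that lets the gender contrast be compared with the species contrasts; no
correction is applied.  The shipped tree
(`inst/extdata/guild_tree_synthetic.nwk`) is an illustrative synthetic
topology, not a reconstruction of any published phylogeny.

## The synthetic-data generator

`generate_world()` builds mark-recapture datasets with the structure the
analysis assumes, plus the latent truth the estimators are asked to
recover.  The default world mirrors a realistic multi-estuary
mark-recapture design: 17 sites in three
estuaries (creek and pan habitats), two growing periods (about 94 and 154
growing days) in the two southern estuaries, roughly 114 snails per site,
eight castrator species plus uninfected males and females, and a strict
linear dominance order with two deliberate exceptions — a tissue-refuge
species (`renc`, killed only by the top rank) and a spatially segregated
species (`smcy`, recruiting mainly where dominants are rare).  Recruitment
is independent across species within a host at site-specific prevalences,
so the mortality estimator's core assumption holds by construction; within
a host every recruit dominated by a co-recruit is killed; two or more
survivors make a mixed-species infection.  Growth is drawn from a
gamma-mixed Poisson (variance $= \varphi \mu$, $\varphi \ge 1$) whose mean
follows each group's log-linear size relation, scaled by growing days and
fixed site effects, and the raw shell measurements (degrees, widths,
lengths) are back-computed through the shell-geometry inverses so the
pipeline can start from raw measurements.

Defaults with no externally fixed value were chosen once, on field
realism, and are not revisited: per-species GSI values for the castrators
are free parameters of the generator, set between 0.10 and 0.27 and
increasing with a species'
expected mortality; growth at the mean-sized snail spans 7–48 mm$^3$ per
reference period and decreases with expected mortality; overdispersion
defaults to $\varphi = 4$; shell width is 0.364 of length, which makes
the cone volume agree with the cube-root scaling relation; initial
lengths are uniform on 8–43 mm.  Generated worlds therefore carry a
negative growth–mortality coupling and a positive RRA–mortality coupling
by construction, which is what the end-to-end sign-recovery suite
detects.  What the generator does *not* emulate: multi-clone same-species
infections, temporal recruitment dynamics, snail movement between sites,
measurement error in degrees of growth beyond rounding, and
non-castrating pathologies.  Passing tests therefore validate the
estimators under the analysis' own assumptions; they cannot certify those
assumptions in field data.

## Filters and the pipeline

The exclusion chain drops, in order: mixed-species infections; records
with undetermined initial size, gender or infection status; flagged
outliers; and infections of rare species.  The rare threshold is strict —
a species needs *more than* `min_group_n = 20` retained individuals —
because low samples underestimate means for overdispersed data; the
boundary case (exactly 20, excluded) is unit-tested.  The outlier rule is
configurable: a pre-flagged indicator column (default) or an absolute
Studentized deviance residual above 4 in a preliminary quasi-Poisson fit;
the rule used is recorded in the run manifest, since a single-record
exclusion cannot be reconstructed from a rule that was never stated.
`run_pipeline()` sequences everything — filter, geometry, growth fit,
curves and integrals, mortality, allocation table, species-level and
contrast-level correlations (with configurable drop-lists for robustness
re-runs, e.g. excluding the uninfected genders), the two-stage guard and
the plasticity test — and emits delimited output tables plus a JSON
manifest (configuration hash, seeds, per-stage counts, all statistics).
Identical configuration and seeds reproduce the manifest exactly.  The
package's functions are its interface; there is no shell executable, and
`scripts/acceptance.R` is a thin Rscript over the same functions.

## Numerical choices and problem sizes

Quadrature: `stats::integrate` with absolute tolerance $10^{-8}$ of the
curve scale.  Factor coding: treatment contrasts, alphabetically first
level as reference; aliased nesting dummies are reported as `NA` and
excluded from Wald machinery.  Randomization p-values are never zero by
construction ($p \ge 1/(B+1)$); ties between permuted and observed
statistics count toward rejection, with a $10^{-12}$ guard against
floating-point equality artifacts.  Validation problem sizes were chosen
as the package's own trade-off between Monte-Carlo resolution and
turnaround: 200 seeds for coefficient-recovery coverage, 500 seeds at
$B = 2{,}000$ for null calibration, 2,000 snails per site for the
estimator-oracle check, and 25 seeds for end-to-end sign recovery.

## Known limitations

The mortality estimator assumes independent recruitment across species
within hosts; facilitation or avoidance in real guilds biases it (which is
precisely why negative estimates are interpretable as facilitation).  The
dominance hierarchy is deterministic; probabilistic killing is not
modelled.  Site effects are fixed, so nothing here generalizes beyond the
sampled sites.  The two-stage guard is a reconstruction.  The tree is
user input; contrasts inherit whatever is wrong with it.  Background
(non-trematode) mortality is assumed equal across groups and is not
estimated.
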