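---
title: "Methods: seedling-stage drought screening and multi-trait selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seedling-stage drought screening and multi-trait selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtsel)
```

## The screening design

`droughtsel` analyses seedling-stage drought screens of diverse wheat
panels grown in a randomized complete block design (RCBD): every genotype
appears once per replication block, water is withheld until most plants
wilt, shoots are then cut and re-watered, and regrowth is followed until it
stops. Two families of traits describe the outcome:

* **tolerance traits**, scored during stress: days to wilting (DTW), the
  ordinal 1–9 leaf-wilting score repeated on five dates, and their sum
  S_LW in 5–45;
* **recovery traits**, scored after cutting and re-watering: the
  arctangent disposition-to-regrowth (DTR, degrees), regrowth biomass
  (RB, g), and the drought survival rate (DSR, %).

Seedling length (SL, cm) is scored before stress. Low values of SL, S_LW,
DTR and of the selection indices indicate tolerance; high values of DTW,
RB, DSR do.

### Trait-scoring transforms

* `sum_leaf_wilting()` adds the five ordinal scores; the bounds 5 (never
  wilted) and 45 (fully wilted throughout) are attained exactly.
* `days_to_wilting()` returns the first day the cumulative fraction of
  wilted plants reaches a threshold (default 50%). Plants that never wilt
  stay in the denominator. When the threshold is never reached the value
  is reported missing rather than imputed as zero; an option right-censors
  at the length of the stress window instead (e.g. 13 days), because a
  panel member that never reaches 50% wilting genuinely survived the whole
  window. The per-replication aggregation is the default: the 50% day is
  computed within each block, keeping one observation per genotype and
  block so the RCBD analysis applies unchanged.
* `regrowth_disposition()` maps days-to-regrowth x onto
  `atan(x / mu_x)` *in degrees*. Degrees are the only reading under which
  the stated 0–90 range is attainable; radians would cap at about 1.57.
  Plants that never regrow are lifeless and score exactly 90, which
  dominates every regrower's score. The reference mean `mu_x` is computed
  once over all regrowing plants in the experiment so that scores are
  comparable across genotypes; a per-genotype mean can be passed where a
  within-genotype standardisation is wanted.
* `drought_survival_rate()` is the percentage of cut plants that regrew;
  it is scale-free in (survivors, cut).

Monotonicity of wilting scores over dates is a property of the biology,
not of field scoring: observers can regress a score between visits. The
data model therefore warns rather than errors on non-monotone series.

## Variance components and heritability

Model 1 (single treatment) is `Y_ij = mu + g_i + r_j + e_ij`, where the
genotype x replication interaction is the error. `rcbd_anova()` fits it
through `stats::aov`; the test suite verifies the sums of squares against
a direct mean-decomposition oracle. The genotypic variance is
`sigma2_G = (MS_G - MS_e) / r`, and broad-sense heritability is computed
on the **entry-mean basis**,

```
H2 = sigma2_G / (sigma2_G + MS_e / r) = 1 - 1/F ,
```

reported as a percentage. The entry-mean denominator is the reading under
which the published H² values for this design are reproduced from their F
ratios (e.g. F = 12.94 with 7 replications gives 92.27%); the plot-level
denominator `sigma2_G + sigma2_e` would give materially smaller values
(63% for the same F). Negative variance-component estimates are truncated
to zero but the raw estimate is retained and flagged, following breeding
convention. `lsd()` is the usual `t * sqrt(2 MS_e / r)`.

Model 2 (control vs drought) is
`Y_ijk = mu + g_i + r_j + t_k + tg_ik + e_ijk` with treatment fixed and
genotypes and replications random. Genotypes and the interaction are
tested against the residual; the fixed treatment effect is tested against
the interaction mean square, which is its expectation denominator in the
mixed model. Missing cells are a hard error throughout: the designs this
package targets are balanced, and expected-mean-square solutions for
unbalanced data are out of scope.

## Correlations

Phenotypic correlations are Spearman rank correlations of entry means
(the genotype level is where selection operates), with two-sided p-values
from the t approximation and `*`/`**` marks at 0.05/0.01. Genotypic
correlations come from the analysis-of-covariance decomposition of mean
cross-products that mirrors the ANOVA:
`cov_g(x, y) = (MP_G - MP_e) / r` and
`r_g = cov_g / sqrt(sigma2_g(x) sigma2_g(y))`. Estimates can exceed 1 in
magnitude; they are flagged, never clipped, because truncation would bias
downstream use of the matrices. The `+`/`++` marks compare `|r_g|` to one
and two approximate standard errors. The SE is a Mode–Robinson-style
approximation assembled from the chi-square sampling variances of the
mean squares; the exact formula used by legacy field-trial software is
not documented, so the approximation is isolated in one internal function
(`rg_standard_error`) and is deliberately swappable. Only property-based
tests (recovery of planted correlations, the ++ mark at planted |r_g| = 1)
rely on it.

## Selection indices

The Smith–Hazel weights solve `b = P^-1 G a`, with `P` and `G` the
phenotypic and genotypic covariance matrices of entry means and `a` the
economic weights. `smith_hazel_weights()` solves the linear system
directly (no explicit inverse) and reports the reciprocal condition
number of `P`, rejecting numerically singular inputs.

Two coefficient modes are provided and every report states which was
used:

* `"printed"` — the published three-trait coefficient vectors for the
  tolerance index TI (over S_LW, DTW, SL) and recovery index RI (over
  DTR, RB, DSR) ship as constants, so published scores are reproducible
  exactly;
* `"estimate"` — weights re-derived from the data's own `P` and `G`. The
  economic weight vector is not published; the default places weight 1 on
  the primary trait of each index (S_LW for TI, DTR for RI) and 0 on the
  auxiliaries, which is the configuration in which an index "better
  describes" its primary trait through auxiliaries. It is configurable.

The composite drought tolerance index is the **mean** of the two
standardised indices, `DTI = (TI/SD_TI + RI/SD_RI) / 2`, not a square
root. With the published panel means and SDs the multiplier reading
reproduces the published population mean (5.62) and maximum (7.03),
whereas a square-root reading would give 3.35 and 3.75, outside the
published range — so the "1/2" is unambiguous in context. Low DTI means
tolerant.

In the pipeline the index traits are computed per plot and carried as
additional traits, so ANOVA, heritability and genotypic correlations
cover TI, RI and DTI too; because the indices are linear (DTI uses fixed
population SDs), entry means of plot-level indices equal indices of entry
means exactly.

## Multi-trait selection

`rank_by_trait()` sorts in each trait's tolerance direction with
alphabetical tie-breaks, so rankings are deterministic.
`multi_trait_select()` selects a genotype when it sits in the top k
(default 20) of at least m (default 5) of the nine screening columns and
— by default — also in the top k of DTI; the DTI requirement is a toggle
because the verbal rule "in at least five traits and DTI" admits either
reading, and every selection in the published panel carries the DTI flag.
Ties at the k-th value admit all tied genotypes (the inflation is
logged): dropping an exact tie on label order would be arbitrary in a way
that affects selections, while admitting ties only enlarges the reported
set. `categorize_dti()` partitions scores at two cutpoints, defaulting to
tertiles; published tolerant/intermediate/susceptible counts are not a
target because the cutpoints behind them were never stated.

## Physiological change metrics

`change_due_to_drought()` implements the asymmetric percent-change pair:
reduction `100 (XC - XD) / XC` when control exceeds drought, increase
`100 (XD - XC) / XD` otherwise — the *larger* mean is always the
denominator, so increase and reduction percentages are not mirror images
of one another. Equal means return 0 with direction "none". Population
changes use grand means over genotypes per treatment; group contrasts use
within-group means, typically the ten most tolerant against the ten most
susceptible genotypes. Published population-change percentages from this
kind of screen cannot be reproduced from rounded table means (they were
computed from unrounded data), so the package asserts the formulas, not
those printed numbers.

## Genetic diversity of the selected set

`simple_matching_distance()` is `1 - (matching calls / comparable calls)`
per pair with pairwise deletion of missing calls; calls are matched as
exact categorical symbols, with no partial credit for heterozygotes,
since allele-dosage similarity coefficients are a different method.
`upgma()` performs average-linkage clustering (single and complete
linkage are options) and returns a rooted ultrametric `ape::phylo` tree
whose cherries sit at half the pairwise distance; export is newick.
Average linkage is the default because it is the conventional partner of
simple-matching distances in germplasm diversity work.
`gene_panel_summary()` totals a binary gene presence/absence panel (e.g.
DREB transcription-factor alleles) and reports the Pearson correlation of
the totals with DTI.

## The synthetic-data generators

No raw plant-level data are distributed with screens of this kind, so the
package carries generators that emulate the statistical structure the
analysis assumes; they are first-class, tested code.

* `simulate_rcbd()` draws genotype effects `g_i ~ MVN(0, G_true)`, plot
  errors `~ MVN(0, E_true)` and normal replication effects. Multivariate
  normality is the minimal assumption consistent with the ANOVA the data
  feed.
* `simulate_two_treatment()` adds a fixed drought shift and an
  independent genotype x treatment interaction; genotype main effects are
  shared across treatments.
* `simulate_wilting_series()` produces ordinal 1–9 scores by flooring a
  latent cumulative-stress process whose increments scale with one minus
  a per-genotype tolerance latent: scores are non-decreasing within plant
  by construction, a tolerance latent of 1 pins every score at 1, and a
  latent of 0 is guaranteed to reach 9 (the increments have a positive
  floor).
* `simulate_snp_matrix()` draws biallelic calls (AA/AB/BB) from
  cluster-perturbed allele frequencies with a controlled missing-call
  rate, recording the true cluster assignment for recovery tests.
* `simulate_wheat_panel()` is the study-scale generator: 172 genotypes x
  7 replications by default, with trait means, entry-mean SDs,
  heritabilities and the genotypic correlation structure parameterised
  from a published diverse spring-wheat screen. The printed genotypic
  correlation matrix includes a -1.00 pair and is not positive
  semidefinite, so it is repaired once, deterministically, by flooring
  eigenvalues and rescaling to unit diagonal. Planted tolerant genotypes
  are shifted toward tolerance in every trait by 3.5 genotypic SDs by
  default, matching the separation of the most tolerant lines observed in
  diverse panels (roughly 3 phenotypic SDs below the panel DTI mean).
  Residual correlations default to zero, which reproduces the observed
  pattern that genotypic correlations exceed phenotypic ones.

All randomness flows from one integer seed through a per-simulator
derived stream, and each simulator restores the global RNG state it
found, so runs are reproducible and adding a simulator does not perturb
the others.

What the generators do **not** emulate: spatial field trends within
blocks, observer drift in ordinal scoring, non-normal or heteroskedastic
errors, genotype-specific missingness, and linkage disequilibrium between
markers. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those real-data
features.

## Numerical choices and problem sizes

* PSD checks tolerate eigenvalues down to `-1e-8` times the spectral
  radius; the singular-`P` guard in the index solver triggers at 100
  machine epsilons of reciprocal condition number.
* Degenerate ANOVA inputs (zero error mean square) flag F as undefined
  instead of dividing by zero; a zero-error table reports H² = 100.
* Parameter-recovery tests run 500 simulations of a 200-genotype x
  7-replication panel (heritability unbiased within 0.02, genotypic
  correlation within 0.05 of truth); the end-to-end selection test plants
  10 tolerant genotypes in a 172 x 7 panel and requires at least 9 back
  at k = 20, m = 5; smaller panels (25–120 genotypes) back the remaining
  property tests. These sizes keep the full suite under a minute on one
  CPU while leaving Monte-Carlo error an order of magnitude below every
  asserted tolerance.

## Known limitations

* Balanced designs only; no REML path for unbalanced or spatial data.
* The genotypic-correlation SE is an approximation; its marks are
  conventions, not tests.
* Index re-estimation inherits the sampling noise of `P` and `G`; with
  few genotypes the solved weights are unstable even when `P` is
  numerically invertible (watch the reported condition number).
* The DTI category cutpoints are user parameters; there is no canonical
  three-way split.

## A worked run

```{r example, eval = FALSE}
tab <- simulate_wheat_panel(n_genotypes = 172, n_reps = 7,
                            n_tolerant = 10, seed = 42)
run <- run_pipeline(tab, k = 20, m = 5, seed = 42, out_dir = "screen_out")
run$components          # per-trait variance components, H2, LSD
run$selection           # the multi-trait selection report
intersect(attr(tab, "planted_tolerant"),
          run$selection$genotype[run$selection$selected])
```
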