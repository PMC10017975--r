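---
title: "Models and methods in metgxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in metgxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(metgxe)
```

`metgxe` analyses multi-environment trials (METs) of clonally replicated
plant populations for genotype-by-environment (G×E) and QTL-by-environment
(QTL×E) interaction, with flowering date in a sweet cherry F1 full-sib
family as the motivating application.  This vignette documents the models,
the tunable parameters and their defaults, the numerical choices inside the
REML engine, what the synthetic generator does and does not emulate, and
the design decisions that were genuinely open.

## The G×E mixed model

An observation is one tree (a grafted clonal copy of a genotype) scored in
one environment, where an environment is a location × season combination.
The phenotype of individual $i$ in block $k$ of environment $lj$ is

$$y_{ljki} = m + e_{lj} + eb_{ljk} + g_i + ge_{lji} + r_{ljki}$$

* $e_{lj}$, $eb_{ljk}$: fixed environment and block-within-environment
  effects.  Blocks are encoded as environment-qualified labels, so the same
  field-block name in two environments is two distinct levels.
* $g_i \sim N(0, v_g)$: the genotype main effect — the *total* (additive
  plus non-additive) genetic effect, appropriate for clones; individuals
  are treated as unrelated (identity relationship).
* $ge_{lji} \sim N(0, \mathbf{V}_{ge})$: environment-specific genetic
  effects with an environment × environment covariance structure.
* $r_{ljki}$: residuals, independent between trees, with either one
  variance per environment (default) or an unstructured season × season
  covariance within each tree at a location (`us_season`) — trees are
  perennial, so their residuals can carry over between seasons.

Before fitting, observations are scaled by the raw phenotypic standard
deviation of their environment (`scale_by_env_sd()`, on by default in
`fit_gxe_model()`).  This curbs scale-change G×E so that the interaction
structure reflects rank changes; the stored SDs back-transform effect sizes
to days.

### Covariance structures and identifiability

`Vge` structures: `iid`, `diag` (default), `cs_het`, `fa1`, `us`.  A fully
unstructured `Vge` *together with* a separate $v_g$ is not identifiable — a
constant can be shifted between $v_g$ and all of `Vge` without changing the
likelihood.  The package therefore pairs the genotype main effect only with
`iid`/`diag` interaction structures; `cs_het`, `fa1` and `us` model the
full between-environment genetic covariance themselves and are fitted
without the separate $v_g$ term (`met_model_spec()` enforces this and says
so).  `diag` with $v_g$ is the default: heterogeneous interaction variances
with a common genetic covariance, the structure under which the genetic
correlations below are defined.

### Genetic correlations, heritabilities, variance fractions

From the fitted components, for environments $lj$ and $l'j'$:

$$\mathrm{var}_{GEI}(lj) = v_g + \mathbf{V}_{ge}[lj,lj], \qquad
  \mathrm{cov}_{GEI} = v_g + \mathbf{V}_{ge}[lj,l'j'], \qquad
  \mathrm{cor} = \frac{\mathrm{cov}_{GEI}}
  {\sqrt{\mathrm{var}_{GEI}(lj)\,\mathrm{var}_{GEI}(l'j')}}.$$

Correlations below one indicate genotype ranking changes.  The summary
reported is the unweighted mean over environment pairs (how a published
average over pairs was weighted is generally not stated; unweighted is the
simplest reproducible choice).  Correlations are computed on the scaled
trait — they are invariant to per-environment scaling, so this is a
bookkeeping convention, not a substantive choice.

Broad-sense heritabilities of clonal means use the classical formulas
$H^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e/(nr))$ per location and
$H^2_{MET} = \sigma^2_g/(\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(er))$
across the MET, with components estimated by `lme4` fits (genotype random;
season/block or environment fixed; for the MET model also an iid G×E
term).  The formulas assume balance; under unbalance the plug-ins are $n$ =
number of seasons, $e$ = number of environments, and $r$ = the *median*
replicate count per genotype (per season or per environment), a counting
rule recorded in the output.  Variance fractions come from the same pooled
model; the environment (fixed-effect) share is the empirical variance of
the fitted environment means across observations — the conventional choice
when a "variance" of a fixed effect is wanted — and all four shares are
normalized to sum to one.

## The REML engine

All genetic and residual terms only correlate observations of the same
genotype, so the marginal covariance $V$ is block diagonal by genotype
(block size ≤ replicates × environments).  The restricted log-likelihood

$$\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py
  + (n-p)\log 2\pi\right]$$

is accumulated over genotype blocks; genotypes with identical layouts
(same environments and tree structure) share one Cholesky factorization,
and their fixed-matrix cross-products are evaluated as single stacked BLAS
operations.  This makes balanced simulation studies (hundreds of REML fits)
practical while remaining exact; the test suite pins the block path against
a dense brute-force evaluation of the same criterion to $10^{-8}$.

Numerical choices:

* **Parametrization.** Log-variances; Cholesky factors with
  log-diagonals for unstructured blocks; loadings free and specific
  variances log-scaled for `fa1`; the `cs_het` correlation mapped
  logistically into $(-1/(E-1), 1)$.  All materialized matrices are PSD by
  construction.
* **Search.** BFGS with numerical gradients; convergence at relative
  log-likelihood change below `tol` (default $10^{-8}$), followed by a
  short machine-precision "polish" run that sharpens parameter estimates
  beyond the log-likelihood stopping rule (needed for the closed-form
  equivalence tests).
* **Initialization.** A method-of-moments start: pooled within-cell
  variance for the residual, the mean between-environment covariance of
  genotype deviations for $v_g$, the remainder for the interaction —
  clipped away from zero.  Three equal/skewed splits of the raw variance
  serve as fallback restarts.  The moment start matters: from a flat
  equal split the search can stall in a basin where all interaction
  variances collapse to zero.
* **Boundary estimates** (variance → 0) are flagged, not errors.
  Non-convergence after all restarts is an error.
* **Aliasing.** The fixed matrix is reduced to full rank by QR with
  pivoting; dropped columns are reported and recorded per term.
* **Wald tests** are conditional (Type-III-like) on all other terms, with
  sum-to-zero factor contrasts so that a main-effect test averages over the
  levels of interacting factors; the reference is chi-square with df equal
  to the rank of the term's coefficient block (no denominator-df
  approximation — reproducible, and accurate at the population sizes METs
  use).  A sequential mode is available.
* **lsmeans** are predictions averaged with equal weights over the other
  factors' levels; contrasts use t (fixed-effect linear models) or normal
  (mixed fits) references.  On balanced data they equal raw class means;
  on unbalanced fixtures they are pinned against `emmeans` in the tests.

## QTL and QTL×E models

A QTL is a factor whose levels are the concatenated genotype classes of its
two flanking markers (e.g. `AB/AA`); individuals missing either marker are
dropped, and classes with fewer than five individuals (double recombinants)
are dropped with a warning.  The single-QTL model adds fixed class and
class × environment terms to the G×E model, keeping a random polygenic
background ($x_i$, $xe_{lji}$) so the QTL test is not inflated by
background genetic covariance.  QTLs with a significant main or interaction
Wald p-value (raw $p < 0.05$; a Bonferroni option exists) are combined in a
complete model where each QTL is tested conditional on the others.

Per environment, the QTL effect $d_{lj}$ is the contrast between the two
classes most extreme in overall adjusted mean (for a two-class
pseudo-testcross QTL, the only contrast; for three classes, the homozygote
difference).  The variance explained is estimated as

$$\mathrm{PVE}_{lj} = 100\, \frac{p_{lj}(1-p_{lj})\, d_{lj}^2}
  {\widehat{\mathrm{var}}_{pheno}(lj)}$$

with $p_{lj}$ the observed frequency of the later-flowering extreme class
among scored individuals carrying either extreme class, $d$
back-transformed to days when the model was fitted on scaled data, and the
raw phenotypic variance in the denominator.  This is an estimator defined
by this package — interval-mapping software reports PVE from its own
likelihood model — and the two should agree in magnitude, not digit for
digit.  `effect_temperature_correlation()` then correlates $d$ or PVE with
the environments' October–March mean temperatures: a strongly negative
correlation is the signature of a cold-expressed, conditionally neutral
locus.

The per-location marker analysis (`class_contrasts_by_location()`) is a
fixed-effect linear model (class + season + block) per location with
lsmeans and all pairwise t-contrasts — the classical allele-effect table.

## The synthetic MET generator

`synth_config()` defines the emulated study conditions; its defaults are
fixed once and the analysis stack is validated against them:

* 121 F1 full-sib genotypes; markers segregate 1:1 (`ABxAA`) or 1:2:1
  (`ABxAB`), with recombination between linked loci at the Haldane fraction
  of their cM distance, both parents in coupling phase.
* Five locations with October–March mean temperatures 4.5, 7.5, 9.0, 9.5
  and 12.5 °C (continental-cold to Mediterranean-warm), 3–5 seasons per
  location between 2016 and 2021 → 20 environments; two clonal replicates;
  15% of genotypes absent per environment (whole genotypes, mirroring how
  nurseries fail to deliver or trees die — not record-wise).
* Daily temperature series per environment: a seasonal curve with a
  mid-January trough (amplitude 6 °C), a season offset (SD 1.5 °C) and
  day-to-day noise (SD 2 °C), centred so the October–March mean equals the
  location mean plus the offset.
* Phenotypes in Julian days around a grand mean of 90: environment effects
  track the realized October–March mean at −2.5 JD/°C (warm winters →
  earlier flowering) plus noise (SD 1 JD); block effects SD 0.5 JD;
  polygenic $v_g = 4$; interaction variances $v_{ge} = 1$ per environment
  (independent across environments, matching the default fitting
  structure and keeping the truth identifiable); residual variance 3 with
  correlation 0.2 between seasons within a tree.
* Two conditionally-neutral QTLs with piecewise-linear hinge rules: a
  "cold" QTL (pseudo-testcross, effect $0.5\,\max(0, 10 - T)$ JD) and a
  "warm" QTL (both parents heterozygous, effect $0.4\,\max(0, T - 7)$ JD).
  The hinge is a minimal stand-in for the temperature response of real
  dormancy loci — no quantitative effect-vs-temperature law was available
  to copy — and is labelled as such wherever it appears.

With these defaults the simulated partition reproduces the qualitative
structure of real flowering-date METs: the environment explains far more
variance than genotype, which exceeds G×E (about 85/7/2% with ~4% residual);
MET clonal-mean heritability is high (≈ 0.96); mean between-environment
genetic correlation is ≈ 0.75–0.8 (the plain $v_g/(v_g+v_{ge})$ ratio of
0.8 modulated by the conditionally-neutral QTLs); and the cold QTL's
per-environment PVE correlates strongly negatively (≈ −0.8 to −0.9) with
October–March temperature.  None of these simulated values is a reproduction
of any real data set; they demonstrate that the machinery recovers the
structure it is pointed at.

What the generator does **not** emulate: genotyping error, pedigree
structure beyond one F1 family, epistasis, spatial field trends,
chilling/heat-requirement physiology (the temperature link is a linear
hinge, not a dormancy model), and scoring censoring (missing phenotypes are
absent records, since how dead or unscored trees were coded in real data is
typically not published).  Passing tests therefore validate the estimators
under the stated statistical structure, not the biology of any particular
orchard.

## Validation sizes and expectations

The test suite validates (sizes chosen to give stable Monte-Carlo
estimates at desk scale):

* likelihood oracle: 50 random instances of ≤ 50 observations against the
  dense evaluation, tolerance $10^{-8}$;
* closed forms: balanced one-way REML vs expected-mean-squares (and
  `lme4`), balanced lsmeans vs raw means, heritability arithmetic;
* genetic-correlation limits and a no-interaction recovery study (20
  seeds, 150 genotypes × 6 environments × 2 replicates, mean off-diagonal
  correlation ≥ 0.95);
* component recovery at the same scale ($v_g = 1$, $v_{ge} = 0.25$,
  $v_e = 0.5$; median relative errors ≤ 20%);
* QTL×E calibration: 500 null METs (100 genotypes, 6 environments, 1
  replicate) with interaction and main rejection rates in [0.03, 0.07] and
  uniform null p-values; power ≥ 0.9 under the default cold-QTL hinge over
  200 METs at full design scale (121 × 20 × 2);
* the PVE–temperature correlation ≤ −0.6 (median over 20 full-scale
  seeds);
* Mendelian segregation chi-square at n = 10,000.

Calibration and power studies use the `iid` interaction/residual
structures: the Wald tests are about the fixed QTL terms, and the leaner
covariance keeps 700 REML fits affordable without changing the tests'
operating characteristics in the balanced designs used.

## Known limitations

* Numerical gradients make fits with many environments and an `us`
  interaction structure slow; average-information REML with analytic
  derivatives is the classical remedy and out of scope here.
* Chi-square Wald references are anti-conservative in very small samples
  (few genotypes); no Kenward–Roger/Satterthwaite denominator df are
  offered.
* lsmeans for mixed fits use normal references and ignore the uncertainty
  of the variance components.
* Under empty class × environment cells, per-environment QTL effects rest
  on aliased columns and are masked (with a warning) rather than imputed.
* The identity relationship matrix treats full sibs as unrelated; the
  genotype main effect is a total genetic effect, so heritabilities are
  broad-sense by construction.
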