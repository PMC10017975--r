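# metgxe

Genotype-by-environment (G×E) and QTL-by-environment (QTL×E) analysis for
multi-environment trials (METs) of clonally replicated plant populations.

The package grew out of flowering-date genetics in sweet cherry (*Prunus
avium* L.): an F1 full-sib family, clonally replicated across locations that
span cold to warm winter climates, scored for beginning of flowering (BF)
and full flowering (FF) in Julian days over several seasons.  Flowering
date responds strongly to dormancy-season temperature, genotype rankings
change between environments, and major flowering-date loci are
*conditionally neutral* — expressed in cold regions but silent in warm ones
(or vice versa).  Quantifying those interactions is what this package is
for: breeders deciding whether selection transfers across regions, and
geneticists asking whether a QTL's effect tracks the environment.

## The models

**G×E mixed model.** For individual *i* in block *k* of environment *lj*
(season *j* at location *l*):

y_ljki = m + e_lj + eb_ljk + g_i + ge_lji + r_ljki

with environment and block-within-environment fixed; g_i ~ N(0, v_g) the
genotype main (total genetic) effect; ge_lji ~ N(0, **V**_ge) the
environment-specific genetic effect, **V**_ge an environment × environment
covariance structure (heterogeneous-diagonal by default; compound-symmetric
heterogeneous, single-factor analytic and unstructured forms are available);
and residuals with per-environment variances or an unstructured
season × season covariance within each tree.  Estimation is REML, with the
likelihood evaluated by genotype blocks (the marginal covariance is block
diagonal by genotype).  Observations are first scaled by the raw phenotypic
SD of their environment to curb variance heterogeneity.

**Genetic correlations.** The total genetic variance in environment *lj* is
var_GEI(lj) = v_g + **V**_ge[lj,lj], the covariance between environments is
cov_GEI = v_g + **V**_ge[lj,l'j'], and their ratio is the
between-environment genetic correlation — below 1 it measures rank-change
G×E.

**Heritabilities of clonal means.** Per location,
H² = σ²_g / (σ²_g + σ²_e/(n·r)); across the MET,
H²_MET = σ²_g / (σ²_g + σ²_ge/e + σ²_e/(e·r)), with n seasons, e
environments and r clonal replicates.

**QTL×E.** A QTL is represented by the combined genotype classes of its two
flanking markers and enters the G×E model as fixed class and
class × environment terms over a random polygenic background
(y = m + e_lj + eb_ljk + q_i + qe_lji + x_i + xe_lji + r_ljki).  Wald tests
(chi-square, conditional on the other terms, sum-to-zero contrasts) assess
the QTL main and QTL×E effects; QTLs significant in single-QTL models are
combined in a complete model.  Per environment, the effect size d is the
contrast between the two extreme classes and
PVE = 100·p(1−p)·d²/var_pheno, which can be correlated with each
environment's October–March mean temperature to test conditional
neutrality.

A synthetic MET generator (`simulate_met()`) emulates the motivating study
design — 121 F1 genotypes, five locations at 4.5–12.5 °C October–March
means, 20 environments, two clonal replicates, 15% missing genotypes per
environment, two conditionally-neutral QTLs with opposite temperature
responses — and returns the realized truth for validation.

## Worked example

Published marker-class means ship with the package; differences of class
lsmeans are the allele-effect sizes:

```r
library(metgxe)
kasp <- kasp_reference_means("KASP_9.936")
kasp
#>       marker class n_individuals Forli Maribor Murcia Nimes Toulenne
#> 7 KASP_9.936   A:A            57  92.7    91.6   86.5  84.9     89.0
#> 8 KASP_9.936   G:A            60  94.4    95.1   87.2  86.8     91.4
class_contrast(setNames(kasp$Maribor, kasp$class), "G:A", "A:A")
#> [1] 3.5
```

Heterozygotes at this cold-region marker flower 3.5 days later than
homozygotes in Maribor (the coldest site) but only 0.7 days later in Murcia
(the warmest) — conditional neutrality at the marker level.

The same analysis end-to-end on a synthetic MET:

```r
sim <- simulate_met(synth_config(), seed = 42)   # 121 genotypes, 20 envs
fit <- fit_gxe_model(sim$pheno)                  # REML, ~1 min
fit
#> MET mixed model (REML), trait BF
#>   observations: 4120  genotypes: 121  environments: 20
#>   fixed terms: env, block_in_env
#>   genotype variance vg: 0.5167
#>   G x E structure: diag  residual: diag_env
#>   restricted log-likelihood: -4365.3122
#>   converged: TRUE ( 278 evaluations, 0 restarts)
genetic_correlations(fit)$mean_offdiag
#> [1] 0.747
met_h2(sim$pheno)$H2_MET
#> [1] 0.967
round(100 * variance_fractions(sim$pheno), 1)
#>    genotype environment         gxe    residual
#>         5.8        88.5         2.1         3.6
```

The environment dominates the phenotypic variance, the genotype share
exceeds the G×E share, and clonal-mean heritability is high — the signature
of a highly heritable, strongly environment-driven phenology trait.  The
cold QTL shows the expected temperature dependence:

```r
q <- encode_qtl_classes(sim$markers, "qR4", c("R4_m1", "R4_m2"))
f <- fit_single_qtl(sim$pheno, q, gxe = "iid", residual = "iid")
f$wald
#>      term       wald df            p      effect
#> 1     qR4   5.283207  1 2.153205e-02        main
#> 2 env:qR4 234.045042 19 5.174692e-39 interaction
pv <- qtl_pve_by_env(f, sim$pheno)
cc <- characterize_climate(sim$climate,
        unique(as.data.frame(sim$pheno)[, c("location", "season")]))
effect_temperature_correlation(
  setNames(pv$pve, pv$env),
  setNames(cc$env_temperature$t_octmar, cc$env_temperature$env))$r
#> [1] -0.82
```

The QTL×E Wald test is overwhelming and the per-environment variance
explained falls with dormancy-season temperature — a large negative
correlation, as expected for a cold-expressed locus.

`run_pipeline(out_dir, seed)` chains simulate → describe → fit-gxe →
fit-qtlxe → marker-effects, writing CSV outputs and a JSON run manifest.

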