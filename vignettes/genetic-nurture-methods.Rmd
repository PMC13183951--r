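---
title: "Separating genetic nurture from direct transmission: models and design choices"
author: "GeneticNurture package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genetic nurture from direct transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneticNurture)
```

## The problem

Substance use runs in families for two entangled reasons: offspring inherit
risk alleles from their parents (direct genetic transmission), and parents'
genotypes shape the rearing environment the offspring grows up in (genetic
nurture, a form of passive gene-environment correlation). The two can be
separated with family genotype data, because at each meiosis a parent
transmits exactly one of their two haplotypes: the *non-transmitted*
haplotype never enters the child's genome, so any association between a
polygenic score built on non-transmitted alleles (PGS~NT~) and the
offspring outcome must act through the environment the parent provides. The
transmitted score (PGS~T~) captures both pathways, and the direct
transmission effect is estimated by subtraction,
$\beta_{DGT} = \beta_T - \beta_{NT}$.

This package implements the full pipeline: a synthetic family-cohort
generator with known ground truth, haplotype-tile inference of
transmitted/non-transmitted alleles in trios and single-genotyped-parent
pairs, polygenic-score decomposition, family-clustered mixed models,
longitudinal score-by-age models, parent-of-origin path models with
full-information maximum likelihood (FIML), clustered-bootstrap mediation
through parental phenotypes, and Monte Carlo power analysis for
parent-of-origin contrasts.

## The synthetic cohort

Real cohorts with genotyped parent-offspring structures are
access-restricted, so every stage here is validated against a simulator
whose generative model mirrors the analysis models.

Founder couples receive independent biallelic markers with allele
frequencies drawn from `Uniform(mafRange)` (default 0.05-0.5) on a uniform
1 cM genetic map. Meiosis draws a Poisson number of crossovers per
chromosome (default rate 1.5) with breakpoints uniform on the genetic map
and no interference; offspring haplotype 1 is the maternal gamete and
haplotype 2 the paternal gamete, and every segment's source haplotype is
recorded as a `TransmissionTruth` object. Phasing imperfection is emulated
by switch errors: with per-marker probability `phaseErrorRate` the
haplotype assignment toggles from that marker onward, leaving genotype
dosages untouched.

Phenotypes follow a linear generative model on the standardized scale.
Parental phenotypes load on the parent's own full polygenic score
(`aM`, `aP`) with a free mate-pair phenotype correlation (`amCorr`,
default 0) for assortative mating. The offspring outcome at assessment
wave $w$ is

$$y_w = (\delta + s_T\,\mathrm{age}_c)\,z_T + (\beta_{NT} + s_{NT}\,
\mathrm{age}_c)\,z_{NT} + b_M M_m + b_P M_p + u_{fam} + u_{per} +
u_{slope}\,\mathrm{age}_c + \varepsilon_w,$$

with age centered at the wave-1 mean (33.0 years; waves at mean ages
33.0/38.9/44.8 with between-person spread so that age, birth year and wave
are not collinear). The residual SD defaults to the value that makes the
baseline outcome variance 1, so generative coefficients are directly
standardized effects. Defaults are calibrated to the study conditions the
package is validated against: transmitted effect 0.202, nurture effect
0.037, trio fraction 3267/19233, 61.9% female offspring, 41.4%
smoking-initiation prevalence via a liability threshold, transmitted-effect
attenuation of -0.004 per year with a stable nurture effect. The mediated
nurture paths `bM`/`bP` default to 0 so that `betaNurture` *is* the entire
nurture effect; mediation scenarios switch them on (full, partial and null
mediation are all reachable). Binary traits are generated by thresholding
the standardized latent outcome but analyzed by mixed logistic regression
-- a deliberate, mild model mismatch, since the analysis model is never the
data-generating truth in practice.

Two deliberate simplifications: founders carry *independent* markers (no
linkage disequilibrium), and the genetic map is uniform. Tile matching and
score decomposition do not depend on LD structure -- in real data LD is
handled upstream by the phasing software, which is out of scope here -- but
this means passing tests say nothing about LD-driven phenomena such as
clumping or local ancestry. Likewise the simulator has no mutation,
selection, X chromosome, or multi-generation chains beyond
parent-offspring.

A score-level generator (`simulateScoreCohort()`) skips markers entirely:
per-parent transmitted and non-transmitted haplotype scores are drawn as
`N(0, 1/2)` variables whose sums reproduce the unit-variance parental and
offspring scores, with the decomposition `transmitted + non-transmitted =
parental score` holding exactly. Operating-characteristic studies
(parameter recovery over hundreds of replicates, type-I error, power) use
this path; marker-level simulation is reserved for the transmission and
scoring stages it actually exercises.

## Transmission inference

Offspring haplotypes are compared to the available parental haplotypes in
tiles of 150 adjacent markers per chromosome (trailing remainders are
merged into the last tile rather than forming short, noisy end tiles).
Per tile the Hamming mismatch fraction against each candidate parental
haplotype is computed over non-missing markers; the argmin labels the tile,
ties are broken by continuity with the previous tile (minimizing spurious
crossovers), and tiles whose best match exceeds `tau` (default 10% of the
tile length, chosen to separate phase noise from wrong-parent matches) are
left unresolved. A genome-wide vote then assigns each offspring haplotype
to a parent by total mismatch count, enforcing one maternal and one
paternal haplotype in trios (an offspring whose haplotypes both vote for
the same parent is flagged and excluded); in pairs the closer haplotype
gets the genotyped parent and the other is labeled `missing_parent`.

Crossovers appear as label switches between resolved tile runs. The
breakpoint is refined to the marker minimizing the cumulative
left-plus-right mismatch across the switch region; the same scan is applied
(i) across unresolved tiles sandwiched between differing labels, (ii)
inside the first and last tile of each chromosome, where a crossover leaves
no flanking run boundary, and (iii) within runs, where a *pair* of
crossovers inside one tile (or straddling adjacent tiles) is accepted only
if the interior segment removes at least two mismatches -- the threshold
that keeps single genotype errors from minting phantom double crossovers.
Remaining unresolved tiles inherit the flanking consensus when the flanks
agree, otherwise their markers are set missing rather than guessed.

For a genotyped parent, the transmitted allele at a resolved marker is the
parent's source-haplotype allele and the non-transmitted allele is the
other haplotype's allele, so `transmitted + non-transmitted = parental
dosage` holds by construction; for an ungenotyped parent the transmitted
allele is read off the offspring haplotype and the non-transmitted allele
is missing. On the validation configuration (500 trios, 5,000 markers over
two chromosomes, Poisson(1.5) crossovers, no phase error) the inferred
non-transmitted alleles agree with the simulation truth for well over
99.8% of alleles; the residual disagreements trace to crossover pairs in
marker-sparse windows. Concordance is computed per allele. Degradation
with phasing error is monotone and mostly expresses as missingness (tiles
failing `tau`) rather than wrong calls.

## Scores

Raw scores are weighted sums of effect-allele dosages over non-missing
markers. Markers missing from a haplotype are skipped, not mean-imputed;
the used-marker count is reported so coverage is auditable. The four
per-parent values (maternal/paternal x transmitted/non-transmitted) sum to
the combined PGS~T~ and PGS~NT~. In pairs the ungenotyped parent's
non-transmitted score is missing; for combined-score analyses it is imputed
with the mean non-transmitted score of the observed parents -- read as the
cohort-wide mean over genotyped parents, computed on the raw scale before
standardization, since within a single pair no other average exists. A
per-role variant (mothers-only / fathers-only means) is available. The
imputed value is a constant, so it carries no outcome signal (verified
under the null) and shrinks the pair-subsample score variance -- an
attenuation that is a property of the published imputation strategy itself,
which is why coefficient-recovery benchmarks run on complete trios.

Standardization is per genotyping batch: each score column is regressed on
any supplied ancestry covariates (none in simulation, where founders are
homogeneous; the regression pathway is still exercised by synthetic
covariate scenarios in the tests), residualized, and z-scored within batch.
Batches under 3 members fall back to pooled standardization with a warning.

## Mixed models

`fitJointTN()` enters both scores jointly with sex and age and a family
random intercept: linear mixed models by REML for continuous outcomes,
mixed logistic by adaptive Gauss-Hermite quadrature (configurable nodes,
Laplace fallback) for binary ones. Standardized coefficients come from
z-scoring the outcome and continuous predictors before fitting (binary
covariates untouched); Wald tests use a normal reference, and no
denominator-degrees-of-freedom correction is applied. The five
non-transmitted p-values (one per outcome) form one Benjamini-Hochberg
family, and the transmitted p-values a second family of the same size --
the reading that reproduces the published adjusted column.
$\beta_{DGT} = \beta_T - \beta_{NT}$ is reported for continuous outcomes
only (on the odds-ratio scale the subtraction has no such interpretation),
and the nurture ratio $\beta_{NT}/\beta_{DGT}$ is flagged undefined when
$\beta_{DGT} \approx 0$.

The longitudinal model adds PGS~T~ x age and PGS~NT~ x age interactions to
repeated current-smoking-quantity measures, with random intercepts for
person and family and a person-level random age slope constrained
orthogonal to the intercept (an identification aid, matching the published
specification). Age stays in years so the interactions are per-year
changes of a standardized effect. Both interactions live in a single model,
so no multiplicity correction is applied to them.

## Path models, FIML and the bootstrap

lavaan-style machinery is implemented in-package as a small recursive
linear path-model engine: exogenous variables (the four parental scores)
carry free means and a full free covariance block -- which is where
genetic assortative mating, if any, is absorbed -- endogenous variables are
linear in their path parents plus fixed covariates, and residuals are
grouped into free covariance blocks (the two parental-phenotype residuals
share one, capturing phenotypic assortment). The implied distribution is
multivariate normal; with missing data the log-likelihood is accumulated
pattern-wise (FIML), maximized numerically (BFGS on a Cholesky
parameterization that keeps covariance blocks positive definite) from a
complete-case start. With complete data the maximum has a closed form --
equation-wise OLS plus ML moments -- and the package uses it both as the
fast path and as an independent oracle that the FIML optimizer must
reproduce to 1e-4. Binary covariates are conditioned on as fixed
regressors, never modeled as normal.

Parent-of-origin standard errors are cluster-robust (sandwich) on the
family, built from per-family likelihood-score contributions; Wald equality
tests of maternal vs paternal standardized coefficients use that robust
covariance with a chi-square(1) reference. Mediation fits one joint model
-- each parental phenotype on that parent's two scores, the outcome on all
four scores plus both phenotypes -- rather than two single-mediator models,
so maternal and paternal pathways are estimated simultaneously. Indirect
effects are products of standardized paths; total effects come from the
path-tracing matrix $(I - A)^{-1}$, making `total = direct + indirect` an
exact identity asserted inside every bootstrap replicate. Inference is by
clustered bootstrap: families are resampled with replacement (respecting
the same dependence the mixed models adjust for), the whole model refit
per replicate, and 95% percentile intervals reported; degenerate resamples
are discarded and counted. Multi-group models by offspring sex free all
paths across groups and pair bootstrap draws across groups for between-sex
contrasts. Model-fit indices (CFI/RMSEA) and latent measurement models are
deliberately absent.

## Power

Parent-of-origin power uses estimate-level simulation: the maternal and
paternal coefficient estimates are drawn from a bivariate normal with the
stated standard errors and correlation (default 0, justified by the null
maternal-paternal score correlation), and the two-sided Wald equality test
applied per replicate. This is the minimal faithful reading of a
supplementary simulation whose exact mechanism is not recoverable from the
main text; it is validated against the closed normal-theory form
$\Phi(|\Delta\beta|/SE_\Delta - z_{1-\alpha/2}) + \Phi(-|\Delta\beta|/SE_\Delta
- z_{1-\alpha/2})$ on every evaluated row, and a full-pipeline cross-check
(simulate, fit, test) is available through `simulateScoreCohort()` +
`fitPoe()` + `waldEquality()` at reduced replication counts.

## Numerical and design notes

* Tie-breaks: tile-label ties go to the previous tile's label, else
  unresolved; equal-mismatch breakpoint scans take the leftmost minimizing
  split (rightmost at chromosome ends, preferring no trailing switch) --
  within such windows the parent is homozygous, so non-transmitted calls
  are unaffected.
* The Hamming metric over non-missing markers is the simplest distance
  consistent with biallelic haplotypes; missing calls are removed from
  numerator and denominator.
* `fitJointTN()` refuses perfectly collinear score pairs instead of
  silently dropping one; degenerate designs (no age variance, a single
  wave, all-missing score columns, empty subgroups) raise errors.
* Bootstrap and simulation functions take explicit seeds; identical seeds
  give byte-identical cohorts, draws and intervals.
* Problem sizes used in the shipped validation suite: 500 trios x 5,000
  markers for transmission concordance; 200 replicates of 6,000-family
  score-level cohorts for coefficient recovery; 500 1,000-family cohorts
  for type-I error; 1,000 Monte Carlo replications for power rows. These
  sizes give Monte Carlo standard errors comfortably below the tolerances
  being checked.
* The pairs' genotyped parent is the mother with probability
  `maternalBias` (default 0.66). The underlying mother/father ratio among
  genotyped pairs is not published; the default is a settable guess, and
  nothing downstream is calibrated against it.

## Limitations

Simulation without LD cannot probe reference-panel or clumping artifacts;
the liability-threshold/logistic mismatch means binary-trait odds ratios
are calibration-checked only qualitatively; FIML assumes multivariate
normality of scores and outcome (scores are sums of many small
contributions, so this is mild in simulation but untested against real
phenotype skew); and the imputation of missing non-transmitted scores by a
cohort mean attenuates pair-subsample variance by construction. Real-data
concerns -- genotyping QC, imputation quality, ancestry structure,
GWAS-weight construction -- are upstream of this package and consumed as
given.
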