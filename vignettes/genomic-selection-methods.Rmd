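---
title: "Models and methods for clonal-trial genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for clonal-trial genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pinegs` evaluates genomic selection for low-heritability, categorically
scored traits in clonally replicated forest-tree progeny trials — the
situation of radiata pine "non-key" traits such as branch-cluster frequency,
stem straightness, internal checking and external resin bleeding. This
vignette is the package's own account of the models it fits, the parameters
that matter, the numerical choices made, and what its synthetic-data tests
do and do not demonstrate.

## The evaluation models

For one trait, the pedigree-based model (ABLUP) is

$$ y = X\beta + Z_a a + Z_d d + Z_r r + Z_w w + Z_b b + e $$

where $\beta$ holds the intercept and site effects, $a \sim N(0,
\sigma^2_a A)$ are additive genetic effects with $A$ the pedigree numerator
relationship matrix, $d \sim N(0, \sigma^2_d I)$ is a clone-level
non-additive effect (the clonal design separates it from additive merit and
from the residual: ramets of a clone share both $a$ and $d$), and $r$, $w$,
$b$ are replicate, set-within-replicate and incomplete-block effects. The
$r$, $w$, $b$ and residual variances are heterogeneous across sites
(diagonal across-site structure, no covariances), while the genetic
variances are homogeneous — with few genotypes per site a full across-site
genetic covariance is not estimable, so it is not attempted.

The genomic model (GBLUP) adds a marker term and keeps a residual polygenic
term:

$$ y = X\beta + Z_m m + Z_{a^*} a^* + Z_d d + Z_r r + Z_w w + Z_b b + e $$

with $m \sim N(0, \sigma^2_m G)$, $G$ the VanRaden (method 1) genomic
relationship matrix built from centred allele dosages,
$G = WW^\top / (2\sum_j p_j(1-p_j))$, and $a^* \sim N(0, \sigma^2_{a^*} A)$
the additive variance not captured by markers. The GEBV reported is
$\hat m$ alone — the scale on which the accuracy formula below plugs in
$\sigma^2_m$ — and $\hat m + \hat a^*$ is also available as the total EBV.

Ordinal scores (9-point and 0–3 scales) are modelled as Gaussian; their
score distributions in these trials are near-normal and no threshold model
is fitted.

## Reported genetic parameters

Per site $i$ (and as unweighted cross-site averages — no weighting scheme
is defensible without per-site precision targets):

* ABLUP heritability $h^2_{a_i} = \sigma^2_a / (\sigma^2_a + \sigma^2_d +
  \sigma^2_{e_i})$;
* marker heritability $h^2_{m_i} = \sigma^2_m / (\sigma^2_m +
  \sigma^2_{a^*} + \sigma^2_d + \sigma^2_{e_i})$ and combined heritability
  $h^2_{am_i}$ with $\sigma^2_m + \sigma^2_{a^*}$ in the numerator;
* individual accuracy $r_i = \sqrt{1 - \mathrm{PEV}_i / ((1 + F_i)\,
  \sigma^2)}$, with $\sigma^2 = \sigma^2_a$ (ABLUP) or $\sigma^2_m$
  (GBLUP). $F_i$ is taken from the diagonal of the relationship matrix the
  term uses ($A_{ii}-1$ or $G_{ii}-1$): using the pedigree $F$ for the
  marker term can put realized diagonals above $1+F$ and make the accuracy
  complex. The summary accuracy is the mean over phenotyped genotypes;
  per-individual values are returned so parents or unphenotyped candidates
  can be averaged separately;
* marker-captured additive share $\%VA = 100\,\sigma^2_m / (\sigma^2_m +
  \sigma^2_{a^*})$.

## Predictive ability and relative efficiency

Predictive ability is deliberately *not* a correlation with phenotypes: the
reference is the EBV from a full-data ABLUP fit. The population is split
into $k$ folds (clones travel whole — all ramets of a clone share a fold);
each fold's phenotypes are set missing, the model is refitted, and withheld
genotypes' predictions are correlated with the reference EBVs per
replication; the mean over replications is reported. The default plan is
10 replications of 10-fold validation with seed 20191227 (an optional
phenotype-correlation mode exists but is off by default; the full-data
reference is used as defined, not recomputed per fold).

Relative efficiency of genomic over pedigree forward selection is

$$ E = \frac{r_{IH_g}\,\sigma_{A_g}}{r_{IH_a}\,\sigma_{A_a}} \cdot
      \frac{L_a}{L_g} \cdot 100\% $$

with $\sigma_{A_g} = \sqrt{\sigma^2_m}$ from the full-data GBLUP,
$\sigma_{A_a} = \sqrt{\sigma^2_a}$ from the full-data ABLUP, and generation
intervals $L_g = 9$ years (genomic forward selection) versus $L_a = 14$ or
$17$ years (with or without a clonal archive of tested material). Selection
intensity cancels and is not an argument.

## Pedigree correction by trio exclusion

Documented pedigrees in breeding programs carry errors; `pinegs` corrects
them from a marker panel. Panel criteria: call rate > 0.75, MAF in
[0.35, 0.5] (maximally informative for exclusions), Hardy–Weinberg exact
test p ≥ 0.05 (a hand-rolled conditional exact test — no installed package
provides one), pairwise LD $r^2 \le 0.2$ by a greedy prune keeping the
better call rate, capped at 704 markers. For every progeny, each unordered
candidate-parent pair (self-pairs allowed, permitting selfing) is scored by
the number of panel markers at which the progeny genotype cannot be formed
from one transmitted allele of each candidate; markers with any missing
call in the trio are skipped. The minimum-exclusion pair is assigned. Ties
prefer the documented pair, then the pair with more informative markers,
then lexicographic order — deterministic and logged.

A trio whose best pair still conflicts at more than `max_exclusion_rate` of
its informative markers is left unassigned (the documented parents are
kept, flagged). The default is 0.15: a trio reads three genotype calls per
marker, so a per-call error rate $e \approx 5\%$ corrupts roughly
$1-(1-e)^3 \approx 14\%$ of a true trio's markers. Simulated true trios
under 5% error show best-pair exclusion rates of about 0.02–0.10, while
unrelated pairs sit far above 0.15, so the threshold separates cleanly; a
tolerance equal to the per-call rate itself would reject most true
assignments.

## REML: algorithm and numerical choices

Variance components are estimated by EM-REML on Henderson's mixed-model
equations with the heterogeneous residual weights built in. EM was chosen
over average-information updates: it is monotone in the restricted
likelihood, needs no second derivatives, and is robust at the problem sizes
this package targets; its slowness near flat directions is handled by
Aitken extrapolation (attempted every third iteration, accepted only when
the restricted likelihood does not decrease). Further numerical choices:

* *Floor*: components are clamped at $10^{-8}$ times the phenotypic
  variance; components that shrink monotonically below $10^{-4}$ of the
  phenotypic variance for three consecutive iterations are frozen at the
  floor and reported in the convergence record — EM decays geometrically
  toward such boundaries and would otherwise dominate the iteration count.
* *Convergence*: largest relative component change below `tol` (default
  $10^{-6}$; changes are measured relative to
  $\max(\theta, 10^{-4}\,\mathrm{var}\,y)$ so vanishing components cannot
  stall the criterion), or the restricted likelihood flat to $10^{-9}$
  relative for ten consecutive iterations — beyond that point component
  movement is numerical noise from the dense solves.
* *Singular relationship matrices*: before inversion, a matrix whose
  Cholesky fails or whose pivot ratio falls below $10^{-6}$ is blended as
  $0.99K + 0.01I$, logged. Realized genomic matrices on a few hundred
  individuals are routinely rank-deficient.
* Strata absent from the data (e.g. no block labels) drop their term with a
  warning; with a single site the site fixed effect is absorbed into the
  intercept.
* PEVs are the diagonal blocks of the inverse MME coefficient matrix, so
  $\mathrm{PEV}_i \le (1+F_i)\hat\sigma^2$ holds by construction and the
  accuracy is always real.

## The synthetic-data generator

No genotype or phenotype data accompany the study this package replays, so
the generator is first-class, tested code that emulates the study's
conditions: two clonal trial series — one single-pair-mated (each founder
pair produces one full-sib family), one factorially mated — planted on two
to three sites with a shared site; unlinked biallelic SNPs with founder
allele frequencies uniform over a MAF window and Hardy–Weinberg founder
genotypes; gene-dropped progeny (one uniformly chosen allele per parent per
marker); ~5% genotyping error and ~8% missing calls; a configurable
fraction (default 50%) of documented parent records corrupted; and
phenotypes generated from the GBLUP form itself, with the additive variance
split $\%VA$-at-markers versus residual-polygenic so marker-capture
recovery is directly testable. Marker effects are Gaussian at a
configurable QTL subset (default: all markers). Scores can be cut to
9-point or 0–3 scales by quantile mapping; the default leaves the latent
Gaussian, matching how the traits are analysed.

Desk-scale defaults (60 founders / 200 progeny single-pair; 24 founders /
200 progeny factorial; 2000 markers; 2 ramets per site; heritabilities in
the 0.1–0.35 range via `trait_config()`) keep a full pipeline run in
minutes while preserving the structure that matters: family structure for
parentage, clonal replication for separating $d$, multiple sites for the
heterogeneous variances. What the generator does *not* emulate: linkage and
LD (the analyses never use a map), genotype-by-environment interaction,
selection history in the founders, and assessor effects in scoring. Tests
passing on this generator therefore validate the estimation machinery under
the model's own assumptions; they do not certify behaviour under model
misspecification on real data.

The mean-imputation population is a documented switch: frequencies and
imputation means default to the designated unrelated reference set (as when
frequencies come from a dedicated unrelated panel), falling back to all
genotyped individuals with a log line.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use sizes chosen so the whole
battery runs on a laptop: heritability recovery uses 100 (tests) or 30
(script) single-pair datasets of 1000 observations each at true
$h^2 = 0.3$, fitted at `tol = 1e-4`; marker-capture recovery uses 10–12
factorial datasets of 1000 observations with all additive variance at 150
markers, simulated without non-additive effects and fitted with the matched
model — the split between marker and residual-polygenic additive variance
is identified by the deviation of realized genomic relationships from their
pedigree expectation, and adding a clone-level non-additive term makes that
three-way partition too weakly identified at desk scale to test the
marker-capture property in isolation; pedigree
correction uses one two-series dataset (300 progeny, 1200 markers, 300-SNP
panel, 50% pedigree errors, 5% genotyping error); and the
corrected-versus-erroneous comparison runs 20 single-site factorial
datasets with 2×5-fold cross-validation at `tol = 1e-3`. Coarser REML
tolerances in these batteries change heritabilities by well under 0.01 —
far below the sampling noise they are averaged against.

## Known limitations

* Univariate analyses only; no multi-trait or factor-analytic G×E models.
* No threshold model for the ordinal scores.
* Exclusion-based parentage only; no likelihood-based (LOD) assignment and
  no sibship reconstruction.
* No standard errors on heritabilities (delta-method SEs are future work).
* Dense linear algebra throughout: intended for thousands, not millions, of
  observations and relationship-matrix rows.
* Whether unrelated reference trees should enter the evaluation pedigree is
  left to the caller; by default they only anchor allele frequencies and
  imputation and stay out of the phenotyped analyses.
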