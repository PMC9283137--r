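---
title: "Two-step MVMR mediation: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MVMR mediation: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepmr)
```

## The causal model and the two-step decomposition

The package estimates mediation in a two-sample Mendelian-randomisation
setting. An exposure $X$ (here, standardised years of schooling; one unit
= 1 SD = 4.2 years) affects a binary disease outcome $Y$ directly and
through mediators $M_1, \dots, M_K$ (BMI, blood pressure, television
watching, smoking, ...). All outcome-scale effects live on log-odds, since
disease GWAS report log odds ratios.

Writing $\alpha_j$ for the causal effect of $X$ on $M_j$, $\theta_j$ for
the effect of $M_j$ on $Y$ conditional on $X$, and $\delta$ for the direct
effect of $X$ on $Y$, the linear mediation identities are

$$\text{indirect}_j = \alpha_j \theta_j, \qquad
  \tau = \delta + \sum_j \alpha_j\theta_j, \qquad
  pm_j = \frac{\alpha_j\theta_j}{\tau}.$$

Two-sample MR estimates each piece from GWAS summary statistics only:

1. **Total effect** $\hat\tau$: IVW meta-analysis of per-SNP Wald ratios
   over the exposure's instruments — identical to weighted least squares of
   SNP–outcome betas on SNP–exposure betas through the origin with weights
   $1/se_Y^2$.
2. **Step 1** $\hat\alpha_j$: the same estimator with the mediator's GWAS
   as outcome.
3. **Step 2** $\hat\theta_j, \hat\delta$: multivariable MR — weighted
   least squares of SNP–outcome betas on the $K{+}1$ SNP-effect columns of
   exposure and mediators jointly, no intercept, weights $1/se_Y^2$, over
   the **union** of the traits' instrument sets. The union rule is the
   common convention for regression-based MVMR; the source analyses do not
   state theirs.
4. **Decomposition**: product of coefficients for single mediators;
   difference in coefficients ($\hat\tau - \hat\delta$ with $\hat\delta$
   adjusted for a whole mediator set) for combined mediation, explored over
   the full subset lattice (capped, default 6) and sorted by proportion
   mediated.

Key assumptions inherited from the design: valid instruments (relevance,
no confounding of instrument–outcome, exclusion restriction), linearity
and no exposure–mediator interaction, and non-overlapping GWAS samples.
The sensitivity suite (below) probes the exclusion restriction; the others
are structural.

## Estimator conventions

Several conventions are needed that the surrounding literature often
leaves implicit; the package fixes them as follows.

* **Wald-ratio SE**: first-order $|se_Y/\hat\beta_{GX}|$ by default — this
  is the weighting scheme the conventional IVW uses. A second-order
  version ($\sqrt{se_Y^2/\beta_X^2 + \beta_Y^2 se_X^2/\beta_X^4}$) is
  available via `se_order = "second"`.
* **IVW model**: multiplicative random effects by default — the SE is
  inflated by $\sqrt{\max(Q/(n{-}1),\,1)}$ — because instrument
  heterogeneity is the norm for behavioural exposures; a fixed-effect
  model is a flag away. The floor at 1 means a fixed-effect SE is never
  exceeded from below.
* **Cochran's $Q$**: $\sum_i w_i(\hat\theta_i - \hat\theta_{IVW})^2$ with
  first-order weights, $\chi^2_{n-1}$ reference.
* **MR-Egger**: WLS with intercept after orienting every SNP to a
  non-negative exposure beta (without a fixed orientation the intercept is
  meaningless); multiplicative residual scaling floored at 1 for both slope
  and intercept SEs. MVMR-Egger orients on the first-listed exposure.
* **Weighted median**: interpolated 50th weighted percentile on cumulative
  weights minus half-weight; SE by seeded parametric bootstrap
  (default 1000 draws). The seed is a mandatory argument — there is no
  silent global-RNG dependence anywhere in the package.
* **Conditional instrument strength**: for exposure $k$, the other
  exposures' beta columns are projected out (weights $1/se_Y^2$), residuals
  are scaled by exposure $k$'s own SEs, and
  $F_k = \sum_i r_i^2/se_{X_k,i}^2 \,/\, (n - K + 1)$. Only the
  conventional qualitative read-out (adequate above 10) is asserted in
  validation; the scalar itself is a diagnostic, not an estimate.
* **CIs** use the normal quantile 1.959964 (summary-data asymptotics), not
  a t quantile.
* **Proportion mediated**: first-order ratio delta method treating
  indirect and total as independent,
  $se_{pm} = |pm|\sqrt{se_{ind}^2/ind^2 + se_{tot}^2/tot^2}$. The
  independence approximation is partially justified by the two-sample
  design but ignores the shared outcome GWAS between the step-2 and total
  estimates; this is a documented limitation, and the same convention is
  applied to combined (difference-method) proportions. $pm$ and its CI are
  never truncated to $[0,1]$ — values outside it are diagnostic.
* **ORs are presentation-layer only**: every computation is on log-odds;
  `mr_report()`/`mediation_report()` append $e^\beta$ columns, which are
  `NA` for continuous outcomes so report schemas are stable.
* **Multiple testing**: none applied anywhere; $\alpha = 0.05$ throughout.

## Harmonisation and instrument selection

Summary files are matched on rsID only (summary sources rarely share a
genome build; positions are used solely for clumping windows). Indels and
multi-allelic rows are rejected at read time with per-row reasons.

Instrument selection is a p-value filter (`pval < p_threshold`, strictly)
followed by greedy LD clumping: SNPs are visited in ascending p-value
(ties broken lexicographically by rsID, making the output invariant to
input row order), the best remaining SNP is kept, and unselected SNPs with
$r^2 \ge$ threshold within the window are pruned. Pairwise $r^2$ is a
supplied input (3-column table or matrix), never computed from genotypes;
absent pairs count as independent. Thresholds are per-trait configuration,
not constants, because source GWAS differ (e.g. a stricter genome-wide
threshold for BMI, $r^2 < 0.005$ within 5 Mb for television watching,
500 kb windows for smoking).

Harmonisation aligns every trait to the first exposure's effect allele:
direct or strand-complement matches are kept, swaps flip the beta sign and
replace EAF by $1-\text{EAF}$. Palindromic SNPs (A/T, C/G) are resolved by
allele-frequency agreement — after alignment all EAFs must fall on the same
side of 0.5 — and dropped whenever any EAF lies inside the **closed**
ambiguity interval $[0.3, 0.7]$ (closed is the conservative reading of the
conventional rule) or is missing, since strand cannot then be inferred.
Instruments absent from the outcome GWAS are dropped and logged, not
proxied.

MVMR design matrices are guarded by a condition-number check
($>10^8$ errors, naming the worst pair of exposures). Exposure columns
that are exactly zero are excluded from the fit with `NA` estimates
(`lm()`-style aliasing) rather than treated as rank deficiency: they carry
no information, and this keeps the remaining coefficients identical to the
model without them.

## The synthetic-data generator

`sim_config()`/`simulate_cohort()` generate individual-level cohorts under
a fully known structural model — independent biallelic SNPs
(`genotype ~ Binomial(2, maf)`), a standard-normal confounder $U$, a unit
variance exposure with SNP effects scaled so the realised heritability is
exactly the target, mediators $M_j = \alpha_j X + G_j\gamma_j + c_m U + e$,
and a logistic outcome whose intercept is solved by bisection to hit the
target prevalence in the outcome cohort. Three disjoint cohorts (exposure,
mediator, outcome GWAS) emulate the two-sample design; a switch reuses the
exposure cohort for the outcome GWAS to study overlap bias.
`gwas_summarise()` then produces ordinary per-SNP GWAS summaries: closed
form simple linear regression for continuous traits, and for the binary
outcome a per-SNP logistic Wald fit computed by Newton–Raphson on the
collapsed genotype×case table (exactly the full logistic regression, since
the covariate takes three values; iteration cap 25, tolerance $10^{-8}$,
non-converged SNPs flagged). Optional covariate residualisation emulates
quirks such as BMI-adjusted blood-pressure GWAS.

Structural options cover the scenarios the validation needs: directional
or balanced pleiotropy (directional effects are signed relative to the
exposure-increasing allele — the frame in which an Egger intercept is
interpreted; with symmetric SNP-effect signs an allele-agnostic mean would
cancel identically), a mediator→exposure `reverse_beta` for
bidirectionality (applied to the mediator's pre-exposure component, so the
graph stays acyclic while reverse MR with mediator instruments recovers
it), and a lower-triangular `med_on_med` matrix for overlapping mediators.
`SimTruth` records total/direct/indirect/pm per mediator with the chain
solved recursively, so `total = direct + sum(indirect)` holds exactly on
the log-odds scale by construction.

**Default preset and why.** The defaults are a desk-scale analogue of the
large consortium GWAS this design targets: 20,000 individuals per cohort,
25 exposure SNPs explaining 11% of exposure variance, 20 SNPs per mediator
explaining 10%, MAF uniform on (0.1, 0.5), confounder loadings 0.2,
outcome prevalence 8%. SNP counts were chosen to preserve the *mean
per-instrument F statistic* (~90–100) of the source GWAS rather than their
raw SNP counts: instrument strength, not instrument number, governs
two-sample estimator behaviour, and a preset with hundreds of weak
instruments at this sample size would manufacture regression-dilution bias
that the real data do not have. Effect-size defaults mirror a BMI-like
single-mediator model ($\alpha = -0.34$, $\theta = \ln 2.60$, total
$\ln 0.53$).

**What the generator does not emulate** — hence what passing tests do not
show about real data: LD between loci (clumping is exercised on supplied
$r^2$ tables, not simulated LD), binary mediators (the mediation
arithmetic consumes log-odds $\alpha$s regardless of origin, but the
generator's mediators are continuous), dynastic effects and assortative
mating, population stratification, and winner's-curse selection (recovery
scenarios use the known causal SNPs as instruments, which is the honest
choice when truth is known but sidesteps selection bias present in real
instrument discovery).

## Validation design and problem sizes

The test suite validates each estimator against an independent route
(`stats::lm(weights =)` oracles, explicit normal equations, brute-force
cumulative-weight interpolation, hand IRLS for the observational module)
on fixed small instances, and the full pipeline by parameter recovery:
seeded scenarios with true $pm \in \{0.25, 0.5, 0.75\}$, 100 replicates
each, asserting mean recovered total, direct and $pm$ within $\pm 0.05$ of
truth. Recovery scenarios use outcome prevalence 0.02 with a 60,000-person
outcome cohort: at common prevalences the *marginal* log-OR a disease GWAS
measures is attenuated relative to the conditional truth (odds-ratio
non-collapsibility, several percent at 8% prevalence), while for rare
outcomes log-odds effects collapse and product- and difference-method
proportions coincide — which the suite also asserts as a paired
comparison. Diagnostic calibration (uniform Cochran's $Q$ p-values;
Egger-intercept type-I error within $[0.03, 0.07]$ at nominal 0.05) is
checked on 1000–2000 summary-level replicates of a homogeneous
no-pleiotropy null with near-noiseless exposure betas, which isolates the
statistic being calibrated from weak-instrument artefacts.

## Degenerate inputs and numerical choices

Single-instrument sets degenerate IVW to the Wald ratio; empty mediator
sets degenerate the direct effect to the univariable total. Zero exposure
betas make the Wald ratio an error, not an `Inf`. `pm` is an error when
the total effect is exactly zero. Combined-mediation failures for
individual sets (e.g. too few instruments after harmonisation) are logged
and skipped, never fatal. Weighted-median interpolation returns the
extreme ratio when half the weight sits in the first or last order
statistic. The bisection for the simulator's logistic intercept runs on
$[-50, 50]$ with tolerance $10^{-10}$.

## Using the pipeline

`run_pipeline()` drives everything from a YAML config (per-trait files and
column maps, per-trait thresholds, estimator options, mediator list and
combination cap, reverse-MR toggle, mandatory seed, output directory) and
writes the full table set plus `run.log` and a machine-readable
`manifest.json`; stage failures leave earlier outputs in place and are
recorded in the manifest. Identical config + seed gives byte-identical
tables. A "final model" restricted to mediators without reverse-direction
signals (e.g. dropping television watching and smoking after reverse MR
flags bidirectionality) is expressed purely as a config whose `mediators`
list is the restricted set — the exclusion rule is an analysis decision,
not package logic.

## Known limitations

The proportion-mediated CI ignores indirect–total covariance (shared
outcome GWAS); combined-proportion CIs use the same independence
convention. Non-collapsibility means MR mediation arithmetic on common
binary outcomes mixes marginal and conditional log-ORs — results for
prevalent diseases should be read with that in mind. Survey weights are
out of scope in the observational module (unweighted regressions with
listwise deletion). MVMR with correlated instruments (LD-aware generalised
least squares) is not implemented; instruments are assumed clumped to
approximate independence.
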