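---
title: "Quantifying toxicodynamic population variability with popvitro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying toxicodynamic population variability with popvitro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popvitro)
```

## The problem

Risk assessment of chemicals (and of defined chemical mixtures) needs an
estimate of how much the human population varies in its sensitivity. The
regulatory default is a half-log allowance (a factor of $10^{1/2} \approx
3.16$) for toxicodynamic variability, or 10 for toxicokinetics and
toxicodynamics combined. Population-based in vitro models — panels of
genotyped, immortalized lymphoblastoid cell lines from many human donors —
let that default be replaced by a chemical-specific, experimentally derived
number: expose every donor's cells to the substance in concentration–response,
derive each donor's point of departure (POD), and read the population spread
directly off the distribution of PODs. Because the donors are genotyped, the
same phenotype supports exploratory genome-wide association mapping of
susceptibility loci.

`popvitro` implements that pipeline end to end: plate normalization and QC,
hierarchical Bayesian concentration–response modeling, POD and variability
factor derivation with full posterior uncertainty, and single-variant
association mapping — together with a synthetic-data generator that emulates
the screen, so every stage is testable without access to laboratory data.

## The concentration–response model

Cytotoxicity is measured as well-level luminescence (ATP content), normalized
per plate to the mean of the vehicle-control wells. For each substance,
donor $i$'s normalized response at concentration $x$ follows a *downward
Hill* curve

$$y = y_0 \left(1 - \frac{(x/x_0)^n}{1+(x/x_0)^n}\right) + \epsilon,$$

with baseline $y_0$ (fitted rather than fixed at 1, to absorb residual
baseline drift after normalization), EC50 $x_0$, and Hill coefficient $n$.
Two structural choices matter:

* **$n \ge 1$.** Shallow fitted slopes ($n < 1$) are an artifact of noise and
  make low-dose extrapolation erratic. The package enforces the constraint
  smoothly by parameterizing $n = 1 + e^{z}$ and giving $z = \ln(n-1)$ a
  normal random effect. This keeps the support correct without a hard
  truncation boundary that samplers handle poorly.
* **Robust errors.** Residuals are scaled Student-$t$ with $\nu = 5$,
  so single outlier wells are penalized logarithmically rather than
  quadratically and cannot drag a whole curve.

All three parameters have lognormal population structure: $\ln y_0$,
$\ln x_0$ and $\ln(n-1)$ are normal across donors with population mean and SD
hyperparameters. Hyperpriors are weakly informative: normal for population
means — $\mathcal N(0, 2)$ for $\ln y_0$, $\mathcal N(\ln 30, 3)$ for
$\ln x_0$ (centered inside the tested 0.01–100 µM span, wide enough to allow
no activity), $\mathcal N(0, 1)$ for $\ln(n-1)$ — and half-normal for the
population SDs (scale 1) and the residual scale $\sigma$ (scale 0.5). All are
configurable through `fit_config()`. The scale parameters carry a numerical
lower bound of $10^{-6}$ so the noiseless limit remains sampleable.

Posterior sampling runs four chains of 4000 iterations, the first half
discarded as warm-up. Convergence is gated on the classic Gelman–Rubin
potential scale reduction factor for every monitored parameter, with
$\hat R \le 1.2$ required; on failure the chain length is doubled and the
model refit, to at most 16,000 iterations, after which the fit is returned
flagged non-converged rather than silently. The sampler is JAGS
(Gibbs/slice), fully seeded, so refits with the same configuration are
bit-identical. Replicate-plate wells enter the likelihood as independent
observations (they are separate measurements, not technical reads of one
well); vehicle wells are not part of the substance likelihood — they define
the normalization.

## POD, activity, and the variability factor

The POD is the EC10, available in closed form from each MCMC draw:

$$\mathrm{EC}_{10} = x_0 \,(0.1/0.9)^{1/n}.$$

Since $(1/9)^{1/n} < 1$ for $n \ge 1$, every EC10 draw lies below its EC50
draw. A substance is called **inactive** when the population median EC10
exceeds 3× the maximum tested concentration (strict inequality). The package
applies this rule deterministically — no visual corroboration step — and
implements both readings of "population median": the default takes each
donor's posterior-median EC10 and then the median across donors; a per-draw
alternative (median across donors within each MCMC sample) is available via
`classify_activity(..., rule = "per_draw")`. The distinction rarely matters
in practice; the default is the more interpretable per-donor summary.
Classification near the 3× boundary is meaningful only for PODs within
reach of the tested range: when the true EC10 sits far above the top tested
concentration, the data constrain it only to "large", and any finer
comparison is extrapolation — which is exactly why the rule exists.

The **toxicodynamic variability factor** at the 5th percentile is

$$\mathrm{TDVF}_{05} = \frac{\mathrm{EC}_{10,\text{median}}}{\mathrm{EC}_{10,\text{5th percentile}}},$$

with both quantiles taken *across donors within one MCMC sample*, then
repeated for every sample, yielding an uncertainty distribution for the
TDVF05 itself. Quantiles interpolate linearly between order statistics
(type 7, the mainstream default); at 146 donors the 5th percentile
interpolates near the 7th/8th order statistic. The TDVF05 uses the measured
donors' random effects, not hypothetical new draws from the hyperdistribution.
It is a ratio statistic, hence scale-free, and $\ge 1$ by construction. For a
lognormal POD distribution with ln-scale SD $s$ the large-population value is
$e^{1.6449\,s}$; the test suite uses this closed form as an oracle. Reported
point estimate: the posterior median, flagged against the $10^{1/2}$ and 10
benchmarks.

## Plate QC

Two plate-level gates mirror screening practice: the coefficient of
variation of the raw vehicle wells must be strictly below 20%, and the
positive-control wells (100 µM tetra-octyl ammonium bromide, a complete
kill) must average at most 0.05 in normalized response — "100% cytotoxicity"
needs a numeric tolerance, and 5% of baseline is the package's documented
choice. The CV is computed on *raw* counts with the sample (n−1) SD, because
the gate guards measurement quality before normalization. A failing gate
excludes the whole plate, not individual wells. Reproducibility statistics
are plain Pearson correlations with two-sided $t$ p-values: intra-plate from
duplicate chemicals, inter-plate from a seeded random pair of the three
replicate plates per donor; zero-variance profiles are flagged rather than
returned as NaN.

## GWAS of the POD phenotype

The mapped phenotype is $\log_{10}$ of each donor's posterior-median EC10
(EC10 is multiplicative; the raw scale is available by configuration). SNPs
are coded as minor-allele counts (0/1/2; columns arriving major-allele coded
are flipped), filtered at MAF ≥ 0.05, and tested one at a time by OLS with
intercept, sex, and three genotype principal components as covariates — the
test is the two-sided $t$-test on the allele-count coefficient, with fixed
thresholds $10^{-5}$ (suggestive) and $5\times10^{-8}$ (genome-wide), no FDR
machinery. PCs are computed on the standardized genotype matrix without LD
pruning (panel sizes here are small; documented limitation), with signs
fixed by the largest-loading convention. Missing genotypes are mean-imputed
for PCA and the GRM, but association drops the affected samples per SNP.
Calibration is monitored by the genomic-control $\lambda$ (median 1-df
chi-square over 0.4549), acceptable in [0.9, 1.1]. At a few thousand SNPs
$\lambda$ itself has sampling SD ≈ 0.05, so occasional excursions outside
the band under a true null are expected and are not evidence of structure.

A mixed-linear-model alternative (`mlma_association`) adds a polygenic
random effect with covariance proportional to the GRM
$A_{jk} = M^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$; variance
components are estimated once by REML via the GRM eigendecomposition, then
each SNP is tested by GLS. With an identity GRM the weights are constant and
the statistics reduce exactly to OLS — a property the tests assert to
machine precision. Ancestry groups (e.g. a 106/40 European/African split)
can be analyzed separately and combined by the sample-size-weighted z-score
meta-analysis $z = \sum_g \sqrt{n_g / \sum_h n_h}\; z_g$ — weights chosen so
their squares sum to one, the standard Stouffer sample-size scheme; the
"relative sample size" phrasing admits other weightings, and this is the
package's documented choice.

## What the synthetic generator emulates — and what it does not

`simulate_population()` draws donor-level Hill parameters from exactly the
lognormal random-effects structure the model assumes; `simulate_plates()`
lays out 384-well-style plates with five 10× serial dilutions (0.01–100 µM),
three identical replicate plates per donor, 16 vehicle and 8 positive-control
wells per plate (the real plate map is not public; these counts are
configurable defaults), vehicle luminescence fluctuating at 5% CV around
2×10⁵ counts, and multiplicative Student-$t$ noise applied to raw treatment
counts so that *post-normalization* residuals match the fitting model's
error structure. Genotypes come from Hardy–Weinberg draws with
Balding–Nichols per-group allele-frequency divergence (one Fst-like
parameter) and optional causal variants that shift $\ln$ EC50 additively.
Mixture recipes normalize user-supplied per-chemical reference values into
mass fractions.

The generator is deliberately *self-consistent* with the model: passing
recovery tests demonstrates the implementation is correct, not that the
model is true of real screens. Real data bring plate-edge effects, spatial
drift, batch structure, non-lognormal donor tails, assay-specific
heteroscedasticity, and LD between SNPs — none of which are simulated, and
the QC gates here (CV, positive control) are the only defenses exercised.
Default generator settings (20 donors for model-recovery work, ln-EC50 SD
0.5, 5% noise) are the package's standing simulation conditions, chosen to
match the screening design's scale and typical luminescence assay noise.

## Numerical choices and degenerate inputs

* Concentrations are modeled on the natural-log scale internally; the Hill
  mean is computed as $y_0/(1+(x/x_0)^n)$, which stays finite as the power
  term overflows.
* `error_scale = 0` (with zero vehicle CV) reproduces the Hill curve to
  1e-12 after normalization — the fully noiseless condition is exact, and
  the sampler recovers it to well under 1%.
* Raw counts are truncated at zero (luminescence is non-negative);
  normalized responses above 1 (stimulation) are not clipped.
* Zero-variance vectors anywhere (correlations, PCA, association, GRM)
  either raise a named error or return a flagged result — never a silent NaN.
* Fully resistant donors are retained: the hierarchy shrinks their
  parameters toward the population rather than excluding them.
* Tie-breaks: quantile type 7 everywhere; PCA sign by largest loading;
  the inter-plate pair choice is seeded and recorded.

## Reduced-scale validation

The package validates itself at desk scale (problem sizes chosen as the
package's own test design): hyperparameter recovery uses 20 replicate
simulations of 20 donors × 5 concentrations × 3 plates with 4 chains × 1000
retained draws, requiring 95% credible intervals to cover the true
population mean and SD of $\ln$ EC50 in at least 17 of 20 replicates with
all $\hat R \le 1.2$; TDVF05 recovery uses 200 replicate populations of 146
donors; GWAS calibration uses 100 replicates of 146 samples × 2000 SNPs. A
full-scale screen (146 lines × 50 substances, ~1.3M SNPs) is a
straightforward scale-up of the same calls.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  seed = 11,
  population = list(n_individuals = 20),
  substances = data.frame(chemical_id = c("chemA", "chemB"),
                          mu_log_ec50 = c(log(5), log(8000)),
                          sd_log_ec50 = c(0.5, 0.2)),
  genotypes = list(n_snps = 1000),
  fit = list(initial_iterations = 2000)
)
sim <- simulate_study(cfg, dir = "study")
res <- run_pipeline(sim$plates, sim$genotypes, cfg, dir = "study/out")
res$activity
res$tdvfs$chemA
```

`chemB`, with a true median EC50 of 8 mM against a top tested concentration
of 100 µM, is reported inactive and carries no TDVF row; `chemA` yields a
TDVF05 posterior and a GWAS table with its genomic-control lambda.

## Known limitations

* The sampler is Gibbs/slice (JAGS), not gradient-based; for very flat
  posteriors (inactive substances) mixing is slower and the doubling rule
  may engage.
* No spatial/edge-effect modeling, no LD-aware PCA, no reference-panel
  imputation, no dose-addition mixture reconstruction (out of scope by
  design).
* The activity rule compares a posterior summary against 3× the top tested
  concentration; distinctions between PODs far above the tested range are
  extrapolations and should be read only through that rule.
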