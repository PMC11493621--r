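---
title: "Two-sample MR with two-step mediation: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem and the model

`mrmediate` estimates the causal effect of an exposure (here typically a gut
microbial abundance) on a disease outcome (a binary endpoint such as
coagulation-defect/purpura/hemorrhagic conditions) from GWAS *summary
statistics* of two non-overlapping samples, and decomposes that effect
through an intermediate trait (an immune-cell phenotype) by two-step
mediation.

Each SNP $j$ used as an instrument contributes a pair of estimated
associations: $\hat\beta_{Xj}$ (with the exposure, standard error
$\sigma_{Xj}$) and $\hat\beta_{Yj}$ (with the outcome, $\sigma_{Yj}$). Under
the three instrumental-variable assumptions — relevance, independence from
confounders, and exclusion (no path to the outcome except through the
exposure) — every Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the
same causal effect $\theta$, and the estimators differ in how they pool the
ratios when some instruments are invalid:

* **IVW**: the zero-intercept weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$, in closed form
  $\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum_j w_j
  \hat\beta_{Xj}^2$. The default is the multiplicative random-effects
  variant: the fixed-effect standard error is inflated by
  $\max\{1, \sqrt{Q/(k-1)}\}$, never deflated.
* **MR-Egger**: the same regression with a free intercept, after orienting
  all instruments to $\hat\beta_{Xj} \ge 0$. The slope is robust to
  *directional* pleiotropy when the InSIDE condition holds; the intercept,
  with its normal test, is the horizontal-pleiotropy diagnostic.
* **Weighted median**: the weighted 50% percentile of the ratios with
  weights $(\hat\beta_{Xj}/\sigma_{Yj})^2$, using the centered
  cumulative-weight interpolation rule $s_j = (\mathrm{cum}_j - w_j/2) /
  \sum w$; consistent while valid instruments carry more than half the
  weight.
* **Weighted mode**: the argmax of the weighted normal-kernel density of
  the ratios; bandwidth is a MAD-based Silverman rule
  $0.9\,\mathrm{mad}(\hat\theta_j)\,k^{-1/5}$ times a user factor;
  consistent under plurality validity.
* **Bayesian weighted MR**: the hierarchical model
  $\hat\beta_{Yj} \sim N(\theta\gamma_j, \sigma_{Yj}^2 + \tau^2)$,
  $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
  $\theta \sim N(0, 10^2)$, fitted by blockwise conditional updates with a
  per-SNP inlier responsibility under a two-component
  (inlier / heavy-tailed contaminant) model of the standardized residuals.

Median and mode report bootstrap standard errors (seeded parametric
resampling of both association vectors); all p-values, including those, use
the two-sided normal approximation, and 95% intervals use the fixed
multiplier 1.959963985 on the log-odds scale before exponentiation.

## Instrument QC

Instruments are selected at the genome-wide *suggestive* threshold
$p < 10^{-5}$ — conventional for molecular and microbial traits whose GWAS
rarely yield hits at $5\times10^{-8}$ — then pruned by greedy LD clumping
(visit SNPs by ascending p, ties broken by identifier; drop any SNP within
10,000 kb of an accepted SNP on the same chromosome with $r^2 \ge 0.001$).
Pairs absent from the LD table count as $r^2 = 0$, since pairwise LD exports
are sparse below their reporting threshold.

Instrument strength is assessed per trait:
$R^2_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)\beta_j^2$ for a standardized
trait, summed over instruments, and
$F = \frac{N-k-1}{k}\cdot\frac{R^2}{1-R^2}$. Traits with $F < 10$ are
excluded wholesale (the conventional weak-instrument bar); $F = 10$ exactly
is retained since the exclusion rule is strict. A second $R^2$ convention,
$2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2/\mathrm{se}^2$, circulates in
summary-statistics pipelines; because the two differ by orders of magnitude
the variant is an explicit argument (`snp_r2(..., formula =
"beta_over_se")`), never a silent default.

## Harmonization

SNPs are matched by identifier. Swapped allele pairs flip the outcome beta
and complement its frequency; non-palindromic single-base pairs are also
matched across strands. Palindromic SNPs (A/T, C/G) cannot be strand-resolved
from alleles alone, so they are kept only when both allele frequencies fall
outside $0.5 \pm 0.08$ *and* agree on which side of 0.5 they sit; ambiguous
or discordant palindromes are dropped and counted. Indel alleles match
exactly or as exact swaps only — complementing a multi-base allele is not
well defined. No proxy-SNP lookup is attempted. These defaults mirror common
two-sample MR practice and are assumptions, not estimates: the counts of
every dropped category are carried on the harmonized object.

A useful pair of exact symmetries, enforced in the test suite: jointly
flipping the signs of $(\hat\beta_{Xj}, \hat\beta_{Yj})$ is an allele
recoding and leaves every estimate unchanged, while flipping the outcome
signs alone negates every estimate. (A "joint flip negates the estimate"
convention sometimes stated in pipeline documentation is arithmetically
impossible — the Wald ratios are unchanged.)

## Screening and mediation

The batch screen runs, per exposure: selection, clumping, F-filter,
harmonization, the full estimator panel (Wald ratio at $k=1$, IVW only at
$k=2$, all five at $k\ge3$), and diagnostics (Cochran's Q at the IVW
estimate with $k-1$ df, the Egger residual Q with $k-2$ df, the intercept
test, leave-one-out IVW with influence flags, and per-SNP Wald ratios).
Failures — no instruments, weak instruments, empty harmonization — become
per-exposure records with reasons; a batch never aborts.

Tiers come from the IVW p-value with strict thresholds: significant
($p<0.01$), suggestive ($p<0.05$), else rejected. Exposures at suggestive or
better are re-tested in reverse (outcome as exposure, instruments re-selected
under the same rules); `reverse_clear` requires reverse $p > 0.05$. A
reverse leg with no usable instruments counts as clear — it cannot show
reverse causation. Significant records are then re-validated with the
Bayesian estimator at strict $p < 0.05$; failures are demoted with reason
`bayes_unconfirmed` (so a Bayesian $p = 0.052$, or exactly 0.05, demotes).
Raw p-values are used throughout, as in the screening design this package
reproduces; a Benjamini–Hochberg column is emitted for information only and
never filters.

Mediator candidacy requires both legs at $p<0.05$ — exposure→mediator
($\beta_1$, on the exposure's instruments) and mediator→outcome ($\beta_2$,
on the mediator's own instruments, univariable by design) — each passing the
Bayesian gate. The decomposition is pure product-of-coefficients arithmetic:
mediated $= \beta_1\beta_2$; direct $=$ total $- \beta_1\beta_2$ (defined
exactly so; note that re-adding the two floats can differ from the total by
one ulp); proportion $= 100\,\beta_1\beta_2/\text{total}$, reported only
when mediated and total effects share sign and printed as `/` otherwise
(the mediated path then runs against the overall trend). A zero mediated
effect prints `0%`; a proportion above 100% is kept and flagged. From the
printed rounded pair $(-0.216, -0.016)$ the proportion is
$7.41\%$; published two-step analyses that print $7.26\%$ for the same pair
divided unrounded effects, so the printed inputs alone cannot reproduce that
figure — this package always computes from full precision. A delta-method
standard error for the product,
$\sqrt{\beta_2^2\mathrm{se}_1^2 + \beta_1^2\mathrm{se}_2^2}$, is attached as
an extension; the two legs come from non-overlapping samples and are treated
as independent.

## The synthetic generator

`simulate_pair()` draws, per SNP: MAF uniform on a configurable range
(default 0.05–0.5); true instrument effects $\gamma_j \sim N(0,
\gamma_{sd}^2)$ (optionally folded positive, the exposure-increasing-allele
orientation that directional-pleiotropy designs require); standard errors
from the standardized-trait approximation $1/\sqrt{2\,\mathrm{MAF}(1-
\mathrm{MAF})\,n}$; observed effects with Gaussian sampling noise; outcome
effects $\theta\gamma_j + \alpha_j$ with the direct effect $\alpha_j$ drawn
from a regime (none; balanced $N(0, sd^2)$; directional $N(\mu, sd^2)$)
on a configurable fraction of instruments, independently of $\gamma_j$
(InSIDE holds unless the user breaks it by construction). LD blocks
replicate one signal across co-located SNPs and emit the pairwise $r^2$
the clumping step consumes. Default sample sizes (7,738 exposure; 412,181
outcome) mirror a microbiome-scale exposure GWAS against a biobank
endpoint. `simulate_mediation_triple()` adds the chain: exposure
instruments act on the mediator with slope $\beta_1$ and on the outcome
with slope $\theta_{direct} + \beta_1\beta_2$, while an independent set of
mediator-specific instruments carries the mediator→outcome leg.

What the generator does *not* emulate: case–control imbalance (standard
errors follow the quantitative-trait approximation), outcome-specific causal
loci, winner's-curse selection of instruments from discovery scans, LD
beyond perfect within-block proxies, and real microbiome abundance
distributions. Passing tests therefore demonstrate estimator correctness
and pipeline integrity under the stated generating model, not performance
on real cohort data.

## Simulation designs used by the tests and the acceptance script

Problem sizes were chosen so each experiment isolates the property under
test:

* **Type-I calibration** — 100 candidate SNPs at the default paper-scale
  sample sizes, $\theta = 0$, no pleiotropy, 500 replicates; IVW,
  Egger-slope and Q rejection rates at $\alpha = 0.05$ must lie in
  $[0.03, 0.07]$.
* **Recovery** — 30 SNPs, $\theta = 0.2$, $\gamma_{sd} = 0.15$, exposure
  $n = 10^5$, outcome $n = 5\times10^4$, instruments selected at $10^{-5}$
  before harmonization, 200 replicates; every estimator's mean within 2
  Monte-Carlo standard errors of $\theta$. The large exposure GWAS keeps
  weak-instrument dilution ($\approx \theta\,\sigma_X^2/\bar\gamma^2$,
  the NOME violation all ratio estimators share) an order of magnitude
  below the Monte-Carlo band; at an exposure $n$ of a few thousand the
  dilution, not any implementation defect, would dominate such a band.
* **Robustness** — the recovery design plus directional pleiotropy
  $N(0.1, 0.02^2)$ on 40% of instruments, positive orientation. IVW is
  pulled far from $\theta$ (mean $\approx 0.42$) while the weighted median
  stays close (mean $\approx 0.30$). One assertion in this block is known
  to fail and is retained deliberately: a weighted quantile under one-sided
  contamination $c$ keeps a finite-sample shift of about
  $z_{0.5/(1-c)}\times$ (ratio-noise sd), and since that shift and the
  Monte-Carlo standard error of a 200-replicate mean both scale linearly
  with the ratio noise, their ratio ($\approx$ 15–30 here) cannot be
  driven below 2 by any admissible choice of sample sizes or effect
  scales. The estimator is consistent (the shift vanishes as GWAS
  precision grows), but not at the rate a fixed-replicate mean test
  demands.
* **Pleiotropy detection** — 30 positively-oriented SNPs, $\theta = 0$,
  directional pleiotropy mean 0.05, 200 replicates; the mean Egger
  intercept must sit within 2 Monte-Carlo standard errors of 0.05.
  Instrument selection matters here: without it, SNPs whose observed
  exposure effect flips sign under noise flip their pleiotropy into the
  orientation step and bias the intercept toward zero.
* **Mediation recovery** — the chain $\beta_1 = 0.15$, $\beta_2 = 0.4$,
  $\theta_{direct} = 0.1$ (design proportion 37.5%), mediator GWAS
  $n = 2\times10^4$ chosen so exposure instruments rarely reach the
  selection threshold through the mediator (keeping the mediator→outcome
  leg on the mediator's own instruments), 200 replicates.
* **Reverse-screen clearance** — forward-only causal pairs ($\theta=0.2$)
  against a modestly powered outcome GWAS ($n = 15{,}000$, 30 candidate
  SNPs), 200 replicates. The generator gives the outcome no loci of its
  own, so at biobank precision the exposure's instruments become
  individually detectable in the outcome scan and reverse MR — with
  directionality (Steiger) filtering deliberately out of scope — would
  correctly flag the forward signal running backwards. The calibration
  scenario is therefore the regime where reverse instruments can only be
  false positives, which is also the regime the screening design assumes.

## Numerical choices and degenerate inputs

Zero p-values are clamped to 1e-300 at load with a warning; estimator
p-values are floored at the same bound. Duplicate SNP identifiers keep the
most significant record. A missing allele frequency disables a SNP's $R^2$
contribution (with a warning) and makes a palindromic SNP ambiguous.
Clumping ties are broken lexicographically, making results invariant to row
order. `bx = 0` is a degenerate Wald instrument (error); an all-zero
exposure vector is a degenerate IVW input (error). The Bayesian fit declares
non-convergence beyond 500 iterations at tolerance 1e-6 on $\theta$ and
reports it as a per-method failure in batch runs. All stochastic routines
take explicit seeds; simulation and bootstrap draws run inside a local RNG
scope that restores the caller's generator state.

## Known limitations

Univariable mediation only (no multivariable direct-effect estimation, no
joint mediators); no MR-PRESSO or Steiger filtering; no proxy instruments;
no correction for sample overlap; the binary-outcome scale is taken as
log-odds throughout, matching odds-ratio reporting conventions. The
weighted-median finite-sample contamination shift and the weak-instrument
dilution shared by all ratio estimators are quantified above.
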