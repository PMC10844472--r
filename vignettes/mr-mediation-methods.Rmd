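---
title: "Two-sample MR and two-step mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR and two-step mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The estimation problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here, dietary habits such as the type of breakfast cereal a person
mainly eats) on an outcome (cardiovascular disease risk, on the log-odds
scale) from two independent sets of GWAS summary statistics. For each
genetic instrument $j$ we observe the SNP–exposure association
$\hat\gamma_j$ with standard error $\sigma_{\gamma j}$ and the SNP–outcome
association $\hat\Gamma_j$ with standard error $\sigma_{\Gamma j}$. If the
instruments are valid — associated with the exposure, independent of
confounders, and affecting the outcome only through the exposure — then
each Wald ratio $\hat\Gamma_j / \hat\gamma_j$ estimates the same causal
effect $\theta$.

`mrmediate` implements the full inference pipeline around this idea:
instrument selection, allele harmonization, the estimator family (IVW,
MR-Egger, weighted median, MR-PRESSO, multivariable IVW), and a two-step
mediation decomposition that splits a total effect into the part running
through a measured mediator (adiposity, glycaemic or lipid traits in the
motivating application) and the remainder.

# Instrument selection

Four screens are applied in a fixed order, each configurable through
`iv_config()`:

1. **Genome-wide significance.** `pval < 5e-8`, strict. An empty result at
   this stage (or at the end) raises an explicit empty-instrument error,
   because no downstream estimator is defined for $J = 0$.
2. **Greedy LD clumping** (`clump_greedy()`): repeatedly take the remaining
   SNP with the smallest p-value as an index SNP and discard remaining SNPs
   on the same chromosome within 10,000 kb whose $r^2$ with it is at least
   0.001. Both conditions (distance *and* $r^2$) are required. Ties on
   p-value are broken by smaller coordinate, then lexicographic id, so the
   output is deterministic and independent of input order. LD is an input
   (`ld_info()`), not computed from genotypes; pairs absent from the table
   are treated as unlinked.
3. **Confounder exclusion.** A local association catalog
   (`confounder_catalog()`) stands in for a phenotype-lookup service: any
   catalog association with $p < 5\times10^{-8}$ removes the SNP, and each
   removal is reported as a (snp, trait, p) row.
4. **Instrument strength.** The per-SNP F statistic is the squared z-score
   $F_j = (\hat\gamma_j/\sigma_{\gamma j})^2$ — the standard summary-data
   approximation — and instruments must have $F > 10$ (strict), the
   conventional weak-instrument screen.

The audit trail records the count entering the pipeline and after each
stage, so selection is fully reconstructible.

# Harmonization

Estimators need all effects expressed for the same allele.
`harmonize()` aligns outcome and mediator panels to the exposure's
effect-allele coding over the SNPs shared by all panels:

* matching allele pairs are kept; swapped pairs flip the beta's sign and
  replace EAF by $1-$EAF;
* strand flips (complement-base matches) are reconciled before a pair is
  declared irreconcilable;
* palindromic SNPs (A/T, C/G) cannot be oriented by labels. They are
  oriented by comparing effect-allele frequencies when both traits' EAFs
  fall outside the window $[0.42, 0.58]$ (flag `eaf_inferred`), and dropped
  otherwise (`dropped_palindromic`). The window matches common two-sample
  MR practice; the motivating study does not state its rule, so this is an
  explicit, configurable choice rather than an inference about intent.
* a missing EAF drops a palindromic SNP (conservative) but a
  non-palindromic SNP is aligned by labels alone.

Per-SNP provenance flags partition the shared SNP set, and a per-panel
report is attached for auditing.

# Estimators

**IVW.** With weights $w_j = \sigma_{\Gamma j}^{-2}$, the estimate is the
zero-intercept weighted regression slope
$\hat\theta = \sum w_j \hat\gamma_j \hat\Gamma_j / \sum w_j \hat\gamma_j^2$,
equivalently the inverse-variance meta-analysis of Wald ratios. The
fixed-effect SE is $(\sum w_j\hat\gamma_j^2)^{-1/2}$; Cochran's
$Q = \sum w_j(\hat\Gamma_j - \hat\theta\hat\gamma_j)^2$ is referred to
$\chi^2_{J-1}$. The multiplicative random-effects (mre) SE multiplies the
fixed-effect SE by $\max(1, \sqrt{Q/(J-1)})$ — never deflating it.
`model = "auto"` switches to mre exactly when Q's p-value is below 0.05,
recording the choice in `model_note`; this mirrors the convention of using
the multiplicative random-effects model as the conservative primary
estimate in the presence of significant heterogeneity. With $J = 1$ IVW
reduces exactly to the Wald ratio, whose first-order SE
$\sigma_{\Gamma}/|\hat\gamma|$ ignores exposure-side noise (the
no-measurement-error assumption; at $F > 10$ the neglected term is small).

**MR-Egger.** Weighted least squares of $\hat\Gamma_j$ on $\hat\gamma_j$
*with* an intercept, after orienting every pair so $\hat\gamma_j \ge 0$
(the fit is invariant to the original orientation). The intercept estimates
the average directional pleiotropy; the slope is consistent under the
weaker InSIDE assumption. Both SEs are scaled by
$\max(1, \sqrt{\mathrm{RSS}_w/(J-2)})$ and p-values use $t_{J-2}$.

**Weighted median.** Ratio estimates $\hat\theta_j$ with normalized weights
$w_j \propto (\sigma_{\Gamma j}/|\hat\gamma_j|)^{-2}$ are sorted; the
estimate interpolates $\hat\theta$ against the cumulative weight midpoints
$p_j = \sum_{k\le j} w_k - w_j/2$ at $p = 0.5$. It is consistent when
instruments carrying at least half the weight are valid. The SE is the
standard deviation over seeded parametric-bootstrap replicates
(default 1,000), resampling both $\hat\gamma$ and $\hat\Gamma$.

**MR-PRESSO.** For each SNP the IVW slope is recomputed leaving it out
(computed in $O(J)$ from running sums), and the observed global statistic
is the sum of weighted squared residuals about those leave-one-out slopes.
The null distribution comes from parametric simulation (default 1,000
draws; outcome effects redrawn about the leave-one-out fits), fully
vectorized. Empirical p-values use the add-one rule $(1+b)/(1+m)$, so the
attainable minimum is $1/(m+1)$ and a p-value of zero is impossible.
Per-SNP outliers are flagged at the Bonferroni-adjusted level
$\alpha/J$ (default $\alpha = 0.05$), and the corrected estimate refits IVW
without them. The distortion test is intentionally not implemented.

**Multivariable IVW.** Weighted least squares of $\hat\Gamma_j$ on $K$
exposure/mediator effect columns jointly, no intercept, with the same
overdispersion-scaled SEs (floored at 1, df $J-K$) for both homogeneity
regimes, and normal-reference p-values. Identically-zero columns carry no
information: they are excluded from the solve and reported as aliased
(coefficient `NA`) rather than raising the collinearity error reserved for
genuinely collinear informative columns. Requiring $J > K$ enforces
identification.

# Two-step mediation

Writing $\beta_1$ for the total exposure→outcome effect, $\beta_2$ for the
exposure→mediator effect and $\beta_3$ for the mediator→outcome effect
adjusted for the exposure:

* $\beta_1$, $\beta_2$ come from univariable IVW (`model = "auto"`) on the
  exposure's instruments;
* $\beta_3$ is the mediator's coefficient in a $K = 2$ multivariable IVW
  over the mediator's instruments (mediator + exposure effect columns). The
  instrument set for this step is the union of each trait's selected,
  clumped instruments, restricted to SNPs present in every panel
  (complete case), re-harmonized jointly;
* indirect $= \beta_2\beta_3$, direct $= \beta_1 - \beta_2\beta_3$,
  proportion mediated $= 100\,\beta_2\beta_3/\beta_1$.

Direct and indirect effects sum to the total exactly by construction. A
zero total effect leaves the proportion undefined (flagged, not invented);
proportions outside $[0, 100]\%$ — inconsistent mediation — are reported as
computed and flagged, never truncated. No standard error is attached to the
proportion by default, matching the point-estimate reporting convention of
the motivating analysis; a seeded parametric bootstrap interval
(`mediation_proportion_ci()`) is available but off by default.

# The synthetic-data generator

`simulation_truth()` + `simulate_panels()` encode the causal diagram the
analysis assumes: SNP $j$ affects the exposure by $\gamma_j$; the mediator
responds with slope $\tau$ and carries SNP-specific effects
$\delta_j \sim N(0, \texttt{mediator\_effect\_sd}^2)$; the outcome receives
$\theta_{\mathrm{direct}}$ per unit exposure, $\beta_3$ per unit mediator,
and, for a fraction `prop_invalid` of SNPs, a direct pleiotropic effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$. The generating total effect
is $\theta_{\mathrm{direct}} + \tau\beta_3$ by construction.

Design choices, fixed once:

* **SE model**: $\mathrm{se} \approx 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n\,v}$
  with $v = 1$ for continuous traits and $v = \mathrm{cf}(1-\mathrm{cf})$
  for a binary outcome with case fraction cf — the standard large-sample
  approximation.
* **Defaults** chosen to resemble biobank-scale GWAS: $J = 50$ instruments,
  MAF uniform on $[0.1, 0.4]$, $n = 350{,}000$ (exposure), $300{,}000$
  (mediator), $200{,}000$ (outcome) with case fraction 0.25; exposure
  effect magnitudes uniform on $[0.03, 0.08]$ so that every true instrument
  clears genome-wide significance at these sample sizes.
* **Orientation**: effect alleles are the exposure-increasing alleles, as
  an exposure GWAS reports its lead variants; directional pleiotropy
  ($\mu_\alpha \ne 0$) is defined relative to that orientation, which is
  what makes the Egger intercept a meaningful target.
* **`mediator_effect_sd` (default 0.03)**: without SNP-specific mediator
  effects the multivariable design $(\tau\gamma_j, \gamma_j)$ is exactly
  collinear and $\beta_3$ is unidentified; $\delta_j$ gives the mediator
  its own genetic signal, as real mediator GWAS have. It also induces
  genuine heterogeneity in the exposure→outcome ratios (balanced
  mediator-channel pleiotropy) whenever $\beta_3 \ne 0$.
* **Independence**: variants are spaced 25 Mb apart (beyond the 10,000 kb
  clumping window), so default instruments are mutually unlinked; clumping
  is exercised by dedicated LD fixtures instead of every simulation.
* Identical seeds give identical panels; all stochastic operations
  (weighted-median bootstrap, MR-PRESSO, outlier planting) take explicit
  seeds and record them, and restore the caller's RNG state.

What the generator does **not** emulate: realistic LD from reference
panels, individual-level genotypes, sample overlap between the exposure and
outcome GWAS, MAF-dependent effect-size architecture, winner's-curse bias
from in-sample instrument discovery, and non-normal summary-statistic
noise. Passing recovery and calibration tests therefore demonstrates
internal correctness of the estimators under the assumed causal structure,
not robustness to those real-data complications.

# Numerical conventions

* All thresholds that the screening rules state as "below"/"above" are
  strict inequalities (`pval < 5e-8`, `F > 10`, outlier p `< alpha/J`).
* The 95% multiplier is $\Phi^{-1}(0.975) = 1.959964$.
* Empirical p-values are never zero (add-one rule); analytic p-values are
  floored away from zero only where they feed the label classifier, which
  requires $p \in (0, 1]$.
* Overdispersion scalings are floored at 1 everywhere, so random-effects
  SEs can never undercut their fixed-effect counterparts.
* The significance classifier treats the Bonferroni boundary
  $p = \alpha/m$ as suggestive (strict `<` for significant). The loose
  verbal convention "suggestive means $p > 0.005$" is internally
  inconsistent with $\alpha/9 = 0.0056$; the implementation uses the exact
  threshold and documents the discrepancy rather than guessing intent.
* Reports round ORs and betas to 3 decimals, proportions to 2, p-values to
  3 significant figures; JSON serializations keep full precision.

# Problem sizes used in the test suite

The shipped tests exercise the estimators at the scale of the motivating
analysis: null calibration over 2,000 replicates at $J = 50$ (type-I error
and the $\chi^2_{J-1}$ law of Q), recovery of a total effect of $-0.5$ over
500 replicates, mediation-proportion recovery over 300 replicates (plus 150
at a 10% generating proportion), 200 seeded MR-PRESSO runs against a
planted 10-SE outlier, and 500-replicate comparisons of weighted-median vs
IVW bias under 30% directional pleiotropy. These sizes were chosen so
Monte-Carlo error is small relative to the tested tolerances.

# Known limitations

* First-order Wald SEs (NOME) throughout; no exact or second-order
  variance for weak instruments.
* No correlated-instrument (generalized) IVW; LD enters only through
  clumping.
* No Steiger directionality filtering, mode-based estimators, or
  MR-PRESSO distortion test.
* The mediation decomposition treats mediators one at a time; no joint
  multi-mediator decomposition.
* Binary-outcome effects are treated as log-odds throughout; no
  non-collapsibility correction is attempted.
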