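---
title: "Sex-combined joint main and SNP-by-sex interaction testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-combined joint main and SNP-by-sex interaction testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmeta)
```

## The problem

Genetic effects on quantitative traits can differ between the sexes —
sometimes in magnitude (serum urate), sometimes the effect exists in one sex
only, and occasionally the minor allele pushes the trait in *opposite*
directions in females and males. Sex hormone traits such as testosterone are
the extreme case, with largely distinct genetic architectures per sex.

A sex-stratified GWAS gives interpretable per-sex effect estimates
$\hat\beta_F, \hat\beta_M$ with standard errors $\hat v_F, \hat v_M$ and
Wald statistics $T_F = \hat\beta_F/\hat v_F$, $T_M = \hat\beta_M/\hat v_M$,
but it is not the most powerful *screening* strategy. This package
implements the sex-combined alternatives that operate directly on the
stratified summary statistics:

* **Linear (fixed-effect) meta-analysis**
  $T_{1,metaL} = \dfrac{(1/\hat v_F)\,T_F + (1/\hat v_M)\,T_M}
  {\sqrt{1/\hat v_F^2 + 1/\hat v_M^2}} \sim N(0,1)$ — the traditional
  main-effect-only combination. It is optimal under homogeneous effects and
  *structurally blind* to equal-and-opposite effects, where its
  noncentrality is exactly zero.
* **Interaction-only (effect-difference) test**
  $T_{Diff} = \dfrac{\hat\beta_F - \hat\beta_M}
  {\sqrt{\hat v_F^2 + \hat v_M^2}} \sim N(0,1)$, targeting the SNP-by-sex
  interaction alone.
* **Omnibus quadratic meta-analysis**
  $T_{2,metaQ} = T_F^2 + T_M^2 \sim \chi^2_2$, a 2-df joint test of the
  main and interaction effects. Because the combination is quadratic it is
  direction-agnostic: it retains power under any heterogeneity pattern, at
  the modest cost of one extra degree of freedom when effects happen to be
  homogeneous.

When individual-level data are available, the mega-analysis counterparts
are linear regressions

$$y = a + b_g g + b_s s + b_{gs}\, g s + X b_X + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2_{s}),$$

with a *sex-specific* residual variance ($\sigma^2_F$ for females,
$\sigma^2_M$ for males; many traits differ between sexes in both mean and
variance). The 2-df Wald test of $H_0: b_g = b_{gs} = 0$ is the mega
analogue of $T_{2,metaQ}$; dropping the interaction term and testing
$H_0: b'_g = 0$ gives the standard sex-adjusted main-effect test, the
analogue of $T_{1,metaL}$.

## Estimation of the heteroskedastic model

The model above states sex-specific error variances but not an estimator.
We use iterative feasible generalized least squares (FGLS): an unweighted
OLS fit, per-group variance estimates from the group residuals, a weighted
refit with weights $1/\hat\sigma^2_{s_i}$, iterated until the maximum
relative coefficient change falls below $10^{-8}$ (at most 100 iterations;
all test fixtures converge in a handful). Convergence failure returns the
last iterate with a warning rather than an error, so a genome-wide scan is
not derailed by one pathological variant.

Degrees of freedom for the variance estimates are chosen so standard errors
are reproducible:

* `covariate_mode = "fully_stratified"` (every non-genotype column
  interacted with sex) with the joint model: each group's denominator is
  $n_g - p/2$, its own parameter count. The design then decouples and the
  fit is *numerically identical* to two per-stratum OLS fits — which is why
  the 2-df Wald statistic equals $T_F^2 + T_M^2$ to machine precision
  (`check_meta_mega_equivalence()` asserts $<10^{-6}$ on every cohort).
* otherwise (shared covariates): each group is attributed its proportional
  share of the $p$ parameters, denominator $n_g - p\,n_g/n$.

The fully stratified mode is the exact-equivalence path; the shared mode is
what a typical single-model GWAS would run, and agrees with the
meta-analysis statistics with correlation $>0.999$ across simulated cohorts.

## Numerical choices

All tail probabilities are computed in log space:
$\log p = \log 2 + \log\Phi(-|z|)$ via `pnorm(log.p = TRUE)`, and for the
2-df chi-square the closed form $p = e^{-\chi^2/2}$, i.e.
$-\log_{10} p = \chi^2 / (2\ln 10)$. The `p` fields underflow to 0 in
double precision somewhere below $10^{-308}$; the paired `neglog10p`
fields are therefore the authoritative scale and stay finite and accurate
for $|z|$ well beyond 40 (biobank-scale associations routinely exceed
$-\log_{10} p = 200$). Significance filtering always compares on the
$-\log_{10}$ scale, with strict inequality ($p = \alpha$ is not
significant).

Summary files may carry `beta` with `se`, with `p`, or with both. When both
are present and disagree by more than 1% on the z scale, `se` wins with a
warning — printed p columns are usually rounded. A `p` of exactly 0 is
rejected as unparseable. `beta = 0` with a valid `se` is legal ($z = 0$);
MAF is always stored as $\min(f, 1-f)$ relative to the shared minor allele,
which makes the stored value invariant to allele-orientation flips. The X
chromosome is coded 23 and flows through the autosomal code path; dosage
models are out of scope.

## The synthetic-data generator

`scenario()` fixes per-sex sample sizes, MAF, true effects
$\beta_F, \beta_M$, sex-specific means and residual SDs.
`simulate_cohort()` draws HWE genotypes and
$y = \mu_s + \beta_s g + X b_X + \varepsilon$. `simulate_sumstats()` is the
summary-level shortcut: $\hat\beta_s \sim N(\beta_s, v_s^2)$ with the
asymptotic variance $v_s^2 = \sigma_s^2 / (2\,\mathrm{maf}(1-\mathrm{maf})\,n_s)$
and `se` reported as the true $v_s$, so each $z_s$ is *exactly* normal with
noncentrality $\beta_s/v_s$. The two engines agree distributionally (KS
checks in the test suite), and the summary engine is what makes a
20,000-replicate calibration study run in seconds.

The preset grid (`scenario_grid()`) covers the qualitative heterogeneity
configurations: no effect, homogeneous, female-only, male-only,
equal-and-opposite, and magnitude difference. Defaults were chosen once
from the closed-form power expressions at $n = 2{,}000$ per sex,
$\mathrm{maf} = 0.3$, $\sigma = 1$: homogeneous $\beta = 0.08$ in both
sexes, one-sex-only $\beta = 0.11$, opposite $\pm 0.10$, magnitude
difference $0.12/0.04$. These give mid-range per-sex power (roughly
0.6–0.9 at $\alpha = 0.05$), which keeps method comparisons discriminative:
a grid where every method saturates at power 1 shows nothing. The presets
use $\mu_F = 0, \mu_M = 1$ (a sex-dimorphic mean) and equal unit variances
so the analytic oracle is exact; sex-specific variances are exercised
separately in the mega-model tests.

What the generator does **not** emulate: linkage disequilibrium between
simulated variants (single-variant tests do not need it; LD enters only
through the abstract post-GWAS provider), relatedness between or within
sexes (which would break the independence of $T_F$ and $T_M$ and hence the
$\chi^2_2$ null), detection-limit truncation, binary traits, and
participation bias. Passing tests therefore demonstrate correctness of the
statistics under the stated sampling model, not robustness to those
real-data complications.

Power/size study parameters: the calibration check uses 20,000
summary-level replicates of the null preset; the power-ordering check
20,000 replicates per grid preset; the shared-covariate meta/mega agreement
500 cohorts of 4,000 individuals — sizes chosen as the package's desk-scale
defaults that still pin each Monte-Carlo estimate to about $\pm 0.005$.
Monte-Carlo results are validated against the noncentral closed forms
(`analytic_power()`): per-sex noncentrality
$\lambda_s = \beta_s^2\, 2\,\mathrm{maf}(1-\mathrm{maf})\, n_s / \sigma_s^2$,
normal tails for the 1-df tests, and the noncentral $\chi^2_2$ tail at
$\lambda_F + \lambda_M$ for the omnibus test. Genome-wide $\alpha = 5\times
10^{-8}$ power is available through the analytic path only; Monte-Carlo at
that $\alpha$ is not desk-feasible.

## Post-GWAS stage

Greedy clumping follows the clump-index convention: repeatedly take the
remaining variant with the smallest p-value as index, absorb everything on
the same chromosome within 10 Mb with $r^2 > 0.01$ (strict), remove, and
repeat. Ties in p break canonically by (chromosome, position, id), so the
output is invariant to input shuffling. Independent variants within 250 kb
then merge into risk loci by single linkage (chains merge transitively),
each locus led by its smallest-p member. LD is consumed through an abstract
provider — a dense matrix fixture or a synthetic block generator — because
reproducing a reference-panel LD computation is explicitly out of scope.

Opposite-direction flagging is independent of the meta-analysis statistics:
a variant qualifies when both per-sex p-values clear the threshold and the
nonzero betas disagree in sign.

## Design choices that were genuinely open

* **Rounded printed inputs.** Worked-example tolerances are $\pm 0.05$ on
  $-\log_{10} p$ where printed p-values are inverted exactly, and
  $\pm 0.2$ where standard errors must be back-derived from betas printed
  to 1–4 significant figures. One printed testosterone lead (rs4946386,
  printed omnibus p $4.99\times10^{-8}$) recomputes to $5.006\times10^{-8}$
  from its rounded per-sex p-values and so falls just outside the strict
  genome-wide cut when the pipeline recomputes everything; the pipeline
  tests assert the recomputed count and note the borderline row.
* **IRNT offset.** The rank-based inverse normal transform uses
  $\Phi^{-1}((r - 0.5)/n)$ with average ranks for ties; the offset is
  configurable since export pipelines differ. Per-group IRNT centres every
  group at zero, which is exactly why sex-specific transforms break
  meta/mega equivalence — the utility exists largely to demonstrate that.
* **No random-effects meta-analysis.** With two groups, the
  between-group heterogeneity variance cannot be estimated reliably; the
  2-df omnibus test is the principled alternative and is what the package
  recommends.
* **Strand-ambiguous variants** are kept and matched by id by default
  (both strata originate from one imputation panel); a flag drops them for
  cross-study use.
* **Column mapping is explicit.** A shipped default matches Neale-style
  exports; there is no header auto-detection.

## Worked examples

Two printed lead-SNP tables ship as plain-text fixtures:
`worked_example("testosterone")` (12 novel loci significant only under the
omnibus test) and `worked_example("urate")` (19 SNPs near *SLC2A9*,
genome-wide significant in both sexes with opposite directions).
`worked_example_sumstats()` re-expresses either table as a pair of per-sex
summary files so the whole pipeline can be exercised end to end:

```{r}
paths <- worked_example_sumstats("urate")
cfg <- run_config(female = paths[["female"]], male = paths[["male"]],
                  ld = ld_block_provider(list(worked_example("urate")$variant)))
run <- cmd_meta(cfg)
head(run$results[, c("variant", "beta_F", "beta_M", "p_metaL", "neglog10_p_metaQ")])
rep <- cmd_report(cfg)
rep$loci
nrow(rep$opposite)
```

## Known limitations

Linear models for quantitative traits only; unrelated individuals assumed;
no mixed models, no binary/ordinal outcomes, no X-specific dosage
compensation, no liftover or multi-ancestry harmonization, and no
reference-panel LD computation. The omnibus test is a *screening* tool:
follow-up sex-stratified estimation remains the way to interpret any hit.
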