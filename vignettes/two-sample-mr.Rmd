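---
title: "Two-sample Mendelian randomization with summr: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with summr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summr)
```

## The causal model

Two-sample Mendelian randomization treats genetic variants as natural
randomizers. For variant $j$, let $\beta_{Xj}$ be its effect on the
exposure (SD units for continuous traits, log-odds for binary traits)
and $\beta_{Yj}$ its effect on the outcome, each estimated with standard
error $\sigma_{Xj}$, $\sigma_{Yj}$ in two non-overlapping samples. If
the variant affects the outcome only through the exposure, every Wald
ratio $\theta_j = \beta_{Yj}/\beta_{Xj}$ estimates the same causal
effect $\theta$. The estimators differ in how they pool the ratios and
which violations they tolerate:

* **IVW** solves the weighted regression of $\beta_{Yj}$ on
  $\beta_{Xj}$ through the origin with weights $\sigma_{Yj}^{-2}$,
  algebraically identical to the fixed-effect inverse-variance
  meta-analysis of the $\theta_j$ (asserted to $10^{-12}$ in the test
  suite). It is efficient but assumes all instruments valid.
* **MR-Egger** adds an intercept after orienting every variant so
  $\beta_{Xj} \ge 0$. Under InSIDE (instrument strength independent of
  direct effects), the slope is a consistent causal estimate and the
  intercept estimates the average directional pleiotropy; its deviation
  from zero is tested on $t_{k-2}$.
* The **weighted median** interpolates the ordered ratios at the 50th
  percentile of the normalized NOME weights
  $w_j = \beta_{Xj}^2/\sigma_{Yj}^2$ and is consistent while less than
  half the weight sits on invalid instruments.
* The **weighted mode** maximizes the weighted Gaussian kernel density
  of the ratios — consistent when the largest homogeneous cluster of
  instruments is valid (ZEMPA).

All four run through `estimate_all()`; a binary outcome adds the OR
scale, $e^{\hat\theta}$ with its CI.

## Error models and intervals

GWAS summary SEs are treated as known. The IVW standard error uses a
multiplicative random-effects model floored at the fixed-effect scale:
$\mathrm{SE} = (\sum \beta_{Xj}^2\sigma_{Yj}^{-2})^{-1/2}\cdot
\max\{1, \sqrt{Q/(k-1)}\}$, where $Q$ is Cochran's statistic. The floor
prevents under-dispersion from shrinking the SE below what the known
$\sigma_{Yj}$ permit; a pure fixed-effect variant is exposed as
`re_model = "fixed"`. MR-Egger applies the same floored inflation to
its coefficient SEs, computed from the exact weighted-least-squares
covariance (so a perfect fit yields the fixed-dispersion SE rather than
a degenerate zero). Intervals use the normal 0.975 quantile for
IVW/median/mode and $t_{k-2}$ for Egger, matching the methods' source
conventions; all p-values are two-sided.

The median and mode take bootstrap SEs: `n_boot` parametric replicates
drawing $\beta_{Xj}^* \sim N(\beta_{Xj}, \sigma_{Xj})$,
$\beta_{Yj}^* \sim N(\beta_{Yj}, \sigma_{Yj})$, seeded for
reproducibility. The default is 1000; below 100 a warning is issued,
and `n_boot = 0` skips the SE (point estimates only, used by the
large simulation studies in the tests).

## Instrument preparation defaults

| Parameter | Default | Meaning |
|---|---|---|
| `p_instrument` | 5e-8 | genome-wide significance; **strict** `<` |
| `clump_window_kb` | 10,000 kb | greedy clumping window |
| `clump_r2` | 0.001 | LD independence cutoff |
| F floor | 10 | weak-instrument exclusion |
| proxy r² | > 0.8 | outcome-side proxy substitution |
| palindrome band | [0.42, 0.58] | unresolvable EAF range |
| `alpha_family` | 0.05 | family-wise level |

Clumping is greedy and deterministic: sort by p-value, keep the best
remaining variant, discard all within-window variants in LD at or above
the cutoff; variants on different chromosomes or lacking positions are
compared on r² alone, and survivors are returned in genomic order. The
F ≥ 10 filter is applied **after** clumping in the pipeline (removing a
weak lead variant must not resurrect variants already pruned on LD);
`select_instruments()` applies it immediately when used standalone.

Harmonization aligns outcome records to the exposure's effect allele:
swapped labels negate $\beta_Y$ and reflect EAF, strand flips are
resolved by complementing, and palindromic (A/T, C/G) variants follow a
policy. The default `drop_ambiguous` discards them when either trait's
EAF lies in [0.42, 0.58] and otherwise infers the strand from frequency
agreement; `infer` always infers and `drop_all` discards every
palindromic variant. The band is the established community default —
inference from frequencies that close to 0.5 is little better than a
coin flip. Proxy substitution replaces only the outcome record; the
exposure effect and SE remain those of the original instrument.
p-values of exactly 0 in input files (underflowed exports) are clamped
to the smallest positive normal double with a warning; missing EAF is
recorded as absent, never imputed, and operations needing it fail
loudly.

## Heterogeneity, outliers, directionality, power

Cochran's $Q = \sum_j (\beta_{Xj}/\sigma_{Yj})^2 (\theta_j -
\hat\theta_{IVW})^2$ on $k-1$ df with $I^2 = \max(0, (Q - df)/Q)$;
Rucker's $Q'$ is the weighted residual sum of the Egger fit on $k-2$
df, never exceeding $Q$, with $Q'/Q$ diagnosing how much heterogeneity
the intercept absorbs.

MR-PRESSO computes the observed residual sum of squares with
leave-one-out IVW predictions and compares it against `n_sim`
parametric replicates (default 1000, configurable — the reference
implementation's published algorithm, with per-variant tests Bonferroni
adjusted by $k$). An empirical p of zero is reported as `<1/n_sim`,
matching the usual "<0.001" table convention. The distortion test is
deliberately not implemented: outlier-corrected estimates are obtained
transparently by `filter_snps()` plus re-estimation.

The Steiger test pools $R^2 = \sum_j 2\beta_j^2 \mathrm{EAF}_j
(1-\mathrm{EAF}_j)$ on each side and compares $\mathrm{atanh}\sqrt{R^2}$
via Fisher's z with variances $1/(n-3)$. For binary traits this $R^2$
is computed on the observed log-odds scale — an approximation, flagged
in the result (`approx_binary_r2`). When outcome EAFs are unavailable
the per-variant $F/(F + n - 2)$ approximation substitutes. Effective
sample size for case-control traits uses the total n; a different
convention can be passed explicitly.

Binary-outcome power uses the normal approximation
$\Phi(\sqrt{N R^2 K(1-K)}\,|\ln \mathrm{OR}| - z_{1-\alpha/2})$ — the
convention of the standard online MR power calculator — cross-validated
in the tests against a Monte-Carlo score-test oracle on simulated
cohorts (agreement within 0.02). `detectable_effect()` inverts it by
bisection to $10^{-6}$; risky and protective solutions are exact
reciprocals since only $|\ln \mathrm{OR}|$ enters.

Multiple testing uses Bonferroni, default `n_tests = "auto"` = pairs ×
directions. A 7 × 5 forward design gives 35 tests and the threshold
0.05/35 ≈ 1.43 × 10⁻³. Running both directions doubles the automatic
count; because some published analyses keep 35 even with reverse runs,
the pipeline warns rather than silently choosing, and `n_tests` can be
fixed explicitly.

## Multivariable IVW

`mvmr_ivw()` regresses $\beta_Y$ jointly on all exposure-effect columns
(no intercept, weights $\sigma_{Yj}^{-2}$), estimating direct effects.
Instrument pooling takes the union of the exposures' clumped
instruments; a variant missing from one exposure GWAS is imputed as
zero effect with that table's median SE and flagged (standard
multivariable-MR practice — dropping such variants would bias the union
toward well-covered exposures). Collinearity is detected at a weighted
condition number of 1e8 and reported with the offending pair named.

## What the synthetic generator emulates — and what it does not

`simulate_gwas_pair()` draws, per variant: MAF uniform on
`maf_range`; true exposure effects whose magnitudes follow a floor of
~0.82× the mean share with an exponential right tail, scaled so the
pooled $R^2$ hits `instrument_h2` exactly — the left-truncated strength
profile of published post-selection instrument lists (F floor near 30,
median mid-30s, occasional many-fold stronger hits); observed effects
with Wald-scale noise $\sigma = (2p(1-p)\,n_{\mathrm{eff}})^{-1/2}$,
where $n_{\mathrm{eff}} = nK(1-K)$ on the log-odds scale for
case-control traits; and outcome effects $\theta\,\beta_{Xj}$ plus a
pleiotropy term. Directional pleiotropy acts in the frame of the
exposure-increasing allele — the frame in which MR-Egger's intercept is
defined; with sign-random allele coding an outcome-frame shift would
cancel under orientation and be invisible to every estimator. Pleiotropic
effects are drawn independently of instrument strength, so InSIDE holds;
an InSIDE-violating mode is deliberately left out.

The reference conditions used by the generator defaults are a binary
exposure of ~403k individuals (case fraction 0.626) whose instruments
explain 5.75 % of variance, against a case-control outcome of ~455k at
K = 0.158 — the scale of current sleep-trait and retinal-disease
meta-analyses. `simulate_study()` writes a 7-exposure × 5-outcome
fixture at those sample sizes with desk-scale instrument counts
(19/10/6/39/32/7/11); each exposure's pooled $R^2$ is derived from a
mean per-variant F of 60, keeping simulated instruments comfortably
clear of the significance boundary the way real post-selection lists
are, so that even the 6-instrument exposure survives selection intact.

The generator works at summary level only. It does **not** simulate
genotypes, sample overlap between the two GWAS, LD between instruments
(LD enters only through the separate block-panel fixture), allele
frequency mismatches between studies, winner's curse in the exposure
effects, or population stratification. Passing tests therefore
demonstrate correctness of the estimators and pipeline under the stated
generating model, not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* Ties in the weighted-mode bandwidth: $h = \phi \cdot 0.9 \cdot
  \min(\mathrm{sd}, \mathrm{mad}) \cdot k^{-1/5}$ with the
  normal-consistent MAD; when the MAD collapses to zero under heavy
  ties the SD substitutes, and if all ratios coincide the common ratio
  is returned directly. The density is scanned on a 10,001-point grid
  spanning the ratio range ± 3 bandwidths.
* A single instrument degrades IVW to the Wald ratio with a logged
  note; `estimate_all()` reports methods whose preconditions fail
  (k < 3 for Egger/median/mode, k < 4 for MR-PRESSO) as not-applicable
  rows rather than aborting.
* Weighted-median interpolation uses cumulative midpoint percentiles
  $s_j = \mathrm{cum}_j - w_j/2$ with boundary extrapolation clamped to
  the extreme ratios.
* Zero exposure effects are rejected as degenerate before any ratio is
  formed (the F ≥ 10 filter removes them upstream in practice).
* All simulation entry points take explicit seeds and restore the
  caller's RNG state, so embedding them in a larger seeded script never
  perturbs it.

## Simulation sizes used by the test suite

The suite verifies operating characteristics at desk scale: type-I
error of IVW from 2000 null replicates (k = 30); parameter recovery
from 200 replicates (k = 50, continuous exposure, pooled R² = 0.1 —
instrument-strength heterogeneity $I^2_{GX} \approx 0.99$, the regime
in which MR-Egger's NOME-sensitive slope is near-unbiased alongside the
other three estimators); Egger intercept recovery and weighted-median
contamination from 500 replicates; MR-PRESSO detection from 100
runs at 1000 null draws and global size from 1000 runs at 500 draws;
Steiger direction from 200 replicates. These sizes give Monte-Carlo
error comfortably inside the asserted bands while keeping the full
suite under a minute of simulation time.

## Known limitations

* MR-RAPS, simple/penalized mode variants, MVMR-Egger and
  instrument-strength Q statistics for MVMR are not implemented.
* No LD computation from genotypes and no reference-panel retrieval:
  LD matrices and proxy tables are always supplied by the user or the
  simulator.
* The Steiger binary-trait $R^2$ and the case-control power formula are
  normal approximations; both are flagged and cross-checked against
  Monte-Carlo oracles in the tests, but liability-scale refinements are
  out of scope.
* Coordinate lift-over and variant-identifier resolution are the
  caller's responsibility; tables are matched on identifiers as given.
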