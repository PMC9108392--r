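# summr — two-sample Mendelian randomization from GWAS summary statistics

`summr` is an R package for complete two-sample Mendelian randomization
(MR) studies driven entirely by GWAS summary statistics. It is aimed at
genetic epidemiologists who want a self-contained, fully testable pipeline
covering every stage of a bidirectional multi-trait analysis — for
example, asking whether genetic liability to sleep or chronic-pain traits
causally influences neurodegenerative disease risk — without individual-
level data.

## What it does

Given per-variant association tables (identifier, alleles, effect-allele
frequency, effect size, SE, p-value, sample sizes) for an exposure and an
outcome measured in non-overlapping samples:

1. **Instrument preparation** — genome-wide-significant variant selection
   (p < 5×10⁻⁸, strict), per-variant strength scoring with
   F = (β/se)² and variance explained R² = 2β²·EAF·(1−EAF), greedy LD
   clumping (10,000 kb window, r² < 0.001 against a user-supplied LD
   panel), the weak-instrument filter (F ≥ 10), and allele harmonization
   with strand-flip resolution, proxy substitution (r² > 0.8) and
   configurable palindromic-variant policies.
2. **Causal estimation** — the four standard estimators, each consuming
   the harmonized effects (β̂ₓ, seₓ, β̂ᵧ, seᵧ):
   * **IVW** (primary): β̂ = Σβ̂ₓβ̂ᵧseᵧ⁻² / Σβ̂ₓ²seᵧ⁻², the
     inverse-variance-weighted combination of the Wald ratios
     θⱼ = β̂ᵧⱼ/β̂ₓⱼ, with a multiplicative random-effects SE floored at
     the fixed-effect scale;
   * **MR-Egger**: weighted regression with an intercept that estimates
     average directional pleiotropy (intercept deviation test on
     t(k−2));
   * **weighted median**: interpolated 50th weight percentile of the
     ordered Wald ratios, robust to <50 % invalid weight;
   * **weighted mode** (NOME weights): argmax of the weighted Gaussian
     kernel density of the ratios.
   Binary outcomes are reported as OR per exposure SD (continuous
   exposures) or per unit log-odds (binary exposures).
3. **Diagnostics** — Cochran's Q and I² for IVW, Rucker's Q′ for Egger
   with the Q′/Q ratio, the MR-PRESSO global and per-variant outlier
   test, leave-one-out / leave-one-group-out re-estimation, and
   plot-ready scatter/funnel tables.
4. **Directionality and power** — the Steiger test comparing instrument
   variance explained in exposure versus outcome via Fisher's z, a
   binary-outcome power calculator (power = Φ(√(N·R²·K(1−K))·|ln OR| −
   z₁₋α/₂)), detectable-effect search, and Bonferroni bookkeeping.
5. **Multivariable MR** — joint IVW regression across correlated
   co-exposures to estimate direct effects.
6. **Synthetic data** — a seeded summary-statistic generator with known
   ground truth (causal effect, pleiotropy mode, instrument strength),
   block LD panels, correlated multi-exposure systems and a full
   ready-to-run study fixture, so every stage above is verifiable at
   desk scale.

## Worked example

```r
library(summr)

truth <- sim_truth(beta_causal = 0.2, n_instruments = 40, seed = 2025)
pair  <- simulate_gwas_pair(truth)          # exposure + outcome tables
instr <- select_instruments(pair$exposure, p_threshold = 5e-8)
h     <- harmonize(instr, pair$outcome)
estimate_all(h, n_boot = 1000, seed = 1)
```

```
  method nsnp  beta     se     pval   or or_ci_low or_ci_high
1    ivw   40 0.201 0.0165 4.47e-34 1.22      1.18       1.26
2  egger   40 0.284 0.0834 1.59e-03 1.33      1.12       1.57
3    wme   40 0.205 0.0229 3.45e-19 1.23      1.17       1.28
4    mbe   40 0.274 0.0538 3.61e-07 1.32      1.18       1.46
```

All four estimators recover the simulated causal log-odds of 0.2 (IVW
0.201, OR 1.22 per exposure unit). The diagnostics agree that the
instruments are well behaved:

```r
heterogeneity_report(h, presso_n_sim = 1000, seed = 2)
#> Cochran Q = 33.66 (df 39, p = 0.712), I2 = 0.0%
#> Egger intercept p = 0.316, Rucker Q'/Q = 0.969, PRESSO global p 0.748

steiger_test(h)
#> r2_exposure = 0.0608 vs r2_outcome = 0.0030, direction_ok = TRUE
```

The instruments explain ~6 % of exposure variance but only 0.3 % of the
outcome, so the exposure → outcome orientation is supported.

A whole 7-exposure × 5-outcome study runs from one YAML config:

```r
cfg <- simulate_study("study_dir", seed = 1)   # writes 12 TSVs + config
res <- run_study(cfg)                          # 35 results, Bonferroni 0.05/35
write_results_table(results_table(res), "study_dir/results.tsv")
```

A thin CLI with `simulate-study`, `run`, `rerun-sensitivity` and
`power-grid` subcommands is installed at `inst/cli/mr-study.R`.

## Scope notes

Cross-trait LD-score regression, live Phenoscanner/GTEx queries and
1000 Genomes proxy lookup are out of scope: external knowledge enters
only as user-supplied exclusion lists, groupings, proxy tables and LD
matrices. See the methods vignette (`vignettes/two-sample-mr.Rmd`) for
the statistical background, parameter defaults and known limitations.
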