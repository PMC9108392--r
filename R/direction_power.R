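# Steiger directionality, binary-outcome power, detectable effect sizes,
# and multiple-testing bookkeeping.

#' Steiger test of directionality
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome.  Exposure-side r2 is
#' `sum(2 bx^2 eaf (1-eaf))`; outcome-side r2 uses the same formula on the
#' outcome associations when outcome EAFs are available, else the
#' per-variant F approximation `r2_j = F_j / (F_j + n_y - 2)`.  The pooled
#' r2 values are converted to correlations and compared with Fisher's z:
#' `z = (atanh(r_x) - atanh(r_y)) / sqrt(1/(n_x-3) + 1/(n_y-3))`, two
#' sided.  A causal interpretation in the exposure -> outcome direction
#' requires `r2_exposure > r2_outcome` (strict).
#'
#' For binary traits the r2 is computed on the observed log-odds scale via
#' the same formula, an approximation flagged in the result.
#'
#' @param h An `mr_harmonized` set with exposure EAFs.
#' @param n_x,n_y Effective sample sizes (defaults: the set's recorded
#'   medians).
#' @param use_eaf_y Use outcome EAFs when present (default TRUE).
#' @return List of class `steiger_result` with `r2_exposure`,
#'   `r2_outcome`, `direction_ok`, `zval`, `pval`, `n_exposure`,
#'   `n_outcome`, `approx_binary_r2`.
#' @export
steiger_test <- function(h, n_x = NULL, n_y = NULL, use_eaf_y = TRUE) {
  n_x <- n_x %||% h$n_x
  n_y <- n_y %||% h$n_y
  if (is.na(n_x) || is.na(n_y) || n_x <= 3 || n_y <= 3)
    stop("steiger_test needs sample sizes > 3 for both traits")
  if (all(is.na(h$eaf_x)))
    stop("steiger_test requires exposure effect-allele frequencies")
  r2x <- sum(2 * h$bx^2 * h$eaf_x * (1 - h$eaf_x))
  if (use_eaf_y && !all(is.na(h$eaf_y))) {
    r2y <- sum(2 * h$by^2 * h$eaf_y * (1 - h$eaf_y), na.rm = TRUE)
  } else {
    fy <- (h$by / h$sey)^2
    r2y <- sum(fy / (fy + n_y - 2))
  }
  r2x <- min(r2x, 1 - 1e-12)
  r2y <- min(r2y, 1 - 1e-12)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  structure(list(r2_exposure = r2x, r2_outcome = r2y,
                 n_exposure = n_x, n_outcome = n_y,
                 direction_ok = r2x > r2y, zval = z,
                 pval = two_sided_p(z),
                 approx_binary_r2 = identical(h$outcome_type, "binary")),
            class = "steiger_result")
}

#' Specify a binary-outcome power calculation
#'
#' @param n Outcome GWAS sample size.
#' @param case_fraction Proportion of cases K in (0, 1).
#' @param r2 Pooled variance in the exposure explained by the instruments,
#'   in (0, 1).
#' @param alpha Significance level (default the 0.05/35 family threshold).
#' @param power_target Target power in (0, 1) for detectable-effect
#'   searches (default 0.8).
#' @return A `power_spec` list.
#' @export
power_spec <- function(n, case_fraction, r2, alpha = 0.05 / 35,
                       power_target = 0.8) {
  stopifnot(n > 0, case_fraction > 0, case_fraction < 1,
            r2 > 0, r2 < 1, alpha > 0, alpha < 1,
            power_target > 0, power_target < 1)
  structure(list(n = n, case_fraction = case_fraction, r2 = r2,
                 alpha = alpha, power_target = power_target),
            class = "power_spec")
}

#' Power to detect a causal odds ratio
#'
#' Normal approximation for a binary outcome: with `beta = ln(OR)` the
#' square-root noncentrality is
#' `sqrt(n r2 K (1 - K)) |beta|` and
#' `power = Phi(sqrt(NCP) - z_{1-alpha/2})`.
#'
#' @param spec A [power_spec()].
#' @param odds_ratio Causal odds ratio per exposure unit (> 0).
#' @return Power in (0, 1).
#' @export
power_binary <- function(spec, odds_ratio) {
  if (!inherits(spec, "power_spec")) stop("spec must be a power_spec")
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0")
  b <- log(odds_ratio)
  ncp_sqrt <- sqrt(spec$n * spec$r2 * spec$case_fraction *
                     (1 - spec$case_fraction)) * abs(b)
  stats::pnorm(ncp_sqrt - stats::qnorm(1 - spec$alpha / 2))
}

#' Smallest detectable odds ratio at target power
#'
#' Bisection on `beta = ln(OR)` until [power_binary()] reaches
#' `spec$power_target` within 1e-6.  The risky and protective solutions
#' are reciprocal since power depends on `|beta|` only.
#'
#' @param spec A [power_spec()] with `power_target > alpha`.
#' @param side `"risky"` (OR > 1) or `"protective"` (OR < 1).
#' @return The detectable odds ratio.
#' @export
detectable_effect <- function(spec, side = c("risky", "protective")) {
  side <- match.arg(side)
  if (spec$power_target <= spec$alpha)
    stop("power_target must exceed alpha")
  f <- function(b) power_binary(spec, exp(b)) - spec$power_target
  upper <- 1
  while (f(upper) < 0 && upper < 1e6) upper <- upper * 2
  if (f(upper) < 0) stop("detectable effect search failed to bracket")
  b <- stats::uniroot(f, c(0, upper), tol = 1e-10)$root
  if (side == "risky") exp(b) else exp(-b)
}

#' Detectable-effect grid across outcomes and instrument strengths
#'
#' Mirrors the supplementary power-table layout: for each outcome and each
#' pooled-r2 value, the risky and protective odds ratios detectable at the
#' target power.
#'
#' @param outcomes Data.frame with columns `outcome`, `n`,
#'   `case_fraction`.
#' @param r2_values Pooled variance-explained values (e.g. 0.0025-0.075).
#' @param alpha Significance level (default 0.05/35).
#' @param power_target Target power (default 0.8).
#' @return Data.frame with columns `outcome`, `r2`,
#'   `detectable_or_risky`, `detectable_or_protective`.
#' @export
power_grid <- function(outcomes, r2_values, alpha = 0.05 / 35,
                       power_target = 0.8) {
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    ors <- vapply(r2_values, function(r2) {
      sp <- power_spec(outcomes$n[i], outcomes$case_fraction[i], r2,
                       alpha, power_target)
      detectable_effect(sp, "risky")
    }, numeric(1))
    data.frame(outcome = outcomes$outcome[i], r2 = r2_values,
               detectable_or_risky = ors,
               detectable_or_protective = 1 / ors,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of independent tests (>= 1).
#' @param alpha_family Family-wise significance level.
#' @return `alpha_family / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha_family = 0.05) {
  stopifnot(n_tests >= 1)
  alpha_family / n_tests
}
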