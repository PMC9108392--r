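# The four causal estimators: inverse-variance weighted, MR-Egger,
# weighted median and weighted mode (NOME-weighted), plus per-variant
# Wald ratios and a one-call wrapper.
#
# All methods consume an mr_harmonized set and return an mr_estimate row:
# a one-row data.frame with method, nsnp, beta, se, ci_low, ci_high, pval,
# OR-scale columns for binary outcomes, and Egger intercept fields.

Z95 <- stats::qnorm(0.975)

new_estimate <- function(method, k, beta, se, ci_low, ci_high, pval,
                         outcome_type = "continuous",
                         intercept = NA, intercept_se = NA,
                         intercept_pval = NA, note = NA_character_) {
  binary <- identical(outcome_type, "binary")
  out <- data.frame(method = method, nsnp = k, beta = beta, se = se,
                    ci_low = ci_low, ci_high = ci_high, pval = pval,
                    or = if (binary) exp(beta) else NA_real_,
                    or_ci_low = if (binary) exp(ci_low) else NA_real_,
                    or_ci_high = if (binary) exp(ci_high) else NA_real_,
                    egger_intercept = intercept,
                    intercept_se = intercept_se,
                    intercept_pval = intercept_pval,
                    note = note, stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

#' Per-variant Wald ratio estimates
#'
#' `theta_j = by_j / bx_j` with first-order standard error
#' `sey_j / |bx_j|`.
#'
#' @param h An `mr_harmonized` set with no zero exposure effects.
#' @return List with numeric vectors `theta` and `theta_se`.
#' @export
wald_ratios <- function(h) {
  if (any(h$bx == 0)) {
    stop(errorCondition("degenerate instrument with bx = 0",
                        class = c("summr_degenerate_instrument", "error",
                                  "condition")))
  }
  list(theta = h$by / h$bx, theta_se = h$sey / abs(h$bx))
}

#' Inverse-variance-weighted causal estimate
#'
#' The primary estimator: weighted regression of outcome on exposure
#' effects through the origin, `beta = sum(bx by / sey^2) / sum(bx^2 /
#' sey^2)`, algebraically the fixed-effect inverse-variance meta-analysis
#' of the Wald ratios.  Under the default `multiplicative_floored` error
#' model the fixed-effect SE `(sum(bx^2/sey^2))^-1/2` is inflated by
#' `max(1, sqrt(Q/(k-1)))` with Cochran's Q, so it never undercuts the
#' fixed-effect SE.  p-values are two-sided normal; the 95% CI is
#' `beta +/- 1.96 SE`.  A single instrument degrades to the Wald ratio
#' (method `"wald"`) with a note.
#'
#' @param h An `mr_harmonized` set.
#' @param re_model `"multiplicative_floored"` (default) or `"fixed"`.
#' @return An `mr_estimate` row.
#' @export
mr_ivw <- function(h, re_model = c("multiplicative_floored", "fixed")) {
  re_model <- match.arg(re_model)
  k <- nsnp(h)
  if (k == 0) stop("empty harmonized set")
  w <- 1 / h$sey^2
  beta <- sum(h$bx * h$by * w) / sum(h$bx^2 * w)
  se <- sqrt(1 / sum(h$bx^2 * w))
  method <- "ivw"
  note <- NA_character_
  if (k == 1) {
    method <- "wald"
    note <- "single instrument: Wald ratio reported in place of IVW"
    message(note)
  } else if (re_model == "multiplicative_floored") {
    theta <- h$by / h$bx
    q <- sum((h$bx / h$sey)^2 * (theta - beta)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  p <- two_sided_p(beta / se)
  new_estimate(method, k, beta, se, beta - Z95 * se, beta + Z95 * se, p,
               h$outcome_type, note = note)
}

#' MR-Egger regression
#'
#' Orients every variant so its exposure effect is non-negative (negating
#' bx and by jointly), then fits weighted least squares of by on bx with
#' an intercept and weights `1/sey^2`.  The slope is the causal estimate;
#' the intercept estimates average directional pleiotropy, with the
#' intercept deviation test on t(k-2).  Coefficient SEs use the
#' multiplicative residual inflation floored at the fixed-effect scale,
#' and the 95% CI uses the t(k-2) quantile.
#'
#' @param h An `mr_harmonized` set with at least 3 variants.
#' @return An `mr_estimate` row carrying `egger_intercept`,
#'   `intercept_se` and `intercept_pval`.
#' @export
mr_egger <- function(h) {
  k <- nsnp(h)
  if (k < 3) {
    stop(errorCondition("MR-Egger requires at least 3 instruments",
                        class = c("summr_insufficient_instruments", "error",
                                  "condition")))
  }
  s <- ifelse(h$bx < 0, -1, 1)
  bx <- h$bx * s
  by <- h$by * s
  w <- 1 / h$sey^2
  X <- cbind(intercept = 1, bx = bx)
  fit <- stats::lm.wfit(X, by, w)
  # fixed-dispersion covariance, then residual inflation floored at 1 so
  # the SEs never undercut the known-sey scale
  V <- chol2inv(chol(crossprod(X * sqrt(w))))
  sigma2 <- sum(w * fit$residuals^2) / (k - 2)
  infl <- max(1, sqrt(sigma2))
  slope <- fit$coefficients[["bx"]]
  slope_se <- sqrt(V[2, 2]) * infl
  int <- fit$coefficients[["intercept"]]
  int_se <- sqrt(V[1, 1]) * infl
  tq <- stats::qt(0.975, df = k - 2)
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), df = k - 2)
  int_p <- 2 * stats::pt(-abs(int / int_se), df = k - 2)
  new_estimate("egger", k, slope, slope_se,
               slope - tq * slope_se, slope + tq * slope_se,
               max(slope_p, .Machine$double.xmin), h$outcome_type,
               intercept = int, intercept_se = int_se,
               intercept_pval = max(int_p, .Machine$double.xmin))
}

# Point estimate of the weighted median of Wald ratios: order the ratios,
# take NOME weights bx^2/sey^2 normalized to 1, and interpolate the
# ordered ratios at cumulative midpoint percentile 0.5.
weighted_median_point <- function(bx, by, sey) {
  theta <- by / bx
  w <- bx^2 / sey^2
  w <- w / sum(w)
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- cumsum(w) - w / 2
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

boot_se <- function(h, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (n_boot < 100)
    warning("n_boot < 100 gives unstable bootstrap standard errors",
            call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  k <- length(h$bx)
  est <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, h$bx, h$sex)
    by <- stats::rnorm(k, h$by, h$sey)
    bx[bx == 0] <- .Machine$double.eps
    point_fun(bx, by, h$sey)
  }, numeric(1))
  stats::sd(est)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Weighted median causal estimate
#'
#' Orders the Wald ratios, weights each by `bx^2/sey^2` (normalized), and
#' linearly interpolates the ordered ratios at the cumulative midpoint
#' percentile 0.5.  Consistent when under half the weight lies on invalid
#' instruments.  The SE is the standard deviation of the estimate over
#' `n_boot` parametric-bootstrap replicates drawing
#' `bx* ~ N(bx, sex)`, `by* ~ N(by, sey)`; seeded and reproducible.
#'
#' @param h An `mr_harmonized` set with at least 3 variants.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_estimate` row.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  k <- nsnp(h)
  if (k < 3) {
    stop(errorCondition("weighted median requires at least 3 instruments",
                        class = c("summr_insufficient_instruments", "error",
                                  "condition")))
  }
  beta <- weighted_median_point(h$bx, h$by, h$sey)
  se <- boot_se(h, weighted_median_point, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else two_sided_p(beta / se)
  new_estimate("wme", k, beta, se, beta - Z95 * se, beta + Z95 * se, p,
               h$outcome_type)
}

weighted_mode_point <- function(bx, by, sey, phi = 1, grid_points = 10001) {
  theta <- by / bx
  w <- bx^2 / sey^2
  w <- w / sum(w)
  k <- length(theta)
  spread <- min(stats::sd(theta), stats::mad(theta))
  if (spread == 0) spread <- stats::sd(theta)  # mad collapses under ties
  bw <- phi * 0.9 * spread * k^(-1 / 5)
  if (!is.finite(bw) || bw == 0) return(theta[1])
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw,
              length.out = grid_points)
  dens <- colSums(w * stats::dnorm(outer(theta, grid, "-") / bw))
  grid[which.max(dens)]
}

#' Weighted mode causal estimate (NOME weights)
#'
#' Maximizes the weighted Gaussian kernel density of the Wald ratios with
#' NOME weights `bx^2/sey^2` and bandwidth
#' `phi * 0.9 * min(sd, mad) * k^(-1/5)` (mad on the normal-consistent
#' scale), scanning a dense grid of `grid_points` points spanning
#' `[min(theta) - 3h, max(theta) + 3h]`.  If all ratios coincide the common
#' ratio is returned.  SE by the same parametric bootstrap as the weighted
#' median.
#'
#' @param h An `mr_harmonized` set with at least 3 variants.
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the SE).
#' @param seed Optional integer seed for the bootstrap.
#' @param grid_points Density grid resolution (default 10001).
#' @return An `mr_estimate` row.
#' @export
mr_weighted_mode <- function(h, phi = 1, n_boot = 1000, seed = NULL,
                             grid_points = 10001) {
  k <- nsnp(h)
  if (k < 3) {
    stop(errorCondition("weighted mode requires at least 3 instruments",
                        class = c("summr_insufficient_instruments", "error",
                                  "condition")))
  }
  if (phi <= 0) stop("phi must be > 0")
  beta <- weighted_mode_point(h$bx, h$by, h$sey, phi, grid_points)
  se <- boot_se(h, function(bx, by, sey)
    weighted_mode_point(bx, by, sey, phi, grid_points), n_boot, seed)
  p <- if (is.na(se)) NA_real_ else two_sided_p(beta / se)
  new_estimate("mbe", k, beta, se, beta - Z95 * se, beta + Z95 * se, p,
               h$outcome_type)
}

#' Run all applicable causal estimators
#'
#' Runs IVW (or the Wald ratio for a single instrument), MR-Egger, the
#' weighted median and the weighted mode, skipping any method whose
#' instrument-count precondition fails; failures are reported as
#' not-applicable rows (NA estimates with the failure message in `note`),
#' never an aborted run.  Deterministic given `seed`.
#'
#' @param h An `mr_harmonized` set.
#' @param re_model IVW error model, see [mr_ivw()].
#' @param n_boot,seed,phi Passed to the bootstrap-based estimators.
#' @return An `mr_estimate` data.frame with one row per method.
#' @export
estimate_all <- function(h, re_model = c("multiplicative_floored", "fixed"),
                         n_boot = 1000, seed = NULL, phi = 1) {
  re_model <- match.arg(re_model)
  runs <- list(
    ivw = function() mr_ivw(h, re_model),
    egger = function() mr_egger(h),
    wme = function() mr_weighted_median(h, n_boot, seed),
    mbe = function() mr_weighted_mode(h, phi, n_boot,
                                      if (is.null(seed)) NULL else seed + 1)
  )
  rows <- lapply(names(runs), function(m) {
    tryCatch(runs[[m]](), error = function(e) {
      new_estimate(m, nsnp(h), NA_real_, NA_real_, NA_real_, NA_real_,
                   NA_real_, h$outcome_type,
                   note = paste0("not applicable: ", conditionMessage(e)))
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mr_estimate", "data.frame")
  out
}
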