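# Heterogeneity statistics, the MR-PRESSO global/outlier test, leave-out
# re-estimation, and plot-ready scatter/funnel tables.

#' Cochran's Q heterogeneity test for the IVW fit
#'
#' With weights `w_j = (bx_j/sey_j)^2` and Wald ratios `theta_j`,
#' `Q = sum w_j (theta_j - theta_ivw)^2` on k-1 degrees of freedom;
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param h An `mr_harmonized` set with at least 2 variants.
#' @param beta Optional IVW estimate to test around; defaults to the
#'   fixed-effect IVW estimate of `h`.
#' @return List with `q`, `q_df`, `q_pval`, `i2` (percent).
#' @export
cochran_q <- function(h, beta = NULL) {
  k <- nsnp(h)
  if (k < 2) stop("Cochran's Q requires at least 2 instruments")
  if (is.null(beta)) {
    w <- 1 / h$sey^2
    beta <- sum(h$bx * h$by * w) / sum(h$bx^2 * w)
  }
  theta <- h$by / h$bx
  wq <- (h$bx / h$sey)^2
  q <- sum(wq * (theta - beta)^2)
  df <- k - 1
  list(q = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = max(0, (q - df) / q) * 100)
}

#' Rucker's Q heterogeneity test for the MR-Egger fit
#'
#' Weighted residual sum of squares of the Egger regression on the
#' bx >= 0 oriented data, `Q' = sum sey^-2 (by - a - b bx)^2`, on k-2
#' degrees of freedom.  `Q' <= Q` always (the intercept can only reduce
#' the weighted RSS); the ratio `Q'/Q` diagnoses how much heterogeneity
#' the intercept absorbs.
#'
#' @param h An `mr_harmonized` set with at least 3 variants.
#' @param egger_fit Optional `mr_estimate` from [mr_egger()]; refit if
#'   omitted.
#' @return List with `rucker_q`, `rucker_df`, `rucker_pval`,
#'   `rucker_ratio`.
#' @export
rucker_q <- function(h, egger_fit = NULL) {
  k <- nsnp(h)
  if (k < 3) stop("Rucker's Q requires at least 3 instruments")
  if (is.null(egger_fit)) egger_fit <- mr_egger(h)
  s <- ifelse(h$bx < 0, -1, 1)
  bx <- h$bx * s
  by <- h$by * s
  resid <- by - egger_fit$egger_intercept - egger_fit$beta * bx
  rq <- sum(resid^2 / h$sey^2)
  q <- cochran_q(h)$q
  list(rucker_q = rq, rucker_df = k - 2,
       rucker_pval = stats::pchisq(rq, k - 2, lower.tail = FALSE),
       rucker_ratio = rq / q)
}

# Leave-one-out IVW estimates and per-variant weighted residual terms, in
# O(k) via running sums.  Rows of bx/by may be a matrix (replicates).
presso_residual_terms <- function(bx, by, w) {
  if (is.matrix(bx)) {
    t1 <- bx * by * rep(w, each = nrow(bx))
    t2 <- bx^2 * rep(w, each = nrow(bx))
    theta_loo <- (rowSums(t1) - t1) / (rowSums(t2) - t2)
    rep(w, each = nrow(bx)) * (by - theta_loo * bx)^2
  } else {
    t1 <- bx * by * w
    t2 <- bx^2 * w
    theta_loo <- (sum(t1) - t1) / (sum(t2) - t2)
    w * (by - theta_loo * bx)^2
  }
}

#' MR-PRESSO global and outlier test
#'
#' The observed residual sum of squares is
#' `RSS = sum_j w_j (by_j - theta_(-j) bx_j)^2`, with `theta_(-j)` the IVW
#' estimate excluding variant j and `w_j = sey_j^-2`.  The null
#' distribution comes from `n_sim` parametric replicates drawing
#' `bx* ~ N(bx, sex)` and `by* ~ N(theta_(-j) bx_j, sey_j)`, with the
#' leave-one-out predictions recomputed inside each replicate.  The global
#' p-value is the proportion of simulated RSS at or above the observed
#' value, reported as "<1/n_sim" when no replicate exceeds it.  Per-variant
#' p-values compare the j-th residual terms and are Bonferroni-adjusted by
#' k; variants below `outlier_alpha` are flagged as outliers.
#'
#' @param h An `mr_harmonized` set with at least 4 variants.
#' @param n_sim Number of null replicates (default 1000).
#' @param seed Optional integer seed.
#' @param outlier_alpha Adjusted per-variant significance level
#'   (default 0.05).
#' @return List with `global_pval`, `global_pval_display`, `rss_obs`,
#'   `per_snp_pvals` (adjusted), `outlier_ids`, `n_sim`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  k <- nsnp(h)
  if (k < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  w <- 1 / h$sey^2
  res_obs <- presso_residual_terms(h$bx, h$by, w)
  rss_obs <- sum(res_obs)

  t1 <- h$bx * h$by * w
  t2 <- h$bx^2 * w
  theta_loo <- (sum(t1) - t1) / (sum(t2) - t2)

  bxs <- matrix(stats::rnorm(n_sim * k, mean = rep(h$bx, each = n_sim),
                             sd = rep(h$sex, each = n_sim)), n_sim, k)
  bys <- matrix(stats::rnorm(n_sim * k,
                             mean = rep(theta_loo * h$bx, each = n_sim),
                             sd = rep(h$sey, each = n_sim)), n_sim, k)
  res_sim <- presso_residual_terms(bxs, bys, w)
  rss_sim <- rowSums(res_sim)

  exceed <- sum(rss_sim >= rss_obs)
  global_pval <- exceed / n_sim
  display <- if (exceed == 0) sprintf("<%g", 1 / n_sim) else
    sprintf("%.4g", global_pval)

  per_raw <- colMeans(res_sim >= rep(res_obs, each = n_sim))
  per_adj <- pmin(1, per_raw * k)
  names(per_adj) <- h$snp
  list(global_pval = global_pval, global_pval_display = display,
       rss_obs = rss_obs, per_snp_pvals = per_adj,
       outlier_ids = h$snp[per_adj < outlier_alpha], n_sim = n_sim)
}

estimator_fun <- function(estimator) {
  switch(estimator,
         ivw = function(h) mr_ivw(h),
         egger = mr_egger,
         wme = function(h) mr_weighted_median(h, n_boot = 0),
         mbe = function(h) mr_weighted_mode(h, n_boot = 0),
         stop("unknown estimator: ", estimator))
}

#' Leave-one-out and leave-one-group-out re-estimation
#'
#' Without a grouping, drops each variant in turn and re-runs the chosen
#' estimator; with a grouping (named vector/list mapping variant id to a
#' group label) drops each group wholesale.  Every row must leave at
#' least 2 variants.
#'
#' @param h An `mr_harmonized` set.
#' @param grouping Optional named map snp id -> group label.
#' @param estimator One of `"ivw"`, `"egger"`, `"wme"`, `"mbe"`.
#' @return Data.frame with columns `left_out`, `nsnp_used`, `beta`, `se`,
#'   `pval`.
#' @export
leave_out <- function(h, grouping = NULL, estimator = "ivw") {
  fun <- estimator_fun(estimator)
  if (is.null(grouping)) {
    labels <- h$snp
    drops <- lapply(seq_along(h$snp), function(i) i)
  } else {
    grouping <- unlist(grouping)
    labels <- unique(grouping[names(grouping) %in% h$snp])
    drops <- lapply(labels, function(g)
      which(h$snp %in% names(grouping)[grouping == g]))
  }
  rows <- lapply(seq_along(labels), function(i) {
    idx <- drops[[i]]
    remaining <- setdiff(seq_along(h$snp), idx)
    if (length(remaining) < 2) {
      stop(errorCondition(
        sprintf("leaving out '%s' leaves fewer than 2 instruments",
                labels[i]),
        class = c("summr_group_exhausts_set", "error", "condition")))
    }
    est <- suppressMessages(fun(subset_harmonized(h, remaining)))
    data.frame(left_out = labels[i], nsnp_used = length(remaining),
               beta = est$beta, se = est$se, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot-ready scatter and funnel tables
#'
#' The scatter table pairs each variant's exposure and outcome effects
#' with SEs; `scatter_lines` carries one (slope, intercept) row per
#' method (intercept 0 except MR-Egger).  The funnel table holds the Wald
#' ratios against their precisions `1/theta_se`, with vertical reference
#' lines at each method's estimate.
#'
#' @param h An `mr_harmonized` set.
#' @param estimates An `mr_estimate` data.frame from [estimate_all()].
#' @return List of data.frames `scatter`, `scatter_lines`, `funnel`,
#'   `funnel_lines`.
#' @export
scatter_funnel_data <- function(h, estimates) {
  if (nrow(estimates) == 0) stop("estimates must be non-empty")
  wr <- wald_ratios(h)
  list(
    scatter = data.frame(snp = h$snp, bx = h$bx, by = h$by,
                         sex = h$sex, sey = h$sey, stringsAsFactors = FALSE),
    scatter_lines = data.frame(
      method = estimates$method, slope = estimates$beta,
      intercept = ifelse(estimates$method == "egger",
                         estimates$egger_intercept, 0),
      stringsAsFactors = FALSE),
    funnel = data.frame(snp = h$snp, theta = wr$theta,
                        precision = 1 / wr$theta_se, stringsAsFactors = FALSE),
    funnel_lines = data.frame(method = estimates$method,
                              beta = estimates$beta, stringsAsFactors = FALSE)
  )
}

#' Full heterogeneity and pleiotropy report
#'
#' Bundles Cochran's Q, Rucker's Q, the Egger intercept deviation test and
#' the MR-PRESSO global test for one harmonized set.  Components whose
#' instrument-count preconditions fail are returned as `NA` with a note.
#'
#' @param h An `mr_harmonized` set.
#' @param egger_fit Optional precomputed [mr_egger()] row.
#' @param presso_n_sim MR-PRESSO replicates (default 1000).
#' @param seed Optional seed for MR-PRESSO.
#' @return List of class `heterogeneity_report`.
#' @export
heterogeneity_report <- function(h, egger_fit = NULL, presso_n_sim = 1000,
                                 seed = NULL) {
  notes <- character()
  grab <- function(expr) tryCatch(expr, error = function(e) {
    notes <<- c(notes, conditionMessage(e))
    NULL
  })
  cq <- grab(cochran_q(h))
  if (is.null(egger_fit)) egger_fit <- grab(mr_egger(h))
  rq <- grab(rucker_q(h, egger_fit))
  pr <- grab(mr_presso(h, n_sim = presso_n_sim, seed = seed))
  structure(list(
    q = cq$q %||% NA_real_, q_df = cq$q_df %||% NA_integer_,
    q_pval = cq$q_pval %||% NA_real_, i2 = cq$i2 %||% NA_real_,
    rucker_q = rq$rucker_q %||% NA_real_,
    rucker_df = rq$rucker_df %||% NA_integer_,
    rucker_pval = rq$rucker_pval %||% NA_real_,
    rucker_ratio = rq$rucker_ratio %||% NA_real_,
    intercept_pval = if (is.null(egger_fit)) NA_real_ else
      egger_fit$intercept_pval,
    presso_global_pval = pr$global_pval %||% NA_real_,
    presso_global_display = pr$global_pval_display %||% NA_character_,
    presso_outliers = pr$outlier_ids %||% character(),
    notes = notes), class = "heterogeneity_report")
}
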