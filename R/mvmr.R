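# Multivariable IVW: joint regression of outcome effects on several
# exposures' instrument effects, estimating direct effects adjusted for
# the co-exposures.

#' Construct a multivariable harmonized set from aligned arrays
#'
#' @param bx_matrix k x m matrix of exposure effects (one column per
#'   exposure), column names naming the exposures.
#' @param sex_matrix k x m matrix of matching standard errors.
#' @param by,sey Outcome effect and SE arrays of length k.
#' @param snp Optional variant identifiers.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param imputed Optional logical k x m matrix flagging entries imputed
#'   as zero-effect.
#' @return An `mr_multi` object.
#' @export
multi_harmonized_set <- function(bx_matrix, sex_matrix, by, sey,
                                 snp = NULL, outcome_type = "continuous",
                                 imputed = NULL) {
  bx_matrix <- as.matrix(bx_matrix)
  sex_matrix <- as.matrix(sex_matrix)
  k <- nrow(bx_matrix)
  m <- ncol(bx_matrix)
  stopifnot(m >= 1, nrow(sex_matrix) == k, ncol(sex_matrix) == m,
            length(by) == k, length(sey) == k)
  if (is.null(colnames(bx_matrix)))
    colnames(bx_matrix) <- paste0("exposure", seq_len(m))
  if (is.null(snp)) snp <- paste0("snp", seq_len(k))
  if (is.null(imputed))
    imputed <- matrix(FALSE, k, m, dimnames = dimnames(bx_matrix))
  structure(list(snp = snp, bx_matrix = bx_matrix, sex_matrix = sex_matrix,
                 by = by, sey = sey,
                 exposure_names = colnames(bx_matrix),
                 outcome_type = outcome_type, imputed = imputed,
                 dropped = data.frame(snp = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)),
            class = "mr_multi")
}

#' Assemble a multivariable harmonized set from instrument sets
#'
#' Pools the union of the exposures' (clumped) instruments, looks each
#' variant up in every exposure table and in the outcome, and aligns all
#' effects to the orientation of the first exposure table that carries
#' the variant (the harmonization rules of [harmonize()]).  A variant
#' missing from one exposure table is imputed as zero effect with that
#' table's median SE and flagged; a variant missing from the outcome, or
#' with irreconcilable alleles anywhere, is dropped with a reason.
#'
#' @param instrument_sets List of `instrument_set` objects (>= 2
#'   exposures).
#' @param exposure_tables List of the matching full `assoc_table`s, same
#'   order.
#' @param outcome An `assoc_table` for the outcome.
#' @param palindrome_policy,ambiguity_band As in [harmonize()].
#' @return An `mr_multi` object.
#' @export
build_multi_set <- function(instrument_sets, exposure_tables, outcome,
                            palindrome_policy = "drop_ambiguous",
                            ambiguity_band = c(0.42, 0.58)) {
  m <- length(instrument_sets)
  if (m < 2) stop("multivariable MR needs at least 2 exposures")
  stopifnot(length(exposure_tables) == m)
  exposure_names <- vapply(instrument_sets, attr, character(1),
                           "trait_name")

  union_snp <- character()
  ref_idx <- integer()  # which exposure table defines the orientation
  for (e in seq_len(m)) {
    new <- setdiff(instrument_sets[[e]]$snp, union_snp)
    union_snp <- c(union_snp, new)
    ref_idx <- c(ref_idx, rep(e, length(new)))
  }

  k <- length(union_snp)
  bx <- sex <- matrix(NA_real_, k, m,
                      dimnames = list(union_snp, exposure_names))
  imputed <- matrix(FALSE, k, m, dimnames = list(union_snp, exposure_names))
  by <- sey <- rep(NA_real_, k)
  drop_snp <- character(); drop_reason <- character()
  med_se <- vapply(exposure_tables, function(t)
    stats::median(t$se, na.rm = TRUE), numeric(1))

  keep <- logical(k)
  for (i in seq_len(k)) {
    ref_tab <- exposure_tables[[ref_idx[i]]]
    r <- match(union_snp[i], ref_tab$snp)
    ea <- ref_tab$effect_allele[r]; oa <- ref_tab$other_allele[r]
    eaf <- ref_tab$eaf[r]
    ok <- TRUE
    for (e in seq_len(m)) {
      j <- match(union_snp[i], exposure_tables[[e]]$snp)
      if (is.na(j)) {
        bx[i, e] <- 0
        sex[i, e] <- med_se[e]
        imputed[i, e] <- TRUE
        next
      }
      tab <- exposure_tables[[e]]
      al <- align_alleles(ea, oa, eaf, tab$effect_allele[j],
                          tab$other_allele[j], tab$eaf[j], tab$beta[j],
                          palindrome_policy, ambiguity_band)
      if (al$action == "drop") {
        ok <- FALSE
        drop_snp <- c(drop_snp, union_snp[i])
        drop_reason <- c(drop_reason,
                         paste0(al$reason, " (", exposure_names[e], ")"))
        break
      }
      bx[i, e] <- al$by
      sex[i, e] <- tab$se[j]
    }
    if (!ok) next
    j <- match(union_snp[i], outcome$snp)
    if (is.na(j)) {
      drop_snp <- c(drop_snp, union_snp[i])
      drop_reason <- c(drop_reason, "missing_in_outcome")
      next
    }
    al <- align_alleles(ea, oa, eaf, outcome$effect_allele[j],
                        outcome$other_allele[j], outcome$eaf[j],
                        outcome$beta[j], palindrome_policy, ambiguity_band)
    if (al$action == "drop") {
      drop_snp <- c(drop_snp, union_snp[i])
      drop_reason <- c(drop_reason, paste0(al$reason, " (outcome)"))
      next
    }
    by[i] <- al$by
    sey[i] <- outcome$se[j]
    keep[i] <- TRUE
  }

  if (sum(keep) == 0) {
    stop(errorCondition("multivariable harmonization left zero variants",
                        class = c("summr_harmonization_empty", "error",
                                  "condition")))
  }
  out <- multi_harmonized_set(bx[keep, , drop = FALSE],
                              sex[keep, , drop = FALSE],
                              by[keep], sey[keep], snp = union_snp[keep],
                              outcome_type = attr(outcome, "trait_type"),
                              imputed = imputed[keep, , drop = FALSE])
  out$dropped <- data.frame(snp = drop_snp, reason = drop_reason,
                            stringsAsFactors = FALSE)
  out
}

#' Multivariable IVW regression
#'
#' Weighted least squares of the outcome effects on all exposure-effect
#' columns jointly, without intercept, with weights `1/sey^2`.  Per
#' exposure, SEs carry the multiplicative residual inflation floored at
#' the fixed-dispersion scale; p-values are two-sided normal and binary
#' outcomes are reported on the OR scale too.  A rank-deficient design
#' (condition number above `kappa_max`) raises an error naming the most
#' collinear exposure pair.
#'
#' @param mh An `mr_multi` set with more variants than exposures.
#' @param kappa_max Collinearity threshold on the weighted design's
#'   condition number (default 1e8).
#' @return An `mr_estimate` data.frame, one row per exposure, with an
#'   `adjusted_for` column listing the co-exposures.
#' @export
mvmr_ivw <- function(mh, kappa_max = 1e8) {
  X <- mh$bx_matrix
  k <- nrow(X)
  m <- ncol(X)
  if (k <= m) stop("multivariable IVW needs more variants than exposures")
  w <- 1 / mh$sey^2
  Xw <- X * sqrt(w)
  kap <- kappa(Xw, exact = TRUE)
  if (kap > kappa_max) {
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop(errorCondition(
      sprintf("collinear exposures: %s and %s (condition number %.3g)",
              mh$exposure_names[worst[1]], mh$exposure_names[worst[2]], kap),
      class = c("summr_collinear_exposures", "error", "condition")))
  }
  fit <- stats::lm.wfit(X, mh$by, w)
  coefs <- fit$coefficients
  XtWX_inv <- chol2inv(chol(crossprod(Xw)))
  base_se <- sqrt(diag(XtWX_inv))
  sigma2 <- sum(w * fit$residuals^2) / (k - m)
  infl <- max(1, sqrt(sigma2))
  se <- base_se * infl
  rows <- lapply(seq_len(m), function(e) {
    est <- new_estimate("mvmr_ivw", k, coefs[e], se[e],
                        coefs[e] - Z95 * se[e], coefs[e] + Z95 * se[e],
                        two_sided_p(coefs[e] / se[e]), mh$outcome_type)
    est$exposure <- mh$exposure_names[e]
    est$adjusted_for <- paste(mh$exposure_names[-e], collapse = ",")
    est
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mr_estimate", "data.frame")
  out
}
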