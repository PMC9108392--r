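# Instrument selection, strength scoring, LD clumping and allele
# harmonization against an outcome summary table.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Per-variant instrument strength
#'
#' The variance in the exposure explained by one variant is
#' `r2 = 2 * beta^2 * eaf * (1 - eaf)` (standardized trait, Hardy-Weinberg
#' genotype variance), and the strength F-statistic is the squared Wald
#' ratio `(beta / se)^2`.  Vectorized.
#'
#' @param beta,se Effect size and standard error (se > 0).
#' @param eaf Effect-allele frequency in (0, 1); `NA` yields `r2 = NA`.
#' @return List with numeric vectors `f` and `r2`.
#' @export
instrument_strength <- function(beta, se, eaf = NA) {
  if (any(!is.na(se) & se <= 0)) stop("se must be > 0")
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1)))
    stop("eaf must lie in (0, 1)")
  list(f = (beta / se)^2, r2 = 2 * beta^2 * eaf * (1 - eaf))
}

new_instrument_set <- function(df, exposure_name, trait_type, p_threshold) {
  structure(df,
            class = c("instrument_set", "assoc_table", "data.frame"),
            trait_name = exposure_name,
            trait_type = trait_type,
            p_threshold = p_threshold,
            pooled_r2 = if (all(is.na(df$r2))) NA_real_ else
              sum(df$r2, na.rm = TRUE))
}

#' Select genetic instruments for an exposure
#'
#' Retains variants with `pval` strictly below `p_threshold` (in input
#' order), annotates each with its F-statistic and variance explained via
#' [instrument_strength()], and by default excludes weak instruments with
#' F below `f_min`.  Pass `f_min = NULL` to defer the weak-instrument
#' filter (e.g. until after clumping, as [run_study()] does).
#'
#' @param table An `assoc_table`.
#' @param p_threshold Genome-wide significance cutoff (default 5e-8).
#' @param f_min Minimum F-statistic (default 10), or `NULL` to skip.
#' @return An `instrument_set`: the surviving rows plus columns `f_stat`
#'   and `r2`, with attribute `pooled_r2`.
#' @export
select_instruments <- function(table, p_threshold = 5e-8, f_min = 10) {
  if (nrow(table) == 0) stop("association table is empty")
  trait <- attr(table, "trait_name")
  keep <- table[table$pval < p_threshold, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop(errorCondition(
      sprintf("no instruments for trait '%s' at p < %g", trait, p_threshold),
      class = c("summr_empty_instruments", "error", "condition")))
  }
  st <- instrument_strength(keep$beta, keep$se, keep$eaf)
  keep$f_stat <- st$f
  keep$r2 <- st$r2
  if (!is.null(f_min)) {
    keep <- keep[keep$f_stat >= f_min, , drop = FALSE]
    if (nrow(keep) == 0) {
      stop(errorCondition(
        sprintf("no instruments for trait '%s' with F >= %g", trait, f_min),
        class = c("summr_empty_instruments", "error", "condition")))
    }
  }
  new_instrument_set(as.data.frame(keep), trait,
                     attr(table, "trait_type"), p_threshold)
}

#' Remove weak instruments
#'
#' Drops instruments whose F-statistic falls below `f_min`.  Applied by the
#' pipeline after clumping, so that removing a weak lead variant cannot
#' resurrect variants already pruned on LD.
#'
#' @param instruments An `instrument_set`.
#' @param f_min Minimum F-statistic (default 10).
#' @return The filtered `instrument_set`.
#' @export
filter_weak_instruments <- function(instruments, f_min = 10) {
  keep <- instruments[instruments$f_stat >= f_min, , drop = FALSE]
  if (nrow(keep) == 0) {
    stop(errorCondition(
      sprintf("no instruments for trait '%s' with F >= %g",
              attr(instruments, "trait_name"), f_min),
      class = c("summr_empty_instruments", "error", "condition")))
  }
  new_instrument_set(as.data.frame(keep), attr(instruments, "trait_name"),
                     attr(instruments, "trait_type"),
                     attr(instruments, "p_threshold"))
}

#' Construct an LD panel
#'
#' @param r2 Square symmetric matrix of pairwise r-squared values in
#'   \[0, 1\] with unit diagonal and variant identifiers as dimnames.
#' @param proxy_table Optional data.frame with columns `snp`, `proxy`,
#'   `r2` (proxies require r2 > 0.8).
#' @return An `ld_panel` list.
#' @export
ld_panel <- function(r2, proxy_table = NULL) {
  if (is.null(rownames(r2)) || is.null(colnames(r2)))
    stop("LD matrix needs variant identifiers as dimnames")
  if (!isSymmetric(unname(r2), tol = 1e-8)) stop("LD matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(r2 < 0 | r2 > 1)) stop("LD r2 values must lie in [0, 1]")
  if (!is.null(proxy_table)) {
    stopifnot(all(c("snp", "proxy", "r2") %in% names(proxy_table)))
    if (any(proxy_table$r2 <= 0.8))
      stop("proxy variants require r2 > 0.8")
  }
  structure(list(snp_ids = rownames(r2), r2 = r2, proxy_table = proxy_table),
            class = "ld_panel")
}

#' Read an LD matrix from delimited text
#'
#' Expects a square table with a header row and a leading identifier
#' column naming the variants.
#'
#' @param path File path.
#' @param proxy_path Optional 3-column TSV (snp, proxy, r2).
#' @return An `ld_panel`.
#' @export
read_ld_matrix <- function(path, proxy_path = NULL) {
  m <- utils::read.table(path, header = TRUE, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(m)
  proxies <- NULL
  if (!is.null(proxy_path)) {
    proxies <- utils::read.table(proxy_path, header = TRUE,
                                 stringsAsFactors = FALSE)
    names(proxies) <- c("snp", "proxy", "r2")
  }
  ld_panel(m, proxies)
}

#' Greedy LD clumping
#'
#' Sorts instruments by p-value (ascending), repeatedly keeps the most
#' significant remaining variant and discards all remaining variants whose
#' panel r-squared with it is at least `r2_threshold` *and* which lie
#' within `window_kb` of it.  Variants on different chromosomes or lacking
#' positions are compared on r-squared alone.  The kept variants are
#' returned in genomic order; the procedure is deterministic.
#'
#' @param instruments An `instrument_set`.
#' @param panel An `ld_panel` covering every instrument.
#' @param r2_threshold Independence cutoff (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @return The pruned `instrument_set`.
#' @export
ld_clump <- function(instruments, panel, r2_threshold = 0.001,
                     window_kb = 10000) {
  missing <- setdiff(instruments$snp, panel$snp_ids)
  if (length(missing) > 0) {
    stop(errorCondition(
      paste0("variants absent from LD panel: ",
             paste(missing, collapse = ", ")),
      class = c("summr_missing_in_panel", "error", "condition")))
  }
  ord <- order(instruments$pval)
  remaining <- ord
  kept <- integer()
  r2m <- panel$r2
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    r2v <- r2m[instruments$snp[lead], instruments$snp[remaining]]
    in_ld <- r2v >= r2_threshold
    same_chr <- !is.na(instruments$chrom[remaining]) &
      !is.na(instruments$chrom[lead]) &
      instruments$chrom[remaining] == instruments$chrom[lead]
    has_pos <- !is.na(instruments$pos[remaining]) &
      !is.na(instruments$pos[lead])
    near <- rep(TRUE, length(remaining))  # no positions: r2 decides alone
    idx <- same_chr & has_pos
    near[idx] <- abs(instruments$pos[remaining][idx] -
                       instruments$pos[lead]) <= window_kb * 1000
    prune <- in_ld & near
    remaining <- remaining[!prune]
  }
  kept_df <- instruments[kept, , drop = FALSE]
  g_ord <- order(suppressWarnings(as.numeric(kept_df$chrom)),
                 kept_df$pos, method = "radix", na.last = TRUE)
  kept_df <- kept_df[g_ord, , drop = FALSE]
  new_instrument_set(as.data.frame(kept_df), attr(instruments, "trait_name"),
                     attr(instruments, "trait_type"),
                     attr(instruments, "p_threshold"))
}

is_palindromic <- function(ea, oa) oa == unname(COMPLEMENT[ea])

new_harmonized <- function(snp, bx, sex, by, sey, eaf_x, eaf_y,
                           exposure_name, outcome_name, outcome_type,
                           dropped, n_x = NA, n_y = NA,
                           n_case_y = NA, n_control_y = NA,
                           notes = character()) {
  structure(list(snp = snp, bx = bx, sex = sex, by = by, sey = sey,
                 eaf_x = eaf_x, eaf_y = eaf_y,
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 outcome_type = outcome_type, dropped = dropped,
                 n_x = n_x, n_y = n_y,
                 n_case_y = n_case_y, n_control_y = n_control_y,
                 notes = notes),
            class = "mr_harmonized")
}

#' Number of variants in a harmonized set
#' @param h An `mr_harmonized` object.
#' @return Integer count.
#' @export
nsnp <- function(h) length(h$snp)

#' Subset a harmonized set
#' @param h An `mr_harmonized` object.
#' @param idx Logical or integer index of variants to keep.
#' @return The subset `mr_harmonized` object.
#' @export
subset_harmonized <- function(h, idx) {
  for (f in c("snp", "bx", "sex", "by", "sey", "eaf_x", "eaf_y"))
    h[[f]] <- h[[f]][idx]
  h
}

# Align one outcome record to the exposure's allele orientation.
# Returns list(action = keep|flip|drop, reason, by, eaf_y).
align_alleles <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, eaf_y, by,
                          palindrome_policy, band) {
  if (is_palindromic(ea_x, oa_x)) {
    if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x)))
      return(list(action = "drop", reason = "allele_mismatch"))
    if (palindrome_policy == "drop_all")
      return(list(action = "drop", reason = "palindromic_ambiguous"))
    if (is.na(eaf_x) || is.na(eaf_y))
      return(list(action = "drop", reason = "palindromic_ambiguous"))
    if (palindrome_policy == "drop_ambiguous" &&
        ((eaf_x >= band[1] && eaf_x <= band[2]) ||
         (eaf_y >= band[1] && eaf_y <= band[2])))
      return(list(action = "drop", reason = "palindromic_ambiguous"))
    # label alignment first, then strand inference by frequency agreement
    if (ea_y == oa_x) {
      by <- -by
      eaf_y <- 1 - eaf_y
    }
    if ((eaf_x - 0.5) * (eaf_y - 0.5) < 0) {
      by <- -by
      eaf_y <- 1 - eaf_y
    }
    return(list(action = "keep", by = by, eaf_y = eaf_y))
  }
  if (setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
    if (ea_y == ea_x) return(list(action = "keep", by = by, eaf_y = eaf_y))
    return(list(action = "keep", by = -by, eaf_y = 1 - eaf_y))
  }
  cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
  if (setequal(c(cea, coa), c(ea_x, oa_x))) {
    if (cea == ea_x) return(list(action = "keep", by = by, eaf_y = eaf_y))
    return(list(action = "keep", by = -by, eaf_y = 1 - eaf_y))
  }
  list(action = "drop", reason = "allele_mismatch")
}

#' Harmonize instruments against an outcome table
#'
#' For each instrument, looks up the same identifier in the outcome table
#' (falling back to a proxy from `panel$proxy_table` with r2 > 0.8, else
#' dropping with reason `missing_in_outcome`).  Outcome effects are
#' re-oriented to the exposure's effect allele: swapped alleles negate the
#' outcome beta (and reflect its EAF), strand flips are resolved by
#' complementing, and palindromic (A/T, C/G) variants are handled by
#' `palindrome_policy`:
#' * `"drop_ambiguous"` (default) drops a palindromic variant when either
#'   trait's EAF falls inside `ambiguity_band`, otherwise infers the strand
#'   from frequency agreement;
#' * `"infer"` always infers from frequencies;
#' * `"drop_all"` drops every palindromic variant.
#' Irreconcilable allele sets are dropped with reason `allele_mismatch`.
#' Proxy substitution replaces only the outcome record; the exposure
#' effect and SE remain those of the original instrument.
#'
#' @param instruments An `instrument_set`.
#' @param outcome An `assoc_table` for the outcome trait.
#' @param palindrome_policy See above.
#' @param ambiguity_band Frequency band treated as unresolvable (default
#'   c(0.42, 0.58)).
#' @param panel Optional `ld_panel` carrying a proxy table.
#' @return An `mr_harmonized` object with aligned effect arrays and a
#'   `dropped` data.frame of (snp, reason).
#' @export
harmonize <- function(instruments, outcome,
                      palindrome_policy = c("drop_ambiguous", "infer",
                                            "drop_all"),
                      ambiguity_band = c(0.42, 0.58), panel = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(instruments) == 0) stop("instrument set is empty")
  out_idx <- match(instruments$snp, outcome$snp)
  proxies <- if (!is.null(panel)) panel$proxy_table else NULL
  notes <- character()

  k <- nrow(instruments)
  keep <- logical(k)
  by <- sey <- eaf_y <- rep(NA_real_, k)
  drop_snp <- character(); drop_reason <- character()

  for (i in seq_len(k)) {
    j <- out_idx[i]
    if (is.na(j) && !is.null(proxies)) {
      pr <- proxies[proxies$snp == instruments$snp[i], , drop = FALSE]
      if (nrow(pr) > 0) {
        j <- match(pr$proxy[1], outcome$snp)
        if (!is.na(j))
          notes <- c(notes, sprintf("proxy %s used for %s (r2=%.3g)",
                                    pr$proxy[1], instruments$snp[i],
                                    pr$r2[1]))
      }
    }
    if (is.na(j)) {
      drop_snp <- c(drop_snp, instruments$snp[i])
      drop_reason <- c(drop_reason, "missing_in_outcome")
      next
    }
    al <- align_alleles(instruments$effect_allele[i],
                        instruments$other_allele[i], instruments$eaf[i],
                        outcome$effect_allele[j], outcome$other_allele[j],
                        outcome$eaf[j], outcome$beta[j],
                        palindrome_policy, ambiguity_band)
    if (al$action == "drop") {
      drop_snp <- c(drop_snp, instruments$snp[i])
      drop_reason <- c(drop_reason, al$reason)
      next
    }
    keep[i] <- TRUE
    by[i] <- al$by
    sey[i] <- outcome$se[j]
    eaf_y[i] <- al$eaf_y
  }

  if (!any(keep)) {
    stop(errorCondition(
      sprintf("harmonization of '%s' on '%s' left zero variants",
              attr(instruments, "trait_name"), attr(outcome, "trait_name")),
      class = c("summr_harmonization_empty", "error", "condition")))
  }
  dropped <- data.frame(snp = drop_snp, reason = drop_reason,
                        stringsAsFactors = FALSE)
  new_harmonized(snp = instruments$snp[keep],
                 bx = instruments$beta[keep], sex = instruments$se[keep],
                 by = by[keep], sey = sey[keep],
                 eaf_x = instruments$eaf[keep], eaf_y = eaf_y[keep],
                 exposure_name = attr(instruments, "trait_name"),
                 outcome_name = attr(outcome, "trait_name"),
                 outcome_type = attr(outcome, "trait_type"),
                 dropped = dropped,
                 n_x = stats::median(instruments$n, na.rm = TRUE),
                 n_y = stats::median(outcome$n, na.rm = TRUE),
                 n_case_y = stats::median(outcome$n_case, na.rm = TRUE),
                 n_control_y = stats::median(outcome$n_control, na.rm = TRUE),
                 notes = notes)
}

#' Exclude variants from a harmonized set
#'
#' Removes the listed variants (e.g. a user-supplied pleiotropic-locus
#' list) and records them in `dropped` under the given reason, keeping all
#' arrays aligned.
#'
#' @param h An `mr_harmonized` object.
#' @param exclude Character vector of variant identifiers (may be empty).
#' @param reason Drop reason recorded for excluded variants.
#' @return The filtered `mr_harmonized` object.
#' @export
filter_snps <- function(h, exclude, reason = "user_excluded") {
  hit <- h$snp %in% exclude
  if (!any(hit)) return(h)
  if (all(hit)) {
    stop(errorCondition(
      "exclusion list empties the harmonized set",
      class = c("summr_harmonization_empty", "error", "condition")))
  }
  h$dropped <- rbind(h$dropped,
                     data.frame(snp = h$snp[hit], reason = reason,
                                stringsAsFactors = FALSE))
  subset_harmonized(h, !hit)
}

#' Build a harmonized set directly from aligned arrays
#'
#' Convenience constructor for already-aligned exposure/outcome effects
#' (toy examples, simulations).
#'
#' @param bx,sex Exposure effects and standard errors.
#' @param by,sey Outcome effects and standard errors.
#' @param snp Optional identifiers (defaults to `snp1..k`).
#' @param eaf_x,eaf_y Optional effect-allele frequencies.
#' @param exposure_name,outcome_name Trait labels.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param n_x,n_y Trait sample sizes (used by the Steiger test).
#' @return An `mr_harmonized` object.
#' @export
harmonized_set <- function(bx, sex, by, sey, snp = NULL,
                           eaf_x = NA, eaf_y = NA,
                           exposure_name = "exposure",
                           outcome_name = "outcome",
                           outcome_type = "continuous",
                           n_x = NA, n_y = NA) {
  k <- length(bx)
  sex <- rep_len(sex, k)
  sey <- rep_len(sey, k)
  stopifnot(length(by) == k)
  if (any(sex <= 0) || any(sey <= 0)) stop("standard errors must be > 0")
  if (is.null(snp)) snp <- paste0("snp", seq_len(k))
  new_harmonized(snp = snp, bx = bx, sex = sex, by = by, sey = sey,
                 eaf_x = rep_len(eaf_x, k), eaf_y = rep_len(eaf_y, k),
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 outcome_type = outcome_type,
                 dropped = data.frame(snp = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE),
                 n_x = n_x, n_y = n_y)
}
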