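# Orchestration of a full bidirectional study: for every exposure-outcome
# pair and direction, select -> clump -> harmonize -> estimate ->
# heterogeneity -> Steiger, with Bonferroni bookkeeping on the IVW p.

derive_seed <- function(base, index) {
  as.integer((as.numeric(base) + 7919 * index) %% 2147483647L)
}

run_one_pair <- function(exp_tab, out_tab, direction, cfg, panel = NULL,
                         exclusions = NULL, pair_seed = 1L) {
  exposure_name <- attr(exp_tab, "trait_name")
  outcome_name <- attr(out_tab, "trait_name")
  notes <- character()
  result <- list(exposure = exposure_name, outcome = outcome_name,
                 direction = direction, estimates = NULL,
                 heterogeneity = NULL, steiger = NULL, nsnp = 0L,
                 nsnp_clumped = 0L, passes_bonferroni = NA, notes = notes)
  class(result) <- "mr_result"

  step <- function(expr) tryCatch(expr, error = function(e) {
    result$notes <<- c(result$notes, conditionMessage(e))
    NULL
  })

  instr <- step(select_instruments(exp_tab, cfg$p_instrument, f_min = NULL))
  if (is.null(instr)) return(result)
  if (!is.null(panel)) {
    instr <- step(ld_clump(instr, panel, cfg$clump_r2, cfg$clump_window_kb))
    if (is.null(instr)) return(result)
  } else {
    result$notes <- c(result$notes,
                      "no LD panel supplied: clumping skipped")
  }
  instr <- step(filter_weak_instruments(instr, 10))
  if (is.null(instr)) return(result)
  result$nsnp_clumped <- nrow(instr)

  h <- step(harmonize(instr, out_tab,
                      palindrome_policy = cfg$palindrome_policy))
  if (is.null(h)) return(result)
  if (!is.null(exclusions)) {
    h <- step(filter_snps(h, exclusions, reason = "user_excluded"))
    if (is.null(h)) return(result)
  }
  result$nsnp <- nsnp(h)
  result$harmonized <- h

  est <- step(suppressMessages(
    estimate_all(h, re_model = cfg$re_model, n_boot = cfg$n_boot,
                 seed = pair_seed)))
  if (is.null(est)) return(result)
  result$estimates <- est
  egger_row <- est[est$method == "egger" & !is.na(est$beta), , drop = FALSE]
  result$heterogeneity <- heterogeneity_report(
    h, egger_fit = if (nrow(egger_row)) egger_row else NULL,
    presso_n_sim = cfg$presso_n_sim, seed = pair_seed + 1L)
  result$steiger <- step(steiger_test(h))
  result$notes <- c(result$notes, h$notes)
  result
}

#' Run a complete multi-trait MR study
#'
#' For every exposure x outcome pair and each configured direction,
#' executes instrument selection, optional LD clumping, the weak-
#' instrument filter, harmonization, all four causal estimators, the
#' heterogeneity/pleiotropy report, and the Steiger directionality test.
#' Partial failures (e.g. no significant instruments in the reverse
#' direction) yield a result whose `notes` explain the failure, never an
#' aborted run.  The Bonferroni flag marks IVW p-values below
#' `alpha_family / n_tests`, with `n_tests = "auto"` meaning pairs x
#' directions.  Deterministic given the config seed.
#'
#' @param config A `study_config` (or path to one).
#' @param panels Optional named list of `ld_panel`s keyed by trait name;
#'   pairs without a panel skip clumping with a note.
#' @param exclusions Optional named list of variant-id vectors keyed by
#'   `"exposure:outcome"` or exposure name.
#' @return A list of `mr_result` objects with attributes `n_tests`,
#'   `bonferroni_alpha` and `config`.
#' @export
run_study <- function(config, panels = NULL, exclusions = NULL) {
  cfg <- if (is.character(config)) read_study_config(config) else
    validate_study_config(config)
  base <- cfg$base_dir %||% "."
  read_side <- function(entries) {
    tabs <- lapply(entries, function(tr) {
      path <- if (file.exists(tr$file)) tr$file else file.path(base, tr$file)
      suppressMessages(read_gwas_summary(path, trait_type = tr$type,
                                         trait_name = tr$name))
    })
    names(tabs) <- vapply(entries, `[[`, character(1), "name")
    tabs
  }
  exp_tabs <- read_side(cfg$exposures)
  out_tabs <- read_side(cfg$outcomes)

  directions <- switch(cfg$directions, forward = "forward",
                       reverse = "reverse", both = c("forward", "reverse"))
  n_pairs <- length(exp_tabs) * length(out_tabs)
  n_tests <- if (identical(cfg$n_tests, "auto")) {
    n_pairs * length(directions)
  } else {
    as.integer(cfg$n_tests)
  }
  if (identical(cfg$n_tests, "auto") && length(directions) == 2) {
    warning(paste("n_tests counts forward and reverse analyses separately;",
                  "supply n_tests explicitly to adopt another convention"),
            call. = FALSE)
  }
  alpha <- bonferroni_threshold(n_tests, cfg$alpha_family)

  results <- list()
  idx <- 0L
  for (direction in directions) {
    for (en in names(exp_tabs)) {
      for (on in names(out_tabs)) {
        idx <- idx + 1L
        if (direction == "forward") {
          a <- exp_tabs[[en]]; b <- out_tabs[[on]]
          panel <- panels[[en]]
        } else {
          a <- out_tabs[[on]]; b <- exp_tabs[[en]]
          panel <- panels[[on]]
        }
        excl <- exclusions[[paste0(en, ":", on)]] %||% exclusions[[en]]
        res <- run_one_pair(a, b, direction, cfg, panel = panel,
                            exclusions = excl,
                            pair_seed = derive_seed(cfg$seed, idx))
        ivw_p <- ivw_pval(res)
        res$passes_bonferroni <- if (is.na(ivw_p)) NA else ivw_p < alpha
        results[[idx]] <- res
      }
    }
  }
  structure(results, n_tests = n_tests, bonferroni_alpha = alpha,
            config = cfg, class = "mr_study")
}

ivw_pval <- function(res) {
  if (is.null(res$estimates)) return(NA_real_)
  row <- res$estimates[res$estimates$method %in% c("ivw", "wald"), ,
                       drop = FALSE]
  if (nrow(row) == 0) return(NA_real_)
  row$pval[1]
}

#' Flatten study results to the canonical results-table schema
#'
#' @param results An `mr_study` list from [run_study()].
#' @return Data.frame with the [write_results_table()] schema, one row
#'   per (pair, direction, method).
#' @export
results_table <- function(results) {
  rows <- lapply(results, function(res) {
    if (is.null(res$estimates)) {
      return(data.frame(exposure = res$exposure, outcome = res$outcome,
                        direction = res$direction, method = NA_character_,
                        nsnp = res$nsnp, stringsAsFactors = FALSE))
    }
    het <- res$heterogeneity
    st <- res$steiger
    data.frame(exposure = res$exposure, outcome = res$outcome,
               direction = res$direction, method = res$estimates$method,
               nsnp = res$estimates$nsnp, beta = res$estimates$beta,
               se = res$estimates$se, ci_low = res$estimates$ci_low,
               ci_high = res$estimates$ci_high, pval = res$estimates$pval,
               or = res$estimates$or, or_ci_low = res$estimates$or_ci_low,
               or_ci_high = res$estimates$or_ci_high,
               q = het$q, q_df = het$q_df, q_pval = het$q_pval, i2 = het$i2,
               egger_intercept = res$estimates$egger_intercept,
               intercept_pval = res$estimates$intercept_pval,
               rucker_q = het$rucker_q, rucker_pval = het$rucker_pval,
               presso_global_pval = het$presso_global_display,
               steiger_dir = if (is.null(st)) NA else st$direction_ok,
               steiger_pval = if (is.null(st)) NA_real_ else st$pval,
               passes_bonferroni = res$passes_bonferroni,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, lapply(rows, function(r) {
    for (col in setdiff(RESULTS_COLUMNS, names(r))) r[[col]] <- NA
    r[, RESULTS_COLUMNS]
  }))
}

#' Re-run a study variant for sensitivity analysis
#'
#' Re-executes only the affected pairs under one of three modifications,
#' tagging each result for side-by-side reporting:
#' * `"exclude_list"`: payload is a named list of variant ids (keys
#'   `"exposure:outcome"` or exposure names) to exclude before
#'   re-estimation;
#' * `"leave_group"`: payload has `grouping` (named map snp -> label) and
#'   `group` (the label to drop), applied as an exclusion;
#' * `"alternate_outcome"`: payload has `outcome` (the configured outcome
#'   name to replace), `name`, `file`, `type` of the replacement dataset.
#'
#' @param results An `mr_study` from [run_study()].
#' @param variant One of `"exclude_list"`, `"leave_group"`,
#'   `"alternate_outcome"`.
#' @param payload See above.
#' @param panels As in [run_study()].
#' @return An `mr_study` of the re-run pairs, each result carrying
#'   `variant` and lineage notes.
#' @export
sensitivity_rerun <- function(results, variant = c("exclude_list",
                                                   "leave_group",
                                                   "alternate_outcome"),
                              payload, panels = NULL) {
  variant <- match.arg(variant)
  cfg <- attr(results, "config")
  if (is.null(cfg)) stop("results carry no configuration")
  if (variant == "exclude_list") {
    if (!is.list(payload)) stop("payload must be a named list of snp ids")
    rerun <- run_study(cfg, panels = panels, exclusions = payload)
  } else if (variant == "leave_group") {
    if (is.null(payload$grouping) || is.null(payload$group))
      stop("payload needs 'grouping' and 'group'")
    grouping <- unlist(payload$grouping)
    snps <- names(grouping)[grouping == payload$group]
    if (length(snps) == 0) stop("unknown group: ", payload$group)
    excl <- stats::setNames(
      rep(list(snps), length(cfg$exposures)),
      vapply(cfg$exposures, `[[`, character(1), "name"))
    rerun <- run_study(cfg, panels = panels, exclusions = excl)
  } else {
    target <- payload$outcome
    hit <- vapply(cfg$outcomes, function(o) o$name == target, logical(1))
    if (!any(hit)) stop("unknown outcome in payload: ", target)
    old_name <- cfg$outcomes[[which(hit)]]$name
    cfg$outcomes[[which(hit)]] <- list(name = payload$name,
                                       file = payload$file,
                                       type = payload$type)
    rerun <- run_study(cfg, panels = panels)
    rerun <- structure(lapply(rerun, function(res) {
      if (res$outcome == payload$name) {
        res$notes <- c(res$notes,
                       sprintf("alternate outcome: %s replaced %s",
                               payload$name, old_name))
      }
      res
    }), n_tests = attr(rerun, "n_tests"),
    bonferroni_alpha = attr(rerun, "bonferroni_alpha"),
    config = attr(rerun, "config"), class = "mr_study")
  }
  for (i in seq_along(rerun)) rerun[[i]]$variant <- variant
  rerun
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR result: %s -> %s (%s), %d instruments\n",
              x$exposure, x$outcome, x$direction, x$nsnp))
  if (!is.null(x$estimates)) {
    print(x$estimates[, c("method", "nsnp", "beta", "se", "pval")])
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
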