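# Reading, validating and writing GWAS summary-statistic tables.
#
# The variant-level data model used throughout the package is a plain
# data.frame ("assoc_table") with one row per variant and the columns
# snp, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n,
# n_case, n_control.  Trait metadata (name, continuous/binary) travels as
# attributes, in the style of summary-data MR packages.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column-name mapping for GWAS summary files
#'
#' Maps the internal field names to the column headers expected in input
#' files.  Override individual entries via the `column_map` argument of
#' [read_gwas_summary()].
#'
#' @return Named character vector (internal field -> file column).
#' @export
default_column_map <- function() {
  c(snp = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N",
    n_case = "N_CASE", n_control = "N_CONTROL")
}

# Columns every table must carry, in canonical order.
ASSOC_COLUMNS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n", "n_case", "n_control")

new_assoc_table <- function(df, trait_name, trait_type,
                            n_dropped = 0L, drop_reasons = character()) {
  for (col in setdiff(ASSOC_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, ASSOC_COLUMNS, drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("assoc_table", "data.frame"),
            trait_name = trait_name,
            trait_type = trait_type,
            n_dropped = n_dropped,
            drop_reasons = drop_reasons)
}

#' Construct a summary-association table from vectors
#'
#' Programmatic counterpart of [read_gwas_summary()]; applies the same
#' row-level validity filters.
#'
#' @param snp Variant identifiers.
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @param beta,se Effect size and standard error (SD units for continuous
#'   traits, log-odds for binary traits).
#' @param pval Association p-value in (0, 1].
#' @param eaf Effect-allele frequency in (0, 1); may be `NA`.
#' @param n Total sample size.
#' @param chrom,pos Optional chromosome and 1-based position.
#' @param n_case,n_control Optional case/control counts for binary traits.
#' @param trait_name Trait label.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return An `assoc_table` data.frame.
#' @export
assoc_table <- function(snp, effect_allele, other_allele, beta, se, pval,
                        eaf = NA, n = NA, chrom = NA, pos = NA,
                        n_case = NA, n_control = NA,
                        trait_name = "trait",
                        trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  df <- data.frame(snp = as.character(snp), chrom = as.character(chrom),
                   pos = as.numeric(pos),
                   effect_allele = toupper(as.character(effect_allele)),
                   other_allele = toupper(as.character(other_allele)),
                   eaf = as.numeric(eaf), beta = as.numeric(beta),
                   se = as.numeric(se), pval = as.numeric(pval),
                   n = as.numeric(n), n_case = as.numeric(n_case),
                   n_control = as.numeric(n_control),
                   stringsAsFactors = FALSE)
  validate_assoc_rows(df, trait_name, trait_type)
}

# Row-level validity filters.  Invalid rows are dropped (never repaired,
# except the documented p = 0 clamp) and counted.
validate_assoc_rows <- function(df, trait_name, trait_type) {
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  zero_p <- !is.na(df$pval) & df$pval == 0
  if (any(zero_p)) {
    warning(sprintf("%d p-value(s) of 0 clamped to smallest positive normal float in '%s'",
                    sum(zero_p), trait_name), call. = FALSE)
    df$pval[zero_p] <- .Machine$double.xmin
  }

  reasons <- character()
  bad <- rep(FALSE, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    new <- cond & !bad
    if (any(new)) reasons <<- c(reasons, rep(why, sum(new)))
    bad <<- bad | cond
  }
  flag(is.na(df$snp) | df$snp == "", "missing_snp_id")
  flag(!(df$effect_allele %in% VALID_ALLELES) |
         !(df$other_allele %in% VALID_ALLELES), "invalid_allele")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(is.na(df$beta), "missing_beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive_se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "invalid_pval")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "invalid_eaf")
  flag(!is.na(df$n) & df$n <= 0, "nonpositive_n")
  flag(!is.na(df$n_case) & !is.na(df$n_control) & !is.na(df$n) &
         (df$n_case + df$n_control != df$n), "case_control_sum_mismatch")
  flag(duplicated(df$snp), "duplicate_snp_id")

  kept <- df[!bad, , drop = FALSE]
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    message(sprintf("%s: dropped %d of %d row(s) failing validity filters",
                    trait_name, n_dropped, nrow(df)))
  }
  new_assoc_table(kept, trait_name, trait_type,
                  n_dropped = as.integer(n_dropped), drop_reasons = reasons)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              "," = lengths(regmatches(header, gregexpr(",", header))))
  if (counts[["\t"]] > 0) "\t" else if (counts[[","]] > 0) "," else ""
}

#' Read a GWAS summary-statistics table
#'
#' Reads a headered delimited text file (delimiter auto-detected among tab,
#' comma and runs of whitespace unless `delim` is given), maps columns via
#' `column_map`, uppercases alleles, clamps p-values of exactly 0 to the
#' smallest positive normal float (with a warning), and drops rows that
#' violate the variant-level invariants (non-ACGT or identical alleles,
#' se <= 0, p outside (0, 1], EAF outside (0, 1), duplicated identifiers),
#' reporting the dropped count.  Row order is preserved.  Strand flips are
#' never applied at read time: allele logic belongs to [harmonize()].
#'
#' @param path File path.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param column_map Named character vector overriding entries of
#'   [default_column_map()].
#' @param trait_name Trait label; defaults to the file name.
#' @param delim Optional delimiter override (`"\t"`, `","` or `""` for
#'   whitespace runs).
#' @return An `assoc_table` data.frame with attributes `trait_name`,
#'   `trait_type`, `n_dropped` and `drop_reasons`.
#' @export
read_gwas_summary <- function(path, trait_type = c("continuous", "binary"),
                              column_map = NULL, trait_name = NULL,
                              delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  map <- default_column_map()
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  if (is.null(delim)) delim <- detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (nrow(raw) == 0) {
    stop(errorCondition(paste0("empty summary table: ", path),
                        class = c("summr_empty_table", "error", "condition")))
  }

  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- mandatory[!(map[mandatory] %in% names(raw))]
  if (length(missing_cols) > 0) {
    stop(errorCondition(
      sprintf("missing mandatory column(s) in %s: %s", path,
              paste(map[missing_cols], collapse = ", ")),
      class = c("summr_config_error", "error", "condition")))
  }

  take <- function(field, as = as.numeric) {
    col <- map[[field]]
    if (col %in% names(raw)) as(raw[[col]]) else rep(NA, nrow(raw))
  }
  df <- data.frame(snp = as.character(raw[[map[["snp"]]]]),
                   chrom = as.character(take("chrom", as.character)),
                   pos = take("pos"),
                   effect_allele = as.character(raw[[map[["effect_allele"]]]]),
                   other_allele = as.character(raw[[map[["other_allele"]]]]),
                   eaf = take("eaf"), beta = take("beta"), se = take("se"),
                   pval = take("pval"), n = take("n"),
                   n_case = take("n_case"), n_control = take("n_control"),
                   stringsAsFactors = FALSE)
  validate_assoc_rows(df, trait_name, trait_type)
}

#' Write a summary-association table
#'
#' Writes the canonical TSV layout read back by [read_gwas_summary()] with
#' the default column map (all-`NA` optional columns are omitted).
#'
#' @param table An `assoc_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gwas_summary <- function(table, path) {
  map <- default_column_map()
  out <- as.data.frame(table)
  keep <- vapply(out, function(x) !all(is.na(x)), logical(1))
  out <- out[, keep, drop = FALSE]
  names(out) <- map[names(out)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Canonical results-table schema (one row per exposure x outcome x method).
RESULTS_COLUMNS <- c("exposure", "outcome", "direction", "method", "nsnp",
                     "beta", "se", "ci_low", "ci_high", "pval",
                     "or", "or_ci_low", "or_ci_high",
                     "q", "q_df", "q_pval", "i2",
                     "egger_intercept", "intercept_pval",
                     "rucker_q", "rucker_pval", "presso_global_pval",
                     "steiger_dir", "steiger_pval", "passes_bonferroni")

#' Write an MR results table
#'
#' Emits one TSV row per (exposure, outcome, method) with a fixed,
#' deterministic column order; missing fields are written as `NA`.  With
#' zero rows a header-only file is produced.
#'
#' @param rows A data.frame of result records (any subset of the schema
#'   columns; extras are dropped).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- data.frame(matrix(NA, nrow = nrow(rows),
                           ncol = length(RESULTS_COLUMNS)))
  names(out) <- RESULTS_COLUMNS
  for (col in intersect(names(rows), RESULTS_COLUMNS)) out[[col]] <- rows[[col]]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write results table to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a study configuration
#'
#' Parses a YAML study configuration naming exposure and outcome summary
#' files, analysis directions, and thresholds.  Relative file paths are
#' resolved against the configuration file's directory.
#'
#' @param path Path to a YAML file with keys `exposures` and `outcomes`
#'   (each a list of `name`/`file`/`type` entries), `directions`
#'   (`forward`, `reverse` or `both`), `p_instrument`, `clump_window_kb`,
#'   `clump_r2`, `alpha_family`, `n_tests` (integer or `"auto"`), and
#'   optional `seed`, `n_boot`, `presso_n_sim`, `palindrome_policy`,
#'   `re_model`.
#' @return A validated `study_config` list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  validate_study_config(cfg)
}

#' @rdname read_study_config
#' @param cfg A configuration list (as produced by YAML parsing).
#' @export
validate_study_config <- function(cfg) {
  fail <- function(...) stop(errorCondition(
    sprintf(...), class = c("summr_config_error", "error", "condition")))
  for (side in c("exposures", "outcomes")) {
    if (is.null(cfg[[side]]) || length(cfg[[side]]) == 0)
      fail("config: '%s' must list at least one trait", side)
    for (tr in cfg[[side]]) {
      if (is.null(tr$name) || is.null(tr$file) || is.null(tr$type))
        fail("config: every %s entry needs name, file and type", side)
      if (!tr$type %in% c("continuous", "binary"))
        fail("config: trait type must be continuous or binary (%s)", tr$name)
    }
  }
  cfg$directions <- cfg$directions %||% "forward"
  if (!cfg$directions %in% c("forward", "reverse", "both"))
    fail("config: directions must be forward, reverse or both")
  cfg$p_instrument <- cfg$p_instrument %||% 5e-8
  cfg$clump_window_kb <- cfg$clump_window_kb %||% 10000
  cfg$clump_r2 <- cfg$clump_r2 %||% 0.001
  cfg$alpha_family <- cfg$alpha_family %||% 0.05
  cfg$n_tests <- cfg$n_tests %||% "auto"
  cfg$seed <- cfg$seed %||% 1L
  cfg$n_boot <- cfg$n_boot %||% 1000L
  cfg$presso_n_sim <- cfg$presso_n_sim %||% 1000L
  cfg$palindrome_policy <- cfg$palindrome_policy %||% "drop_ambiguous"
  cfg$re_model <- cfg$re_model %||% "multiplicative_floored"
  if (cfg$p_instrument <= 0 || cfg$p_instrument >= 1)
    fail("config: p_instrument must lie in (0,1)")
  if (cfg$clump_r2 <= 0 || cfg$clump_r2 >= 1)
    fail("config: clump_r2 must lie in (0,1)")
  if (cfg$alpha_family <= 0 || cfg$alpha_family >= 1)
    fail("config: alpha_family must lie in (0,1)")
  class(cfg) <- "study_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
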