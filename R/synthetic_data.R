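# Seeded generator of GWAS summary-statistic pairs, LD panels and
# multi-exposure systems with known ground truth.
#
# The generator works at summary level: it never simulates genotypes.
# Per-variant sampling variances follow the standard Wald approximations
# se = 1/sqrt(2 p (1-p) n) for a standardized continuous trait and
# se = 1/sqrt(2 p (1-p) n K (1-K)) on the log-odds scale for a
# case-control trait with case fraction K.

#' Ground truth for a synthetic exposure-outcome pair
#'
#' Defines the generating parameters of one simulated two-sample MR
#' analysis.  The defaults emulate a well-powered modern GWAS pair: a
#' binary exposure measured on ~400k individuals whose genome-wide
#' significant, LD-independent instruments explain ~5.7% of trait
#' variance (per-variant strength F roughly 28-170), and a case-control
#' outcome of ~450k individuals at a 15% case fraction.
#'
#' Per-variant true effect magnitudes are drawn with a floor at about
#' 0.82 times the mean share of `instrument_h2` plus an exponential right
#' tail, mimicking the left-truncated strength profile of published
#' genome-wide-significant instrument lists, then scaled so that the
#' pooled variance explained `sum(2 beta^2 maf (1-maf))` equals
#' `instrument_h2` exactly.
#'
#' @param beta_causal True causal effect (log-odds of the outcome per
#'   exposure unit for binary outcomes).
#' @param n_instruments Number of instruments.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#'   Pleiotropic effects are drawn independently of instrument strength,
#'   so the InSIDE assumption holds in every mode.
#' @param pleiotropy_sd SD of the per-variant pleiotropic effect.
#' @param pleiotropy_mean Mean pleiotropic effect (directional mode).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param exposure_type,outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction Outcome case fraction K (binary outcomes).
#' @param case_fraction_exp Exposure case fraction (binary exposures).
#' @param maf_range Range of simulated minor-allele frequencies, within
#'   (0.01, 0.5).
#' @param instrument_h2 Target pooled variance explained, in (0, 0.5).
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A `sim_truth` list echoing the parameters.
#' @export
sim_truth <- function(beta_causal = 0.2, n_instruments = 50,
                      pleiotropy_mode = c("none", "balanced", "directional"),
                      pleiotropy_sd = 0, pleiotropy_mean = 0,
                      n_exp = 403195, n_out = 455258,
                      exposure_type = c("binary", "continuous"),
                      outcome_type = c("binary", "continuous"),
                      case_fraction = 0.158, case_fraction_exp = 0.626,
                      maf_range = c(0.05, 0.45), instrument_h2 = 0.0575,
                      seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  exposure_type <- match.arg(exposure_type)
  outcome_type <- match.arg(outcome_type)
  stopifnot(instrument_h2 > 0, instrument_h2 < 0.5,
            maf_range[1] > 0.01, maf_range[2] < 0.5,
            maf_range[1] <= maf_range[2], n_instruments >= 1)
  structure(list(beta_causal = beta_causal, n_instruments = n_instruments,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 n_exp = n_exp, n_out = n_out,
                 exposure_type = exposure_type, outcome_type = outcome_type,
                 case_fraction = case_fraction,
                 case_fraction_exp = case_fraction_exp,
                 maf_range = maf_range, instrument_h2 = instrument_h2,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

effective_n <- function(n, type, k_frac) {
  if (type == "binary") n * k_frac * (1 - k_frac) else n
}

# Core draw shared by the table-level and harmonized-level entry points.
sim_pair_core <- function(truth) {
  k <- truth$n_instruments
  maf <- stats::runif(k, truth$maf_range[1], truth$maf_range[2])
  # effect shares with a floor at ~0.8x the mean and an exponential right
  # tail: genome-wide-significant instrument lists show exactly this
  # left-truncated strength profile (F floor near 28 with occasional
  # many-fold stronger hits)
  shares <- 0.82 + 0.18 * stats::rexp(k)
  shares <- shares / sum(shares)
  var_g <- 2 * maf * (1 - maf)
  beta_x_true <- sample(c(-1, 1), k, replace = TRUE) *
    sqrt(truth$instrument_h2 * shares / var_g)
  ne_x <- effective_n(truth$n_exp, truth$exposure_type,
                      truth$case_fraction_exp)
  ne_y <- effective_n(truth$n_out, truth$outcome_type, truth$case_fraction)
  sex <- 1 / sqrt(var_g * ne_x)
  sey <- 1 / sqrt(var_g * ne_y)
  bx <- stats::rnorm(k, beta_x_true, sex)
  pleio <- switch(truth$pleiotropy_mode,
                  none = rep(0, k),
                  balanced = stats::rnorm(k, 0, truth$pleiotropy_sd),
                  directional = stats::rnorm(k, truth$pleiotropy_mean,
                                             truth$pleiotropy_sd))
  # pleiotropy acts in the frame of the exposure-increasing allele (the
  # frame in which directional pleiotropy is defined for MR-Egger), and is
  # drawn independently of instrument strength, so InSIDE holds
  by_true <- truth$beta_causal * beta_x_true + sign(beta_x_true) * pleio
  by <- stats::rnorm(k, by_true, sey)
  mean_f <- mean((beta_x_true / sex)^2)
  if (mean_f < 10)
    warning(sprintf("weak-instrument regime: mean true F = %.1f", mean_f),
            call. = FALSE)
  list(k = k, maf = maf, beta_x_true = beta_x_true, by_true = by_true,
       bx = bx, sex = sex, by = by, sey = sey, pleio = pleio)
}

# Non-palindromic allele pairs keep synthetic tables free of strand
# ambiguity; harmonization-specific cases are built explicitly in tests.
sim_alleles <- function(k) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), k, replace = TRUE), , drop = FALSE]
}

sim_positions <- function(k) {
  chrom <- as.character(rep_len(1:22, k))
  pos <- 1e6 + (seq_len(k) - 1) %/% 22 * 2.5e7 + sample.int(1e6, k,
                                                            replace = TRUE)
  list(chrom = chrom, pos = pos)
}

clamp_p <- function(p) pmax(p, .Machine$double.xmin)

#' Simulate a GWAS summary-statistic pair with known truth
#'
#' Draws one exposure and one outcome association table over the same
#' `n_instruments` variants (shared identifiers, alleles and frequencies),
#' under the generating model of [sim_truth()]: observed effects are the
#' true effects plus Wald-scale noise, outcome effects are
#' `beta_causal * beta_true` plus the chosen pleiotropy term, and
#' p-values come from the Wald z.  Byte-identical on repeated calls with
#' the same truth.
#'
#' @param truth A [sim_truth()].
#' @return List with `exposure` and `outcome` (`assoc_table`s) and the
#'   echoed `truth` augmented with the true per-variant effects.
#' @export
simulate_gwas_pair <- function(truth) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(truth$seed)
  core <- sim_pair_core(truth)
  al <- sim_alleles(core$k)
  loc <- sim_positions(core$k)
  snp <- sprintf("rs%06d", seq_len(core$k))
  exposure <- assoc_table(
    snp = snp, chrom = loc$chrom, pos = loc$pos,
    effect_allele = al[, 1], other_allele = al[, 2],
    eaf = core$maf, beta = core$bx, se = core$sex,
    pval = clamp_p(2 * stats::pnorm(-abs(core$bx / core$sex))),
    n = truth$n_exp,
    n_case = if (truth$exposure_type == "binary")
      round(truth$n_exp * truth$case_fraction_exp) else NA,
    n_control = if (truth$exposure_type == "binary")
      truth$n_exp - round(truth$n_exp * truth$case_fraction_exp) else NA,
    trait_name = "sim_exposure", trait_type = truth$exposure_type)
  outcome <- assoc_table(
    snp = snp, chrom = loc$chrom, pos = loc$pos,
    effect_allele = al[, 1], other_allele = al[, 2],
    eaf = core$maf, beta = core$by, se = core$sey,
    pval = clamp_p(2 * stats::pnorm(-abs(core$by / core$sey))),
    n = truth$n_out,
    n_case = if (truth$outcome_type == "binary")
      round(truth$n_out * truth$case_fraction) else NA,
    n_control = if (truth$outcome_type == "binary")
      truth$n_out - round(truth$n_out * truth$case_fraction) else NA,
    trait_name = "sim_outcome", trait_type = truth$outcome_type)
  truth$beta_x_true <- core$beta_x_true
  truth$pleiotropy <- core$pleio
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate an already-harmonized exposure-outcome set
#'
#' Fast path for simulation studies: the same generating model as
#' [simulate_gwas_pair()] but returning the aligned effect arrays
#' directly, skipping table assembly and allele bookkeeping.
#'
#' @param truth A [sim_truth()].
#' @return An `mr_harmonized` set with the echoed `truth` attached as
#'   attribute `"truth"`.
#' @export
simulate_harmonized <- function(truth) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(truth$seed)
  core <- sim_pair_core(truth)
  h <- harmonized_set(bx = core$bx, sex = core$sex, by = core$by,
                      sey = core$sey,
                      snp = sprintf("rs%06d", seq_len(core$k)),
                      eaf_x = core$maf, eaf_y = core$maf,
                      exposure_name = "sim_exposure",
                      outcome_name = "sim_outcome",
                      outcome_type = truth$outcome_type,
                      n_x = truth$n_exp, n_y = truth$n_out)
  truth$beta_x_true <- core$beta_x_true
  truth$pleiotropy <- core$pleio
  attr(h, "truth") <- truth
  h
}

#' Simulate a block-structured LD panel with matching associations
#'
#' Builds a block-diagonal r-squared matrix (`within_r2` inside each
#' block, 0 between blocks, 1 on the diagonal) and one association per
#' variant in which each block's first ("lead") variant is the most
#' significant, providing a fully known clumping fixture.
#'
#' @param n_blocks,block_size Panel dimensions.
#' @param within_r2 Within-block r-squared in (0, 1).
#' @param seed Integer seed.
#' @return List with `panel` (an `ld_panel`) and `table` (an
#'   `assoc_table`).
#' @export
simulate_ld_panel <- function(n_blocks, block_size, within_r2, seed = 1L) {
  stopifnot(within_r2 >= 0, within_r2 < 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  k <- n_blocks * block_size
  snp <- sprintf("rs%06d", seq_len(k))
  block <- rep(seq_len(n_blocks), each = block_size)
  r2 <- outer(block, block, `==`) * within_r2
  diag(r2) <- 1
  dimnames(r2) <- list(snp, snp)
  lead <- !duplicated(block)
  z <- ifelse(lead, 12 + stats::runif(k, 0, 2), 6 + stats::runif(k, 0, 2))
  se <- 0.01
  al <- sim_alleles(k)
  tab <- assoc_table(snp = snp, chrom = as.character(block),
                     pos = (seq_len(k) - (block - 1) * block_size) * 1e5,
                     effect_allele = al[, 1], other_allele = al[, 2],
                     eaf = stats::runif(k, 0.1, 0.5),
                     beta = z * se, se = se,
                     pval = clamp_p(2 * stats::pnorm(-z)), n = 100000,
                     trait_name = "sim_ld_trait")
  list(panel = ld_panel(r2), table = tab)
}

#' Simulate correlated exposures with known direct effects
#'
#' Generates `m` exposure tables over a shared variant set whose true
#' effects mix a shared and an exposure-specific component, inducing a
#' genetic correlation of about `exposure_correlation` between exposures,
#' plus an outcome generated from `direct_effects` only.  This is the
#' confounding structure multivariable IVW is designed to resolve: a
#' null direct effect looks non-null univariably through the correlated
#' co-exposure.
#'
#' @param m Number of exposures (>= 2).
#' @param direct_effects Length-m vector of true direct effects.
#' @param exposure_correlation Target genetic correlation, |rho| < 1.
#' @param n_instruments Variants shared across exposures.
#' @param instrument_h2 Pooled variance explained per exposure.
#' @param n_exp,n_out,case_fraction,outcome_type,maf_range As in
#'   [sim_truth()]; exposures are continuous.
#' @param seed Integer seed.
#' @return List with `exposures` (list of `assoc_table`s), `outcome`,
#'   and the echoed `truth` (including the true effect matrix).
#' @export
simulate_multi_exposure <- function(m = 2, direct_effects = c(0.3, 0),
                                    exposure_correlation = 0.5,
                                    n_instruments = 60,
                                    instrument_h2 = 0.05,
                                    n_exp = 400000, n_out = 450000,
                                    case_fraction = 0.158,
                                    outcome_type = "binary",
                                    maf_range = c(0.05, 0.45), seed = 1L) {
  stopifnot(m >= 2, length(direct_effects) == m,
            abs(exposure_correlation) < 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  k <- n_instruments
  maf <- stats::runif(k, maf_range[1], maf_range[2])
  var_g <- 2 * maf * (1 - maf)
  rho <- exposure_correlation
  shared <- stats::rnorm(k)
  raw <- vapply(seq_len(m), function(e)
    sqrt(abs(rho)) * sign(rho)^(e - 1) * shared +
      sqrt(1 - abs(rho)) * stats::rnorm(k), numeric(k))
  B <- vapply(seq_len(m), function(e) {
    col <- raw[, e]
    col * sqrt(instrument_h2 / sum(col^2 * var_g))
  }, numeric(k))
  colnames(B) <- paste0("exposure", seq_len(m))
  sex <- 1 / sqrt(var_g * n_exp)
  ne_y <- effective_n(n_out, outcome_type, case_fraction)
  sey <- 1 / sqrt(var_g * ne_y)
  by_true <- as.numeric(B %*% direct_effects)
  by <- stats::rnorm(k, by_true, sey)
  snp <- sprintf("rs%06d", seq_len(k))
  al <- sim_alleles(k)
  loc <- sim_positions(k)
  exposures <- lapply(seq_len(m), function(e) {
    bx <- stats::rnorm(k, B[, e], sex)
    assoc_table(snp = snp, chrom = loc$chrom, pos = loc$pos,
                effect_allele = al[, 1], other_allele = al[, 2],
                eaf = maf, beta = bx, se = sex,
                pval = clamp_p(2 * stats::pnorm(-abs(bx / sex))),
                n = n_exp, trait_name = colnames(B)[e],
                trait_type = "continuous")
  })
  outcome <- assoc_table(snp = snp, chrom = loc$chrom, pos = loc$pos,
                         effect_allele = al[, 1], other_allele = al[, 2],
                         eaf = maf, beta = by, se = sey,
                         pval = clamp_p(2 * stats::pnorm(-abs(by / sey))),
                         n = n_out, trait_name = "sim_outcome",
                         trait_type = outcome_type)
  truth <- list(m = m, direct_effects = direct_effects,
                exposure_correlation = exposure_correlation,
                n_instruments = k, instrument_h2 = instrument_h2,
                n_exp = n_exp, n_out = n_out, seed = as.integer(seed),
                beta_true = B)
  list(exposures = exposures, outcome = outcome, truth = truth)
}

#' Write a complete synthetic study directory
#'
#' Emits a ready-to-run fixture shaped like a seven-exposure (four sleep
#' traits, chronotype and morning-person, plus multisite chronic pain) by
#' five-outcome neurodegeneration study: one summary TSV per trait, plus
#' a YAML configuration wired for a forward analysis of all 35 pairs.
#' Instrument counts per exposure default to a desk-scale fraction of
#' typical genome-wide yields, and all true causal effects are null
#' unless `beta_causal` says otherwise.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_instruments Per-exposure instrument counts (length 7).
#' @param beta_causal True causal effect applied to every pair
#'   (default 0).
#' @param f_target Mean true per-variant F-statistic of the generated
#'   instruments (default 60).  Each exposure's pooled variance explained
#'   is derived as `f_target * k / n_effective`, keeping simulated
#'   instruments comfortably clear of the genome-wide significance
#'   boundary the way published post-selection instrument lists are.
#' @param n_boot,presso_n_sim Analysis settings recorded in the config.
#' @return Invisibly, the config file path.
#' @export
simulate_study <- function(dir, seed = 1L,
                           n_instruments = c(19, 10, 6, 39, 32, 7, 11),
                           beta_causal = 0, f_target = 60,
                           n_boot = 0, presso_n_sim = 200) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exposures <- data.frame(
    name = c("SD", "SS", "LS", "CHR", "MP", "INS", "MCP"),
    type = c("continuous", "binary", "binary", "continuous", "binary",
             "binary", "continuous"),
    n = c(446118, 411934, 339926, 449734, 403195, 386533, 387649),
    case_frac = c(NA, 0.258, 0.101, NA, 0.626, 0.283, NA),
    stringsAsFactors = FALSE)
  ne_exp <- ifelse(exposures$type == "binary",
                   exposures$n * exposures$case_frac *
                     (1 - exposures$case_frac), exposures$n)
  exposures$h2 <- f_target * n_instruments / ne_exp
  outcomes <- data.frame(
    name = c("AD", "AMD", "ALS", "MS", "PD"),
    n = c(33976, 455258, 36052, 115635, 482730),
    case_frac = c(0.475, 0.158, 0.349, 0.409, 0.070),
    stringsAsFactors = FALSE)
  stopifnot(length(n_instruments) == 7)

  exp_tables <- list()
  for (i in seq_len(nrow(exposures))) {
    tr <- sim_truth(beta_causal = beta_causal,
                    n_instruments = n_instruments[i],
                    n_exp = exposures$n[i], n_out = outcomes$n[1],
                    exposure_type = exposures$type[i],
                    outcome_type = "binary",
                    case_fraction = outcomes$case_frac[1],
                    case_fraction_exp = if (is.na(exposures$case_frac[i]))
                      0.5 else exposures$case_frac[i],
                    instrument_h2 = exposures$h2[i],
                    seed = seed + i * 101L)
    if (exposures$type[i] == "continuous") tr$exposure_type <- "continuous"
    pair <- suppressWarnings(simulate_gwas_pair(tr))
    exp_tables[[exposures$name[i]]] <- pair
  }

  # outcome tables: every exposure's variants, outcome-scale effects
  for (j in seq_len(nrow(outcomes))) {
    rows <- list()
    for (i in seq_len(nrow(exposures))) {
      pair <- exp_tables[[exposures$name[i]]]
      truth <- pair$truth
      k <- truth$n_instruments
      set.seed(seed + i * 101L + j * 7919L)
      maf <- pair$exposure$eaf
      sey <- 1 / sqrt(2 * maf * (1 - maf) *
                        effective_n(outcomes$n[j], "binary",
                                    outcomes$case_frac[j]))
      by <- stats::rnorm(k, beta_causal * truth$beta_x_true, sey)
      ex <- pair$exposure
      ex$snp <- paste0(exposures$name[i], "_", ex$snp)
      rows[[i]] <- data.frame(snp = ex$snp, chrom = ex$chrom, pos = ex$pos,
                              effect_allele = ex$effect_allele,
                              other_allele = ex$other_allele,
                              eaf = maf, beta = by, se = sey,
                              pval = clamp_p(2 * stats::pnorm(-abs(by / sey))),
                              n = outcomes$n[j],
                              n_case = round(outcomes$n[j] *
                                               outcomes$case_frac[j]),
                              n_control = outcomes$n[j] -
                                round(outcomes$n[j] * outcomes$case_frac[j]),
                              stringsAsFactors = FALSE)
    }
    out_tab <- do.call(rbind, rows)
    out_tab <- new_assoc_table(out_tab, outcomes$name[j], "binary")
    write_gwas_summary(out_tab, file.path(dir,
                                          paste0(outcomes$name[j], ".tsv")))
  }

  # exposure files need the same prefixed ids the outcome files carry
  for (i in seq_len(nrow(exposures))) {
    pair <- exp_tables[[exposures$name[i]]]
    ex <- pair$exposure
    ex$snp <- paste0(exposures$name[i], "_", ex$snp)
    write_gwas_summary(ex, file.path(dir, paste0(exposures$name[i], ".tsv")))
  }

  cfg <- list(
    exposures = lapply(seq_len(nrow(exposures)), function(i)
      list(name = exposures$name[i],
           file = paste0(exposures$name[i], ".tsv"),
           type = exposures$type[i])),
    outcomes = lapply(seq_len(nrow(outcomes)), function(j)
      list(name = outcomes$name[j],
           file = paste0(outcomes$name[j], ".tsv"),
           type = "binary")),
    directions = "forward", p_instrument = 5e-8,
    clump_window_kb = 10000, clump_r2 = 0.001,
    alpha_family = 0.05, n_tests = "auto",
    seed = as.integer(seed), n_boot = n_boot,
    presso_n_sim = presso_n_sim)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
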