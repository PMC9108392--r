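test_that("instrument strength matches the closed-form variance formula", {
  st <- instrument_strength(0.1, 0.01, 0.5)
  expect_equal(st$f, 100)
  expect_equal(st$r2, 0.005)

  st0 <- instrument_strength(0, 0.02, 0.3)
  expect_equal(st0$f, 0)
  expect_equal(st0$r2, 0)

  st2 <- instrument_strength(0.06, 0.0102, 0.25)
  expect_equal(st2$f, (0.06 / 0.0102)^2, tolerance = 1e-12)
  expect_equal(st2$f, 34.6, tolerance = 0.01)
  expect_equal(st2$r2, 2 * 0.06^2 * 0.25 * 0.75)
  expect_equal(st2$r2, 0.00135)

  expect_true(is.na(instrument_strength(0.1, 0.01, NA)$r2))
  expect_error(instrument_strength(0.1, 0.01, 1.2), "eaf")
})

test_that("selection uses a strict p-value threshold and F floor", {
  tab <- quick_table(paste0("rs", 1:3), beta = c(0.1, 0.1, 0.1),
                     se = 0.01, pval = c(1e-9, 1e-7, 5e-8))
  sel <- select_instruments(tab, 5e-8)
  expect_equal(sel$snp, "rs1")  # 5e-8 itself excluded: strict less-than

  sel2 <- select_instruments(tab, 1.01e-7)
  expect_equal(sel2$snp, c("rs1", "rs2", "rs3"))  # input order preserved
  expect_equal(attr(sel2, "pooled_r2"), sum(sel2$r2))

  weak <- quick_table("rs9", beta = 0.01, se = 0.01, pval = 1e-9)
  expect_error(select_instruments(weak, 5e-8, f_min = 10),
               class = "summr_empty_instruments")
  sel3 <- select_instruments(weak, 5e-8, f_min = NULL)
  expect_equal(nrow(sel3), 1)
  expect_error(filter_weak_instruments(sel3, 10),
               class = "summr_empty_instruments")

  all_null <- quick_table(paste0("rs", 1:3), beta = 0.1, se = 0.01,
                          pval = 0.5)
  expect_error(select_instruments(all_null, 5e-8),
               class = "summr_empty_instruments")
})

test_that("greedy clumping keeps the hand-worked set", {
  tab <- quick_table(paste0("rs", 1:3), beta = 0.1, se = 0.01,
                     pval = c(1e-10, 1e-9, 1e-8),
                     chrom = "1", pos = c(1e6, 2e6, 3e6))
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.5
  r2[1, 3] <- r2[3, 1] <- 0.0005
  r2[2, 3] <- r2[3, 2] <- 0.0005
  dimnames(r2) <- list(tab$snp, tab$snp)
  sel <- select_instruments(tab, 5e-7)
  kept <- ld_clump(sel, ld_panel(r2), 0.001, 10000)
  expect_equal(kept$snp, c("rs1", "rs3"))

  # identity matrix keeps everything; full LD keeps the single best
  id <- diag(3)
  dimnames(id) <- list(tab$snp, tab$snp)
  kept_all <- ld_clump(sel, ld_panel(id), 0.001, 10000)
  expect_equal(nrow(kept_all), 3)
  r2_full <- matrix(1, 3, 3, dimnames = list(tab$snp, tab$snp))
  kept_one <- ld_clump(sel, ld_panel(r2_full), 0.001, 10000)
  expect_equal(kept_one$snp, "rs1")
})

test_that("clumping honours the window and reports panel gaps", {
  # same LD but far apart: outside the window both survive
  tab <- quick_table(c("rs1", "rs2"), beta = 0.1, se = 0.01,
                     pval = c(1e-10, 1e-9), chrom = "1",
                     pos = c(1e6, 2e6 + 1e7))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(tab$snp, tab$snp))
  sel <- select_instruments(tab, 5e-7)
  expect_equal(nrow(ld_clump(sel, ld_panel(r2), 0.001, 10000)), 2)
  expect_equal(ld_clump(sel, ld_panel(r2), 0.001, 20000)$snp, "rs1")

  gap <- matrix(1, 1, 1, dimnames = list("rs1", "rs1"))
  expect_error(ld_clump(sel, ld_panel(gap)),
               class = "summr_missing_in_panel")
  expect_error(ld_clump(sel, ld_panel(gap)), "rs2")
})

test_that("clumped output is LD-independent at the threshold", {
  sim <- simulate_ld_panel(6, 5, 0.4, seed = 42)
  sel <- select_instruments(sim$table, 1e-5, f_min = NULL)
  kept <- ld_clump(sel, sim$panel, r2_threshold = 0.001)
  r2 <- sim$panel$r2[kept$snp, kept$snp]
  diag(r2) <- 0
  expect_lt(max(r2), 0.001)
  # block-diagonal panel: exactly one survivor per block, the block minimum
  expect_equal(nrow(kept), 6)
  expect_equal(sort(kept$pval),
               sort(tapply(sim$table$pval,
                           rep(1:6, each = 5), min)), ignore_attr = TRUE)
})

test_that("harmonization follows the allele-orientation truth table", {
  # truth table written before implementation: exposure is A/G, eaf 0.3
  cases <- list(
    list(ea = "A", oa = "G", act = "keep", flip = FALSE),  # identical
    list(ea = "G", oa = "A", act = "keep", flip = TRUE),   # swapped
    list(ea = "T", oa = "C", act = "keep", flip = FALSE),  # strand flip
    list(ea = "C", oa = "T", act = "keep", flip = TRUE),   # strand + swap
    list(ea = "A", oa = "C", act = "drop"),                # half mismatch
    list(ea = "T", oa = "G", act = "drop"),                # irreconcilable
    list(ea = "C", oa = "G", act = "drop"),                # wrong pair
    list(ea = "A", oa = "T", act = "drop"))                # palindromic pair
  for (cs in cases) {
    instr <- select_instruments(
      quick_table("rs1", beta = 0.1, se = 0.01, pval = 1e-10,
                  ea = "A", oa = "G", eaf = 0.3), 5e-8)
    out <- quick_table("rs1", beta = 0.2, se = 0.02, pval = 0.5,
                       ea = cs$ea, oa = cs$oa, eaf = 0.3)
    if (cs$act == "drop") {
      expect_error(harmonize(instr, out),
                   class = "summr_harmonization_empty",
                   info = paste(cs$ea, cs$oa))
    } else {
      h <- harmonize(instr, out)
      expect_equal(h$by, if (cs$flip) -0.2 else 0.2,
                   info = paste(cs$ea, cs$oa))
    }
  }
})

test_that("palindromic variants follow the frequency policy", {
  instr_pal <- function(eaf_x) select_instruments(
    quick_table("rs1", beta = 0.1, se = 0.01, pval = 1e-10,
                ea = "A", oa = "T", eaf = eaf_x), 5e-8)
  out_pal <- function(eaf_y) quick_table("rs1", beta = 0.2, se = 0.02,
                                         pval = 0.5, ea = "A", oa = "T",
                                         eaf = eaf_y)

  # ambiguous band drops under the default policy
  expect_error(harmonize(instr_pal(0.50), out_pal(0.50)),
               class = "summr_harmonization_empty")

  # frequencies agree outside the band: kept unflipped
  h <- harmonize(instr_pal(0.20), out_pal(0.25))
  expect_equal(h$by, 0.2)
  # frequencies disagree: strand inferred flipped
  h2 <- harmonize(instr_pal(0.20), out_pal(0.75))
  expect_equal(h2$by, -0.2)
  expect_equal(h2$eaf_y, 0.25)
  # drop_all removes palindromic variants outright
  expect_error(harmonize(instr_pal(0.20), out_pal(0.25),
                         palindrome_policy = "drop_all"),
               class = "summr_harmonization_empty")
})

test_that("missing outcome variants use proxies or are dropped", {
  instr <- select_instruments(
    quick_table(c("rs1", "rs2"), beta = c(0.1, 0.12), se = 0.01,
                pval = 1e-10, eaf = 0.3), 5e-8)
  out <- quick_table(c("rs1", "rs2_proxy"), beta = c(0.2, 0.3), se = 0.02,
                     pval = 0.5, eaf = 0.3)
  h <- harmonize(instr, out)
  expect_equal(h$snp, "rs1")
  expect_equal(h$dropped$reason, "missing_in_outcome")

  pan <- ld_panel(matrix(1, 1, 1, dimnames = list("rs1", "rs1")),
                  proxy_table = data.frame(snp = "rs2",
                                           proxy = "rs2_proxy", r2 = 0.9))
  h2 <- harmonize(instr, out, panel = pan)
  expect_equal(nsnp(h2), 2)
  expect_equal(h2$by[2], 0.3)   # proxy outcome effect
  expect_equal(h2$bx[2], 0.12)  # exposure stats stay the original's
  expect_match(h2$notes, "proxy", all = FALSE)
})

test_that("harmonization is idempotent on aligned data", {
  truth <- sim_truth(n_instruments = 12, seed = 7)
  pair <- simulate_gwas_pair(truth)
  instr <- select_instruments(pair$exposure, 5e-8, f_min = NULL)
  h1 <- harmonize(instr, pair$outcome)
  # the generator emits aligned tables, so nothing may flip or drop
  expect_equal(nsnp(h1), nrow(instr))
  out_idx <- match(h1$snp, pair$outcome$snp)
  expect_equal(h1$by, pair$outcome$beta[out_idx])
  expect_equal(nrow(h1$dropped), 0)
})

test_that("filter_snps removes the requested variants and accounts for them", {
  h <- toy_b()
  expect_identical(filter_snps(h, character(0)), h)
  h2 <- filter_snps(h, "snp2", reason = "pleiotropic")
  expect_equal(nsnp(h2), 2)
  expect_equal(h2$dropped$reason, "pleiotropic")
  expect_equal(h2$bx, c(0.1, 0.3))
  expect_error(filter_snps(h, h$snp), class = "summr_harmonization_empty")
  # count arithmetic mirrors excluding 46 of 121 pleiotropic variants
  big <- harmonized_set(bx = rep(0.1, 121), sex = rep(0.01, 121),
                        by = rep(0.05, 121), sey = rep(0.02, 121))
  kept <- filter_snps(big, paste0("snp", 1:46), reason = "pleiotropic")
  expect_equal(nsnp(kept), 75)
})

test_that("selection on simulated strong instruments lands in the reported F envelope", {
  # mean true F target 35 = n * h2 / k
  meds <- vapply(1:20, function(s) {
    truth <- sim_truth(n_instruments = 100, instrument_h2 = 0.01,
                       n_exp = 350000, exposure_type = "continuous",
                       seed = s)
    pair <- simulate_gwas_pair(truth)
    sel <- select_instruments(pair$exposure, 5e-8)
    median(sel$f_stat)
  }, numeric(1))
  expect_gt(mean(meds), 29)
  expect_lt(mean(meds), 42)
})
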