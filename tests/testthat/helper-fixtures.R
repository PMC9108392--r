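# Shared fixtures: the two hand-computed toy sets and small builders.

# Exact-fit set: by = 0.5 * bx, so every ratio-based method returns 0.5
# and all heterogeneity statistics vanish.
toy_a <- function() {
  harmonized_set(bx = c(0.1, 0.2, 0.3), sex = rep(0.001, 3),
                 by = 0.5 * c(0.1, 0.2, 0.3), sey = rep(0.02, 3))
}

# Heterogeneous set with hand-worked oracles: IVW 0.4, Egger slope 0.2 /
# intercept 0.046667, WME 0.4, Q 6.5 (I2 69.23%), ratios (0.5, 0.6, 0.3).
toy_b <- function() {
  harmonized_set(bx = c(0.1, 0.2, 0.3), sex = rep(0.02, 3),
                 by = c(0.05, 0.12, 0.09), sey = rep(0.02, 3))
}

# A small valid summary table written to a temp TSV; returns the path.
write_toy_gwas <- function(lines = NULL) {
  path <- tempfile(fileext = ".tsv")
  if (is.null(lines)) {
    lines <- c("SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
               "rs1\tA\tG\t0.30\t0.10\t0.010\t1e-20\t100000",
               "rs2\tC\tT\t0.45\t-0.08\t0.012\t1e-12\t100000",
               "rs3\tG\tA\t0.20\t0.05\t0.009\t1e-9\t100000")
  }
  writeLines(lines, path)
  path
}

# Quick association table from vectors with defaults filled in.
quick_table <- function(snp, beta, se, pval, ea = "A", oa = "G",
                        eaf = 0.3, n = 1e5, chrom = NA, pos = NA,
                        trait = "trait", type = "continuous") {
  assoc_table(snp = snp, effect_allele = ea, other_allele = oa,
              eaf = eaf, beta = beta, se = se, pval = pval, n = n,
              chrom = chrom, pos = pos, trait_name = trait,
              trait_type = type)
}
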