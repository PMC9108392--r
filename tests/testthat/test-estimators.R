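test_that("Wald ratios match hand arithmetic and reject zero bx", {
  h <- harmonized_set(bx = 0.2, sex = 0.01, by = 0.1, sey = 0.02)
  wr <- wald_ratios(h)
  expect_equal(wr$theta, 0.5)
  expect_equal(wr$theta_se, 0.1)

  wrB <- wald_ratios(toy_b())
  expect_equal(wrB$theta, c(0.5, 0.6, 0.3))

  h0 <- harmonized_set(bx = c(0.2, 0), sex = c(0.01, 0.01),
                       by = c(0.1, 0), sey = c(0.02, 0.02))
  expect_error(wald_ratios(h0), class = "summr_degenerate_instrument")

  hz <- harmonized_set(bx = c(0.1, 0.2), sex = 0.01, by = c(0, 0),
                       sey = 0.02)
  expect_equal(wald_ratios(hz)$theta, c(0, 0))
})

test_that("IVW reproduces the closed-form toy values", {
  a <- mr_ivw(toy_a())
  expect_equal(a$beta, 0.5, tolerance = 1e-12)
  expect_equal(a$se, 1 / sqrt(350), tolerance = 1e-12)

  b <- mr_ivw(toy_b())
  expect_equal(b$beta, 0.4, tolerance = 1e-12)

  # floored multiplicative SE never undercuts the fixed-effect SE
  b_fixed <- mr_ivw(toy_b(), re_model = "fixed")
  expect_gte(b$se, b_fixed$se)
  a2 <- mr_ivw(toy_a(), re_model = "multiplicative_floored")
  expect_equal(a2$se, 1 / sqrt(350), tolerance = 1e-12)  # Q = 0: floor binds

  one <- harmonized_set(bx = 0.2, sex = 0.01, by = 0.1, sey = 0.02)
  est <- suppressMessages(mr_ivw(one))
  expect_equal(est$method, "wald")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
})

test_that("IVW is the inverse-variance meta-analysis of the Wald ratios", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    h <- harmonized_set(bx = runif(k, 0.02, 0.3) * sample(c(-1, 1), k, TRUE),
                        sex = runif(k, 0.001, 0.01),
                        by = rnorm(k, 0, 0.05), sey = runif(k, 0.005, 0.05))
    wr <- wald_ratios(h)
    w <- 1 / wr$theta_se^2
    meta <- sum(w * wr$theta) / sum(w)
    expect_equal(mr_ivw(h, re_model = "fixed")$beta, meta,
                 tolerance = 1e-12)
    expect_equal(mr_ivw(h, re_model = "fixed")$se, 1 / sqrt(sum(w)),
                 tolerance = 1e-12)
  }
})

test_that("rescaling the exposure rescales every estimate reciprocally", {
  h <- toy_b()
  c_scale <- 2.5
  hs <- harmonized_set(bx = h$bx * c_scale, sex = h$sex * c_scale,
                       by = h$by, sey = h$sey)
  expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / c_scale, tolerance = 1e-12)
  expect_equal(mr_egger(hs)$beta, mr_egger(h)$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, n_boot = 0)$beta,
               mr_weighted_median(h, n_boot = 0)$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(hs, n_boot = 0)$beta,
               mr_weighted_mode(h, n_boot = 0)$beta / c_scale,
               tolerance = 1e-3)
})

test_that("MR-Egger matches the hand WLS oracle and is orientation invariant", {
  a <- mr_egger(toy_a())
  expect_equal(a$beta, 0.5, tolerance = 1e-9)
  expect_equal(a$egger_intercept, 0, tolerance = 1e-9)
  expect_gt(a$intercept_pval, 0.99)

  b <- mr_egger(toy_b())
  expect_equal(b$beta, 0.2, tolerance = 1e-12)
  expect_equal(b$egger_intercept, 0.046667, tolerance = 1e-5)

  # joint negation of one variant's (bx, by) leaves the fit unchanged
  h <- toy_b()
  hneg <- harmonized_set(bx = h$bx * c(-1, 1, 1), sex = h$sex,
                         by = h$by * c(-1, 1, 1), sey = h$sey)
  bn <- mr_egger(hneg)
  expect_equal(bn$beta, b$beta, tolerance = 1e-12)
  expect_equal(bn$egger_intercept, b$egger_intercept, tolerance = 1e-12)

  two <- harmonized_set(bx = c(0.1, 0.2), sex = 0.01, by = c(0.05, 0.1),
                        sey = 0.02)
  expect_error(mr_egger(two), class = "summr_insufficient_instruments")
})

test_that("weighted median interpolates the hand oracle and ignores order", {
  b <- mr_weighted_median(toy_b(), n_boot = 0)
  expect_equal(b$beta, 0.4, tolerance = 1e-12)

  h <- toy_b()
  perm <- c(3, 1, 2)
  hp <- harmonized_set(bx = h$bx[perm], sex = h$sex[perm],
                       by = h$by[perm], sey = h$sey[perm])
  expect_equal(mr_weighted_median(hp, n_boot = 0)$beta, b$beta,
               tolerance = 1e-12)

  # identical ratios: estimate equals the common ratio, bootstrap SE small
  hc <- harmonized_set(bx = c(0.1, 0.2, 0.3), sex = rep(1e-6, 3),
                       by = 0.7 * c(0.1, 0.2, 0.3), sey = rep(1e-6, 3))
  est <- mr_weighted_median(hc, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.7, tolerance = 1e-9)
  expect_lt(est$se, 1e-4)

  # seeded bootstrap is reproducible
  e1 <- mr_weighted_median(toy_b(), n_boot = 200, seed = 5)
  e2 <- mr_weighted_median(toy_b(), n_boot = 200, seed = 5)
  expect_identical(e1$se, e2$se)
  expect_warning(mr_weighted_median(toy_b(), n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("weighted mode finds the dominant ratio cluster", {
  # three ratios at 0.5, one at 2.0, equal weights: mode near 0.5
  h <- harmonized_set(bx = rep(0.2, 4), sex = rep(0.01, 4),
                      by = c(0.1, 0.1, 0.1, 0.4), sey = rep(0.02, 4))
  est <- mr_weighted_mode(h, n_boot = 0)
  theta <- h$by / h$bx
  spread <- min(sd(theta), mad(theta))
  if (spread == 0) spread <- sd(theta)  # same tie fallback as the estimator
  bw <- 0.9 * spread * 4^(-1 / 5)
  expect_lt(abs(est$beta - 0.5), bw)

  # identical ratios collapse to the common value
  hc <- harmonized_set(bx = c(0.1, 0.2, 0.3), sex = rep(0.01, 3),
                       by = 0.7 * c(0.1, 0.2, 0.3), sey = rep(0.02, 3))
  expect_equal(mr_weighted_mode(hc, n_boot = 0)$beta, 0.7)

  # the mode of a kernel mixture stays inside the ratio range for any phi
  for (phi in c(0.5, 1, 2, 4)) {
    est_phi <- mr_weighted_mode(h, phi = phi, n_boot = 0)
    expect_gte(est_phi$beta, min(theta))
    expect_lte(est_phi$beta, max(theta))
  }
  expect_error(mr_weighted_mode(h, phi = 0, n_boot = 0), "phi")
})

test_that("estimate_all gates methods on their preconditions", {
  res <- estimate_all(toy_a(), n_boot = 0)
  expect_setequal(res$method, c("ivw", "egger", "wme", "mbe"))
  expect_equal(res$beta[res$method == "ivw"], 0.5, tolerance = 1e-9)
  expect_equal(res$beta[res$method == "egger"], 0.5, tolerance = 1e-6)
  expect_equal(res$beta[res$method == "wme"], 0.5, tolerance = 1e-9)
  expect_equal(res$beta[res$method == "mbe"], 0.5, tolerance = 1e-3)

  two <- harmonized_set(bx = c(0.1, 0.2), sex = 0.01, by = c(0.05, 0.1),
                        sey = 0.02)
  res2 <- estimate_all(two, n_boot = 0)
  expect_false(is.na(res2$beta[res2$method == "ivw"]))
  for (m in c("egger", "wme", "mbe")) {
    row <- res2[res2$method == m, ]
    expect_true(is.na(row$beta))
    expect_match(row$note, "not applicable")
  }
})

test_that("binary outcomes are reported on the odds-ratio scale", {
  h <- toy_b()
  h$outcome_type <- "binary"
  est <- mr_ivw(h)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
  expect_true(est$or_ci_low <= est$or & est$or <= est$or_ci_high)
  cont <- mr_ivw(toy_b())
  expect_true(is.na(cont$or))
})

test_that("confidence intervals always bracket the estimate", {
  set.seed(3)
  for (i in 1:10) {
    h <- simulate_harmonized(sim_truth(n_instruments = 20, seed = i))
    for (est in list(mr_ivw(h), mr_egger(h),
                     mr_weighted_median(h, n_boot = 100, seed = i),
                     mr_weighted_mode(h, n_boot = 100, seed = i))) {
      expect_lte(est$ci_low, est$beta)
      expect_gte(est$ci_high, est$beta)
      expect_gt(est$pval, 0)
      expect_lte(est$pval, 1)
    }
  }
})
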