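test_that("the Steiger z follows the Fisher-z arithmetic oracle", {
  # equal variance explained: symmetric null, no direction claim
  h_eq <- harmonized_set(bx = c(0.1, 0.1), sex = 0.01, by = c(0.1, 0.1),
                         sey = 0.01, eaf_x = 0.3, eaf_y = 0.3,
                         n_x = 1e5, n_y = 1e5)
  st <- steiger_test(h_eq)
  expect_equal(st$zval, 0)
  expect_equal(st$pval, 1)
  expect_false(st$direction_ok)

  # hand-built r2 values 0.05 vs 0.001 at n = 400k (one variant carries
  # the whole variance explained)
  bx <- sqrt(0.05 / (2 * 0.3 * 0.7))
  by <- sqrt(0.001 / (2 * 0.3 * 0.7))
  h <- harmonized_set(bx = bx, sex = 0.01, by = by, sey = 0.01,
                      eaf_x = 0.3, eaf_y = 0.3, n_x = 4e5, n_y = 4e5)
  st2 <- steiger_test(h)
  expect_equal(st2$r2_exposure, 0.05, tolerance = 1e-12)
  expect_equal(st2$r2_outcome, 0.001, tolerance = 1e-12)
  z_oracle <- (atanh(sqrt(0.05)) - atanh(sqrt(0.001))) /
    sqrt(2 / (4e5 - 3))
  expect_equal(st2$zval, z_oracle, tolerance = 1e-12)
  expect_true(st2$direction_ok)
  expect_lt(st2$pval, 1e-10)
})

test_that("swapping exposure and outcome flips the Steiger direction exactly", {
  h <- simulate_harmonized(sim_truth(n_instruments = 25, seed = 12))
  fwd <- steiger_test(h)
  swapped <- harmonized_set(bx = h$by, sex = h$sey, by = h$bx,
                            sey = h$sex, eaf_x = h$eaf_y, eaf_y = h$eaf_x,
                            n_x = h$n_y, n_y = h$n_x)
  rev <- steiger_test(swapped)
  expect_equal(rev$zval, -fwd$zval, tolerance = 1e-12)
  expect_equal(rev$pval, fwd$pval, tolerance = 1e-12)
  expect_equal(rev$direction_ok, !fwd$direction_ok)
})

test_that("forward-causal simulations give the right direction nearly always", {
  ok <- vapply(1:200, function(i) {
    h <- simulate_harmonized(sim_truth(beta_causal = 0.2,
                                       n_instruments = 30,
                                       seed = 5000 + i))
    steiger_test(h)$direction_ok
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("missing inputs fail loudly", {
  h <- harmonized_set(bx = c(0.1, 0.2), sex = 0.01, by = c(0.05, 0.1),
                      sey = 0.02)  # no eaf, no n
  expect_error(steiger_test(h), "sample sizes")
  expect_error(steiger_test(h, n_x = 1e5, n_y = 1e5), "frequencies")
})

test_that("binary-outcome power follows the noncentrality formula", {
  sp <- power_spec(n = 455258, case_fraction = 0.158, r2 = 0.0575,
                   alpha = 1.42e-3)
  # null effect: power collapses to alpha/2 under the normal approximation
  expect_equal(power_binary(sp, 1), sp$alpha / 2, tolerance = 1e-12)
  # direct substitution oracle
  b <- log(1.19)
  oracle <- pnorm(sqrt(455258 * 0.0575 * 0.158 * 0.842) * b -
                    qnorm(1 - 1.42e-3 / 2))
  expect_equal(power_binary(sp, 1.19), oracle, tolerance = 1e-12)
  # saturation with overwhelming instrument strength
  sp_big <- power_spec(n = 455258, case_fraction = 0.158, r2 = 0.4,
                       alpha = 1.42e-3)
  expect_gt(power_binary(sp_big, 1.19), 0.999)
  expect_error(power_binary(sp, -1), "odds_ratio")
})

test_that("power is monotone in n, r2 and effect size", {
  base <- power_spec(n = 5e4, case_fraction = 0.2, r2 = 0.02,
                     alpha = 1.42e-3)
  expect_lt(power_binary(base, 1.1), power_binary(base, 1.3))
  expect_lt(power_binary(base, 1 / 1.3), power_binary(base, 1 / 1.5))
  bigger_n <- power_spec(n = 2e5, case_fraction = 0.2, r2 = 0.02,
                         alpha = 1.42e-3)
  expect_lt(power_binary(base, 1.2), power_binary(bigger_n, 1.2))
  bigger_r2 <- power_spec(n = 5e4, case_fraction = 0.2, r2 = 0.06,
                          alpha = 1.42e-3)
  expect_lt(power_binary(base, 1.2), power_binary(bigger_r2, 1.2))
  stricter <- power_spec(n = 5e4, case_fraction = 0.2, r2 = 0.02,
                         alpha = 1e-6)
  expect_gt(power_binary(base, 1.2), power_binary(stricter, 1.2))
})

test_that("power agrees with a Monte-Carlo score-test oracle", {
  # down-scaled sample with re-scaled r2, score test on simulated cohorts
  n <- 8000; K <- 0.158; r2 <- 0.03; alpha <- 1.42e-3
  sp <- power_spec(n = n, case_fraction = K, r2 = r2, alpha = alpha)
  or <- 1.25
  analytic <- power_binary(sp, or)
  set.seed(99)
  zcrit <- qnorm(1 - alpha / 2)
  rejections <- vapply(1:4000, function(i) {
    s <- rnorm(n, 0, sqrt(r2))           # instrument score, exposure SD units
    eta <- qlogis(K) + log(or) * s
    y <- rbinom(n, 1, plogis(eta))
    ybar <- mean(y)
    z <- sum((y - ybar) * s) / sqrt(ybar * (1 - ybar) * sum(s^2))
    abs(z) > zcrit
  }, logical(1))
  expect_lt(abs(mean(rejections) - analytic), 0.02)
})

test_that("detectable effects invert the power function symmetrically", {
  sp <- power_spec(n = 455258, case_fraction = 0.158, r2 = 0.0575,
                   alpha = 1.42e-3, power_target = 0.8)
  risky <- detectable_effect(sp, "risky")
  protective <- detectable_effect(sp, "protective")
  expect_gt(risky, 1)
  expect_lt(protective, 1)
  expect_equal(risky * protective, 1, tolerance = 1e-9)
  expect_equal(power_binary(sp, risky), 0.8, tolerance = 1e-4)
  expect_equal(power_binary(sp, protective), 0.8, tolerance = 1e-4)

  # quadrupling r2 halves the detectable log-OR (NCP scales with r2 b^2)
  sp4 <- power_spec(n = 455258, case_fraction = 0.158, r2 = 4 * 0.0575,
                    alpha = 1.42e-3, power_target = 0.8)
  expect_equal(log(detectable_effect(sp4, "risky")), log(risky) / 2,
               tolerance = 1e-6)
})

test_that("the power grid mirrors the supplementary layout", {
  outcomes <- data.frame(outcome = c("A", "B"), n = c(4e5, 5e4),
                         case_fraction = c(0.158, 0.3))
  grid <- power_grid(outcomes, r2_values = c(0.0025, 0.025, 0.075))
  expect_equal(nrow(grid), 6)
  expect_equal(grid$detectable_or_risky * grid$detectable_or_protective,
               rep(1, 6), tolerance = 1e-9)
  # detectable effects shrink with instrument strength
  expect_true(all(diff(grid$detectable_or_risky[1:3]) < 0))
})

test_that("the Bonferroni threshold matches the family arithmetic", {
  thr <- bonferroni_threshold(35, 0.05)
  expect_equal(thr, 0.05 / 35, tolerance = 1e-15)
  expect_gte(thr, 1.42e-3)
  expect_lt(thr, 1.43e-3)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(70, 0.05), 7.142857e-4,
               tolerance = 1e-6)
  expect_error(bonferroni_threshold(0, 0.05))
})
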