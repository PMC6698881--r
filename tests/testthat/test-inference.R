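test_that("bootstrap resamples families reproducibly and matches the full fit", {
  co <- generate_cohort(quick_config(n_families = 300, seed = 21))
  b1 <- bootstrap_pairs(co, "outcome", "gps", n_boot = 100, seed = 7)
  b2 <- bootstrap_pairs(co, "outcome", "gps", n_boot = 100, seed = 7)
  expect_identical(b1$reps, b2$reps)
  expect_equal(b1$beta_w, b1$fit$coefficients[["gps_within"]])
  # replicate estimator is the same estimator as the full-sample fit:
  # a "resample" equal to the original data reproduces the fit exactly
  rot <- twinwb:::.boot_design(validate_pairs(co, c("outcome", "gps")),
                               "outcome", "gps", character())
  bb <- twinwb:::.boot_betas(rot, seq_len(nrow(co) / 2))
  expect_equal(unname(bb["beta_w"]), b1$beta_w, tolerance = 1e-10)
  expect_equal(unname(bb["beta_b"]), b1$beta_b, tolerance = 1e-10)
})

test_that("bootstrap CI endpoints are stable across seeds", {
  co <- generate_cohort(quick_config(n_families = 1000, seed = 22))
  bA <- bootstrap_pairs(co, "outcome", "gps", n_boot = 500, seed = 1)
  bB <- bootstrap_pairs(co, "outcome", "gps", n_boot = 500, seed = 2)
  expect_lt(max(abs(bA$ci - bB$ci)), 0.02)
})

test_that("degenerate outcome equal to predictor collapses the bootstrap", {
  co <- random_pair_cohort(50, seed = 3)
  co$outcome <- co$gps
  b <- bootstrap_pairs(co, "outcome", "gps", n_boot = 50, seed = 1)
  expect_true(all(abs(b$reps[, "beta_w"] - 1) < 1e-8))
  expect_true(all(abs(b$reps[, "beta_b"] - 1) < 1e-8))
  expect_lt(max(b$ci[2, ] - b$ci[1, ]), 1e-8)
  expect_error(diff_test(b), "degenerate")
})

test_that("difference test is centered and invariant to outcome shifts", {
  co <- generate_cohort(quick_config(n_families = 500, seed = 23))
  b <- bootstrap_pairs(co, "outcome", "gps", n_boot = 300, seed = 9)
  dt <- diff_test(b)
  expect_equal(dt$z, (b$beta_b - b$beta_w) / b$diff_sd)
  expect_equal(dt$p, 2 * pnorm(-abs(dt$z)))
  co2 <- co
  co2$outcome <- co2$outcome + 100
  b2 <- bootstrap_pairs(co2, "outcome", "gps", n_boot = 300, seed = 9)
  expect_equal(diff_test(b2)$z, dt$z, tolerance = 1e-6)
})

test_that("attenuation is the percentage change with a bootstrap CI", {
  expect_equal(attenuation(beta_w = 0.2, beta_b = 0.4)$attenuation_pct, 50)
  expect_equal(attenuation(beta_w = 0.3, beta_b = 0.3)$attenuation_pct, 0)
  a0 <- attenuation(beta_w = 0.2, beta_b = 0)
  expect_false(a0$defined)
  expect_true(is.na(a0$attenuation_pct))

  co <- generate_cohort(quick_config(n_families = 800, beta_direct = 0.2,
                                     beta_nurture = 0.3, seed = 24))
  b <- bootstrap_pairs(co, "outcome", "gps", n_boot = 400, seed = 11)
  a <- attenuation(b)
  expect_true(a$defined)
  expect_true(a$ci[1] < a$attenuation_pct && a$attenuation_pct < a$ci[2])
})

test_that("mean attenuation matches its analytic expectation under nurture", {
  # with beta_nurture = 1.5 * beta_direct the between slope is twice the
  # within slope in expectation (midparent loads on family means with
  # coefficient cov(mid, zbar)/var(zbar) = 2/3), giving 50% attenuation
  vals <- vapply(1:30, function(s) {
    co <- generate_cohort(sim_config(n_families = 1500, n_loci = 120,
                                     beta_direct = 0.2, beta_nurture = 0.3,
                                     seed = 3000 + s))
    ft <- fit_within_between(co, "outcome", "gps")
    100 * (ft$coefficients[["gps_between"]] -
             ft$coefficients[["gps_within"]]) /
      ft$coefficients[["gps_between"]]
  }, numeric(1))
  expect_equal(mean(vals), 50, tolerance = 5)
})

test_that("SES conditioning shrinks the between coefficient, leaves within alone", {
  cfg <- sim_config(n_families = 1500, n_loci = 120, beta_direct = 0.3,
                    beta_nurture = 0.3, lambda_ses = 1, nu_ses = 0,
                    sigma_ses = 0, seed = 91)
  co <- generate_cohort(cfg)
  b <- bootstrap_pairs(co, "outcome", "gps", n_boot = 300, seed = 5,
                       adjusted_covariates = "ses")
  sh <- covariate_shift_test(b)
  expect_gt(sh$delta_beta_b, 0)
  expect_lt(sh$p, 0.05)
  # the within-family coefficient does not move under SES adjustment
  expect_lt(abs(sh$delta_beta_w), 0.02)
  # adjusted between estimate approaches the within estimate
  badj <- b$fit_adjusted$coefficients
  expect_lt(abs(badj[["gps_between"]] - badj[["gps_within"]]), 0.12)
})

test_that("a covariate independent of everything changes nothing", {
  co <- generate_cohort(quick_config(n_families = 600, seed = 25))
  set.seed(99)
  co$noise_cov <- rep(rnorm(600), each = 2)
  b <- bootstrap_pairs(co, "outcome", "gps", n_boot = 300, seed = 6,
                       adjusted_covariates = "noise_cov")
  sh <- covariate_shift_test(b)
  expect_lt(abs(sh$delta_beta_b), 0.02)
  expect_gt(sh$p, 0.05)
  expect_error(covariate_shift_test(
    bootstrap_pairs(co, "outcome", "gps", n_boot = 10, seed = 1)),
    "adjusted_covariates")
})

test_that("BH step-up matches brute-force enumeration and p.adjust", {
  r <- bh_fdr(c(0.001, 0.012, 0.02, 0.9), alpha = 0.05)
  expect_equal(r$threshold, 0.02)
  expect_equal(r$n_discoveries, 3L)

  expect_equal(bh_fdr(rep(1, 5))$n_discoveries, 0L)
  r1 <- bh_fdr(0.04, alpha = 0.05)
  expect_equal(r1$threshold, 0.04)
  expect_equal(r1$n_discoveries, 1L)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(42)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 4)
    a <- runif(1, 0.01, 0.2)
    mine <- bh_fdr(p, a)
    ref <- brute_force_bh(p, a)
    expect_identical(mine$significant, ref$significant)
    expect_identical(mine$threshold, ref$threshold)
    # cross-check against the standard adjusted-p formulation
    expect_identical(mine$significant, p.adjust(p, "BH") <= a)
  }
})

test_that("BH controls the false discovery proportion under a global null", {
  set.seed(7)
  fdp <- replicate(400, {
    r <- bh_fdr(runif(20), alpha = 0.05)
    r$n_discoveries > 0
  })
  expect_lt(mean(fdp), 0.05 + 0.03)
})
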