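test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(n_loci = 0), "n_loci")
  expect_error(sim_config(freq_low = 0), "freq")
  expect_error(sim_config(freq_low = 0.6, freq_high = 0.4), "freq")
  expect_error(sim_config(r_mate = 1), "r_mate")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(sigma_e = -1), "SD parameters")
})

test_that("parent genotypes follow the configured allele frequencies", {
  cfg <- sim_config(n_families = 4000, n_loci = 20, freq_low = 0.5,
                    freq_high = 0.5, seed = 1)
  pool <- simulate_parents(cfg, seed = 1)
  # binomial(2, 0.5) has mean dosage 1 at every locus
  expect_equal(mean(colMeans(pool$fathers)), 1.0, tolerance = 0.02)
  expect_equal(dim(pool$fathers), c(4000L, 20L))
})

test_that("Balding-Nichols drift spreads subpopulation frequencies as p(1-p)fst", {
  cfg <- sim_config(n_families = 100, n_loci = 2000, n_subpops = 2,
                    fst = 0.5, freq_low = 0.3, freq_high = 0.7, seed = 2)
  pool <- simulate_parents(cfg, seed = 2)
  # per-locus between-subpopulation variance of realized frequencies,
  # averaged over loci, matches the Balding-Nichols variance
  v_real <- mean(apply(pool$subpop_freqs, 2, var))
  v_theory <- mean(pool$freqs * (1 - pool$freqs) * 0.5)
  expect_gt(v_real, 0)
  expect_equal(v_real, v_theory, tolerance = 0.15)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- quick_config(n_families = 50, seed = 99)
  pool1 <- simulate_parents(cfg, seed = 42)
  pool2 <- simulate_parents(cfg, seed = 42)
  expect_identical(pool1$fathers, pool2$fathers)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
})

test_that("Mendelian transmission honors parental alleles", {
  # forced heterozygote: AA x aa -> always dosage 1
  expect_equal(transmit(rep(2, 50), rep(0, 50), seed = 1), rep(1, 50))
  # het x het: dosage distribution {0: 1/4, 1: 1/2, 2: 1/4}
  off <- transmit(rep(1, 40000), rep(1, 40000), seed = 2)
  tab <- tabulate(off + 1, nbins = 3) / 40000
  expect_equal(tab, c(0.25, 0.5, 0.25), tolerance = 0.02)
  expect_error(transmit(3, 1), "dosages")
})

test_that("every offspring allele is traceable to a parental allele", {
  cfg <- quick_config(n_families = 80, n_loci = 60, seed = 7)
  co <- generate_cohort(cfg, keep_genotypes = TRUE)
  par <- attr(co, "parents")
  geno <- attr(co, "genotypes")
  for (m in 1:2) {
    off <- geno[co$member == m, , drop = FALSE]
    fa <- par$fathers
    mo <- par$mothers
    # per parent contribution bounds: offspring dosage must lie between
    # floor-sum and ceiling-sum of possible parental gametes
    min_gam <- function(g) (g == 2) * 1
    max_gam <- function(g) (g >= 1) * 1
    lo <- min_gam(fa) + min_gam(mo)
    hi <- max_gam(fa) + max_gam(mo)
    expect_true(all(off >= lo & off <= hi))
  }
})

test_that("co-twin polygenic scores correlate near 0.5 under random mating", {
  cfg <- sim_config(n_families = 3000, n_loci = 400, r_mate = 0, fst = 0,
                    seed = 31)
  co <- generate_cohort(cfg)
  r <- cor(co$gps[co$member == 1], co$gps[co$member == 2])
  expect_equal(r, 0.5, tolerance = 0.03)
})

test_that("assortative mating calibrates mate correlation and inflates sibling correlation", {
  cfg <- sim_config(n_families = 5000, n_loci = 200, seed = 17)
  pool <- simulate_parents(cfg, seed = 17)
  w <- rnorm(cfg$n_loci)
  zf <- as.numeric(pool$fathers %*% w)
  zm <- as.numeric(pool$mothers %*% w)

  m0 <- mate_assortatively(zf, zm, pool$subpop, r_mate = 0, seed = 5)
  expect_lt(abs(cor(zf, zm[m0])), 0.05)

  m4 <- mate_assortatively(zf, zm, pool$subpop, r_mate = 0.4, seed = 5)
  expect_lt(abs(cor(zf, zm[m4]) - 0.4), 0.05)

  expect_error(mate_assortatively(zf, zm, r_mate = 1.2), "r_mate")

  # strong assortment pushes the sibling score correlation above 0.5
  cfg9 <- sim_config(n_families = 2500, n_loci = 200, r_mate = 0.9, seed = 23)
  co9 <- generate_cohort(cfg9)
  r9 <- cor(co9$gps[co9$member == 1], co9$gps[co9$member == 2])
  expect_gt(r9, 0.55)
})

test_that("cohort table has the contracted shape and family-constant fields", {
  cfg <- quick_config(n_families = 10, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 20L)
  expect_equal(length(unique(co$family_id)), 10L)
  for (col in c("ses", "subpop", "true_midparent", "true_shared_env",
                "true_subpop_shift")) {
    per_fam <- tapply(co[[col]], co$family_id, function(v) length(unique(v)))
    expect_true(all(per_fam == 1L), info = col)
  }
})

test_that("pure nurture yields a between-family but no within-family signal", {
  # analytic expectation under the generative model: with beta_direct = 0 the
  # within-pair outcome difference is independent of the score difference,
  # while family means inherit the mid-parent pathway
  cfg <- sim_config(n_families = 3000, n_loci = 150, beta_direct = 0,
                    beta_nurture = 0.5, c_shared = 0.3, seed = 13)
  co <- generate_cohort(cfg)
  ft <- fit_within_between(co, "outcome", "gps")
  expect_lt(abs(ft$coefficients[["gps_within"]]), 0.05)
  expect_gt(ft$coefficients[["gps_between"]], 0.2)
})

test_that("with all family-level terms off, within and between slopes converge", {
  cfg <- sim_config(n_families = 4000, n_loci = 150, beta_direct = 0.3,
                    beta_nurture = 0, c_shared = 0, strat_shift = 0,
                    r_mate = 0, sigma_e = 0.9, seed = 29)
  co <- generate_cohort(cfg)
  ft <- fit_within_between(co, "outcome", "gps")
  expect_equal(ft$coefficients[["gps_within"]],
               ft$coefficients[["gps_between"]], tolerance = 0.06)
  expect_equal(ft$coefficients[["gps_within"]], 0.3, tolerance = 0.05)
})

test_that("config files round-trip through YAML with field validation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_families: 25", "n_loci: 40", "seed: 8", "r_mate: 0.2"),
             path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_families, 25L)
  expect_equal(cfg$r_mate, 0.2)

  writeLines(c("n_families: 25", "seed: 1", "not_a_field: 3"), path)
  expect_error(read_sim_config(path), "not_a_field")
  writeLines("n_loci: 40", path)
  expect_error(read_sim_config(path), "n_families")
})
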