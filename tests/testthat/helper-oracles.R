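# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Closed-form paired-OLS oracle for balanced 2-member clusters without extra
# covariates: the GLS problem decouples, so beta_w is the through-origin OLS
# slope of within-pair outcome differences on score differences, and beta_b
# (with the intercept) is the OLS of pair means on pair mean scores.
paired_ols_oracle <- function(cohort, outcome, predictor) {
  o <- cohort[order(cohort$family_id, cohort$member), ]
  i1 <- seq(1, nrow(o), 2)
  i2 <- i1 + 1
  dy <- o[[outcome]][i1] - o[[outcome]][i2]
  dx <- o[[predictor]][i1] - o[[predictor]][i2]
  my <- (o[[outcome]][i1] + o[[outcome]][i2]) / 2
  mx <- (o[[predictor]][i1] + o[[predictor]][i2]) / 2
  beta_w <- sum(dx * dy) / sum(dx^2)
  fit_b <- lm(my ~ mx)
  c(beta_w = beta_w, beta_b = unname(coef(fit_b)[2]),
    intercept = unname(coef(fit_b)[1]))
}

# Brute-force Benjamini-Hochberg step-up: for every candidate p-value test
# the printed rule directly (rank of p <= (rank/m) * alpha), then take the
# largest passing p as threshold.
brute_force_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  ps <- sort(p)
  passing <- c()
  for (k in seq_len(m)) {
    if (ps[k] <= (k / m) * alpha) passing <- c(passing, ps[k])
  }
  if (length(passing) == 0)
    return(list(threshold = NA_real_, significant = rep(FALSE, m)))
  thr <- max(passing)
  list(threshold = thr, significant = p <= thr)
}

# A random balanced twin cohort with no generative structure, for exactness
# checks of the estimator algebra.
random_pair_cohort <- function(n_pairs, seed) {
  set.seed(seed)
  data.frame(
    family_id = rep(seq_len(n_pairs), each = 2),
    member = rep(c(1L, 2L), n_pairs),
    gps = rnorm(2 * n_pairs),
    outcome = rnorm(2 * n_pairs),
    ses = rep(rnorm(n_pairs), each = 2)
  )
}

# Small-cohort defaults that keep simulation-heavy tests fast while
# preserving the generative structure (loci count only affects Monte-Carlo
# noise in the score correlation, not the estimators under test).
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_families = 500L, n_loci = 150L)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  do.call(sim_config, defaults)
}
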