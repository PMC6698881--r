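# Percentile bootstrap quantiles via the canonical (B+1)*alpha order
# statistics with interpolation on the normal-quantile scale (the "perc"
# convention of standard bootstrap software).
.perc_quantile <- function(t, probs) {
  t <- t[is.finite(t)]
  B <- length(t)
  if (B == 0) return(rep(NA_real_, length(probs)))
  ts <- sort(t)
  vapply(probs, function(pr) {
    rk <- (B + 1) * pr
    if (rk <= 1) return(ts[1])
    if (rk >= B) return(ts[B])
    k1 <- floor(rk)
    k2 <- k1 + 1
    a <- (qnorm(rk / (B + 1)) - qnorm(k1 / (B + 1))) /
      (qnorm(k2 / (B + 1)) - qnorm(k1 / (B + 1)))
    (1 - a) * ts[k1] + a * ts[k2]
  }, numeric(1))
}

# Fast refit machinery for the pair bootstrap. The rotated design is built
# once; resampling families with replacement is then a row-index operation on
# the per-family difference/sum contrasts. When no design column has nonzero
# entries in both the difference and the sum parts (true whenever covariates
# are family-constant, e.g. SES), the GLS fixed effects decouple into two
# independent OLS problems and do not depend on the variance ratio, so each
# replicate needs no variance-component search.

.boot_design <- function(cohort, outcome, predictor, covariates) {
  cohort <- build_design(cohort, predictor)
  y <- cohort[[outcome]]
  X <- cbind(`(Intercept)` = 1, gps_within = cohort$gps_within,
             gps_between = cohort$gps_between)
  if (length(covariates) > 0) {
    cm <- model.matrix(~ ., data = cohort[covariates])[, -1, drop = FALSE]
    X <- cbind(X, cm)
  }
  rot <- .rotate_pairs(X, y)
  tol <- 1e-10
  in_d <- colSums(abs(rot$Xd)) > tol
  in_s <- colSums(abs(rot$Xs)) > tol
  rot$decoupled <- !any(in_d & in_s)
  rot$cols_d <- which(in_d)
  rot$cols_s <- which(in_s)
  rot$n <- length(y)
  rot$p <- ncol(X)
  rot
}

# Returns c(beta_w, beta_b) for a (resampled) rotated design.
.boot_betas <- function(rot, idx = NULL) {
  Xd <- rot$Xd; Xs <- rot$Xs; yd <- rot$yd; ys <- rot$ys
  if (!is.null(idx)) {
    Xd <- Xd[idx, , drop = FALSE]; Xs <- Xs[idx, , drop = FALSE]
    yd <- yd[idx]; ys <- ys[idx]
  }
  if (rot$decoupled) {
    bw <- NA_real_; bb <- NA_real_
    if (length(rot$cols_d) > 0) {
      A <- Xd[, rot$cols_d, drop = FALSE]
      bd <- solve(crossprod(A), crossprod(A, yd))
      bd <- setNames(drop(bd), colnames(A))
      if ("gps_within" %in% names(bd)) bw <- bd[["gps_within"]]
    }
    if (length(rot$cols_s) > 0) {
      B <- Xs[, rot$cols_s, drop = FALSE]
      bs <- solve(crossprod(B), crossprod(B, ys))
      bs <- setNames(drop(bs), colnames(B))
      if ("gps_between" %in% names(bs)) bb <- bs[["gps_between"]]
    }
    c(beta_w = bw, beta_b = bb)
  } else {
    sub <- list(Xd = Xd, Xs = Xs, yd = yd, ys = ys)
    obj <- function(l) .wb_criterion(l, sub, rot$n, rot$p, reml = TRUE)
    ols <- .wls_at_lambda(sub, 0)
    if (ols$rss <= 1e-12 * (sum(yd^2) + sum(ys^2))) {
      f <- ols
    } else {
      opt <- optimize(obj, interval = c(0, 1e3), tol = 1e-7)
      l_hat <- if (obj(0) <= opt$objective) 0 else opt$minimum
      f <- .wls_at_lambda(sub, l_hat)
    }
    c(beta_w = f$beta[["gps_within"]], beta_b = f$beta[["gps_between"]])
  }
}

#' Twin-pair cluster bootstrap of the decomposition model
#'
#' Resamples families (both co-twins together, never individuals) with
#' replacement to the original family count, refits the decomposition model
#' per replicate, and summarizes the replicate coefficients with 95%
#' percentile intervals (empirical 2.5/97.5 quantiles via the canonical
#' `(B+1)*alpha` order-statistic convention). Optionally a second,
#' covariate-adjusted model is refitted on the same resampled families
#' (paired replicates), as required by [covariate_shift_test()].
#'
#' @param cohort Twin-pair cohort data frame.
#' @param outcome,predictor,covariates As in [fit_within_between()].
#' @param n_boot Number of bootstrap replicates (study-scale default 10,000).
#' @param seed Integer seed; fixing it makes the bootstrap fully
#'   reproducible.
#' @param adjusted_covariates Optional extra covariates (e.g. `"ses"`)
#'   defining a paired adjusted model refitted on the same resamples.
#' @param conf_level Confidence level of the percentile intervals.
#' @return An object of class `wb_bootstrap`: full-sample fits (`fit`, and
#'   `fit_adjusted` if requested), replicate matrices (`reps`,
#'   `reps_adjusted`), percentile `ci`, `diff_sd` (SD of replicate
#'   `beta_b - beta_w`), the attenuation replicates, the number of dropped
#'   (non-converged) replicates, and the seed.
#' @export
bootstrap_pairs <- function(cohort, outcome, predictor,
                            covariates = character(), n_boot = 10000,
                            seed = NULL, adjusted_covariates = NULL,
                            conf_level = 0.95) {
  if (n_boot < 0) stop("n_boot must be >= 0")
  fit <- fit_within_between(cohort, outcome, predictor, covariates)
  has_adj <- !is.null(adjusted_covariates) && length(adjusted_covariates) > 0
  fit_adj <- if (has_adj)
    fit_within_between(cohort, outcome, predictor,
                       c(covariates, adjusted_covariates)) else NULL

  all_cols <- c(outcome, predictor, covariates,
                if (has_adj) adjusted_covariates)
  cohort_v <- validate_pairs(cohort, columns = all_cols)
  rot_raw <- .boot_design(cohort_v, outcome, predictor, covariates)
  rot_adj <- if (has_adj)
    .boot_design(cohort_v, outcome, predictor,
                 c(covariates, adjusted_covariates)) else NULL
  J <- length(rot_raw$yd)

  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("beta_w", "beta_b")))
  reps_adj <- if (has_adj) reps else NULL
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(J, J, replace = TRUE)
    ok <- tryCatch({
      reps[b, ] <- .boot_betas(rot_raw, idx)
      if (has_adj) reps_adj[b, ] <- .boot_betas(rot_adj, idx)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_boot > 0 && n_failed > 0.01 * n_boot)
    warning(n_failed, " of ", n_boot, " bootstrap replicates failed")
  keep <- stats::complete.cases(reps)
  if (has_adj) keep <- keep & stats::complete.cases(reps_adj)
  reps <- reps[keep, , drop = FALSE]
  if (has_adj) reps_adj <- reps_adj[keep, , drop = FALSE]

  alpha <- (1 - conf_level) / 2
  probs <- c(alpha, 1 - alpha)
  ci <- if (nrow(reps) > 0)
    apply(reps, 2, .perc_quantile, probs = probs) else
    matrix(NA_real_, 2, 2, dimnames = list(NULL, colnames(reps)))
  rownames(ci) <- paste0(format(100 * probs, trim = TRUE), "%")

  diffs <- reps[, "beta_b"] - reps[, "beta_w"]
  bw <- fit$coefficients[["gps_within"]]
  bb <- fit$coefficients[["gps_between"]]
  atten_reps <- ifelse(abs(reps[, "beta_b"]) > 1e-8,
                       100 * (reps[, "beta_b"] - reps[, "beta_w"]) /
                         reps[, "beta_b"], NA_real_)
  res <- list(
    fit = fit, fit_adjusted = fit_adj,
    beta_w = bw, beta_b = bb,
    n_boot = n_boot, n_failed = n_failed, seed = seed,
    reps = reps, reps_adjusted = reps_adj,
    ci = ci, conf_level = conf_level,
    diff_sd = if (nrow(reps) > 1) sd(diffs) else NA_real_,
    attenuation_reps = atten_reps
  )
  class(res) <- "wb_bootstrap"
  res
}

#' @export
print.wb_bootstrap <- function(x, ...) {
  cat(sprintf("Pair bootstrap: %d replicates (%d failed), seed %s\n",
              x$n_boot, x$n_failed,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("beta_w = %.4f [%.4f, %.4f]\n", x$beta_w,
              x$ci[1, "beta_w"], x$ci[2, "beta_w"]))
  cat(sprintf("beta_b = %.4f [%.4f, %.4f]\n", x$beta_b,
              x$ci[1, "beta_b"], x$ci[2, "beta_b"]))
  invisible(x)
}

#' Bootstrap difference test between the two family-level coefficients
#'
#' Divides the full-sample coefficient difference `beta_b - beta_w` by the
#' standard deviation of the bootstrap sampling distribution of that
#' difference; the two-sided p-value uses a standard normal reference.
#'
#' @param boot A [bootstrap_pairs()] result.
#' @return A list with `z`, `p`, `diff` and `diff_sd`.
#' @export
diff_test <- function(boot) {
  if (!inherits(boot, "wb_bootstrap")) stop("boot must be a wb_bootstrap")
  if (!is.finite(boot$diff_sd) || boot$diff_sd < 1e-12)
    stop("degenerate bootstrap difference distribution (diff_sd = 0)")
  d <- boot$beta_b - boot$beta_w
  z <- d / boot$diff_sd
  list(z = z, p = 2 * pnorm(-abs(z)), diff = d, diff_sd = boot$diff_sd)
}

#' Attenuation of the within- relative to the between-family coefficient
#'
#' The percentage change `100 * (beta_b - beta_w) / beta_b`. When a bootstrap
#' result is supplied, a percentile confidence interval is computed from the
#' replicate-wise attenuations. A between-family coefficient within `tol` of
#' zero makes the ratio unreliable and returns `NA` with a flag.
#'
#' @param boot Optional [bootstrap_pairs()] result (source of the point
#'   estimates and of the CI).
#' @param beta_w,beta_b Point estimates; taken from `boot` when omitted.
#' @param tol Smallest `|beta_b|` considered interpretable.
#' @param conf_level Confidence level for the percentile interval.
#' @return A list with `attenuation_pct`, `ci` (or `NULL`), and `defined`.
#' @export
attenuation <- function(boot = NULL, beta_w = NULL, beta_b = NULL,
                        tol = 1e-8, conf_level = 0.95) {
  if (!is.null(boot)) {
    if (!inherits(boot, "wb_bootstrap")) stop("boot must be a wb_bootstrap")
    if (is.null(beta_w)) beta_w <- boot$beta_w
    if (is.null(beta_b)) beta_b <- boot$beta_b
  }
  if (is.null(beta_w) || is.null(beta_b))
    stop("supply either a bootstrap result or both coefficients")
  if (abs(beta_b) <= tol)
    return(list(attenuation_pct = NA_real_, ci = NULL, defined = FALSE))
  est <- 100 * (beta_b - beta_w) / beta_b
  ci <- NULL
  if (!is.null(boot) && any(is.finite(boot$attenuation_reps))) {
    a <- (1 - conf_level) / 2
    ci <- .perc_quantile(boot$attenuation_reps, c(a, 1 - a))
  }
  list(attenuation_pct = est, ci = ci, defined = TRUE)
}

#' Test the shift of the between-family coefficient after adjustment
#'
#' Compares `beta_b` before and after conditioning on extra covariates
#' (typically family SES), using paired bootstrap replicates: the same
#' resampled families underlie both models, so the replicate-wise difference
#' `beta_b_raw - beta_b_adjusted` has the correct sampling variance.
#'
#' @param boot A [bootstrap_pairs()] result created with
#'   `adjusted_covariates`.
#' @param conf_level Confidence level for the percentile interval of the
#'   difference.
#' @return A list with `delta_beta_b`, `z`, `p`, `ci`, and the analogous
#'   within-family quantities (`delta_beta_w`, for the expectation that the
#'   within-family coefficient does not move).
#' @export
covariate_shift_test <- function(boot, conf_level = 0.95) {
  if (!inherits(boot, "wb_bootstrap")) stop("boot must be a wb_bootstrap")
  if (is.null(boot$reps_adjusted))
    stop("bootstrap was run without adjusted_covariates; ",
         "paired replicates are required")
  d_b <- boot$reps[, "beta_b"] - boot$reps_adjusted[, "beta_b"]
  d_w <- boot$reps[, "beta_w"] - boot$reps_adjusted[, "beta_w"]
  delta_b <- boot$beta_b - boot$fit_adjusted$coefficients[["gps_between"]]
  delta_w <- boot$beta_w - boot$fit_adjusted$coefficients[["gps_within"]]
  s <- sd(d_b)
  if (!is.finite(s) || s <= 0)
    stop("degenerate paired difference distribution")
  z <- delta_b / s
  a <- (1 - conf_level) / 2
  list(delta_beta_b = delta_b, z = z, p = 2 * pnorm(-abs(z)),
       ci = .perc_quantile(d_b, c(a, 1 - a)),
       delta_beta_w = delta_w, sd_delta_w = sd(d_w))
}

#' Benjamini-Hochberg false discovery rate threshold
#'
#' Step-up rule: with p-values ranked increasingly, the corrected threshold
#' is the largest p(k) satisfying `p(k) <= (k/m) * alpha`; every p-value at
#' or below it is declared a discovery. With no such k there are no
#' discoveries and the threshold is `NA`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Target false discovery rate.
#' @return A list with `threshold`, `significant` (logical flags in input
#'   order), and `n_discoveries`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= (seq_len(m) / m) * alpha)
  if (length(ok) == 0)
    return(list(threshold = NA_real_,
                significant = rep(FALSE, m), n_discoveries = 0L))
  thr <- ps[max(ok)]
  sig <- p_values <= thr
  list(threshold = thr, significant = sig, n_discoveries = sum(sig))
}
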