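#' Within-pair difference table
#'
#' Builds one row per family with the signed member-1 minus member-2
#' differences of the score and the outcome, plus the absolute score
#' difference used for the decile split. Member order is fixed (elder twin
#' first where known; the simulator's arbitrary-but-fixed order otherwise) -
#' oriented downstream quantities are invariant to a label swap.
#'
#' @param cohort Twin-pair cohort data frame.
#' @param gps_col,outcome_col Score and outcome column names.
#' @return A data frame with `family_id`, `gps_diff`, `outcome_diff`,
#'   `abs_gps_diff`; attribute `n_dropped_families` counts incomplete pairs.
#' @export
pair_differences <- function(cohort, gps_col, outcome_col) {
  for (cl in c(gps_col, outcome_col))
    if (!cl %in% names(cohort)) stop("column '", cl, "' not in cohort")
  cohort <- validate_pairs(cohort, columns = c(gps_col, outcome_col))
  i1 <- seq(1L, nrow(cohort), 2L)
  i2 <- i1 + 1L
  out <- data.frame(
    family_id = cohort$family_id[i1],
    gps_diff = cohort[[gps_col]][i1] - cohort[[gps_col]][i2],
    outcome_diff = cohort[[outcome_col]][i1] - cohort[[outcome_col]][i2]
  )
  out$abs_gps_diff <- abs(out$gps_diff)
  attr(out, "n_dropped_families") <- attr(cohort, "n_dropped_families")
  out
}

#' Split pairs into near-equal quantile groups of absolute score difference
#'
#' Rank-based split into `n_quantiles` groups ordered from the smallest
#' (group 1) to the largest absolute score differences; group sizes differ by
#' at most one (remainders go to the lowest groups) and ties are broken by
#' stable input order.
#'
#' @param table A [pair_differences()] table.
#' @param n_quantiles Number of groups (default 10, i.e. deciles).
#' @return The table with a `decile` column appended.
#' @export
decile_split <- function(table, n_quantiles = 10) {
  n <- nrow(table)
  if (n < n_quantiles)
    stop("need at least ", n_quantiles, " pairs for a ", n_quantiles,
         "-quantile split")
  sizes <- rep(n %/% n_quantiles, n_quantiles)
  extra <- n %% n_quantiles
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(table$abs_gps_diff)  # stable for ties
  dec <- integer(n)
  dec[ord] <- rep(seq_len(n_quantiles), times = sizes)
  table$decile <- dec
  table
}

#' Outcome contrast between the extreme score-difference deciles
#'
#' Orients each pair's outcome difference toward the higher-score twin
#' (multiplies `outcome_diff` by the sign of `gps_diff`), then compares the
#' mean oriented outcome difference in the highest decile against the lowest
#' decile with a Welch two-sample test. `oriented = FALSE` instead contrasts
#' absolute outcome differences.
#'
#' @param table A [decile_split()] table.
#' @param oriented Orient outcome differences toward the higher-score twin?
#' @return A list with `mean_low`, `mean_high`, `contrast`
#'   (high minus low), `t`, `df`, `p`, and the group sizes.
#' @export
extreme_decile_test <- function(table, oriented = TRUE) {
  if (!"decile" %in% names(table)) stop("run decile_split() first")
  k <- max(table$decile)
  v <- if (oriented) sign(table$gps_diff) * table$outcome_diff else
    abs(table$outcome_diff)
  lo <- v[table$decile == 1]
  hi <- v[table$decile == k]
  if (length(lo) == 0 || length(hi) == 0) stop("empty extreme decile")
  tt <- t.test(hi, lo)
  list(mean_low = mean(lo), mean_high = mean(hi),
       contrast = mean(hi) - mean(lo),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_low = length(lo), n_high = length(hi),
       oriented = oriented)
}

#' Regression through the origin of outcome differences on score differences
#'
#' No-intercept OLS of the signed outcome difference on the signed score
#' difference (the intercept is structurally zero for pair differences). The
#' reported R-squared is the uncentered version,
#' `1 - SS_res / sum(outcome_diff^2)`, standard for through-origin fits.
#' The slope is invariant to swapping member labels, which negates both
#' variables.
#'
#' @param table A [pair_differences()] table.
#' @return A list with `B` (slope), `se`, `t`, `p`, `r_squared`, `n`.
#' @export
origin_regression <- function(table) {
  x <- table$gps_diff
  y <- table$outcome_diff
  if (sum(x != 0) < 2) stop("need at least 2 pairs with nonzero score ",
                            "difference")
  if (all(x == 0)) stop("all score differences are zero: singular fit")
  fit <- lm(y ~ 0 + x)
  sm <- summary(fit)
  list(B = unname(coef(fit)[1]),
       se = sm$coefficients[1, 2],
       t = sm$coefficients[1, 3],
       p = sm$coefficients[1, 4],
       r_squared = sm$r.squared,  # uncentered for through-origin lm
       n = length(y))
}

#' Full quantile analysis of within-pair score differences
#'
#' Runs [pair_differences()], [decile_split()], [extreme_decile_test()] and
#' [origin_regression()] and summarizes each decile. When the analysis
#' columns are z-standardized, `outcome_sd` (and `outcome_mean`, which
#' cancels in differences but is recorded) back-transform the contrasts to
#' the original scale, e.g. `outcome_sd = 15` for an IQ-like scale.
#'
#' @param cohort Twin-pair cohort data frame.
#' @param gps_col,outcome_col Column names.
#' @param n_quantiles Number of quantile groups.
#' @param oriented Orientation of the outcome contrast (see
#'   [extreme_decile_test()]).
#' @param outcome_sd,outcome_mean Optional back-transformation parameters of
#'   the standardized outcome.
#' @return A list with `decile_table` (decile, n, mean absolute score
#'   difference, mean oriented outcome difference with 95% CI),
#'   `extreme_test`, `origin_fit`, and `n_dropped_families`.
#' @export
run_quantile <- function(cohort, gps_col, outcome_col, n_quantiles = 10,
                         oriented = TRUE, outcome_sd = NULL,
                         outcome_mean = NULL) {
  tab <- pair_differences(cohort, gps_col, outcome_col)
  if (!is.null(outcome_sd)) tab$outcome_diff <- tab$outcome_diff * outcome_sd
  tab <- decile_split(tab, n_quantiles)
  v <- if (oriented) sign(tab$gps_diff) * tab$outcome_diff else
    abs(tab$outcome_diff)
  dt <- do.call(rbind, lapply(seq_len(n_quantiles), function(k) {
    vv <- v[tab$decile == k]
    m <- mean(vv)
    se <- sd(vv) / sqrt(length(vv))
    ci <- m + c(-1, 1) * qt(0.975, length(vv) - 1) * se
    data.frame(decile = k, n = length(vv),
               mean_abs_gps_diff = mean(tab$abs_gps_diff[tab$decile == k]),
               mean_outcome_diff = m, ci_low = ci[1], ci_high = ci[2])
  }))
  list(decile_table = dt,
       extreme_test = extreme_decile_test(tab, oriented = oriented),
       origin_fit = origin_regression(tab),
       n_dropped_families = attr(tab, "n_dropped_families"))
}
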