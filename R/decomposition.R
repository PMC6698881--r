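#' Validate a twin-pair cohort table
#'
#' Keeps families with exactly two members that are complete on the listed
#' columns, mirroring the inclusion rule that only co-twin pairs with
#' complete data enter the model. Member labels must be unique within family.
#'
#' @param cohort Long-format data frame with columns `family_id` and `member`.
#' @param columns Columns that must be complete.
#' @param strict Error (rather than drop) on incomplete families?
#' @return The validated cohort, ordered by family then member, with
#'   attribute `n_dropped_families`.
#' @export
validate_pairs <- function(cohort, columns = character(), strict = FALSE) {
  if (!all(c("family_id", "member") %in% names(cohort)))
    stop("cohort must have columns 'family_id' and 'member'")
  columns <- intersect(columns, names(cohort))
  missing_cols <- setdiff(columns, names(cohort))
  if (length(missing_cols) > 0)
    stop("column(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  ok_row <- if (length(columns) > 0)
    complete.cases(cohort[columns]) else rep(TRUE, nrow(cohort))
  keep <- cohort[ok_row, , drop = FALSE]
  cnt <- table(keep$family_id)
  good_fams <- names(cnt)[cnt == 2L]
  n_total <- length(unique(cohort$family_id))
  n_dropped <- n_total - length(good_fams)
  if (n_dropped > 0 && strict)
    stop(n_dropped, " famil(ies) without 2 complete members (strict mode)")
  keep <- keep[as.character(keep$family_id) %in% good_fams, , drop = FALSE]
  keep <- keep[order(match(as.character(keep$family_id), good_fams),
                     keep$member), , drop = FALSE]
  dup <- tapply(keep$member, keep$family_id, function(m) anyDuplicated(m) > 0)
  if (any(dup))
    stop("duplicated member labels within family: ",
         paste(names(dup)[dup][seq_len(min(3, sum(dup)))], collapse = ", "))
  rownames(keep) <- NULL
  attr(keep, "n_dropped_families") <- n_dropped
  keep
}

#' Append within- and between-family predictor columns
#'
#' Adds `gps_within = GPS_ij - mean_j(GPS)` (the individual's deviation from
#' the family mean) and `gps_between = mean_j(GPS)` (the family mean) for the
#' chosen predictor, the two fixed-effect regressors of the decomposition
#' model.
#'
#' @param cohort Twin-pair cohort data frame.
#' @param predictor Name of the score column to center.
#' @param strict Passed to [validate_pairs()].
#' @return The validated cohort with columns `gps_within` and `gps_between`
#'   appended.
#' @export
build_design <- function(cohort, predictor, strict = FALSE) {
  if (!predictor %in% names(cohort))
    stop("predictor column '", predictor, "' not in cohort")
  cohort <- validate_pairs(cohort, columns = predictor, strict = strict)
  x <- cohort[[predictor]]
  fam_mean <- ave(x, cohort$family_id)
  cohort$gps_within <- x - fam_mean
  cohort$gps_between <- fam_mean
  cohort
}

# Rotate paired rows into orthogonal difference and sum contrasts:
# d = (row1 - row2)/sqrt(2) has variance sigma_eps^2,
# s = (row1 + row2)/sqrt(2) has variance sigma_eps^2 (1 + 2 lambda),
# lambda = sigma_gamma^2 / sigma_eps^2. The REML problem becomes a
# heteroscedastic diagonal GLS profiled over the single ratio lambda.
.rotate_pairs <- function(X, y) {
  n <- length(y)
  i1 <- seq(1L, n, 2L)
  i2 <- i1 + 1L
  s2 <- sqrt(2)
  list(Xd = (X[i1, , drop = FALSE] - X[i2, , drop = FALSE]) / s2,
       Xs = (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / s2,
       yd = (y[i1] - y[i2]) / s2,
       ys = (y[i1] + y[i2]) / s2)
}

# Weighted LS pieces at a given lambda. Returns beta, XtWX, weighted RSS.
.wls_at_lambda <- function(rot, lambda) {
  ws <- 1 / (1 + 2 * lambda)
  XtWX <- crossprod(rot$Xd) + ws * crossprod(rot$Xs)
  XtWy <- crossprod(rot$Xd, rot$yd) + ws * crossprod(rot$Xs, rot$ys)
  beta <- solve(XtWX, XtWy)
  rss <- sum(rot$yd^2) + ws * sum(rot$ys^2) - sum(beta * XtWy)
  rss <- max(rss, 0)
  list(beta = drop(beta), XtWX = XtWX, rss = rss)
}

# Negative twice the profiled (restricted) log-likelihood, up to a constant.
.wb_criterion <- function(lambda, rot, n, p, reml = TRUE) {
  f <- .wls_at_lambda(rot, lambda)
  J <- length(rot$yd)
  logdet_sigma <- J * log(1 + 2 * lambda)
  dof <- if (reml) n - p else n
  if (f$rss <= 0) return(-Inf)
  crit <- dof * log(f$rss) + logdet_sigma
  if (reml) crit <- crit + determinant(f$XtWX, logarithm = TRUE)$modulus
  as.numeric(crit)
}

#' Fit the within/between-family random-intercept decomposition model
#'
#' Fits the Gaussian random-intercept model
#' \deqn{Y_{ij} = \alpha_0 + \beta_W (GPS_{ij} - \overline{GPS}_j) +
#'   \beta_B \overline{GPS}_j + c^T x_{ij} + \gamma_j + \epsilon_{ij}}
#' with \eqn{\gamma_j \sim N(0, \sigma_\gamma^2)} and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma_\epsilon^2)}, on clusters of exactly
#' two twins per family. Including both regressors makes each estimate
#' adjusted for, and independent of, the other.
#'
#' Estimation is restricted maximum likelihood (REML; ML behind
#' `method = "ml"`): the pair rotation into sum and difference contrasts
#' reduces the problem to a diagonal GLS profiled over the single variance
#' ratio \eqn{\lambda = \sigma_\gamma^2/\sigma_\epsilon^2}, which is found by
#' bounded 1-D search; the boundary \eqn{\sigma_\gamma^2 = 0} is a legal
#' solution and is flagged. Standard errors come from the observed
#' information of the GLS fit; p-values are Wald with a normal reference
#' (cluster bootstrap is the primary inference layer, see
#' [bootstrap_pairs()]).
#'
#' @param cohort Twin-pair cohort data frame (see [validate_pairs()]).
#' @param outcome Name of the outcome column.
#' @param predictor Name of the polygenic score column.
#' @param covariates Character vector of additional fixed-effect columns
#'   (entered at the individual level; family-constant covariates such as SES
#'   load on the between part by construction). No further centering is
#'   applied to covariates.
#' @param method `"reml"` (default) or `"ml"`.
#' @param min_pairs Minimum number of complete pairs required.
#' @param strict Passed to [validate_pairs()].
#' @return An object of class `wb_fit`: coefficients (`(Intercept)`,
#'   `gps_within`, `gps_between`, covariates), `se`, `z`, `p_value`,
#'   `sigma_gamma2`, `sigma_eps2`, `icc`, `total_effect`, `n_pairs`,
#'   `n_dropped_families`, `loglik`, `lambda`, `boundary`, `converged`.
#' @seealso [icc()], [total_effect()], [bootstrap_pairs()]
#' @export
fit_within_between <- function(cohort, outcome, predictor,
                               covariates = character(),
                               method = c("reml", "ml"),
                               min_pairs = 10, strict = FALSE) {
  method <- match.arg(method)
  for (cl in c(outcome, predictor, covariates))
    if (!cl %in% names(cohort)) stop("column '", cl, "' not in cohort")
  cohort <- validate_pairs(cohort, columns = c(outcome, predictor, covariates),
                           strict = strict)
  n_dropped <- attr(cohort, "n_dropped_families")
  cohort <- build_design(cohort, predictor)
  J <- nrow(cohort) / 2L
  if (J < min_pairs) stop("fewer than ", min_pairs, " complete pairs")
  y <- cohort[[outcome]]
  if (var(y) <= 0) stop("outcome has zero variance")

  X <- cbind(`(Intercept)` = 1, gps_within = cohort$gps_within,
             gps_between = cohort$gps_between)
  if (length(covariates) > 0) {
    cm <- model.matrix(~ ., data = cohort[covariates])[, -1, drop = FALSE]
    X <- cbind(X, cm)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    if (any(c("gps_within", "gps_between") %in% dropped))
      stop("design is rank deficient in the score terms (no within-family ",
           "or between-family variation in the predictor)")
    warning("dropping collinear column(s): ", paste(dropped, collapse = ", "))
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  n <- length(y)
  p <- ncol(X)
  rot <- .rotate_pairs(X, y)
  reml <- method == "reml"

  # guard: (near-)perfect fit leaves nothing for the variance components
  ols <- .wls_at_lambda(rot, 0)
  perfect <- ols$rss <= 1e-12 * sum(y^2)
  if (perfect) {
    lambda_hat <- 0
    fit <- ols
    sigma_eps2 <- fit$rss / (n - p)
    converged <- TRUE
  } else {
    obj <- function(l) .wb_criterion(l, rot, n, p, reml)
    opt <- optimize(obj, interval = c(0, 1e3), tol = 1e-9)
    lambda_hat <- opt$minimum
    if (obj(0) <= opt$objective) lambda_hat <- 0
    fit <- .wls_at_lambda(rot, lambda_hat)
    sigma_eps2 <- fit$rss / (if (reml) n - p else n)
    converged <- TRUE
  }
  sigma_gamma2 <- lambda_hat * sigma_eps2
  icc_hat <- if (sigma_gamma2 + sigma_eps2 <= 0) NA_real_ else
    sigma_gamma2 / (sigma_gamma2 + sigma_eps2)

  vcov_beta <- sigma_eps2 * solve(fit$XtWX)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  zst <- ifelse(se > 0, fit$beta / se,
                ifelse(fit$beta == 0, 0, Inf * sign(fit$beta)))
  pv <- 2 * pnorm(-abs(zst))
  names(se) <- names(zst) <- names(pv) <- colnames(X)

  ll <- if (sigma_eps2 > 0) {
    J_log <- length(rot$yd) * log(1 + 2 * lambda_hat)
    dof <- if (reml) n - p else n
    extra <- if (reml)
      as.numeric(determinant(fit$XtWX, logarithm = TRUE)$modulus) -
        p * log(sigma_eps2) else 0
    -0.5 * (dof * log(2 * pi * sigma_eps2) + dof + J_log + extra)
  } else NA_real_

  bw <- fit$beta[["gps_within"]]
  bb <- fit$beta[["gps_between"]]
  res <- list(
    coefficients = fit$beta, se = se, z = zst, p_value = pv,
    vcov = vcov_beta,
    sigma_gamma2 = sigma_gamma2, sigma_eps2 = sigma_eps2,
    lambda = lambda_hat, icc = icc_hat,
    total_effect = if (is.na(icc_hat)) NA_real_ else
      total_effect(bw, bb, icc_hat),
    n_pairs = J, n_dropped_families = n_dropped,
    loglik = ll, method = method, boundary = lambda_hat == 0,
    converged = converged, outcome = outcome, predictor = predictor,
    covariates = covariates
  )
  class(res) <- "wb_fit"
  res
}

#' @export
print.wb_fit <- function(x, ...) {
  cat(sprintf("Within/between-family decomposition (%s), %d pairs\n",
              toupper(x$method), x$n_pairs))
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = signif(x$p_value, 3))
  print(round(tab, 4))
  cat(sprintf("sigma_gamma2 = %.4f, sigma_eps2 = %.4f, ICC = %.3f%s\n",
              x$sigma_gamma2, x$sigma_eps2, x$icc,
              if (x$boundary) " (boundary: zero family variance)" else ""))
  cat(sprintf("total effect = %.4f\n", x$total_effect))
  invisible(x)
}

#' @export
coef.wb_fit <- function(object, ...) object$coefficients

#' Intraclass correlation of a decomposition fit
#'
#' The ratio of the family (random-intercept) variance over the total
#' variance, \eqn{\sigma_\gamma^2 / (\sigma_\gamma^2 + \sigma_\epsilon^2)},
#' estimated from the model that includes the fixed effects.
#'
#' @param fit A `wb_fit` object.
#' @return The ICC in `[0, 1]`.
#' @export
icc <- function(fit) {
  if (!inherits(fit, "wb_fit")) stop("fit must be a wb_fit object")
  if (is.na(fit$icc))
    stop("ICC undefined: both variance components are zero")
  fit$icc
}

#' ICC-weighted total effect
#'
#' Combines the within- and between-family coefficients into the total
#' (population-level) effect, `beta_w * (1 - icc) + beta_b * icc`, which is
#' bounded by the two coefficients: an ICC near 0 returns the within-family
#' effect, an ICC near 1 the between-family effect.
#'
#' @param beta_w,beta_b Within- and between-family coefficients.
#' @param icc Intraclass correlation in `[0, 1]`.
#' @return The weighted total effect.
#' @export
total_effect <- function(beta_w, beta_b, icc) {
  if (!is.numeric(icc) || any(is.na(icc)) || any(icc < 0) || any(icc > 1))
    stop("icc must lie in [0, 1]")
  beta_w * (1 - icc) + beta_b * icc
}
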