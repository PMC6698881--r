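#' Genetic relationship matrix from genotype dosages
#'
#' Entry for individuals `m`, `n` averaged over variants:
#' \deqn{A_{mn} = \frac{1}{N} \sum_{i=1}^{N}
#'   \frac{(x_{im} - 2 p_i)(x_{in} - 2 p_i)}{2 p_i (1 - p_i)}}
#' with `x` the counted-allele dosage and `p_i` the counted-allele frequency
#' (estimated from the sample by default, as GREML software does;
#' user-supplied frequencies accepted). Monomorphic variants are excluded
#' with a count. The matrix is invariant to variant order and to a
#' consistent allele flip (`x -> 2 - x`, `p -> 1 - p`).
#'
#' @param genotypes Numeric matrix, individuals x variants, dosages in
#'   `[0, 2]`; row names identify individuals.
#' @param freqs Optional per-variant counted-allele frequencies in `(0, 1)`.
#' @return An object of class `grm`: `ids`, symmetric matrix `A`,
#'   `n_variants` used, `n_excluded`.
#' @export
compute_grm <- function(genotypes, freqs = NULL) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix")
  rng <- range(genotypes)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 2)
    stop("genotype dosages must lie in [0, 2]")
  p <- if (is.null(freqs)) colMeans(genotypes) / 2 else freqs
  if (length(p) != ncol(genotypes))
    stop("freqs length must match the number of variants")
  usable <- p > 0 & p < 1
  n_excluded <- sum(!usable)
  if (!any(usable)) stop("no polymorphic variants usable for the GRM")
  X <- genotypes[, usable, drop = FALSE]
  p <- p[usable]
  M <- sweep(X, 2, 2 * p, "-")
  M <- sweep(M, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(M) / ncol(M)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  dimnames(A) <- list(ids, ids)
  structure(list(ids = ids, A = A, n_variants = ncol(M),
                 n_excluded = n_excluded),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d individuals, %d variants (%d monomorphic excluded)\n",
              length(x$ids), x$n_variants, x$n_excluded))
  cat(sprintf("diagonal mean %.3f, off-diagonal mean %.4f\n",
              mean(diag(x$A)), mean(x$A[lower.tri(x$A)])))
  invisible(x)
}

#' Write / read a GRM as plain-text triplets
#'
#' The upper triangle (including the diagonal) is stored as TSV rows
#' `id1, id2, value`; the id order is preserved through an `#ids:` header
#' comment.
#'
#' @param grm A [compute_grm()] object.
#' @param path Output path.
#' @export
write_grm <- function(grm, path) {
  ids <- grm$ids
  n <- length(ids)
  iu <- which(upper.tri(grm$A, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = ids[iu[, 1]], id2 = ids[iu[, 2]],
                   value = grm$A[iu])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#ids:", paste(ids, collapse = ",")),
               paste0("#n_variants:", grm$n_variants)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  hdr <- readLines(path, n = 2)
  ids <- strsplit(sub("^#ids:", "", hdr[1]), ",")[[1]]
  n_variants <- as.integer(sub("^#n_variants:", "", hdr[2]))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(df$id1, ids)
  j <- match(df$id2, ids)
  A[cbind(i, j)] <- df$value
  A[cbind(j, i)] <- df$value
  structure(list(ids = ids, A = A, n_variants = n_variants, n_excluded = 0L),
            class = "grm")
}

#' Decomposition fixed effects with a genome-wide random effect
#'
#' Relatedness sensitivity model: the fixed-effect part is identical to
#' [fit_within_between()] (`y = alpha + beta_w (GPS_ij - mean_j) +
#' beta_b mean_j + g + eps`) but the family random intercept is replaced by a
#' genome-wide random effect `g ~ N(0, A sigma_g^2)` with `A` the genetic
#' relationship matrix. Estimation is REML after rotating into the
#' eigenbasis of `A` (where the covariance is diagonal,
#' `sigma_eps^2 (1 + lambda d_i)`), profiling the variance ratio by bounded
#' 1-D search. Negative eigenvalues are clipped at zero with a warning.
#'
#' @param cohort Twin-pair cohort with an `id` column matching the GRM ids.
#' @param grm A [compute_grm()] object covering every fitted individual.
#' @param outcome,predictor Column names, as in [fit_within_between()].
#' @param min_pairs Minimum number of complete pairs.
#' @return An object of class `grm_fit`: coefficients, `se`, `p_value`,
#'   `sigma_g2`, `sigma_eps2`, `loglik`, `boundary`, `converged`, `n`.
#' @export
fit_grm_lmm <- function(cohort, grm, outcome, predictor, min_pairs = 10) {
  if (!inherits(grm, "grm")) stop("grm must be a compute_grm() result")
  if (!"id" %in% names(cohort)) stop("cohort must have an 'id' column")
  cohort <- validate_pairs(cohort, columns = c("id", outcome, predictor))
  if (nrow(cohort) / 2 < min_pairs)
    stop("fewer than ", min_pairs, " complete pairs")
  cohort <- build_design(cohort, predictor)
  pos <- match(cohort$id, grm$ids)
  if (anyNA(pos))
    stop("GRM does not cover ", sum(is.na(pos)), " cohort individual(s)")
  A <- grm$A[pos, pos]
  if (max(abs(A - t(A))) > 1e-8) stop("GRM must be symmetric")

  y <- cohort[[outcome]]
  X <- cbind(`(Intercept)` = 1, gps_within = cohort$gps_within,
             gps_between = cohort$gps_between)
  n <- length(y)
  p <- ncol(X)

  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  d <- eg$values
  if (any(d < -1e-8))
    warning(sum(d < -1e-8), " negative GRM eigenvalue(s) clipped at 0")
  d <- pmax(d, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  fit_at <- function(lambda) {
    w <- 1 / (1 + lambda * d)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    rss <- max(sum(w * ys^2) - sum(beta * XtWy), 0)
    list(beta = drop(beta), XtWX = XtWX, rss = rss, w = w)
  }
  crit <- function(lambda) {
    f <- fit_at(lambda)
    if (f$rss <= 0) return(-Inf)
    (n - p) * log(f$rss) + sum(log(1 + lambda * d)) +
      as.numeric(determinant(f$XtWX, logarithm = TRUE)$modulus)
  }
  ols <- fit_at(0)
  if (ols$rss <= 1e-12 * sum(y^2)) {
    lambda_hat <- 0
    f <- ols
  } else {
    opt <- optimize(crit, interval = c(0, 1e3), tol = 1e-9)
    lambda_hat <- if (crit(0) <= opt$objective) 0 else opt$minimum
    f <- fit_at(lambda_hat)
  }
  sigma_eps2 <- f$rss / (n - p)
  sigma_g2 <- lambda_hat * sigma_eps2
  vcov_beta <- sigma_eps2 * solve(f$XtWX)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  zst <- ifelse(se > 0, f$beta / se,
                ifelse(f$beta == 0, 0, Inf * sign(f$beta)))
  pv <- 2 * pnorm(-abs(zst))
  names(se) <- names(zst) <- names(pv) <- colnames(X)
  ll <- if (sigma_eps2 > 0)
    -0.5 * ((n - p) * log(2 * pi * sigma_eps2) + (n - p) +
              sum(log(1 + lambda_hat * d)) +
              as.numeric(determinant(f$XtWX, logarithm = TRUE)$modulus) -
              p * log(sigma_eps2)) else NA_real_
  res <- list(coefficients = f$beta, se = se, z = zst, p_value = pv,
              sigma_g2 = sigma_g2, sigma_eps2 = sigma_eps2,
              lambda = lambda_hat, loglik = ll,
              boundary = lambda_hat == 0, converged = TRUE,
              n = n, outcome = outcome, predictor = predictor)
  class(res) <- "grm_fit"
  res
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("GRM mixed model (REML), n = %d\n", x$n))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    p = signif(x$p_value, 3))
  print(round(tab, 4))
  cat(sprintf("sigma_g2 = %.4f, sigma_eps2 = %.4f%s\n", x$sigma_g2,
              x$sigma_eps2,
              if (x$boundary) " (boundary: zero genetic variance)" else ""))
  invisible(x)
}
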