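#' Compute polygenic scores as weighted allele-dosage sums
#'
#' The score of individual `m` is `sum_i w_i x_mi` over the variants shared
#' between the weights table and the genotype matrix. Scoring is performed on
#' the intersection of variants; weights variants absent from the genotypes
#' are dropped with a warning that reports the count.
#'
#' Allele handling (active when the genotype matrix carries counted-allele
#' metadata): a variant whose counted allele equals the effect allele is used
#' directly; if the effect allele matches the variant's other allele the
#' dosage is flipped (`x -> 2 - x`); if it matches the strand complement of
#' the counted allele the variant is used as-is; strand-ambiguous pairs
#' (A/T, G/C) that require a flip or complement are dropped rather than
#' guessed.
#'
#' @param genotypes Numeric matrix, individuals x variants, entries in
#'   `[0, 2]` (hard calls or imputed dosages); column names are variant ids.
#'   Optional attributes `counted_allele` and `other_allele` (character
#'   vectors named by variant id) enable allele matching.
#' @param weights A data frame with columns `variant_id`, `effect_allele`,
#'   `weight` (see [read_weights()]).
#' @return Named numeric vector of raw scores (one per individual), with
#'   attributes `n_used`, `n_missing`, `n_dropped_allele`.
#' @export
score_individuals <- function(genotypes, weights) {
  if (!is.matrix(genotypes) || is.null(colnames(genotypes)))
    stop("genotypes must be a matrix with variant ids as column names")
  if (!all(c("variant_id", "effect_allele", "weight") %in% names(weights)))
    stop("weights must have columns variant_id, effect_allele, weight")
  if (anyDuplicated(weights$variant_id))
    stop("weights variant ids must be unique")
  if (!all(is.finite(weights$weight))) stop("weights must be finite")
  rng <- range(genotypes)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 2)
    stop("genotype dosages must lie in [0, 2]")

  shared <- intersect(weights$variant_id, colnames(genotypes))
  if (length(shared) == 0L)
    stop("no overlap between weights variants and genotype variants")
  n_missing <- nrow(weights) - length(shared)
  if (n_missing > 0L)
    warning(n_missing, " weight variant(s) absent from genotypes; ",
            "scoring over the overlap")

  w <- setNames(weights$weight, weights$variant_id)[shared]
  eff <- setNames(weights$effect_allele, weights$variant_id)[shared]
  X <- genotypes[, shared, drop = FALSE]

  counted <- attr(genotypes, "counted_allele")
  dropped_allele <- 0L
  if (!is.null(counted)) {
    other <- attr(genotypes, "other_allele")
    counted <- counted[shared]
    other <- if (is.null(other)) rep(NA_character_, length(shared)) else
      other[shared]
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
    ambiguous <- eq(counted, comp[other]) | eq(other, comp[counted])
    direct <- eq(eff, counted)
    flip <- !direct & eq(eff, other) & !ambiguous
    strand <- !direct & !flip & eq(eff, comp[counted]) & !ambiguous
    keep <- direct | flip | strand
    dropped_allele <- sum(!keep)
    if (dropped_allele > 0L)
      warning(dropped_allele,
              " variant(s) dropped: effect allele not resolvable ",
              "(mismatch or strand-ambiguous A/T, G/C)")
    if (!any(keep)) stop("no variants usable after allele matching")
    X <- X[, keep, drop = FALSE]
    w <- w[keep]
    if (any(flip[keep])) {
      fl <- flip[keep]
      X[, fl] <- 2 - X[, fl]
    }
  }
  scores <- as.numeric(X %*% w)
  names(scores) <- rownames(genotypes)
  attr(scores, "n_used") <- length(w)
  attr(scores, "n_missing") <- n_missing
  attr(scores, "n_dropped_allele") <- dropped_allele
  scores
}

#' Residualize on covariates and z-standardize
#'
#' Regresses `values` on the covariates (plus an intercept) by ordinary least
#' squares and returns the residuals standardized to mean 0, SD 1 (SD with
#' denominator n - 1). This is the standard "regression method" adjustment
#' applied to polygenic scores (principal components, genotyping chip, plate)
#' and outcomes (sex, age) before model fitting.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param covariates Optional data frame (numeric columns or factors, which
#'   are one-hot expanded). `NULL` or zero columns means plain
#'   z-standardization.
#' @return Numeric vector of standardized residuals.
#' @export
residualize_standardize <- function(values, covariates = NULL) {
  if (!is.numeric(values) || length(unique(values)) < 2L)
    stop("values must be numeric with at least 2 distinct values")
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    r <- values - mean(values)
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(values))
      stop("covariates must have one row per value")
    mm <- model.matrix(~ ., data = covariates)
    q <- qr(mm)
    if (q$rank < ncol(mm)) {
      drop_cols <- colnames(mm)[q$pivot[(q$rank + 1L):ncol(mm)]]
      warning("dropping collinear covariate column(s): ",
              paste(drop_cols, collapse = ", "))
      mm <- mm[, q$pivot[seq_len(q$rank)], drop = FALSE]
      q <- qr(mm)
    }
    r <- qr.resid(q, values)
  }
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12 * max(1, sd(values)))
    stop("degenerate variable: zero residual variance after adjustment")
  (r - mean(r)) / s
}

#' Adjust an outcome for sex and age and z-standardize
#'
#' Convenience wrapper around [residualize_standardize()] with covariates
#' `{sex, age}`, mirroring the usual pre-analysis cleaning of twin outcomes.
#'
#' @param outcome Numeric outcome vector.
#' @param sex Sex indicator (numeric, factor or character).
#' @param age Numeric age.
#' @return Standardized residuals (mean 0, SD 1).
#' @export
preprocess_outcome <- function(outcome, sex, age) {
  covs <- data.frame(sex = sex, age = age)
  residualize_standardize(outcome, covs)
}
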