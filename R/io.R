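# Polynomial rolling hash over a string (mod 2^31 - 1); enough to
# fingerprint a config in provenance records without external dependencies.
.config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a cohort table with a provenance sidecar
#'
#' Writes the long-format cohort as TSV and, by default, a
#' `<path>.provenance.json` recording the simulation configuration, its
#' hash, the seed and the package version, so a rerun from the provenance
#' file is bit-identical.
#'
#' @param cohort A [generate_cohort()] table (or any twin-pair cohort).
#' @param path Output TSV path.
#' @param provenance Write the JSON sidecar (when a config is attached)?
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, provenance = TRUE) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (provenance && !is.null(cfg)) {
    cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                 digits = I(17))
    prov <- list(config = unclass(cfg),
                 config_hash = .config_hash(as.character(cfg_json)),
                 seed = cfg$seed,
                 package = "twinwb",
                 version = as.character(packageVersion("twinwb")))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort table
#'
#' @param path TSV/CSV path with at least `family_id` and `member` columns
#'   (delimiter inferred from the extension; `.csv` is comma).
#' @return A data frame.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("family_id", "member") %in% names(df)))
    stop("cohort file must have columns 'family_id' and 'member'")
  df
}

#' Read a polygenic weights table
#'
#' Three-column TSV with a header: `variant_id`, `effect_allele`, `weight`.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_weights <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "weight")
  if (!all(need %in% names(df)))
    stop("weights file must have header columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$variant_id)) stop("duplicate variant ids in weights")
  if (!is.numeric(df$weight) || !all(is.finite(df$weight)))
    stop("weights must be finite numbers")
  df[need]
}

#' Read a genotype dosage matrix from TSV
#'
#' Rows are individuals (first column their ids), remaining columns variant
#' dosages in `[0, 2]`.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with individual row names and variant column names.
#' @export
read_genotype_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  rng <- range(X)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 2)
    stop("genotype dosages must lie in [0, 2]")
  X
}

#' Read genotypes from a VCF file
#'
#' Uses the `DS` (dosage) FORMAT field when present, otherwise counts ALT
#' alleles from `GT`. The counted allele is ALT; REF is recorded as the
#' other allele, enabling allele matching in [score_individuals()]. VCF
#' coordinates are 1-based and stay in the variant ids.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return Individuals x variants dosage matrix with attributes
#'   `counted_allele` and `other_allele`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  vid <- ifelse(is.na(fx$ID) | fx$ID == ".",
                paste0(fx$CHROM, ":", fx$POS), fx$ID)
  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(fmt) || all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    fmt <- apply(gt, 2, cnt)
    if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(gt),
                                         dimnames = dimnames(gt))
  }
  X <- t(fmt)
  colnames(X) <- vid
  attr(X, "counted_allele") <- setNames(fx$ALT, vid)
  attr(X, "other_allele") <- setNames(fx$REF, vid)
  X
}

#' Run a grid of decomposition models from a manifest
#'
#' Drives the full analysis over every outcome x predictor x covariate-set
#' combination: decomposition fit, pair bootstrap (with percentile
#' intervals), within/between difference test, attenuation, and a single
#' Benjamini-Hochberg correction across all fixed-effect p-values of the
#' grid (one family of hypotheses). Per-model failures are recorded and the
#' run continues.
#'
#' @param manifest A named list (or path to a YAML file) with fields:
#'   `cohort` (data frame or file path), `outcomes`, `predictors` (character
#'   vectors), `covariate_sets` (named list of character vectors; default one
#'   unadjusted set), `n_boot` (default 1000; 0 means point estimates only),
#'   `alpha` (default 0.05), `seed`, and optional `out_dir`.
#' @return A list with `results` (tidy data frame, one row per model
#'   coefficient), `model_stats` (per-model difference test and attenuation),
#'   `fdr` (threshold and discovery count), `failures`, `seed`. When
#'   `out_dir` is set, writes `results.tsv`, `model_stats.tsv` and
#'   `run.json` (provenance: manifest hash, seed, version).
#' @export
run_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  if (is.character(manifest$cohort))
    manifest$cohort <- read_cohort(manifest$cohort)
  cohort <- manifest$cohort
  outcomes <- manifest$outcomes
  predictors <- manifest$predictors
  if (is.null(outcomes) || is.null(predictors))
    stop("manifest must list 'outcomes' and 'predictors'")
  missing_cols <- setdiff(c(outcomes, predictors,
                            unlist(manifest$covariate_sets)),
                          names(cohort))
  if (length(missing_cols) > 0)
    stop("manifest references column(s) not in cohort: ",
         paste(missing_cols, collapse = ", "))
  covariate_sets <- manifest$covariate_sets
  if (is.null(covariate_sets)) covariate_sets <- list(none = character())
  n_boot <- if (is.null(manifest$n_boot)) 1000 else manifest$n_boot
  alpha <- if (is.null(manifest$alpha)) 0.05 else manifest$alpha
  seed <- if (is.null(manifest$seed)) 1L else as.integer(manifest$seed)

  rows <- list()
  stats_rows <- list()
  failures <- list()
  mi <- 0L
  for (cs in names(covariate_sets)) {
    covs <- covariate_sets[[cs]]
    if (length(covs) == 1 && is.na(covs[1])) covs <- character()
    for (oc in outcomes) for (pr in predictors) {
      mi <- mi + 1L
      model_seed <- (seed + 7919L * mi) %% 2147483647L
      res <- tryCatch({
        if (n_boot > 0) {
          bt <- bootstrap_pairs(cohort, oc, pr, covariates = covs,
                                n_boot = n_boot, seed = model_seed)
          ft <- bt$fit
          dt <- diff_test(bt)
          at <- attenuation(bt)
          ci <- bt$ci
        } else {
          ft <- fit_within_between(cohort, oc, pr, covariates = covs)
          bt <- NULL
          dt <- list(z = NA_real_, p = NA_real_)
          at <- attenuation(beta_w = ft$coefficients[["gps_within"]],
                            beta_b = ft$coefficients[["gps_between"]])
          ci <- NULL
        }
        for (term in c("gps_within", "gps_between")) {
          rows[[length(rows) + 1L]] <- data.frame(
            outcome = oc, predictor = pr, covariate_set = cs, term = term,
            estimate = ft$coefficients[[term]], se = ft$se[[term]],
            p = ft$p_value[[term]],
            ci_low = if (is.null(ci)) NA_real_ else
              ci[1, sub("gps_within", "beta_w",
                        sub("gps_between", "beta_b", term))],
            ci_high = if (is.null(ci)) NA_real_ else
              ci[2, sub("gps_within", "beta_w",
                        sub("gps_between", "beta_b", term))],
            stringsAsFactors = FALSE)
        }
        stats_rows[[length(stats_rows) + 1L]] <- data.frame(
          outcome = oc, predictor = pr, covariate_set = cs,
          n_pairs = ft$n_pairs, icc = ft$icc,
          total_effect = ft$total_effect,
          diff_z = dt$z, diff_p = dt$p,
          attenuation_pct = at$attenuation_pct,
          seed = model_seed, stringsAsFactors = FALSE)
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error"))
        failures[[paste(oc, pr, cs, sep = "|")]] <- conditionMessage(res)
    }
  }
  results <- do.call(rbind, rows)
  model_stats <- do.call(rbind, stats_rows)
  fdr <- if (!is.null(results) && nrow(results) > 0)
    bh_fdr(results$p, alpha = alpha) else NULL
  if (!is.null(fdr)) results$significant <- fdr$significant

  if (!is.null(manifest$out_dir)) {
    dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(results, file.path(manifest$out_dir, "results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(model_stats, file.path(manifest$out_dir, "model_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    man <- manifest
    man$cohort <- NULL
    man_json <- jsonlite::toJSON(man, auto_unbox = TRUE, digits = I(17))
    jsonlite::write_json(
      list(manifest = man, manifest_hash = .config_hash(as.character(man_json)),
           seed = seed, alpha = alpha,
           fdr_threshold = if (is.null(fdr)) NA else fdr$threshold,
           version = as.character(packageVersion("twinwb"))),
      file.path(manifest$out_dir, "run.json"),
      auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  }
  list(results = results, model_stats = model_stats, fdr = fdr,
       failures = failures, seed = seed)
}
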