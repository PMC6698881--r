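#' Simulation configuration for a DZ-twin cohort
#'
#' Parameterizes the generative family model used by [generate_cohort()].
#' Outcomes are generated on a standardized scale:
#' \deqn{Y_{ij} = \beta_{direct} z_{ij} + \beta_{nurture} \bar{z}_{parents,j}
#'   + c_{shared} C_j + \delta_{subpop(j)} + e_{ij}}
#' where \eqn{z_{ij}} is the twin's standardized polygenic score,
#' \eqn{\bar{z}_{parents,j}} the mid-parent standardized score (the carrier of
#' passive gene-environment correlation / genetic nurture), \eqn{C_j} a shared
#' family environment draw, and \eqn{\delta} a per-subpopulation environmental
#' offset. The family socio-economic status variable is
#' \deqn{SES_j = \lambda_{ses} \bar{z}_{parents,j} + \nu_{ses} C_j +
#'   \sigma_{ses} u_j.}
#'
#' Defaults describe a cohort with a moderate direct genetic effect
#' (0.3 per score SD), no genetic nurture, a shared-environment SD of 0.5 and a
#' residual SD chosen so the outcome variance is close to 1, under random
#' mating in a single unstructured population.
#'
#' @param n_families Number of DZ twin families (2 twins each).
#' @param n_loci Number of unlinked biallelic loci.
#' @param freq_low,freq_high Bounds of the uniform distribution of base
#'   effect-allele frequencies; must satisfy `0 < freq_low <= freq_high < 1`.
#' @param beta_direct Direct effect of the twin's standardized score on the
#'   outcome (per-SD units).
#' @param beta_nurture Effect of the mid-parent standardized score on the
#'   outcome via the family environment (per-SD units).
#' @param c_shared SD of the family-level shared-environment term.
#' @param sigma_e SD of the individual residual.
#' @param r_mate Target mate correlation in genetic value, in `[0, 1)`;
#'   0 means random mating.
#' @param n_subpops Number of subpopulations (>= 1).
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`.
#' @param strat_shift SD of the per-subpopulation environmental offset.
#' @param lambda_ses,nu_ses,sigma_ses Loadings of the mid-parent score, the
#'   shared environment and independent noise on family SES.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical cohort.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_cohort()], [read_sim_config()]
#' @export
#' @examples
#' cfg <- sim_config(n_families = 100, n_loci = 50, seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(cohort)
sim_config <- function(n_families = 1000L,
                       n_loci = 500L,
                       freq_low = 0.05,
                       freq_high = 0.95,
                       beta_direct = 0.3,
                       beta_nurture = 0,
                       c_shared = 0.5,
                       sigma_e = sqrt(0.66),
                       r_mate = 0,
                       n_subpops = 1L,
                       fst = 0,
                       strat_shift = 0,
                       lambda_ses = 0.5,
                       nu_ses = 0.5,
                       sigma_ses = sqrt(0.5),
                       seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families), n_loci = as.integer(n_loci),
    freq_low = freq_low, freq_high = freq_high,
    beta_direct = beta_direct, beta_nurture = beta_nurture,
    c_shared = c_shared, sigma_e = sigma_e, r_mate = r_mate,
    n_subpops = as.integer(n_subpops), fst = fst, strat_shift = strat_shift,
    lambda_ses = lambda_ses, nu_ses = nu_ses, sigma_ses = sigma_ses,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param config A list of configuration fields.
#' @export
validate_sim_config <- function(config) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(ok, msg) if (!ok) stop("invalid simulation config: ", msg,
                                         call. = FALSE)
  for (f in c("n_families", "n_loci", "freq_low", "freq_high", "beta_direct",
              "beta_nurture", "c_shared", "sigma_e", "r_mate", "n_subpops",
              "fst", "strat_shift", "lambda_ses", "nu_ses", "sigma_ses",
              "seed")) {
    chk(f %in% names(config) && num1(config[[f]]),
        paste0("field '", f, "' missing or not a finite scalar"))
  }
  chk(config$n_families >= 1, "n_families must be >= 1")
  chk(config$n_loci >= 1, "n_loci must be >= 1")
  chk(config$freq_low > 0 && config$freq_low <= config$freq_high &&
        config$freq_high < 1,
      "need 0 < freq_low <= freq_high < 1")
  chk(config$c_shared >= 0 && config$sigma_e >= 0 &&
        config$strat_shift >= 0 && config$sigma_ses >= 0,
      "SD parameters must be >= 0")
  chk(config$r_mate >= 0 && config$r_mate < 1, "r_mate must be in [0, 1)")
  chk(config$fst >= 0 && config$fst < 1, "fst must be in [0, 1)")
  chk(config$n_subpops >= 1, "n_subpops must be >= 1")
  invisible(config)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file must use the field names of [sim_config()] exactly; unknown
#' fields are an error. Fields left out fall back to the defaults of
#' [sim_config()], except those listed in `required`.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @param required Fields that must be present in the file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path, required = c("n_families", "seed")) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a mapping of fields")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    stop("missing required config field(s): ",
         paste(missing_req, collapse = ", "))
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("DZ twin cohort simulation config\n")
  cat(sprintf("  families: %d   loci: %d   seed: %d\n",
              x$n_families, x$n_loci, x$seed))
  cat(sprintf("  effects: direct %.3g, nurture %.3g, shared-env SD %.3g, residual SD %.3g\n",
              x$beta_direct, x$beta_nurture, x$c_shared, x$sigma_e))
  cat(sprintf("  mating r: %.3g   subpops: %d (Fst %.3g, shift SD %.3g)\n",
              x$r_mate, x$n_subpops, x$fst, x$strat_shift))
  cat(sprintf("  SES loadings: midparent %.3g, shared env %.3g, noise %.3g\n",
              x$lambda_ses, x$nu_ses, x$sigma_ses))
  invisible(x)
}
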