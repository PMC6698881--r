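#' Simulate parental genotype pools
#'
#' Draws base effect-allele frequencies uniformly on
#' `[freq_low, freq_high]`, then, when `fst > 0`, per-subpopulation
#' frequencies from a Balding-Nichols beta distribution with mean `p` and
#' variance `p (1 - p) fst`. One father pool and one mother pool of size
#' `n_families` are generated; parent genotypes are independent
#' `Binomial(2, p)` dosages per locus. Fathers and mothers in the same family
#' slot are assigned to the same subpopulation so mating can stay within
#' subpopulations.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed (the orchestrating [generate_cohort()]
#'   seeds the stream once instead).
#' @return A list of class `parent_pool` with elements `fathers`, `mothers`
#'   (`n_families x n_loci` dosage matrices), `subpop` (integer labels),
#'   `freqs` (base frequencies) and `subpop_freqs`
#'   (`n_subpops x n_loci` realized frequencies).
#' @export
simulate_parents <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  nf <- config$n_families
  L <- config$n_loci
  K <- config$n_subpops
  p <- runif(L, config$freq_low, config$freq_high)
  if (config$fst > 0) {
    a <- p * (1 - config$fst) / config$fst
    b <- (1 - p) * (1 - config$fst) / config$fst
    subpop_freqs <- matrix(0, K, L)
    for (k in seq_len(K)) {
      pk <- rbeta(L, a, b)
      subpop_freqs[k, ] <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
    }
  } else {
    subpop_freqs <- matrix(p, K, L, byrow = FALSE)
    subpop_freqs <- matrix(rep(p, each = K), K, L)
  }
  subpop <- rep_len(seq_len(K), nf)
  pr <- subpop_freqs[subpop, , drop = FALSE]
  fathers <- matrix(rbinom(nf * L, 2L, as.vector(pr)), nf, L)
  mothers <- matrix(rbinom(nf * L, 2L, as.vector(pr)), nf, L)
  structure(list(fathers = fathers, mothers = mothers, subpop = subpop,
                 freqs = p, subpop_freqs = subpop_freqs),
            class = "parent_pool")
}

#' Pair mates assortatively on a noisy proxy of genetic value
#'
#' Within each subpopulation, each parent receives a proxy
#' `u = sqrt(r_mate) * z + sqrt(1 - r_mate) * e` of their standardized genetic
#' value `z`; fathers and mothers are then paired by matching proxy ranks.
#' Because rank matching makes the paired proxies essentially perfectly
#' correlated, the realized correlation of mate genetic values is close to
#' `cor(z, u)^2 = r_mate`. With `r_mate = 0` pairing is uniformly random.
#'
#' @param father_score,mother_score Numeric genetic values (e.g. raw polygenic
#'   scores); standardized internally.
#' @param subpop Integer subpopulation labels, same for fathers and mothers
#'   (equal counts per subpopulation in both sexes).
#' @param r_mate Target mate correlation in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return An integer vector `m` such that father `i` is paired with mother
#'   `m[i]`.
#' @export
mate_assortatively <- function(father_score, mother_score, subpop = NULL,
                               r_mate = 0, seed = NULL) {
  if (!is.numeric(r_mate) || length(r_mate) != 1L || r_mate < 0 || r_mate >= 1)
    stop("r_mate must be a scalar in [0, 1)")
  nf <- length(father_score)
  if (length(mother_score) != nf)
    stop("father and mother pools must have equal size")
  if (is.null(subpop)) subpop <- rep(1L, nf)
  if (!is.null(seed)) set.seed(seed)
  zf <- as.numeric(scale(father_score))
  zm <- as.numeric(scale(mother_score))
  mate <- integer(nf)
  for (k in unique(subpop)) {
    fi <- which(subpop == k)
    mi <- which(subpop == k)
    if (length(fi) != length(mi))
      stop("unequal father/mother counts within subpopulation ", k)
    if (r_mate == 0) {
      mate[fi] <- mi[sample.int(length(mi))]
    } else {
      a <- sqrt(r_mate)
      b <- sqrt(1 - r_mate)
      uf <- a * zf[fi] + b * rnorm(length(fi))
      um <- a * zm[mi] + b * rnorm(length(mi))
      mate[fi[order(uf)]] <- mi[order(um)]
    }
  }
  mate
}

#' Mendelian transmission of unlinked biallelic loci
#'
#' Each parent contributes one allele per locus: a homozygote transmits
#' deterministically and a heterozygote transmits the effect allele with
#' probability 1/2, independently across loci (no linkage). Two independent
#' calls with the same parents produce DZ co-twins.
#'
#' @param father_genotype,mother_genotype Dosage vectors or matrices
#'   (individuals x loci) with entries in `{0, 1, 2}`.
#' @param seed Optional integer seed.
#' @return Offspring dosages with the same shape as the inputs.
#' @export
transmit <- function(father_genotype, mother_genotype, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fg <- father_genotype
  mg <- mother_genotype
  if (length(fg) != length(mg)) stop("parental genotype shapes differ")
  if (!all(fg %in% c(0, 1, 2)) || !all(mg %in% c(0, 1, 2)))
    stop("parental dosages must be in {0, 1, 2}")
  gam_f <- (fg == 2) + (fg == 1) * rbinom(length(fg), 1L, 0.5)
  gam_m <- (mg == 2) + (mg == 1) * rbinom(length(mg), 1L, 0.5)
  off <- gam_f + gam_m
  if (is.matrix(fg)) dim(off) <- dim(fg)
  off
}

#' Simulate outcomes and family SES from genetic and family components
#'
#' Applies the generative model of [sim_config()]: the outcome of twin `i` in
#' family `j` is `beta_direct * z_ij + beta_nurture * midparent_j +
#' c_shared * C_j + delta_subpop(j) + e_ij`, with `C_j ~ N(0,1)`,
#' `e_ij ~ N(0, sigma_e^2)` and a per-subpopulation offset with SD
#' `strat_shift`. Family SES is `lambda_ses * midparent_j + nu_ses * C_j +
#' sigma_ses * u_j`. Co-twins share `C_j`, the offset and SES.
#'
#' @param twin1_z,twin2_z Standardized twin polygenic scores (length =
#'   number of families).
#' @param midparent Mid-parent standardized scores.
#' @param subpop Integer subpopulation label per family.
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed.
#' @return A list with `outcome1`, `outcome2`, `ses`, `shared_env`,
#'   `subpop_shift` (per family).
#' @export
simulate_phenotypes <- function(twin1_z, twin2_z, midparent, subpop, config,
                                seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  J <- length(twin1_z)
  K <- config$n_subpops
  delta <- rnorm(K, 0, config$strat_shift)
  shift <- delta[subpop]
  C <- rnorm(J)
  fampart <- config$beta_nurture * midparent + config$c_shared * C + shift
  outcome1 <- config$beta_direct * twin1_z + fampart +
    rnorm(J, 0, config$sigma_e)
  outcome2 <- config$beta_direct * twin2_z + fampart +
    rnorm(J, 0, config$sigma_e)
  ses <- config$lambda_ses * midparent + config$nu_ses * C +
    config$sigma_ses * rnorm(J)
  list(outcome1 = outcome1, outcome2 = outcome2, ses = ses,
       shared_env = C, subpop_shift = shift)
}

#' Generate a complete synthetic DZ-twin cohort
#'
#' Orchestrates [simulate_parents()], [mate_assortatively()], [transmit()]
#' (twice, giving DZ co-twins), polygenic scoring and
#' [simulate_phenotypes()], all from one seeded random stream
#' (`config$seed`), so the same configuration always regenerates a
#' byte-identical table.
#'
#' Per-allele weights are drawn `N(0, 1/(2 L pbar (1 - pbar)))` with `pbar`
#' the mean base frequency, so raw scores have variance near 1 and the
#' configured effects are per-SD after the scores are z-standardized on the
#' offspring distribution.
#'
#' @param config A [sim_config()] object.
#' @param keep_genotypes Attach twin and parent genotype matrices and the
#'   weights table as attributes (`genotypes`, `parents`, `weights`)?
#' @return A long-format `data.frame`, two rows per family, with columns
#'   `id`, `family_id`, `member` (1|2), `subpop`, `gps` (standardized score),
#'   `outcome`, `ses`, and oracle columns prefixed `true_` (`true_score`,
#'   `true_midparent`, `true_shared_env`, `true_subpop_shift`) carried for
#'   recovery tests only. Attributes: `config`, `score_scale`
#'   (mean/SD used to standardize raw scores), and the genotype attributes
#'   when requested.
#' @export
generate_cohort <- function(config, keep_genotypes = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed)
  nf <- config$n_families
  L <- config$n_loci

  pool <- simulate_parents(config)
  pbar <- mean(pool$freqs)
  weights <- rnorm(L, 0, sqrt(1 / (2 * L * pbar * (1 - pbar))))

  raw_f <- as.numeric(pool$fathers %*% weights)
  raw_m <- as.numeric(pool$mothers %*% weights)
  par_mu <- mean(c(raw_f, raw_m))
  par_sd <- sd(c(raw_f, raw_m))
  zf <- (raw_f - par_mu) / par_sd
  zm <- (raw_m - par_mu) / par_sd

  mate <- mate_assortatively(raw_f, raw_m, pool$subpop, config$r_mate)
  mo <- pool$mothers[mate, , drop = FALSE]
  zm <- zm[mate]

  g1 <- transmit(pool$fathers, mo)
  g2 <- transmit(pool$fathers, mo)
  raw1 <- as.numeric(g1 %*% weights)
  raw2 <- as.numeric(g2 %*% weights)
  off_mu <- mean(c(raw1, raw2))
  off_sd <- sd(c(raw1, raw2))
  z1 <- (raw1 - off_mu) / off_sd
  z2 <- (raw2 - off_mu) / off_sd
  midparent <- (zf + zm) / 2

  ph <- simulate_phenotypes(z1, z2, midparent, pool$subpop, config)

  fam <- seq_len(nf)
  ids1 <- sprintf("F%05d_1", fam)
  ids2 <- sprintf("F%05d_2", fam)
  cohort <- data.frame(
    id = as.vector(rbind(ids1, ids2)),
    family_id = rep(fam, each = 2L),
    member = rep(c(1L, 2L), nf),
    subpop = rep(pool$subpop, each = 2L),
    gps = as.vector(rbind(z1, z2)),
    outcome = as.vector(rbind(ph$outcome1, ph$outcome2)),
    ses = rep(ph$ses, each = 2L),
    true_score = as.vector(rbind(z1, z2)),
    true_midparent = rep(midparent, each = 2L),
    true_shared_env = rep(ph$shared_env, each = 2L),
    true_subpop_shift = rep(ph$subpop_shift, each = 2L),
    stringsAsFactors = FALSE
  )
  attr(cohort, "config") <- config
  attr(cohort, "score_scale") <- c(mean = off_mu, sd = off_sd)
  if (keep_genotypes) {
    # interleave twin1/twin2 rows to match the table order
    geno <- matrix(0, 2L * nf, L)
    geno[seq(1L, 2L * nf, 2L), ] <- g1
    geno[seq(2L, 2L * nf, 2L), ] <- g2
    rownames(geno) <- cohort$id
    vid <- sprintf("v%04d", seq_len(L))
    colnames(geno) <- vid
    attr(cohort, "genotypes") <- geno
    attr(cohort, "parents") <- list(fathers = pool$fathers, mothers = mo)
    attr(cohort, "weights") <- data.frame(
      variant_id = vid,
      effect_allele = rep_len(c("A", "C"), L),
      weight = weights,
      stringsAsFactors = FALSE
    )
    attr(cohort, "freqs") <- pool$freqs
  }
  cohort
}
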