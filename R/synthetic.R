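#' Configuration for the summary-level two-sample simulator
#'
#' The generator works directly at the summary-statistic level, emulating
#' the post-clumping state of a two-sample MR analysis: K independent
#' instruments with true exposure associations `gamma_k` drawn uniformly
#' from `gamma_range`, observed exposure betas `X_k ~ N(gamma_k, se_X_k)`
#' and outcome log-ORs `Y_k ~ N(beta_causal * gamma_k + alpha_k, se_Y_k)`
#' with independent noise (no sample overlap). Direct (pleiotropic) effects
#' `alpha_k` are zero (`"none"`), mean-zero (`"balanced"`) or shifted
#' (`"directional"`); `inside_violation = TRUE` makes `alpha_k` proportional
#' to `gamma_k` plus noise, breaking the InSIDE assumption. A fraction
#' `frac_pleiotropic` of instruments receives a direct effect; the rest stay
#' valid.
#'
#' Default SE magnitudes place the generator in the strong-instrument
#' regime the first-order Wald/IVW theory assumes: `se_X_level = 0.005`
#' (instrument F-statistics in the hundreds-to-thousands, as for
#' genome-wide-significant instruments from large exposure GWAS) and
#' `se_Y_level = 0.02` (per-SNP log-OR SE implied by a case-control outcome
#' GWAS with roughly 15k cases / 27k controls at common allele
#' frequencies). Per-SNP SEs are jittered uniformly by `+/- se_jitter`.
#'
#' @param K Number of instruments (>= 1).
#' @param beta_causal True causal log-OR per 1 SD exposure.
#' @param gamma_range Range of true instrument strengths (default 0.05-0.3).
#' @param se_X_level,se_Y_level Per-SNP SE magnitudes (> 0).
#' @param se_jitter Relative jitter applied to per-SNP SEs (default 0.2).
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param alpha_mean,alpha_sd Direct-effect distribution; both must be 0
#'   when `pleiotropy = "none"`, and `alpha_mean` must be 0 when balanced.
#' @param frac_pleiotropic Fraction of instruments with a direct effect.
#' @param inside_violation Correlate direct effects with instrument
#'   strength.
#' @param maf_range Minor-allele-frequency range (default 0.01-0.5).
#' @param palindromic_fraction Expected fraction of A/T or C/G variants.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(K, beta_causal = 0, gamma_range = c(0.05, 0.3),
                       se_X_level = 0.005, se_Y_level = 0.02,
                       se_jitter = 0.2,
                       pleiotropy = c("none", "balanced", "directional"),
                       alpha_mean = 0, alpha_sd = 0,
                       frac_pleiotropic = 1, inside_violation = FALSE,
                       maf_range = c(0.01, 0.5),
                       palindromic_fraction = 1 / 3, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(K >= 1, se_X_level > 0, se_Y_level > 0,
            se_jitter >= 0, se_jitter < 1,
            frac_pleiotropic >= 0, frac_pleiotropic <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            length(gamma_range) == 2, gamma_range[1] > 0,
            diff(gamma_range) >= 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5)
  if (pleiotropy == "none" && (alpha_mean != 0 || alpha_sd != 0)) {
    stop("pleiotropy = 'none' requires alpha_mean = alpha_sd = 0",
         call. = FALSE)
  }
  if (pleiotropy == "balanced" && alpha_mean != 0) {
    stop("balanced pleiotropy requires alpha_mean = 0", call. = FALSE)
  }
  structure(
    list(K = as.integer(K), beta_causal = beta_causal,
         gamma_range = gamma_range, se_X_level = se_X_level,
         se_Y_level = se_Y_level, se_jitter = se_jitter,
         pleiotropy = pleiotropy, alpha_mean = alpha_mean,
         alpha_sd = alpha_sd, frac_pleiotropic = frac_pleiotropic,
         inside_violation = inside_violation, maf_range = maf_range,
         palindromic_fraction = palindromic_fraction,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

NON_PALINDROMIC_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "T"),
                              c("G", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("C", "G"))

#' Simulate one two-sample summary-statistic study
#'
#' Draws exposure and outcome GWAS record tables for the configured study
#' (see [sim_config()]) together with the generating truth. Exposure
#' p-values are computed from `X_k / se_X_k` (two-sided normal), so
#' instrument selection can be exercised end-to-end; both tables share SNP
#' ids, alleles (forward strand) and effect-allele frequencies, as in
#' pre-harmonized repository downloads.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional seed override (defaults to `cfg$seed`).
#' @return List with `exposure` and `outcome` record data frames (the format
#'   [read_gwas_table()] returns) and `truth` (a `sim_truth`: `beta_causal`,
#'   `gamma`, `alpha`, `pleiotropic` index vector, alleles, `eaf`).
#' @export
simulate_study <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  k <- cfg$K
  with_preserved_rng(seed, {
    gamma <- stats::runif(k, cfg$gamma_range[1], cfg$gamma_range[2])
    jit <- function(level) level * stats::runif(k, 1 - cfg$se_jitter,
                                                1 + cfg$se_jitter)
    se_x <- jit(cfg$se_X_level)
    se_y <- jit(cfg$se_Y_level)
    alpha <- numeric(k)
    pleio_idx <- integer(0)
    if (cfg$pleiotropy != "none") {
      n_inv <- round(cfg$frac_pleiotropic * k)
      pleio_idx <- sort(sample.int(k, n_inv))
      if (n_inv > 0) {
        if (cfg$inside_violation) {
          g <- gamma[pleio_idx]
          alpha[pleio_idx] <- cfg$alpha_mean * g / mean(g) +
            stats::rnorm(n_inv, 0, cfg$alpha_sd)
        } else {
          alpha[pleio_idx] <- stats::rnorm(n_inv, cfg$alpha_mean,
                                           cfg$alpha_sd)
        }
      }
    }
    x <- stats::rnorm(k, gamma, se_x)
    y <- stats::rnorm(k, cfg$beta_causal * gamma + alpha, se_y)
    pal <- stats::runif(k) < cfg$palindromic_fraction
    pick <- function(pairs) {
      p <- pairs[[sample.int(length(pairs), 1)]]
      if (stats::runif(1) < 0.5) p else rev(p)
    }
    alleles <- t(vapply(pal, function(is_pal) {
      pick(if (is_pal) PALINDROMIC_PAIRS else NON_PALINDROMIC_PAIRS)
    }, character(2)))
    maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
    eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)
    ids <- sprintf("rs%08d", sample.int(9e7, k))
    chrom <- as.character(sample.int(22L, k, replace = TRUE))
    pos <- sample.int(2.4e8, k)
    pclamp <- function(z) pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    rec <- function(beta, se) {
      data.frame(snp_id = ids, effect_allele = alleles[, 1],
                 other_allele = alleles[, 2], beta = beta, se = se,
                 eaf = eaf, pvalue = pclamp(beta / se), chrom = chrom,
                 pos = pos, stringsAsFactors = FALSE)
    }
    truth <- structure(
      list(beta_causal = cfg$beta_causal, gamma = gamma, alpha = alpha,
           pleiotropic = pleio_idx, effect_allele = alleles[, 1],
           other_allele = alleles[, 2], eaf = eaf),
      class = "sim_truth"
    )
    list(exposure = rec(x, se_x), outcome = rec(y, se_y), truth = truth)
  })
}

#' Convert a simulated study straight into a harmonized set
#'
#' Convenience wrapper for estimator studies: the simulator emits already
#' allele-aligned tables, so this is the identity harmonization.
#'
#' @param sim Output of [simulate_study()].
#' @param exposure_name,outcome_name Labels.
#' @return A [harmonized_set()].
#' @export
sim_to_harmonized <- function(sim, exposure_name = "sim_exposure",
                              outcome_name = "sim_outcome") {
  harmonized_set(exposure_name, outcome_name, sim$exposure$snp_id,
                 sim$exposure$beta, sim$exposure$se,
                 sim$outcome$beta, sim$outcome$se)
}

#' Named validation scenarios with pinned seeds
#'
#' Fixed configurations covering the assumption space of the three
#' estimators:
#' * `null` — no causal effect, no pleiotropy (type-I error checks);
#' * `causal_no_pleiotropy` — K = 7, beta = -0.46, echoing the scale of a
#'   strong protective growth-factor effect (parameter-recovery checks);
#' * `balanced` — mean-zero direct effects (IVW remains consistent);
#' * `directional_inside_ok` — directional pleiotropy with InSIDE holding
#'   (Egger intercept recovers the mean direct effect);
#' * `directional_inside_violated` — same but with direct effects
#'   correlated with instrument strength (documented Egger failure mode);
#' * `minority_invalid` — 30% of instruments carry a directional direct
#'   effect (weighted median outperforms IVW).
#'
#' @return Named list of [sim_config()] objects.
#' @export
scenario_suite <- function() {
  list(
    null = sim_config(K = 10, beta_causal = 0, seed = 101L),
    causal_no_pleiotropy = sim_config(K = 7, beta_causal = -0.46,
                                      seed = 202L),
    balanced = sim_config(K = 20, beta_causal = 0.1,
                          pleiotropy = "balanced", alpha_sd = 0.05,
                          seed = 303L),
    directional_inside_ok = sim_config(K = 100, beta_causal = 0.1,
                                       pleiotropy = "directional",
                                       alpha_mean = 0.05, alpha_sd = 0.02,
                                       seed = 404L),
    directional_inside_violated = sim_config(K = 100, beta_causal = 0.1,
                                             pleiotropy = "directional",
                                             alpha_mean = 0.05,
                                             alpha_sd = 0.02,
                                             inside_violation = TRUE,
                                             seed = 505L),
    minority_invalid = sim_config(K = 10, beta_causal = 0.1,
                                  pleiotropy = "directional",
                                  alpha_mean = 0.2, alpha_sd = 0.05,
                                  frac_pleiotropic = 0.3, seed = 606L)
  )
}
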