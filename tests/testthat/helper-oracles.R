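# Fixture builders and independent oracles. Oracles deliberately use a
# different computational route (lm(), explicit CDF construction, pairwise
# enumeration) from the implementation they check.

make_records <- function(snp_id, effect_allele = "A", other_allele = "G",
                         beta = 0.1, se = 0.01, eaf = NA_real_,
                         pvalue = 1e-9, chrom = "1",
                         pos = seq_along(snp_id) * 10000L) {
  if (length(snp_id) == 0L) return(mrpipe:::empty_gwas_table())
  data.frame(snp_id = snp_id, effect_allele = effect_allele,
             other_allele = other_allele, beta = beta, se = se, eaf = eaf,
             pvalue = pvalue, chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

make_hset <- function(X, se_X, Y, se_Y,
                      snp_ids = sprintf("rs%03d", seq_along(X)), ...) {
  harmonized_set("exp", "out", snp_ids, X, se_X, Y, se_Y, ...)
}

rand_hset <- function(k, seed) {
  set.seed(seed)
  make_hset(
    X = stats::runif(k, 0.05, 0.3) * sample(c(-1, 1), k, replace = TRUE),
    se_X = stats::runif(k, 0.005, 0.02),
    Y = stats::rnorm(k, 0, 0.1),
    se_Y = stats::runif(k, 0.01, 0.05)
  )
}

# weighted regression through the origin via lm(); returns beta and the
# fixed-effect (unit-dispersion) SE (the SE needs at least one residual df)
wls_origin_oracle <- function(X, Y, se_Y) {
  fit <- stats::lm(Y ~ 0 + X, weights = se_Y^-2)
  s <- summary(fit)
  se <- if (fit$df.residual > 0) unname(s$coefficients[1, 2] / s$sigma)
        else NA_real_
  list(beta = unname(stats::coef(fit)[1]), se = se)
}

# weighted regression with intercept via lm(), SEs rescaled by the
# bounded-below multiplicative dispersion factor
wls_egger_oracle <- function(X, Y, se_Y) {
  neg <- X < 0
  X[neg] <- -X[neg]
  Y[neg] <- -Y[neg]
  fit <- stats::lm(Y ~ X, weights = se_Y^-2)
  s <- summary(fit)
  adj <- max(1, s$sigma) / s$sigma
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       intercept_se = unname(s$coefficients[1, 2]) * adj,
       slope_se = unname(s$coefficients[2, 2]) * adj)
}

# explicit weighted empirical CDF built point by point, inverted at 1/2
weighted_median_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  n <- length(r)
  cdf <- numeric(n)  # midpoint CDF: mass of w_k split around its atom
  acc <- 0
  for (k in seq_len(n)) {
    cdf[k] <- acc + w[k] / 2
    acc <- acc + w[k]
  }
  if (0.5 <= cdf[1]) return(r[1])
  if (0.5 >= cdf[n]) return(r[n])
  hi <- which(cdf >= 0.5)[1]
  lo <- hi - 1
  r[lo] + (0.5 - cdf[lo]) * (r[hi] - r[lo]) / (cdf[hi] - cdf[lo])
}

# brute-force pairwise verification that a clumped set satisfies the
# constraint and is maximal under the greedy order
clump_constraint_ok <- function(records, ld, r2_max, window_bp) {
  n <- nrow(records)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- records$chrom[i] == records$chrom[j]
      close <- same && abs(records$pos[i] - records$pos[j]) <= window_bp
      if (close) {
        r2 <- ld_r2(ld, records$snp_id[i], records$snp_id[j])
        if (is.na(r2)) r2 <- 1
        if (r2 > r2_max) return(FALSE)
      }
    }
  }
  TRUE
}

write_tmp_tsv <- function(df, headers = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  if (!is.null(headers)) names(df) <- headers
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
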