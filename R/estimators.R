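#' Construct an MR estimate
#'
#' Internal constructor shared by all estimators. The confidence interval is
#' computed on the log-odds scale and exponentiated; a finite `df` switches
#' the reference distribution from standard normal to Student t (used for the
#' MR-Egger slope and intercept, with K - 2 degrees of freedom).
#'
#' @param method One of `"wald"`, `"ivw"`, `"weighted_median"`,
#'   `"mr_egger_slope"`.
#' @param n_snp Number of instruments K.
#' @param beta,se Log-odds effect per 1 SD exposure and its standard error.
#' @param df Degrees of freedom for the reference distribution (`Inf` =
#'   normal).
#' @param level Confidence level (default 0.95).
#' @param exposure,outcome Optional trait labels carried into reports.
#' @return An `mr_estimate` object with fields `method`, `n_snp`, `beta`,
#'   `se`, `pvalue`, `odds_ratio`, `ci_low`, `ci_high`.
#' @export
mr_estimate <- function(method, n_snp, beta, se, df = Inf, level = 0.95,
                        exposure = NULL, outcome = NULL) {
  stopifnot(se > 0, level > 0, level < 1)
  stat <- beta / se
  pvalue <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else
    2 * stats::pnorm(-abs(stat))
  ci <- to_odds_scale(beta, se, level = level, df = df)
  structure(
    list(method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
         pvalue = pvalue, odds_ratio = ci$odds_ratio, ci_low = ci$ci_low,
         ci_high = ci$ci_high, df = df, level = level,
         exposure = exposure, outcome = outcome),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (K = %d): OR %s (%d%% CI %s-%s), p = %s\n",
              x$method, x$n_snp, format_or(x$odds_ratio),
              round(100 * x$level), format_or(x$ci_low),
              format_or(x$ci_high), format_pvalue(x$pvalue)))
  invisible(x)
}

# report rounding: 2 decimals for OR/CI; p < 0.001 in scientific notation
# with 2 significant digits
format_or <- function(x) sprintf("%.2f", x)
format_pvalue <- function(p) {
  if (p < 1e-3) sprintf("%.1e", p) else sprintf("%.3g", p)
}

#' Per-SNP Wald ratio
#'
#' The causal estimate from a single instrument is the ratio of the outcome
#' association to the exposure association, `beta = Y / X`, with the
#' first-order standard error `se = se_Y / |X|` that treats the exposure
#' association as known (the exposure-side uncertainty is ignored, as is
#' standard for strong instruments).
#'
#' @param X,se_X Exposure beta and SE (`se_X` is accepted for interface
#'   symmetry; it does not enter the first-order SE).
#' @param Y,se_Y Outcome beta (log-OR) and SE.
#' @param snp_id Optional id used in error messages.
#' @return List with `beta` and `se`. Vectorized over its arguments.
#' @export
wald_ratio <- function(X, se_X = NULL, Y, se_Y, snp_id = NULL) {
  if (any(X == 0)) {
    bad <- if (is.null(snp_id)) which(X == 0) else snp_id[X == 0]
    stop("Wald ratio undefined for X = 0 (", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  }
  stopifnot(all(se_Y > 0))
  list(beta = Y / X, se = se_Y / abs(X))
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW with first-order weights:
#' \deqn{\hat\beta = \frac{\sum_k X_k Y_k \sigma_{Y_k}^{-2}}
#'                        {\sum_k X_k^2 \sigma_{Y_k}^{-2}}, \qquad
#'       \hat\sigma = \sqrt{1 / \textstyle\sum_k X_k^2 \sigma_{Y_k}^{-2}},}
#' equivalent to weighted least squares of Y on X through the origin with
#' weights \eqn{\sigma_{Y_k}^{-2}}. The p-value is a two-sided standard
#' normal test of `beta / se`. With K = 1 this collapses exactly to the Wald
#' ratio. `random_effects = TRUE` applies a multiplicative over-dispersion
#' factor `max(1, sqrt(Q / (K - 1)))` to the SE (not the default).
#'
#' @param h A [harmonized_set()].
#' @param random_effects Apply multiplicative over-dispersion scaling.
#' @param level Confidence level.
#' @return An [mr_estimate()] with `method = "ivw"`.
#' @export
mr_ivw <- function(h, random_effects = FALSE, level = 0.95) {
  k <- length(h$snp_ids)
  if (k < 1L) stop("IVW requires at least one SNP", call. = FALSE)
  w <- h$se_Y^-2
  denom <- sum(h$X^2 * w)
  beta <- sum(h$X * h$Y * w) / denom
  se <- sqrt(1 / denom)
  if (random_effects && k > 1L) {
    r <- h$Y / h$X
    q <- sum((h$X / h$se_Y)^2 * (r - beta)^2)
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  mr_estimate("ivw", k, beta, se, level = level,
              exposure = h$exposure_name, outcome = h$outcome_name)
}

# weighted empirical median with midpoint-style cumulative weights:
# s_k = sum_{j<=k} w_j - w_k / 2 (weights normalized), linearly
# interpolated at s = 0.5 over the sorted ratios
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (length(r) == 1L) return(r)
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Median of the weighted empirical distribution of the per-SNP Wald ratios,
#' with weights proportional to \eqn{(X_k/\sigma_{Y_k})^2} (the inverse
#' variance of each ratio). The estimator is consistent when instruments
#' carrying more than half of the weight are valid. The standard error is
#' the standard deviation of the estimate over `n_boot` parametric-bootstrap
#' replicates that redraw `X_k ~ N(X_k, se_X_k)` and `Y_k ~ N(Y_k, se_Y_k)`;
#' the p-value is a two-sided normal test. SNPs are sorted canonically by
#' snp_id before resampling so the result is invariant to input order for a
#' fixed seed.
#'
#' @param h A [harmonized_set()] with K >= 3.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required, for
#'   reproducibility).
#' @param level Confidence level.
#' @return An [mr_estimate()] with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed, level = 0.95) {
  k <- length(h$snp_ids)
  if (k < 3L) stop("weighted median requires K >= 3 instruments", call. = FALSE)
  stopifnot(n_boot >= 1L)
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  o <- order(h$snp_ids)
  X <- h$X[o]; se_X <- h$se_X[o]; Y <- h$Y[o]; se_Y <- h$se_Y[o]
  w <- (X / se_Y)^2
  beta <- weighted_median_point(Y / X, w)
  ests <- with_preserved_rng(seed, {
    Xb <- matrix(stats::rnorm(k * n_boot, mean = X, sd = se_X), nrow = k)
    Yb <- matrix(stats::rnorm(k * n_boot, mean = Y, sd = se_Y), nrow = k)
    vapply(seq_len(n_boot), function(j) {
      weighted_median_point(Yb[, j] / Xb[, j], (Xb[, j] / se_Y)^2)
    }, numeric(1))
  })
  se <- stats::sd(ests)
  mr_estimate("weighted_median", k, beta, se, level = level,
              exposure = h$exposure_name, outcome = h$outcome_name)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with a free intercept, `Y_k = a + b X_k`, weights
#' \eqn{\sigma_{Y_k}^{-2}}. Each SNP is first oriented so that `X_k >= 0`
#' (negating both `X_k` and `Y_k` where needed) because the fit is not
#' invariant to allele coding. The intercept estimates the average direct
#' (pleiotropic) effect — a nonzero value signals unbalanced horizontal
#' pleiotropy — and the slope is the pleiotropy-adjusted causal estimate,
#' consistent under the InSIDE assumption. Standard errors use the
#' unit-dispersion WLS covariance scaled by the multiplicative
#' over-dispersion factor `max(1, sqrt(RSE))`, `RSE` the weighted residual
#' sum of squares over K - 2; p-values and the slope CI use t with K - 2
#' degrees of freedom.
#'
#' @param h A [harmonized_set()] with K >= 3.
#' @param level Confidence level.
#' @param constrain_intercept Internal test mode: force the intercept to 0,
#'   in which case the slope reproduces the IVW estimate.
#' @return An `egger_estimate`: list with `slope` (an [mr_estimate()] with
#'   `method = "mr_egger_slope"`), `intercept`, `intercept_se`,
#'   `intercept_pvalue`.
#' @export
mr_egger <- function(h, level = 0.95, constrain_intercept = FALSE) {
  k <- length(h$snp_ids)
  if (!constrain_intercept && k < 3L) {
    stop("MR-Egger requires K >= 3 instruments", call. = FALSE)
  }
  X <- h$X; Y <- h$Y
  neg <- X < 0
  X[neg] <- -X[neg]
  Y[neg] <- -Y[neg]
  if (!constrain_intercept && stats::var(X) == 0) {
    stop("degenerate design: no variance in oriented exposure betas",
         call. = FALSE)
  }
  w <- h$se_Y^-2
  m <- if (constrain_intercept) cbind(slope = X) else cbind(intercept = 1, slope = X)
  a <- crossprod(m, m * w)
  coefs <- drop(solve(a, crossprod(m, Y * w)))
  res <- Y - drop(m %*% coefs)
  df <- k - ncol(m)
  rse <- if (df > 0) sum(w * res^2) / df else NA_real_
  disp <- if (df > 0) max(1, sqrt(rse)) else 1
  ses <- sqrt(diag(solve(a))) * disp
  if (constrain_intercept) {
    return(mr_estimate("mr_egger_slope", k, coefs[["slope"]], ses[["slope"]],
                       df = max(df, 1), level = level,
                       exposure = h$exposure_name, outcome = h$outcome_name))
  }
  slope <- mr_estimate("mr_egger_slope", k, coefs[["slope"]], ses[["slope"]],
                       df = df, level = level,
                       exposure = h$exposure_name, outcome = h$outcome_name)
  intercept <- coefs[["intercept"]]
  intercept_se <- ses[["intercept"]]
  structure(
    list(slope = slope, intercept = intercept, intercept_se = intercept_se,
         intercept_pvalue = 2 * stats::pt(-abs(intercept / intercept_se), df)),
    class = "egger_estimate"
  )
}

#' @export
print.egger_estimate <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.3f (SE %.3f), p = %s\n", x$intercept,
              x$intercept_se, format_pvalue(x$intercept_pvalue)))
  invisible(x)
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' `OR = exp(beta)`; the interval is `exp(beta -/+ q * se)` with `q` the
#' `(1 + level)/2` quantile of the standard normal (`df = Inf`, default,
#' q = 1.959964 at 95%) or of Student t with `df` degrees of freedom (used
#' for the MR-Egger slope with K - 2 df).
#'
#' @param beta,se Estimate on the log-odds scale; `se > 0`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param df Degrees of freedom (`Inf` = normal quantile).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
to_odds_scale <- function(beta, se, level = 0.95, df = Inf) {
  stopifnot(se > 0, level > 0, level < 1)
  q <- if (is.finite(df)) stats::qt((1 + level) / 2, df) else
    stats::qnorm((1 + level) / 2)
  list(odds_ratio = exp(beta), ci_low = exp(beta - q * se),
       ci_high = exp(beta + q * se))
}

# evaluate expr with a local RNG stream, restoring the caller's RNG state
with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
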