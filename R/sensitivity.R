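#' Cochran's Q heterogeneity statistic
#'
#' Q is the weighted sum of squared deviations of the per-SNP Wald ratios
#' about the fixed-effect IVW estimate,
#' \deqn{Q = \sum_k w_k (r_k - \hat\beta_{IVW})^2, \qquad
#'       w_k = (X_k/\sigma_{Y_k})^2,}
#' referred to a chi-square distribution with K - 1 degrees of freedom.
#' Large Q flags heterogeneous instruments (possible pleiotropy or
#' outliers).
#'
#' @param h A [harmonized_set()] with K >= 2.
#' @return List (`heterogeneity_result`) with `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h) {
  k <- length(h$snp_ids)
  if (k < 2L) stop("Cochran's Q requires K >= 2 instruments", call. = FALSE)
  r <- h$Y / h$X
  w <- (h$X / h$se_Y)^2
  beta <- mr_ivw(h)$beta
  q <- sum(w * (r - beta)^2)
  structure(
    list(Q = q, df = k - 1L,
         pvalue = stats::pchisq(q, df = k - 1L, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %s\n", x$Q, x$df,
              format_pvalue(x$pvalue)))
  invisible(x)
}

subset_hset <- function(h, keep) {
  harmonized_set(h$exposure_name, h$outcome_name, h$snp_ids[keep],
                 h$X[keep], h$se_X[keep], h$Y[keep], h$se_Y[keep],
                 h$flags[keep])
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate omitting each SNP in turn; the final row
#' (`snp_id = "All"`) is the full-set estimate. With K = 2 each omission row
#' degenerates to the remaining SNP's Wald ratio (flagged in the `note`
#' attribute). A SNP is flagged as a potential outlier — reported, never
#' removed — when its omission moves the IVW beta by more than one full-set
#' SE, or when its Q contribution exceeds the chi-square(1) critical value at
#' 0.05/K.
#'
#' @param h A [harmonized_set()] with K >= 2.
#' @param level Confidence level.
#' @return Data frame with columns `snp_id`, `n_snp`, `beta`, `se`,
#'   `pvalue`, `OR`, `ci_low`, `ci_high`, `outlier_flag` (NA for the "All"
#'   row).
#' @export
leave_one_out <- function(h, level = 0.95) {
  k <- length(h$snp_ids)
  if (k < 2L) stop("leave-one-out requires K >= 2 instruments", call. = FALSE)
  full <- mr_ivw(h, level = level)
  r <- h$Y / h$X
  w <- (h$X / h$se_Y)^2
  qcrit <- stats::qchisq(0.05 / k, df = 1, lower.tail = FALSE)
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(subset_hset(h, -i), level = level)
    flag <- abs(est$beta - full$beta) > full$se ||
      w[i] * (r[i] - full$beta)^2 > qcrit
    data.frame(snp_id = h$snp_ids[i], n_snp = est$n_snp, beta = est$beta,
               se = est$se, pvalue = est$pvalue, OR = est$odds_ratio,
               ci_low = est$ci_low, ci_high = est$ci_high,
               outlier_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$snp_id), , drop = FALSE]
  out <- rbind(out, data.frame(
    snp_id = "All", n_snp = full$n_snp, beta = full$beta, se = full$se,
    pvalue = full$pvalue, OR = full$odds_ratio, ci_low = full$ci_low,
    ci_high = full$ci_high, outlier_flag = NA, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  if (k == 2L) attr(out, "note") <- "K = 2: omission rows are single-SNP Wald ratios"
  out
}

#' Per-SNP Wald-ratio table with combined estimates
#'
#' One row per SNP (sorted canonically by snp_id) with the Wald-ratio
#' estimate on both scales, followed by combined rows for IVW and — when
#' K >= 3 — the weighted median and the MR-Egger slope. This table is the
#' canonical input for scatter and forest displays.
#'
#' @param h A [harmonized_set()].
#' @param level Confidence level.
#' @param n_boot,seed Passed to [mr_weighted_median()] when K >= 3; `seed`
#'   is required in that case.
#' @return Data frame with columns `snp_id`, `method`, `n_snp`, `beta`,
#'   `se`, `pvalue`, `OR`, `ci_low`, `ci_high`.
#' @export
single_snp_table <- function(h, level = 0.95, n_boot = 1000L, seed = NULL) {
  o <- order(h$snp_ids)
  wr <- wald_ratio(h$X[o], h$se_X[o], h$Y[o], h$se_Y[o], snp_id = h$snp_ids[o])
  q <- stats::qnorm((1 + level) / 2)
  z <- wr$beta / wr$se
  rows <- data.frame(
    snp_id = h$snp_ids[o], method = "wald", n_snp = 1L, beta = wr$beta,
    se = wr$se, pvalue = 2 * stats::pnorm(-abs(z)), OR = exp(wr$beta),
    ci_low = exp(wr$beta - q * wr$se), ci_high = exp(wr$beta + q * wr$se),
    stringsAsFactors = FALSE
  )
  combined <- list(mr_ivw(h, level = level))
  if (length(h$snp_ids) >= 3L) {
    if (is.null(seed)) {
      stop("seed is required for the weighted-median rows when K >= 3",
           call. = FALSE)
    }
    combined <- c(combined, list(
      mr_weighted_median(h, n_boot = n_boot, seed = seed, level = level),
      mr_egger(h, level = level)$slope
    ))
  }
  for (est in combined) {
    rows <- rbind(rows, data.frame(
      snp_id = "All", method = est$method, n_snp = est$n_snp,
      beta = est$beta, se = est$se, pvalue = est$pvalue,
      OR = est$odds_ratio, ci_low = est$ci_low, ci_high = est$ci_high,
      stringsAsFactors = FALSE
    ))
  }
  rownames(rows) <- NULL
  rows
}
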