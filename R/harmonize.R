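COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1] == a2)

#' Pairwise linkage-disequilibrium information
#'
#' Wraps user-supplied r-squared values, either as a pair list (data frame
#' with columns `snp_a`, `snp_b`, `r2`) or as a square matrix with SNP ids as
#' dimnames. Values must lie in \[0, 1\]; the diagonal is implicitly 1. Pairs
#' absent from the table have unknown LD (`NA` on lookup); [clump()] decides
#' how to treat them.
#'
#' @param pairs Data frame `snp_a`, `snp_b`, `r2`, or a symmetric numeric
#'   matrix with dimnames.
#' @return An `ld_info` object.
#' @export
ld_info <- function(pairs) {
  if (is.matrix(pairs)) {
    ids <- rownames(pairs)
    idx <- which(upper.tri(pairs), arr.ind = TRUE)
    pairs <- data.frame(snp_a = ids[idx[, 1]], snp_b = ids[idx[, 2]],
                        r2 = pairs[idx], stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  r2 <- as.numeric(pairs$r2)
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pmin(pairs$snp_a, pairs$snp_b),
               pmax(pairs$snp_a, pairs$snp_b), sep = "\r")
  tab <- tapply(r2, key, max)  # duplicates collapse conservatively to max
  structure(list(tab = tab), class = "ld_info")
}

#' Look up the r-squared between two SNPs
#'
#' @param ld An [ld_info()] object (or `NULL`, meaning no information).
#' @param a,b SNP identifiers.
#' @return r-squared, 1 when `a == b`, `NA` when the pair is unknown.
#' @export
ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  if (is.null(ld)) return(NA_real_)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  v <- ld$tab[key]
  if (is.na(v)) NA_real_ else unname(v)
}

#' Select genome-wide-significant instruments
#'
#' Keeps records with `pvalue` strictly below the threshold (the
#' conventional instrument filter is p < 5e-8), preserving input order.
#'
#' @param records Data frame of GWAS records.
#' @param p_threshold Strict upper bound on the p-value, in (0, 1).
#' @return The filtered data frame (possibly empty).
#' @export
select_instruments <- function(records, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  records[records$pvalue < p_threshold, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Thins the record set so retained SNPs are approximately independent.
#' Candidates are visited in order of ascending p-value (ties broken by
#' chromosome, position, then snp_id); a candidate is accepted iff no
#' already-accepted SNP on the same chromosome lies within `window_bp` base
#' pairs *and* has r-squared strictly greater than `r2_max` with it. With the
#' defaults this removes pairs with r² > 0.01 within a 1 Mb window; a pair at
#' exactly r² = 0.01 is kept.
#'
#' Pairs inside the window whose r² is unknown are an error in strict mode
#' and treated as r² = 1 (conservative removal) in lenient mode.
#'
#' @param records Data frame of GWAS records with `chrom` and `pos` set.
#' @param ld [ld_info()] object.
#' @param r2_max Exclusive r-squared cutoff (default 0.01).
#' @param window_bp Window in base pairs (default 1e6).
#' @param strict Error on unknown in-window pairs (default `TRUE`).
#' @return Subset of `records`, input order preserved.
#' @export
clump <- function(records, ld, r2_max = 0.01, window_bp = 1e6L,
                  strict = TRUE) {
  if (nrow(records) == 0L) return(records)
  if (any(is.na(records$chrom) | is.na(records$pos))) {
    stop("clumping requires chrom and pos for every record", call. = FALSE)
  }
  o <- order(records$pvalue, records$chrom, records$pos, records$snp_id)
  kept <- integer(0)
  for (i in o) {
    ok <- TRUE
    for (j in kept) {
      same_chr <- records$chrom[j] == records$chrom[i]
      if (same_chr && abs(records$pos[j] - records$pos[i]) <= window_bp) {
        r2 <- ld_r2(ld, records$snp_id[i], records$snp_id[j])
        if (is.na(r2)) {
          if (strict) {
            stop("no r2 available for in-window pair ", records$snp_id[i],
                 " / ", records$snp_id[j], call. = FALSE)
          }
          r2 <- 1
        }
        if (r2 > r2_max) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  records[sort(kept), , drop = FALSE]
}

#' Substitute proxy SNPs for instruments absent from the outcome data
#'
#' For each missing instrument, picks the proxy with the highest r-squared
#' at or above `r2_min` among proxies actually present in the outcome data;
#' ties are broken by lexicographic proxy id. Instruments with no qualifying
#' proxy are reported as dropped, which is an outcome, not an error.
#'
#' @param missing Character vector of instrument snp_ids absent from the
#'   outcome data.
#' @param proxy_table Data frame with columns `snp`, `proxy`, `r2` and
#'   optionally `proxy_effect_allele`, `proxy_other_allele` (the proxy's
#'   alleles phased to the instrument's effect/other alleles).
#' @param outcome_ids Character vector of snp_ids available in the outcome
#'   data.
#' @param r2_min Inclusive lower bound for an acceptable proxy (default 0.8).
#' @return List with `map` (data frame `snp`, `proxy`, `r2`, plus phase
#'   columns when supplied) and `dropped` (character vector).
#' @export
substitute_proxies <- function(missing, proxy_table, outcome_ids,
                               r2_min = 0.8) {
  empty <- data.frame(snp = character(), proxy = character(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  if (length(missing) == 0L) return(list(map = empty, dropped = character()))
  if (is.null(proxy_table) || nrow(proxy_table) == 0L) {
    return(list(map = empty, dropped = missing))
  }
  rows <- lapply(missing, function(id) {
    cand <- proxy_table[proxy_table$snp == id &
                          proxy_table$r2 >= r2_min &
                          proxy_table$proxy %in% outcome_ids, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[order(-cand$r2, cand$proxy), , drop = FALSE][1, , drop = FALSE]
  })
  found <- do.call(rbind, rows)
  if (is.null(found)) found <- empty
  list(map = found, dropped = setdiff(missing, found$snp))
}

#' Align one outcome record to an exposure record's effect allele
#'
#' Harmonization cases, applied in order: identical alleles (unchanged);
#' swapped alleles (outcome beta negated, eaf reflected); strand-complement
#' match (outcome alleles complemented, then the above). Palindromic variants
#' (A/T or C/G), whose strand is ambiguous, follow `palindromic_mode`:
#' * `"keep"` — trust the stated alleles (appropriate when both datasets are
#'   harmonized to the forward strand) and flag `palindromic_kept`;
#' * `"drop"` — discard the variant;
#' * `"frequency"` — keep only when both effect-allele frequencies are known,
#'   fall outside the ambiguity window \[0.42, 0.58\], and lie on the same
#'   side of 0.5 after allele alignment; otherwise drop.
#'
#' @param exp,out Single records (one-row data frames or lists) sharing a
#'   snp_id (or an accepted proxy).
#' @param palindromic_mode `"keep"`, `"drop"` or `"frequency"`.
#' @param ambiguity_window Frequency window within which a palindromic
#'   variant is considered unresolvable in `"frequency"` mode.
#' @return A list `(snp_id, X, se_X, Y, se_Y, eaf_exp, eaf_out, flag)` or,
#'   when the variant must be discarded, `(dropped = TRUE, reason = ...)`.
#' @export
harmonize_pair <- function(exp, out,
                           palindromic_mode = c("keep", "drop", "frequency"),
                           ambiguity_window = c(0.42, 0.58)) {
  palindromic_mode <- match.arg(palindromic_mode)
  exp <- as.list(exp); out <- as.list(out)
  drop_signal <- function(reason) list(dropped = TRUE, reason = reason,
                                       snp_id = exp$snp_id)
  keep <- function(y, eaf_out, flag) {
    list(dropped = FALSE, snp_id = exp$snp_id,
         X = exp$beta, se_X = exp$se, Y = y, se_Y = out$se,
         eaf_exp = exp$eaf %||% NA_real_, eaf_out = eaf_out, flag = flag)
  }
  ea <- out$effect_allele; oa <- out$other_allele
  pal <- is_palindromic(exp$effect_allele, exp$other_allele)

  if (pal) {
    # for a palindromic pair, strand complementing equals an allele swap, so
    # orientation cannot be inferred from the labels alone
    if (identical(ea, exp$effect_allele) && identical(oa, exp$other_allele)) {
      y <- out$beta; eaf_out <- out$eaf %||% NA_real_
    } else if (identical(ea, exp$other_allele) && identical(oa, exp$effect_allele)) {
      y <- -out$beta
      eaf_out <- if (is.null(out$eaf) || is.na(out$eaf)) NA_real_ else 1 - out$eaf
    } else {
      return(drop_signal("incompatible_alleles"))
    }
    if (palindromic_mode == "drop") return(drop_signal("palindromic"))
    if (palindromic_mode == "frequency") {
      fe <- exp$eaf %||% NA_real_; fo <- eaf_out
      lo <- ambiguity_window[1]; hi <- ambiguity_window[2]
      resolvable <- !is.na(fe) && !is.na(fo) &&
        (fe < lo || fe > hi) && (fo < lo || fo > hi) &&
        sign(fe - 0.5) == sign(fo - 0.5)
      if (!resolvable) return(drop_signal("palindromic_ambiguous"))
    }
    return(keep(y, eaf_out, "palindromic_kept"))
  }

  if (identical(ea, exp$effect_allele) && identical(oa, exp$other_allele)) {
    return(keep(out$beta, out$eaf %||% NA_real_, "unchanged"))
  }
  if (identical(ea, exp$other_allele) && identical(oa, exp$effect_allele)) {
    eaf_out <- if (is.null(out$eaf) || is.na(out$eaf)) NA_real_ else 1 - out$eaf
    return(keep(-out$beta, eaf_out, "allele_flipped"))
  }
  # strand complement, then retry the two cases above
  cea <- unname(COMPLEMENT[ea]); coa <- unname(COMPLEMENT[oa])
  if (identical(cea, exp$effect_allele) && identical(coa, exp$other_allele)) {
    return(keep(out$beta, out$eaf %||% NA_real_, "unchanged"))
  }
  if (identical(cea, exp$other_allele) && identical(coa, exp$effect_allele)) {
    eaf_out <- if (is.null(out$eaf) || is.na(out$eaf)) NA_real_ else 1 - out$eaf
    return(keep(-out$beta, eaf_out, "allele_flipped"))
  }
  drop_signal("incompatible_alleles")
}

#' Construct a harmonized exposure/outcome SNP set
#'
#' @param exposure_name,outcome_name Trait labels.
#' @param snp_ids Unique SNP identifiers.
#' @param X,se_X Exposure betas and standard errors.
#' @param Y,se_Y Outcome betas (log-OR for binary outcomes) and standard
#'   errors.
#' @param flags Per-SNP harmonization action (`unchanged`, `allele_flipped`,
#'   `palindromic_kept`, `proxy_substituted`).
#' @param audit Optional per-SNP audit data frame carried for reporting.
#' @return A `harmonized_set` object.
#' @export
harmonized_set <- function(exposure_name, outcome_name, snp_ids,
                           X, se_X, Y, se_Y,
                           flags = rep("unchanged", length(snp_ids)),
                           audit = NULL) {
  k <- length(snp_ids)
  if (k < 1L) {
    stop("empty harmonized set for analysis ", exposure_name, " -> ",
         outcome_name, call. = FALSE)
  }
  recycle <- function(v) if (length(v) == 1L && k > 1L) rep(v, k) else v
  X <- recycle(X); se_X <- recycle(se_X)
  Y <- recycle(Y); se_Y <- recycle(se_Y); flags <- recycle(flags)
  if (!all(lengths(list(X, se_X, Y, se_Y, flags)) == k)) {
    stop("all harmonized vectors must have length ", k, call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique", call. = FALSE)
  if (any(se_X <= 0) || any(se_Y <= 0)) {
    stop("standard errors must be strictly positive", call. = FALSE)
  }
  structure(
    list(exposure_name = exposure_name, outcome_name = outcome_name,
         snp_ids = as.character(snp_ids), X = as.numeric(X),
         se_X = as.numeric(se_X), Y = as.numeric(Y), se_Y = as.numeric(se_Y),
         flags = as.character(flags), audit = audit),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s (%d SNPs)\n",
              x$exposure_name, x$outcome_name, length(x$snp_ids)))
  flagged <- x$flags != "unchanged"
  if (any(flagged)) {
    tab <- table(x$flags[flagged])
    cat("  actions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Merge exposure instruments with outcome records into an analysis-ready set
#'
#' Applies, in order: proxy substitution for instruments missing from the
#' outcome data, then per-SNP allele harmonization. Every dropped SNP is
#' recorded with a reason in the audit table attached to the result.
#'
#' @param exposure Data frame of selected (and clumped) instrument records.
#' @param outcome Data frame of outcome records (the lookup).
#' @param exposure_name,outcome_name Trait labels.
#' @param palindromic_mode Passed to [harmonize_pair()].
#' @param proxy_table Optional proxy table (see [substitute_proxies()]).
#' @param proxy_r2 Minimum proxy r-squared (default 0.8).
#' @return A [harmonized_set()]; errors if no SNP survives.
#' @export
build_harmonized_set <- function(exposure, outcome,
                                 exposure_name = "exposure",
                                 outcome_name = "outcome",
                                 palindromic_mode = "keep",
                                 proxy_table = NULL, proxy_r2 = 0.8) {
  if (nrow(exposure) == 0L) {
    stop("no instruments supplied for analysis ", exposure_name, " -> ",
         outcome_name, call. = FALSE)
  }
  missing_ids <- setdiff(exposure$snp_id, outcome$snp_id)
  prox <- substitute_proxies(missing_ids, proxy_table, outcome$snp_id,
                             r2_min = proxy_r2)
  audit <- list()
  rows <- list()
  for (i in seq_len(nrow(exposure))) {
    e <- exposure[i, , drop = FALSE]
    id <- e$snp_id
    via_proxy <- FALSE
    if (id %in% outcome$snp_id) {
      o <- outcome[match(id, outcome$snp_id), , drop = FALSE]
    } else if (id %in% prox$map$snp) {
      pr <- prox$map[match(id, prox$map$snp), , drop = FALSE]
      o <- outcome[match(pr$proxy, outcome$snp_id), , drop = FALSE]
      via_proxy <- TRUE
      if (all(c("proxy_effect_allele", "proxy_other_allele") %in% names(pr))) {
        # phase supplied: relabel the proxy's alleles as the instrument's
        if (identical(o$effect_allele, pr$proxy_effect_allele) &&
            identical(o$other_allele, pr$proxy_other_allele)) {
          o$effect_allele <- e$effect_allele
          o$other_allele <- e$other_allele
        } else if (identical(o$effect_allele, pr$proxy_other_allele) &&
                   identical(o$other_allele, pr$proxy_effect_allele)) {
          o$effect_allele <- e$other_allele
          o$other_allele <- e$effect_allele
        }
      }
    } else {
      audit[[id]] <- data.frame(snp_id = id, status = "dropped",
                                detail = "no_proxy", stringsAsFactors = FALSE)
      next
    }
    h <- harmonize_pair(e, o, palindromic_mode = palindromic_mode)
    if (!via_proxy && isTRUE(h$dropped)) {
      audit[[id]] <- data.frame(snp_id = id, status = "dropped",
                                detail = h$reason, stringsAsFactors = FALSE)
      next
    }
    if (via_proxy && isTRUE(h$dropped) && h$reason == "incompatible_alleles") {
      # unphased proxy with different alleles: fall back to frequency
      # alignment when both frequencies are informative, otherwise drop
      fe <- e$eaf; fo <- o$eaf
      if (!is.na(fe) && !is.na(fo) &&
          abs(fe - 0.5) > 0.08 && abs(fo - 0.5) > 0.08) {
        y <- if (sign(fe - 0.5) == sign(fo - 0.5)) o$beta else -o$beta
        h <- list(dropped = FALSE, snp_id = id, X = e$beta, se_X = e$se,
                  Y = y, se_Y = o$se, eaf_exp = fe, eaf_out = fo,
                  flag = "proxy_substituted")
        audit[[id]] <- data.frame(snp_id = id, status = "kept",
                                  detail = paste0("proxy:", o$snp_id,
                                                  ":frequency_aligned"),
                                  stringsAsFactors = FALSE)
      } else {
        audit[[id]] <- data.frame(snp_id = id, status = "dropped",
                                  detail = "proxy_unresolvable",
                                  stringsAsFactors = FALSE)
        next
      }
    } else if (via_proxy && isTRUE(h$dropped)) {
      audit[[id]] <- data.frame(snp_id = id, status = "dropped",
                                detail = paste0("proxy:", h$reason),
                                stringsAsFactors = FALSE)
      next
    }
    if (isTRUE(h$dropped)) next
    if (via_proxy) {
      h$flag <- "proxy_substituted"
      if (is.null(audit[[id]])) {
        audit[[id]] <- data.frame(snp_id = id, status = "kept",
                                  detail = paste0("proxy:", o$snp_id),
                                  stringsAsFactors = FALSE)
      }
    } else {
      audit[[id]] <- data.frame(snp_id = id, status = "kept",
                                detail = h$flag, stringsAsFactors = FALSE)
    }
    rows[[id]] <- h
  }
  audit_df <- do.call(rbind, unname(audit))
  if (length(rows) == 0L) {
    stop("empty harmonized set for analysis ", exposure_name, " -> ",
         outcome_name, ": all instruments dropped", call. = FALSE)
  }
  harmonized_set(
    exposure_name, outcome_name,
    snp_ids = vapply(rows, `[[`, "", "snp_id"),
    X = vapply(rows, `[[`, 0, "X"),
    se_X = vapply(rows, `[[`, 0, "se_X"),
    Y = vapply(rows, `[[`, 0, "Y"),
    se_Y = vapply(rows, `[[`, 0, "se_Y"),
    flags = vapply(rows, `[[`, "", "flag"),
    audit = audit_df
  )
}
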