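#' Declarative configuration for a multi-exposure MR study
#'
#' A study pairs one outcome with one or more exposures and fixes every
#' threshold up front. Each trait entry is a list with `name`, `path`,
#' optional `column_map` (preset name or named vector), `trait_type`,
#' `effect_scale` and `n_samples`. The Bonferroni threshold applied to the
#' primary (IVW) p-values is `alpha / n_tests` with `n_tests` defaulting to
#' the number of exposures — the correction is per exposure, not per
#' exposure-times-method, IVW being the designated primary test.
#'
#' @param outcome Outcome trait entry.
#' @param exposures List of exposure trait entries (at least one).
#' @param ld_file Optional TSV of LD pairs (`snp_a`, `snp_b`, `r2`); when
#'   absent, instruments are assumed pre-clumped and clumping is skipped.
#' @param proxy_file Optional TSV proxy table (`snp`, `proxy`, `r2`, and
#'   optionally `proxy_effect_allele`, `proxy_other_allele`).
#' @param p_instrument Instrument p-value threshold (default 5e-8).
#' @param clump_r2,clump_window Clumping thresholds (defaults 0.01, 1 Mb).
#' @param proxy_r2 Minimum proxy r-squared (default 0.8).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Bonferroni divisor (default: number of exposures).
#' @param palindromic_mode Passed to [harmonize_pair()].
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Integer seed (required: the weighted median resamples).
#' @return A validated `study_config` object.
#' @export
study_config <- function(outcome, exposures, ld_file = NULL,
                         proxy_file = NULL, p_instrument = 5e-8,
                         clump_r2 = 0.01, clump_window = 1e6L,
                         proxy_r2 = 0.8, alpha = 0.05, n_tests = NULL,
                         palindromic_mode = "keep", n_boot = 1000L, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("study_config requires a seed (the weighted median resamples)",
         call. = FALSE)
  }
  stopifnot(length(exposures) >= 1, p_instrument > 0, p_instrument < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_window > 0,
            proxy_r2 > 0, proxy_r2 <= 1, alpha > 0, alpha < 1,
            n_boot >= 1)
  check_trait <- function(tr, what) {
    if (is.null(tr$name) || is.null(tr$path)) {
      stop(what, " entries need 'name' and 'path'", call. = FALSE)
    }
    tr$column_map <- tr$column_map %||% "twosamplemr"
    tr$trait_type <- tr$trait_type %||% "continuous"
    tr$effect_scale <- tr$effect_scale %||% "beta"
    tr$meta <- trait_meta(tr$name, tr$trait_type, tr$effect_scale,
                          tr$n_samples %||% NA_integer_)
    tr
  }
  outcome <- check_trait(outcome, "outcome")
  exposures <- lapply(exposures, check_trait, what = "exposure")
  if (is.null(n_tests)) n_tests <- length(exposures)
  structure(
    list(outcome = outcome, exposures = exposures, ld_file = ld_file,
         proxy_file = proxy_file, p_instrument = p_instrument,
         clump_r2 = clump_r2, clump_window = as.integer(clump_window),
         proxy_r2 = proxy_r2, alpha = alpha, n_tests = as.integer(n_tests),
         palindromic_mode = palindromic_mode, n_boot = as.integer(n_boot),
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Read a study configuration from a JSON file
#'
#' The file mirrors the arguments of [study_config()]; relative `path`,
#' `ld_file` and `proxy_file` entries are resolved against the config
#' file's directory. JSON was chosen over YAML so the only parser required
#' is jsonlite.
#'
#' @param path Path to a JSON config.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  raw$outcome$path <- resolve(raw$outcome$path)
  raw$exposures <- lapply(raw$exposures, function(e) {
    e$path <- resolve(e$path); e
  })
  raw$ld_file <- resolve(raw$ld_file)
  raw$proxy_file <- resolve(raw$proxy_file)
  do.call(study_config, raw)
}

#' Read an LD pair list from a TSV file
#' @param path TSV with columns `snp_a`, `snp_b`, `r2`.
#' @return An [ld_info()] object.
#' @export
read_ld_pairs <- function(path) {
  ld_info(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a proxy table from a TSV file
#' @param path TSV with columns `snp`, `proxy`, `r2` (optional phase
#'   columns `proxy_effect_allele`, `proxy_other_allele`).
#' @return Data frame.
#' @export
read_proxy_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full multi-exposure MR study
#'
#' For every exposure: instrument selection (p < `p_instrument`), LD
#' clumping (when an LD table is configured), proxy substitution, allele
#' harmonization, the three causal estimators (IVW primary, weighted
#' median and MR-Egger where K >= 3), Cochran's Q, leave-one-out and the
#' per-SNP table. An exposure whose harmonized set comes out empty is
#' recorded as a failed analysis and the study continues. The IVW p-value
#' is compared against the Bonferroni threshold `alpha / n_tests`.
#'
#' @param cfg A [study_config()] or a path to a JSON config.
#' @return A `study_report`: list with `analyses` (one entry per exposure),
#'   `bonferroni` (the threshold used) and `config`.
#' @export
run_study <- function(cfg) {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  stopifnot(inherits(cfg, "study_config"))
  outcome_tab <- read_gwas_table(cfg$outcome$path, cfg$outcome$column_map,
                                 cfg$outcome$meta)
  ld <- if (!is.null(cfg$ld_file)) read_ld_pairs(cfg$ld_file) else NULL
  proxies <- if (!is.null(cfg$proxy_file)) read_proxy_table(cfg$proxy_file)
             else NULL
  bonferroni <- cfg$alpha / cfg$n_tests
  analyses <- lapply(cfg$exposures, function(ex) {
    run_one_exposure(ex, outcome_tab, cfg, ld, proxies, bonferroni)
  })
  names(analyses) <- vapply(cfg$exposures, `[[`, "", "name")
  structure(list(analyses = analyses, bonferroni = bonferroni, config = cfg),
            class = "study_report")
}

run_one_exposure <- function(ex, outcome_tab, cfg, ld, proxies, bonferroni) {
  tryCatch({
    tab <- read_gwas_table(ex$path, ex$column_map, ex$meta)
    inst <- select_instruments(tab, cfg$p_instrument)
    if (!is.null(ld)) {
      inst <- clump(inst, ld, r2_max = cfg$clump_r2,
                    window_bp = cfg$clump_window, strict = FALSE)
    }
    h <- build_harmonized_set(inst, outcome_tab,
                              exposure_name = ex$name,
                              outcome_name = cfg$outcome$name,
                              palindromic_mode = cfg$palindromic_mode,
                              proxy_table = proxies,
                              proxy_r2 = cfg$proxy_r2)
    k <- length(h$snp_ids)
    estimates <- list(ivw = mr_ivw(h))
    egger <- NULL
    if (k >= 3L) {
      estimates$weighted_median <- mr_weighted_median(
        h, n_boot = cfg$n_boot, seed = cfg$seed)
      egger <- mr_egger(h)
      estimates$mr_egger_slope <- egger$slope
    }
    het <- if (k >= 2L) cochran_q(h) else NULL
    loo <- if (k >= 2L) leave_one_out(h) else NULL
    snp_tab <- single_snp_table(h, n_boot = cfg$n_boot, seed = cfg$seed)
    list(name = ex$name, status = "ok", hset = h, estimates = estimates,
         egger = egger, heterogeneity = het, leave_one_out = loo,
         single_snp = snp_tab,
         significant = estimates$ivw$pvalue < bonferroni)
  }, error = function(e) {
    list(name = ex$name, status = "failed",
         message = conditionMessage(e), significant = NA)
  })
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("MR study: %d exposure(s), Bonferroni threshold p < %g\n",
              length(x$analyses), x$bonferroni))
  for (a in x$analyses) {
    if (a$status == "failed") {
      cat(sprintf("  %s: failed (%s)\n", a$name, a$message))
    } else {
      ivw <- a$estimates$ivw
      cat(sprintf("  %s: K = %d, IVW OR %s (%s-%s), p = %s%s\n", a$name,
                  ivw$n_snp, format_or(ivw$odds_ratio),
                  format_or(ivw$ci_low), format_or(ivw$ci_high),
                  format_pvalue(ivw$pvalue),
                  if (isTRUE(a$significant)) "  *" else ""))
    }
  }
  invisible(x)
}

#' Write the study report to disk
#'
#' Emits a consolidated tab-delimited estimate table (`mr_report.tsv`, one
#' row per exposure x method; failed analyses appear as explicit
#' `failed` rows, never silently omitted), per-exposure single-SNP,
#' leave-one-out and harmonization-audit tables, and `study.json` with
#' full-precision numbers. Rendering only serializes stored results — no
#' estimate is recomputed — so reruns on identical inputs are
#' byte-identical.
#'
#' @param report A `study_report` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  }
  files <- character()
  consolidated <- list()
  for (a in report$analyses) {
    if (a$status == "ok") {
      consolidated <- c(consolidated, unname(a$estimates))
    }
  }
  df <- if (length(consolidated)) mr_estimates_to_df(consolidated) else NULL
  for (a in report$analyses) {
    if (a$status == "failed") {
      fail_row <- data.frame(
        exposure = a$name, outcome = report$config$outcome$name,
        method = paste0("failed: ", a$message), n_snp = 0L, beta = NA_real_,
        se = NA_real_, OR = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        pvalue = NA_real_, stringsAsFactors = FALSE)
      df <- rbind(df, fail_row)
    }
  }
  path <- file.path(out_dir, "mr_report.tsv")
  num <- vapply(df, is.numeric, TRUE) & names(df) != "n_snp"
  df$significant <- vapply(df$exposure, function(nm) {
    s <- report$analyses[[nm]]$significant
    if (is.null(s)) NA else s
  }, NA)
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, path)
  for (a in report$analyses) {
    if (a$status != "ok") next
    safe <- gsub("[^A-Za-z0-9._-]", "_", a$name)
    write_tab <- function(tab, suffix) {
      p <- file.path(out_dir, paste0(safe, "_", suffix, ".tsv"))
      numc <- vapply(tab, is.numeric, TRUE) & names(tab) != "n_snp"
      tab[numc] <- lapply(tab[numc], function(x) sprintf("%.15g", x))
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <<- c(files, p)
    }
    write_tab(a$single_snp, "single_snp")
    if (!is.null(a$leave_one_out)) write_tab(a$leave_one_out, "loo")
    if (!is.null(a$hset$audit)) write_tab(a$hset$audit, "audit")
  }
  json_path <- file.path(out_dir, "study.json")
  jsonlite::write_json(report_to_list(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  files <- c(files, json_path)
  invisible(files)
}

report_to_list <- function(report) {
  list(
    bonferroni = report$bonferroni,
    analyses = lapply(report$analyses, function(a) {
      if (a$status == "failed") {
        return(list(name = a$name, status = "failed", message = a$message))
      }
      list(
        name = a$name, status = "ok", n_snp = length(a$hset$snp_ids),
        significant = a$significant,
        estimates = lapply(a$estimates, function(e) {
          e[c("method", "n_snp", "beta", "se", "pvalue", "odds_ratio",
              "ci_low", "ci_high")]
        }),
        egger_intercept = if (!is.null(a$egger)) {
          list(estimate = a$egger$intercept, se = a$egger$intercept_se,
               pvalue = a$egger$intercept_pvalue)
        },
        heterogeneity = if (!is.null(a$heterogeneity)) {
          unclass(a$heterogeneity)
        }
      )
    })
  )
}
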