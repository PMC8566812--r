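#' Column-name presets for common GWAS summary-statistic layouts
#'
#' A column map is a named character vector translating the semantic fields
#' used throughout the package (`snp_id`, `effect_allele`, `other_allele`,
#' `beta`, `se`, `pvalue`, and optionally `eaf`, `chrom`, `pos`) into the
#' column names of a particular file dialect. Two presets are shipped:
#' `"twosamplemr"` (SNP / effect_allele / other_allele / beta / se / pval /
#' eaf) and `"gwas_catalog"` (variant_id / effect_allele / other_allele /
#' beta / standard_error / p_value / effect_allele_frequency / chromosome /
#' base_pair_location).
#'
#' @param name Preset name, `"twosamplemr"` or `"gwas_catalog"`.
#' @return Named character vector, names are semantic fields.
#' @export
#' @examples
#' gwas_column_preset("twosamplemr")
gwas_column_preset <- function(name = c("twosamplemr", "gwas_catalog")) {
  name <- match.arg(name)
  switch(name,
    twosamplemr = c(
      snp_id = "SNP", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "beta", se = "se",
      pvalue = "pval", eaf = "eaf", chrom = "chr", pos = "pos"
    ),
    gwas_catalog = c(
      snp_id = "variant_id", effect_allele = "effect_allele",
      other_allele = "other_allele", beta = "beta", se = "standard_error",
      pvalue = "p_value", eaf = "effect_allele_frequency",
      chrom = "chromosome", pos = "base_pair_location"
    )
  )
}

#' Describe a trait and the scale its effects are reported on
#'
#' Binary traits in GWAS are frequently reported as odds ratios;
#' [read_gwas_table()] log-transforms these to the additive (log-OR) scale on
#' ingestion so that all downstream computation operates on betas. The
#' standard error of an OR-scale file is taken as already being on the log
#' scale (the usual convention of summary files that print OR next to the
#' SE of log-OR).
#'
#' @param trait_name Label used in reports.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param effect_scale `"beta"` or `"odds_ratio"`; `"odds_ratio"` is only
#'   meaningful for binary traits.
#' @param n_samples Optional sample size (informational).
#' @return A `trait_meta` object.
#' @export
trait_meta <- function(trait_name,
                       trait_type = c("continuous", "binary"),
                       effect_scale = c("beta", "odds_ratio"),
                       n_samples = NA_integer_) {
  trait_type <- match.arg(trait_type)
  effect_scale <- match.arg(effect_scale)
  if (effect_scale == "odds_ratio" && trait_type != "binary") {
    stop("effect_scale = 'odds_ratio' requires trait_type = 'binary'",
         call. = FALSE)
  }
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         effect_scale = effect_scale, n_samples = n_samples),
    class = "trait_meta"
  )
}

gwas_columns <- c("snp_id", "effect_allele", "other_allele", "beta",
                  "se", "eaf", "pvalue", "chrom", "pos")

empty_gwas_table <- function() {
  data.frame(
    snp_id = character(), effect_allele = character(),
    other_allele = character(), beta = numeric(), se = numeric(),
    eaf = numeric(), pvalue = numeric(), chrom = character(),
    pos = integer(), stringsAsFactors = FALSE
  )
}

#' Validate a table of per-SNP GWAS records
#'
#' Enforces the record invariants: alleles are single bases among A/C/G/T and
#' differ from each other, `se > 0`, `pvalue` in (0, 1], and `eaf` (when
#' present) strictly inside (0, 1). Violations are reported together with the
#' offending row indices.
#'
#' @param df Data frame with the canonical columns (see [read_gwas_table()]).
#' @return The validated data frame (alleles upper-cased), invisibly usable.
#' @export
validate_gwas_records <- function(df) {
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  if (nrow(df) == 0L) return(df)
  bases <- c("A", "C", "G", "T")
  problems <- character()
  bad <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf(
        "%s (rows %s)", what, paste(rows, collapse = ", ")))
    }
  }
  bad(which(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases)),
      "allele not a single base among A/C/G/T")
  bad(which(df$effect_allele == df$other_allele),
      "effect allele equals other allele")
  bad(which(!is.finite(df$se) | df$se <= 0), "standard error not > 0")
  bad(which(!is.finite(df$beta)), "non-finite beta")
  bad(which(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1),
      "p-value outside (0, 1]")
  if ("eaf" %in% names(df)) {
    e <- df$eaf
    bad(which(!is.na(e) & (e <= 0 | e >= 1)),
        "effect-allele frequency outside (0, 1)")
  }
  if (anyDuplicated(df$snp_id)) {
    bad(which(duplicated(df$snp_id)), "duplicated snp_id")
  }
  if (length(problems)) {
    stop("invalid GWAS records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file (delimiter auto-detected by
#' [data.table::fread()], or forced via `delim`), renames columns according
#' to `column_map`, validates every record and returns a data frame with one
#' row per SNP and the canonical columns `snp_id`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `eaf`, `pvalue`, `chrom`, `pos` (missing
#' optional fields are filled with `NA`).
#'
#' If `trait_meta$effect_scale == "odds_ratio"` the mapped `beta` column is
#' interpreted as an odds ratio and natural-log transformed; the `se` column
#' is taken as already on the log scale.
#'
#' @param path Path to a TSV/CSV file.
#' @param column_map Preset name (see [gwas_column_preset()]) or a named
#'   character vector mapping semantic fields to file column names.
#' @param trait_meta Optional [trait_meta()] describing the trait; default is
#'   a continuous beta-scale trait.
#' @param delim Optional delimiter override.
#' @return Data frame of validated records (possibly zero rows).
#' @export
read_gwas_table <- function(path, column_map = "twosamplemr",
                            trait_meta = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(column_map) && length(column_map) == 1L && is.null(names(column_map))) {
    column_map <- gwas_column_preset(column_map)
  }
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_sem <- setdiff(required, names(column_map))
  if (length(missing_sem)) {
    stop("column_map lacks required fields: ",
         paste(missing_sem, collapse = ", "), call. = FALSE)
  }
  raw <- if (is.null(delim)) {
    data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  } else {
    data.table::fread(path, sep = delim, data.table = FALSE, showProgress = FALSE)
  }
  # only demand columns the map names AND the file is expected to carry;
  # optional fields absent from the file are tolerated unless required
  present <- names(column_map)[column_map %in% names(raw)]
  missing_cols <- setdiff(required, present)
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(column_map[missing_cols], collapse = ", "),
         " (mapped from ", paste(missing_cols, collapse = ", "), ")",
         call. = FALSE)
  }
  out <- empty_gwas_table()
  if (nrow(raw) == 0L) return(out)
  out <- data.frame(snp_id = as.character(raw[[column_map[["snp_id"]]]]),
                    stringsAsFactors = FALSE)
  out$effect_allele <- as.character(raw[[column_map[["effect_allele"]]]])
  out$other_allele <- as.character(raw[[column_map[["other_allele"]]]])
  out$beta <- as.numeric(raw[[column_map[["beta"]]]])
  out$se <- as.numeric(raw[[column_map[["se"]]]])
  out$eaf <- if ("eaf" %in% present) as.numeric(raw[[column_map[["eaf"]]]]) else NA_real_
  out$pvalue <- as.numeric(raw[[column_map[["pvalue"]]]])
  out$chrom <- if ("chrom" %in% present) as.character(raw[[column_map[["chrom"]]]]) else NA_character_
  out$pos <- if ("pos" %in% present) as.integer(raw[[column_map[["pos"]]]]) else NA_integer_

  if (!is.null(trait_meta) && trait_meta$effect_scale == "odds_ratio") {
    if (any(!is.finite(out$beta) | out$beta <= 0)) {
      stop("odds-ratio column must be strictly positive (rows ",
           paste(which(!is.finite(out$beta) | out$beta <= 0), collapse = ", "),
           ")", call. = FALSE)
    }
    out$beta <- log(out$beta)
  }
  validate_gwas_records(out)
}

#' Write GWAS records in the layout [read_gwas_table()] reads by default
#'
#' @param records Data frame of canonical GWAS records.
#' @param path Output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(records, path) {
  preset <- gwas_column_preset("twosamplemr")
  out <- records[, gwas_columns]
  names(out) <- preset[gwas_columns]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a consolidated MR report table
#'
#' Serializes a list of [mr_estimate] objects to a tab-delimited table with
#' columns `exposure`, `outcome`, `method`, `n_snp`, `beta`, `se`, `OR`,
#' `ci_low`, `ci_high`, `pvalue`. Floats are written with 15 significant
#' digits so a read-back reproduces them to at least 12 significant digits.
#'
#' @param results Non-empty list of `mr_estimate` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_mr_report()]
#' @export
write_mr_report <- function(results, path) {
  if (inherits(results, "mr_estimate")) results <- list(results)
  if (length(results) == 0L) stop("results must be non-empty", call. = FALSE)
  df <- mr_estimates_to_df(results)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "n_snp"
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

mr_estimates_to_df <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      exposure = r$exposure %||% NA_character_,
      outcome = r$outcome %||% NA_character_,
      method = r$method, n_snp = r$n_snp, beta = r$beta, se = r$se,
      OR = r$odds_ratio, ci_low = r$ci_low, ci_high = r$ci_high,
      pvalue = r$pvalue, stringsAsFactors = FALSE
    )
  }))
}

#' Read back a report written by [write_mr_report()]
#'
#' @param path Path to the report.
#' @return Data frame with the report columns.
#' @export
read_mr_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
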